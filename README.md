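# cordmaskvar

Group analysis of spinal cord fMRI requires registering each participant's
functional data to a standard template (e.g. PAM50), and nearly all spinal
cord registration tools take a manually contoured cord mask as input.
Different raters draw different masks — especially where the cord/CSF
contrast breaks down — and those differences propagate through spatial
normalization into activation maps. `cordmaskvar` implements, as a tested
and reusable R pipeline, the statistical machinery for quantifying that
propagation:

- **Agreement metrics** — volumetric and slicewise Dice similarity
  `DSC = 2|REF ∩ RM| / (|REF| + |RM|)` between rater (RM) and reference
  (REF) masks, logit-transformed for linear modeling; slice trimming at the
  stack ends.
- **Image-quality metrics** — per slice, the coefficient of variation of
  voxels adjacent to the cord (a 2-voxel in-plane dilation of the reference
  mask, minus the mask) and the Adjacent:SC signal ratio (mean adjacent /
  mean cord intensity; values < 1 flag contrast breakdown).
- **Registration-accuracy proxy** — the GM:WM contrast of the registered
  image under fixed atlas regions: maximal under perfect alignment,
  reduced by any misregistration that mixes tissue classes.
- **Inference** — two-way additive ANOVA (rater + dataset) with η² effect
  sizes on mean logit DSC and log GM:WM; slicewise Spearman correlations
  between DSC and each image-quality outcome, pooled per rater as the mean
  Fisher z over datasets, with family-wise-adjusted two-tailed p-values from
  a max-T permutation scheme (DSC values permuted across slices within each
  rater–dataset pair; the max |pooled z| across raters per permutation forms
  the null).
- **Activation comparison** — left/right hemicord partition (excluding the
  center voxel column), ipsilateral/contralateral spatial correlations
  (Fisher z) of unthresholded z-maps, z > 2.3 thresholding, and voxelwise
  standardization of a reference map against the rater distribution:
  z̄ = (1/n) Σᵢ (yᵢ − x̄ᵢ)/σᵢ with its sample SD.

Because raw spinal cord fMRI data of this kind are not openly downloadable,
the package ships a **synthetic phantom and rater simulator**: an axial
cord built from a per-slice ellipse with a gray-matter butterfly inside
white matter and surrounding CSF whose contrast varies by slice; raters with
tunable systematic bias, contour jitter, and boundary flip rates;
misregistration by in-plane translation; and lateralized activation maps
coupled to mask fidelity. Every downstream stage is testable at study scale
(8 raters × 21 datasets × 25 slices of 1×1×3 mm voxels) without any
download.

## Worked example

```r
library(cordmaskvar)

cfg <- study_config(n_datasets = 6L,
                    rater_models = default_rater_models(
                      flip_rates = c(0.04, 0.10, 0.18, 0.28)),
                    master_seed = 7L)
report <- run_all(cfg, n_perm = 1000L)

report$anova_dsc
#> Two-way additive ANOVA on mean_logit_dsc
#>       term df     sum_sq   mean_sq statistic  p_value     eta_sq
#> 1    rater  3 14.9359291 4.9786430 317.65533 8.60e-14 0.88897712
#> 2  dataset  5  1.6302270 0.3260454  20.80287 2.92e-06 0.09703009
#> 3 residual 15  0.2350965 0.0156731        NA     <NA> 0.01399279
```

Rater identity explains most of the variance in logit Dice here (η² = 0.89)
because the simulated roster spans a wide fidelity ladder; the dataset
effect (η² = 0.10) comes from the per-dataset contrast profiles. Slicewise
Dice is positively associated with the Adjacent:SC ratio for every rater
(low-contrast slices are simulated as harder to contour), and the max-T
adjusted p-values control the family-wise error across raters:

```r
report$perm$adjacent_sc_ratio
#> Max-T permutation test: DSC vs adjacent_sc_ratio (1000 permutations, seed 18)
#>   rater n_datasets mean_fisher_z p_adjusted
#> 1     A          6     0.3329191   0.001998
#> 2     B          6     0.3910922   0.000999
#> 3     C          6     0.9588033   0.000999
#> 4     D          6     0.2856342   0.009990
```

Group-level activation maps (fixed-effects combination of participant maps)
correlate more strongly with the reference ipsilaterally than
contralaterally, and standardizing the reference's z-statistics against the
rater distribution yields means near zero — mask variability blurs the
group maps without biasing the average z-score:

```r
summarize_fisher_table(report$group_corr)
#>       condition  n  mean  min   max
#> 1 contralateral  8 1.138 0.95 1.363
#> 2   ipsilateral  8 2.336 2.18 2.608
#> 3           all 16 1.737 0.95 2.608

report$group_standardized
#>    side     condition       z_bar      sd_z n_voxels
#> 1  left   ipsilateral  0.10639206 0.7117899      700
#> 2  left contralateral  0.03775701 0.8939797      550
#> 3 right   ipsilateral  0.15424900 0.7991291      550
#> 4 right contralateral -0.04664333 0.8178424      700
```

`run_all(cfg, out_dir = "out")` additionally writes every table as CSV with
a JSON provenance block, and `generate_study(cfg, out_dir = "study")` writes
all volumes as NIfTI-1 with a JSON manifest. A thin command-line wrapper
with `simulate | metrics | anova | permtest | run` subcommands is installed
at `inst/cli/cordmaskvar.R`. See the vignette
(`vignettes/cord-mask-variability.Rmd`) for the model, its assumptions and
the design choices.

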