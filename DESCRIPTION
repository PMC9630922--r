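Package: cordmaskvar
Title: Rater Variability in Spinal Cord fMRI Masks and Its Downstream Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how variability in manually contoured spinal
    cord masks propagates through spatial normalization into functional MRI
    activation results. Provides a synthetic axial spinal-cord phantom and a
    parametric rater simulator; volumetric and slicewise Dice agreement with
    logit aggregation; peri-cord image-quality metrics (coefficient of
    variation of adjacent voxels and the Adjacent:SC signal ratio); gray
    matter to white matter contrast as a registration-accuracy proxy; a
    two-way ANOVA layer with eta-squared effect sizes; slicewise Spearman
    correlations pooled via Fisher's z with max-T permutation adjustment for
    family-wise error; and hemicord-based comparison of activation maps,
    including spatial correlation and voxelwise standardization of a
    reference map against a rater distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
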