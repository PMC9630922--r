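#' Configure a simulated contouring study
#'
#' Defines the conditions of a full synthetic study: a number of datasets
#' (participants), a roster of simulated raters, the phantom grid, and the
#' activation model. The defaults emulate the design this package targets:
#' 21 datasets contoured by 8 raters plus a reference, on a 44 x 128 x 25
#' grid of 1 x 1 x 3 mm voxels.
#'
#' Each dataset receives its own CSF-to-cord contrast profile: a baseline
#' ratio drawn per dataset with a droop toward the inferior slices, so some
#' slices show an Adjacent:SC ratio below 1 (contrast breakdown). Slices with
#' poorer contrast are harder to contour: the rater flip rate and image
#' noise are scaled up on those slices via `difficulty_coupling`, coupling
#' mask agreement to the image-quality metrics in the direction observed in
#' real data (agreement rises with the Adjacent:SC ratio and falls with the
#' adjacent-voxel CV).
#'
#' @param n_datasets number of simulated datasets.
#' @param rater_models named list of [rater_model()] objects, ordered from
#'   most to least accurate by convention; seeds are overridden per dataset
#'   from `master_seed`.
#' @param grid_shape,voxel_size_mm phantom grid, see [phantom_spec()].
#' @param wm_mean,gm_mean white and gray matter mean intensities (gray matter
#'   is brighter, as in T2*-weighted data).
#' @param act_amplitude z-statistic amplitude of the true activation blob.
#' @param act_extent slice indices carrying activation; default is the middle
#'   two fifths of the stack.
#' @param act_noise_sd z-statistic noise standard deviation inside the cord.
#' @param act_mismatch_sd scale of the extra activation noise given to a
#'   rater, multiplied by (1 - volume DSC) of that rater's mask, emulating
#'   analysis differences beyond pure displacement.
#' @param difficulty_coupling nonnegative scalar controlling how strongly
#'   low-contrast slices increase rater flip rates and image noise.
#' @param master_seed integer; all other seeds derive deterministically from
#'   it, so adding a rater or dataset never changes the others' data.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_datasets = 21L,
                         rater_models = default_rater_models(),
                         grid_shape = c(44L, 128L, 25L),
                         voxel_size_mm = c(1, 1, 3),
                         wm_mean = 100,
                         gm_mean = 115,
                         act_amplitude = 3,
                         act_extent = NULL,
                         act_noise_sd = 1,
                         act_mismatch_sd = 0.8,
                         difficulty_coupling = 1.5,
                         master_seed = 20221020L) {
  stopifnot(n_datasets >= 1L, length(rater_models) >= 1L,
            all(vapply(rater_models, inherits, logical(1), "rater_model")),
            difficulty_coupling >= 0)
  if (is.null(names(rater_models)) || anyNA(names(rater_models)) ||
      any(names(rater_models) == "")) {
    names(rater_models) <- LETTERS[seq_along(rater_models)]
  }
  if (any(names(rater_models) == "REF")) {
    stop("rater name 'REF' is reserved for the reference")
  }
  ns <- as.integer(grid_shape[3])
  if (is.null(act_extent)) {
    act_extent <- seq.int(max(1L, floor(ns * 0.3)), ceiling(ns * 0.7))
  }
  structure(list(n_datasets = as.integer(n_datasets),
                 rater_models = rater_models,
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 wm_mean = wm_mean, gm_mean = gm_mean,
                 act_amplitude = act_amplitude,
                 act_extent = as.integer(act_extent),
                 act_noise_sd = act_noise_sd,
                 act_mismatch_sd = act_mismatch_sd,
                 difficulty_coupling = difficulty_coupling,
                 master_seed = as.integer(master_seed)),
            class = "study_config")
}

#' Default roster of simulated raters
#'
#' Eight raters forming a fidelity ladder: boundary flip rates increase from
#' 0.02 to 0.27 with a common 0.3 mm contour jitter and no systematic bias,
#' spanning slicewise Dice agreement from near-perfect to roughly 0.6-0.7,
#' comparable to the spread among human raters of varying experience.
#'
#' @param flip_rates per-rater boundary flip rates.
#' @param slice_jitter_mm common contour jitter (mm).
#' @param bias_voxels per-rater signed morphological bias.
#' @return Named list of [rater_model()] objects (A, B, C, ...).
#' @export
default_rater_models <- function(flip_rates = c(0.02, 0.04, 0.06, 0.09,
                                                0.12, 0.16, 0.21, 0.27),
                                 slice_jitter_mm = 0.3,
                                 bias_voxels = rep(0L, length(flip_rates))) {
  stopifnot(length(bias_voxels) == length(flip_rates))
  models <- mapply(function(f, b) {
    rater_model(bias_voxels = b, flip_rate = f,
                slice_jitter_mm = slice_jitter_mm)
  }, flip_rates, bias_voxels, SIMPLIFY = FALSE)
  names(models) <- LETTERS[seq_along(models)]
  models
}

# per-dataset phantom spec + difficulty profile, deterministic in the master
# seed and dataset index
dataset_profile <- function(config, d) {
  set.seed(derive_seed(config$master_seed, d, 0L))
  ns <- config$grid_shape[3]
  base <- stats::runif(1, 0.90, 1.55)
  droop <- stats::runif(1, 0.30, 0.90)
  wiggle <- stats::rnorm(ns, 0, 0.04)
  ratio <- base - droop * ((seq_len(ns) - 1) / (ns - 1))^1.5 + wiggle
  ratio <- clamp(ratio, 0.55, 1.8)
  difficulty <- clamp((1.25 - ratio) / 0.6, 0, 1)
  noise_base <- stats::runif(1, 5, 10)
  noise_sd <- noise_base * (1 + 0.8 * difficulty)
  radii <- c(5.7, 3.7) * stats::runif(2, 0.9, 1.1)
  spec <- phantom_spec(grid_shape = config$grid_shape,
                       voxel_size_mm = config$voxel_size_mm,
                       cord_radii = radii,
                       mean_intensity = list(csf = ratio * config$wm_mean,
                                             wm = config$wm_mean,
                                             gm = config$gm_mean),
                       noise_sd = noise_sd,
                       seed = derive_seed(config$master_seed, d, 1L))
  list(spec = spec, csf_ratio = ratio, difficulty = difficulty)
}

# compact storage for activation maps inside a study bundle: z restricted to
# the cord mask
act_compact <- function(map, cord) {
  list(z = map$z[cord], side = map$stimulus_side)
}

#' Extract an activation map from a study bundle
#'
#' @param bundle a `study_bundle`.
#' @param dataset dataset index.
#' @param rater rater name (e.g. `"A"`), or `"REF"` for the reference.
#' @param side `"left"` or `"right"` stimulus.
#' @return An `activation_map` at participant level.
#' @export
get_activation_map <- function(bundle, dataset, rater, side) {
  ds <- bundle$datasets[[dataset]]
  rec <- if (identical(rater, "REF")) ds$act$REF[[side]] else
    ds$act$raters[[rater]][[side]]
  if (is.null(rec)) stop(sprintf("no activation map for rater %s side %s", rater, side))
  z <- array(0, dim(ds$phantom$cord_mask))
  z[ds$phantom$cord_mask] <- rec$z
  activation_map(z, ds$phantom$cord_mask, stimulus_side = rec$side,
                 level = "participant")
}

#' Reconstruct a rater's registered image
#'
#' Emulates the outcome of a spatial normalization informed by the rater's
#' mask: the image is translated slice-by-slice by the negated centroid
#' displacement between the rater's mask and the reference mask, so a
#' mask that is systematically off-center misplaces the tissue relative to
#' the (fixed) atlas regions. For `rater = "REF"` this is the original image.
#'
#' @inheritParams get_activation_map
#' @return A 3-D numeric array.
#' @export
registered_image <- function(bundle, dataset, rater) {
  ds <- bundle$datasets[[dataset]]
  img <- ds$phantom$image
  if (identical(rater, "REF")) return(img)
  dv <- ds$displacement[[rater]]
  for (s in seq_len(dim(img)[3])) {
    img[, , s] <- translate_slice(img[, , s], -dv[s, 1], -dv[s, 2],
                                  fill = "replicate")
  }
  img
}

#' Generate a full synthetic contouring study
#'
#' For every dataset, generates a phantom volume, the reference masks, one
#' simulated mask per rater (with flip rates scaled up on low-contrast
#' slices), per-rater registration displacements derived from mask centroid
#' disagreement, and left/right participant-level activation maps for the
#' reference and every rater. A rater's activation map is the reference map
#' displaced by that rater's registration error plus extra noise scaled by
#' mask disagreement, so activation agreement degrades with mask fidelity.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, all volumes are written as
#'   NIfTI files together with a JSON manifest (see [write_study()]).
#' @return An object of class `study_bundle`.
#' @export
generate_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  rn <- names(config$rater_models)
  datasets <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    prof <- dataset_profile(config, d)
    ph <- generate_phantom(prof$spec)
    ns <- dim(ph$cord_mask)[3]
    ref_cent <- t(vapply(seq_len(ns),
                         function(s) slice_centroid(ph$cord_mask[, , s]),
                         numeric(2)))
    rater_masks <- list(); displacement <- list(); vol_dsc <- list()
    displacement$REF <- matrix(0L, ns, 2L)
    for (r in seq_along(rn)) {
      m0 <- config$rater_models[[r]]
      fr <- clamp(rep_len(m0$flip_rate, ns) *
                    (1 + config$difficulty_coupling * prof$difficulty),
                  0, 0.45)
      mod <- rater_model(bias_voxels = m0$bias_voxels, flip_rate = fr,
                         slice_jitter_mm = m0$slice_jitter_mm,
                         seed = derive_seed(config$master_seed, d, 100L + r))
      rm <- simulate_rater_mask(ph$cord_mask, mod,
                                voxel_size_mm = config$voxel_size_mm)
      rater_masks[[rn[r]]] <- rm
      cent <- t(vapply(seq_len(ns),
                       function(s) slice_centroid(rm[, , s]), numeric(2)))
      dv <- round_half_up(cent - ref_cent)
      dv[!is.finite(dv)] <- 0L
      displacement[[rn[r]]] <- dv
      vol_dsc[[rn[r]]] <- dsc(ph$cord_mask, rm)
    }
    # reference activation maps (shared measurement noise)
    act_ref <- list(
      left = generate_activation_map(ph, "left", config$act_amplitude,
                                     config$act_extent, config$act_noise_sd,
                                     seed = derive_seed(config$master_seed, d, 201L)),
      right = generate_activation_map(ph, "right", config$act_amplitude,
                                      config$act_extent, config$act_noise_sd,
                                      seed = derive_seed(config$master_seed, d, 202L)))
    act_raters <- list()
    for (r in seq_along(rn)) {
      dv <- displacement[[rn[r]]]
      mismatch <- config$act_mismatch_sd * (1 - vol_dsc[[rn[r]]])
      maps <- list()
      for (side in c("left", "right")) {
        z <- act_ref[[side]]$z
        for (s in seq_len(ns)) {
          z[, , s] <- translate_slice(z[, , s], -dv[s, 1], -dv[s, 2],
                                      fill = "constant", value = 0)
        }
        set.seed(derive_seed(config$master_seed, d,
                             300L + 2L * r + (side == "right")))
        if (mismatch > 0) {
          z[ph$cord_mask] <- z[ph$cord_mask] +
            stats::rnorm(sum(ph$cord_mask), 0, mismatch)
        }
        maps[[side]] <- act_compact(
          activation_map(z, ph$cord_mask, stimulus_side = side), ph$cord_mask)
      }
      act_raters[[rn[r]]] <- maps
    }
    datasets[[d]] <- list(
      phantom = ph,
      profile = prof[c("csf_ratio", "difficulty")],
      rater_masks = rater_masks,
      displacement = displacement,
      volume_dsc = unlist(vol_dsc),
      act = list(REF = lapply(act_ref, act_compact, cord = ph$cord_mask),
                 raters = act_raters))
  }
  bundle <- structure(list(config = config, datasets = datasets),
                      class = "study_bundle")
  if (!is.null(out_dir)) bundle <- write_study(bundle, out_dir)
  bundle
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %d datasets x %d raters (+ reference), grid %s\n",
              x$config$n_datasets, length(x$config$rater_models),
              paste(x$config$grid_shape, collapse = " x ")))
  invisible(x)
}

#' Simulate a synthetic slicewise metric table
#'
#' Generates a slicewise metric table directly (without phantom volumes) for
#' calibration experiments on the inference layer: `R` raters by `D` datasets
#' by `S` slices, with Dice values on the unit interval and image-quality
#' outcomes that carry a controlled rank correlation with Dice. The rank
#' correlation is injected through a Gaussian copula: a latent normal shared
#' between Dice and the outcomes with Pearson correlation
#' `2 sin(pi rho / 6)`, which yields a population Spearman correlation of
#' `rho`. With `rank_rho = 0` the outcomes are independent of Dice
#' (the exchangeable-slices null).
#'
#' @param n_raters,n_datasets,n_slices design dimensions.
#' @param rank_rho target population Spearman correlation between Dice and
#'   both outcomes (the CV outcome receives `-rank_rho`, matching its
#'   expected negative association).
#' @param seed integer seed.
#' @return Data frame with columns `rater, dataset, slice, dsc, cv_adjacent,
#'   adjacent_sc_ratio, included` (all rows included).
#' @export
simulate_metric_table <- function(n_raters = 8L, n_datasets = 21L,
                                  n_slices = 23L, rank_rho = 0, seed = 1L) {
  stopifnot(abs(rank_rho) < 1)
  set.seed(seed)
  df <- expand.grid(slice = seq_len(n_slices),
                    rater = LETTERS[seq_len(n_raters)],
                    dataset = seq_len(n_datasets),
                    stringsAsFactors = FALSE)[, c("rater", "dataset", "slice")]
  n <- nrow(df)
  rho_p <- 2 * sin(pi * rank_rho / 6)
  base <- stats::rnorm(n)
  mix <- function(sign) {
    sign * rho_p * base + sqrt(1 - rho_p^2) * stats::rnorm(n)
  }
  df$dsc <- stats::plogis(1.5 + base)
  df$adjacent_sc_ratio <- exp(0.1 + 0.3 * mix(1))
  df$cv_adjacent <- exp(-2 + 0.4 * mix(-1))
  df$included <- TRUE
  df
}
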