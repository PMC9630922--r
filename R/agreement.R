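#' Dice similarity coefficient between two binary masks
#'
#' Computes `2 |A intersect B| / (|A| + |B|)` over the whole volume or over a
#' single axial slice. Symmetric in its arguments and bounded in \[0, 1\];
#' equals 1 exactly when the masks agree on the scope.
#'
#' @param ref,rm 3-D logical masks on the same grid (reference and rater
#'   mask; the metric itself is symmetric).
#' @param slice optional slice index restricting the scope to one axial
#'   slice; `NULL` (default) uses the full volume.
#' @return A number in \[0, 1\].
#' @export
dsc <- function(ref, rm, slice = NULL) {
  ref <- as_mask_array(ref); rm <- as_mask_array(rm)
  stopifnot(identical(dim(ref), dim(rm)))
  if (!is.null(slice)) {
    ref <- ref[, , slice, drop = FALSE]
    rm <- rm[, , slice, drop = FALSE]
  }
  denom <- sum(ref) + sum(rm)
  if (denom == 0) {
    stop_undefined("DSC undefined: both masks are empty in the requested scope")
  }
  2 * sum(ref & rm) / denom
}

#' Clamped logit transform
#'
#' `log(p / (1 - p))` after clamping `p` into `[eps, 1 - eps]`, so that
#' proportions of exactly 0 or 1 (for example a perfect Dice score) map to
#' finite values and remain usable in linear models.
#'
#' @param p numeric vector of proportions.
#' @param eps clamping margin, default `1e-6`.
#' @return Numeric vector of logits.
#' @export
logit <- function(p, eps = 1e-6) {
  p <- clamp(p, eps, 1 - eps)
  log(p / (1 - p))
}

#' Inverse logit
#' @param x numeric vector.
#' @return Numeric vector of proportions.
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Included slice indices after end trimming
#'
#' The most superior and most inferior slices of an axial stack are usually
#' excluded from slicewise analyses because of poor image quality; this
#' returns the retained slice indices after removing `n_trim` slices from
#' each end.
#'
#' @param x a 3-D array (slice axis third) or an integer slice count.
#' @param n_trim nonnegative number of slices removed from each end
#'   (default 1).
#' @return Integer vector of included slice indices.
#' @export
slice_inclusion <- function(x, n_trim = 1L) {
  n <- if (is.array(x)) dim(x)[3] else as.integer(x)
  n_trim <- as.integer(n_trim)
  stopifnot(n_trim >= 0L)
  if (2L * n_trim >= n) {
    stop("n_trim too large: trimming would leave no slices")
  }
  seq.int(1L + n_trim, n - n_trim)
}

#' Peri-cord adjacent region by in-plane dilation
#'
#' Defines the voxels adjacent to a reference cord mask: per axial slice,
#' `n_dilate` iterations of morphological dilation with the 8-connected
#' (3 x 3) structuring element, minus the original mask, clipped at the image
#' borders. With the default of two iterations this is the set of non-mask
#' voxels within in-plane Chebyshev distance 2 of the mask.
#'
#' @param ref 3-D logical reference mask.
#' @param n_dilate number of one-voxel dilation iterations (default 2).
#' @return 3-D logical mask of adjacent voxels, disjoint from `ref`.
#' @export
adjacent_region <- function(ref, n_dilate = 2L) {
  ref <- as_mask_array(ref)
  stopifnot(length(dim(ref)) == 3L, n_dilate >= 1L)
  out <- array(FALSE, dim(ref))
  for (s in seq_len(dim(ref)[3])) {
    m <- ref[, , s]
    if (!any(m)) next
    out[, , s] <- dilate_slice(m, n_dilate) & !m
  }
  out
}

adjacent_slice <- function(ref, slice, n_dilate) {
  m <- ref[, , slice]
  if (!any(m)) {
    stop_undefined(sprintf("adjacent region undefined: empty mask on slice %d", slice))
  }
  dilate_slice(m, n_dilate) & !m
}

#' Coefficient of variation of peri-cord voxels on one slice
#'
#' Sample standard deviation over mean of the image intensities in the
#' dilation-defined adjacent region of one axial slice. Captures
#' inconsistency in the signal surrounding the cord (CSF flow and
#' susceptibility effects), which makes the cord boundary harder to contour.
#'
#' @param image 3-D numeric array.
#' @param ref 3-D logical reference cord mask.
#' @param slice slice index.
#' @param n_dilate dilation iterations defining adjacency (default 2).
#' @return Nonnegative number.
#' @export
cv_adjacent <- function(image, ref, slice, n_dilate = 2L) {
  ref <- as_mask_array(ref)
  stopifnot(identical(dim(image), dim(ref)))
  adj <- adjacent_slice(ref, slice, n_dilate)
  v <- image[, , slice][adj]
  if (length(v) < 2L) {
    stop_undefined("CV undefined: fewer than 2 adjacent voxels")
  }
  m <- mean(v)
  if (m == 0) stop_undefined("CV undefined: zero mean of adjacent intensities")
  stats::sd(v) / m
}

#' Adjacent-to-cord signal ratio on one slice
#'
#' Mean intensity of the dilation-defined adjacent region divided by the mean
#' intensity inside the reference cord mask, on one axial slice. Values above
#' 1 indicate the expected bright-CSF contrast; values below 1 indicate
#' contrast breakdown.
#'
#' @inheritParams cv_adjacent
#' @return Positive number.
#' @export
adjacent_sc_ratio <- function(image, ref, slice, n_dilate = 2L) {
  ref <- as_mask_array(ref)
  stopifnot(identical(dim(image), dim(ref)))
  adj <- adjacent_slice(ref, slice, n_dilate)
  sl <- image[, , slice]
  cord_mean <- mean(sl[ref[, , slice]])
  if (!is.finite(cord_mean) || cord_mean <= 0) {
    stop_undefined("Adjacent:SC ratio undefined: nonpositive cord mean")
  }
  mean(sl[adj]) / cord_mean
}

#' Gray-to-white matter contrast
#'
#' Mean image intensity over the gray-matter region divided by the mean over
#' the white-matter region. Used as a registration-accuracy proxy: with atlas
#' regions fixed in template space, contrast is maximal under perfect
#' alignment and is reduced by any misregistration that mixes tissues across
#' the region boundaries. The logarithm (for inference) is taken by the
#' caller.
#'
#' @param image 3-D numeric array (registered functional image).
#' @param gm,wm disjoint, nonempty 3-D logical atlas masks.
#' @return Positive number.
#' @export
gm_wm_contrast <- function(image, gm, wm) {
  gm <- as_mask_array(gm); wm <- as_mask_array(wm)
  stopifnot(identical(dim(image), dim(gm)), identical(dim(image), dim(wm)))
  if (!any(gm) || !any(wm)) {
    stop_undefined("GM:WM contrast undefined: empty region")
  }
  if (any(gm & wm)) stop("gm and wm masks must be disjoint")
  wm_mean <- mean(image[wm])
  if (wm_mean <= 0) {
    stop_undefined("GM:WM contrast undefined: nonpositive WM mean")
  }
  mean(image[gm]) / wm_mean
}

#' Build the slicewise and rater-by-dataset metric tables for a study
#'
#' Computes, for every dataset, rater and included axial slice: the slicewise
#' Dice coefficient against the reference mask and its logit, plus the
#' slice's image-quality metrics (adjacent-voxel CV and Adjacent:SC ratio,
#' both derived from the reference mask and therefore shared across raters).
#' Aggregates to one record per rater-by-dataset cell: the mean slicewise
#' logit Dice over included slices, and the GM:WM contrast of that rater's
#' registered image (also computed for the reference itself, labelled
#' `"REF"`, for which Dice agreement is not defined).
#'
#' @param bundle a `study_bundle` from [generate_study()] or [read_study()].
#' @param n_trim slices trimmed from each end of the stack (default 1).
#' @param n_dilate dilation iterations defining the adjacent region.
#' @return A list with two data frames: `slice_metrics` with columns
#'   `dataset, rater, slice, dsc, logit_dsc, cv_adjacent, adjacent_sc_ratio,
#'   included`, and `rater_dataset` with columns `rater, dataset,
#'   mean_logit_dsc, gm_wm_ratio, log_gm_wm`.
#' @export
build_tables <- function(bundle, n_trim = 1L, n_dilate = 2L) {
  stopifnot(inherits(bundle, "study_bundle"))
  rn <- names(bundle$config$rater_models)
  slice_rows <- list(); cell_rows <- list()
  for (d in seq_along(bundle$datasets)) {
    ds <- bundle$datasets[[d]]
    ph <- ds$phantom
    ns <- dim(ph$cord_mask)[3]
    inc <- slice_inclusion(ns, n_trim)
    cv_s <- rep(NA_real_, ns); ratio_s <- rep(NA_real_, ns)
    for (s in inc) {
      cv_s[s] <- cv_adjacent(ph$image, ph$cord_mask, s, n_dilate)
      ratio_s[s] <- adjacent_sc_ratio(ph$image, ph$cord_mask, s, n_dilate)
    }
    for (r in rn) {
      rm <- ds$rater_masks[[r]]
      d_s <- rep(NA_real_, ns)
      for (s in inc) d_s[s] <- dsc(ph$cord_mask, rm, slice = s)
      slice_rows[[length(slice_rows) + 1L]] <- data.frame(
        dataset = d, rater = r, slice = seq_len(ns),
        dsc = d_s, logit_dsc = ifelse(is.na(d_s), NA_real_, logit(d_s)),
        cv_adjacent = cv_s, adjacent_sc_ratio = ratio_s,
        included = seq_len(ns) %in% inc,
        stringsAsFactors = FALSE)
    }
    for (r in c("REF", rn)) {
      reg <- registered_image(bundle, d, r)
      gw <- gm_wm_contrast(reg, ph$gm_mask, ph$wm_mask)
      mld <- if (identical(r, "REF")) NA_real_ else {
        rows <- slice_rows[[length(slice_rows) - length(rn) + match(r, rn)]]
        mean(rows$logit_dsc[rows$included])
      }
      cell_rows[[length(cell_rows) + 1L]] <- data.frame(
        rater = r, dataset = d, mean_logit_dsc = mld,
        gm_wm_ratio = gw, log_gm_wm = log(gw), stringsAsFactors = FALSE)
    }
  }
  list(slice_metrics = do.call(rbind, slice_rows),
       rater_dataset = do.call(rbind, cell_rows))
}
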