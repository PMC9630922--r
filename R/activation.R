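#' Partition a cord mask into left and right hemicords
#'
#' Per axial slice, the excluded center is the single left-right voxel
#' column at the rounded left-right center of mass of the cord mask; voxels
#' strictly to the left or right of it form the respective hemicords. The
#' left-right axis is the first array dimension (lower indices are "left").
#' A slice of in-plane width 1 leaves both hemicords empty on that slice
#' (with a warning); a cord empty on all slices is an error.
#'
#' @param cord 3-D logical cord mask.
#' @return An object of class `hemicord_partition`: list of logical masks
#'   `left`, `right`, `excluded_center` forming an exact disjoint partition
#'   of `cord`.
#' @export
hemicord_partition <- function(cord) {
  cord <- as_mask_array(cord)
  stopifnot(length(dim(cord)) == 3L)
  if (!any(cord)) stop("cord mask is empty on all slices")
  dims <- dim(cord)
  left <- array(FALSE, dims); right <- array(FALSE, dims)
  center <- array(FALSE, dims)
  for (s in seq_len(dims[3])) {
    m <- cord[, , s]
    if (!any(m)) next
    idx <- which(m, arr.ind = TRUE)
    cx <- round_half_up(mean(idx[, 1]))
    rows <- idx[, 1]
    if (all(rows == rows[1])) {
      warning(sprintf("slice %d has in-plane width 1: both hemicords empty", s))
    }
    sel_l <- idx[rows < cx, , drop = FALSE]
    sel_r <- idx[rows > cx, , drop = FALSE]
    sel_c <- idx[rows == cx, , drop = FALSE]
    l <- m & FALSE; r <- l; cc <- l
    l[sel_l] <- TRUE; r[sel_r] <- TRUE; cc[sel_c] <- TRUE
    left[, , s] <- l; right[, , s] <- r; center[, , s] <- cc
  }
  structure(list(left = left, right = right, excluded_center = center),
            class = "hemicord_partition")
}

#' Map a stimulus side to ipsilateral and contralateral hemicord regions
#'
#' Ipsilateral pairs the hemicord with the same-side stimulus (left cord,
#' left stimulation; right cord, right stimulation); contralateral pairs the
#' opposite hemicord.
#'
#' @param partition a [hemicord_partition()].
#' @param stimulus_side `"left"` or `"right"`.
#' @return List with logical masks `ipsilateral` and `contralateral`.
#' @export
condition_regions <- function(partition, stimulus_side = c("left", "right")) {
  stopifnot(inherits(partition, "hemicord_partition"))
  stimulus_side <- match.arg(stimulus_side)
  if (stimulus_side == "left") {
    list(ipsilateral = partition$left, contralateral = partition$right)
  } else {
    list(ipsilateral = partition$right, contralateral = partition$left)
  }
}

#' Spatial correlation between two activation maps, as Fisher's z
#'
#' Correlates the unthresholded z-statistics of two maps over the voxels of
#' a region and returns the Fisher z transform of the correlation
#' (Pearson by default, Spearman optionally). Identical maps clamp at
#' `atanh(1 - 1e-7)`.
#'
#' @param a,b `activation_map` objects on the same grid.
#' @param region 3-D logical mask, a subset of both analysis masks, with at
#'   least 3 voxels.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Fisher z value (scalar).
#' @export
spatial_correlation <- function(a, b, region, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "activation_map"), inherits(b, "activation_map"))
  region <- as_mask_array(region)
  stopifnot(identical(dim(a$z), dim(region)), identical(dim(b$z), dim(region)))
  if (any(region & !a$analysis_mask) || any(region & !b$analysis_mask)) {
    stop("region must be a subset of both analysis masks")
  }
  va <- a$z[region]; vb <- b$z[region]
  if (length(va) < 3L) stop_undefined("spatial correlation undefined: fewer than 3 voxels")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop_undefined("spatial correlation undefined: zero variance in region")
  }
  fisher_z(stats::cor(va, vb, method = method))
}

#' Standardize a reference activation map against a rater distribution
#'
#' For each region voxel i, computes `(y_i - xbar_i) / s_i`, where `y_i` is
#' the reference z-statistic and `xbar_i`, `s_i` are the mean and sample
#' standard deviation of the raters' z-statistics at that voxel; then
#' summarizes the voxelwise scores by their mean `z_bar` and sample standard
#' deviation `sd_z` over the n region voxels. If the reference behaves like
#' one more draw from the rater distribution, `z_bar` is distributed about 0.
#' Voxels with zero rater standard deviation are dropped with a warning;
#' `sd_z` is `NA` when only one usable voxel remains.
#'
#' @param ref reference `activation_map`.
#' @param raters list of at least 2 rater `activation_map` objects.
#' @param region 3-D logical mask of the voxels to standardize over.
#' @return An object of class `standardized_comparison`: list with `z_bar`,
#'   `sd_z`, `n_voxels` and the voxelwise `scores`.
#' @export
standardize_reference <- function(ref, raters, region) {
  stopifnot(inherits(ref, "activation_map"), length(raters) >= 2L,
            all(vapply(raters, inherits, logical(1), "activation_map")))
  region <- as_mask_array(region)
  y <- ref$z[region]
  x <- vapply(raters, function(m) m$z[region], numeric(sum(region)))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  k <- ncol(x)
  xbar <- rowMeans(x)
  sx <- sqrt(rowSums((x - xbar)^2) / (k - 1))
  ok <- sx > 0
  if (!all(ok)) {
    warning(sprintf("dropped %d voxel(s) with zero rater standard deviation",
                    sum(!ok)))
  }
  if (sum(ok) < 1L) stop("no usable voxels after drops")
  scores <- (y[ok] - xbar[ok]) / sx[ok]
  structure(list(z_bar = mean(scores),
                 sd_z = if (length(scores) > 1L) stats::sd(scores) else NA_real_,
                 n_voxels = sum(ok),
                 scores = scores),
            class = "standardized_comparison")
}

#' @export
print.standardized_comparison <- function(x, ...) {
  cat(sprintf("z_bar = %.3f +/- %.3f (SD), n = %d voxels\n",
              x$z_bar, x$sd_z, x$n_voxels))
  invisible(x)
}

#' Threshold an activation map
#'
#' Classifies as active the voxels of the analysis mask whose z-statistic
#' strictly exceeds the threshold (default 2.3, i.e. p < 0.01 uncorrected).
#'
#' @param map an `activation_map`.
#' @param z_thresh threshold (strict inequality).
#' @return 3-D logical mask of active voxels.
#' @export
threshold_map <- function(map, z_thresh = 2.3) {
  stopifnot(inherits(map, "activation_map"))
  (map$z > z_thresh) & map$analysis_mask
}

#' Summarize a labelled collection of Fisher z correlations
#'
#' @param values data frame with a `fisher_z` column and optionally a
#'   `condition` column; or a bare numeric vector.
#' @param digits rounding for the reported summaries (default 3).
#' @return Data frame with one row per condition (plus `"all"` when a
#'   condition column is present) and columns `condition, n, mean, min, max`.
#' @export
summarize_fisher_table <- function(values, digits = 3L) {
  if (is.numeric(values)) values <- data.frame(fisher_z = values)
  stopifnot(is.data.frame(values), "fisher_z" %in% names(values),
            nrow(values) > 0L)
  one <- function(v, label) data.frame(
    condition = label, n = length(v),
    mean = round(mean(v), digits), min = round(min(v), digits),
    max = round(max(v), digits), stringsAsFactors = FALSE)
  if ("condition" %in% names(values)) {
    parts <- lapply(split(values$fisher_z, values$condition),
                    function(v) v)
    out <- do.call(rbind, c(
      mapply(one, parts, names(parts), SIMPLIFY = FALSE),
      list(one(values$fisher_z, "all"))))
    rownames(out) <- NULL
    out
  } else {
    one(values$fisher_z, "all")
  }
}
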