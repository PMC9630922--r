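# Internal helpers: in-plane binary morphology, slice translation, seed
# derivation, numeric clamping. All morphology is 2-D (per axial slice) with
# the 8-connected 3x3 structuring element; the slice axis is always the third
# array dimension.

`%||%` <- function(a, b) if (is.null(a)) b else a

.brush3 <- local({
  k <- NULL
  function() {
    if (is.null(k)) k <<- EBImage::makeBrush(3L, shape = "box")
    k
  }
})

# one or more 8-connected dilations of a logical slice
dilate_slice <- function(m, steps = 1L) {
  x <- m * 1
  for (i in seq_len(steps)) x <- EBImage::dilate(x, .brush3())
  x > 0
}

erode_slice <- function(m, steps = 1L) {
  x <- m * 1
  for (i in seq_len(steps)) x <- EBImage::erode(x, .brush3())
  x > 0
}

# integer in-plane translation of a slice; dx moves along rows (dim 1),
# dy along columns (dim 2). fill = "constant" pads with `value`;
# fill = "replicate" repeats the nearest border sample (used for images so
# that a shift followed by its inverse restores all interior voxels).
translate_slice <- function(m, dx, dy, fill = c("constant", "replicate"),
                            value = 0) {
  fill <- match.arg(fill)
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  if (dx == 0L && dy == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (fill == "replicate") {
    ri <- pmin(pmax(seq_len(nr) - dx, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) - dy, 1L), nc)
    return(m[ri, ci, drop = FALSE])
  }
  out <- matrix(value, nr, nc)
  r_dst <- max(1L, 1L + dx):min(nr, nr + dx)
  c_dst <- max(1L, 1L + dy):min(nc, nc + dy)
  if (length(r_dst) > 0L && length(c_dst) > 0L &&
      r_dst[1] <= r_dst[length(r_dst)] && c_dst[1] <= c_dst[length(c_dst)]) {
    out[r_dst, c_dst] <- m[r_dst - dx, c_dst - dy, drop = FALSE]
  }
  out
}

# round half away from zero (base round() uses banker's rounding, which would
# make mirror-image geometry asymmetric)
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# deterministic 32-bit seed derived from a master seed and up to two indices;
# adding a rater or dataset never changes the seeds of the others
derive_seed <- function(master, i = 0L, j = 0L) {
  m <- as.numeric(master) %% 2147483647
  as.integer((m * 1000003 + as.numeric(i) * 10007 + as.numeric(j) * 101 + 1) %%
               2147483647)
}

# per-slice centroid (row, col) of a logical slice; NA if empty
slice_centroid <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(c(NA_real_, NA_real_))
  c(mean(idx[, 1]), mean(idx[, 2]))
}

as_mask_array <- function(x) {
  if (is.logical(x)) return(x)
  stopifnot(is.numeric(x))
  x > 0
}

stop_undefined <- function(msg) stop(msg, call. = FALSE)
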