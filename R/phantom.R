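#' Specify a synthetic axial spinal-cord phantom
#'
#' Describes the geometry and signal model of a synthetic spinal-cord volume:
#' an elliptical cord cross-section per axial slice, containing a four-lobed
#' gray-matter "butterfly" inside white matter, surrounded by CSF whose mean
#' intensity may vary by slice (and may dip below the cord mean to emulate
#' the contrast breakdown seen in T2*-weighted acquisitions). The slice axis
#' is the third array dimension; in-plane axes are left-right (rows) and
#' anterior-posterior (columns).
#'
#' @param grid_shape integer triple: in-plane rows (left-right), in-plane
#'   columns (anterior-posterior), number of axial slices. The default
#'   emulates a 44 x 128 matrix with 25 slices.
#' @param voxel_size_mm positive real triple, default `c(1, 1, 3)` mm.
#' @param cord_center in-plane cord center: a length-2 vector (constant
#'   across slices) or an `n_slices` x 2 matrix (smooth drift allowed).
#'   Defaults to the grid center.
#' @param cord_radii semi-axes of the cord ellipse in voxels, left-right and
#'   anterior-posterior: length-2 vector or `n_slices` x 2 matrix. The
#'   default `c(5.7, 3.7)` matches a cord of roughly 11.4 mm left-right by
#'   7.4 mm anterior-posterior at 1 mm in-plane resolution.
#' @param gm_scale size of the gray-matter butterfly relative to the cord,
#'   in (0, 1).
#' @param mean_intensity named list with elements `csf`, `wm`, `gm`; each a
#'   scalar or per-slice vector of nonnegative tissue means.
#' @param noise_sd nonnegative Gaussian noise standard deviation; scalar or
#'   per-slice vector.
#' @param seed integer seed controlling the noise realization.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(44L, 128L, 25L),
                         voxel_size_mm = c(1, 1, 3),
                         cord_center = NULL,
                         cord_radii = c(5.7, 3.7),
                         gm_scale = 0.55,
                         mean_intensity = list(csf = 150, wm = 100, gm = 115),
                         noise_sd = 8,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 3L),
            length(voxel_size_mm) == 3L, all(is.finite(voxel_size_mm)),
            all(voxel_size_mm > 0),
            is.numeric(gm_scale), length(gm_scale) == 1L,
            gm_scale > 0, gm_scale < 1)
  ns <- grid_shape[3]
  if (is.null(cord_center)) {
    cord_center <- c((grid_shape[1] + 1) / 2, (grid_shape[2] + 1) / 2)
  }
  cord_center <- per_slice_pairs(cord_center, ns, "cord_center")
  cord_radii <- per_slice_pairs(cord_radii, ns, "cord_radii")
  if (any(!is.finite(cord_radii)) || any(cord_radii <= 0)) {
    stop("cord_radii must be finite and positive")
  }
  mi <- lapply(mean_intensity[c("csf", "wm", "gm")],
               function(v) rep_len(as.numeric(v), ns))
  if (anyNA(names(mean_intensity)) ||
      !all(c("csf", "wm", "gm") %in% names(mean_intensity))) {
    stop("mean_intensity must name csf, wm and gm")
  }
  vals <- unlist(mi, use.names = FALSE)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("tissue mean intensities must be finite and nonnegative")
  }
  noise_sd <- rep_len(as.numeric(noise_sd), ns)
  if (any(!is.finite(noise_sd)) || any(noise_sd < 0)) {
    stop("noise_sd must be finite and nonnegative")
  }
  # the cord ellipse must fit strictly inside the in-plane grid on every slice
  lo <- cord_center - cord_radii
  hi <- cord_center + cord_radii
  if (any(lo[, 1] <= 1) || any(lo[, 2] <= 1) ||
      any(hi[, 1] >= grid_shape[1]) || any(hi[, 2] >= grid_shape[2])) {
    stop("geometry error: cord ellipse exceeds the in-plane grid bounds")
  }
  structure(list(grid_shape = grid_shape,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 cord_center = cord_center,
                 cord_radii = cord_radii,
                 gm_scale = gm_scale,
                 mean_intensity = mi,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

per_slice_pairs <- function(x, ns, what) {
  if (is.matrix(x)) {
    if (nrow(x) != ns || ncol(x) != 2L) {
      stop(sprintf("%s matrix must be n_slices x 2", what))
    }
    return(x)
  }
  if (length(x) != 2L) stop(sprintf("%s must be a pair or n_slices x 2 matrix", what))
  matrix(rep(as.numeric(x), each = ns), ns, 2L)
}

# gray-matter butterfly built from scaled ellipses: one vertically elongated
# column per hemicord (whose superior/inferior ends form the dorsal and
# ventral horns) bridged by a central commissure, restricted to the cord
# interior so GM never touches the cord boundary
butterfly_slice <- function(xs, ys, cx, cy, rx, ry, scale) {
  lobe <- function(ox, oy, ax, ay) {
    outer((xs - (cx + ox))^2 / ax^2, (ys - (cy + oy))^2 / ay^2, "+") <= 1
  }
  dx <- 0.50 * rx
  lobe(dx, 0, scale * 0.30 * rx, scale * 1.35 * ry) |
    lobe(-dx, 0, scale * 0.30 * rx, scale * 1.35 * ry) |
    lobe(0, 0, scale * 1.00 * rx, scale * 0.35 * ry)
}

#' Generate a synthetic spinal-cord volume
#'
#' Builds the noiseless tissue geometry (cord, gray matter, white matter) from
#' a [phantom_spec()] and adds independent Gaussian voxel noise to the image.
#' The masks are always the noiseless geometry. Gray and white matter
#' partition the cord exactly: `gm | wm == cord` and `gm & wm` is empty.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_volume`: a list with elements `image`
#'   (3-D numeric array), `cord_mask`, `gm_mask`, `wm_mask` (3-D logical
#'   arrays) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape; ns <- gs[3]
  xs <- seq_len(gs[1]); ys <- seq_len(gs[2])
  cord <- array(FALSE, gs); gm <- array(FALSE, gs)
  for (s in seq_len(ns)) {
    cx <- spec$cord_center[s, 1]; cy <- spec$cord_center[s, 2]
    rx <- spec$cord_radii[s, 1]; ry <- spec$cord_radii[s, 2]
    d2 <- outer((xs - cx)^2 / rx^2, (ys - cy)^2 / ry^2, "+")
    cs <- d2 <= 1
    gs_slice <- butterfly_slice(xs, ys, cx, cy, rx, ry, spec$gm_scale) &
      d2 <= 0.85^2
    cord[, , s] <- cs
    gm[, , s] <- gs_slice & cs
  }
  wm <- cord & !gm
  img <- array(0, gs)
  set.seed(spec$seed)
  npx <- gs[1] * gs[2]
  for (s in seq_len(ns)) {
    base <- matrix(spec$mean_intensity$csf[s], gs[1], gs[2])
    base[wm[, , s]] <- spec$mean_intensity$wm[s]
    base[gm[, , s]] <- spec$mean_intensity$gm[s]
    if (spec$noise_sd[s] > 0) {
      base <- base + matrix(stats::rnorm(npx, 0, spec$noise_sd[s]), gs[1], gs[2])
    }
    img[, , s] <- base
  }
  structure(list(image = img, cord_mask = cord, gm_mask = gm, wm_mask = wm,
                 spec = spec),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  gs <- x$spec$grid_shape
  cat(sprintf("<phantom_volume> %d x %d x %d (%g x %g x %g mm), cord %d voxels, GM %d, WM %d\n",
              gs[1], gs[2], gs[3],
              x$spec$voxel_size_mm[1], x$spec$voxel_size_mm[2],
              x$spec$voxel_size_mm[3],
              sum(x$cord_mask), sum(x$gm_mask), sum(x$wm_mask)))
  invisible(x)
}

#' Parametric model of a simulated rater
#'
#' Describes how a simulated rater deviates from a reference contour:
#' a signed systematic bias (morphological over- or under-segmentation),
#' a per-slice random in-plane jitter of the contour, and random flips of
#' boundary voxels. A model with all parameters zero reproduces the
#' reference exactly.
#'
#' @param bias_voxels signed integer: `+k` applies k in-plane dilations,
#'   `-k` applies k erosions, per slice.
#' @param flip_rate probability in `[0, 1)` that each boundary voxel (a voxel
#'   within in-plane Chebyshev distance 1 of the mask edge) has its
#'   membership flipped; scalar or per-slice vector.
#' @param slice_jitter_mm standard deviation (mm) of the random in-plane
#'   translation applied to the contour on each slice, rounded to voxels.
#' @param seed integer seed.
#' @return An object of class `rater_model`.
#' @export
rater_model <- function(bias_voxels = 0L, flip_rate = 0, slice_jitter_mm = 0,
                        seed = 1L) {
  stopifnot(length(bias_voxels) == 1L,
            all(is.finite(flip_rate)), all(flip_rate >= 0), all(flip_rate < 1),
            length(slice_jitter_mm) == 1L, is.finite(slice_jitter_mm),
            slice_jitter_mm >= 0)
  structure(list(bias_voxels = as.integer(bias_voxels),
                 flip_rate = as.numeric(flip_rate),
                 slice_jitter_mm = as.numeric(slice_jitter_mm),
                 seed = as.integer(seed)),
            class = "rater_model")
}

#' Simulate a rater's spinal-cord mask
#'
#' Applies, per axial slice and in order: the signed morphological bias, the
#' random in-plane jitter (rounded to whole voxels), and independent flips of
#' boundary voxels. Boundary voxels are those within in-plane Chebyshev
#' distance 1 of the mask edge. If an erosion empties a slice, that slice is
#' left as a single voxel at the cord centroid and a warning is raised.
#' Deterministic given the model seed.
#'
#' @param ref 3-D logical reference mask (slices on the third axis).
#' @param model a [rater_model()].
#' @param voxel_size_mm voxel dimensions, used to convert jitter from mm to
#'   voxels.
#' @return A 3-D logical mask with the same dimensions as `ref`.
#' @export
simulate_rater_mask <- function(ref, model, voxel_size_mm = c(1, 1, 3)) {
  stopifnot(inherits(model, "rater_model"))
  ref <- as_mask_array(ref)
  stopifnot(length(dim(ref)) == 3L)
  ns <- dim(ref)[3]
  fr <- rep_len(model$flip_rate, ns)
  set.seed(model$seed)
  out <- ref
  for (s in seq_len(ns)) {
    m <- ref[, , s]
    if (!any(m)) next
    ctr <- round_half_up(slice_centroid(m))
    b <- model$bias_voxels
    if (b > 0L) {
      m <- dilate_slice(m, b)
    } else if (b < 0L) {
      m <- erode_slice(m, -b)
      if (!any(m)) {
        m[ctr[1], ctr[2]] <- TRUE
        warning(sprintf("erosion emptied slice %d; kept a single centroid voxel", s))
      }
    }
    if (model$slice_jitter_mm > 0) {
      sh <- round_half_up(stats::rnorm(2, 0, model$slice_jitter_mm) /
                            voxel_size_mm[1:2])
      m <- translate_slice(m, sh[1], sh[2], fill = "constant", value = FALSE)
    }
    if (fr[s] > 0) {
      edge <- m & !erode_slice(m, 1L)
      zone <- which(dilate_slice(edge, 1L))
      if (length(zone) > 0L) {
        flip <- zone[stats::runif(length(zone)) < fr[s]]
        m[flip] <- !m[flip]
      }
    }
    out[, , s] <- m
  }
  out
}

#' Simulate misregistration of a phantom volume
#'
#' Translates the phantom image in-plane (nearest-neighbor resampling)
#' relative to its untouched atlas masks, emulating an imperfect spatial
#' normalization: after a nonzero shift, atlas gray- and white-matter regions
#' sample a mixture of tissues, reducing the observed GM:WM contrast. A zero
#' shift returns the input unchanged.
#'
#' @param vol a `phantom_volume`.
#' @param shift_mm in-plane shift in mm: a length-2 vector applied to every
#'   slice, or (with `per_slice = TRUE`) an `n_slices` x 2 matrix.
#' @param per_slice logical; whether `shift_mm` gives one shift per slice.
#' @return A `phantom_volume` with the translated image; masks unchanged. The
#'   applied integer voxel shifts are stored in the
#'   `misregistration_voxels` element.
#' @export
simulate_misregistration <- function(vol, shift_mm, per_slice = FALSE) {
  stopifnot(inherits(vol, "phantom_volume"))
  ns <- dim(vol$image)[3]
  vs <- vol$spec$voxel_size_mm
  if (per_slice) {
    stopifnot(is.matrix(shift_mm), nrow(shift_mm) == ns, ncol(shift_mm) == 2L)
    shifts <- shift_mm
  } else {
    stopifnot(length(shift_mm) == 2L)
    shifts <- matrix(rep(as.numeric(shift_mm), each = ns), ns, 2L)
  }
  dv <- round_half_up(sweep(shifts, 2, vs[1:2], "/"))
  # the (true) cord must stay inside the grid after the shift
  for (s in seq_len(ns)) {
    idx <- which(vol$cord_mask[, , s], arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    r <- range(idx[, 1]) + dv[s, 1]; cc <- range(idx[, 2]) + dv[s, 2]
    if (r[1] < 1 || cc[1] < 1 || r[2] > dim(vol$image)[1] ||
        cc[2] > dim(vol$image)[2]) {
      stop("geometry error: shift pushes the cord out of the grid")
    }
  }
  img <- vol$image
  for (s in seq_len(ns)) {
    img[, , s] <- translate_slice(img[, , s], dv[s, 1], dv[s, 2],
                                  fill = "replicate")
  }
  vol$image <- img
  vol$misregistration_voxels <- dv
  vol
}

#' Construct an activation map object
#'
#' @param z 3-D numeric array of z-statistics.
#' @param analysis_mask 3-D logical mask of analyzable voxels.
#' @param stimulus_side `"left"` or `"right"`.
#' @param level `"participant"` or `"group"`.
#' @return An object of class `activation_map`.
#' @export
activation_map <- function(z, analysis_mask, stimulus_side = c("left", "right"),
                           level = c("participant", "group")) {
  stimulus_side <- match.arg(stimulus_side)
  level <- match.arg(level)
  analysis_mask <- as_mask_array(analysis_mask)
  stopifnot(identical(dim(z), dim(analysis_mask)),
            all(is.finite(z[analysis_mask])))
  structure(list(z = z, analysis_mask = analysis_mask,
                 stimulus_side = stimulus_side, level = level),
            class = "activation_map")
}

#' Generate a synthetic participant-level activation map
#'
#' Places a lateralized activation blob (constant amplitude) in one hemicord
#' over a range of slices and adds zero-mean Gaussian noise everywhere inside
#' the analysis mask (the cord).
#'
#' @param vol a `phantom_volume`.
#' @param side `"left"` or `"right"`: the stimulated side; the blob occupies
#'   the ipsilateral hemicord.
#' @param amplitude z-statistic amplitude of the blob.
#' @param extent_slices integer vector of slice indices carrying the blob.
#' @param noise_sd standard deviation of the z-statistic noise.
#' @param seed integer seed.
#' @return An `activation_map` at participant level.
#' @export
generate_activation_map <- function(vol, side = c("left", "right"),
                                    amplitude = 3, extent_slices = NULL,
                                    noise_sd = 1, seed = 1L) {
  stopifnot(inherits(vol, "phantom_volume"))
  side <- match.arg(side)
  dims <- dim(vol$cord_mask)
  if (is.null(extent_slices)) {
    extent_slices <- seq_len(dims[3])
  }
  part <- hemicord_partition(vol$cord_mask)
  hemi <- if (side == "left") part$left else part$right
  blob <- array(FALSE, dims)
  blob[, , extent_slices] <- hemi[, , extent_slices]
  if (!any(blob)) stop("empty hemicord: no voxels available for activation")
  am <- vol$cord_mask
  z <- array(0, dims)
  set.seed(seed)
  if (noise_sd > 0) z[am] <- stats::rnorm(sum(am), 0, noise_sd)
  z[blob] <- z[blob] + amplitude
  activation_map(z, am, stimulus_side = side, level = "participant")
}
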