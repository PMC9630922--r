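# Shared fixtures, built in code. Small grids keep the unit tests fast;
# study-scale conditions live in the acceptance tests.

# a small noiseless phantom spec with known tissue means
tiny_spec <- function(csf = 200, wm = 100, gm = 120, noise_sd = 0,
                      n_slices = 6L, seed = 42L) {
  phantom_spec(grid_shape = c(24L, 32L, n_slices),
               cord_radii = c(5.5, 3.5),
               mean_intensity = list(csf = csf, wm = wm, gm = gm),
               noise_sd = noise_sd, seed = seed)
}

# random blob mask on a small grid: a filled disc plus random voxel noise,
# guaranteed nonempty per slice
random_mask <- function(dims = c(16L, 16L, 4L), p = 0.25, seed = 1L) {
  set.seed(seed)
  m <- array(stats::runif(prod(dims)) < p, dims)
  for (s in seq_len(dims[3])) m[sample.int(dims[1], 1), sample.int(dims[2], 1), s] <- TRUE
  m
}

# brute-force Dice via explicit voxel enumeration (independent oracle)
brute_dsc <- function(a, b) {
  inter <- 0L; na <- 0L; nb <- 0L
  for (i in seq_along(a)) {
    inter <- inter + (a[[i]] && b[[i]])
    na <- na + a[[i]]; nb <- nb + b[[i]]
  }
  2 * inter / (na + nb)
}

# brute-force in-plane Chebyshev-distance adjacency oracle
brute_adjacent <- function(mask2d, n_dilate) {
  nr <- nrow(mask2d); nc <- ncol(mask2d)
  out <- matrix(FALSE, nr, nc)
  idx <- which(mask2d, arr.ind = TRUE)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask2d[i, j]) next
    d <- min(pmax(abs(idx[, 1] - i), abs(idx[, 2] - j)))
    if (d <= n_dilate) out[i, j] <- TRUE
  }
  out
}

# independent sums-of-squares oracle for the balanced additive two-way layout
brute_anova_ss <- function(df, response) {
  y <- df[[response]]
  gm <- mean(y)
  ra <- tapply(y, df$rater, mean); da <- tapply(y, df$dataset, mean)
  R <- length(ra); D <- length(da)
  ss_rater <- D * sum((ra - gm)^2)
  ss_dataset <- R * sum((da - gm)^2)
  ss_total <- sum((y - gm)^2)
  list(rater = ss_rater, dataset = ss_dataset,
       residual = ss_total - ss_rater - ss_dataset, total = ss_total)
}

# small default study for pipeline-level tests
small_study_config <- function(n_datasets = 3L, n_raters = 3L, seed = 7L) {
  study_config(n_datasets = n_datasets,
               rater_models = default_rater_models(
                 flip_rates = seq(0.05, 0.25, length.out = n_raters)),
               grid_shape = c(24L, 48L, 8L),
               master_seed = seed)
}
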