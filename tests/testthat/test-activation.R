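symmetric_cord <- function(width = 7L, height = 5L, dims = c(15L, 15L, 2L),
                           center = 8L) {
  cord <- array(FALSE, dims)
  half_w <- (width - 1L) %/% 2L
  rows <- (center - half_w):(center + half_w)
  cols <- (8L - (height - 1L) %/% 2L):(8L + (height - 1L) %/% 2L)
  cord[rows, cols, ] <- TRUE
  cord
}

test_that("hemicord partition splits a width-7 cord 3/1/3 at its center", {
  cord <- symmetric_cord(width = 7L, center = 8L)
  part <- hemicord_partition(cord)
  for (s in 1:2) {
    expect_equal(sum(part$left[, , s]), 3 * 5)
    expect_equal(sum(part$excluded_center[, , s]), 5)
    expect_equal(sum(part$right[, , s]), 3 * 5)
    expect_true(all(which(part$excluded_center[, , s], arr.ind = TRUE)[, 1] == 8L))
  }
})

test_that("partition is exact and disjoint for random masks", {
  for (k in 1:100) {
    cord <- random_mask(dims = c(10L, 10L, 3L), p = 0.3, seed = k)
    part <- hemicord_partition(cord)
    expect_identical(part$left | part$right | part$excluded_center, cord)
    expect_false(any(part$left & part$right))
    expect_false(any(part$left & part$excluded_center))
    expect_false(any(part$right & part$excluded_center))
  }
})

test_that("mirroring the cord left-right swaps the hemicords", {
  cord <- symmetric_cord(width = 5L, center = 6L)   # integer-center cord
  dims <- dim(cord)
  mirrored <- cord[dims[1]:1, , , drop = FALSE]
  p1 <- hemicord_partition(cord)
  p2 <- hemicord_partition(mirrored)
  expect_identical(p2$left, p1$right[dims[1]:1, , , drop = FALSE])
  expect_identical(p2$right, p1$left[dims[1]:1, , , drop = FALSE])
})

test_that("width-1 slices leave both hemicords empty with a warning", {
  cord <- array(FALSE, c(9L, 9L, 1L)); cord[5, 3:7, 1] <- TRUE
  expect_warning(part <- hemicord_partition(cord), "width 1")
  expect_equal(sum(part$left) + sum(part$right), 0)
  expect_identical(part$excluded_center, cord)
  expect_error(hemicord_partition(array(FALSE, c(3, 3, 2))), "empty")
})

test_that("condition regions implement the ipsilateral/contralateral pairing", {
  cord <- symmetric_cord()
  part <- hemicord_partition(cord)
  left_stim <- condition_regions(part, "left")
  expect_identical(left_stim$ipsilateral, part$left)
  expect_identical(left_stim$contralateral, part$right)
  right_stim <- condition_regions(part, "right")
  expect_identical(right_stim$ipsilateral, part$right)
  expect_identical(right_stim$contralateral, part$left)
})

noise_map <- function(cord, seed, side = "left") {
  set.seed(seed)
  z <- array(0, dim(cord)); z[cord] <- rnorm(sum(cord))
  activation_map(z, cord, stimulus_side = side)
}

test_that("spatial correlation honors identity, antisymmetry and affine invariance", {
  cord <- symmetric_cord(dims = c(15L, 15L, 10L))
  a <- noise_map(cord, 1L)
  expect_equal(spatial_correlation(a, a, cord), fisher_z(1))
  neg <- activation_map(-a$z, cord, "left")
  expect_equal(spatial_correlation(a, neg, cord), fisher_z(-1))
  b <- noise_map(cord, 2L)
  z0 <- spatial_correlation(a, b, cord)
  scaled <- activation_map(3 * b$z + 7 * cord, cord, "left")
  expect_equal(spatial_correlation(a, scaled, cord), z0, tolerance = 1e-9)
  expect_equal(spatial_correlation(a, neg, cord),
               -spatial_correlation(a, a, cord))
  flat <- activation_map(array(0, dim(cord)) + cord * 2, cord, "left")
  expect_error(spatial_correlation(a, flat, cord), "zero variance")
})

test_that("independent maps over >= 2000 voxels have near-zero Fisher z", {
  cord <- array(FALSE, c(20L, 20L, 8L)); cord[3:18, 3:18, ] <- TRUE
  expect_gte(sum(cord), 2000)
  z <- spatial_correlation(noise_map(cord, 10L), noise_map(cord, 20L), cord)
  expect_lt(abs(z), 0.1)
})

test_that("standardize_reference reproduces the voxelwise formula", {
  cord <- array(FALSE, c(3L, 3L, 1L)); cord[2, 2, 1] <- TRUE
  mk <- function(v) {
    z <- array(0, dim(cord)); z[2, 2, 1] <- v
    activation_map(z, cord, "left")
  }
  # single voxel, rater values {1,2,3}: mean 2, sample SD 1, y = 3 -> score 1
  std <- standardize_reference(mk(3), list(mk(1), mk(2), mk(3)), cord)
  expect_equal(std$scores, 1)
  expect_equal(std$z_bar, 1)
  expect_true(is.na(std$sd_z))
  expect_equal(std$n_voxels, 1L)
})

test_that("standardization is centered and translation invariant", {
  cord <- symmetric_cord(dims = c(15L, 15L, 6L))
  raters <- lapply(1:6, function(k) noise_map(cord, 100L + k))
  xbar <- Reduce(`+`, lapply(raters, function(m) m$z)) / length(raters)
  ref_mean <- activation_map(xbar, cord, "left")
  std0 <- standardize_reference(ref_mean, raters, cord)
  expect_equal(std0$z_bar, 0, tolerance = 1e-12)

  ref <- noise_map(cord, 999L)
  std1 <- standardize_reference(ref, raters, cord)
  shift <- function(m, c) activation_map(m$z + c * cord, cord, "left")
  std2 <- standardize_reference(shift(ref, 5),
                                lapply(raters, shift, c = 5), cord)
  expect_equal(std2$z_bar, std1$z_bar, tolerance = 1e-9)
  expect_equal(std2$sd_z, std1$sd_z, tolerance = 1e-9)
})

test_that("thresholding is strict and monotone", {
  cord <- symmetric_cord()
  z <- array(0, dim(cord)); z[cord] <- 2.3
  m <- activation_map(z, cord, "left")
  expect_equal(sum(threshold_map(m, 2.3)), 0)

  blob <- hemicord_partition(cord)$left
  z2 <- array(0, dim(cord)); z2[blob] <- 5
  m2 <- activation_map(z2, cord, "left")
  expect_identical(threshold_map(m2, 2.3), blob)
  noisy <- noise_map(cord, 3L)
  for (th in c(0, 1, 2, 3)) {
    expect_true(all(threshold_map(noisy, th + 0.5) <= threshold_map(noisy, th)))
  }
})

test_that("Fisher z summaries aggregate labelled collections", {
  one <- summarize_fisher_table(data.frame(fisher_z = 0.4))
  expect_equal(one$mean, 0.4)
  expect_equal(one$min, one$max)
  tab <- example_group_correlations()
  sm <- summarize_fisher_table(tab)
  ipsi <- sm[sm$condition == "ipsilateral", ]
  expect_equal(ipsi$n, 16L)
  expect_equal(ipsi$mean, 0.923)
})
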