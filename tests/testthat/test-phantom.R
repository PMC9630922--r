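test_that("zero-noise phantom reproduces tissue means exactly and is deterministic", {
  spec <- tiny_spec(csf = 200, wm = 100, gm = 120, noise_sd = 0)
  ph <- generate_phantom(spec)
  expect_true(all(ph$image[!ph$cord_mask] == 200))
  expect_true(all(ph$image[ph$wm_mask] == 100))
  expect_true(all(ph$image[ph$gm_mask] == 120))
  # GM/WM partition the cord exactly
  expect_true(all((ph$gm_mask | ph$wm_mask) == ph$cord_mask))
  expect_false(any(ph$gm_mask & ph$wm_mask))
  expect_gt(sum(ph$gm_mask), 0)
  # same spec + seed: bit-identical
  spec2 <- tiny_spec(noise_sd = 5, seed = 99L)
  expect_identical(generate_phantom(spec2), generate_phantom(spec2))
})

test_that("phantom spec validates geometry and intensities", {
  expect_error(phantom_spec(grid_shape = c(10L, 32L, 4L),
                            cord_radii = c(6, 3)),
               "geometry")
  expect_error(tiny_spec(csf = -5), "nonnegative")
  expect_error(phantom_spec(gm_scale = 1.5))
})

test_that("per-slice CSF profile drives the Adjacent:SC ratio across 1", {
  # CSF dips below the cord mean on the lowest slices: ratio < 1 there
  csf <- c(150, 150, 150, 80, 80, 80)
  spec <- tiny_spec(csf = csf, wm = 100, gm = 100, noise_sd = 0)
  ph <- generate_phantom(spec)
  for (s in 1:3) expect_gt(adjacent_sc_ratio(ph$image, ph$cord_mask, s), 1)
  for (s in 4:6) {
    # with gm = wm = 100 the cord mean is exactly 100, so the ratio is exact
    expect_equal(adjacent_sc_ratio(ph$image, ph$cord_mask, s), 0.8)
  }
})

test_that("an all-zero rater model reproduces the reference exactly", {
  ph <- generate_phantom(tiny_spec())
  rm <- simulate_rater_mask(ph$cord_mask, rater_model())
  expect_identical(rm, ph$cord_mask)
  expect_equal(dsc(ph$cord_mask, rm), 1)
})

test_that("pure positive bias is a per-slice one-step dilation", {
  ph <- generate_phantom(tiny_spec())
  rm <- simulate_rater_mask(ph$cord_mask, rater_model(bias_voxels = 1L))
  expect_identical(rm, adjacent_region(ph$cord_mask, 1L) | ph$cord_mask)
})

test_that("erosion emptying a slice falls back to a centroid voxel with warning", {
  ref <- array(FALSE, c(12L, 12L, 2L))
  ref[6:7, 6:7, 1] <- TRUE           # 2x2: one erosion empties it
  ref[4:9, 4:9, 2] <- TRUE
  expect_warning(rm <- simulate_rater_mask(ref, rater_model(bias_voxels = -1L)),
                 "emptied")
  expect_equal(sum(rm[, , 1]), 1)
  expect_true(rm[7, 7, 1] || rm[6, 6, 1])
})

test_that("mean DSC degrades monotonically with the boundary flip rate", {
  ph <- generate_phantom(tiny_spec(n_slices = 4L))
  rates <- c(0.0, 0.1, 0.2, 0.3)
  mean_dsc <- vapply(seq_along(rates), function(i) {
    sims <- vapply(seq_len(200), function(k) {
      rm <- simulate_rater_mask(ph$cord_mask,
                                rater_model(flip_rate = rates[i],
                                            seed = 1000L * i + k))
      dsc(ph$cord_mask, rm)
    }, numeric(1))
    mean(sims)
  }, numeric(1))
  expect_equal(mean_dsc[1], 1)
  expect_true(all(diff(mean_dsc) < 0))
})

test_that("misregistration is identity at zero shift and invertible on interiors", {
  ph <- generate_phantom(tiny_spec(noise_sd = 0))
  expect_identical(simulate_misregistration(ph, c(0, 0))$image, ph$image)
  fwd <- simulate_misregistration(ph, c(1, 0))
  back <- simulate_misregistration(fwd, c(-1, 0))
  interior <- ph$image[2:23, , , drop = FALSE]
  expect_equal(back$image[2:23, , , drop = FALSE], interior)
  expect_error(simulate_misregistration(ph, c(50, 0)), "geometry")
})

test_that("misregistration reduces GM:WM contrast on a noiseless phantom", {
  ph <- generate_phantom(tiny_spec(csf = 150, wm = 100, gm = 120, noise_sd = 0))
  c0 <- gm_wm_contrast(ph$image, ph$gm_mask, ph$wm_mask)
  for (sh in 1:3) {
    cs <- gm_wm_contrast(simulate_misregistration(ph, c(sh, 0))$image,
                         ph$gm_mask, ph$wm_mask)
    expect_lte(cs, c0)
  }
})

test_that("activation maps honor the zero-noise and determinism contracts", {
  ph <- generate_phantom(tiny_spec())
  part <- hemicord_partition(ph$cord_mask)
  m0 <- generate_activation_map(ph, "left", amplitude = 4, noise_sd = 0)
  expect_true(all(m0$z[part$left] == 4))
  expect_true(all(m0$z[!part$left] == 0))
  m1 <- generate_activation_map(ph, "right", noise_sd = 1, seed = 5L)
  m2 <- generate_activation_map(ph, "right", noise_sd = 1, seed = 5L)
  expect_equal(spatial_correlation(m1, m2, ph$cord_mask), fisher_z(1))
})

test_that("null activation maps are spatially uncorrelated", {
  spec <- phantom_spec(grid_shape = c(30L, 40L, 20L), cord_radii = c(9, 6),
                       noise_sd = 0, seed = 1L)
  ph <- generate_phantom(spec)
  expect_gte(sum(ph$cord_mask), 2000)
  a <- generate_activation_map(ph, "left", amplitude = 0, noise_sd = 1, seed = 11L)
  b <- generate_activation_map(ph, "left", amplitude = 0, noise_sd = 1, seed = 22L)
  r <- fisher_z_inv(spatial_correlation(a, b, ph$cord_mask))
  expect_lt(abs(r), 0.1)
})

test_that("study generation is reproducible and counts masks correctly", {
  cfg <- small_study_config(n_datasets = 2L, n_raters = 3L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- generate_study(cfg, out_dir = d1)
  b2 <- generate_study(cfg, out_dir = d2)
  m1 <- jsonlite::read_json(file.path(d1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  expect_identical(m1$datasets, m2$datasets)
  roles <- unlist(lapply(m1$datasets, function(ds)
    vapply(ds$files, function(f) f$role, character(1))))
  expect_equal(sum(roles %in% c("reference", "rater")), 2L * (1L + 3L))
  # in-memory bundles identical too
  expect_identical(b1$datasets, b2$datasets)
})

test_that("an error-free simulated rater attains study-wide mean DSC of 1", {
  cfg <- study_config(n_datasets = 2L,
                      rater_models = list(perfect = rater_model(),
                                          noisy = rater_model(flip_rate = 0.2)),
                      grid_shape = c(24L, 48L, 8L),
                      difficulty_coupling = 0,
                      master_seed = 3L)
  bundle <- generate_study(cfg)
  tabs <- build_tables(bundle)
  cells <- tabs$rater_dataset[tabs$rater_dataset$rater == "perfect", ]
  expect_equal(cells$mean_logit_dsc, rep(logit(1), 2L))
})
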