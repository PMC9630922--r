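make_cells <- function(R, D, seed = 1L, response = "y", constant = NULL) {
  set.seed(seed)
  df <- expand.grid(rater = LETTERS[seq_len(R)], dataset = seq_len(D),
                    stringsAsFactors = FALSE)
  df[[response]] <- if (is.null(constant)) rnorm(nrow(df)) else constant
  df
}

test_that("two-way ANOVA matches the independent sums-of-squares oracle", {
  for (k in 1:50) {
    R <- sample(2:6, 1); D <- sample(2:8, 1)
    cells <- make_cells(R, D, seed = k)
    fit <- two_way_anova(cells, "y")
    ss <- brute_anova_ss(cells, "y")
    expect_equal(fit$sum_sq, c(ss$rater, ss$dataset, ss$residual),
                 tolerance = 1e-9)
    expect_equal(fit$df, c(R - 1L, D - 1L, (R - 1L) * (D - 1L)))
    expect_equal(fit$eta_sq, c(ss$rater, ss$dataset, ss$residual) / ss$total,
                 tolerance = 1e-9)
    expect_equal(sum(fit$eta_sq), 1, tolerance = 1e-10)
    # F and p from first principles
    ms_res <- ss$residual / ((R - 1) * (D - 1))
    f_rater <- (ss$rater / (R - 1)) / ms_res
    expect_equal(fit$statistic[1], f_rater, tolerance = 1e-9)
    expect_equal(fit$p_value[1],
                 pf(f_rater, R - 1, (R - 1) * (D - 1), lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("ANOVA guards incomplete designs and handles constant responses", {
  cells <- make_cells(3, 4)
  expect_error(two_way_anova(cells[-1, ], "y"), "complete")
  expect_error(two_way_anova(make_cells(1, 4), "y"), "levels")
  fit0 <- two_way_anova(make_cells(3, 4, constant = 2.5), "y")
  expect_equal(fit0$eta_sq, c(0, 0, 0))
  expect_true(all(is.na(fit0$statistic)))
})

test_that("Spearman correlation handles monotone, enumerated and degenerate input", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 1, 2)), -0.5)
  expect_warning(r <- spearman_rho(1:2, 2:1), "fewer than 3")
  expect_true(is.na(r))
  expect_warning(r2 <- spearman_rho(c(1, 1, 1), 1:3), "zero rank variance")
  expect_true(is.na(r2))
})

test_that("Spearman under independent permutations is centered at zero", {
  set.seed(202L)
  x <- rnorm(23)
  rhos <- vapply(1:2000, function(i) spearman_rho(x, sample(x)), numeric(1))
  expect_lt(abs(mean(rhos)), 0.02)
})

test_that("Fisher z is atanh with clamping and exact inverse", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_true(is.finite(fisher_z(1)) && is.finite(fisher_z(-1)))
  for (r in seq(-0.9, 0.9, by = 0.1)) {
    expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
  }
})

perm_table <- function(R, D, S, seed, rho = 0) {
  # synthetic slicewise table; rho injects a rank correlation between the
  # outcome and DSC via a shared component
  set.seed(seed)
  df <- expand.grid(slice = seq_len(S), rater = LETTERS[seq_len(R)],
                    dataset = seq_len(D), stringsAsFactors = FALSE)
  n <- nrow(df)
  base <- rnorm(n)
  df$dsc <- plogis(base)
  df$cv_adjacent <- abs(rho * base + sqrt(1 - rho^2) * rnorm(n)) + 0.01
  df$adjacent_sc_ratio <- exp(rho * base + sqrt(1 - rho^2) * rnorm(n))
  df$included <- TRUE
  df
}

test_that("max-T permutation result is deterministic and structurally sound", {
  tab <- perm_table(3, 4, 10, seed = 9L, rho = 0.4)
  r1 <- maxt_permutation(tab, "adjacent_sc_ratio", n_perm = 200L, seed = 5L)
  r2 <- maxt_permutation(tab, "adjacent_sc_ratio", n_perm = 200L, seed = 5L)
  expect_identical(r1$by_rater, r2$by_rater)
  expect_identical(r1$null_max_abs_z, r2$null_max_abs_z)
  expect_length(r1$null_max_abs_z, 200L)
  expect_equal(r1$by_rater$n_datasets, rep(4L, 3L))
  expect_true(all(r1$by_rater$p_adjusted >= 1 / 201))
  expect_true(all(abs(r1$rho_by_dataset$rho) <= 1))
  # observed statistics agree with a direct slicewise computation
  for (i in seq_len(nrow(r1$rho_by_dataset))) {
    row <- r1$rho_by_dataset[i, ]
    sub <- tab[tab$rater == row$rater & tab$dataset == as.integer(row$dataset), ]
    expect_equal(row$rho, spearman_rho(sub$dsc, sub$adjacent_sc_ratio),
                 tolerance = 1e-12)
  }
  grp <- tapply(r1$rho_by_dataset$fisher_z, r1$rho_by_dataset$rater, mean)
  expect_equal(as.numeric(grp[r1$by_rater$rater]), r1$by_rater$mean_fisher_z,
               tolerance = 1e-12)
})

test_that("an observed statistic beyond every null replicate attains the floor p", {
  # perfect monotone association in every block: observed mean Fisher z is
  # at the clamp and cannot be matched by any permutation
  df <- expand.grid(slice = 1:12, rater = "A", dataset = 1:3,
                    stringsAsFactors = FALSE)
  df$dsc <- rep(seq(0.3, 0.9, length.out = 12), 3)
  df$adjacent_sc_ratio <- df$dsc * 2
  df$cv_adjacent <- 1 - df$dsc / 2
  df$included <- TRUE
  res <- maxt_permutation(df, "adjacent_sc_ratio", n_perm = 99L, seed = 2L)
  expect_equal(res$by_rater$p_adjusted, 1 / 100)
  # and the perfectly anti-monotone outcome attains the floor too (two-tailed)
  res2 <- maxt_permutation(df, "cv_adjacent", n_perm = 99L, seed = 2L)
  expect_equal(res2$by_rater$p_adjusted, 1 / 100)
  expect_lt(res2$by_rater$mean_fisher_z, 0)
})

test_that("adjusted p-values are monotone in the observed statistic magnitude", {
  tab <- perm_table(4, 5, 12, seed = 31L, rho = 0.35)
  res <- maxt_permutation(tab, "adjacent_sc_ratio", n_perm = 500L, seed = 7L)
  o <- order(abs(res$by_rater$mean_fisher_z))
  expect_true(all(diff(res$by_rater$p_adjusted[o]) <= 0))
})

test_that("rater-dataset pairs with too few slices are dropped with a message", {
  tab <- perm_table(2, 3, 8, seed = 4L)
  tab <- tab[!(tab$rater == "A" & tab$dataset == 1 & tab$slice > 2), ]
  expect_message(res <- maxt_permutation(tab, "cv_adjacent", n_perm = 50L,
                                         seed = 1L),
                 "dropped 1")
  expect_equal(res$by_rater$n_datasets[res$by_rater$rater == "A"], 2L)
  expect_equal(nrow(res$dropped), 1L)
})

test_that("single rater, single dataset reduces to an ordinary permutation test", {
  set.seed(88L)
  df <- data.frame(slice = 1:15, rater = "A", dataset = 1,
                   dsc = runif(15), cv_adjacent = runif(15), included = TRUE)
  res <- maxt_permutation(df, "cv_adjacent", n_perm = 2000L, seed = 3L)
  # oracle: direct two-tailed permutation p for one Spearman correlation,
  # Fisher-z scale, same add-one convention
  obs <- abs(fisher_z(spearman_rho(df$dsc, df$cv_adjacent)))
  set.seed(1234L)
  null <- replicate(2000, abs(fisher_z(spearman_rho(sample(df$dsc),
                                                    df$cv_adjacent))))
  p_oracle <- (1 + sum(null >= obs)) / 2001
  expect_equal(res$by_rater$p_adjusted, p_oracle, tolerance = 0.05)
})
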