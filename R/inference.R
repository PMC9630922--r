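#' Two-way ANOVA with eta-squared on a complete rater-by-dataset table
#'
#' Fits the additive model `response ~ rater + dataset` on a complete,
#' balanced design with one observation per cell, and reports per-factor F
#' statistics, degrees of freedom, p-values and eta-squared effect sizes
#' (factor sum of squares over total sum of squares). For an R x D design the
#' residual degrees of freedom are (R-1)(D-1).
#'
#' @param cells data frame with columns `rater`, `dataset` and the response.
#' @param response name of the response column, typically `"mean_logit_dsc"`
#'   or `"log_gm_wm"`.
#' @return A data frame of class `anova_table` with rows `rater`, `dataset`,
#'   `residual` and columns `term, df, sum_sq, mean_sq, statistic, p_value,
#'   eta_sq`.
#' @export
two_way_anova <- function(cells, response = "mean_logit_dsc") {
  stopifnot(is.data.frame(cells), response %in% names(cells),
            all(c("rater", "dataset") %in% names(cells)))
  df <- data.frame(rater = factor(cells$rater),
                   dataset = factor(cells$dataset),
                   y = as.numeric(cells[[response]]))
  if (anyNA(df$y)) stop("response contains missing values")
  tab <- table(df$rater, df$dataset)
  if (any(tab != 1L)) {
    stop("design must be complete with exactly one observation per rater x dataset cell")
  }
  if (nlevels(df$rater) < 2L || nlevels(df$dataset) < 2L) {
    stop("both factors need at least 2 levels")
  }
  fit <- stats::aov(y ~ rater + dataset, data = df)
  sm <- summary(fit)[[1]]
  ss <- sm[["Sum Sq"]]; dfs <- sm[["Df"]]
  ss_total <- sum(ss)
  if (ss_total <= 1e-10 * max(1, sum(df$y^2))) {
    # constant response: no variance to attribute
    out <- data.frame(term = c("rater", "dataset", "residual"),
                      df = dfs, sum_sq = 0, mean_sq = 0,
                      statistic = NA_real_, p_value = NA_real_, eta_sq = 0)
  } else {
    out <- data.frame(term = c("rater", "dataset", "residual"),
                      df = dfs, sum_sq = ss, mean_sq = ss / dfs,
                      statistic = c(sm[["F value"]][1:2], NA_real_),
                      p_value = c(sm[["Pr(>F)"]][1:2], NA_real_),
                      eta_sq = ss / ss_total)
  }
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  attr(out, "response") <- response
  out
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf("Two-way additive ANOVA on %s\n", attr(x, "response") %||% "response"))
  y <- as.data.frame(x)
  y$p_value <- ifelse(is.na(y$p_value), NA,
                      ifelse(y$p_value < 2e-16, "< 2e-16",
                             format(y$p_value, digits = 3)))
  print(y, ...)
  invisible(x)
}

#' Spearman rank correlation with average ranks for ties
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @return Correlation in \[-1, 1\], or `NA` (with a warning) when fewer than
#'   3 complete pairs remain or either variable has zero rank variance.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    warning("Spearman rho undefined: fewer than 3 complete pairs")
    return(NA_real_)
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("Spearman rho undefined: zero rank variance")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' Fisher's z transform of a correlation
#'
#' `atanh(r)` after clamping `r` into the open interval
#' `(-(1 - 1e-7), 1 - 1e-7)`, so correlations of exactly +/-1 map to large
#' finite values.
#'
#' @param r numeric vector of correlations.
#' @return Numeric vector.
#' @seealso [fisher_z_inv()]
#' @export
fisher_z <- function(r) atanh(clamp(r, -(1 - 1e-7), 1 - 1e-7))

#' Inverse Fisher z transform
#' @param z numeric vector.
#' @return Numeric vector of correlations.
#' @export
fisher_z_inv <- function(z) tanh(z)

# standardized ranks: mean 0, crossprod with another standardized-rank vector
# divided by (n - 1) gives the Spearman correlation
std_ranks <- function(v) {
  r <- rank(v)
  s <- stats::sd(r)
  if (s == 0) return(NULL)
  (r - mean(r)) / s
}

#' Max-T permutation test for slicewise correlations
#'
#' Tests, for each rater, the pooled association between slicewise Dice
#' agreement and a slicewise image-quality outcome. The observed statistic
#' per rater is the mean over datasets of Fisher's z of the Spearman
#' correlation (over slices) between DSC and the outcome within each
#' rater-dataset pair. The null distribution is built by independently
#' permuting the DSC values across slices within every rater-dataset pair
#' (slices assumed exchangeable), recomputing the pooled statistics, and
#' recording the maximum absolute value across raters; this max-T scheme
#' adjusts the two-tailed p-values for multiple comparisons while respecting
#' the dependence between raters. P-values use the add-one convention
#' `(1 + count) / (n_perm + 1)` and are therefore never smaller than
#' `1 / (n_perm + 1)`.
#'
#' Rater-dataset pairs with fewer than 3 usable slices, or with zero rank
#' variance in either variable, are dropped from pooling with a message. A
#' permuted replicate whose correlation is degenerate contributes Fisher z =
#' 0 (this cannot occur when the observed ranks are non-degenerate, since
#' permutation preserves the rank distribution).
#'
#' @param slices the `slice_metrics` data frame from [build_tables()] (or any
#'   data frame with columns `rater, dataset, slice, dsc, included` and the
#'   outcome).
#' @param outcome `"cv_adjacent"` or `"adjacent_sc_ratio"`.
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed; results are deterministic given the seed.
#' @return An object of class `maxt_result`: list with `by_rater` (data frame
#'   `rater, n_datasets, mean_fisher_z, p_adjusted`), `rho_by_dataset` (data
#'   frame of per-pair observed Spearman rho and Fisher z), `null_max_abs_z`
#'   (numeric vector of length `n_perm`), plus `outcome`, `n_perm`, `seed`
#'   and `dropped` (data frame of excluded pairs).
#' @export
maxt_permutation <- function(slices, outcome = c("cv_adjacent", "adjacent_sc_ratio"),
                             n_perm = 5000L, seed = 1L) {
  outcome <- match.arg(outcome)
  stopifnot(all(c("rater", "dataset", "dsc", outcome) %in% names(slices)),
            n_perm >= 1L)
  d <- slices
  if ("included" %in% names(d)) d <- d[d$included, , drop = FALSE]
  d <- d[is.finite(d$dsc) & is.finite(d[[outcome]]), , drop = FALSE]
  if (nrow(d) == 0L) stop("no usable slice records")
  d$block <- interaction(d$rater, d$dataset, drop = TRUE)
  blocks <- split(d, d$block)
  keep <- list(); dropped <- list()
  for (b in blocks) {
    reason <- NULL
    if (nrow(b) < 3L) {
      reason <- "fewer than 3 usable slices"
    } else {
      rx <- std_ranks(b$dsc); ry <- std_ranks(b[[outcome]])
      if (is.null(rx) || is.null(ry)) reason <- "zero rank variance"
    }
    if (is.null(reason)) {
      keep[[length(keep) + 1L]] <- list(rater = b$rater[1],
                                        dataset = b$dataset[1],
                                        n = nrow(b), rx = rx, ry = ry)
    } else {
      dropped[[length(dropped) + 1L]] <- data.frame(
        rater = b$rater[1], dataset = b$dataset[1], n_slices = nrow(b),
        reason = reason, stringsAsFactors = FALSE)
    }
  }
  if (length(dropped) > 0L) {
    message(sprintf("maxt_permutation: dropped %d rater-dataset pair(s)",
                    length(dropped)))
  }
  if (length(keep) == 0L) stop("no rater-dataset pair has enough usable slices")
  raters <- sort(unique(vapply(keep, function(k) as.character(k$rater), character(1))))
  rater_of <- match(vapply(keep, function(k) as.character(k$rater), character(1)),
                    raters)
  nb <- length(keep); nr <- length(raters)
  blocks_per_rater <- tabulate(rater_of, nr)

  obs_rho <- vapply(keep, function(k) sum(k$rx * k$ry) / (k$n - 1), numeric(1))
  obs_z <- fisher_z(obs_rho)
  obs_mean <- as.numeric(rowsum(obs_z, rater_of)) / blocks_per_rater

  set.seed(seed)
  z_sum <- matrix(0, nr, n_perm)
  for (i in seq_len(nb)) {
    k <- keep[[i]]
    n <- k$n
    # one radix sort yields n_perm independent uniform permutations
    o <- order(rep(seq_len(n_perm), each = n), stats::runif(n * n_perm))
    perm_idx <- ((o - 1L) %% n) + 1L
    m <- matrix(k$rx[perm_idx], n, n_perm)
    rho <- crossprod(m, k$ry)[, 1] / (n - 1)
    z_sum[rater_of[i], ] <- z_sum[rater_of[i], ] + fisher_z(rho)
  }
  z_mean <- z_sum / blocks_per_rater
  null_max <- apply(abs(z_mean), 2, max)
  p_adj <- vapply(abs(obs_mean),
                  function(o) (1 + sum(null_max >= o)) / (n_perm + 1),
                  numeric(1))
  structure(list(
    by_rater = data.frame(rater = raters, n_datasets = blocks_per_rater,
                          mean_fisher_z = obs_mean, p_adjusted = p_adj,
                          stringsAsFactors = FALSE),
    rho_by_dataset = data.frame(
      rater = vapply(keep, function(k) as.character(k$rater), character(1)),
      dataset = vapply(keep, function(k) as.character(k$dataset), character(1)),
      n_slices = vapply(keep, function(k) k$n, numeric(1)),
      rho = obs_rho, fisher_z = obs_z, stringsAsFactors = FALSE),
    null_max_abs_z = null_max,
    outcome = outcome, n_perm = as.integer(n_perm), seed = as.integer(seed),
    dropped = if (length(dropped)) do.call(rbind, dropped) else NULL),
    class = "maxt_result")
}

#' @export
print.maxt_result <- function(x, ...) {
  cat(sprintf("Max-T permutation test: DSC vs %s (%d permutations, seed %d)\n",
              x$outcome, x$n_perm, x$seed))
  print(transform(x$by_rater,
                  p_adjusted = format.pval(p_adjusted, digits = 3)), ...)
  invisible(x)
}
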