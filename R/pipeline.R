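#' Marginal means with normal-approximation 95% confidence intervals
#'
#' Row and column means of a complete rater-by-dataset table, each with a
#' 95% confidence interval `mean +/- 1.96 * sd / sqrt(m)` over the margin of
#' size m. A margin of size 1 is reported as the point value (no interval).
#'
#' @param mat numeric matrix (raters in rows, datasets in columns), complete.
#' @return List with data frames `rows` and `cols` (columns `level, mean,
#'   lower, upper, n`) and the scalar `grand_mean`.
#' @export
marginal_means <- function(mat) {
  stopifnot(is.matrix(mat), !anyNA(mat))
  margin_df <- function(v_mean, v_sd, n, levels) {
    half <- ifelse(n > 1, 1.96 * v_sd / sqrt(n), 0)
    data.frame(level = levels, mean = v_mean,
               lower = v_mean - half, upper = v_mean + half, n = n,
               stringsAsFactors = FALSE)
  }
  rows <- margin_df(rowMeans(mat), apply(mat, 1, stats::sd), ncol(mat),
                    rownames(mat) %||% as.character(seq_len(nrow(mat))))
  cols <- margin_df(colMeans(mat), apply(mat, 2, stats::sd), nrow(mat),
                    colnames(mat) %||% as.character(seq_len(ncol(mat))))
  rownames(rows) <- rownames(cols) <- NULL
  list(rows = rows, cols = cols, grand_mean = mean(mat))
}

# long (rater, dataset, value) -> complete matrix raters x datasets
cells_to_matrix <- function(df, value) {
  raters <- unique(df$rater); datasets <- sort(unique(df$dataset))
  mat <- matrix(NA_real_, length(raters), length(datasets),
                dimnames = list(raters, as.character(datasets)))
  mat[cbind(match(df$rater, raters), match(df$dataset, datasets))] <- df[[value]]
  if (anyNA(mat)) stop(sprintf("incomplete rater x dataset table for %s", value))
  mat
}

# sort rows and columns by ascending margin (used for all report heatmaps,
# with the ordering fixed by the Dice table)
sort_by_margin <- function(mat) {
  mat[order(rowMeans(mat)), order(colMeans(mat)), drop = FALSE]
}

# fixed-effects combination of participant-level z maps: sum / sqrt(k)
group_map <- function(bundle, rater, side, analysis_mask) {
  dims <- dim(bundle$datasets[[1]]$phantom$cord_mask)
  acc <- array(0, dims)
  k <- length(bundle$datasets)
  for (d in seq_len(k)) {
    acc <- acc + get_activation_map(bundle, d, rater, side)$z
  }
  activation_map(acc / sqrt(k), analysis_mask, stimulus_side = side,
                 level = "group")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: study simulation (or loading), metric tables, the two
#' ANOVAs (mean logit Dice over the raters, log GM:WM contrast over the
#' raters plus reference), the max-T permutation tests of slicewise Dice
#' against both image-quality outcomes, participant-level ipsilateral
#' activation-map correlations against the reference, group-level map
#' correlations by side and condition, and voxelwise standardization of the
#' reference group maps against the rater distribution. Heatmap tables are
#' ordered by ascending marginal mean logit Dice. Fully reproducible from
#' the configuration and seeds.
#'
#' @param config a [study_config()], an existing `study_bundle`, or the path
#'   to a study directory written by [write_study()].
#' @param out_dir optional directory for CSV/JSON outputs (and, when the
#'   study is simulated here, the study volumes under `<out_dir>/study`).
#' @param n_trim,n_dilate see [build_tables()].
#' @param n_perm,perm_seed see [maxt_permutation()].
#' @param z_thresh activation threshold used for the reported active-voxel
#'   counts.
#' @param corr_method `"pearson"` or `"spearman"` spatial correlation.
#' @param write_study_volumes logical; write the simulated NIfTI volumes
#'   under `out_dir/study` (ignored when `out_dir` is `NULL`).
#' @return An object of class `report_bundle`; see Details.
#' @details The returned list contains `tables` (slice and cell metric data
#'   frames), `anova_dsc`, `anova_gmwm`, `perm` (one `maxt_result` per
#'   outcome), `participant_corr`, `group_corr`, `group_standardized`,
#'   `heatmaps` (sorted matrices with marginal means and 95% CIs),
#'   `active_voxels`, and a `settings` provenance block echoed into every
#'   written output.
#' @export
run_all <- function(config = study_config(), out_dir = NULL,
                    n_trim = 1L, n_dilate = 2L,
                    n_perm = 5000L, perm_seed = 17L,
                    z_thresh = 2.3, corr_method = "pearson",
                    write_study_volumes = FALSE) {
  stage <- function(name, expr) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  bundle <- stage("simulate", {
    if (inherits(config, "study_bundle")) config
    else if (is.character(config)) read_study(config)
    else generate_study(config,
                        out_dir = if (!is.null(out_dir) && write_study_volumes)
                          file.path(out_dir, "study") else NULL)
  })
  cfg <- bundle$config
  rn <- names(cfg$rater_models)
  tabs <- stage("metrics", build_tables(bundle, n_trim, n_dilate))

  anova_dsc <- stage("anova-dsc", two_way_anova(
    tabs$rater_dataset[tabs$rater_dataset$rater != "REF", ],
    response = "mean_logit_dsc"))
  anova_gmwm <- stage("anova-gmwm", two_way_anova(
    tabs$rater_dataset, response = "log_gm_wm"))

  perm <- stage("permtest", list(
    cv_adjacent = maxt_permutation(tabs$slice_metrics, "cv_adjacent",
                                   n_perm = n_perm, seed = perm_seed),
    adjacent_sc_ratio = maxt_permutation(tabs$slice_metrics,
                                         "adjacent_sc_ratio",
                                         n_perm = n_perm,
                                         seed = perm_seed + 1L)))

  participant_corr <- stage("activation-participant", {
    rows <- list()
    for (d in seq_along(bundle$datasets)) {
      part <- hemicord_partition(bundle$datasets[[d]]$phantom$cord_mask)
      for (side in c("left", "right")) {
        ipsi <- condition_regions(part, side)$ipsilateral
        ref_map <- get_activation_map(bundle, d, "REF", side)
        for (r in rn) {
          fz <- spatial_correlation(get_activation_map(bundle, d, r, side),
                                    ref_map, ipsi, method = corr_method)
          rows[[length(rows) + 1L]] <- data.frame(
            rater = r, dataset = d, side = side, fisher_z = fz,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })

  group <- stage("activation-group", {
    inter <- Reduce(`&`, lapply(bundle$datasets,
                                function(ds) ds$phantom$cord_mask))
    part <- hemicord_partition(inter)
    gmaps <- list()
    for (r in c("REF", rn)) {
      gmaps[[r]] <- list(left = group_map(bundle, r, "left", inter),
                        right = group_map(bundle, r, "right", inter))
    }
    corr_rows <- list(); std_rows <- list(); act_rows <- list()
    for (side in c("left", "right")) {
      regions <- condition_regions(part, side)
      for (cond in c("ipsilateral", "contralateral")) {
        reg <- regions[[cond]]
        for (r in rn) {
          fz <- spatial_correlation(gmaps[[r]][[side]], gmaps$REF[[side]],
                                    reg, method = corr_method)
          corr_rows[[length(corr_rows) + 1L]] <- data.frame(
            rater = r, side = side, condition = cond, fisher_z = fz,
            stringsAsFactors = FALSE)
        }
        std <- standardize_reference(gmaps$REF[[side]],
                                     lapply(rn, function(r) gmaps[[r]][[side]]),
                                     reg)
        std_rows[[length(std_rows) + 1L]] <- data.frame(
          side = side, condition = cond, z_bar = std$z_bar, sd_z = std$sd_z,
          n_voxels = std$n_voxels, stringsAsFactors = FALSE)
      }
      for (r in c("REF", rn)) {
        act_rows[[length(act_rows) + 1L]] <- data.frame(
          rater = r, side = side,
          n_active = sum(threshold_map(gmaps[[r]][[side]], z_thresh)),
          stringsAsFactors = FALSE)
      }
    }
    list(corr = do.call(rbind, corr_rows), std = do.call(rbind, std_rows),
         active = do.call(rbind, act_rows), maps = gmaps)
  })

  heatmaps <- stage("report", {
    dsc_mat <- cells_to_matrix(
      tabs$rater_dataset[tabs$rater_dataset$rater != "REF", ],
      "mean_logit_dsc")
    dsc_sorted <- sort_by_margin(dsc_mat)
    rater_order <- rownames(dsc_sorted); dataset_order <- colnames(dsc_sorted)
    gm_mat <- cells_to_matrix(tabs$rater_dataset, "log_gm_wm")
    # keep the Dice ordering, reference row on top
    gm_sorted <- gm_mat[c(rater_order, "REF"), dataset_order, drop = FALSE]
    pc <- stats::aggregate(fisher_z ~ rater + dataset, participant_corr, mean)
    pz_mat <- cells_to_matrix(pc, "fisher_z")[rater_order, dataset_order,
                                              drop = FALSE]
    list(dsc = list(values = dsc_sorted, margins = marginal_means(dsc_sorted)),
         gm_wm = list(values = gm_sorted, margins = marginal_means(gm_sorted)),
         participant_z = list(values = pz_mat,
                              margins = marginal_means(pz_mat)))
  })

  settings <- list(n_datasets = cfg$n_datasets, raters = rn,
                   grid_shape = cfg$grid_shape, master_seed = cfg$master_seed,
                   n_trim = n_trim, n_dilate = n_dilate, n_perm = n_perm,
                   perm_seed = perm_seed, z_thresh = z_thresh,
                   corr_method = corr_method)
  report <- structure(list(tables = tabs, anova_dsc = anova_dsc,
                           anova_gmwm = anova_gmwm, perm = perm,
                           participant_corr = participant_corr,
                           group_corr = group$corr,
                           group_standardized = group$std,
                           active_voxels = group$active,
                           group_maps = group$maps,
                           heatmaps = heatmaps,
                           settings = settings),
                      class = "report_bundle")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write the tabular outputs of a report bundle
#'
#' @param report a `report_bundle` from [run_all()].
#' @param dir output directory (created if needed).
#' @return The vector of written file paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  perm_df <- function(p) cbind(outcome = p$outcome, p$by_rater)
  paths <- c(
    wr(report$tables$slice_metrics, "slice_metrics.csv"),
    wr(report$tables$rater_dataset, "rater_dataset.csv"),
    wr(as.data.frame(report$anova_dsc), "anova_dsc.csv"),
    wr(as.data.frame(report$anova_gmwm), "anova_gmwm.csv"),
    wr(perm_df(report$perm$cv_adjacent), "perm_cv_adjacent.csv"),
    wr(perm_df(report$perm$adjacent_sc_ratio), "perm_adjacent_sc_ratio.csv"),
    wr(report$participant_corr, "participant_corr.csv"),
    wr(report$group_corr, "group_corr.csv"),
    wr(report$group_standardized, "group_standardized.csv"),
    wr(report$active_voxels, "active_voxels.csv"))
  jsonlite::write_json(report$settings, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, file.path(dir, "provenance.json")))
}

#' @export
print.report_bundle <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<report_bundle> %d datasets x %d raters (+REF)\n",
              s$n_datasets, length(s$raters)))
  cat("ANOVA (mean logit DSC):\n"); print(x$anova_dsc)
  cat("ANOVA (log GM:WM):\n"); print(x$anova_gmwm)
  cat("Group-level spatial correlations:\n")
  print(summarize_fisher_table(x$group_corr))
  invisible(x)
}

#' Heatmap of a rater-by-dataset table
#'
#' Color map with marginal means, mirroring the standard presentation of
#' rater-by-dataset agreement tables. Requires ggplot2.
#'
#' @param mat numeric matrix (raters x datasets), e.g. a `values` element of
#'   `report$heatmaps`.
#' @param title plot title.
#' @return A ggplot object.
#' @export
plot_rater_dataset_map <- function(mat, title = "") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- data.frame(rater = factor(rep(rownames(mat), ncol(mat)),
                                  levels = rownames(mat)),
                   dataset = factor(rep(colnames(mat), each = nrow(mat)),
                                    levels = colnames(mat)),
                   value = as.vector(mat))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dataset, y = .data$rater,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = title, fill = NULL) +
    ggplot2::theme_minimal()
}
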