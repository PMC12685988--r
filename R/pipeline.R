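#' Run the end-to-end analysis pipeline
#'
#' Simulates (or ingests) a cohort of load-test recordings, converts each
#' to a corrected stress-strain curve, computes CS/CE profiles, classifies
#' the crush pattern, merges CT density, and writes the cohort tables:
#' `results.csv` (one row per nodule), `quartile_table.csv`,
#' `summaries.csv`, `correlations.csv`, `comparisons.csv`, figures, and a
#' `config.yaml` echo with the seed and R version so a run is fully
#' reproducible. No timestamps enter the data files.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of class `crush_analysis` with the in-memory
#'   tables (`results`, `quartile_table`, `summaries`, `correlations`,
#'   `comparisons`, `nodules`, `out_dir`).
#' @examples
#' \donttest{
#' cfg <- run_config(cohort = cohort_spec(n_nodules = 6, seed = 3),
#'                   figures = FALSE)
#' res <- run_pipeline(cfg)
#' res$results
#' }
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$mode == "simulate") {
    cohort <- simulate_cohort(config$cohort, machine = config$machine)
    nodules <- cohort$nodules
    recordings <- cohort$recordings
  } else {
    nod_path <- file.path(config$input_dir, "nodules.csv")
    nodules <- .stage("ingest", "nodules.csv", read_nodule_table(nod_path))
    recordings <- lapply(nodules$nodule_id, function(id) {
      .stage("ingest", id,
             read_load_test(file.path(config$input_dir, paste0(id, ".csv")),
                            machine = config$machine, nodule_id = id))
    })
    names(recordings) <- nodules$nodule_id
  }

  profiles <- vector("list", nrow(nodules))
  classes <- vector("list", nrow(nodules))
  grids <- vector("list", nrow(nodules))
  for (i in seq_len(nrow(nodules))) {
    id <- nodules$nodule_id[i]
    curve <- .stage("mechanics", id,
                    to_stress_strain(recordings[[id]], nodules[i, ],
                                     preload_threshold = config$preload_threshold_n_mm2))
    grid <- .stage("resample", id,
                   resample_to_grid(curve, increment = config$grid_increment))
    profiles[[i]] <- .stage("stiffness", id,
                            stiffness_profile(curve, levels = config$levels))
    classes[[i]] <- .stage("classify", id,
                           classify_phase(grid,
                                          area_threshold = config$area_ratio_threshold,
                                          slope_window = config$slope_window,
                                          baseline = config$classifier_baseline))
    grids[[i]] <- grid
  }
  profiles <- bind_rows(profiles)
  classes <- bind_rows(classes)
  names(grids) <- nodules$nodule_id

  per_nodule <- left_join(profiles, classes, by = "nodule_id")
  results <- write_results(per_nodule, nodules,
                           path = file.path(config$out_dir, "results.csv"))

  qtable <- stress_quartile_table(grids, quantile_type = config$quantile_type)
  readr::write_csv(qtable, file.path(config$out_dir, "quartile_table.csv"))

  summaries <- stiffness_summary(profiles, quantile_type = config$quantile_type)
  readr::write_csv(summaries, file.path(config$out_dir, "summaries.csv"))

  correlations <- NULL
  if (any(!is.na(nodules$ct_hu))) {
    correlations <- correlate_with_ct(profiles, nodules)
    readr::write_csv(correlations, file.path(config$out_dir, "correlations.csv"))
  }

  comparisons <- NULL
  lab <- results$label
  if (!all(is.na(results$dialysis)) && length(unique(lab[!is.na(lab)])) == 2) {
    cmp <- compare_groups(results[!is.na(lab), ], "label", "dialysis")
    comparisons <- dplyr::bind_cols(
      glance(cmp),
      tidyr::pivot_wider(tidy(cmp), names_from = "group",
                         values_from = c("n", "events", "proportion"))
    )
    readr::write_csv(comparisons, file.path(config$out_dir, "comparisons.csv"))
  }

  if (isTRUE(config$figures)) {
    fig_dir <- file.path(config$out_dir, "figures")
    dir.create(fig_dir, showWarnings = FALSE)
    .save_fig(plot_quartile_band(qtable), file.path(fig_dir, "stress_quartiles.png"))
    .save_fig(plot_stiffness_box(profiles), file.path(fig_dir, "cs_ce_boxplots.png"))
    if (!is.null(correlations)) {
      .save_fig(plot_ct_scatter(profiles, nodules),
                file.path(fig_dir, "ct_scatter.png"))
    }
  }

  .write_run_log(config)

  structure(list(results = results, quartile_table = qtable,
                 summaries = summaries, correlations = correlations,
                 comparisons = comparisons, nodules = nodules,
                 out_dir = config$out_dir),
            class = "crush_analysis")
}

.stage <- function(stage, id, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed for nodule '%s': %s",
                  stage, id, conditionMessage(e)),
          class = "crushcurve_pipeline_error", parent = e)
  })
}

.save_fig <- function(p, path) {
  tryCatch(
    suppressMessages(ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 150)),
    error = function(e) warn(paste0("could not write figure ", path, ": ",
                                    conditionMessage(e)))
  )
}

.config_to_list <- function(x) {
  if (is.list(x)) lapply(unclass(x), .config_to_list) else x
}

.write_run_log <- function(config) {
  echo <- .config_to_list(config)
  echo$provenance <- list(r_version = as.character(getRversion()),
                          package_version = as.character(utils::packageVersion("crushcurve")))
  yaml::write_yaml(echo, file.path(config$out_dir, "config.yaml"))
  invisible(NULL)
}

#' @export
print.crush_analysis <- function(x, ...) {
  cat(sprintf("<crush_analysis> %d nodules -> %s\n", nrow(x$results), x$out_dir))
  print(glance(x))
  invisible(x)
}

#' Tidy the per-nodule results of a pipeline run
#'
#' @param x A `crush_analysis` from [run_pipeline()].
#' @param ... Unused.
#' @return The per-nodule results tibble.
#' @method tidy crush_analysis
#' @export
tidy.crush_analysis <- function(x, ...) x$results

#' One-row summary of a pipeline run
#'
#' @param x A `crush_analysis` from [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble: nodule counts by label, median CS10/CS50,
#'   and the dialysis contrast p value when computed.
#' @method glance crush_analysis
#' @export
glance.crush_analysis <- function(x, ...) {
  lab <- x$results$label
  tibble(
    n_nodules = nrow(x$results),
    n_three_phase = sum(lab == "three_phase", na.rm = TRUE),
    n_gradual = sum(lab == "gradual", na.rm = TRUE),
    n_unclassifiable = sum(is.na(lab)),
    median_cs10 = median(x$results$CS10, na.rm = TRUE),
    median_cs50 = if ("CS50" %in% names(x$results))
      median(x$results$CS50, na.rm = TRUE) else NA_real_,
    dialysis_p = if (!is.null(x$comparisons)) x$comparisons$p_value else NA_real_
  )
}
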