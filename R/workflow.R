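# End-to-end study orchestration -------------------------------------------
#
# simulate -> process -> gate -> calibrate -> report, driven by one nested
# configuration and one master seed.  All rule constants (7 crossings,
# 350-570 Hz band, 3 valid pulses, k_p = 2, 5 s pre-evaluation) live in the
# configuration with their standard defaults and are never hard-coded in the
# stage operations.

#' Build a study run configuration
#'
#' @param n_subjects number of virtual subjects (two eyes each).
#' @param sim a [sim_config()]; its `n_subjects` and `rng_seed` are
#'   overridden by `n_subjects` and `master_seed`.
#' @param quality list with `min_crossings`, `band`, `min_valid_pulses`,
#'   `touchdown_threshold`, `pressure_threshold`.
#' @param ann list with `architecture`, `n_trials`, `keep_fraction`,
#'   `split_fractions`, `features`, `epochs`, `lr`.
#' @param k_p coverage factor for the uncertainty reports.
#' @param master_seed single seed from which every stage seed is derived
#'   via [child_seed()].
#' @param write_recordings write every raw recording (CSV + JSON sidecar)
#'   into the run directory.
#' @param make_plots write regression and Bland-Altman plot files.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(n_subjects = 20,
                       sim = sim_config(n_subjects = n_subjects),
                       quality = list(min_crossings = 7, band = c(350, 570),
                                      min_valid_pulses = 3,
                                      touchdown_threshold = 50,
                                      pressure_threshold = 300),
                       ann = list(architecture = c(7, 10), n_trials = 200,
                                  keep_fraction = 0.1,
                                  split_fractions = c(0.7, 0.15, 0.15),
                                  features = tonocal_default_features,
                                  epochs = 500, lr = 0.02),
                       k_p = 2,
                       master_seed = 1,
                       write_recordings = FALSE,
                       make_plots = FALSE) {
  assert_count(n_subjects, "n_subjects")
  assert_number(k_p, "k_p", lo = 1e-9)
  assert_count(quality$min_crossings, "quality$min_crossings")
  assert_count(quality$min_valid_pulses, "quality$min_valid_pulses")
  if (length(quality$band) != 2L || any(quality$band <= 0)) {
    stop("configuration error: 'quality$band' must be two positive frequencies",
         call. = FALSE)
  }
  sim$n_subjects <- as.integer(n_subjects)
  sim$rng_seed <- child_seed(master_seed, 1)
  structure(list(n_subjects = as.integer(n_subjects), sim = sim,
                 quality = quality, ann = ann, k_p = k_p,
                 master_seed = master_seed,
                 write_recordings = isTRUE(write_recordings),
                 make_plots = isTRUE(make_plots)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; omitted keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- run_config()
  sim_args <- y$sim %||% list()
  if (!is.null(y$n_subjects)) sim_args$n_subjects <- y$n_subjects
  sim <- do.call(sim_config, sim_args)
  run_config(
    n_subjects = y$n_subjects %||% base$n_subjects,
    sim = sim,
    quality = modifyList(base$quality, y$quality %||% list()),
    ann = modifyList(base$ann, y$ann %||% list()),
    k_p = y$k_p %||% base$k_p,
    master_seed = y$master_seed %||% base$master_seed,
    write_recordings = y$write_recordings %||% base$write_recordings,
    make_plots = y$make_plots %||% base$make_plots
  )
}

#' Run a complete synthetic study
#'
#' Simulates the cohort and recordings, extracts features, applies the
#' validity gate, trains the trial ensemble and writes all artifacts
#' (cohort CSV, per-pulse and per-measurement feature CSVs, success-rate
#' summary CSV, best-model JSON, agreement JSON, optional plots, and a
#' manifest with the master seed and MD5 hash of every artifact) into
#' `out_dir`.  Fully deterministic for a fixed `master_seed`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with `cohort`, `measurements`, `pulses`,
#'   `categories`, `summary`, `feature_table`, `ensemble`, `agreement`,
#'   `table2`, `manifest`.
#' @export
run_study <- function(config = run_config(), out_dir = tempfile("tonocal_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  q <- config$quality

  cohort <- draw_cohort(config$sim)

  res <- lapply(seq_len(nrow(cohort)), function(i) {
    rec <- synthesize_recording(cohort[i, ], cohort[i, ], config$sim,
                                seed = child_seed(config$master_seed, 100 + i))
    if (config$write_recordings) write_recording(rec, file.path(out_dir, "recordings"))
    process_recording(rec, min_crossings = q$min_crossings, band = q$band,
                      touchdown_threshold = q$touchdown_threshold,
                      pressure_threshold = q$pressure_threshold)
  })
  pulses <- do.call(rbind, lapply(res, `[[`, "pulses"))
  measurements <- do.call(rbind, lapply(res, `[[`, "measurement"))

  categories <- classify_measurement(measurements,
                                     min_valid_pulses = q$min_valid_pulses)
  summary <- summarize_cohort(categories)
  feats <- build_feature_table(cohort, measurements, categories)

  ann <- config$ann
  ensemble <- run_trials(feats, architecture = ann$architecture,
                         n_trials = ann$n_trials,
                         keep_fraction = ann$keep_fraction,
                         seed = child_seed(config$master_seed, 2),
                         split_fractions = ann$split_fractions,
                         features = ann$features,
                         epochs = ann$epochs %||% 500, lr = ann$lr %||% 0.02)
  agr <- ensemble_agreement(ensemble, k_p = config$k_p)

  # ---- artifacts ----
  paths <- c(cohort = "cohort.csv", measurements = "measurement_features.csv",
             pulses = "pulse_features.csv", categories = "categories.csv",
             table2 = "table2.csv", agreement = "agreement.json",
             model = "best_model.json")
  paths <- setNames(file.path(out_dir, paths), names(paths))
  write.csv(cohort, paths["cohort"], row.names = FALSE)
  write.csv(measurements, paths["measurements"], row.names = FALSE)
  write.csv(pulses, paths["pulses"], row.names = FALSE)
  write.csv(categories, paths["categories"], row.names = FALSE)
  write.csv(summary$table, paths["table2"], row.names = FALSE)
  best_idx <- with(ensemble$stats, trial[selected][which.min(score[selected])])
  save_model(ensemble$models[[best_idx]], paths["model"])
  rep <- agr$ensemble_report
  jsonlite::write_json(list(
    n_test = rep$n, bias = rep$bias, sd_diff = rep$sd_diff, k_p = rep$k_p,
    expanded_uncertainty = rep$expanded_uncertainty,
    loa = c(rep$loa_lower, rep$loa_upper),
    slope = rep$slope, intercept = rep$intercept, r = rep$r,
    meets_iso_limit = rep$meets_iso_limit,
    mean_slope_over_selected = agr$slope_mean,
    sd_slope_over_selected = agr$slope_sd,
    mean_u_over_selected = agr$u_mean,
    difference_orientation = "prediction - reference"
  ), paths["agreement"], auto_unbox = TRUE, digits = NA)
  if (config$make_plots) {
    p1 <- file.path(out_dir, "regression.pdf")
    p2 <- file.path(out_dir, "bland_altman.pdf")
    ggplot2::ggsave(p1, plot_regression(rep), width = 5, height = 4)
    ggplot2::ggsave(p2, plot_bland_altman(rep), width = 5, height = 4)
    paths <- c(paths, regression_plot = p1, bland_altman_plot = p2)
  }
  manifest <- data.frame(artifact = names(paths),
                         file = basename(unname(paths)),
                         md5 = unname(tools::md5sum(unname(paths))),
                         stringsAsFactors = FALSE)
  manifest_obj <- list(master_seed = config$master_seed,
                       n_subjects = config$n_subjects,
                       package_version = as.character(utils::packageVersion("tonocal")),
                       artifacts = manifest)
  jsonlite::write_json(manifest_obj, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(cohort = cohort, measurements = measurements, pulses = pulses,
                 categories = categories, summary = summary,
                 feature_table = feats, ensemble = ensemble, agreement = agr,
                 table2 = summary$table, manifest = manifest_obj,
                 out_dir = out_dir))
}

#' Format a success-rate (Table-2 style) summary
#'
#' Accepts either per-measurement categories (a data.frame with a
#' `category` column and one row per measurement, or a path to such a CSV)
#' or pre-tabulated counts (a data.frame with `category` and `count`
#' columns, or a named numeric vector), and returns counts with
#' one-decimal percentage shares.
#'
#' @param x categories, counts, or a CSV path.
#' @return data.frame with columns `category`, `count`, `share_percent`; a
#'   total row is prepended.  When a `self_administered` column is present
#'   the self-administered success rate is attached as attribute
#'   `self_success_rate_percent`.
#' @export
make_table2 <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("format error: no such file: ", x, call. = FALSE)
    x <- read.csv(x, stringsAsFactors = FALSE)
  }
  if (is.numeric(x) && !is.null(names(x))) {
    x <- data.frame(category = names(x), count = as.numeric(x),
                    stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x) || is.null(x$category)) {
    stop("format error: missing column 'category'", call. = FALSE)
  }
  if (nrow(x) == 0L) stop("input error: empty input", call. = FALSE)
  self_rate <- NA_real_
  if (!is.null(x$count)) {
    counts <- x[, c("category", "count")]
  } else {
    cs <- summarize_cohort(x)
    counts <- cs$table[, c("category", "count")]
    self_rate <- cs$self_success_rate_percent
  }
  total <- sum(counts$count)
  out <- rbind(data.frame(category = "total", count = total,
                          share_percent = 100.0),
               data.frame(category = counts$category, count = counts$count,
                          share_percent = round(100 * counts$count / total, 1)))
  rownames(out) <- NULL
  attr(out, "self_success_rate_percent") <- self_rate
  out
}
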