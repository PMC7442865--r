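# Validity gating ----------------------------------------------------------
#
# Expectation ranges for a successful measurement: every usable signal pulse
# needs at least `min_crossings` zero crossings and a frequency inside the
# validity band (closed interval), must not be clipped at the sensor rail,
# and at least `min_valid_pulses` valid pulses are required per measurement.

#' Apply the per-pulse validity rules
#'
#' A pulse is valid iff its zero-crossing count is at least `min_crossings`,
#' its frequency lies inside the closed `band`, and it is not clipped.  An
#' undefined frequency counts as out of band.
#'
#' @param pf per-pulse feature table (see [pulse_features()]); zero rows
#'   allowed.
#' @param min_crossings minimum zero-crossing count (default 7).
#' @param band frequency validity band in Hz, closed interval (default
#'   `c(350, 570)`).
#' @return `pf` with logical `valid` and character `invalid_reasons`
#'   (comma-separated subset of `too_few_crossings`, `out_of_band`,
#'   `clipped`; empty when valid) columns.
#' @export
validate_pulse <- function(pf, min_crossings = 7, band = c(350, 570)) {
  stopifnot(length(band) == 2L, band[1] <= band[2])
  n <- nrow(pf)
  if (n == 0L) {
    pf$valid <- logical(0)
    pf$invalid_reasons <- character(0)
    return(pf)
  }
  too_few <- pf$n_zero_crossings < min_crossings
  oob <- is.na(pf$frequency) | pf$frequency < band[1] | pf$frequency > band[2]
  clip <- isTRUE_vec(pf$clipped)
  reasons <- character(n)
  for (i in seq_len(n)) {
    r <- c(if (too_few[i]) "too_few_crossings",
           if (oob[i]) "out_of_band",
           if (clip[i]) "clipped")
    reasons[i] <- paste(r, collapse = ",")
  }
  pf$valid <- !(too_few | oob | clip)
  pf$invalid_reasons <- reasons
  pf
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Classify one (or several) measurements into the success-rate taxonomy
#'
#' Categories, in precedence order: `no_start` (no touchdown pattern or no
#' pulses detected at all), `pressure_deviation` (unusually large chamber-
#' pressure fluctuation during the evaluation window), `quality_fail`
#' (fewer than `min_valid_pulses` valid pulses), else
#' `expectancy_compliant`.
#'
#' @param mf measurement feature table (rows from
#'   [summarize_measurement()]).
#' @param min_valid_pulses minimum number of valid pulses (default 3).
#' @return data.frame with columns `measurement_id`, `category`,
#'   `self_administered` (if present in `mf`).
#' @export
classify_measurement <- function(mf, min_valid_pulses = 3) {
  category <- ifelse(!mf$touchdown_detected | mf$n_pulses_total == 0L, "no_start",
              ifelse(mf$pressure_deviation_flag, "pressure_deviation",
              ifelse(mf$n_pulses_valid < min_valid_pulses, "quality_fail",
                     "expectancy_compliant")))
  out <- data.frame(measurement_id = mf$measurement_id,
                    category = category,
                    stringsAsFactors = FALSE)
  if (!is.null(mf$self_administered)) out$self_administered <- mf$self_administered
  out
}

tonocal_categories <- c("expectancy_compliant", "no_start", "quality_fail",
                        "pressure_deviation")

#' Summarize the usability of a cohort of measurements
#'
#' Per-category counts and percentage shares (one decimal), plus the
#' self-administered success rate: the fraction of self-administered
#' measurements that did start (i.e. are not `no_start`).
#'
#' @param categories data.frame from [classify_measurement()]; a
#'   `self_administered` logical column is used when present.
#' @return object of class `cohort_summary`: list with `table` (columns
#'   `category`, `count`, `share_percent`), `total`, `n_self`, `n_assisted`,
#'   `self_success_rate_percent`.
#' @export
summarize_cohort <- function(categories) {
  if (is.null(categories) || nrow(categories) == 0L) {
    stop("input error: empty category list", call. = FALSE)
  }
  bad <- setdiff(unique(categories$category), tonocal_categories)
  if (length(bad)) {
    stop("input error: unknown category ", paste(bad, collapse = ", "), call. = FALSE)
  }
  total <- nrow(categories)
  counts <- vapply(tonocal_categories,
                   function(k) sum(categories$category == k), 0L)
  tab <- data.frame(category = tonocal_categories,
                    count = unname(counts),
                    share_percent = round(100 * unname(counts) / total, 1),
                    stringsAsFactors = FALSE)
  self <- categories$self_administered
  if (is.null(self)) self <- rep(NA, total)
  n_self <- sum(isTRUE_vec(self))
  n_assisted <- sum(!is.na(self) & !self)
  rate <- if (n_self > 0) {
    round(100 * sum(isTRUE_vec(self) & categories$category != "no_start") / n_self, 1)
  } else NA_real_
  structure(list(table = tab, total = total, n_self = n_self,
                 n_assisted = n_assisted,
                 self_success_rate_percent = rate),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort usability summary (n = %d)\n", x$total))
  print(rbind(data.frame(category = "total", count = x$total,
                         share_percent = 100.0),
              x$table), row.names = FALSE)
  if (!is.na(x$self_success_rate_percent)) {
    cat(sprintf("self-administered: %d (success rate %.1f%%), assisted: %d\n",
                x$n_self, x$self_success_rate_percent, x$n_assisted))
  }
  invisible(x)
}
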