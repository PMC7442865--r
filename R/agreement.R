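# Agreement analysis -------------------------------------------------------
#
# Regression sensitivity and Bland-Altman expanded measurement uncertainty
# between predicted and reference IOP.  Differences are oriented
# prediction - reference; the expanded uncertainty uses the coverage factor
# k_p exactly (default 2, ~95 % coverage), and the SD of differences uses
# the n-1 denominator.

#' Least-squares regression of prediction on reference
#'
#' @param reference reference-tonometer IOP values, mm Hg.
#' @param prediction device IOP predictions, mm Hg.
#' @return list with `slope`, `intercept`, `r` (Pearson correlation), `n`.
#' @export
regression_analysis <- function(reference, prediction) {
  n <- length(reference)
  if (n != length(prediction)) stop("input error: length mismatch", call. = FALSE)
  if (n < 3) stop("input error: at least 3 pairs required", call. = FALSE)
  if (sd(reference) < 1e-12) {
    stop("degenerate-input error: constant reference values", call. = FALSE)
  }
  fit <- ls_line(reference, prediction)
  list(slope = unname(fit["slope"]), intercept = unname(fit["intercept"]),
       r = cor(reference, prediction), n = n)
}

#' Bland-Altman agreement report
#'
#' Computes the differences \eqn{d_i = prediction_i - reference_i}, their
#' mean (bias), sample SD (n-1 denominator), the expanded measurement
#' uncertainty \eqn{U = k_p \cdot SD(d)} and the limits of agreement
#' \eqn{bias \pm U}.  Intended to be evaluated on held-out test data only.
#'
#' @inheritParams regression_analysis
#' @param k_p coverage factor (default 2).
#' @return object of class `agreement_report`: list with `n`, `bias`,
#'   `sd_diff`, `k_p`, `expanded_uncertainty`, `loa_lower`, `loa_upper`,
#'   `meets_iso_limit` (U < 5 mm Hg), plus the regression fields `slope`,
#'   `intercept`, `r`.
#' @export
bland_altman <- function(reference, prediction, k_p = 2) {
  n <- length(reference)
  if (n != length(prediction)) stop("input error: length mismatch", call. = FALSE)
  if (n < 3) stop("input error: at least 3 pairs required", call. = FALSE)
  d <- prediction - reference
  bias <- mean(d)
  s <- sd(d)
  u <- k_p * s
  reg <- if (sd(reference) > 1e-12) regression_analysis(reference, prediction)
         else list(slope = NA_real_, intercept = NA_real_, r = NA_real_, n = n)
  structure(list(n = n, bias = bias, sd_diff = s, k_p = k_p,
                 expanded_uncertainty = u,
                 loa_lower = bias - u, loa_upper = bias + u,
                 meets_iso_limit = u < 5,
                 slope = reg$slope, intercept = reg$intercept, r = reg$r,
                 reference = reference, prediction = prediction),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d, differences = prediction - reference)\n", x$n))
  cat(sprintf("  bias %.2f mm Hg, SD of differences %.2f mm Hg\n", x$bias, x$sd_diff))
  cat(sprintf("  expanded uncertainty U = k_p * SD = %.2f mm Hg (k_p = %g)%s\n",
              x$expanded_uncertainty, x$k_p,
              if (x$meets_iso_limit) " [< 5 mm Hg]" else " [>= 5 mm Hg]"))
  cat(sprintf("  limits of agreement [%.2f, %.2f] mm Hg\n", x$loa_lower, x$loa_upper))
  if (is.finite(x$slope %||% NA)) {
    cat(sprintf("  regression: slope %.3f, intercept %.2f mm Hg, R %.3f\n",
                x$slope, x$intercept, x$r))
  }
  invisible(x)
}

#' Agreement statistics of a trial ensemble on held-out data
#'
#' Produces a per-selected-model agreement report on the test data, then the
#' mean and SD of the regression slopes and of the expanded uncertainties
#' across the selected models, plus the report of the averaged-prediction
#' ensemble itself.
#'
#' @param ensemble a `trial_ensemble` from [run_trials()].
#' @param test test data.frame; defaults to the ensemble's own test split.
#' @param k_p coverage factor.
#' @return list with `per_model` (data.frame: trial, slope, r, u),
#'   `slope_mean`, `slope_sd`, `u_mean`, `u_sd`, and `ensemble_report` (an
#'   `agreement_report` of the mean prediction).
#' @export
ensemble_agreement <- function(ensemble, test = NULL, k_p = 2) {
  stopifnot(inherits(ensemble, "trial_ensemble"))
  if (is.null(test)) test <- ensemble$split$test
  sel_idx <- which(ensemble$stats$selected)
  if (!length(sel_idx)) stop("input error: ensemble has no selected trials", call. = FALSE)
  label <- ensemble$models[[sel_idx[1]]]$label_col
  ref <- test[[label]]
  rows <- lapply(sel_idx, function(i) {
    p <- predict_iop(ensemble$models[[i]], test)
    rep <- bland_altman(ref, p, k_p = k_p)
    data.frame(trial = i, slope = rep$slope, r = rep$r,
               u = rep$expanded_uncertainty, bias = rep$bias)
  })
  per_model <- do.call(rbind, rows)
  mean_pred <- predict_iop(ensemble, test)
  list(per_model = per_model,
       slope_mean = mean(per_model$slope), slope_sd = sd(per_model$slope),
       u_mean = mean(per_model$u), u_sd = sd(per_model$u),
       ensemble_report = bland_altman(ref, mean_pred, k_p = k_p))
}

#' Diagnostic plots: regression and Bland-Altman panels
#'
#' @param report an `agreement_report` (carries the pairs it was computed
#'   from).
#' @return a ggplot object.
#' @export
plot_regression <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  df <- data.frame(reference = report$reference, prediction = report$prediction)
  ggplot2::ggplot(df, ggplot2::aes(x = reference, y = prediction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = report$slope, intercept = report$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "Reference IOP (GAT), mm Hg",
                  y = "Self-tonometer IOP, mm Hg",
                  title = sprintf("Regression: slope %.2f, R %.2f",
                                  report$slope, report$r)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_regression
#' @export
plot_bland_altman <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  df <- data.frame(mean_iop = (report$reference + report$prediction) / 2,
                   diff = report$prediction - report$reference)
  ggplot2::ggplot(df, ggplot2::aes(x = mean_iop, y = diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = report$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(report$loa_lower, report$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods, mm Hg",
                  y = "ST - GAT difference, mm Hg",
                  title = sprintf("Bland-Altman: U = %.2f mm Hg (k_p = %g)",
                                  report$expanded_uncertainty, report$k_p)) +
    ggplot2::theme_minimal()
}
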