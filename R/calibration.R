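# Network calibration ------------------------------------------------------
#
# Maps per-measurement features plus biometrics to an IOP estimate with a
# small fully connected feedforward network (default 9-7-10-1, tanh hidden
# units, identity output), trained with Adam on squared error and early
# stopping on a validation split.  Because iterative training suffers from
# local minima, many trials with different initialisations are run and the
# trials that best combine regression slope and regression coefficient on
# the validation data are kept; the ensemble prediction is the mean of the
# selected members.

#' Default calibration input features
#'
#' The nine network inputs: the three signal features (mean damping, mean
#' frequency, mean pulse amplitude) and the six biometric covariates.
#' @export
tonocal_default_features <- c(
  "mean_damping", "mean_frequency", "mean_amplitude",
  "age", "visual_acuity", "cornea_radius",
  "central_corneal_thickness", "axial_length", "anterior_chamber_depth")

#' Assemble the calibration feature table
#'
#' Joins the measurement features with the cohort biometrics, keeps only
#' expectancy-compliant measurements, and returns one labelled row per
#' measurement.
#'
#' @param cohort cohort table from [draw_cohort()] (or a real biometric
#'   table with the same columns plus `reference_iop`).
#' @param measurements measurement feature table (stacked rows from
#'   [process_recording()]).
#' @param categories classification table from [classify_measurement()].
#' @return data.frame with `subject_id`, `measurement_id`, the feature
#'   columns and `reference_iop`.
#' @export
build_feature_table <- function(cohort, measurements, categories) {
  keep <- categories$measurement_id[categories$category == "expectancy_compliant"]
  mf <- measurements[measurements$measurement_id %in% keep, , drop = FALSE]
  cols <- c("measurement_id", "mean_damping", "mean_frequency", "mean_amplitude")
  bio <- cohort[, c("subject_id", "measurement_id", "age", "visual_acuity",
                    "cornea_radius", "central_corneal_thickness",
                    "axial_length", "anterior_chamber_depth", "reference_iop")]
  out <- merge(mf[, cols], bio, by = "measurement_id")
  out <- out[complete.cases(out[, tonocal_default_features]), , drop = FALSE]
  out[order(out$measurement_id), , drop = FALSE]
}

#' Split a dataset into train / validation / test
#'
#' Disjoint, exhaustive split stratified by reference-IOP tertile.  When a
#' `subject_id` column is present, both eyes of a subject are kept in the
#' same partition (stratification then uses the subject-mean label).  Counts
#' per stratum are allocated by largest remainder, so e.g. fractions
#' (0.7, 0.15, 0.15) on 100 rows give sizes (70, 15, 15).  The test split is
#' never touched by training or model selection.
#'
#' @param data data.frame containing `label_col` (and optionally
#'   `subject_col`).
#' @param fractions positive split fractions summing to 1, in the order
#'   train, validation, test.
#' @param seed RNG seed for the shuffling.
#' @param label_col name of the reference-IOP column.
#' @param subject_col name of the subject grouping column, or `NULL` for
#'   row-level splitting.
#' @return list with data.frames `train`, `validation`, `test`.
#' @export
split_data <- function(data, fractions = c(0.7, 0.15, 0.15), seed = 1,
                       label_col = "reference_iop", subject_col = "subject_id") {
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop("input error: fractions must be positive and sum to 1", call. = FALSE)
  }
  if (length(fractions) != 3L) {
    stop("input error: exactly three fractions (train, validation, test) required",
         call. = FALSE)
  }
  n <- nrow(data)
  if (any(n * fractions < 10)) {
    stop("input error: dataset smaller than 10 per split", call. = FALSE)
  }
  if (!is.null(subject_col) && subject_col %in% names(data)) {
    grp <- data[[subject_col]]
  } else {
    grp <- as.character(seq_len(n))
  }
  lab <- tapply(data[[label_col]], grp, mean)
  units <- names(lab)
  qs <- quantile(lab, probs = c(1 / 3, 2 / 3), names = FALSE)
  tert <- 1L + (lab > qs[1]) + (lab > qs[2])
  assign <- character(length(units))
  names(assign) <- units
  parts <- c("train", "validation", "test")
  withr::with_seed(as.integer(seed), {
    for (k in 1:3) {
      u <- units[tert == k]
      u <- sample(u)
      m <- length(u)
      quota <- floor(m * fractions)
      rem <- m * fractions - quota
      extra <- m - sum(quota)
      if (extra > 0) {
        give <- order(rem, decreasing = TRUE)[seq_len(extra)]
        quota[give] <- quota[give] + 1L
      }
      idx <- rep(parts, times = quota)
      assign[u] <- idx
    }
  })
  out <- lapply(parts, function(p) {
    data[grp %in% units[assign[units] == p], , drop = FALSE]
  })
  names(out) <- parts
  out
}

# --- network internals ----------------------------------------------------

mlp_init <- function(sizes, seed) {
  withr::with_seed(as.integer(seed), {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      s <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
      W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1L], -s, s),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    list(W = W, b = b)
  })
}

mlp_forward <- function(par, X) {
  A1 <- tanh(sweep(X %*% par$W[[1]], 2, par$b[[1]], "+"))
  A2 <- tanh(sweep(A1 %*% par$W[[2]], 2, par$b[[2]], "+"))
  yhat <- drop(A2 %*% par$W[[3]]) + par$b[[3]]
  list(A1 = A1, A2 = A2, yhat = yhat)
}

mlp_grad <- function(par, X, y, fw) {
  n <- length(y)
  d3 <- matrix(2 * (fw$yhat - y) / n, ncol = 1)          # dL/dyhat
  gW3 <- t(fw$A2) %*% d3
  gb3 <- sum(d3)
  d2 <- (d3 %*% t(par$W[[3]])) * (1 - fw$A2^2)
  gW2 <- t(fw$A1) %*% d2
  gb2 <- colSums(d2)
  d1 <- (d2 %*% t(par$W[[2]])) * (1 - fw$A1^2)
  gW1 <- t(X) %*% d1
  gb1 <- colSums(d1)
  list(W = list(gW1, gW2, gW3), b = list(gb1, gb2, gb3))
}

#' Train one calibration network
#'
#' Full-batch Adam on squared error with early stopping on the validation
#' split (the weights of the best validation epoch are kept).  Inputs and
#' the label are z-score normalized with training-set statistics, which are
#' stored in the model.  Deterministic given `seed`.  A trial whose loss
#' becomes non-finite is returned as a failure record (`failed = TRUE`)
#' rather than raising an error, so ensembles can skip and log it.
#'
#' @param train,validation data.frames with the feature columns and
#'   `label_col`.
#' @param architecture hidden-layer sizes, length 2 (the scanned range is
#'   5-13 neurons per layer, other sizes are allowed).
#' @param seed RNG seed for the weight initialisation.
#' @param features input feature names (default
#'   [tonocal_default_features]).
#' @param label_col label column name.
#' @param epochs maximum number of Adam epochs.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience, epochs.
#' @return object of class `calibration_model`.
#' @export
train_once <- function(train, validation, architecture = c(7, 10), seed = 1,
                       features = tonocal_default_features,
                       label_col = "reference_iop",
                       epochs = 500, lr = 0.02, patience = 60) {
  if (length(architecture) != 2L || any(architecture < 1)) {
    stop("input error: architecture must give two positive hidden-layer sizes",
         call. = FALSE)
  }
  X <- as.matrix(train[, features, drop = FALSE])
  y <- train[[label_col]]
  Xv <- as.matrix(validation[, features, drop = FALSE])
  yv <- validation[[label_col]]
  xc <- colMeans(X)
  xs <- apply(X, 2, sd); xs[xs < 1e-12] <- 1
  yc <- mean(y); ys <- sd(y); if (!is.finite(ys) || ys < 1e-12) ys <- 1
  Xn <- sweep(sweep(X, 2, xc), 2, xs, "/")
  Xvn <- sweep(sweep(Xv, 2, xc), 2, xs, "/")
  yn <- (y - yc) / ys
  yvn <- (yv - yc) / ys

  sizes <- as.integer(c(length(features), architecture, 1L))
  par <- mlp_init(sizes, seed)
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(par = par, val = Inf, epoch = 0L)
  wait <- 0L; failed <- FALSE
  for (ep in seq_len(epochs)) {
    fw <- mlp_forward(par, Xn)
    if (any(!is.finite(fw$yhat))) { failed <- TRUE; break }
    g <- mlp_grad(par, Xn, yn, fw)
    for (l in 1:3) {
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$W[[l]]
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$W[[l]]^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$b[[l]]
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$b[[l]]^2
      mhW <- mW[[l]] / (1 - b1^ep); vhW <- vW[[l]] / (1 - b2^ep)
      mhb <- mb[[l]] / (1 - b1^ep); vhb <- vb[[l]] / (1 - b2^ep)
      par$W[[l]] <- par$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
      par$b[[l]] <- par$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
    val <- mean((mlp_forward(par, Xvn)$yhat - yvn)^2)
    if (!is.finite(val)) { failed <- TRUE; break }
    if (val < best$val - 1e-9) {
      best <- list(par = par, val = val, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  fw_tr <- mlp_forward(best$par, Xn)
  structure(list(
    sizes = sizes,
    W = best$par$W, b = best$par$b,
    activation = "tanh",
    features = features,
    label_col = label_col,
    x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
    seed = as.integer(seed),
    best_epoch = best$epoch,
    train_mse = mean((fw_tr$yhat - yn)^2) * ys^2,
    val_mse = best$val * ys^2,
    failed = failed
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model %s, %s%s, val RMSE %.3f mm Hg>\n",
              paste(x$sizes, collapse = "-"), x$activation,
              if (x$failed) ", FAILED" else "",
              sqrt(x$val_mse)))
  invisible(x)
}

#' Predict IOP from a model or trial ensemble
#'
#' Inputs are matched by name against the feature list stored in the model,
#' so column order in `newdata` does not matter.  For a `trial_ensemble` the
#' prediction is the mean over the selected members.  Inputs lying beyond
#' 5 SD of the training normalization trigger an extrapolation warning but
#' still return a prediction.
#'
#' @param object a `calibration_model` or `trial_ensemble`.
#' @param newdata data.frame containing the model's feature columns.
#' @param ... unused.
#' @return numeric vector of IOP predictions, mm Hg.
#' @export
predict_iop <- function(object, newdata, ...) UseMethod("predict_iop")

#' @rdname predict_iop
#' @export
predict_iop.calibration_model <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) {
    stop("input error: missing feature columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  Xn <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  if (any(abs(Xn) > 5)) {
    warning("predict_iop: inputs beyond 5 SD of the training normalization (extrapolation)")
  }
  par <- list(W = object$W, b = object$b)
  mlp_forward(par, Xn)$yhat * object$y_scale + object$y_center
}

#' @rdname predict_iop
#' @export
predict_iop.trial_ensemble <- function(object, newdata, ...) {
  sel <- object$models[object$stats$selected[!object$stats$failed]]
  preds <- vapply(sel, function(m) predict_iop(m, newdata),
                  numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}

#' Score a trained trial on validation data
#'
#' Computes the two selection statistics of a trial: the slope of the
#' least-squares regression of prediction on reference and the regression
#' coefficient R (Pearson correlation).  Degenerate (near-constant or
#' failed) predictions are flagged so that ranking can assign them the worst
#' rank.
#'
#' @param model a `calibration_model`.
#' @param validation validation data.frame.
#' @return list with `slope`, `r`, `degenerate`.
#' @export
trial_score <- function(model, validation) {
  if (nrow(validation) == 0L) stop("input error: empty validation set", call. = FALSE)
  if (isTRUE(model$failed)) return(list(slope = NA_real_, r = NA_real_, degenerate = TRUE))
  p <- predict_iop(model, validation)
  ref <- validation[[model$label_col]]
  if (!all(is.finite(p)) || sd(p) < 1e-9 || sd(ref) < 1e-12) {
    return(list(slope = NA_real_, r = NA_real_, degenerate = TRUE))
  }
  fit <- ls_line(ref, p)
  list(slope = unname(fit["slope"]), r = cor(ref, p), degenerate = FALSE)
}

#' Rank trials by combined slope and regression coefficient
#'
#' The selection score is the rank sum of |slope - 1| and (1 - R) across the
#' trials; lower is better.  Degenerate trials receive the worst possible
#' rank on both components.
#'
#' @param stats data.frame with columns `slope`, `r`, `degenerate`.
#' @return numeric score vector (one per row of `stats`).
#' @export
rank_trials <- function(stats) {
  a <- abs(stats$slope - 1)
  b <- 1 - stats$r
  worst <- nrow(stats) + 1
  a[stats$degenerate | !is.finite(a)] <- Inf
  b[stats$degenerate | !is.finite(b)] <- Inf
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  ra[!is.finite(a)] <- worst
  rb[!is.finite(b)] <- worst
  ra + rb
}

#' Run repeated training trials and select the best ensemble
#'
#' Trains `n_trials` networks from distinct seeded initialisations on a
#' fixed train/validation/test split, ranks them by [rank_trials()] on the
#' validation split, and marks the best `keep_fraction` as selected.  The
#' ensemble prediction is the mean over selected members.  The test split is
#' used by neither training nor selection.
#'
#' @param data labelled feature table (see [build_feature_table()]), or a
#'   ready-made split list from [split_data()].
#' @param architecture hidden-layer sizes, length 2.
#' @param n_trials number of training trials (>= 10).
#' @param keep_fraction fraction of trials selected (e.g. 0.01 of 100,000
#'   at full scale; desk-scale runs use fewer trials with a larger
#'   fraction).
#' @param seed master seed; trial seeds are derived via [child_seed()].
#' @param split_fractions forwarded to [split_data()] when `data` is a
#'   data.frame.
#' @param ... forwarded to [train_once()] (e.g. `epochs`, `lr`,
#'   `features`).
#' @return object of class `trial_ensemble`: list with `models`, `stats`
#'   (per-trial seed, slope, r, score, selected, failed), `split`,
#'   `architecture`, `keep_fraction`.
#' @export
run_trials <- function(data, architecture = c(7, 10), n_trials = 200,
                       keep_fraction = 0.1, seed = 1,
                       split_fractions = c(0.7, 0.15, 0.15), ...) {
  assert_count(n_trials, "n_trials", lo = 10)
  assert_number(keep_fraction, "keep_fraction", lo = 1e-9, hi = 1)
  split <- if (is.data.frame(data)) {
    split_data(data, fractions = split_fractions, seed = child_seed(seed, 0))
  } else data
  stopifnot(all(c("train", "validation", "test") %in% names(split)))
  seeds <- vapply(seq_len(n_trials), function(i) child_seed(seed, i), 0L)
  models <- vector("list", n_trials)
  slope <- r <- rep(NA_real_, n_trials)
  degen <- failed <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    m <- train_once(split$train, split$validation, architecture = architecture,
                    seed = seeds[i], ...)
    models[[i]] <- m
    failed[i] <- m$failed
    sc <- trial_score(m, split$validation)
    slope[i] <- sc$slope; r[i] <- sc$r; degen[i] <- sc$degenerate
  }
  if (all(failed | degen)) {
    stop("pipeline error: all training trials failed or degenerate", call. = FALSE)
  }
  stats <- data.frame(trial = seq_len(n_trials), seed = seeds,
                      slope = slope, r = r, degenerate = degen, failed = failed)
  stats$score <- rank_trials(stats)
  n_keep <- max(1L, round(n_trials * keep_fraction))
  ord <- order(stats$score, stats$trial)
  stats$selected <- FALSE
  stats$selected[ord[seq_len(min(n_keep, n_trials))]] <- TRUE
  stats$selected[stats$failed | stats$degenerate] <- FALSE
  structure(list(models = models, stats = stats, split = split,
                 architecture = architecture, keep_fraction = keep_fraction,
                 seed = seed),
            class = "trial_ensemble")
}

#' @export
print.trial_ensemble <- function(x, ...) {
  sel <- x$stats[x$stats$selected, ]
  cat(sprintf("<trial_ensemble %d trials (%d selected), architecture %s>\n",
              nrow(x$stats), nrow(sel),
              paste(x$architecture, collapse = "-")))
  if (nrow(sel)) {
    cat(sprintf("  selected validation slope %.3f +/- %.3f, R %.3f +/- %.3f\n",
                mean(sel$slope), sd(sel$slope), mean(sel$r), sd(sel$r)))
  }
  invisible(x)
}

#' Scan two-hidden-layer architectures
#'
#' Evaluates every (h1, h2) combination over `neuron_range` (default 5-13,
#' i.e. an 81-cell grid) with `n_trials_per_arch` training trials per cell
#' on a shared split.  All trials of the whole scan are ranked jointly by
#' [rank_trials()] (rank sum of |slope - 1| and 1 - R on the validation
#' split), and cells are compared by their mean trial score; because ranks
#' are bounded, a single diverged trial cannot dominate a cell.  The mean
#' test-set expanded uncertainty is reported for information only.
#'
#' @param data labelled feature table.
#' @param neuron_range integer vector of admissible hidden-layer sizes.
#' @param n_trials_per_arch trials per architecture cell.
#' @param seed master seed.
#' @param k_p coverage factor for the reported test uncertainty.
#' @param ... forwarded to [train_once()].
#' @return data.frame with one row per architecture: `h1`, `h2`,
#'   `mean_score` (mean joint rank-sum trial score, lower is better),
#'   `mean_abs_slope_err`, `mean_one_minus_r`, `median_one_minus_r`,
#'   `mean_test_u`, `rank` (1 = best), sorted by rank.
#' @export
scan_architectures <- function(data, neuron_range = 5:13,
                               n_trials_per_arch = 10, seed = 1, k_p = 2, ...) {
  if (!length(neuron_range)) stop("input error: empty neuron range", call. = FALSE)
  split <- split_data(data, seed = child_seed(seed, 0))
  grid <- expand.grid(h1 = neuron_range, h2 = neuron_range)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    arch <- c(grid$h1[g], grid$h2[g])
    do.call(rbind, lapply(seq_len(n_trials_per_arch), function(i) {
      m <- train_once(split$train, split$validation, architecture = arch,
                      seed = child_seed(seed, g * 1000 + i), ...)
      sc <- trial_score(m, split$validation)
      u <- if (sc$degenerate) NA_real_ else
        k_p * sd(predict_iop(m, split$test) - split$test[[m$label_col]])
      data.frame(cell = g, slope = sc$slope, r = sc$r,
                 degenerate = sc$degenerate, test_u = u)
    }))
  })
  trials <- do.call(rbind, rows)
  trials$score <- rank_trials(trials)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    tg <- trials[trials$cell == g, , drop = FALSE]
    data.frame(h1 = grid$h1[g], h2 = grid$h2[g],
               mean_score = mean(tg$score),
               mean_abs_slope_err = mean(abs(tg$slope - 1), na.rm = TRUE),
               mean_one_minus_r = mean(1 - tg$r, na.rm = TRUE),
               median_one_minus_r = median(1 - tg$r, na.rm = TRUE),
               mean_test_u = mean(tg$test_u, na.rm = TRUE))
  }))
  out$rank <- rank(out$mean_score, ties.method = "first")
  out[order(out$rank), , drop = FALSE]
}

#' Serialize / restore a calibration model as JSON
#'
#' Layer sizes, row-major weight lists, normalization constants and training
#' metadata are written to a plain-text JSON file.
#'
#' @param model a `calibration_model`.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- list(
    sizes = model$sizes,
    weights = lapply(model$W, function(w) as.numeric(t(w))),  # row-major
    biases = model$b,
    activation = model$activation,
    features = model$features,
    label_col = model$label_col,
    x_center = as.list(model$x_center), x_scale = as.list(model$x_scale),
    y_center = model$y_center, y_scale = model$y_scale,
    seed = model$seed, best_epoch = model$best_epoch,
    train_mse = model$train_mse, val_mse = model$val_mse,
    failed = model$failed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(obj$sizes)
  W <- lapply(seq_len(length(sizes) - 1L), function(l) {
    matrix(obj$weights[[l]], sizes[l], sizes[l + 1L], byrow = TRUE)
  })
  structure(list(
    sizes = sizes, W = W, b = lapply(obj$biases, as.numeric),
    activation = obj$activation, features = obj$features,
    label_col = obj$label_col,
    x_center = unlist(obj$x_center), x_scale = unlist(obj$x_scale),
    y_center = obj$y_center, y_scale = obj$y_scale,
    seed = obj$seed, best_epoch = obj$best_epoch,
    train_mse = obj$train_mse, val_mse = obj$val_mse,
    failed = isTRUE(obj$failed)
  ), class = "calibration_model")
}
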