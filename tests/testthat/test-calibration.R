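test_that("splits are exhaustive, disjoint, sized and stratified", {
  d <- make_feature_data(100, seed = 2)
  sp <- split_data(d, c(0.7, 0.15, 0.15), seed = 3)
  expect_identical(vapply(sp, nrow, 0L), c(train = 70L, validation = 15L, test = 15L))
  ids <- unlist(lapply(sp, `[[`, "measurement_id"))
  expect_setequal(ids, d$measurement_id)
  expect_identical(anyDuplicated(ids), 0L)

  # same seed gives identical splits
  sp2 <- split_data(d, c(0.7, 0.15, 0.15), seed = 3)
  expect_identical(sp, sp2)

  # stratification: per-split tertile proportions within 1 sample of the
  # global thirds, on a constructed 30-point set with equal fractions
  d30 <- make_feature_data(30, seed = 4)
  d30$reference_iop <- seq(6, 35, length.out = 30)   # clean tertiles
  sp30 <- split_data(d30, c(1, 1, 1) / 3, seed = 5)
  qs <- quantile(d30$reference_iop, c(1 / 3, 2 / 3), names = FALSE)
  for (part in sp30) {
    tert <- table(cut(part$reference_iop, c(-Inf, qs, Inf)))
    expect_true(all(abs(tert - nrow(part) / 3) <= 1))
  }

  expect_error(split_data(d[1:20, ], c(0.7, 0.15, 0.15), seed = 1),
               "smaller than 10 per split")
  expect_error(split_data(d, c(0.5, 0.5, 0.5), seed = 1), "sum to 1")
})

test_that("both eyes of one subject stay in the same partition", {
  cfg <- clean_sim_config(n_subjects = 30, rng_seed = 8)
  coh <- draw_cohort(cfg)
  coh$mean_damping <- coh$true_damping
  coh$mean_frequency <- coh$true_frequency
  coh$mean_amplitude <- 1
  sp <- split_data(coh, c(0.6, 0.2, 0.2), seed = 9)
  part_of <- do.call(rbind, lapply(names(sp), function(p)
    data.frame(subject_id = sp[[p]]$subject_id, part = p)))
  expect_true(all(tapply(part_of$part, part_of$subject_id,
                         function(v) length(unique(v))) == 1))
})

test_that("training fits a representable target and is seed-reproducible", {
  withr::local_seed(3)
  n <- 200
  lin <- data.frame(x1 = rnorm(n))
  for (k in 2:9) lin[[paste0("x", k)]] <- rnorm(n)
  lin$y <- lin$x1
  lin$subject_id <- as.character(seq_len(n))
  sp <- split_data(lin, c(0.6, 0.2, 0.2), seed = 1, label_col = "y")
  m <- train_once(sp$train, sp$validation, c(7, 10), seed = 1,
                  features = paste0("x", 1:9), label_col = "y",
                  epochs = 1500, patience = 200)
  expect_lt(sqrt(m$val_mse), 0.05)
  m2 <- train_once(sp$train, sp$validation, c(7, 10), seed = 1,
                   features = paste0("x", 1:9), label_col = "y",
                   epochs = 1500, patience = 200)
  expect_identical(m$W, m2$W)
  expect_identical(m$b, m2$b)
  expect_error(train_once(sp$train, sp$validation, c(7, 10, 3), seed = 1),
               "two positive hidden-layer sizes")
})

test_that("a single network inverts the noiseless forward model", {
  d <- make_feature_data(150, seed = 6)
  sp <- split_data(d, c(0.7, 0.15, 0.15), seed = 7)
  m <- train_once(sp$train, sp$validation, c(7, 10), seed = 11,
                  epochs = 1500, patience = 200)
  rmse <- sqrt(mean((predict_iop(m, sp$test) - sp$test$reference_iop)^2))
  expect_lt(rmse, 1)
})

test_that("predictions are keyed by feature name and ensemble-averaged", {
  d <- make_feature_data(80, seed = 8)
  sp <- split_data(d, c(0.6, 0.2, 0.2), seed = 9)
  m <- train_once(sp$train, sp$validation, c(5, 5), seed = 2, epochs = 200)
  p1 <- predict_iop(m, sp$test)
  shuffled <- sp$test[, rev(names(sp$test))]
  expect_identical(predict_iop(m, shuffled), p1)
  expect_error(predict_iop(m, sp$test[, 1:3]), "missing feature")
  far <- sp$test
  far$mean_damping <- far$mean_damping * 50
  expect_warning(predict_iop(m, far), "extrapolation")

  ens <- run_trials(d, c(5, 5), n_trials = 10, keep_fraction = 0.3, seed = 13,
                    epochs = 150)
  sel <- which(ens$stats$selected)
  expect_identical(length(sel), 3L)
  manual <- rowMeans(vapply(ens$models[sel],
                            function(mm) predict_iop(mm, ens$split$test),
                            numeric(nrow(ens$split$test))))
  expect_equal(predict_iop(ens, ens$split$test), manual, tolerance = 1e-12)
})

test_that("trial scoring prefers slope near 1 and high R", {
  d <- make_feature_data(60, seed = 10)
  sp <- split_data(d, c(0.6, 0.2, 0.2), seed = 11)
  m <- train_once(sp$train, sp$validation, c(5, 5), seed = 3, epochs = 300)
  sc <- trial_score(m, sp$validation)
  expect_false(sc$degenerate)
  expect_true(is.finite(sc$slope) && is.finite(sc$r))

  # degenerate constant predictor gets flagged and ranked worst
  mconst <- m
  for (l in 1:3) mconst$W[[l]] <- mconst$W[[l]] * 0
  scc <- trial_score(mconst, sp$validation)
  expect_true(scc$degenerate)
  stats <- data.frame(slope = c(1, 0.9, 0.7, NA),
                      r = c(1, 0.95, 0.95, NA),
                      degenerate = c(FALSE, FALSE, FALSE, TRUE))
  sc_all <- rank_trials(stats)
  expect_identical(which.min(sc_all), 1L)           # perfect predictions win
  expect_lt(sc_all[2], sc_all[3])                   # slope 0.9 beats 0.7 at equal R
  expect_identical(which.max(sc_all), 4L)           # degenerate ranks worst
})

test_that("trial selection keeps the requested fraction with best scores", {
  d <- make_feature_data(80, seed = 12)
  ens <- run_trials(d, c(5, 5), n_trials = 10, keep_fraction = 0.2, seed = 17,
                    epochs = 150)
  st <- ens$stats
  expect_identical(sum(st$selected), 2L)
  expect_lte(mean(st$score[st$selected]), mean(st$score))
  # reproducibility of the whole ensemble
  ens2 <- run_trials(d, c(5, 5), n_trials = 10, keep_fraction = 0.2, seed = 17,
                     epochs = 150)
  expect_identical(ens$stats, ens2$stats)
  expect_identical(ens$models[[1]]$W, ens2$models[[1]]$W)
})

test_that("architecture scan covers the grid and shows small spread on an easy target", {
  withr::local_seed(5)
  n <- 400
  d <- data.frame(x1 = rnorm(n))
  for (k in 2:9) d[[paste0("x", k)]] <- rnorm(n)
  d$reference_iop <- 16 + 4 * d$x1
  d$subject_id <- as.character(seq_len(n))
  sc <- scan_architectures(d, neuron_range = 5:7, n_trials_per_arch = 4,
                           seed = 19, epochs = 600,
                           features = paste0("x", 1:9))
  expect_identical(nrow(sc), 9L)
  expect_setequal(interaction(sc$h1, sc$h2),
                  interaction(expand.grid(5:7, 5:7)[, 1], expand.grid(5:7, 5:7)[, 2]))
  expect_identical(sort(sc$rank), 1:9)
  # every architecture can represent the linear map: per-cell (robust) lack
  # of fit small, spread < 2x the best cell
  expect_lt(max(sc$median_one_minus_r),
            2 * max(min(sc$median_one_minus_r), 0.005))
})

test_that("models survive a JSON round trip bit-for-bit in prediction", {
  d <- make_feature_data(60, seed = 14)
  sp <- split_data(d, c(0.6, 0.2, 0.2), seed = 15)
  m <- train_once(sp$train, sp$validation, c(6, 9), seed = 4, epochs = 200)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(predict_iop(back, sp$test), predict_iop(m, sp$test),
               tolerance = 1e-12)
  expect_identical(back$sizes, m$sizes)
  expect_equal(back$x_center, m$x_center, tolerance = 1e-15)
})
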