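test_that("touchdown detection follows the sustained-overpressure semantics", {
  sr <- 1000
  t <- seq(0, 6 - 1 / sr, by = 1 / sr)
  expect_false(detect_touchdown(rep(0, 6 * sr), sr))
  # half-threshold step is rejected
  half <- ifelse(t >= 2.8, 25, 0)
  expect_false(detect_touchdown(half, sr, threshold = 50))
  # decaying 100 Pa step at 2.8 s is accepted
  step <- ifelse(t >= 2.8, 100 * exp(-(t - 2.8)), 0)
  expect_true(detect_touchdown(step, sr, threshold = 50))
  # above threshold but too briefly
  blip <- ifelse(t >= 2.8 & t < 2.85, 100, 0)
  expect_false(detect_touchdown(blip, sr, threshold = 50))
  expect_error(detect_touchdown(rep(0, 100), sr), "input error")
})

test_that("baseline balancing removes cubic drift and is idempotent", {
  sr <- 10000
  cfg <- clean_sim_config(noise_sd = 0, drift_amplitude = 0, rng_seed = 13)
  coh <- draw_cohort(cfg)
  rec <- synthesize_recording(coh[1, ], coh[1, ], cfg, seed = 3)
  x <- rec$displacement
  n <- length(x)
  t <- (seq_len(n) - 1) / sr

  # zero-baseline input passes through within 0.1% RMS
  anch <- quiet_anchors(x, sr)
  expect_gte(nrow(anch), 4)
  y <- detrend_offset(x, anch)
  expect_lt(sqrt(mean((y - x)^2)) / sqrt(mean(x^2)), 0.001)

  # known cubic drift is removed: residual baseline RMS < 1% of drift amplitude
  drift <- 0.5 * (1 - 2 * (t / max(t)) + 3 * (t / max(t))^2 - 2 * (t / max(t))^3)
  xd <- x + drift
  yd <- detrend_offset(xd, quiet_anchors(xd, sr))
  quiet_idx <- which(t > 5.05 & t < 5.45)   # between t_start and first pulse
  expect_lt(sqrt(mean(yd[quiet_idx]^2)), 0.01 * 0.5)

  # constant offset is annihilated
  yc <- detrend_offset(x + 3, quiet_anchors(x + 3, sr))
  expect_lt(abs(median(yc[quiet_idx])), 1e-3)

  # idempotence: a second pass changes nothing beyond 0.1% RMS
  y2 <- detrend_offset(yd, quiet_anchors(yd, sr))
  expect_lt(sqrt(mean((y2 - yd)^2)) / sqrt(mean(yd^2)), 0.001)

  # < 4 anchors falls back to a single cubic, with a message
  expect_message(detrend_offset(x, anch[1:2, ], sr), "single cubic")
})

test_that("pulse segmentation finds each excitation response", {
  cfg <- clean_sim_config(rng_seed = 17)
  coh <- draw_cohort(cfg)
  rec <- synthesize_recording(coh[1, ], coh[1, ], cfg, seed = 21)
  out <- process_recording(rec)
  expect_identical(out$measurement$n_pulses_total, 20L)

  # silent trace yields no segments
  expect_length(segment_pulses(rnorm(80000, 0, 0.01), 10000, noise_floor = 0.01),
                0)

  # constructed trace: 3 pulses, one clipped at the rail
  sr <- 10000
  x <- rnorm(8 * sr, 0, 0.005)
  t <- (seq_along(x) - 1) / sr
  for (on in c(5.5, 6.0, 6.5)) {
    idx <- which(t >= on & t < on + 0.04)
    x[idx] <- x[idx] + damped_pulse(t[idx] - on, 1, 150, 450)
  }
  clip <- 0.8
  x <- pmin(pmax(x, -clip), clip)
  segs <- segment_pulses(x, sr, noise_floor = 0.005, clip_level = clip, raw = x)
  expect_length(segs, 3)
  expect_identical(vapply(segs, `[[`, TRUE, "clipped"), rep(TRUE, 3))
  expect_error(segment_pulses(x[1:1000], sr), "input error")
})

test_that("zero-crossing counts match the analytic crossing times", {
  sr <- 10000
  # one full sine cycle (sampled a hair past the period): crossings at T/2 and T
  f <- 450; T <- 1 / f
  t <- seq(1, 23) * (T / 20)
  expect_identical(count_zero_crossings(sin(2 * pi * f * t)), 2L)

  # 450 Hz damped sinusoid over 10 ms (window padded by one sample so the
  # crossing at exactly 10 ms is bracketed): crossings at k/900 s, k = 1..9
  x <- make_pulse(450, 200, dur = 0.0102)
  expect_identical(count_zero_crossings(x), 9L)

  # symmetry and scale invariance
  expect_identical(count_zero_crossings(-x), count_zero_crossings(x))
  expect_identical(count_zero_crossings(10 * x), count_zero_crossings(x))

  expect_warning(n0 <- count_zero_crossings(rep(0, 50)), "all-zero")
  expect_identical(n0, 0L)
  expect_error(count_zero_crossings(numeric(0)), "empty")
})

test_that("frequency estimates are within tolerance of the generating value", {
  sr <- 10000
  expect_lt(abs(estimate_frequency(make_pulse(450, 0.001), sr) - 450), 2)
  expect_lt(abs(estimate_frequency(make_pulse(570, 0.001), sr) - 570), 3)
  expect_lt(abs(estimate_frequency(make_pulse(400, 200), sr) - 400), 4)
  expect_error(estimate_frequency(make_pulse(450, 150)[1:20], sr),
               class = "tonocal_undefined_frequency")
})

test_that("damping estimates recover the generating decay rate", {
  sr <- 10000
  lam <- estimate_damping(make_pulse(450, 150), sr)
  expect_gte(lam, 148.5)
  expect_lte(lam, 151.5)
  # scale invariance
  expect_equal(estimate_damping(10 * make_pulse(450, 150), sr), lam,
               tolerance = 1e-9)
  expect_error(estimate_damping(make_pulse(450, 150)[1:12], sr),
               class = "tonocal_undefined_damping")
})

test_that("damping estimator is nearly unbiased under 2% amplitude noise", {
  withr::local_seed(99)
  lams <- replicate(500, {
    x <- make_pulse(450, 150, noise_sd = 0.02)
    estimate_damping(x, 10000, noise_floor = 0.02)
  })
  expect_lt(abs(mean(lams) / 150 - 1), 0.02)
})

test_that("envelope fit agrees with a full nonlinear model fit", {
  skip_if_not_installed("minpack.lm")
  sr <- 10000
  x <- make_pulse(430, 180)
  t <- seq(0, length(x) - 1) / sr
  df <- data.frame(t = t, x = x)
  fit <- minpack.lm::nlsLM(x ~ A * exp(-l * t) * sin(2 * pi * f * t),
                           data = df, start = list(A = 0.9, l = 120, f = 400))
  expect_equal(estimate_damping(x, sr), coef(fit)[["l"]], tolerance = 0.005)
  expect_equal(estimate_frequency(x, sr), coef(fit)[["f"]], tolerance = 0.002)
})

test_that("features are invariant to integer-sample time shifts and rescaling", {
  cfg <- clean_sim_config(rng_seed = 23)
  coh <- draw_cohort(cfg)
  rec <- synthesize_recording(coh[1, ], coh[1, ], cfg, seed = 31)
  base <- process_recording(rec)$measurement

  shift <- 250L   # 25 ms
  rec2 <- rec
  rec2$displacement <- c(rep(0, shift), rec$displacement)
  rec2$pressure <- c(rep(rec$pressure[1], shift), rec$pressure)
  rec2$t_start_evaluation <- rec$t_start_evaluation + shift / rec$sample_rate
  shifted <- process_recording(rec2)$measurement
  expect_equal(shifted$mean_frequency, base$mean_frequency, tolerance = 1e-3)
  expect_equal(shifted$mean_damping, base$mean_damping, tolerance = 5e-3)
  expect_identical(shifted$n_pulses_valid, base$n_pulses_valid)

  rec3 <- rec
  rec3$displacement <- 0.5 * rec$displacement
  rec3$clip_level <- 0.5 * rec$clip_level
  rec3$nominal_amplitude <- 0.5
  scaled <- process_recording(rec3)$measurement
  expect_equal(scaled$mean_frequency, base$mean_frequency, tolerance = 1e-6)
  expect_equal(scaled$mean_damping, base$mean_damping, tolerance = 1e-6)
  expect_equal(scaled$mean_amplitude, 0.5 * base$mean_amplitude, tolerance = 1e-6)
})

test_that("measurement summaries average valid pulses only", {
  pf <- data.frame(pulse_index = 1:5, t0 = 1:5, n_zero_crossings = 9L,
                   frequency = c(450, 450, 450, 600, 450),
                   damping = c(150, 150, 150, 999, 150),
                   amplitude = 1, clipped = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  pf <- validate_pulse(pf)
  m <- summarize_measurement(pf, touchdown = TRUE, pressure_flag = FALSE, "m1")
  expect_identical(m$n_pulses_total, 5L)
  expect_identical(m$n_pulses_valid, 3L)
  expect_equal(m$mean_damping, 150)
  expect_equal(m$sd_damping, 0)
  expect_equal(m$cv_damping_percent, 0)

  empty <- summarize_measurement(pf[0, ], TRUE, FALSE, "m2")
  expect_identical(empty$n_pulses_total, 0L)
  expect_true(is.na(empty$mean_damping))
})

test_that("per-measurement damping spread sits in the low single digits", {
  # simulator defaults: coefficient of variation of damping across the ~20
  # repeated pulses of a measurement, compared qualitatively with the
  # clinical 2.1% regime
  cfg <- clean_sim_config(n_subjects = 5, rng_seed = 37)
  coh <- draw_cohort(cfg)
  cvs <- vapply(seq_len(10), function(i) {
    rec <- synthesize_recording(coh[i, ], coh[i, ], cfg, seed = 400 + i)
    process_recording(rec)$measurement$cv_damping_percent
  }, 0)
  expect_lt(mean(cvs), 5)
  expect_gt(mean(cvs), 0.1)
})
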