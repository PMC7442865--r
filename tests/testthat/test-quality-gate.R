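pf_row <- function(ncr, f, clipped = FALSE) {
  data.frame(pulse_index = 1L, t0 = 0, n_zero_crossings = ncr, frequency = f,
             damping = 150, amplitude = 1, clipped = clipped)
}

test_that("pulse validity boundaries are exact", {
  v <- function(ncr, f, clipped = FALSE) validate_pulse(pf_row(ncr, f, clipped))
  expect_true(v(8, 450)$valid)
  expect_true(v(7, 450)$valid)          # boundary: exactly 7 crossings
  expect_false(v(6, 450)$valid)
  expect_match(v(6, 450)$invalid_reasons, "too_few_crossings")
  expect_true(v(9, 350)$valid)          # band endpoints inclusive
  expect_true(v(9, 570)$valid)
  expect_false(v(9, 349.9)$valid)
  expect_false(v(9, 570.1)$valid)
  expect_match(v(9, 600)$invalid_reasons, "out_of_band")
  expect_false(v(9, 450, clipped = TRUE)$valid)
  expect_match(v(9, 450, clipped = TRUE)$invalid_reasons, "clipped")
  # undefined frequency counts as out of band
  und <- v(9, NA_real_)
  expect_false(und$valid)
  expect_match(und$invalid_reasons, "out_of_band")
  # valid implies empty reasons
  expect_identical(v(8, 450)$invalid_reasons, "")
})

mf_row <- function(valid, total = 20L, touchdown = TRUE, pflag = FALSE,
                   id = "m1") {
  data.frame(measurement_id = id, n_pulses_total = total,
             n_pulses_valid = valid, mean_damping = 150, sd_damping = 1,
             cv_damping_percent = 0.7, mean_frequency = 450, sd_frequency = 1,
             mean_amplitude = 1, touchdown_detected = touchdown,
             pressure_deviation_flag = pflag)
}

test_that("measurement classification respects rules and precedence", {
  expect_identical(classify_measurement(mf_row(3))$category, "expectancy_compliant")
  expect_identical(classify_measurement(mf_row(2))$category, "quality_fail")
  expect_identical(classify_measurement(mf_row(3, touchdown = FALSE))$category,
                   "no_start")
  expect_identical(classify_measurement(mf_row(0, total = 0L))$category, "no_start")
  expect_identical(classify_measurement(mf_row(3, pflag = TRUE))$category,
                   "pressure_deviation")
  # precedence: no_start > pressure_deviation > quality_fail
  expect_identical(classify_measurement(mf_row(2, touchdown = FALSE, pflag = TRUE))$category,
                   "no_start")
  expect_identical(classify_measurement(mf_row(2, pflag = TRUE))$category,
                   "pressure_deviation")
})

test_that("each simulated failure mode lands in its category", {
  cfg <- sim_config(n_subjects = 1, rng_seed = 2)
  coh <- draw_cohort(cfg)
  got <- vapply(c("none", "no_start", "movement", "pressure_deviation"),
                function(mode) {
    tr <- coh[1, ]; tr$failure_mode <- mode
    rec <- synthesize_recording(tr, tr, cfg, seed = 42)
    classify_measurement(process_recording(rec)$measurement)$category
  }, "")
  expect_identical(unname(got),
                   c("expectancy_compliant", "no_start", "quality_fail",
                     "pressure_deviation"))
  # chamber leakage is not identifiable from the gate: it passes
  tr <- coh[1, ]; tr$failure_mode <- "leakage"
  rec <- synthesize_recording(tr, tr, cfg, seed = 42)
  expect_identical(classify_measurement(process_recording(rec)$measurement)$category,
                   "expectancy_compliant")
})

test_that("cohort summary reproduces the printed share arithmetic", {
  cats <- data.frame(
    measurement_id = sprintf("m%03d", 1:828),
    category = rep(c("expectancy_compliant", "no_start", "quality_fail",
                     "pressure_deviation"), times = c(504, 56, 264, 4)))
  s <- summarize_cohort(cats)
  expect_identical(s$total, 828L)
  expect_equal(s$table$share_percent,
               c(60.9, 6.8, 31.9, 0.5))
  expect_equal(sum(s$table$count), 828)

  one <- summarize_cohort(data.frame(measurement_id = "m1",
                                     category = "expectancy_compliant"))
  expect_equal(one$table$share_percent[1], 100.0)
  expect_error(summarize_cohort(cats[0, ]), "empty")
})

test_that("classification shares track configured failure probabilities", {
  # mode assignment at n = 2000 eyes; the per-mode category mapping is
  # verified deterministically above, so the shares follow the binomial law
  cfg <- sim_config(n_subjects = 1000,
                    failure_probabilities = c(no_start = 0.07, movement = 0.30,
                                              leakage = 0, pressure_deviation = 0.005),
                    rng_seed = 55)
  coh <- draw_cohort(cfg)
  n <- nrow(coh)
  for (mode in c("no_start", "movement", "pressure_deviation")) {
    p <- cfg$failure_probabilities[[mode]]
    k <- sum(coh$failure_mode == mode)
    expect_lt(abs(k / n - p), 1.96 * sqrt(p * (1 - p) / n) + 1e-12)
  }
  # full-chain spot check on a subsample: classified shares stay consistent
  idx <- seq_len(150)
  cats <- do.call(rbind, lapply(idx, function(i) {
    rec <- synthesize_recording(coh[i, ], coh[i, ], cfg, seed = 600 + i)
    classify_measurement(process_recording(rec)$measurement)
  }))
  expected <- c(no_start = 0.07, quality_fail = 0.30, pressure_deviation = 0.005)
  for (cat in names(expected)) {
    p <- expected[[cat]]
    k <- sum(cats$category == cat)
    expect_lt(abs(k / length(idx) - p),
              2.6 * sqrt(p * (1 - p) / length(idx)) + 1e-12)
  }
})

test_that("raising simulator noise never lowers the quality-fail share", {
  share_qf <- function(noise_sd, seed) {
    cfg <- clean_sim_config(n_subjects = 15, noise_sd = noise_sd,
                            pulses_per_measurement = 6, rng_seed = seed)
    coh <- draw_cohort(cfg)
    cats <- vapply(seq_len(nrow(coh)), function(i) {
      rec <- synthesize_recording(coh[i, ], coh[i, ], cfg, seed = seed + i)
      classify_measurement(process_recording(rec)$measurement)$category
    }, "")
    mean(cats == "quality_fail")
  }
  shares <- vapply(c(0.01, 0.06, 0.12), function(ns) {
    mean(vapply(1:3, function(s) share_qf(ns, 700 + 13 * s), 0))
  }, 0)
  expect_true(all(diff(shares) >= 0))
})
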