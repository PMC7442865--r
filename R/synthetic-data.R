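# Synthetic cohorts and raw recordings ------------------------------------
#
# The simulator emulates the statistical structure the downstream analysis
# assumes: a pre-evaluation phase 0-5 s with a touchdown overpressure near
# 2.8 s, a train of ~20 damped-sinusoid excitation responses after 5 s with
# frequencies in the 350-570 Hz band, IOP- and biometry-dependent damping and
# frequency, baseline drift from subject movement, sensor-range clipping,
# chamber leakage, and non-start failures.  Ground truth is retained per eye
# so parameter recovery can be measured.

#' Default forward-model coefficients
#'
#' Coefficients of the latent map from (IOP, biometrics) to the damping and
#' frequency of the coupled eye-air-loudspeaker oscillation:
#' \deqn{f = f_0 + a_f (IOP - 16) + b_f (AL - 24)}
#' \deqn{\lambda = d_0 \exp(-a_d (IOP - 16)) (1 + b_d (CCT - 545)/545)}
#' with IOP in mm Hg, axial length AL in mm and central corneal thickness CCT
#' in µm.  Defaults keep the frequency inside the 350-570 Hz validity band
#' for IOP in [8, 35] mm Hg across the biometric ranges the cohort generator
#' can produce, and keep damping positive and strictly decreasing in IOP so
#' the map is smooth and invertible.
#'
#' @return named list of coefficients `f0, a_f, b_f, d0, a_d, b_d`.
#' @export
default_forward_coefficients <- function() {
  list(f0 = 450, a_f = 4, b_f = 5, d0 = 200, a_d = 0.04, b_d = 0.3)
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic-data generator.
#' Defaults encode the study conditions: ~20 excitation pulses per
#' measurement, a 0-5 s pre-evaluation phase with a 100 Pa touchdown
#' overpressure at 2.8 s decaying with tau = 1 s, 10 kHz sampling (Nyquist
#' margin above the 570 Hz band edge), sensor clipping at ±1.2 × nominal
#' pulse amplitude, and failure-mode probabilities emulating the observed
#' success-rate regime.
#'
#' @param n_subjects number of virtual subjects (two eyes each).
#' @param pulses_per_measurement excitation pulses per recording.
#' @param noise_sd additive Gaussian sensor noise, as a fraction of the
#'   nominal pulse amplitude.
#' @param drift_amplitude slow baseline drift amplitude, fraction of pulse
#'   amplitude (movement of the subject holding the device).
#' @param pulse_amplitude nominal pulse amplitude in sensor units.
#' @param sample_rate sampling rate in Hz.
#' @param t_start_evaluation end of the pre-evaluation phase, s.
#' @param first_pulse_time onset of the first excitation pulse, s.
#' @param pulse_spacing cadence of the excitation pulses, s.
#' @param touchdown_time,touchdown_pressure,touchdown_tau timing (s),
#'   magnitude (Pa) and decay constant (s) of the touchdown overpressure.
#' @param pressure_noise_sd chamber-pressure sensor noise, Pa.
#' @param clip_factor sensor range as a multiple of `pulse_amplitude`.
#' @param failure_probabilities named numeric vector with entries
#'   `no_start`, `movement`, `leakage`, `pressure_deviation`; the remainder
#'   is the probability of a clean measurement.
#' @param leak_damping_factor,leak_frequency_shift effect of chamber leakage
#'   on the realised damping (multiplicative) and frequency (additive, Hz).
#' @param reference_noise_sd SD of the reference-tonometer reading around the
#'   true IOP, mm Hg.
#' @param self_administered_prob probability that a measurement is performed
#'   by the subject rather than assisted.
#' @param inter_eye_correlation correlation between the two eyes of one
#'   subject for biometric and IOP draws.
#' @param coefficients forward-model coefficients, see
#'   [default_forward_coefficients()].
#' @param rng_seed seed for cohort generation.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 20,
                       pulses_per_measurement = 20,
                       noise_sd = 0.01,
                       drift_amplitude = 0.1,
                       pulse_amplitude = 1,
                       sample_rate = 10000,
                       t_start_evaluation = 5,
                       first_pulse_time = 5.5,
                       pulse_spacing = 0.5,
                       touchdown_time = 2.8,
                       touchdown_pressure = 100,
                       touchdown_tau = 1,
                       pressure_noise_sd = 2,
                       clip_factor = 1.2,
                       failure_probabilities = c(no_start = 0.068,
                                                 movement = 0.30,
                                                 leakage = 0.08,
                                                 pressure_deviation = 0.005),
                       leak_damping_factor = 1.6,
                       leak_frequency_shift = -40,
                       reference_noise_sd = 0.75,
                       self_administered_prob = 626 / 828,
                       inter_eye_correlation = 0.8,
                       coefficients = default_forward_coefficients(),
                       rng_seed = 1L) {
  assert_count(n_subjects, "n_subjects")
  assert_count(pulses_per_measurement, "pulses_per_measurement")
  assert_number(noise_sd, "noise_sd", lo = 0)
  assert_number(drift_amplitude, "drift_amplitude", lo = 0)
  assert_number(pulse_amplitude, "pulse_amplitude", lo = 1e-12)
  assert_number(sample_rate, "sample_rate", lo = 4 * 570)
  assert_number(t_start_evaluation, "t_start_evaluation", lo = 0)
  assert_number(first_pulse_time, "first_pulse_time", lo = t_start_evaluation)
  assert_number(pulse_spacing, "pulse_spacing", lo = 0.05)
  assert_number(clip_factor, "clip_factor", lo = 1)
  assert_number(inter_eye_correlation, "inter_eye_correlation", lo = -1, hi = 1)
  assert_number(reference_noise_sd, "reference_noise_sd", lo = 0)
  assert_number(self_administered_prob, "self_administered_prob", lo = 0, hi = 1)
  modes <- c("no_start", "movement", "leakage", "pressure_deviation")
  if (!is.numeric(failure_probabilities) ||
      !all(modes %in% names(failure_probabilities))) {
    stop("configuration error: 'failure_probabilities' must be a named numeric ",
         "vector with entries ", paste(modes, collapse = ", "), call. = FALSE)
  }
  failure_probabilities <- failure_probabilities[modes]
  if (any(failure_probabilities < 0) || any(failure_probabilities > 1) ||
      sum(failure_probabilities) > 1) {
    stop("configuration error: 'failure_probabilities' must lie in [0,1] and sum to <= 1",
         call. = FALSE)
  }
  for (nm in c("f0", "a_f", "b_f", "d0", "a_d", "b_d")) {
    assert_number(coefficients[[nm]] %||% NA_real_, paste0("coefficients$", nm))
  }
  cfg <- list(n_subjects = as.integer(n_subjects),
              pulses_per_measurement = as.integer(pulses_per_measurement),
              noise_sd = noise_sd,
              drift_amplitude = drift_amplitude,
              pulse_amplitude = pulse_amplitude,
              sample_rate = sample_rate,
              t_start_evaluation = t_start_evaluation,
              first_pulse_time = first_pulse_time,
              pulse_spacing = pulse_spacing,
              touchdown_time = touchdown_time,
              touchdown_pressure = touchdown_pressure,
              touchdown_tau = touchdown_tau,
              pressure_noise_sd = pressure_noise_sd,
              clip_factor = clip_factor,
              failure_probabilities = failure_probabilities,
              leak_damping_factor = leak_damping_factor,
              leak_frequency_shift = leak_frequency_shift,
              reference_noise_sd = reference_noise_sd,
              self_administered_prob = self_administered_prob,
              inter_eye_correlation = inter_eye_correlation,
              coefficients = coefficients,
              rng_seed = rng_seed)
  class(cfg) <- "sim_config"
  cfg
}

# Biometric priors: per-eye marginal mean/SD of the cohort the device was
# evaluated on, with hard physical clipping ranges.
biometric_priors <- function() {
  list(
    age        = list(od = c(61.7, 17.1), os = c(61.7, 17.1), lim = c(18, 100), per_subject = TRUE),
    iop        = list(od = c(16.4, 4.4),  os = c(17.0, 5.7),  lim = c(5, 60)),
    visual_acuity = list(od = c(0.7, 0.3), os = c(0.7, 0.3), lim = c(0.05, 2)),
    cornea_radius = list(od = c(7.8, 0.3), os = c(7.8, 0.3), lim = c(6, 10)),
    central_corneal_thickness = list(od = c(546.9, 36.4), os = c(544.0, 37.6), lim = c(400, 700)),
    axial_length = list(od = c(24.0, 3.1), os = c(24.2, 1.7), lim = c(19, 32)),
    anterior_chamber_depth = list(od = c(3.1, 0.7), os = c(3.1, 0.7), lim = c(1.5, 5))
  )
}

# correlated per-eye Gaussian draws with marginal (mean, sd) per eye,
# clipped to the physical range
draw_eye_pair <- function(n, od, os, rho, lim) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  v_od <- pmin(pmax(od[1] + od[2] * z1, lim[1]), lim[2])
  v_os <- pmin(pmax(os[1] + os[2] * z2, lim[1]), lim[2])
  cbind(v_od, v_os)
}

#' Draw a virtual cohort
#'
#' Generates `n_subjects` subjects with two eyes each.  Biometric covariates
#' and IOP are drawn from Gaussian priors matching the per-eye marginal
#' means and SDs of the evaluated cohort, clipped to physical ranges, with
#' inter-eye correlation `config$inter_eye_correlation`.  Each eye receives
#' latent (damping, frequency) ground truth from [forward_model()], a
#' reference-tonometer reading, a failure mode, and a self-administered flag.
#'
#' @param config a [sim_config()].
#' @return a data.frame with one row per eye, columns `subject_id`,
#'   `eye_side`, `measurement_id`, the six biometric covariates, `true_iop`,
#'   `reference_iop`, `true_damping`, `true_frequency`, `failure_mode`,
#'   `self_administered`.
#' @export
draw_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_subjects
  rho <- config$inter_eye_correlation
  pri <- biometric_priors()
  with_seed_if(config$rng_seed, {
    age <- pmin(pmax(rnorm(n, pri$age$od[1], pri$age$od[2]), 18), 100)
    draws <- lapply(pri[setdiff(names(pri), "age")], function(p)
      draw_eye_pair(n, p$od, p$os, rho, p$lim))
    modes <- c("none", names(config$failure_probabilities))
    probs <- c(1 - sum(config$failure_probabilities), config$failure_probabilities)
    eye_row <- function(side, col) {
      data.frame(
        subject_id = sprintf("S%03d", seq_len(n)),
        eye_side = side,
        age = age,
        visual_acuity = draws$visual_acuity[, col],
        cornea_radius = draws$cornea_radius[, col],
        central_corneal_thickness = draws$central_corneal_thickness[, col],
        axial_length = draws$axial_length[, col],
        anterior_chamber_depth = draws$anterior_chamber_depth[, col],
        true_iop = draws$iop[, col],
        stringsAsFactors = FALSE
      )
    }
    cohort <- rbind(eye_row("OD", 1L), eye_row("OS", 2L))
    cohort <- cohort[order(cohort$subject_id, cohort$eye_side), , drop = FALSE]
    rownames(cohort) <- NULL
    fm <- forward_model(cohort, cohort$true_iop, config$coefficients,
                        nyquist_hz = config$sample_rate / 2)
    cohort$true_damping <- fm$damping
    cohort$true_frequency <- fm$frequency
    cohort$reference_iop <- pmax(cohort$true_iop +
                                   rnorm(nrow(cohort), 0, config$reference_noise_sd), 1)
    cohort$failure_mode <- sample(modes, nrow(cohort), replace = TRUE, prob = probs)
    cohort$self_administered <- rbinom(nrow(cohort), 1, config$self_administered_prob) == 1
    cohort$measurement_id <- paste0(cohort$subject_id, "-", cohort$eye_side, "-M1")
    cohort
  })
}

#' Latent forward model: (biometrics, IOP) -> (damping, frequency)
#'
#' The response of the eye to the acoustic excitation is modelled as a damped
#' oscillation whose frequency rises linearly with IOP and axial length and
#' whose decay rate falls exponentially with IOP, modulated by corneal
#' thickness.  The functional form is a smooth, invertible stand-in for the
#' physical coupling; only the existence and direction of the sensitivities
#' is taken from the measurement principle.
#'
#' @param biometrics data.frame with columns `axial_length` (mm) and
#'   `central_corneal_thickness` (µm); extra columns are ignored.
#' @param iop intraocular pressure, mm Hg (recycled against rows).
#' @param coefficients see [default_forward_coefficients()].
#' @param nyquist_hz upper admissible frequency; the model errors out if a
#'   parameter combination drives the frequency outside `(0, nyquist_hz)`.
#' @return data.frame with columns `damping` (1/s) and `frequency` (Hz).
#' @export
forward_model <- function(biometrics, iop,
                          coefficients = default_forward_coefficients(),
                          nyquist_hz = 5000) {
  co <- coefficients
  if (any(!is.finite(unlist(co)))) {
    stop("forward_model: coefficients must be finite", call. = FALSE)
  }
  if (any(iop <= 0)) stop("forward_model: iop must be positive", call. = FALSE)
  f <- co$f0 + co$a_f * (iop - 16) + co$b_f * (biometrics$axial_length - 24)
  d <- co$d0 * exp(-co$a_d * (iop - 16)) *
    (1 + co$b_d * (biometrics$central_corneal_thickness - 545) / 545)
  if (any(f <= 0) || any(f >= nyquist_hz)) {
    stop(sprintf("forward_model: model-range error, frequency outside (0, %g) Hz",
                 nyquist_hz), call. = FALSE)
  }
  if (any(d <= 0)) stop("forward_model: model-range error, damping <= 0", call. = FALSE)
  data.frame(damping = d, frequency = f)
}

#' Closed-form damped excitation pulse
#'
#' \eqn{A e^{-\lambda t} \sin(2 \pi f t)} evaluated at `t >= 0` (0 elsewhere).
#'
#' @param t time since pulse onset, s (vector).
#' @param amplitude A, sensor units.
#' @param damping decay rate lambda, 1/s.
#' @param frequency f, Hz.
#' @export
damped_pulse <- function(t, amplitude, damping, frequency) {
  ifelse(t >= 0, amplitude * exp(-damping * t) * sin(2 * pi * frequency * t), 0)
}

# smooth raised-cosine gate, 1 inside [a, b], 0 outside [a-r, b+r]
cosine_gate <- function(t, a, b, r) {
  up <- (t - (a - r)) / r
  dn <- ((b + r) - t) / r
  g <- pmin(pmax(pmin(up, dn), 0), 1)
  0.5 - 0.5 * cos(pi * g)
}

#' Synthesize one raw recording
#'
#' Builds the two-channel raw measurement for one eye: a chamber-pressure
#' trace with the touchdown overpressure step (a 100 Pa step at 2.8 s
#' decaying with tau = 1 s by default) and a displacement trace carrying the
#' train of damped-sinusoid excitation responses after the pre-evaluation
#' phase, plus sensor noise, slow baseline drift, and hard clipping at the
#' sensor range.  Failure modes:
#' \describe{
#'   \item{no_start}{no touchdown step and no excitation pulses.}
#'   \item{movement}{large low-frequency excursions; all but two pulses are
#'     pushed into the sensor rail (clipped).}
#'   \item{leakage}{damping multiplied by the leak factor and frequency
#'     shifted; otherwise indistinguishable from a clean recording.}
#'   \item{pressure_deviation}{an out-of-band chamber-pressure swing during
#'     the evaluation window.}
#' }
#'
#' @param biometrics one cohort row (see [draw_cohort()]); only identifiers
#'   are used here.
#' @param truth list or row with `true_damping`, `true_frequency`,
#'   `failure_mode`.
#' @param config a [sim_config()].
#' @param seed optional seed for the recording noise; `NULL` uses the
#'   caller's RNG state.
#' @return an object of class `raw_measurement`: list with `subject_id`,
#'   `eye_side`, `measurement_id`, `sample_rate`, `displacement`, `pressure`,
#'   `t_start_evaluation`, `excitation_times`, `clip_level`,
#'   `nominal_amplitude`, `self_administered`.
#' @export
synthesize_recording <- function(biometrics, truth, config, seed = NULL) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_seed_if(seed, {
    sr <- config$sample_rate
    np <- config$pulses_per_measurement
    onsets <- config$first_pulse_time + config$pulse_spacing * (seq_len(np) - 1)
    duration <- max(onsets) + 0.2
    nsamp <- round(duration * sr)
    t <- (seq_len(nsamp) - 1) / sr
    A <- config$pulse_amplitude
    mode <- as.character(truth$failure_mode %||% "none")

    lam <- truth$true_damping
    f <- truth$true_frequency
    if (mode == "leakage") {
      lam <- lam * config$leak_damping_factor
      f <- f + config$leak_frequency_shift
    }

    x <- rnorm(nsamp, 0, config$noise_sd * A)
    if (config$drift_amplitude > 0) {
      ph <- runif(2, 0, 2 * pi)
      x <- x + config$drift_amplitude * A *
        (sin(2 * pi * 0.3 * t + ph[1]) + 0.4 * sin(2 * pi * 0.8 * t + ph[2]))
    }
    if (mode != "no_start") {
      for (on in onsets) {
        idx <- which(t >= on & t < on + 0.05)
        x[idx] <- x[idx] + damped_pulse(t[idx] - on, A, lam, f)
      }
    }
    if (mode == "movement") {
      # slow excursion plus offsets that drive all but the first two pulses
      # into the sensor rail
      ph <- runif(1, 0, 2 * pi)
      x <- x + 0.6 * A * sin(2 * pi * 0.25 * t + ph)
      if (np > 2) {
        for (on in onsets[-(1:2)]) {
          x <- x + 1.6 * A * cosine_gate(t, on - 0.005, on + 0.05, 0.02)
        }
      }
    }
    clip_level <- config$clip_factor * A
    x <- pmin(pmax(x, -clip_level), clip_level)

    p <- rnorm(nsamp, 0, config$pressure_noise_sd)
    if (mode != "no_start") {
      td <- t >= config$touchdown_time
      p[td] <- p[td] + config$touchdown_pressure *
        exp(-(t[td] - config$touchdown_time) / config$touchdown_tau)
    }
    if (mode == "pressure_deviation") {
      t_dev <- config$t_start_evaluation + 2
      p <- p + 4 * config$touchdown_pressure * exp(-((t - t_dev) / 0.15)^2 / 2)
    }

    structure(list(
      subject_id = as.character(biometrics$subject_id %||% "S000"),
      eye_side = as.character(biometrics$eye_side %||% "OD"),
      measurement_id = as.character(biometrics$measurement_id %||% "S000-OD-M1"),
      sample_rate = sr,
      displacement = x,
      pressure = p,
      t_start_evaluation = config$t_start_evaluation,
      excitation_times = if (mode == "no_start") numeric(0) else onsets,
      clip_level = clip_level,
      nominal_amplitude = A,
      self_administered = isTRUE(biometrics$self_administered %||% TRUE)
    ), class = "raw_measurement")
  })
}

#' @export
print.raw_measurement <- function(x, ...) {
  cat(sprintf("<raw_measurement %s: %d samples @ %g Hz, %d excitation pulses>\n",
              x$measurement_id, length(x$displacement), x$sample_rate,
              length(x$excitation_times)))
  invisible(x)
}

#' Write / read a raw recording
#'
#' The on-disk form is a two-channel CSV (`time_s`, `displacement`,
#' `pressure_pa`) plus a JSON sidecar holding identifiers, sample rate,
#' evaluation start and sensor range.  The same schema is intended for
#' exported real device data.
#'
#' @param rec a `raw_measurement`.
#' @param dir output directory (created if needed).
#' @return `write_recording()` returns the CSV path invisibly;
#'   `read_recording()` returns a `raw_measurement`.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "raw_measurement"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, rec$measurement_id)
  n <- length(rec$displacement)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$sample_rate,
                   displacement = rec$displacement,
                   pressure_pa = rec$pressure)
  write.csv(df, paste0(base, ".csv"), row.names = FALSE)
  meta <- rec[c("subject_id", "eye_side", "measurement_id", "sample_rate",
                "t_start_evaluation", "excitation_times", "clip_level",
                "nominal_amplitude", "self_administered")]
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(base, ".csv"))
}

#' @param csv_path path to the two-channel CSV; the JSON sidecar is expected
#'   next to it.
#' @rdname write_recording
#' @export
read_recording <- function(csv_path) {
  df <- read.csv(csv_path)
  need <- c("time_s", "displacement", "pressure_pa")
  if (!all(need %in% names(df))) {
    stop("format error: recording CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", csv_path), simplifyVector = TRUE)
  structure(list(
    subject_id = meta$subject_id, eye_side = meta$eye_side,
    measurement_id = meta$measurement_id, sample_rate = meta$sample_rate,
    displacement = df$displacement, pressure = df$pressure_pa,
    t_start_evaluation = meta$t_start_evaluation,
    excitation_times = as.numeric(meta$excitation_times %||% numeric(0)),
    clip_level = meta$clip_level, nominal_amplitude = meta$nominal_amplitude,
    self_administered = isTRUE(meta$self_administered)
  ), class = "raw_measurement")
}
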