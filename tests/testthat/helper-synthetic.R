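# Shared fixtures, all generated in code.

# sampled damped sinusoid starting at t = 0, default 40 ms @ 10 kHz
make_pulse <- function(frequency, damping, sr = 10000, dur = 0.04,
                       amplitude = 1, noise_sd = 0) {
  t <- seq(0, dur - 1 / sr, by = 1 / sr)
  damped_pulse(t, amplitude, damping, frequency) + rnorm(length(t), 0, noise_sd)
}

# feature-level synthetic dataset through the forward model (no recordings);
# quick fixture for calibration and agreement tests
make_feature_data <- function(n, seed = 1, feature_noise = 0, ref_noise = 0) {
  withr::with_seed(seed, {
    bio <- data.frame(
      subject_id = sprintf("P%03d", seq_len(n)),
      measurement_id = sprintf("P%03d-OD-M1", seq_len(n)),
      age = pmin(pmax(rnorm(n, 61.7, 17.1), 18), 100),
      visual_acuity = pmin(pmax(rnorm(n, 0.7, 0.3), 0.05), 2),
      cornea_radius = pmin(pmax(rnorm(n, 7.8, 0.3), 6), 10),
      central_corneal_thickness = pmin(pmax(rnorm(n, 545, 36), 400), 700),
      axial_length = pmin(pmax(rnorm(n, 24, 2), 19), 32),
      anterior_chamber_depth = pmin(pmax(rnorm(n, 3.1, 0.7), 1.5), 5)
    )
    iop <- runif(n, 8, 35)
    fm <- forward_model(bio, iop)
    bio$mean_damping <- fm$damping * (1 + rnorm(n, 0, feature_noise))
    bio$mean_frequency <- fm$frequency * (1 + rnorm(n, 0, feature_noise))
    bio$mean_amplitude <- rnorm(n, 1, 0.02)
    bio$reference_iop <- iop + rnorm(n, 0, ref_noise)
    bio
  })
}

# a small clean simulation config with no failures
clean_sim_config <- function(n_subjects = 2, ...) {
  sim_config(n_subjects = n_subjects,
             failure_probabilities = c(no_start = 0, movement = 0,
                                       leakage = 0, pressure_deviation = 0),
             ...)
}
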