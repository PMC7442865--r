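# Raw-signal preprocessing and feature extraction --------------------------
#
# Turns a raw_measurement into per-pulse and per-measurement damping and
# frequency features: touchdown detection on the pressure channel, baseline
# balancing by piecewise third-order polynomials through quiet-segment
# anchors, pulse segmentation, zero-crossing frequency estimation, and
# log-envelope damping estimation.

#' Detect the touchdown overpressure pattern
#'
#' A pressure fluctuation is expected when the tonometer seals correctly on
#' the orbit: the chamber volume is compressed and the pressure rises.  The
#' detector reports `TRUE` iff a sustained overpressure (at or above
#' `threshold` for at least `min_duration` seconds) occurs within the
#' pre-evaluation phase `[0, t_end]`.
#'
#' @param pressure chamber-pressure trace, Pa (relative).
#' @param sample_rate Hz.
#' @param t_end end of the pre-evaluation phase, s.
#' @param threshold overpressure threshold, Pa.
#' @param min_duration minimum sustained duration, s.
#' @return logical scalar.
#' @export
detect_touchdown <- function(pressure, sample_rate, t_end = 5,
                             threshold = 50, min_duration = 0.2) {
  n_end <- floor(t_end * sample_rate)
  if (length(pressure) < n_end) {
    stop("input error: pressure trace shorter than t_end", call. = FALSE)
  }
  above <- pressure[seq_len(n_end)] >= threshold
  r <- rle(above)
  any(r$values & r$lengths >= min_duration * sample_rate)
}

#' Locate quiet-segment anchors for baseline balancing
#'
#' Finds the quiet (pulse-free) stretches of the displacement trace —
#' including the pre-evaluation phase — and returns baseline anchors along
#' them: each quiet run is subdivided into chunks of about `chunk_s`
#' seconds, and every chunk contributes one anchor (sample index at the
#' chunk midpoint, value = median of the trace over the chunk; the median
#' is insensitive to any residual symmetric oscillation).  Pulse regions
#' are located robustly on a running-median detrended copy of the trace, so
#' slow drift does not mask them.
#'
#' @param x displacement trace.
#' @param sample_rate Hz.
#' @param t_start start of the evaluation window, s (used to scale the
#'   activity threshold on the evaluation part of the trace).
#' @param guard_s guard time excluded around detected pulse activity, s.
#' @param chunk_s anchor spacing along quiet stretches, s.
#' @return data.frame with columns `index`, `value`; zero rows if no quiet
#'   segment is found.
#' @export
quiet_anchors <- function(x, sample_rate, t_start = 5, guard_s = 0.02,
                          chunk_s = 0.12) {
  n <- length(x)
  i0 <- max(1L, min(floor(t_start * sample_rate) + 1L, n))
  k <- 2L * floor(0.025 * sample_rate) + 1L   # ~50 ms running median
  base <- runmed(x, min(k, 2L * (n %/% 2L) - 1L))
  r <- x - base
  eval_idx <- i0:n
  floor_sd <- mad(r[eval_idx])
  thr <- max(5 * floor_sd, 0.05 * max(abs(r[eval_idx])), 1e-12)
  active <- abs(r) > thr
  guard <- ceiling(guard_s * sample_rate)
  act_idx <- which(active)
  if (length(act_idx)) {
    # dilate activity by the guard on both sides (interval-count trick)
    d <- integer(n + 1L)
    lo <- pmax(act_idx - guard, 1L)
    hi <- pmin(act_idx + guard, n)
    for (q in seq_along(lo)) { d[lo[q]] <- d[lo[q]] + 1L; d[hi[q] + 1L] <- d[hi[q] + 1L] - 1L }
    active <- cumsum(d[seq_len(n)]) > 0L
  }
  quiet <- !active
  rq <- rle(quiet)
  ends <- cumsum(rq$lengths)
  starts <- ends - rq$lengths + 1L
  keep <- which(rq$values & rq$lengths >= ceiling(0.02 * sample_rate))
  if (!length(keep)) return(data.frame(index = integer(0), value = numeric(0)))
  chunk <- max(ceiling(chunk_s * sample_rate), 1L)
  idx <- integer(0); val <- numeric(0)
  for (j in keep) {
    m <- ceiling((ends[j] - starts[j] + 1L) / chunk)
    edges <- round(seq(starts[j], ends[j] + 1L, length.out = m + 1L))
    for (q in seq_len(m)) {
      a <- edges[q]; b <- edges[q + 1L] - 1L
      if (b < a) next
      idx <- c(idx, as.integer(round((a + b) / 2)))
      val <- c(val, median(x[a:b]))
    }
  }
  data.frame(index = idx, value = val)
}

#' Balance the varying signal offset
#'
#' Subtracts a piecewise third-order polynomial (natural cubic spline)
#' through the quiet-segment anchor medians, removing the slow baseline
#' drift caused by subject movement while leaving the high-frequency pulses
#' untouched.  With fewer than 4 anchors the function falls back to a single
#' cubic fitted over the evaluation window (a message is emitted).
#'
#' @param x displacement trace.
#' @param anchors data.frame with columns `index`, `value`, e.g. from
#'   [quiet_anchors()].
#' @param sample_rate Hz (used only by the fallback to locate the
#'   evaluation window).
#' @param t_start start of the evaluation window, s (fallback only).
#' @return the detrended trace (same length as `x`).
#' @export
detrend_offset <- function(x, anchors, sample_rate = NULL, t_start = 5) {
  n <- length(x)
  if (is.null(anchors) || nrow(anchors) < 4L) {
    message("detrend_offset: fewer than 4 anchors, falling back to a single cubic fit")
    i0 <- if (!is.null(sample_rate)) max(1L, floor(t_start * sample_rate) + 1L) else 1L
    idx <- i0:n
    tt <- idx / n
    fit <- lm(x[idx] ~ poly(tt, 3, raw = TRUE))
    all_t <- seq_len(n) / n
    base <- cbind(1, all_t, all_t^2, all_t^3) %*% coef(fit)
    return(x - as.numeric(base))
  }
  o <- order(anchors$index)
  sf <- splinefun(anchors$index[o], anchors$value[o], method = "natural")
  x - sf(seq_len(n))
}

#' Segment the excitation-pulse responses
#'
#' Detects pulse onsets in the evaluation window as excursions of the
#' detrended trace above `k_onset` times the noise floor (median absolute
#' deviation based), groups them into pulses separated by at least `gap_s`,
#' and cuts a fixed window (default 40 ms) per pulse, truncated at the next
#' onset.  Segments before `t_start` are discarded.  The `clipped` flag is
#' set when any raw sample of the window sits at the sensor rail.
#'
#' @param x detrended displacement trace.
#' @param sample_rate Hz.
#' @param t_start start of the evaluation window, s.
#' @param noise_floor robust noise SD; estimated from the evaluation window
#'   when `NULL`.
#' @param clip_level sensor rail magnitude (from the device metadata);
#'   `NULL` disables clip detection.
#' @param raw undetrended trace used for clip detection (defaults to `x`).
#' @param window_s fixed analysis window per pulse, s.
#' @param gap_s minimum quiet gap separating pulses, s.
#' @param k_onset onset threshold in noise-floor multiples.
#' @return list of `pulse_segment` objects (fields `samples`, `t0`,
#'   `sample_rate`, `pulse_index`, `clipped`, `noise_floor`); empty list if
#'   nothing is detected.
#' @export
segment_pulses <- function(x, sample_rate, t_start = 5, noise_floor = NULL,
                           clip_level = NULL, raw = NULL, window_s = 0.04,
                           gap_s = 0.02, k_onset = 5) {
  n <- length(x)
  i0 <- floor(t_start * sample_rate) + 1L
  if (n <= i0) stop("input error: trace does not extend beyond t_start", call. = FALSE)
  if (is.null(raw)) raw <- x
  eval_idx <- i0:n
  if (is.null(noise_floor)) noise_floor <- mad(x[eval_idx])
  thr <- max(k_onset * noise_floor, 1e-9 * max(abs(x[eval_idx]), 1e-300))
  hot <- which(abs(x) > thr)
  hot <- hot[hot >= i0]
  if (!length(hot)) return(list())
  gap <- ceiling(gap_s * sample_rate)
  brk <- which(diff(hot) > gap)
  starts <- hot[c(1L, brk + 1L)]
  wlen <- round(window_s * sample_rate)
  out <- vector("list", length(starts))
  for (j in seq_along(starts)) {
    on <- max(starts[j] - 2L, i0)            # small backoff to catch the rise
    end <- min(on + wlen - 1L, n)
    if (j < length(starts)) end <- min(end, starts[j + 1L] - 1L)
    if (end - on + 1L < 8L) { out[j] <- list(NULL); next }
    seg <- x[on:end]
    clipped <- if (is.null(clip_level)) FALSE else
      any(abs(raw[on:end]) >= clip_level * (1 - 1e-6))
    out[[j]] <- structure(list(
      samples = seg,
      t0 = (on - 1L) / sample_rate,
      sample_rate = sample_rate,
      pulse_index = j,
      clipped = clipped,
      noise_floor = noise_floor
    ), class = "pulse_segment")
  }
  out <- out[!vapply(out, is.null, TRUE)]
  for (j in seq_along(out)) out[[j]]$pulse_index <- j
  out
}

#' Count strict zero crossings
#'
#' Number of strict sign changes in the samples (samples equal to zero are
#' ignored).  Invariant under positive amplitude scaling and under overall
#' sign flip.  An all-zero segment yields 0 with a warning.
#'
#' @param segment a `pulse_segment` or numeric vector.
#' @return integer count.
#' @export
count_zero_crossings <- function(segment) {
  x <- if (inherits(segment, "pulse_segment")) segment$samples else segment
  if (!length(x)) stop("input error: empty segment", call. = FALSE)
  s <- sign(x)
  s <- s[s != 0]
  if (!length(s)) {
    warning("count_zero_crossings: all-zero segment")
    return(0L)
  }
  sum(diff(s) != 0)
}

# adaptive analysis window: keep samples until the rolling-max envelope
# first falls below max(4*floor, frac*peak) after the peak -- beyond that
# point the trace is sensor noise, not oscillation
usable_window <- function(x, sample_rate, noise_floor, frac = 0.01) {
  w <- max(3L, ceiling(1.5 * sample_rate / 350 / 2))
  env <- running_max(x, w)
  ipk <- which.max(env)
  thr <- max(4 * noise_floor, frac * env[ipk])
  below <- which(env < thr)
  below <- below[below > ipk]
  last <- if (length(below)) below[1] - 1L else length(x)
  seq_len(max(last, min(length(x), 8L)))
}

# zero-crossing times with optional hysteresis h: only samples with |x| > h
# define the oscillation state; crossing time by linear interpolation
# between the bracketing retained samples
crossing_times <- function(x, sample_rate, h = 0) {
  t <- (seq_along(x) - 1) / sample_rate
  keep <- which(abs(x) > h)
  if (length(keep) < 2L) return(numeric(0))
  xs <- x[keep]
  flip <- which(sign(xs[-1]) != sign(xs[-length(xs)]))
  if (!length(flip)) return(numeric(0))
  i <- keep[flip]; j <- keep[flip + 1L]
  t[i] + (t[j] - t[i]) * x[i] / (x[i] - x[j])
}

#' Estimate the pulse frequency from zero crossings
#'
#' \eqn{\hat f = (n_c - 1) / (2 (t_{last} - t_{first}))} over the
#' interpolated zero-crossing times of the analysis window.  Crossings are
#' detected with a Schmitt-trigger hysteresis of `2 * noise_floor` so that
#' sensor noise near a crossing is not counted as extra oscillation; for a
#' noiseless sinusoid the estimator is exact to interpolation error
#' (< 0.5 %).
#'
#' @param segment a `pulse_segment` or numeric vector.
#' @param sample_rate Hz (taken from the segment when available).
#' @param noise_floor robust noise SD (taken from the segment when
#'   available).
#' @return frequency in Hz.
#' @export
estimate_frequency <- function(segment, sample_rate = NULL, noise_floor = 0) {
  if (inherits(segment, "pulse_segment")) {
    sample_rate <- segment$sample_rate
    noise_floor <- segment$noise_floor %||% 0
    x <- segment$samples
  } else x <- segment
  if (is.null(sample_rate)) stop("estimate_frequency: sample_rate required", call. = FALSE)
  idx <- usable_window(x, sample_rate, noise_floor)
  tc <- crossing_times(x[idx], sample_rate, h = 2 * noise_floor)
  if (length(tc) < 3L) {
    stop(structure(class = c("tonocal_undefined_frequency", "error", "condition"),
                   list(message = "undefined frequency: fewer than 3 zero crossings",
                        call = NULL)))
  }
  (length(tc) - 1) / (2 * (tc[length(tc)] - tc[1]))
}

#' Estimate the damping (exponential decay rate) of a pulse
#'
#' Least-squares line through \eqn{(t_i, \ln |A_i|)} over successive local
#' extrema magnitudes of the analysis window; the decay rate is the negated
#' slope, in 1/s.  Extremum times and magnitudes are refined by parabolic
#' interpolation through the three samples around each peak; only extrema
#' above 4x the noise floor enter the fit, peak magnitudes are deflated for
#' the expected noise inflation (\eqn{\sqrt{A^2 - (2.2\sigma)^2}}), and the
#' fit is weighted by squared magnitude (inverse variance of the
#' log-magnitude).  Invariant under positive amplitude scaling; for a
#' noiseless damped sinusoid the relative error is < 1 %.
#'
#' @inheritParams estimate_frequency
#' @return decay rate lambda, 1/s.
#' @export
estimate_damping <- function(segment, sample_rate = NULL, noise_floor = 0) {
  if (inherits(segment, "pulse_segment")) {
    sample_rate <- segment$sample_rate
    noise_floor <- segment$noise_floor %||% 0
    x <- segment$samples
  } else x <- segment
  if (is.null(sample_rate)) stop("estimate_damping: sample_rate required", call. = FALSE)
  idx <- usable_window(x, sample_rate, noise_floor)
  x <- x[idx]
  n <- length(x)
  if (n < 3L) stop_undefined_damping()
  ax <- abs(x)
  i <- 2:(n - 1L)
  is_peak <- ax[i] >= ax[i - 1L] & ax[i] > ax[i + 1L] &
    ax[i] > max(4 * noise_floor, 1e-300)
  pk <- i[is_peak]
  if (length(pk) < 3L) stop_undefined_damping()
  # parabolic refinement on the signed samples around each extremum
  y1 <- x[pk - 1L]; y2 <- x[pk]; y3 <- x[pk + 1L]
  denom <- y1 - 2 * y2 + y3
  delta <- ifelse(abs(denom) > 1e-300, 0.5 * (y1 - y3) / denom, 0)
  delta[abs(delta) > 1] <- 0
  amp <- abs(y2 - 0.25 * (y1 - y3) * delta)
  if (noise_floor > 0) {
    # deflate for the expected upward noise bias of a picked peak magnitude
    amp <- sqrt(pmax(amp^2 - (2.2 * noise_floor)^2, (0.5 * noise_floor)^2))
  }
  tt <- (pk - 1 + delta) / sample_rate
  # inverse-variance weights: SD of log|A| scales as noise_floor / A
  w <- amp^2
  mw <- sum(w * tt) / sum(w)
  my <- sum(w * log(amp)) / sum(w)
  -sum(w * (tt - mw) * (log(amp) - my)) / sum(w * (tt - mw)^2)
}

stop_undefined_damping <- function() {
  stop(structure(class = c("tonocal_undefined_damping", "error", "condition"),
                 list(message = "undefined damping: fewer than 3 usable extrema",
                      call = NULL)))
}

#' Per-pulse feature extraction
#'
#' Computes zero-crossing count, frequency, damping and amplitude for one
#' segmented pulse.  Frequency or damping that cannot be determined (too few
#' crossings or extrema) are returned as `NA`; validity is decided
#' downstream by [validate_pulse()].
#'
#' @param segment a `pulse_segment`.
#' @return one-row data.frame with columns `pulse_index`, `t0`,
#'   `n_zero_crossings`, `frequency`, `damping`, `amplitude`, `clipped`.
#' @export
pulse_features <- function(segment) {
  stopifnot(inherits(segment, "pulse_segment"))
  idx <- usable_window(segment$samples, segment$sample_rate,
                       segment$noise_floor %||% 0)
  ncr <- count_zero_crossings(segment$samples[idx])
  f <- tryCatch(estimate_frequency(segment), tonocal_undefined_frequency = function(e) NA_real_)
  lam <- tryCatch(estimate_damping(segment), tonocal_undefined_damping = function(e) NA_real_)
  data.frame(pulse_index = segment$pulse_index,
             t0 = segment$t0,
             n_zero_crossings = ncr,
             frequency = f,
             damping = lam,
             amplitude = max(abs(segment$samples)),
             clipped = isTRUE(segment$clipped))
}

#' Flag out-of-band chamber-pressure swings in the evaluation window
#'
#' Any pressure sample deviating more than `threshold` from the evaluation-
#' window baseline (median) marks the measurement as showing an unusually
#' large pressure fluctuation.
#'
#' @param pressure chamber-pressure trace, Pa.
#' @param sample_rate Hz.
#' @param t_start start of the evaluation window, s.
#' @param threshold deviation threshold, Pa; default 3x the nominal
#'   touchdown overpressure.
#' @return logical scalar.
#' @export
pressure_deviation_flag <- function(pressure, sample_rate, t_start = 5,
                                    threshold = 300) {
  idx <- (floor(t_start * sample_rate) + 1L):length(pressure)
  base <- median(pressure[idx])
  any(abs(pressure[idx] - base) > threshold)
}

#' Summarize per-pulse features into measurement-level features
#'
#' Means and SDs are computed over valid pulses only; the damping SD is also
#' reported as a coefficient of variation (percent of the mean).  With zero
#' valid pulses the feature fields are `NA` but the counts are still filled.
#'
#' @param pf per-pulse feature table carrying a logical `valid` column (see
#'   [validate_pulse()]); may have zero rows.
#' @param touchdown logical, touchdown detected.
#' @param pressure_flag logical, out-of-band pressure swing present.
#' @param measurement_id identifier copied into the result.
#' @return one-row data.frame (`measurement_features`).
#' @export
summarize_measurement <- function(pf, touchdown, pressure_flag,
                                  measurement_id = NA_character_) {
  if (is.null(pf) || nrow(pf) == 0L) {
    v <- pf[integer(0), , drop = FALSE]
    nv <- 0L; ntot <- 0L
  } else {
    if (is.null(pf$valid)) stop("summarize_measurement: 'valid' column required; run validate_pulse first",
                                call. = FALSE)
    v <- pf[pf$valid, , drop = FALSE]
    nv <- nrow(v); ntot <- nrow(pf)
  }
  m <- function(col) if (nv > 0L) mean(v[[col]]) else NA_real_
  s <- function(col) if (nv > 1L) sd(v[[col]]) else if (nv == 1L) 0 else NA_real_
  md <- m("damping"); sdd <- s("damping")
  data.frame(measurement_id = measurement_id,
             n_pulses_total = ntot,
             n_pulses_valid = nv,
             mean_damping = md,
             sd_damping = sdd,
             cv_damping_percent = if (nv > 0L && is.finite(md) && md != 0)
               100 * sdd / abs(md) else NA_real_,
             mean_frequency = m("frequency"),
             sd_frequency = s("frequency"),
             mean_amplitude = m("amplitude"),
             touchdown_detected = isTRUE(touchdown),
             pressure_deviation_flag = isTRUE(pressure_flag),
             stringsAsFactors = FALSE)
}

#' Process one raw recording end to end
#'
#' Runs the full signal chain: touchdown detection, robust quiet-segment
#' anchoring, baseline balancing, pulse segmentation, per-pulse feature
#' extraction, validity flagging, and measurement-level summarization.
#'
#' @param rec a `raw_measurement`.
#' @param min_crossings,band validity thresholds forwarded to
#'   [validate_pulse()].
#' @param touchdown_threshold Pa, see [detect_touchdown()].
#' @param pressure_threshold Pa, see [pressure_deviation_flag()].
#' @return list with elements `pulses` (per-pulse feature table, validated)
#'   and `measurement` (one-row measurement feature table).
#' @export
process_recording <- function(rec, min_crossings = 7, band = c(350, 570),
                              touchdown_threshold = 50,
                              pressure_threshold = 300) {
  stopifnot(inherits(rec, "raw_measurement"))
  sr <- rec$sample_rate
  t0 <- rec$t_start_evaluation
  touchdown <- detect_touchdown(rec$pressure, sr, t_end = t0,
                                threshold = touchdown_threshold)
  pflag <- pressure_deviation_flag(rec$pressure, sr, t_start = t0,
                                   threshold = pressure_threshold)
  anch <- quiet_anchors(rec$displacement, sr, t_start = t0)
  x <- if (nrow(anch) >= 4L) detrend_offset(rec$displacement, anch)
       else suppressMessages(detrend_offset(rec$displacement, anch, sr, t0))
  i0 <- floor(t0 * sr) + 1L
  floor_sd <- mad(x[i0:length(x)])
  segs <- segment_pulses(x, sr, t_start = t0, noise_floor = floor_sd,
                         clip_level = rec$clip_level, raw = rec$displacement)
  pf <- if (length(segs)) do.call(rbind, lapply(segs, pulse_features))
        else data.frame(pulse_index = integer(0), t0 = numeric(0),
                        n_zero_crossings = integer(0), frequency = numeric(0),
                        damping = numeric(0), amplitude = numeric(0),
                        clipped = logical(0))
  pf <- validate_pulse(pf, min_crossings = min_crossings, band = band)
  if (nrow(pf)) pf$measurement_id <- rec$measurement_id
  mf <- summarize_measurement(pf, touchdown, pflag, rec$measurement_id)
  mf$self_administered <- isTRUE(rec$self_administered)
  list(pulses = pf, measurement = mf)
}
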