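#' Idealized spherical 10-10 montage
#'
#' Builds unit-sphere electrode positions for a 64-channel cap laid out
#' on an idealized spherical 10-10 grid (vertex at Cz, nasion forward).
#' Positions are generated geometrically from each label's anterior-
#' posterior row and lateral index; they are a smooth, plausible cap for
#' simulation and spherical-spline interpolation, not digitized
#' coordinates from any particular headset.
#'
#' @param n_channels number of channels (<= 64). For fewer than 64, a
#'   deterministic evenly spaced subset of the 64 labels is used so
#'   scalp coverage is retained.
#' @return data.frame of class `montage` with columns `label`, `x`
#'   (right+), `y` (front+), `z` (up+); rows are unit vectors.
#' @export
montage_positions <- function(n_channels = 64L) {
  labels <- c("Fp1", "Fpz", "Fp2",
              "AF7", "AF3", "AFz", "AF4", "AF8",
              "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
              "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
              "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
              "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
              "P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10",
              "PO7", "PO3", "POz", "PO4", "PO8",
              "O1", "Oz", "O2", "Iz")
  stopifnot(n_channels >= 2L, n_channels <= length(labels))
  row_angle <- c(Fp = 72, AF = 54, F = 36, FT = 18, FC = 18, T = 0, C = 0,
                 TP = -18, CP = -18, P = -36, PO = -54, O = -72, I = -90)
  parse_one <- function(lab) {
    m <- regmatches(lab, regexec("^([A-Za-z]+)(z|[0-9]+)$", lab))[[1]]
    row <- m[2]; idx <- m[3]
    a <- row_angle[[row]]
    if (idx == "z") l <- 0 else {
      d <- as.integer(idx)
      l <- ceiling(d / 2) * 18 * if (d %% 2 == 1) -1 else 1
    }
    theta <- sqrt(a^2 + l^2) * pi / 180
    phi <- atan2(l, a)
    c(x = sin(theta) * sin(phi), y = sin(theta) * cos(phi), z = cos(theta))
  }
  pos <- t(vapply(labels, parse_one, numeric(3)))
  if (n_channels < length(labels)) {
    idx <- unique(round(seq(1, length(labels), length.out = n_channels)))
    labels <- labels[idx]; pos <- pos[idx, , drop = FALSE]
  }
  structure(data.frame(label = labels, x = pos[, 1], y = pos[, 2],
                       z = pos[, 3], row.names = NULL),
            class = c("montage", "data.frame"))
}

#' Parameters of the synthetic SNR-dependent TRF kernel
#'
#' The simulated temporal response function is a sum of three Gaussian
#' deflections: positive peaks P1 (~50 ms) and P2 (~200 ms) and a
#' negative trough N1 (~120 ms), shared across channels up to a smooth
#' frontocentrally peaked topographic gain. Latencies and amplitudes
#' change linearly with SNR; the default per-dB slopes are the
#' mixed-model coefficients estimated on real listeners (latency:
#' -0.940/-1.517/-6.001 ms per dB and amplitude: 0.011/-0.015/0.018 a.u.
#' per dB for P1/N1/P2), so latencies shorten and amplitude magnitudes
#' grow as SNR increases.
#'
#' @param l0 baseline latencies (ms) at `snr_ref` for P1, N1, P2.
#' @param p0 baseline amplitudes (a.u.); N1 must be negative.
#' @param w Gaussian widths (ms).
#' @param latency_slope ms per dB of SNR per component (dl/dSNR).
#' @param amplitude_slope a.u. per dB per component (dp/dSNR).
#' @param snr_ref reference SNR in dB (relative to the listener's SRT) at
#'   which baselines apply.
#' @param clean_effective_snr effective relative SNR assigned to the
#'   clean-speech condition: the highest gain and shortest latencies.
#' @param topo_center,topo_sd_deg center label and angular spread
#'   (degrees) of the Gaussian topographic gain.
#' @param montage a [montage_positions()] data.frame.
#' @return a list of class `synth_trf_params` with a `components`
#'   data.frame and a unit-norm per-channel `topography`.
#' @export
synth_trf_params <- function(l0 = c(50, 120, 200),
                             p0 = c(0.10, -0.15, 0.18),
                             w = c(25, 30, 40),
                             latency_slope = c(-0.940, -1.517, -6.001),
                             amplitude_slope = c(0.011, -0.015, 0.018),
                             snr_ref = 0,
                             clean_effective_snr = 6,
                             topo_center = "FCz",
                             topo_sd_deg = 45,
                             montage = montage_positions()) {
  stopifnot(all(w > 0), p0[1] > 0, p0[2] < 0, p0[3] > 0,
            l0[1] < l0[2], l0[2] < l0[3])
  comps <- data.frame(component = c("P1", "N1", "P2"),
                      l0 = l0, p0 = p0, w = w,
                      latency_slope = latency_slope,
                      amplitude_slope = amplitude_slope)
  center <- if (topo_center %in% montage$label) {
    as.numeric(montage[montage$label == topo_center, c("x", "y", "z")])
  } else c(0, sin(18 * pi / 180), cos(18 * pi / 180)) # FCz position
  pos <- as.matrix(montage[, c("x", "y", "z")])
  ang <- acos(pmin(1, pmax(-1, pos %*% center))) * 180 / pi
  topo <- exp(-ang^2 / (2 * topo_sd_deg^2))
  topo <- as.numeric(topo / sqrt(sum(topo^2)))
  structure(list(components = comps, snr_ref = snr_ref,
                 clean_effective_snr = clean_effective_snr,
                 topography = topo, montage = montage),
            class = "synth_trf_params")
}

#' Component latencies and amplitudes at a given SNR
#'
#' @param params a [synth_trf_params()].
#' @param snr_db numeric SNR in dB relative to the listener's SRT, or
#'   `"clean"`.
#' @return the `components` data.frame with columns `l` (ms) and `p`
#'   (a.u.) evaluated at the requested SNR.
#' @export
kernel_components_at <- function(params, snr_db) {
  s <- if (identical(snr_db, "clean")) params$clean_effective_snr
       else as.numeric(snr_db)
  cmp <- params$components
  cmp$l <- cmp$l0 + cmp$latency_slope * (s - params$snr_ref)
  cmp$p <- cmp$p0 + cmp$amplitude_slope * (s - params$snr_ref)
  if (is.unsorted(cmp$l, strictly = TRUE))
    stop(sprintf("component latency order P1 < N1 < P2 violated at SNR %s",
                 as.character(snr_db)))
  if (cmp$p[1] <= 0 || cmp$p[2] >= 0 || cmp$p[3] <= 0)
    stop(sprintf("component amplitude sign violated at SNR %s",
                 as.character(snr_db)))
  cmp
}

#' Synthetic per-channel TRF kernel
#'
#' `kernel(tau) = sum_c p_c(snr) * exp(-((tau - l_c(snr)) / w_c)^2)`,
#' scaled per channel by the topographic gain.
#'
#' @param params a [synth_trf_params()].
#' @param snr_db SNR in dB relative to the listener's SRT, or `"clean"`.
#' @param window [lag_window()] of the kernel; default 0-400 ms at 64 Hz.
#' @return a list of class `trf_kernel`: `weights` (lags by channels),
#'   `window`, `timecourse`, `components` (evaluated latencies and
#'   amplitudes), `snr_db`.
#' @export
make_trf_kernel <- function(params, snr_db, window = lag_window(0, 400, 64)) {
  stopifnot(inherits(params, "synth_trf_params"))
  cmp <- kernel_components_at(params, snr_db)
  tau <- window$tau_ms
  tc <- numeric(length(tau))
  for (i in seq_len(nrow(cmp)))
    tc <- tc + cmp$p[i] * exp(-((tau - cmp$l[i]) / cmp$w[i])^2)
  structure(list(weights = outer(tc, params$topography), window = window,
                 timecourse = tc, components = cmp, snr_db = snr_db),
            class = "trf_kernel")
}

#' A simulated listener
#'
#' Defines the listener's true speech reception threshold, the per-word
#' logistic psychometric function (probability correct is exactly 0.5 at
#' `srt_true`), and a monotone neural gain profile `g(SNR)` in `(0, 1]`
#' mapping stimulus SNR to the strength of neural envelope tracking. The
#' gain is logistic and centered on `srt_true`, which places the
#' informative region of the reconstruction-accuracy-versus-SNR curve
#' around the behavioral threshold; clean speech gets gain 1.
#'
#' @param srt_true true SRT in dB.
#' @param word_slope logistic growth rate per word per dB (the
#'   psychometric slope at midpoint is `word_slope / 4` per dB).
#' @param gain_slope logistic growth rate per dB of the neural gain.
#' @return a list of class `simulated_listener` including the gain
#'   function `gain(snr_db)` (accepts `"clean"`).
#' @export
simulated_listener <- function(srt_true = -5, word_slope = 0.5,
                               gain_slope = 0.35) {
  stopifnot(word_slope > 0, gain_slope > 0)
  gain <- function(snr_db) {
    if (identical(snr_db, "clean")) return(1)
    stats::plogis(gain_slope * (as.numeric(snr_db) - srt_true))
  }
  structure(list(srt_true = srt_true, word_slope = word_slope,
                 gain_slope = gain_slope, gain = gain),
            class = "simulated_listener")
}

#' Simulate a word-scored sentence response
#'
#' Words correct follow `Binomial(n_words, plogis(word_slope * (snr -
#' srt_true)))`; the per-word probability is exactly 0.5 at the
#' listener's true SRT.
#'
#' @param listener a [simulated_listener()].
#' @param snr_db presentation SNR in dB.
#' @param n_words words per sentence.
#' @param seed integer seed (deterministic given seed).
#' @return integer number of words correct.
#' @export
simulate_sentence_response <- function(listener, snr_db, n_words = 5L,
                                       seed = 1L) {
  stopifnot(inherits(listener, "simulated_listener"), n_words >= 1L)
  p <- stats::plogis(listener$word_slope * (snr_db - listener$srt_true))
  set.seed(seed)
  stats::rbinom(1L, n_words, p)
}

#' Generate a speech-like surrogate envelope
#'
#' Gaussian noise band-pass filtered to 1-8 Hz (zero-phase Butterworth,
#' as in the envelope pipeline) and mean-removed; its modulation spectrum
#' peaks in the 2-6 Hz range typical of speech.
#'
#' @param duration duration in seconds (>= 10).
#' @param seed integer seed (deterministic given seed).
#' @param rate output rate in Hz.
#' @param band band-pass edges in Hz.
#' @param trial_id,snr_db labels stored on the output.
#' @return an [envelope_signal()] with `round(duration * rate)` samples.
#' @export
make_envelope <- function(duration, seed, rate = 64, band = c(1, 8),
                          trial_id = NA_character_, snr_db = NA) {
  if (duration < 10) stop("duration must be at least 10 s")
  n <- round(duration * rate)
  set.seed(seed)
  x <- stats::rnorm(n)
  x <- bandpass_filtfilt(x, band, rate)
  x <- x - mean(x)
  envelope_signal(x, rate, trial_id, snr_db)
}

# Unit-SD 1/f (pink) noise via FFT spectral shaping.
#' @keywords internal
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  f <- stats::fft(w)
  k <- c(1, pmin(seq_len(n - 1), n - seq_len(n - 1)))
  f <- f / sqrt(k)
  x <- Re(stats::fft(f, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Construct an EEG trial container
#'
#' @param data time-by-channels numeric matrix.
#' @param rate sampling rate in Hz.
#' @param channel_labels character vector, one per column.
#' @param condition condition label (e.g. `"-4"`, `"0"`, `"clean"`).
#' @param snr_db absolute presentation SNR in dB (`NA` for clean).
#' @param participant_id,trial_id identifiers.
#' @return object of class `eeg_trial`.
#' @export
eeg_trial <- function(data, rate, channel_labels,
                      condition = NA_character_, snr_db = NA,
                      participant_id = NA_character_,
                      trial_id = NA_character_) {
  data <- as.matrix(data)
  stopifnot(ncol(data) == length(channel_labels))
  structure(list(data = data, rate = rate, channel_labels = channel_labels,
                 condition = condition, snr_db = snr_db,
                 participant_id = participant_id, trial_id = trial_id),
            class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial %s: %d ch x %d samples at %g Hz, condition %s>\n",
              x$trial_id, ncol(x$data), nrow(x$data), x$rate,
              as.character(x$condition)))
  invisible(x)
}

#' Simulate one EEG trial from an envelope and a TRF kernel
#'
#' Each channel is `g(snr) * (envelope (*) kernel)` plus 1/f-shaped noise
#' mixed with 10 percent white sensor noise. The noise standard deviation
#' is `noise_level` times the mean across channels of the clean (gain 1)
#' convolution's SD, so `noise_level` is a dimensionless noise-to-signal
#' ratio and reconstruction accuracy increases monotonically with
#' stimulus SNR in expectation.
#'
#' @param envelope an [envelope_signal()].
#' @param kernel a [make_trf_kernel()] result.
#' @param listener a [simulated_listener()] providing the gain profile.
#' @param snr_db absolute presentation SNR in dB, or `"clean"`.
#' @param noise_level non-negative noise-to-signal ratio.
#' @param seed integer seed (deterministic given seed).
#' @param white_fraction fraction of noise variance that is white.
#' @param ... labels forwarded to [eeg_trial()].
#' @return an [eeg_trial()] at the envelope's rate.
#' @export
simulate_eeg <- function(envelope, kernel, listener, snr_db,
                         noise_level = 10, seed = 1L,
                         white_fraction = 0.1, ...) {
  stopifnot(inherits(envelope, "envelope_signal"),
            inherits(kernel, "trf_kernel"))
  if (noise_level < 0) stop("noise_level must be non-negative")
  env <- envelope$values
  n <- length(env)
  if (max(kernel$window$lags) >= n)
    stop("kernel lag span exceeds envelope duration")
  X <- build_lag_matrix(matrix(env, ncol = 1), kernel$window,
                        direction = "forward")
  base <- as.numeric(X %*% kernel$timecourse)
  # per-channel topographic gains (kernel is separable: weights = tc x topo)
  topo <- sqrt(colSums(kernel$weights^2) / sum(kernel$timecourse^2))
  g <- listener$gain(snr_db)
  sig <- outer(base * g, topo)
  sd_ref <- stats::sd(base) * mean(topo)
  nch <- length(topo)
  noise <- matrix(0, n, nch)
  if (noise_level > 0) {
    set.seed(seed)
    for (ch in seq_len(nch)) {
      noise[, ch] <- noise_level * sd_ref *
        (sqrt(1 - white_fraction) * pink_noise(n) +
         sqrt(white_fraction) * stats::rnorm(n))
    }
  }
  eeg_trial(sig + noise, envelope$rate, seq_len(nch), snr_db =
              if (identical(snr_db, "clean")) NA else snr_db, ...)
}

#' Simulate a full multi-condition EEG dataset for one listener
#'
#' Generates equal numbers of ~1-minute trials at five SNRs in 2-dB steps
#' around a center (by default the listener's true SRT) plus a
#' clean-speech condition: the 6 x 16 = 96-trial design of a single
#' recording session. Ground truth (parameters, listener, per-trial
#' envelopes and kernels) is attached for validation.
#'
#' @param listener a [simulated_listener()].
#' @param params a [synth_trf_params()]; its montage fixes the channels.
#' @param n_trials_per_condition trials per condition (default 16).
#' @param trial_duration trial length in seconds (default 60).
#' @param noise_level noise-to-signal ratio passed to [simulate_eeg()].
#' @param seed master seed; all per-trial seeds derive from it.
#' @param center_db center of the SNR grid in dB; defaults to
#'   `listener$srt_true` (in an experiment, the measured behavioral SRT).
#' @param offsets_db SNR grid relative to the center.
#' @param include_clean include the clean-speech condition.
#' @return object of class `eeg_dataset`: `trials` (list of
#'   [eeg_trial()]), `envelopes` (matched [envelope_signal()]s),
#'   `condition` (character per trial, relative-dB label or `"clean"`),
#'   `snr_rel`, `snr_abs`, `channel_labels`, `montage`, `rate`, `seed`,
#'   and `ground_truth`.
#' @export
make_dataset <- function(listener, params = synth_trf_params(),
                         n_trials_per_condition = 16L,
                         trial_duration = 60,
                         noise_level = 10,
                         seed = 1L,
                         center_db = listener$srt_true,
                         offsets_db = c(-4, -2, 0, 2, 4),
                         include_clean = TRUE) {
  stopifnot(inherits(listener, "simulated_listener"),
            inherits(params, "synth_trf_params"),
            n_trials_per_condition >= 1L)
  cond_labels <- c(sprintf("%+d", offsets_db), if (include_clean) "clean")
  kernels <- list()
  trials <- list(); envs <- list()
  condition <- character(0); snr_rel <- numeric(0); snr_abs <- numeric(0)
  k <- 0L
  for (ci in seq_along(cond_labels)) {
    lab <- cond_labels[ci]
    clean <- identical(lab, "clean")
    rel <- if (clean) "clean" else offsets_db[ci]
    abs_snr <- if (clean) "clean" else center_db + offsets_db[ci]
    kernels[[lab]] <- make_trf_kernel(params, rel)
    for (i in seq_len(n_trials_per_condition)) {
      k <- k + 1L
      env <- make_envelope(trial_duration,
                           seed = derive_seed(seed, "env", lab, i),
                           trial_id = sprintf("%s_%02d", lab, i),
                           snr_db = rel)
      tr <- simulate_eeg(env, kernels[[lab]], listener, abs_snr,
                         noise_level = noise_level,
                         seed = derive_seed(seed, "eeg", lab, i),
                         condition = lab,
                         trial_id = sprintf("%s_%02d", lab, i))
      tr$channel_labels <- params$montage$label
      trials[[k]] <- tr; envs[[k]] <- env
      condition[k] <- lab
      snr_rel[k] <- if (clean) NA_real_ else offsets_db[ci]
      snr_abs[k] <- if (clean) NA_real_ else center_db + offsets_db[ci]
    }
  }
  structure(list(trials = trials, envelopes = envs, condition = condition,
                 snr_rel = snr_rel, snr_abs = snr_abs,
                 channel_labels = params$montage$label,
                 montage = params$montage, rate = 64, seed = seed,
                 center_db = center_db,
                 ground_truth = list(params = params, listener = listener,
                                     kernels = kernels,
                                     noise_level = noise_level)),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf("<eeg_dataset: %d trials (%s), %d channels at %g Hz>\n",
              length(x$trials),
              paste(names(table(x$condition)), collapse = ", "),
              length(x$channel_labels), x$rate))
  invisible(x)
}

#' Generate a pool of mismatched surrogate envelopes
#'
#' Envelopes produced by the same generator under seeds never used for
#' presented trials; they stand in for unused excerpts of the same
#' speech material when computing the reconstruction-accuracy noise
#' floor.
#'
#' @param n pool size (default 68).
#' @param duration duration in seconds of each envelope.
#' @param seed master seed.
#' @return list of [envelope_signal()]s.
#' @export
make_mismatch_pool <- function(n = 68L, duration = 60, seed = 1L) {
  lapply(seq_len(n), function(i)
    make_envelope(duration, seed = derive_seed(seed, "mismatch", i),
                  trial_id = sprintf("mismatch_%02d", i)))
}

#' Simulate a cohort of listeners
#'
#' True SRTs are drawn from a normal distribution matching the spread
#' observed in young normal-hearing adults on the Danish HINT (mean about
#' -5.35 dB, SD well under 1 dB at the cohort level).
#'
#' @param n cohort size.
#' @param seed master seed.
#' @param srt_mean,srt_sd mean and SD (dB) of the true SRT distribution.
#' @param word_slope,gain_slope forwarded to [simulated_listener()].
#' @return list of [simulated_listener()]s.
#' @export
simulate_cohort <- function(n = 20L, seed = 1L, srt_mean = -5.35,
                            srt_sd = 0.7, word_slope = 0.5,
                            gain_slope = 0.35) {
  stopifnot(n >= 1L)
  lapply(seq_len(n), function(i) {
    set.seed(derive_seed(seed, "listener", i))
    simulated_listener(srt_true = stats::rnorm(1, srt_mean, srt_sd),
                       word_slope = word_slope, gain_slope = gain_slope)
  })
}
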