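#' Detect bad channels by the RMS rule
#'
#' Flags every channel whose RMS exceeds 3 times the mean RMS across all
#' channels (candidates included in the mean). The decision is invariant
#' to a global rescaling of the recording. When a list of trials is
#' given, RMS is pooled over the whole recording so the labeling is done
#' once per recording.
#'
#' @param x an [eeg_trial()], a time-by-channels matrix, or a list of
#'   trials from the same recording.
#' @param factor multiple of the mean RMS above which a channel is bad.
#' @return character vector of bad channel labels (column indices when no
#'   labels exist).
#' @export
detect_bad_channels <- function(x, factor = 3) {
  if (inherits(x, "eeg_trial")) {
    labels <- x$channel_labels; mats <- list(x$data)
  } else if (is.list(x) && inherits(x[[1]], "eeg_trial")) {
    labels <- x[[1]]$channel_labels
    mats <- lapply(x, function(t) t$data)
  } else {
    x <- as.matrix(x); labels <- colnames(x) %||% as.character(seq_len(ncol(x)))
    mats <- list(x)
  }
  if (ncol(mats[[1]]) < 2L) stop("need at least 2 channels")
  if (nrow(mats[[1]]) == 0L) stop("zero-length data")
  ss <- Reduce(`+`, lapply(mats, function(m) colSums(m^2)))
  n <- sum(vapply(mats, nrow, numeric(1)))
  rms <- sqrt(ss / n)
  as.character(labels[rms > factor * mean(rms)])
}

# Legendre polynomials P_1..P_nmax evaluated at x (vector), by recurrence.
#' @keywords internal
legendre_terms <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  pm1 <- rep(1, length(x)) # P_0
  p <- x                   # P_1
  out[, 1] <- p
  for (n in 2:nmax) {
    pn <- ((2 * n - 1) * x * p - (n - 1) * pm1) / n
    out[, n] <- pn
    pm1 <- p; p <- pn
  }
  out
}

# Perrin-style spherical spline kernel g(cos angle), stiffness m, series
# truncated at nmax terms.
#' @keywords internal
spline_g <- function(cosang, m = 4, nmax = 50) {
  n <- seq_len(nmax)
  coef <- (2 * n + 1) / (n^m * (n + 1)^m)
  P <- legendre_terms(pmin(1, pmax(-1, cosang)), nmax)
  as.numeric(P %*% coef) / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces bad channels with spherical-spline (Perrin-style, stiffness
#' m = 4) interpolation from the good channels; good channels are left
#' unchanged.
#'
#' @param trial an [eeg_trial()].
#' @param bad character vector of bad channel labels (may be empty).
#' @param montage a [montage_positions()] covering the trial's channels.
#' @param stiffness spline stiffness exponent m.
#' @param nterms number of Legendre terms in the kernel series.
#' @param reg small diagonal regularization of the spline system.
#' @return the trial with bad channels replaced.
#' @export
spherical_interpolate <- function(trial, bad, montage, stiffness = 4,
                                  nterms = 50, reg = 1e-8) {
  stopifnot(inherits(trial, "eeg_trial"))
  if (length(bad) == 0) return(trial)
  labels <- trial$channel_labels
  if (!all(bad %in% labels)) stop("bad channels not present in the trial")
  good <- setdiff(labels, bad)
  if (length(good) < 4L) stop("need at least 4 good channels")
  pos <- as.matrix(montage[match(labels, montage$label), c("x", "y", "z")])
  if (anyNA(pos)) stop("montage is missing channel positions")
  gi <- match(good, labels); bi <- match(bad, labels)
  G <- matrix(spline_g(tcrossprod(pos[gi, , drop = FALSE]),
                       stiffness, nterms), length(gi))
  diag(G) <- diag(G) + reg
  # solve [G 1; 1' 0] [c; c0] = [v; 0] for every time sample at once
  ng <- length(gi)
  A <- rbind(cbind(G, 1), c(rep(1, ng), 0))
  V <- rbind(t(trial$data[, gi, drop = FALSE]), 0)
  sol <- solve(A, V) # (ng+1) x time
  Gb <- matrix(spline_g(pos[bi, , drop = FALSE] %*% t(pos[gi, , drop = FALSE]),
                        stiffness, nterms), length(bi))
  interp <- Gb %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1, ], length(bi), ncol(sol), byrow = TRUE)
  trial$data[, bi] <- t(interp)
  trial
}

#' @keywords internal
common_average <- function(data) {
  data - rowMeans(data)
}

#' Preprocess one EEG trial
#'
#' Fixed order: bad-channel replacement, common-average reference,
#' zero-phase 1-8 Hz Butterworth band-pass (third-order sections run
#' forward and backward), resampling to 64 Hz, division of every channel
#' by the mean of the per-channel standard deviations (one scalar per
#' trial, preserving relative topography), and a final common-average
#' re-reference. Recordings already at 64 Hz (synthetic data are
#' generated band-limited at 64 Hz) skip the filtering and resampling
#' stages.
#'
#' @param trial an [eeg_trial()].
#' @param montage a [montage_positions()]; required when `bad` is
#'   non-empty.
#' @param bad bad channel labels to replace; default detects them with
#'   [detect_bad_channels()] on this trial. Pass the pooled recording
#'   labels to mirror once-per-recording detection.
#' @param band band-pass edges in Hz.
#' @param target_rate output rate in Hz.
#' @param artifact_hook optional `function(trial) trial` inserted after
#'   referencing, where an artifact-removal stage (e.g. ICA-based) would
#'   run on real recordings; the default is a no-op.
#' @return the preprocessed [eeg_trial()] at `target_rate`.
#' @export
preprocess_trial <- function(trial, montage = NULL, bad = NULL,
                             band = c(1, 8), target_rate = 64,
                             artifact_hook = NULL) {
  stopifnot(inherits(trial, "eeg_trial"))
  stop_if_nan(trial$data, "EEG data")
  if (is.null(bad)) bad <- detect_bad_channels(trial)
  if (length(bad) > 0) {
    if (is.null(montage)) stop("montage required to interpolate bad channels")
    trial <- spherical_interpolate(trial, bad, montage)
  }
  trial$data <- common_average(trial$data)
  if (!is.null(artifact_hook)) trial <- artifact_hook(trial)
  if (trial$rate > target_rate) {
    if (trial$rate < 2 * target_rate)
      stop("input rate must be >= 128 Hz or already at the target rate")
    filt <- apply(trial$data, 2, bandpass_filtfilt, band = band,
                  rate = trial$rate)
    trial$data <- apply(filt, 2, resample_to, rate = trial$rate,
                        target = target_rate)
    trial$rate <- target_rate
  }
  sds <- apply(trial$data, 2, stats::sd)
  trial$data <- trial$data / mean(sds)
  trial$data <- common_average(trial$data)
  trial
}

#' Preprocess every trial of a dataset
#'
#' Bad channels are detected once, pooled over all trials of the
#' recording, then each trial is passed through [preprocess_trial()].
#'
#' @param dataset an `eeg_dataset`.
#' @param ... forwarded to [preprocess_trial()].
#' @return the dataset with preprocessed trials and the detected bad
#'   channels stored as `bad_channels`.
#' @export
preprocess_dataset <- function(dataset, ...) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  bad <- detect_bad_channels(dataset$trials)
  dataset$trials <- lapply(dataset$trials, preprocess_trial,
                           montage = dataset$montage, bad = bad, ...)
  dataset$bad_channels <- bad
  dataset$rate <- dataset$trials[[1]]$rate
  dataset
}

#' Read an electrode position table
#'
#' Reads a whitespace- or comma-separated table with columns `label`,
#' `x`, `y`, `z` and normalizes positions to the unit sphere.
#'
#' @param path file path.
#' @return a `montage` data.frame as from [montage_positions()].
#' @export
read_montage <- function(path) {
  d <- if (grepl(",", readLines(path, n = 1L)[1])) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("label", "x", "y", "z") %in% names(d)))
  r <- sqrt(d$x^2 + d$y^2 + d$z^2)
  structure(data.frame(label = d$label, x = d$x / r, y = d$y / r,
                       z = d$z / r),
            class = c("montage", "data.frame"))
}
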