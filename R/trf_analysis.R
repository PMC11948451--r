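#' Table of parameter bounds for Gaussian deflection fits
#'
#' Amplitude `p` (a.u.), latency `l` (ms) and width `w` (ms) bounds for
#' the P1, N1 and P2 deflections of the TRF.
#'
#' @return data.frame with one row per component.
#' @export
deflection_bounds <- function() {
  data.frame(component = c("P1", "N1", "P2"),
             p_lo = c(0, -5, 0), p_hi = c(5, 0, 5),
             l_lo = c(0, 70, 100), l_hi = c(100, 150, 300),
             w_lo = 0, w_hi = 50)
}

#' Fit forward encoders (TRFs) per condition
#'
#' Within each condition the encoder predicting every EEG channel from
#' the lagged envelope is trained with leave-one-out over the trials at a
#' fixed dimensionless regularization of 100 (shared across conditions
#' and participants so TRFs stay comparable). The condition's TRF is the
#' mean of the fold models; prediction accuracy is the per-channel
#' Pearson correlation between predicted and recorded EEG on the held-out
#' trial, averaged over folds.
#'
#' @param dataset an `eeg_dataset` (preprocessed).
#' @param lambda fixed regularization (default 100).
#' @param window encoder lag window; default -100 to 500 ms.
#' @return list of class `trf_estimates`, one element per condition:
#'   `condition`, `trf` (lags-by-channels mean TRF), `pred_r` (mean
#'   per-channel accuracy), `pred_r_trials` (trials-by-channels held-out
#'   accuracies), `lambda`, `window`, `channel_labels`, `snr_rel`.
#' @export
fit_encoder <- function(dataset, lambda = 100,
                        window = lag_window(-100, 500, dataset$rate)) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  conds <- unique(dataset$condition)
  out <- list()
  for (cond in conds) {
    idx <- which(dataset$condition == cond)
    if (length(idx) < 2L)
      stop(sprintf("condition %s has fewer than 2 trials", cond))
    Xs <- lapply(idx, function(i)
      build_lag_matrix(matrix(dataset$envelopes[[i]]$values, ncol = 1),
                       window, "forward"))
    Ys <- lapply(idx, function(i) dataset$trials[[i]]$data)
    moms <- mapply(trial_moments, Xs, Ys, SIMPLIFY = FALSE)
    total <- Reduce(moments_combine, moms)
    nch <- ncol(Ys[[1]])
    w_sum <- 0
    acc <- matrix(NA_real_, length(idx), nch)
    for (f in seq_along(idx)) {
      sol <- ridge_solve_moments(moments_combine(total, moms[[f]], -1),
                                 lambda)
      pred <- sweep(Xs[[f]] %*% sol$weights, 2, sol$intercept, "+")
      for (ch in seq_len(nch)) {
        acc[f, ch] <- tryCatch(pearson_accuracy(pred[, ch], Ys[[f]][, ch]),
                               error = function(e) NA_real_)
      }
      w_sum <- w_sum + sol$weights
    }
    out[[cond]] <- list(condition = cond,
                        trf = w_sum / length(idx),
                        pred_r = colMeans(acc, na.rm = TRUE),
                        pred_r_trials = acc,
                        lambda = lambda, window = window,
                        channel_labels = dataset$channel_labels,
                        snr_rel = dataset$snr_rel[idx[1]])
  }
  structure(out, class = "trf_estimates")
}

#' Encoder prediction-accuracy significance gate
#'
#' Per condition, tests whether the mean prediction accuracy over the
#' selected channels significantly exceeds an encoder noise floor built
#' from mismatched envelopes (one-sided permutation test at alpha,
#' per-trial matched accuracies against per-trial mismatch means). Only
#' conditions passing the gate should enter the deflection analysis.
#'
#' @param estimates a `trf_estimates` from [fit_encoder()].
#' @param dataset the matching `eeg_dataset`.
#' @param channels channel labels to average over (e.g. the selected 17);
#'   defaults to all channels.
#' @param mismatch pool of mismatched envelopes; generated when `NULL`.
#' @param n_mismatch pool size when generated.
#' @param alpha significance level.
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @return data.frame with `condition`, `mean_accuracy`, `floor`, `p`,
#'   `included`.
#' @export
encoder_significance_gate <- function(estimates, dataset, channels = NULL,
                                      mismatch = NULL, n_mismatch = 68L,
                                      alpha = 0.05, n_perm = 10000L,
                                      seed = 1L) {
  stopifnot(inherits(estimates, "trf_estimates"))
  labels <- estimates[[1]]$channel_labels
  ch_idx <- if (is.null(channels)) seq_along(labels)
            else match(channels, labels)
  if (anyNA(ch_idx)) stop("unknown channel labels")
  if (is.null(mismatch)) {
    dur <- nrow(dataset$trials[[1]]$data) / dataset$rate
    mismatch <- make_mismatch_pool(n_mismatch, dur,
                                   seed = derive_seed(seed, "encfloor"))
  }
  out <- data.frame()
  for (cond in names(estimates)) {
    est <- estimates[[cond]]
    idx <- which(dataset$condition == cond)
    matched <- rowMeans(est$pred_r_trials[, ch_idx, drop = FALSE])
    fl <- numeric(length(idx))
    for (k in seq_along(idx)) {
      eeg <- dataset$trials[[idx[k]]]$data
      rs <- numeric(length(mismatch))
      for (j in seq_along(mismatch)) {
        env <- mismatch[[j]]$values
        m <- min(length(env), nrow(eeg))
        X <- build_lag_matrix(matrix(env[seq_len(m)], ncol = 1),
                              est$window, "forward")
        pred <- X %*% est$trf[, ch_idx, drop = FALSE]
        rs[j] <- mean(vapply(seq_along(ch_idx), function(c2)
          tryCatch(pearson_accuracy(pred[, c2], eeg[seq_len(m), ch_idx[c2]]),
                   error = function(e) NA_real_), numeric(1)), na.rm = TRUE)
      }
      fl[k] <- mean(rs, na.rm = TRUE)
    }
    g <- gate_participant(matched, fl, n_perm = n_perm, alpha = alpha,
                          seed = derive_seed(seed, "encgate", cond))
    out <- rbind(out, data.frame(condition = cond,
                                 mean_accuracy = mean(matched),
                                 floor = mean(fl), p = g$p,
                                 included = g$pass))
  }
  out
}

#' Global channel selection by prediction accuracy
#'
#' Ranks channels by their grand-average encoder prediction accuracy
#' across participants and conditions and returns the top `k` (default
#' 17); ties are broken by montage order.
#'
#' @param estimates a `trf_estimates`, or a list of them (one per
#'   participant).
#' @param k number of channels to select.
#' @return character vector of selected channel labels, in montage order.
#' @export
select_channels <- function(estimates, k = 17L) {
  if (k < 1L) stop("k must be at least 1")
  if (inherits(estimates, "trf_estimates")) estimates <- list(estimates)
  labels <- estimates[[1]][[1]]$channel_labels
  acc <- rowMeans(vapply(estimates, function(p)
    rowMeans(vapply(p, `[[`, numeric(length(labels)), "pred_r")),
    numeric(length(labels))))
  if (k > length(labels)) k <- length(labels)
  ord <- order(-acc, seq_along(labels)) # ties -> earlier montage position
  sel <- ord[seq_len(k)]
  labels[sort(sel)]
}

#' Mean TRF over selected channels
#'
#' @param est one element of a `trf_estimates`.
#' @param channels selected channel labels.
#' @return list with `tau_ms` and the mean `trf` time course.
#' @export
mean_trf <- function(est, channels) {
  ch <- match(channels, est$channel_labels)
  if (anyNA(ch)) stop("unknown channel labels")
  list(tau_ms = est$window$tau_ms,
       trf = rowMeans(est$trf[, ch, drop = FALSE]))
}

#' Fit Gaussian deflections (P1, N1, P2) to a mean TRF
#'
#' Each deflection is parameterized as
#' `a(t) = p * exp(-((t - l) / w)^2)` and fitted by bounded least squares
#' to the TRF samples falling inside the component's latency window, with
#' the amplitude, latency and width bounds of [deflection_bounds()].
#' Fits with R^2 below `r2_min` are flagged `excluded`; fits whose
#' latency lands on a window bound are flagged `at_bound` (unreliable).
#'
#' @param tau_ms time axis in ms.
#' @param trf mean TRF values on `tau_ms`.
#' @param bounds bounds table as from [deflection_bounds()].
#' @param r2_min exclusion threshold on R^2 (default 0.5).
#' @return data.frame with `component`, `p`, `l`, `w`, `r_squared`,
#'   `excluded`, `at_bound`.
#' @export
fit_deflections <- function(tau_ms, trf, bounds = deflection_bounds(),
                            r2_min = 0.5) {
  stopifnot(length(tau_ms) == length(trf))
  out <- data.frame()
  for (i in seq_len(nrow(bounds))) {
    bd <- bounds[i, ]
    sel <- tau_ms >= bd$l_lo & tau_ms <= bd$l_hi
    tt <- tau_ms[sel]; yy <- trf[sel]
    ss_tot <- sum((yy - mean(yy))^2)
    if (ss_tot == 0) {
      out <- rbind(out, data.frame(component = bd$component, p = NA_real_,
                                   l = NA_real_, w = NA_real_,
                                   r_squared = NA_real_, excluded = TRUE,
                                   at_bound = FALSE))
      next
    }
    neg <- bd$p_hi <= 0
    ext <- if (neg) which.min(yy) else which.max(yy)
    init <- c(p = min(max(yy[ext], bd$p_lo), bd$p_hi), l = tt[ext], w = 25)
    obj <- function(par)
      sum((yy - par[1] * exp(-((tt - par[2]) / par[3])^2))^2)
    fit <- stats::optim(init, obj, method = "L-BFGS-B",
                        lower = c(bd$p_lo, bd$l_lo, max(bd$w_lo, 1e-3)),
                        upper = c(bd$p_hi, bd$l_hi, bd$w_hi),
                        control = list(maxit = 1000, factr = 100))
    r2 <- 1 - fit$value / ss_tot
    at_bound <- fit$par[2] <= bd$l_lo + 1e-9 || fit$par[2] >= bd$l_hi - 1e-9
    out <- rbind(out, data.frame(component = bd$component,
                                 p = fit$par[1], l = fit$par[2],
                                 w = fit$par[3], r_squared = r2,
                                 excluded = r2 < r2_min,
                                 at_bound = at_bound))
  }
  rownames(out) <- NULL
  out
}

#' Holm-Bonferroni step-down decisions
#'
#' @param p vector of raw p-values.
#' @param alpha family-wise error level.
#' @return logical vector of rejections (monotone in sorted p order).
#' @export
holm_significant <- function(p, alpha = 0.05) {
  stats::p.adjust(p, method = "holm") < alpha
}

#' Mixed-model tests of SNR effects on deflection features
#'
#' For each of the six features (P1/N1/P2 amplitude and latency), fits a
#' random-intercept linear mixed model `feature ~ SNR + (1 | participant)`
#' by maximum likelihood, reports the Wald test of the SNR fixed effect,
#' and applies a Holm-Bonferroni correction across the six tests. The
#' clean-speech condition must not be present (its SNR is undefined);
#' excluded deflection fits are dropped.
#'
#' @param deflections data.frame with columns `participant_id`,
#'   `snr_rel`, `component`, `p` (amplitude), `l` (latency) and
#'   optionally `excluded`.
#' @param alpha family-wise error level.
#' @return data.frame with one row per component-by-parameter:
#'   `component`, `parameter`, `coefficient` (per-dB slope),
#'   `std_error`, `t`, `df`, `p`, `holm_significant`.
#' @export
lmm_snr_effects <- function(deflections, alpha = 0.05) {
  d <- deflections
  if (!is.null(d$excluded)) d <- d[!d$excluded, ]
  if (any(is.na(d$snr_rel)))
    stop("clean condition (undefined SNR) must be excluded")
  feats <- expand.grid(component = c("P1", "N1", "P2"),
                       parameter = c("Amplitude", "Latency"),
                       stringsAsFactors = FALSE)
  out <- data.frame()
  for (i in seq_len(nrow(feats))) {
    sub <- d[d$component == feats$component[i], ]
    value <- if (feats$parameter[i] == "Amplitude") sub$p else sub$l
    dat <- data.frame(value = value, snr = sub$snr_rel,
                      participant = factor(sub$participant_id))
    row <- data.frame(component = feats$component[i],
                      parameter = feats$parameter[i],
                      coefficient = NA_real_, std_error = NA_real_,
                      t = NA_real_, df = NA_real_, p = NA_real_)
    if (length(unique(dat$participant)) >= 3L && nrow(dat) >= 6L) {
      fit <- tryCatch(
        nlme::lme(value ~ snr, random = ~ 1 | participant, data = dat,
                  method = "ML"),
        error = function(e) NULL)
      if (!is.null(fit)) {
        tt <- summary(fit)$tTable["snr", ]
        row$coefficient <- unname(tt["Value"])
        row$std_error <- unname(tt["Std.Error"])
        row$t <- unname(tt["t-value"])
        row$df <- unname(tt["DF"])
        row$p <- unname(tt["p-value"])
      }
    }
    out <- rbind(out, row)
  }
  out$holm_significant <- NA
  ok <- !is.na(out$p)
  out$holm_significant[ok] <- holm_significant(out$p[ok], alpha)
  out
}

#' Grand-average TRF across participants
#'
#' Averages the selected-channel mean TRFs across participants, per
#' condition, truncating the display window (default -100 to 400 ms; the
#' final stretch of the window is affected by edge effects).
#'
#' @param participant_trfs list over participants; each element is a
#'   named list `condition -> list(tau_ms, trf)` as from [mean_trf()].
#' @param tau_display length-2 ms window kept for display.
#' @return data.frame with `condition`, `tau_ms`, `trf`.
#' @export
grand_average_trf <- function(participant_trfs, tau_display = c(-100, 400)) {
  conds <- names(participant_trfs[[1]])
  out <- data.frame()
  for (cond in conds) {
    tau <- participant_trfs[[1]][[cond]]$tau_ms
    m <- rowMeans(vapply(participant_trfs,
                         function(p) p[[cond]]$trf, numeric(length(tau))))
    keep <- tau >= tau_display[1] & tau <= tau_display[2]
    out <- rbind(out, data.frame(condition = cond, tau_ms = tau[keep],
                                 trf = m[keep]))
  }
  out
}

#' Tidy export of TRF kernels
#'
#' @param estimates a `trf_estimates`.
#' @param participant_id identifier column value.
#' @return data.frame with `participant`, `condition`, `channel`,
#'   `tau_ms`, `weight`.
#' @export
trf_tidy <- function(estimates, participant_id = NA_character_) {
  do.call(rbind, lapply(estimates, function(est) {
    data.frame(participant = participant_id, condition = est$condition,
               channel = rep(est$channel_labels,
                             each = length(est$window$tau_ms)),
               tau_ms = rep(est$window$tau_ms, length(est$channel_labels)),
               weight = as.numeric(est$trf))
  }))
}
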