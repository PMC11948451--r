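#' Train the backward decoder on the clean-speech condition
#'
#' Pools the rows of all clean-condition trials into one lagged ridge
#' regression reconstructing the speech envelope from the EEG. The
#' regularization parameter is participant-specific: it is chosen by
#' leave-one-out cross-validation over the clean trials on a grid of
#' integer powers of 10 from 1e-4 to 1e10 (ties toward the larger
#' value), unless supplied.
#'
#' @param dataset an `eeg_dataset` (preprocessed).
#' @param window decoder decision window; default -100 to 350 ms.
#' @param lambda fixed lambda, or `NULL` to cross-validate.
#' @param lambda_grid grid searched when `lambda` is `NULL`.
#' @return a `lagged_linear_model` (backward) with the chosen `lambda`
#'   and the cross-validation curve in `cv`.
#' @export
train_decoder <- function(dataset, window = lag_window(-100, 350, dataset$rate),
                          lambda = NULL, lambda_grid = 10 ^ seq(-4, 10)) {
  idx <- which(dataset$condition == "clean")
  if (length(idx) == 0) stop("dataset has no clean condition")
  trials <- lapply(idx, function(i) list(
    X = build_lag_matrix(dataset$trials[[i]]$data, window, "backward"),
    y = dataset$envelopes[[i]]$values))
  cv <- NULL
  if (is.null(lambda)) {
    cv <- loo_lambda_search(trials, lambda_grid)
    lambda <- cv$lambda
  }
  moms <- lapply(trials, function(tr) trial_moments(tr$X, as.matrix(tr$y)))
  sol <- ridge_solve_moments(Reduce(moments_combine, moms), lambda)
  model <- structure(list(weights = sol$weights, intercept = sol$intercept,
                          lambda = lambda, window = window,
                          direction = "backward",
                          n_channels = length(dataset$channel_labels),
                          cv = cv),
                     class = "lagged_linear_model")
  model
}

#' Per-trial reconstruction accuracies
#'
#' Reconstructs the envelope of every trial and returns Pearson's
#' correlation with the presented envelope. Noise-condition trials use
#' the decoder trained on all clean trials; clean-condition accuracies
#' are computed by leave-one-out training within the clean condition (at
#' the decoder's lambda), so no trial is scored by a model that saw it.
#'
#' @param dataset an `eeg_dataset` (preprocessed).
#' @param decoder the [train_decoder()] model.
#' @param participant_id identifier recorded in the table.
#' @return data.frame (`accuracy_table`) with columns `participant_id`,
#'   `trial_id`, `condition`, `snr_rel`, `snr_abs`, `r`.
#' @export
compute_accuracies <- function(dataset, decoder,
                               participant_id = NA_character_) {
  stopifnot(inherits(dataset, "eeg_dataset"),
            inherits(decoder, "lagged_linear_model"),
            decoder$direction == "backward")
  if (!any(dataset$condition == "clean")) stop("missing clean condition")
  n <- length(dataset$trials)
  Xs <- lapply(dataset$trials, function(t)
    build_lag_matrix(t$data, decoder$window, "backward"))
  r <- numeric(n)
  clean_idx <- which(dataset$condition == "clean")
  moms <- lapply(clean_idx, function(i)
    trial_moments(Xs[[i]], as.matrix(dataset$envelopes[[i]]$values)))
  total <- Reduce(moments_combine, moms)
  if (length(clean_idx) < 2L)
    warning("only one clean trial: its accuracy is in-sample, not leave-one-out")
  for (i in seq_len(n)) {
    if (dataset$condition[i] == "clean" && length(clean_idx) >= 2L) {
      mom <- moments_combine(total, moms[[match(i, clean_idx)]], sign = -1)
      sol <- ridge_solve_moments(mom, decoder$lambda)
      pred <- as.numeric(Xs[[i]] %*% sol$weights[, 1] + sol$intercept[1])
    } else {
      pred <- as.numeric(Xs[[i]] %*% decoder$weights[, 1] +
                           decoder$intercept[1])
    }
    r[i] <- pearson_accuracy(pred, dataset$envelopes[[i]]$values)
  }
  structure(data.frame(participant_id = participant_id,
                       trial_id = vapply(dataset$trials, `[[`, "",
                                         "trial_id"),
                       condition = dataset$condition,
                       snr_rel = dataset$snr_rel,
                       snr_abs = dataset$snr_abs, r = r),
            class = c("accuracy_table", "data.frame"))
}

#' Reconstruction-accuracy noise floor from mismatched envelopes
#'
#' Correlates the reconstructed envelope of every noise-condition trial
#' with each envelope in a pool of mismatched (never-presented) excerpts,
#' truncating both series to the shorter length. The floor `b` is the
#' mean over all (trial x mismatch) pairs.
#'
#' @param dataset an `eeg_dataset` (preprocessed).
#' @param decoder the clean-trained decoder.
#' @param mismatch list of [envelope_signal()]s; by default a pool of
#'   `n_mismatch` surrogate envelopes generated under unused seeds.
#' @param n_mismatch pool size when `mismatch` is `NULL` (default 68).
#' @param conditions which trials to reconstruct: `"noise"` (default,
#'   defines the sigmoid's lower asymptote), `"clean"` (used by the
#'   participant inclusion gate, one floor value per clean trial), or
#'   `"all"`.
#' @return list of class `noise_floor`: `b` (scalar mean), `per_trial`
#'   (per-trial mean over mismatches), `raw` (trials x mismatches
#'   matrix), `trial_id`.
#' @export
compute_noise_floor <- function(dataset, decoder, mismatch = NULL,
                                n_mismatch = 68L,
                                conditions = c("noise", "clean", "all")) {
  conditions <- match.arg(conditions)
  if (is.null(mismatch)) {
    dur <- nrow(dataset$trials[[1]]$data) / dataset$rate
    mismatch <- make_mismatch_pool(n_mismatch, dur,
                                   seed = derive_seed(dataset$seed, "floor"))
  }
  if (length(mismatch) == 0) stop("mismatch pool is empty")
  idx <- switch(conditions,
                noise = which(dataset$condition != "clean"),
                clean = which(dataset$condition == "clean"),
                all = seq_along(dataset$condition))
  if (length(idx) == 0) stop("no trials in the requested conditions")
  raw <- matrix(NA_real_, length(idx), length(mismatch))
  for (k in seq_along(idx)) {
    i <- idx[k]
    rec <- predict(decoder, dataset$trials[[i]]$data)
    for (j in seq_along(mismatch)) {
      env <- mismatch[[j]]$values
      m <- min(length(rec), length(env))
      raw[k, j] <- pearson_accuracy(rec[seq_len(m)], env[seq_len(m)])
    }
  }
  structure(list(b = mean(raw), per_trial = rowMeans(raw), raw = raw,
                 trial_id = vapply(dataset$trials[idx], `[[`, "", "trial_id")),
            class = "noise_floor")
}

#' Participant inclusion gate for the sigmoid fit
#'
#' One-sided two-sample permutation test of whether clean-condition
#' reconstruction accuracies exceed the noise floor: the 16 clean
#' accuracies are tested against the 16 within-trial mean floor values
#' (difference of means statistic). The sigmoid is only fitted for
#' participants passing at alpha.
#'
#' @param clean_r clean-condition accuracies.
#' @param floor a `noise_floor` or a numeric vector of per-trial floor
#'   means; must have the same length as `clean_r`.
#' @param n_perm number of random label permutations.
#' @param alpha significance level.
#' @param seed integer seed for the permutation draw.
#' @return list with `pass`, `p`, `stat`.
#' @export
gate_participant <- function(clean_r, floor, n_perm = 10000L, alpha = 0.05,
                             seed = 1L) {
  fl <- if (inherits(floor, "noise_floor")) {
    # one mean floor value per clean trial: average mismatches within
    # matched groups of noise trials so counts match the clean trials
    floor$per_trial
  } else as.numeric(floor)
  if (length(clean_r) != length(fl))
    stop("clean accuracies and floor values must have equal counts")
  n <- length(clean_r)
  pool <- c(clean_r, fl)
  obs <- mean(clean_r) - mean(fl)
  set.seed(seed)
  cnt <- 0L
  for (k in seq_len(n_perm)) {
    sel <- sample.int(2L * n, n)
    stat <- mean(pool[sel]) - mean(pool[-sel])
    if (stat >= obs - 1e-12) cnt <- cnt + 1L
  }
  p <- (1 + cnt) / (1 + n_perm)
  list(pass = p < alpha, p = p, stat = obs)
}

#' Population-level tests of adjacent SNR conditions
#'
#' For each adjacent pair of noise conditions, a one-sided paired
#' sign-flip permutation test on the participant-mean accuracy
#' differences (higher SNR expected larger). Sign patterns are
#' enumerated exactly when there are at most 2^14 of them; otherwise at
#' least 10^4 random flips are drawn (p resolution 0.01 or better).
#'
#' @param table an `accuracy_table` covering several participants.
#' @param n_perm random permutations when exact enumeration is not used.
#' @param seed integer seed.
#' @return data.frame with `pair`, `delta` (mean difference) and `p` per
#'   adjacent SNR pair.
#' @export
adjacent_snr_tests <- function(table, n_perm = 10000L, seed = 1L) {
  noise <- table[table$condition != "clean", ]
  means <- stats::aggregate(r ~ participant_id + snr_rel, noise, mean)
  snrs <- sort(unique(means$snr_rel))
  participants <- unique(means$participant_id)
  if (length(participants) < 2L) stop("need at least 2 participants")
  out <- data.frame()
  for (k in seq_len(length(snrs) - 1)) {
    lo <- means[means$snr_rel == snrs[k], ]
    hi <- means[means$snr_rel == snrs[k + 1], ]
    d <- hi$r[match(participants, hi$participant_id)] -
      lo$r[match(participants, lo$participant_id)]
    d <- d[!is.na(d)]
    n <- length(d)
    obs <- mean(d)
    if (2^n <= 2^14) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      stats_all <- as.numeric(signs %*% d) / n
      p <- mean(stats_all >= obs - 1e-12)
    } else {
      set.seed(derive_seed(seed, "adjacent", k))
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        s <- sample(c(-1, 1), n, replace = TRUE)
        if (mean(s * d) >= obs - 1e-12) cnt <- cnt + 1L
      }
      p <- (1 + cnt) / (1 + n_perm)
    }
    out <- rbind(out, data.frame(
      pair = sprintf("%+d vs %+d", snrs[k], snrs[k + 1]),
      delta = obs, p = p))
  }
  out
}

#' Evaluate the accuracy-versus-SNR sigmoid
#'
#' `S(SNR) = (p - b) / (1 + exp(4 s / (p - b) * (m - SNR))) + b`:
#' lower asymptote `b` (noise floor), upper asymptote `p` (clean
#' accuracy), midpoint `m` (the neural SRT) where `S(m) = (p + b) / 2`,
#' and slope `s = dS/dSNR` at the midpoint.
#'
#' @param model a `sigmoid_model` or a list/vector with `p`, `b`, `s`,
#'   `m`.
#' @param snr numeric SNR values in dB.
#' @return accuracy values.
#' @export
sigmoid_eval <- function(model, snr) {
  p <- model$p %||% model["p"]; b <- model$b %||% model["b"]
  s <- model$s %||% model["s"]; m <- model$m %||% model["m"]
  if (s == 0) return(rep((p + b) / 2, length(snr)))
  b + (p - b) * stats::plogis(4 * s / (p - b) * (snr - m))
}

#' Fit the sigmoid to trial-level accuracy-versus-SNR points
#'
#' Least squares over slope `s` and midpoint `m` only; the asymptotes are
#' fixed at the clean-condition mean accuracy (`p_fixed`) and the noise
#' floor (`b_fixed`). Bounds are `s` in `[0, 1e10]` and `m` in
#' `[-1e10, 1e10]`. The slope is always initialized at 0 and the midpoint
#' uniformly within +/- 10 dB of -2.52 dB (the average behavioral SRT of
#' normal-hearing listeners on the Danish HINT); the fit is restarted
#' `n_restarts` times and the final parameters are the mean of the
#' `n_best` restarts with the highest R^2.
#'
#' @param snr,r trial-level SNR (dB) and reconstruction accuracy pairs.
#' @param p_fixed,b_fixed fixed asymptotes, `p_fixed > b_fixed`.
#' @param seed integer seed (deterministic given seed).
#' @param n_restarts,n_best restart protocol (defaults 100 and 10).
#' @param m_init_center,m_init_halfwidth midpoint initialization range.
#' @return object of class `sigmoid_model` with `p`, `b`, `s`, `m`,
#'   `r_squared` and the per-restart results in `restarts`.
#' @export
fit_sigmoid <- function(snr, r, p_fixed, b_fixed, seed = 1L,
                        n_restarts = 100L, n_best = 10L,
                        m_init_center = -2.52, m_init_halfwidth = 10) {
  stopifnot(length(snr) == length(r))
  if (length(unique(snr)) < 3L) stop("points must span at least 3 SNRs")
  if (!(p_fixed > b_fixed)) stop("p_fixed must exceed b_fixed")
  ss_tot <- sum((r - mean(r))^2)
  if (ss_tot == 0) stop("all accuracies identical: R^2 undefined")
  obj <- function(par) {
    pred <- sigmoid_eval(list(p = p_fixed, b = b_fixed,
                              s = par[1], m = par[2]), snr)
    sum((r - pred)^2)
  }
  # damped Gauss-Newton polish: the least-squares basin is extremely
  # flat in (s, m), so the quasi-Newton search is finished off with a
  # few analytic-Jacobian steps to reach the optimum to ~1e-8
  polish <- function(par) {
    s <- par[1]; m <- par[2]
    lam_gn <- 1e-10
    for (it in 1:60) {
      u <- 4 * s / (p_fixed - b_fixed) * (snr - m)
      sig <- stats::plogis(u)
      pred <- b_fixed + (p_fixed - b_fixed) * sig
      res <- r - pred
      w <- sig * (1 - sig)
      J <- cbind(4 * w * (snr - m), -4 * s * w)
      A <- crossprod(J); diag(A) <- diag(A) * (1 + lam_gn)
      step <- tryCatch(solve(A, crossprod(J, res)), error = function(e) NULL)
      if (is.null(step)) break
      s_new <- max(0, s + step[1]); m_new <- m + step[2]
      if (obj(c(s_new, m_new)) <= obj(c(s, m))) {
        moved <- max(abs(s_new - s), abs(m_new - m))
        s <- s_new; m <- m_new
        lam_gn <- max(lam_gn / 10, 1e-12)
        if (moved < 1e-10) break
      } else {
        lam_gn <- lam_gn * 100
        if (lam_gn > 1e6) break
      }
    }
    c(s, m)
  }
  set.seed(seed)
  m0 <- stats::runif(n_restarts, m_init_center - m_init_halfwidth,
                     m_init_center + m_init_halfwidth)
  res <- matrix(NA_real_, n_restarts, 3,
                dimnames = list(NULL, c("s", "m", "r_squared")))
  for (k in seq_len(n_restarts)) {
    fit <- stats::optim(c(0, m0[k]), obj, method = "L-BFGS-B",
                        lower = c(0, -1e10), upper = c(1e10, 1e10),
                        control = list(maxit = 1000, factr = 1,
                                       pgtol = 0))
    par <- polish(fit$par)
    res[k, ] <- c(par, 1 - obj(par) / ss_tot)
  }
  top <- order(res[, "r_squared"], decreasing = TRUE)[seq_len(min(n_best,
                                                                  n_restarts))]
  s_hat <- mean(res[top, "s"]); m_hat <- mean(res[top, "m"])
  r2 <- 1 - obj(c(s_hat, m_hat)) / ss_tot
  structure(list(p = p_fixed, b = b_fixed, s = s_hat, m = m_hat,
                 r_squared = r2, restarts = as.data.frame(res)),
            class = "sigmoid_model")
}

#' @export
print.sigmoid_model <- function(x, ...) {
  cat(sprintf("<sigmoid_model: p = %.4f, b = %.4f, s = %.5f, m = %.2f dB (R^2 = %.3f)>\n",
              x$p, x$b, x$s, x$m, x$r_squared))
  invisible(x)
}

#' Estimate the neural SRT for one participant
#'
#' Runs the inclusion gate (clean accuracies versus noise floor), then
#' fits the sigmoid to the trial-level noise-condition points with the
#' full restart protocol. The whole fitting procedure is repeated
#' `n_reps` times with fresh restart seeds; the robustness spread is the
#' maximum pairwise difference among the repeated midpoints.
#'
#' @param table an `accuracy_table` for the participant.
#' @param floor a `noise_floor` for the participant (noise-condition
#'   trials against the mismatch pool); its mean is the fixed lower
#'   asymptote `b`.
#' @param gate_floor per-trial floor means used by the inclusion gate,
#'   one per clean trial (a `noise_floor` computed on the clean trials,
#'   or a numeric vector of the same length as the clean accuracies).
#' @param seed integer master seed.
#' @param n_reps repetitions of the full fitting procedure.
#' @param snr_scale `"abs"` to fit on absolute SNR in dB (default) or
#'   `"rel"` for SNR relative to the grid center.
#' @param ... forwarded to [fit_sigmoid()].
#' @return list of class `srt_neuro_estimate`: `fitted`, `gate`
#'   (gate result), and when fitted `model`, `srt_neuro`,
#'   `robustness_spread`, `all_m` (midpoints of all repetitions).
#' @export
estimate_srt_neuro <- function(table, floor, gate_floor, seed = 1L,
                               n_reps = 100L,
                               snr_scale = c("abs", "rel"), ...) {
  snr_scale <- match.arg(snr_scale)
  clean_r <- table$r[table$condition == "clean"]
  if (length(clean_r) == 0) stop("missing clean condition")
  fl <- if (inherits(gate_floor, "noise_floor")) gate_floor$per_trial
        else as.numeric(gate_floor)
  gate <- gate_participant(clean_r, fl, seed = derive_seed(seed, "gate"))
  if (!gate$pass)
    return(structure(list(fitted = FALSE, gate = gate),
                     class = "srt_neuro_estimate"))
  noise <- table[table$condition != "clean", ]
  snr <- if (snr_scale == "abs") noise$snr_abs else noise$snr_rel
  p_fixed <- mean(clean_r); b_fixed <- floor$b
  ms <- numeric(n_reps); model <- NULL
  for (rep_i in seq_len(n_reps)) {
    fit <- fit_sigmoid(snr, noise$r, p_fixed, b_fixed,
                       seed = derive_seed(seed, "fitrep", rep_i), ...)
    ms[rep_i] <- fit$m
    if (rep_i == 1L) model <- fit
  }
  structure(list(fitted = TRUE, gate = gate, model = model,
                 srt_neuro = model$m,
                 robustness_spread = max(ms) - min(ms), all_m = ms),
            class = "srt_neuro_estimate")
}

#' Plot-ready fitted sigmoid curve
#'
#' @param model a `sigmoid_model`.
#' @param snr_range length-2 dB range.
#' @param n number of points.
#' @return data.frame with `snr_db` and `accuracy`.
#' @export
sigmoid_curve <- function(model, snr_range = c(-20, 10), n = 200L) {
  snr <- seq(snr_range[1], snr_range[2], length.out = n)
  data.frame(snr_db = snr, accuracy = sigmoid_eval(model, snr))
}
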