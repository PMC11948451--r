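# Accuracy tables, noise floor, permutation gates, the accuracy-versus-
# SNR sigmoid and the neural SRT estimate.

test_that("sigmoid identities hold to machine precision", {
  m <- list(p = 0.31, b = 0.014, s = 0.02, m = -4.7)
  # midpoint
  expect_equal(sigmoid_eval(m, -4.7), (0.31 + 0.014) / 2, tolerance = 1e-12)
  # asymptotes
  expect_equal(sigmoid_eval(m, 1e6), 0.31, tolerance = 1e-12)
  expect_equal(sigmoid_eval(m, -1e6), 0.014, tolerance = 1e-12)
  # slope at the midpoint equals s (central finite difference)
  h <- 1e-6
  num <- (sigmoid_eval(m, -4.7 + h) - sigmoid_eval(m, -4.7 - h)) / (2 * h)
  expect_equal(num, 0.02, tolerance = 1e-6)
  # same identities for a fitted model object
  set.seed(1)
  snr <- rep(c(-9, -7, -5, -3, -1), each = 10)
  r <- sigmoid_eval(m, snr) + rnorm(length(snr), sd = 0.01)
  fit <- fit_sigmoid(snr, r, p_fixed = 0.31, b_fixed = 0.014, seed = 2)
  expect_equal(sigmoid_eval(fit, fit$m), (fit$p + fit$b) / 2,
               tolerance = 1e-12)
  num2 <- (sigmoid_eval(fit, fit$m + h) - sigmoid_eval(fit, fit$m - h)) /
    (2 * h)
  expect_equal(num2, fit$s, tolerance = 1e-5)
})

test_that("noiseless sigmoid samples are recovered exactly", {
  truth <- list(p = 0.25, b = 0.01, s = 0.005, m = -5)
  snr <- rep(seq(-9, -1, by = 2), each = 16)
  r <- sigmoid_eval(truth, snr)
  fit <- fit_sigmoid(snr, r, p_fixed = 0.25, b_fixed = 0.01, seed = 3)
  expect_equal(fit$s, 0.005, tolerance = 1e-6)
  expect_equal(fit$m, -5, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("fit_sigmoid validates degenerate inputs", {
  expect_error(fit_sigmoid(c(-4, -4, -2, -2), c(1, 2, 1, 2), 0.3, 0, seed = 1),
               "3 SNRs")
  expect_error(fit_sigmoid(c(-4, -2, 0), rep(0.1, 3), 0.3, 0, seed = 1),
               "identical")
  expect_error(fit_sigmoid(c(-4, -2, 0), c(0.1, 0.2, 0.3), 0.1, 0.3, seed = 1),
               "exceed")
})

test_that("midpoint recovery stays within 1 dB under trial-level noise", {
  truth <- list(p = 0.30, b = 0.01, s = 0.02, m = -5)
  snr <- rep(seq(-9, -1, by = 2), each = 16)
  errs <- vapply(1:40, function(s) {
    set.seed(s)
    r <- sigmoid_eval(truth, snr) + rnorm(length(snr), sd = 0.03)
    fit <- fit_sigmoid(snr, r, 0.30, 0.01, seed = s, n_restarts = 50L)
    fit$m - truth$m
  }, numeric(1))
  expect_lt(stats::median(abs(errs)), 1)
})

test_that("the fitting protocol is deterministic given its seed", {
  set.seed(9)
  snr <- rep(seq(-9, -1, by = 2), each = 8)
  r <- sigmoid_eval(list(p = 0.3, b = 0, s = 0.02, m = -5), snr) +
    rnorm(length(snr), sd = 0.03)
  f1 <- fit_sigmoid(snr, r, 0.3, 0, seed = 77)
  f2 <- fit_sigmoid(snr, r, 0.3, 0, seed = 77)
  expect_identical(f1[c("s", "m", "r_squared")], f2[c("s", "m", "r_squared")])
})

test_that("accuracy tables have the designed layout", {
  ds <- tiny_dataset(n_trials = 3L, duration = 15, n_channels = 8L,
                     noise_level = 6, seed = 31)
  ds <- preprocess_dataset(ds)
  dec <- train_decoder(ds, lambda = 10)
  acc <- compute_accuracies(ds, dec, participant_id = "P01")
  expect_equal(nrow(acc), 18L) # 3 x (5 noise + clean)
  expect_equal(sum(acc$condition == "clean"), 3L)
  expect_true(all(acc$r >= -1 & acc$r <= 1))
  expect_equal(sum(!is.na(acc$snr_rel)), 15L)
})

test_that("the noise floor is near zero for independent envelopes", {
  ds <- tiny_dataset(n_trials = 2L, duration = 15, n_channels = 8L,
                     noise_level = 6, seed = 32)
  ds <- preprocess_dataset(ds)
  dec <- train_decoder(ds, lambda = 10)
  mismatch <- make_mismatch_pool(12, 15, seed = 9999)
  fl <- compute_noise_floor(ds, dec, mismatch)
  expect_equal(dim(fl$raw), c(10L, 12L)) # 2 x 5 noise trials x pool
  se <- stats::sd(fl$raw) / sqrt(length(fl$raw))
  expect_lt(abs(fl$b), 3 * se + 0.02)
  expect_error(compute_noise_floor(ds, dec, list()), "empty")
})

test_that("a matched 'mismatch' pool reproduces the matched accuracy", {
  # degenerate control: single noise trial, pool = its own envelope
  ds <- tiny_dataset(n_trials = 1L, duration = 15, n_channels = 8L,
                     noise_level = 6, seed = 33)
  # keep one noise condition + clean so the decoder can be trained
  keep <- c(which(ds$condition == "+0"), which(ds$condition == "clean"))
  ds$trials <- ds$trials[keep]; ds$envelopes <- ds$envelopes[keep]
  ds$condition <- ds$condition[keep]
  ds$snr_rel <- ds$snr_rel[keep]; ds$snr_abs <- ds$snr_abs[keep]
  ds <- preprocess_dataset(ds)
  # decoder needs >= 2 clean trials for cv; fix lambda instead
  dec <- train_decoder(ds, lambda = 10)
  expect_warning(acc <- compute_accuracies(ds, dec), "one clean trial")
  fl <- compute_noise_floor(ds, dec, mismatch = ds$envelopes[1])
  expect_equal(fl$b, acc$r[acc$condition == "+0"], tolerance = 1e-12)
})

test_that("the inclusion gate separates signal from floor and is calibrated", {
  set.seed(5)
  clean <- rnorm(16, mean = 0.3, sd = 0.03)
  floor <- rnorm(16, mean = 0.0, sd = 0.03)
  g <- gate_participant(clean, floor, seed = 1)
  expect_true(g$pass)
  expect_lte(g$p, 0.001)
  # identical samples cannot pass
  same <- rep(0.1, 16)
  g2 <- gate_participant(same, same, seed = 1)
  expect_false(g2$pass)
  expect_gt(g2$p, 0.5)
  expect_error(gate_participant(clean, floor[1:8]), "equal counts")
  # type-I calibration under the null (moderate rep count; the
  # acceptance suite runs the full calibration)
  rejections <- vapply(1:300, function(s) {
    set.seed(s)
    a <- rnorm(8); b <- rnorm(8)
    gate_participant(a, b, n_perm = 400L, seed = s)$pass
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.03)
})

test_that("adjacent-condition tests reject under signal and not under null", {
  # build participant-mean accuracy tables directly
  make_table <- function(gains, n_participants, sd = 0.02, seed = 1) {
    set.seed(seed)
    do.call(rbind, lapply(seq_len(n_participants), function(p) {
      data.frame(participant_id = sprintf("P%02d", p),
                 condition = rep(sprintf("%+d", c(-4, -2, 0, 2, 4)), each = 4),
                 snr_rel = rep(c(-4, -2, 0, 2, 4), each = 4),
                 r = rnorm(20, mean = rep(gains, each = 4), sd = sd))
    }))
  }
  signal_tab <- make_table(c(0.05, 0.10, 0.15, 0.20, 0.25), 12)
  res <- adjacent_snr_tests(signal_tab, seed = 2)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$p < 0.05))
  null_tab <- make_table(rep(0.1, 5), 12, seed = 3)
  res0 <- adjacent_snr_tests(null_tab, seed = 4)
  expect_true(all(res0$p > 0.01)) # no extreme rejection expected
  one <- signal_tab[signal_tab$participant_id == "P01", ]
  expect_error(adjacent_snr_tests(one), "2 participants")
})

test_that("estimate_srt_neuro recovers the threshold and reports robustness", {
  listener <- simulated_listener(-5)
  ds <- tiny_dataset(n_trials = 6L, duration = 20, n_channels = 16L,
                     noise_level = 8, seed = 41, listener = listener)
  ds <- preprocess_dataset(ds)
  dec <- train_decoder(ds)
  acc <- compute_accuracies(ds, dec, "P01")
  mismatch <- make_mismatch_pool(16, 20, seed = 4242)
  fl <- compute_noise_floor(ds, dec, mismatch)
  flc <- compute_noise_floor(ds, dec, mismatch, conditions = "clean")
  est <- estimate_srt_neuro(acc, fl, gate_floor = flc, seed = 7, n_reps = 5)
  expect_true(est$fitted)
  expect_lt(abs(est$srt_neuro - (-5)), 2)
  expect_true(est$robustness_spread >= 0)
  expect_equal(length(est$all_m), 5L)
})

test_that("noiseless accuracies on an exact sigmoid give a rigid fit", {
  truth <- list(p = 0.3, b = 0.02, s = 0.02, m = -5.2)
  snr <- rep(seq(-9.2, -1.2, by = 2), each = 16)
  r <- sigmoid_eval(truth, snr)
  ms <- vapply(1:10, function(k)
    fit_sigmoid(snr, r, 0.3, 0.02, seed = k)$m, numeric(1))
  expect_lt(max(ms) - min(ms), 1e-3)
})

test_that("participants failing the gate are marked unfitted", {
  # clean accuracies indistinguishable from the floor
  acc <- data.frame(participant_id = "P01",
                    trial_id = sprintf("t%02d", 1:24),
                    condition = rep(c(sprintf("%+d", c(-4, -2, 0, 2, 4)),
                                      "clean"), each = 4),
                    snr_rel = rep(c(-4, -2, 0, 2, 4, NA), each = 4),
                    snr_abs = rep(c(-9, -7, -5, -3, -1, NA), each = 4))
  set.seed(11)
  acc$r <- rnorm(24, 0, 0.02)
  fl <- structure(list(b = 0, per_trial = rnorm(20, 0, 0.02),
                       raw = NULL, trial_id = NULL), class = "noise_floor")
  est <- estimate_srt_neuro(acc, fl, gate_floor = rnorm(4, 0, 0.02),
                            seed = 3, n_reps = 2)
  expect_false(est$fitted)
  expect_null(est$srt_neuro)
})

test_that("grid shifts do not bias the fitted midpoint", {
  # conditions sampled on a grid shifted relative to the true midpoint:
  # recovered midpoints show no systematic dependence on the shift
  truth <- list(p = 0.3, b = 0.01, s = 0.02, m = -5)
  shifts <- c(-2, 0, 2)
  reps <- 25
  err <- matrix(NA_real_, reps, length(shifts))
  for (j in seq_along(shifts)) {
    grid <- truth$m + shifts[j] + c(-4, -2, 0, 2, 4)
    snr <- rep(grid, each = 16)
    for (k in seq_len(reps)) {
      set.seed(1000 * j + k)
      r <- sigmoid_eval(truth, snr) + rnorm(length(snr), sd = 0.03)
      err[k, j] <- fit_sigmoid(snr, r, 0.3, 0.01, seed = k,
                               n_restarts = 30L)$m - truth$m
    }
  }
  fit <- stats::aov(err ~ shift,
                    data = data.frame(err = as.numeric(err),
                                      shift = factor(rep(shifts,
                                                         each = reps))))
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  expect_gt(p, 0.01) # no detectable shift effect
  expect_lt(max(abs(colMeans(err))), 0.75)
})

test_that("sigmoid curves export a plot-ready table", {
  m <- list(p = 0.3, b = 0.01, s = 0.02, m = -5)
  curve <- sigmoid_curve(m, c(-15, 5), n = 50)
  expect_equal(nrow(curve), 50L)
  expect_true(all(diff(curve$accuracy) >= 0))
})
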