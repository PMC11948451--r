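# Forward encoders, channel selection, Gaussian deflection fits and the
# mixed-model SNR tests.

test_that("encoders recover the generating kernel on noise-free data", {
  ds <- noisefree_dataset(n_trials = 3L, duration = 20, n_channels = 16L)
  enc <- fit_encoder(ds, lambda = 1e-8)
  expect_setequal(names(enc), unique(ds$condition))
  for (cond in c("-4", "+4", "clean")) {
    est <- enc[[cond]]
    true_k <- ds$ground_truth$kernels[[cond]]$weights
    sel <- est$window$tau_ms >= 0 &
      est$window$tau_ms <= max(ds$ground_truth$kernels[[cond]]$window$tau_ms)
    for (ch in c(1, 8, 16)) {
      expect_gt(stats::cor(est$trf[sel, ch][seq_len(nrow(true_k))],
                           true_k[, ch]), 0.99)
    }
    expect_true(all(est$pred_r > 0.999)) # noise-free prediction
  }
  # fixed lambda is recorded on every condition
  enc100 <- fit_encoder(ds, lambda = 100)
  expect_true(all(vapply(enc100, `[[`, numeric(1), "lambda") == 100))
})

test_that("encoder errors on a condition with fewer than 2 trials", {
  ds <- noisefree_dataset(n_trials = 3L, duration = 20, n_channels = 8L)
  drop <- which(ds$condition == "+4")[1:2]
  ds$trials <- ds$trials[-drop]; ds$envelopes <- ds$envelopes[-drop]
  ds$condition <- ds$condition[-drop]
  ds$snr_rel <- ds$snr_rel[-drop]; ds$snr_abs <- ds$snr_abs[-drop]
  expect_error(fit_encoder(ds), "fewer than 2 trials")
})

test_that("channels with higher topographic gain predict better", {
  ds <- noisefree_dataset(n_trials = 2L, duration = 15, n_channels = 16L)
  # add a little noise so accuracy differentiates across channels
  set.seed(12)
  for (i in seq_along(ds$trials))
    ds$trials[[i]]$data <- ds$trials[[i]]$data +
      matrix(rnorm(length(ds$trials[[i]]$data), sd = 0.05),
             nrow(ds$trials[[i]]$data))
  enc <- fit_encoder(ds, lambda = 100)
  topo <- ds$ground_truth$params$topography
  acc <- rowMeans(vapply(enc, `[[`, numeric(16), "pred_r"))
  expect_gt(stats::cor(topo, acc, method = "spearman"), 0.8)
})

test_that("select_channels ranks by grand-average accuracy with stable ties", {
  labels <- paste0("ch", 1:6)
  fake <- function(acc) {
    est <- list(condition = "x", pred_r = acc, channel_labels = labels,
                window = lag_window(-100, 500, 64))
    structure(list(x = est), class = "trf_estimates")
  }
  e1 <- fake(c(0.9, 0.1, 0.5, 0.5, 0.2, 0.8))
  expect_equal(select_channels(e1, k = 3), c("ch1", "ch3", "ch6"))
  # tie between ch3 and ch4 broken toward earlier montage order
  expect_equal(select_channels(e1, k = 4), c("ch1", "ch3", "ch4", "ch6"))
  expect_equal(select_channels(e1, k = 6), labels)
  expect_equal(select_channels(e1, k = 99), labels) # capped at n_channels
  expect_error(select_channels(e1, k = 0), "at least 1")
})

test_that("selection concentrates on the high-gain scalp region", {
  # unreferenced data: prediction accuracy tracks the raw topographic
  # gain (after common-average referencing it tracks |gain - mean gain|)
  ds <- tiny_dataset(n_trials = 4L, duration = 15, n_channels = 32L,
                     noise_level = 4, seed = 77)
  enc <- fit_encoder(ds, lambda = 100)
  sel <- select_channels(enc, k = 8)
  topo <- ds$ground_truth$params$topography
  top_half <- ds$channel_labels[order(-topo)][1:16]
  expect_gte(sum(sel %in% top_half), 7)
})

test_that("deflection fits recover exact Gaussians and flag degenerates", {
  tau <- lag_window(-100, 500, 64)$tau_ms
  shape <- -0.05 * exp(-((tau - 120) / 30)^2)
  fits <- fit_deflections(tau, shape)
  n1 <- fits[fits$component == "N1", ]
  expect_equal(n1$p, -0.05, tolerance = 1e-6)
  expect_equal(n1$l, 120, tolerance = 1e-4)
  expect_equal(n1$w, 30, tolerance = 1e-3)
  expect_gt(n1$r_squared, 1 - 1e-8)
  expect_false(n1$excluded)
  # a flat TRF yields no fit and is excluded
  flat <- fit_deflections(tau, rep(0, length(tau)))
  expect_true(all(flat$excluded))
  # bounds are hard constraints
  big <- 10 * exp(-((tau - 50) / 20)^2)
  p1 <- fit_deflections(tau, big)[1, ]
  expect_lte(p1$p, 5)
  expect_gte(p1$w, 0)
})

test_that("deflection fits stay accurate under 10 percent noise", {
  tau <- lag_window(-100, 500, 64)$tau_ms
  errs_l <- c(); errs_p <- c()
  for (s in 1:60) {
    set.seed(s)
    shape <- 0.05 * exp(-((tau - 200) / 35)^2) +
      rnorm(length(tau), sd = 0.005)
    p2 <- fit_deflections(tau, shape)[3, ]
    errs_l <- c(errs_l, p2$l - 200)
    errs_p <- c(errs_p, (p2$p - 0.05) / 0.05)
  }
  expect_lt(stats::median(abs(errs_l)), 5)
  expect_lt(stats::median(abs(errs_p)), 0.15)
})

test_that("Holm decisions match a hand-enumerated step-down procedure", {
  p <- c(0.001, 0.011, 0.02, 0.03, 0.04, 0.2)
  # brute-force step-down at alpha = 0.05: compare sorted p_(i) against
  # alpha / (m - i + 1), stop at the first failure
  ord <- order(p)
  reject_sorted <- logical(6)
  for (i in 1:6) {
    if (p[ord][i] < 0.05 / (6 - i + 1)) reject_sorted[i] <- TRUE else break
  }
  brute <- logical(6); brute[ord] <- reject_sorted
  expect_equal(holm_significant(p, alpha = 0.05), brute)
  # monotone in sorted order
  dec <- holm_significant(p)
  expect_true(all(diff(dec[order(p)]) <= 0))
})

test_that("the mixed model recovers feature slopes from a deflection table", {
  # simulate the deflection table directly: per-participant random
  # intercepts plus the per-dB slopes used by the generator
  slopes <- data.frame(component = c("P1", "N1", "P2"),
                       lat = c(-0.940, -1.517, -6.001),
                       amp = c(0.011, -0.015, 0.018))
  set.seed(22)
  tab <- do.call(rbind, lapply(1:20, function(pid) {
    do.call(rbind, lapply(1:3, function(ci) {
      snr <- c(-4, -2, 0, 2, 4)
      data.frame(participant_id = sprintf("P%02d", pid),
                 snr_rel = snr,
                 component = slopes$component[ci],
                 p = c(0.10, -0.15, 0.18)[ci] + slopes$amp[ci] * snr +
                   rnorm(1, 0, 0.02) + rnorm(5, 0, 0.01),
                 l = c(50, 120, 200)[ci] + slopes$lat[ci] * snr +
                   rnorm(1, 0, 4) + rnorm(5, 0, 3))
    }))
  }))
  res <- lmm_snr_effects(tab)
  expect_equal(nrow(res), 6L)
  p2lat <- res[res$component == "P2" & res$parameter == "Latency", ]
  expect_lt(abs(p2lat$coefficient - (-6.001)), 2 * p2lat$std_error)
  expect_lt(p2lat$p, 0.05)
  expect_true(p2lat$holm_significant)
  n1amp <- res[res$component == "N1" & res$parameter == "Amplitude", ]
  expect_lt(abs(n1amp$coefficient - (-0.015)), 2 * n1amp$std_error)
  # clean condition (NA SNR) is rejected
  bad <- tab; bad$snr_rel[1] <- NA
  expect_error(lmm_snr_effects(bad), "clean")
})

test_that("zero-slope features are rejected at roughly the nominal rate", {
  set.seed(31)
  ps <- vapply(1:120, function(k) {
    tab <- do.call(rbind, lapply(1:8, function(pid)
      data.frame(participant_id = pid, snr_rel = c(-4, -2, 0, 2, 4),
                 component = "P2",
                 p = 0.18 + rnorm(1, 0, 0.02) + rnorm(5, 0, 0.01),
                 l = 200 + rnorm(1, 0, 4) + rnorm(5, 0, 3))))
    res <- lmm_snr_effects(tab)
    res$p[res$component == "P2" & res$parameter == "Latency"]
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.06)
})

test_that("features with too few participants are marked not estimable", {
  tab <- data.frame(participant_id = c("P1", "P2"),
                    snr_rel = c(-4, 4), component = "P1",
                    p = c(0.1, 0.12), l = c(50, 48))
  res <- lmm_snr_effects(tab)
  expect_true(all(is.na(res$coefficient)))
  expect_true(all(is.na(res$holm_significant)))
})

test_that("grand averages are identity for one participant and truncate", {
  tau <- lag_window(-100, 500, 64)$tau_ms
  one <- list(P1 = list(clean = list(tau_ms = tau, trf = sin(tau / 100)),
                        `+0` = list(tau_ms = tau, trf = cos(tau / 100))))
  ga <- grand_average_trf(one$P1 |> list())
  expect_true(all(ga$tau_ms <= 400 & ga$tau_ms >= -100))
  sub <- ga[ga$condition == "clean", ]
  expect_equal(sub$trf, sin(tau[tau >= -100 & tau <= 400] / 100))
  # two participants: the mean
  two <- list(A = one$P1, B = lapply(one$P1, function(x)
    list(tau_ms = x$tau_ms, trf = x$trf + 1)))
  ga2 <- grand_average_trf(two)
  sub2 <- ga2[ga2$condition == "clean", ]
  expect_equal(sub2$trf, sub$trf + 0.5)
})

test_that("the encoder gate includes strong conditions and reports p-values", {
  # >= 5 trials per condition: with 3-vs-3 values a permutation test
  # cannot reach p < 0.05 (only 20 distinct splits)
  ds <- tiny_dataset(n_trials = 5L, duration = 15, n_channels = 8L,
                     noise_level = 4, seed = 55)
  ds <- preprocess_dataset(ds)
  enc <- fit_encoder(ds, lambda = 100)
  mismatch <- make_mismatch_pool(6, 15, seed = 321)
  gate <- encoder_significance_gate(enc, ds, mismatch = mismatch,
                                    n_perm = 2000L, seed = 2)
  expect_equal(nrow(gate), 6L)
  expect_true(all(c("condition", "p", "included") %in% names(gate)))
  # high-gain conditions separate clearly from the mismatched floor
  expect_true(gate$included[gate$condition == "clean"])
  expect_true(gate$included[gate$condition == "+4"])
})

test_that("tidy TRF export carries all labels", {
  ds <- noisefree_dataset(n_trials = 2L, duration = 15, n_channels = 4L)
  enc <- fit_encoder(ds, lambda = 100)
  tidy <- trf_tidy(enc, participant_id = "P01")
  expect_equal(nrow(tidy),
               6 * 4 * length(enc[[1]]$window$tau_ms))
  expect_setequal(unique(tidy$channel), ds$channel_labels)
})
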