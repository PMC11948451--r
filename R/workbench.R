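#' Experiment run configuration
#'
#' Validated flat key-value configuration for [run_experiment()]. A run
#' is reproducible from the configuration plus the master seed alone.
#' Unknown keys raise an error listing them.
#'
#' @param ... overrides of the defaults listed below.
#' @return a list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    cohort_size = 20L,
    n_trials_per_condition = 16L,
    trial_duration = 60,
    n_channels = 64L,
    noise_level = 10,
    offsets_db = c(-4, -2, 0, 2, 4),
    srt_mean = -5.35,
    srt_sd = 0.7,
    word_slope = 0.5,
    gain_slope = 0.35,
    decoder_lambda_grid = 10 ^ seq(-4, 10),
    n_mismatch = 68L,
    n_fit_reps = 100L,
    n_restarts = 100L,
    run_trf = TRUE,
    encoder_lambda = 100,
    k_channels = 17L,
    verbose = FALSE)
  args <- list(...)
  if (length(args) > 0 && (is.null(names(args)) || any(names(args) == "")))
    stop("all configuration entries must be named")
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, args)
  if (cfg$cohort_size < 1L) stop("cohort_size must be at least 1")
  structure(cfg, class = "run_config")
}

#' Run the full simulated experiment
#'
#' Simulates a cohort of listeners; for each listener runs the adaptive
#' behavioral track to measure the behavioral SRT, generates an EEG
#' dataset at SNRs centered on that measured SRT, trains the clean-speech
#' decoder, computes per-trial reconstruction accuracies and the
#' mismatched-envelope noise floor, and estimates the neural SRT from the
#' sigmoid fit. Optionally fits per-condition forward encoders, selects
#' channels, parameterizes the TRF deflections and tests SNR effects with
#' the mixed model.
#'
#' @param config a [run_config()].
#' @return a list of class `run_summary`: `participants` (one row per
#'   listener with `srt_true`, `srt_beh`, `srt_neuro`, `difference`,
#'   `robustness_spread`, gate and fit diagnostics), `cohort` (medians,
#'   SD of the difference, within +/-2 and +/-3 dB fractions),
#'   `adjacent_tests`, `accuracies`, and when `run_trf` is set
#'   `deflections`, `lmm`, `selected_channels`, `grand_average`.
#' @export
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  listeners <- simulate_cohort(config$cohort_size, seed = seed,
                               srt_mean = config$srt_mean,
                               srt_sd = config$srt_sd,
                               word_slope = config$word_slope,
                               gain_slope = config$gain_slope)
  montage <- montage_positions(config$n_channels)
  params <- synth_trf_params(montage = montage)
  rows <- data.frame()
  acc_all <- data.frame()
  enc_all <- list(); trf_means <- list()
  for (i in seq_along(listeners)) {
    pid <- sprintf("P%02d", i)
    if (config$verbose) message("listener ", pid)
    listener <- listeners[[i]]
    track <- run_track(listener, adaptive_config(),
                       seed = derive_seed(seed, "beh", i))
    srt_beh <- compute_srt_beh(track)
    dataset <- make_dataset(listener, params,
                            n_trials_per_condition =
                              config$n_trials_per_condition,
                            trial_duration = config$trial_duration,
                            noise_level = config$noise_level,
                            seed = derive_seed(seed, "data", i),
                            center_db = srt_beh,
                            offsets_db = config$offsets_db)
    dataset <- preprocess_dataset(dataset)
    decoder <- train_decoder(dataset,
                             lambda_grid = config$decoder_lambda_grid)
    acc <- compute_accuracies(dataset, decoder, participant_id = pid)
    mismatch <- make_mismatch_pool(config$n_mismatch,
                                   config$trial_duration,
                                   seed = derive_seed(seed, "mm", i))
    floor_noise <- compute_noise_floor(dataset, decoder, mismatch)
    floor_clean <- compute_noise_floor(dataset, decoder, mismatch,
                                       conditions = "clean")
    est <- estimate_srt_neuro(acc, floor_noise, gate_floor = floor_clean,
                              seed = derive_seed(seed, "srt", i),
                              n_reps = config$n_fit_reps,
                              n_restarts = config$n_restarts)
    rows <- rbind(rows, data.frame(
      participant_id = pid,
      srt_true = listener$srt_true,
      srt_beh = srt_beh,
      fitted = est$fitted,
      gate_p = est$gate$p,
      srt_neuro = if (est$fitted) est$srt_neuro else NA_real_,
      difference = if (est$fitted) est$srt_neuro - srt_beh else NA_real_,
      robustness_spread = if (est$fitted) est$robustness_spread
                          else NA_real_,
      lambda = decoder$lambda,
      p_clean = mean(acc$r[acc$condition == "clean"]),
      b_floor = floor_noise$b,
      slope = if (est$fitted) est$model$s else NA_real_,
      r_squared = if (est$fitted) est$model$r_squared else NA_real_))
    acc_all <- rbind(acc_all, acc)
    if (config$run_trf) {
      enc <- fit_encoder(dataset, lambda = config$encoder_lambda)
      enc_all[[pid]] <- enc
    }
  }
  adjacent <- if (config$cohort_size >= 2L)
    adjacent_snr_tests(acc_all, seed = derive_seed(seed, "adjacent"))
  summary <- list(participants = rows,
                  cohort = summarize_cohort(rows),
                  adjacent_tests = adjacent,
                  accuracies = acc_all,
                  config = unclass(config), seed = seed)
  if (config$run_trf) {
    selected <- select_channels(enc_all, k = config$k_channels)
    defl <- data.frame()
    for (pid in names(enc_all)) {
      trf_means[[pid]] <- lapply(enc_all[[pid]], mean_trf,
                                 channels = selected)
      for (cond in names(enc_all[[pid]])) {
        mt <- trf_means[[pid]][[cond]]
        dd <- fit_deflections(mt$tau_ms, mt$trf)
        dd$participant_id <- pid
        dd$condition <- cond
        dd$snr_rel <- enc_all[[pid]][[cond]]$snr_rel
        defl <- rbind(defl, dd)
      }
    }
    noise_defl <- defl[!is.na(defl$snr_rel), ]
    summary$deflections <- defl
    summary$lmm <- if (length(unique(noise_defl$participant_id)) >= 3)
      lmm_snr_effects(noise_defl)
    summary$selected_channels <- selected
    summary$grand_average <- grand_average_trf(trf_means)
  }
  structure(summary, class = "run_summary")
}

#' Cohort-level summary statistics
#'
#' @param participants the per-participant data.frame of a `run_summary`.
#' @return list with medians of the behavioral and neural SRT, median and
#'   SD of their difference, and the fractions of fitted participants
#'   with `|difference|` within 2 and 3 dB.
#' @export
summarize_cohort <- function(participants) {
  if (nrow(participants) == 0) stop("empty summary")
  d <- participants$difference[participants$fitted]
  d <- d[!is.na(d)]
  list(n = nrow(participants), n_fitted = sum(participants$fitted),
       median_srt_beh = stats::median(participants$srt_beh),
       median_srt_neuro = stats::median(participants$srt_neuro,
                                        na.rm = TRUE),
       median_difference = stats::median(d),
       sd_difference = stats::sd(d),
       within_2db = mean(abs(d) <= 2),
       within_3db = mean(abs(d) <= 3))
}

#' Write human- and machine-readable reports of a run
#'
#' Emits a JSON summary (cohort statistics, per-participant table,
#' adjacent-condition tests, mixed-model table) and CSV tables, and
#' prints the headline numbers.
#'
#' @param summary a `run_summary`.
#' @param dir output directory (created if missing); `NULL` to skip
#'   writing files.
#' @return invisibly, the cohort statistics list (including the within
#'   +/-2 dB and +/-3 dB fractions).
#' @export
report <- function(summary, dir = NULL) {
  if (is.null(summary$participants) || nrow(summary$participants) == 0)
    stop("empty summary")
  coh <- summary$cohort
  cat(sprintf("cohort n = %d (fitted %d)\n", coh$n, coh$n_fitted))
  cat(sprintf("median SRT_beh   = %6.2f dB\n", coh$median_srt_beh))
  cat(sprintf("median SRT_neuro = %6.2f dB\n", coh$median_srt_neuro))
  cat(sprintf("median difference = %.2f dB (SD %.2f dB)\n",
              coh$median_difference, coh$sd_difference))
  cat(sprintf("within +/-2 dB: %.0f%%; within +/-3 dB: %.0f%%\n",
              100 * coh$within_2db, 100 * coh$within_3db))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    obj <- list(seed = summary$seed, config = summary$config,
                cohort = coh, participants = summary$participants,
                adjacent_tests = summary$adjacent_tests,
                lmm = summary$lmm)
    jsonlite::write_json(obj, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    utils::write.csv(summary$participants,
                     file.path(dir, "participants.csv"), row.names = FALSE)
    utils::write.csv(summary$accuracies,
                     file.path(dir, "accuracies.csv"), row.names = FALSE)
    if (!is.null(summary$deflections))
      utils::write.csv(summary$deflections,
                       file.path(dir, "deflections.csv"), row.names = FALSE)
    if (!is.null(summary$lmm))
      utils::write.csv(summary$lmm, file.path(dir, "lmm.csv"),
                       row.names = FALSE)
  }
  invisible(coh)
}

#' Write an EEG dataset to a directory (CSV + JSON sidecar)
#'
#' Trials and envelopes go to plain CSV; conditions, labels, rate and
#' seeds go to a JSON sidecar. [read_dataset()] restores the dataset
#' (ground truth is not serialized).
#'
#' @param dataset an `eeg_dataset`.
#' @param dir output directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(rate = dataset$rate, seed = dataset$seed,
               center_db = dataset$center_db,
               channel_labels = dataset$channel_labels,
               condition = dataset$condition, snr_rel = dataset$snr_rel,
               snr_abs = dataset$snr_abs,
               trial_id = vapply(dataset$trials, `[[`, "", "trial_id"))
  jsonlite::write_json(meta, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  eeg <- do.call(rbind, lapply(seq_along(dataset$trials), function(i) {
    d <- as.data.frame(dataset$trials[[i]]$data)
    names(d) <- dataset$channel_labels
    cbind(trial = i, sample = seq_len(nrow(d)), d)
  }))
  utils::write.csv(eeg, file.path(dir, "eeg.csv"), row.names = FALSE)
  env <- do.call(rbind, lapply(seq_along(dataset$envelopes), function(i)
    data.frame(trial = i, sample = seq_along(dataset$envelopes[[i]]$values),
               value = dataset$envelopes[[i]]$values)))
  utils::write.csv(env, file.path(dir, "envelopes.csv"), row.names = FALSE)
  utils::write.csv(dataset$montage, file.path(dir, "montage.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read an EEG dataset written by [write_dataset()]
#' @param dir dataset directory.
#' @return an `eeg_dataset` (without ground truth).
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  eeg <- utils::read.csv(file.path(dir, "eeg.csv"), check.names = FALSE)
  env <- utils::read.csv(file.path(dir, "envelopes.csv"))
  mont <- utils::read.csv(file.path(dir, "montage.csv"))
  class(mont) <- c("montage", "data.frame")
  trials <- list(); envelopes <- list()
  for (i in sort(unique(eeg$trial))) {
    d <- as.matrix(eeg[eeg$trial == i, meta$channel_labels, drop = FALSE])
    dimnames(d) <- NULL
    snr <- meta$snr_abs[i]
    trials[[i]] <- eeg_trial(d, meta$rate, meta$channel_labels,
                             condition = meta$condition[i],
                             snr_db = if (is.null(snr)) NA else snr,
                             trial_id = meta$trial_id[i])
    envelopes[[i]] <- envelope_signal(env$value[env$trial == i], meta$rate,
                                      trial_id = meta$trial_id[i],
                                      snr_db = meta$snr_rel[i])
  }
  structure(list(trials = trials, envelopes = envelopes,
                 condition = meta$condition,
                 snr_rel = as.numeric(meta$snr_rel),
                 snr_abs = as.numeric(meta$snr_abs),
                 channel_labels = meta$channel_labels, montage = mont,
                 rate = meta$rate, seed = meta$seed,
                 center_db = meta$center_db, ground_truth = NULL),
            class = "eeg_dataset")
}
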