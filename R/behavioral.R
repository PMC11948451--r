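#' Configuration of the adaptive speech-in-noise staircase
#'
#' Word-scored adaptive procedure for the hearing-in-noise test (HINT):
#' after each 5-word sentence the noise level is changed by
#' `dL = (p_previous - p_target) * g` dB, where `p_previous` is the
#' proportion of words repeated correctly, `p_target = 0.5`, and the step
#' constant `g` is 8 dB for the first 4 sentences and 4 dB afterwards
#' (step size halved). The speech level is fixed, so the SNR changes by
#' `-dL`.
#'
#' @param p_target target proportion of words correct (0.5 targets the
#'   50 percent speech reception threshold).
#' @param g_initial,g_final step constants in dB before/after the switch.
#' @param switch_after_sentence last sentence using `g_initial`.
#' @param n_sentences total sentences in the track (two concatenated
#'   20-sentence lists).
#' @param start_snr SNR of the first sentence in dB.
#' @param words_per_sentence words scored per sentence.
#' @param speech_level fixed speech presentation level in dB SPL
#'   (metadata only; the procedure operates on SNR).
#' @return a list of class `adaptive_config`.
#' @export
adaptive_config <- function(p_target = 0.5, g_initial = 8, g_final = 4,
                            switch_after_sentence = 4L, n_sentences = 40L,
                            start_snr = -10, words_per_sentence = 5L,
                            speech_level = 65) {
  stopifnot(p_target > 0, p_target < 1, g_initial > 0, g_final > 0,
            switch_after_sentence >= 1L, n_sentences > switch_after_sentence,
            words_per_sentence >= 1L)
  structure(list(p_target = p_target, g_initial = g_initial,
                 g_final = g_final,
                 switch_after_sentence = as.integer(switch_after_sentence),
                 n_sentences = as.integer(n_sentences),
                 start_snr = start_snr,
                 words_per_sentence = as.integer(words_per_sentence),
                 speech_level = speech_level),
            class = "adaptive_config")
}

#' SNR change applied by the adaptive rule
#'
#' @param words_correct number of words repeated correctly for the
#'   previous sentence (0..`words_per_sentence`).
#' @param sentence_index index of the sentence that was just scored
#'   (1-based); determines whether the initial or final step constant
#'   applies.
#' @param config an [adaptive_config()].
#' @return the SNR change in dB for the next sentence. The noise level
#'   moves by `dL = (p - p_target) * g` while speech is fixed, so the
#'   returned SNR change is `-dL`.
#' @export
adaptive_step <- function(words_correct, sentence_index,
                          config = adaptive_config()) {
  stopifnot(inherits(config, "adaptive_config"))
  if (words_correct < 0 || words_correct > config$words_per_sentence)
    stop("words_correct out of range")
  if (sentence_index < 1) stop("sentence_index must be >= 1")
  g <- if (sentence_index <= config$switch_after_sentence)
    config$g_initial else config$g_final
  dL <- (words_correct / config$words_per_sentence - config$p_target) * g
  -dL
}

#' Run an adaptive track against a simulated listener
#'
#' Iterates [simulate_sentence_response()] and [adaptive_step()] starting
#' from `config$start_snr`.
#'
#' @param listener a [simulated_listener()].
#' @param config an [adaptive_config()].
#' @param seed integer seed; the track is deterministic given the seed.
#' @return a data.frame of class `adaptive_track` with one row per
#'   sentence: `sentence`, `snr_db`, `words_correct`, `delta_applied`
#'   (the SNR change applied after that sentence).
#' @export
run_track <- function(listener, config = adaptive_config(), seed = 1L) {
  stopifnot(inherits(config, "adaptive_config"))
  n <- config$n_sentences
  snr <- numeric(n); wc <- integer(n); delta <- numeric(n)
  snr[1] <- config$start_snr
  for (i in seq_len(n)) {
    wc[i] <- simulate_sentence_response(listener, snr[i],
                                        n_words = config$words_per_sentence,
                                        seed = derive_seed(seed, "track", i))
    delta[i] <- adaptive_step(wc[i], i, config)
    if (i < n) snr[i + 1] <- snr[i] + delta[i]
  }
  structure(data.frame(sentence = seq_len(n), snr_db = snr,
                       words_correct = wc, delta_applied = delta),
            class = c("adaptive_track", "data.frame"))
}

#' Behavioral speech reception threshold from an adaptive track
#'
#' The behavioral SRT is the mean SNR over sentences 5-40, i.e. the
#' sentences presented with the smaller step constant.
#'
#' @param track an `adaptive_track` (or data.frame with `snr_db`).
#' @param from first sentence included (default 5).
#' @return SRT in dB.
#' @export
compute_srt_beh <- function(track, from = 5L) {
  if (nrow(track) < from)
    stop(sprintf("track has fewer than %d sentences", from))
  mean(track$snr_db[seq(from, nrow(track))])
}

#' Write an adaptive track log to CSV
#' @param track an `adaptive_track`.
#' @param path output path.
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}
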