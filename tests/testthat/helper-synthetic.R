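# Shared small fixtures, built in code. Kept deliberately tiny: 16
# channels, short trials, few trials per condition, so every test file
# stays fast. Heavier end-to-end checks live in test-acceptance.R.

tiny_montage <- function(n = 16L) montage_positions(n)

tiny_params <- function(n_channels = 16L)
  synth_trf_params(montage = montage_positions(n_channels))

# A small noise-free clean-condition dataset: ideal for exact
# forward/backward recovery checks.
noisefree_dataset <- function(n_trials = 3L, duration = 20,
                              n_channels = 16L, seed = 101L) {
  listener <- simulated_listener(-5)
  make_dataset(listener, tiny_params(n_channels),
               n_trials_per_condition = n_trials,
               trial_duration = duration, noise_level = 0,
               seed = seed, center_db = -5)
}

# Independent re-statement of common-average referencing for oracles.
common_average_oracle <- function(d) sweep(d, 1, apply(d, 1, mean))

# A small noisy dataset under default-like conditions, scaled down.
tiny_dataset <- function(n_trials = 4L, duration = 15, n_channels = 16L,
                         noise_level = 10, seed = 202L,
                         listener = simulated_listener(-5)) {
  make_dataset(listener, tiny_params(n_channels),
               n_trials_per_condition = n_trials,
               trial_duration = duration, noise_level = noise_level,
               seed = seed, center_db = listener$srt_true)
}
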