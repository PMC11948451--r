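#' Derive a child seed from a master seed and a key
#'
#' All randomness in the package flows from a single master seed. Child
#' seeds for independent artifacts (trials, restarts, listeners, ...) are
#' derived deterministically from the master seed and a string key, so a
#' run is reproducible from `(config, seed)` alone and artifacts generated
#' under different keys are decorrelated.
#'
#' @param seed integer master seed.
#' @param ... components (coerced to character) identifying the artifact;
#'   concatenated with `/` into the key.
#' @return an integer in `[1, 2^31 - 2]` suitable for `set.seed()`.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  key <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1)), collapse = "/")
  m <- 2147483647 # 2^31 - 1, prime
  h <- (abs(seed) %% m)
  # multiplicative string hash folded into the seed; doubles are exact
  # below 2^53 so (h * 31 + code) stays exact for h < m
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m
  h <- (h * 48271 + 1) %% m
  as.integer(h %/% 1 + 1)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_if_nan <- function(x, what = "input") {
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("%s contains NA/NaN/Inf values", what), call. = FALSE)
  invisible(x)
}

#' Pearson correlation between two series
#'
#' Thin wrapper over [stats::cor()] that rejects degenerate inputs
#' instead of silently returning `NA` or 0: reconstruction accuracies
#' must never be fabricated from a flat signal.
#'
#' @param a,b numeric vectors of equal length (>= 3).
#' @return Pearson's r in `[-1, 1]`.
#' @export
pearson_accuracy <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length")
  if (length(a) < 3L) stop("need at least 3 samples")
  stop_if_nan(a, "a"); stop_if_nan(b, "b")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance input: correlation undefined")
  stats::cor(a, b)
}
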