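#' Lag window for a lagged linear (TRF) model
#'
#' @param tau_min,tau_max window edges in ms. The backward decoder uses
#'   -100 to 350 ms; the forward encoder uses -100 to 500 ms. Positive
#'   lags mean the EEG follows the stimulus (causal response); the
#'   negative edge provides an acausal margin.
#' @param rate sampling rate in Hz.
#' @return object of class `lag_window` with integer sample lags and
#'   their times in ms. Lag count is `round((tau_max - tau_min)/1000 *
#'   rate) + 1`.
#' @export
lag_window <- function(tau_min, tau_max, rate = 64) {
  stopifnot(tau_min < tau_max, rate > 0)
  n_lags <- round((tau_max - tau_min) / 1000 * rate) + 1L
  lag0 <- round(tau_min / 1000 * rate)
  lags <- lag0 + seq_len(n_lags) - 1L
  structure(list(tau_min = tau_min, tau_max = tau_max, rate = rate,
                 lags = as.integer(lags), tau_ms = lags / rate * 1000),
            class = "lag_window")
}

#' Build a lagged design matrix
#'
#' Row `t` contains, for every channel and lag in the window, the sample
#' at `t + tau` under the backward convention (EEG shifted relative to
#' the envelope sample being reconstructed) or at `t - tau` under the
#' forward convention (stimulus history driving the EEG sample). Out of
#' range samples are zero-padded, so trials are processed independently
#' and never concatenated across the lag boundary.
#'
#' @param x numeric vector or time-by-channels matrix.
#' @param window a [lag_window()].
#' @param direction `"backward"` (default) or `"forward"`.
#' @return a matrix with one row per time sample and
#'   `n_channels * n_lags` columns, ordered channel-block by lag.
#' @export
build_lag_matrix <- function(x, window, direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  x <- as.matrix(x)
  n <- nrow(x); nc <- ncol(x); nl <- length(window$lags)
  if (nl >= n) stop("lag window longer than the signal")
  X <- matrix(0, n, nc * nl)
  sgn <- if (direction == "backward") 1L else -1L
  t_all <- seq_len(n)
  for (li in seq_len(nl)) {
    src <- t_all + sgn * window$lags[li]
    ok <- src >= 1L & src <= n
    for (ci in seq_len(nc)) {
      X[ok, (ci - 1L) * nl + li] <- x[src[ok], ci]
    }
  }
  X
}

# Sufficient statistics of (X, y) for pooled / leave-one-out ridge fits.
#' @keywords internal
trial_moments <- function(X, y) {
  y <- as.matrix(y)
  list(n = nrow(X), sx = colSums(X), sy = colSums(y),
       G = crossprod(X), C = crossprod(X, y))
}

#' @keywords internal
moments_combine <- function(a, b, sign = 1) {
  list(n = a$n + sign * b$n, sx = a$sx + sign * b$sx,
       sy = a$sy + sign * b$sy, G = a$G + sign * b$G,
       C = a$C + sign * b$C)
}

# Ridge solve from moments: columns and targets are mean-centered, the
# penalty is lambda * mean(diag(Gc)) * I (dimensionless lambda), and the
# intercept restores the target mean.
#' @keywords internal
ridge_solve_moments <- function(mom, lambda) {
  xbar <- mom$sx / mom$n
  ybar <- mom$sy / mom$n
  Gc <- mom$G - mom$n * tcrossprod(xbar)
  Cc <- mom$C - mom$n * outer(xbar, ybar)
  mbar <- mean(diag(Gc))
  A <- Gc
  if (lambda > 0) diag(A) <- diag(A) + lambda * mbar
  w <- tryCatch(solve(A, Cc), error = function(e) {
    if (lambda == 0)
      stop("singular normal equations with lambda = 0; use lambda > 0",
           call. = FALSE)
    stop(e)
  })
  w <- as.matrix(w)
  intercept <- as.numeric(ybar - crossprod(w, xbar))
  list(weights = w, intercept = intercept, mbar = mbar)
}

#' Fit a lagged ridge regression
#'
#' Solves `(X'X + lambda * mbar * I) w = X'y` on mean-centered columns,
#' where `mbar = trace(X'X)/ncol(X)` makes `lambda` dimensionless (a
#' given lambda has comparable shrinkage across trials and participants).
#' The intercept restores the target mean.
#'
#' @param X design matrix, e.g. from [build_lag_matrix()].
#' @param y numeric vector (backward: envelope) or matrix with one column
#'   per target (forward: EEG channels).
#' @param lambda non-negative dimensionless regularization parameter.
#' @param window optional [lag_window()] stored on the model.
#' @param direction `"backward"` or `"forward"`; stored on the model.
#' @param n_channels number of input channels encoded in `X` (backward
#'   models); inferred as `ncol(X)/n_lags` when a window is given.
#' @return a `lagged_linear_model` with fields `weights`
#'   (columns-of-X by targets), `intercept`, `lambda`, `window`,
#'   `direction`.
#' @export
ridge_fit <- function(X, y, lambda, window = NULL,
                      direction = c("backward", "forward"),
                      n_channels = NULL) {
  direction <- match.arg(direction)
  y <- as.matrix(y)
  if (nrow(X) != nrow(y)) stop("X and y must have the same number of rows")
  if (lambda < 0) stop("lambda must be non-negative")
  sol <- ridge_solve_moments(trial_moments(X, y), lambda)
  if (!is.null(window) && is.null(n_channels))
    n_channels <- ncol(X) %/% length(window$lags)
  structure(list(weights = sol$weights, intercept = sol$intercept,
                 lambda = lambda, window = window, direction = direction,
                 n_channels = n_channels),
            class = "lagged_linear_model")
}

#' @export
print.lagged_linear_model <- function(x, ...) {
  cat(sprintf("<lagged_linear_model: %s, %d weights x %d target(s), lambda = %g>\n",
              x$direction, nrow(x$weights), ncol(x$weights), x$lambda))
  invisible(x)
}

#' Predict from a lagged linear model
#'
#' @param object a `lagged_linear_model`.
#' @param signal backward: time-by-channels EEG matrix; forward: envelope
#'   vector. A lagged design matrix is built with the model's window.
#' @param ... unused.
#' @return backward: the reconstructed envelope (numeric vector);
#'   forward: a time-by-channels matrix of predicted EEG.
#' @export
predict.lagged_linear_model <- function(object, signal, ...) {
  if (is.null(object$window))
    stop("model has no lag window; cannot build the design matrix")
  x <- if (object$direction == "backward") as.matrix(signal) else
    matrix(as.numeric(if (inherits(signal, "envelope_signal")) signal$values
                      else signal), ncol = 1)
  nl <- length(object$window$lags)
  if (ncol(x) * nl != nrow(object$weights))
    stop(sprintf("signal has %d channel(s); model expects %d",
                 ncol(x), nrow(object$weights) %/% nl))
  X <- build_lag_matrix(x, object$window, object$direction)
  pred <- X %*% object$weights
  pred <- sweep(pred, 2, object$intercept, "+")
  if (object$direction == "backward") as.numeric(pred) else pred
}

#' Leave-one-out cross-validated lambda search
#'
#' For each lambda on the grid, fits the ridge model on all trials but
#' one (pooled rows), evaluates Pearson's correlation between prediction
#' and held-out target, and averages across folds; returns the lambda
#' maximizing the mean correlation. Ties are broken toward the larger
#' (more regularized) lambda.
#'
#' @param trials list of `list(X = design matrix, y = target)` pairs.
#' @param grid lambda values; default integer powers of 10 from 1e-4 to
#'   1e10.
#' @return list with `lambda` (the selected value) and `mean_r` (named
#'   mean held-out correlation per grid value).
#' @export
loo_lambda_search <- function(trials, grid = 10 ^ seq(-4, 10)) {
  if (length(grid) == 0) stop("empty lambda grid")
  if (length(trials) < 2L) stop("need at least 2 trials for leave-one-out")
  grid <- sort(as.numeric(grid))
  moms <- lapply(trials, function(tr) trial_moments(tr$X, as.matrix(tr$y)))
  total <- Reduce(moments_combine, moms)
  scores <- matrix(NA_real_, length(trials), length(grid))
  for (i in seq_along(trials)) {
    mom <- moments_combine(total, moms[[i]], sign = -1)
    Xi <- trials[[i]]$X
    yi <- as.numeric(as.matrix(trials[[i]]$y)[, 1])
    for (k in seq_along(grid)) {
      sol <- ridge_solve_moments(mom, grid[k])
      pred <- as.numeric(Xi %*% sol$weights[, 1] + sol$intercept[1])
      scores[i, k] <- tryCatch(pearson_accuracy(pred, yi),
                               error = function(e) NA_real_)
    }
  }
  mean_r <- colMeans(scores, na.rm = TRUE)
  mean_r[is.nan(mean_r)] <- -Inf
  best <- max(mean_r)
  k_best <- max(which(mean_r == best)) # tie -> larger lambda
  list(lambda = grid[k_best],
       mean_r = stats::setNames(mean_r, format(grid, scientific = TRUE)))
}

#' Serialize a lagged linear model to JSON
#' @param model a `lagged_linear_model`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "lagged_linear_model"))
  obj <- list(direction = model$direction, lambda = model$lambda,
              n_channels = model$n_channels,
              window = if (!is.null(model$window))
                model$window[c("tau_min", "tau_max", "rate")],
              intercept = model$intercept,
              weights = as.numeric(model$weights),
              dim = dim(model$weights))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a lagged linear model written by [write_model_json()]
#' @param path file path.
#' @return a `lagged_linear_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  win <- if (!is.null(obj$window))
    lag_window(obj$window$tau_min, obj$window$tau_max, obj$window$rate)
  structure(list(weights = matrix(obj$weights, obj$dim[1], obj$dim[2]),
                 intercept = obj$intercept, lambda = obj$lambda,
                 window = win, direction = obj$direction,
                 n_channels = obj$n_channels),
            class = "lagged_linear_model")
}
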