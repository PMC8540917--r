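# Two-stage change-score computation.
#
# Stage 1 learns an AR(k) model of the input with sequentially discounted
# sufficient statistics (SDAR), scores each sample by the negative log
# predictive density of the model *before* that sample, and smooths the
# scores with a causal moving average of width w. Stage 2 runs the identical
# machinery on the stage-1 scores with smoothing width round(w/2), which
# suppresses isolated noise spikes and leaves genuine shifts in the
# generating process. The final smoothed sequence is the change score S(t).

#' Parameters of the two-stage change-score detector
#'
#' @param order AR model order k (default 1).
#' @param discount Forgetting rate r in (0, 1); each update weighs the new
#'   sample by r and discounts the past by 1 - r, so the effective memory is
#'   about 1/r samples (default 0.025, i.e. roughly 40 s at 1 Hz).
#' @param smooth_width Causal moving-average width w of the first stage, in
#'   samples (default 5).
#' @param second_width Smoothing width of the second stage; defaults to
#'   `round(smooth_width / 2)` under R's round-half-even, so w = 5 gives 2.
#' @return Object of class `changefinder_params`.
#' @export
changefinder_params <- function(order = 1L, discount = 0.025,
                                smooth_width = 5L, second_width = NULL) {
  order <- as.integer(order)
  smooth_width <- as.integer(smooth_width)
  if (is.na(order) || order < 1L) stop_config("order must be a positive integer")
  if (!is.numeric(discount) || discount <= 0 || discount >= 1)
    stop_config("discount must lie strictly between 0 and 1")
  if (is.na(smooth_width) || smooth_width < 1L)
    stop_config("smooth_width must be >= 1")
  if (is.null(second_width))
    second_width <- max(1L, as.integer(round(smooth_width / 2)))
  second_width <- as.integer(second_width)
  if (is.na(second_width) || second_width < 1L)
    stop_config("second_width must be >= 1")
  structure(list(order = order, discount = discount,
                 smooth_width = smooth_width, second_width = second_width),
            class = "changefinder_params")
}

#' @export
print.changefinder_params <- function(x, ...) {
  cat(sprintf("<changefinder_params> order=%d, discount=%g, smooth_width=%d, second_width=%d\n",
              x$order, x$discount, x$smooth_width, x$second_width))
  invisible(x)
}

#' Fresh SDAR model state
#'
#' Holds the discounted running statistics of the AR(k) learner: mean,
#' autocovariances C_0..C_k, Yule-Walker coefficients a_1..a_k, residual
#' variance, and the k most recent observations. Everything starts at zero
#' except the mean, which is seeded with the first observation on the first
#' update so that a constant input is an exact fixed point.
#'
#' @param order AR order k.
#' @param discount Forgetting rate r in (0, 1).
#' @return Object of class `sdar_state`.
#' @export
sdar_new <- function(order = 1L, discount = 0.025) {
  order <- as.integer(order)
  if (is.na(order) || order < 1L) stop_config("order must be a positive integer")
  if (!is.numeric(discount) || discount <= 0 || discount >= 1)
    stop_config("discount must lie strictly between 0 and 1")
  structure(list(order = order, discount = discount,
                 mean = NA_real_,
                 autocov = rep(0, order + 1L),
                 coefficients = rep(0, order),
                 variance = 0,
                 history = numeric(0),   # most recent observation first
                 t = 0L),
            class = "sdar_state")
}

#' One-step prediction from the current SDAR state
#'
#' Computes `xhat = mean + sum(a_i * (x_{t-i} - mean))` from the current
#' coefficients and mean, together with the current residual variance. Both
#' describe the model *before* the next observation is incorporated, which is
#' what the log-loss score needs.
#'
#' @param state An [sdar_new()] state.
#' @param history The last k observations, most recent first; defaults to the
#'   history carried in the state.
#' @return List with `predicted` and `variance`.
#' @export
sdar_predict <- function(state, history = state$history) {
  k <- state$order
  if (length(history) < k)
    stop_insufficient("SDAR prediction needs %d prior observation(s), have %d",
                      k, length(history))
  mu <- state$mean
  list(predicted = mu + sum(state$coefficients * (history[seq_len(k)] - mu)),
       variance = state$variance)
}

#' Solve the Yule-Walker system for AR coefficients
#'
#' Finds `a` with `C_i = sum_j a_j C_{i-j}` for i = 1..k under the symmetry
#' convention `C_{-i} = C_i`, i.e. solves the k x k Toeplitz system built
#' from `C_0..C_{k-1}` against the right-hand side `C_1..C_k`. A singular
#' system (e.g. all-zero autocovariances at the start of a stream) yields the
#' zero vector plus a flag rather than an error, which reduces the predictor
#' to the running mean.
#'
#' @param autocov Numeric vector `C_0..C_k` (length k + 1 at least).
#' @param k AR order.
#' @return List with `coefficients` (length k) and logical `singular`.
#' @export
solve_yule_walker <- function(autocov, k = length(autocov) - 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop_config("k must be a positive integer")
  if (length(autocov) < k + 1L)
    stop_config("need k + 1 autocovariances, got %d", length(autocov))
  M <- stats::toeplitz(autocov[seq_len(k)])
  rhs <- autocov[2:(k + 1L)]
  a <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(a) || any(!is.finite(a)))
    return(list(coefficients = rep(0, k), singular = TRUE))
  list(coefficients = as.numeric(a), singular = FALSE)
}

#' Update the SDAR state with one observation
#'
#' Applies the discounted updates
#' `mu <- (1-r) mu + r x`,
#' `C_i <- (1-r) C_i + r (x - mu)(x_{t-i} - mu)` for i = 0..k,
#' re-solves the Yule-Walker system for the coefficients, and updates the
#' residual variance `sigma <- (1-r) sigma + r (x - xhat)^2` where `xhat` is
#' the one-step prediction made from the state *before* this update. While
#' fewer than k past observations exist, unavailable autocovariance lags are
#' left at zero and the prediction falls back to the running mean.
#'
#' @param state An [sdar_new()] state.
#' @param x New observation.
#' @return The updated state.
#' @export
sdar_update <- function(state, x) {
  k <- state$order
  r <- state$discount
  h <- state$history
  mu_prev <- if (state$t == 0L) x else state$mean
  xhat <- if (length(h) >= k)
    mu_prev + sum(state$coefficients * (h[seq_len(k)] - mu_prev))
  else mu_prev
  mu <- (1 - r) * mu_prev + r * x
  C <- state$autocov
  C[1L] <- (1 - r) * C[1L] + r * (x - mu)^2
  m <- min(k, length(h))
  if (m > 0L)
    C[seq_len(m) + 1L] <- (1 - r) * C[seq_len(m) + 1L] +
      r * (x - mu) * (h[seq_len(m)] - mu)
  yw <- solve_yule_walker(C, k)
  state$mean <- mu
  state$autocov <- C
  state$coefficients <- yw$coefficients
  state$variance <- (1 - r) * state$variance + r * (x - xhat)^2
  state$history <- c(x, h)[seq_len(min(state$t + 1L, k))]
  state$t <- state$t + 1L
  state
}

#' Gaussian negative log predictive density
#'
#' `y = 0.5 log(2 pi v) + (x - predicted)^2 / (2 v)` with the variance `v`
#' floored at `floor` so constant stretches (variance collapsing to 0) give
#' large but finite scores. Note `variance` is a variance, not a standard
#' deviation; the log is natural.
#'
#' @param x Observation.
#' @param predicted One-step prediction.
#' @param variance Predictive variance (>= 0).
#' @param floor Variance floor (default 1e-12).
#' @return The log-loss score (vectorized over the inputs).
#' @export
log_loss <- function(x, predicted, variance, floor = 1e-12) {
  if (any(variance < 0)) stop_config("variance must be non-negative")
  v <- pmax(variance, floor)
  0.5 * log(2 * pi * v) + (x - predicted)^2 / (2 * v)
}

#' Causal moving average
#'
#' Trailing mean over the last `width` samples; positions with fewer than
#' `width` predecessors average over the available prefix, keeping the output
#' aligned 1:1 with the input.
#'
#' @param x Numeric vector.
#' @param width Window width in samples (>= 1).
#' @return Numeric vector of the same length.
#' @export
causal_smooth <- function(x, width) {
  width <- as.integer(width)
  if (is.na(width) || width < 1L) stop_config("width must be >= 1")
  n <- length(x)
  if (n == 0L) return(numeric(0))
  cs <- cumsum(x)
  prev <- c(rep(0, width), cs)[seq_len(n)]
  (cs - prev) / pmin(seq_len(n), width)
}

# One SDAR learning round: predict -> score -> update per sample, then smooth.
# A sample is scored only once the model is ready: it has k prior
# observations AND a positive residual-variance estimate. Scoring against an
# exactly-zero variance would hit the floor and emit a huge startup spike
# whose magnitude would dominate the second stage's discounted statistics for
# a long stretch; the variance is exactly zero only while every residual so
# far has been zero (startup, or an all-constant input), so the gate ends as
# soon as the data vary. Unscored samples get y = 0 and are reported via the
# `scored` vector so they can be flagged downstream.
cf_stage <- function(x, order, discount, width) {
  st <- sdar_new(order, discount)
  y <- numeric(length(x))
  scored <- logical(length(x))
  for (t in seq_along(x)) {
    if (t > order && st$variance > 0) {
      pr <- sdar_predict(st)
      y[t] <- log_loss(x[t], pr$predicted, pr$variance)
      scored[t] <- TRUE
    }
    st <- sdar_update(st, x[t])
  }
  list(score = causal_smooth(y, width), scored = scored)
}

#' Construct a change-score series
#'
#' Container for per-timestamp change scores, with burn-in metadata and a
#' flag vector marking leading samples produced before the model could make
#' predictions.
#'
#' @param times Sample times in seconds.
#' @param scores Finite numeric scores, same length as `times`.
#' @param flagged Logical vector marking unreliable leading samples.
#' @param burn_in Leading window (seconds) to exclude from thresholds and
#'   metrics (default 30).
#' @param params Optional [changefinder_params()] provenance.
#' @return Object of class `change_score_series`.
#' @export
change_score_series <- function(times, scores, flagged = rep(FALSE, length(times)),
                                burn_in = 30, params = NULL) {
  times <- as.numeric(times)
  scores <- as.numeric(scores)
  if (length(times) != length(scores) || length(flagged) != length(scores))
    stop_config("times, scores and flagged must have equal length")
  if (any(!is.finite(scores))) stop_config("scores must be finite")
  if (burn_in < 0) stop_config("burn_in must be >= 0")
  structure(list(times = times, scores = scores, flagged = as.logical(flagged),
                 burn_in = as.numeric(burn_in), params = params),
            class = "change_score_series")
}

#' @export
print.change_score_series <- function(x, ...) {
  cat(sprintf("<change_score_series> n=%d, burn_in=%gs, %d flagged\n",
              length(x$scores), x$burn_in, sum(x$flagged)))
  invisible(x)
}

#' Two-stage change score of a univariate series
#'
#' Runs the SDAR learning round on the input, smooths the log-loss scores
#' with width `smooth_width`, then runs the identical round on the smoothed
#' scores with width `second_width` and returns the second smoothed sequence
#' S(t), aligned 1:1 with the input timestamps. Leading positions at which
#' either stage could not yet score (fewer than `order` prior observations,
#' or a residual variance still at its zero initialization) are emitted as
#' flagged zeros - for order 1 on noisy data that is the first 3 samples; an
#' all-constant input stays flagged throughout. The burn-in window, which
#' downstream steps exclude, absorbs the remaining initialization transient.
#'
#' @param x Numeric vector, or a single-feature [feature_series()] (whose
#'   start time and step are then inherited).
#' @param params A [changefinder_params()].
#' @param start_time,step Time metadata for plain numeric input.
#' @param burn_in Burn-in metadata in seconds (default 30).
#' @return A [change_score_series()].
#' @examples
#' x <- c(rnorm(100), rnorm(100, mean = 8))
#' s <- change_score(x, changefinder_params(), burn_in = 30)
#' which.max(s$scores)
#' @export
change_score <- function(x, params = changefinder_params(),
                         start_time = 0, step = 1, burn_in = 30) {
  if (inherits(x, "feature_series")) {
    if (length(x$names) != 1L)
      stop_config("change_score needs a single-feature series; got %d features",
                  length(x$names))
    start_time <- x$start_time
    step <- x$step
    x <- as.numeric(x$values[, 1L])
  }
  x <- as.numeric(x)
  if (length(x) == 0L) stop_insufficient("cannot score an empty series")
  if (anyNA(x)) stop_input("series must not contain missing values")
  if (!inherits(params, "changefinder_params"))
    stop_config("params must be changefinder_params()")
  s1 <- cf_stage(x, params$order, params$discount, params$smooth_width)
  s2 <- cf_stage(s1$score, params$order, params$discount, params$second_width)
  # scoring starts strictly later than it stops being impossible, and once a
  # stage has scored it keeps scoring, so the unscored samples of each stage
  # form a prefix; flag the union of the two prefixes
  flagged <- !(s1$scored & s2$scored)
  flagged <- cumsum(flagged) == seq_along(flagged)  # keep only the prefix
  scores <- s2$score
  scores[flagged] <- 0
  change_score_series(times = start_time + (seq_along(x) - 1) * step,
                      scores = scores, flagged = flagged, burn_in = burn_in,
                      params = params)
}

#' Plot a change-score series with its threshold and candidates
#'
#' @param x A [change_score_series()].
#' @param gamma Optional threshold to draw.
#' @param pois Optional [extract_poi()] result; candidate times are marked.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.change_score_series <- function(x, gamma = NULL, pois = NULL, ...) {
  graphics::plot(x$times, x$scores, type = "l", xlab = "time [s]",
                 ylab = "change score", ...)
  if (x$burn_in > 0)
    graphics::abline(v = x$times[1] + x$burn_in, lty = 3)
  if (!is.null(gamma)) graphics::abline(h = gamma, lty = 2)
  if (!is.null(pois) && nrow(pois$candidates) > 0)
    graphics::points(pois$candidates$time, pois$candidates$score,
                     pch = 19, col = "red")
  invisible(x)
}
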