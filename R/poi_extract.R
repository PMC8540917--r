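# PoI candidate extraction.
#
# A PoI candidate is the argmax of the change score within an excursion: a
# maximal run of consecutive samples whose score strictly exceeds the
# threshold gamma. Each excursion contributes exactly one candidate. The
# default threshold is gamma = mean + sd of the post-burn-in scores; the
# raw-value baseline applies the same excursion rule to the raw composite
# values with threshold mean + n * sd.

#' Threshold policy
#'
#' @param mode `"score_mean_sd"` (gamma = mean + sd of the change score,
#'   the default) or `"raw_mean_nsd"` (mean + `n_sigma` * sd of the raw
#'   values, the baseline detector).
#' @param n_sigma Multiplier n for the raw baseline (ignored in score mode).
#' @param burn_in Leading seconds excluded from threshold estimation,
#'   candidate extraction and metrics (default 30, the time the discounted
#'   learner needs before its scores are informative).
#' @return Object of class `threshold_policy`.
#' @export
threshold_policy <- function(mode = c("score_mean_sd", "raw_mean_nsd"),
                             n_sigma = 1, burn_in = 30) {
  mode <- match.arg(mode)
  if (!is.numeric(n_sigma) || length(n_sigma) != 1L)
    stop_config("n_sigma must be a single number")
  if (!is.numeric(burn_in) || burn_in < 0)
    stop_config("burn_in must be >= 0")
  structure(list(mode = mode, n_sigma = as.numeric(n_sigma),
                 burn_in = as.numeric(burn_in)),
            class = "threshold_policy")
}

# post-burn-in, unflagged sample indices of a change_score_series
post_burn_idx <- function(scores, burn_in) {
  which((scores$times - scores$times[1L]) >= burn_in & !scores$flagged)
}

#' Compute the detection threshold gamma
#'
#' `gamma = mean + m * sd` over the score values after dropping the first
#' `burn_in` seconds and any flagged samples, with `m = 1` in score mode and
#' `m = n_sigma` in raw mode. The standard deviation is the population one.
#'
#' @param scores A [change_score_series()].
#' @param policy A [threshold_policy()].
#' @return The threshold gamma (single number).
#' @export
compute_threshold <- function(scores, policy = threshold_policy()) {
  if (!inherits(scores, "change_score_series"))
    stop_config("scores must be a change_score_series")
  idx <- post_burn_idx(scores, policy$burn_in)
  if (length(idx) == 0L)
    stop_insufficient("no samples remain after the %gs burn-in", policy$burn_in)
  v <- scores$scores[idx]
  mult <- if (policy$mode == "score_mean_sd") 1 else policy$n_sigma
  mean(v) + mult * fp_sd(v)
}

# shared excursion-argmax scan over (times, values) already restricted to the
# post-burn-in window
scan_excursions <- function(tt, ss, gamma, step) {
  above <- ss > gamma
  n_o <- sum(above)
  cand <- data.frame(time = numeric(0), score = numeric(0),
                     excursion_start = numeric(0), excursion_end = numeric(0))
  if (n_o > 0L) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      a <- starts[i]
      b <- ends[i]
      j <- a + which.max(ss[a:b]) - 1L            # earliest max wins ties
      end_t <- if (b < length(ss)) tt[b + 1L] else tt[b] + step
      cand <- rbind(cand, data.frame(time = tt[j], score = ss[j],
                                     excursion_start = tt[a],
                                     excursion_end = end_t))
    }
  }
  list(candidates = cand, n_o = n_o)
}

new_poi_set <- function(candidates, gamma, n_o, n, burn_in) {
  structure(list(candidates = candidates, gamma = as.numeric(gamma),
                 n_p = nrow(candidates), n_o = as.integer(n_o),
                 n = as.integer(n), burn_in = as.numeric(burn_in)),
            class = "poi_set")
}

#' @export
print.poi_set <- function(x, ...) {
  cat(sprintf("<poi_set> gamma=%.4g, n_p=%d, n_o=%d over n=%d post-burn-in samples\n",
              x$gamma, x$n_p, x$n_o, x$n))
  if (x$n_p > 0) print(x$candidates, row.names = FALSE)
  invisible(x)
}

#' Extract PoI candidates from a change-score series
#'
#' Scans the post-burn-in scores; every maximal run of consecutive samples
#' with score strictly above `gamma` (an excursion) yields one candidate at
#' the run's argmax (earliest sample on ties). An excursion still open at the
#' end of the series also yields its candidate. `n_o` counts all post-burn-in
#' samples above the threshold; together with `n_p` (the number of
#' candidates) it measures how far the method narrows down the data a human
#' needs to review.
#'
#' @param scores A [change_score_series()].
#' @param gamma Threshold, typically from [compute_threshold()].
#' @param burn_in Seconds to exclude at the start; defaults to the series'
#'   own burn-in metadata.
#' @return Object of class `poi_set`: `candidates` (data frame with `time`,
#'   `score`, `excursion_start`, `excursion_end`), `gamma`, `n_p`, `n_o` and
#'   `n` (the post-burn-in sample count used in the ratios).
#' @export
extract_poi <- function(scores, gamma, burn_in = scores$burn_in) {
  if (!inherits(scores, "change_score_series"))
    stop_config("scores must be a change_score_series")
  if (!is.finite(gamma)) stop_config("gamma must be finite")
  idx <- which((scores$times - scores$times[1L]) >= burn_in)
  if (length(idx) == 0L)
    stop_insufficient("no samples remain after the %gs burn-in", burn_in)
  step <- if (length(scores$times) > 1L)
    scores$times[2L] - scores$times[1L] else 1
  sc <- scan_excursions(scores$times[idx], scores$scores[idx], gamma, step)
  new_poi_set(sc$candidates, gamma, sc$n_o, length(idx), burn_in)
}

#' Raw-value threshold baseline
#'
#' The comparison detector that skips change scoring entirely: the threshold
#' `mean + n_sigma * sd` is computed on the raw (composite) values after the
#' burn-in, and the same excursion-argmax rule as [extract_poi()] is applied
#' to the raw values themselves.
#'
#' @param x Numeric vector of raw composite values, or a single-feature
#'   [feature_series()].
#' @param n_sigma Threshold multiplier n.
#' @param burn_in Seconds excluded at the start (default 30).
#' @param start_time,step Time metadata for plain numeric input.
#' @return A `poi_set`, as for [extract_poi()].
#' @export
raw_threshold_baseline <- function(x, n_sigma, burn_in = 30,
                                   start_time = 0, step = 1) {
  if (inherits(x, "feature_series")) {
    if (length(x$names) != 1L)
      stop_config("baseline needs a single-feature series")
    start_time <- x$start_time
    step <- x$step
    x <- as.numeric(x$values[, 1L])
  }
  series <- change_score_series(times = start_time + (seq_along(x) - 1) * step,
                                scores = x, burn_in = burn_in)
  gamma <- compute_threshold(series,
                             threshold_policy("raw_mean_nsd", n_sigma, burn_in))
  extract_poi(series, gamma, burn_in)
}
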