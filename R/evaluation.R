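# Matching PoI candidates to annotated event points and the derived metrics.

candidate_times <- function(candidates) {
  if (inherits(candidates, "poi_set")) return(candidates$candidates$time)
  as.numeric(candidates)
}

event_times <- function(events) {
  if (inherits(events, "event_annotation")) return(events$events$time)
  as.numeric(events)
}

#' Match PoI candidates to event points within a tolerance window
#'
#' An event point counts as captured when at least one candidate lies within
#' `tolerance` seconds of it (closed interval, before or after). Each event
#' point is counted once no matter how many candidates fall inside its
#' window, and one candidate may serve several event points; no one-to-one
#' assignment is enforced.
#'
#' @param candidates A `poi_set` or numeric vector of candidate times.
#' @param events An [event_annotation()] or numeric vector of event times.
#' @param tolerance Matching half-window in seconds (default 10).
#' @return List with `n_c` (number of captured event points) and
#'   `correct_pois` (distinct candidate times matched to at least one event).
#' @export
match_events <- function(candidates, events, tolerance = 10) {
  if (!is.numeric(tolerance) || tolerance < 0)
    stop_config("tolerance must be >= 0")
  ct <- candidate_times(candidates)
  et <- event_times(events)
  hit_event <- vapply(et, function(e) any(abs(ct - e) <= tolerance), logical(1))
  hit_cand <- vapply(ct, function(p) any(abs(et - p) <= tolerance), logical(1))
  list(n_c = sum(hit_event), correct_pois = sort(unique(ct[hit_cand])))
}

#' Evaluate PoI candidates against event points
#'
#' Computes the counts and ratios used to judge the detector: recall
#' `n_c / n_e` (fraction of event points captured), precision `n_c / n_p`
#' (fraction of candidates that are valid), and the data-reduction ratios
#' `n_p / n` and `n_o / n` (the smaller, the less data a human has to
#' review). Division-by-zero cases (`n_p = 0` or `n_e = 0`) yield 0 with the
#' corresponding `*_defined` flag set to `FALSE` instead of an error, so
#' batch runs complete.
#'
#' @param candidates A `poi_set` (supplying `n_p`, `n_o` and `n`) or a
#'   numeric vector of candidate times (then pass `n` and `n_o` explicitly).
#' @param events An [event_annotation()], numeric event times, or `NULL`
#'   when no annotation exists (recall/precision are then `NA`).
#' @param n Number of samples entering the ratios; defaults to the
#'   `poi_set`'s post-burn-in count.
#' @param n_o Number of threshold-exceeding samples; defaults to the
#'   `poi_set`'s.
#' @param tolerance Matching half-window in seconds (default 10).
#' @return Object of class `eval_report`.
#' @export
evaluate_candidates <- function(candidates, events = NULL, n = NULL,
                                n_o = NULL, tolerance = 10) {
  if (inherits(candidates, "poi_set")) {
    if (is.null(n)) n <- candidates$n
    if (is.null(n_o)) n_o <- candidates$n_o
  }
  if (is.null(n) || n <= 0) stop_config("n must be a positive sample count")
  if (is.null(n_o)) stop_config("n_o is required for plain candidate vectors")
  ct <- candidate_times(candidates)
  n_p <- length(ct)
  rep_ <- list(n = as.integer(n), n_p = n_p, n_o = as.integer(n_o),
               n_e = NA_integer_, n_c = NA_integer_,
               recall = NA_real_, precision = NA_real_,
               ratio_p = n_p / n, ratio_o = n_o / n,
               recall_defined = FALSE, precision_defined = FALSE,
               correct_pois = numeric(0), tolerance = tolerance)
  if (!is.null(events)) {
    et <- event_times(events)
    m <- match_events(ct, et, tolerance)
    rep_$n_e <- length(et)
    rep_$n_c <- m$n_c
    rep_$correct_pois <- m$correct_pois
    rep_$recall_defined <- rep_$n_e > 0L
    rep_$precision_defined <- n_p > 0L
    rep_$recall <- if (rep_$recall_defined) m$n_c / rep_$n_e else 0
    rep_$precision <- if (rep_$precision_defined) m$n_c / n_p else 0
  }
  structure(rep_, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  n_p=%d  n_o=%d  n_p/n=%.4f  n_o/n=%.4f\n",
              x$n, x$n_p, x$n_o, x$ratio_p, x$ratio_o))
  if (!is.na(x$n_e)) {
    cat(sprintf("  n_e=%d  n_c=%d  recall=%.4f%s  precision=%.4f%s  (tolerance %gs)\n",
                x$n_e, x$n_c,
                x$recall, if (x$recall_defined) "" else " (undefined)",
                x$precision, if (x$precision_defined) "" else " (undefined)",
                x$tolerance))
  }
  invisible(x)
}
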