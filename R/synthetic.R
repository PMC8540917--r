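# Synthetic labelled recordings.
#
# The generator emulates the data regime the detector targets: ~1 Hz
# facial-feature streams with a small number of smile episodes, optional
# amplitude attenuation (micro expressions), sparse frames (~3 s intervals)
# later padded to 1 Hz, Gaussian measurement noise and occasional spike
# outliers. Baseline levels and per-feature episode deltas default to
# neutral-face averages and neutral-to-smiling differences measured on real
# faces, so the default simulation moves each facial part by a realistic
# amount.

#' Episode model for the synthetic generator
#'
#' @param n_seconds Total recording length in seconds (default 1200).
#' @param episodes List of `c(onset, offset)` pairs in seconds,
#'   non-overlapping and inside `[0, n_seconds]`. The defaults place three
#'   one-minute smile episodes well apart.
#' @param expression_gain Amplitude multiplier in (0, 1]: 1 reproduces an
#'   expressive face, values well below 1 emulate the attenuated movement of
#'   micro expressions.
#' @param baseline Named per-feature neutral level.
#' @param feature_deltas Named per-feature signed change during an episode
#'   (positive for mouth width h9, negative for a1/a3/a4).
#' @param noise_sd Gaussian measurement noise, scalar or named per feature.
#' @param frame_interval Seconds between raw observations (1 for a webcam
#'   stream, ~3 for sparse frame captures that are later padded).
#' @param outlier_rate Probability per sample of a spike outlier of
#'   `10 * noise_sd` magnitude.
#' @param ramp On/off ramp length in seconds (a face takes a couple of
#'   seconds to move; default 2).
#' @param seed Optional RNG seed; with a seed the generated recording is
#'   fully reproducible.
#' @return Object of class `episode_model`.
#' @export
episode_model <- function(n_seconds = 1200,
                          episodes = list(c(200, 260), c(600, 660), c(1000, 1060)),
                          expression_gain = 1,
                          baseline = c(h9 = 0.8199, a1 = 0.4270,
                                       a3 = 0.0901, a4 = 1.0431),
                          feature_deltas = c(h9 = 0.0715, a1 = -0.0289,
                                             a3 = -0.0398, a4 = -0.0614),
                          noise_sd = 0.005, frame_interval = 1,
                          outlier_rate = 0, ramp = 2, seed = NULL) {
  if (!is.numeric(n_seconds) || n_seconds <= 0)
    stop_config("n_seconds must be positive")
  if (!is.numeric(expression_gain) || expression_gain <= 0 || expression_gain > 1)
    stop_config("expression_gain must lie in (0, 1]")
  if (is.null(names(baseline)) || !setequal(names(baseline), names(feature_deltas)))
    stop_config("baseline and feature_deltas must name the same features")
  if (length(noise_sd) == 1L && is.null(names(noise_sd)))
    noise_sd <- stats::setNames(rep(noise_sd, length(baseline)), names(baseline))
  if (!setequal(names(noise_sd), names(baseline)) || any(noise_sd < 0))
    stop_config("noise_sd must be a non-negative scalar or cover every feature")
  if (frame_interval <= 0) stop_config("frame_interval must be positive")
  if (outlier_rate < 0 || outlier_rate > 1)
    stop_config("outlier_rate must lie in [0, 1]")
  if (ramp < 0) stop_config("ramp must be >= 0")
  if (length(episodes)) {
    ep <- do.call(rbind, lapply(episodes, function(e) {
      if (length(e) != 2L || e[1] >= e[2])
        stop_config("each episode must be c(onset, offset) with onset < offset")
      e
    }))
    ep <- ep[order(ep[, 1L]), , drop = FALSE]
    if (any(ep < 0) || any(ep > n_seconds))
      stop_config("episodes must lie inside [0, n_seconds]")
    if (nrow(ep) > 1L && any(ep[-1L, 1L] <= ep[-nrow(ep), 2L]))
      stop_config("episodes must not overlap")
    episodes <- lapply(seq_len(nrow(ep)), function(i) ep[i, ])
  }
  structure(list(n_seconds = n_seconds, episodes = episodes,
                 expression_gain = expression_gain, baseline = baseline,
                 feature_deltas = feature_deltas[names(baseline)],
                 noise_sd = noise_sd[names(baseline)],
                 frame_interval = frame_interval,
                 outlier_rate = outlier_rate, ramp = ramp, seed = seed),
            class = "episode_model")
}

# trapezoidal 0..1 indicator: linear rise over [on, on+ramp], plateau,
# linear fall over [off, off+ramp]
episode_indicator <- function(t, episodes, ramp) {
  ind <- rep(0, length(t))
  for (ep in episodes) {
    if (ramp > 0) {
      up <- pmin(1, pmax(0, (t - ep[1]) / ramp))
      down <- pmin(1, pmax(0, (ep[2] + ramp - t) / ramp))
      contrib <- pmin(up, down)
    } else {
      contrib <- as.numeric(t >= ep[1] & t <= ep[2])
    }
    ind <- pmax(ind, contrib)
  }
  ind
}

#' Generate a labelled synthetic recording
#'
#' Each feature follows `baseline + expression_gain * delta * indicator(t)`
#' where the indicator ramps linearly from 0 to 1 at an episode onset and
#' back at its offset, plus i.i.d. Gaussian noise. Samples are emitted every
#' `frame_interval` seconds; spike outliers of `10 * noise_sd` magnitude are
#' injected with probability `outlier_rate` per sample. Each episode
#' contributes one `happy_onset` and one `happy_offset` event at its
#' boundaries.
#'
#' @param model An [episode_model()].
#' @return List with `recording` (a [raw_recording()]) and `events` (an
#'   [event_annotation()], empty if the model has no episodes).
#' @export
generate_recording <- function(model) {
  if (!inherits(model, "episode_model")) stop_config("model must be an episode_model")
  if (!is.null(model$seed)) set.seed(model$seed)
  n <- max(1L, as.integer(floor(model$n_seconds / model$frame_interval)))
  times <- (seq_len(n) - 1) * model$frame_interval
  ind <- episode_indicator(times, model$episodes, model$ramp)
  feats <- names(model$baseline)
  recs <- do.call(rbind, lapply(feats, function(f) {
    v <- model$baseline[[f]] +
      model$expression_gain * model$feature_deltas[[f]] * ind +
      stats::rnorm(n, 0, model$noise_sd[[f]])
    if (model$outlier_rate > 0) {
      spike <- stats::runif(n) < model$outlier_rate
      if (any(spike))
        v[spike] <- v[spike] +
          sample(c(-1, 1), sum(spike), replace = TRUE) * 10 * model$noise_sd[[f]]
    }
    data.frame(t = times, feature = f, value = v, stringsAsFactors = FALSE)
  }))
  ev_t <- unlist(lapply(model$episodes, function(e) c(e[1], e[2])))
  ev_p <- rep(c("happy_onset", "happy_offset"), length(model$episodes))
  list(recording = raw_recording(recs),
       events = event_annotation(ev_t, ev_p))
}

#' Small deterministic score vectors for oracle tests
#'
#' @param kind `"constant"`, `"step"` or `"two_excursions"`.
#' @param length Vector length for `constant` and `step`.
#' @param value Constant value.
#' @param pre,post,change_at Step parameters: `pre` before index
#'   `change_at`, `post` from there on (0-based change position).
#' @return Numeric vector.
#' @export
score_testvector <- function(kind = c("constant", "step", "two_excursions"),
                             length = 10L, value = 3, pre = 0, post = 5,
                             change_at = 5L) {
  kind <- match.arg(kind)
  switch(kind,
         constant = rep(value, length),
         step = c(rep(pre, change_at), rep(post, length - change_at)),
         two_excursions = c(0, 3, 0, 0, 5, 6, 0))
}
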