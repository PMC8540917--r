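# End-to-end pipeline: read -> regularize -> (outliers) -> standardize ->
# compose -> change score -> threshold -> PoI candidates -> evaluation.
# These functions are also what the inst/cli wrapper script calls.

#' Assemble a fully explicit pipeline configuration
#'
#' Defaults mirror the study settings: AR order 1, discount 0.025, smoothing
#' width 5 (second stage 2), 30 s burn-in, gamma = mean + sd of the change
#' score, and a +/- 10 s matching tolerance.
#'
#' @param features Path to a feature CSV, or a [raw_recording()] /
#'   [feature_series()] already in memory.
#' @param events Optional path to an events CSV or an [event_annotation()].
#' @param feature Optional single feature label; when set the pipeline skips
#'   the composite and scores that standardized feature alone.
#' @param spec [composite_spec()] used when `feature` is `NULL`
#'   (default [smile_scale()]).
#' @param params [changefinder_params()].
#' @param policy [threshold_policy()].
#' @param tolerance Event-matching half-window in seconds (default 10).
#' @param outlier_method,outlier_k Passed to [remove_outliers()]
#'   (default `"none"`).
#' @param step Regularization grid in seconds (default 1).
#' @param out_dir Optional directory; when set, [run_pipeline()] writes
#'   `scores.csv`, `candidates.csv`, `report.json` and `run_log.json` there.
#' @return Object of class `run_config`.
#' @export
run_config <- function(features, events = NULL, feature = NULL,
                       spec = smile_scale(), params = changefinder_params(),
                       policy = threshold_policy(), tolerance = 10,
                       outlier_method = "none", outlier_k = 5,
                       step = 1, out_dir = NULL) {
  if (!inherits(params, "changefinder_params"))
    stop_config("params must be changefinder_params()")
  if (!inherits(policy, "threshold_policy"))
    stop_config("policy must be threshold_policy()")
  if (is.null(feature) && !inherits(spec, "composite_spec"))
    stop_config("spec must be a composite_spec when no single feature is chosen")
  if (!is.numeric(tolerance) || tolerance < 0)
    stop_config("tolerance must be >= 0")
  structure(list(features = features, events = events, feature = feature,
                 spec = spec, params = params, policy = policy,
                 tolerance = tolerance, outlier_method = outlier_method,
                 outlier_k = outlier_k, step = step, out_dir = out_dir),
            class = "run_config")
}

resolve_series <- function(features, step, outlier_method, outlier_k) {
  series <- if (inherits(features, "feature_series")) {
    features
  } else {
    raw <- if (inherits(features, "raw_recording")) features
           else read_feature_csv(features)
    regularize(raw, step = step)
  }
  remove_outliers(series, method = outlier_method, k = outlier_k)
}

# resolved parameter set, echoed to run_log.json for provenance
config_log <- function(config) {
  list(feature = if (is.null(config$feature)) NA else config$feature,
       composite = config$spec$name,
       coefficients = as.list(config$spec$coefficients),
       order = config$params$order,
       discount = config$params$discount,
       smooth_width = config$params$smooth_width,
       second_width = config$params$second_width,
       threshold_mode = config$policy$mode,
       n_sigma = config$policy$n_sigma,
       burn_in = config$policy$burn_in,
       tolerance = config$tolerance,
       outlier_method = config$outlier_method,
       outlier_k = config$outlier_k,
       step = config$step)
}

report_as_list <- function(report, gamma) {
  out <- list(gamma = gamma, n = report$n, n_p = report$n_p, n_o = report$n_o,
              ratio_p = report$ratio_p, ratio_o = report$ratio_o)
  if (!is.na(report$n_e)) {
    out$n_e <- report$n_e
    out$n_c <- report$n_c
    out$recall <- report$recall
    out$precision <- report$precision
    out$recall_defined <- report$recall_defined
    out$precision_defined <- report$precision_defined
    out$correct_pois <- report$correct_pois
  }
  out
}

#' Run the full PoI pipeline
#'
#' Reads (or accepts) the feature recording, regularizes it to a uniform
#' grid, optionally removes outliers, standardizes every feature, builds the
#' composite value (or selects one standardized feature), computes the
#' two-stage change score, thresholds it, extracts PoI candidates and - when
#' events are supplied - evaluates recall and precision. In
#' `"raw_mean_nsd"` mode the change score is skipped and the raw-value
#' baseline detector is used instead.
#'
#' @param config A [run_config()].
#' @return List with `series`, `stats`, `composite` (the scored sequence),
#'   `scores` (`NULL` in raw mode), `gamma`, `pois`, `report` and `config`,
#'   invisibly. If `config$out_dir` is set, the score CSV, candidate CSV,
#'   report JSON and a log of every resolved parameter are written there.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop_config("config must be a run_config")
  series <- resolve_series(config$features, config$step,
                           config$outlier_method, config$outlier_k)
  std <- standardize(series)
  x <- if (!is.null(config$feature)) {
    if (!config$feature %in% std$series$names)
      stop_config("feature '%s' not present; available: %s", config$feature,
                  paste(std$series$names, collapse = ", "))
    as.numeric(std$series$values[, config$feature])
  } else {
    compose(std$series, config$spec)
  }
  events <- if (is.null(config$events)) NULL
            else if (inherits(config$events, "event_annotation")) config$events
            else read_events_csv(config$events)

  scores <- NULL
  if (config$policy$mode == "raw_mean_nsd") {
    pois <- raw_threshold_baseline(x, config$policy$n_sigma,
                                   config$policy$burn_in,
                                   series$start_time, series$step)
  } else {
    scores <- change_score(x, config$params, series$start_time, series$step,
                           burn_in = config$policy$burn_in)
    gamma <- compute_threshold(scores, config$policy)
    pois <- extract_poi(scores, gamma)
  }
  report <- evaluate_candidates(pois, events = events,
                                tolerance = config$tolerance)
  result <- list(series = series, stats = std$stats, composite = x,
                 scores = scores, gamma = pois$gamma, pois = pois,
                 report = report, config = config)
  if (!is.null(config$out_dir)) write_run_outputs(result, config$out_dir)
  invisible(result)
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tt <- series_times(result$series)
  if (!is.null(result$scores)) {
    utils::write.csv(data.frame(t = result$scores$times,
                                score = result$scores$scores,
                                flagged = result$scores$flagged),
                     file.path(out_dir, "scores.csv"), row.names = FALSE)
  } else {
    utils::write.csv(data.frame(t = tt, value = result$composite),
                     file.path(out_dir, "scores.csv"), row.names = FALSE)
  }
  utils::write.csv(result$pois$candidates,
                   file.path(out_dir, "candidates.csv"), row.names = FALSE)
  jsonlite::write_json(report_as_list(result$report, result$gamma),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(config_log(result$config),
                       file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write a synthetic recording to CSV files
#'
#' @param model An [episode_model()].
#' @param features_path Output path for the wide feature CSV.
#' @param events_path Output path for the events CSV.
#' @return List with the generated `recording` and `events`, invisibly.
#' @export
simulate_to_csv <- function(model, features_path, events_path) {
  g <- generate_recording(model)
  rec <- g$recording$records
  wide <- data.frame(t = unique(rec$t))
  for (f in g$recording$features)
    wide[[f]] <- rec$value[rec$feature == f]
  utils::write.csv(wide, features_path, row.names = FALSE)
  write_events_csv(g$events, events_path)
  invisible(g)
}

#' Derive composite weights from two sample CSV files
#'
#' @param neutral_path,smiling_path CSV files, one row per sampled frame,
#'   one column per feature.
#' @param reference Reference feature label (default `"h9"`).
#' @return A `weight_report`, see [derive_weights()].
#' @export
weights_from_csv <- function(neutral_path, smiling_path, reference = "h9") {
  read_tbl <- function(p) {
    if (!file.exists(p)) stop_input("file not found: '%s'", p)
    utils::read.csv(p, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  derive_weights(read_tbl(neutral_path), read_tbl(smiling_path), reference)
}

#' Raw-threshold baseline over a grid of multipliers
#'
#' Runs the `mean + n * sd` raw-value detector for each multiplier in
#' `n_grid` on the pipeline's composite sequence and tabulates the counts,
#' ratios and (when events are available) recall and precision, one row per
#' threshold.
#'
#' @param config A [run_config()]; its threshold mode is ignored.
#' @param n_grid Multipliers to sweep (default `c(0, 0.5, 1, 2)`).
#' @return Data frame with one row per multiplier.
#' @export
baseline_grid <- function(config, n_grid = c(0, 0.5, 1, 2)) {
  if (!inherits(config, "run_config")) stop_config("config must be a run_config")
  series <- resolve_series(config$features, config$step,
                           config$outlier_method, config$outlier_k)
  std <- standardize(series)
  x <- if (!is.null(config$feature))
    as.numeric(std$series$values[, config$feature])
  else compose(std$series, config$spec)
  events <- if (is.null(config$events)) NULL
            else if (inherits(config$events, "event_annotation")) config$events
            else read_events_csv(config$events)
  rows <- lapply(n_grid, function(ns) {
    pois <- raw_threshold_baseline(x, ns, config$policy$burn_in,
                                   series$start_time, series$step)
    rp <- evaluate_candidates(pois, events = events,
                              tolerance = config$tolerance)
    data.frame(n_sigma = ns, gamma = pois$gamma, n = rp$n, n_p = rp$n_p,
               n_o = rp$n_o, ratio_p = rp$ratio_p, ratio_o = rp$ratio_o,
               n_c = rp$n_c, recall = rp$recall, precision = rp$precision)
  })
  do.call(rbind, rows)
}
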