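# Composite feature values.
#
# A composite feature is a purpose-built linear combination of z-standardized
# single features. The built-in "Smile scale" X = 2 h9 - a1 - a3 - 2 a4
# targets happiness-related movement: mouth width h9 grows with a smile while
# eyebrow height a1, eyes opening a3 and mouth-corner lowering a4 shrink, so
# their coefficients are negative.

# population (divide by n) or sample (divide by n-1) standard deviation
fp_sd <- function(x, type = c("population", "sample")) {
  type <- match.arg(type)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (type == "sample") return(stats::sd(x))
  sqrt(sum((x - mean(x))^2) / n)
}

#' Z-standardize every feature of a series
#'
#' Each column is centered by its mean and scaled by its standard deviation
#' over the full input series (retrospective batch statistics, matching an
#' offline analysis). The default is the population standard deviation
#' (divide by n).
#'
#' @param series A [feature_series()].
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return List with `series` (the standardized [feature_series()]) and
#'   `stats` (data frame of per-feature `mean` and `sd`, reusable to
#'   standardize new data consistently).
#' @export
standardize <- function(series, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  v <- series$values
  m <- colMeans(v)
  s <- apply(v, 2L, fp_sd, type = sd_type)
  if (any(s == 0))
    stop_degenerate("constant feature(s) cannot be standardized: %s",
                    paste(series$names[s == 0], collapse = ", "))
  z <- sweep(sweep(v, 2L, m, "-"), 2L, s, "/")
  list(series = feature_series(z, start_time = series$start_time,
                               step = series$step),
       stats = data.frame(feature = series$names, mean = unname(m),
                          sd = unname(s), stringsAsFactors = FALSE))
}

#' Define a composite feature
#'
#' @param name Label of the composite.
#' @param coefficients Named numeric vector mapping feature labels to
#'   weights; at least one weight must be nonzero.
#' @return Object of class `composite_spec`.
#' @seealso [smile_scale()] for the built-in default.
#' @export
composite_spec <- function(name, coefficients) {
  if (!is.numeric(coefficients) || is.null(names(coefficients)) ||
      any(!nzchar(names(coefficients))))
    stop_config("coefficients must be a named numeric vector")
  if (all(coefficients == 0))
    stop_config("composite '%s' needs at least one nonzero coefficient", name)
  structure(list(name = as.character(name), coefficients = coefficients),
            class = "composite_spec")
}

#' The Smile scale composite
#'
#' `X = 2 h9 - a1 - a3 - 2 a4` on standardized features: mouth width (h9)
#' enters positively, eyebrow height (a1), eyes opening (a3) and mouth-corner
#' lowering (a4) negatively, with double weight on the mouth features whose
#' absolute movement during a smile is about twice that of the eye region.
#'
#' @return A [composite_spec()].
#' @export
smile_scale <- function() {
  composite_spec("smile_scale", c(h9 = 2, a1 = -1, a3 = -1, a4 = -2))
}

#' @export
print.composite_spec <- function(x, ...) {
  cat(sprintf("<composite_spec> %s: %s\n", x$name,
              paste(sprintf("%+g*%s", unname(x$coefficients),
                            names(x$coefficients)), collapse = " ")))
  invisible(x)
}

#' Evaluate a composite feature pointwise
#'
#' @param z_series A standardized [feature_series()] containing every feature
#'   the spec references.
#' @param spec A [composite_spec()].
#' @return Numeric vector X(t), one value per time sample.
#' @export
compose <- function(z_series, spec) {
  if (!inherits(spec, "composite_spec")) stop_config("spec must be a composite_spec")
  absent <- setdiff(names(spec$coefficients), z_series$names)
  if (length(absent))
    stop_config("composite '%s' references missing feature(s): %s",
                spec$name, paste(absent, collapse = ", "))
  as.numeric(z_series$values[, names(spec$coefficients), drop = FALSE] %*%
               spec$coefficients)
}

#' Derive composite weights from paired neutral/smiling samples
#'
#' Given tables of feature values sampled in a neutral and in a smiling
#' state, computes per-feature state means, their difference (smiling minus
#' neutral) and the ratio of each feature's absolute difference to that of a
#' reference feature. The ratios quantify how much each facial part moves
#' relative to the reference and inform (but, to stay robust across
#' subjects, are rounded to simple integers rather than used verbatim as)
#' composite coefficients.
#'
#' @param neutral,smiling Data frames, one row per sampled frame, one column
#'   per feature; both must cover the same features.
#' @param reference Feature label whose ratio is fixed at 1.
#' @return A `weight_report` data frame with columns `feature`,
#'   `neutral_mean`, `smiling_mean`, `difference`, `ratio`.
#' @export
derive_weights <- function(neutral, smiling, reference) {
  neutral <- as.data.frame(neutral)
  smiling <- as.data.frame(smiling)
  if (nrow(neutral) == 0L || nrow(smiling) == 0L)
    stop_input("both sample tables must be non-empty")
  if (!setequal(names(neutral), names(smiling)))
    stop_input("neutral and smiling tables must cover the same features")
  feats <- names(neutral)
  if (!reference %in% feats)
    stop_config("reference feature '%s' not in the tables", reference)
  nm <- vapply(neutral[feats], function(x) mean(as.numeric(x)), numeric(1))
  sm <- vapply(smiling[feats], function(x) mean(as.numeric(x)), numeric(1))
  d <- sm - nm
  if (d[reference] == 0)
    stop_degenerate("reference feature '%s' shows no difference between states",
                    reference)
  out <- data.frame(feature = feats,
                    neutral_mean = unname(nm),
                    smiling_mean = unname(sm),
                    difference = unname(d),
                    ratio = unname(abs(d) / abs(d[reference])),
                    stringsAsFactors = FALSE)
  class(out) <- c("weight_report", "data.frame")
  out
}

#' @export
print.weight_report <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y[-1L] <- lapply(y[-1L], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
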