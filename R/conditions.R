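# Structured error conditions, so programmatic callers and the command-line
# wrapper can tell bad input files, bad configuration, degenerate data and
# insufficient data apart without parsing messages.

fp_stop <- function(class, msg, ...) {
  if (...length() > 0L) msg <- sprintf(msg, ...)
  stop(errorCondition(msg, class = c(class, "facepoi_error")))
}

stop_input        <- function(msg, ...) fp_stop("facepoi_input_error", msg, ...)
stop_config       <- function(msg, ...) fp_stop("facepoi_config_error", msg, ...)
stop_degenerate   <- function(msg, ...) fp_stop("facepoi_degenerate_error", msg, ...)
stop_insufficient <- function(msg, ...) fp_stop("facepoi_insufficient_error", msg, ...)
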