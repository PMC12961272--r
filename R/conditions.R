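## Classed conditions so callers (and tests) can distinguish failure modes.

ml_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "mirlink_error")))
}

ml_stop_format      <- function(msg, ...) ml_stop("mirlink_format_error", msg, ...)
ml_stop_value       <- function(msg, ...) ml_stop("mirlink_value_error", msg, ...)
ml_stop_consistency <- function(msg, ...) ml_stop("mirlink_consistency_error", msg, ...)
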