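# Structured conditions so callers (and the CLI) can distinguish bad input
# from bad files from undefined statistics.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("twinpaf_validation_error", "twinpaf_error")))
}

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("twinpaf_format_error", "twinpaf_error")))
}

stop_undefined <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("twinpaf_undefined_statistic", "twinpaf_error")))
}

stop_linkage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("twinpaf_linkage_error", "twinpaf_error")))
}
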