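# Classed error helpers so callers and tests can distinguish failure modes.
stop_format <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("metabonet_format_error", "metabonet_error")))
}

stop_reference <- function(msg) {
  stop(errorCondition(msg, class = c("metabonet_reference_error", "metabonet_error")))
}

stop_usage <- function(msg) {
  stop(errorCondition(msg, class = c("metabonet_usage_error", "metabonet_error")))
}

stop_internal <- function(msg) {
  stop(errorCondition(msg, class = c("metabonet_internal_error", "metabonet_error")))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == as.integer(x)
}

is_positive_scalar <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x > 0
}

#' @useDynLib metabonet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL
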