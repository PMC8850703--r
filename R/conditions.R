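#' @title Typed error conditions
#' @description Internal helpers that raise classed conditions so callers can
#'   distinguish, e.g., a missing file from a degenerate (constant) signal.
#'   All conditions inherit from `"ecgsubband_error"`.
#' @keywords internal
#' @name conditions
NULL

esb_abort <- function(class, message, call = sys.call(-1), ...) {
  stop(errorCondition(message, ..., class = c(class, "ecgsubband_error"),
                      call = call))
}

esb_warn <- function(class, message, ...) {
  warning(warningCondition(message, ..., class = c(class, "ecgsubband_warning")))
}
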