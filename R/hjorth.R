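#' First difference of a sequence
#'
#' `y[k] = x[k+1] - x[k]`; the output is one element shorter than the
#' input. Used as the slope proxy in the Hjorth descriptors.
#'
#' @param x Numeric vector of length at least 2.
#' @return Numeric vector of length `length(x) - 1`.
#' @export
first_difference <- function(x) {
  x <- as_samples(x)
  if (length(x) < 2L)
    esb_abort("esb_short_signal", "need at least 2 samples for a first difference")
  diff(x)
}

# population standard deviation (denominator N)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Hjorth descriptors of a sequence
#'
#' The three classical time-domain descriptors, with population (divide by
#' N) standard deviations throughout:
#' \itemize{
#'   \item activity: the signal variance \eqn{\sigma_x^2};
#'   \item mobility: \eqn{\sigma_{x'}/\sigma_x}, the SD of the slope
#'     relative to the SD of the amplitude;
#'   \item complexity: \eqn{(\sigma_{x''}/\sigma_{x'}) / (\sigma_{x'}/\sigma_x)},
#'     the mobility of the first difference relative to the mobility of the
#'     signal.
#' }
#' Mobility and complexity are invariant to amplitude scaling and offset;
#' activity scales with the square of the amplitude.
#'
#' @param x Numeric vector (length >= 3) or an [ecg_signal()].
#' @return A list of class `hjorth_features` with elements `activity`,
#'   `mobility`, `complexity`.
#' @details Degenerate inputs raise typed errors rather than returning
#'   `NaN`: a zero-variance (constant) input raises
#'   `esb_degenerate_signal`; a linear ramp, whose first difference is
#'   constant, raises `esb_degenerate_slope`.
#' @examples
#' hjorth_features(sin(seq(0, 10 * pi, length.out = 200)))
#' @export
hjorth_features <- function(x) {
  x <- as_samples(x)
  if (length(x) < 3L)
    esb_abort("esb_short_signal", "need at least 3 samples for Hjorth descriptors")
  s0 <- sd_pop(x)
  if (s0 == 0)
    esb_abort("esb_degenerate_signal",
              "zero-variance input: Hjorth mobility undefined")
  d1 <- diff(x)
  s1 <- sd_pop(d1)
  if (s1 == 0)
    esb_abort("esb_degenerate_slope",
              "constant first difference (linear ramp): complexity undefined")
  d2 <- diff(d1)
  s2 <- sd_pop(d2)
  mob <- s1 / s0
  structure(list(activity = s0^2, mobility = mob,
                 complexity = (s2 / s1) / mob),
            class = "hjorth_features")
}

#' @export
print.hjorth_features <- function(x, ...) {
  cat(sprintf("<hjorth_features> activity=%.6g mobility=%.6g complexity=%.6g\n",
              x$activity, x$mobility, x$complexity))
  invisible(x)
}
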