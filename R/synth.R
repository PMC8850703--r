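#' Rhythm model for the synthetic ECG generator
#'
#' A phenomenological per-class beat model: each beat is a sum of five
#' Gaussian bumps (P, Q, R, S, T) placed relative to the R peak, beats
#' are spaced by a class-specific RR-interval distribution (truncated
#' normal), and class-specific extras are added on top. The three
#' defaults emulate the qualitative electrophysiology of the classes:
#' \itemize{
#'   \item `NSR`: regular rhythm (60 bpm, RR coefficient of variation
#'     0.04), full P-QRS-T morphology, and the highest broadband noise
#'     floor -- normal-rhythm reference recordings are ambulatory Holter
#'     recordings, noisier than in-hospital ones;
#'   \item `AF`: irregular RR intervals (CV 0.25), suppressed P wave,
#'     and an episodic band-limited fibrillatory oscillation in the
#'     atrial-rate band (5.5-9.5 Hz, i.e. 330-570 cycles/min) that waxes
#'     and wanes, leaving quiet stretches as real f-waves do;
#'   \item `CHF`: metronomically regular rhythm (CV 0.02) with a large,
#'     broadened T wave dominating the low-frequency content.
#' }
#' The constants are frozen: tests and experiments vary only the seed.
#'
#' @param class One of `"AF"`, `"CHF"`, `"NSR"`.
#' @return A list of class `rhythm_model` with fields `rr_mean`, `rr_cv`,
#'   `rr_min` (seconds), `waves` (five bumps, `center`/`width` in
#'   seconds, `amp` in normalized units), `fib_amp`, `fib_band` (Hz),
#'   `fib_burst` (episode-length range, seconds) and `noise_sd`.
#' @export
rhythm_model <- function(class = c("NSR", "AF", "CHF")) {
  class <- match.arg(class)
  waves <- list(P = list(center = -0.20, width = 0.025, amp = 0.15),
                Q = list(center = -0.040, width = 0.010, amp = -0.12),
                R = list(center = 0.000, width = 0.010, amp = 1.00),
                S = list(center = 0.040, width = 0.010, amp = -0.20),
                T = list(center = 0.20, width = 0.055, amp = 0.35))
  m <- switch(class,
    NSR = list(rr_mean = 1.00, rr_cv = 0.04, rr_min = 0.45,
               fib_amp = 0.00, noise_sd = 0.055),
    AF = list(rr_mean = 0.90, rr_cv = 0.25, rr_min = 0.60,
              fib_amp = 0.55, noise_sd = 0.015),
    CHF = list(rr_mean = 0.90, rr_cv = 0.02, rr_min = 0.45,
               fib_amp = 0.00, noise_sd = 0.010))
  if (class == "AF") waves$P$amp <- 0
  if (class == "CHF") {
    waves$T$width <- 0.08
    waves$T$amp <- 0.70
  }
  structure(c(list(class = class, waves = waves), m,
              list(fib_band = c(5.5, 9.5), fib_burst = c(1.0, 1.5))),
            class = "rhythm_model")
}

#' Generate one synthetic ECG record
#'
#' Renders a short fixed-rate segment from a [rhythm_model()]: beat
#' onsets are drawn from the class's truncated-normal RR distribution,
#' each beat contributes the five Gaussian bumps, AF superimposes one
#' fibrillatory episode (three random tones in `fib_band`, raised-sine
#' envelope over a `fib_burst`-long window placed at random), and white
#' noise with the class's SD is added. Deterministic for a given seed.
#'
#' @param model A [rhythm_model()].
#' @param duration_s Record length in seconds (default 2; must be at
#'   least twice the RR mean so the window holds two beats).
#' @param fs Sampling rate in Hz (default 250).
#' @param seed Integer seed.
#' @return A labeled [ecg_signal()] of `round(duration_s * fs)` samples.
#' @export
generate_record <- function(model, duration_s = 2, fs = 250, seed = 1L) {
  stopifnot(inherits(model, "rhythm_model"))
  if (duration_s < 2 * model$rr_mean)
    esb_abort("esb_bad_argument",
              sprintf("duration %.2f s too short: need at least two beats (2 x RR mean = %.2f s)",
                      duration_s, 2 * model$rr_mean))
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  withr::with_seed(seed, {
    # beat train starts just before the window so the first beat is complete
    beats <- -stats::runif(1, 0, model$rr_mean)
    while (beats[length(beats)] < duration_s + model$rr_mean) {
      rr <- stats::rnorm(1, model$rr_mean, model$rr_cv * model$rr_mean)
      beats <- c(beats, beats[length(beats)] + max(rr, model$rr_min))
    }
    x <- numeric(n)
    for (b in beats) for (w in model$waves) {
      if (w$amp == 0) next
      x <- x + w$amp * exp(-((t - b - w$center)^2) / (2 * w$width^2))
    }
    if (model$fib_amp > 0) {
      wa <- stats::runif(1, model$fib_burst[1], model$fib_burst[2])
      wa <- min(wa, duration_s)
      t0 <- stats::runif(1, 0, duration_s - wa)
      env <- ifelse(t >= t0 & t <= t0 + wa, sin(pi * (t - t0) / wa)^2, 0)
      fr <- stats::runif(3, model$fib_band[1], model$fib_band[2])
      ph <- stats::runif(3, 0, 2 * pi)
      fib <- rowSums(sapply(1:3, function(i)
        sin(2 * pi * fr[i] * t + ph[i]))) / sqrt(3)
      x <- x + model$fib_amp * env * fib
    }
    x <- x + stats::rnorm(n, 0, model$noise_sd)
  })
  ecg_signal(x, fs = fs, label = model$class,
             record_id = sprintf("%s_seed%d", model$class, seed))
}

#' Generate a labeled synthetic three-class dataset
#'
#' `n_per_class` records for each of AF, CHF and NSR (150 records by
#' default), each rendered by [generate_record()] with a distinct
#' per-record seed derived deterministically from the master seed. The
#' default four-second records keep every level-5 sub-band long enough
#' (at least 31 coefficients) for the sample-entropy estimator to find
#' template matches.
#'
#' @param n_per_class Records per class (default 50).
#' @param seed Master seed (default 3, the frozen fixture seed).
#' @param duration_s,fs Passed to [generate_record()] (defaults 4 s,
#'   250 Hz).
#' @return A list of labeled [ecg_signal()] records with attribute
#'   `"manifest"`, a `data.frame` of `record_id`, `class` and `seed`.
#' @export
generate_dataset <- function(n_per_class = 50L, seed = 3L,
                             duration_s = 4, fs = 250) {
  if (n_per_class < 1L)
    esb_abort("esb_bad_argument", "n_per_class must be >= 1")
  classes <- c("AF", "CHF", "NSR")
  n_tot <- 3L * n_per_class
  rec_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max - 1L, n_tot))
  records <- vector("list", n_tot)
  i <- 0L
  for (cl in classes) {
    model <- rhythm_model(cl)
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      records[[i]] <- generate_record(model, duration_s = duration_s,
                                      fs = fs, seed = rec_seeds[i])
      records[[i]]$record_id <- sprintf("%s_%03d", cl, j)
    }
  }
  manifest <- data.frame(record_id = vapply(records, `[[`, "", "record_id"),
                         class = vapply(records, `[[`, "", "label"),
                         seed = rec_seeds)
  structure(records, manifest = manifest, class = "ecg_dataset")
}

#' @export
print.ecg_dataset <- function(x, ...) {
  m <- attr(x, "manifest")
  cat(sprintf("<ecg_dataset> %d records (%s)\n", length(x),
              paste(names(table(m$class)), table(m$class),
                    sep = ": ", collapse = ", ")))
  invisible(x)
}

#' @export
`[.ecg_dataset` <- function(x, i) {
  out <- unclass(x)[i]
  attr(out, "manifest") <- attr(x, "manifest")[i, , drop = FALSE]
  class(out) <- "ecg_dataset"
  out
}
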