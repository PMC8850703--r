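#' Entropy estimator parameters
#'
#' Bundles the tunable parameters of the six entropy measures. The paper's
#' source literature for each measure motivates the defaults: embedding
#' `m = 2` and tolerance `r = 0.2 * SD` for sample entropy, ordinal order
#' `m = 3` for permutation entropy, embedding `m = 2` with `a = 6` classes
#' for dispersion entropy, embedding `m = 8` for bubble entropy, and
#' embedding `m = 3` with thresholds `gamma = 1.0` (steep slope, in
#' normalized amplitude units per sample) and `delta = 1e-3` (flatness) for
#' slope entropy. `tau` is the common time lag.
#'
#' @param m_sampen,r_factor,tau Sample-entropy embedding, tolerance factor
#'   (multiple of the sequence SD) and lag.
#' @param m_perm Permutation-entropy ordinal order.
#' @param m_disp,n_classes Dispersion-entropy embedding and class count.
#' @param m_bubble Bubble-entropy embedding.
#' @param m_slope,slope_gamma,slope_delta Slope-entropy embedding and
#'   slope thresholds (`0 <= slope_delta < slope_gamma`).
#' @param normalize Named logical vector switching per-measure
#'   normalization to \[0, 1\] (Shannon by `ln N`, permutation by
#'   `ln m!`, dispersion by `ln a^m`, slope by `ln 5^(m-1)`). Bubble
#'   entropy carries its own normalizer and sample entropy has no finite
#'   supremum, so neither takes a flag.
#' @return A list of class `entropy_params`.
#' @export
entropy_params <- function(m_sampen = 2L, r_factor = 0.2, tau = 1L,
                           m_perm = 3L, m_disp = 2L, n_classes = 6L,
                           m_bubble = 8L, m_slope = 3L,
                           slope_gamma = 1.0, slope_delta = 1e-3,
                           normalize = c(shannon = TRUE, permutation = TRUE,
                                         dispersion = TRUE, slope = TRUE)) {
  p <- list(m_sampen = as.integer(m_sampen), r_factor = r_factor,
            tau = as.integer(tau), m_perm = as.integer(m_perm),
            m_disp = as.integer(m_disp), n_classes = as.integer(n_classes),
            m_bubble = as.integer(m_bubble), m_slope = as.integer(m_slope),
            slope_gamma = slope_gamma, slope_delta = slope_delta,
            normalize = normalize)
  if (any(c(p$m_sampen, p$m_perm, p$m_disp, p$m_bubble, p$m_slope) < 2L))
    esb_abort("esb_bad_argument", "all embedding dimensions must be >= 2")
  if (p$n_classes < 2L)
    esb_abort("esb_bad_argument", "n_classes must be >= 2")
  if (p$r_factor <= 0)
    esb_abort("esb_bad_argument", "r_factor must be > 0")
  if (p$tau < 1L)
    esb_abort("esb_bad_argument", "tau must be >= 1")
  if (p$slope_delta < 0 || p$slope_delta >= p$slope_gamma)
    esb_abort("esb_bad_argument", "need 0 <= slope_delta < slope_gamma")
  structure(p, class = "entropy_params")
}

# Shannon entropy of a probability vector (0 log 0 := 0)
shannon_of <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# time-delay embedding: rows are (x[i], x[i+tau], ..., x[i+(m-1)tau])
embed_delay <- function(x, m, tau) {
  n_vec <- length(x) - (m - 1L) * tau
  idx <- outer(seq_len(n_vec), (0L:(m - 1L)) * tau, `+`)
  matrix(x[idx], nrow = n_vec)
}

#' Shannon entropy of a coefficient energy distribution
#'
#' Treats the normalized squared coefficients \eqn{p_i = x_i^2 / \sum_j
#' x_j^2} as a probability distribution over the sequence (the
#' wavelet-energy convention) and returns \eqn{-\sum_i p_i \ln p_i}.
#' Because the distribution is built from energies, the measure is scale-
#' but not shift-invariant.
#'
#' @param x Numeric sequence (wavelet coefficients of one sub-band).
#' @param normalize Divide by `ln(length(x))` so the result lies in
#'   \[0, 1\] (default `TRUE`).
#' @return Entropy value.
#' @export
shannon_entropy <- function(x, normalize = TRUE) {
  x <- as_samples(x)
  if (length(x) < 2L)
    esb_abort("esb_short_signal", "need at least 2 values for Shannon entropy")
  e <- x^2
  s <- sum(e)
  if (s == 0)
    esb_abort("esb_undefined_entropy",
              "all-zero sequence: energy distribution undefined")
  h <- shannon_of(e / s)
  if (normalize) h / log(length(x)) else h
}

#' Sample entropy
#'
#' \eqn{-\ln(A/B)} where `B` counts pairs of length-`m` templates within
#' Chebyshev distance `r = r_factor * SD(x)` of each other and `A` counts
#' the same pairs extended to length `m + 1`. Self-matches are excluded;
#' templates are restricted to the `N - m*tau` positions that admit the
#' `m + 1` extension, the standard estimator convention.
#'
#' @param x Numeric sequence, length at least `m_sampen * tau + 2`.
#' @param params An [entropy_params()] object.
#' @return Non-negative entropy value (unnormalized; sample entropy has no
#'   finite upper bound).
#' @details A constant sequence (SD 0) raises `esb_degenerate_signal`.
#'   When no template pair matches at either length the conditional
#'   probability is undefined and an `esb_undefined_entropy` error is
#'   raised rather than returning a silent number; the feature pipeline
#'   converts it to a flagged-missing value and drops the record.
#' @export
sample_entropy <- function(x, params = entropy_params()) {
  x <- as_samples(x)
  m <- params$m_sampen; tau <- params$tau
  if (length(x) < m * tau + 2L)
    esb_abort("esb_short_signal",
              sprintf("need at least %d samples for sample entropy", m * tau + 2L))
  s <- stats::sd(x)
  if (s == 0)
    esb_abort("esb_degenerate_signal",
              "zero-SD input: sample-entropy tolerance r collapses to 0")
  r <- params$r_factor * s
  emb <- embed_delay(x, m + 1L, tau)     # N - m*tau rows
  nt <- nrow(emb)
  if (nt < 2L)
    esb_abort("esb_short_signal", "too few templates for sample entropy")
  # Chebyshev distances over the first m coordinates and all m+1
  dm <- matrix(0, nt, nt)
  for (j in seq_len(m)) dm <- pmax(dm, abs(outer(emb[, j], emb[, j], `-`)))
  dm1 <- pmax(dm, abs(outer(emb[, m + 1L], emb[, m + 1L], `-`)))
  ut <- upper.tri(dm)
  b <- sum(dm[ut] <= r)
  a <- sum(dm1[ut] <= r)
  if (b == 0L || a == 0L)
    esb_abort("esb_undefined_entropy",
              sprintf("no template matches (B=%d, A=%d): sample entropy undefined", b, a))
  -log(a / b)
}

# ordinal pattern key for each row of an embedding matrix; ties broken by
# position (stable order), so repeated calls are byte-identical
ordinal_patterns <- function(emb) {
  apply(emb, 1L, function(w) paste(order(w), collapse = "-"))
}

#' Permutation entropy
#'
#' Shannon entropy of the distribution of ordinal (rank-order) patterns of
#' the `m`-point delay embeddings of `x`. Ties are broken by order of
#' appearance, giving deterministic patterns.
#'
#' @param x Numeric sequence, length at least `m_perm * tau + 1`.
#' @param params An [entropy_params()] object.
#' @param normalize Divide by `ln(m!)` (default from
#'   `params$normalize["permutation"]`).
#' @return Entropy value; 0 for a monotone sequence (a single pattern).
#' @export
permutation_entropy <- function(x, params = entropy_params(),
                                normalize = params$normalize[["permutation"]]) {
  x <- as_samples(x)
  m <- params$m_perm; tau <- params$tau
  if (length(x) < m * tau + 1L)
    esb_abort("esb_short_signal",
              sprintf("need at least %d samples for permutation entropy", m * tau + 1L))
  pat <- ordinal_patterns(embed_delay(x, m, tau))
  h <- shannon_of(as.vector(table(pat)) / length(pat))
  if (normalize) h / log(factorial(m)) else h
}

#' Dispersion entropy
#'
#' Samples are mapped through the normal cumulative distribution fitted to
#' the sequence mean and SD, discretized into `a = n_classes` levels by
#' `round(a * u + 0.5)` (clamped to `1..a`), and embedded into
#' `m_disp`-length dispersion patterns at lag `tau`; the result is the
#' Shannon entropy of the observed pattern frequencies. Captures amplitude
#' and frequency structure simultaneously.
#'
#' @param x Numeric sequence, length at least `m_disp * tau + 1`.
#' @param params An [entropy_params()] object.
#' @param normalize Divide by `ln(a^m)` (default from `params`).
#' @return Entropy value. A constant sequence collapses to a single class
#'   and returns 0 with a warning.
#' @export
dispersion_entropy <- function(x, params = entropy_params(),
                               normalize = params$normalize[["dispersion"]]) {
  x <- as_samples(x)
  m <- params$m_disp; tau <- params$tau; a <- params$n_classes
  if (length(x) < m * tau + 1L)
    esb_abort("esb_short_signal",
              sprintf("need at least %d samples for dispersion entropy", m * tau + 1L))
  s <- stats::sd(x)
  if (s == 0) {
    esb_warn("esb_degenerate_signal",
             "zero-SD input: all dispersion patterns identical, entropy 0")
    return(0)
  }
  u <- stats::pnorm(x, mean = mean(x), sd = s)
  cls <- pmin(pmax(round(a * u + 0.5), 1L), a)
  emb <- embed_delay(cls, m, tau)
  pat <- apply(emb, 1L, paste, collapse = "-")
  h <- shannon_of(as.vector(table(pat)) / length(pat))
  if (normalize) h / log(a^m) else h
}

# bubble-sort swap count = number of strict inversions of a vector
count_inversions <- function(emb) {
  m <- ncol(emb)
  inv <- integer(nrow(emb))
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
    inv <- inv + (emb[, i] > emb[, j])
  inv
}

#' Bubble entropy
#'
#' Embeds the sequence at sizes `m` and `m + 1`, counts the bubble-sort
#' swaps needed to sort each embedded vector ascending, and takes the
#' Renyi-2 entropy \eqn{H = -\log \sum_i p_i^2} of each swap-count
#' distribution. The result is the normalized difference
#' \deqn{bEn = (H_{m+1} - H_m) / \log((m+1)/(m-1)),}
#' which is 0 for monotone sequences (point distributions at both sizes).
#'
#' @param x Numeric sequence, length at least `(m_bubble + 1) * tau + 1`.
#' @param params An [entropy_params()] object (`m_bubble` defaults to 8).
#' @return Entropy value.
#' @export
bubble_entropy <- function(x, params = entropy_params()) {
  x <- as_samples(x)
  m <- params$m_bubble; tau <- params$tau
  if (length(x) < (m + 1L) * tau + 1L)
    esb_abort("esb_short_signal",
              sprintf("need at least %d samples for bubble entropy",
                      (m + 1L) * tau + 1L))
  h_swaps <- function(mm) {
    inv <- count_inversions(embed_delay(x, mm, tau))
    p <- as.vector(table(inv)) / length(inv)
    -log(sum(p^2))
  }
  (h_swaps(m + 1L) - h_swaps(m)) / log((m + 1) / (m - 1))
}

#' Slope entropy
#'
#' Symbolizes consecutive differences `d` into five slope classes --
#' `+2` if `d > gamma`, `+1` if `delta < d <= gamma`, `0` if `|d| <=
#' delta`, and the mirrored negative classes -- then takes the Shannon
#' entropy of the relative frequencies of length-`(m - 1)` symbol
#' patterns. Unlike purely ordinal measures the symbols carry amplitude
#' information, so the measure is not shift/scale-invariant by design.
#'
#' @param x Numeric sequence, length at least `m_slope + 1`.
#' @param params An [entropy_params()] object (`m_slope`, `slope_gamma`,
#'   `slope_delta`).
#' @param normalize Divide by `ln(5^(m-1))`, the log pattern-space size
#'   (default from `params`).
#' @return Entropy value; 0 when all symbol patterns coincide (constant or
#'   uniformly steep sequences).
#' @export
slope_entropy <- function(x, params = entropy_params(),
                          normalize = params$normalize[["slope"]]) {
  x <- as_samples(x)
  m <- params$m_slope
  if (length(x) < m + 1L)
    esb_abort("esb_short_signal",
              sprintf("need at least %d samples for slope entropy", m + 1L))
  g <- params$slope_gamma; dl <- params$slope_delta
  d <- diff(x)
  sym <- ifelse(d > g, 2L,
         ifelse(d > dl, 1L,
         ifelse(d >= -dl, 0L,
         ifelse(d >= -g, -1L, -2L))))
  emb <- embed_delay(sym, m - 1L, 1L)
  pat <- apply(emb, 1L, paste, collapse = "-")
  h <- shannon_of(as.vector(table(pat)) / length(pat))
  if (normalize) h / ((m - 1) * log(5)) else h
}

#' All six entropy measures of one sequence
#'
#' Convenience wrapper returning the Shannon (energy), sample,
#' permutation, dispersion, bubble and slope entropies as a named vector.
#' An undefined sample entropy (no template matches) is returned as `NA`
#' with the reason in the `"flags"` attribute instead of aborting, so the
#' caller can drop the record with a logged reason.
#'
#' @param x Numeric sequence.
#' @param params An [entropy_params()] object.
#' @return Named numeric vector of length 6, with a `"flags"` attribute
#'   (character vector of flagged-missing reasons, empty when all defined).
#' @export
entropy_features <- function(x, params = entropy_params()) {
  flags <- character()
  samp <- tryCatch(sample_entropy(x, params),
                   esb_undefined_entropy = function(e) {
                     flags <<- c(flags, conditionMessage(e)); NA_real_
                   })
  out <- c(shannon = shannon_entropy(x, params$normalize[["shannon"]]),
           sample = samp,
           permutation = permutation_entropy(x, params),
           dispersion = dispersion_entropy(x, params),
           bubble = bubble_entropy(x, params),
           slope = slope_entropy(x, params))
  attr(out, "flags") <- flags
  out
}
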