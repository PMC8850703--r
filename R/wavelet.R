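#' Orthogonal wavelet filter banks
#'
#' Returns the four-filter bank (analysis/synthesis low/high-pass) for a
#' named orthogonal mother wavelet. Daubechies-4 (`"db4"`), the de-facto
#' standard for ECG work, is the package default; Haar, Daubechies-2 and
#' Symlet-4 are also available.
#'
#' @param name Wavelet identifier: `"haar"` (= `"db1"`), `"db2"`, `"db4"`,
#'   `"sym4"`.
#' @return A list with elements `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` and
#'   `length` (the filter length).
#' @export
wavelet_filters <- function(name = "db4") {
  # scaling (synthesis low-pass) filters; the rest follow by QMF relations
  rec_lo <- switch(name,
    haar = ,
    db1 = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(0.48296291314469025, 0.8365163037378079,
            0.22414386804185735, -0.12940952255092145),
    db4 = c(0.23037781330885523, 0.7148465705525415,
            0.6308807679295904, -0.02798376941698385,
            -0.18703481171888114, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278),
    sym4 = c(0.0322231006040427, -0.012603967262037833,
             -0.09921954357684722, 0.29785779560527736,
             0.8037387518059161, 0.49761866763201545,
             -0.02963552764599851, -0.07576571478927333),
    esb_abort("esb_unknown_wavelet", sprintf("unknown wavelet '%s'", name))
  )
  f <- length(rec_lo)
  rec_hi <- (-1)^(seq_len(f) - 1) * rev(rec_lo)
  list(dec_lo = rev(rec_lo), dec_hi = rev(rec_hi),
       rec_lo = rec_lo, rec_hi = rec_hi, length = f)
}

# -- single-level analysis/synthesis ----------------------------------------

# symmetric (edge-repeating) extension indices for positions 1-pad .. n+pad
ext_symmetric <- function(x, pad) {
  n <- length(x)
  idx <- seq.int(1L - pad, n + pad)
  # repeated half-point reflection: ... x2 x1 | x1 x2 ... xn | xn x(n-1) ...
  per <- 2L * n
  j <- ((idx - 1L) %% per + per) %% per   # 0 .. 2n-1
  j <- ifelse(j < n, j + 1L, 2L * n - j)
  x[j]
}

conv_valid <- function(x, f) {
  # y[i] = sum_k f[k] * x[i + k - 1]
  nf <- length(f)
  ny <- length(x) - nf + 1L
  y <- numeric(ny)
  for (k in seq_len(nf)) y <- y + f[k] * x[k:(k + ny - 1L)]
  y
}

conv_full <- function(x, f) {
  nf <- length(f)
  y <- numeric(length(x) + nf - 1L)
  for (k in seq_len(nf)) {
    y[k:(k + length(x) - 1L)] <- y[k:(k + length(x) - 1L)] + f[k] * x
  }
  y
}

dwt_step_sym <- function(x, flt) {
  f <- flt$length
  xe <- ext_symmetric(x, f - 1L)
  # true convolution with the analysis filters = correlation with rev(dec_*)
  lo <- conv_valid(xe, rev(flt$dec_lo))
  hi <- conv_valid(xe, rev(flt$dec_hi))
  keep <- seq.int(2L, length(lo), by = 2L)
  list(a = lo[keep], d = hi[keep])
}

idwt_step_sym <- function(a, d, flt, out_len) {
  f <- flt$length
  la <- length(a)
  ua <- numeric(2L * la); ua[seq.int(1L, 2L * la, 2L)] <- a
  ud <- numeric(2L * la); ud[seq.int(1L, 2L * la, 2L)] <- d
  y <- conv_full(ua, flt$rec_lo) + conv_full(ud, flt$rec_hi)
  # boundary coefficients are redundant; trim f-2 from each side, then cut
  y <- y[(f - 1L):(length(y) - (f - 2L))]
  y[seq_len(out_len)]
}

dwt_step_per <- function(x, flt) {
  n0 <- length(x)
  if (n0 %% 2L == 1L) x <- c(x, x[n0])   # pad odd lengths by edge repeat
  n <- length(x)
  m <- n %/% 2L
  f <- flt$length
  h <- flt$rec_lo   # orthonormal rows are the scaling filter at even shifts
  g <- flt$rec_hi
  a <- numeric(m); d <- numeric(m)
  base <- 2L * (seq_len(m) - 1L)
  for (k in seq_len(f)) {
    idx <- (base + (k - 1L)) %% n + 1L
    a <- a + h[k] * x[idx]
    d <- d + g[k] * x[idx]
  }
  list(a = a, d = d)
}

idwt_step_per <- function(a, d, flt, out_len) {
  m <- length(a)
  n <- 2L * m
  f <- flt$length
  h <- flt$rec_lo
  g <- flt$rec_hi
  x <- numeric(n)
  base <- 2L * (seq_len(m) - 1L)
  for (k in seq_len(f)) {
    idx <- (base + (k - 1L)) %% n + 1L
    x[idx] <- x[idx] + h[k] * a + g[k] * d
  }
  x[seq_len(out_len)]
}

band_len <- function(n, f, mode) {
  if (mode == "periodic") ceiling(n / 2) else (n + f - 1L) %/% 2L
}

#' Multi-level discrete wavelet decomposition
#'
#' Mallat-pyramid DWT of a normalized ECG segment. A five-level
#' decomposition (the default) yields six sub-bands: one approximation
#' (`cA5`) and five detail bands (`cD5` ... `cD1`), ordered coarse to fine.
#' All downstream Hjorth/entropy features are computed on these coefficient
#' sequences.
#'
#' @param z An `ecg_normalized` / [ecg_signal()] object or numeric vector.
#' @param levels Decomposition depth (default 5).
#' @param wavelet Mother-wavelet name, see [wavelet_filters()] (default
#'   `"db4"`).
#' @param mode Boundary extension: `"symmetric"` (default, edge-repeating
#'   reflection) or `"periodic"` (orthogonal periodization, which conserves
#'   energy exactly for even dyadic lengths).
#' @return A `wavelet_decomposition`: list with `bands` (named list
#'   `cA<levels>`, `cD<levels>`, ..., `cD1`), `wavelet`, `levels`, `mode`
#'   and the per-level input lengths needed for reconstruction.
#' @details The deepest approximation band must keep at least 2
#'   coefficients; shorter inputs raise `esb_short_signal` reporting the
#'   minimum admissible length.
#' @examples
#' z <- normalize_signal(sin(seq(0, 8 * pi, length.out = 512)))
#' d <- dwt_decompose(z)
#' names(d$bands)
#' @export
dwt_decompose <- function(z, levels = 5L, wavelet = "db4",
                          mode = c("symmetric", "periodic")) {
  mode <- match.arg(mode)
  x <- as_samples(z)
  levels <- as.integer(levels)
  if (levels < 1L) esb_abort("esb_bad_argument", "levels must be >= 1")
  flt <- wavelet_filters(wavelet)
  # depth precondition: the ideally decimated level-`levels` approximation
  # must keep >= 2 coefficients, i.e. n >= 2^(levels + 1); the periodized
  # transform additionally needs the deepest band at least one filter long
  # to stay orthogonal
  lens <- integer(levels)
  n <- length(x)
  for (l in seq_len(levels)) {
    lens[l] <- n
    n <- band_len(n, flt$length, mode)
  }
  nmin <- min_dwt_length(levels, flt$length, mode)
  if (length(x) < nmin)
    esb_abort("esb_short_signal",
              sprintf(paste0("signal of length %d too short for a %d-level '%s'",
                             " decomposition (minimum length %d)"),
                      length(x), levels, wavelet, nmin))
  step <- if (mode == "periodic") dwt_step_per else dwt_step_sym
  bands <- vector("list", levels + 1L)
  cur <- x
  for (l in seq_len(levels)) {
    s <- step(cur, flt)
    bands[[levels + 2L - l]] <- s$d   # cD_l goes at the tail
    cur <- s$a
  }
  bands[[1L]] <- cur
  names(bands) <- c(paste0("cA", levels), paste0("cD", levels:1))
  structure(list(bands = bands, wavelet = wavelet, levels = levels,
                 mode = mode, level_lengths = lens,
                 original_length = length(x)),
            class = "wavelet_decomposition")
}

min_dwt_length <- function(levels, f, mode) {
  nmin <- 2L^(levels + 1L)
  if (mode == "periodic") {
    while (TRUE) {
      m <- nmin
      for (l in seq_len(levels)) m <- band_len(m, f, mode)
      if (m >= max(2L, f)) return(nmin)
      nmin <- nmin + 1L
    }
  }
  nmin
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("<wavelet_decomposition> %s, %d levels, %s extension\n",
              x$wavelet, x$levels, x$mode))
  for (nm in names(x$bands))
    cat(sprintf("  %-4s %5d coefficients\n", nm, length(x$bands[[nm]])))
  invisible(x)
}

#' Invert a wavelet decomposition
#'
#' Reconstructs the time-domain signal from a [dwt_decompose()] result.
#' With unmodified bands this is the exact inverse up to numerical
#' round-off; zeroing a band before reconstruction removes that band's
#' frequency content (a crude sub-band filter, used by the test harness).
#'
#' @param d A `wavelet_decomposition`.
#' @return Numeric vector of length `d$original_length`.
#' @export
dwt_reconstruct <- function(d) {
  stopifnot(inherits(d, "wavelet_decomposition"))
  flt <- wavelet_filters(d$wavelet)
  istep <- if (d$mode == "periodic") idwt_step_per else idwt_step_sym
  a <- d$bands[[1L]]
  for (l in rev(seq_len(d$levels))) {
    dd <- d$bands[[paste0("cD", l)]]
    if (length(dd) != length(a))
      esb_abort("esb_bad_argument",
                sprintf("band length mismatch at level %d (%d vs %d)",
                        l, length(a), length(dd)))
    a <- istep(a, dd, flt, d$level_lengths[l])
  }
  a
}
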