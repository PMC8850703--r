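# Independent brute-force transcriptions of the feature definitions.
# Deliberately written as plain loops, separate from the package
# implementations, so the two can be compared on random inputs.

oracle_hjorth <- function(x) {
  n <- length(x)
  xbar <- sum(x) / n
  sx <- sqrt(sum((x - xbar)^2) / n)
  d1 <- numeric(n - 1)
  for (k in 2:n) d1[k - 1] <- x[k] - x[k - 1]
  m1 <- sum(d1) / length(d1)
  sx1 <- sqrt(sum((d1 - m1)^2) / length(d1))
  d2 <- numeric(length(d1) - 1)
  for (k in 2:length(d1)) d2[k - 1] <- d1[k] - d1[k - 1]
  m2 <- sum(d2) / length(d2)
  sx2 <- sqrt(sum((d2 - m2)^2) / length(d2))
  c(activity = sx^2, mobility = sx1 / sx,
    complexity = (sx2 / sx1) / (sx1 / sx))
}

oracle_shannon <- function(x, normalize = TRUE) {
  e <- x^2 / sum(x^2)
  h <- 0
  for (p in e) if (p > 0) h <- h - p * log(p)
  if (normalize) h / log(length(x)) else h
}

oracle_sampen <- function(x, m = 2, r_factor = 0.2, tau = 1) {
  r <- r_factor * sd(x)
  nt <- length(x) - m * tau
  cheb <- function(i, j, len) {
    d <- 0
    for (k in 0:(len - 1)) d <- max(d, abs(x[i + k * tau] - x[j + k * tau]))
    d
  }
  a <- 0; b <- 0
  for (i in 1:(nt - 1)) for (j in (i + 1):nt) {
    if (cheb(i, j, m) <= r) b <- b + 1
    if (cheb(i, j, m + 1) <= r) a <- a + 1
  }
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

oracle_perm <- function(x, m = 3, tau = 1, normalize = TRUE) {
  nw <- length(x) - (m - 1) * tau
  pats <- character(nw)
  for (i in 1:nw) {
    w <- x[i + (0:(m - 1)) * tau]
    pats[i] <- paste(order(w), collapse = "-")
  }
  p <- table(pats) / nw
  h <- -sum(p * log(p))
  if (normalize) h / log(factorial(m)) else h
}

oracle_disp <- function(x, m = 2, a = 6, tau = 1, normalize = TRUE) {
  u <- pnorm(x, mean(x), sd(x))
  cls <- round(a * u + 0.5)
  cls[cls < 1] <- 1; cls[cls > a] <- a
  nw <- length(cls) - (m - 1) * tau
  pats <- character(nw)
  for (i in 1:nw) pats[i] <- paste(cls[i + (0:(m - 1)) * tau], collapse = "-")
  p <- table(pats) / nw
  h <- -sum(p * log(p))
  if (normalize) h / log(a^m) else h
}

# counts swaps by actually running bubble sort on every embedded vector
oracle_bubble <- function(x, m = 8, tau = 1) {
  h_swaps <- function(mm) {
    nv <- length(x) - (mm - 1) * tau
    swaps <- integer(nv)
    for (i in 1:nv) {
      v <- x[i + (0:(mm - 1)) * tau]
      cnt <- 0
      repeat {
        moved <- FALSE
        for (j in 1:(length(v) - 1)) {
          if (v[j] > v[j + 1]) {
            tmp <- v[j]; v[j] <- v[j + 1]; v[j + 1] <- tmp
            cnt <- cnt + 1; moved <- TRUE
          }
        }
        if (!moved) break
      }
      swaps[i] <- cnt
    }
    p <- table(swaps) / nv
    -log(sum(p^2))
  }
  (h_swaps(m + 1) - h_swaps(m)) / log((m + 1) / (m - 1))
}

oracle_slope <- function(x, m = 3, gamma = 1, delta = 1e-3,
                         normalize = TRUE) {
  d <- x[-1] - x[-length(x)]
  sym <- integer(length(d))
  for (i in seq_along(d)) {
    sym[i] <- if (d[i] > gamma) 2 else if (d[i] > delta) 1 else
      if (d[i] >= -delta) 0 else if (d[i] >= -gamma) -1 else -2
  }
  nw <- length(sym) - (m - 2)
  pats <- character(nw)
  for (i in 1:nw) pats[i] <- paste(sym[i:(i + m - 2)], collapse = "-")
  p <- table(pats) / nw
  h <- -sum(p * log(p))
  if (normalize) h / ((m - 1) * log(5)) else h
}

# textbook one-way fixed-effects ANOVA from sums of squares
oracle_anova <- function(groups) {
  allv <- unlist(groups)
  grand <- mean(allv)
  ssb <- 0; ssw <- 0; k <- length(groups); n <- length(allv)
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - grand)^2
    ssw <- ssw + sum((g - mean(g))^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  c(F = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}
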