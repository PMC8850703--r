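test_that("Shannon energy entropy matches closed forms", {
  expect_equal(shannon_entropy(rep(2, 8), normalize = FALSE), log(8))
  expect_equal(shannon_entropy(rep(c(1, -1), 4), normalize = FALSE), log(8))
  expect_equal(shannon_entropy(c(0, 0, 3, 0), normalize = FALSE), 0)
  expect_equal(shannon_entropy(c(1, 1, sqrt(2)), normalize = FALSE),
               1.5 * log(2))
  expect_equal(shannon_entropy(rep(1, 8), normalize = TRUE), 1)
  expect_error(shannon_entropy(numeric(10)), class = "esb_undefined_entropy")
})

test_that("sample entropy is zero for strict periodicity and errs when degenerate", {
  x <- rep(c(1, 2, 3), 20)
  expect_equal(sample_entropy(x), 0)
  expect_error(sample_entropy(rep(1, 30)), class = "esb_degenerate_signal")
  y <- withr::with_seed(7, runif(64))
  v <- sample_entropy(y)
  expect_gt(v, 0)
  expect_equal(v, oracle_sampen(y), tolerance = 1e-12)
})

test_that("sample entropy agrees with an independent library estimator", {
  for (s in 1:5) {
    x <- withr::with_seed(s, rnorm(150))
    expect_equal(sample_entropy(x),
                 pracma::sample_entropy(x, edim = 2, r = 0.2 * sd(x), tau = 1),
                 tolerance = 1e-10)
  }
})

test_that("permutation entropy spans its analytic range", {
  expect_equal(permutation_entropy(1:50), 0)
  expect_equal(permutation_entropy(exp(1:20)), 0)
  p2 <- entropy_params(m_perm = 2)
  expect_equal(permutation_entropy(c(1, 3, 2), p2), 1)
  for (s in 1:10) {
    x <- withr::with_seed(s, rnorm(40))
    v <- permutation_entropy(x)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("dispersion entropy handles degenerate input and matches the oracle", {
  expect_warning(v0 <- dispersion_entropy(rep(4, 30)),
                 class = "esb_degenerate_signal")
  expect_equal(v0, 0)
  saw <- rep(0:9, 4)
  p <- entropy_params(m_disp = 2, n_classes = 3)
  expect_equal(dispersion_entropy(saw, p),
               oracle_disp(saw, m = 2, a = 3), tolerance = 1e-12)
  for (s in 1:10) {
    x <- withr::with_seed(100 + s, rnorm(35))
    expect_lte(dispersion_entropy(x), 1)
  }
})

test_that("bubble entropy collapses for monotone input and matches brute force", {
  expect_equal(bubble_entropy(1:30), 0)
  expect_equal(bubble_entropy(30:1), 0)
  x <- withr::with_seed(11, rnorm(30))
  expect_equal(bubble_entropy(x), oracle_bubble(x), tolerance = 1e-12)
})

test_that("slope entropy symbolizes differences as specified", {
  expect_equal(slope_entropy(rep(2, 20)), 0)
  # unit steps with gamma = 0.5: every diff is the +2 symbol
  p <- entropy_params(slope_gamma = 0.5)
  expect_equal(slope_entropy(1:20, p), 0)
  # +-2 alternation: two patterns, each half the windows
  alt <- rep(c(1, -1), 10)
  expect_equal(slope_entropy(alt, normalize = FALSE), log(2))
  expect_equal(slope_entropy(alt), log(2) / (2 * log(5)))
})

test_that("every measure matches its brute-force transcription on random input", {
  p <- entropy_params()
  for (x in random_sequences(100, c(20, 40), seed = 202)) {
    expect_equal(shannon_entropy(x), oracle_shannon(x), tolerance = 1e-10)
    expect_equal(permutation_entropy(x, p), oracle_perm(x), tolerance = 1e-10)
    expect_equal(dispersion_entropy(x, p), oracle_disp(x), tolerance = 1e-10)
    expect_equal(slope_entropy(x, p), oracle_slope(x), tolerance = 1e-10)
    so <- oracle_sampen(x)
    si <- tryCatch(sample_entropy(x, p),
                   esb_undefined_entropy = function(e) NA_real_)
    expect_equal(si, so, tolerance = 1e-10)
  }
  # bubble needs slightly longer input for its m = 8 embedding
  for (x in random_sequences(100, c(25, 40), seed = 203))
    expect_equal(bubble_entropy(x, p), oracle_bubble(x), tolerance = 1e-10)
})

test_that("ordinal measures are shift-invariant; all normalized outputs bounded", {
  p <- entropy_params()
  for (s in 1:10) {
    x <- withr::with_seed(300 + s, rnorm(40))
    b <- withr::with_seed(s, rnorm(1, sd = 10))
    expect_equal(permutation_entropy(x + b, p), permutation_entropy(x, p),
                 tolerance = 1e-10)
    expect_equal(dispersion_entropy(x + b, p), dispersion_entropy(x, p),
                 tolerance = 1e-10)
    expect_equal(bubble_entropy(x + b, p), bubble_entropy(x, p),
                 tolerance = 1e-10)
    si <- tryCatch(sample_entropy(x, p),
                   esb_undefined_entropy = function(e) NA_real_)
    sib <- tryCatch(sample_entropy(x + b, p),
                    esb_undefined_entropy = function(e) NA_real_)
    expect_equal(sib, si, tolerance = 1e-10)
    ef <- suppressWarnings(entropy_features(x, p))
    expect_true(all(ef[c("shannon", "permutation", "dispersion", "slope")] >= 0))
    expect_true(all(ef[c("shannon", "permutation", "dispersion", "slope")] <= 1))
  }
})

test_that("entropy computations are byte-identical across repeated calls", {
  x <- withr::with_seed(9, rnorm(64))
  p <- entropy_params()
  expect_identical(entropy_features(x, p), entropy_features(x, p))
})

test_that("parameter validation rejects inconsistent settings", {
  expect_error(entropy_params(m_perm = 1), class = "esb_bad_argument")
  expect_error(entropy_params(n_classes = 1), class = "esb_bad_argument")
  expect_error(entropy_params(r_factor = 0), class = "esb_bad_argument")
  expect_error(entropy_params(slope_delta = 2, slope_gamma = 1),
               class = "esb_bad_argument")
})
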