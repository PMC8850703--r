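test_that("the feature vector has 54 stable band-major names", {
  nm <- feature_names()
  expect_length(nm, 54)
  expect_false(anyDuplicated(nm) > 0)
  expect_equal(nm[1:3], c("cA5_activity", "cA5_mobility", "cA5_complexity"))
  expect_equal(nm[54], "cD1_slope")
  expect_equal(unique(sub("_.*", "", nm)),
               c("cA5", "cD5", "cD4", "cD3", "cD2", "cD1"))
})

test_that("extraction is deterministic and absorbs amplitude scaling", {
  x <- generate_record(rhythm_model("NSR"), duration_s = 4, seed = 5)
  fv <- extract_features(x)
  expect_length(fv, 54)
  expect_named(fv, feature_names())
  expect_identical(fv, extract_features(x))
  x10 <- ecg_signal(10 * x$samples, fs = x$fs, label = x$label,
                    record_id = x$record_id)
  expect_equal(unname(extract_features(x10)), unname(fv), tolerance = 1e-12)
})

test_that("feature families subset to 18 / 36 / 54 columns consistently", {
  fm <- frozen_feature_matrix()
  expect_equal(dim(fm), c(150, 55))
  h <- subset_features(fm, "hjorth")
  e <- subset_features(fm, "entropy")
  a <- subset_features(fm, "all")
  expect_length(setdiff(colnames(h), "label"), 18)
  expect_length(setdiff(colnames(e), "label"), 36)
  expect_length(setdiff(colnames(a), "label"), 54)
  expect_setequal(c(setdiff(colnames(h), "label"),
                    setdiff(colnames(e), "label")),
                  setdiff(colnames(a), "label"))
})

test_that("ANOVA screen reproduces hand-computed sums of squares", {
  fm <- structure(data.frame(x_f = c(1, 2, 3, 4, 5, 6),
                             label = factor(rep(c("a", "b"), each = 3))),
                  class = c("feature_matrix", "data.frame"))
  res <- anova_screen(fm)
  expect_equal(res$F[1], 13.5)
  expect_equal(res$p[1], oracle_anova(list(1:3, 4:6))[["p"]])
  expect_true(res$significant[1])
})

test_that("zero within-group variance is flagged degenerate", {
  fm <- structure(data.frame(x_f = c(1, 1, 2, 2, 3, 3),
                             label = factor(rep(c("a", "b", "c"), each = 2))),
                  class = c("feature_matrix", "data.frame"))
  res <- anova_screen(fm)
  expect_true(res$degenerate[1])
  expect_true(res$significant[1])
  fm$x_f <- rep(2, 6)
  res2 <- anova_screen(fm)
  expect_true(res2$degenerate[1])
  expect_equal(res2$p[1], 1)
})

test_that("screen matches the textbook transcription on random data", {
  for (s in 1:50) {
    g <- withr::with_seed(s, {
      list(rnorm(sample(3:8, 1)), rnorm(sample(3:8, 1), mean = runif(1)),
           rnorm(sample(3:8, 1)))
    })
    fm <- structure(data.frame(v_f = unlist(g),
                               label = factor(rep(c("a", "b", "c"),
                                                  times = lengths(g)))),
                    class = c("feature_matrix", "data.frame"))
    res <- anova_screen(fm)
    o <- oracle_anova(g)
    expect_equal(res$F[1], o[["F"]], tolerance = 1e-10)
    expect_equal(res$p[1], o[["p"]], tolerance = 1e-10)
  }
})

test_that("p-values are uniform under permuted labels", {
  base <- withr::with_seed(50, rnorm(15))
  lab <- rep(c("a", "b", "c"), each = 5)
  ps <- withr::with_seed(51, vapply(1:1000, function(i) {
    fm <- structure(data.frame(v_f = base, label = factor(sample(lab))),
                    class = c("feature_matrix", "data.frame"))
    anova_screen(fm)$p[1]
  }, 0))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("feature CSV round-trips values, labels and column order", {
  fm <- frozen_feature_matrix()
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fm, p)
  back <- read_feature_csv(p)
  expect_equal(colnames(back), colnames(fm))
  expect_equal(as.matrix(back[, 1:54]), as.matrix(fm[, 1:54]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(as.character(back$label), as.character(fm$label))
  expect_false(is.null(attr(back, "config_hash")))
})
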