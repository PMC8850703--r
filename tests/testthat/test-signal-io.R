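test_that("CSV records parse in both layouts and carry metadata", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("0.1,0.2,0.3", p)
  x <- read_record(p, fs = 250, label = "NSR")
  expect_s3_class(x, "ecg_signal")
  expect_equal(x$samples, c(0.1, 0.2, 0.3))
  expect_equal(x$fs, 250)
  expect_equal(x$label, "NSR")

  writeLines(c("0.1", "0.2", "0.3"), p)
  expect_equal(read_record(p)$samples, c(0.1, 0.2, 0.3))

  writeLines(c("amplitude", "1", "2"), p)
  expect_equal(read_record(p, header = TRUE)$samples, c(1, 2))
})

test_that("reader raises distinct classed errors", {
  expect_error(read_record(file.path(tempdir(), "no-such-file.csv")),
               class = "esb_missing_file")
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.1", "abc", "0.3"), p)
  err <- tryCatch(read_record(p), error = identity)
  expect_s3_class(err, "esb_parse_error")
  expect_match(conditionMessage(err), "line 2")
  writeLines(character(), p)
  expect_error(read_record(p), class = "esb_empty_signal")
})

test_that("write_record / read_record round-trips to full precision", {
  p <- withr::local_tempfile(fileext = ".csv")
  x <- withr::with_seed(1, rnorm(257))
  write_record(ecg_signal(x), p)
  expect_equal(read_record(p)$samples, x, tolerance = 1e-12)
})

test_that("WFDB formats 16 and 212 read back synthetic records exactly", {
  dir <- withr::local_tempdir()
  adc <- as.integer(round(1000 * sin(2 * pi * 5 * (0:199) / 250)))
  # format 16: interleave two identical channels, int16 little-endian
  writeLines(c("synt16 2 250 200",
               "synt16.dat 16 200(0)/mV 12 0 0 0 0 ch1",
               "synt16.dat 16 200(0)/mV 12 0 0 0 0 ch2"),
             file.path(dir, "synt16.hea"))
  writeBin(as.integer(rbind(adc, adc)), file.path(dir, "synt16.dat"),
           size = 2L, endian = "little")
  x <- read_record(file.path(dir, "synt16"), format = "wfdb")
  expect_equal(x$fs, 250)
  expect_equal(x$samples, adc / 200, tolerance = 1e-12)
  # format 212: single channel, pairs of 12-bit samples in 3 bytes
  a12 <- adc %% 4096L
  s1 <- a12[seq(1, 200, 2)]; s2 <- a12[seq(2, 200, 2)]
  bytes <- as.raw(rbind(s1 %% 256L,
                        (s1 %/% 256L) + 16L * (s2 %/% 256L),
                        s2 %% 256L))
  writeLines(c("synt212 1 250 200",
               "synt212.dat 212 200(0)/mV 12 0 0 0 0 ch1"),
             file.path(dir, "synt212.hea"))
  writeBin(bytes, file.path(dir, "synt212.dat"))
  y <- read_record(file.path(dir, "synt212.hea"), format = "wfdb")
  expect_equal(y$samples, adc / 200, tolerance = 1e-12)
})

test_that("resampling preserves length arithmetic, identity and spectral peaks", {
  x <- ecg_signal(withr::with_seed(2, rnorm(1000)), fs = 500)
  y <- resample_signal(x, 250)
  expect_equal(length(y$samples), 500)
  expect_equal(y$fs, 250)
  expect_identical(resample_signal(x, 500)$samples, x$samples)
  expect_error(resample_signal(x, -1), class = "esb_bad_argument")
  # a pure 5 Hz tone keeps its dominant peak after 500 -> 250 Hz
  t <- (0:999) / 500
  tone <- ecg_signal(sin(2 * pi * 5 * t), fs = 500)
  z <- resample_signal(tone, 250)
  spec <- Mod(stats::fft(z$samples))[1:250]
  peak_hz <- (which.max(spec[-1])) * 250 / length(z$samples)
  expect_equal(peak_hz, 5, tolerance = 0.26)
})

test_that("segmentation enumerates exact windows and drops partials", {
  x <- ecg_signal(seq_len(1500), fs = 250, label = "AF")
  segs <- segment_signal(x, window_s = 2, hop_s = 2)
  expect_length(segs, 3)
  expect_true(all(vapply(segs, function(s) length(s$samples), 0L) == 500))
  expect_true(all(vapply(segs, `[[`, "", "label") == "AF"))

  short <- ecg_signal(seq_len(499), fs = 250)
  expect_warning(out <- segment_signal(short, window_s = 2),
                 class = "esb_short_signal")
  expect_length(out, 0)

  x2 <- ecg_signal(seq_len(1250), fs = 250)
  segs2 <- segment_signal(x2, window_s = 2, hop_s = 1)
  expect_length(segs2, 4)
  starts <- vapply(segs2, function(s) s$samples[1], 0)
  expect_equal(starts, c(1, 251, 501, 751))
})

test_that("normalization is the exact two-step map with unit peak", {
  expect_equal(normalize_signal(c(0, 2))$samples, c(-1, 1))
  expect_equal(normalize_signal(c(1, 2, 3))$samples, c(-1, 0, 1))
  expect_error(normalize_signal(c(5, 5, 5)), class = "esb_degenerate_signal")
  for (i in 1:20) {
    z <- normalize_signal(withr::with_seed(i, rnorm(100)))$samples
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(max(abs(z)), 1)
    expect_true(all(z >= -1 & z <= 1))
  }
})

test_that("normalization is idempotent and affine-invariant", {
  for (i in 1:10) {
    x <- withr::with_seed(100 + i, rnorm(80))
    z1 <- normalize_signal(x)$samples
    expect_equal(normalize_signal(z1)$samples, z1, tolerance = 1e-12)
    a <- withr::with_seed(i, runif(1, 0.1, 10)) * sample(c(-1, 1), 1)
    b <- withr::with_seed(i, rnorm(1, sd = 5))
    expect_equal(normalize_signal(a * x + b)$samples, sign(a) * z1,
                 tolerance = 1e-12)
  }
})
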