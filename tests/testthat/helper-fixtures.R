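# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# The frozen default synthetic dataset's full feature matrix (150 x 54).
frozen_feature_matrix <- function() {
  if (is.null(.fixture_cache$fm)) {
    ds <- generate_dataset()
    .fixture_cache$fm <- suppressWarnings(build_feature_matrix(ds))
  }
  .fixture_cache$fm
}

# Three well-separated Gaussian point clouds in 5 dimensions, as a
# feature_matrix; linearly separable by a wide margin.
separable_clouds <- function(n_per_class = 20, seed = 77) {
  withr::with_seed(seed, {
    centers <- rbind(AF = c(0, 0, 0, 0, 0),
                     CHF = c(8, 8, 0, 0, 0),
                     NSR = c(0, 0, 8, 8, 0))
    rows <- do.call(rbind, lapply(rownames(centers), function(cl) {
      sweep(matrix(rnorm(n_per_class * 5, sd = 0.5), n_per_class, 5),
            2, centers[cl, ], `+`)
    }))
    df <- as.data.frame(rows)
    colnames(df) <- paste0("f", 1:5)
    df$label <- factor(rep(rownames(centers), each = n_per_class))
    structure(df, class = c("feature_matrix", "data.frame"))
  })
}

# seeded random sequences for oracle-equivalence sweeps
random_sequences <- function(n = 100, len_range = c(20, 40), seed = 123) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i)
      rnorm(sample(len_range[1]:len_range[2], 1)))
  })
}
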