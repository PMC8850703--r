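#' Canonical feature names
#'
#' The fixed, band-major feature ordering: for each sub-band (`cA5`,
#' `cD5`, ..., `cD1` for a five-level decomposition) the three Hjorth
#' descriptors followed by the six entropies. With the default five
#' levels this yields 6 bands x 9 features = 54 names of the form
#' `<band>_<feature>`.
#'
#' @param levels Decomposition depth (default 5).
#' @return Character vector of feature names.
#' @export
feature_names <- function(levels = 5L) {
  bands <- c(paste0("cA", levels), paste0("cD", levels:1))
  as.vector(t(outer(bands, feature_kinds(), paste, sep = "_")))
}

feature_kinds <- function() {
  c("activity", "mobility", "complexity",
    "shannon", "sample", "permutation", "dispersion", "bubble", "slope")
}

hjorth_kinds <- function() feature_kinds()[1:3]
entropy_kinds <- function() feature_kinds()[4:9]

#' Extract the sub-band feature vector of one ECG record
#'
#' The full feature pipeline for a single record: amplitude normalization,
#' five-level DWT into six sub-bands, then per band the three Hjorth
#' descriptors and six entropy measures, concatenated in the fixed
#' band-major order of [feature_names()]. Because normalization absorbs
#' amplitude scale and offset, the vector is identical for `x` and
#' `a * x + b` (`a > 0`).
#'
#' @param x An [ecg_signal()] (or numeric vector at 250 Hz).
#' @param wavelet,levels,mode Decomposition settings, see
#'   [dwt_decompose()].
#' @param params Entropy settings, see [entropy_params()].
#' @return Named numeric vector (54 values for the defaults) with
#'   attributes `label`, `record_id`, `meta` (resolved settings) and
#'   `flags` (reasons for any flagged-missing values, which appear as
#'   `NA`).
#' @details Degenerate sub-bands (constant, or linear-ramp coefficient
#'   sequences) re-raise their typed error with the band name attached.
#' @export
extract_features <- function(x, wavelet = "db4", levels = 5L,
                             mode = "symmetric", params = entropy_params()) {
  z <- normalize_signal(x)
  dec <- dwt_decompose(z, levels = levels, wavelet = wavelet, mode = mode)
  flags <- character()
  vals <- lapply(names(dec$bands), function(bn) {
    b <- dec$bands[[bn]]
    hj <- withCallingHandlers(
      tryCatch(hjorth_features(b), ecgsubband_error = function(e) {
        esb_abort(class(e)[1],
                  sprintf("band %s: %s", bn, conditionMessage(e)))
      }),
      ecgsubband_warning = function(w) invokeRestart("muffleWarning"))
    en <- entropy_features(b, params)
    if (length(attr(en, "flags")))
      flags <<- c(flags, paste0("band ", bn, ": ", attr(en, "flags")))
    c(hj$activity, hj$mobility, hj$complexity, as.numeric(en))
  })
  out <- unlist(vals, use.names = FALSE)
  names(out) <- feature_names(levels)
  attr(out, "label") <- if (inherits(x, "ecg_signal")) x$label else NULL
  attr(out, "record_id") <- if (inherits(x, "ecg_signal")) x$record_id else NULL
  attr(out, "meta") <- list(wavelet = wavelet, levels = levels, mode = mode,
                            entropy = unclass(params))
  attr(out, "flags") <- flags
  out
}

#' Build a labeled feature matrix from a set of records
#'
#' Applies [extract_features()] to each record and assembles a
#' `feature_matrix` (a `data.frame` of feature columns plus a `label`
#' factor). Records with flagged-missing entropies are excluded with a
#' warning naming the record and reason, so the matrix never contains
#' missing values.
#'
#' @param records List of labeled [ecg_signal()] objects (e.g. from
#'   [generate_dataset()]).
#' @inheritParams extract_features
#' @return A `feature_matrix` with one row per retained record; row names
#'   are record ids, metadata in `attr(, "meta")`.
#' @export
build_feature_matrix <- function(records, wavelet = "db4", levels = 5L,
                                 mode = "symmetric",
                                 params = entropy_params()) {
  rows <- list(); labels <- character(); ids <- character()
  meta <- NULL
  for (i in seq_along(records)) {
    r <- records[[i]]
    fv <- extract_features(r, wavelet, levels, mode, params)
    id <- attr(fv, "record_id") %||% paste0("rec", i)
    if (anyNA(fv)) {
      esb_warn("esb_dropped_record",
               sprintf("dropping record %s: %s", id,
                       paste(attr(fv, "flags"), collapse = "; ")))
      next
    }
    rows[[length(rows) + 1L]] <- fv
    labels <- c(labels, attr(fv, "label") %||% NA_character_)
    ids <- c(ids, id)
    meta <- attr(fv, "meta")
  }
  if (length(rows) == 0L)
    esb_abort("esb_empty_signal", "no records survived feature extraction")
  df <- as.data.frame(do.call(rbind, rows))
  df$label <- factor(labels)
  rownames(df) <- make.unique(ids)
  structure(df, meta = meta, class = c("feature_matrix", "data.frame"))
}

feature_columns <- function(fm) setdiff(colnames(fm), "label")

#' Select a feature family
#'
#' Restricts a feature matrix to the Hjorth columns (6 bands x 3 = 18),
#' the entropy columns (6 x 6 = 36) or all 54, preserving the fixed
#' band-major column order. `subset_features(fm, "all")` is the
#' column-wise concatenation of the `"hjorth"` and `"entropy"` subsets.
#'
#' @param fm A `feature_matrix`.
#' @param family One of `"all"`, `"hjorth"`, `"entropy"`.
#' @return A `feature_matrix` with the selected columns plus `label`.
#' @export
subset_features <- function(fm, family = c("all", "hjorth", "entropy")) {
  family <- match.arg(family)
  keep <- switch(family,
    all = feature_columns(fm),
    hjorth = grep(paste0("_(", paste(hjorth_kinds(), collapse = "|"), ")$"),
                  feature_columns(fm), value = TRUE),
    entropy = grep(paste0("_(", paste(entropy_kinds(), collapse = "|"), ")$"),
                   feature_columns(fm), value = TRUE))
  out <- fm[, c(keep, "label"), drop = FALSE]
  attr(out, "meta") <- attr(fm, "meta")
  class(out) <- class(fm)
  out
}

#' One-way ANOVA feature screen
#'
#' Fixed-effects one-way ANOVA of every feature column across the class
#' groups, reporting the F statistic, raw p-value and per-class mean and
#' SD, plus a significance flag at `alpha`. In addition to the per-band
#' rows, a convenience row per feature family (band `"(mean)"`) screens
#' the feature averaged over its six bands. Raw p-values are reported by
#' default; `bonferroni = TRUE` adds an adjusted column.
#'
#' @param fm A `feature_matrix` with at least 2 classes and 2 rows per
#'   class.
#' @param alpha Significance level (default 0.05).
#' @param bonferroni Add a Bonferroni-adjusted p-value column.
#' @return A `data.frame` with columns `feature`, `band`, `family`, `F`,
#'   `p`, `significant`, `degenerate` and `mean_<class>` / `sd_<class>`
#'   per class.
#' @details When every group has zero within-group variance the F ratio
#'   is undefined; such rows are flagged `degenerate` and reported with
#'   `p = 1` for equal group means and `p = 0` (significant) otherwise.
#' @export
anova_screen <- function(fm, alpha = 0.05, bonferroni = FALSE) {
  g <- fm$label
  if (nlevels(droplevels(g)) < 2L)
    esb_abort("esb_bad_argument", "ANOVA screen needs at least 2 classes")
  if (any(table(g) < 2L))
    esb_abort("esb_bad_argument", "every class needs at least 2 rows")
  cols <- feature_columns(fm)
  one <- function(v, feat, band, fam) {
    ms <- tapply(v, g, mean); sds <- tapply(v, g, stats::sd)
    ssw <- sum(tapply(v, g, function(u) sum((u - mean(u))^2)))
    ssb <- sum(tapply(v, g, length) * (ms - mean(v))^2)
    if (ssw <= .Machine$double.eps * sum(v^2)) {
      degen <- TRUE
      p <- if (ssb <= .Machine$double.eps * max(sum(v^2), 1)) 1 else 0
      f <- Inf
    } else {
      degen <- FALSE
      tt <- stats::oneway.test(v ~ g, var.equal = TRUE)
      f <- unname(tt$statistic); p <- tt$p.value
    }
    row <- data.frame(feature = feat, band = band, family = fam,
                      F = f, p = p, significant = p < alpha,
                      degenerate = degen)
    for (cl in levels(g)) {
      row[[paste0("mean_", cl)]] <- unname(ms[cl])
      row[[paste0("sd_", cl)]] <- unname(sds[cl])
    }
    row
  }
  res <- lapply(cols, function(cn) {
    parts <- strsplit(cn, "_", fixed = TRUE)[[1]]
    one(fm[[cn]], cn, parts[1], parts[2])
  })
  fams <- unique(vapply(strsplit(cols, "_", fixed = TRUE), `[`, "", 2L))
  fam_rows <- lapply(fams, function(fam) {
    sel <- grep(paste0("_", fam, "$"), cols, value = TRUE)
    v <- rowMeans(fm[, sel, drop = FALSE])
    one(v, fam, "(mean)", fam)
  })
  out <- do.call(rbind, c(res, fam_rows))
  if (bonferroni) out$p_bonferroni <- pmin(out$p * length(cols), 1)
  rownames(out) <- NULL
  out
}

#' Write / read a feature matrix as annotated CSV
#'
#' Plain CSV with the 54 feature columns plus `label`; `#` comment lines
#' carry the resolved wavelet and entropy settings and the package
#' version so any downstream result is traceable to its configuration.
#' Values are written in full double precision and round-trip exactly.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path` invisibly (writer); a `feature_matrix` (reader).
#' @export
write_feature_csv <- function(fm, path) {
  meta <- attr(fm, "meta")
  hdr <- c(sprintf("# ecgsubband %s feature matrix",
                   as.character(utils::packageVersion("ecgsubband"))),
           sprintf("# wavelet=%s levels=%d mode=%s",
                   meta$wavelet, meta$levels, meta$mode),
           sprintf("# entropy: %s",
                   paste(names(meta$entropy)[1:10],
                         unlist(meta$entropy[1:10]), sep = "=", collapse = " ")),
           sprintf("# config_hash=%s", config_hash(meta)))
  cols <- feature_columns(fm)
  lines <- c(hdr, paste(c(cols, "label"), collapse = ","))
  body <- apply(fm[, cols, drop = FALSE], 1L,
                function(v) paste(sprintf("%.17g", v), collapse = ","))
  lines <- c(lines, paste(body, as.character(fm$label), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path))
    esb_abort("esb_missing_file", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  com <- lines[grepl("^#", lines)]
  lines <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        check.names = FALSE)
  df$label <- factor(df$label)
  hash <- sub(".*config_hash=", "", com[grepl("config_hash=", com)])
  structure(df, meta = NULL, config_hash = if (length(hash)) hash else NULL,
            class = c("feature_matrix", "data.frame"))
}

# stable md5 of a settings list (serialized as canonical yaml text)
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(x), tmp)
  unname(tools::md5sum(tmp))
}
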