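#' Train/test split specification
#'
#' Per-class held-out test counts. The defaults reproduce the reference
#' protocol: from 150 records (50 per class), 38 test records composed of
#' 12 AF, 14 CHF and 12 NSR, leaving 112 for training.
#'
#' @param test_counts Named integer vector of per-class test sizes.
#' @param seed Integer seed for the per-class sampling.
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(test_counts = c(AF = 12L, CHF = 14L, NSR = 12L),
                       seed = 1L) {
  structure(list(test_counts = test_counts, seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a feature matrix into train and test sets
#'
#' Per-class sampling without replacement with a seeded generator; the
#' train and test sets are disjoint and their union is the input. The
#' same seed always yields the same partition.
#'
#' @param fm A `feature_matrix`.
#' @param spec A [split_spec()].
#' @return List with elements `train` and `test` (both `feature_matrix`).
#' @export
split_dataset <- function(fm, spec = split_spec()) {
  cnt <- table(fm$label)
  for (cl in names(spec$test_counts)) {
    if (is.na(cnt[cl]) || cnt[cl] < spec$test_counts[[cl]])
      esb_abort("esb_bad_argument",
                sprintf("class %s has %d rows, fewer than the %d test rows requested",
                        cl, if (is.na(cnt[cl])) 0L else cnt[cl],
                        spec$test_counts[[cl]]))
  }
  test_idx <- withr::with_seed(spec$seed, {
    unlist(lapply(names(spec$test_counts), function(cl) {
      idx <- which(fm$label == cl)
      sort(sample(idx, spec$test_counts[[cl]]))
    }))
  })
  test_idx <- sort(test_idx)
  keep_attrs <- function(d) {
    attr(d, "meta") <- attr(fm, "meta"); class(d) <- class(fm); d
  }
  list(train = keep_attrs(fm[-test_idx, , drop = FALSE]),
       test = keep_attrs(fm[test_idx, , drop = FALSE]))
}

#' Class-stratified cross-validation folds
#'
#' Assigns each row to one of `k` folds so that every fold's class
#' proportions are within one sample of the global proportions.
#'
#' @param labels Factor of class labels.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  if (any(table(labels) < k))
    esb_abort("esb_bad_argument",
              sprintf("every class needs at least k=%d rows for %d-fold CV", k, k))
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  folds
}

#' Default hyperparameter grids
#'
#' The exhaustive grids searched for each classifier family, enumerated
#' in a fixed, documented order (ties in CV accuracy are broken by the
#' first cell in this order):
#' \itemize{
#'   \item `knn`: distance (Euclidean, Minkowski order 3, Chebyshev) x
#'     odd `k` in 1..31 -- 48 cells. Minkowski defaults to order 3 so it
#'     is distinct from Euclidean.
#'   \item `svm`: kernel (linear, radial, polynomial degree 3) x
#'     `gamma` in \{1e-1 .. 1e-6\} x `C` in \{1, 10, ..., 1e5\} -- 108
#'     cells.
#'   \item `rf`: trees in \{10, 50, 100, 150, 200, 300, 400, 500\} with
#'     the Gini split criterion.
#'   \item `ann`, `rbfn`: a single cell (fixed topology: 32 hidden /
#'     RBF nodes; Adam lr 0.001, 200 epochs / RMSprop lr 0.001, 500
#'     epochs), so "search" reduces to cross-validated assessment.
#' }
#'
#' @param family One of `"knn"`, `"svm"`, `"rf"`, `"ann"`, `"rbfn"`.
#' @return A `data.frame`, one row per grid cell.
#' @export
default_grid <- function(family = c("knn", "svm", "rf", "ann", "rbfn")) {
  family <- match.arg(family)
  switch(family,
    knn = expand.grid(k = seq(1L, 31L, by = 2L),
                      distance = c("euclidean", "minkowski", "chebyshev"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    svm = expand.grid(C = 10^(0:5), gamma = 10^-(1:6),
                      kernel = c("linear", "radial", "polynomial"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    rf = expand.grid(ntree = c(10L, 50L, 100L, 150L, 200L, 300L, 400L, 500L),
                     criterion = "gini",
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    ann = data.frame(hidden = 32L, lr = 1e-3, epochs = 200L, batch = 16L),
    rbfn = data.frame(centers = 32L, lr = 1e-3, epochs = 500L, batch = 16L))
}

fm_xy <- function(fm) {
  list(X = as.matrix(fm[, feature_columns(fm), drop = FALSE]),
       y = droplevels(fm$label))
}

fit_model <- function(X, y, family, params, seed = 1L, standardize = FALSE) {
  scaler <- NULL
  if (standardize) {
    mu <- colMeans(X); sg <- apply(X, 2L, stats::sd); sg[sg == 0] <- 1
    X <- sweep(sweep(X, 2L, mu), 2L, sg, "/")
    scaler <- list(mu = mu, sd = sg)
  }
  fit <- switch(family,
    knn = list(X = X, y = y, k = params$k, distance = params$distance,
               minkowski_p = params$minkowski_p %||% 3),
    svm = e1071::svm(x = X, y = y, kernel = params$kernel,
                     gamma = params$gamma, cost = params$C, degree = 3,
                     scale = FALSE),
    rf = withr::with_seed(seed,
           randomForest::randomForest(x = X, y = y, ntree = params$ntree)),
    ann = mlp_train(X, y, hidden = params$hidden, lr = params$lr,
                    epochs = params$epochs, batch = params$batch, seed = seed),
    rbfn = rbfn_train(X, y, centers = params$centers, lr = params$lr,
                      epochs = params$epochs, batch = params$batch,
                      seed = seed),
    esb_abort("esb_bad_argument", sprintf("unknown classifier family '%s'", family)))
  list(family = family, fit = fit, params = params, seed = seed,
       scaler = scaler, classes = levels(y))
}

predict_model <- function(model, X) {
  if (!is.null(model$scaler))
    X <- sweep(sweep(X, 2L, model$scaler$mu), 2L, model$scaler$sd, "/")
  switch(model$family,
    knn = knn_predict(model$fit$X, model$fit$y, X, model$fit$k,
                      model$fit$distance, model$fit$minkowski_p),
    svm = stats::predict(model$fit, X),
    rf = stats::predict(model$fit, X),
    ann = mlp_predict(model$fit, X),
    rbfn = rbfn_predict(model$fit, X))
}

#' k-nearest-neighbor prediction
#'
#' Plain k-NN with a choice of Euclidean, Minkowski (order `p`) or
#' Chebyshev distance. Distance ties are resolved by training-row order;
#' a tied class vote falls to the tied class with the nearest neighbor,
#' so predictions are deterministic.
#'
#' @param X_train,y_train Training matrix and label factor.
#' @param X_test Matrix of query rows.
#' @param k Number of neighbors.
#' @param distance `"euclidean"`, `"minkowski"` or `"chebyshev"`.
#' @param p Minkowski order (default 3).
#' @return Factor of predicted labels with the training levels.
#' @export
knn_predict <- function(X_train, y_train, X_test, k,
                        distance = c("euclidean", "minkowski", "chebyshev"),
                        p = 3) {
  distance <- match.arg(distance)
  X_test <- matrix(X_test, ncol = ncol(X_train))
  pred <- character(nrow(X_test))
  for (i in seq_len(nrow(X_test))) {
    df <- sweep(X_train, 2L, X_test[i, ])
    d <- switch(distance,
                euclidean = sqrt(rowSums(df^2)),
                minkowski = rowSums(abs(df)^p)^(1 / p),
                chebyshev = apply(abs(df), 1L, max))
    o <- order(d)[seq_len(min(k, length(d)))]
    votes <- table(y_train[o])
    winners <- names(votes)[votes == max(votes)]
    pred[i] <- if (length(winners) == 1L) winners else {
      # nearest neighbor belonging to a tied class decides
      as.character(y_train[o][as.character(y_train[o]) %in% winners][1L])
    }
  }
  factor(pred, levels = levels(y_train))
}

#' Grid search with stratified k-fold cross-validation
#'
#' Exhaustively evaluates every cell of the family's hyperparameter grid
#' by mean accuracy over `cv_folds` class-stratified folds and returns
#' the best cell (first in grid order on ties) together with the full CV
#' table.
#'
#' @param train A `feature_matrix` of training rows.
#' @param family Classifier family, see [default_grid()].
#' @param grid Optional replacement grid (`data.frame`, same columns as
#'   the default).
#' @param cv_folds Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment and any
#'   stochastic fits.
#' @param standardize Z-score features (fit on each training part);
#'   default `FALSE` -- the pipeline applies no scaling beyond the
#'   amplitude normalization of the raw signal.
#' @return List of class `grid_search_result` with `best_params`
#'   (one-row `data.frame`), `best_cv_accuracy`, `cv_table` (grid +
#'   `mean_accuracy` + per-fold columns) and bookkeeping fields.
#' @export
grid_search <- function(train, family = c("knn", "svm", "rf", "ann", "rbfn"),
                        grid = NULL, cv_folds = 5L, seed = 1L,
                        standardize = FALSE) {
  family <- match.arg(family)
  if (is.null(grid)) grid <- default_grid(family)
  xy <- fm_xy(train)
  folds <- stratified_folds(xy$y, k = cv_folds, seed = seed)
  acc <- matrix(NA_real_, nrow(grid), cv_folds)
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    for (ci in seq_len(nrow(grid))) {
      params <- as.list(grid[ci, , drop = FALSE])
      m <- fit_model(xy$X[tr, , drop = FALSE], droplevels(xy$y[tr]),
                     family, params, seed = seed, standardize = standardize)
      pr <- predict_model(m, xy$X[!tr, , drop = FALSE])
      acc[ci, f] <- mean(as.character(pr) == as.character(xy$y[!tr]))
    }
  }
  mean_acc <- rowMeans(acc)
  best <- which.max(mean_acc)   # first maximum in documented grid order
  cv_table <- cbind(grid, mean_accuracy = mean_acc,
                    stats::setNames(as.data.frame(acc),
                                    paste0("fold", seq_len(cv_folds))))
  structure(list(family = family, best_params = grid[best, , drop = FALSE],
                 best_cv_accuracy = mean_acc[best],
                 cv_table = cv_table, cv_folds = cv_folds, seed = seed,
                 standardize = standardize),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> %s, %d cells, %d-fold CV\n",
              x$family, nrow(x$cv_table), x$cv_folds))
  cat("best:", paste(names(x$best_params),
                     vapply(x$best_params, format, ""), sep = "=",
                     collapse = " "),
      sprintf(" (CV accuracy %.3f)\n", x$best_cv_accuracy))
  invisible(x)
}

#' Train the final model on the full training set
#'
#' Fits the chosen family with the selected hyperparameters on all
#' training rows; deterministic given `seed`.
#'
#' @param train A `feature_matrix`.
#' @param family Classifier family.
#' @param best_params One-row `data.frame` or named list of
#'   hyperparameters (e.g. `grid_search(...)$best_params`).
#' @param seed Integer seed.
#' @param standardize Z-score features (stored and re-applied at
#'   prediction time).
#' @return A fitted model handle of class `esb_model` carrying the
#'   feature names and configuration for auditing.
#' @export
train_final <- function(train, family, best_params, seed = 1L,
                        standardize = FALSE) {
  xy <- fm_xy(train)
  m <- fit_model(xy$X, xy$y, family, as.list(best_params), seed = seed,
                 standardize = standardize)
  m$feature_names <- feature_columns(train)
  m$meta <- attr(train, "meta")
  class(m) <- "esb_model"
  m
}

#' Evaluate a fitted model on held-out data
#'
#' Predicts the test rows and reports overall accuracy and the per-class
#' confusion matrix (rows = true class, columns = predicted). The
#' confusion-matrix entries sum to the test size and the accuracy equals
#' the trace over the total.
#'
#' @param model An `esb_model` from [train_final()].
#' @param test A `feature_matrix` whose feature columns match the
#'   training columns (checked; mismatch raises `esb_column_mismatch`).
#' @param cv An optional [grid_search()] result to embed in the report.
#' @return A list of class `evaluation_report`: `accuracy`, `confusion`,
#'   `n_test`, `best_params`, `family`, `feature_family`, `cv_accuracies`.
#' @export
evaluate_model <- function(model, test, cv = NULL) {
  cols <- feature_columns(test)
  if (!identical(cols, model$feature_names))
    esb_abort("esb_column_mismatch",
              "test feature columns do not match the training columns")
  xy <- fm_xy(test)
  pred <- predict_model(model, xy$X)
  lev <- model$classes
  conf <- table(true = factor(as.character(xy$y), levels = lev),
                predicted = factor(as.character(pred), levels = lev))
  structure(list(accuracy = mean(as.character(pred) == as.character(xy$y)),
                 confusion = conf, n_test = nrow(test),
                 family = model$family, best_params = model$params,
                 cv_accuracies = if (!is.null(cv)) cv$cv_table$mean_accuracy,
                 best_cv_accuracy = if (!is.null(cv)) cv$best_cv_accuracy,
                 predictions = pred),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: accuracy %.3f on %d test records\n",
              x$family, x$accuracy, x$n_test))
  cat("hyperparameters:",
      paste(names(x$best_params), vapply(x$best_params, format, ""),
            sep = "=", collapse = " "), "\n")
  print(x$confusion)
  invisible(x)
}

#' Serialize an evaluation report as structured text
#'
#' Key/value lines followed by a confusion-matrix block; the confusion
#' matrix is additionally written as CSV next to the report when `path`
#' is given.
#'
#' @param x An `evaluation_report`.
#' @param path Optional output path for the text report (a
#'   `*_confusion.csv` sibling file is written alongside).
#' @return Character vector of report lines, invisibly if written.
#' @export
format_report <- function(x, path = NULL) {
  lines <- c(sprintf("family: %s", x$family),
             sprintf("accuracy: %.6f", x$accuracy),
             sprintf("n_test: %d", x$n_test),
             sprintf("params: %s",
                     paste(names(x$best_params),
                           vapply(x$best_params, format, ""),
                           sep = "=", collapse = " ")),
             if (!is.null(x$best_cv_accuracy))
               sprintf("cv_accuracy: %.6f", x$best_cv_accuracy),
             "confusion (rows = true, cols = predicted):",
             utils::capture.output(print(x$confusion)))
  if (!is.null(path)) {
    writeLines(lines, path)
    conf_path <- sub("\\.[^.]*$", "", path)
    utils::write.csv(as.data.frame.matrix(x$confusion),
                     paste0(conf_path, "_confusion.csv"))
    return(invisible(lines))
  }
  lines
}
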