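test_that("the default split reproduces the 112/38 protocol deterministically", {
  fm <- frozen_feature_matrix()
  sp <- split_dataset(fm, split_spec(seed = 1))
  expect_equal(nrow(sp$train), 112)
  expect_equal(nrow(sp$test), 38)
  expect_equal(as.vector(table(sp$test$label)), c(12, 14, 12))
  sp2 <- split_dataset(fm, split_spec(seed = 1))
  expect_identical(rownames(sp$test), rownames(sp2$test))
  expect_length(intersect(rownames(sp$train), rownames(sp$test)), 0)
  expect_setequal(c(rownames(sp$train), rownames(sp$test)), rownames(fm))
  expect_error(split_dataset(fm[1:20, ], split_spec()),
               class = "esb_bad_argument")
})

test_that("cross-validation folds are class-stratified within one sample", {
  fm <- frozen_feature_matrix()
  folds <- stratified_folds(fm$label, k = 5, seed = 2)
  tab <- table(fm$label, folds)
  expect_true(all(abs(tab - 10) <= 1))
  expect_identical(folds, stratified_folds(fm$label, k = 5, seed = 2))
})

test_that("grids enumerate the documented cell counts", {
  expect_equal(nrow(default_grid("knn")), 48)   # 16 odd k x 3 distances
  expect_equal(nrow(default_grid("svm")), 108)  # 3 kernels x 6 gamma x 6 C
  expect_equal(nrow(default_grid("rf")), 8)
  expect_equal(default_grid("knn")$k[1:16], seq(1, 31, 2))
  expect_equal(sort(unique(default_grid("svm")$C)), 10^(0:5))
})

test_that("k-NN distances separate the synthetic clouds perfectly", {
  fm <- separable_clouds()
  sp <- split_dataset(fm, split_spec(c(AF = 5, CHF = 5, NSR = 5), seed = 3))
  gs <- grid_search(sp$train, "knn", cv_folds = 5, seed = 3)
  expect_equal(gs$best_cv_accuracy, 1.0)
  for (d in c("euclidean", "minkowski", "chebyshev")) {
    xy_tr <- sp$train[, 1:5]; xy_te <- sp$test[, 1:5]
    pred <- knn_predict(as.matrix(xy_tr), sp$train$label,
                        as.matrix(xy_te), k = 3, distance = d)
    expect_equal(mean(pred == sp$test$label), 1.0)
  }
})

test_that("each family reaches at least 0.95 on the separable fixture", {
  fm <- separable_clouds()
  sp <- split_dataset(fm, split_spec(c(AF = 5, CHF = 5, NSR = 5), seed = 4))
  for (fam in c("knn", "svm", "rf", "ann", "rbfn")) {
    gs <- grid_search(sp$train, fam, seed = 4)
    m <- train_final(sp$train, fam, gs$best_params, seed = 4)
    rep <- evaluate_model(m, sp$test)
    expect_gte(rep$accuracy, 0.95)
    if (fam %in% c("knn", "svm", "rf")) expect_equal(rep$accuracy, 1.0)
  }
})

test_that("1-NN memorizes its own training set", {
  fm <- separable_clouds()
  xy <- as.matrix(fm[, 1:5])
  pred <- knn_predict(xy, fm$label, xy, k = 1, distance = "euclidean")
  expect_equal(mean(pred == fm$label), 1.0)
})

test_that("random forest fits the separable fixture exactly", {
  fm <- separable_clouds()
  m <- train_final(fm, "rf", list(ntree = 150, criterion = "gini"), seed = 5)
  rep <- evaluate_model(m, fm)
  expect_equal(rep$accuracy, 1.0)
})

test_that("evaluation reports conserve the confusion-matrix bookkeeping", {
  fm <- frozen_feature_matrix()
  sp <- split_dataset(fm, split_spec(seed = 1))
  m <- train_final(sp$train, "knn", list(k = 5, distance = "euclidean"),
                   seed = 1)
  rep <- evaluate_model(m, sp$test)
  expect_equal(sum(rep$confusion), 38)
  expect_equal(unname(rowSums(rep$confusion)), c(12, 14, 12))
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / 38)
  # feature-column mismatch is refused
  expect_error(evaluate_model(m, subset_features(sp$test, "hjorth")),
               class = "esb_column_mismatch")
})

test_that("a majority-class predictor scores 14/38 on the default composition", {
  fm <- frozen_feature_matrix()
  sp <- split_dataset(fm, split_spec(seed = 1))
  # a 1-NN trained on a single CHF row always predicts CHF
  one <- sp$train[sp$train$label == "CHF", ][1, , drop = FALSE]
  class(one) <- class(sp$train)
  m <- train_final(one, "knn", list(k = 1, distance = "euclidean"), seed = 1)
  m$classes <- levels(sp$train$label)
  rep <- evaluate_model(m, sp$test)
  expect_equal(rep$accuracy, 14 / 38)
})

test_that("grid search is reproducible with fixed seeds", {
  fm <- separable_clouds(n_per_class = 12, seed = 9)
  gs1 <- grid_search(fm, "knn", seed = 11)
  gs2 <- grid_search(fm, "knn", seed = 11)
  expect_identical(gs1$best_params, gs2$best_params)
  expect_identical(gs1$cv_table$mean_accuracy, gs2$cv_table$mean_accuracy)
})
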