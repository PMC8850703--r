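#' Single-hidden-layer neural network (ReLU / softmax, Adam)
#'
#' A small fully-connected classifier: input -> `hidden` ReLU units ->
#' softmax output over the classes, trained by minimizing categorical
#' cross-entropy with the Adam optimizer (learning rate `lr`, default
#' 0.001) over `epochs` passes of shuffled mini-batches. Weight
#' initialization (He-scaled normal) and the per-epoch shuffles are
#' driven by `seed`, so training is fully deterministic.
#'
#' @param X Numeric training matrix (rows = records).
#' @param y Factor of class labels.
#' @param hidden Hidden-layer width (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs Training epochs (default 200).
#' @param batch Mini-batch size (default 16).
#' @param seed Integer seed.
#' @return A fitted `esb_mlp` handle for [mlp_predict()].
#' @export
mlp_train <- function(X, y, hidden = 32L, lr = 1e-3, epochs = 200L,
                      batch = 16L, seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  n <- nrow(X); d <- ncol(X); k <- nlevels(y)
  Y <- matrix(0, n, k); Y[cbind(seq_len(n), as.integer(y))] <- 1
  withr::with_seed(seed, {
    W1 <- matrix(stats::rnorm(d * hidden, 0, sqrt(2 / d)), d, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(stats::rnorm(hidden * k, 0, sqrt(2 / hidden)), hidden, k)
    b2 <- numeric(k)
    adam <- lapply(list(W1, b1, W2, b2), function(p) list(m = 0 * p, v = 0 * p))
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0L
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      for (start in seq(1L, n, by = batch)) {
        idx <- perm[start:min(start + batch - 1L, n)]
        Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
        H <- pmax(Xb %*% W1 + rep(b1, each = length(idx)), 0)
        Z <- H %*% W2 + rep(b2, each = length(idx))
        Z <- Z - apply(Z, 1L, max)
        P <- exp(Z); P <- P / rowSums(P)
        dZ <- (P - Yb) / length(idx)
        gW2 <- crossprod(H, dZ); gb2 <- colSums(dZ)
        dH <- dZ %*% t(W2) * (H > 0)
        gW1 <- crossprod(Xb, dH); gb1 <- colSums(dH)
        t <- t + 1L
        grads <- list(gW1, gb1, gW2, gb2)
        pars <- list(W1, b1, W2, b2)
        for (j in 1:4) {
          adam[[j]]$m <- beta1 * adam[[j]]$m + (1 - beta1) * grads[[j]]
          adam[[j]]$v <- beta2 * adam[[j]]$v + (1 - beta2) * grads[[j]]^2
          mhat <- adam[[j]]$m / (1 - beta1^t)
          vhat <- adam[[j]]$v / (1 - beta2^t)
          pars[[j]] <- pars[[j]] - lr * mhat / (sqrt(vhat) + eps)
        }
        W1 <- pars[[1]]; b1 <- pars[[2]]; W2 <- pars[[3]]; b2 <- pars[[4]]
      }
    }
  })
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, classes = levels(y)),
            class = "esb_mlp")
}

#' @rdname mlp_train
#' @param model A fitted `esb_mlp`.
#' @param prob Return the softmax probability matrix instead of labels.
#' @export
mlp_predict <- function(model, X, prob = FALSE) {
  X <- as.matrix(X)
  H <- pmax(X %*% model$W1 + rep(model$b1, each = nrow(X)), 0)
  Z <- H %*% model$W2 + rep(model$b2, each = nrow(X))
  Z <- Z - apply(Z, 1L, max)
  P <- exp(Z); P <- P / rowSums(P)
  if (prob) {
    colnames(P) <- model$classes
    return(P)
  }
  factor(model$classes[max.col(P, ties.method = "first")],
         levels = model$classes)
}

#' Radial basis function network classifier
#'
#' One hidden layer of `centers` Gaussian radial-basis units whose
#' centers are initialized by seeded k-means on the training features and
#' whose common width is the mean nearest-center distance; a linear
#' output layer onto one-hot class targets is trained by RMSprop on the
#' mean-squared error (learning rate `lr`, default 0.001, 500 epochs).
#' Prediction takes the arg-max output unit.
#'
#' @param X Numeric training matrix.
#' @param y Factor of class labels.
#' @param centers Number of RBF units (default 32; capped at the number
#'   of distinct training rows).
#' @param lr RMSprop learning rate (default 1e-3).
#' @param epochs Training epochs (default 500).
#' @param batch Mini-batch size (default 16).
#' @param seed Integer seed (k-means starts, init, shuffles).
#' @return A fitted `esb_rbfn` handle for [rbfn_predict()].
#' @export
rbfn_train <- function(X, y, centers = 32L, lr = 1e-3, epochs = 500L,
                       batch = 16L, seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  n <- nrow(X); k <- nlevels(y)
  centers <- min(centers, nrow(unique(X)) - 1L)
  Y <- matrix(0, n, k); Y[cbind(seq_len(n), as.integer(y))] <- 1
  withr::with_seed(seed, {
    km <- stats::kmeans(X, centers = centers, nstart = 5L, iter.max = 100L)
    C <- km$centers
    dc <- as.matrix(stats::dist(C))
    diag(dc) <- Inf
    sigma <- mean(apply(dc, 1L, min))
    if (!is.finite(sigma) || sigma == 0) sigma <- 1
    Phi_all <- rbf_design(X, C, sigma)
    W <- matrix(stats::rnorm(ncol(Phi_all) * k, 0, 0.1), ncol(Phi_all), k)
    v <- 0 * W; rho <- 0.9; eps <- 1e-8
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      for (start in seq(1L, n, by = batch)) {
        idx <- perm[start:min(start + batch - 1L, n)]
        Pb <- Phi_all[idx, , drop = FALSE]
        err <- Pb %*% W - Y[idx, , drop = FALSE]
        g <- 2 * crossprod(Pb, err) / length(idx)
        v <- rho * v + (1 - rho) * g^2
        W <- W - lr * g / (sqrt(v) + eps)
      }
    }
  })
  structure(list(centers = C, sigma = sigma, W = W, classes = levels(y)),
            class = "esb_rbfn")
}

rbf_design <- function(X, C, sigma) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), `+`) - 2 * X %*% t(C)
  d2[d2 < 0] <- 0
  cbind(exp(-d2 / (2 * sigma^2)), 1)   # bias column
}

#' @rdname rbfn_train
#' @param model A fitted `esb_rbfn`.
#' @export
rbfn_predict <- function(model, X) {
  X <- as.matrix(X)
  out <- rbf_design(X, model$centers, model$sigma) %*% model$W
  factor(model$classes[max.col(out, ties.method = "first")],
         levels = model$classes)
}
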