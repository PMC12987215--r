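# Classifier implementations behind the benchmark: a CART decision tree and
# a bagged random forest (split search in C++), and a multilayer perceptron
# trained by minibatch Adam or SGD-with-momentum. Interfaces and defaults
# mirror the widely used scikit-learn estimators so published hyperparameter
# grids transfer verbatim.

resolve_mtry <- function(max_features, p) {
  if (is.null(max_features) || identical(max_features, "all")) return(p)
  if (is.numeric(max_features)) {
    if (max_features < 1) return(max(1L, as.integer(floor(max_features * p))))
    return(min(p, as.integer(max_features)))
  }
  switch(max_features,
         auto = ,  # deprecated alias: square root for classification
         sqrt = max(1L, as.integer(floor(sqrt(p)))),
         log2 = max(1L, as.integer(floor(log2(p)))),
         stop("unknown max_features: ", max_features))
}

as_xy <- function(x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("model matrices must be imputed before fitting")
  y <- as.integer(y)
  stopifnot(all(y %in% 1:6) || all(y >= 1))
  list(x = x, y = y)
}

#' Fit a CART decision tree classifier
#'
#' Binary recursive partitioning with Gini impurity and exact threshold
#' enumeration. `max_depth = NULL` grows until purity or the node-size
#' constraints bind.
#'
#' @param x numeric feature matrix (no missing values).
#' @param y integer class labels in `1..n_classes`.
#' @param max_depth,min_samples_split,min_samples_leaf usual CART controls.
#' @param max_features features considered per split: `"all"` (default),
#'   `"sqrt"`, `"log2"`, `"auto"` (alias of `"sqrt"`), or a count/fraction.
#' @param n_classes number of classes (defaults to `max(y)`).
#' @param seed RNG seed for feature subsampling.
#' @return object of class `cm_tree` with a [predict()] method
#'   (`type = "class"` or `"prob"`).
#' @export
fit_decision_tree <- function(x, y, max_depth = NULL, min_samples_split = 2,
                              min_samples_leaf = 1, max_features = "all",
                              n_classes = max(as.integer(y)), seed = 1L) {
  d <- as_xy(x, y)
  mtry <- resolve_mtry(max_features, ncol(d$x))
  tree <- fit_cart_cpp(d$x, d$y - 1L, as.integer(n_classes),
                       if (is.null(max_depth)) -1L else as.integer(max_depth),
                       as.integer(min_samples_split),
                       as.integer(min_samples_leaf), mtry, as.integer(seed),
                       seq_len(nrow(d$x)) - 1L)
  structure(list(tree = tree, n_classes = as.integer(n_classes)),
            class = "cm_tree")
}

#' @export
predict.cm_tree <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  P <- predict_cart_cpp(object$tree, X)
  if (type == "prob") P else max.col(P, ties.method = "first")
}

#' Fit a random forest classifier
#'
#' Bagged CART trees with per-split random feature subsets; predictions
#' average the leaf class distributions across trees.
#'
#' @inheritParams fit_decision_tree
#' @param n_estimators number of trees.
#' @param max_features default `"sqrt"`; `"auto"` maps to `"sqrt"`.
#' @return object of class `cm_forest` with a [predict()] method.
#' @export
fit_random_forest <- function(x, y, n_estimators = 100, max_depth = NULL,
                              min_samples_split = 2, min_samples_leaf = 1,
                              max_features = "sqrt",
                              n_classes = max(as.integer(y)), seed = 1L) {
  d <- as_xy(x, y)
  mtry <- resolve_mtry(max_features, ncol(d$x))
  trees <- fit_forest_cpp(d$x, d$y - 1L, as.integer(n_classes),
                          as.integer(n_estimators),
                          if (is.null(max_depth)) -1L
                          else as.integer(max_depth),
                          as.integer(min_samples_split),
                          as.integer(min_samples_leaf), mtry,
                          as.integer(seed))
  structure(list(trees = trees, n_classes = as.integer(n_classes)),
            class = "cm_forest")
}

#' @export
predict.cm_forest <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  P <- predict_forest_cpp(object$trees, X, object$n_classes)
  if (type == "prob") P else max.col(P, ties.method = "first")
}

mlp_activation <- function(name) {
  switch(name,
         relu = list(f = function(z) pmax(z, 0),
                     df = function(a) (a > 0) * 1),
         tanh = list(f = tanh, df = function(a) 1 - a^2),
         stop("unknown activation: ", name))
}

#' Fit a multilayer perceptron classifier
#'
#' Fully connected feedforward network with softmax output and cross-entropy
#' loss, trained by minibatch Adam or SGD with Nesterov momentum. Inputs are
#' expected pre-standardised (see [preprocess_splits()]); there is no early
#' stopping, the optimiser runs for `max_iter` epochs.
#'
#' @inheritParams fit_decision_tree
#' @param hidden_layer_sizes integer vector of hidden widths, e.g.
#'   `c(100, 50)`.
#' @param activation `"relu"` or `"tanh"`.
#' @param solver `"adam"` or `"sgd"`.
#' @param learning_rate `"constant"` or `"adaptive"` (divide the step by 5
#'   after two epochs without loss improvement).
#' @param learning_rate_init initial step size.
#' @param alpha L2 penalty.
#' @param batch_size minibatch size (capped at `n`).
#' @param max_iter training epochs.
#' @return object of class `cm_mlp` with a [predict()] method.
#' @export
fit_mlp <- function(x, y, hidden_layer_sizes = c(100, 50),
                    activation = c("relu", "tanh"),
                    solver = c("adam", "sgd"),
                    learning_rate = c("constant", "adaptive"),
                    learning_rate_init = 1e-3, alpha = 1e-4,
                    batch_size = 200, max_iter = 1000,
                    n_classes = max(as.integer(y)), seed = 1L) {
  activation <- match.arg(activation)
  solver <- match.arg(solver)
  learning_rate <- match.arg(learning_rate)
  d <- as_xy(x, y)
  n <- nrow(d$x); p <- ncol(d$x); K <- as.integer(n_classes)
  sizes <- c(p, as.integer(hidden_layer_sizes), K)
  L <- length(sizes) - 1L
  act <- mlp_activation(activation)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), d$y)] <- 1
  batch_size <- min(batch_size, n)

  with_seed(seed, {
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -lim, lim),
                       sizes[l], sizes[l + 1])
      b[[l]] <- numeric(sizes[l + 1])
    }
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    velW <- lapply(W, function(w) w * 0); velb <- lapply(b, function(x) x * 0)
    lr <- learning_rate_init
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; momentum <- 0.9
    t_adam <- 0L
    best_loss <- Inf; stall <- 0L

    for (epoch in seq_len(max_iter)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      for (start in seq(1, n, by = batch_size)) {
        rows <- ord[start:min(start + batch_size - 1L, n)]
        nb <- length(rows)
        A <- vector("list", L + 1L)
        A[[1]] <- d$x[rows, , drop = FALSE]
        for (l in seq_len(L)) {
          Z <- A[[l]] %*% W[[l]]
          Z <- sweep(Z, 2, b[[l]], `+`)
          A[[l + 1]] <- if (l < L) act$f(Z) else {
            Zs <- Z - apply(Z, 1, max)
            E <- exp(Zs)
            E / rowSums(E)
          }
        }
        P <- A[[L + 1]]
        Yb <- Y[rows, , drop = FALSE]
        epoch_loss <- epoch_loss -
          sum(Yb * log(pmax(P, 1e-12))) / nb * (nb / n)
        dZ <- (P - Yb) / nb
        for (l in rev(seq_len(L))) {
          gW <- crossprod(A[[l]], dZ) + (alpha / nb) * W[[l]]
          gb <- colSums(dZ)
          if (l > 1) dZ <- (dZ %*% t(W[[l]])) * act$df(A[[l]])
          if (solver == "adam") {
            t_adam <- t_adam + 1L
            mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
            vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
            mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
            vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
            c1 <- 1 - beta1^t_adam; c2 <- 1 - beta2^t_adam
            W[[l]] <- W[[l]] - lr * (mW[[l]] / c1) /
              (sqrt(vW[[l]] / c2) + eps)
            b[[l]] <- b[[l]] - lr * (mb[[l]] / c1) /
              (sqrt(vb[[l]] / c2) + eps)
          } else {
            velW[[l]] <- momentum * velW[[l]] - lr * gW
            velb[[l]] <- momentum * velb[[l]] - lr * gb
            W[[l]] <- W[[l]] + momentum * velW[[l]] - lr * gW  # Nesterov
            b[[l]] <- b[[l]] + momentum * velb[[l]] - lr * gb
          }
        }
      }
      if (learning_rate == "adaptive") {
        if (epoch_loss > best_loss - 1e-4) stall <- stall + 1L else stall <- 0L
        if (stall >= 2L) {
          lr <- max(lr / 5, 1e-6)
          stall <- 0L
        }
      }
      if (epoch_loss < best_loss) best_loss <- epoch_loss
    }
    structure(list(W = W, b = b, activation = activation,
                   n_classes = K, loss = best_loss),
              class = "cm_mlp")
  })
}

#' @export
predict.cm_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  A <- as.matrix(newdata)
  storage.mode(A) <- "double"
  act <- mlp_activation(object$activation)
  L <- length(object$W)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% object$W[[l]], 2, object$b[[l]], `+`)
    A <- if (l < L) act$f(Z) else {
      Zs <- Z - apply(Z, 1, max)
      E <- exp(Zs)
      E / rowSums(E)
    }
  }
  if (type == "prob") A else max.col(A, ties.method = "first")
}
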