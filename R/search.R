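# Hyperparameter search spaces and the canonical high/low-performance
# configurations, plus randomized / exhaustive cross-validated search with
# full fit accounting (every fit is logged, so the planned candidate x fold
# counts are auditable: DT 100 x 3 = 300, RF 960 x 3 = 2880,
# MLP 48 x 3 = 144).

#' Hyperparameter search space for one model family
#'
#' The published grids: the decision tree draws 100 random candidates from
#' `max_depth` 3..20, `min_samples_split` 2..20, `min_samples_leaf` 1..20;
#' the random forest grid crosses `n_estimators` \{50,100,150,200\},
#' `max_depth` \{3,5,10,15,20\}, `min_samples_split` \{2,5,10,15\},
#' `min_samples_leaf` \{1,2,5,10\}, `max_features` \{auto,sqrt,log2\}
#' (4x5x4x4x3 = 960); the MLP grid crosses six architectures with
#' \{relu,tanh\} x \{adam,sgd\} x \{constant,adaptive\} (6x2x2x2 = 48). All
#' use 3-fold cross-validation.
#'
#' @param model `"DT"`, `"RF"` or `"MLP"`.
#' @return object of class `search_space` with fields `model`, `grid`,
#'   `search_type` (`"randomized"`/`"exhaustive"`), `n_iter` (DT only) and
#'   `cv_folds`.
#' @export
search_space <- function(model = c("DT", "RF", "MLP")) {
  model <- match.arg(model)
  sp <- switch(model,
    DT = list(grid = list(max_depth = 3:20, min_samples_split = 2:20,
                          min_samples_leaf = 1:20),
              search_type = "randomized", n_iter = 100L),
    RF = list(grid = list(n_estimators = c(50, 100, 150, 200),
                          max_depth = c(3, 5, 10, 15, 20),
                          min_samples_split = c(2, 5, 10, 15),
                          min_samples_leaf = c(1, 2, 5, 10),
                          max_features = c("auto", "sqrt", "log2")),
              search_type = "exhaustive", n_iter = NA_integer_),
    MLP = list(grid = list(hidden_layer_sizes = list(4L, c(100L, 50L),
                             c(100L, 100L, 50L), c(200L, 100L, 50L),
                             c(200L, 200L, 100L, 50L),
                             c(300L, 200L, 100L, 50L)),
                           activation = c("relu", "tanh"),
                           solver = c("adam", "sgd"),
                           learning_rate = c("constant", "adaptive")),
               search_type = "exhaustive", n_iter = NA_integer_))
  structure(c(list(model = model), sp, list(cv_folds = 3L)),
            class = "search_space")
}

#' Number of grid combinations in a search space
#'
#' @param space a [search_space()].
#' @return integer; for the randomized DT search this is the grid size, not
#'   the number of candidates drawn (`space$n_iter`).
#' @export
n_combinations <- function(space) {
  prod(vapply(space$grid, length, 0L))
}

#' Canonical high/low-performance model configurations
#'
#' The six benchmark configurations. High tier: DT
#' (min_samples_split 3, min_samples_leaf 1, max_depth 19); RF
#' (100 trees, max_depth 10, max_features auto, min_samples_leaf 1,
#' min_samples_split 2); MLP (relu, hidden (100, 50), constant learning
#' rate, adam). Low tier: DT (20, 18, 3); RF (100 trees, max_depth 3,
#' max_features log2, min_samples_leaf 10, min_samples_split 2); MLP (relu,
#' hidden (4), constant, sgd). Both RF tiers use 100 trees, inside the
#' published 50--100 / 50--200 ranges, so tier contrasts isolate the depth,
#' leaf and feature settings.
#'
#' @param model `"DT"`, `"RF"` or `"MLP"`.
#' @param tier `"high"` or `"low"`.
#' @return object of class `model_config` with `model`, `params`, `tier`.
#' @export
model_config <- function(model = c("DT", "RF", "MLP"),
                         tier = c("high", "low")) {
  model <- match.arg(model)
  tier <- match.arg(tier)
  params <- switch(model,
    DT = if (tier == "high") {
      list(min_samples_split = 3, min_samples_leaf = 1, max_depth = 19)
    } else {
      list(min_samples_split = 20, min_samples_leaf = 18, max_depth = 3)
    },
    RF = if (tier == "high") {
      list(n_estimators = 100, max_depth = 10, max_features = "auto",
           min_samples_leaf = 1, min_samples_split = 2)
    } else {
      list(n_estimators = 100, max_depth = 3, max_features = "log2",
           min_samples_leaf = 10, min_samples_split = 2)
    },
    MLP = if (tier == "high") {
      list(activation = "relu", hidden_layer_sizes = c(100L, 50L),
           learning_rate = "constant", solver = "adam")
    } else {
      list(activation = "relu", hidden_layer_sizes = 4L,
           learning_rate = "constant", solver = "sgd")
    })
  structure(list(model = model, params = params, tier = tier),
            class = "model_config")
}

# Fit one model family with a named parameter list.
fit_model <- function(model, params, x, y, seed, n_classes = 6L,
                      overrides = list()) {
  params <- modifyList(params, overrides)
  if (is.null(params$n_classes)) params$n_classes <- n_classes
  args <- c(list(x = x, y = y, seed = seed), params)
  switch(model,
         DT = do.call(fit_decision_tree, args),
         RF = do.call(fit_random_forest, args),
         MLP = do.call(fit_mlp, args),
         stop("unknown model: ", model))
}

# Stratified k-fold assignment (fold id per row).
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(derive_seed(seed, "cvfolds"), {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Enumerate grid candidates as a list of named parameter lists.
grid_candidates <- function(grid) {
  idx <- expand.grid(lapply(grid, seq_along), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(idx)), function(i) {
    out <- lapply(names(grid), function(nm) grid[[nm]][[idx[i, nm]]])
    names(out) <- names(grid)
    out
  })
}

#' Cross-validated hyperparameter search
#'
#' Runs the planned search on the supplied data (conventionally the training
#' plus validation rows): randomized sampling of `n_iter` candidates for the
#' decision tree, the exhaustive grid for forest and MLP, each scored by
#' stratified `cv_folds`-fold cross-validated accuracy. Missing values are
#' imputed (and, for the MLP, features standardised) inside each fold from
#' that fold's training rows only. Every individual fit is logged; the log
#' has exactly `candidates x cv_folds` rows.
#'
#' @param space a [search_space()].
#' @param x feature matrix (may contain `NA`).
#' @param y integer labels 1..6.
#' @param seed search seed (candidate sampling, fold assignment, model fits).
#' @param fit_overrides named list overriding fit arguments for every
#'   candidate (e.g. `list(max_iter = 30)` to shorten MLP training when only
#'   the search accounting matters).
#' @return list with `best` (a `model_config` carrying the winning
#'   parameters), `log` (data.frame, one row per fit) and `scores`
#'   (per-candidate mean CV accuracy).
#' @export
run_search <- function(space, x, y, seed = 1L, fit_overrides = list()) {
  stopifnot(inherits(space, "search_space"))
  if (!length(space$grid)) stop("empty search grid")
  x <- as.matrix(x)
  y <- as.integer(y)

  candidates <- if (space$search_type == "randomized") {
    sizes <- vapply(space$grid, length, 0L)
    total <- prod(sizes)
    with_seed(derive_seed(seed, "randsearch"), {
      picks <- sample.int(total, space$n_iter)
      lapply(picks, function(kk) {
        k0 <- kk - 1L
        out <- vector("list", length(sizes))
        names(out) <- names(space$grid)
        for (j in seq_along(sizes)) {
          out[[j]] <- space$grid[[j]][[(k0 %% sizes[j]) + 1L]]
          k0 <- k0 %/% sizes[j]
        }
        out
      })
    })
  } else {
    grid_candidates(space$grid)
  }

  fold <- stratified_folds(y, space$cv_folds, seed)
  log_rows <- vector("list", length(candidates) * space$cv_folds)
  scores <- numeric(length(candidates))
  li <- 0L
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    accs <- numeric(space$cv_folds)
    for (f in seq_len(space$cv_folds)) {
      tr <- fold != f
      xtr <- x[tr, , drop = FALSE]; xte <- x[!tr, , drop = FALSE]
      mu <- colMeans(xtr, na.rm = TRUE)
      for (j in seq_len(ncol(xtr))) {
        xtr[is.na(xtr[, j]), j] <- mu[j]
        xte[is.na(xte[, j]), j] <- mu[j]
      }
      if (space$model == "MLP") {
        ctr <- colMeans(xtr); scl <- apply(xtr, 2, sd); scl[scl == 0] <- 1
        xtr <- sweep(sweep(xtr, 2, ctr), 2, scl, `/`)
        xte <- sweep(sweep(xte, 2, ctr), 2, scl, `/`)
      }
      t0 <- proc.time()[["elapsed"]]
      fit <- fit_model(space$model, cand, xtr, y[tr],
                       seed = derive_seed(seed, "searchfit", li),
                       overrides = fit_overrides)
      fit_s <- proc.time()[["elapsed"]] - t0
      accs[f] <- mean(predict(fit, xte) == y[!tr])
      li <- li + 1L
      log_rows[[li]] <- data.frame(
        candidate = ci, fold = f,
        params = paste(names(cand),
                       vapply(cand, function(v) paste(v, collapse = "x"), ""),
                       sep = "=", collapse = ";"),
        accuracy = accs[f], fit_seconds = fit_s)
    }
    scores[ci] <- mean(accs)
  }
  best_i <- which.max(scores)
  best <- structure(list(model = space$model, params = candidates[[best_i]],
                         tier = "searched"), class = "model_config")
  list(best = best, log = do.call(rbind, log_rows), scores = scores)
}
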