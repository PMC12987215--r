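test_that("split sizes, stratification and grouping contracts hold", {
  tab <- default_features()
  sp <- split_dataset(tab, split_spec("60-20-20", seed = 3))
  expect_equal(as.vector(table(sp$split)[c("train", "validation", "test")]),
               c(2160L, 720L, 720L))
  # stratification: per-class proportions within one sample of global
  for (part in c("train", "validation", "test")) {
    n_part <- sum(sp$split == part)
    for (cl in 1:6) {
      got <- sum(sp$split == part & sp$label_code == cl)
      want <- sum(sp$label_code == cl) * n_part / nrow(sp)
      expect_lte(abs(got - want), 1)
    }
  }
  gp <- split_dataset(tab, split_spec("70-15-15", seed = 4,
                                      group_level = "base"))
  cross <- table(gp$base_id, gp$split)
  expect_true(all(rowSums(cross > 0) == 1L))
  expect_error(split_spec(c(0.5, 0.3, 0.3)), "summing to 1")
  expect_error(split_spec("80-10-10"), "preset")
})

test_that("preprocessing imputes with training means and standardises MLP", {
  tab <- default_features()[1:300, ]
  tab$split <- rep(c("train", "validation", "test"), each = 100)
  # hand-check: column with train values {10, 12} and a missing test cell
  tab$d001 <- NA
  tab$d001[tab$split == "train"] <- rep(c(10, 12), 50)
  prep <- preprocess_splits(tab, "DT")
  expect_equal(unique(prep$test$x[, "d001"]), 11)
  expect_false(anyNA(prep$train$x))
  # DT pass-through: non-missing values unchanged
  expect_equal(prep$train$x[, "d005"],
               tab$d005[tab$split == "train"], ignore_attr = TRUE)
  prep_mlp <- preprocess_splits(tab, "MLP")
  expect_equal(colMeans(prep_mlp$train$x), rep(0, 138),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(apply(prep_mlp$train$x, 2, sd), rep(1, 138),
               tolerance = 1e-9, ignore_attr = TRUE)
  tab$d002 <- NA_real_
  expect_error(preprocess_splits(tab, "DT"), "entirely missing")
})

test_that("search spaces carry the published cardinalities", {
  expect_equal(n_combinations(search_space("RF")), 960L)
  expect_equal(n_combinations(search_space("MLP")), 48L)
  dt <- search_space("DT")
  expect_equal(dt$n_iter, 100L)
  expect_equal(dt$search_type, "randomized")
  expect_equal(dt$cv_folds, 3L)
  expect_equal(n_combinations(dt), 18L * 19L * 20L)
})

test_that("randomized DT search logs candidates x folds fits", {
  tab <- small_features()
  set.seed(1)
  rows <- sort(sample(nrow(tab), 180))
  x <- as.matrix(tab[rows, grep("^d", names(tab))])
  y <- tab$label_code[rows]
  res <- run_search(search_space("DT"), x, y, seed = 2)
  expect_equal(nrow(res$log), 300L)
  expect_equal(length(unique(res$log$candidate)), 100L)
  expect_s3_class(res$best, "model_config")
  expect_true(all(c("max_depth", "min_samples_split",
                    "min_samples_leaf") %in% names(res$best$params)))
  expect_gte(max(res$scores), 0.8)
  # determinism of the search
  res2 <- run_search(search_space("DT"), x, y, seed = 2)
  expect_identical(res$log$params, res2$log$params)
  expect_equal(res$scores, res2$scores)
})

test_that("exhaustive search enumerates the full grid", {
  toy <- separable_toy(n_per = 24)
  space <- search_space("MLP")
  space$grid <- list(hidden_layer_sizes = list(4L, 8L),
                     activation = c("relu", "tanh"),
                     solver = "adam", learning_rate = "constant")
  res <- run_search(space, toy$x, toy$y, seed = 1,
                    fit_overrides = list(max_iter = 30, n_classes = 2))
  expect_equal(nrow(res$log), 4L * 3L)
  expect_error(run_search(structure(list(model = "DT", grid = list(),
                                         search_type = "exhaustive",
                                         cv_folds = 3L),
                                    class = "search_space"),
                          toy$x, toy$y), "empty")
})

test_that("train_eval reports coherent metrics, timing and errors", {
  tab <- small_features()
  tab <- split_dataset(tab, split_spec("60-20-20", seed = 5))
  res <- train_eval(model_config("DT", "high"), tab, seed = 1)
  expect_s3_class(res, "eval_result")
  expect_equal(sum(res$confusion), sum(tab$split == "test"))
  expect_equal(as.vector(rowSums(res$confusion)),
               as.vector(table(factor(tab$label_code[tab$split == "test"],
                                      levels = 1:6))))
  expect_true(all(res$timing >= 0))
  expect_gte(res$f1, 0.8)
  # a class absent from training errors by name
  broken <- tab
  broken$split[broken$label_code == 6 & broken$split == "train"] <- "test"
  expect_error(train_eval(model_config("DT", "high"), broken),
               "normocephaly")
})

test_that("experiment matrix runs 18 cells and report renders", {
  tab <- small_features()
  mat <- run_experiment_matrix(
    tab, seeds = 1L,
    fit_overrides = list(MLP = list(max_iter = 40)))
  expect_equal(nrow(mat$grid), 18L)
  expect_equal(length(mat$results), 18L)
  expect_setequal(unique(mat$grid$model), c("DT", "RF", "MLP"))
  expect_setequal(unique(mat$grid$tier), c("high", "low"))
  expect_setequal(unique(mat$grid$ratio),
                  c("60-20-20", "70-15-15", "90-5-5"))
  md <- report_markdown(mat)
  expect_true(any(grepl("^\\| 60-20-20 \\| DT \\| high", md)))
  expect_length(grep("^\\|", md), 2 * (18 + 2))
})

test_that("high tier beats low tier on most seeds", {
  tab <- small_features()
  wins <- 0L
  for (seed in 1:3) {
    sp <- split_dataset(tab, split_spec("60-20-20", seed = seed))
    for (model in c("DT", "RF")) {
      hi <- train_eval(model_config(model, "high"), sp, seed = seed)
      lo <- train_eval(model_config(model, "low"), sp, seed = seed)
      wins <- wins + (hi$f1 >= lo$f1)
    }
  }
  expect_gte(wins, 5L)  # majority of the 6 comparisons
})
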