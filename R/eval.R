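# Model evaluation: confusion matrix, per-class and macro/weighted
# precision/recall/F1, wall-clock fit/predict timing, and the full
# 3 models x 2 tiers x 3 split-ratio experiment matrix.

#' Classification metrics from truth and prediction
#'
#' @param truth,pred integer labels in `1..n_classes`.
#' @param n_classes number of classes (default 6).
#' @return list with `confusion` (n x n count matrix, rows = truth),
#'   `per_class` (data.frame precision/recall/f1/support), `precision`,
#'   `recall`, `f1` (macro averages) and `weighted` (support-weighted
#'   averages). Undefined ratios (empty class) count as 0.
#' @export
classification_metrics <- function(truth, pred, n_classes = 6L) {
  lev <- seq_len(n_classes)
  conf <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  conf <- unclass(conf)
  dimnames(conf) <- list(truth = lev, predicted = lev)
  tp <- diag(conf)
  support <- rowSums(conf)
  predn <- colSums(conf)
  prec <- ifelse(predn > 0, tp / predn, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- support / sum(support)
  list(confusion = conf,
       per_class = data.frame(class = lev, precision = prec, recall = rec,
                              f1 = f1, support = as.integer(support)),
       precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       weighted = c(precision = sum(w * prec), recall = sum(w * rec),
                    f1 = sum(w * f1)))
}

#' Train a configuration and evaluate it on the test partition
#'
#' Preprocesses the split table for the configuration's model family, fits
#' on the training partition, and reports macro precision/recall/F1, the
#' 6 x 6 confusion matrix and fit/predict wall-clock seconds measured on the
#' test partition.
#'
#' @param config a [model_config()].
#' @param table feature table with split tags (see [split_dataset()]).
#' @param seed fit seed.
#' @param fit_overrides named list overriding fit arguments (e.g.
#'   `list(max_iter = 300)`).
#' @return object of class `eval_result`: metrics plus `timing`
#'   (`fit`/`predict` seconds), `config` and partition sizes.
#' @export
train_eval <- function(config, table, seed = 1L, fit_overrides = list()) {
  stopifnot(inherits(config, "model_config"))
  prep <- preprocess_splits(table, config$model)
  if (length(unique(prep$train$y)) <
      length(unique(table$label_code))) {
    missing_cls <- setdiff(unique(table$label_code), unique(prep$train$y))
    stop("class absent from training partition: ",
         paste(label_name(missing_cls), collapse = ", "))
  }
  t0 <- proc.time()[["elapsed"]]
  fit <- fit_model(config$model, config$params, prep$train$x, prep$train$y,
                   seed = seed, overrides = fit_overrides)
  fit_s <- proc.time()[["elapsed"]] - t0
  t1 <- proc.time()[["elapsed"]]
  pred <- predict(fit, prep$test$x)
  pred_s <- proc.time()[["elapsed"]] - t1
  m <- classification_metrics(prep$test$y, pred)
  structure(c(m, list(timing = c(fit = fit_s, predict = pred_s),
                      config = config,
                      n = c(train = length(prep$train$y),
                            validation = length(prep$validation$y),
                            test = length(prep$test$y)))),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> %s (%s): macro P %.3f R %.3f F1 %.3f | fit %.2fs predict %.2fs\n",
    x$config$model, x$config$tier, x$precision, x$recall, x$f1,
    x$timing["fit"], x$timing["predict"]))
  invisible(x)
}

#' Run the full benchmark matrix
#'
#' Evaluates \{DT, RF, MLP\} x \{high, low tier\} x the three canonical split
#' ratios (60/20/20, 70/15/15, 90/5/5), 18 cells per seed, and returns both
#' the individual `eval_result`s and a tidy metrics/timing grid.
#'
#' @param table feature table (splits are assigned internally per ratio).
#' @param seeds integer vector; each seed re-splits and re-fits.
#' @param group_level forwarded to [split_spec()].
#' @param fit_overrides per-model named list of fit-argument overrides, e.g.
#'   `list(MLP = list(max_iter = 300))`.
#' @return list with `grid` (data.frame: seed, ratio, model, tier, metrics,
#'   timings) and `results` (named list of `eval_result`).
#' @export
run_experiment_matrix <- function(table, seeds = 1L,
                                  group_level = "sample",
                                  fit_overrides = list()) {
  stopifnot(length(unique(table$label_code)) == 6L)
  rows <- list()
  results <- list()
  for (seed in seeds) {
    for (ratio in names(SPLIT_PRESETS)) {
      tab <- split_dataset(table, split_spec(ratio, seed = seed,
                                             group_level = group_level))
      for (model in c("DT", "RF", "MLP")) {
        for (tier in c("high", "low")) {
          ov <- fit_overrides[[model]]
          if (is.null(ov)) ov <- list()
          res <- train_eval(model_config(model, tier), tab,
                            seed = derive_seed(seed, paste(model, tier)),
                            fit_overrides = ov)
          key <- sprintf("s%d_%s_%s_%s", seed, ratio, model, tier)
          results[[key]] <- res
          rows[[key]] <- data.frame(
            seed = seed, ratio = ratio, model = model, tier = tier,
            precision = res$precision, recall = res$recall, f1 = res$f1,
            fit_seconds = res$timing[["fit"]],
            predict_seconds = res$timing[["predict"]])
        }
      }
    }
  }
  list(grid = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       results = results)
}

#' Render the benchmark grid as a Markdown report
#'
#' One metrics table (precision/recall/F1 by split, model and tier, averaged
#' over seeds) and one timing table, mirroring the benchmark layout.
#'
#' @param matrix_result output of [run_experiment_matrix()].
#' @return character vector of Markdown lines.
#' @export
report_markdown <- function(matrix_result) {
  g <- matrix_result$grid
  agg <- aggregate(cbind(precision, recall, f1, fit_seconds,
                         predict_seconds) ~ ratio + model + tier,
                   data = g, FUN = mean)
  agg <- agg[order(agg$ratio, agg$model, agg$tier), ]
  lines <- c("# Benchmark report", "",
             "## Precision, recall and F1 by split and configuration", "",
             "| Train-Val-Test | Model | Tier | Precision | Recall | F1 |",
             "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(agg))) {
    lines <- c(lines, sprintf("| %s | %s | %s | %.2f | %.2f | %.2f |",
                              agg$ratio[i], agg$model[i], agg$tier[i],
                              agg$precision[i], agg$recall[i], agg$f1[i]))
  }
  lines <- c(lines, "", "## Computation time (seconds)", "",
             "| Train-Val-Test | Model | Tier | Fit | Predict |",
             "|---|---|---|---|---|")
  for (i in seq_len(nrow(agg))) {
    lines <- c(lines, sprintf("| %s | %s | %s | %.2f | %.3f |",
                              agg$ratio[i], agg$model[i], agg$tier[i],
                              agg$fit_seconds[i], agg$predict_seconds[i]))
  }
  lines
}
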