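# Train/validation/test splitting (stratified, optionally grouped by base
# cloud) and model-specific preprocessing: training-mean imputation for all
# models, plus standardisation for the MLP.

SPLIT_PRESETS <- list(`60-20-20` = c(0.60, 0.20, 0.20),
                      `70-15-15` = c(0.70, 0.15, 0.15),
                      `90-5-5`   = c(0.90, 0.05, 0.05))

#' Split specification
#'
#' @param ratios length-3 numeric (train, validation, test) summing to 1, or
#'   a preset name: `"60-20-20"`, `"70-15-15"`, `"90-5-5"`.
#' @param seed assignment seed.
#' @param stratified preserve per-class proportions in every partition.
#' @param group_level `"sample"` (augmented variants of one base may span
#'   partitions, as in a naive benchmark) or `"base"` (all variants of one
#'   base cloud stay together, the leakage-free alternative).
#' @return object of class `split_spec`.
#' @export
split_spec <- function(ratios = "60-20-20", seed = 1L, stratified = TRUE,
                       group_level = c("sample", "base")) {
  if (is.character(ratios)) {
    if (!ratios %in% names(SPLIT_PRESETS))
      stop("unknown split preset: ", ratios)
    ratios <- SPLIT_PRESETS[[ratios]]
  }
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-9)
    stop("split ratios must be a length-3 vector summing to 1")
  structure(list(ratios = ratios, seed = as.integer(seed),
                 stratified = isTRUE(stratified),
                 group_level = match.arg(group_level)),
            class = "split_spec")
}

# Largest-remainder allocation of n units to 3 partitions.
allocate_counts <- function(n, ratios) {
  target <- n * ratios
  base <- floor(target)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Assign train/validation/test tags to a feature table
#'
#' Disjoint exhaustive assignment into the three partitions. With
#' `stratified = TRUE` each class is allocated separately (largest-remainder
#' rounding, so partitions stay within one sample of the global proportion
#' per class). With `group_level = "base"` the allocation unit is the base
#' cloud, so no `base_id` appears in two partitions.
#'
#' @param table a feature table from [build_feature_table()].
#' @param spec a [split_spec()].
#' @return the table with its `split` column set to
#'   `"train"`/`"validation"`/`"test"`.
#' @export
split_dataset <- function(table, spec = split_spec()) {
  stopifnot(nrow(table) > 0, inherits(spec, "split_spec"))
  labels <- c("train", "validation", "test")
  unit <- if (spec$group_level == "base") table$base_id else table$cloud_id
  u <- unique(unit)
  # class of a unit = class of its rows (constant within a base)
  ucls <- table$label_code[match(u, unit)]
  strata <- if (spec$stratified) split(u, ucls) else list(u)
  assign_u <- character(0)
  names_u <- character(0)
  with_seed(derive_seed(spec$seed, "split"), {
    for (grp in strata) {
      grp <- sample(grp)
      counts <- allocate_counts(length(grp), spec$ratios)
      assign_u <- c(assign_u, rep(labels, times = counts))
      names_u <- c(names_u, grp)
    }
  })
  table$split <- assign_u[match(unit, names_u)]
  table
}

#' Preprocess a split feature table for one model family
#'
#' Missing descriptors are imputed with the training-partition column mean;
#' for the MLP the features are additionally centred and scaled to unit
#' variance using training statistics only. Trees and forests receive the
#' imputed, unscaled features.
#'
#' @param table a feature table with split tags assigned.
#' @param model `"DT"`, `"RF"` or `"MLP"`.
#' @return list with `train`, `validation`, `test` (each `list(x, y)`), the
#'   imputation `means`, and the `center`/`scale` vectors (MLP only).
#' @export
preprocess_splits <- function(table, model = c("DT", "RF", "MLP")) {
  model <- match.arg(model)
  if (!all(table$split %in% c("train", "validation", "test")))
    stop("split tags must be assigned before preprocessing")
  cols <- descriptor_columns(table)
  parts <- lapply(c(train = "train", validation = "validation",
                    test = "test"), function(s) {
    rows <- table$split == s
    list(x = as.matrix(table[rows, cols, drop = FALSE]),
         y = table$label_code[rows])
  })
  means <- colMeans(parts$train$x, na.rm = TRUE)
  if (anyNA(means))
    stop("descriptor column(s) entirely missing in training partition: ",
         paste(cols[is.na(means)], collapse = ", "))
  impute <- function(X) {
    for (j in seq_len(ncol(X))) {
      miss <- is.na(X[, j])
      if (any(miss)) X[miss, j] <- means[j]
    }
    X
  }
  parts <- lapply(parts, function(p) {
    p$x <- impute(p$x)
    p
  })
  ctr <- NULL; scl <- NULL
  if (model == "MLP") {
    ctr <- colMeans(parts$train$x)
    scl <- apply(parts$train$x, 2, sd)
    scl[scl == 0] <- 1
    parts <- lapply(parts, function(p) {
      p$x <- sweep(sweep(p$x, 2, ctr), 2, scl, `/`)
      p
    })
  }
  c(parts, list(means = means, center = ctr, scale = scl))
}
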