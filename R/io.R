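# On-disk interchange: the cloud CSV schema (one row per vertex), binary
# little-endian PLY export, feature-table CSV, and YAML run configuration.

#' Write head clouds to the cloud CSV schema
#'
#' One row per vertex of every present marker, columns `cloud_id`, `base_id`,
#' `class_label`, `marker_slot`, `role`, `vertex_index` (0-3), `x_mm`,
#' `y_mm`, `z_mm`. Comma separator, dot decimal, UTF-8, mandatory header.
#'
#' @param clouds a `head_cloud` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cloud_csv <- function(clouds, path) {
  if (inherits(clouds, "head_cloud")) clouds <- list(clouds)
  rows <- lapply(clouds, function(cl) {
    slots <- which(cl$present)
    vr <- unlist(lapply(slots, vertex_rows))
    data.frame(cloud_id = cl$cloud_id, base_id = cl$base_id,
               class_label = cl$class_label,
               marker_slot = rep(slots, each = 4L),
               role = rep(cl$role[slots], each = 4L),
               vertex_index = rep(0:3, length(slots)),
               x_mm = cl$vertices[vr, 1], y_mm = cl$vertices[vr, 2],
               z_mm = cl$vertices[vr, 3])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read head clouds from the cloud CSV schema
#'
#' Validates on load: marker counts (131 minimum, reference stickers
#' present), exactly 4 vertices per present marker, finite coordinates.
#'
#' @param path CSV file written by [write_cloud_csv()].
#' @return list of `head_cloud` objects.
#' @export
read_cloud_csv <- function(path) {
  need <- c("cloud_id", "base_id", "class_label", "marker_slot", "role",
            "vertex_index", "x_mm", "y_mm", "z_mm")
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no clouds in ", path)
  if (!all(need %in% names(df)))
    stop("cloud CSV header must contain: ", paste(need, collapse = ", "))
  lapply(split(df, factor(df$cloud_id, levels = unique(df$cloud_id))),
         function(d) {
    present <- rep(FALSE, N_SLOTS)
    V <- matrix(NA_real_, 4L * N_SLOTS, 3L)
    for (s in unique(d$marker_slot)) {
      rows <- d[d$marker_slot == s, ]
      if (nrow(rows) != 4L)
        stop("marker slot ", s, " of cloud ", d$cloud_id[1], " has ",
             nrow(rows), " vertices, expected 4 (line ",
             which(df$cloud_id == d$cloud_id[1] &
                     df$marker_slot == s)[1] + 1L, ")")
      rows <- rows[order(rows$vertex_index), ]
      V[vertex_rows(s), ] <- as.matrix(rows[, c("x_mm", "y_mm", "z_mm")])
      present[s] <- TRUE
    }
    validate_head_cloud(new_head_cloud(d$cloud_id[1], d$base_id[1],
                                       d$class_label[1], present, V))
  }) |> unname()
}

#' Export a cloud as binary little-endian PLY
#'
#' Standard PLY with per-vertex float32 x/y/z and a uchar RGB colour derived
#' from the marker slot, 4 vertices per present marker (552 for a complete
#' cloud). Readable by common point-cloud viewers.
#'
#' @param cloud a `head_cloud`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path) {
  stopifnot(inherits(cloud, "head_cloud"))
  slots <- which(cloud$present)
  vr <- unlist(lapply(slots, vertex_rows))
  V <- cloud$vertices[vr, , drop = FALSE]
  n <- nrow(V)
  header <- c("ply", "format binary_little_endian 1.0",
              sprintf("comment craniomorph cloud %s", cloud$cloud_id),
              sprintf("element vertex %d", n),
              "property float x", "property float y", "property float z",
              "property uchar red", "property uchar green",
              "property uchar blue", "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  slot4 <- rep(slots, each = 4L)
  col <- cbind((slot4 * 53L) %% 256L, (slot4 * 101L) %% 256L,
               (slot4 * 197L) %% 256L)
  for (i in seq_len(n)) {
    writeBin(as.numeric(V[i, ]), con, size = 4, endian = "little")
    writeBin(as.raw(col[i, ]), con)
  }
  invisible(path)
}

#' Read a PLY written by [write_ply()]
#'
#' Minimal reader for the package's own binary little-endian layout; used
#' for round-trip checks.
#'
#' @param path PLY file.
#' @return numeric matrix of vertex coordinates (n x 3, float32 precision).
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  n <- NA_integer_
  repeat {
    line <- readLines(con, 1)
    if (grepl("^element vertex", line))
      n <- as.integer(sub("element vertex ", "", line))
    if (identical(line, "end_header")) break
  }
  if (is.na(n)) stop("no vertex element in PLY header")
  V <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    V[i, ] <- readBin(con, "numeric", 3, size = 4, endian = "little")
    readBin(con, "raw", 3)
  }
  V
}

#' Write / read a feature table CSV
#'
#' Columns `cloud_id`, `base_id`, `label_code`, `split`, `d001`..`d138`;
#' empty cells mark missing descriptors.
#'
#' @param table a feature table.
#' @param path CSV file.
#' @return `path` / the feature table.
#' @export
write_feature_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Run configuration for the end-to-end pipeline
#'
#' One global seed deterministically derives every stage seed
#' (cohort, scaling, noise, splits, model fits), so a single integer
#' reproduces the whole run.
#'
#' @param out_dir output directory.
#' @param seed global seed.
#' @param plan,scale,noise optional [cohort_plan()], [scale_plan()],
#'   [noise_spec()]; defaults are derived from `seed`.
#' @param benchmark_seeds seeds for the experiment matrix.
#' @param fit_overrides forwarded to [run_experiment_matrix()].
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, plan = NULL, scale = NULL,
                       noise = NULL, benchmark_seeds = NULL,
                       fit_overrides = list()) {
  if (is.null(plan)) plan <- cohort_plan(seed = derive_seed(seed, "cohort"))
  if (is.null(scale)) scale <- scale_plan(seed = derive_seed(seed, "scale"))
  if (is.null(noise)) noise <- noise_spec(seed = derive_seed(seed, "noise"))
  if (is.null(benchmark_seeds)) benchmark_seeds <- derive_seed(seed, "bench")
  structure(list(out_dir = out_dir, seed = as.integer(seed), plan = plan,
                 scale = scale, noise = noise,
                 benchmark_seeds = benchmark_seeds,
                 fit_overrides = fit_overrides),
            class = "run_config")
}

#' Build a run configuration from a YAML file
#'
#' Recognised top-level keys: `out_dir`, `seed`, `scale` (fields of
#' [scale_plan()]), `noise` (fields of [noise_spec()]), `benchmark_seeds`.
#' Missing keys fall back to the seed-derived defaults.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$out_dir)) stop("configuration must set out_dir")
  seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
  run_config(
    out_dir = y$out_dir, seed = seed,
    scale = if (!is.null(y$scale)) do.call(scale_plan, y$scale),
    noise = if (!is.null(y$noise)) do.call(noise_spec, y$noise),
    benchmark_seeds = y$benchmark_seeds)
}

#' Execute the full pipeline: generate, augment, features, train, report
#'
#' Writes the base-cohort CSV, the augmentation manifest, the feature-table
#' CSV, the benchmark grid (CSV + JSON) and a Markdown report under
#' `config$out_dir`. Rerunning with an identical configuration reproduces
#' identical feature tables and metrics.
#'
#' @param config a [run_config()].
#' @return list with `bases`, `augmented` counts, the feature `table` and the
#'   benchmark `matrix`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  bases <- stage("generate", generate_cohort(config$plan))
  write_cloud_csv(bases, file.path(config$out_dir, "base_cohort.csv"))
  aug <- stage("augment",
               augment_cohort(bases, config$scale, config$noise))
  manifest <- do.call(rbind, lapply(aug, function(cl)
    data.frame(cloud_id = cl$cloud_id, base_id = cl$provenance$base_id,
               factor = cl$provenance$factor, mode = cl$provenance$mode,
               noise_seed = cl$provenance$noise_seed)))
  write.csv(manifest, file.path(config$out_dir, "augmentation_manifest.csv"),
            row.names = FALSE)
  table <- stage("features", build_feature_table(aug))
  write_feature_csv(table, file.path(config$out_dir, "features.csv"))
  mat <- stage("train",
               run_experiment_matrix(table, seeds = config$benchmark_seeds,
                                     fit_overrides = config$fit_overrides))
  write.csv(mat$grid, file.path(config$out_dir, "benchmark_grid.csv"),
            row.names = FALSE)
  jsonlite::write_json(mat$grid, file.path(config$out_dir,
                                           "benchmark_grid.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  writeLines(report_markdown(mat), file.path(config$out_dir, "report.md"))
  writeLines(jsonlite::toJSON(list(global_seed = config$seed,
                                   package_version =
                                     as.character(utils::packageVersion(
                                       "craniomorph"))),
                              auto_unbox = TRUE),
             file.path(config$out_dir, "provenance.json"))
  invisible(list(bases = bases, augmented = length(aug), table = table,
                 matrix = mat))
}
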