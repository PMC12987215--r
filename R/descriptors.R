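# 138-slot mean origin-to-marker distance descriptors and labelled feature
# tables. Distances are measured in the sticker-defined canonical frame, so
# the frame is re-established from the (possibly perturbed) stickers of each
# cloud before extraction.

#' Extract the 138-slot distance descriptor vector of one cloud
#'
#' The cloud is canonicalised via [establish_frame()]; for each present
#' marker slot the descriptor is, by default, the mean of the four
#' origin-to-vertex Euclidean distances (`mode = "mean_of_distances"`). The
#' alternative reading, distance from the origin to the quad centroid, is
#' available as `mode = "distance_to_centroid"`; the two differ only by the
#' quad's curvature about the viewing ray. Absent slots are `NA`, never 0.
#'
#' @param cloud a `head_cloud` with at least 131 present markers and the 3
#'   reference stickers.
#' @param mode descriptor definition, see above.
#' @return list with `values` (length 138, mm, `NA` for absent slots),
#'   `presence` (logical 138), `label_code` (1..6), `cloud_id`, `base_id`;
#'   class `descriptor_vector`.
#' @examples
#' cl <- generate_base_cloud(shape_params("towering"), seed = 2)
#' d <- extract_descriptors(cl)
#' sum(d$presence); d$label_code  # 138, 3
#' @export
extract_descriptors <- function(cloud,
                                mode = c("mean_of_distances",
                                         "distance_to_centroid")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cloud, "head_cloud"))
  if (sum(cloud$present) < MIN_PRESENT)
    stop("cloud below marker minimum (131 present markers required)")
  cloud <- canonicalise_cloud(cloud)
  if (mode == "mean_of_distances") {
    dv <- sqrt(rowSums(cloud$vertices^2))
    vals <- (dv[seq(1, by = 4, length.out = N_SLOTS)] +
               dv[seq(2, by = 4, length.out = N_SLOTS)] +
               dv[seq(3, by = 4, length.out = N_SLOTS)] +
               dv[seq(4, by = 4, length.out = N_SLOTS)]) / 4
  } else {
    vals <- sqrt(rowSums(marker_centroids(cloud)^2))
  }
  vals[!cloud$present] <- NA_real_
  structure(list(values = unname(vals), presence = cloud$present,
                 label_code = label_code(cloud$class_label),
                 cloud_id = cloud$cloud_id, base_id = cloud$base_id),
            class = "descriptor_vector")
}

#' Assemble a labelled feature table from clouds
#'
#' One row per cloud: identifiers, numeric label code (1 brachycephaly,
#' 2 dolichocephaly, 3 towering, 4 trigonocephaly, 5 plagiocephaly,
#' 6 normocephaly), a `split` tag (initially `"unassigned"`) and descriptor
#' columns `d001`..`d138` with `NA` marking absent markers.
#'
#' @param clouds non-empty list of `head_cloud`s with unique `cloud_id`s.
#' @param mode forwarded to [extract_descriptors()].
#' @return `data.frame` with `nrow = length(clouds)` and 138 descriptor
#'   columns, class `feature_table`.
#' @export
build_feature_table <- function(clouds, mode = "mean_of_distances") {
  if (length(clouds) == 0) stop("no clouds supplied")
  ds <- lapply(clouds, extract_descriptors, mode = mode)
  ids <- vapply(ds, `[[`, "", "cloud_id")
  if (anyDuplicated(ids)) stop("duplicate cloud_id in input")
  X <- do.call(rbind, lapply(ds, `[[`, "values"))
  colnames(X) <- sprintf("d%03d", seq_len(N_SLOTS))
  out <- data.frame(cloud_id = ids,
                    base_id = vapply(ds, `[[`, "", "base_id"),
                    label_code = vapply(ds, `[[`, 0L, "label_code"),
                    split = "unassigned",
                    X, stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("feature_table", "data.frame")
  out
}

# Descriptor column accessor shared by the modelling code.
descriptor_columns <- function(table) {
  grep("^d[0-9]{3}$", names(table), value = TRUE)
}

#' Descriptor (present-marker) count per feature-table row
#'
#' @param table a feature table from [build_feature_table()].
#' @return integer vector of non-missing descriptor counts.
#' @export
descriptor_counts <- function(table) {
  cols <- descriptor_columns(table)
  as.integer(rowSums(!is.na(as.matrix(table[, cols]))))
}
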