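# Canonical reference frame from the three fiducial stickers, marker
# centroids and the preauricular distance. All coordinates in mm.

#' Centroid of one marker's quad
#'
#' Arithmetic mean of the marker's 4 vertices.
#'
#' @param cloud a `head_cloud`.
#' @param slot marker slot in 1..138.
#' @return length-3 numeric vector (mm).
#' @export
marker_centroid <- function(cloud, slot) {
  stopifnot(inherits(cloud, "head_cloud"), slot %in% seq_len(N_SLOTS))
  if (!cloud$present[slot]) stop("missing marker: slot ", slot)
  colMeans(cloud$vertices[vertex_rows(slot), , drop = FALSE])
}

#' Centroids of all 138 marker slots
#'
#' @param cloud a `head_cloud`.
#' @return 138 x 3 matrix; rows of absent markers are `NA`.
#' @export
marker_centroids <- function(cloud) {
  V <- cloud$vertices
  # mean of each consecutive block of 4 rows
  out <- (V[seq(1, by = 4, length.out = N_SLOTS), , drop = FALSE] +
            V[seq(2, by = 4, length.out = N_SLOTS), , drop = FALSE] +
            V[seq(3, by = 4, length.out = N_SLOTS), , drop = FALSE] +
            V[seq(4, by = 4, length.out = N_SLOTS), , drop = FALSE]) / 4
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

#' Establish the sticker-defined reference frame
#'
#' Origin at the midpoint of the left and right tragus sticker centroids;
#' lateral axis the unit left-to-right vector; anterior axis the front-sticker
#' direction Gram-Schmidt orthogonalised against the lateral axis; vertical
#' axis their cross product (right-handed).
#'
#' @param cloud a `head_cloud` with all 3 reference stickers present.
#' @return list with `origin` (length-3) and `rotation` (3 x 3 orthonormal,
#'   columns lateral/anterior/vertical), class `reference_frame`.
#' @export
establish_frame <- function(cloud) {
  stopifnot(inherits(cloud, "head_cloud"))
  refs <- c(SLOT_REF_FRONT, SLOT_REF_LEFT, SLOT_REF_RIGHT)
  if (!all(cloud$present[refs]))
    stop("frame undefined: reference sticker missing")
  f <- marker_centroid(cloud, SLOT_REF_FRONT)
  l <- marker_centroid(cloud, SLOT_REF_LEFT)
  r <- marker_centroid(cloud, SLOT_REF_RIGHT)
  origin <- (l + r) / 2
  ex <- r - l
  nx <- sqrt(sum(ex^2))
  if (nx < 1e-9) stop("degenerate frame: left and right stickers coincide")
  ex <- ex / nx
  fa <- f - origin
  ey <- fa - sum(fa * ex) * ex
  ny <- sqrt(sum(ey^2))
  if (ny < 1e-9) stop("degenerate frame: collinear reference stickers")
  ey <- ey / ny
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  structure(list(origin = origin, rotation = cbind(ex, ey, ez,
                                                   deparse.level = 0)),
            class = "reference_frame")
}

#' Express a cloud in its canonical sticker frame
#'
#' Applies the rigid transform of [establish_frame()] so that the tragus
#' midpoint becomes the origin and the sticker axes align with x/y/z.
#' Idempotent: a canonical cloud maps to itself.
#'
#' @param cloud a `head_cloud`.
#' @param frame optional precomputed `reference_frame`.
#' @return the transformed `head_cloud`.
#' @export
canonicalise_cloud <- function(cloud, frame = NULL) {
  if (is.null(frame)) frame <- establish_frame(cloud)
  V <- cloud$vertices
  ok <- stats::complete.cases(V)
  V[ok, ] <- sweep(V[ok, , drop = FALSE], 2, frame$origin) %*% frame$rotation
  cloud$vertices <- V
  cloud
}

# Apply an arbitrary rigid motion (rotation matrix R, translation t) to a
# cloud; used by tests and by consumers needing posed exports.
transform_cloud <- function(cloud, R = diag(3), t = c(0, 0, 0)) {
  V <- cloud$vertices
  ok <- stats::complete.cases(V)
  V[ok, ] <- V[ok, , drop = FALSE] %*% t(R) +
    matrix(t, sum(ok), 3, byrow = TRUE)
  cloud$vertices <- V
  cloud
}

#' Preauricular distance
#'
#' Euclidean distance between the centroids of the left and right tragus
#' stickers: the anatomical reference length that bounds admissible scaling
#' in the semi-synthetic augmentation.
#'
#' @param cloud a `head_cloud` with both tragus stickers present.
#' @return positive scalar (mm).
#' @export
preauricular_distance <- function(cloud) {
  l <- marker_centroid(cloud, SLOT_REF_LEFT)
  r <- marker_centroid(cloud, SLOT_REF_RIGHT)
  sqrt(sum((l - r)^2))
}
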