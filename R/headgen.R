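# Parametric generator of marker-cap head point clouds for the six cranial
# shape classes. The head surface is a superellipsoid in the canonical frame
# (x mediolateral, y anteroposterior, z vertical, mm), optionally deformed by
# a posterior diagonal shear (plagiocephaly) or an anterior linear taper
# (trigonocephaly). 135 coded cap markers are laid out quasi-uniformly above
# the tragus plane; 3 reference stickers sit at the two tragus points and on
# the anterior midline.

N_CAP <- 135L
N_SLOTS <- 138L
SLOT_REF_FRONT <- 136L
SLOT_REF_LEFT <- 137L
SLOT_REF_RIGHT <- 138L
MARKER_ROLES <- c(rep("cap", N_CAP), "ref_front", "ref_left", "ref_right")
MIN_PRESENT <- 131L
QUAD_HALF_MM <- 3.5  # coded markers are 7 mm squares in the tangent plane

# Evaluate user code under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Shape parameters for one cranial class
#'
#' Describes the analytic head surface: a superellipsoid with semi-axes
#' `length_ap` (anteroposterior, y), `width_ml` (mediolateral, x) and
#' `height` (vertical, z), exponent `squareness`, plus two class-specific
#' deformations: `shear_asym` shears the posterior half laterally
#' (plagiocephaly's parallelogram flattening) and `frontal_taper` narrows the
#' anterior 40 percent of the head linearly (trigonocephaly's pointed
#' forehead). `jitter_sd` is the per-cloud Gaussian standard deviation (mm)
#' applied to each semi-axis to create within-class variability.
#'
#' Class defaults are chosen so the normative cephalic-index ordering holds:
#' brachycephaly above 90, normocephaly in 75--90, dolichocephaly below 75,
#' towering strictly tallest relative to length.
#'
#' @param class_label one of `"brachycephaly"`, `"dolichocephaly"`,
#'   `"normocephaly"`, `"plagiocephaly"`, `"towering"`, `"trigonocephaly"`.
#' @param ... overrides for the class defaults (`length_ap`, `width_ml`,
#'   `height`, `squareness`, `shear_asym`, `frontal_taper`, `jitter_sd`).
#' @return an object of class `shape_params`.
#' @examples
#' p <- shape_params("brachycephaly")
#' p$width_ml / p$length_ap * 100 > 90
#' @export
shape_params <- function(class_label, ...) {
  defaults <- list(
    brachycephaly  = list(length_ap = 85,  width_ml = 82, height = 70,
                          shear_asym = 0,    frontal_taper = 0),
    dolichocephaly = list(length_ap = 105, width_ml = 72, height = 70,
                          shear_asym = 0,    frontal_taper = 0),
    normocephaly   = list(length_ap = 95,  width_ml = 78, height = 70,
                          shear_asym = 0,    frontal_taper = 0),
    plagiocephaly  = list(length_ap = 95,  width_ml = 78, height = 70,
                          shear_asym = 0.15, frontal_taper = 0),
    towering       = list(length_ap = 95,  width_ml = 78, height = 95,
                          shear_asym = 0,    frontal_taper = 0),
    trigonocephaly = list(length_ap = 95,  width_ml = 78, height = 70,
                          shear_asym = 0,    frontal_taper = 0.25)
  )
  class_label <- match.arg(class_label, names(defaults))
  p <- c(list(class_label = class_label), defaults[[class_label]],
         list(squareness = 2.5, jitter_sd = 2))
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown shape parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  if (p$length_ap <= 0 || p$width_ml <= 0 || p$height <= 0)
    stop("all semi-axes must be positive")
  if (p$jitter_sd < 0) stop("jitter_sd must be non-negative")
  if (p$squareness <= 0) stop("squareness must be positive")
  structure(p, class = "shape_params")
}

#' @export
print.shape_params <- function(x, ...) {
  cat(sprintf(
    "<shape_params> %s: AP %g x ML %g x H %g mm, exp %g, shear %g, taper %g, jitter sd %g\n",
    x$class_label, x$length_ap, x$width_ml, x$height, x$squareness,
    x$shear_asym, x$frontal_taper, x$jitter_sd))
  invisible(x)
}

# Radius multiplier placing unit directions on the superellipsoid
# |x/a|^n + |y/b|^n + |z/c|^n = 1.
superellipsoid_radius <- function(dirs, axes, n) {
  s <- (abs(dirs[, 1] / axes[1])^n + abs(dirs[, 2] / axes[2])^n +
          abs(dirs[, 3] / axes[3])^n)
  s^(-1 / n)
}

# Quasi-uniform Fibonacci lattice on the upper unit hemisphere (z > 0,
# the region above the tragus plane). Deterministic.
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n)
  z <- (i - 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Forward class deformation applied to points in the canonical frame.
# Taper first (anterior narrowing over y in [0.2 b, b]), then posterior shear.
deform_points <- function(P, length_ap, shear_asym, frontal_taper) {
  x <- P[, 1]; y <- P[, 2]
  if (frontal_taper != 0) {
    y0 <- 0.2 * length_ap
    w <- pmax(0, (y - y0) / (length_ap - y0))
    x <- x * (1 - frontal_taper * w)
  }
  if (shear_asym != 0) x <- x + shear_asym * pmax(-y, 0)
  cbind(x, y, P[, 3], deparse.level = 0)
}

# Orthonormal tangent basis at superellipsoid surface points (rows of P).
tangent_basis <- function(P, axes, n) {
  g <- cbind((n / axes[1]) * abs(P[, 1] / axes[1])^(n - 1) * sign(P[, 1]),
             (n / axes[2]) * abs(P[, 2] / axes[2])^(n - 1) * sign(P[, 2]),
             (n / axes[3]) * abs(P[, 3] / axes[3])^(n - 1) * sign(P[, 3]))
  nrm <- g / sqrt(rowSums(g^2))
  # any vector not parallel to the normal; z-pole markers have |nz| ~ 1
  ref <- cbind(1 - abs(nrm[, 1]) > 0.5, 0 + (1 - abs(nrm[, 1]) <= 0.5), 0)
  t1 <- cbind(ref[, 2] * nrm[, 3] - ref[, 3] * nrm[, 2],
              ref[, 3] * nrm[, 1] - ref[, 1] * nrm[, 3],
              ref[, 1] * nrm[, 2] - ref[, 2] * nrm[, 1])
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cbind(nrm[, 2] * t1[, 3] - nrm[, 3] * t1[, 2],
              nrm[, 3] * t1[, 1] - nrm[, 1] * t1[, 3],
              nrm[, 1] * t1[, 2] - nrm[, 2] * t1[, 1])
  list(t1 = t1, t2 = t2)
}

# Expand marker centre rows into 4 ordered quad vertices in the tangent plane.
quad_vertices <- function(centres, t1, t2, half = QUAD_HALF_MM) {
  n <- nrow(centres)
  V <- matrix(NA_real_, 4L * n, 3L)
  offs <- list(c(1, 1), c(1, -1), c(-1, -1), c(-1, 1))
  for (k in 1:4) {
    o <- offs[[k]]
    V[seq(k, by = 4L, length.out = n), ] <-
      centres + half * (o[1] * t1 + o[2] * t2)
  }
  V
}

new_head_cloud <- function(cloud_id, base_id, class_label, present, vertices,
                           provenance = "original") {
  structure(list(cloud_id = cloud_id, base_id = base_id,
                 class_label = class_label, role = MARKER_ROLES,
                 present = present, vertices = vertices,
                 provenance = provenance),
            class = "head_cloud")
}

#' Validate a head cloud's structural invariants
#'
#' Checks the 138-slot layout, the always-present reference stickers, the
#' 131 minimum present markers, finite vertex coordinates and the bounded
#' quad diagonal of every present marker.
#'
#' @param cloud a `head_cloud`.
#' @return the cloud, invisibly; errors describe the first violation.
#' @export
validate_head_cloud <- function(cloud) {
  stopifnot(inherits(cloud, "head_cloud"))
  if (length(cloud$present) != N_SLOTS)
    stop("cloud must have exactly 138 marker slots")
  if (!all(cloud$present[c(SLOT_REF_FRONT, SLOT_REF_LEFT, SLOT_REF_RIGHT)]))
    stop("reference stickers must always be present")
  np <- sum(cloud$present)
  if (np < MIN_PRESENT) stop("below minimum marker count (131)")
  if (nrow(cloud$vertices) != 4L * N_SLOTS || ncol(cloud$vertices) != 3L)
    stop("vertex matrix must be 552 x 3")
  for (s in which(cloud$present)) {
    V <- cloud$vertices[vertex_rows(s), , drop = FALSE]
    if (!all(is.finite(V)))
      stop("present marker ", s, " has non-finite vertices")
    d <- sqrt(sum((V[1, ] - V[3, ])^2))
    if (d > 15) stop("marker ", s, " quad diagonal exceeds 15 mm")
  }
  invisible(cloud)
}

# Row indices of a marker slot in the 552 x 3 vertex matrix.
vertex_rows <- function(slot) (4L * (slot - 1L) + 1L):(4L * slot)

#' @export
print.head_cloud <- function(x, ...) {
  cat(sprintf("<head_cloud> %s (%s): %d/138 markers present, base %s\n",
              x$cloud_id, x$class_label, sum(x$present), x$base_id))
  invisible(x)
}

#' Generate one synthetic marker-cap head cloud
#'
#' Places 135 coded cap markers quasi-uniformly on the class's superellipsoid
#' surface above the tragus plane, each expanded to a 7 mm tangent-plane
#' square of 4 vertices, plus the three reference stickers (left/right tragus,
#' anterior midline). `n_missing` cap markers are flagged absent to emulate
#' undetected stickers; reference stickers are never dropped.
#'
#' @param params a [shape_params()] object.
#' @param n_missing number of absent cap markers, 0..7 (keeps the present
#'   count at or above the 131 minimum).
#' @param seed integer seed; generation is deterministic given `seed`.
#' @param cloud_id,base_id identifiers stored on the cloud.
#' @return a `head_cloud` with 138 marker slots (552 vertex rows, absent
#'   markers' rows `NA`).
#' @examples
#' cl <- generate_base_cloud(shape_params("normocephaly"), n_missing = 0,
#'                           seed = 1)
#' sum(cl$present)  # 138
#' @export
generate_base_cloud <- function(params, n_missing = 0L, seed = 1L,
                                cloud_id = NULL, base_id = cloud_id) {
  stopifnot(inherits(params, "shape_params"))
  n_missing <- as.integer(n_missing)
  if (n_missing < 0L || n_missing > 7L)
    stop("below minimum marker count: n_missing must be in 0..7")
  if (is.null(cloud_id))
    cloud_id <- sprintf("%s_s%d", params$class_label, as.integer(seed))
  if (is.null(base_id)) base_id <- cloud_id

  with_seed(seed, {
    axes <- c(params$width_ml, params$length_ap, params$height)
    if (params$jitter_sd > 0)
      axes <- pmax(axes + rnorm(3, 0, params$jitter_sd), 20)
    n <- params$squareness

    dirs <- fibonacci_hemisphere(N_CAP)
    r <- superellipsoid_radius(dirs, axes, n)
    centres <- dirs * r
    tb <- tangent_basis(centres, axes, n)
    capV <- quad_vertices(centres, tb$t1, tb$t2)

    # reference stickers on the tragus plane / anterior midline (base frame).
    # The tragus points sit below and inside the cap surface: their lateral
    # offset is 52% of the ML semi-axis, landing preauricular distances in
    # the 75-90 mm band that keeps the default scale grid admissible under
    # the +-1.5 mm margin.
    refC <- rbind(front = c(0, axes[2], 0),
                  left  = c(-0.52 * axes[1], 0, 0),
                  right = c(0.52 * axes[1], 0, 0))
    refT1 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 1, 0))
    refT2 <- rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1))
    refV <- quad_vertices(refC, refT1, refT2)

    V <- deform_points(rbind(capV, refV), axes[2],
                       params$shear_asym, params$frontal_taper)

    present <- rep(TRUE, N_SLOTS)
    if (n_missing > 0L) {
      drop <- sample.int(N_CAP, n_missing)
      present[drop] <- FALSE
      for (s in drop) V[vertex_rows(s), ] <- NA_real_
    }
    cl <- new_head_cloud(cloud_id, base_id, params$class_label, present, V)
    attr(cl, "axes") <- axes
    cl
  })
}

#' Cohort plan: per-class base counts and marker-dropout histogram
#'
#' The default plan reproduces the study design the generator emulates: 60
#' base clouds split 10/11/5/9/13/12 across brachycephaly, dolichocephaly,
#' normocephaly, plagiocephaly, towering and trigonocephaly, with a per-class
#' histogram of present-marker (descriptor) counts whose minimum is 131.
#'
#' @param class_counts named integer vector, class -> number of base clouds.
#' @param dropout_histogram named list, class -> named vector mapping
#'   descriptor count (131..138) to number of base clouds.
#' @param seed integer seed controlling per-cloud jitter and dropout.
#' @return an object of class `cohort_plan`.
#' @export
cohort_plan <- function(class_counts = NULL, dropout_histogram = NULL,
                        seed = 1L) {
  if (is.null(class_counts))
    class_counts <- c(brachycephaly = 10L, dolichocephaly = 11L,
                      normocephaly = 5L, plagiocephaly = 9L,
                      towering = 13L, trigonocephaly = 12L)
  if (is.null(dropout_histogram))
    dropout_histogram <- list(
      brachycephaly  = c(`138` = 3, `136` = 2, `135` = 3, `133` = 1, `132` = 1),
      dolichocephaly = c(`138` = 1, `137` = 1, `136` = 3, `135` = 2,
                         `134` = 2, `133` = 2),
      normocephaly   = c(`138` = 3, `136` = 2),
      plagiocephaly  = c(`138` = 3, `136` = 1, `134` = 3, `133` = 2),
      towering       = c(`138` = 3, `137` = 2, `136` = 3, `135` = 3,
                         `134` = 2),
      trigonocephaly = c(`138` = 5, `137` = 1, `136` = 2, `134` = 3,
                         `131` = 1))
  stopifnot(all(names(class_counts) %in% CLASS_LEVELS),
            all(names(dropout_histogram) %in% names(class_counts)))
  for (cl in names(class_counts)) {
    h <- dropout_histogram[[cl]]
    if (is.null(h)) stop("no dropout histogram for class ", cl)
    k <- as.integer(names(h))
    if (any(k < MIN_PRESENT | k > N_SLOTS))
      stop("descriptor counts must lie in 131..138 (class ", cl, ")")
    if (sum(h) != class_counts[[cl]])
      stop("dropout histogram for ", cl, " sums to ", sum(h),
           ", expected ", class_counts[[cl]])
  }
  structure(list(class_counts = class_counts,
                 dropout_histogram = dropout_histogram,
                 seed = as.integer(seed)),
            class = "cohort_plan")
}

#' Generate a cohort of base head clouds
#'
#' One cloud per planned case, using each class's default [shape_params()]
#' with per-cloud semi-axis jitter; marker dropout is assigned so the
#' cohort's present-marker histogram matches the plan's histogram exactly.
#' Fully reproducible given the plan (including its seed).
#'
#' @param plan a [cohort_plan()].
#' @return list of `head_cloud` objects (default plan: 60).
#' @examples
#' bases <- generate_cohort(cohort_plan(seed = 7))
#' length(bases)
#' @export
generate_cohort <- function(plan = cohort_plan()) {
  stopifnot(inherits(plan, "cohort_plan"))
  clouds <- list()
  for (cl in names(plan$class_counts)) {
    h <- plan$dropout_histogram[[cl]]
    counts <- rep(as.integer(names(h)), times = h)
    for (i in seq_along(counts)) {
      s <- derive_seed(plan$seed, cl, i)
      id <- sprintf("%s_base%02d", cl, i)
      clouds[[id]] <- generate_base_cloud(
        shape_params(cl), n_missing = N_SLOTS - counts[i], seed = s,
        cloud_id = id)
    }
  }
  unname(clouds)
}

#' Cephalic index of a head cloud
#'
#' Maximum mediolateral extent over maximum anteroposterior extent of the cap
#' marker centroids, times 100, measured in the canonical sticker-defined
#' frame. Invariant under rigid motion and under uniform scaling.
#'
#' @param cloud a `head_cloud` with the 3 reference stickers and at least 3
#'   present cap markers.
#' @return positive scalar percentage.
#' @export
cephalic_index <- function(cloud) {
  cloud <- canonicalise_cloud(cloud)
  cent <- marker_centroids(cloud)
  cap <- cent[seq_len(N_CAP), , drop = FALSE]
  cap <- cap[cloud$present[seq_len(N_CAP)], , drop = FALSE]
  if (nrow(cap) < 3L) stop("need at least 3 present cap markers")
  width <- diff(range(cap[, 1]))
  len <- diff(range(cap[, 2]))
  width / len * 100
}
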