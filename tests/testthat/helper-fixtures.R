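# Shared fixtures and independent brute-force oracles. The oracles
# deliberately use plain loops and re-derived formulas, not the package's
# vectorised code paths.

N_SLOTS <- 138L
N_CAP <- 135L

# Build a head_cloud directly from marker centroids: each present marker gets
# a flat 2 x 2 mm quad in the xy-plane around its centroid.
toy_cloud <- function(centroids, present = rep(TRUE, N_SLOTS),
                      class_label = "normocephaly", cloud_id = "toy") {
  V <- matrix(NA_real_, 4L * N_SLOTS, 3L)
  offs <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, -1, 0), c(-1, 1, 0))
  for (s in which(present)) {
    rows <- (4 * (s - 1) + 1):(4 * s)
    V[rows, ] <- matrix(centroids[s, ], 4, 3, byrow = TRUE) + offs
  }
  craniomorph:::new_head_cloud(cloud_id, cloud_id, class_label, present, V)
}

# A complete toy cloud with refs in canonical position and cap markers on a
# hemisphere of radius r.
toy_complete_cloud <- function(r = 80, cloud_id = "toy") {
  C <- matrix(0, N_SLOTS, 3)
  i <- seq_len(N_CAP)
  z <- (i - 0.5) / N_CAP
  phi <- i * pi * (3 - sqrt(5))
  C[i, ] <- r * cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  C[136, ] <- c(0, r, 0)   # ref_front
  C[137, ] <- c(-r, 0, 0)  # ref_left
  C[138, ] <- c(r, 0, 0)   # ref_right
  toy_cloud(C, cloud_id = cloud_id)
}

# Random rigid motion (rotation from QR with det +1, bounded translation).
random_rigid <- function(seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = runif(3, -50, 50))
}

# Independent descriptor oracle: explicit frame construction and per-vertex
# distance loops on the raw vertex matrix.
oracle_descriptors <- function(cloud) {
  cent <- function(s) {
    rows <- (4 * (s - 1) + 1):(4 * s)
    colMeans(cloud$vertices[rows, , drop = FALSE])
  }
  l <- cent(137); r <- cent(138); f <- cent(136)
  o <- (l + r) / 2
  ex <- (r - l) / sqrt(sum((r - l)^2))
  fa <- f - o
  ey <- fa - sum(fa * ex) * ex
  ey <- ey / sqrt(sum(ey^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2], ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  R <- cbind(ex, ey, ez)
  out <- rep(NA_real_, N_SLOTS)
  for (s in which(cloud$present)) {
    dsum <- 0
    for (k in 1:4) {
      v <- cloud$vertices[4 * (s - 1) + k, ]
      w <- as.numeric(t(R) %*% (v - o))
      dsum <- dsum + sqrt(sum(w^2))
    }
    out[s] <- dsum / 4
  }
  out
}

# Memoised default cohort + features so several expensive tests share one
# computation. Seeds fixed: the generated world, not a tuning knob.
.fixture_env <- new.env(parent = emptyenv())
default_features <- function() {
  if (is.null(.fixture_env$tab)) {
    bases <- generate_cohort(cohort_plan(seed = 11))
    aug <- augment_cohort(bases, scale_plan(seed = 12), noise_spec(seed = 13))
    .fixture_env$bases <- bases
    .fixture_env$tab <- build_feature_table(aug)
  }
  .fixture_env$tab
}
default_bases <- function() {
  default_features()
  .fixture_env$bases
}

# Small augmented cohort (5 factors x 3 modes per base = 900 rows) for
# model-level property tests that do not need the full 3600 rows.
small_features <- function() {
  if (is.null(.fixture_env$small)) {
    bases <- generate_cohort(cohort_plan(seed = 21))
    aug <- augment_cohort(bases, scale_plan(n_selected = 5, seed = 22),
                          noise_spec(seed = 23))
    .fixture_env$small <- build_feature_table(aug)
  }
  .fixture_env$small
}

# Two well-separated Gaussian blobs: any sane classifier reaches F1 = 1.
separable_toy <- function(seed = 1, n_per = 40) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2), ncol = 2),
             matrix(rnorm(n_per * 2, mean = 8), ncol = 2))
  y <- rep(1:2, each = n_per)
  idx <- sample(length(y))
  list(x = x[idx, ], y = y[idx])
}
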