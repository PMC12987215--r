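# Semi-synthetic cohort expansion: admissible scale-factor derivation,
# stratified factor selection, three similarity-scaling modes (XYZ, XY, Z)
# and bounded per-marker noise. One base cloud expands to
# n_selected x 3 variants (default 60).

SCALE_MODES <- c("XYZ", "XY", "Z")

#' Scale plan for semi-synthetic augmentation
#'
#' The defaults encode the augmentation design: scale factors are restricted
#' so the preauricular distance moves by at most `margin_mm` (+-1.5 mm), the
#' admissible grid runs from 0.983 to 1.016 in steps of 0.001, and 20 factors
#' are selected at random but evenly spread across that grid.
#'
#' @param margin_mm preauricular variation margin (mm).
#' @param grid_lo,grid_hi,grid_step arithmetic factor grid.
#' @param n_selected number of factors to select.
#' @param seed selection seed.
#' @return object of class `scale_plan`.
#' @export
scale_plan <- function(margin_mm = 1.5, grid_lo = 0.983, grid_hi = 1.016,
                       grid_step = 0.001, n_selected = 20L, seed = 1L) {
  stopifnot(margin_mm > 0, grid_lo < 1, grid_hi > 1, grid_step > 0)
  grid <- seq(grid_lo, grid_hi, by = grid_step)
  if (n_selected > length(grid))
    stop("n_selected exceeds the factor grid size (", length(grid), ")")
  structure(list(margin_mm = margin_mm, grid_lo = grid_lo, grid_hi = grid_hi,
                 grid_step = grid_step, n_selected = as.integer(n_selected),
                 seed = as.integer(seed)),
            class = "scale_plan")
}

#' Noise specification for marker perturbation
#'
#' Each targeted marker receives one rigid offset with independent components
#' uniform on `[-amplitude_mm, amplitude_mm]`, applied to all four of its
#' vertices, emulating cap-placement variability.
#'
#' @param amplitude_mm per-axis bound (mm); default 2.
#' @param targets `"all_markers"` (default) or `"reference_only"`.
#' @param seed base seed for noise draws.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(amplitude_mm = 2, targets = c("all_markers",
                                                     "reference_only"),
                       seed = 1L) {
  if (amplitude_mm < 0) stop("amplitude_mm must be non-negative")
  structure(list(amplitude_mm = amplitude_mm, targets = match.arg(targets),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Admissible scale-factor range for a preauricular distance
#'
#' Factors keeping the scaled preauricular distance within `margin_mm` of the
#' original: `(1 - margin/d, 1 + margin/d)`.
#'
#' @param d_preauricular preauricular distance (mm), positive.
#' @param margin_mm allowed absolute change (mm).
#' @return named numeric vector `c(lo, hi)`.
#' @examples
#' admissible_scale_range(100, 1.5)  # 0.985 1.015
#' @export
admissible_scale_range <- function(d_preauricular, margin_mm = 1.5) {
  if (d_preauricular <= 0) stop("preauricular distance must be positive")
  c(lo = 1 - margin_mm / d_preauricular,
    hi = 1 + margin_mm / d_preauricular)
}

#' Select scale factors from the plan grid
#'
#' Stratified random selection: the grid is partitioned into `n_selected`
#' contiguous strata and one factor is drawn per stratum, honouring both the
#' "random" and the "evenly distributed" requirements. Deterministic given
#' the plan seed.
#'
#' @param plan a [scale_plan()].
#' @return sorted numeric vector of `n_selected` distinct factors.
#' @export
select_scale_factors <- function(plan = scale_plan()) {
  stopifnot(inherits(plan, "scale_plan"))
  grid <- seq(plan$grid_lo, plan$grid_hi, by = plan$grid_step)
  k <- plan$n_selected
  if (k == length(grid)) return(grid)
  bounds <- as.integer(round(seq(0, length(grid), length.out = k + 1)))
  with_seed(derive_seed(plan$seed, "scale_factors"), {
    idx <- vapply(seq_len(k), function(i) {
      lo <- bounds[i] + 1L; hi <- bounds[i + 1L]
      if (hi > lo) sample(lo:hi, 1L) else lo
    }, integer(1))
    sort(grid[idx])
  })
}

#' Scale a canonical cloud
#'
#' Multiplies vertex coordinates by `factor` on the axes selected by `mode`:
#' `"XYZ"` all three, `"XY"` the horizontal plane only, `"Z"` vertical only.
#' Marker topology, presence flags and labels are preserved; provenance is
#' recorded.
#'
#' @param cloud a canonicalised `head_cloud`.
#' @param factor positive scale factor.
#' @param mode one of `"XYZ"`, `"XY"`, `"Z"`.
#' @return the scaled `head_cloud`.
#' @export
apply_scaling <- function(cloud, factor, mode = c("XYZ", "XY", "Z")) {
  stopifnot(inherits(cloud, "head_cloud"))
  mode <- match.arg(mode)
  if (factor <= 0) stop("scale factor must be positive")
  s <- switch(mode, XYZ = c(factor, factor, factor),
              XY = c(factor, factor, 1), Z = c(1, 1, factor))
  cloud$vertices <- sweep(cloud$vertices, 2, s, `*`)
  cloud$provenance <- list(base_id = cloud$base_id, factor = factor,
                           mode = mode, noise_seed = NA_integer_)
  cloud
}

#' Apply bounded rigid per-marker noise
#'
#' For each targeted present marker one offset vector with independent
#' components uniform on `[-amplitude, amplitude]` is added to all four of
#' its vertices, so quad shape and size are preserved exactly.
#'
#' @param cloud a `head_cloud`.
#' @param spec a [noise_spec()].
#' @return the perturbed `head_cloud`.
#' @export
apply_marker_noise <- function(cloud, spec = noise_spec()) {
  stopifnot(inherits(cloud, "head_cloud"), inherits(spec, "noise_spec"))
  if (spec$amplitude_mm == 0) return(cloud)
  targets <- if (spec$targets == "reference_only") {
    c(SLOT_REF_FRONT, SLOT_REF_LEFT, SLOT_REF_RIGHT)
  } else which(cloud$present)
  with_seed(spec$seed, {
    off <- matrix(runif(3L * length(targets), -spec$amplitude_mm,
                        spec$amplitude_mm), ncol = 3)
    for (i in seq_along(targets)) {
      rows <- vertex_rows(targets[i])
      cloud$vertices[rows, ] <- cloud$vertices[rows, , drop = FALSE] +
        matrix(off[i, ], 4, 3, byrow = TRUE)
    }
  })
  if (is.list(cloud$provenance)) cloud$provenance$noise_seed <- spec$seed
  cloud
}

#' Expand one base cloud into its semi-synthetic variants
#'
#' Every selected factor is applied under every scaling mode, and each of the
#' resulting clouds receives an independent noise draw. With the default plan
#' this yields 20 x 3 = 60 variants per base.
#'
#' @param cloud a base `head_cloud` (canonicalised internally).
#' @param plan a [scale_plan()].
#' @param noise a [noise_spec()].
#' @return list of `head_cloud` variants with full provenance.
#' @export
augment_cloud <- function(cloud, plan = scale_plan(), noise = noise_spec()) {
  stopifnot(inherits(cloud, "head_cloud"))
  cloud <- canonicalise_cloud(cloud)
  factors <- select_scale_factors(plan)
  out <- vector("list", length(factors) * length(SCALE_MODES))
  k <- 0L
  for (f in factors) {
    for (m in SCALE_MODES) {
      k <- k + 1L
      v <- apply_scaling(cloud, f, m)
      ns <- derive_seed(noise$seed, paste(cloud$base_id, m), k)
      v <- apply_marker_noise(v, noise_spec(noise$amplitude_mm,
                                            noise$targets, seed = ns))
      v$cloud_id <- sprintf("%s_f%.3f_%s", cloud$base_id, f, m)
      out[[k]] <- v
    }
  }
  out
}

#' Expand a cohort of base clouds
#'
#' Concatenation of [augment_cloud()] over all bases:
#' `n_bases * n_selected * 3` clouds (default 60 bases -> 3600).
#'
#' @param bases non-empty list of base `head_cloud`s.
#' @param plan a [scale_plan()].
#' @param noise a [noise_spec()].
#' @return list of augmented `head_cloud`s.
#' @export
augment_cohort <- function(bases, plan = scale_plan(),
                           noise = noise_spec()) {
  if (length(bases) == 0) stop("need at least one base cloud")
  do.call(c, lapply(bases, augment_cloud, plan = plan, noise = noise))
}
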