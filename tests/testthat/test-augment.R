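test_that("admissible scale range follows the closed form", {
  expect_equal(admissible_scale_range(100, 1.5),
               c(lo = 0.985, hi = 1.015), tolerance = 1e-12)
  # the distance whose upper bound reproduces the published grid maximum
  expect_equal(admissible_scale_range(93.75, 1.5)[["hi"]], 1.016,
               tolerance = 1e-12)
  r0 <- admissible_scale_range(80, 0)
  expect_equal(unname(r0), c(1, 1))
  expect_error(admissible_scale_range(0, 1.5), "positive")
})

test_that("factor selection is stratified, bounded and deterministic", {
  plan <- scale_plan(seed = 31)
  f <- select_scale_factors(plan)
  expect_length(f, 20L)
  expect_equal(anyDuplicated(f), 0L)
  expect_true(all(f >= plan$grid_lo - 1e-12 & f <= plan$grid_hi + 1e-12))
  expect_identical(f, select_scale_factors(plan))
  # even spread: consecutive gaps bounded by two strata widths
  grid_size <- length(seq(plan$grid_lo, plan$grid_hi, by = plan$grid_step))
  max_gap <- 2 * ceiling(grid_size / plan$n_selected) * plan$grid_step
  expect_true(all(diff(f) <= max_gap + 1e-12))

  full <- scale_plan(n_selected = 34, seed = 1)
  expect_equal(select_scale_factors(full),
               seq(0.983, 1.016, by = 0.001), tolerance = 1e-12)
  expect_error(scale_plan(n_selected = 35), "grid size")
})

test_that("scaling acts on the axes its mode names", {
  cl <- toy_complete_cloud()
  cl$vertices[1, ] <- c(10, 20, 30)
  z <- apply_scaling(cl, 1.01, "Z")
  expect_equal(z$vertices[1, ], c(10, 20, 30.3), tolerance = 1e-12)
  expect_equal(apply_scaling(cl, 1, "XY")$vertices, cl$vertices)
  expect_error(apply_scaling(cl, -0.5, "XYZ"), "positive")

  # XYZ mode multiplies every origin-to-vertex distance exactly (brute force)
  s <- 1.007
  xyz <- apply_scaling(cl, s, "XYZ")
  for (i in seq(1, 552, by = 37)) {
    expect_equal(sqrt(sum(xyz$vertices[i, ]^2)),
                 s * sqrt(sum(cl$vertices[i, ]^2)), tolerance = 1e-9)
  }
})

test_that("marker noise is bounded, rigid per marker and seeded", {
  cl <- generate_base_cloud(shape_params("dolichocephaly"), seed = 6)
  expect_identical(apply_marker_noise(cl, noise_spec(0))$vertices,
                   cl$vertices)
  ns <- noise_spec(2, seed = 17)
  nz <- apply_marker_noise(cl, ns)
  d <- abs(nz$vertices - cl$vertices)
  expect_lte(max(d, na.rm = TRUE), 2)
  expect_gt(max(d, na.rm = TRUE), 0.5)  # noise actually applied
  # intra-marker geometry preserved
  for (s in c(1, 50, 135, 137)) {
    rows <- craniomorph:::vertex_rows(s)
    expect_equal(as.vector(dist(nz$vertices[rows, ])),
                 as.vector(dist(cl$vertices[rows, ])), tolerance = 1e-9)
  }
  expect_identical(apply_marker_noise(cl, ns)$vertices, nz$vertices)
  ref_only <- apply_marker_noise(cl, noise_spec(2, "reference_only",
                                                seed = 17))
  expect_identical(ref_only$vertices[1:540, ], cl$vertices[1:540, ])
  expect_false(identical(ref_only$vertices[541:552, ],
                         cl$vertices[541:552, ]))
  expect_error(noise_spec(-1), "non-negative")
})

test_that("augmentation counts and labels are conserved", {
  base <- generate_base_cloud(shape_params("towering"), n_missing = 2,
                              seed = 9, cloud_id = "tow1")
  out <- augment_cloud(base, scale_plan(n_selected = 2, seed = 1),
                       noise_spec(seed = 2))
  expect_length(out, 6L)
  expect_true(all(vapply(out, `[[`, "", "class_label") == "towering"))
  expect_true(all(vapply(out, function(x) sum(x$present), 0L) == 136L))
  expect_true(all(vapply(out, function(x) x$provenance$base_id, "") ==
                    "tow1"))
  full <- augment_cloud(base, scale_plan(seed = 1), noise_spec(seed = 2))
  expect_length(full, 60L)
  expect_error(augment_cohort(list()), "at least one")
})

test_that("preauricular distance responds to mode as the geometry dictates", {
  base <- canonicalise_cloud(generate_base_cloud(
    shape_params("normocephaly", jitter_sd = 0), seed = 10))
  d0 <- preauricular_distance(base)
  # default tragus placement lands in the 75-90 mm band for which the whole
  # default grid is admissible under the 1.5 mm margin
  expect_gt(d0, 75); expect_lt(d0, 90)
  rng <- admissible_scale_range(d0, 1.5)
  expect_lte(rng[["lo"]], 0.983)
  expect_gte(rng[["hi"]], 1.016)
  for (f in c(0.983, 1.016)) {
    expect_equal(preauricular_distance(apply_scaling(base, f, "XYZ")),
                 f * d0, tolerance = 1e-9)
    expect_equal(preauricular_distance(apply_scaling(base, f, "XY")),
                 f * d0, tolerance = 1e-9)
    expect_equal(preauricular_distance(apply_scaling(base, f, "Z")),
                 d0, tolerance = 1e-9)
    # analytic constraint: every factor inside the admissible range keeps
    # the preauricular change within the margin, in XY and XYZ modes
    expect_lte(abs(f * d0 - d0), 1.5 + 1e-9)
  }
  # zero-jitter defaults of all classes stay admissible
  for (cls in c("brachycephaly", "dolichocephaly", "towering"))
    expect_lte(preauricular_distance(generate_base_cloud(
      shape_params(cls, jitter_sd = 0), seed = 1)), 1.5 / 0.017 + 1e-9)
})
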