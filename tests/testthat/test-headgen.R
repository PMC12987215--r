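test_that("base clouds carry the fixed marker schema", {
  cl <- generate_base_cloud(shape_params("normocephaly"), n_missing = 0,
                            seed = 1)
  expect_s3_class(cl, "head_cloud")
  expect_equal(sum(cl$present), 138L)
  expect_equal(sum(stats::complete.cases(cl$vertices)), 552L)
  expect_silent(validate_head_cloud(cl))

  cl7 <- generate_base_cloud(shape_params("towering"), n_missing = 7,
                             seed = 2)
  expect_equal(sum(cl7$present), 131L)
  # reference stickers are never dropped
  expect_true(all(cl7$present[136:138]))
  expect_true(all(is.na(cl7$vertices[!rep(cl7$present, each = 4), ])))
})

test_that("generation is deterministic and rejects invalid requests", {
  p <- shape_params("plagiocephaly")
  a <- generate_base_cloud(p, n_missing = 3, seed = 99)
  b <- generate_base_cloud(p, n_missing = 3, seed = 99)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$present, b$present)
  c2 <- generate_base_cloud(p, n_missing = 3, seed = 100)
  expect_false(identical(a$vertices, c2$vertices))

  expect_error(generate_base_cloud(p, n_missing = 8, seed = 1),
               "minimum marker count")
  expect_error(shape_params("normocephaly", width_ml = -1), "positive")
  expect_error(shape_params("normocephaly", jitter_sd = -0.1),
               "non-negative")
})

test_that("class defaults satisfy the separability invariants", {
  defs <- lapply(c("brachycephaly", "dolichocephaly", "normocephaly",
                   "plagiocephaly", "towering", "trigonocephaly"),
                 shape_params)
  names(defs) <- vapply(defs, `[[`, "", "class_label")
  idx <- vapply(defs, function(p) p$width_ml / p$length_ap * 100, 0)
  expect_gt(idx[["brachycephaly"]], 90)
  expect_lt(idx[["dolichocephaly"]], 75)
  expect_true(idx[["normocephaly"]] >= 75 && idx[["normocephaly"]] <= 90)
  hl <- vapply(defs, function(p) p$height / p$length_ap, 0)
  expect_true(all(hl[["towering"]] > hl[names(hl) != "towering"]))
  expect_true(abs(defs[["plagiocephaly"]]$shear_asym) > 0)
  expect_true(defs[["trigonocephaly"]]$frontal_taper > 0)
  others <- setdiff(names(defs), c("plagiocephaly", "trigonocephaly"))
  expect_true(all(vapply(defs[others], `[[`, 0, "shear_asym") == 0))
  expect_true(all(vapply(defs[setdiff(names(defs), "trigonocephaly")],
                         `[[`, 0, "frontal_taper") == 0))
})

test_that("cohort plan validates and the default generates 60 clouds", {
  plan <- cohort_plan(seed = 5)
  expect_equal(sum(plan$class_counts), 60L)
  bases <- generate_cohort(plan)
  expect_length(bases, 60L)
  cls <- vapply(bases, `[[`, "", "class_label")
  expect_equal(as.vector(table(cls)[c("brachycephaly", "dolichocephaly",
                                      "normocephaly", "plagiocephaly",
                                      "towering", "trigonocephaly")]),
               c(10L, 11L, 5L, 9L, 13L, 12L))
  # histogram fidelity, e.g. exactly 3 complete brachycephaly bases
  present <- vapply(bases, function(b) sum(b$present), 0L)
  expect_equal(sum(cls == "brachycephaly" & present == 138L), 3L)
  expect_equal(sum(cls == "trigonocephaly" & present == 131L), 1L)
  for (cl in unique(cls)) {
    h <- table(present[cls == cl])
    want <- plan$dropout_histogram[[cl]]
    expect_equal(h[names(want)], table(rep(as.integer(names(want)),
                                           want))[names(want)],
                 ignore_attr = TRUE)
  }

  expect_error(cohort_plan(dropout_histogram = list(
    brachycephaly = c(`138` = 9), dolichocephaly = c(`138` = 11),
    normocephaly = c(`138` = 5), plagiocephaly = c(`138` = 9),
    towering = c(`138` = 13), trigonocephaly = c(`138` = 12))),
    "sums to")

  single <- cohort_plan(class_counts = c(normocephaly = 1L),
                        dropout_histogram = list(normocephaly = c(`138` = 1)))
  one <- generate_cohort(single)
  expect_length(one, 1L)
  expect_equal(sum(one[[1]]$present), 138L)
})

test_that("cohorts are bitwise reproducible given the plan", {
  p <- cohort_plan(class_counts = c(towering = 2L, normocephaly = 2L),
                   dropout_histogram = list(towering = c(`138` = 1,
                                                         `134` = 1),
                                            normocephaly = c(`136` = 2)),
                   seed = 42)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(lapply(a, `[[`, "vertices"), lapply(b, `[[`, "vertices"))
})

test_that("cephalic index matches its definition and invariances", {
  # synthetic cloud with exactly known extents: width 90, length 100
  C <- matrix(0, 138, 3)
  C[1, ] <- c(-45, 0, 10); C[2, ] <- c(45, 0, 10)
  C[3, ] <- c(0, 50, 10); C[4, ] <- c(0, -50, 10)
  C[136, ] <- c(0, 60, 0); C[137, ] <- c(-48, 0, 0); C[138, ] <- c(48, 0, 0)
  present <- rep(FALSE, 138); present[c(1:4, 136:138)] <- TRUE
  cl <- toy_cloud(C, present)
  expect_equal(cephalic_index(cl), 90.0, tolerance = 1e-12)

  # brachycephaly default: above 90, checked against a brute-force extent
  # scan over all cap centroids
  br <- generate_base_cloud(shape_params("brachycephaly", jitter_sd = 0),
                            seed = 3)
  ci <- cephalic_index(br)
  expect_gt(ci, 90)
  cent <- t(sapply(which(br$present[1:135]), function(s)
    colMeans(br$vertices[(4 * (s - 1) + 1):(4 * s), ])))
  brute <- (max(cent[, 1]) - min(cent[, 1])) /
    (max(cent[, 2]) - min(cent[, 2])) * 100
  expect_equal(ci, brute, tolerance = 1e-9)

  # scale invariance of the ratio
  sc <- br
  sc$vertices <- sc$vertices * 1.37
  expect_equal(cephalic_index(sc), ci, tolerance = 1e-9)
})

test_that("index ordering is strict at zero jitter", {
  ci <- vapply(c("dolichocephaly", "normocephaly", "brachycephaly"),
               function(cl) cephalic_index(generate_base_cloud(
                 shape_params(cl, jitter_sd = 0), seed = 7)), 0)
  expect_true(ci[1] < ci[2] && ci[2] < ci[3])
})

test_that("cap centroids lie on the analytic surface", {
  # oracle: undo the class deformation, then evaluate the superellipsoid
  # implicit equation radially
  for (cls in c("normocephaly", "plagiocephaly", "trigonocephaly")) {
    p <- shape_params(cls, jitter_sd = 0)
    cl <- generate_base_cloud(p, seed = 4)
    axes <- c(p$width_ml, p$length_ap, p$height)
    n <- p$squareness
    for (s in seq_len(135)) {
      cent <- colMeans(cl$vertices[(4 * (s - 1) + 1):(4 * s), ])
      x <- cent[1]; y <- cent[2]; z <- cent[3]
      if (p$shear_asym != 0 && y < 0) x <- x - p$shear_asym * (-y)
      if (p$frontal_taper != 0) {
        y0 <- 0.2 * p$length_ap
        if (y > y0) {
          w <- (y - y0) / (p$length_ap - y0)
          x <- x / (1 - p$frontal_taper * w)
        }
      }
      m <- (abs(x / axes[1])^n + abs(y / axes[2])^n +
              abs(z / axes[3])^n)^(1 / n)
      radial <- sqrt(x^2 + y^2 + z^2) * abs(1 - 1 / m)
      expect_lt(radial, 1)
    }
  }
})
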