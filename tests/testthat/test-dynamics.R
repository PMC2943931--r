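test_that("voxelwise z-transform standardizes rows and handles degenerates", {
  expect_equal(ztransform_voxelwise(matrix(c(1, 2, 3), 1))[1, ], c(-1, 0, 1))
  expect_equal(ztransform_voxelwise(matrix(c(5, 5, 5), 1))[1, ], c(0, 0, 0))
  # idempotent on already standardized input
  x <- matrix(rnorm(5 * 20), 5, 20)
  z <- ztransform_voxelwise(x)
  expect_equal(ztransform_voxelwise(z), z, tolerance = 1e-12)
  expect_equal(rowMeans(z), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(z, 1, sd), rep(1, 5), tolerance = 1e-12)
  expect_error(ztransform_voxelwise(matrix(1, 3, 1)), "2 volumes")
})

test_that("IC-template matching is sign-invariant and thresholds correctly", {
  set.seed(3)
  templates <- matrix(rnorm(3 * 300), 3, 300)
  # identical ICs in scrambled order, one flipped
  ics <- templates[c(2, 3, 1), ]
  ics[2, ] <- -ics[2, ]
  asg <- match_ics_to_templates(ics, templates)
  expect_equal(asg$similarity, rep(1, 3), tolerance = 1e-12)
  expect_identical(asg$ic, c(3L, 1L, 2L))
  expect_identical(asg$flipped, c(FALSE, FALSE, TRUE))
  # independent random maps stay unassigned at the default threshold
  set.seed(4)
  t2 <- matrix(rnorm(2 * 1e4), 2, 1e4)
  ic2 <- matrix(rnorm(2 * 1e4), 2, 1e4)
  asg2 <- match_ics_to_templates(ic2, t2, min_similarity = 0.25)
  expect_true(all(is.na(asg2$ic)))
  asg3 <- match_ics_to_templates(ic2, t2, min_similarity = 0)
  expect_lt(max(asg3$similarity), 0.1)
  expect_error(match_ics_to_templates(matrix(1, 2, 5), matrix(1, 2, 6)),
               "grid")
})

test_that("assignment is invariant to IC presentation order", {
  set.seed(8)
  templates <- matrix(rnorm(4 * 400), 4, 400)
  ics <- templates + matrix(rnorm(4 * 400, sd = 0.8), 4, 400)
  base <- match_ics_to_templates(ics, templates)
  perm <- c(3L, 1L, 4L, 2L)
  shuf <- match_ics_to_templates(ics[perm, ], templates)
  # same template-IC pairs after undoing the shuffle
  expect_identical(perm[shuf$ic], base$ic)
  expect_equal(shuf$similarity, base$similarity, tolerance = 1e-12)
})

test_that("group components are one-sample t-maps with degenerate rules", {
  vals <- c(0.5, 0.7, 0.9, 1.1, 1.3)
  gc <- group_component(cbind(vals, c(-1, 1, -2, 2, 0)))
  # hand value 6.364 on the first voxel; textbook oracle agrees
  expect_equal(gc$tmap[1], 6.363961, tolerance = 1e-6)
  expect_equal(gc$tmap[1], brute_tstat(vals), tolerance = 1e-12)
  # symmetric about zero -> t = 0; zero-variance zero-mean -> t = 0
  m <- cbind(c(-1, 1, -2, 2), 0)
  expect_equal(group_component(m)$tmap, c(0, 0))
  expect_error(group_component(matrix(1, 1, 4)), "2 contributing")
})

test_that("back-projection equals the explicit dot product and is linear", {
  set.seed(5)
  maps <- matrix(rnorm(3 * 4), 3, 4)
  gc <- group_component(maps)
  bold <- matrix(rnorm(4 * 3), 4, 3)
  # brute-force double loop
  expected <- sapply(1:3, function(t) sum(gc$tmap * bold[, t]))
  expect_equal(backproject(gc, bold), expected, tolerance = 1e-12)
  # one-hot template reads out a single voxel; zero template gives zeros
  gc1 <- gc; gc1$tmap <- c(0, 1, 0, 0)
  expect_equal(backproject(gc1, bold), bold[2, ])
  gc0 <- gc; gc0$tmap <- rep(0, 4)
  expect_equal(backproject(gc0, bold), rep(0, 3))
  # linearity
  x <- matrix(rnorm(12), 4, 3); y <- matrix(rnorm(12), 4, 3)
  expect_equal(backproject(gc, 2 * x - 3 * y),
               2 * backproject(gc, x) - 3 * backproject(gc, y),
               tolerance = 1e-12)
  expect_error(backproject(gc, matrix(1, 5, 3)), "grid")
})

test_that("zero-noise IC sets put the extreme group t on template support", {
  templates <- rbind(c(0, 0, 3, 3, 0, 0, 0, 0),
                     c(0, 0, 0, 0, 0, 2, 2, 2))
  sim <- simulate_ic_maps(templates, n_subjects = 4, spatial_noise_sd = 0,
                          sign_flip_prob = 0.5, seed = 12)
  for (tpl in 1:2) {
    assigned <- t(sapply(1:4, function(s) {
      asg <- match_ics_to_templates(sim$subjects[[s]], templates)
      m <- sim$subjects[[s]][asg$ic[tpl], ]
      if (asg$flipped[tpl]) -m else m
    }))
    tm <- group_component(assigned)$tmap
    support <- templates[tpl, ] != 0
    expect_true(min(abs(tm[support])) > max(abs(tm[!support])))
  }
})

test_that("display thresholding zeroes small clusters but not back-projection", {
  set.seed(6)
  # 5x5x1 grid: one 4-voxel blob and one isolated suprathreshold voxel
  blob <- c(7, 8, 12, 13); lone <- 22
  maps <- matrix(rnorm(6 * 25, sd = 0.05), 6, 25)
  maps[, blob] <- maps[, blob] + 5
  maps[, lone] <- maps[, lone] + 5
  gc <- group_component(maps, grid_dims = c(5, 5, 1))
  thr <- threshold_gc(gc, p_threshold = 0.005, min_cluster = 3)
  expect_true(all(thr[blob] != 0))
  expect_identical(thr[lone], 0)
  # unthresholded weights untouched by display settings
  expect_identical(backproject(gc, diag(25))[lone], gc$tmap[lone])
})

test_that("per-volume normalization across RSNs fixes unit variance", {
  expect_equal(normalize_across_rsns(matrix(c(3, -3), 2, 1))[, 1],
               c(0.7071068, -0.7071068), tolerance = 1e-6)
  # already unit-variance columns unchanged
  x <- matrix(rnorm(4 * 10), 4, 10)
  xs <- sweep(x, 2, apply(x, 2, sd), `/`)
  expect_equal(normalize_across_rsns(xs), xs, tolerance = 1e-12,
               ignore_attr = TRUE)
  # constant columns map to zeros
  y <- cbind(c(1, 2, 3), c(5, 5, 5))
  expect_equal(normalize_across_rsns(y)[, 2], c(0, 0, 0))
  out <- normalize_across_rsns(y)
  expect_equal(apply(out, 2, sd)[1], 1, tolerance = 1e-12)
  expect_error(normalize_across_rsns(matrix(1, 1, 5)), "single RSN")
})
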