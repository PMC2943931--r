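test_that("simulated RSN dynamics have the requested AR(1) structure", {
  # white case: lag-1 autocorrelation near 0
  dyn <- simulate_rsn_dynamics(1, 2000, 2, ar = 0, seed = 7)
  x <- dyn[[1]]
  for (r in 1:2) {
    ac <- cor(x[r, -1], x[r, -2000])
    expect_lt(abs(ac), 0.06)
  }
  # persistent case: estimate on a 10,000-sample series
  dyn <- simulate_rsn_dynamics(1, 10000, 1, ar = 0.9, seed = 8)
  ac <- cor(dyn[[1]][1, -1], dyn[[1]][1, -10000])
  expect_lt(abs(ac - 0.9), 0.05)
  # unit marginal variance by construction
  expect_lt(abs(sd(dyn[[1]][1, ]) - 1), 0.1)
})

test_that("dynamics generation is deterministic and validates inputs", {
  a <- simulate_rsn_dynamics(3, 50, 4, ar = 0.5, seed = 123)
  b <- simulate_rsn_dynamics(3, 50, 4, ar = 0.5, seed = 123)
  expect_identical(a, b)
  c <- simulate_rsn_dynamics(3, 50, 4, ar = 0.5, seed = 124)
  expect_false(identical(a, c))
  expect_error(simulate_rsn_dynamics(1, 10, 2, ar = 1), "\\[0, 1\\)")
  expect_error(simulate_rsn_dynamics(1, 10, 2, ar = NaN), "\\[0, 1\\)")
  expect_error(simulate_rsn_dynamics(0, 10, 2), "positive integer")
})

make_coupling <- function(n_rsns, n_bands, n_channels, bands,
                          strength = 1, noise_sd = 1, seed = 1) {
  topo <- with(list(), {
    set.seed(seed)
    x <- array(rnorm(n_rsns * n_bands * n_channels),
               dim = c(n_rsns, n_bands, n_channels))
    x
  })
  coupling_spec(topo, matrix(strength, n_rsns, n_bands), bands, noise_sd)
}

test_that("noiseless single-RSN spectra are exactly topography x dynamics", {
  topo <- array(c(2, -1, 0.5, 3), dim = c(1, 1, 4))
  coup <- coupling_spec(topo, matrix(1.5, 1, 1), list(1:3), noise_sd = 0)
  dyn <- matrix(c(1, -2, 0.5), nrow = 1)
  sim <- simulate_spectra(dyn, coup, n_channels = 4, n_bins = 3, seed = 5)
  amp <- sim$spectra$amplitudes
  for (t in 1:3) for (f in 1:3)
    expect_equal(amp[t, , f], 1.5 * topo[1, 1, ] * dyn[1, t])
})

test_that("zero coupling yields pure-noise spectra with null-centered t-maps", {
  dyn <- simulate_rsn_dynamics(6, 40, 2, ar = 0, seed = 21)
  dyn <- lapply(dyn, normalize_across_rsns)
  coup <- make_coupling(2, 2, 8, bands = list(1:3, 4:6),
                        strength = 0, noise_sd = 1)
  slices <- lapply(seq_along(dyn), function(s) {
    sim <- simulate_spectra(dyn[[s]], coup, 8, 6, seed = 100 + s)
    covariance_map(normalize_spectra(sim$spectra), dyn[[s]])
  })
  tm <- tmap(covariance_tensor(slices))
  expect_lt(abs(mean(tm$t)), 0.15)      # group t-maps center on zero
  expect_lt(max(abs(tm$t)), 8)          # no planted structure
})

test_that("spectra generation validates coupling dimensions", {
  coup <- make_coupling(2, 1, 4, bands = list(1:2))
  dyn <- matrix(rnorm(20), 2, 10)
  expect_error(simulate_spectra(dyn, coup, n_channels = 5, n_bins = 2, seed = 1),
               "channels")
  expect_error(simulate_spectra(dyn, coup, n_channels = 4, n_bins = 1, seed = 1),
               "bin")
  expect_error(simulate_spectra(matrix(rnorm(30), 3, 10), coup, 4, 2, seed = 1),
               "RSNs")
  expect_error(coupling_spec(array(1, c(1, 1, 4)), matrix(1, 1, 1),
                             list(1:2), noise_sd = -1), "non-negative")
})

test_that("epoch dropout masks epochs without deleting them", {
  coup <- make_coupling(2, 1, 4, bands = list(1:2))
  dyn <- matrix(rnorm(40), 2, 20)
  sim <- simulate_spectra(dyn, coup, 4, 2, seed = 3, dropout = 0.25)
  expect_length(sim$spectra$valid, 20)
  expect_identical(sum(!sim$spectra$valid), 5L)
  expect_true(all(is.na(sim$spectra$amplitudes[!sim$spectra$valid, , ])))
})

test_that("simulated IC maps recover the identity assignment", {
  set.seed(42)
  templates <- matrix(rnorm(5 * 200), 5, 200)
  # clean case: exact recovery with similarity 1
  sim <- simulate_ic_maps(templates, n_subjects = 3, spatial_noise_sd = 0,
                          sign_flip_prob = 0, seed = 9)
  for (s in 1:3) {
    asg <- match_ics_to_templates(sim$subjects[[s]], templates)
    expect_equal(asg$similarity, rep(1, 5), tolerance = 1e-12)
    expect_identical(order(sim$truth[[s]]$order), asg$ic)
    expect_false(any(asg$flipped))
  }
  # all-flipped case: sign-invariant similarity still recovers the mapping
  sim <- simulate_ic_maps(templates, n_subjects = 2, spatial_noise_sd = 0,
                          sign_flip_prob = 1, seed = 10)
  for (s in 1:2) {
    asg <- match_ics_to_templates(sim$subjects[[s]], templates)
    expect_equal(asg$similarity, rep(1, 5), tolerance = 1e-12)
    expect_true(all(asg$flipped))
  }
  expect_error(simulate_ic_maps(templates, 2, spatial_noise_sd = -1),
               "non-negative")
})

test_that("moderate spatial noise gives the similarity regime of real group ICA", {
  set.seed(1)
  templates <- matrix(rnorm(5 * 500), 5, 500)
  sim <- simulate_ic_maps(templates, n_subjects = 10, spatial_noise_sd = 2.2,
                          sign_flip_prob = 0.5, seed = 11)
  sims <- unlist(lapply(sim$subjects, function(m)
    match_ics_to_templates(m, templates, min_similarity = 0)$similarity))
  expect_gt(mean(sims), 0.3)   # above the floor reported for IC clustering
  expect_lt(mean(sims), 0.6)
})

test_that("the whole generator is bit-identical under a fixed master seed", {
  run <- function() {
    dyn <- simulate_rsn_dynamics(2, 30, 3, ar = 0.4, seed = 77)
    coup <- make_coupling(3, 2, 6, bands = list(1:2, 3:4))
    simulate_spectra(dyn, coup, 6, 4, seed = 78, dropout = 0.1)
  }
  expect_identical(run(), run())
})

test_that("zero-coupling pipelines reject at the nominal rate", {
  # full generator -> normalization -> covariance -> consistency test, with
  # no planted coupling: the fraction of (RSN, band) maps significant at
  # alpha = 0.05 must match the nominal level (within +-0.03 over 500
  # datasets)
  coup <- make_coupling(2, 2, 8, bands = list(1:3, 4:6),
                        strength = 0, noise_sd = 1)
  n_data <- 500L
  hits <- 0L; total <- 0L
  for (d in seq_len(n_data)) {
    dyn <- simulate_rsn_dynamics(6, 40, 2, ar = 0, seed = 1000 + d)
    dyn <- lapply(dyn, normalize_across_rsns)
    slices <- lapply(seq_along(dyn), function(s) {
      sim <- simulate_spectra(dyn[[s]], coup, 8, 6, seed = 5000 + 10 * d + s)
      covariance_map(normalize_spectra(sim$spectra), dyn[[s]])
    })
    cb <- band_average(covariance_tensor(slices),
                       band_partition(c(3, 6), c("lo", "hi"), 1:6, tol = 0))
    for (r in 1:2) for (b in 1:2) {
      res <- consistency_test(matrix(cb[, r, b, ], nrow = 6),
                              n_perm = 199, seed = 90000 + total)
      hits <- hits + (res$p <= 0.05)
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.02)
  expect_lte(hits / total, 0.08)
})
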