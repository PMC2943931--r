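# Global randomization statistics: the topographic consistency test and
# one-/two-factorial TANOVA. All tests reduce a multichannel map to a single
# global statistic (an RMS across channels), so no electrode pre-selection
# or multiple-testing correction over channels is needed.

rand_test_result <- function(statistic, null, n_perm, seed) {
  p <- (1 + sum(null >= statistic)) / (n_perm + 1)
  structure(list(statistic = statistic, null = null, p = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "rand_test")
}

#' @export
print.rand_test <- function(x, ...) {
  cat(sprintf("<rand_test> statistic = %.6g, p = %.4g (%d permutations, seed %d)\n",
              x$statistic, x$p, x$n_perm, x$seed))
  invisible(x)
}

#' Topographic consistency test
#'
#' Tests whether a set of per-subject channel maps shares a common spatial
#' structure. Under the null hypothesis the values at every electrode have
#' zero mean across subjects, so the observed statistic -- the RMS across
#' channels of the across-subject mean map -- should be no larger than what
#' arises when each subject's values are randomly shuffled among electrodes
#' (which preserves each subject's overall variance but destroys any common
#' topography). The p-value is `(1 + #{null >= observed}) / (n_perm + 1)`,
#' counting ties as exceedances so p is never zero.
#'
#' @param maps numeric matrix, subjects x channels (`>= 2` each).
#' @param n_perm number of random shuffles.
#' @param seed integer seed.
#' @return a `rand_test` object (`statistic`, `null`, `p`, `n_perm`, `seed`).
#' @export
consistency_test <- function(maps, n_perm = 5000L, seed = 1L) {
  stopifnot(is.matrix(maps))
  n_s <- nrow(maps); n_c <- ncol(maps)
  if (n_s < 2L || n_c < 2L)
    stop("need at least 2 subjects and 2 channels")
  obs <- rms(.colMeans(maps, n_s, n_c))
  rows <- lapply(seq_len(n_s), function(s) maps[s, ])
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      acc <- numeric(n_c)
      for (s in seq_len(n_s)) acc <- acc + rows[[s]][sample.int(n_c)]
      rms(acc / n_s)
    }, numeric(1))
  })
  rand_test_result(obs, null, n_perm, seed)
}

# statistic shared by the TANOVA variants, computed from the levels x
# channels matrix of condition-mean maps: mean over conditions of the RMS
# across channels of (condition-mean map - grand-mean map)
tanova_statistic_lm <- function(lm) {
  n_l <- nrow(lm); n_c <- ncol(lm)
  gm <- .colMeans(lm, n_l, n_c)
  dev <- lm - rep(gm, each = n_l)
  mean(sqrt(.rowMeans(dev * dev, n_l, n_c)))
}

tanova_statistic <- function(maps) {        # subjects x levels x channels
  d <- dim(maps)
  lm <- matrix(.colMeans(matrix(maps, nrow = d[1]), d[1], d[2] * d[3]),
               d[2], d[3])
  tanova_statistic_lm(lm)
}

#' One-way repeated-measures TANOVA
#'
#' Tests for differences between condition maps with a single global
#' dissimilarity measure: the mean over levels of the RMS across channels of
#' the deviation of each level's mean map from the grand-mean map. The null
#' distribution permutes, independently within every subject, that subject's
#' maps across levels, so the repeated-measures structure is respected.
#'
#' @param maps numeric array, subjects x levels x channels (complete
#'   design, `>= 2` levels).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return a `rand_test` object.
#' @export
tanova_oneway <- function(maps, n_perm = 5000L, seed = 1L) {
  stopifnot(is.array(maps), length(dim(maps)) == 3L)
  d <- dim(maps)
  if (d[1] < 2L || d[2] < 2L) stop("need >= 2 subjects and >= 2 levels")
  if (anyNA(maps)) stop("incomplete repeated-measures design (missing cells)")
  obs <- tanova_statistic(maps)
  Ms <- lapply(seq_len(d[1]), function(s)
    matrix(maps[s, , ], d[2], d[3]))        # per-subject levels x channels
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      acc <- matrix(0, d[2], d[3])
      for (s in seq_len(d[1]))
        acc <- acc + Ms[[s]][sample.int(d[2]), ]
      tanova_statistic_lm(acc / d[1])
    }, numeric(1))
  })
  rand_test_result(obs, null, n_perm, seed)
}

#' Two-factorial repeated-measures TANOVA
#'
#' Tests the two main effects and their interaction on a crossed
#' within-subject design of channel maps. Each main effect collapses (by
#' mean) over the other factor and applies the one-way scheme. The
#' interaction removes, subject by subject, the subject's additive model
#' (grand mean + row effect + column effect from that subject's cell means)
#' and tests the residual cell means: the statistic is the mean over cells
#' of the RMS across channels of the across-subject residual means. Its null
#' randomly flips the sign of each subject's whole residual set
#' (sign-flipping of within-subject residuals): the residuals span only the
#' interaction subspace and are sign-symmetric under the null hypothesis, so
#' this reflection scheme is exactly calibrated and immune to main-effect
#' leakage. The three p-values are reported independently.
#'
#' @param maps numeric array, subjects x A-levels x B-levels x channels
#'   (complete crossed design, `>= 2` levels per factor).
#' @param n_perm number of permutations.
#' @param seed integer seed; the three component tests use seeds derived
#'   from it.
#' @return list with `rand_test` objects `A`, `B`, `interaction`.
#' @export
tanova_twofactor <- function(maps, n_perm = 5000L, seed = 1L) {
  stopifnot(is.array(maps), length(dim(maps)) == 4L)
  d <- dim(maps)
  if (d[1] < 2L || d[2] < 2L || d[3] < 2L)
    stop("need >= 2 subjects and >= 2 levels per factor")
  if (anyNA(maps)) stop("incomplete crossed design (missing cells)")
  seeds <- derive_seeds(seed, 3L)
  mapsA <- apply(maps, c(1, 2, 4), mean)     # collapse over B
  mapsB <- apply(maps, c(1, 3, 4), mean)     # collapse over A
  resA <- tanova_oneway(mapsA, n_perm = n_perm, seed = seeds[1])
  resB <- tanova_oneway(mapsB, n_perm = n_perm, seed = seeds[2])

  # interaction: within-subject residuals from the additive model, per
  # channel. The residual maps live entirely in the interaction subspace and
  # are sign-symmetric across subjects under the null, so the null sample
  # flips the sign of each subject's whole residual set at random -- an
  # exactly calibrated reflection scheme that is unaffected by main effects
  n_cells <- d[2] * d[3]
  a_idx <- rep(seq_len(d[2]), times = d[3])   # cell layout: A fastest
  b_idx <- rep(seq_len(d[3]), each = d[2])
  Rs <- lapply(seq_len(d[1]), function(s) {
    cells <- matrix(maps[s, , , ], n_cells, d[4])
    residualize_cells(cells, a_idx, b_idx)
  })
  cm <- Reduce(`+`, Rs) / d[1]
  obs <- mean(sqrt(.rowMeans(cm * cm, n_cells, d[4])))
  null <- with_seed(seeds[3], {
    vapply(seq_len(n_perm), function(bb) {
      flips <- sample(c(-1, 1), d[1], replace = TRUE)
      acc <- matrix(0, n_cells, d[4])
      for (s in seq_len(d[1])) acc <- acc + flips[s] * Rs[[s]]
      cm <- acc / d[1]
      mean(sqrt(.rowMeans(cm * cm, n_cells, d[4])))
    }, numeric(1))
  })
  list(A = resA, B = resB,
       interaction = rand_test_result(obs, null, n_perm, seeds[3]))
}

# remove the additive (grand + row + column) model from a cells x channels
# matrix of one subject's maps; a_idx/b_idx give each cell's factor levels
residualize_cells <- function(cells, a_idx, b_idx) {
  n_cells <- nrow(cells)
  a_means <- rowsum.default(cells, a_idx, reorder = TRUE) /
    tabulate(a_idx)[sort(unique(a_idx))]
  b_means <- rowsum.default(cells, b_idx, reorder = TRUE) /
    tabulate(b_idx)[sort(unique(b_idx))]
  grand <- .colMeans(cells, n_cells, ncol(cells))
  cells - a_means[a_idx, , drop = FALSE] - b_means[b_idx, , drop = FALSE] +
    rep(grand, each = n_cells)
}

#' Full randomization battery on a band-averaged covariance tensor
#'
#' Runs the complete statistical program for one dataset: the topographic
#' consistency test for every (RSN, band) covariance map, the overall
#' two-factorial TANOVA with RSN and band as repeated measures, and one-way
#' TANOVAs over RSNs separately within each band. All component tests draw
#' their seeds deterministically from `seed`, so the whole table reproduces
#' bit-for-bit.
#'
#' @param cov_bands a band-averaged [covariance_tensor()]
#'   (subjects x RSNs x bands x channels).
#' @param n_perm permutations per test.
#' @param seed master integer seed.
#' @param alpha significance level used for the `significant` column.
#' @return list with `consistency` (data.frame: rsn, band, statistic, p,
#'   significant, n_perm, seed), `overall` (two-factor TANOVA results), and
#'   `per_band` (data.frame: band, statistic, p).
#' @export
covmap_battery <- function(cov_bands, n_perm = 5000L, seed = 1L,
                           alpha = 0.05) {
  stopifnot(is.array(cov_bands), length(dim(cov_bands)) == 4L)
  d <- dim(cov_bands)
  band_names <- attr(cov_bands, "bands") %||% sprintf("band%d", seq_len(d[3]))
  n_maps <- d[2] * d[3]
  seeds <- derive_seeds(seed, n_maps + 1L + d[3])
  rows <- vector("list", n_maps)
  i <- 0L
  for (r in seq_len(d[2])) for (b in seq_len(d[3])) {
    i <- i + 1L
    res <- consistency_test(matrix(cov_bands[, r, b, ], nrow = d[1]),
                            n_perm = n_perm, seed = seeds[i])
    rows[[i]] <- data.frame(rsn = r, band = band_names[b],
                            statistic = res$statistic, p = res$p,
                            significant = res$p < alpha,
                            n_perm = n_perm, seed = seeds[i])
  }
  consistency <- do.call(rbind, rows)
  overall <- tanova_twofactor(cov_bands, n_perm = n_perm,
                              seed = seeds[n_maps + 1L])
  pb <- lapply(seq_len(d[3]), function(b) {
    res <- tanova_oneway(array(cov_bands[, , b, ], dim = d[c(1, 2, 4)]),
                         n_perm = n_perm, seed = seeds[n_maps + 1L + b])
    data.frame(band = band_names[b], statistic = res$statistic, p = res$p,
               n_perm = n_perm, seed = seeds[n_maps + 1L + b])
  })
  list(consistency = consistency, overall = overall,
       per_band = do.call(rbind, pb))
}
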