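#' Coupling specification for synthetic EEG--RSN data
#'
#' Describes how planted network dynamics drive the synthetic EEG spectra:
#' for every (RSN, band) pair a scalp topography (one weight per channel) and
#' a scalar coupling strength, plus the standard deviation of the additive
#' i.i.d. Gaussian noise and the band definitions over retained bin indices.
#' Bins not covered by any band receive pure noise.
#'
#' @param topographies numeric array, RSNs x bands x channels; finite.
#' @param strengths numeric matrix, RSNs x bands.
#' @param bands list of integer vectors of retained-bin indices (1-based),
#'   pairwise disjoint.
#' @param noise_sd standard deviation of the additive noise, `>= 0`.
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(topographies, strengths, bands, noise_sd = 1) {
  stopifnot(is.array(topographies), length(dim(topographies)) == 3L,
            is.matrix(strengths),
            all(dim(strengths) == dim(topographies)[1:2]),
            is.list(bands), length(bands) == dim(topographies)[2])
  if (!all(is.finite(topographies))) stop("topographies must be finite")
  if (!all(is.finite(strengths))) stop("strengths must be finite")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || !is.finite(noise_sd) ||
      noise_sd < 0)
    stop("`noise_sd` must be a single non-negative number")
  idx <- unlist(bands)
  if (length(idx) && (anyDuplicated(idx) || any(idx < 1 | idx != round(idx))))
    stop("`bands` must be disjoint sets of positive bin indices")
  structure(list(topographies = topographies, strengths = strengths,
                 bands = lapply(bands, as.integer), noise_sd = noise_sd),
            class = "coupling_spec")
}

#' Default coupling specification at study scale
#'
#' Plants an independent random smooth topography (zero mean, unit RMS across
#' channels) for every (RSN, band) pair, all with a common coupling strength.
#' With the defaults every one of the 10 x 8 = 80 (RSN, band) combinations
#' carries a detectable planted effect at n = 20 subjects.
#'
#' @param n_rsns,n_channels counts.
#' @param partition a band partition (see [band_partition()]); defaults to
#'   the canonical 8-band layout over the 75 retained bins.
#' @param strength common coupling strength.
#' @param noise_sd additive noise standard deviation.
#' @param seed integer seed for the topography draw.
#' @return a [coupling_spec()].
#' @export
default_coupling <- function(n_rsns = 10L, n_channels = 92L,
                             partition = reference_bands(),
                             strength = 1, noise_sd = 1, seed = 1L) {
  n_bands <- nrow(partition)
  topo <- with_seed(seed, {
    x <- array(stats::rnorm(n_rsns * n_bands * n_channels),
               dim = c(n_rsns, n_bands, n_channels))
    for (r in seq_len(n_rsns)) for (b in seq_len(n_bands)) {
      v <- x[r, b, ]
      v <- v - mean(v)
      x[r, b, ] <- v / rms(v)
    }
    x
  })
  coupling_spec(topo, matrix(strength, n_rsns, n_bands),
                attr(partition, "bins"), noise_sd = noise_sd)
}

#' Simulate per-subject RSN activity timecourses
#'
#' Draws, for each subject, an RSNs x volumes matrix of stationary
#' first-order autoregressive Gaussian series with lag-1 autocorrelation
#' `ar` and unit marginal variance (innovation sd `sqrt(1 - ar^2)`).
#' Regeneration with the same seed is bit-identical.
#'
#' @param n_subjects,n_volumes,n_rsns counts (all `>= 1`).
#' @param ar autoregressive coefficient in `[0, 1)`.
#' @param seed integer seed.
#' @param tr repetition time in seconds (metadata only).
#' @return list of RSNs x volumes matrices, one per subject.
#' @export
simulate_rsn_dynamics <- function(n_subjects, n_volumes, n_rsns, ar = 0.3,
                                  seed = 1L, tr = 1.98) {
  stop_if_not_scalar_count(n_subjects, "n_subjects")
  stop_if_not_scalar_count(n_volumes, "n_volumes")
  stop_if_not_scalar_count(n_rsns, "n_rsns")
  if (!is.numeric(ar) || length(ar) != 1L || !is.finite(ar) || ar < 0 || ar >= 1)
    stop("`ar` must be a finite number in [0, 1)")
  with_seed(seed, lapply(seq_len(n_subjects), function(s) {
    x <- matrix(0, n_rsns, n_volumes)
    x[, 1] <- stats::rnorm(n_rsns)
    if (n_volumes > 1L) {
      innov_sd <- sqrt(1 - ar^2)
      for (t in 2:n_volumes)
        x[, t] <- ar * x[, t - 1] + stats::rnorm(n_rsns, sd = innov_sd)
    }
    attr(x, "tr") <- tr
    x
  }))
}

#' Simulate coupled EEG spectral epochs
#'
#' Builds, for each subject, an epochs x channels x bins amplitude tensor in
#' which the amplitude at (epoch t, channel c, bin f) is
#' `sum_r strength(r, band(f)) * topography(r, band(f), c) * dynamics(r, t)`
#' plus i.i.d. Gaussian noise; one epoch per volume (positional pairing).
#' Epoch dropout is modeled by masking, not deletion.
#'
#' @param rsn_dynamics a single RSNs x volumes matrix or a list of them (one
#'   per subject), e.g. from [simulate_rsn_dynamics()].
#' @param coupling a [coupling_spec()].
#' @param n_channels,n_bins counts; must match the coupling spec.
#' @param seed integer seed.
#' @param dropout fraction of epochs to mask invalid (default 0).
#' @param freqs bin center frequencies; defaults to the standard 75-bin
#'   layout when `n_bins` is 75, otherwise to the bin index in Hz-less units.
#' @return for a single matrix, a list with `spectra` (a
#'   [spectral_epochs()]) and `truth`; for a list input, lists of each.
#'   `truth` records the coupling spec, seed, and the dynamics used.
#' @export
simulate_spectra <- function(rsn_dynamics, coupling, n_channels, n_bins,
                             seed = 1L, dropout = 0, freqs = NULL) {
  stopifnot(inherits(coupling, "coupling_spec"))
  stop_if_not_scalar_count(n_channels, "n_channels")
  stop_if_not_scalar_count(n_bins, "n_bins")
  if (dim(coupling$topographies)[3] != n_channels)
    stop("coupling topographies define ", dim(coupling$topographies)[3],
         " channels but n_channels = ", n_channels)
  bidx <- unlist(coupling$bands)
  if (length(bidx) && max(bidx) > n_bins)
    stop("coupling bands reference bin ", max(bidx),
         " but n_bins = ", n_bins)
  if (is.null(freqs))
    freqs <- if (n_bins == 75L) frequency_bins()$freq else seq_len(n_bins)
  if (is.list(rsn_dynamics)) {
    seeds <- derive_seeds(seed, length(rsn_dynamics))
    out <- lapply(seq_along(rsn_dynamics), function(s)
      simulate_spectra(rsn_dynamics[[s]], coupling, n_channels, n_bins,
                       seed = seeds[s], dropout = dropout, freqs = freqs))
    return(list(spectra = lapply(out, `[[`, "spectra"),
                truth = lapply(out, `[[`, "truth")))
  }
  dyn <- rsn_dynamics
  stopifnot(is.matrix(dyn))
  if (nrow(dyn) != dim(coupling$topographies)[1])
    stop("dynamics define ", nrow(dyn), " RSNs but the coupling spec has ",
         dim(coupling$topographies)[1])
  n_t <- ncol(dyn)
  amp <- with_seed(seed, {
    a <- array(stats::rnorm(n_t * n_channels * n_bins,
                            sd = coupling$noise_sd),
               dim = c(n_t, n_channels, n_bins))
    for (b in seq_along(coupling$bands)) {
      bins <- coupling$bands[[b]]
      if (!length(bins)) next
      w <- coupling$strengths[, b] * coupling$topographies[, b, , drop = TRUE]
      if (nrow(dyn) == 1L) w <- matrix(coupling$strengths[1, b] *
                                         coupling$topographies[1, b, ], nrow = 1L)
      sig <- crossprod(dyn, w)                      # volumes x channels
      for (f in bins) a[, , f] <- a[, , f] + sig
    }
    a
  })
  valid <- rep(TRUE, n_t)
  if (dropout > 0) {
    n_drop <- floor(dropout * n_t)
    if (n_drop > 0) {
      drop_idx <- with_seed(seed + 1L, sample.int(n_t, n_drop))
      valid[drop_idx] <- FALSE
      amp[drop_idx, , ] <- NA_real_
    }
  }
  truth <- structure(list(coupling = coupling, seed = seed, dynamics = dyn),
                     class = "ground_truth")
  list(spectra = spectral_epochs(amp, freqs, valid = valid, normalized = FALSE),
       truth = truth)
}

#' Simulate per-subject IC maps around group templates
#'
#' Each subject's independent-component maps are the templates plus i.i.d.
#' Gaussian spatial noise, presented in shuffled order and with random sign
#' flips to emulate the sign indeterminacy of ICA.
#'
#' @param templates numeric matrix, templates x voxels (common grid).
#' @param n_subjects count.
#' @param spatial_noise_sd noise standard deviation, `>= 0`.
#' @param sign_flip_prob probability that a component's sign is flipped.
#' @param seed integer seed.
#' @return list with `subjects` (list of component x voxel matrices) and
#'   `truth` (per subject, the template order and sign flips used).
#' @export
simulate_ic_maps <- function(templates, n_subjects, spatial_noise_sd = 0.5,
                             sign_flip_prob = 0.5, seed = 1L) {
  stopifnot(is.matrix(templates), nrow(templates) >= 1L)
  stop_if_not_scalar_count(n_subjects, "n_subjects")
  if (!is.numeric(spatial_noise_sd) || spatial_noise_sd < 0)
    stop("`spatial_noise_sd` must be non-negative")
  stopifnot(sign_flip_prob >= 0, sign_flip_prob <= 1)
  n_c <- nrow(templates); n_v <- ncol(templates)
  with_seed(seed, {
    subjects <- vector("list", n_subjects)
    truth <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      ord <- sample.int(n_c)
      flips <- ifelse(stats::runif(n_c) < sign_flip_prob, -1, 1)
      maps <- templates[ord, , drop = FALSE] * flips +
        matrix(stats::rnorm(n_c * n_v, sd = spatial_noise_sd), n_c, n_v)
      subjects[[s]] <- maps
      truth[[s]] <- list(order = ord, flips = flips)
    }
    list(subjects = subjects, truth = truth)
  })
}
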