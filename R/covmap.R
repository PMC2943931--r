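#' Subject-level covariance map between EEG spectra and RSN dynamics
#'
#' For one subject, dot-multiplies the dynamics of the normalized spectral
#' amplitude at every electrode and frequency bin with the dynamics of every
#' network: `cov(r, f, c) = sum_t amplitude(t, c, f) * activity(r, t)` over
#' the valid epoch/volume pairs (positional pairing; volumes whose epoch is
#' invalid are dropped pairwise). The raw dot product is kept, with no
#' rescaling by the number of valid pairs; the pair count is returned so a
#' caller may rescale when subjects differ in usable epochs.
#'
#' @param spectra a normalized [spectral_epochs()] object.
#' @param dynamics numeric matrix, RSNs x volumes (one column per epoch).
#' @return numeric array RSNs x bins x channels with attribute
#'   `n_valid_pairs`.
#' @export
covariance_map <- function(spectra, dynamics) {
  stopifnot(inherits(spectra, "spectral_epochs"), is.matrix(dynamics))
  if (!spectra$normalized)
    stop("spectra must be normalized (see normalize_spectra()) before mapping")
  d <- dim(spectra$amplitudes)
  if (ncol(dynamics) != d[1])
    stop("dynamics has ", ncol(dynamics), " volumes but spectra has ",
         d[1], " epochs (pairing is positional)")
  vidx <- which(spectra$valid)
  if (length(vidx) < 2L) stop("need at least 2 valid epoch/volume pairs")
  amp <- spectra$amplitudes[vidx, , , drop = FALSE]     # T x C x F
  act <- dynamics[, vidx, drop = FALSE]                 # R x T
  flat <- matrix(amp, nrow = length(vidx))              # T x (C*F), c fastest
  cv <- act %*% flat                                    # R x (C*F)
  out <- aperm(array(cv, dim = c(nrow(dynamics), d[2], d[3])), c(1, 3, 2))
  attr(out, "n_valid_pairs") <- length(vidx)
  attr(out, "freqs") <- spectra$freqs
  out
}

#' Stack subject covariance maps into the group tensor
#'
#' @param slices list of per-subject RSNs x bins x channels arrays from
#'   [covariance_map()].
#' @return object of class `cov_tensor`: array subjects x RSNs x bins x
#'   channels with `freqs`, `axis` ("bins") and per-subject
#'   `n_valid_pairs` attributes.
#' @export
covariance_tensor <- function(slices) {
  stopifnot(is.list(slices), length(slices) >= 1L)
  d <- dim(slices[[1]])
  for (s in slices) if (!identical(dim(s), d))
    stop("all subject slices must have identical dimensions")
  out <- array(NA_real_, dim = c(length(slices), d))
  for (i in seq_along(slices)) out[i, , , ] <- slices[[i]]
  structure(out,
            freqs = attr(slices[[1]], "freqs"),
            axis = "bins",
            n_valid_pairs = vapply(slices, function(s)
              as.integer(attr(s, "n_valid_pairs") %||% NA_integer_), 1L),
            class = "cov_tensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group t-maps of a covariance tensor
#'
#' One-sample t-test against zero across subjects for every (RSN, bin/band,
#' channel) cell: `t = mean / (SD / sqrt(n))` with the n-1 SD. Since the data
#' are centered across epochs upstream, these t-values serve as standardized
#' signal-to-noise indices across subjects. Zero-variance cells map to 0 when
#' the mean is zero and to a flagged +-1e12 sentinel otherwise.
#'
#' @param cov a [covariance_tensor()] (subjects x RSNs x bins x channels).
#' @return object of class `tmap_set`: list with `t` (RSNs x bins x
#'   channels), `degenerate` flags, `n`, `freqs`, `axis`.
#' @export
tmap <- function(cov) {
  stopifnot(is.array(cov), length(dim(cov)) == 4L)
  d <- dim(cov)
  if (d[1] < 2L) stop("need at least 2 subjects")
  flat <- matrix(cov, nrow = d[1])
  ts <- tstat_cols(flat)
  structure(list(t = array(ts$t, dim = d[2:4]),
                 degenerate = array(ts$degenerate, dim = d[2:4]),
                 n = d[1],
                 freqs = attr(cov, "freqs"),
                 axis = attr(cov, "axis") %||% "bins"),
            class = "tmap_set")
}

#' Frequency-band partition
#'
#' Maps every retained frequency bin to exactly one named, contiguous band.
#' A bin belongs to the band whose interval `(lower, upper]` contains its
#' center, evaluated with a tolerance of half the bin resolution on the upper
#' border: printed band borders are conventionally rounded bin centers, so
#' the half-bin tolerance keeps the last bin of each band with its band.
#'
#' @param breaks increasing upper borders in Hz, one per band; the last must
#'   cover the highest retained bin (within tolerance).
#' @param names band names.
#' @param freqs retained bin center frequencies in Hz.
#' @param tol border tolerance in Hz; defaults to half the bin spacing.
#' @param first_lower printed lower border of the first band (cosmetic; bin
#'   assignment always starts at the first retained bin).
#' @return object of class `band_partition`: data.frame (`name`, `lower`,
#'   `upper`, `n_bins`) with a `bins` attribute listing member bin indices.
#' @export
band_partition <- function(breaks, names, freqs,
                           tol = (freqs[2] - freqs[1]) / 2,
                           first_lower = min(freqs) - (freqs[2] - freqs[1])) {
  stopifnot(length(breaks) == length(names), !is.unsorted(breaks, strictly = TRUE),
            !is.unsorted(freqs, strictly = TRUE))
  upper <- breaks + tol
  lower <- c(-Inf, utils::head(upper, -1))
  bins <- lapply(seq_along(breaks), function(j)
    which(freqs > lower[j] & freqs <= upper[j]))
  covered <- sort(unlist(bins))
  if (!identical(covered, seq_along(freqs)))
    stop("band partition must cover every retained bin exactly once; ",
         "uncovered or doubly covered bins: ",
         paste(setdiff(seq_along(freqs), covered), collapse = ", "))
  out <- data.frame(name = as.character(names),
                    lower = c(first_lower, breaks[-length(breaks)]),
                    upper = breaks,
                    n_bins = lengths(bins), stringsAsFactors = FALSE)
  attr(out, "bins") <- bins
  attr(out, "freqs") <- freqs
  class(out) <- c("band_partition", "data.frame")
  out
}

#' Canonical 8-band partition of the 75 retained bins
#'
#' The standard EEG band layout over the 1--30 Hz range at 0.39 Hz
#' resolution: delta <= 3.5, theta1 <= 6.25, theta2 <= 8.2, alpha1 <= 10.5,
#' alpha2 <= 14.0, beta1 <= 18.75, beta2 <= 21.88, beta3 <= 30.0 Hz (upper
#' borders exclusive below, inclusive above; borders are rounded bin
#' centers). Member bin counts are 7, 7, 5, 6, 9, 12, 8, 21.
#'
#' @param freqs retained bin center frequencies; defaults to the standard
#'   75-bin layout.
#' @return a [band_partition()].
#' @export
reference_bands <- function(freqs = frequency_bins()$freq) {
  band_partition(breaks = c(3.5, 6.25, 8.2, 10.5, 14.0, 18.75, 21.88, 30.0),
                 names = c("delta", "theta1", "theta2", "alpha1", "alpha2",
                           "beta1", "beta2", "beta3"),
                 freqs = freqs, first_lower = 1.0)
}

#' Band-averaged covariance tensor
#'
#' Collapses the frequency axis to bands by the unweighted mean over each
#' band's member bins, per subject, RSN and channel.
#'
#' @param cov a [covariance_tensor()] over bins.
#' @param partition a [band_partition()] covering all retained bins.
#' @return a `cov_tensor` over bands (`axis = "bands"`, `bands` attribute).
#' @export
band_average <- function(cov, partition) {
  stopifnot(is.array(cov), length(dim(cov)) == 4L,
            inherits(partition, "band_partition"))
  bins <- attr(partition, "bins")
  d <- dim(cov)
  if (!identical(sort(unlist(bins)), seq_len(d[3])))
    stop("partition must cover the tensor's ", d[3],
         " bins exactly once (no gaps, no overlap)")
  out <- array(NA_real_, dim = c(d[1], d[2], length(bins), d[4]))
  for (j in seq_along(bins)) {
    sub <- cov[, , bins[[j]], , drop = FALSE]
    out[, , j, ] <- apply(sub, c(1, 2, 4), mean)
  }
  structure(out, axis = "bands", bands = partition$name,
            n_valid_pairs = attr(cov, "n_valid_pairs"),
            class = "cov_tensor")
}
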