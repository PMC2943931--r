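#' Frequency-bin bookkeeping for pre-scan EEG epochs
#'
#' Computes the DFT bin layout for an epoch of `n_samples` samples at
#' `rate` Hz restricted to a frequency band. With the default 256 samples at
#' 100 Hz the resolution is 0.390625 Hz and the 1--30 Hz band retains 75 bins
#' (harmonics k = 3 ... 77, centers 1.17--30.08 Hz).
#'
#' Two conventions for the band edges are supported. `"count"` (default)
#' takes bins `floor(lo/res)+1` through `floor(hi/res)+1`, which reproduces
#' the conventional 75-bin count for 1--30 Hz; `"interval"` takes the bins
#' whose centers fall in the closed interval `[lo, hi]` (74 bins for the
#' default layout).
#'
#' @param n_samples epoch length in samples.
#' @param rate sampling rate in Hz.
#' @param band numeric length-2, band limits in Hz (must lie below Nyquist).
#' @param rule `"count"` or `"interval"`; see Details.
#' @return list with `k` (harmonic numbers), `freq` (bin centers, Hz),
#'   `resolution` (Hz), `n_bins`.
#' @export
frequency_bins <- function(n_samples = 256L, rate = 100, band = c(1, 30),
                           rule = c("count", "interval")) {
  rule <- match.arg(rule)
  stop_if_not_scalar_count(n_samples, "n_samples")
  stopifnot(is.numeric(rate), rate > 0, length(band) == 2L, band[1] < band[2])
  if (band[2] > rate / 2)
    stop(sprintf("band upper limit %.3g Hz exceeds the Nyquist frequency %.3g Hz",
                 band[2], rate / 2))
  res <- rate / n_samples
  k <- switch(rule,
    count    = (floor(band[1] / res) + 1L):(floor(band[2] / res) + 1L),
    interval = ceiling(band[1] / res):floor(band[2] / res))
  list(k = as.integer(k), freq = k * res, resolution = res, n_bins = length(k))
}

#' Epoch window preceding each scan onset
#'
#' Defines the fixed-length EEG segment extracted before every MR volume
#' onset to account for the hemodynamic delay: by default 256 datapoints at
#' 100 Hz starting 6560 ms before the scan marker (so the window ends
#' 4000 ms before the marker).
#'
#' @param start_offset_ms window start, in ms before the marker.
#' @param n_samples samples per epoch.
#' @param rate sampling rate in Hz.
#' @return an object of class `epoch_window`.
#' @export
epoch_window <- function(start_offset_ms = 6560, n_samples = 256L, rate = 100) {
  stop_if_not_scalar_count(n_samples, "n_samples")
  stopifnot(is.numeric(start_offset_ms), start_offset_ms > 0,
            is.numeric(rate), rate > 0)
  if (start_offset_ms <= n_samples * 1000 / rate)
    stop("epoch window must lie entirely before the marker: ",
         "start_offset_ms must exceed n_samples * 1000 / rate")
  structure(list(start_offset_ms = start_offset_ms,
                 n_samples = as.integer(n_samples), rate = rate),
            class = "epoch_window")
}

#' Extract pre-scan epochs from continuous EEG
#'
#' Epoch i starts `round(start_offset_ms * rate / 1000)` samples before
#' marker i and spans `n_samples` samples. Epochs that would begin before the
#' first recorded sample, run past the end of the recording, or overlap a
#' marked artifact span are flagged invalid (their samples are `NA`), never
#' deleted, so the positional pairing with MR volumes is preserved.
#'
#' @param signal numeric matrix, channels x samples.
#' @param markers integer vector of scan-onset sample indices (1-based,
#'   sorted ascending).
#' @param window an [epoch_window()].
#' @param artifact_spans optional 2-column matrix of artifact `[start, end]`
#'   sample indices (inclusive).
#' @return list with `epochs` (array epochs x channels x samples) and
#'   `valid` (logical per epoch).
#' @export
extract_epochs <- function(signal, markers, window = epoch_window(),
                           artifact_spans = NULL) {
  stopifnot(is.matrix(signal), inherits(window, "epoch_window"))
  if (is.unsorted(markers, strictly = TRUE))
    stop("`markers` must be strictly increasing sample indices")
  offset <- round(window$start_offset_ms * window$rate / 1000)
  n <- window$n_samples
  starts <- as.integer(markers) - offset
  ends <- starts + n - 1L
  valid <- starts >= 1L & ends <= ncol(signal)
  if (!is.null(artifact_spans)) {
    artifact_spans <- as.matrix(artifact_spans)
    stopifnot(ncol(artifact_spans) == 2L)
    for (j in seq_len(nrow(artifact_spans))) {
      hit <- starts <= artifact_spans[j, 2] & ends >= artifact_spans[j, 1]
      valid <- valid & !hit
    }
  }
  epochs <- array(NA_real_, dim = c(length(markers), nrow(signal), n))
  for (i in which(valid))
    epochs[i, , ] <- signal[, starts[i]:ends[i], drop = FALSE]
  list(epochs = epochs, valid = valid)
}

# Taper with a cosine (Hann-shaped) ramp over the first and last `fraction`
# of the epoch and a flat middle -- the established reading of a "10% Hanning
# window" in EEG analysis software.
taper_weights <- function(n, fraction = 0.1) {
  stopifnot(fraction >= 0, fraction <= 0.5)
  w <- rep(1, n)
  L <- round(fraction * n)
  if (L > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(L) - 0.5) / L))
    w[seq_len(L)] <- ramp
    w[n + 1 - seq_len(L)] <- ramp
  }
  w
}

#' Container for per-subject spectral epoch data
#'
#' Holds the epochs x channels x bins tensor of EEG spectral amplitudes with
#' bin center frequencies, a per-epoch validity mask aligned to MR volumes,
#' and a flag recording whether the two-stage normalization has been applied.
#'
#' @param amplitudes numeric array, epochs x channels x bins.
#' @param freqs bin center frequencies in Hz, strictly increasing.
#' @param valid logical vector, one flag per epoch.
#' @param channels optional channel labels.
#' @param normalized logical; `TRUE` after [normalize_spectra()].
#' @return an object of class `spectral_epochs`.
#' @export
spectral_epochs <- function(amplitudes, freqs,
                            valid = rep(TRUE, dim(amplitudes)[1]),
                            channels = NULL, normalized = FALSE) {
  stopifnot(is.array(amplitudes), length(dim(amplitudes)) == 3L,
            length(freqs) == dim(amplitudes)[3],
            !is.unsorted(freqs, strictly = TRUE),
            length(valid) == dim(amplitudes)[1])
  if (!is.null(channels) && length(channels) != dim(amplitudes)[2])
    stop("`channels` length must match the channel dimension")
  structure(list(amplitudes = amplitudes, freqs = freqs, valid = valid,
                 channels = channels, normalized = isTRUE(normalized)),
            class = "spectral_epochs")
}

#' @export
print.spectral_epochs <- function(x, ...) {
  d <- dim(x$amplitudes)
  cat(sprintf("<spectral_epochs> %d epochs (%d valid) x %d channels x %d bins [%.2f-%.2f Hz]%s\n",
              d[1], sum(x$valid), d[2], d[3], min(x$freqs), max(x$freqs),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Amplitude spectra of extracted epochs
#'
#' Applies the 10% cosine taper, takes the discrete Fourier transform of each
#' epoch and channel, and retains the amplitude (modulus) at the bins selected
#' by [frequency_bins()]. Amplitudes are the raw DFT moduli (no 1/N or
#' taper-gain correction): the downstream normalization cancels any global
#' scale.
#'
#' @param epochs result of [extract_epochs()] (or a compatible list with
#'   `epochs` and `valid`).
#' @param window the [epoch_window()] the epochs were cut with.
#' @param band frequency band in Hz.
#' @param rule bin-selection convention, see [frequency_bins()].
#' @param taper_fraction fraction of the epoch tapered at each end.
#' @param channels optional channel labels.
#' @return a [spectral_epochs()] object (not yet normalized).
#' @export
spectral_transform <- function(epochs, window = epoch_window(), band = c(1, 30),
                               rule = c("count", "interval"),
                               taper_fraction = 0.1, channels = NULL) {
  rule <- match.arg(rule)
  arr <- epochs$epochs
  valid <- epochs$valid
  stopifnot(is.array(arr), length(dim(arr)) == 3L,
            dim(arr)[3] == window$n_samples)
  fb <- frequency_bins(window$n_samples, window$rate, band, rule)
  w <- taper_weights(window$n_samples, taper_fraction)
  n_ep <- dim(arr)[1]; n_ch <- dim(arr)[2]
  out <- array(NA_real_, dim = c(n_ep, n_ch, fb$n_bins))
  rows <- fb$k + 1L  # DFT row for harmonic k (row 1 is DC)
  for (i in which(valid)) {
    seg <- t(arr[i, , , drop = TRUE])          # samples x channels
    if (n_ch == 1L) seg <- matrix(arr[i, 1, ], ncol = 1L)
    ft <- stats::mvfft(seg * w)
    out[i, , ] <- t(Mod(ft[rows, , drop = FALSE]))
  }
  spectral_epochs(out, fb$freq, valid = valid, channels = channels,
                  normalized = FALSE)
}

#' Two-stage normalization of spectral epochs
#'
#' Stage 1 removes, separately for each channel and frequency bin, the mean
#' amplitude over valid epochs, so every (channel, bin) series is centered on
#' its session mean. Stage 2 scales each (epoch, bin) channel vector to unit
#' sample variance across channels, so each momentary spectral topography
#' carries shape information only. Channel vectors with zero spread map to
#' all zeros; invalid epochs are excluded from the stage-1 mean and stay
#' masked.
#'
#' @param s a [spectral_epochs()] object.
#' @return the normalized `spectral_epochs` object.
#' @export
normalize_spectra <- function(s) {
  stopifnot(inherits(s, "spectral_epochs"))
  a <- s$amplitudes
  d <- dim(a)
  vidx <- which(s$valid)
  if (length(vidx) < 2L) stop("need at least 2 valid epochs")
  if (d[2] < 2L) stop("need at least 2 channels")
  # stage 1: mean over valid epochs per (channel, bin)
  mu <- apply(a[vidx, , , drop = FALSE], c(2, 3), mean)
  for (i in vidx) a[i, , ] <- a[i, , , drop = TRUE] - mu
  # stage 2: unit sample variance across channels per (epoch, bin)
  nc <- d[2]
  for (i in vidx) {
    m <- array(a[i, , , drop = FALSE], dim = d[2:3])   # channels x bins
    sds <- sqrt(.colSums(m * m, nc, d[3]) / (nc - 1) -
                  .colMeans(m, nc, d[3])^2 * nc / (nc - 1))
    sds <- pmax(sds, 0)
    scale <- ifelse(sds > 0, 1 / sds, 0)
    a[i, , ] <- sweep(m, 2L, scale, `*`)
  }
  a[-vidx, , ] <- NA_real_
  spectral_epochs(a, s$freqs, valid = s$valid, channels = s$channels,
                  normalized = TRUE)
}
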