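# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately use naive loops / direct formulas.

# O(N^2) direct DFT modulus at harmonics `ks` of a (pre-tapered) signal
direct_dft_mod <- function(x, ks) {
  N <- length(x)
  vapply(ks, function(k)
    Mod(sum(x * exp(-2i * pi * k * (0:(N - 1)) / N))), numeric(1))
}

# triple-loop covariance map: cov(r, f, c) = sum_t amp[t, c, f] * act[r, t]
brute_covariance <- function(amp, act) {
  nr <- nrow(act); nf <- dim(amp)[3]; nc <- dim(amp)[2]
  out <- array(0, dim = c(nr, nf, nc))
  for (r in seq_len(nr)) for (f in seq_len(nf)) for (c in seq_len(nc))
    out[r, f, c] <- sum(amp[, c, f] * act[r, ])
  out
}

# two-loop consistency statistic: RMS over channels of the mean map
brute_consistency_stat <- function(maps) {
  nc <- ncol(maps)
  total <- 0
  for (c in seq_len(nc)) {
    m <- 0
    for (s in seq_len(nrow(maps))) m <- m + maps[s, c]
    total <- total + (m / nrow(maps))^2
  }
  sqrt(total / nc)
}

# one-sample t against zero by the textbook formula
brute_tstat <- function(x) mean(x) / (stats::sd(x) / sqrt(length(x)))

# wrap a raw amplitude array as an (already) normalized spectral_epochs
# object so covariance_map accepts arbitrary small test tensors
as_norm_spectra <- function(amp, freqs = seq_len(dim(amp)[3])) {
  spectral_epochs(amp, freqs, normalized = TRUE)
}
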