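# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based fan-out of a master seed into per-stage seeds (all < 2^31-1).
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer((abs(as.double(master)) * 1000003 + seq_len(n) * 7919) %% 2147483647)
}

rms <- function(x) sqrt(mean(x^2))

# One-sample t against zero down the rows of `x` (n subjects x p positions),
# n-1 variance denominator. Zero-variance positions map to 0 when the mean is
# also zero and to a +-1e12 sentinel (flagged) otherwise, so arrays stay
# finite and serializable.
tstat_cols <- function(x, sentinel = 1e12) {
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) stop("need at least 2 subjects for a t-statistic")
  m <- .colMeans(x, n, p)
  ss <- .colSums(x * x, n, p)
  v <- (ss - n * m^2) / (n - 1)
  # relative tolerance: identical values can leave roundoff-sized variance
  deg <- v <= 1e-12 * pmax(ss / n, .Machine$double.xmin)
  v[v < 0] <- 0
  t <- numeric(p)
  ok <- !deg
  t[ok] <- m[ok] / sqrt(v[ok] / n)
  t[deg] <- ifelse(m[deg] == 0, 0, sign(m[deg]) * sentinel)
  list(t = t, degenerate = deg & m != 0, n = n)
}

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
    stop(sprintf("`%s` must be a positive integer, got %s", name, deparse(substitute(x))))
  invisible(as.integer(x))
}
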