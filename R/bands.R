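#' Per-bin feature matrix for band discovery
#'
#' Concatenates, for every retained frequency bin, the group t-values of all
#' RSNs and channels into one feature row (RSN-major, channel-minor order):
#' at study scale 10 RSNs x 92 channels = 920 values per bin. The maps carry
#' no information about which frequency they came from, so any band
#' structure recovered downstream is driven purely by topography.
#'
#' @param tmaps a [tmap()] result computed over bins (not bands).
#' @return numeric matrix, bins x (RSNs * channels), with a `freqs`
#'   attribute.
#' @export
build_features <- function(tmaps) {
  stopifnot(inherits(tmaps, "tmap_set"))
  if (!identical(tmaps$axis, "bins"))
    stop("band discovery requires bin-level t-maps, not band-level")
  d <- dim(tmaps$t)                      # RSNs x bins x channels
  # columns ordered (rsn 1: ch 1..C, rsn 2: ch 1..C, ...)
  feat <- matrix(aperm(tmaps$t, c(2, 3, 1)), nrow = d[2])
  attr(feat, "freqs") <- tmaps$freqs
  attr(feat, "n_rsns") <- d[1]
  attr(feat, "n_channels") <- d[3]
  feat
}

# one pass of window-3 median smoothing over an integer label sequence;
# endpoints are kept as-is
smooth_labels <- function(lab) {
  n <- length(lab)
  if (n < 3L) return(lab)
  out <- lab
  for (i in 2:(n - 1L))
    out[i] <- stats::median(lab[(i - 1L):(i + 1L)])
  as.integer(out)
}

# fraction of bins outside the longest run of their own label
fragmentation_score <- function(lab) {
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  in_major <- rep(FALSE, length(lab))
  for (val in unique(lab)) {
    runs <- which(r$values == val)
    major <- runs[which.max(r$lengths[runs])]
    in_major[starts[major]:ends[major]] <- TRUE
  }
  mean(!in_major)
}

#' Discover frequency-band borders by k-means on t-map topographies
#'
#' Clusters the per-bin feature rows with k-means (Euclidean distance,
#' `n_restarts` random initializations, best within-cluster sum of squares
#' kept), relabels clusters by ascending mean member frequency, applies one
#' pass of window-3 median smoothing to repair isolated border-crossing
#' bins, and places band borders at the label transitions. The raw label
#' sequence and a fragmentation score (fraction of bins outside their
#' label's majority run) are always reported alongside; contiguity is never
#' enforced during the clustering itself.
#'
#' @param features matrix from [build_features()].
#' @param k number of clusters (`1 <= k <=` number of bins).
#' @param n_restarts number of random initializations.
#' @param seed integer seed.
#' @return list with `partition` (a [band_partition()] whose upper borders
#'   are the last member bin's center), `labels_raw`, `labels_smoothed`,
#'   `inertia` (total within-cluster sum of squares), `fragmentation`, `k`,
#'   and `seed`.
#' @export
cluster_bins <- function(features, k, n_restarts = 100L, seed = 1L) {
  stopifnot(is.matrix(features))
  freqs <- attr(features, "freqs")
  if (is.null(freqs)) freqs <- seq_len(nrow(features))
  n_bins <- nrow(features)
  stop_if_not_scalar_count(k, "k")
  if (k > n_bins) stop("k = ", k, " exceeds the number of bins (", n_bins, ")")
  km <- with_seed(seed, {
    if (k == n_bins)
      list(cluster = seq_len(n_bins), tot.withinss = 0)
    else
      suppressWarnings(stats::kmeans(features, centers = k,
                                     nstart = n_restarts, iter.max = 200L))
  })
  lab <- as.integer(km$cluster)
  # relabel by ascending mean member frequency
  ord <- order(vapply(seq_len(max(lab)), function(j) mean(freqs[lab == j]),
                      numeric(1)))
  lab <- match(lab, ord)
  frag <- fragmentation_score(lab)
  sm <- smooth_labels(lab)
  runs <- rle(sm)
  ends <- cumsum(runs$lengths)
  upper <- freqs[ends]
  part <- band_partition(breaks = upper,
                         names = sprintf("band%d", seq_along(upper)),
                         freqs = freqs)
  list(partition = part, labels_raw = lab, labels_smoothed = sm,
       inertia = km$tot.withinss, fragmentation = frag,
       k = as.integer(k), seed = as.integer(seed))
}

#' Cluster-count sweep for band discovery
#'
#' Runs [cluster_bins()] over a range of cluster counts and tabulates the
#' per-k inertia, fragmentation, and the number of contiguous bands after
#' smoothing. No automatic k is selected: the caller inspects the table and
#' chooses, mirroring visual selection of an apparently optimal match.
#'
#' @param features matrix from [build_features()].
#' @param k_range integer vector of cluster counts.
#' @param n_restarts,seed as in [cluster_bins()].
#' @return data.frame with columns `k`, `inertia`, `fragmentation`,
#'   `n_bands`.
#' @export
sweep_k <- function(features, k_range, n_restarts = 100L, seed = 1L) {
  if (!length(k_range)) stop("`k_range` must not be empty")
  seeds <- derive_seeds(seed, length(k_range))
  rows <- lapply(seq_along(k_range), function(i) {
    fit <- cluster_bins(features, k_range[i], n_restarts = n_restarts,
                        seed = seeds[i])
    data.frame(k = k_range[i], inertia = fit$inertia,
               fragmentation = fit$fragmentation,
               n_bands = nrow(fit$partition))
  })
  do.call(rbind, rows)
}
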