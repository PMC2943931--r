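#' Voxelwise z-transform of a BOLD series
#'
#' Standardizes every voxel timecourse to mean 0 and sample SD 1 (n-1
#' denominator). Voxels with zero variance map to all-zero rows so the
#' pipeline stays total on degenerate input.
#'
#' @param bold numeric matrix, voxels x volumes (`>= 2` volumes).
#' @return matrix of the same shape.
#' @export
ztransform_voxelwise <- function(bold) {
  stopifnot(is.matrix(bold))
  if (ncol(bold) < 2L) stop("need at least 2 volumes to z-transform")
  n <- ncol(bold)
  m <- rowMeans(bold)
  v <- (rowSums(bold * bold) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  s <- sqrt(v)
  out <- (bold - m) / ifelse(s > 0, s, Inf)
  out[s == 0, ] <- 0
  out
}

#' Assign individual ICs to network templates
#'
#' Greedy best-match assignment of independent components to RSN templates
#' on sign-invariant spatial similarity (Pearson correlation over voxels,
#' taking the better of the IC and its negative, since ICA sign is
#' arbitrary). Each template receives at most one IC and each IC serves at
#' most one template; matches below `min_similarity` are left unassigned.
#' Ties are broken by ascending IC index. When the winning match is
#' sign-negative the IC is flagged for flipping before use.
#'
#' @param ic_maps numeric matrix, components x voxels.
#' @param templates numeric matrix, templates x voxels (same grid).
#' @param min_similarity assignment threshold on `|r|`.
#' @return data.frame with one row per template: `template`, `ic` (NA when
#'   unassigned), `similarity` (absolute correlation), `flipped`.
#' @export
match_ics_to_templates <- function(ic_maps, templates, min_similarity = 0.25) {
  stopifnot(is.matrix(ic_maps), is.matrix(templates))
  if (ncol(ic_maps) != ncol(templates))
    stop("ic_maps and templates must share a common voxel grid")
  r <- suppressWarnings(stats::cor(t(templates), t(ic_maps)))
  r[!is.finite(r)] <- 0                       # zero-variance maps never match
  sim <- abs(r)
  n_t <- nrow(templates); n_c <- nrow(ic_maps)
  out <- data.frame(template = seq_len(n_t), ic = NA_integer_,
                    similarity = NA_real_, flipped = NA)
  open_t <- rep(TRUE, n_t); open_c <- rep(TRUE, n_c)
  repeat {
    s <- sim
    s[!open_t, ] <- -Inf
    s[, !open_c] <- -Inf
    best <- max(s)
    if (!is.finite(best) || best < min_similarity) break
    # ties: lowest IC index, then lowest template index
    hits <- which(s == best, arr.ind = TRUE)
    hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]
    ti <- hits[1, 1]; ci <- hits[1, 2]
    out$ic[ti] <- ci
    out$similarity[ti] <- sim[ti, ci]
    out$flipped[ti] <- r[ti, ci] < 0
    open_t[ti] <- FALSE; open_c[ci] <- FALSE
  }
  out
}

#' Group component: voxelwise one-sample t-map across subjects
#'
#' Tests every voxel of the assigned (sign-corrected) individual IC maps
#' against zero across subjects, yielding the group template used for
#' back-projection. Display thresholding (see [threshold_gc()]) is applied
#' only in reporting, never to the weights used for back-projection.
#'
#' @param maps numeric matrix, subjects x voxels (`>= 2` subjects).
#' @param grid_dims optional integer grid dimensions (e.g. `c(x, y, z)`) for
#'   cluster-extent thresholding of displays.
#' @return object of class `group_component` with `tmap`, `n_contributing`,
#'   `degenerate` flags, and `grid_dims`.
#' @export
group_component <- function(maps, grid_dims = NULL) {
  stopifnot(is.matrix(maps))
  if (nrow(maps) < 2L) stop("need at least 2 contributing subjects")
  ts <- tstat_cols(maps)
  if (!is.null(grid_dims) && prod(grid_dims) != ncol(maps))
    stop("prod(grid_dims) must equal the number of voxels")
  structure(list(tmap = ts$t, n_contributing = nrow(maps),
                 degenerate = ts$degenerate, grid_dims = grid_dims),
            class = "group_component")
}

#' Display threshold for a group component
#'
#' Keeps voxels whose two-sided one-sample t-test p-value falls below
#' `p_threshold` and that belong to a 6-connected cluster of at least
#' `min_cluster` suprathreshold voxels; everything else is zeroed. This is a
#' reporting device only.
#'
#' @param gc a [group_component()] with `grid_dims` set.
#' @param p_threshold voxelwise two-sided p threshold.
#' @param min_cluster minimum cluster size in voxels.
#' @return thresholded t-map (numeric vector over voxels).
#' @export
threshold_gc <- function(gc, p_threshold = 0.005, min_cluster = 10L) {
  stopifnot(inherits(gc, "group_component"))
  if (is.null(gc$grid_dims)) stop("grid_dims required for cluster thresholding")
  df <- gc$n_contributing - 1L
  p <- 2 * stats::pt(abs(gc$tmap), df = df, lower.tail = FALSE)
  supra <- p < p_threshold
  keep <- cluster_filter(supra, gc$grid_dims, min_cluster)
  out <- gc$tmap
  out[!keep] <- 0
  out
}

# Label 6-connected components of a logical 3-D mask (flattened, column-major)
# and keep only those of size >= min_cluster.
cluster_filter <- function(mask, grid_dims, min_cluster) {
  d <- as.integer(grid_dims)
  if (length(d) < 3L) d <- c(d, rep(1L, 3L - length(d)))
  arr <- array(mask, dim = d)
  keep <- array(FALSE, dim = d)
  seen <- array(FALSE, dim = d)
  idx <- which(arr)
  for (start in idx) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      co <- arrayInd(v, d)
      for (axis in 1:3) for (step in c(-1L, 1L)) {
        nb <- co
        nb[axis] <- nb[axis] + step
        if (nb[axis] < 1L || nb[axis] > d[axis]) next
        lin <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (arr[lin] && !seen[lin]) {
          seen[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    if (length(comp) >= min_cluster) keep[comp] <- TRUE
  }
  as.vector(keep)
}

#' Back-project a BOLD series onto a group component
#'
#' Uses the (unthresholded) group t-map as a spatial weighting of every
#' momentary BOLD image: `activity(t) = sum_v tmap(v) * bold_z(v, t)`, i.e.
#' the dot product of the template with each volume. Set
#' `weights = "thresholded"` to use the display-thresholded map instead.
#'
#' @param gc a [group_component()].
#' @param bold_z numeric matrix, voxels x volumes (z-transformed).
#' @param weights `"unthresholded"` (default) or `"thresholded"`.
#' @param ... passed to [threshold_gc()] when thresholded weights are used.
#' @return numeric activity timecourse, one value per volume.
#' @export
backproject <- function(gc, bold_z, weights = c("unthresholded", "thresholded"),
                        ...) {
  weights <- match.arg(weights)
  stopifnot(inherits(gc, "group_component"), is.matrix(bold_z))
  if (length(gc$tmap) != nrow(bold_z))
    stop("group component and BOLD data must share a common voxel grid")
  w <- if (weights == "thresholded") threshold_gc(gc, ...) else gc$tmap
  as.vector(crossprod(bold_z, w))
}

#' Normalize stacked RSN activity across networks per volume
#'
#' Divides, volume by volume, the column of network activities by its sample
#' SD across RSNs, so every volume carries the relative distribution of
#' activity over networks rather than its overall amplitude. Zero-spread
#' columns map to zeros.
#'
#' @param activity numeric matrix, RSNs x volumes (`>= 2` RSNs).
#' @param tr repetition time in seconds (stored as an attribute).
#' @return matrix of the same shape with per-volume unit variance across RSNs.
#' @export
normalize_across_rsns <- function(activity, tr = attr(activity, "tr")) {
  stopifnot(is.matrix(activity))
  if (nrow(activity) < 2L)
    stop("variance across RSNs is undefined for a single RSN")
  n <- nrow(activity)
  m <- colMeans(activity)
  v <- (.colSums(activity * activity, n, ncol(activity)) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  s <- sqrt(v)
  out <- sweep(activity, 2L, ifelse(s > 0, s, Inf), `/`)
  out[, s == 0] <- 0
  attr(out, "tr") <- tr
  out
}
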