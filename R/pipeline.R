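#' Pipeline run configuration
#'
#' Collects every stage parameter with defaults at study scale: 20 subjects,
#' 252 volumes at TR 1.98 s, 10 RSNs, 92 channels, a 256-sample / 100 Hz
#' epoch window starting 6560 ms before each scan onset, the 1--30 Hz band
#' (75 retained bins), k = 8 bands, and 5000 randomization runs. Unknown
#' keys are rejected; every random stage receives a seed derived from the
#' master seed by a counter scheme recorded in the manifest.
#'
#' @param ... overrides of the defaults listed above.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    schema = "topocov-config/1",
    n_subjects = 20L, n_volumes = 252L, n_rsns = 10L, n_channels = 92L,
    tr = 1.98, ar = 0.3,
    start_offset_ms = 6560, n_samples = 256L, rate = 100, band = c(1, 30),
    bin_rule = "count",
    coupling_strength = 1, noise_sd = 1, dropout = 0,
    k = 8L, n_restarts = 100L,
    n_perm = 5000L, alpha = 0.05,
    min_similarity = 0.25,
    seed = 1L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  stopifnot(cfg$n_subjects >= 2L, cfg$n_rsns >= 2L, cfg$n_channels >= 2L,
            cfg$n_perm >= 1L, cfg$k >= 1L, cfg$noise_sd >= 0)
  structure(cfg, class = "run_config")
}

#' Run the full synthetic pipeline end to end
#'
#' Simulates coupled network dynamics and spectral epochs, normalizes both
#' sides, computes the subject covariance tensor and group t-maps, discovers
#' frequency bands by clustering, band-averages, and runs the full
#' randomization battery. All stage outputs plus a manifest (config echo,
#' derived seeds, config hash) are written to `out_dir` as TSV/JSON; a rerun
#' with the same config is bit-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory stage results
#'   (`dynamics`, `cov`, `tmaps`, `clustering`, `cov_bands`, `battery`,
#'   `manifest`).
#' @export
run_all <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (missing(out_dir)) stop("`out_dir` is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 5L)
  names(seeds) <- c("dynamics", "coupling", "spectra", "clustering", "stats")
  fb <- frequency_bins(config$n_samples, config$rate, config$band,
                       config$bin_rule)
  partition0 <- reference_bands(fb$freq)

  dyn <- simulate_rsn_dynamics(config$n_subjects, config$n_volumes,
                               config$n_rsns, ar = config$ar,
                               seed = seeds["dynamics"], tr = config$tr)
  dyn <- lapply(dyn, normalize_across_rsns)
  coupling <- default_coupling(config$n_rsns, config$n_channels,
                               partition = partition0,
                               strength = config$coupling_strength,
                               noise_sd = config$noise_sd,
                               seed = seeds["coupling"])
  subj_seeds <- derive_seeds(seeds["spectra"], config$n_subjects)
  slices <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    sim <- simulate_spectra(dyn[[s]], coupling, config$n_channels, fb$n_bins,
                            seed = subj_seeds[s], dropout = config$dropout,
                            freqs = fb$freq)
    slices[[s]] <- covariance_map(normalize_spectra(sim$spectra), dyn[[s]])
  }
  cov <- covariance_tensor(slices)
  tm <- tmap(cov)
  clus <- cluster_bins(build_features(tm), k = config$k,
                       n_restarts = config$n_restarts,
                       seed = seeds["clustering"])
  cov_bands <- band_average(cov, clus$partition)
  battery <- covmap_battery(cov_bands, n_perm = config$n_perm,
                            seed = seeds["stats"], alpha = config$alpha)

  # --- persist ---------------------------------------------------------
  dyn_tab <- do.call(rbind, lapply(seq_along(dyn), function(s)
    data.frame(subject = s, rsn = seq_len(nrow(dyn[[s]])), dyn[[s]])))
  write_tsv(dyn_tab, file.path(out_dir, "rsn_dynamics.tsv"))
  part_out <- data.frame(name = clus$partition$name,
                         lower = clus$partition$lower,
                         upper = clus$partition$upper,
                         n_bins = clus$partition$n_bins)
  jsonlite::write_json(
    list(schema = "topocov-partition/1", bands = part_out,
         member_bins = attr(clus$partition, "bins"),
         labels_raw = clus$labels_raw,
         labels_smoothed = clus$labels_smoothed,
         fragmentation = clus$fragmentation, inertia = clus$inertia),
    file.path(out_dir, "band_partition.json"),
    auto_unbox = TRUE, digits = NA)
  write_results(battery, out_dir)

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(schema = "topocov-manifest/1",
                   config_hash = unname(tools::md5sum(cfg_path)),
                   master_seed = config$seed,
                   stage_seeds = as.list(seeds),
                   subject_seeds = subj_seeds,
                   tensor_dims = dim(cov),
                   n_bins = fb$n_bins,
                   resolution_hz = fb$resolution)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dynamics = dyn, cov = cov, tmaps = tm, clustering = clus,
                 cov_bands = cov_bands, battery = battery,
                 manifest = manifest))
}

#' Write the randomization battery tables
#'
#' Writes `consistency.tsv` (per RSN x band consistency test),
#' `tanova.tsv` (overall two-factor effects plus per-band one-way TANOVAs)
#' to `dir`.
#'
#' @param battery result of [covmap_battery()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_results <- function(battery, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "consistency.tsv")
  write_tsv(battery$consistency, p1)
  ov <- battery$overall
  tanova_tab <- rbind(
    data.frame(test = "overall_rsn", band = NA,
               statistic = ov$A$statistic, p = ov$A$p,
               n_perm = ov$A$n_perm, seed = ov$A$seed),
    data.frame(test = "overall_band", band = NA,
               statistic = ov$B$statistic, p = ov$B$p,
               n_perm = ov$B$n_perm, seed = ov$B$seed),
    data.frame(test = "overall_interaction", band = NA,
               statistic = ov$interaction$statistic, p = ov$interaction$p,
               n_perm = ov$interaction$n_perm, seed = ov$interaction$seed),
    data.frame(test = "per_band_rsn", band = battery$per_band$band,
               statistic = battery$per_band$statistic,
               p = battery$per_band$p,
               n_perm = battery$per_band$n_perm,
               seed = battery$per_band$seed))
  p2 <- file.path(dir, "tanova.tsv")
  write_tsv(tanova_tab, p2)
  invisible(c(p1, p2))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an electrode montage
#'
#' Reads a tab-separated montage with columns `label`, `x`, `y` (2-D layout
#' coordinates for topographic plotting). Duplicate labels and malformed
#' rows are rejected. The package ships a synthetic 92-position layout as
#' `system.file("extdata", "montage92_synthetic.tsv", package = "topocov")`.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `label`, `x`, `y`.
#' @export
read_montage <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y")
  if (!all(need %in% names(tab)))
    stop("montage must have columns: ", paste(need, collapse = ", "))
  if (anyNA(tab$x) || anyNA(tab$y) || !is.numeric(tab$x) || !is.numeric(tab$y))
    stop("montage coordinates must be numeric and complete")
  dup <- tab$label[duplicated(tab$label)]
  if (length(dup))
    stop("duplicate channel label(s) in montage: ",
         paste(unique(dup), collapse = ", "))
  tab[need]
}
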