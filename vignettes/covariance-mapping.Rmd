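---
title: "Topographic covariance mapping of EEG spectral fluctuations and RSN dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topographic covariance mapping of EEG spectral fluctuations and RSN dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topocov)
```

## The problem

Resting-state networks (RSNs) are sets of brain regions whose spontaneous
BOLD fluctuations are synchronized at rest. Simultaneous EEG–fMRI makes it
possible to ask what electrophysiological activity accompanies the waxing
and waning of each network — not just *which frequency* co-fluctuates with a
network, but *where on the scalp* that spectral power changes. `topocov`
implements the full analysis chain for this question:

1. derive a per-subject activity timecourse for each RSN by back-projecting
   the subject's BOLD data onto group network templates;
2. extract hemodynamically lagged pre-scan EEG epochs and compute normalized
   spectral amplitude topographies per frequency bin;
3. covary the two sides, electrode by electrode and bin by bin, into a
   subjects × RSNs × bins × channels covariance tensor;
4. discover frequency-band borders by clustering the per-bin group t-map
   topographies;
5. test topographic consistency across subjects and condition differences
   with global randomization statistics that need no per-electrode multiple
   testing correction.

Because raw simultaneous recordings of this kind are rarely shareable, the
package ships a first-class synthetic-data generator with planted coupling
structure, so every stage is testable against a known ground truth.

## Pipeline stages and their models

### RSN dynamics (fMRI side)

Individual spatial ICA is treated as an external interface: any spatial-ICA
implementation may supply per-subject component maps (a configuration
default of 30 components per subject is assumed at study scale). The package
then:

* assigns ICs to RSN templates by greedy best-match on **sign-invariant
  Pearson correlation** over voxels (`match_ics_to_templates()`). ICA sign
  is arbitrary, so the better of ±IC is used and sign-negative winners are
  flipped before use. Matches below `min_similarity` (default 0.25) stay
  unassigned — real group studies routinely fail to identify every network
  in every subject;
* forms a **group component** per RSN as the voxelwise one-sample t-map of
  the assigned maps across subjects (`group_component()`). Display
  thresholding (voxel p < 0.005 plus a minimum cluster size, default 10
  voxels, 6-connectivity) is a reporting device only;
* **back-projects** each subject's voxelwise z-transformed BOLD series onto
  the *unthresholded* t-map — the activity at volume `t` is the dot product
  of the template with the momentary image. Whether thresholded weights were
  ever intended is genuinely open; the unthresholded choice is the default
  because thresholding discards graded template information, and a
  `weights = "thresholded"` switch exists for the alternative;
* normalizes the stacked activity matrix to **unit variance across RSNs at
  every volume** (`normalize_across_rsns()`), so each volume carries the
  relative distribution of activity over networks.

### EEG spectra

Epochs of 256 samples at 100 Hz are cut starting 6560 ms before each scan
onset (`epoch_window()`, `extract_epochs()`), placing the EEG window at the
hemodynamic lag of the following volume. Note one deliberate convention: a
256-sample epoch at 100 Hz spans 2550 ms, so a window printed as
"6560–4010 ms before scan" is internally inconsistent by one sample; we
define the epoch as 256 samples starting at −6560 ms (ending −4000 ms),
honoring the sample count, and document the choice here. Epochs that leave
the recording or touch an artifact span are masked, never deleted, so the
positional epoch↔volume pairing survives.

`spectral_transform()` applies a 10% cosine taper — Hann-shaped ramps over
the first and last 10% of the epoch, flat in between, the established
meaning of a "10% Hanning window" in EEG analysis software — and retains DFT
amplitude at harmonics k = 3…77 (centers 1.17–30.08 Hz, resolution
100/256 = 0.390625 Hz, 75 bins). The literal closed interval [1, 30] Hz
would keep 74 bins; the `rule = "count"` convention reproducing the
conventional 75-bin layout is the default and `rule = "interval"` is
available. Amplitudes are raw DFT moduli: any global scale cancels in the
normalization below.

`normalize_spectra()` is the two-stage normalization that makes covariance
maps interpretable as *relative* spectral redistribution: (1) remove the
mean over valid epochs per channel × bin, (2) scale each (epoch, bin)
channel vector to unit sample variance across channels. Both fMRI and EEG
sides are therefore centered and variance-normalized before combination.

### Covariance mapping

For each subject, `covariance_map()` computes the plain dot product

    cov(r, f, c) = Σ_t  amplitude(t, c, f) · activity(r, t)

over valid epoch/volume pairs. The dot product is *not* rescaled by the
number of pairs; subjects can differ in usable epochs, so the pair count is
stored alongside (`n_valid_pairs`) for optional rescaling. A positive value
means spectral power at channel `c`, bin `f` rises when network `r` is
relatively more active. `tmap()` summarizes consistency across subjects as
one-sample t-values — used as standardized signal-to-noise indices, not as
parametric inference. `band_average()` collapses bins to bands by the
unweighted member mean.

### Band discovery

`build_features()` concatenates, per bin, the group t-maps of all RSNs over
all channels (10 × 92 = 920 values at study scale); the rows carry no
frequency information, so any recovered band structure is purely
topographic. `cluster_bins()` runs k-means (Euclidean distance,
`stats::kmeans`, Hartigan–Wong, 100 random restarts, best within-cluster sum
of squares kept). We use R's canonical k-means rather than a hand-rolled
k-means++ initializer: with 100 restarts the best-of solution is stable on
this problem size, which is the purpose the initialization choice serves.
Labels are relabeled by ascending mean member frequency; one pass of
window-3 median smoothing repairs isolated border-crossing bins before
borders are read off label transitions. The raw label sequence and a
fragmentation score (fraction of bins outside their label's majority run)
are always reported, so the post-hoc repair is visible. `k` is a user
choice; `sweep_k()` tabulates inertia and fragmentation over a range and
deliberately selects nothing.

The canonical 8-band partition (`reference_bands()`) fixes the borders
delta ≤ 3.5 < theta1 ≤ 6.25 < theta2 ≤ 8.2 < alpha1 ≤ 10.5 < alpha2 ≤ 14.0
< beta1 ≤ 18.75 < beta2 ≤ 21.88 < beta3 ≤ 30.0 Hz. These printed borders
are rounded centers of each band's last member bin at 0.390625 Hz
resolution (8.2 ≈ 8.203, 21.88 = 21.875, 30.0 ≈ 30.078), so bin membership
is evaluated with a half-bin tolerance on the upper border; a literal
"≤ 30.0 Hz" would orphan the highest retained bin. Member counts are
7, 7, 5, 6, 9, 12, 8, 21.

### Randomization statistics

All tests reduce a map to one global number, so the α level is spent once:

* **Topographic consistency test** (`consistency_test()`): observed
  statistic is the RMS across channels of the across-subject mean map; the
  null shuffles each subject's values among electrodes independently,
  destroying common spatial structure while preserving per-subject variance.
* **One-way TANOVA** (`tanova_oneway()`): mean over levels of the RMS of
  (level mean − grand mean), null permutes each subject's maps across
  levels. No average-reference re-centering or GFP normalization is applied:
  covariance maps are not potentials, and re-centering is available as an
  explicit preprocessing step if wanted.
* **Two-factor TANOVA** (`tanova_twofactor()`): main effects collapse over
  the other factor and reuse the one-way scheme. The interaction removes
  each subject's additive model and tests the residual cell means. Its null
  **sign-flips each subject's whole residual set** rather than shuffling
  residual maps across cells. This is the package's single largest
  interpretive decision, so the reasoning is spelled out: residuals live
  entirely in the interaction subspace and are sign-symmetric under the
  null, so the reflection scheme mirrors the observed statistic's structure
  exactly and is immune to main-effect leakage. Cell-shuffling of
  precomputed residuals is measurably anticonservative in small crossed
  designs (the observed statistic has fully coherent cell structure that
  shuffled nulls average away), and re-residualizing shuffled residuals
  collapses pure main-effect arrangements to zero, which is far worse; the
  calibration suite in `tests/testthat/` checks the implemented scheme
  holds its nominal type-I error.

p-values use `(1 + #{null ≥ observed}) / (n_perm + 1)`, counting ties as
exceedances — the "percentage larger" formulation can yield p = 0, which a
randomization test cannot honestly claim. Default `n_perm = 5000`;
the test-suite uses 199–999 with correspondingly coarser p resolution.

`covmap_battery()` runs the whole program on a band-averaged tensor:
consistency per (RSN, band), the overall RSN × band two-factor TANOVA, and
per-band one-way TANOVAs over RSNs, each with a deterministically derived
seed, so the full table reproduces bit-for-bit.

## The synthetic generator

`simulate_rsn_dynamics()` draws stationary AR(1) Gaussian series (default
lag-1 coefficient 0.3, unit marginal variance — the innovation sd is
`sqrt(1 − ar²)`, so the marginal scale is fixed and the downstream
per-volume normalization is exercised, not relied on). The AR coefficient
emulates the slow autocorrelated character of BOLD network dynamics at
TR ≈ 2 s; its exact value is not critical to any test, and the statistics
operate per-volume.

`simulate_spectra()` plants, for each (RSN, band) pair, a channel topography
scaled by a coupling strength and the network's momentary activity, plus
i.i.d. Gaussian noise across epochs, channels and bins — the simplest model
satisfying the exchangeability assumptions of the randomization tests. The
default coupling (`default_coupling()`) gives every (RSN, band) pair an
independent random topography (zero mean, unit RMS) at strength 1 with noise
sd 1. No per-network effect sizes are available to calibrate against real
recordings, so the default is chosen once to make planted effects clearly
detectable at n = 20 subjects and 252 volumes, and is not tuned thereafter.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: volume conduction and spatially correlated channel
noise, 1/f spectral background, scanner and cardioballistic artifact
residue, subject-specific topography deformation, non-Gaussian and
non-stationary dynamics, and hemodynamic convolution (the lag is handled
structurally by epoch placement, not by an HRF model). Calibration results
here certify the statistics under exchangeable noise, which is exactly the
assumption the randomization schemes make.

`simulate_ic_maps()` adds spatial noise, random sign flips and order
shuffling to template maps, emulating ICA's sign and order indeterminacy;
with noise sd ≈ 2.2 the mean template–IC similarity lands near 0.4, the
regime reported for real group-ICA clustering.

## Numerical conventions

* All sample SDs use the n−1 denominator, consistent with the t-statistics.
* Degenerate variance maps to zero output everywhere (z-transform, spectral
  normalization, per-volume normalization), keeping pipelines total.
* A zero-variance, nonzero-mean cell in a t-map is stored as ±1e12 with a
  degeneracy flag, so arrays stay finite and serializable.
* Every random operation takes an explicit seed; `run_all()` fans a master
  seed out to stage seeds by a counter scheme recorded in the manifest, and
  reruns are bit-identical.
* Tensors and tables serialize to TSV/JSON; configuration and manifest to
  JSON with an md5 config hash.

## Problem sizes used by the test suite

The suite exercises the full study scale where shape matters (20 subjects ×
10 RSNs × 75 bins × 92 channels for the covariance tensor, the 80-map
battery, and band recovery) and reduced dimensions where only calibration
matters (type-I error checked over 500 null datasets at 500 permutations
each, with 10 subjects × 16 channels; the permutation count bounds the p
resolution, not the validity). Oracle checks (direct O(N²) DFT, triple-loop
covariance, two-loop RMS) run on small random instances at 10⁻⁹ relative
tolerance.

## Known limitations

* ICA itself, fMRI preprocessing, EEG artifact correction and channel
  interpolation are out of scope; inputs are assumed cleaned, downsampled
  and average-referenced.
* The consistency battery reports uncorrected per-map p-values; no
  correction is applied across the 80 maps, matching standard practice of
  reporting the count of significant maps.
* Band discovery assumes bands are contiguous in frequency; the median
  smoothing can absorb genuinely fragmented structure — inspect
  `labels_raw` and the fragmentation score when in doubt.
* The covariance dot product grows with the number of valid pairs; compare
  subjects on equal footing or rescale by `n_valid_pairs` when dropout
  differs substantially.
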