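---
title: "Consistency of source-space MEG measures under anatomical mismatch: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistency of source-space MEG measures under anatomical mismatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megconsist)
```

## The question this package answers

Atlas-based MEG connectivity analyses reconstruct one "virtual electrode"
(VE) time series per cortical region with a beamformer, then derive
spectral power, phase-coupling and network-topology measures from those
series. The beamformer's lead fields come from a head model that must be
co-registered to an anatomical image. When a template anatomy replaces the
subject's own, the assumed source positions are wrong by some spatial
displacement — and that error propagates, possibly nonlinearly, through
connectivity into network topology. `megconsist` turns this into a
controlled simulation: the *same* simulated sensor recording is analysed
twice, once with lead fields from the true source geometry ("native") and
once from a geometry whose voxels were displaced by a configurable amount
("template"). Everything downstream is then compared between the two
conditions.

Because only the lead fields differ, a zero displacement yields bitwise
identical pipelines and every consistency statistic is exactly 1 — a
built-in positive control that the test-suite asserts to `1e-9`.

## Synthetic data model

`generate_sources()` builds `n_rois` regions (default 78, the cortical
atlas count typical for this analysis style), each a compact patch of
`voxels_per_roi` voxels on a 2 mm grid inside a 90 mm homogeneous
conducting sphere, at mid-depth (0.45–0.75 of the radius, chosen so the
patches stay comfortably inside the conductor while not collapsing to its
center where sources become silent). Each region carries one narrowband
time series per configured frequency band: Gaussian white noise brick-wall
filtered to the band. A coupling `(i, j, band, phase_lag, strength)` makes
region *j*'s band series a constant-phase-shifted copy of region *i*'s
(every positive-frequency component rotated by the lag), mixed with
independent narrowband noise weighted `1 - strength`. This matches the
analysis's band-limited view of the data without committing to a particular
oscillator model, and gives exact ground truth for the phase lag index: at
`strength = 1` the instantaneous phase difference equals the configured lag
at every sample.

The six classical bands are delta 0.5–4, theta 4–8, lower alpha 8–10,
upper alpha 10–13, beta 13–30 and gamma 30–48 Hz. Band intervals are
half-open `[low, high)` so the six bands partition 0.5–48 Hz without double
counting the touching edges; the relative-power denominator is fixed to
that 0.5–48 Hz union. Series are demeaned before the FFT.

Sensors are a quasi-uniform golden-angle spiral of 151 radially oriented
channels on an upper hemisphere at 1.1 × the conductor radius — a generic
stand-in for a whole-head axial-gradiometer array. The forward model is the
Sarvas closed form for a dipole in a conducting sphere; radially oriented
dipoles are magnetically silent, which the tests verify together with an
exact independent identity (the radial field component outside the sphere
equals the bare dipole's Biot–Savart field). Sensor noise is white Gaussian
scaled so that total signal power over noise power equals `snr`.

**What the generator does not emulate:** 1/f background spectra,
physiological and muscle artifacts, realistic (multisphere/BEM) head
geometry, inter-subject anatomical variability, spatially correlated sensor
noise, and the spatial leakage structure of a real atlas parcellation.
Passing tests therefore demonstrate that the *analysis chain* behaves as
specified and that consistency degrades with anatomical mismatch in the
expected direction — not that any particular ICC value would be observed on
real recordings.

The default `snr = 2` is a free parameter of the simulation (real-data SNR
is not characterized here); it was chosen once as a moderate value at which
sources are clearly reconstructible but noise still matters, and the sweep
design treats it as a constant, not a tuning dial.

## Anatomy perturbation

`perturb_anatomy()` displaces voxel positions while leaving time series,
couplings and region membership untouched. `per_voxel` mode moves every
voxel by exactly `displacement_mm` in an independent uniform random
direction (redrawing up to 100 times if a move would exit the conductor) —
this emulates the spatially incoherent part of a co-registration mismatch
and makes the representative-voxel displacement directly controllable.
`rigid` mode applies one random translation of the given magnitude (plus an
optional rotation about the sphere center), preserving all inter-voxel
distances.

## Beamformer

Per band, sensor epochs are brick-wall filtered, pooled into one covariance
`C` (channels demeaned), and Tikhonov-loaded as
`C + λ · trace(C)/M · I` with `λ = 0.01` — a conventional loading fraction
for pooled MEG covariances; the analysis chain is insensitive to its exact
value because both conditions share it. Weights are the unit-gain LCMV
solution `W = C⁻¹L (LᵀC⁻¹L)⁻¹`. The scalar source orientation maximizes
the unit-gain output power `1/(uᵀ LᵀC⁻¹L u)`: the eigenvector of the
smallest eigenvalue of `LᵀC⁻¹L` restricted to the non-null (tangential)
subspace of the vector lead field, with the sign fixed so the first nonzero
component is non-negative (orientation sign is unobservable in power and
PLI). Pseudo-Z is `sqrt(WᵀCW / (σ² WᵀW))` with the noise power `σ²`
estimated as the mean of the smallest `⌈M/4⌉` covariance eigenvalues, a
noise-floor estimate that equals the true noise variance for white noise.

Each region is represented by a single voxel: the **peak** voxel (maximum
pseudo-Z per band, ties to the lowest voxel id) or the **centroid** (voxel
minimizing the summed Euclidean distance to all other voxels of the region;
band-independent; ties to the lowest id). The VE series is `WᵀB` applied to
the *broadband* data: band-specific weights, broadband content. This keeps
relative power meaningful (a VE extracted from band-filtered data would
trivially have all its power in that band), and is equivalent for PLI,
since band-limiting commutes with the fixed linear weights.

## Connectivity and networks

Instantaneous phases come from the FFT-based analytic signal. The phase
lag index of a phase-difference series is `|mean(sign(sin Δφ))|`, with
`sign(0) = 0` so exactly zero-lag samples contribute nothing — the index's
defining insensitivity to volume conduction. Adjacency matrices (one per
epoch, band, method and condition) are symmetric, zero-diagonal, entries in
[0, 1].

Network metrics per adjacency matrix:

* **Weighted clustering**: the triple-product form
  `C_i = Σ w_ik w_il w_kl / Σ_{k≠l} w_ik w_il`, zero-denominator → 0,
  averaged over nodes.
* **Weighted path length**: Dijkstra on edge lengths `1/w` (via igraph);
  mean over pairs, or the harmonic-mean convention `1/mean(1/d)` if any
  pair is disconnected (a guard only — PLI matrices are almost surely fully
  weighted).
* **Modularity**: weighted Newman quality
  `Q = (1/2m) Σ (w_ij − s_i s_j/2m) δ(c_i, c_j)`, maximized by simulated
  annealing with a fully pinned schedule (random initial partition,
  single-node moves to any — possibly new — module, `T₀ = 1`, geometric
  cooling 0.995 per proposal, stop at `T < 1e-4` or after `100·R`
  consecutive rejections), implemented in C++ on R's RNG so runs are
  deterministic per seed. Q and the module count are averaged over
  `modularity_runs` independent runs (default 100; reduced in the scaled
  test profile) because single annealing runs are themselves a noise
  source.
* **Minimum spanning tree**: Kruskal on lengths `1/w` with deterministic
  tie-breaking (length, smaller id, larger id), summarized by per-node
  degree, leaf fraction, and hop-count diameter (unnormalized).

## Consistency statistics

`icc31()` is the two-way mixed, consistency, single-measure intraclass
correlation: from the two-way ANOVA without interaction,
`ICC = (MS_rows − MS_err) / (MS_rows + MS_err)` for two raters, with the
95% CI from the F-bounds construction. It ignores additive rater bias and
can be negative; ratings use right-closed bands — (0.80, 1] very good,
(0.60, 0.80] good, (0.40, 0.60] moderate, (0.20, 0.40] fair, ≤ 0.20 poor —
resolving the boundary ambiguity of the conventional verbal scale at
exactly 0.80/0.60/0.40/0.20, with negative values additionally flagged not
reliable. When both raters are identical the residual mean square is zero
and the ICC is exactly 1 with a degenerate CI of (1, 1).

`bland_altman()` uses differences template − native, the sample SD (n − 1),
and limits at mean ± 1.96 SD; points strictly outside are counted.

Regional consistency pools epochs across subjects (one ICC per region,
band and measure — relative power, regional PLI as the node's mean
connectivity excluding the diagonal, and MST degree). Global consistency
operates on per-subject epoch averages of eight measures: mean power, mean
PLI, clustering, path length, modularity Q, module count, MST leaf
fraction, and MST diameter. Subject-level ICCs need at least three
subjects; smaller designs get NA rows with a warning rather than a hard
failure so report completeness is preserved. `distance_vs_icc()`
correlates per-region representative-voxel displacement with per-region
power ICC, skipping degenerate (constant) bands with a warning.

## The displacement-sweep experiment

`run_experiment()` executes the full chain per subject and displacement
level; `consistency_sweep()` repeats it over seeds and summarises the mean
global ICC per displacement, its Spearman correlation with displacement per
seed, and the pooled distance-versus-power-ICC Pearson correlation.
`sweep_profile_config()` is the scaled profile used by the tests and the
acceptance script: 5 subjects, 20 regions × 5 voxels, 10 epochs of 1024
samples at 256 Hz, 64 channels, two bands (lower alpha, beta), SNR 2,
displacements 0/5/15/30 mm, peak-voxel method, 10 modularity runs. These
sizes were fixed once as the smallest design that preserves the full
structure (multi-band coupled sources, per-epoch networks, subject-level
aggregation) while a 10-seed sweep completes in minutes on one CPU.

Numerical/degeneracy conventions worth knowing: brick-wall filtering treats
epochs whole with no taper; voxels exactly at the sphere center are
rejected ("degenerate geometry"); an all-zero adjacency is an "empty
graph" error; a constant series has no phase ("no oscillation"); zero
total covariance and silent lead fields are errors, not silent zeros; all
tie-breaks are by lowest id.

## Known limitations

* The orientation optimizer is the closed-form power-maximizing one;
  nonlinear SAM-style optimizers can differ in detail.
* The single-sphere forward model understates the localization errors a
  realistic head model would show; displacement magnitudes here measure
  geometric mismatch, not clinical co-registration error.
* Regional ICCs pool epochs across subjects without subject stratification
  (the per-epoch design treats each epoch as an item).
* Persistence is CSV/JSON; large arrays are regenerated from
  `(config, seed)` rather than stored.
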