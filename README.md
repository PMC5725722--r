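# megconsist

Source-space MEG studies estimate functional connectivity and brain-network
topology from beamformed regional time series, and the beamformer's forward
model depends on co-registration with an anatomical image. When no native
MRI is available, a template anatomy can be substituted — at the price of a
spatial mismatch between the assumed and the true source geometry.
`megconsist` quantifies how such anatomical mismatch propagates through a
full source-space analysis chain: band-limited relative power, phase lag
index (PLI) connectivity, and graph/minimum-spanning-tree network metrics,
compared between the true ("native") and a displaced ("template") source
geometry with intraclass correlations, Bland–Altman agreement, and
distance-versus-consistency correlations.

Because real recordings and anatomies are rarely shareable, the package is
simulation-first: it generates phase-coupled cortical sources inside a
spherical conductor, projects them to a whole-head sensor array, and runs
the identical analysis under both anatomies — the sensor data are shared,
only the lead fields differ, exactly as in a template-vs-native
co-registration comparison.

## The method in brief

* **Forward model.** Magnetic field of a current dipole in a homogeneous
  conducting sphere (Sarvas closed form); radial dipoles are silent.
* **Beamformer.** Unit-gain LCMV/SAM spatial filter per voxel and band,
  `W = C⁻¹L (LᵀC⁻¹L)⁻¹`, with the scalar orientation chosen to maximize
  output power and regional representatives picked as the pseudo-Z **peak
  voxel** or the geometric **centroid** of each region.
* **Connectivity.** Phase lag index per epoch and region pair,
  `PLI = |⟨sign sin Δφ(t_k)⟩|`, insensitive to zero-lag (volume-conduction)
  coupling.
* **Networks.** Weighted clustering coefficient, Dijkstra weighted path
  length (edge length `1/PLI`), Newman modularity maximized by simulated
  annealing and averaged over runs, and the Kruskal minimum spanning tree
  summarized by degree, leaf fraction, and diameter.
* **Consistency.** ICC(3,1) (two-way mixed, consistency, single measure)
  with F-based 95% CIs and qualitative ratings, at the regional per-epoch
  level and at the subject level for eight global measures; Bland–Altman
  limits of agreement at mean ± 1.96 SD; Pearson correlation between
  representative-voxel displacement and power consistency.

## Worked example

Two coupled regions (constant π/4 phase lag in the lower alpha band) are
simulated, beamformed, and their PLI matrix computed:

```r
library(megconsist)

bands <- classical_bands()
model <- generate_sources(
  n_rois = 4, voxels_per_roi = 3,
  bands = bands[bands$band == "alpha1", ],
  couplings = data.frame(roi_i = 1, roi_j = 2, band = "alpha1",
                         phase_lag = pi / 4, strength = 0.9),
  fs = 256, epoch_len = 1024, n_epochs = 5, seed = 1)
sensors <- meg_sensor_array(n_channels = 64)
epochs  <- project_to_sensors(model, sensors, snr = 2, seed = 2)
ve <- beamform_rois(epochs, model, sensors,
                    bands = bands[bands$band == "alpha1", ], methods = "peak")
x <- t(ve$series[["alpha1"]][["peak"]][, , 1])
x <- apply(x, 2, bandpass_fft, f_low = 8, f_high = 10, fs = 256)
round(pli_adjacency(x), 2)
#>      [,1] [,2] [,3] [,4]
#> [1,] 0.00 0.96 0.11 0.39
#> [2,] 0.96 0.00 0.15 0.31
#> [3,] 0.11 0.15 0.00 0.51
#> [4,] 0.39 0.31 0.51 0.00
```

The coupled pair (regions 1–2) stands out with PLI 0.96; the uncoupled
pairs sit near the noise floor. The consistency statistics work on any
paired measurements:

```r
r <- icc31(c(0.52, 0.48, 0.61, 0.55, 0.44), c(0.50, 0.49, 0.60, 0.57, 0.45))
r
#> ICC(3,1) = 0.966 [0.718, 0.996] (very good), n = 5
tidy(r)
#> # A tibble: 1 × 5
#>     icc ci_low ci_high rating    not_reliable
#>   <dbl>  <dbl>   <dbl> <chr>     <lgl>
#> 1 0.966  0.718   0.996 very good FALSE
```

A small end-to-end experiment (3 subjects, 6 regions, displacements 0 and
10 mm) and the per-measure subject-level consistency it produces:

```r
cfg <- validate_config(list(
  n_subjects = 3, n_rois = 6, voxels_per_roi = 3, n_epochs = 5,
  epoch_len = 512, fs = 256, n_channels = 32,
  bands = bands[bands$band == "alpha1", ],
  displacement_mm = c(0, 10), modularity_runs = 10,
  log_level = "quiet", seed = 7))
rep <- run_experiment(cfg)
subset(rep$global_icc, displacement == 10 & method == "peak")[,
       c("band", "measure", "icc", "rating", "mean_diff")]
#>     band       measure        icc   rating    mean_diff
#> 1 alpha1            cw  0.7935795     good -0.028387572
#> 2 alpha1      diameter  0.5000000 moderate -0.066666667
#> 3 alpha1 leaf_fraction  0.5000000 moderate  0.011111111
#> 4 alpha1            lw  0.4830946 moderate -0.709504504
#> 5 alpha1     n_modules -0.7250755     poor -0.013333333
#> 6 alpha1           pli  0.6358996     good -0.004166667
#> 7 alpha1         power  0.5947118 moderate -0.051163981
#> 8 alpha1             q  0.7109787     good -0.020403419
rep$distance_icc
#> # A tibble: 2 × 5
#>   method   band       n      r          p
#>   <chr>    <chr>  <int>  <dbl>      <dbl>
#> 1 centroid alpha1    12 -0.934 0.00000866
#> 2 peak     alpha1    12 -0.945 0.00000365
```

At 0 mm displacement every ICC is exactly 1 (identical pipelines); at 10 mm
consistency drops, most strongly for the higher-order network measures, and
regions whose representative voxels moved furthest show the lowest power
consistency (negative `r`). `autoplot(rep)`, `plot_distance_icc(rep)` and
`autoplot(bland_altman(a, b))` visualize the report.

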