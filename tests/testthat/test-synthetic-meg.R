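test_that("coupled sources carry the configured constant phase lag", {
  m <- two_roi_model(strength = 1, lag = pi / 4, seed = 5)
  ph1 <- instantaneous_phase(m$roi_series[, 1])
  ph2 <- instantaneous_phase(m$roi_series[, 2])
  dphi <- Arg(exp(1i * (ph1 - ph2)))   # wrap to (-pi, pi]
  expect_lt(max(abs(dphi - pi / 4)), 1e-6)
})

test_that("source generation is deterministic per seed", {
  m1 <- two_roi_model(strength = 0.7, lag = 0.5, seed = 42)
  m2 <- two_roi_model(strength = 0.7, lag = 0.5, seed = 42)
  expect_identical(m1, m2)
  m3 <- two_roi_model(strength = 0.7, lag = 0.5, seed = 43)
  expect_false(identical(m1$roi_series, m3$roi_series))
})

test_that("zero-strength coupling leaves regions without phase coupling", {
  # Monte-Carlo null: the mean resultant of the phase differences should be
  # statistically indistinguishable from zero over seeds (narrowband series
  # are autocorrelated, so per-run bounds use the across-seed distribution).
  n_seeds <- 100
  cs <- vapply(seq_len(n_seeds), function(s) {
    m <- two_roi_model(strength = 0, lag = pi / 4, seed = 1000 + s,
                       epoch_len = 1024)
    d <- instantaneous_phase(m$roi_series[, 1]) -
      instantaneous_phase(m$roi_series[, 2])
    c(mean(cos(d)), mean(sin(d)))
  }, numeric(2))
  for (i in 1:2) {
    tstat <- abs(mean(cs[i, ])) / (sd(cs[i, ]) / sqrt(n_seeds))
    expect_lt(tstat, 4)
  }
  # contrast: full-strength coupling gives resultant ~ 1
  m <- two_roi_model(strength = 1, lag = pi / 4, seed = 77, epoch_len = 1024)
  d <- instantaneous_phase(m$roi_series[, 1]) -
    instantaneous_phase(m$roi_series[, 2])
  expect_gt(Mod(mean(exp(1i * d))), 0.999)
})

test_that("source band content stays inside the configured band", {
  m <- two_roi_model(strength = 0.5, lag = 0.3, seed = 9)
  b <- alpha1_band()
  for (r in 1:2) {
    frac <- relative_power(m$roi_series[, r], b$f_low, b$f_high, m$fs)
    expect_gte(frac, 0.99)
  }
})

test_that("coupling validation rejects unknown regions and bands", {
  b <- alpha1_band()
  bad_band <- tibble::tibble(roi_i = 1L, roi_j = 2L, band = "mu",
                             phase_lag = 0.1, strength = 1)
  expect_error(generate_sources(n_rois = 2, bands = b, couplings = bad_band,
                                seed = 1), "unknown band")
  bad_roi <- tibble::tibble(roi_i = 1L, roi_j = 5L, band = b$band,
                            phase_lag = 0.1, strength = 1)
  expect_error(generate_sources(n_rois = 2, bands = b, couplings = bad_roi,
                                seed = 1), "unknown ROI")
})

test_that("radial dipoles are magnetically silent, tangential ones are not", {
  sens <- small_sensors()
  pos <- c(40, 20, 25)
  radial <- pos / sqrt(sum(pos^2))
  tang <- c(-pos[2], pos[1], 0)
  tang <- tang / sqrt(sum(tang^2))
  lf_rad <- compute_leadfield(pos, sens, orientation = radial)
  lf_tan <- compute_leadfield(pos, sens, orientation = tang)
  expect_lt(max(abs(lf_rad)), 1e-10 * max(abs(lf_tan)))
})

test_that("lead fields are linear in the dipole moment", {
  sens <- small_sensors()
  u <- c(0, 0.6, 0.8)
  l1 <- compute_leadfield(c(30, -10, 40), sens, orientation = u)
  l2 <- compute_leadfield(c(30, -10, 40), sens, orientation = 2 * u)
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
})

test_that("radial field component matches the primary-dipole Biot-Savart law", {
  # Outside a spherical conductor the volume currents contribute nothing to
  # the radial field component, so B_sarvas . r_hat must equal the bare
  # dipole field (Q x a)/|a|^3 projected radially. Independent closed form.
  sens <- small_sensors()
  pos <- c(25, 30, 35)
  q <- c(-0.4, 0.7, 0.59)
  L <- compute_leadfield(pos, sens)   # channel orientations are radial
  measured <- as.numeric(L %*% q)
  oracle <- apply(sens$positions, 1, function(r) {
    a <- r - pos
    Bp <- c(q[2] * a[3] - q[3] * a[2],
            q[3] * a[1] - q[1] * a[3],
            q[1] * a[2] - q[2] * a[1]) / sqrt(sum(a^2))^3
    sum(Bp * r / sqrt(sum(r^2)))
  })
  expect_lt(max(abs(measured - oracle)) / max(abs(oracle)), 1e-3)
})

test_that("lead-field geometry errors are caught", {
  sens <- small_sensors()
  expect_error(compute_leadfield(c(200, 0, 0), sens), "outside the conductor")
  expect_error(compute_leadfield(c(0, 0, 0), sens), "degenerate")
})

test_that("zero displacement leaves the anatomy untouched", {
  m <- two_roi_model(strength = 1, lag = 0.2, seed = 3, voxels_per_roi = 4)
  p <- perturb_anatomy(m, 0, mode = "per_voxel", seed = 1)
  expect_identical(p$positions, m$positions)
  expect_identical(p$roi_series, m$roi_series)
})

test_that("per-voxel perturbation moves every voxel by exactly d mm", {
  m <- two_roi_model(strength = 1, lag = 0.2, seed = 3, voxels_per_roi = 4)
  p <- perturb_anatomy(m, 5, mode = "per_voxel", seed = 8)
  moves <- sqrt(rowSums((p$positions - m$positions)^2))
  expect_equal(moves, rep(5, nrow(m$positions)), tolerance = 1e-9)
  expect_identical(p$roi_series, m$roi_series)
})

test_that("rigid perturbation is an isometry", {
  m <- two_roi_model(strength = 1, lag = 0.2, seed = 3, voxels_per_roi = 5)
  p <- perturb_anatomy(m, 8, mode = "rigid", seed = 8, rotation_deg = 25)
  expect_equal(as.matrix(dist(p$positions)), as.matrix(dist(m$positions)),
               tolerance = 1e-9)
})

test_that("negative displacement is rejected", {
  m <- two_roi_model(strength = 1, lag = 0.2, seed = 3)
  expect_error(perturb_anatomy(m, -1, seed = 1), ">= 0")
})

test_that("noiseless single-source sensor data has rank 1", {
  m <- two_roi_model(strength = 0, lag = 0, seed = 6, epoch_len = 512)
  m$roi_series[, 2] <- 0
  sens <- small_sensors()
  ep <- project_to_sensors(m, sens, snr = Inf, seed = 1)
  X <- matrix(ep$data, nrow = dim(ep$data)[1])
  sv <- svd(X)$d
  expect_lt(sv[2] / sv[1], 1e-10)
})

test_that("sensor projection is deterministic and snr-calibrated", {
  m <- two_roi_model(strength = 0.8, lag = 0.4, seed = 6, epoch_len = 512)
  sens <- small_sensors()
  e1 <- project_to_sensors(m, sens, snr = 4, seed = 21)
  e2 <- project_to_sensors(m, sens, snr = 4, seed = 21)
  expect_identical(e1, e2)
  e0 <- project_to_sensors(m, sens, snr = Inf, seed = 21)
  noise <- e1$data - e0$data
  ratio <- mean(e0$data^2) / mean(noise^2)
  expect_equal(ratio, 4, tolerance = 0.1)
})

test_that("forward projection is linear in the source amplitudes", {
  m <- two_roi_model(strength = 0.8, lag = 0.4, seed = 6, epoch_len = 512)
  sens <- small_sensors()
  e1 <- project_to_sensors(m, sens, snr = Inf, seed = 1)
  m2 <- m
  m2$roi_series <- 3 * m$roi_series
  e3 <- project_to_sensors(m2, sens, snr = Inf, seed = 1)
  expect_equal(e3$data, 3 * e1$data, tolerance = 1e-12)
})

test_that("source model geometry satisfies its invariants", {
  m <- generate_sources(n_rois = 6, voxels_per_roi = 4, seed = 2,
                        epoch_len = 256, n_epochs = 1, fs = 625)
  expect_equal(sqrt(rowSums(m$orientations^2)), rep(1, nrow(m$orientations)),
               tolerance = 1e-9)
  expect_setequal(unique(m$roi_labels), 1:6)
  rad <- sqrt(rowSums(sweep(m$positions, 2, m$conductor$center)^2))
  expect_true(all(rad < m$conductor$radius))
})
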