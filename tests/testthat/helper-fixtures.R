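# Small simulation fixtures shared across test files.

alpha1_band <- function() {
  b <- classical_bands()
  b[b$band == "alpha1", ]
}

# Two-region model with a single configurable coupling in one band.
two_roi_model <- function(strength, lag, seed, band = alpha1_band(),
                          fs = 256, epoch_len = 2048, n_epochs = 1,
                          voxels_per_roi = 1) {
  generate_sources(
    n_rois = 2, voxels_per_roi = voxels_per_roi, bands = band,
    couplings = tibble::tibble(roi_i = 1L, roi_j = 2L, band = band$band,
                               phase_lag = lag, strength = strength),
    fs = fs, epoch_len = epoch_len, n_epochs = n_epochs, seed = seed)
}

small_sensors <- function(n_channels = 32) {
  meg_sensor_array(n_channels = n_channels)
}

# Single-dipole sensor data: B = L s(t) (+ optional noise), returning the
# ingredients needed by beamformer tests.
single_source_data <- function(seed, n_channels = 24, fs = 256, n = 2048,
                               noise_sd = 0) {
  sens <- meg_sensor_array(n_channels)
  set.seed(seed)
  pos <- c(35, 10, 30)
  u_full <- c(0.3, -0.5, 0.8)
  L_vec <- compute_leadfield(pos, sens)
  # project the orientation on the non-silent subspace so that the scalar
  # lead field captures the full forward field of this dipole
  sv <- svd(L_vec)
  u <- sv$v[, 1:2] %*% crossprod(sv$v[, 1:2], u_full)
  u <- u / sqrt(sum(u^2))
  L <- as.numeric(L_vec %*% u)
  s <- bandpass_fft(rnorm(n), 8, 12, fs)
  B <- outer(L, s)
  if (noise_sd > 0) B <- B + matrix(rnorm(length(B), sd = noise_sd), nrow(B))
  list(sensors = sens, position = pos, orientation = as.numeric(u),
       L_vec = L_vec, L = L, s = s, B = B, fs = fs)
}

unwrap_phase <- function(p) cumsum(c(p[1], Arg(exp(1i * diff(p)))))

smoke_config <- function(seed = 11, n_subjects = 2, displacement = c(0, 10)) {
  validate_config(list(
    n_subjects = n_subjects, n_rois = 4, voxels_per_roi = 3, n_epochs = 5,
    epoch_len = 512, fs = 256, n_channels = 32, bands = alpha1_band(),
    displacement_mm = displacement, modularity_runs = 5,
    log_level = "quiet", seed = seed))
}
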