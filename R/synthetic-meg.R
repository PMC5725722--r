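#' Spherical volume conductor
#'
#' Single homogeneous sphere used for the forward model. Positions are in mm
#' in the head frame.
#'
#' @param radius Sphere radius in mm.
#' @param center Sphere center, length-3 (mm).
#' @return An object of class `meg_conductor`.
#' @export
meg_conductor <- function(radius = 90, center = c(0, 0, 0)) {
  stopifnot(is.numeric(radius), length(radius) == 1, radius > 0,
            is.numeric(center), length(center) == 3)
  structure(list(radius = radius, center = as.numeric(center)),
            class = "meg_conductor")
}

#' Quasi-uniform sensor array on an upper hemisphere
#'
#' Generic stand-in for a whole-head axial-gradiometer system: channels are
#' placed on a golden-angle spiral over the upper hemisphere of a sphere with
#' radius `scale` times the conductor radius, with radial channel
#' orientations.
#'
#' @param n_channels Number of channels (default 151).
#' @param conductor A [meg_conductor()].
#' @param scale Sensor shell radius as a multiple of the conductor radius.
#' @return An object of class `meg_sensor_array` with fields `positions`
#'   (n x 3, mm), `orientations` (n x 3, unit), `n_channels`.
#' @export
meg_sensor_array <- function(n_channels = 151, conductor = meg_conductor(),
                             scale = 1.1) {
  stopifnot(n_channels >= 2, scale > 1)
  r <- conductor$radius * scale
  i <- seq_len(n_channels)
  z <- 1 - (i - 0.5) / n_channels * 0.95     # z in (0.05, 1): upper cap
  theta <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(rho * cos(theta), rho * sin(theta), z) * r
  pos <- sweep(pos, 2, conductor$center, "+")
  ori <- (pos - matrix(conductor$center, n_channels, 3, byrow = TRUE))
  ori <- ori / sqrt(rowSums(ori^2))
  structure(list(positions = pos, orientations = ori,
                 n_channels = n_channels, conductor = conductor),
            class = "meg_sensor_array")
}

# Phase-shift every positive-frequency component of x by -lag radians, so the
# instantaneous phase of the output lags the input by `lag`.
phase_shift <- function(x, lag) {
  n <- length(x)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  pos <- k > 0 & k < n / 2
  neg <- k > n / 2
  X[pos] <- X[pos] * exp(-1i * lag)
  X[neg] <- X[neg] * exp(1i * lag)
  # DC and (for even n) Nyquist bins are real; a narrowband signal has no
  # energy there, leave them untouched.
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Generate a ground-truth phase-coupled source model
#'
#' Builds a source space of `n_rois` cortical regions, each a compact patch
#' of voxels on a 2 mm grid inside the conductor, with per-region narrowband
#' oscillatory time series. Couplings impose a constant phase lag between two
#' regions within one frequency band: the target region's band series is a
#' phase-shifted copy of the source region's series mixed with independent
#' narrowband noise scaled by `1 - strength`.
#'
#' All voxels of a region share the region's time series (a coherent patch).
#'
#' @param n_rois Number of regions (default 78).
#' @param voxels_per_roi Voxels per region patch (default 8).
#' @param bands Band definitions, see [classical_bands()].
#' @param couplings Tibble/data.frame with columns `roi_i`, `roi_j`, `band`,
#'   `phase_lag` (radians, in (-pi, pi]) and `strength` in \[0, 1\], or NULL
#'   for no coupling.
#' @param fs Sampling frequency, Hz (default 625).
#' @param epoch_len Samples per epoch (default 4096).
#' @param n_epochs Number of epochs (default 35).
#' @param conductor A [meg_conductor()].
#' @param grid_mm Grid step of the voxel patch (default 2 mm).
#' @param seed Integer seed; the model is a pure function of the arguments.
#' @return An object of class `meg_source_model` with fields `positions`
#'   (V x 3 mm), `orientations` (V x 3 unit), `roi_labels` (V), `roi_series`
#'   (N x n_rois, summed over bands), `bands`, `couplings`, `fs`,
#'   `epoch_len`, `n_epochs`, `conductor`.
#' @export
generate_sources <- function(n_rois = 78, voxels_per_roi = 8,
                             bands = classical_bands(), couplings = NULL,
                             fs = 625, epoch_len = 4096, n_epochs = 35,
                             conductor = meg_conductor(), grid_mm = 2,
                             seed) {
  stopifnot(n_rois >= 2, voxels_per_roi >= 1, n_epochs >= 1, epoch_len >= 2)
  if (missing(seed)) abort("`seed` is required")
  validate_bands(bands, fs)
  couplings <- validate_couplings(couplings, n_rois, bands)

  local_seed(seed, {
    # ROI centers: random directions at mid-depth inside the sphere.
    centers <- random_unit_vectors(n_rois) *
      runif(n_rois, 0.45, 0.75) * conductor$radius
    offs <- voxel_patch_offsets(voxels_per_roi, grid_mm)
    positions <- do.call(rbind, lapply(seq_len(n_rois), function(r) {
      sweep(offs, 2, centers[r, ], "+")
    }))
    positions <- sweep(positions, 2, conductor$center, "+")
    roi_labels <- rep(seq_len(n_rois), each = voxels_per_roi)
    orientations <- random_unit_vectors(nrow(positions))

    n <- epoch_len * n_epochs
    roi_series <- matrix(0, n, n_rois)
    for (b in seq_len(nrow(bands))) {
      base <- matrix(rnorm(n * n_rois), n, n_rois)
      base <- apply(base, 2, bandpass_fft,
                    f_low = bands$f_low[b], f_high = bands$f_high[b], fs = fs)
      band_sig <- base
      cb <- couplings[couplings$band == bands$band[b], , drop = FALSE]
      for (k in seq_len(nrow(cb))) {
        i <- cb$roi_i[k]; j <- cb$roi_j[k]
        s <- cb$strength[k]; lag <- cb$phase_lag[k]
        band_sig[, j] <- s * phase_shift(base[, i], lag) +
          (1 - s) * base[, j]
      }
      roi_series <- roi_series + band_sig
    }

    structure(list(positions = positions, orientations = orientations,
                   roi_labels = roi_labels, roi_series = roi_series,
                   bands = tibble::as_tibble(bands), couplings = couplings,
                   fs = fs, epoch_len = epoch_len, n_epochs = n_epochs,
                   conductor = conductor, seed = seed, displacement = 0),
              class = "meg_source_model")
  })
}

validate_couplings <- function(couplings, n_rois, bands) {
  if (is.null(couplings) || (is.data.frame(couplings) && nrow(couplings) == 0)) {
    return(tibble::tibble(roi_i = integer(), roi_j = integer(),
                          band = character(), phase_lag = numeric(),
                          strength = numeric()))
  }
  couplings <- tibble::as_tibble(couplings)
  need <- c("roi_i", "roi_j", "band", "phase_lag", "strength")
  if (!all(need %in% names(couplings))) {
    abort(paste("couplings need columns", paste(need, collapse = ", ")))
  }
  if (!all(couplings$band %in% bands$band)) {
    abort(sprintf("coupling references unknown band '%s'",
                  setdiff(couplings$band, bands$band)[1]))
  }
  rois <- c(couplings$roi_i, couplings$roi_j)
  if (!all(rois %in% seq_len(n_rois))) {
    abort("coupling references unknown ROI")
  }
  if (any(couplings$phase_lag <= -pi | couplings$phase_lag > pi)) {
    abort("phase lags must lie in (-pi, pi]")
  }
  if (any(couplings$strength < 0 | couplings$strength > 1)) {
    abort("coupling strength must lie in [0, 1]")
  }
  couplings
}

# Compact patch of voxel offsets on a cubic grid, centered at the origin.
voxel_patch_offsets <- function(n_voxels, grid_mm) {
  side <- ceiling(n_voxels^(1 / 3))
  g <- (seq_len(side) - (side + 1) / 2) * grid_mm
  offs <- as.matrix(expand.grid(x = g, y = g, z = g))
  d <- sqrt(rowSums(offs^2))
  offs <- offs[order(d, offs[, 1], offs[, 2], offs[, 3]), , drop = FALSE]
  unname(offs[seq_len(n_voxels), , drop = FALSE])
}

#' Magnetic lead field of a dipole in a spherical conductor
#'
#' Closed-form (Sarvas) magnetic field of a current dipole inside a
#' homogeneous conducting sphere, evaluated at every channel and projected on
#' the channel orientation. Radially oriented dipoles are magnetically
#' silent.
#'
#' @param position Length-3 dipole position (mm), strictly inside the sphere.
#' @param sensors A [meg_sensor_array()].
#' @param conductor A [meg_conductor()]; defaults to the sensors' conductor.
#' @param orientation Optional unit 3-vector. If given, the scalar lead field
#'   (channels) for that orientation is returned; otherwise the channels x 3
#'   vector-mode lead field (one column per dipole-moment axis).
#' @return Numeric matrix (channels x 3) or vector (channels).
#' @export
compute_leadfield <- function(position, sensors, conductor = sensors$conductor,
                              orientation = NULL) {
  stopifnot(inherits(sensors, "meg_sensor_array"))
  r0 <- as.numeric(position) - conductor$center
  if (vnorm(r0) >= conductor$radius) {
    abort("source position lies outside the conductor sphere")
  }
  if (vnorm(r0) < 1e-9) {
    abort("degenerate geometry: source at the sphere center")
  }
  sens <- sweep(sensors$positions, 2, conductor$center)
  if (any(sqrt(rowSums(sens^2)) <= conductor$radius)) {
    abort("channels must lie strictly outside the conductor sphere")
  }
  L <- vapply(1:3, function(ax) {
    q <- c(0, 0, 0); q[ax] <- 1
    B <- sarvas_field(r0, q, sens)
    rowSums(B * sensors$orientations)
  }, numeric(nrow(sens)))
  if (!is.null(orientation)) as.numeric(L %*% as.numeric(orientation)) else L
}

# Sarvas closed form: field of dipole moment q at r0 (sphere centered at the
# origin), evaluated at sensor rows of `sens`. Constant mu0/4pi dropped
# (arbitrary units).
sarvas_field <- function(r0, q, sens) {
  qxr0 <- cross3(q, r0)
  t(apply(sens, 1, function(r) {
    a <- r - r0
    an <- vnorm(a); rn <- vnorm(r)
    ar <- sum(a * r)
    F_ <- an * (rn * an + rn^2 - sum(r0 * r))
    gF <- (an^2 / rn + ar / an + 2 * an + 2 * rn) * r -
      (an + 2 * rn + ar / an) * r0
    (F_ * qxr0 - sum(qxr0 * r) * gF) / F_^2
  }))
}

#' Spatially perturb a source model's anatomy
#'
#' Emulates the anatomical mismatch introduced by co-registering with a
#' template instead of the native anatomy: voxel positions move while time
#' series, couplings and region membership stay unchanged.
#'
#' @param model A [generate_sources()] model.
#' @param displacement_mm Non-negative displacement magnitude (mm).
#' @param mode `"per_voxel"`: every voxel moves `displacement_mm` in an
#'   independent uniformly random direction; `"rigid"`: one random rigid
#'   translation of norm `displacement_mm` plus a rotation of
#'   `rotation_deg` degrees about the conductor center is applied to all
#'   voxels.
#' @param seed Integer seed.
#' @param rotation_deg Rotation angle for rigid mode (default 0).
#' @return A `meg_source_model` with perturbed positions.
#' @export
perturb_anatomy <- function(model, displacement_mm,
                            mode = c("per_voxel", "rigid"), seed,
                            rotation_deg = 0) {
  stopifnot(inherits(model, "meg_source_model"))
  mode <- match.arg(mode)
  if (displacement_mm < 0) abort("displacement_mm must be >= 0")
  if (missing(seed)) abort("`seed` is required")
  out <- model
  out$displacement <- displacement_mm
  if (displacement_mm == 0 && (mode == "per_voxel" || rotation_deg == 0)) {
    return(out)
  }
  ctr <- model$conductor$center
  rad <- model$conductor$radius
  pos <- sweep(model$positions, 2, ctr)
  local_seed(seed, {
    if (mode == "per_voxel") {
      for (v in seq_len(nrow(pos))) {
        ok <- FALSE
        for (try in seq_len(100)) {
          p <- pos[v, ] + random_unit_vectors(1)[1, ] * displacement_mm
          if (vnorm(p) < rad) { pos[v, ] <- p; ok <- TRUE; break }
        }
        if (!ok) abort("perturbed voxel cannot stay inside the conductor")
      }
    } else {
      rot <- rotation_matrix(random_unit_vectors(1)[1, ],
                             rotation_deg * pi / 180)
      ok <- FALSE
      for (try in seq_len(100)) {
        shift <- random_unit_vectors(1)[1, ] * displacement_mm
        cand <- t(rot %*% t(pos)) +
          matrix(shift, nrow(pos), 3, byrow = TRUE)
        if (all(sqrt(rowSums(cand^2)) < rad)) { pos <- cand; ok <- TRUE; break }
      }
      if (!ok) abort("perturbed voxel cannot stay inside the conductor")
    }
  })
  out$positions <- sweep(pos, 2, ctr, "+")
  out
}

rotation_matrix <- function(axis, angle) {
  u <- axis / vnorm(axis)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Project a source model to the sensors
#'
#' Forward simulation `B(t) = sum_v L_v s_v(t) + noise`, with white Gaussian
#' sensor noise scaled so that sensor-level signal power / noise power equals
#' `snr`. Use `snr = Inf` for noiseless data.
#'
#' @param model A [generate_sources()] model (source of the time series and,
#'   by default, of the lead-field geometry).
#' @param sensors A [meg_sensor_array()].
#' @param snr Sensor-level signal-to-noise power ratio, > 0 (may be `Inf`).
#' @param seed Integer seed for the noise.
#' @param condition_tag Label stored on the epochs, e.g. `"native"`.
#' @return An object of class `meg_epoch_set` with fields `data`
#'   (channels x samples x epochs), `fs`, `epoch_len`, `n_epochs`,
#'   `condition_tag`.
#' @export
project_to_sensors <- function(model, sensors, snr = Inf, seed,
                               condition_tag = "native") {
  stopifnot(inherits(model, "meg_source_model"),
            inherits(sensors, "meg_sensor_array"))
  if (!isTRUE(snr > 0)) abort("snr must be > 0")
  if (missing(seed)) abort("`seed` is required")
  if (!isTRUE(all.equal(sensors$conductor$radius, model$conductor$radius)) ||
      !isTRUE(all.equal(sensors$conductor$center, model$conductor$center))) {
    abort("model and sensor geometry use different conductors")
  }
  Lroi <- roi_leadfields(model, sensors)
  B <- Lroi %*% t(model$roi_series)    # channels x N
  if (is.finite(snr)) {
    p_sig <- mean(B^2)
    sigma <- sqrt(p_sig / snr)
    B <- B + local_seed(seed, matrix(rnorm(length(B), sd = sigma), nrow(B)))
  }
  data <- array(B, dim = c(nrow(B), model$epoch_len, model$n_epochs))
  structure(list(data = data, fs = model$fs, epoch_len = model$epoch_len,
                 n_epochs = model$n_epochs, condition_tag = condition_tag),
            class = "meg_epoch_set")
}

# Channels x n_rois matrix: summed scalar lead fields of each region's voxels.
roi_leadfields <- function(model, sensors) {
  n_rois <- max(model$roi_labels)
  L <- matrix(0, sensors$n_channels, n_rois)
  for (v in seq_len(nrow(model$positions))) {
    lf <- compute_leadfield(model$positions[v, ], sensors, model$conductor,
                            orientation = model$orientations[v, ])
    L[, model$roi_labels[v]] <- L[, model$roi_labels[v]] + lf
  }
  L
}
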