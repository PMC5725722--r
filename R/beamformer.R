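#' Band-pass filter every channel of an epoch set
#'
#' @param epochs A `meg_epoch_set`.
#' @param f_low,f_high Band edges in Hz.
#' @return A `meg_epoch_set` with band-limited data.
#' @export
filter_epochs <- function(epochs, f_low, f_high) {
  stopifnot(inherits(epochs, "meg_epoch_set"))
  keep <- band_bins(epochs$epoch_len, epochs$fs, f_low, f_high)
  out <- epochs
  for (e in seq_len(epochs$n_epochs)) {
    X <- stats::mvfft(t(epochs$data[, , e]))
    X[!keep, ] <- 0
    out$data[, , e] <- t(Re(stats::mvfft(X, inverse = TRUE)) / epochs$epoch_len)
  }
  out
}

#' Regularized sensor covariance
#'
#' Pooled covariance over all concatenated epochs (channels demeaned), with
#' diagonal Tikhonov loading `C + lambda * (trace(C)/M) * I`.
#'
#' @param epochs A `meg_epoch_set` or a channels x samples matrix.
#' @param lambda Regularization as a fraction of mean sensor power
#'   (default 0.01).
#' @return An object of class `meg_covariance` with fields `matrix`,
#'   `n_samples`, `lambda`.
#' @export
estimate_covariance <- function(epochs, lambda = 0.01) {
  X <- if (inherits(epochs, "meg_epoch_set")) {
    matrix(epochs$data, nrow = dim(epochs$data)[1])
  } else {
    as.matrix(epochs)
  }
  if (!all(is.finite(X))) abort("non-finite values in the data")
  m <- nrow(X); n <- ncol(X)
  if (n < m) warn("fewer samples than channels; covariance is rank deficient")
  X <- X - rowMeans(X)
  C <- tcrossprod(X) / (n - 1)
  tr <- sum(diag(C))
  if (tr <= 0) abort("zero covariance: data carry no signal")
  C <- C + lambda * (tr / m) * diag(m)
  structure(list(matrix = C, n_samples = n, lambda = lambda),
            class = "meg_covariance")
}

cov_matrix <- function(C) {
  if (inherits(C, "meg_covariance")) C$matrix else as.matrix(C)
}

#' LCMV beamformer weights
#'
#' Unit-gain spatial filter `W = C^-1 L (L' C^-1 L)^-1` for a scalar lead
#' field, so that `W' L = 1` and the virtual-electrode series is `W' B`.
#'
#' @param L Scalar lead field (channel vector).
#' @param C Sensor covariance ([estimate_covariance()] or a matrix).
#' @return Numeric weight vector.
#' @export
lcmv_weights <- function(L, C) {
  L <- as.numeric(L)
  if (vnorm(L) < 1e-12) abort("silent source: lead field is (numerically) zero")
  w <- solve(cov_matrix(C), L)
  as.numeric(w / sum(L * w))
}

#' Power-maximizing scalar source orientation
#'
#' The unit-gain beamformer output power at orientation `u` is
#' `1 / (u' (L' C^-1 L) u)`; the returned orientation is the eigenvector of
#' the smallest eigenvalue of `L' C^-1 L`, restricted to the non-null
#' (tangential) subspace of the vector lead field. Sign is fixed so the first
#' nonzero component is non-negative.
#'
#' @param L_vec Channels x 3 vector-mode lead field.
#' @param C Sensor covariance.
#' @param tol Relative singular-value cutoff for the null space.
#' @return A unit 3-vector.
#' @export
scalar_orientation <- function(L_vec, C, tol = 1e-8) {
  L_vec <- as.matrix(L_vec)
  sv <- svd(L_vec)
  keep <- sv$d > tol * max(sv$d)
  if (!any(keep)) abort("all-zero tangential lead field")
  Vk <- sv$v[, keep, drop = FALSE]
  M <- crossprod(L_vec, solve(cov_matrix(C), L_vec))
  Mr <- crossprod(Vk, M %*% Vk)
  eg <- eigen((Mr + t(Mr)) / 2, symmetric = TRUE)
  u <- as.numeric(Vk %*% eg$vectors[, ncol(Mr)])
  u <- u / vnorm(u)
  nz <- which(abs(u) > 1e-12)[1]
  if (u[nz] < 0) u <- -u
  u
}

#' Pseudo-Z of a beamformer weight vector
#'
#' Output power normalized by projected noise power,
#' `Z = sqrt((W' C W) / (sigma2 * W' W))`. By default `sigma2` is the mean of
#' the smallest `ceiling(M/4)` eigenvalues of `C` (a noise-floor estimate).
#'
#' @param w Weight vector.
#' @param C Sensor covariance.
#' @param sigma2 Noise power; `NULL` for the eigenvalue-floor default.
#' @return Scalar pseudo-Z.
#' @export
pseudo_z <- function(w, C, sigma2 = NULL) {
  Cm <- cov_matrix(C)
  ww <- sum(w^2)
  if (ww == 0) abort("zero weight vector")
  if (is.null(sigma2)) {
    ev <- eigen(Cm, symmetric = TRUE, only.values = TRUE)$values
    k <- ceiling(nrow(Cm) / 4)
    sigma2 <- mean(sort(ev)[seq_len(k)])
  }
  if (!isTRUE(sigma2 > 0)) abort("sigma2 must be > 0")
  sqrt(as.numeric(crossprod(w, Cm %*% w)) / (sigma2 * ww))
}

#' Representative voxel of a region
#'
#' `"peak"` picks the voxel with the highest pseudo-Z; `"centroid"` picks the
#' voxel nearest (in summed Euclidean distance) to all other voxels of the
#' region. Ties break to the lowest voxel id, for determinism.
#'
#' @param voxel_ids Integer ids of the region's voxels.
#' @param positions Matching voxel positions (n x 3), required for centroid.
#' @param method `"peak"` or `"centroid"`.
#' @param pseudo_z Pseudo-Z per voxel (required for `"peak"`).
#' @return The selected voxel id.
#' @export
select_representative <- function(voxel_ids, positions = NULL,
                                  method = c("peak", "centroid"),
                                  pseudo_z = NULL) {
  method <- match.arg(method)
  if (length(voxel_ids) == 0) abort("empty ROI")
  if (method == "peak") {
    if (is.null(pseudo_z) || length(pseudo_z) != length(voxel_ids)) {
      abort("peak method needs one pseudo_z value per voxel")
    }
    ord <- order(-pseudo_z, voxel_ids)
  } else {
    if (is.null(positions)) abort("centroid method needs voxel positions")
    positions <- as.matrix(positions)
    if (nrow(positions) == 1) return(voxel_ids[1])
    dsum <- rowSums(as.matrix(stats::dist(positions)))
    ord <- order(dsum, voxel_ids)
  }
  voxel_ids[ord[1]]
}

#' Euclidean distance between two voxel positions (mm)
#'
#' @param a,b Length-3 coordinates in the same frame.
#' @return Non-negative distance in mm.
#' @export
voxel_distance <- function(a, b) {
  stopifnot(length(a) == 3, length(b) == 3)
  vnorm(as.numeric(a) - as.numeric(b))
}

#' Beamform regional virtual electrodes under one anatomy
#'
#' For each frequency band: band-filters the sensor epochs, estimates the
#' pooled covariance, computes per-voxel power-maximizing orientations,
#' unit-gain LCMV weights and pseudo-Z using the lead fields of
#' `anatomy` (which may be the true model or a spatially perturbed copy),
#' selects a representative voxel per region (peak and/or centroid) and
#' extracts its virtual-electrode time series.
#'
#' @param epochs Sensor `meg_epoch_set` (broadband; filtering done here).
#' @param anatomy `meg_source_model` supplying voxel positions/orientations
#'   for the lead fields (its time series are not used).
#' @param sensors A [meg_sensor_array()].
#' @param bands Band definitions.
#' @param lambda Covariance regularization.
#' @param methods Subset of `c("peak", "centroid")`.
#' @return An object of class `meg_ve_set`: `series[[band]][[method]]` is a
#'   regions x samples x epochs array of band-limited VE series;
#'   `representatives` is a tibble (roi, band, method, voxel, x, y, z);
#'   plus `fs`, `bands`, `condition_tag`.
#' @export
beamform_rois <- function(epochs, anatomy, sensors,
                          bands = classical_bands(), lambda = 0.01,
                          methods = c("peak", "centroid")) {
  stopifnot(inherits(epochs, "meg_epoch_set"),
            inherits(anatomy, "meg_source_model"))
  methods <- match.arg(methods, c("peak", "centroid"), several.ok = TRUE)
  validate_bands(bands, epochs$fs)
  n_vox <- nrow(anatomy$positions)
  n_rois <- max(anatomy$roi_labels)
  rois <- split(seq_len(n_vox), anatomy$roi_labels)

  # Vector lead fields per voxel (shared across bands).
  Lv <- lapply(seq_len(n_vox), function(v) {
    compute_leadfield(anatomy$positions[v, ], sensors, anatomy$conductor)
  })

  # Band-independent centroid choices.
  centroid_voxel <- vapply(rois, function(ids) {
    select_representative(ids, anatomy$positions[ids, , drop = FALSE],
                          method = "centroid")
  }, integer(1))

  series <- list()
  reps <- list()
  for (b in seq_len(nrow(bands))) {
    bn <- bands$band[b]
    ep_f <- filter_epochs(epochs, bands$f_low[b], bands$f_high[b])
    C <- estimate_covariance(ep_f, lambda = lambda)
    Cm <- C$matrix
    Cinv <- chol2inv(chol(Cm))
    ev <- eigen(Cm, symmetric = TRUE, only.values = TRUE)$values
    sigma2 <- mean(sort(ev)[seq_len(ceiling(nrow(Cm) / 4))])

    W <- matrix(0, sensors$n_channels, n_vox)
    z <- numeric(n_vox)
    for (v in seq_len(n_vox)) {
      u <- scalar_orientation(Lv[[v]], C)
      Ls <- as.numeric(Lv[[v]] %*% u)
      w <- Cinv %*% Ls
      w <- w / as.numeric(crossprod(Ls, w))
      W[, v] <- w
      z[v] <- pseudo_z(w, Cm, sigma2 = sigma2)
    }

    # VE series keep broadband content (weights are band-specific, the data
    # are not): relative power is meaningful, and band-limiting for phase
    # analysis commutes with the fixed linear weights.
    Xb <- matrix(epochs$data, nrow = sensors$n_channels)
    series[[bn]] <- list()
    for (method in methods) {
      rep_vox <- if (method == "peak") {
        vapply(rois, function(ids) {
          select_representative(ids, method = "peak", pseudo_z = z[ids])
        }, integer(1))
      } else {
        centroid_voxel
      }
      ve <- crossprod(W[, rep_vox, drop = FALSE], Xb)  # regions x N
      series[[bn]][[method]] <- array(ve, dim = c(n_rois, epochs$epoch_len,
                                                  epochs$n_epochs))
      reps[[paste(bn, method)]] <- tibble::tibble(
        roi = seq_len(n_rois), band = bn, method = method,
        voxel = as.integer(rep_vox),
        x = anatomy$positions[rep_vox, 1],
        y = anatomy$positions[rep_vox, 2],
        z = anatomy$positions[rep_vox, 3],
        pseudo_z = z[rep_vox])
    }
  }
  structure(list(series = series, representatives = dplyr::bind_rows(reps),
                 fs = epochs$fs, bands = tibble::as_tibble(bands),
                 epoch_len = epochs$epoch_len, n_epochs = epochs$n_epochs,
                 condition_tag = epochs$condition_tag),
            class = "meg_ve_set")
}
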