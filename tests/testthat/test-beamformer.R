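test_that("large-sample covariance of independent channels is the identity", {
  set.seed(1)
  n <- 20000
  X <- matrix(rnorm(8 * n), 8, n)
  C <- estimate_covariance(X, lambda = 0)
  off <- C$matrix[upper.tri(C$matrix)]
  expect_lt(max(abs(off)), 3 / sqrt(n))
  expect_equal(unname(diag(C$matrix)), rep(1, 8), tolerance = 0.05)
})

test_that("covariance estimation rejects degenerate input and regularizes", {
  expect_error(estimate_covariance(matrix(0, 4, 100), lambda = 0.01), "zero covariance")
  expect_error(estimate_covariance(matrix(c(1, NA), 2, 50)), "non-finite")
  set.seed(2)
  X <- matrix(rnorm(6 * 40), 6, 40)
  C <- estimate_covariance(X, lambda = 0.05)
  expect_equal(C$matrix, t(C$matrix), tolerance = 1e-12)
  expect_gt(min(eigen(C$matrix, symmetric = TRUE)$values), 0)
  expect_warning(estimate_covariance(matrix(rnorm(20), 10, 2)), "fewer samples")
})

test_that("LCMV weights solve the textbook cases", {
  # identity covariance picks the lead-field channel directly
  expect_equal(lcmv_weights(c(1, 0), diag(2)), c(1, 0))
  # hand case: L = (1,1)', C = diag(1,4) -> W = (0.8, 0.2)'
  expect_equal(lcmv_weights(c(1, 1), diag(c(1, 4))), c(0.8, 0.2))
  # independent linear-solve oracle on a random pair
  set.seed(3)
  A <- matrix(rnorm(36), 6)
  C <- crossprod(A) + diag(6)
  L <- rnorm(6)
  w <- lcmv_weights(L, C)
  w_oracle <- solve(C, L) / as.numeric(t(L) %*% solve(C, L))
  expect_equal(w, as.numeric(w_oracle), tolerance = 1e-10)
  expect_error(lcmv_weights(rep(0, 6), C), "silent source")
})

test_that("weights have unit gain and scale inversely with the lead field", {
  set.seed(4)
  for (i in 1:25) {
    A <- matrix(rnorm(64), 8)
    C <- crossprod(A) + 0.1 * diag(8)
    L <- rnorm(8)
    w <- lcmv_weights(L, C)
    expect_lt(abs(sum(w * L) - 1), 1e-8)
    expect_equal(lcmv_weights(2 * L, C), w / 2, tolerance = 1e-10)
  }
})

test_that("a noiseless single source is reconstructed almost perfectly", {
  d <- single_source_data(seed = 5)
  C <- estimate_covariance(d$B, lambda = 1e-6)
  w <- lcmv_weights(d$L, C)
  ve <- as.numeric(crossprod(w, d$B))
  expect_gt(cor(ve, d$s), 0.999)
  # beamformer linearity: scaled data give scaled reconstruction
  expect_equal(as.numeric(crossprod(w, 2.5 * d$B)), 2.5 * ve,
               tolerance = 1e-12)
})

test_that("the scalar orientation recovers a strongly active source", {
  d <- single_source_data(seed = 6)
  # moderate sensor noise so the covariance is invertible but the source dominates
  set.seed(60)
  B <- d$B + matrix(rnorm(length(d$B), sd = 0.005 * stats::sd(d$B)), nrow(d$B))
  C <- estimate_covariance(B, lambda = 1e-4)
  u <- scalar_orientation(d$L_vec, C)
  expect_gt(abs(sum(u * d$orientation)), 0.99)
})

test_that("orientation under identity covariance follows the SVD structure", {
  # with C = I the criterion reduces to the eigenstructure of L'L restricted
  # to the non-silent subspace: the minor right-singular direction
  set.seed(7)
  L_vec <- matrix(rnorm(30), 10, 3)
  u <- scalar_orientation(L_vec, diag(10))
  sv <- svd(L_vec)
  expected <- sv$v[, 3]
  expect_gt(abs(sum(u * expected)), 1 - 1e-8)
  # sign convention: first nonzero component non-negative
  nz <- which(abs(u) > 1e-12)[1]
  expect_gte(u[nz], 0)
})

test_that("pseudo-Z is 1 for pure noise and increases with source power", {
  set.seed(8)
  n <- 1e5
  X <- matrix(rnorm(8 * n, sd = 2), 8, n)
  C <- estimate_covariance(X, lambda = 0)
  w <- rnorm(8)
  expect_equal(pseudo_z(w, C, sigma2 = 4), 1, tolerance = 0.05)
  # doubling the source amplitude strictly increases Z
  d <- single_source_data(seed = 9, noise_sd = 0.01)
  C1 <- estimate_covariance(d$B, lambda = 1e-6)$matrix
  d2 <- d$B + outer(d$L, d$s)          # doubled source, same noise
  C2 <- estimate_covariance(d2, lambda = 1e-6)$matrix
  w <- lcmv_weights(d$L, C1)
  expect_gt(pseudo_z(w, C2, sigma2 = 1), pseudo_z(w, C1, sigma2 = 1))
})

test_that("the pseudo-Z peak localizes an embedded source", {
  d <- single_source_data(seed = 10, n_channels = 32)
  set.seed(10)
  B <- d$B + matrix(rnorm(length(d$B), sd = 0.02 * stats::sd(d$B)), nrow(d$B))
  C <- estimate_covariance(B, lambda = 1e-3)
  # candidate grid: the true voxel plus displaced neighbours
  cand <- rbind(d$position,
                d$position + c(8, 0, 0), d$position - c(8, 0, 0),
                d$position + c(0, 8, 0), d$position + c(0, 0, 8),
                d$position - c(0, 0, 8))
  z <- apply(cand, 1, function(p) {
    Lv <- compute_leadfield(p, d$sensors)
    u <- scalar_orientation(Lv, C)
    w <- lcmv_weights(as.numeric(Lv %*% u), C)
    pseudo_z(w, C)
  })
  expect_equal(which.max(z), 1L)
})

test_that("representative-voxel selection follows peak and centroid rules", {
  # collinear voxels: the middle one is the centroid
  pos <- cbind(c(0, 1, 2), 0, 0)
  expect_equal(select_representative(1:3, pos, "centroid"), 2L)
  # peak = argmax pseudo-Z
  expect_equal(select_representative(1:3, method = "peak",
                                     pseudo_z = c(0.1, 0.9, 0.4)), 2L)
  # ties break to the lowest voxel id
  expect_equal(select_representative(4:6, method = "peak",
                                     pseudo_z = c(0.9, 0.9, 0.1)), 4L)
  expect_error(select_representative(integer(0), method = "peak",
                                     pseudo_z = numeric(0)), "empty ROI")
})

test_that("centroid matches the brute-force minimum-sum-distance voxel", {
  set.seed(11)
  pos <- matrix(rnorm(50 * 3, sd = 10), 50, 3)
  got <- select_representative(1:50, pos, "centroid")
  dsum <- rowSums(as.matrix(dist(pos)))
  expect_equal(got, unname(which.min(dsum)))
})

test_that("voxel distances follow the Euclidean norm", {
  expect_equal(voxel_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(voxel_distance(c(0, 0, 0), c(3, 4, 0)), 5)
})

test_that("per-voxel displacement concentrates centroid distances near d", {
  m <- generate_sources(n_rois = 3, voxels_per_roi = 5, bands = alpha1_band(),
                        fs = 256, epoch_len = 256, n_epochs = 1, seed = 12)
  p <- perturb_anatomy(m, 5, mode = "per_voxel", seed = 13)
  for (r in 1:3) {
    ids <- which(m$roi_labels == r)
    vn <- select_representative(ids, m$positions[ids, ], "centroid")
    vt <- select_representative(ids, p$positions[ids, ], "centroid")
    d <- voxel_distance(m$positions[vn, ], p$positions[vt, ])
    expect_lt(abs(d - 5), 5)   # same patch, move dominated by the 5 mm shift
  }
})

test_that("beamformed virtual electrodes recover source coupling structure", {
  m <- two_roi_model(strength = 1, lag = pi / 3, seed = 14, epoch_len = 1024,
                     n_epochs = 2, voxels_per_roi = 3)
  sens <- small_sensors()
  ep <- project_to_sensors(m, sens, snr = 20, seed = 15)
  ve <- beamform_rois(ep, m, sens, bands = alpha1_band(),
                      methods = c("peak", "centroid"))
  expect_s3_class(ve, "meg_ve_set")
  arr <- ve$series[["alpha1"]][["peak"]]
  expect_equal(dim(arr), c(2, 1024, 2))
  # the two reconstructed regions keep their constant phase lag
  b <- alpha1_band()
  x1 <- bandpass_fft(arr[1, , 1], b$f_low, b$f_high, 256)
  x2 <- bandpass_fft(arr[2, , 1], b$f_low, b$f_high, 256)
  expect_gt(pli(instantaneous_phase(x1) - instantaneous_phase(x2)), 0.9)
  expect_equal(nrow(ve$representatives), 2 * 2)  # 2 rois x 2 methods x 1 band
})
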