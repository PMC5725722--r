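config_defaults <- function() {
  list(
    n_rois = 78, voxels_per_roi = 8, n_channels = 151,
    fs = 625, epoch_len = 4096, n_epochs = 35, n_subjects = 17,
    bands = classical_bands(), couplings = NULL,
    snr = 2, displacement_mm = c(0, 5, 15, 30),
    perturb_mode = "per_voxel", rotation_deg = 0,
    methods = c("peak", "centroid"), lambda = 0.01,
    modularity_runs = 100, grid_mm = 2, conductor_radius = 90,
    sensor_scale = 1.1, seed = 1, output_dir = NULL, log_level = "info")
}

#' Validate an experiment configuration
#'
#' Injects the default acquisition constants (151 channels, 625 Hz sampling,
#' 4096-sample epochs, 78 regions, six classical bands) into a partial
#' configuration and rejects contradictions with messages naming the key.
#'
#' @param config A named list (possibly empty), or a path to a YAML/JSON
#'   file holding one.
#' @return An object of class `meg_experiment_config` (a validated list).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config_file(config)
  }
  if (inherits(config, "meg_experiment_config")) return(config)
  if (!is.list(config)) abort("config must be a named list")
  defaults <- config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- defaults
  for (k in names(config)) cfg[k] <- list(config[[k]])
  if (is.list(cfg$bands) && !is.data.frame(cfg$bands)) {
    cfg$bands <- dplyr::bind_rows(lapply(cfg$bands, tibble::as_tibble))
  }
  validate_bands(cfg$bands, cfg$fs)
  if (cfg$n_subjects < 1) abort("n_subjects must be >= 1")
  if (cfg$n_rois < 2) abort("n_rois must be >= 2")
  if (cfg$n_channels < 2) abort("n_channels must be >= 2")
  if (any(cfg$displacement_mm < 0)) abort("displacement_mm must be >= 0")
  if (!isTRUE(cfg$snr > 0)) abort("snr must be > 0")
  if (!all(cfg$methods %in% c("peak", "centroid"))) {
    abort("methods must be a subset of 'peak', 'centroid'")
  }
  if (!cfg$perturb_mode %in% c("per_voxel", "rigid")) {
    abort("perturb_mode must be 'per_voxel' or 'rigid'")
  }
  if (!is.null(cfg$couplings)) {
    cfg$couplings <- validate_couplings(tibble::as_tibble(cfg$couplings),
                                        cfg$n_rois, cfg$bands)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("meg_experiment_config", "list"))
}

read_config_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

# Default coupling graph: per band, ~n_rois/3 distinct region pairs with
# nonzero lags (PLI is blind to zero lag) and strong coupling.
default_couplings <- function(n_rois, bands, seed) {
  local_seed(seed, {
    out <- lapply(seq_len(nrow(bands)), function(b) {
      n_pairs <- max(1, floor(n_rois / 3))
      all_pairs <- utils::combn(n_rois, 2)
      take <- sample(ncol(all_pairs), min(n_pairs, ncol(all_pairs)))
      tibble::tibble(
        roi_i = as.integer(all_pairs[1, take]),
        roi_j = as.integer(all_pairs[2, take]),
        band = bands$band[b],
        phase_lag = sample(c(-1, 1), length(take), replace = TRUE) *
          runif(length(take), 0.2, 1.2),
        strength = runif(length(take), 0.6, 0.95))
    })
    dplyr::bind_rows(out)
  })
}

# Deterministic modularity seed per (subject base seed, band, method, epoch),
# independent of condition and displacement so identical adjacency matrices
# anneal identically.
mod_seed_for <- function(base, band_idx, method_idx, epoch) {
  as.integer((abs(base) * 131 + band_idx * 7919 +
                method_idx * 104729 + epoch * 37) %% 2147483629L)
}

# All per-condition measures of one virtual-electrode set.
ve_measures <- function(ve, bands, fs, modularity_runs, seed_base,
                        condition) {
  power <- list(); regional <- list(); global_ep <- list()
  for (b in seq_len(nrow(bands))) {
    bn <- bands$band[b]
    keep <- band_bins(ve$epoch_len, fs, bands$f_low[b], bands$f_high[b])
    for (mi in seq_along(names(ve$series[[bn]]))) {
      method <- names(ve$series[[bn]])[mi]
      arr <- ve$series[[bn]][[method]]
      n_rois <- dim(arr)[1]
      pw <- relative_power_table(arr, bands = bands[b, ], fs = fs)
      pw$band <- bn; pw$method <- method
      power[[paste(bn, method)]] <- pw
      for (e in seq_len(ve$n_epochs)) {
        x <- t(arr[, , e])                       # samples x regions, broadband
        X <- stats::mvfft(x)
        X[!keep, ] <- 0
        xf <- Re(stats::mvfft(X, inverse = TRUE)) / nrow(x)
        A <- pli_adjacency(xf)
        nm <- network_metrics(A, modularity_runs = modularity_runs,
                              seed = mod_seed_for(seed_base, b, mi, e))
        regional[[paste(bn, method, e)]] <- tibble::tibble(
          method = method, band = bn, epoch = e,
          roi = rep(seq_len(n_rois), 2),
          measure = rep(c("pli", "mst_degree"), each = n_rois),
          value = c(rowSums(A) / (n_rois - 1), as.numeric(nm$mst_degree[[1]])))
        global_ep[[paste(bn, method, e)]] <- tibble::tibble(
          method = method, band = bn, epoch = e,
          pli = nm$pli, cw = nm$cw, lw = nm$lw, q = nm$q,
          n_modules = nm$n_modules, leaf_fraction = nm$leaf_fraction,
          diameter = as.numeric(nm$diameter))
      }
    }
  }
  power <- dplyr::bind_rows(power) |>
    dplyr::mutate(measure = "power") |>
    dplyr::select("method", "band", "epoch", "roi", "measure", "value")
  regional <- dplyr::bind_rows(c(list(power), regional))
  global_ep <- dplyr::bind_rows(global_ep)
  gp <- power |>
    dplyr::group_by(.data$method, .data$band, .data$epoch) |>
    dplyr::summarise(power = mean(.data$value), .groups = "drop")
  global_sub <- dplyr::left_join(global_ep, gp,
                                 by = c("method", "band", "epoch")) |>
    tidyr::pivot_longer(cols = c("power", "pli", "cw", "lw", "q", "n_modules",
                                 "leaf_fraction", "diameter"),
                        names_to = "measure", values_to = "value") |>
    dplyr::group_by(.data$method, .data$band, .data$measure) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  regional$condition <- condition
  global_sub$condition <- condition
  list(regional = regional, global_subject = global_sub)
}

#' Run the full template-versus-native consistency experiment
#'
#' Executes the complete pipeline for every subject: generate coupled
#' sources, project to the sensors once (the sensor recording is shared by
#' both conditions, as in a real study where only the co-registration
#' differs), beamform under the true ("native") anatomy and under a
#' spatially perturbed ("template") anatomy at each displacement level,
#' compute relative power, PLI connectivity and network metrics per epoch,
#' and compare the two conditions with ICC(3,1), Bland-Altman and
#' distance-versus-consistency correlations.
#'
#' @param config A configuration list or [validate_config()] result.
#' @return An object of class `meg_consistency_report`: tibbles
#'   `regional_icc`, `global_icc`, `global_measures`, `distances`,
#'   `distance_icc`, plus `config` and `manifest`. Tables are also written as
#'   CSV/JSON when `config$output_dir` is set.
#' @export
run_experiment <- function(config = list()) {
  cfg <- validate_config(config)
  log_info <- function(...) {
    if (identical(cfg$log_level, "info")) message(sprintf(...))
  }
  conductor <- meg_conductor(radius = cfg$conductor_radius)
  sensors <- meg_sensor_array(cfg$n_channels, conductor, cfg$sensor_scale)
  disp <- cfg$displacement_mm

  regional <- list(); global_sub <- list(); dists <- list()
  for (s in seq_len(cfg$n_subjects)) {
    subj_seed <- as.integer((cfg$seed + 10000 + s * 101) %% 2147480000)
    couplings <- cfg$couplings %||%
      default_couplings(cfg$n_rois, cfg$bands, subj_seed + 1L)
    log_info("subject %d/%d: generating sources", s, cfg$n_subjects)
    model <- generate_sources(
      n_rois = cfg$n_rois, voxels_per_roi = cfg$voxels_per_roi,
      bands = cfg$bands, couplings = couplings, fs = cfg$fs,
      epoch_len = cfg$epoch_len, n_epochs = cfg$n_epochs,
      conductor = conductor, grid_mm = cfg$grid_mm, seed = subj_seed + 2L)
    epochs <- project_to_sensors(model, sensors, snr = cfg$snr,
                                 seed = subj_seed + 3L)
    ve_nat <- beamform_rois(epochs, model, sensors, bands = cfg$bands,
                            lambda = cfg$lambda, methods = cfg$methods)
    meas_nat <- ve_measures(ve_nat, cfg$bands, cfg$fs, cfg$modularity_runs,
                            seed_base = subj_seed, condition = "native")
    for (di in seq_along(disp)) {
      d <- disp[di]
      log_info("subject %d: displacement %.1f mm", s, d)
      tmpl <- perturb_anatomy(model, d, mode = cfg$perturb_mode,
                              seed = subj_seed + 50L + di,
                              rotation_deg = cfg$rotation_deg)
      ve_tmp <- beamform_rois(epochs, tmpl, sensors, bands = cfg$bands,
                              lambda = cfg$lambda, methods = cfg$methods)
      meas_tmp <- ve_measures(ve_tmp, cfg$bands, cfg$fs, cfg$modularity_runs,
                              seed_base = subj_seed, condition = "template")
      tag <- function(x) dplyr::mutate(x, subject = s, displacement = d)
      regional[[paste(s, di)]] <- dplyr::bind_rows(tag(meas_nat$regional),
                                                   tag(meas_tmp$regional))
      global_sub[[paste(s, di)]] <- dplyr::bind_rows(
        tag(meas_nat$global_subject), tag(meas_tmp$global_subject))
      dd <- dplyr::inner_join(
        dplyr::select(ve_nat$representatives, "roi", "band", "method",
                      nx = "x", ny = "y", nz = "z"),
        dplyr::select(ve_tmp$representatives, "roi", "band", "method",
                      tx = "x", ty = "y", tz = "z"),
        by = c("roi", "band", "method"))
      dists[[paste(s, di)]] <- dd |>
        dplyr::mutate(
          subject = s, displacement = d,
          distance = sqrt((.data$nx - .data$tx)^2 + (.data$ny - .data$ty)^2 +
                            (.data$nz - .data$tz)^2)) |>
        dplyr::select("subject", "displacement", "method", "band", "roi",
                      "distance")
    }
  }
  regional <- dplyr::bind_rows(regional)
  global_sub <- dplyr::bind_rows(global_sub)
  dists <- dplyr::bind_rows(dists)

  # Pooled-epoch regional ICC (epochs concatenated across subjects).
  regional <- dplyr::mutate(
    regional, pooled_epoch = (.data$subject - 1) * cfg$n_epochs + .data$epoch)
  regional_icc <- regional |>
    dplyr::group_by(.data$displacement, .data$method) |>
    dplyr::group_modify(function(g, key) {
      regional_consistency(dplyr::select(
        g, "roi", "band", "measure", epoch = "pooled_epoch", "condition",
        "value"))
    }) |>
    dplyr::ungroup()

  global_icc <- global_sub |>
    dplyr::group_by(.data$displacement, .data$method) |>
    dplyr::group_modify(function(g, key) {
      global_consistency(dplyr::select(
        g, "subject", "band", "measure", "condition", "value"))
    }) |>
    dplyr::ungroup()

  mean_dist <- dists |>
    dplyr::group_by(.data$displacement, .data$method, .data$band, .data$roi) |>
    dplyr::summarise(distance = mean(.data$distance), .groups = "drop")

  # Distance vs power-ICC, pooled over displacement levels per (method, band).
  power_icc <- regional_icc |>
    dplyr::filter(.data$measure == "power") |>
    dplyr::select("displacement", "method", "band", "roi", "icc")
  pooled <- dplyr::inner_join(mean_dist, power_icc,
                              by = c("displacement", "method", "band", "roi"))
  distance_icc <- pooled |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(function(g, key) {
      distance_vs_icc(dplyr::select(g, "band", "roi", "distance", "icc"))
    }) |>
    dplyr::ungroup()

  manifest <- list(
    package_version = as.character(utils::packageVersion("megconsist")),
    config_hash = rlang::hash(unclass(cfg)),
    seed = cfg$seed,
    n_subjects = cfg$n_subjects,
    displacement_mm = disp,
    timestamp = format(Sys.time(), tz = "UTC"))

  report <- structure(list(
    regional_icc = regional_icc, global_icc = global_icc,
    global_measures = global_sub, distances = mean_dist,
    distance_points = pooled, distance_icc = distance_icc,
    config = cfg, manifest = manifest),
    class = "meg_consistency_report")
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  wr(report$regional_icc, "regional_icc")
  wr(report$global_icc, "global_icc")
  wr(report$global_measures, "global_measures")
  wr(report$distances, "distances")
  wr(report$distance_icc, "distance_icc")
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

#' @export
print.meg_consistency_report <- function(x, ...) {
  cat(sprintf("MEG consistency report: %d subject(s), displacements %s mm\n",
              x$config$n_subjects,
              paste(x$config$displacement_mm, collapse = "/")))
  cat(sprintf("  regional ICC rows: %d; global ICC rows: %d\n",
              nrow(x$regional_icc), nrow(x$global_icc)))
  invisible(x)
}
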