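#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed model, consistency, single measure: raters (the two
#' co-registration approaches) are fixed, items are random.
#' `ICC = (MS_rows - MS_error) / (MS_rows + (k - 1) MS_error)` from the
#' two-way ANOVA without interaction; the 95% CI uses the F-distribution
#' construction (McGraw & Wong case 3). The consistency ICC ignores a purely
#' additive rater bias and can be negative; negative values are rated
#' "poor" and flagged not reliable.
#'
#' @param a,b Paired measurements of the two raters (equal length, n >= 3).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `meg_icc` with fields `icc`, `ci_low`,
#'   `ci_high`, `rating`, `not_reliable`, `n`, `k`, `msr`, `mse`, `fvalue`.
#' @export
icc31 <- function(a, b, conf_level = 0.95) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) abort("paired vectors must have equal length")
  if (anyNA(a) || anyNA(b)) abort("missing values after pairing")
  n <- length(a); k <- 2
  if (n < 3) abort("ICC needs at least 3 items")
  x <- cbind(a, b)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  sst <- sum((x - grand)^2)
  if (sst == 0) abort("constant data: total variance is zero")
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse)
  alpha <- 1 - conf_level
  if (mse == 0) {
    ci <- c(1, 1)
    fobs <- Inf
  } else {
    fobs <- msr / mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 rating = rate_icc(icc), not_reliable = icc < 0,
                 n = n, k = k, msr = msr, mse = mse, fvalue = fobs,
                 conf_level = conf_level),
            class = "meg_icc")
}

#' @export
print.meg_icc <- function(x, ...) {
  cat(sprintf("ICC(3,1) = %.3f [%.3f, %.3f] (%s%s), n = %d\n",
              x$icc, x$ci_low, x$ci_high, x$rating,
              if (x$not_reliable) ", not reliable" else "", x$n))
  invisible(x)
}

#' Qualitative rating of an ICC value
#'
#' Bands: (0.80, 1\] very good; (0.60, 0.80\] good; (0.40, 0.60\] moderate;
#' (0.20, 0.40\] fair; <= 0.20 poor (the "very good" band is strictly above
#' 0.80, so 0.80 itself rates good). Negative ICCs rate poor.
#'
#' @param icc ICC value(s), <= 1.
#' @return Character rating(s).
#' @export
rate_icc <- function(icc) {
  stopifnot(all(icc <= 1 + 1e-12))
  cut_lab <- function(v) {
    if (v > 0.80) "very good"
    else if (v > 0.60) "good"
    else if (v > 0.40) "moderate"
    else if (v > 0.20) "fair"
    else "poor"
  }
  vapply(icc, cut_lab, character(1))
}

#' Bland-Altman agreement analysis
#'
#' Per-item differences `d_i = a_i - b_i`; limits of agreement are the mean
#' difference plus and minus 1.96 times the sample standard deviation
#' (n - 1 denominator) of the differences.
#'
#' @param a,b Paired measurements (length n >= 2); by convention `a` is the
#'   template condition and `b` the native condition.
#' @return An object of class `meg_bland_altman` with `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n_outside` (points strictly outside the limits)
#'   and a per-point `data` tibble (`mean`, `diff`).
#' @export
bland_altman <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) abort("paired vectors must have equal length")
  if (length(a) < 2) abort("Bland-Altman needs at least 2 pairs")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  loa <- c(m - 1.96 * s, m + 1.96 * s)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = loa[1], loa_high = loa[2],
                 n_outside = sum(d < loa[1] | d > loa[2]),
                 n = length(a),
                 data = tibble::tibble(mean = (a + b) / 2, diff = d)),
            class = "meg_bland_altman")
}

#' @export
print.meg_bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.4g, LoA [%.4g, %.4g], %d/%d outside\n",
              x$mean_diff, x$loa_low, x$loa_high, x$n_outside, x$n))
  invisible(x)
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y Numeric vectors, n >= 3, neither constant.
#' @return A list with `r` and `p`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("need paired vectors of length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Regional (per-epoch) consistency between two conditions
#'
#' One ICC(3,1) per (roi, band, measure), computed across all pooled epochs
#' (all subjects concatenated), pairing the template and native condition
#' values of the same epoch.
#'
#' @param df Long tibble with columns `roi`, `band`, `measure`, `epoch`
#'   (a pooled epoch identifier, unique across subjects), `condition`
#'   (`"template"` / `"native"`) and `value`.
#' @return A tibble: one row per (roi, band, measure) with `n`, `icc`,
#'   `ci_low`, `ci_high`, `rating`, `not_reliable`.
#' @export
regional_consistency <- function(df) {
  need <- c("roi", "band", "measure", "epoch", "condition", "value")
  if (!all(need %in% names(df))) {
    abort(paste("need columns", paste(need, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(df, names_from = "condition",
                             values_from = "value")
  if (!all(c("template", "native") %in% names(wide))) {
    abort("conditions must be 'template' and 'native'")
  }
  if (anyNA(wide$template) || anyNA(wide$native)) {
    abort("epoch misalignment between conditions")
  }
  wide |>
    dplyr::group_by(.data$roi, .data$band, .data$measure) |>
    dplyr::group_modify(function(g, key) icc_row(g$template, g$native)) |>
    dplyr::ungroup()
}

# One-row tibble of ICC fields; NA row (with a warning) when the ICC is not
# computable (too few items or constant data).
icc_row <- function(a, b) {
  res <- tryCatch(icc31(a, b), error = function(e) e)
  if (inherits(res, "error")) {
    warn(paste("ICC not computable:", conditionMessage(res)))
    return(tibble::tibble(n = length(a), icc = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, rating = NA_character_,
                          not_reliable = NA))
  }
  tibble::tibble(n = res$n, icc = res$icc, ci_low = res$ci_low,
                 ci_high = res$ci_high, rating = res$rating,
                 not_reliable = res$not_reliable)
}

#' Global (per-subject) consistency between two conditions
#'
#' Subject-level ICC(3,1) with rating plus Bland-Altman statistics per
#' (band, measure), for epoch-averaged global measures.
#'
#' @param df Long tibble with columns `subject`, `band`, `measure`,
#'   `condition` (`"template"` / `"native"`) and `value`.
#' @return A tibble per (band, measure) with ICC fields and `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n_outside`.
#' @export
global_consistency <- function(df) {
  need <- c("subject", "band", "measure", "condition", "value")
  if (!all(need %in% names(df))) {
    abort(paste("need columns", paste(need, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(df, names_from = "condition",
                             values_from = "value")
  if (!all(c("template", "native") %in% names(wide))) {
    abort("conditions must be 'template' and 'native'")
  }
  if (anyNA(wide$template) || anyNA(wide$native)) {
    abort("subject misalignment between conditions")
  }
  wide |>
    dplyr::group_by(.data$band, .data$measure) |>
    dplyr::group_modify(function(g, key) {
      ir <- icc_row(g$template, g$native)
      ba <- bland_altman(g$template, g$native)
      dplyr::bind_cols(ir, tibble::tibble(
        mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
        loa_low = ba$loa_low, loa_high = ba$loa_high,
        n_outside = ba$n_outside))
    }) |>
    dplyr::ungroup()
}

#' Correlation between voxel displacement and power consistency
#'
#' Pearson correlation, per band, between the per-ROI representative-voxel
#' distance and the per-ROI relative-power ICC. Degenerate bands (constant
#' distances or ICCs, e.g. a zero-displacement run) are skipped with a
#' warning and reported as NA.
#'
#' @param df Tibble with columns `band`, `roi`, `distance`, `icc`.
#' @return A tibble per band: `n`, `r`, `p`.
#' @export
distance_vs_icc <- function(df) {
  need <- c("band", "roi", "distance", "icc")
  if (!all(need %in% names(df))) {
    abort(paste("need columns", paste(need, collapse = ", ")))
  }
  df |>
    dplyr::group_by(.data$band) |>
    dplyr::group_modify(function(g, key) {
      res <- tryCatch(pearson(g$distance, g$icc), error = function(e) e)
      if (inherits(res, "error")) {
        warn(sprintf("band skipped: %s", conditionMessage(res)))
        return(tibble::tibble(n = nrow(g), r = NA_real_, p = NA_real_))
      }
      tibble::tibble(n = nrow(g), r = res$r, p = res$p)
    }) |>
    dplyr::ungroup()
}
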