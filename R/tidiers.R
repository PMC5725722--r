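#' Tidy an ICC(3,1) result
#'
#' @param x A [icc31()] object.
#' @param ... Unused.
#' @return One-row tibble: `icc`, `ci_low`, `ci_high`, `rating`,
#'   `not_reliable`.
#' @method tidy meg_icc
#' @export
tidy.meg_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 rating = x$rating, not_reliable = x$not_reliable)
}

#' Model-level summary of an ICC(3,1) result
#'
#' @param x A [icc31()] object.
#' @param ... Unused.
#' @return One-row tibble with the ANOVA mean squares and F statistic.
#' @method glance meg_icc
#' @export
glance.meg_icc <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, msr = x$msr, mse = x$mse,
                 statistic = x$fvalue, conf_level = x$conf_level)
}

#' Tidy a Bland-Altman result (per-point rows)
#'
#' @param x A [bland_altman()] object.
#' @param ... Unused.
#' @return Tibble with one row per pair: `mean`, `diff`, `outside`.
#' @method tidy meg_bland_altman
#' @export
tidy.meg_bland_altman <- function(x, ...) {
  dplyr::mutate(x$data,
                outside = .data$diff < x$loa_low | .data$diff > x$loa_high)
}

#' One-row summary of a Bland-Altman result
#'
#' @param x A [bland_altman()] object.
#' @param ... Unused.
#' @return One-row tibble: `mean_diff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `n`, `n_outside`.
#' @method glance meg_bland_altman
#' @export
glance.meg_bland_altman <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 n = x$n, n_outside = x$n_outside)
}
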