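# broom-style tidiers for fitted agreement objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn bland_altman One row per pair: `mean`, `difference`.
#' @param x An `rns_bland_altman`.
#' @param ... Unused.
#' @export
tidy.rns_bland_altman <- function(x, ...) {
  x$pairs
}

#' @describeIn bland_altman One-row summary: bias, sd, limits of agreement.
#' @export
glance.rns_bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high,
         loa_multiplier = x$loa_multiplier,
         n_pairs = x$n_pairs, n_dropped = x$n_dropped)
}

#' @describeIn wilcoxon_signed_rank One-row test summary.
#' @param x An `rns_signed_rank`.
#' @param ... Unused.
#' @export
tidy.rns_signed_rank <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         n_pairs = x$n_pairs, n_effective = x$n_effective,
         mean_abs_difference = x$mean_abs_difference, method = x$method)
}

#' @describeIn wilcoxon_signed_rank Alias of `tidy()`.
#' @export
glance.rns_signed_rank <- function(x, ...) {
  tidy(x)
}
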