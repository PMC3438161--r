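#' Tidy an asymmetry summary
#'
#' @param x An `asymmetry_summary` from [asymmetry_stats()].
#' @param ... Unused.
#' @return One-row tibble of the headline estimates.
#' @export
tidy.asymmetry_summary <- function(x, ...) {
  tibble(mean_r_fast = x$mean_r_fast, mean_r_slow = x$mean_r_slow,
         mean_ratio = x$mean_ratio, ratio_of_means = x$ratio_of_means,
         frac_faster_on_shorter = x$frac_faster_on_shorter,
         pearson_r = x$pearson_r, pearson_p = x$pearson_p)
}

#' @rdname tidy.asymmetry_summary
#' @export
glance.asymmetry_summary <- function(x, ...) {
  tibble(n = x$n, n_valid_ratio = x$n_valid_ratio)
}

#' Tidy a rank variability test
#'
#' @param x A `rank_variability_test` from [length_variability_test()].
#' @param ... Unused.
#' @return One-row tibble with statistic, p-value and method.
#' @export
tidy.rank_variability_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, method = x$method,
         n_a = x$n_a, n_b = x$n_b)
}

#' Tidy a placement summary
#'
#' @param x A `placement_stats` from [summarize_population()].
#' @param ... Unused.
#' @return One-row tibble of population summaries.
#' @export
tidy.placement_stats <- function(x, ...) {
  tibble(n_cells = x$n_cells, mean_length = x$mean_length,
         sd_length = x$sd_length, n_positions = length(x$positions),
         central_fraction = x$central_fraction)
}
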