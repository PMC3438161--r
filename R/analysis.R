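#' Normalized and folded position of a focus along the cell
#'
#' @param s Arclength from pole A, microns (vectorized).
#' @param L Cell length, microns.
#' @return Tibble with `p = s/L` in `[0, 1]` and the folded position
#'   `q = min(p, 1 - p)` in `[0, 0.5]`.
#' @examples
#' relative_position(3.2, 8)
#' @export
relative_position <- function(s, L) {
  if (any(L <= 0)) abort("cell length L must be > 0")
  if (any(s < 0 | s > L)) abort("s must lie within [0, L]")
  p <- s / L
  tibble(p = p, q = pmin(p, 1 - p))
}

#' Fraction of positions within the central band of the cell
#'
#' The central 20-percentile band of a cell covers normalized positions
#' `|p - 0.5| <= band_width / 2` (boundary inclusive), i.e. 0.4-0.6 for
#' the default band.
#'
#' @param positions Normalized positions in `[0, 1]`.
#' @param band_width Width of the central band as a fraction of length.
#' @return The fraction of `positions` inside the band.
#' @examples
#' central_fraction(c(0.3, 0.5, 0.55))  # 2/3
#' @export
central_fraction <- function(positions, band_width = 0.2) {
  if (length(positions) == 0) {
    abort("central_fraction is undefined for an empty positions list")
  }
  if (any(positions < 0 | positions > 1)) {
    abort("positions must lie in [0, 1]")
  }
  if (band_width <= 0 || band_width > 1) {
    abort("band_width must lie in (0, 1]")
  }
  mean(abs(positions - 0.5) <= band_width / 2)
}

#' Per-pole exponential growth rates between septum placement and division
#'
#' Assuming exponential elongation of each side of the septum plane, the
#' per-side rate is `r = ln(side_at_div / side_at_sep) / (t_div - t_sep)`,
#' computed from the side lengths at the moment of initial septum
#' placement (condensation of the septal spot) and at division.
#' `r_fast`/`r_slow` are the per-cell maximum/minimum;
#' `ratio = r_fast / r_slow` is undefined (NA) when `r_slow <= 0`, and
#' such records are flagged invalid for ratio statistics;
#' `faster_on_shorter` records whether the faster side was the shorter
#' one at septum placement (ties resolved as `FALSE`).
#'
#' @param records Tibble with columns `side_a_at_sep`, `side_b_at_sep`,
#'   `side_a_at_div`, `side_b_at_div`, `t_sep`, `t_div` (minutes); extra
#'   columns pass through.
#' @return `records` with added columns `r_a`, `r_b`, `r_fast`, `r_slow`,
#'   `ratio`, `faster_on_shorter`, `valid_ratio`.
#' @examples
#' pole_growth_rates(tibble::tibble(
#'   side_a_at_sep = 2, side_b_at_sep = 2.5,
#'   side_a_at_div = 4, side_b_at_div = 2.6,
#'   t_sep = 0, t_div = 100))
#' @export
pole_growth_rates <- function(records) {
  need <- c("side_a_at_sep", "side_b_at_sep", "side_a_at_div",
            "side_b_at_div", "t_sep", "t_div")
  miss <- setdiff(need, names(records))
  if (length(miss)) abort(paste0("missing columns: ",
                                 paste(miss, collapse = ", ")))
  r <- records
  if (nrow(r) == 0) {
    r$r_a <- r$r_b <- r$r_fast <- r$r_slow <- r$ratio <- numeric(0)
    r$faster_on_shorter <- logical(0)
    r$valid_ratio <- logical(0)
    return(r)
  }
  if (any(r$t_div <= r$t_sep)) abort("t_div must exceed t_sep")
  if (any(r$side_a_at_sep <= 0 | r$side_b_at_sep <= 0 |
            r$side_a_at_div <= 0 | r$side_b_at_div <= 0)) {
    abort("side lengths must be positive")
  }
  dt <- r$t_div - r$t_sep
  r$r_a <- log(r$side_a_at_div / r$side_a_at_sep) / dt
  r$r_b <- log(r$side_b_at_div / r$side_b_at_sep) / dt
  r$r_fast <- pmax(r$r_a, r$r_b)
  r$r_slow <- pmin(r$r_a, r$r_b)
  r$valid_ratio <- r$r_slow > 0
  r$ratio <- ifelse(r$valid_ratio, r$r_fast / r$r_slow, NA_real_)
  a_faster <- r$r_a > r$r_b
  a_shorter <- r$side_a_at_sep < r$side_b_at_sep
  tie <- r$r_a == r$r_b | r$side_a_at_sep == r$side_b_at_sep
  r$faster_on_shorter <- ifelse(tie, FALSE, a_faster == a_shorter)
  r
}

## Pearson correlation from its definitional sum formula.
pearson_def <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den == 0) return(NA_real_)
  sum(xc * yc) / den
}

#' Growth-asymmetry summary of a population
#'
#' Computes the fraction of cells that grew faster on the side that was
#' shorter at septum placement, the mean and ratio-of-means summaries of
#' the per-cell fast:slow rate ratio, and the Pearson correlation (with
#' a two-sided p-value from the t transform) between the degree of
#' asymmetry at septum placement — the signed relative side-length
#' difference `(a - b) / (a + b)` — and differential growth `r_a - r_b`.
#'
#' @param records Output of [pole_growth_rates()].
#' @return An object of class `asymmetry_summary`: a list with
#'   `n`, `n_valid_ratio`, `frac_faster_on_shorter`, `mean_r_fast`,
#'   `mean_r_slow`, `mean_ratio` (mean of per-cell ratios),
#'   `ratio_of_means`, `pearson_r`, `pearson_p`.  The correlation is
#'   reported as NA (undefined) when either variable has zero variance
#'   or fewer than 3 records exist.
#' @export
asymmetry_stats <- function(records) {
  stopifnot(all(c("r_a", "r_b", "ratio") %in% names(records)))
  n <- nrow(records)
  x <- (records$side_a_at_sep - records$side_b_at_sep) /
    (records$side_a_at_sep + records$side_b_at_sep)
  y <- records$r_a - records$r_b
  r_p <- NA_real_; p_p <- NA_real_
  if (n >= 3 && sd(x) > 0 && sd(y) > 0) {
    r_p <- pearson_def(x, y)
    tstat <- r_p * sqrt((n - 2) / (1 - r_p^2))
    p_p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  valid <- records$valid_ratio
  structure(list(
    n = n,
    n_valid_ratio = sum(valid),
    frac_faster_on_shorter = mean(records$faster_on_shorter),
    mean_r_fast = mean(records$r_fast),
    mean_r_slow = mean(records$r_slow),
    mean_ratio = if (any(valid)) mean(records$ratio[valid]) else NA_real_,
    ratio_of_means = mean(records$r_fast) / mean(records$r_slow),
    pearson_r = r_p, pearson_p = p_p
  ), class = "asymmetry_summary")
}

#' @export
print.asymmetry_summary <- function(x, ...) {
  cat("<asymmetry_summary>\n")
  cat(sprintf("  cells: %d (%d with positive slow rate)\n",
              x$n, x$n_valid_ratio))
  cat(sprintf("  faster on shorter side: %.1f%%\n",
              100 * x$frac_faster_on_shorter))
  cat(sprintf("  mean r_fast: %.3e  mean r_slow: %.3e  (min^-1)\n",
              x$mean_r_fast, x$mean_r_slow))
  cat(sprintf("  mean fast:slow ratio: %.3f  (ratio of means: %.3f)\n",
              x$mean_ratio, x$ratio_of_means))
  cat(sprintf("  asymmetry ~ differential growth: Pearson r = %.3f, p = %.4f\n",
              x$pearson_r, x$pearson_p))
  invisible(x)
}

#' Rank test for unequal length variability between two populations
#'
#' A two-sample rank test of dispersion: each observation is reduced to
#' its absolute deviation from its own sample median, and the two sets
#' of deviations are compared with a Wilcoxon-type rank-sum statistic
#' (midranks for ties).  The null distribution is enumerated exactly over
#' all assignments when the combined sample size is at most
#' `exact_limit`; otherwise a normal approximation with tie correction
#' and continuity correction is used.  Two-sided p-values double the
#' smaller tail (capped at 1).  When all pooled deviations are identical
#' there is no evidence of unequal variability and p = 1.
#'
#' @param lengths_a,lengths_b Numeric samples (each of size >= 2).
#' @param exact_limit Combined-size cutoff for exact enumeration.
#' @return A `rank_variability_test` object: list with `statistic` (rank
#'   sum of sample A deviations), `p_value`, `method` ("exact" or
#'   "normal"), `n_a`, `n_b`.
#' @export
length_variability_test <- function(lengths_a, lengths_b,
                                    exact_limit = 12) {
  if (length(lengths_a) < 2 || length(lengths_b) < 2) {
    abort("each sample needs at least 2 observations")
  }
  dev_a <- abs(lengths_a - median(lengths_a))
  dev_b <- abs(lengths_b - median(lengths_b))
  rank_sum_test(dev_a, dev_b, exact_limit)
}

## Wilcoxon-type rank-sum comparison of two sets of dispersion scores.
rank_sum_test <- function(dev_a, dev_b, exact_limit = 12) {
  na <- length(dev_a); nb <- length(dev_b); N <- na + nb
  pooled <- c(dev_a, dev_b)
  ranks <- rank(pooled)
  W <- sum(ranks[seq_len(na)])

  if (max(pooled) - min(pooled) < .Machine$double.eps) {
    p <- 1; method <- "degenerate"
  } else if (N <= exact_limit) {
    combs <- combn(N, na)
    Ws <- colSums(matrix(ranks[combs], nrow = na))
    eps <- 1e-9
    p_low <- mean(Ws <= W + eps)
    p_high <- mean(Ws >= W - eps)
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact"
  } else {
    mu <- na * (N + 1) / 2
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    v <- na * nb / 12 * ((N + 1) - tie_corr)
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(v)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  structure(list(statistic = W, p_value = p, method = method,
                 n_a = na, n_b = nb),
            class = "rank_variability_test")
}

#' @export
print.rank_variability_test <- function(x, ...) {
  cat("<rank_variability_test>\n")
  cat(sprintf("  rank sum (sample A deviations): %.1f  (n = %d vs %d)\n",
              x$statistic, x$n_a, x$n_b))
  cat(sprintf("  two-sided p = %.4g (%s)\n", x$p_value, x$method))
  invisible(x)
}

#' Population summary of cell lengths and septum placement
#'
#' Mean and SD of cell lengths, the list of internal-focus normalized
#' positions, the central-band fraction, and a position histogram.  When
#' foci are supplied, the summary is restricted to three-spot cells
#' (exactly two polar and one internal focus), mirroring the selection
#' applied to static snapshots of pre-divisional cells.
#'
#' @param lengths Cell lengths in microns, or a measured-mask tibble with
#'   a `length_um` column (and `cell_label`).
#' @param foci Optional tibble from [detect_foci()]; used both to select
#'   three-spot cells and to supply internal positions.
#' @param band_width Central band width for [central_fraction()].
#' @param n_bins Number of bins of the position histogram.
#' @return A `placement_stats` object: list with `n_cells`,
#'   `mean_length`, `sd_length`, `lengths`, `positions`,
#'   `central_fraction` (NA, flagged, when no positions exist) and
#'   `histogram` (tibble of bin mids and counts).
#' @export
summarize_population <- function(lengths, foci = NULL, band_width = 0.2,
                                 n_bins = 20) {
  if (is.data.frame(lengths)) {
    masks <- lengths
    stopifnot("length_um" %in% names(masks))
    if (!is.null(foci) && nrow(foci)) {
      counts <- foci |>
        dplyr::group_by(.data$cell_label) |>
        dplyr::summarise(
          n_polar = sum(.data$focus_class == "polar"),
          n_internal = sum(.data$focus_class == "internal"),
          .groups = "drop")
      three <- counts$cell_label[counts$n_polar == 2 & counts$n_internal == 1]
      masks <- masks[masks$label %in% three, , drop = FALSE]
      positions <- foci$p_norm[foci$focus_class == "internal" &
                                 foci$cell_label %in% three]
    } else {
      positions <- numeric()
    }
    lens <- masks$length_um[is.finite(masks$length_um)]
  } else {
    lens <- lengths
    positions <- if (is.null(foci)) numeric() else
      foci$p_norm[foci$focus_class == "internal"]
  }
  if (!length(lens)) abort("no cells to summarize")
  cf <- if (length(positions)) central_fraction(positions, band_width) else
    NA_real_
  breaks <- seq(0, 1, length.out = n_bins + 1)
  hist_counts <- if (length(positions)) {
    as.integer(table(cut(positions, breaks, include.lowest = TRUE)))
  } else integer(n_bins)
  structure(list(
    n_cells = length(lens),
    mean_length = mean(lens), sd_length = sd(lens),
    lengths = lens, positions = positions,
    central_fraction = cf, band_width = band_width,
    histogram = tibble(bin_mid = (head(breaks, -1) + tail(breaks, -1)) / 2,
                       count = hist_counts)
  ), class = "placement_stats")
}

#' @export
print.placement_stats <- function(x, ...) {
  cat("<placement_stats>\n")
  cat(sprintf("  cells: %d, mean length %.2f um (SD %.2f)\n",
              x$n_cells, x$mean_length, x$sd_length))
  if (length(x$positions)) {
    cat(sprintf("  internal spots: %d, %.0f%% within the central %.0f%% of length\n",
                length(x$positions), 100 * x$central_fraction,
                100 * x$band_width))
  } else {
    cat("  no internal-spot positions (lengths-only summary)\n")
  }
  invisible(x)
}
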