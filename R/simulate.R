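## Truncated-normal draw: negative values are rejected and redrawn rather
## than clamped, so zero is never over-represented.  sd = 0 returns the mean
## (which must itself be >= lower).
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  if (sd == 0) {
    if (any(mean < lower)) config_error("degenerate draw below lower bound")
    return(rep_len(mean, n))
  }
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
    guard <- guard + 1L
    if (guard > 10000L) config_error("truncated draw failed to converge")
  }
  out
}

## Split a birth length L0 into the two sides of the eventual septum plane
## so that, after each side has grown exponentially at its own rate for
## T = t_sep - t_birth minutes, side A accounts for exactly fraction f of
## the total length.  Closed form from the linear equation in side_a_birth.
split_birth_length <- function(L0, f, rate_a, rate_b, T) {
  ea <- exp(rate_a * T)
  eb <- exp(rate_b * T)
  a0 <- f * L0 * eb / ((1 - f) * ea + f * eb)
  c(a0, L0 - a0)
}

#' Simulate a population of bipolar-growing rod cells
#'
#' Generates ground-truth trajectories for `config$n_cells` founder
#' lineages of rod-shaped cells that elongate exponentially from both
#' poles at unequal rates.  Each cell carries a fast-pole and a slow-pole
#' rate drawn from the configured normal distributions (negative draws
#' redrawn).  A septum plane is placed at fraction
#' `0.5 + Normal(0, placement_offset_sd)` of the length (clamped into the
#' open unit interval) as realized at condensation time; both sides of
#' that plane grow exponentially at their pole's rate from birth onward,
#' so total length is the sum of two exponentials.  An internal
#' fluorescent patch appears `appearance_delay` minutes after birth,
#' wanders for `condensation_frames` frames, then condenses at the septum
#' plane; division follows `invagination_delay` minutes after
#' condensation (a timer, not a length threshold).  Daughters inherit the
#' parental rate of their old pole and draw a fresh rate for the new
#' pole.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A tibble with one row per cell: identifiers and parentage,
#'   `birth_time`/`birth_length`, per-side pole rates (`pole_rate_a` is
#'   the pole-A side, i.e. the side rendered toward smaller column
#'   indices), event times (`appearance_time`, `condensation_time`,
#'   `division_time`; `NA` when the event falls beyond the movie
#'   horizon), `septum_position_norm` (fraction of length from pole A at
#'   condensation), side lengths at birth, condensation and division, and
#'   `length_at_division`.  The attribute `"config"` stores the
#'   configuration.
#' @examples
#' truths <- simulate_population(sim_config(n_cells = 3, seed = 7))
#' truths[, c("cell_id", "birth_length", "septum_position_norm")]
#' @export
simulate_population <- function(config, seed = config$seed) {
  config <- validate_sim_config(config)
  if (config$n_cells < 1) config_error("n_cells must be >= 1")
  withr::local_seed(seed)

  t_max <- (config$n_frames - 1L) * config$frame_interval
  draw_rate <- function(kind) {
    if (kind == "fast") {
      rnorm_trunc(1L, config$fast_rate_mean, config$fast_rate_sd)
    } else {
      rnorm_trunc(1L, config$slow_rate_mean, config$slow_rate_sd)
    }
  }

  rows <- list()
  next_id <- 1L
  ## queue entries: parent_id, birth_time, birth_length, rate_a, rate_b
  ## (rate_a/rate_b may be NA for founders -> drawn by placement rule)
  queue <- lapply(seq_len(config$n_cells), function(i) {
    list(parent_id = NA_integer_, birth_time = 0,
         birth_length = rnorm_trunc(1L, config$birth_length_mean,
                                    config$birth_length_sd),
         rate_a = NA_real_, rate_b = NA_real_,
         side_of_parent = NA_character_, founder_id = i)
  })

  while (length(queue)) {
    cell <- queue[[1L]]
    queue <- queue[-1L]
    id <- next_id
    next_id <- next_id + 1L

    appearance_delay <- rnorm_trunc(1L, config$appearance_delay_mean,
                                    config$appearance_delay_sd,
                                    lower = config$frame_interval)
    t_app <- cell$birth_time + appearance_delay
    t_cond <- t_app + config$condensation_frames * config$frame_interval
    t_div <- t_cond + config$invagination_delay

    f <- 0.5 + rnorm(1L, 0, config$placement_offset_sd)
    f <- min(max(f, 0.02), 0.98)

    if (is.na(cell$rate_a)) {
      ## founder: one fast and one slow pole; the fast rate goes to the
      ## side that will be shorter at placement with prob fast_on_short_prob
      r_fast <- draw_rate("fast")
      r_slow <- draw_rate("slow")
      shorter_is_a <- if (f == 0.5) runif(1L) < 0.5 else f < 0.5
      fast_on_short <- runif(1L) < config$fast_on_short_prob
      fast_is_a <- xor(!shorter_is_a, fast_on_short)
      rate_a <- if (fast_is_a) r_fast else r_slow
      rate_b <- if (fast_is_a) r_slow else r_fast
    } else {
      rate_a <- cell$rate_a
      rate_b <- cell$rate_b
    }

    T_sep <- t_cond - cell$birth_time
    sides0 <- split_birth_length(cell$birth_length, f, rate_a, rate_b, T_sep)
    side_a_sep <- sides0[1L] * exp(rate_a * T_sep)
    side_b_sep <- sides0[2L] * exp(rate_b * T_sep)
    T_div <- t_div - cell$birth_time
    side_a_div <- sides0[1L] * exp(rate_a * T_div)
    side_b_div <- sides0[2L] * exp(rate_b * T_div)

    divides <- t_div <= t_max
    if (divides) {
      ## daughter A spans parent pole A -> septum: its pole-A side keeps
      ## rate_a, its new (septum-end) pole draws a fresh rate
      new_rate <- function() {
        kind <- if (runif(1L) < config$new_pole_fast_prob) "fast" else "slow"
        draw_rate(kind)
      }
      queue <- c(queue, list(
        list(parent_id = id, birth_time = t_div, birth_length = side_a_div,
             rate_a = rate_a, rate_b = new_rate(),
             side_of_parent = "a", founder_id = cell$founder_id),
        list(parent_id = id, birth_time = t_div, birth_length = side_b_div,
             rate_a = new_rate(), rate_b = rate_b,
             side_of_parent = "b", founder_id = cell$founder_id)
      ))
    }

    rows[[id]] <- tibble(
      cell_id = id, parent_id = cell$parent_id,
      founder_id = cell$founder_id, side_of_parent = cell$side_of_parent,
      birth_time = cell$birth_time, birth_length = cell$birth_length,
      pole_rate_a = rate_a, pole_rate_b = rate_b,
      appearance_time = if (t_app <= t_max) t_app else NA_real_,
      condensation_time = if (t_cond <= t_max) t_cond else NA_real_,
      division_time = if (divides) t_div else NA_real_,
      septum_position_norm = f,
      side_a_birth = sides0[1L], side_b_birth = sides0[2L],
      side_a_at_sep = side_a_sep, side_b_at_sep = side_b_sep,
      side_a_at_div = side_a_div, side_b_at_div = side_b_div,
      length_at_division = side_a_div + side_b_div
    )
  }

  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  attr(out, "t_max") <- t_max
  out
}

#' Per-frame ground-truth length series
#'
#' Evaluates each simulated cell's side and total lengths on the movie's
#' frame grid.  A cell is present from its birth frame up to (and
#' excluding) the first frame at or after its division time.
#'
#' @param truths Output of [simulate_population()].
#' @param config A [sim_config()]; defaults to the one stored in `truths`.
#' @return A long tibble: `cell_id`, `frame` (1-based), `time_min`,
#'   `side_a_um`, `side_b_um`, `length_um`, and `septum_pos_norm`, the
#'   current normalized position of the septum plane
#'   (`side_a_um / length_um`), which drifts as the two sides grow at
#'   unequal rates.
#' @export
cell_length_series <- function(truths, config = attr(truths, "config")) {
  stopifnot(!is.null(config))
  times <- (seq_len(config$n_frames) - 1L) * config$frame_interval
  purrr::pmap_dfr(
    truths[, c("cell_id", "birth_time", "division_time",
               "side_a_birth", "side_b_birth",
               "pole_rate_a", "pole_rate_b")],
    function(cell_id, birth_time, division_time,
             side_a_birth, side_b_birth, pole_rate_a, pole_rate_b) {
      t_end <- if (is.na(division_time)) Inf else division_time
      keep <- which(times >= birth_time & times < t_end)
      if (!length(keep)) return(NULL)
      dt <- times[keep] - birth_time
      a <- side_a_birth * exp(pole_rate_a * dt)
      b <- side_b_birth * exp(pole_rate_b * dt)
      tibble(cell_id = cell_id, frame = keep, time_min = times[keep],
             side_a_um = a, side_b_um = b, length_um = a + b,
             septum_pos_norm = a / (a + b))
    }
  )
}
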