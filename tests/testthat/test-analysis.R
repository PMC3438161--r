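test_that("relative positions and folding", {
  expect_equal(relative_position(5, 10), tibble::tibble(p = 0.5, q = 0.5))
  expect_equal(relative_position(0, 7), tibble::tibble(p = 0, q = 0))
  expect_equal(relative_position(3.2, 8), tibble::tibble(p = 0.4, q = 0.4))
  expect_error(relative_position(1, 0))
  expect_error(relative_position(-1, 5))
})

test_that("central fraction counts the inclusive central band", {
  expect_equal(central_fraction(c(0.5, 0.5, 0.5)), 1)
  expect_equal(central_fraction(c(0.3, 0.5, 0.55)), 2 / 3)
  expect_equal(central_fraction(c(0.4, 0.6)), 1)  # boundary inclusive
  expect_error(central_fraction(numeric()))
  expect_error(central_fraction(c(0.5, 1.2)))
  expect_error(central_fraction(0.5, band_width = 0))
})

test_that("uniform positions give a central fraction near the band width", {
  withr::with_seed(77, p <- runif(1e5))
  se <- sqrt(0.2 * 0.8 / 1e5)
  expect_lt(abs(central_fraction(p) - 0.2), 3 * se)
})

test_that("central fraction is invariant under reflection", {
  withr::with_seed(78, p <- runif(500))
  expect_equal(central_fraction(p), central_fraction(1 - p))
})

test_that("pole growth rates follow the log-ratio formula", {
  rec <- pole_growth_rates(tibble::tibble(
    side_a_at_sep = 2, side_b_at_sep = 3,
    side_a_at_div = 4, side_b_at_div = 3.1,
    t_sep = 0, t_div = 100))
  expect_equal(rec$r_a, log(2) / 100, tolerance = 1e-12)
  expect_equal(rec$r_fast, rec$r_a)
  expect_equal(rec$ratio, rec$r_a / rec$r_b)
  expect_true(rec$faster_on_shorter)  # side a was shorter and faster

  # identical growth factors: ratio 1, tie resolved as FALSE
  rec <- pole_growth_rates(tibble::tibble(
    side_a_at_sep = 2, side_b_at_sep = 3,
    side_a_at_div = 2 * 1.05, side_b_at_div = 3 * 1.05,
    t_sep = 0, t_div = 50))
  expect_equal(rec$ratio, 1)
  expect_false(rec$faster_on_shorter)

  # a shrinking side invalidates the ratio but keeps the record
  rec <- pole_growth_rates(tibble::tibble(
    side_a_at_sep = 2, side_b_at_sep = 3,
    side_a_at_div = 2.2, side_b_at_div = 2.9,
    t_sep = 0, t_div = 50))
  expect_false(rec$valid_ratio)
  expect_true(is.na(rec$ratio))
  expect_lt(rec$r_slow, 0)

  expect_error(pole_growth_rates(tibble::tibble(
    side_a_at_sep = 2, side_b_at_sep = 3,
    side_a_at_div = 4, side_b_at_div = 3.1,
    t_sep = 100, t_div = 100)))
})

test_that("generator truth round-trips through the rate formula exactly", {
  cfg <- sim_config(n_cells = 3, n_frames = 40, seed = 55,
                    fast_rate_mean = 1.66e-4, fast_rate_sd = 0,
                    slow_rate_mean = 1.66e-4, slow_rate_sd = 0,
                    invagination_delay = 160)
  truths <- simulate_population(cfg)
  div <- truths[!is.na(truths$division_time), ]
  rec <- pole_growth_rates(tibble::tibble(
    side_a_at_sep = div$side_a_at_sep, side_b_at_sep = div$side_b_at_sep,
    side_a_at_div = div$side_a_at_div, side_b_at_div = div$side_b_at_div,
    t_sep = div$condensation_time, t_div = div$division_time))
  expect_equal(rec$r_a, rep(1.66e-4, nrow(rec)), tolerance = 1e-12)
  expect_equal(rec$r_b, rep(1.66e-4, nrow(rec)), tolerance = 1e-12)
})

test_that("asymmetry statistics use the definitional Pearson formula", {
  mk <- function(x, y) {
    # construct records whose asymmetry is x and rate difference is y
    tibble::tibble(
      side_a_at_sep = 1 + x, side_b_at_sep = 1 - x,
      side_a_at_div = (1 + x) * exp(1e-4 + y / 2),
      side_b_at_div = (1 - x) * exp(1e-4 - y / 2),
      t_sep = 0, t_div = 1)
  }
  rec <- pole_growth_rates(mk(c(0.1, 0.2, 0.3), c(3, 2, 1) * 1e-5))
  s <- asymmetry_stats(rec)
  expect_equal(s$pearson_r, -1, tolerance = 1e-9)

  rec <- pole_growth_rates(mk(c(0.1, 0.2, 0.3), c(1, 2, 3) * 1e-5))
  expect_equal(asymmetry_stats(rec)$pearson_r, 1, tolerance = 1e-9)

  withr::with_seed(5, { x <- runif(5); y <- runif(5) })
  r_def <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(polargrowth:::pearson_def(x, y), r_def, tolerance = 1e-12)
  # and against the reference implementation
  ct <- cor.test(x, y)
  expect_equal(polargrowth:::pearson_def(x, y), unname(ct$estimate),
               tolerance = 1e-12)
  rec <- pole_growth_rates(mk(x - 0.5, (y - 0.5) * 1e-5))
  s <- asymmetry_stats(rec)
  expect_equal(s$pearson_p, ct$p.value, tolerance = 1e-6)

  # zero variance: correlation undefined
  rec <- pole_growth_rates(mk(c(0.1, 0.1, 0.1), c(1, 2, 3) * 1e-5))
  expect_true(is.na(asymmetry_stats(rec)$pearson_r))
})

test_that("variability test: degenerate, separated and approximate cases", {
  # identical samples: no evidence
  expect_equal(length_variability_test(c(4, 4, 4), c(4, 4, 4))$p_value, 1)

  # deviations of A strictly exceeding B's attain the extremal statistic
  res <- polargrowth:::rank_sum_test(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 4.5))
  expect_equal(res$statistic, sum(6:10))
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$method, "exact")

  # exact enumeration vs normal approximation at n = 6 + 6
  withr::with_seed(31, { a <- rnorm(6, 0, 2); b <- rnorm(6, 0, 1) })
  p_exact <- length_variability_test(a, b, exact_limit = 12)$p_value
  p_norm <- length_variability_test(a, b, exact_limit = 0)$p_value
  expect_lt(abs(p_exact - p_norm), 0.02)

  # the exact null is the permutation distribution: cross-check against
  # an independent enumeration
  dev_a <- abs(a - median(a)); dev_b <- abs(b - median(b))
  pooled <- c(dev_a, dev_b); rk <- rank(pooled)
  W <- sum(rk[1:6])
  Ws <- apply(combn(12, 6), 2, function(ix) sum(rk[ix]))
  p_ref <- min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
  expect_equal(p_exact, p_ref, tolerance = 1e-12)

  expect_error(length_variability_test(1, c(1, 2)))
})

test_that("population summaries report mean, SD and placement stats", {
  s <- summarize_population(c(4, 4, 4))
  expect_equal(s$mean_length, 4)
  expect_equal(s$sd_length, 0)
  expect_true(is.na(s$central_fraction))

  # SD matches the two-pass definitional formula
  withr::with_seed(41, lens <- runif(10, 3, 8))
  s <- summarize_population(lens)
  sd_def <- sqrt(sum((lens - mean(lens))^2) / (length(lens) - 1))
  expect_equal(s$sd_length, sd_def, tolerance = 1e-12)

  expect_error(summarize_population(numeric()))
})

test_that("three-spot selection restricts the placement summary", {
  cfg <- sim_config(noise_sd = 0, seed = 61)
  out <- render_static_snapshot(c(5, 6, 4.5), c(0.45, 0.52, 0.3), cfg)
  ph <- out$stack$phase[, , 1]; fl <- out$stack$fluor[, , 1]
  mk <- measure_frame(ph, cfg$pixel_size)
  fc <- detect_foci(fl, mk, pixel_size = cfg$pixel_size)
  s <- summarize_population(mk, fc)
  expect_equal(s$n_cells, 3L)
  expect_equal(length(s$positions), 3L)
  expect_equal(s$central_fraction, 2 / 3)
  expect_equal(sum(s$histogram$count), 3L)
  td <- tidy(s)
  expect_equal(td$n_cells, 3L)
})

test_that("tidiers return one-row tibbles", {
  rec <- pole_growth_rates(tibble::tibble(
    side_a_at_sep = c(2, 2.2, 1.9), side_b_at_sep = c(2.1, 2.0, 2.2),
    side_a_at_div = c(2.1, 2.25, 2.0), side_b_at_div = c(2.15, 2.1, 2.25),
    t_sep = 0, t_div = 160))
  s <- asymmetry_stats(rec)
  expect_equal(nrow(tidy(s)), 1L)
  expect_equal(glance(s)$n, 3L)
  v <- length_variability_test(c(1, 2, 3, 9), c(4, 4.1, 4.2, 4.3))
  expect_equal(nrow(tidy(v)), 1L)
})
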