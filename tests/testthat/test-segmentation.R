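test_that("uniform images segment to nothing and bad input errors", {
  expect_equal(nrow(segment_frame(matrix(0.8, 50, 50), 0.1)), 0L)
  expect_error(segment_frame(array(0, c(4, 4, 2)), 0.1))
  expect_error(segment_frame(matrix(0.5, 4, 4), -1),
               class = "polargrowth_config_error")
})

test_that("a rendered capsule segments to one mask of the analytic area", {
  # narrow PSF so that blur broadening of the thin rod is negligible, and
  # a rotated cell so the outline samples all sub-pixel phases
  cfg <- sim_config(noise_sd = 0, psf_sigma = 0.05, seed = 9)
  L <- 5; w <- cfg$cell_width
  out <- render_static_snapshot(L, 0.5, cfg, angles = 20)
  mk <- segment_frame(out$stack$phase[, , 1], cfg$pixel_size)
  expect_equal(nrow(mk), 1L)
  ps <- cfg$pixel_size
  # capsule = rectangle between the cap centers plus a full disc
  area_analytic <- ((L - w) * w + pi * (w / 2)^2) / ps^2
  expect_lt(abs(mk$area_px - area_analytic) / area_analytic, 0.05)
})

test_that("separated capsules get distinct labels", {
  cfg <- sim_config(noise_sd = 0, seed = 9)
  out <- render_static_snapshot(c(4, 5), c(0.5, 0.5), cfg, angles = 0)
  mk <- segment_frame(out$stack$phase[, , 1], cfg$pixel_size)
  expect_equal(sort(mk$label), c(1L, 2L))
})

test_that("centerline length recovers a noise-free capsule within 2 px", {
  cfg <- sim_config(noise_sd = 0, seed = 9)
  out <- render_static_snapshot(5, 0.5, cfg, angles = 0)
  mk <- measure_frame(out$stack$phase[, , 1], cfg$pixel_size)
  expect_true(mk$measurable)
  expect_lt(abs(mk$length_um - 5), 2 * cfg$pixel_size)
})

test_that("a horizontal capsule has an essentially constant-row centerline", {
  cfg <- sim_config(noise_sd = 0, seed = 9)
  out <- render_static_snapshot(5, 0.5, cfg, angles = 0)
  mk <- measure_frame(out$stack$phase[, , 1], cfg$pixel_size)
  cl <- mk$centerline[[1]]
  expect_lt(diff(range(cl[, 1])), 0.5)
})

test_that("measured length is rotation robust", {
  cfg <- sim_config(noise_sd = 0, seed = 9)
  out <- render_static_snapshot(rep(5, 3), rep(0.5, 3), cfg,
                                angles = c(0, 30, 45))
  mk <- measure_frame(out$stack$phase[, , 1], cfg$pixel_size)
  expect_true(all(mk$measurable))
  expect_lt(diff(range(mk$length_um)), 2 * cfg$pixel_size)
})

test_that("a disc is flagged unmeasurable, not an error", {
  cfg <- sim_config(noise_sd = 0, seed = 9)
  # length equal to width: a round object with no usable skeleton
  out <- render_static_snapshot(cfg$cell_width, 0.5, cfg, angles = 0)
  expect_warning(
    mk <- extract_centerline(
      segment_frame(out$stack$phase[, , 1], cfg$pixel_size),
      cfg$pixel_size, out$stack$phase[, , 1]),
    "unmeasurable")
  expect_false(any(mk$measurable))
})

test_that("median length error stays below 2 px at default noise", {
  cfg <- sim_config(seed = 14)  # default noise_sd
  withr::with_seed(14, {
    lens <- polargrowth:::rnorm_trunc(110, 4.8, 1.37, lower = 1.5)
    angs <- runif(110, 0, 180)
  })
  out <- render_static_snapshot(lens, rep(0.5, 110), cfg, angles = angs)
  mk <- measure_frame(out$stack$phase[, , 1], cfg$pixel_size)
  mk <- mk[mk$measurable, ]
  expect_gt(nrow(mk), 100)
  truth <- out$truth
  err <- vapply(seq_len(nrow(mk)), function(j) {
    k <- which.min(((truth$pole_a_row + truth$pole_b_row) / 2 -
                      mk$centroid_row[j])^2 +
                     ((truth$pole_a_col + truth$pole_b_col) / 2 -
                        mk$centroid_col[j])^2)
    mk$length_um[j] - truth$length_um[k]
  }, numeric(1))
  expect_lt(median(abs(err)), 2 * cfg$pixel_size)
})

test_that("segmentation and measurement are deterministic", {
  cfg <- sim_config(seed = 15)
  out <- render_static_snapshot(c(4, 6), c(0.4, 0.5), cfg)
  ph <- out$stack$phase[, , 1]
  m1 <- measure_frame(ph, cfg$pixel_size)
  m2 <- measure_frame(ph, cfg$pixel_size)
  expect_identical(m1$length_um, m2$length_um)
  expect_identical(m1$pixels, m2$pixels)
})

test_that("border-touching components are discarded", {
  cfg <- sim_config(noise_sd = 0, seed = 9)
  out <- render_static_snapshot(5, 0.5, cfg, angles = 0)
  ph <- out$stack$phase[, , 1]
  tr <- out$truth
  # crop so the cell touches the left image border
  ph_cut <- ph[, ceiling(tr$pole_a_col + 2):ncol(ph)]
  mk <- segment_frame(ph_cut, cfg$pixel_size)
  expect_equal(nrow(mk), 0L)
})
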