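test_that("one noise-free rendered focus per cell is found at its pixel", {
  cfg <- sim_config(noise_sd = 0, seed = 17)
  out <- render_static_snapshot(c(5, 6), c(0.35, 0.6), cfg, angles = 0)
  ph <- out$stack$phase[, , 1]; fl <- out$stack$fluor[, , 1]
  mk <- measure_frame(ph, cfg$pixel_size)
  fc <- detect_foci(fl, mk, pixel_size = cfg$pixel_size)
  internal <- fc[fc$focus_class == "internal", ]
  expect_equal(nrow(internal), 2L)
  # match cells to truth by centroid proximity
  for (i in 1:2) {
    tr <- out$truth[i, ]
    ctr_r <- (tr$pole_a_row + tr$pole_b_row) / 2
    ctr_c <- (tr$pole_a_col + tr$pole_b_col) / 2
    lab <- mk$label[which.min((mk$centroid_row - ctr_r)^2 +
                                (mk$centroid_col - ctr_c)^2)]
    row <- internal[internal$cell_label == lab, ]
    expect_equal(row$row, round(tr$internal_row))
    expect_equal(row$col, round(tr$internal_col))
  }
  # two polar foci per cell
  expect_equal(sum(fc$focus_class == "polar"), 4L)
})

test_that("equal-intensity maxima break ties in row-major order", {
  m <- fake_mask(30, 60, 12, 18, 10, 50)
  fl <- matrix(0.1, 30, 60)
  # a flat-top plateau: four pixels share the maximum
  fl[14:15, 24:25] <- 0.9
  fc <- detect_foci(fl, m, pixel_size = 0.1)
  expect_equal(nrow(fc), 1L)
  expect_equal(c(fc$row, fc$col), c(14L, 24L))
})

test_that("detection equals a brute-force regional-maximum oracle", {
  set.seed(100)
  for (rep in 1:20) {
    m <- fake_mask(24, 48, 8, 15, 6, 42)
    fl <- matrix(runif(24 * 48, 0, 0.2), 24, 48)
    # sprinkle a few bright spots, some inside and some outside the mask
    for (k in 1:sample(1:4, 1)) {
      rr <- sample(5:20, 1); cc <- sample(3:46, 1)
      fl[rr, cc] <- runif(1, 0.6, 1)
    }
    fc <- detect_foci(fl, m, k_mad = 5, min_prominence = 0.05,
                      pixel_size = 0.1)

    # oracle: scan every pixel of the mask, threshold with the same rule,
    # label candidates by flood fill, take each region's argmax with
    # row-major tie-break
    thr <- median(fl) + max(5 * mad(fl), 0.05)
    inmask <- matrix(FALSE, 24, 48)
    inmask[m$pixels[[1]]] <- TRUE
    cand <- fl > thr & inmask
    lab <- flood_label(cand)
    exp_pix <- NULL
    for (l in seq_len(max(lab))) {
      idx <- which(lab == l, arr.ind = TRUE)
      iv <- fl[idx]
      best <- idx[iv == max(iv), , drop = FALSE]
      best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
      exp_pix <- rbind(exp_pix, best)
    }
    got <- cbind(fc$row, fc$col)
    if (is.null(exp_pix)) {
      expect_equal(nrow(fc), 0L)
    } else {
      ord_g <- order(got[, 1], got[, 2])
      ord_e <- order(exp_pix[, 1], exp_pix[, 2])
      expect_equal(unname(got[ord_g, , drop = FALSE]),
                   unname(exp_pix[ord_e, , drop = FALSE]))
    }
  }
})

test_that("polar classification is boundary inclusive", {
  expect_equal(classify_focus(2.5, 5, 0.5), "internal")   # mid-cell
  expect_equal(classify_focus(0, 7, 0.5), "polar")        # at the pole
  expect_equal(classify_focus(0.5, 5, 0.5), "polar")      # exactly d_pole
  expect_equal(classify_focus(0.51, 5, 0.5), "internal")
  expect_equal(classify_focus(4.5, 5, 0.5), "polar")      # near pole B
})

test_that("a stationary internal focus forms a single track", {
  f <- tibble::tibble(
    frame = 1:10, cell_label = 1L, cell_track_id = 1L,
    row = 10L, col = 25L, intensity = 0.9,
    s_um = 2.5, p_norm = 0.5, focus_class = "internal")
  tracks <- track_foci(f, max_step = 1.5)
  expect_equal(length(unique(tracks$focus_track_id)), 1L)
  expect_equal(nrow(tracks), 10L)
})

test_that("links beyond max_step terminate tracks instead of swapping", {
  f <- tibble::tibble(
    frame = c(1L, 1L, 2L, 2L), cell_label = 1L, cell_track_id = 1L,
    row = 10L, col = 1L, intensity = 1,
    s_um = c(1.0, 4.0, 2.8, 5.8), p_norm = 0.5, focus_class = "internal")
  tracks <- track_foci(f, max_step = 1.5)
  # only 4.0 -> 2.8 is linkable; the other two foci remain singletons
  expect_equal(length(unique(tracks$focus_track_id)), 3L)
  linked <- tracks$focus_track_id[tracks$s_um %in% c(4.0, 2.8)]
  expect_equal(linked[1], linked[2])
})

test_that("frame-to-frame matching equals exhaustive bipartite matching", {
  brute_match <- function(s_prev, s_next, max_step) {
    n <- length(s_prev); m <- length(s_next)
    best <- list(size = -1L, cost = Inf, pairs = NULL)
    consider <- function(pairs) {
      if (length(pairs)) {
        pr <- matrix(pairs, ncol = 2, byrow = TRUE)
        if (any(abs(s_prev[pr[, 1]] - s_next[pr[, 2]]) > max_step)) return()
        size <- nrow(pr)
        cost <- sum(abs(s_prev[pr[, 1]] - s_next[pr[, 2]]))
      } else {
        pr <- matrix(integer(), ncol = 2); size <- 0L; cost <- 0
      }
      if (size > best$size || (size == best$size && cost < best$cost)) {
        best <<- list(size = size, cost = cost, pairs = pr)
      }
    }
    idx_subsets <- function(v) {
      out <- list(integer(0))
      for (x in v) out <- c(out, lapply(out, function(s) c(s, x)))
      out
    }
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
      }
      out
    }
    for (sub_i in idx_subsets(seq_len(n))) {
      for (sub_j in idx_subsets(seq_len(m))) {
        if (length(sub_i) != length(sub_j)) next
        if (!length(sub_i)) { consider(integer()); next }
        for (pj in perms(sub_j)) {
          consider(as.vector(t(cbind(sub_i, pj))))
        }
      }
    }
    best
  }
  set.seed(42)
  for (rep in 1:25) {
    s_prev <- sort(runif(sample(0:3, 1), 0, 6))
    s_next <- sort(runif(sample(0:3, 1), 0, 6))
    got <- polargrowth:::match_foci_sets(s_prev, s_next, max_step = 1.5)
    want <- brute_match(s_prev, s_next, 1.5)
    expect_equal(nrow(got), max(want$size, 0L))
    if (nrow(got)) {
      expect_equal(sum(abs(s_prev[got[, 1]] - s_next[got[, 2]])),
                   want$cost, tolerance = 1e-12)
    }
  }
})

test_that("condensation detection follows the stability definition", {
  mk_track <- function(p) tibble::tibble(frame = seq_along(p),
                                         time_min = (seq_along(p) - 1) * 10,
                                         p_norm = p)
  # constant: stable from the first observation
  ev <- detect_condensation(mk_track(rep(0.5, 8)))
  expect_equal(ev$condensation_frame, 1L)
  expect_equal(ev$p_at_condensation, 0.5)

  # wandering then settling: stable from the third observation
  ev <- detect_condensation(mk_track(c(0.30, 0.62, 0.48, 0.50, 0.51, 0.50)),
                            epsilon = 0.05, k_frames = 3)
  expect_equal(ev$condensation_frame, 3L)
  expect_equal(ev$condensation_time, 20)

  # alternating forever: never stable
  ev <- detect_condensation(mk_track(rep(c(0.3, 0.7), 10)))
  expect_equal(nrow(ev), 0L)

  # too short a track
  ev <- detect_condensation(mk_track(c(0.5, 0.5)), k_frames = 3)
  expect_equal(nrow(ev), 0L)
})
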