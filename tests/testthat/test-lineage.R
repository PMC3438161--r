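mask_row <- function(frame, label, px) {
  tibble::tibble(frame = frame, label = label, area_px = nrow(px),
                 centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]),
                 pixels = list(px))
}

rect_px <- function(r0, r1, c0, c1) {
  as.matrix(expand.grid(row = r0:r1, col = c0:c1))
}

test_that("a static scene yields identity tracks and no divisions", {
  px1 <- rect_px(5, 10, 5, 30); px2 <- rect_px(20, 25, 5, 30)
  m <- dplyr::bind_rows(
    mask_row(1L, 1L, px1), mask_row(1L, 2L, px2),
    mask_row(2L, 1L, px1), mask_row(2L, 2L, px2),
    mask_row(3L, 1L, px1), mask_row(3L, 2L, px2))
  attr(m, "image_dim") <- c(40, 40)
  res <- track_cells(m)
  expect_equal(nrow(res$divisions), 0L)
  expect_equal(nrow(res$info), 2L)
  expect_equal(res$info$birth_frame, c(1L, 1L))
  expect_equal(res$info$end_frame, c(3L, 3L))
})

test_that("one mask splitting into two halves is a division", {
  parent <- rect_px(5, 10, 5, 40)
  da <- rect_px(5, 10, 5, 20); db <- rect_px(5, 10, 25, 40)
  m <- dplyr::bind_rows(
    mask_row(1L, 1L, parent),
    mask_row(2L, 1L, da), mask_row(2L, 2L, db))
  attr(m, "image_dim") <- c(40, 50)
  res <- track_cells(m)
  expect_equal(nrow(res$divisions), 1L)
  d <- res$divisions[1, ]
  expect_equal(d$division_frame, 1L)
  kids <- res$info[res$info$track_id %in% c(d$daughter_a, d$daughter_b), ]
  expect_equal(kids$parent_track_id, c(1L, 1L))
  expect_equal(kids$birth_frame, c(2L, 2L))
  # parent track ends exactly at the division frame
  expect_equal(res$info$end_frame[res$info$track_id == d$parent_track_id],
               d$division_frame)
})

test_that("linking agrees with a brute-force maximal-overlap assignment", {
  set.seed(9)
  iou <- function(p1, p2) {
    k1 <- paste(p1[, 1], p1[, 2]); k2 <- paste(p2[, 1], p2[, 2])
    length(intersect(k1, k2)) / length(union(k1, k2))
  }
  for (rep in 1:5) {
    # three drifting rectangles over three frames
    offs <- matrix(sample(-2:2, 9, replace = TRUE), 3)
    rows <- list()
    base <- list(c(5, 10, 5, 25), c(20, 25, 10, 30), c(32, 37, 3, 23))
    for (fr in 1:3) {
      for (ci in 1:3) {
        b <- base[[ci]]
        o <- offs[ci, fr]
        rows[[length(rows) + 1L]] <-
          mask_row(fr, ci, rect_px(b[1], b[2], b[3] + o, b[4] + o))
      }
    }
    m <- dplyr::bind_rows(rows)
    attr(m, "image_dim") <- c(45, 40)
    res <- track_cells(m, iou_min = 0.3)
    # oracle: per consecutive frame pair, each current mask joins the
    # previous mask with maximal IoU
    expect_equal(nrow(res$info), 3L)
    tr <- dplyr::arrange(res$tracks, .data$track_id, .data$frame)
    for (fr in 2:3) {
      prev <- m[m$frame == fr - 1L, ]
      cur <- m[m$frame == fr, ]
      for (j in seq_len(nrow(cur))) {
        ious <- vapply(prev$pixels, iou, numeric(1), p2 = cur$pixels[[j]])
        best_prev_label <- prev$label[which.max(ious)]
        tid_prev <- tr$track_id[tr$frame == fr - 1L &
                                  tr$label == best_prev_label]
        tid_cur <- tr$track_id[tr$frame == fr & tr$label == cur$label[j]]
        expect_equal(tid_cur, tid_prev)
      }
    }
  }
})

test_that("lineage trees on simulated movies are binary forests and recover divisions", {
  sm <- small_movie(n_cells = 4, seed = 23, noise_sd = 0.01)
  an <- analyze_stack(sm$movie$stack)
  info <- an$track_info
  # daughter count is 0 or 2
  kid_counts <- table(info$parent_track_id[!is.na(info$parent_track_id)])
  expect_true(all(kid_counts == 2))
  # no track has two parents (each track id appears once in info)
  expect_equal(anyDuplicated(info$track_id), 0L)

  ev <- evaluate_against_truth(an, sm$movie$truth)
  expect_equal(ev$division_recovery$n_missed, 0)
  expect_equal(ev$division_recovery$n_spurious, 0)
})

test_that("daughter lengths at division sum to the parent length", {
  sm <- small_movie(n_cells = 4, seed = 29, noise_sd = 0.01)
  an <- analyze_stack(sm$movie$stack)
  expect_gt(nrow(an$divisions), 0L)
  for (i in seq_len(nrow(an$divisions))) {
    d <- an$divisions[i, ]
    mlen <- function(tid, fr) {
      v <- an$masks$length_um[an$masks$cell_track_id == tid &
                                an$masks$frame == fr]
      if (length(v) == 1) v else NA_real_
    }
    parent_L <- mlen(d$parent_track_id, d$division_frame)
    ka <- mlen(d$daughter_a, d$division_frame + 1L)
    kb <- mlen(d$daughter_b, d$division_frame + 1L)
    if (anyNA(c(parent_L, ka, kb))) next
    # tolerance: 2 px plus the true growth over one frame interval
    expect_lt(abs(ka + kb - parent_L), 2 * an$pixel_size + 0.05)
  }
})
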