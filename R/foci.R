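## ---- detection ---------------------------------------------------------

## Arclength of the orthogonal projection of a pixel onto the centerline
## polyline (nearest point on any segment, interpolated arclength), px.
project_on_centerline <- function(centerline, row, col) {
  a <- centerline[-nrow(centerline), , drop = FALSE]
  b <- centerline[-1, , drop = FALSE]
  dr <- b[, 1] - a[, 1]; dc <- b[, 2] - a[, 2]
  len2 <- dr^2 + dc^2
  t <- ((row - a[, 1]) * dr + (col - a[, 2]) * dc) / pmax(len2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  pr <- a[, 1] + t * dr; pc <- a[, 2] + t * dc
  d2 <- (pr - row)^2 + (pc - col)^2
  i <- which.min(d2)
  steps <- sqrt(len2)
  cum <- c(0, cumsum(steps))
  list(s_px = cum[i] + t[i] * steps[i], total_px = cum[length(cum)])
}

#' Detect fluorescent foci as maximal-intensity pixels
#'
#' Within each cell mask, candidate pixels are those above the frame-wide
#' background median plus `k_mad` times the MAD (with a fixed minimum
#' prominence floor so that a noise-free frame does not degenerate to a
#' zero threshold).  Each connected candidate region yields exactly one
#' focus, at its maximal-intensity pixel; among equal maxima the pixel
#' earliest in row-major order is chosen.  Each focus is projected onto
#' its cell's centerline (nearest vertex) to obtain the arclength from
#' pole A, `s_um`, and the normalized position `p_norm = s/L`, and is
#' classified polar or internal with [classify_focus()].
#'
#' @param fluor_image 2-D numeric fluorescence frame congruent with the
#'   masks' frame.
#' @param masks Tibble from [extract_centerline()] (centerlines are
#'   required for arclength positions).
#' @param k_mad Threshold factor on the MAD.
#' @param min_prominence Minimum height above the background median.
#' @param d_pole Polar-classification distance, microns (see
#'   [classify_focus()]).
#' @param pixel_size Microns per pixel; defaults to the masks' attribute.
#' @return Tibble: `frame`, `cell_label`, `row`, `col`, `intensity`,
#'   `s_um`, `p_norm`, `focus_class`.
#' @export
detect_foci <- function(fluor_image, masks, k_mad = 5, min_prominence = 0.05,
                        d_pole = 0.5,
                        pixel_size = attr(masks, "pixel_size")) {
  stopifnot(is.matrix(fluor_image))
  if (is.null(pixel_size)) config_error("pixel_size is required")
  empty <- tibble(frame = integer(), cell_label = integer(),
                  row = integer(), col = integer(), intensity = numeric(),
                  s_um = numeric(), p_norm = numeric(),
                  focus_class = character())
  if (nrow(masks) == 0) return(empty)

  bg_med <- median(fluor_image)
  thr <- bg_med + max(k_mad * mad(fluor_image), min_prominence)

  out <- vector("list", nrow(masks))
  for (i in seq_len(nrow(masks))) {
    if (!isTRUE(masks$measurable[i])) next
    px <- masks$pixels[[i]]
    vals <- fluor_image[px]
    cand <- which(vals > thr)
    if (!length(cand)) next

    ## connected components among candidate pixels of this cell
    r0 <- min(px[, 1]) - 1L; c0 <- min(px[, 2]) - 1L
    sub <- matrix(0, max(px[, 1]) - r0 + 1L, max(px[, 2]) - c0 + 1L)
    sub[cbind(px[cand, 1] - r0, px[cand, 2] - c0)] <- 1
    lab <- EBImage::bwlabel(sub)
    lab <- matrix(as.integer(lab), nrow = nrow(sub))

    cl <- masks$centerline[[i]]
    L_um <- masks$length_um[i]
    foci <- list()
    for (l in seq_len(max(lab))) {
      idx <- which(lab == l, arr.ind = TRUE)
      gidx <- cbind(idx[, 1] + r0, idx[, 2] + c0)
      iv <- fluor_image[gidx]
      best <- which(iv == max(iv))
      if (length(best) > 1) {
        ## row-major tie-break: scan rows top-to-bottom, then columns
        ord <- order(gidx[best, 1], gidx[best, 2])
        best <- best[ord[1]]
      }
      pr <- gidx[best, 1]; pc <- gidx[best, 2]
      proj <- project_on_centerline(cl, pr, pc)
      s_um <- proj$s_px / proj$total_px * L_um
      foci[[l]] <- tibble(
        frame = masks$frame[i], cell_label = masks$label[i],
        row = as.integer(pr), col = as.integer(pc),
        intensity = fluor_image[pr, pc],
        s_um = s_um, p_norm = s_um / L_um,
        focus_class = classify_focus(s_um, L_um, d_pole))
    }
    out[[i]] <- dplyr::bind_rows(foci)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty else res
}

#' Classify a focus as polar or internal
#'
#' A focus is polar when its arclength distance to the nearer pole is at
#' most `d_pole` (boundary inclusive); otherwise internal.  The default
#' `d_pole` of 0.5 um is roughly one cell width.
#'
#' @param s_um Arclength from pole A, microns (vectorized).
#' @param length_um Cell length, microns.
#' @param d_pole Polar cutoff distance, microns.
#' @return Character vector, `"polar"` or `"internal"`.
#' @examples
#' classify_focus(2.5, 5, 0.5)   # mid-cell: internal
#' classify_focus(0.5, 5, 0.5)   # boundary: polar
#' @export
classify_focus <- function(s_um, length_um, d_pole = 0.5) {
  ifelse(pmin(s_um, length_um - s_um) <= d_pole, "polar", "internal")
}

## ---- tracking ----------------------------------------------------------

## Exact minimal-cost bipartite matching of two small arclength sets with
## gating: among maximum-cardinality matchings whose links all satisfy
## |ds| <= max_step, the one with minimal total |ds|.  Exhaustive
## recursion; focus counts per cell are tiny.
match_foci_sets <- function(s_prev, s_next, max_step) {
  n <- length(s_prev); m <- length(s_next)
  if (n == 0 || m == 0) return(matrix(integer(), ncol = 2))
  feasible <- abs(outer(s_prev, s_next, "-")) <= max_step
  best <- list(size = -1L, cost = Inf, pairs = matrix(integer(), ncol = 2))
  recurse <- function(i, used, pairs, cost) {
    if (i > n) {
      size <- nrow(pairs)
      if (size > best$size ||
          (size == best$size && cost < best$cost)) {
        best <<- list(size = size, cost = cost, pairs = pairs)
      }
      return(invisible())
    }
    for (j in seq_len(m)) {
      if (!used[j] && feasible[i, j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, rbind(pairs, c(i, j)),
                cost + abs(s_prev[i] - s_next[j]))
        used[j] <- FALSE
      }
    }
    recurse(i + 1L, used, pairs, cost)  # leave i unmatched
  }
  recurse(1L, rep(FALSE, m), matrix(integer(), ncol = 2), 0)
  best$pairs
}

#' Link internal foci into tracks across frames
#'
#' Within each cell track, internal foci are linked frame-to-frame by
#' arclength proximity: consecutive-frame foci are matched by the exact
#' assignment that maximizes the number of links subject to
#' `|delta s| <= max_step` and, among those, minimizes the total
#' `|delta s|`.  Unlinked foci start new tracks.
#'
#' @param foci Tibble of detected foci carrying a `cell_track_id` column
#'   (cell labels already linked across frames, see [track_cells()]) in
#'   addition to the columns of [detect_foci()].
#' @param max_step Maximum allowed frame-to-frame arclength step, microns.
#' @param classes Focus classes to track (default internal only).
#' @return `foci` filtered to the tracked classes, with a `focus_track_id`
#'   column.
#' @export
track_foci <- function(foci, max_step = 1.5, classes = "internal") {
  if (!"cell_track_id" %in% names(foci)) {
    abort("foci must carry a cell_track_id column (run track_cells first)")
  }
  f <- foci[foci$focus_class %in% classes, , drop = FALSE]
  if (nrow(f) == 0) {
    f$focus_track_id <- integer()
    return(f)
  }
  f <- dplyr::arrange(f, .data$cell_track_id, .data$frame, .data$s_um)
  f$focus_track_id <- NA_integer_
  next_tid <- 1L
  for (ct in unique(f$cell_track_id)) {
    rows_ct <- which(f$cell_track_id == ct)
    frames <- sort(unique(f$frame[rows_ct]))
    prev_rows <- integer()
    for (fr in frames) {
      cur_rows <- rows_ct[f$frame[rows_ct] == fr]
      if (length(prev_rows)) {
        pairs <- match_foci_sets(f$s_um[prev_rows], f$s_um[cur_rows],
                                 max_step)
        if (nrow(pairs)) {
          f$focus_track_id[cur_rows[pairs[, 2]]] <-
            f$focus_track_id[prev_rows[pairs[, 1]]]
        }
      }
      fresh <- cur_rows[is.na(f$focus_track_id[cur_rows])]
      if (length(fresh)) {
        f$focus_track_id[fresh] <- seq(next_tid, length.out = length(fresh))
        next_tid <- next_tid + length(fresh)
      }
      prev_rows <- cur_rows
    }
  }
  f
}

## ---- condensation ------------------------------------------------------

#' Detect the condensation event of an internal-focus track
#'
#' Condensation is the earliest observation from which the track's
#' normalized position stays within `epsilon` of its forward running
#' median for the remainder of the track, with at least `k_frames`
#' observations remaining: a wandering patch fails the criterion, a
#' settled septal spot satisfies it from the first stable frame onward.
#'
#' @param track Tibble with columns `frame`, `time_min` and `p_norm`,
#'   one internal-focus track in frame order.
#' @param epsilon Stability half-band on normalized position.
#' @param k_frames Minimum number of consecutive stable observations.
#' @return A one-row tibble (`condensation_frame`, `condensation_time`,
#'   `p_at_condensation`) or a zero-row tibble when the track never
#'   stabilizes.
#' @examples
#' tr <- tibble::tibble(frame = 1:6, time_min = (0:5) * 10,
#'                      p_norm = c(0.30, 0.62, 0.48, 0.50, 0.51, 0.50))
#' detect_condensation(tr)  # settles at the 3rd observation
#' @export
detect_condensation <- function(track, epsilon = 0.05, k_frames = 3) {
  stopifnot(all(c("frame", "p_norm") %in% names(track)))
  p <- track$p_norm
  n <- length(p)
  if (n < k_frames) {
    return(tibble(condensation_frame = integer(),
                  condensation_time = numeric(),
                  p_at_condensation = numeric()))
  }
  for (i in seq_len(n - k_frames + 1L)) {
    ok <- TRUE
    for (j in i:n) {
      m <- median(p[i:j])
      if (abs(p[j] - m) > epsilon) { ok <- FALSE; break }
    }
    if (ok) {
      ## robust position estimate: median over the first stable window
      return(tibble(
        condensation_frame = track$frame[i],
        condensation_time = if ("time_min" %in% names(track))
          track$time_min[i] else NA_real_,
        p_at_condensation = median(p[i:(i + k_frames - 1L)])))
    }
  }
  tibble(condensation_frame = integer(), condensation_time = numeric(),
         p_at_condensation = numeric())
}
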