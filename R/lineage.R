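## linear pixel indices for fast overlap computation
mask_lin_idx <- function(px, nr) (px[, 2] - 1L) * nr + px[, 1]

iou_of <- function(idx1, idx2) {
  inter <- length(intersect(idx1, idx2))
  if (inter == 0) return(0)
  inter / (length(idx1) + length(idx2) - inter)
}

#' Track cell masks across frames and detect divisions
#'
#' Links masks between consecutive frames by maximal pixel overlap
#' (intersection-over-union): each mask at frame `t + 1` is attached to
#' the frame-`t` mask with which it has the greatest IoU, provided that
#' IoU passes the threshold.  A division is declared when one mask at
#' `t` is claimed by exactly two masks at `t + 1`, each with IoU against
#' the parent of at least `iou_min / 2`; the two daughters record the
#' parent, and which daughter carries the parent's pole A is decided by
#' proximity of the daughter centroid to the parent's pole A (so
#' per-side growth series stay attributable).  A mask claimed by two
#' parents above threshold is resolved toward the larger overlap and
#' counted as a conflict.  Tracks with no link terminate.
#'
#' @param masks_by_frame Tibble of masks over all frames, as produced by
#'   row-binding [extract_centerline()] outputs (columns `frame`,
#'   `label`, `pixels`, and pole coordinates if available).
#' @param iou_min Minimum IoU for a one-to-one link; halves for each
#'   branch of a division.
#' @param image_dim Image dimensions (rows, cols); defaults to the masks'
#'   attribute.
#' @return A list with:
#'   `tracks`: long tibble (`track_id`, `frame`, `label`) mapping each
#'   track to its per-frame mask;
#'   `info`: per-track tibble (`track_id`, `birth_frame`, `end_frame`,
#'   `parent_track_id`);
#'   `divisions`: tibble (`parent_track_id`, `daughter_a`, `daughter_b`,
#'   `division_frame` — the parent's last frame).  The number of
#'   overlap-conflict resolutions is attached as attribute
#'   `"n_conflicts"` on `divisions`.
#' @export
track_cells <- function(masks_by_frame, iou_min = 0.3,
                        image_dim = attr(masks_by_frame, "image_dim")) {
  m <- masks_by_frame
  if (nrow(m) == 0) {
    return(list(tracks = tibble(track_id = integer(), frame = integer(),
                                label = integer()),
                info = tibble(track_id = integer(), birth_frame = integer(),
                              end_frame = integer(),
                              parent_track_id = integer()),
                divisions = tibble(parent_track_id = integer(),
                                   daughter_a = integer(),
                                   daughter_b = integer(),
                                   division_frame = integer())))
  }
  if (is.null(image_dim)) image_dim <- c(max(vapply(m$pixels, function(p)
    max(p[, 1]), numeric(1))), NA)
  nr <- image_dim[1]

  m <- dplyr::arrange(m, .data$frame, .data$label)
  m$.row <- seq_len(nrow(m))
  m$.idx <- lapply(m$pixels, mask_lin_idx, nr = nr)
  frames <- sort(unique(m$frame))

  track_of <- rep(NA_integer_, nrow(m))
  parent_of_track <- integer()
  birth_frame <- integer()
  end_frame <- integer()
  next_track <- 0L
  new_track <- function(fr, parent = NA_integer_) {
    next_track <<- next_track + 1L
    parent_of_track[next_track] <<- parent
    birth_frame[next_track] <<- fr
    end_frame[next_track] <<- fr
    next_track
  }
  divisions <- list()
  n_conflicts <- 0L

  fr0 <- frames[1]
  for (r in m$.row[m$frame == fr0]) track_of[r] <- new_track(fr0)

  for (k in seq_along(frames)[-1]) {
    fr_prev <- frames[k - 1L]; fr <- frames[k]
    prev_rows <- m$.row[m$frame == fr_prev]
    cur_rows <- m$.row[m$frame == fr]
    if (!length(cur_rows)) next

    ## IoU of every (prev, cur) pair with a bounding-box prefilter
    claims <- vector("list", length(cur_rows))
    for (ci in seq_along(cur_rows)) {
      cr <- cur_rows[ci]
      best_iou <- 0; best_prev <- NA_integer_; second <- 0
      for (pr in prev_rows) {
        if (abs(m$centroid_row[cr] - m$centroid_row[pr]) > 60 ||
            abs(m$centroid_col[cr] - m$centroid_col[pr]) > 200) next
        v <- iou_of(m$.idx[[pr]], m$.idx[[cr]])
        if (v > best_iou) {
          second <- best_iou; best_iou <- v; best_prev <- pr
        } else if (v > second) second <- v
      }
      if (second >= iou_min) n_conflicts <- n_conflicts + 1L
      claims[[ci]] <- list(prev = best_prev, iou = best_iou)
    }

    for (pr in prev_rows) {
      kids <- which(vapply(claims, function(cl)
        identical(cl$prev, pr), logical(1)))
      if (!length(kids)) next
      ious <- vapply(claims[kids], function(cl) cl$iou, numeric(1))
      tid <- track_of[pr]
      if (length(kids) == 1L && ious[1] >= iou_min) {
        r <- cur_rows[kids[1]]
        track_of[r] <- tid
        end_frame[tid] <- fr
      } else if (length(kids) >= 2L) {
        ord <- order(ious, decreasing = TRUE)
        two <- kids[ord[1:2]]
        if (all(ious[ord[1:2]] >= iou_min / 2)) {
          ra <- cur_rows[two[1]]; rb <- cur_rows[two[2]]
          ## daughter A = the one nearer the parent's pole A
          if (all(c("pole_a_row", "pole_a_col") %in% names(m)) &&
              !is.na(m$pole_a_row[pr])) {
            da <- (m$centroid_row[ra] - m$pole_a_row[pr])^2 +
              (m$centroid_col[ra] - m$pole_a_col[pr])^2
            db <- (m$centroid_row[rb] - m$pole_a_row[pr])^2 +
              (m$centroid_col[rb] - m$pole_a_col[pr])^2
            if (db < da) { tmp <- ra; ra <- rb; rb <- tmp }
          } else if (m$centroid_col[rb] < m$centroid_col[ra]) {
            tmp <- ra; ra <- rb; rb <- tmp
          }
          ta <- new_track(fr, parent = tid)
          tb <- new_track(fr, parent = tid)
          track_of[ra] <- ta; track_of[rb] <- tb
          divisions[[length(divisions) + 1L]] <- tibble(
            parent_track_id = tid, daughter_a = ta, daughter_b = tb,
            division_frame = fr_prev)
        } else if (ious[ord[1]] >= iou_min) {
          r <- cur_rows[kids[ord[1]]]
          track_of[r] <- tid
          end_frame[tid] <- fr
        }
      }
    }
    ## unlinked current masks start fresh tracks
    for (ci in seq_along(cur_rows)) {
      r <- cur_rows[ci]
      if (is.na(track_of[r])) track_of[r] <- new_track(fr)
    }
  }

  tracks <- tibble(track_id = track_of, frame = m$frame, label = m$label)
  info <- tibble(track_id = seq_len(next_track),
                 birth_frame = birth_frame[seq_len(next_track)],
                 end_frame = end_frame[seq_len(next_track)],
                 parent_track_id = parent_of_track[seq_len(next_track)])
  div <- if (length(divisions)) dplyr::bind_rows(divisions) else
    tibble(parent_track_id = integer(), daughter_a = integer(),
           daughter_b = integer(), division_frame = integer())
  attr(div, "n_conflicts") <- n_conflicts
  list(tracks = tracks, info = info, divisions = div)
}
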