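#' Run the full measurement pipeline on a two-channel movie
#'
#' Segments every frame, measures centerline lengths, tracks cells and
#' detects divisions, detects and tracks internal fluorescent foci,
#' detects condensation events, and assembles per-cell pole-growth
#' records (side lengths at condensation and division, per-side
#' exponential rates).
#'
#' @param stack An `image_stack` (see [render_movie()],
#'   [read_image_stack()]).
#' @param min_area_px,iou_min,k_mad,min_prominence,d_pole,max_step,
#'   epsilon,k_frames Stage parameters, passed to [segment_frame()],
#'   [track_cells()], [detect_foci()], [track_foci()] and
#'   [detect_condensation()].
#' @return A `cell_movie_analysis` list: `masks` (per frame, pixels
#'   dropped), `foci`, `tracks`, `track_info`, `divisions`,
#'   `septum_events`, `growth_records`, `discards` (reason-coded counts),
#'   and the calibration.
#' @export
analyze_stack <- function(stack, min_area_px = 40, iou_min = 0.3,
                          k_mad = 5, min_prominence = 0.05, d_pole = 0.5,
                          max_step = 1.5, epsilon = 0.05, k_frames = 3) {
  nf <- n_frames_of(stack)
  ps <- stack$pixel_size
  dt <- stack$frame_interval

  masks_list <- vector("list", nf)
  foci_list <- vector("list", nf)
  n_small <- n_border <- n_unmeas <- 0L
  for (fi in seq_len(nf)) {
    ph <- get_frame(stack, "phase", fi)
    fl <- get_frame(stack, "fluor", fi)
    mk <- segment_frame(ph, ps, min_area_px = min_area_px, frame = fi)
    mk <- suppressWarnings(extract_centerline(mk, ps, phase_image = ph))
    n_small <- n_small + (attr(mk, "n_discarded_small") %||% 0L)
    n_border <- n_border + (attr(mk, "n_discarded_border") %||% 0L)
    n_unmeas <- n_unmeas + (attr(mk, "n_unmeasurable") %||% 0L)
    masks_list[[fi]] <- mk
    foci_list[[fi]] <- detect_foci(fl, mk, k_mad = k_mad,
                                   min_prominence = min_prominence,
                                   d_pole = d_pole, pixel_size = ps)
  }
  masks <- dplyr::bind_rows(masks_list)
  attr(masks, "image_dim") <- dim(get_frame(stack, "phase", 1L))
  foci <- dplyr::bind_rows(foci_list)

  lin <- track_cells(masks, iou_min = iou_min)
  key <- paste(lin$tracks$frame, lin$tracks$label)
  track_by_key <- setNames(lin$tracks$track_id, key)
  foci$cell_track_id <- unname(track_by_key[paste(foci$frame,
                                                  foci$cell_label)])
  masks$cell_track_id <- unname(track_by_key[paste(masks$frame,
                                                   masks$label)])

  internal <- track_foci(foci, max_step = max_step)
  internal$time_min <- (internal$frame - 1) * dt

  ## condensation: per cell track, among internal-focus tracks that
  ## persist to the cell's final frame, the earliest stable settlement
  septum_events <- list()
  dividing_tracks <- lin$divisions$parent_track_id
  for (ct in unique(internal$cell_track_id[!is.na(internal$cell_track_id)])) {
    sub <- internal[internal$cell_track_id == ct, ]
    cell_end <- lin$info$end_frame[lin$info$track_id == ct]
    ## during the deepest invagination frames the constricted neck makes
    ## skeleton arclength unreliable, so the stability criterion and the
    ## position average skip the final two pre-division frames; the track
    ## itself must still persist to the end of the cell
    eval_end <- if (ct %in% dividing_tracks) cell_end - 2L else cell_end
    best <- NULL
    for (ft in unique(sub$focus_track_id)) {
      tr_full <- sub[sub$focus_track_id == ft, ]
      tr_full <- tr_full[order(tr_full$frame), ]
      if (max(tr_full$frame) < cell_end - 1L) next
      tr <- tr_full[tr_full$frame <= eval_end, ]
      if (nrow(tr) < k_frames) next
      ev <- detect_condensation(tr, epsilon = epsilon, k_frames = k_frames)
      if (!nrow(ev)) next
      if (is.null(best) || ev$condensation_time < best$condensation_time) {
        best <- ev
        best$focus_track_id <- ft
        ## the settled septal spot is stationary at the septum plane, so
        ## averaging its normalized position over the whole stable
        ## stretch suppresses pixel-quantization noise in the side split
        best$p_at_condensation <-
          mean(tr$p_norm[tr$frame >= ev$condensation_frame])
      }
    }
    if (!is.null(best)) {
      best$cell_track_id <- ct
      septum_events[[length(septum_events) + 1L]] <- best
    }
  }
  septum_events <- if (length(septum_events)) {
    dplyr::bind_rows(septum_events)
  } else {
    tibble(condensation_frame = integer(), condensation_time = numeric(),
           p_at_condensation = numeric(), focus_track_id = integer(),
           cell_track_id = integer())
  }

  ## pole-growth records: condensation + division
  grs <- list()
  n_no_septum <- 0L
  if (nrow(lin$divisions)) {
    mask_len <- function(track_id, frame) {
      v <- masks$length_um[masks$cell_track_id == track_id &
                             masks$frame == frame]
      if (length(v) == 1 && is.finite(v)) v else NA_real_
    }
    for (i in seq_len(nrow(lin$divisions))) {
      d <- lin$divisions[i, ]
      ev <- septum_events[septum_events$cell_track_id == d$parent_track_id, ]
      if (!nrow(ev)) { n_no_septum <- n_no_septum + 1L; next }
      ev <- ev[1, ]
      L_sep <- mask_len(d$parent_track_id, ev$condensation_frame)
      La <- mask_len(d$daughter_a, d$division_frame + 1L)
      Lb <- mask_len(d$daughter_b, d$division_frame + 1L)
      if (is.na(L_sep) || is.na(La) || is.na(Lb)) {
        n_no_septum <- n_no_septum + 1L
        next
      }
      grs[[length(grs) + 1L]] <- tibble(
        track_id = d$parent_track_id,
        t_sep = ev$condensation_time,
        t_div = d$division_frame * dt,
        division_frame = d$division_frame,
        condensation_frame = ev$condensation_frame,
        p_at_condensation = ev$p_at_condensation,
        side_a_at_sep = ev$p_at_condensation * L_sep,
        side_b_at_sep = (1 - ev$p_at_condensation) * L_sep,
        side_a_at_div = La, side_b_at_div = Lb,
        parent_length_at_division = mask_len(d$parent_track_id,
                                             d$division_frame))
    }
  }
  growth_records <- if (length(grs)) {
    pole_growth_rates(dplyr::bind_rows(grs))
  } else {
    pole_growth_rates(tibble(
      side_a_at_sep = numeric(), side_b_at_sep = numeric(),
      side_a_at_div = numeric(), side_b_at_div = numeric(),
      t_sep = numeric(), t_div = numeric()))
  }

  discards <- tibble(
    stage = c("segmentation", "segmentation", "centerline",
              "growth_records", "growth_records"),
    reason = c("below_min_area", "touching_border", "unmeasurable",
               "no_septum_event_or_length", "nonpositive_slow_rate"),
    n = c(n_small, n_border, n_unmeas, n_no_septum,
          sum(!growth_records$valid_ratio)))

  structure(list(
    masks = masks[, setdiff(names(masks), "pixels")],
    foci = foci, internal_foci = internal,
    tracks = lin$tracks, track_info = lin$info, divisions = lin$divisions,
    septum_events = septum_events, growth_records = growth_records,
    discards = discards,
    pixel_size = ps, frame_interval = dt
  ), class = "cell_movie_analysis")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cell_movie_analysis <- function(x, ...) {
  cat("<cell_movie_analysis>\n")
  cat(sprintf("  masks: %d over %d frame(s); tracks: %d; divisions: %d\n",
              nrow(x$masks), length(unique(x$masks$frame)),
              nrow(x$track_info), nrow(x$divisions)))
  cat(sprintf("  foci: %d; septum events: %d; growth records: %d\n",
              nrow(x$foci), nrow(x$septum_events), nrow(x$growth_records)))
  invisible(x)
}

#' Compare a pipeline analysis against generator ground truth
#'
#' Matches measured masks to true cells per frame by centroid proximity
#' and reports per-frame length errors, recovery of division events
#' (within +/- 1 frame) and condensation-to-division delays.
#'
#' @param analysis A `cell_movie_analysis`.
#' @param truth Truth tibble from [render_movie()].
#' @return List with `length_errors` (tibble), `division_recovery`
#'   (list: `n_true`, `n_detected`, `n_matched`, `n_spurious`) and
#'   `delays` (tibble of detected condensation-to-division delays, min).
#' @export
evaluate_against_truth <- function(analysis, truth) {
  m <- analysis$masks[analysis$masks$measurable, ]
  errs <- list()
  for (fi in unique(m$frame)) {
    tm <- truth[truth$frame == fi, ]
    mm <- m[m$frame == fi, ]
    if (!nrow(tm) || !nrow(mm)) next
    for (j in seq_len(nrow(mm))) {
      d2 <- (tm$pole_a_row + tm$pole_b_row) / 2
      dc <- (tm$pole_a_col + tm$pole_b_col) / 2
      k <- which.min((d2 - mm$centroid_row[j])^2 + (dc - mm$centroid_col[j])^2)
      errs[[length(errs) + 1L]] <- tibble(
        frame = fi, cell_id = tm$cell_id[k],
        true_length = tm$length_um[k], measured_length = mm$length_um[j],
        error_um = mm$length_um[j] - tm$length_um[k])
    }
  }
  length_errors <- dplyr::bind_rows(errs)

  true_divs <- sort(unique(truth$frame[truth$event == "birth"]))
  det <- analysis$divisions$division_frame + 1L
  n_matched <- 0L
  det_pool <- det
  for (fd in true_divs) {
    hit <- which(abs(det_pool - fd) <= 1L)
    ## several simultaneous true divisions can map to one frame; match
    ## detections one-to-one
    n_here <- sum(truth$event == "birth" & truth$frame == fd) / 2
    take <- head(hit, n_here)
    n_matched <- n_matched + length(take)
    if (length(take)) det_pool <- det_pool[-take]
  }
  n_true <- sum(truth$event == "birth") / 2
  division_recovery <- list(
    n_true = n_true, n_detected = length(det), n_matched = n_matched,
    n_missed = n_true - n_matched,
    n_spurious = length(det) - n_matched)

  delays <- analysis$growth_records
  delays <- if (nrow(delays)) {
    tibble(track_id = delays$track_id, delay_min = delays$t_div - delays$t_sep)
  } else tibble(track_id = integer(), delay_min = numeric())

  list(length_errors = length_errors, division_recovery = division_recovery,
       delays = delays)
}
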