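## ---- low-level rasterization ------------------------------------------

## Add a filled capsule (segment of half-width `radius`, rounded caps) to a
## binary occupancy matrix.  `tip_a`/`tip_b` are (row, col) tip coordinates
## (tip-to-tip distance = cell length in px).  `pinch` is an optional list
## (pos = (row, col) of septum, depth in [0,1), width px) rendering a local
## constriction of the allowed radius around the septum plane.
draw_capsule <- function(occ, tip_a, tip_b, radius, pinch = NULL) {
  L <- sqrt(sum((tip_b - tip_a)^2))
  dir <- if (L > 0) (tip_b - tip_a) / L else c(0, 1)
  a <- tip_a + radius * dir
  b <- tip_b - radius * dir
  seg_len <- max(L - 2 * radius, 0)

  r0 <- max(1L, floor(min(tip_a[1], tip_b[1]) - radius - 1))
  r1 <- min(nrow(occ), ceiling(max(tip_a[1], tip_b[1]) + radius + 1))
  c0 <- max(1L, floor(min(tip_a[2], tip_b[2]) - radius - 1))
  c1 <- min(ncol(occ), ceiling(max(tip_a[2], tip_b[2]) + radius + 1))
  if (r0 > r1 || c0 > c1) return(occ)

  rr <- r0:r1
  cc <- c0:c1
  vr <- outer(rr - a[1], rep(1, length(cc)))
  vc <- outer(rep(1, length(rr)), cc - a[2])
  t_ax <- vr * dir[1] + vc * dir[2]
  t_cl <- pmin(pmax(t_ax, 0), seg_len)
  d2 <- (vr - t_cl * dir[1])^2 + (vc - t_cl * dir[2])^2

  r_eff <- radius
  if (!is.null(pinch) && pinch$depth > 0) {
    sr <- outer(rr - pinch$pos[1], rep(1, length(cc)))
    sc <- outer(rep(1, length(rr)), cc - pinch$pos[2])
    s_ax <- sr * dir[1] + sc * dir[2]
    r_eff <- radius * (1 - pinch$depth * exp(-s_ax^2 / (2 * pinch$width^2)))
  }
  ## anti-aliased coverage: linear ramp over one pixel across the outline,
  ## so the blurred edge crosses its half-level at the true boundary
  ## independent of sub-pixel placement
  cover <- pmin(pmax(r_eff - sqrt(d2) + 0.5, 0), 1)
  occ[rr, cc] <- pmax(occ[rr, cc], cover)
  occ
}

## Add a 2-D Gaussian focus of peak `amp` and SD `sigma` px at (row, col).
draw_focus <- function(img, center, amp, sigma) {
  w <- ceiling(4 * sigma)
  r0 <- max(1L, floor(center[1] - w)); r1 <- min(nrow(img), ceiling(center[1] + w))
  c0 <- max(1L, floor(center[2] - w)); c1 <- min(ncol(img), ceiling(center[2] + w))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  g <- amp * exp(-(outer((rr - center[1])^2, (cc - center[2])^2, "+")) /
                   (2 * sigma^2))
  img[rr, cc] <- img[rr, cc] + g
  img
}

gaussian_blur <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  out <- EBImage::gblur(x, sigma = sigma_px)
  matrix(as.numeric(out), nrow = nrow(x))
}

new_image_stack <- function(phase, fluor, pixel_size, frame_interval) {
  structure(list(phase = phase, fluor = fluor, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf(
    "<image_stack> %d x %d px, %d frame(s), %.3f um/px, %g min/frame\n",
    d[1], d[2], if (length(d) == 3) d[3] else 1L, x$pixel_size,
    x$frame_interval))
  invisible(x)
}

n_frames_of <- function(stack) {
  d <- dim(stack$phase)
  if (length(d) == 3) d[3] else 1L
}

get_frame <- function(stack, channel, i) {
  x <- stack[[channel]]
  if (length(dim(x)) == 3) x[, , i] else x
}

## Reflect a value into [lo, hi] (reflecting random-walk boundary).
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  lo + y
}

## ---- movie rendering ---------------------------------------------------

#' Render a simulated population into a two-channel image stack
#'
#' Rasterizes the ground-truth trajectories from [simulate_population()]
#' into a phase-like channel (dark capsules on a bright background,
#' convolved with a Gaussian PSF) and a fluorescence channel (Gaussian
#' foci at both poles throughout, plus an internal patch that wanders
#' along the centerline before condensation and a stable septal spot
#' after it).  A local width constriction (invagination) is rendered at
#' the septum during the final frames before division, and division is
#' rendered as a physical gap between the two daughters.  Cells are laid
#' out in non-overlapping lanes (one per founder lineage), so masks never
#' merge.
#'
#' @param truths Tibble from [simulate_population()].
#' @param config A [sim_config()]; defaults to the one stored in `truths`.
#' @param seed Seed for rendering randomness (patch walk, pixel noise);
#'   defaults to `config$seed + 1`.
#' @return A list with elements `stack` (an `image_stack`: `phase` and
#'   `fluor` arrays indexed row, col, frame) and `truth`, a per-frame
#'   per-cell tibble (`frame`, `time_min`, `cell_id`, `length_um`, pole
#'   pixel coordinates, `septum_pos_norm`, rendered internal-focus
#'   position and pixel, and an `event` flag).
#' @export
render_movie <- function(truths, config = attr(truths, "config"),
                         seed = config$seed + 1L) {
  config <- validate_sim_config(config)
  if (nrow(truths) == 0) config_error("no cells to render")
  withr::local_seed(seed)

  ps <- config$pixel_size
  R <- (config$cell_width / 2) / ps
  sigma_px <- config$psf_sigma / ps
  ## post-division separation between daughters (px): mycobacterial
  ## daughters snap apart at division; a clear gap also keeps each
  ## daughter's blurred end edge free of its sibling's shadow
  gap_px <- 5
  margin <- ceiling(4 * sigma_px + R + 4)

  series <- cell_length_series(truths, config)
  times <- (seq_len(config$n_frames) - 1L) * config$frame_interval

  ## anchor (pole-A column, px) per cell, inherited through divisions.
  ## founders get a uniform sub-pixel offset so cell tips sample all
  ## pixel phases instead of sitting grid-aligned every frame
  anchors <- setNames(rep(NA_real_, nrow(truths)), truths$cell_id)
  lanes <- setNames(rep(NA_integer_, nrow(truths)), truths$cell_id)
  n_founders <- max(truths$founder_id)
  dither_x <- runif(n_founders)
  dither_y <- runif(n_founders) - 0.5
  for (i in seq_len(nrow(truths))) {
    row <- truths[i, ]
    key <- as.character(row$cell_id)
    lanes[key] <- row$founder_id
    if (is.na(row$parent_id)) {
      anchors[key] <- margin + dither_x[row$founder_id]
    } else {
      pk <- as.character(row$parent_id)
      parent <- truths[truths$cell_id == row$parent_id, ]
      anchors[key] <- if (row$side_of_parent == "a") anchors[pk] else
        anchors[pk] + parent$side_a_at_div / ps + gap_px
    }
  }

  lane_h <- ceiling(2 * R) + 2 * margin
  n_lanes <- max(truths$founder_id)
  extent <- max(anchors[as.character(series$cell_id)] +
                  series$length_um / ps) + margin
  nr <- n_lanes * lane_h
  nc <- ceiling(extent)

  ## pre-compute the wandering-patch path (normalized position per frame)
  wander <- vector("list", nrow(truths))
  names(wander) <- as.character(truths$cell_id)
  lo <- config$wander_bounds[1]; hi <- config$wander_bounds[2]
  for (i in seq_len(nrow(truths))) {
    row <- truths[i, ]
    if (is.na(row$appearance_time)) next
    t_end <- if (is.na(row$condensation_time)) max(times) + 1 else
      row$condensation_time
    fr <- which(times >= row$appearance_time & times < t_end)
    if (!length(fr)) next
    p <- numeric(length(fr))
    p[1] <- runif(1L, lo, hi)
    if (length(fr) > 1) {
      for (k in 2:length(fr)) {
        p[k] <- reflect_into(p[k - 1] + rnorm(1L, 0, config$wander_step_sd),
                             lo, hi)
      }
    }
    wander[[i]] <- setNames(p, fr)
  }

  phase <- array(0, c(nr, nc, config$n_frames))
  fluor <- array(0, c(nr, nc, config$n_frames))
  truth_rows <- vector("list", config$n_frames)
  pinch_window <- 40  # min before division during which invagination deepens
  ## depth capped so the constricted neck always survives thresholding and
  ## morphological opening: the cell must split at division, never before
  max_pinch <- 0.5

  for (fi in seq_len(config$n_frames)) {
    t <- times[fi]
    occ <- matrix(0, nr, nc)
    flu <- matrix(0, nr, nc)
    sub <- series[series$frame == fi, ]
    rows_out <- list()
    for (j in seq_len(nrow(sub))) {
      s <- sub[j, ]
      key <- as.character(s$cell_id)
      cell <- truths[truths$cell_id == s$cell_id, ]
      yc <- (lanes[key] - 1L) * lane_h + lane_h / 2 + dither_y[lanes[key]]
      x0 <- anchors[key]
      Lpx <- s$length_um / ps
      tip_a <- c(yc, x0); tip_b <- c(yc, x0 + Lpx)

      pinch <- NULL
      if (!is.na(cell$division_time) &&
          t >= cell$division_time - pinch_window) {
        depth <- max_pinch *
          min(1, (t - (cell$division_time - pinch_window)) / pinch_window)
        pinch <- list(pos = c(yc, x0 + s$septum_pos_norm * Lpx),
                      depth = depth, width = 1.5)
      }
      occ <- draw_capsule(occ, tip_a, tip_b, R, pinch)

      flu <- draw_focus(flu, tip_a, config$focus_amplitude, sigma_px)
      flu <- draw_focus(flu, tip_b, config$focus_amplitude, sigma_px)

      internal_p <- NA_real_; internal_kind <- ""
      wp <- wander[[key]]
      if (!is.null(wp) && as.character(fi) %in% names(wp)) {
        internal_p <- unname(wp[as.character(fi)])
        internal_kind <- "patch"
      } else if (!is.na(cell$condensation_time) &&
                 t >= cell$condensation_time) {
        internal_p <- s$septum_pos_norm
        internal_kind <- "septal"
      }
      int_row <- int_col <- NA_real_
      if (!is.na(internal_p)) {
        ctr <- c(yc, x0 + internal_p * Lpx)
        int_row <- ctr[1]; int_col <- ctr[2]
        if (internal_kind == "patch") {
          flu <- draw_focus(flu, ctr, 0.4 * config$focus_amplitude,
                            2 * sigma_px)
        } else {
          flu <- draw_focus(flu, ctr, config$focus_amplitude, sigma_px)
        }
      }

      event <- ""
      if (!is.na(cell$appearance_time) && internal_kind != "" &&
          t >= cell$appearance_time &&
          t - config$frame_interval < cell$appearance_time) event <- "appearance"
      if (!is.na(cell$condensation_time) && t >= cell$condensation_time &&
          t - config$frame_interval < cell$condensation_time) event <- "condensation"
      if (!is.na(cell$birth_time) && cell$birth_time > 0 &&
          t >= cell$birth_time &&
          t - config$frame_interval < cell$birth_time) event <- "birth"

      rows_out[[j]] <- tibble(
        frame = fi, time_min = t, cell_id = s$cell_id,
        length_um = s$length_um,
        pole_a_row = yc, pole_a_col = x0,
        pole_b_row = yc, pole_b_col = x0 + Lpx,
        septum_pos_norm = s$septum_pos_norm,
        internal_pos_norm = internal_p, internal_kind = internal_kind,
        internal_row = int_row, internal_col = int_col,
        event = event)
    }
    ph <- config$background_level -
      config$cell_contrast * gaussian_blur(occ, sigma_px)
    fl <- config$fluor_background + flu
    if (config$noise_sd > 0) {
      ph <- ph + matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc)
      fl <- fl + matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc)
    }
    phase[, , fi] <- pmin(pmax(ph, 0), 1)
    fluor[, , fi] <- pmin(pmax(fl, 0), 1)
    truth_rows[[fi]] <- dplyr::bind_rows(rows_out)
  }

  list(stack = new_image_stack(phase, fluor, ps, config$frame_interval),
       truth = dplyr::bind_rows(truth_rows))
}

## ---- static snapshot ---------------------------------------------------

#' Render a single-frame snapshot of three-spot cells
#'
#' Renders `length(lengths)` rod cells in one frame, each carrying two
#' polar foci and one internal focus at the caller-specified normalized
#' position — the static three-spot experiment.  Cells are laid out on a
#' non-overlapping grid; each may be rotated.
#'
#' @param lengths Cell lengths, microns.
#' @param spot_positions_norm Normalized internal-spot positions, one per
#'   cell, each strictly inside (0, 1).
#' @param config A [sim_config()] providing calibration, geometry and
#'   intensities.
#' @param angles Orientation of each cell in degrees (recycled).
#' @param seed Seed for pixel noise; defaults to `config$seed + 2`.
#' @return As [render_movie()]: a list with `stack` (single-frame
#'   `image_stack`) and `truth` (one row per cell; zero rows when
#'   `lengths` is empty).
#' @export
render_static_snapshot <- function(lengths, spot_positions_norm, config,
                                   angles = 0, seed = config$seed + 2L) {
  config <- validate_sim_config(config)
  if (length(lengths) != length(spot_positions_norm)) {
    config_error("lengths and spot_positions_norm must have the same count")
  }
  if (length(spot_positions_norm) &&
      (any(spot_positions_norm <= 0) || any(spot_positions_norm >= 1))) {
    config_error("spot positions must lie strictly inside (0, 1)")
  }
  if (length(lengths) && any(lengths <= 0)) {
    config_error("lengths must be positive")
  }
  withr::local_seed(seed)

  ps <- config$pixel_size
  R <- (config$cell_width / 2) / ps
  sigma_px <- config$psf_sigma / ps
  pad <- ceiling(4 * sigma_px + R + 4)
  n <- length(lengths)

  if (n == 0) {
    nr <- nc <- 2L * pad
    ph <- matrix(config$background_level, nr, nc)
    fl <- matrix(config$fluor_background, nr, nc)
    if (config$noise_sd > 0) {
      ph <- ph + matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc)
      fl <- fl + matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc)
    }
    return(list(
      stack = new_image_stack(
        array(pmin(pmax(ph, 0), 1), c(nr, nc, 1L)),
        array(pmin(pmax(fl, 0), 1), c(nr, nc, 1L)),
        ps, config$frame_interval),
      truth = tibble(frame = integer(), cell_id = integer(),
                     length_um = numeric(), angle_deg = numeric(),
                     pole_a_row = numeric(), pole_a_col = numeric(),
                     pole_b_row = numeric(), pole_b_col = numeric(),
                     septum_pos_norm = numeric(),
                     internal_row = numeric(), internal_col = numeric())))
  }

  angles <- rep_len(angles, n)
  theta <- angles * pi / 180
  Lpx <- lengths / ps
  w_i <- abs(cos(theta)) * Lpx + 2 * pad
  h_i <- abs(sin(theta)) * Lpx + 2 * pad
  tile_w <- ceiling(max(w_i)); tile_h <- ceiling(max(h_i))
  ncols <- max(1L, ceiling(sqrt(n * tile_h / tile_w)))
  nrows <- ceiling(n / ncols)
  nr <- nrows * tile_h; nc <- ncols * tile_w

  occ <- matrix(0, nr, nc)
  flu <- matrix(0, nr, nc)
  rows_out <- vector("list", n)
  for (i in seq_len(n)) {
    gr <- (i - 1L) %/% ncols; gc <- (i - 1L) %% ncols
    ctr <- c(gr * tile_h + tile_h / 2, gc * tile_w + tile_w / 2)
    dir <- c(sin(theta[i]), cos(theta[i]))
    tip1 <- ctr - 0.5 * Lpx[i] * dir
    tip2 <- ctr + 0.5 * Lpx[i] * dir
    ## pole A is the lexicographically smaller tip, matching the
    ## segmentation module's side-labelling convention
    if (tip2[1] < tip1[1] || (tip2[1] == tip1[1] && tip2[2] < tip1[2])) {
      tmp <- tip1; tip1 <- tip2; tip2 <- tmp
    }
    occ <- draw_capsule(occ, tip1, tip2, R)
    flu <- draw_focus(flu, tip1, config$focus_amplitude, sigma_px)
    flu <- draw_focus(flu, tip2, config$focus_amplitude, sigma_px)
    spot <- tip1 + spot_positions_norm[i] * (tip2 - tip1)
    flu <- draw_focus(flu, spot, config$focus_amplitude, sigma_px)
    rows_out[[i]] <- tibble(
      frame = 1L, cell_id = i, length_um = lengths[i],
      angle_deg = angles[i],
      pole_a_row = tip1[1], pole_a_col = tip1[2],
      pole_b_row = tip2[1], pole_b_col = tip2[2],
      septum_pos_norm = spot_positions_norm[i],
      internal_row = spot[1], internal_col = spot[2])
  }

  ph <- config$background_level - config$cell_contrast *
    gaussian_blur(occ, sigma_px)
  fl <- config$fluor_background + flu
  if (config$noise_sd > 0) {
    ph <- ph + matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc)
    fl <- fl + matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc)
  }
  list(stack = new_image_stack(
         array(pmin(pmax(ph, 0), 1), c(nr, nc, 1L)),
         array(pmin(pmax(fl, 0), 1), c(nr, nc, 1L)),
         ps, config$frame_interval),
       truth = dplyr::bind_rows(rows_out))
}

## ---- TIFF I/O ----------------------------------------------------------

#' Write / read a two-channel image stack as multi-page TIFF
#'
#' `write_image_stack()` writes `phase.tif` and `fluor.tif` (16-bit,
#' multi-page) into `dir`; `read_image_stack()` reads them back.
#' Calibration travels in a small `stack.yaml` sidecar.
#'
#' @param stack An `image_stack`.
#' @param dir Output directory (created if needed).
#' @return `write_image_stack()` the directory, invisibly;
#'   `read_image_stack()` an `image_stack`.
#' @export
write_image_stack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  to_pages <- function(x) {
    if (length(dim(x)) == 3) {
      lapply(seq_len(dim(x)[3]), function(i) x[, , i])
    } else list(x)
  }
  tiff::writeTIFF(to_pages(stack$phase), file.path(dir, "phase.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(to_pages(stack$fluor), file.path(dir, "fluor.tif"),
                  bits.per.sample = 16L)
  yaml::write_yaml(list(pixel_size = stack$pixel_size,
                        frame_interval = stack$frame_interval),
                   file.path(dir, "stack.yaml"))
  invisible(dir)
}

#' @rdname write_image_stack
#' @param pixel_size,frame_interval Calibration overrides when the
#'   `stack.yaml` sidecar is absent.
#' @export
read_image_stack <- function(dir, pixel_size = NULL, frame_interval = NULL) {
  pf <- file.path(dir, "phase.tif"); ff <- file.path(dir, "fluor.tif")
  if (!file.exists(pf) || !file.exists(ff)) {
    io_error(sprintf("missing channel file(s) under '%s'", dir))
  }
  meta_file <- file.path(dir, "stack.yaml")
  if (file.exists(meta_file)) {
    meta <- yaml::read_yaml(meta_file)
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size
    if (is.null(frame_interval)) frame_interval <- meta$frame_interval
  }
  if (is.null(pixel_size) || is.null(frame_interval)) {
    config_error("pixel_size and frame_interval are required")
  }
  to_array <- function(pages) {
    if (is.matrix(pages)) pages <- list(pages)
    arr <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
    for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
    arr
  }
  new_image_stack(to_array(tiff::readTIFF(pf, all = TRUE)),
                  to_array(tiff::readTIFF(ff, all = TRUE)),
                  pixel_size, frame_interval)
}
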