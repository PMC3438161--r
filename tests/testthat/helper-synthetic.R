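# Shared fixture builders.  Everything is generated in code at test time;
# small sizes keep the default run fast.

quiet_cfg <- function(...) {
  sim_config(...)
}

# a small movie with divisions inside the horizon
small_movie <- function(n_cells = 4, seed = 7, noise_sd = 0.01,
                        n_frames = 30, ...) {
  cfg <- sim_config(n_cells = n_cells, n_frames = n_frames,
                    noise_sd = noise_sd, seed = seed, ...)
  truths <- simulate_population(cfg)
  movie <- render_movie(truths, cfg)
  list(cfg = cfg, truths = truths, movie = movie)
}

# segment + measure one frame
measure_frame <- function(phase, pixel_size, ...) {
  mk <- segment_frame(phase, pixel_size, ...)
  suppressWarnings(extract_centerline(mk, pixel_size, phase_image = phase))
}

# hand-built rectangular cell mask with a straight centerline, for
# detector tests that need full control over pixel values
fake_mask <- function(nr, nc, r0, r1, c0, c1, frame = 1L, label = 1L,
                      pixel_size = 0.1) {
  px <- as.matrix(expand.grid(row = r0:r1, col = c0:c1))
  rowc <- (r0 + r1) / 2
  cl <- cbind(rep(rowc, c1 - c0 + 1), c0:c1)
  m <- tibble::tibble(
    frame = frame, label = label, area_px = nrow(px),
    centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]),
    pixels = list(px), measurable = TRUE,
    length_um = (c1 - c0) * pixel_size, width_um = (r1 - r0) * pixel_size,
    pole_a_row = rowc, pole_a_col = c0, pole_b_row = rowc, pole_b_col = c1,
    centerline = list(cl))
  attr(m, "image_dim") <- c(nr, nc)
  attr(m, "pixel_size") <- pixel_size
  m
}

# independent flood-fill labelling of a logical matrix (4/8-connectivity),
# used by brute-force oracles
flood_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      r <- (i - 1L) %% nrow(mask) + 1L
      c <- (i - 1L) %/% nrow(mask) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && cc >= 1 && rr <= nrow(mask) && cc <= ncol(mask)) {
          j <- (cc - 1L) * nrow(mask) + rr
          if (mask[j] && lab[j] == 0L) {
            lab[j] <- cur
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  lab
}
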