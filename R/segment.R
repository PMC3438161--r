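## ---- binary thinning ---------------------------------------------------

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## Zhang-Suen binary thinning.  No installed package provides thinning, so
## it is implemented here; fully vectorized over the (small) mask crop.
zs_thin <- function(m) {
  m <- (m > 0) + 0L
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1); p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1);  p9 <- shift_mat(m, 1, 1)
      ## p2..p9 clockwise from north: shifting by (+1,0) brings the value
      ## of the pixel above (r-1, c) into position (r, c)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (sub == 1) {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

## ---- frame segmentation ------------------------------------------------

#' Segment rod-shaped cells from a phase-like frame
#'
#' Global Otsu threshold, inversion (cells are dark on a bright
#' background), morphological opening and connected-component labelling.
#' Components smaller than `min_area_px` or touching the image border are
#' discarded (their geometry is uninformative).
#'
#' @param phase_image 2-D numeric matrix with intensities in `[0, 1]`.
#' @param pixel_size Microns per pixel.
#' @param min_area_px Minimum component area in pixels.
#' @param threshold Optional fixed threshold overriding Otsu.
#' @param frame Frame index recorded in the output.
#' @return A tibble with one row per cell: `frame`, `label`, `area_px`,
#'   centroid coordinates, and a `pixels` list-column of (row, col)
#'   integer matrices.  Attributes: `image_dim`, `threshold`,
#'   `pixel_size`, and the per-frame counts of discarded components
#'   (`n_discarded_small`, `n_discarded_border`).
#' @export
segment_frame <- function(phase_image, pixel_size, min_area_px = 40,
                          threshold = NULL, frame = 1L) {
  if (!is.matrix(phase_image) || !is.numeric(phase_image)) {
    abort("phase_image must be a 2-D numeric matrix")
  }
  if (pixel_size <= 0) config_error("pixel_size must be > 0")

  empty <- tibble(frame = integer(), label = integer(), area_px = integer(),
                  centroid_row = numeric(), centroid_col = numeric(),
                  pixels = list())
  rng <- range(phase_image)
  if (diff(rng) < .Machine$double.eps) {
    attr(empty, "image_dim") <- dim(phase_image)
    return(empty)
  }
  thr <- if (is.null(threshold)) {
    EBImage::otsu(pmin(pmax(phase_image, 0), 1), range = c(0, 1))
  } else threshold
  mask <- (phase_image < thr) + 0
  mask <- EBImage::opening(mask, EBImage::makeBrush(3, shape = "diamond"))
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow = nrow(phase_image))
  nlab <- max(lab)
  if (nlab == 0) {
    attr(empty, "image_dim") <- dim(phase_image)
    attr(empty, "threshold") <- thr
    return(empty)
  }

  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ],
                            lab[, 1], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0]
  areas <- tabulate(lab, nbins = nlab)
  keep <- setdiff(which(areas >= min_area_px), border_labels)
  n_small <- sum(areas < min_area_px)
  n_border <- length(intersect(which(areas >= min_area_px), border_labels))

  rows <- lapply(seq_along(keep), function(i) {
    l <- keep[i]
    idx <- which(lab == l, arr.ind = TRUE)
    tibble(frame = as.integer(frame), label = i,
           area_px = nrow(idx),
           centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]),
           pixels = list(idx))
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty
  attr(out, "image_dim") <- dim(phase_image)
  attr(out, "threshold") <- thr
  attr(out, "pixel_size") <- pixel_size
  attr(out, "n_discarded_small") <- n_small
  attr(out, "n_discarded_border") <- n_border
  out
}

## bilinear intensity sample at fractional (row, col)
bilinear_at <- function(img, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  r0 <- min(max(r0, 1), nrow(img) - 1L)
  c0 <- min(max(c0, 1), ncol(img) - 1L)
  fr <- r - r0; fc <- c - c0
  img[r0, c0] * (1 - fr) * (1 - fc) + img[r0 + 1, c0] * fr * (1 - fc) +
    img[r0, c0 + 1] * (1 - fr) * fc + img[r0 + 1, c0 + 1] * fr * fc
}

## Extend a centerline end outward to the cell boundary.  With an
## intensity image, the boundary is the sub-pixel crossing of the
## half-way level between cell interior and background along the terminal
## direction; otherwise the last in-mask sample of a binary march.
extend_to_boundary <- function(endpoint, direction, mask_lookup, phase,
                               mid_level, max_dist) {
  step <- 0.1
  s_grid <- seq(step, max_dist, by = step)
  if (!is.null(phase)) {
    vals <- vapply(s_grid, function(s) {
      p <- endpoint + s * direction
      bilinear_at(phase, p[1], p[2])
    }, numeric(1))
    v0 <- bilinear_at(phase, endpoint[1], endpoint[2])
    vals <- c(v0, vals)
    cross <- which(vals[-1] >= mid_level & vals[-length(vals)] < mid_level)
    if (length(cross)) {
      i <- cross[1]
      s_lo <- c(0, s_grid)[i]; s_hi <- s_grid[i]
      v_lo <- vals[i]; v_hi <- vals[i + 1]
      s_star <- s_lo + (mid_level - v_lo) / (v_hi - v_lo) * (s_hi - s_lo)
      return(s_star)
    }
  }
  inside <- vapply(s_grid, function(s) {
    p <- round(endpoint + s * direction)
    mask_lookup(p[1], p[2])
  }, logical(1))
  if (all(inside)) return(max_dist)
  first_out <- which(!inside)[1]
  max(s_grid[first_out] - step / 2, 0)
}

moving_average_path <- function(xy, window = 5) {
  n <- nrow(xy)
  if (n < window + 2) return(xy)
  sm <- apply(xy, 2, function(v) {
    as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
  })
  keep <- !is.na(sm[, 1])
  out <- xy
  out[keep, ] <- sm[keep, ]
  out
}

#' Extract centerlines and pole-to-pole lengths
#'
#' For each segmented cell: skeletonize the mask (Zhang-Suen thinning),
#' take the longest endpoint-to-endpoint geodesic through the skeleton
#' (which drops short side branches), smooth the resulting pixel path,
#' and extend each end outward along the terminal direction to the cell
#' boundary (cap correction; skeletons systematically stop short of
#' rounded poles).  When the phase image is supplied, the boundary is
#' located at the sub-pixel crossing of the half-way intensity level
#' between cell interior and background — for a blurred edge this
#' crossing sits at the physical boundary, giving sub-pixel accuracy.
#' Length is the polyline arclength in microns.  Cells whose skeleton has no
#' endpoints (loops) or is a single point, or whose skeleton is shorter
#' than the cell half-width (round objects), are flagged unmeasurable
#' and excluded from downstream statistics.
#'
#' @param masks Tibble from [segment_frame()].
#' @param pixel_size Microns per pixel.
#' @param phase_image Optional phase frame for sub-pixel cap extension;
#'   without it the extension falls back to binary-mask marching
#'   (half-pixel accuracy).
#' @return `masks` with added columns `measurable`, `length_um`,
#'   `width_um`, `pole_a_row`, `pole_a_col`, `pole_b_row`, `pole_b_col`
#'   and a `centerline` list-column of (row, col) polylines ordered from
#'   pole A (the lexicographically smaller endpoint) to pole B.
#' @export
extract_centerline <- function(masks, pixel_size, phase_image = NULL) {
  if (pixel_size <= 0) config_error("pixel_size must be > 0")
  n <- nrow(masks)
  res <- list(
    measurable = logical(n), length_um = rep(NA_real_, n),
    width_um = rep(NA_real_, n),
    pole_a_row = rep(NA_real_, n), pole_a_col = rep(NA_real_, n),
    pole_b_row = rep(NA_real_, n), pole_b_col = rep(NA_real_, n),
    centerline = vector("list", n))

  dims <- attr(masks, "image_dim")
  mid_level <- NULL
  if (!is.null(phase_image) && n > 0) {
    all_px <- do.call(rbind, masks$pixels)
    in_mask <- matrix(FALSE, nrow(phase_image), ncol(phase_image))
    in_mask[all_px] <- TRUE
    bg_med <- median(phase_image[!in_mask])
    fg_med <- median(phase_image[in_mask])
    mid_level <- (bg_med + fg_med) / 2
  }

  for (i in seq_len(n)) {
    px <- masks$pixels[[i]]
    r0 <- min(px[, 1]) - 2L; c0 <- min(px[, 2]) - 2L
    crop <- matrix(0L, max(px[, 1]) - r0 + 2L, max(px[, 2]) - c0 + 2L)
    crop[cbind(px[, 1] - r0, px[, 2] - c0)] <- 1L

    dmap <- EBImage::distmap(crop)
    dmap <- matrix(as.numeric(dmap), nrow = nrow(crop))
    half_width_px <- max(dmap)

    skel <- zs_thin(crop)
    sk <- which(skel == 1L, arr.ind = TRUE)
    if (nrow(sk) < 2) next

    ## skeleton graph: 8-neighbour edges weighted by euclidean step
    key <- (sk[, 2] - 1L) * nrow(crop) + sk[, 1]
    idx_of <- setNames(seq_len(nrow(sk)), key)
    edges <- NULL; weights <- NULL
    for (dd in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      nb_key <- (sk[, 2] + dd[2] - 1L) * nrow(crop) + (sk[, 1] + dd[1])
      hit <- which(!is.na(idx_of[as.character(nb_key)]))
      if (length(hit)) {
        edges <- c(edges, rbind(hit, unname(idx_of[as.character(nb_key[hit])])))
        weights <- c(weights, rep(sqrt(sum(dd^2)), length(hit)))
      }
    }
    if (is.null(edges)) next
    g <- igraph::graph(edges, n = nrow(sk), directed = FALSE)
    deg <- igraph::degree(g)
    ends <- which(deg == 1)
    if (length(ends) < 2) next  # loop or point: unmeasurable

    dmat <- igraph::distances(g, v = ends, to = ends, weights = weights)
    pick <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
    vp <- igraph::shortest_paths(g, from = ends[pick[1]], to = ends[pick[2]],
                                 weights = weights)$vpath[[1]]
    path <- sk[as.integer(vp), , drop = FALSE]
    if (nrow(path) < 2) next

    skel_len <- sum(sqrt(rowSums(diff(path)^2)))
    if (skel_len < half_width_px) next  # round/degenerate object

    sm <- moving_average_path(path, window = 5)

    mask_lookup <- function(r, c) {
      r >= 1 && c >= 1 && r <= nrow(crop) && c <= ncol(crop) &&
        crop[r, c] == 1L
    }
    phase_crop <- NULL
    if (!is.null(phase_image)) {
      ## crop coordinate of global pixel g is g - r0 (resp. g - c0)
      pr <- max(1L, r0 + 1L):min(nrow(phase_image), r0 + nrow(crop))
      pc <- max(1L, c0 + 1L):min(ncol(phase_image), c0 + ncol(crop))
      phase_crop <- matrix(NA_real_, nrow(crop), ncol(crop))
      phase_crop[pr - r0, pc - c0] <- phase_image[pr, pc]
      phase_crop[is.na(phase_crop)] <- 1
    }
    k <- min(7L, nrow(sm))
    ext <- function(end_idx) {
      if (end_idx == 1L) {
        e <- sm[1, ]; m <- colMeans(sm[seq_len(k), , drop = FALSE])
      } else {
        e <- sm[nrow(sm), ]
        m <- colMeans(sm[(nrow(sm) - k + 1L):nrow(sm), , drop = FALSE])
      }
      d <- e - m
      nd <- sqrt(sum(d^2))
      if (nd == 0) return(list(pt = e, s = 0))
      d <- d / nd
      s <- extend_to_boundary(e, d, mask_lookup, phase_crop, mid_level,
                              max_dist = 3 * half_width_px + 2)
      list(pt = e + s * d, s = s)
    }
    ea <- ext(1L); eb <- ext(2L)
    line <- rbind(ea$pt, sm, eb$pt)
    line_global <- cbind(line[, 1] + r0, line[, 2] + c0)

    ## pole A is the endpoint with the smaller coordinate along the cell's
    ## dominant image axis (rows if the cell spans more rows than columns,
    ## else columns).  Comparing along the dominant axis keeps side labels
    ## stable across frames: endpoint jitter transverse to the cell axis
    ## can exceed a pixel and must never flip the ordering
    p_first <- line_global[1, ]; p_last <- line_global[nrow(line_global), ]
    d <- p_last - p_first
    flip <- if (abs(d[1]) >= abs(d[2])) d[1] < 0 else d[2] < 0
    if (flip) {
      line_global <- line_global[nrow(line_global):1, , drop = FALSE]
    }

    len_px <- sum(sqrt(rowSums(diff(line_global)^2)))

    mid <- path[seq(ceiling(nrow(path) / 4), floor(3 * nrow(path) / 4)), ,
                drop = FALSE]
    wpx <- if (nrow(mid)) 2 * mean(dmap[mid]) - 1 else 2 * half_width_px - 1

    res$measurable[i] <- TRUE
    res$length_um[i] <- len_px * pixel_size
    res$width_um[i] <- wpx * pixel_size
    res$pole_a_row[i] <- line_global[1, 1]
    res$pole_a_col[i] <- line_global[1, 2]
    res$pole_b_row[i] <- line_global[nrow(line_global), 1]
    res$pole_b_col[i] <- line_global[nrow(line_global), 2]
    res$centerline[[i]] <- line_global
  }

  out <- masks
  out$measurable <- res$measurable
  out$length_um <- res$length_um
  out$width_um <- res$width_um
  out$pole_a_row <- res$pole_a_row
  out$pole_a_col <- res$pole_a_col
  out$pole_b_row <- res$pole_b_row
  out$pole_b_col <- res$pole_b_col
  out$centerline <- res$centerline
  for (a in c("image_dim", "threshold", "pixel_size",
              "n_discarded_small", "n_discarded_border")) {
    attr(out, a) <- attr(masks, a)
  }
  attr(out, "n_unmeasurable") <- sum(!res$measurable)
  if (any(!res$measurable)) {
    warn(sprintf("%d mask(s) flagged unmeasurable (degenerate skeleton)",
                 sum(!res$measurable)))
  }
  out
}
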