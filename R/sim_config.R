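#' Simulation configuration for the synthetic time-lapse generator
#'
#' Bundles every parameter of the synthetic movie generator: imaging
#' calibration, cell geometry, per-pole elongation-rate distributions,
#' septum-placement noise, the pre-condensation patch walk, event timing,
#' rendering intensities and the master seed.  Defaults describe the study
#' system the generator emulates: *M. smegmatis*-like rods imaged every
#' 10 min, with fast-pole rates around 1.66e-4 min^-1 (SD 2.39e-5),
#' slow-pole rates around 7.87e-5 min^-1 (SD 8.80e-6), and cell-envelope
#' invagination 160 min after condensation of the septal spot.
#'
#' @param frame_interval Minutes between consecutive frames.
#' @param pixel_size Microns per pixel.
#' @param cell_width Cell (capsule) width, in microns.
#' @param psf_sigma Standard deviation of the Gaussian point-spread
#'   function, in microns.
#' @param background_level Phase-channel background intensity (arbitrary
#'   units in `[0, 1]`; cells are darker than background).
#' @param cell_contrast Intensity drop of cell interior below
#'   `background_level` in the phase channel.
#' @param fluor_background Fluorescence-channel background intensity.
#' @param focus_amplitude Peak amplitude of a condensed fluorescent focus
#'   above `fluor_background`.
#' @param noise_sd SD of additive Gaussian pixel noise (both channels).
#' @param fast_rate_mean,fast_rate_sd Mean and SD of the fast-pole
#'   exponential elongation rate, in min^-1.
#' @param slow_rate_mean,slow_rate_sd Mean and SD of the slow-pole rate,
#'   in min^-1.
#' @param birth_length_mean,birth_length_sd Mean and SD of founder-cell
#'   birth length, in microns (negative draws are rejected and redrawn).
#' @param placement_offset_sd SD of the septum-placement offset from
#'   mid-cell, as a fraction of cell length; must lie in `[0, 0.5)`.
#' @param wander_step_sd Per-frame step SD of the pre-condensation patch
#'   random walk, as a fraction of cell length.
#' @param wander_bounds Reflecting bounds of the patch walk on normalized
#'   position.
#' @param appearance_delay_mean,appearance_delay_sd Mean and SD (minutes)
#'   of the delay from birth to first appearance of the internal patch.
#' @param condensation_frames Number of frames between patch appearance and
#'   stable condensation at the septum plane.
#' @param invagination_delay Minutes from condensation of the septal spot
#'   to cell separation (division).
#' @param fast_on_short_prob Probability that the fast rate is assigned to
#'   the side that will be the shorter one at septum placement. `0.5` is
#'   an unbiased coin; raising it emulates a population in which most
#'   cells grow faster on their shorter side.
#' @param new_pole_fast_prob Probability that a daughter's newly created
#'   pole draws its rate from the fast-pole distribution (otherwise the
#'   slow one).
#' @param n_cells Number of founder cells.
#' @param n_frames Number of frames in a rendered movie.
#' @param seed Master seed; all generator randomness derives from it.
#'
#' @return A `sim_config` object (a validated named list).
#' @examples
#' cfg <- sim_config(n_cells = 4, seed = 11)
#' cfg$invagination_delay
#' @export
sim_config <- function(frame_interval = 10,
                       pixel_size = 0.1,
                       cell_width = 0.8,
                       psf_sigma = 0.13,
                       background_level = 0.8,
                       cell_contrast = 0.55,
                       fluor_background = 0.08,
                       focus_amplitude = 0.5,
                       noise_sd = 0.01,
                       fast_rate_mean = 1.66e-4,
                       fast_rate_sd = 2.39e-5,
                       slow_rate_mean = 7.87e-5,
                       slow_rate_sd = 8.80e-6,
                       birth_length_mean = 6.0,
                       birth_length_sd = 1.5,
                       placement_offset_sd = 0.066,
                       wander_step_sd = 0.12,
                       wander_bounds = c(0.15, 0.85),
                       appearance_delay_mean = 40,
                       appearance_delay_sd = 15,
                       condensation_frames = 4,
                       invagination_delay = 160,
                       fast_on_short_prob = 0.5,
                       new_pole_fast_prob = 0.5,
                       n_cells = 20,
                       n_frames = 32,
                       seed = 1L) {
  cfg <- list(
    frame_interval = frame_interval, pixel_size = pixel_size,
    cell_width = cell_width, psf_sigma = psf_sigma,
    background_level = background_level, cell_contrast = cell_contrast,
    fluor_background = fluor_background, focus_amplitude = focus_amplitude,
    noise_sd = noise_sd,
    fast_rate_mean = fast_rate_mean, fast_rate_sd = fast_rate_sd,
    slow_rate_mean = slow_rate_mean, slow_rate_sd = slow_rate_sd,
    birth_length_mean = birth_length_mean, birth_length_sd = birth_length_sd,
    placement_offset_sd = placement_offset_sd,
    wander_step_sd = wander_step_sd, wander_bounds = wander_bounds,
    appearance_delay_mean = appearance_delay_mean,
    appearance_delay_sd = appearance_delay_sd,
    condensation_frames = condensation_frames,
    invagination_delay = invagination_delay,
    fast_on_short_prob = fast_on_short_prob,
    new_pole_fast_prob = new_pole_fast_prob,
    n_cells = n_cells, n_frames = n_frames, seed = seed
  )
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg A named list of generator parameters.
#' @return The validated `sim_config` object (invisibly classed).
#' @export
validate_sim_config <- function(cfg) {
  need_scalar <- function(nm) {
    v <- cfg[[nm]]
    if (is.null(v) || length(v) != 1L || !is.numeric(v) || is.na(v)) {
      config_error(sprintf("config field '%s' must be a single number", nm))
    }
    v
  }
  for (nm in c("frame_interval", "pixel_size", "cell_width", "psf_sigma")) {
    if (need_scalar(nm) <= 0) {
      config_error(sprintf("config field '%s' must be > 0", nm))
    }
  }
  nonneg <- c(
    "background_level", "cell_contrast", "fluor_background",
    "focus_amplitude", "noise_sd", "fast_rate_mean", "fast_rate_sd",
    "slow_rate_mean", "slow_rate_sd", "birth_length_mean",
    "birth_length_sd", "placement_offset_sd", "wander_step_sd",
    "appearance_delay_mean", "appearance_delay_sd", "invagination_delay"
  )
  for (nm in nonneg) {
    if (need_scalar(nm) < 0) {
      config_error(sprintf("config field '%s' must be >= 0", nm))
    }
  }
  if (cfg$placement_offset_sd >= 0.5) {
    config_error("placement_offset_sd must be a fraction in [0, 0.5)")
  }
  for (nm in c("fast_on_short_prob", "new_pole_fast_prob")) {
    v <- need_scalar(nm)
    if (v < 0 || v > 1) config_error(sprintf("'%s' must be in [0, 1]", nm))
  }
  if (!is.numeric(cfg$wander_bounds) || length(cfg$wander_bounds) != 2L ||
      cfg$wander_bounds[1] >= cfg$wander_bounds[2] ||
      cfg$wander_bounds[1] < 0 || cfg$wander_bounds[2] > 1) {
    config_error("wander_bounds must be an increasing pair within [0, 1]")
  }
  for (nm in c("condensation_frames", "n_cells", "n_frames")) {
    v <- need_scalar(nm)
    if (v < 1 || v != round(v)) {
      config_error(sprintf("config field '%s' must be a positive integer", nm))
    }
    cfg[[nm]] <- as.integer(v)
  }
  cfg$seed <- as.integer(need_scalar("seed"))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  flat <- vapply(unclass(x), function(v) paste(format(v), collapse = ", "),
                 character(1))
  cat(paste0("  ", format(names(flat)), " : ", flat, collapse = "\n"), "\n")
  invisible(x)
}

#' Read / write a simulation configuration file
#'
#' Configuration files are flat key-value YAML; unknown keys are rejected
#' so typos cannot silently fall back to defaults.
#'
#' @param path File path.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) io_error(sprintf("config file '%s' not found", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    config_error(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param cfg A `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
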