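pkg_version <- function() {
  as.character(utils::packageVersion("polargrowth"))
}

write_manifest <- function(path, config, seed, inputs, outputs, counts) {
  jsonlite::write_json(
    list(tool = "polargrowth", version = pkg_version(),
         seed = seed, config = unclass(config),
         inputs = inputs, outputs = outputs, counts = counts),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate a movie and write it to disk
#'
#' Generates a population with [simulate_population()], renders it with
#' [render_movie()], and writes the two channel TIFFs, the ground-truth
#' CSV, a snapshot of the configuration and a run manifest into
#' `out_dir`.
#'
#' @param config A [sim_config()] (or path to a YAML config file).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; defaults to `config$seed`.
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_sim_config(config)
  config <- validate_sim_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  truths <- simulate_population(config)
  movie <- render_movie(truths, config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_image_stack(movie$stack, out_dir)
  utils::write.csv(movie$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(truths, file.path(out_dir, "cells.csv"),
                   row.names = FALSE)
  write_sim_config(config, file.path(out_dir, "config.yaml"))
  write_manifest(
    file.path(out_dir, "manifest.json"), config, config$seed,
    inputs = list(), outputs = list(dir = out_dir),
    counts = list(cells = nrow(truths), truth_rows = nrow(movie$truth),
                  frames = config$n_frames))
  invisible(out_dir)
}

#' Analyze a movie directory and write all stage outputs
#'
#' Reads the two channel TIFFs from `in_dir`, runs [analyze_stack()],
#' and writes per-stage CSVs, a JSON report of the headline statistics,
#' and a run manifest into `out_dir`.  When `in_dir` contains a
#' `truth.csv` (evaluation mode) an error table comparing estimates to
#' ground truth is written as well.
#'
#' @param in_dir Directory with `phase.tif`, `fluor.tif` (and optionally
#'   `truth.csv`, `stack.yaml`).
#' @param out_dir Output directory.
#' @param ... Stage parameters forwarded to [analyze_stack()].
#' @param band_width Central band width for the placement summary.
#' @return The `cell_movie_analysis`, invisibly.
#' @export
run_analyze <- function(in_dir, out_dir, ..., band_width = 0.2) {
  stack <- read_image_stack(in_dir)
  analysis <- analyze_stack(stack, ...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  wcsv <- function(x, nm) {
    utils::write.csv(x, file.path(out_dir, nm), row.names = FALSE)
  }
  wcsv(analysis$masks[, setdiff(names(analysis$masks), "centerline")],
       "masks.csv")
  wcsv(analysis$foci, "foci.csv")
  wcsv(analysis$tracks, "tracks.csv")
  wcsv(analysis$track_info, "track_info.csv")
  wcsv(analysis$divisions, "divisions.csv")
  wcsv(analysis$septum_events, "septum_events.csv")
  wcsv(analysis$growth_records, "growth_records.csv")
  wcsv(analysis$discards, "discards.csv")

  gr <- analysis$growth_records
  report <- list(n_tracks = nrow(analysis$track_info),
                 n_divisions = nrow(analysis$divisions),
                 n_septum_events = nrow(analysis$septum_events),
                 n_growth_records = nrow(gr))
  if (nrow(analysis$septum_events)) {
    report$central_fraction <-
      central_fraction(analysis$septum_events$p_at_condensation, band_width)
  }
  if (nrow(gr)) {
    s <- asymmetry_stats(gr)
    report <- c(report, list(
      mean_r_fast = s$mean_r_fast, mean_r_slow = s$mean_r_slow,
      mean_ratio = s$mean_ratio, ratio_of_means = s$ratio_of_means,
      frac_faster_on_shorter = s$frac_faster_on_shorter,
      pearson_r = s$pearson_r, pearson_p = s$pearson_p,
      mean_delay_min = mean(gr$t_div - gr$t_sep)))
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  truth_file <- file.path(in_dir, "truth.csv")
  if (file.exists(truth_file)) {
    truth <- utils::read.csv(truth_file)
    ev <- evaluate_against_truth(analysis, truth)
    wcsv(ev$length_errors, "eval_length_errors.csv")
    jsonlite::write_json(ev$division_recovery,
                         file.path(out_dir, "eval_divisions.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  counts <- list(
    masks_kept = nrow(analysis$masks),
    masks_discarded = sum(analysis$discards$n[
      analysis$discards$stage == "segmentation"]),
    unmeasurable = sum(analysis$discards$n[
      analysis$discards$reason == "unmeasurable"]),
    foci = nrow(analysis$foci),
    tracks = nrow(analysis$track_info),
    divisions = nrow(analysis$divisions),
    growth_records = nrow(gr))
  write_manifest(file.path(out_dir, "manifest.json"),
                 config = list(), seed = NA,
                 inputs = list(dir = in_dir), outputs = list(dir = out_dir),
                 counts = counts)
  invisible(analysis)
}

#' Simulate and analyze in one call
#'
#' @param config A [sim_config()] or config-file path.
#' @param out_dir Output directory; the simulation goes to
#'   `out_dir/movie`, the analysis to `out_dir/analysis`.
#' @param seed Optional master-seed override.
#' @param ... Passed to [run_analyze()].
#' @return The `cell_movie_analysis`, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, ...) {
  movie_dir <- file.path(out_dir, "movie")
  run_simulate(config, movie_dir, seed = seed)
  run_analyze(movie_dir, file.path(out_dir, "analysis"), ...)
}
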