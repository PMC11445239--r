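#' Pipeline configuration
#'
#' Assembles all stage parameters with the standard defaults for
#' single-molecule bilayer imaging: 100 nm pixels, baseline 170 counts, EM
#' gain 65.4 counts per photoelectron, labeling efficiency 0.70, at most 30
#' mixture components, maximum accepted PSF sigma 200 nm, 30 ms lag time.
#' The configuration serializes to flat-key YAML
#' (\code{\link{write_config}} / \code{\link{read_config}}) with unit-suffixed
#' key names and round-trips identically.
#'
#' @param camera a \code{\link{camera_model}}.
#' @param psf_sigma_nm expected PSF sigma for detection.
#' @param threshold DoG detection threshold (robust noise units).
#' @param roi_halfwidth_px,bg_halfwidth_px inner/outer ROI half-widths.
#' @param min_roi_distance_px overlap-filter distance.
#' @param max_sigma_nm width filter.
#' @param photon_units brightness units.
#' @param labeling_p labeling efficiency.
#' @param max_n maximum number of Gaussian mixture components.
#' @param min_fraction occurrence fractions below this report as 0.
#' @param max_disp_px,max_gap_frames tracking linking parameters.
#' @param precision_px localization precision for mobility classification.
#' @param min_immobile_frames,min_mobile_frames mobility persistence bounds.
#' @param first_n_frames frames analyzed for tracking.
#' @param exposure_ms lag time between frames.
#' @param seed default seed for stages that draw random numbers.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(camera = camera_slb(),
                            psf_sigma_nm = 150,
                            threshold = 5,
                            roi_halfwidth_px = 3L,
                            bg_halfwidth_px = 5L,
                            min_roi_distance_px = 7,
                            max_sigma_nm = 200,
                            photon_units = "photoelectrons",
                            labeling_p = 0.7,
                            max_n = 30L,
                            min_fraction = 1e-3,
                            max_disp_px = 3,
                            max_gap_frames = 1L,
                            precision_px = 0.2,
                            min_immobile_frames = 10L,
                            min_mobile_frames = 5L,
                            first_n_frames = 100L,
                            exposure_ms = 30,
                            seed = 1L) {
  structure(list(
    camera = camera,
    detection = list(psf_sigma_nm = psf_sigma_nm, threshold = threshold,
                     roi_halfwidth_px = as.integer(roi_halfwidth_px),
                     bg_halfwidth_px = as.integer(bg_halfwidth_px),
                     min_roi_distance_px = min_roi_distance_px,
                     max_sigma_nm = max_sigma_nm,
                     photon_units = photon_units),
    stoich = list(labeling_p = labeling_p, max_n = as.integer(max_n),
                  min_fraction = min_fraction),
    tracking = list(max_disp_px = max_disp_px,
                    max_gap_frames = as.integer(max_gap_frames),
                    precision_px = precision_px,
                    min_immobile_frames = as.integer(min_immobile_frames),
                    min_mobile_frames = as.integer(min_mobile_frames),
                    first_n_frames = as.integer(first_n_frames)),
    exposure_ms = exposure_ms,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

# flat dotted-key representation used for YAML serialization
flatten_config <- function(config) {
  cam <- config$camera
  c(list(
    camera.offset_counts = cam$offset,
    camera.em_gain = cam$em_gain,
    camera.sensitivity_e_per_count = cam$sensitivity,
    camera.quantum_efficiency = cam$quantum_efficiency,
    camera.pixel_size_nm = cam$pixel_size_nm,
    camera.read_noise_sd_counts = cam$read_noise_sd),
    stats::setNames(config$detection, paste0("detection.", names(config$detection))),
    stats::setNames(config$stoich, paste0("stoich.", names(config$stoich))),
    stats::setNames(config$tracking, paste0("tracking.", names(config$tracking))),
    list(exposure_ms = config$exposure_ms, seed = config$seed))
}

#' Write / read a pipeline configuration as flat-key YAML
#' @param config a \code{\link{pipeline_config}}.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(flatten_config(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  fl <- yaml::read_yaml(path)
  g <- function(key, default) if (!is.null(fl[[key]])) fl[[key]] else default
  def <- pipeline_config()
  pipeline_config(
    camera = camera_model(
      offset = as.numeric(g("camera.offset_counts", def$camera$offset)),
      em_gain = as.numeric(g("camera.em_gain", def$camera$em_gain)),
      sensitivity = as.numeric(g("camera.sensitivity_e_per_count",
                                 def$camera$sensitivity)),
      quantum_efficiency = as.numeric(g("camera.quantum_efficiency",
                                        def$camera$quantum_efficiency)),
      pixel_size_nm = as.numeric(g("camera.pixel_size_nm",
                                   def$camera$pixel_size_nm)),
      read_noise_sd = as.numeric(g("camera.read_noise_sd_counts",
                                   def$camera$read_noise_sd))),
    psf_sigma_nm = as.numeric(g("detection.psf_sigma_nm",
                                def$detection$psf_sigma_nm)),
    threshold = as.numeric(g("detection.threshold", def$detection$threshold)),
    roi_halfwidth_px = g("detection.roi_halfwidth_px",
                         def$detection$roi_halfwidth_px),
    bg_halfwidth_px = g("detection.bg_halfwidth_px",
                        def$detection$bg_halfwidth_px),
    min_roi_distance_px = as.numeric(g("detection.min_roi_distance_px",
                                       def$detection$min_roi_distance_px)),
    max_sigma_nm = as.numeric(g("detection.max_sigma_nm",
                                def$detection$max_sigma_nm)),
    photon_units = g("detection.photon_units", def$detection$photon_units),
    labeling_p = as.numeric(g("stoich.labeling_p", def$stoich$labeling_p)),
    max_n = g("stoich.max_n", def$stoich$max_n),
    min_fraction = as.numeric(g("stoich.min_fraction", def$stoich$min_fraction)),
    max_disp_px = as.numeric(g("tracking.max_disp_px",
                               def$tracking$max_disp_px)),
    max_gap_frames = g("tracking.max_gap_frames", def$tracking$max_gap_frames),
    precision_px = as.numeric(g("tracking.precision_px",
                                def$tracking$precision_px)),
    min_immobile_frames = g("tracking.min_immobile_frames",
                            def$tracking$min_immobile_frames),
    min_mobile_frames = g("tracking.min_mobile_frames",
                          def$tracking$min_mobile_frames),
    first_n_frames = g("tracking.first_n_frames", def$tracking$first_n_frames),
    exposure_ms = as.numeric(g("exposure_ms", def$exposure_ms)),
    seed = g("seed", def$seed)
  )
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the end-to-end stoichiometry pipeline on a movie
#'
#' Stages: frame averaging (immobile-particle photometry substrate) ->
#' spot detection -> 2D Gaussian photometry -> ROI/width filtering ->
#' brightness-based stoichiometry with partial-labeling correction ->
#' particle density; optionally per-frame detection, track linking and
#' mobility classification on the first frames. One structured log line per
#' stage reports input/output counts (accepted + rejected = detected).
#'
#' @param movie a \code{frame_stack} or path to a multi-page TIFF.
#' @param config a \code{\link{pipeline_config}}.
#' @param calibration a \code{\link{monomer_calibration}} (or list with
#'   \code{mu1}, \code{sigma1}). Required unless \code{run_stoich = FALSE}.
#' @param run_stoich run the stoichiometry stage.
#' @param run_track run per-frame detection + tracking on the first
#'   \code{config$tracking$first_n_frames} frames.
#' @param out_dir if given, write intermediates there: localizations.csv,
#'   tracks.csv, pdf.csv (density grid and fitted components), result.json,
#'   config.yaml.
#' @return list of class \code{pipeline_result}: \code{stoich}
#'   (\code{stoich_result} or NULL), \code{density_per_um2},
#'   \code{mobility} (or NULL), \code{localizations}, \code{n_accepted},
#'   \code{area_um2}, \code{config}.
#' @export
run_pipeline <- function(movie, config = pipeline_config(),
                         calibration = NULL, run_stoich = TRUE,
                         run_track = FALSE, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(movie)) {
    if (!file.exists(movie)) stop("movie file not found: ", movie)
    movie <- read_movie(movie, camera = config$camera,
                        exposure_ms = config$exposure_ms)
  }
  stopifnot(inherits(movie, "frame_stack"))
  cam <- config$camera
  det <- config$detection
  nf <- dim(movie$frames)[3]
  stage_log("input", "%d frames of %d x %d px", nf,
            dim(movie$frames)[1], dim(movie$frames)[2])

  avg <- average_frames(movie)
  locs <- tryCatch(
    detect_frame(avg, cam, psf_sigma_nm = det$psf_sigma_nm,
                 threshold = det$threshold,
                 roi_halfwidth = det$roi_halfwidth_px,
                 bg_halfwidth = det$bg_halfwidth_px,
                 min_roi_distance_px = det$min_roi_distance_px,
                 max_sigma_nm = det$max_sigma_nm,
                 n_frames_averaged = nf,
                 photon_units = det$photon_units),
    error = function(e) stop("stage [detect] failed: ", conditionMessage(e)))
  acc <- accepted_localizations(locs)
  stage_log("detect", "detected=%d accepted=%d rejected=%d",
            nrow(locs), nrow(acc), nrow(locs) - nrow(acc))

  area_um2 <- prod(dim(avg)) * (cam$pixel_size_nm / 1000)^2
  density <- particle_density(nrow(acc), area_um2)
  stage_log("density", "%d particles / %.1f um^2 = %.4f per um^2",
            nrow(acc), area_um2, density)

  sres <- NULL
  if (run_stoich) {
    if (is.null(calibration))
      stop("stage [stoich] failed: a monomer calibration is required")
    sres <- tryCatch(
      stoichiometry(acc$brightness_photons, calibration,
                    labeling_p = config$stoich$labeling_p,
                    max_n = config$stoich$max_n,
                    min_fraction = config$stoich$min_fraction),
      error = function(e) stop("stage [stoich] failed: ", conditionMessage(e)))
    stage_log("stoich", "n=%d rms misfit=%.3g", sres$n_particles, sres$residual)
  }

  mob <- NULL
  tracks <- NULL
  if (run_track) {
    trk <- config$tracking
    frames <- seq_len(min(trk$first_n_frames, nf))
    locs_t <- tryCatch(
      detect_movie(movie, frames = frames, camera = cam,
                   psf_sigma_nm = det$psf_sigma_nm, threshold = det$threshold,
                   roi_halfwidth = det$roi_halfwidth_px,
                   bg_halfwidth = det$bg_halfwidth_px,
                   min_roi_distance_px = det$min_roi_distance_px,
                   max_sigma_nm = det$max_sigma_nm,
                   photon_units = det$photon_units),
      error = function(e) stop("stage [track] failed: ", conditionMessage(e)))
    tracks <- link_tracks(accepted_localizations(locs_t),
                          max_disp_px = trk$max_disp_px,
                          max_gap = trk$max_gap_frames)
    mob <- tryCatch(
      classify_mobility(tracks, precision_px = trk$precision_px,
                        min_immobile_frames = trk$min_immobile_frames,
                        min_mobile_frames = trk$min_mobile_frames),
      error = function(e) stop("stage [track] failed: ", conditionMessage(e)))
    stage_log("track", "tracks=%d immobile=%.1f%% mobile=%.1f%%",
              length(unique(tracks$track_id)), mob$percent_immobile,
              mob$percent_mobile)
  }

  result <- structure(list(stoich = sres, density_per_um2 = density,
                           mobility = mob, localizations = locs,
                           tracks = tracks, n_accepted = nrow(acc),
                           area_um2 = area_um2, config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' Write pipeline outputs (CSV tables, JSON summary, YAML config)
#' @param result a \code{pipeline_result}.
#' @param out_dir output directory (created if missing).
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_localizations(result$localizations,
                      file.path(out_dir, "localizations.csv"))
  if (!is.null(result$tracks))
    write_tracks(result$tracks, file.path(out_dir, "tracks.csv"))
  summary <- list(
    n_accepted = result$n_accepted,
    area_um2 = result$area_um2,
    density_per_um2 = result$density_per_um2,
    settings = flatten_config(result$config))
  if (!is.null(result$stoich)) {
    s <- result$stoich
    summary$observed_fractions <- as.list(s$observed_fractions)
    summary$corrected_fractions <- as.list(as.numeric(s$corrected_fractions)) |>
      stats::setNames(names(s$corrected_fractions))
    summary$mixture_residual <- s$residual
    summary$correction_residual <- s$correction_residual
    summary$labeling_p <- s$labeling_p
    pdf_df <- data.frame(brightness = s$pdf$grid, density = s$pdf$density,
                         fitted = s$mixture$fitted)
    utils::write.csv(cbind(pdf_df, s$mixture$components),
                     file.path(out_dir, "pdf.csv"), row.names = FALSE)
  }
  if (!is.null(result$mobility)) {
    summary$percent_immobile <- result$mobility$percent_immobile
    summary$percent_mobile <- result$mobility$percent_mobile
  }
  jsonlite::write_json(summary, file.path(out_dir, "result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_config(result$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d accepted particles, %.4f per um^2\n",
              x$n_accepted, x$density_per_um2))
  if (!is.null(x$stoich)) print(x$stoich)
  if (!is.null(x$mobility))
    cat(sprintf("  mobility: %.1f%% immobile / %.1f%% mobile\n",
                x$mobility$percent_immobile, x$mobility$percent_mobile))
  invisible(x)
}
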