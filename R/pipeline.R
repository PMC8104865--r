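# End-to-end orchestration: run configuration (YAML), the morphometry,
# dynamics, synthesis and kinetics pipelines, group summaries, and
# provenance-stamped reports.

#' Default run configuration
#'
#' All stage parameters with their defaults: Otsu bins 256, opening
#' radius 3 px, junction size filter 3 px, max linking distance 7 px,
#' max gap-closing distance 10 px, max frame gap 3, minimum track span
#' 10 frames, radial distances 8/12/16 um. Override any entry via a
#' YAML file ([load_config()]) or by modifying the returned list.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    pixel_size_um = 0.1,
    frame_interval_s = 0.1,
    seed = 1L,
    out_dir = NULL,
    inputs = NULL,
    synth = list(width_px = 512L, height_px = 512L, n_seed_points = 80L,
                 jitter = 0.35, psf_sigma_px = 1.2, tubule_intensity = 100,
                 background = 5, noise = "poisson_gauss", read_noise_sd = 2,
                 n_frames = 50L, d_um2_s = 0.05),
    segment = list(smooth_sigma_px = 1.2, low_pct = 0.5, high_pct = 99.5,
                   otsu_bins = 256L,
                   use_phase_congruency = FALSE,
                   pc = list(n_scales = 4L, n_orientations = 6L,
                             min_wavelength_px = 3),
                   opening_radius_px = 3L, ac_iterations = 50L,
                   min_cisterna_area_um2 = 0.25,
                   detect_cisternae = FALSE),
    track = list(min_junction_px = 3L, junction_grow_px = 2L,
                 blur_sigma_px = 2, min_distance_px = 5,
                 abs_threshold = NULL, max_link_px = 7, max_gap_px = 10,
                 max_frame_gap = 3L, min_frames = 10L, max_lag = 4L),
    kinetics = list(distances_um = c(8, 12, 16), roi_radius_px = 6,
                    bearing_deg = NULL, activation_center_px = NULL)
  )
}

#' Load a run configuration from YAML
#'
#' Entries present in the file override [default_config()]; everything
#' else keeps its default. Physical calibrations must be positive.
#'
#' @param path Path to a YAML file (may be `NULL` for pure defaults).
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- modify_list_deep(cfg, user)
  }
  stop_if_not_scalar_pos(cfg$pixel_size_um, "pixel_size_um")
  stop_if_not_scalar_pos(cfg$frame_interval_s, "frame_interval_s")
  cfg
}

modify_list_deep <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

config_provenance <- function(cfg) {
  ser <- jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null", digits = NA)
  list(config = cfg,
       config_hash = fnv1a_hash(as.character(ser)),
       seed = cfg$seed,
       package_version = as.character(packageVersion("ernetdyn")))
}

segment_frame <- function(frame, cfg) {
  sm <- cfg$segment$smooth_sigma_px %||% 0
  if (sm > 0) {
    frame <- image_frame(gaussian_smooth(frame$pixels, sm),
                         frame$pixel_size_um)
  }
  norm <- normalize_frame(frame, cfg$segment$low_pct, cfg$segment$high_pct)
  src <- norm
  if (isTRUE(cfg$segment$use_phase_congruency)) {
    src <- enhance_tubules(norm, cfg$segment$pc$n_scales,
                           cfg$segment$pc$n_orientations,
                           cfg$segment$pc$min_wavelength_px)
  }
  mask <- otsu_threshold(src, cfg$segment$otsu_bins)
  list(norm = norm, mask = mask)
}

#' Run the morphometry pipeline
#'
#' For every input frame: percentile normalization, optional
#' phase-congruency enhancement, Otsu segmentation, optional cisterna
#' detection, skeletonization, pixel classification, polygonal-region
#' and branch extraction. Writes per-image JSON reports, a per-polygon
#' CSV and an RGB skeleton overlay PNG into `config$out_dir` (when
#' set), plus a group summary (mean +/- SD over images).
#'
#' @param config Configuration list ([default_config()] /
#'   [load_config()]). Inputs are `config$inputs` (TIFF paths) or, when
#'   `NULL`, one synthetic frame rendered from `config$synth`.
#' @param frames Optional list of [image_frame()] objects overriding
#'   file inputs.
#' @return List with `reports` (per image [morphometry_report()]),
#'   `summary` (data frame of group means and SDs) and `provenance`.
#' @export
run_morphometry <- function(config = default_config(), frames = NULL) {
  prov <- config_provenance(config)
  if (is.null(frames)) {
    if (!is.null(config$inputs)) {
      if (length(config$inputs) == 0L) stop("no input images", call. = FALSE)
      frames <- lapply(config$inputs, read_frames,
                       pixel_size_um = config$pixel_size_um)
      names(frames) <- basename(unlist(config$inputs))
    } else {
      net <- generate_network(config$synth$width_px, config$synth$height_px,
                              config$synth$n_seed_points, config$synth$jitter,
                              config$pixel_size_um, config$seed)
      frames <- list(synthetic = render_network(
        net, config$synth$psf_sigma_px, config$synth$tubule_intensity,
        NULL, config$synth$background, config$synth$noise,
        config$synth$read_noise_sd, config$seed))
    }
  }
  if (is.null(names(frames))) {
    names(frames) <- sprintf("frame_%03d", seq_along(frames))
  }
  reports <- list()
  failures <- character(0L)
  for (nm in names(frames)) {
    res <- tryCatch({
      seg <- segment_frame(frames[[nm]], config)
      cis <- if (isTRUE(config$segment$detect_cisternae)) {
        detect_cisternae(seg$norm, seg$mask, config$segment$opening_radius_px,
                         config$segment$ac_iterations,
                         config$segment$min_cisterna_area_um2)
      } else list()
      skel <- skeletonize_mask(seg$mask)
      labels <- classify_pixels(skel)
      polys <- extract_polygons(skel, cis, config$pixel_size_um)
      bl <- branch_lengths(skel, labels, config$pixel_size_um)
      morphometry_report(labels, polys, bl, provenance = c(
        list(file = nm, threshold = seg$mask$threshold_used), prov["config_hash"]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, nm)
      warning(sprintf("morphometry failed for %s: %s", nm,
                      conditionMessage(res)))
    } else {
      reports[[nm]] <- res
      if (!is.null(config$out_dir)) {
        write_morphometry(res, frames[[nm]], config$out_dir, nm)
      }
    }
  }
  summary_df <- summarize_morphometry(reports)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(prov, file.path(config$out_dir, "run_provenance.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    write.csv(summary_df, file.path(config$out_dir, "group_summary.csv"),
              row.names = FALSE)
  }
  list(reports = reports, summary = summary_df, failures = failures,
       provenance = prov)
}

summarize_morphometry <- function(reports) {
  if (length(reports) == 0L) {
    return(data.frame(metric = character(0L), mean = numeric(0L),
                      sd = numeric(0L), n = integer(0L)))
  }
  metric <- function(name, vals) {
    data.frame(metric = name, mean = mean(vals),
               sd = if (length(vals) > 1L) sd(vals) else NA_real_,
               n = length(reports))
  }
  jt <- vapply(reports, `[[`, numeric(1L), "junction_tubule_ratio")
  pa <- vapply(reports, function(r) mean(r$polygon_areas_um2), numeric(1L))
  np <- vapply(reports, function(r) length(r$polygon_areas_um2), numeric(1L))
  bl <- vapply(reports, function(r) mean(r$branch_lengths_um), numeric(1L))
  nj <- vapply(reports, function(r) as.numeric(r$n_junctions), numeric(1L))
  rbind(metric("junction_tubule_ratio", jt),
        metric("mean_polygon_area_um2", pa),
        metric("n_polygons", np),
        metric("mean_branch_length_um", bl),
        metric("n_junctions", nj))
}

write_morphometry <- function(report, frame, out_dir, name) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(out_dir, gsub("[^A-Za-z0-9_.-]", "_", name))
  jsonlite::write_json(
    report[c("junction_tubule_ratio", "n_junctions", "n_endpoints",
             "polygon_areas_um2", "branch_lengths_um", "provenance")],
    paste0(base, "_morphometry.json"), auto_unbox = TRUE, null = "null",
    digits = NA)
  polys <- data.frame(id = seq_along(report$polygon_areas_um2),
                      area_um2 = report$polygon_areas_um2,
                      circularity = report$polygon_circularity,
                      elongation = report$polygon_elongation)
  write.csv(polys, paste0(base, "_polygons.csv"), row.names = FALSE)
}

#' Write an RGB overlay of the skeleton on the source frame
#'
#' Skeleton pixels in purple, cisternae in white, over the (green)
#' intensity image; a quick visual QC artifact.
#'
#' @param frame Source [image_frame()].
#' @param skel [skeletonize_mask()] result.
#' @param cisternae Optional cisterna list.
#' @param path Output PNG path.
#' @return Invisibly, the path.
#' @export
write_overlay_png <- function(frame, skel, cisternae = NULL, path) {
  img <- frame$pixels / max(frame$pixels, 1e-12)
  h <- nrow(img); w <- ncol(img)
  rgb <- array(0, c(h, w, 3L))
  rgb[, , 2L] <- img
  sk <- skel$pixels
  rgb[, , 1L][sk] <- 1; rgb[, , 3L][sk] <- 1; rgb[, , 2L][sk] <- 0
  if (!is.null(cisternae)) {
    for (cis in cisternae) {
      idx <- cbind(cis$pixels[, 2L] + 1L, cis$pixels[, 1L] + 1L)
      for (ch in 1:3) rgb[, , ch][idx] <- 1
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Run the dynamics (junction-tracking) pipeline
#'
#' Per frame: segmentation, skeletonization, classification, junction
#' spot image, spot detection; then LAP linking, gap closing, track
#' filtering, velocity statistics and diffusion estimation. Writes
#' track and velocity-CDF CSVs plus a JSON run report when
#' `config$out_dir` is set.
#'
#' @param config Configuration list.
#' @param tl Optional [time_lapse()] overriding file input; when both
#'   are absent a Brownian synthetic stack is simulated from
#'   `config$synth`.
#' @return List with `tracks`, `velocities` ([velocity_stats()]),
#'   `diffusion` ([estimate_diffusion()]), `spots_by_frame`, `truth`
#'   (for synthetic runs) and `provenance`.
#' @export
run_dynamics <- function(config = default_config(), tl = NULL) {
  prov <- config_provenance(config)
  truth <- NULL
  if (is.null(tl)) {
    if (!is.null(config$inputs)) {
      tl <- read_frames(config$inputs[[1L]], config$pixel_size_um,
                        config$frame_interval_s)
    } else {
      net <- generate_network(config$synth$width_px, config$synth$height_px,
                              config$synth$n_seed_points, config$synth$jitter,
                              config$pixel_size_um, config$seed)
      sim <- simulate_dynamics(net, config$synth$d_um2_s,
                               config$frame_interval_s,
                               config$synth$n_frames,
                               config$synth$psf_sigma_px,
                               config$synth$tubule_intensity,
                               config$synth$background, config$synth$noise,
                               config$synth$read_noise_sd, config$seed)
      tl <- sim$timelapse
      truth <- sim$truth
    }
  }
  if (!inherits(tl, "TimeLapse") || length(tl$frames) < 2L) {
    stop("dynamics input must be a time lapse with at least 2 frames",
         call. = FALSE)
  }
  tcfg <- config$track
  spots_by_frame <- lapply(tl$frames, function(frame) {
    seg <- segment_frame(frame, config)
    skel <- skeletonize_mask(seg$mask)
    labels <- classify_pixels(skel)
    spot_img <- make_spot_image(labels, frame, tcfg$min_junction_px,
                                tcfg$blur_sigma_px, mask = seg$mask,
                                grow_radius_px = tcfg$junction_grow_px)
    thr <- tcfg$abs_threshold %||% (0.1 * max(spot_img$pixels))
    detect_spots(spot_img, tcfg$min_distance_px, thr)
  })
  tracklets <- link_spots(spots_by_frame, tcfg$max_link_px)
  tracks <- close_gaps(tracklets, tcfg$max_gap_px, tcfg$max_frame_gap)
  tracks <- filter_tracks(tracks, tcfg$min_frames)
  vel <- velocity_stats(tracks, config$pixel_size_um, config$frame_interval_s)
  diff_est <- estimate_diffusion(tracks, config$pixel_size_um,
                                 config$frame_interval_s, tcfg$max_lag)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tracks_to_df(tracks, config$pixel_size_um),
              file.path(config$out_dir, "tracks.csv"), row.names = FALSE)
    write.csv(vel$cdf, file.path(config$out_dir, "velocity_cdf.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      c(prov, list(D_um2_s = diff_est$D, fit_r2 = diff_est$fit_r2,
                   n_tracks = diff_est$n_tracks,
                   n_velocities = length(vel$instantaneous_velocities))),
      file.path(config$out_dir, "dynamics_report.json"),
      auto_unbox = TRUE, null = "null", digits = NA)
  }
  list(tracks = tracks, velocities = vel, diffusion = diff_est,
       spots_by_frame = spots_by_frame, truth = truth, provenance = prov)
}

#' Flatten tracks to a tidy data frame
#'
#' @param tracks List of `Track` objects.
#' @param pixel_size_um Pixel size for the um columns.
#' @return Data frame (track_id, frame, x_px, y_px, x_um, y_um,
#'   intensity).
#' @export
tracks_to_df <- function(tracks, pixel_size_um) {
  if (length(tracks) == 0L) {
    return(data.frame(track_id = integer(0L), frame = integer(0L),
                      x_px = numeric(0L), y_px = numeric(0L),
                      x_um = numeric(0L), y_um = numeric(0L),
                      intensity = numeric(0L)))
  }
  do.call(rbind, lapply(seq_along(tracks), function(i) {
    s <- tracks[[i]]$spots
    data.frame(track_id = i, frame = s$frame, x_px = s$x, y_px = s$y,
               x_um = s$x * pixel_size_um, y_um = s$y * pixel_size_um,
               intensity = s$intensity)
  }))
}

#' Synthesize ground-truthed stacks to disk
#'
#' Renders a network (static frame) or Brownian time lapse from
#' `config$synth`, writing a multi-page float TIFF plus a JSON sidecar
#' holding the full ground truth (node positions, edges, tracks, D,
#' pixel size, intensity scale, seed).
#'
#' @param config Configuration list; `config$out_dir` is required.
#' @return Invisibly, a list with the written `tiff` and `json` paths
#'   and the `truth` object.
#' @export
run_synth <- function(config = default_config()) {
  if (is.null(config$out_dir)) stop("`out_dir` is required", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- config_provenance(config)
  net <- generate_network(config$synth$width_px, config$synth$height_px,
                          config$synth$n_seed_points, config$synth$jitter,
                          config$pixel_size_um, config$seed)
  sim <- simulate_dynamics(net, config$synth$d_um2_s,
                           config$frame_interval_s, config$synth$n_frames,
                           config$synth$psf_sigma_px,
                           config$synth$tubule_intensity,
                           config$synth$background, config$synth$noise,
                           config$synth$read_noise_sd, config$seed)
  tiff_path <- file.path(config$out_dir, "synthetic_stack.tif")
  scale <- write_frames(sim$timelapse, tiff_path)
  truth <- sim$truth
  json_path <- file.path(config$out_dir, "ground_truth.json")
  jsonlite::write_json(list(
    node_positions = truth$node_positions,
    edges = truth$edges,
    node_degrees = truth$node_degrees,
    interior = truth$interior,
    polygon_cells_um2 = truth$polygon_cells,
    true_tracks = truth$true_tracks,
    track_node_ids = truth$track_node_ids,
    true_diffusion_um2_s = truth$true_diffusion_um2_s,
    pixel_size_um = truth$pixel_size_um,
    frame_interval_s = config$frame_interval_s,
    intensity_scale = scale,
    seed = truth$seed,
    coordinate_convention = "0-based, x right, y down, pixel centers at integers",
    provenance = prov[c("config_hash", "package_version")]
  ), json_path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(list(tiff = tiff_path, json = json_path, truth = truth))
}

#' Run the kinetics pipeline
#'
#' Reads (or takes) a photoactivation time lapse and computes the
#' fixed-distance radial traces; writes a tidy CSV (trace_id, time_s,
#' raw, normalized) when `config$out_dir` is set.
#'
#' @param config Configuration list; `config$kinetics` supplies the
#'   activation center, distances, ROI radius and bearing.
#' @param tl Optional [time_lapse()] overriding file input.
#' @return List with `traces` (named list of [kinetic_trace()]),
#'   `half_rise_s` (named vector) and `provenance`.
#' @export
run_kinetics <- function(config = default_config(), tl = NULL) {
  prov <- config_provenance(config)
  if (is.null(tl)) {
    if (is.null(config$inputs)) stop("kinetics needs an input stack",
                                     call. = FALSE)
    tl <- read_frames(config$inputs[[1L]], config$pixel_size_um,
                      config$frame_interval_s)
  }
  kc <- config$kinetics
  d <- dim(tl$frames[[1L]]$pixels)
  center <- kc$activation_center_px %||% c((d[2L] - 1) / 2, (d[1L] - 1) / 2)
  traces <- radial_traces(tl, center, kc$distances_um, kc$roi_radius_px,
                          kc$bearing_deg)
  hr <- vapply(traces, half_rise_time, numeric(1L))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    tidy <- do.call(rbind, lapply(names(traces), function(nm) {
      tr <- traces[[nm]]
      data.frame(trace_id = nm, time_s = tr$times_s, raw = tr$raw,
                 normalized = tr$normalized)
    }))
    write.csv(tidy, file.path(config$out_dir, "kinetic_traces.csv"),
              row.names = FALSE)
    jsonlite::write_json(c(prov, list(half_rise_s = as.list(hr))),
                         file.path(config$out_dir, "kinetics_report.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  list(traces = traces, half_rise_s = hr, provenance = prov)
}
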