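# Synthetic kinetic read-outs: saturating transport traces (the shape of
# biotin-synchronized cargo-release time courses) and a diffusive
# photoactivation spread for fixed-distance ROI measurements.

#' Construct a kinetic trace object
#'
#' @param times_s Strictly increasing numeric vector of times (s).
#' @param raw Raw intensities (a.u.), finite, same length as `times_s`.
#' @param normalized Optional normalized values.
#' @param roi_descriptor,background_descriptor Optional ROI descriptions
#'   carried for provenance.
#' @return An object of class `KineticTrace`.
#' @export
kinetic_trace <- function(times_s, raw, normalized = NULL,
                          roi_descriptor = NULL, background_descriptor = NULL) {
  stopifnot(is.numeric(times_s), is.numeric(raw),
            length(times_s) == length(raw))
  if (any(diff(times_s) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(raw))) stop("raw intensities must be finite", call. = FALSE)
  structure(list(times_s = as.double(times_s), raw = as.double(raw),
                 normalized = normalized, roi_descriptor = roi_descriptor,
                 background_descriptor = background_descriptor),
            class = "KineticTrace")
}

#' @export
print.KineticTrace <- function(x, ...) {
  cat(sprintf("<KineticTrace> %d points over %.4g s%s\n", length(x$times_s),
              diff(range(x$times_s)),
              if (!is.null(x$normalized)) ", normalized" else ""))
  invisible(x)
}

#' Simulate a saturating transport trace
#'
#' Noiseless mean is 0 before `t0_s` and `1 - exp(-k (t - t0))` after,
#' the canonical shape of a synchronized-release trafficking read-out;
#' Gaussian noise of SD `noise_sd` is added.
#'
#' @param t0_s Release time (s).
#' @param rate_k_per_s Rate constant k (1/s, > 0).
#' @param n_points Number of samples (>= 3).
#' @param frame_interval_s Sampling interval (s).
#' @param noise_sd Gaussian noise SD (0 for noiseless).
#' @param seed Integer seed for the noise draw.
#' @return A [kinetic_trace()] sampled at `0, dt, ..., (n_points-1) dt`.
#' @export
simulate_transport_trace <- function(t0_s, rate_k_per_s, n_points,
                                     frame_interval_s, noise_sd = 0,
                                     seed = 1L) {
  stop_if_not_scalar_pos(rate_k_per_s, "rate_k_per_s")
  stopifnot(n_points >= 3, noise_sd >= 0)
  stop_if_not_scalar_pos(frame_interval_s, "frame_interval_s")
  t <- (seq_len(n_points) - 1L) * frame_interval_s
  mu <- ifelse(t < t0_s, 0, 1 - exp(-rate_k_per_s * (t - t0_s)))
  if (noise_sd > 0) {
    set.seed(child_seed(seed, "transport_trace"))
    mu <- mu + rnorm(n_points, sd = noise_sd)
  }
  kinetic_trace(t, mu)
}

#' Simulate photoactivated marker spread by 2-D diffusion
#'
#' A disc of activated marker placed at `center_px` spreads by isotropic
#' diffusion: each frame applies a Gaussian transition kernel of
#' standard deviation `sqrt(2 D dt)` with reflective (zero-flux)
#' boundaries, so total signal is conserved and far ROIs rise later
#' than near ones
#' (the diffusive-front ordering used to validate fixed-distance ROI
#' read-outs).
#'
#' @param width_px,height_px Field size (pixels).
#' @param D_um2_s Luminal diffusion coefficient (um^2/s).
#' @param pixel_size_um Pixel size (um/px).
#' @param frame_interval_s Frame interval (s); the matching acquisition
#'   default is 0.5 s.
#' @param n_frames Number of frames.
#' @param center_px Activation center, 0-based (x, y); default the image
#'   center.
#' @param init_radius_px Radius of the initially activated disc.
#' @param amplitude Initial intensity inside the activated disc.
#' @param noise_sd Additive Gaussian noise SD per frame (counts).
#' @param seed Integer seed for the noise draw.
#' @return A [time_lapse()].
#' @export
simulate_photoactivation <- function(width_px, height_px, D_um2_s,
                                     pixel_size_um = 0.1,
                                     frame_interval_s = 0.5, n_frames = 180,
                                     center_px = NULL, init_radius_px = 8,
                                     amplitude = 100, noise_sd = 0,
                                     seed = 1L) {
  stopifnot(width_px >= 16, height_px >= 16, D_um2_s > 0, n_frames >= 2)
  center_px <- center_px %||% c((width_px - 1) / 2, (height_px - 1) / 2)
  m <- matrix(0, height_px, width_px)
  m <- draw_pixels(m, disc_pixels(center_px[1L], center_px[2L],
                                  init_radius_px), amplitude)
  sigma_step <- sqrt(2 * D_um2_s * frame_interval_s) / pixel_size_um
  set.seed(child_seed(seed, "photoactivation_noise"))
  frames <- vector("list", n_frames)
  cur <- m
  for (f in seq_len(n_frames)) {
    if (f > 1L) cur <- gaussian_smooth(cur, sigma_step, boundary = "reflect")
    obs <- cur
    if (noise_sd > 0) {
      obs <- pmax(obs + matrix(rnorm(length(obs), sd = noise_sd),
                               nrow(obs), ncol(obs)), 0)
    }
    frames[[f]] <- image_frame(obs, pixel_size_um)
  }
  time_lapse(frames, frame_interval_s)
}
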