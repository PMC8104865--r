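# Brownian junction dynamics on a synthetic network. Each interior
# (three-way) vertex performs independent 2-D Brownian motion; edges are
# redrawn to the moved endpoints every frame, and the continuous vertex
# trajectories are recorded as ground-truth tracks.

#' Simulate Brownian junction motion on a synthetic network
#'
#' Every interior (degree-3) vertex of `net` performs independent 2-D
#' Brownian motion with per-axis step variance `2 * D * dt` (converted
#' to pixels); border vertices stay fixed. Edges are redrawn to the
#' moved endpoints each frame. The continuous trajectories are recorded
#' in `true_tracks` (pixel coordinates), providing the oracle for
#' tracking and diffusion estimation.
#'
#' @param net A [generate_network()] result.
#' @param D_um2_s Diffusion coefficient in um^2/s (>= 0).
#' @param frame_interval_s Frame interval in seconds.
#' @param n_frames Number of frames (>= 11, so that tracks longer than
#'   10 frames exist).
#' @param psf_sigma_px,tubule_intensity,background,noise,read_noise_sd
#'   Rendering parameters, as in [render_network()].
#' @param seed Integer seed; motion and noise derive child seeds from it.
#' @param render If `FALSE`, skip image rendering and return only the
#'   ground truth (fast path for statistical checks on true tracks).
#' @return A list with `timelapse` (a [time_lapse()], or `NULL` when
#'   `render = FALSE`) and `truth` (the input network with
#'   `true_tracks`, `true_diffusion_um2_s`, `frame_interval_s` and
#'   `track_node_ids` filled in). `true_tracks` is a list of
#'   `n_frames x 2` matrices of (x, y) pixel positions.
#' @export
simulate_dynamics <- function(net, D_um2_s, frame_interval_s, n_frames,
                              psf_sigma_px = 1.2, tubule_intensity = 100,
                              background = 5,
                              noise = c("none", "poisson_gauss"),
                              read_noise_sd = 2, seed = 1L, render = TRUE) {
  noise <- match.arg(noise)
  stopifnot(D_um2_s >= 0, n_frames >= 11)
  stop_if_not_scalar_pos(frame_interval_s, "frame_interval_s")
  step_sd_px <- sqrt(2 * D_um2_s * frame_interval_s) / net$pixel_size_um
  moving <- which(net$interior)
  n_mov <- length(moving)
  if (n_mov == 0L) stop("network has no interior vertices to move", call. = FALSE)
  if (nrow(net$edges) > 0L) {
    elen <- sqrt(rowSums((net$node_positions[net$edges[, 1L], , drop = FALSE] -
                          net$node_positions[net$edges[, 2L], , drop = FALSE])^2))
    if (step_sd_px > mean(elen) / 4) {
      warning("Brownian step SD exceeds 1/4 of the mean edge length; ",
              "network self-intersection is likely")
    }
  }
  set.seed(child_seed(seed, "brownian"))
  # cumulative per-axis increments, frames x nodes
  dxs <- matrix(rnorm((n_frames - 1L) * n_mov, sd = step_sd_px),
                n_frames - 1L, n_mov)
  dys <- matrix(rnorm((n_frames - 1L) * n_mov, sd = step_sd_px),
                n_frames - 1L, n_mov)
  x0 <- net$node_positions[moving, 1L]
  y0 <- net$node_positions[moving, 2L]
  xs <- rbind(x0, sweep(apply(dxs, 2L, cumsum), 2L, x0, "+"))
  ys <- rbind(y0, sweep(apply(dys, 2L, cumsum), 2L, y0, "+"))
  dimnames(xs) <- dimnames(ys) <- NULL
  true_tracks <- lapply(seq_len(n_mov), function(k) {
    cbind(x = xs[, k], y = ys[, k])
  })
  truth <- net
  truth$true_tracks <- true_tracks
  truth$track_node_ids <- moving
  truth$true_diffusion_um2_s <- D_um2_s
  truth$frame_interval_s <- frame_interval_s

  tl <- NULL
  if (render) {
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      pos <- net$node_positions
      pos[moving, 1L] <- xs[f, ]
      pos[moving, 2L] <- ys[f, ]
      m <- draw_network(net, pos, tubule_intensity, background)
      m <- gaussian_smooth(m, psf_sigma_px)
      if (noise == "poisson_gauss") {
        set.seed(child_seed(seed, paste0("frame_noise_", f)))
        m <- add_poisson_gauss(m, read_noise_sd)
      }
      frames[[f]] <- image_frame(m, net$pixel_size_um)
    }
    tl <- time_lapse(frames, frame_interval_s)
  }
  list(timelapse = tl, truth = truth)
}
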