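# Junction tracking: spot-image construction, sub-pixel spot detection,
# LAP frame-to-frame linking, gap closing, track filtering, velocity
# statistics and MSD-based diffusion estimation.

#' Build a junction spot image
#'
#' Junction-labeled connected components with more than `min_junction_px`
#' pixels are kept, masked against the raw frame intensity, and
#' Gaussian-blurred into trackable bright spots. Optionally the junction
#' pixels are first grown into the binary network mask
#' (`grow_radius_px` > 0 with `mask` supplied), which recovers
#' tubule-width junction objects from a single-pixel skeleton.
#'
#' @param labels A [classify_pixels()] result.
#' @param frame The matching raw [image_frame()].
#' @param min_junction_px Components must exceed this pixel count
#'   (default 3: strictly larger than three pixels).
#' @param blur_sigma_px Gaussian blur SD in pixels.
#' @param mask Optional `BinaryMask` used when growing junction pixels.
#' @param grow_radius_px Dilation radius for junction growth (default 0:
#'   use raw junction-labeled pixels).
#' @return An [image_frame()]; all-zero (with a warning) when no
#'   component survives the size filter.
#' @export
make_spot_image <- function(labels, frame, min_junction_px = 3L,
                            blur_sigma_px = 2, mask = NULL,
                            grow_radius_px = 0L) {
  stopifnot(inherits(labels, "SkeletonLabels"), inherits(frame, "ImageFrame"),
            min_junction_px >= 1L)
  if (!identical(dim(labels$label_map), dim(frame$pixels))) {
    stop("labels and frame must share the same shape", call. = FALSE)
  }
  jmask <- labels$label_map == 3L
  if (grow_radius_px > 0L) {
    grown <- binary_dilation(jmask, grow_radius_px)
    jmask <- if (!is.null(mask)) grown & mask$pixels else grown
  }
  lab <- label_components(jmask, 8L)
  keep <- matrix(FALSE, nrow(jmask), ncol(jmask))
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep_ids <- which(sizes > min_junction_px)
    keep <- matrix(lab %in% keep_ids, nrow(lab), ncol(lab))
  }
  if (!any(keep)) {
    warning("no junction components survive the size filter")
    return(image_frame(matrix(0, nrow(jmask), ncol(jmask)),
                       frame$pixel_size_um))
  }
  spot <- frame$pixels * keep
  spot <- gaussian_smooth(spot, blur_sigma_px)
  image_frame(spot, frame$pixel_size_um)
}

#' Detect spots as local intensity maxima
#'
#' Local maxima above `abs_threshold`, separated by at least
#' `min_distance_px` (brightest first), with sub-pixel position from the
#' intensity-weighted centroid of the 3x3 window.
#'
#' @param spot_image An [image_frame()] (non-negative).
#' @param min_distance_px Minimum separation between accepted spots.
#' @param abs_threshold Absolute intensity threshold.
#' @return Data frame with columns `x`, `y` (0-based sub-pixel) and
#'   `intensity` (peak value); empty when nothing exceeds the threshold.
#' @export
detect_spots <- function(spot_image, min_distance_px = 5, abs_threshold = 0) {
  stopifnot(inherits(spot_image, "ImageFrame"), min_distance_px >= 0)
  m <- spot_image$pixels
  h <- nrow(m); w <- ncol(m)
  p <- matrix(-Inf, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  is_max <- matrix(TRUE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    is_max <- is_max & m >= p[(2L + dy):(h + 1L + dy), (2L + dx):(w + 1L + dx)]
  }
  cand <- which(is_max & m > abs_threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(data.frame(x = numeric(0L), y = numeric(0L),
                      intensity = numeric(0L)))
  }
  vals <- m[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  kept <- matrix(numeric(0L), 0L, 2L)
  keep_idx <- integer(0L)
  for (i in seq_len(nrow(cand))) {
    pt <- cand[i, ]
    if (nrow(kept) > 0L &&
        min(sqrt((kept[, 1L] - pt[1L])^2 + (kept[, 2L] - pt[2L])^2)) <
        min_distance_px) next
    kept <- rbind(kept, pt)
    keep_idx <- c(keep_idx, i)
  }
  out <- data.frame(x = numeric(length(keep_idx)),
                    y = numeric(length(keep_idx)),
                    intensity = vals[keep_idx])
  for (k in seq_along(keep_idx)) {
    r <- cand[keep_idx[k], 1L]; c0 <- cand[keep_idx[k], 2L]
    rr <- max(1L, r - 1L):min(h, r + 1L)
    cc <- max(1L, c0 - 1L):min(w, c0 + 1L)
    win <- m[rr, cc, drop = FALSE]
    tot <- sum(win)
    if (tot > 0) {
      out$x[k] <- sum(rep(cc - 1L, each = length(rr)) * win) / tot
      out$y[k] <- sum(rep(rr - 1L, times = length(cc)) * win) / tot
    } else {
      out$x[k] <- c0 - 1L; out$y[k] <- r - 1L
    }
  }
  out
}

#' Link spots across consecutive frames (LAP)
#'
#' For every consecutive frame pair, solves the linear assignment
#' problem with cost the squared distance, links beyond `max_link_px`
#' forbidden, and per-spot birth/death alternatives at cost
#' `max_link_px^2`; the frame-pair solution is globally cost-minimal.
#'
#' @param spots_by_frame List of per-frame data frames as returned by
#'   [detect_spots()]; list index 1 is frame 0.
#' @param max_link_px Maximum linking distance in pixels (default 7).
#' @return List of tracklets, each a data frame with columns `frame`
#'   (0-based), `x`, `y`, `intensity`.
#' @export
link_spots <- function(spots_by_frame, max_link_px = 7) {
  stopifnot(is.list(spots_by_frame), max_link_px > 0)
  n_frames <- length(spots_by_frame)
  active <- list()    # open tracklets: last spot in previous frame
  done <- list()
  mk <- function(df, f, i) {
    data.frame(frame = f, x = df$x[i], y = df$y[i],
               intensity = df$intensity[i])
  }
  prev <- spots_by_frame[[1L]]
  active <- lapply(seq_len(nrow(prev)), function(i) mk(prev, 0L, i))
  for (f in seq_len(n_frames - 1L)) {
    cur <- spots_by_frame[[f + 1L]]
    n <- length(active); m <- nrow(cur)
    links <- matrix(integer(0L), 0L, 2L)
    if (n > 0L && m > 0L) {
      ends <- do.call(rbind, lapply(active, function(tr) {
        as.numeric(tr[nrow(tr), c("x", "y")])
      }))
      d <- cross_dist(ends, cbind(cur$x, cur$y))
      cost <- d^2
      cost[d > max_link_px] <- Inf
      links <- solve_linking(cost, max_link_px^2)$links
    }
    new_active <- list()
    linked_targets <- integer(0L)
    if (nrow(links) > 0L) {
      for (r in seq_len(nrow(links))) {
        i <- links[r, 1L]; j <- links[r, 2L]
        new_active[[length(new_active) + 1L]] <-
          rbind(active[[i]], mk(cur, f, j))
        linked_targets <- c(linked_targets, j)
      }
    }
    dead <- setdiff(seq_len(n), if (nrow(links) > 0L) links[, 1L] else integer(0L))
    for (i in dead) done[[length(done) + 1L]] <- active[[i]]
    for (j in setdiff(seq_len(max(m, 0L)), linked_targets)) {
      new_active[[length(new_active) + 1L]] <- mk(cur, f, j)
    }
    active <- new_active
  }
  c(done, active)
}

#' Close gaps between tracklets (second LAP stage)
#'
#' Tracklet-end to tracklet-start pairs within `max_gap_px` and with 1
#' to `max_frame_gap` skipped frames are merged by a second globally
#' cost-minimal assignment (cost = squared distance, alternative cost
#' `max_gap_px^2`); chains of merges are followed, and no tracklet is
#' used twice.
#'
#' @param tracklets List of tracklets from [link_spots()].
#' @param max_gap_px Maximum closing distance in pixels (default 10).
#' @param max_frame_gap Maximum number of skipped frames (default 3).
#' @return List of `Track` objects: data frame `spots` plus `gaps`, a
#'   list of skipped-frame runs.
#' @export
close_gaps <- function(tracklets, max_gap_px = 10, max_frame_gap = 3L) {
  stopifnot(max_gap_px > 0, max_frame_gap >= 0)
  k <- length(tracklets)
  if (k == 0L) return(list())
  ends <- do.call(rbind, lapply(tracklets, function(tr) {
    as.numeric(tr[nrow(tr), c("frame", "x", "y")])
  }))
  starts <- do.call(rbind, lapply(tracklets, function(tr) {
    as.numeric(tr[1L, c("frame", "x", "y")])
  }))
  dfr <- outer(starts[, 1L], ends[, 1L], "-")       # start_frame - end_frame
  d <- cross_dist(ends[, 2:3, drop = FALSE], starts[, 2:3, drop = FALSE])
  cost <- d^2
  skipped <- t(dfr) - 1                              # rows = ends, cols = starts
  cost[d > max_gap_px | skipped < 1 | skipped > max_frame_gap] <- Inf
  diag(cost) <- Inf                                  # no self-merge
  links <- solve_linking(cost, max_gap_px^2)$links
  succ <- rep(NA_integer_, k)
  has_pred <- logical(k)
  if (nrow(links) > 0L) {
    succ[links[, 1L]] <- links[, 2L]
    has_pred[links[, 2L]] <- TRUE
  }
  out <- list()
  for (i in which(!has_pred)) {
    spots <- tracklets[[i]]
    gaps <- list()
    j <- i
    while (!is.na(succ[j])) {
      nxt <- succ[j]
      gap_run <- seq.int(spots$frame[nrow(spots)] + 1L,
                         tracklets[[nxt]]$frame[1L] - 1L)
      gaps[[length(gaps) + 1L]] <- gap_run
      spots <- rbind(spots, tracklets[[nxt]])
      j <- nxt
    }
    out[[length(out) + 1L]] <- structure(list(spots = spots, gaps = gaps),
                                         class = "Track")
  }
  out
}

#' @export
print.Track <- function(x, ...) {
  cat(sprintf("<Track> frames %d-%d, %d spots, %d gaps\n",
              x$spots$frame[1L], x$spots$frame[nrow(x$spots)],
              nrow(x$spots), length(x$gaps)))
  invisible(x)
}

#' Keep only tracks longer than `min_frames` frames
#'
#' A track of exactly `min_frames` frames is removed ("longer than" is
#' strict). By default length is the number of frames with a detection
#' (`measure = "spots"`), which also discards sparse chains glued
#' together by gap closing; `measure = "span"` counts first-to-last
#' frame span instead. The two agree on gapless tracks.
#'
#' @param tracks List of `Track` objects.
#' @param min_frames Minimum length in frames (default 10).
#' @param measure `"spots"` (default) or `"span"`.
#' @return Filtered list.
#' @export
filter_tracks <- function(tracks, min_frames = 10L,
                          measure = c("spots", "span")) {
  stopifnot(min_frames >= 1L)
  measure <- match.arg(measure)
  Filter(function(tr) {
    len <- if (measure == "spots") nrow(tr$spots)
           else tr$spots$frame[nrow(tr$spots)] - tr$spots$frame[1L] + 1L
    len > min_frames
  }, tracks)
}

#' Instantaneous velocities and their cumulative distribution
#'
#' One speed per consecutive spot pair: displacement times pixel size
#' over elapsed time (gap-spanning pairs use their true frame
#' difference).
#'
#' @param tracks List of `Track` objects (at least one pair of spots).
#' @param pixel_size_um Pixel size (um/px).
#' @param frame_interval_s Frame interval (s).
#' @return An object of class `VelocityStats`: list with
#'   `instantaneous_velocities` (um/s) and `cdf` (data frame `velocity`,
#'   `fraction`).
#' @export
velocity_stats <- function(tracks, pixel_size_um, frame_interval_s) {
  stop_if_not_scalar_pos(pixel_size_um, "pixel_size_um")
  stop_if_not_scalar_pos(frame_interval_s, "frame_interval_s")
  v <- unlist(lapply(tracks, function(tr) {
    s <- tr$spots
    if (nrow(s) < 2L) return(numeric(0L))
    dx <- diff(s$x); dy <- diff(s$y); df <- diff(s$frame)
    sqrt(dx^2 + dy^2) * pixel_size_um / (df * frame_interval_s)
  }))
  if (length(v) == 0L) {
    stop("no tracks with at least 2 spots", call. = FALSE)
  }
  sv <- sort(v)
  structure(list(
    instantaneous_velocities = v,
    cdf = data.frame(velocity = sv,
                     fraction = seq_along(sv) / length(sv))
  ), class = "VelocityStats")
}

#' @export
print.VelocityStats <- function(x, ...) {
  cat(sprintf("<VelocityStats> %d velocities, median %.4g um/s\n",
              length(x$instantaneous_velocities),
              median(x$instantaneous_velocities)))
  invisible(x)
}

#' Estimate the diffusion coefficient from tracks
#'
#' Ensemble-averaged mean squared displacement over lags `1..max_lag`,
#' fitted by weighted least squares (weights = pair counts). The
#' default fit includes a free intercept, which absorbs the constant
#' MSD offset produced by localization noise; `intercept = "zero"`
#' forces the line through the origin. `D = slope / 4` (2-D); a
#' negative slope is clipped to `D = 0` with `clipped = TRUE`.
#'
#' @param tracks List of `Track` objects.
#' @param pixel_size_um Pixel size (um/px).
#' @param frame_interval_s Frame interval (s).
#' @param max_lag Largest lag (frames) entering the fit (default 4).
#' @param intercept `"free"` (default) or `"zero"`.
#' @param min_tracks Minimum number of usable tracks (default 5).
#' @return An object of class `DiffusionEstimate`: list with `D`
#'   (um^2/s), `fit_lags`, `fit_r2`, `n_tracks`, `msd` (data frame),
#'   `clipped`.
#' @export
estimate_diffusion <- function(tracks, pixel_size_um, frame_interval_s,
                               max_lag = 4L, intercept = c("free", "zero"),
                               min_tracks = 5L) {
  intercept <- match.arg(intercept)
  stop_if_not_scalar_pos(pixel_size_um, "pixel_size_um")
  stop_if_not_scalar_pos(frame_interval_s, "frame_interval_s")
  stopifnot(max_lag >= 1L)
  usable <- Filter(function(tr) nrow(tr$spots) >= max_lag + 1L, tracks)
  if (length(usable) < min_tracks) {
    stop(sprintf("need at least %d tracks with >= %d spots", min_tracks,
                 max_lag + 1L), call. = FALSE)
  }
  sq <- vector("list", max_lag)
  for (tr in usable) {
    s <- tr$spots
    for (tau in seq_len(max_lag)) {
      # pairs at exact frame difference tau (gaps respected)
      f <- s$frame
      idx <- match(f + tau, f)
      ok <- !is.na(idx)
      if (!any(ok)) next
      d2 <- (s$x[idx[ok]] - s$x[ok])^2 + (s$y[idx[ok]] - s$y[ok])^2
      sq[[tau]] <- c(sq[[tau]], d2)
    }
  }
  n_pairs <- vapply(sq, length, integer(1L))
  lags <- which(n_pairs > 0L)
  msd_um2 <- vapply(lags, function(tau) mean(sq[[tau]]), numeric(1L)) *
    pixel_size_um^2
  t_s <- lags * frame_interval_s
  wts <- n_pairs[lags]
  if (length(lags) < 2L && intercept == "free") {
    intercept <- "zero"  # cannot fit two parameters to one point
  }
  if (intercept == "free") {
    fit <- lm(msd_um2 ~ t_s, weights = wts)
    slope <- coef(fit)[["t_s"]]
    r2 <- summary(fit)$r.squared
  } else {
    fit <- lm(msd_um2 ~ t_s + 0, weights = wts)
    slope <- coef(fit)[["t_s"]]
    sst <- sum(wts * msd_um2^2)
    r2 <- 1 - sum(wts * (msd_um2 - slope * t_s)^2) / sst
  }
  clipped <- slope < 0
  structure(list(
    D = max(slope, 0) / 4,
    fit_lags = lags,
    fit_r2 = r2,
    n_tracks = length(usable),
    msd = data.frame(lag = lags, t_s = t_s, msd_um2 = msd_um2,
                     n_pairs = wts),
    clipped = clipped,
    intercept = intercept
  ), class = "DiffusionEstimate")
}

#' @export
print.DiffusionEstimate <- function(x, ...) {
  cat(sprintf("<DiffusionEstimate> D = %.4g um^2/s (lags %s, R2 %.3f, %d tracks%s)\n",
              x$D, paste(range(x$fit_lags), collapse = "-"), x$fit_r2,
              x$n_tracks, if (x$clipped) ", clipped at 0" else ""))
  invisible(x)
}
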