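# Luminal-transport and secretory-trafficking trace quantification:
# ROI definitions, background-subtracted integrated traces, the two
# normalization modes (0-to-1 minmax and max), and fixed-distance
# photoactivation read-outs.

#' Define a disc or polygon region of interest
#'
#' @param x,y Center (disc) in 0-based pixel coordinates.
#' @param radius_px Disc radius in pixels.
#' @return An ROI descriptor (class `roi`).
#' @export
roi_disc <- function(x, y, radius_px) {
  stopifnot(is.finite(x), is.finite(y), radius_px > 0)
  structure(list(shape = "disc", center = c(x = x, y = y),
                 radius_px = radius_px), class = "roi")
}

#' @rdname roi_disc
#' @param xs,ys Polygon vertex coordinates (0-based pixels).
#' @export
roi_polygon <- function(xs, ys) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3L)
  structure(list(shape = "polygon", xs = as.double(xs), ys = as.double(ys)),
            class = "roi")
}

# 0-based (x, y) pixel coordinates covered by an ROI.
roi_pixels <- function(roi) {
  stopifnot(inherits(roi, "roi"))
  if (roi$shape == "disc") {
    disc_pixels(roi$center["x"], roi$center["y"], roi$radius_px)
  } else {
    xr <- seq.int(floor(min(roi$xs)), ceiling(max(roi$xs)))
    yr <- seq.int(floor(min(roi$ys)), ceiling(max(roi$ys)))
    g <- expand.grid(x = xr, y = yr)
    inside <- point_in_polygon(g$x, g$y, roi$xs, roi$ys)
    cbind(x = as.integer(g$x[inside]), y = as.integer(g$y[inside]))
  }
}

# Even-odd rule point-in-polygon test (vectorized over points).
point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (ys[i] > py) != (ys[j] > py)
    xint <- (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i]
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

roi_in_frame <- function(pix, h, w) {
  all(pix[, 1L] >= 0L & pix[, 1L] <= w - 1L &
        pix[, 2L] >= 0L & pix[, 2L] <= h - 1L)
}

#' Background-subtracted integrated ROI trace
#'
#' Per frame, the summed intensity inside `roi` minus the summed
#' intensity inside `background_roi` (which must cover the same number
#' of pixels). Times come from the time lapse's frame interval.
#'
#' @param tl A [time_lapse()].
#' @param roi ROI descriptor from [roi_disc()] or [roi_polygon()].
#' @param background_roi Optional background ROI of identical pixel
#'   count; `NULL` skips subtraction.
#' @return A [kinetic_trace()].
#' @export
integrated_roi_trace <- function(tl, roi, background_roi = NULL) {
  stopifnot(inherits(tl, "TimeLapse"))
  d <- dim(tl$frames[[1L]]$pixels)
  pix <- roi_pixels(roi)
  if (!roi_in_frame(pix, d[1L], d[2L])) {
    stop("ROI extends outside the frame", call. = FALSE)
  }
  bg_pix <- NULL
  if (!is.null(background_roi)) {
    bg_pix <- roi_pixels(background_roi)
    if (!roi_in_frame(bg_pix, d[1L], d[2L])) {
      stop("background ROI extends outside the frame", call. = FALSE)
    }
    if (nrow(bg_pix) != nrow(pix)) {
      stop(sprintf("ROI sizes differ: %d vs %d pixels (identical sizes required)",
                   nrow(pix), nrow(bg_pix)), call. = FALSE)
    }
  }
  idx <- cbind(pix[, 2L] + 1L, pix[, 1L] + 1L)
  bidx <- if (!is.null(bg_pix)) cbind(bg_pix[, 2L] + 1L, bg_pix[, 1L] + 1L)
  vals <- vapply(tl$frames, function(f) {
    v <- sum(f$pixels[idx])
    if (!is.null(bidx)) v <- v - sum(f$pixels[bidx])
    v
  }, numeric(1L))
  kinetic_trace((seq_along(tl$frames) - 1L) * tl$frame_interval_s, vals,
                roi_descriptor = roi, background_descriptor = background_roi)
}

#' Normalize a kinetic trace
#'
#' `minmax` maps the initial value to 0 and the maximum to 1
#' (`(v - v0) / (vmax - v0)`); `max` divides by the maximum
#' (`v / vmax`). Both are idempotent.
#'
#' @param trace A [kinetic_trace()].
#' @param mode `"minmax"` or `"max"`.
#' @return The trace with the `normalized` field filled in.
#' @export
normalize_trace <- function(trace, mode = c("minmax", "max")) {
  stopifnot(inherits(trace, "KineticTrace"))
  mode <- match.arg(mode)
  v <- trace$normalized %||% trace$raw
  if (mode == "minmax") {
    v0 <- v[1L]; vmax <- max(v)
    if (vmax == v0) {
      stop("cannot minmax-normalize a trace whose maximum equals its ",
           "initial value", call. = FALSE)
    }
    trace$normalized <- (v - v0) / (vmax - v0)
  } else {
    vmax <- max(v)
    if (vmax <= 0) {
      stop("cannot max-normalize a trace with non-positive maximum",
           call. = FALSE)
    }
    trace$normalized <- v / vmax
  }
  trace
}

#' Fixed-distance radial photoactivation traces
#'
#' One minmax-normalized ROI trace per distance from the activation
#' site, with ROIs placed along a bearing (default: toward the image
#' center). The canonical distances are 8, 12 and 16 um.
#'
#' @param tl A [time_lapse()].
#' @param activation_center_px Activation site, 0-based (x, y) pixels.
#' @param distances_um Radial distances in micrometres.
#' @param roi_radius_px ROI disc radius in pixels.
#' @param bearing_deg Bearing in degrees (0 = +x, counterclockwise...
#'   measured in image coordinates with y down); default points from
#'   the activation site toward the image center.
#' @return Named list of [kinetic_trace()] objects (`"8um"`, ...), each
#'   minmax-normalized.
#' @export
radial_traces <- function(tl, activation_center_px,
                          distances_um = c(8, 12, 16), roi_radius_px = 6,
                          bearing_deg = NULL) {
  stopifnot(inherits(tl, "TimeLapse"), length(activation_center_px) == 2L)
  d <- dim(tl$frames[[1L]]$pixels)
  px <- tl$frames[[1L]]$pixel_size_um
  if (is.null(bearing_deg)) {
    ctr <- c((d[2L] - 1) / 2, (d[1L] - 1) / 2)
    delta <- ctr - activation_center_px
    bearing_deg <- if (all(delta == 0)) 0 else atan2(delta[2L], delta[1L]) * 180 / pi
  }
  u <- c(cos(bearing_deg * pi / 180), sin(bearing_deg * pi / 180))
  out <- list()
  for (dist_um in distances_um) {
    ctr_px <- activation_center_px + u * dist_um / px
    roi <- roi_disc(ctr_px[1L], ctr_px[2L], roi_radius_px)
    if (!roi_in_frame(roi_pixels(roi), d[1L], d[2L])) {
      stop(sprintf("ROI at distance %g um falls outside the frame", dist_um),
           call. = FALSE)
    }
    tr <- integrated_roi_trace(tl, roi)
    out[[paste0(format(dist_um), "um")]] <- normalize_trace(tr, "minmax")
  }
  out
}

#' Half-rise time of a normalized trace
#'
#' First time the normalized value crosses 0.5, linearly interpolated.
#'
#' @param trace A normalized [kinetic_trace()].
#' @return Time in seconds (`NA` if the trace never crosses 0.5).
#' @export
half_rise_time <- function(trace) {
  stopifnot(inherits(trace, "KineticTrace"), !is.null(trace$normalized))
  v <- trace$normalized
  t <- trace$times_s
  above <- which(v >= 0.5)
  if (length(above) == 0L) return(NA_real_)
  i <- above[1L]
  if (i == 1L) return(t[1L])
  t[i - 1L] + (0.5 - v[i - 1L]) / (v[i] - v[i - 1L]) * (t[i] - t[i - 1L])
}
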