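# Segmentation of ER fluorescence frames: percentile normalization,
# Otsu histogram thresholding, and cisterna detection by morphological
# opening followed by region-based (Chan-Vese-style) active-contour
# refinement.

#' Percentile-normalize a frame
#'
#' Rescales intensities so the `low_pct` percentile maps to 0 and the
#' `high_pct` percentile to 1, clipping to `[0, 1]`. Robust to hot
#' pixels; invariant to affine intensity transforms `a I + b`, `a > 0`.
#'
#' @param frame An [image_frame()].
#' @param low_pct,high_pct Percentiles in `[0, 100]`, `low_pct < high_pct`.
#' @return A normalized [image_frame()].
#' @export
normalize_frame <- function(frame, low_pct = 0.5, high_pct = 99.5) {
  stopifnot(inherits(frame, "ImageFrame"),
            low_pct >= 0, high_pct <= 100, low_pct < high_pct)
  rng <- range(frame$pixels)
  if (rng[2L] - rng[1L] <= 1e-9 * max(abs(rng), 1)) {
    stop("frame has no dynamic range (constant image)", call. = FALSE)
  }
  q <- quantile(frame$pixels, c(low_pct, high_pct) / 100, names = FALSE)
  if (q[2L] <= q[1L]) {
    stop("frame has no dynamic range between the given percentiles",
         call. = FALSE)
  }
  out <- (frame$pixels - q[1L]) / (q[2L] - q[1L])
  image_frame(pmin(pmax(out, 0), 1), frame$pixel_size_um)
}

# Otsu threshold from histogram counts over bins with upper edges
# `edges`; returns the upper edge of the last background bin (the value
# maximizing between-class variance; ties broken toward the smallest
# threshold). Foreground is "strictly above" the returned value.
otsu_from_hist <- function(counts, edges) {
  n <- sum(counts)
  k <- length(counts)
  mids <- edges - (edges[2L] - edges[1L]) / 2  # bin centers
  w0 <- cumsum(counts)[-k]
  w1 <- n - w0
  s0 <- cumsum(counts * mids)[-k]
  mu_tot <- sum(counts * mids) / n
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, k - 1L)
  mu0 <- s0[valid] / w0[valid]
  mu1 <- (mu_tot * n - s0[valid]) / w1[valid]
  sigma_b[valid] <- (w0[valid] / n) * (w1[valid] / n) *
    (mu0 - mu1)^2
  if (all(!is.finite(sigma_b))) {
    stop("cannot threshold: all pixels fall in one histogram bin",
         call. = FALSE)
  }
  edges[which.max(sigma_b)]
}

#' Otsu's threshold segmentation
#'
#' Builds an `n_bins` histogram over the frame's intensity range and
#' picks the threshold maximizing between-class variance. Foreground is
#' strictly above the threshold, which makes masks reproducible
#' bit-for-bit.
#'
#' @param frame An [image_frame()]; must not be constant.
#' @param n_bins Number of histogram bins (default 256).
#' @return An object of class `BinaryMask`: list with logical matrix
#'   `pixels` and `threshold_used`.
#' @export
otsu_threshold <- function(frame, n_bins = 256L) {
  stopifnot(inherits(frame, "ImageFrame"), n_bins >= 2L)
  v <- frame$pixels
  rng <- range(v)
  if (rng[1L] == rng[2L]) {
    stop("cannot threshold a constant frame", call. = FALSE)
  }
  binwidth <- (rng[2L] - rng[1L]) / n_bins
  # right-closed bins: bin k covers (lo + (k-1) w, lo + k w]
  bin <- pmin(pmax(ceiling((v - rng[1L]) / binwidth), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  edges <- rng[1L] + seq_len(n_bins) * binwidth
  thr <- otsu_from_hist(counts, edges)
  binary_mask(v > thr, thr)
}

#' @rdname otsu_threshold
#' @param pixels Logical matrix of foreground pixels.
#' @param threshold_used Intensity threshold that produced the mask.
#' @export
binary_mask <- function(pixels, threshold_used = NA_real_) {
  stopifnot(is.matrix(pixels))
  structure(list(pixels = pixels != 0, threshold_used = threshold_used),
            class = "BinaryMask")
}

#' @export
print.BinaryMask <- function(x, ...) {
  cat(sprintf("<BinaryMask> %d x %d px, %d foreground (thr %.4g)\n",
              ncol(x$pixels), nrow(x$pixels), sum(x$pixels),
              x$threshold_used))
  invisible(x)
}

# Morphological Chan-Vese (region-based active contour): the region
# evolves toward the partition whose inside/outside means best explain
# the local intensities, with a 3x3 majority smoothing playing the role
# of the curvature term. Runs inside a dilated bounding box around the
# seed component.
chan_vese_refine <- function(intens, region, iterations) {
  for (it in seq_len(iterations)) {
    c1 <- mean(intens[region])
    c2 <- if (any(!region)) mean(intens[!region]) else c1
    if (!is.finite(c1) || !is.finite(c2) || c1 == c2) break
    prop <- (intens - c1)^2 < (intens - c2)^2
    # curvature-like smoothing: keep pixels backed by their neighborhood
    nb <- neighbor_counts(prop)
    newr <- (prop & nb >= 3L) | (!prop & nb >= 6L)
    if (identical(newr, region)) break
    region <- newr
  }
  region
}

#' Detect cisternal regions
#'
#' Morphological opening with a disc removes tubule-width structures
#' from the mask; each surviving connected component is refined by a
#' region-based (Chan-Vese-style) active contour on the frame intensity,
#' and components below `min_area_um2` are discarded.
#'
#' @param frame Source [image_frame()] (intensities drive the contour).
#' @param mask A `BinaryMask` from [otsu_threshold()].
#' @param opening_radius_px Disc radius for the opening (>= 1).
#' @param ac_iterations Active-contour iterations (default 50).
#' @param min_area_um2 Minimum region area in um^2.
#' @return A list of `CisternaRegion` objects: list with `pixels`
#'   (2-column 0-based x, y matrix), `area_um2`, `centroid` and
#'   `boundary` (ordered contour, 0-based x, y).
#' @export
detect_cisternae <- function(frame, mask, opening_radius_px = 3L,
                             ac_iterations = 50L, min_area_um2 = 0.25) {
  stopifnot(inherits(frame, "ImageFrame"), inherits(mask, "BinaryMask"),
            opening_radius_px >= 1)
  opened <- binary_opening(mask$pixels, opening_radius_px)
  if (!any(opened)) return(list())
  lab <- label_components(opened, 8L)
  px_area <- frame$pixel_size_um^2
  out <- list()
  for (id in seq_len(max(lab))) {
    comp <- lab == id
    # work in a dilated bounding box around the component
    rows <- range(which(rowSums(comp) > 0))
    cols <- range(which(colSums(comp) > 0))
    pad <- 2L * opening_radius_px + 2L
    r0 <- max(1L, rows[1L] - pad); r1 <- min(nrow(comp), rows[2L] + pad)
    c0 <- max(1L, cols[1L] - pad); c1 <- min(ncol(comp), cols[2L] + pad)
    sub_reg <- comp[r0:r1, c0:c1]
    sub_int <- frame$pixels[r0:r1, c0:c1]
    refined <- chan_vese_refine(sub_int, sub_reg, ac_iterations)
    # keep the refined component(s) overlapping the seed region
    rl <- label_components(refined, 8L)
    keep_ids <- unique(rl[sub_reg & rl > 0L])
    refined <- matrix(rl %in% keep_ids, nrow(rl), ncol(rl))
    if (!any(refined)) refined <- sub_reg
    full <- matrix(FALSE, nrow(comp), ncol(comp))
    full[r0:r1, c0:c1] <- refined
    area <- sum(full) * px_area
    if (area < min_area_um2) next
    idx <- which(full, arr.ind = TRUE)
    pix <- cbind(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L)
    out[[length(out) + 1L]] <- structure(list(
      pixels = pix,
      area_um2 = area,
      centroid = c(x = mean(pix[, 1L]), y = mean(pix[, 2L])),
      boundary = trace_boundary(full)
    ), class = "CisternaRegion")
  }
  out
}
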