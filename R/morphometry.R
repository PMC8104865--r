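# Polygonal-region morphometry: regions fully enclosed by the
# skeletonized network (plus cisternae) with area, circularity and
# elongation; branch lengths; Pearson colocalization.

# Moore-neighbor boundary tracing of a single connected region.
# Returns an ordered (x, y) 0-based contour matrix (closed implicitly).
trace_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- mask
  idx <- which(p, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0L), 0L, 2L))
  s <- idx[order(idx[, 1L], idx[, 2L])[1L], ]
  if (nrow(idx) == 1L) {
    return(cbind(x = s[2L] - 2L, y = s[1L] - 2L))
  }
  # clockwise Moore neighborhood as (dr, dc), starting W
  dd <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
              c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  contour <- matrix(s, 1L, 2L)
  cur <- s
  back <- 1L   # backtrack direction: the W neighbor of the start is bg
  first_move <- NULL
  for (guard in seq_len(8L * (h * w + 1L))) {
    found <- FALSE
    for (k in 1:8) {
      d <- ((back - 1L + k) %% 8L) + 1L
      cand <- cur + dd[d, ]
      if (p[cand[1L], cand[2L]]) {
        # new backtrack points from cand toward the last bg neighbor
        prev_d <- ((d - 2L) %% 8L) + 1L
        bg <- cur + dd[prev_d, ]
        rel <- bg - cand
        back <- which(dd[, 1L] == rel[1L] & dd[, 2L] == rel[2L])
        if (is.null(first_move)) first_move <- d
        if (all(cand == s) && nrow(contour) > 1L) {
          return(cbind(x = contour[, 2L] - 2L, y = contour[, 1L] - 2L))
        }
        contour <- rbind(contour, cand)
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel (handled above) or done
  }
  cbind(x = contour[, 2L] - 2L, y = contour[, 1L] - 2L)
}

# Contour step-length perimeter (1 for axial, sqrt(2) for diagonal
# steps), in pixels; degenerate tiny contours fall back to the
# equivalent-circle perimeter so circularity stays bounded.
contour_perimeter_px <- function(contour, area_px) {
  n <- nrow(contour)
  if (n >= 3L) {
    nxt <- rbind(contour[-1L, , drop = FALSE], contour[1L, , drop = FALSE])
    steps <- sqrt(rowSums((nxt - contour)^2))
    p <- sum(steps)
  } else {
    p <- 0
  }
  max(p, 2 * sqrt(pi * area_px))
}

# Elongation: major/minor axis ratio of the second-moment (best-fit)
# ellipse of the pixel set.
region_elongation <- function(pix) {
  if (nrow(pix) < 3L) return(1)
  cv <- stats::cov(pix) + diag(2L) / 12  # add per-pixel variance
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev) / max(min(ev), 1e-12))
}

#' Extract polygonal regions enclosed by the network
#'
#' Background connected components (4-connectivity, the topological dual
#' of the 8-connected skeleton) of the union of skeleton and cisterna
#' pixels that do not touch the image border, with area, perimeter,
#' circularity `4 pi A / P^2` and elongation (major/minor axis ratio of
#' the second-moment ellipse).
#'
#' @param skel A [skeletonize_mask()] result (non-empty).
#' @param cisternae Optional list of `CisternaRegion` objects whose
#'   pixels are added to the enclosing structure.
#' @param pixel_size_um Pixel size in um/px.
#' @param min_area_um2 Regions smaller than this are dropped (default 0:
#'   keep everything).
#' @return A list of `PolygonRegion` objects: list with `pixels`
#'   (0-based x, y matrix), `area_um2`, `perimeter_um`, `circularity`,
#'   `elongation`.
#' @export
extract_polygons <- function(skel, cisternae = NULL, pixel_size_um = NULL,
                             min_area_um2 = 0) {
  stopifnot(inherits(skel, "Skeleton"))
  if (!any(skel$pixels)) stop("skeleton is empty", call. = FALSE)
  pixel_size_um <- pixel_size_um %||% 1
  fg <- skel$pixels
  if (!is.null(cisternae)) {
    for (cis in cisternae) {
      fg[cbind(cis$pixels[, 2L] + 1L, cis$pixels[, 1L] + 1L)] <- TRUE
    }
  }
  lab <- label_components(!fg, 4L)
  if (max(lab) == 0L) return(list())
  border_ids <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L],
                         lab[, ncol(lab)]))
  out <- list()
  for (id in setdiff(seq_len(max(lab)), border_ids)) {
    comp <- lab == id
    area_px <- sum(comp)
    area <- area_px * pixel_size_um^2
    if (area < min_area_um2) next
    contour <- trace_boundary(comp)
    per_px <- contour_perimeter_px(contour, area_px)
    idx <- which(comp, arr.ind = TRUE)
    pix <- cbind(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L)
    out[[length(out) + 1L]] <- structure(list(
      pixels = pix,
      area_um2 = area,
      perimeter_um = per_px * pixel_size_um,
      circularity = 4 * pi * area_px / per_px^2,
      elongation = region_elongation(pix)
    ), class = "PolygonRegion")
  }
  out
}

#' @export
print.PolygonRegion <- function(x, ...) {
  cat(sprintf("<PolygonRegion> area %.4g um^2, circ %.3f, elong %.3f\n",
              x$area_um2, x$circularity, x$elongation))
  invisible(x)
}

#' Branch lengths of a labeled skeleton
#'
#' Tubule segments are maximal runs of tubule-class pixels between
#' critical (end-point or junction) pixels; length is the sum of
#' inter-pixel steps (1 axial, sqrt(2) diagonal) times the pixel size.
#' Pure tubule loops (cycles without any critical pixel) count as one
#' closed branch each.
#'
#' @param skel A [skeletonize_mask()] result.
#' @param labels Matching [classify_pixels()] result.
#' @param pixel_size_um Pixel size in um/px.
#' @return Numeric vector of branch lengths (um).
#' @export
branch_lengths <- function(skel, labels, pixel_size_um) {
  stopifnot(inherits(skel, "Skeleton"), inherits(labels, "SkeletonLabels"))
  stop_if_not_scalar_pos(pixel_size_um, "pixel_size_um")
  lab <- labels$label_map
  h <- nrow(lab); w <- ncol(lab)
  offs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L), c(0L, 1L),
                c(1L, -1L), c(1L, 0L), c(1L, 1L))
  at <- function(y, x) if (y < 1L || y > h || x < 1L || x > w) 0L else lab[y, x]
  nbrs <- function(y, x) {
    ys <- y + offs[, 1L]; xs <- x + offs[, 2L]
    ok <- ys >= 1L & ys <= h & xs >= 1L & xs <= w
    cbind(ys[ok], xs[ok])[lab[cbind(ys[ok], xs[ok])] > 0L, , drop = FALSE]
  }
  step_len <- function(a, b) if (sum(abs(a - b)) == 2L) sqrt(2) else 1
  visited <- matrix(FALSE, h, w)  # tubule pixels consumed by a branch
  lengths <- numeric(0L)
  crit <- which(lab == 1L | lab == 3L, arr.ind = TRUE)
  for (r in seq_len(nrow(crit))) {
    c0 <- crit[r, ]
    for (nb in split(nbrs(c0[1L], c0[2L]),
                     seq_len(nrow(nbrs(c0[1L], c0[2L]))))) {
      nb <- as.integer(nb)
      if (lab[nb[1L], nb[2L]] != 2L || visited[nb[1L], nb[2L]]) next
      # walk along tubule pixels from c0 through nb
      len <- step_len(c0, nb)
      prev <- c0; cur <- nb
      visited[cur[1L], cur[2L]] <- TRUE
      repeat {
        nxt <- nbrs(cur[1L], cur[2L])
        nxt <- nxt[!(nxt[, 1L] == prev[1L] & nxt[, 2L] == prev[2L]), ,
                   drop = FALSE]
        # prefer the continuation: a critical pixel ends the branch
        if (nrow(nxt) == 0L) break
        critn <- nxt[lab[nxt] != 2L, , drop = FALSE]
        if (nrow(critn) > 0L) {
          len <- len + step_len(cur, critn[1L, ])
          break
        }
        tub <- nxt[!visited[nxt], , drop = FALSE]
        if (nrow(tub) == 0L) break
        len <- len + step_len(cur, tub[1L, ])
        prev <- cur; cur <- tub[1L, ]
        visited[cur[1L], cur[2L]] <- TRUE
      }
      lengths <- c(lengths, len)
    }
  }
  # pure tubule loops with no critical pixel
  left <- which(lab == 2L & !visited, arr.ind = TRUE)
  while (nrow(left) > 0L) {
    start <- left[1L, ]
    prev <- start; cur <- start
    visited[cur[1L], cur[2L]] <- TRUE
    len <- 0
    repeat {
      nxt <- nbrs(cur[1L], cur[2L])
      nxt <- nxt[!(nxt[, 1L] == prev[1L] & nxt[, 2L] == prev[2L]), ,
                 drop = FALSE]
      nxt <- nxt[!visited[nxt] | (nxt[, 1L] == start[1L] &
                                    nxt[, 2L] == start[2L]), , drop = FALSE]
      if (nrow(nxt) == 0L) break
      len <- len + step_len(cur, nxt[1L, ])
      prev <- cur; cur <- nxt[1L, ]
      if (all(cur == start)) break
      visited[cur[1L], cur[2L]] <- TRUE
    }
    lengths <- c(lengths, len)
    left <- which(lab == 2L & !visited, arr.ind = TRUE)
  }
  lengths * pixel_size_um
}

#' Pearson colocalization of two channels over a mask
#'
#' @param ch1,ch2 [image_frame()] objects of identical shape.
#' @param fg_mask A `BinaryMask` with at least 10 foreground pixels.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
pearson_colocalization <- function(ch1, ch2, fg_mask) {
  stopifnot(inherits(ch1, "ImageFrame"), inherits(ch2, "ImageFrame"),
            inherits(fg_mask, "BinaryMask"))
  if (!identical(dim(ch1$pixels), dim(ch2$pixels)) ||
      !identical(dim(ch1$pixels), dim(fg_mask$pixels))) {
    stop("channels and mask must share the same shape", call. = FALSE)
  }
  if (sum(fg_mask$pixels) < 10L) {
    stop("mask must contain at least 10 pixels", call. = FALSE)
  }
  a <- ch1$pixels[fg_mask$pixels]
  b <- ch2$pixels[fg_mask$pixels]
  if (sd(a) == 0 || sd(b) == 0) {
    stop("a channel is constant on the mask", call. = FALSE)
  }
  cor(a, b)
}

#' Per-image morphometry report
#'
#' Bundles the skeleton-based readouts of one frame: junction/tubule
#' ratio, class counts, polygon areas and branch lengths, plus
#' provenance (threshold and parameters).
#'
#' @param labels A [classify_pixels()] result.
#' @param polygons List of `PolygonRegion` from [extract_polygons()].
#' @param branch_lengths_um Numeric vector from [branch_lengths()].
#' @param provenance Named list (file, threshold, parameters...).
#' @return An object of class `MorphometryReport`.
#' @export
morphometry_report <- function(labels, polygons, branch_lengths_um,
                               provenance = list()) {
  stopifnot(inherits(labels, "SkeletonLabels"))
  structure(list(
    junction_tubule_ratio = junction_tubule_ratio(labels),
    n_junctions = max(label_components(labels$label_map == 3L, 8L)),
    n_endpoints = unname(labels$counts["ENDPOINT"]),
    class_counts = labels$counts,
    polygon_areas_um2 = vapply(polygons, `[[`, numeric(1L), "area_um2"),
    polygon_circularity = vapply(polygons, `[[`, numeric(1L), "circularity"),
    polygon_elongation = vapply(polygons, `[[`, numeric(1L), "elongation"),
    branch_lengths_um = branch_lengths_um,
    provenance = provenance
  ), class = "MorphometryReport")
}

#' @export
print.MorphometryReport <- function(x, ...) {
  cat(sprintf(paste0("<MorphometryReport> J/T ratio %.4f, %d junctions, ",
                     "%d polygons (mean %.3g um^2), %d branches\n"),
              x$junction_tubule_ratio, x$n_junctions,
              length(x$polygon_areas_um2), mean(x$polygon_areas_um2),
              length(x$branch_lengths_um)))
  invisible(x)
}
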