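# Ground-truthed synthetic ER-network geometry.
#
# The peripheral ER is a planar polygonal network dominated by three-way
# junctions. A jittered Voronoi tessellation reproduces that topology:
# generic Voronoi vertices are exactly three-way, so the ground-truth
# junction count is the interior vertex count. Cells are built by
# half-plane (perpendicular-bisector) clipping of the field rectangle,
# which is exact and dependency-free.

# Sutherland-Hodgman clip of a convex polygon (n x 2) by {p : a.p <= b}.
clip_halfplane <- function(poly, a, b, tol = 1e-9) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  d <- as.vector(poly %*% a) - b
  keep <- d <= tol
  out <- matrix(numeric(0L), 0L, 2L)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    if (keep[k]) out <- rbind(out, poly[k, ])
    if (xor(keep[k], keep[k2])) {
      t <- d[k] / (d[k] - d[k2])
      out <- rbind(out, poly[k, ] + t * (poly[k2, ] - poly[k, ]))
    }
  }
  out
}

# Voronoi cell of seed i inside the rectangle [0, w1] x [0, h1], clipping
# nearest seeds first and stopping once no farther seed can cut the cell.
voronoi_cell <- function(seeds, i, w1, h1) {
  poly <- rbind(c(0, 0), c(w1, 0), c(w1, h1), c(0, h1))
  si <- seeds[i, ]
  d2 <- (seeds[, 1L] - si[1L])^2 + (seeds[, 2L] - si[2L])^2
  ord <- order(d2)
  ord <- ord[ord != i]
  for (j in ord) {
    rmax2 <- max((poly[, 1L] - si[1L])^2 + (poly[, 2L] - si[2L])^2)
    if (d2[j] > 4 * rmax2) break   # bisector cannot reach the cell
    sj <- seeds[j, ]
    a <- sj - si
    b <- sum(a * (si + sj) / 2)
    poly <- clip_halfplane(poly, a, b)
    if (nrow(poly) == 0L) break
  }
  poly
}

shoelace_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  abs(sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y)) / 2
}

#' Generate a ground-truthed synthetic ER network
#'
#' Builds a jittered-Voronoi tessellation of the field and returns its
#' edge graph and bounded-cell areas as ground truth for segmentation,
#' skeletonization and polygon morphometry. Interior vertices of a
#' generic Voronoi diagram have degree exactly 3, mirroring the
#' three-way junctions that dominate the peripheral ER.
#'
#' Seed points sit on a jittered rectangular grid. `jitter = 0` gives
#' the regular (degenerate, four-way) grid diagram; values around
#' 0.3-0.5 give natural-looking generic networks.
#'
#' @param width_px,height_px Field size in pixels (both >= 64).
#' @param n_seed_points Number of Voronoi seed points (>= 4).
#' @param jitter Jitter amplitude as a fraction of the grid spacing
#'   (uniform in `+/- jitter/2` per axis).
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param seed Integer random seed; identical seeds give identical
#'   networks.
#' @param seed_points Optional explicit `n x 2` matrix of seed-point
#'   coordinates (0-based pixels) overriding the jittered grid.
#' @return An object of class `NetworkGroundTruth` with fields
#'   `node_positions` (vertex coordinates, 0-based pixels), `edges`
#'   (2-column index matrix), `node_degrees`, `interior` (logical; FALSE
#'   for vertices on the field border), `polygon_cells` (areas of
#'   bounded cells in um^2), `cells` (per-seed clipped polygons),
#'   `bounded` (logical per cell), plus the field geometry and seed.
#' @export
generate_network <- function(width_px, height_px, n_seed_points, jitter = 0.35,
                             pixel_size_um = 0.1, seed = 1L,
                             seed_points = NULL) {
  stopifnot(width_px >= 64, height_px >= 64, n_seed_points >= 4)
  stop_if_not_scalar_pos(pixel_size_um, "pixel_size_um")
  w1 <- width_px - 1; h1 <- height_px - 1
  if (is.null(seed_points)) {
    if (sqrt(w1 * h1 / n_seed_points) < 8) {
      stop("degenerate geometry: field too small to host n_seed_points ",
           "(mean seed spacing below 8 px)", call. = FALSE)
    }
    set.seed(child_seed(seed, "network"))
    nx <- max(2L, as.integer(round(sqrt(n_seed_points * width_px / height_px))))
    ny <- as.integer(ceiling(n_seed_points / nx))
    sx <- w1 / nx; sy <- h1 / ny
    grid <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
    cx <- (grid$ix + 0.5) * sx
    cy <- (grid$iy + 0.5) * sy
    keep <- if (nrow(grid) > n_seed_points) {
      sort(sample.int(nrow(grid), n_seed_points))
    } else seq_len(nrow(grid))
    jx <- runif(length(keep), -0.5, 0.5) * jitter * sx
    jy <- runif(length(keep), -0.5, 0.5) * jitter * sy
    seeds <- cbind(pmin(pmax(cx[keep] + jx, 0), w1),
                   pmin(pmax(cy[keep] + jy, 0), h1))
  } else {
    seeds <- matrix(as.double(seed_points), ncol = 2L)
    if (nrow(seeds) < 4L) stop("need at least 4 seed points", call. = FALSE)
    if (min(dist(seeds)) < 2) {
      stop("degenerate geometry: seed points closer than 2 px", call. = FALSE)
    }
  }
  n <- nrow(seeds)
  cells <- lapply(seq_len(n), function(i) voronoi_cell(seeds, i, w1, h1))

  # Deduplicate vertices across cells (rounding keys) and build the edge
  # graph; edges lying along the field border are not part of the
  # network.
  vkey <- new.env(hash = TRUE, parent = emptyenv())
  verts <- list()
  vid <- function(p) {
    key <- paste(sprintf("%.5f", p), collapse = ",")
    id <- vkey[[key]]
    if (is.null(id)) {
      id <- length(verts) + 1L
      verts[[id]] <<- p
      vkey[[key]] <- id
    }
    id
  }
  on_border_pt <- function(p, tol = 1e-6) {
    p[1L] < tol || p[1L] > w1 - tol || p[2L] < tol || p[2L] > h1 - tol
  }
  edge_set <- new.env(hash = TRUE, parent = emptyenv())
  edges <- matrix(integer(0L), 0L, 2L)
  bounded <- logical(n)
  for (i in seq_len(n)) {
    poly <- cells[[i]]
    if (nrow(poly) < 3L) { bounded[i] <- FALSE; next }
    ids <- vapply(seq_len(nrow(poly)), function(k) vid(poly[k, ]), integer(1L))
    border <- vapply(seq_len(nrow(poly)),
                     function(k) on_border_pt(poly[k, ]), logical(1L))
    bounded[i] <- !any(border)
    for (k in seq_len(nrow(poly))) {
      k2 <- if (k == nrow(poly)) 1L else k + 1L
      a <- ids[k]; b <- ids[k2]
      if (a == b) next
      # drop edges running along the border (both ends on one side)
      p1 <- poly[k, ]; p2 <- poly[k2, ]
      same_side <- (abs(p1[1L]) < 1e-6 && abs(p2[1L]) < 1e-6) ||
        (abs(p1[1L] - w1) < 1e-6 && abs(p2[1L] - w1) < 1e-6) ||
        (abs(p1[2L]) < 1e-6 && abs(p2[2L]) < 1e-6) ||
        (abs(p1[2L] - h1) < 1e-6 && abs(p2[2L] - h1) < 1e-6)
      if (same_side) next
      key <- paste(min(a, b), max(a, b))
      if (is.null(edge_set[[key]])) {
        edge_set[[key]] <- TRUE
        edges <- rbind(edges, c(min(a, b), max(a, b)))
      }
    }
  }
  node_positions <- do.call(rbind, verts)
  nv <- nrow(node_positions)
  degrees <- tabulate(as.vector(edges), nbins = nv)
  # drop isolated vertices (field corners and border artifacts with no
  # incident network edge)
  keep_v <- degrees > 0L
  if (!all(keep_v)) {
    remap <- cumsum(keep_v)
    node_positions <- node_positions[keep_v, , drop = FALSE]
    edges <- matrix(remap[edges], ncol = 2L)
    nv <- nrow(node_positions)
    degrees <- tabulate(as.vector(edges), nbins = nv)
  }
  interior <- !vapply(seq_len(nv),
                      function(k) on_border_pt(node_positions[k, ]),
                      logical(1L))
  areas_px <- vapply(cells, shoelace_area, numeric(1L))
  polygon_cells <- areas_px[bounded] * pixel_size_um^2
  structure(list(
    node_positions = node_positions,
    edges = edges,
    node_degrees = degrees,
    interior = interior,
    polygon_cells = polygon_cells,
    cells = cells,
    cell_areas_px2 = areas_px,
    bounded = bounded,
    seed_points = seeds,
    width_px = as.integer(width_px),
    height_px = as.integer(height_px),
    pixel_size_um = as.double(pixel_size_um),
    seed = as.integer(seed),
    true_diffusion_um2_s = NULL,
    true_tracks = NULL
  ), class = "NetworkGroundTruth")
}

#' @export
print.NetworkGroundTruth <- function(x, ...) {
  cat(sprintf(paste0("<NetworkGroundTruth> %d x %d px (%.3g um/px), ",
                     "%d nodes (%d interior), %d edges, %d bounded cells\n"),
              x$width_px, x$height_px, x$pixel_size_um,
              nrow(x$node_positions), sum(x$interior), nrow(x$edges),
              length(x$polygon_cells)))
  if (!is.null(x$true_diffusion_um2_s)) {
    cat(sprintf("  Brownian ground truth: D = %.4g um^2/s, %d tracks\n",
                x$true_diffusion_um2_s, length(x$true_tracks)))
  }
  invisible(x)
}
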