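# Topology-preserving skeletonization (Zhang-Suen thinning with a
# thinness cleanup pass) and skeleton-pixel classification into the
# three morphological classes: end point, tubule, junction.

# Shifted copies of padded matrix p for the 8 neighbors, in the
# Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW). p is the padded
# (h+2) x (w+2) logical matrix; returns a list of h x w matrices.
zs_neighbors <- function(p, h, w) {
  sh <- function(dy, dx) p[(2L + dy):(h + 1L + dy), (2L + dx):(w + 1L + dx)]
  list(P2 = sh(-1L, 0L), P3 = sh(-1L, 1L), P4 = sh(0L, 1L),
       P5 = sh(1L, 1L), P6 = sh(1L, 0L), P7 = sh(1L, -1L),
       P8 = sh(0L, -1L), P9 = sh(-1L, -1L))
}

# number of 0 -> 1 transitions in the circular sequence P2..P9 P2
zs_transitions <- function(nb) {
  seqs <- nb[c(2:8, 1L)]
  acc <- matrix(0L, nrow(nb$P2), ncol(nb$P2))
  for (k in 1:8) acc <- acc + (!nb[[k]] & seqs[[k]])
  acc
}

#' Skeletonize a binary mask
#'
#' Zhang-Suen iterative thinning, followed by a cleanup pass that
#' removes topology-preserving pixels from any remaining 2x2 blocks so
#' the thinness invariant (no fully set 2x2 block) holds exactly.
#' Connectivity (8-connected foreground components, enclosed holes) is
#' preserved.
#'
#' @param mask A `BinaryMask` or logical matrix with at least one
#'   foreground pixel.
#' @return An object of class `Skeleton`: list with logical matrix
#'   `pixels`, `connectivity = 8` and `source_shape`.
#' @export
skeletonize_mask <- function(mask) {
  m <- if (inherits(mask, "BinaryMask")) mask$pixels else mask != 0
  stopifnot(is.matrix(m))
  if (!any(m)) stop("cannot skeletonize an empty mask", call. = FALSE)
  h <- nrow(m); w <- ncol(m)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- matrix(FALSE, h + 2L, w + 2L)
      p[2:(h + 1L), 2:(w + 1L)] <- m
      nb <- zs_neighbors(p, h, w)
      B <- Reduce(`+`, nb)
      A <- zs_transitions(nb)
      if (sub == 1L) {
        c1 <- !(nb$P2 & nb$P4 & nb$P6)
        c2 <- !(nb$P4 & nb$P6 & nb$P8)
      } else {
        c1 <- !(nb$P2 & nb$P4 & nb$P8)
        c2 <- !(nb$P2 & nb$P6 & nb$P8)
      }
      del <- m & B >= 2L & B <= 6L & A == 1L & c1 & c2
      if (any(del)) { m[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m <- remove_redundant_pixels(m)
  structure(list(pixels = m, connectivity = 8L, source_shape = c(h, w)),
            class = "Skeleton")
}

# Offsets of the 8-neighborhood in ring order N, NE, E, SE, S, SW, W, NW
# as (dy, dx).
ring_offsets <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                      c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))

# Is the center of a 3x3 neighborhood a removable (simple, non-end)
# pixel? nbv: logical ring vector N, NE, E, SE, S, SW, W, NW.
# Conditions: >= 2 foreground neighbors (protect end points); the
# foreground neighbors form a single 8-connected component (so removal
# cannot split the skeleton); the background 4-neighbors remain
# 4-connected within the neighborhood (so removal cannot merge two
# enclosed regions).
is_redundant_pixel <- function(nbv) {
  fg <- which(nbv)
  if (length(fg) < 2L) return(FALSE)
  # component count of foreground neighbors under true pixel adjacency
  pos <- ring_offsets[fg, , drop = FALSE]
  seen <- logical(length(fg))
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack) > 0L) {
    i <- stack[[1L]]; stack <- stack[-1L]
    adj <- which(!seen &
                   pmax(abs(pos[, 1L] - pos[i, 1L]),
                        abs(pos[, 2L] - pos[i, 2L])) <= 1L)
    seen[adj] <- TRUE
    stack <- c(stack, adj)
  }
  if (!all(seen)) return(FALSE)
  # background 4-neighbors must be 4-connected within the ring after
  # removal: walking the ring N -> NE -> E ... , two bg 4-neighbors are
  # connected iff some path of bg ring cells joins them
  four <- c(1L, 3L, 5L, 7L)
  bg4 <- four[!nbv[four]]
  if (length(bg4) >= 2L) {
    ring_bg <- !nbv
    # count bg runs around the ring containing a 4-neighbor
    runs <- 0L
    in_run <- FALSE
    has4 <- FALSE
    for (k in c(seq_len(8L), 1L)) {  # wrap once to close circular runs
      if (ring_bg[k]) {
        if (!in_run) { in_run <- TRUE; has4 <- FALSE }
        if (k %in% four) has4 <- TRUE
      } else if (in_run) {
        if (has4) runs <- runs + 1L
        in_run <- FALSE
      }
    }
    if (in_run && has4) runs <- runs + 1L
    if (runs > 1L) return(FALSE)
  }
  TRUE
}

# Remove redundant skeleton pixels (staircase artifacts of the thinning
# pass and residual 2x2 blocks) in deterministic raster order until
# stable. End points are never removed, so branch lengths are
# unaffected; topology is preserved by the simple-pixel test.
remove_redundant_pixels <- function(m) {
  h <- nrow(m); w <- ncol(m)
  repeat {
    p <- matrix(FALSE, h + 2L, w + 2L)
    p[2:(h + 1L), 2:(w + 1L)] <- m
    nb <- zs_neighbors(p, h, w)
    B <- Reduce(`+`, nb)
    # candidates: some consecutive ring pair set (a potential chord)
    ring <- nb[c(1, 2, 3, 4, 5, 6, 7, 8)]  # P2..P9 = N NE E SE S SW W NW
    pairs <- ring[[1L]] & ring[[2L]]
    for (k in 2:8) {
      k2 <- if (k == 8L) 1L else k + 1L
      pairs <- pairs | (ring[[k]] & ring[[k2]])
    }
    cand <- which(m & B >= 2L & pairs, arr.ind = TRUE)
    removed <- FALSE
    for (r in seq_len(nrow(cand))) {
      yy <- cand[r, 1L]; xx <- cand[r, 2L]
      if (!m[yy, xx]) next
      nbv <- vapply(seq_len(8L), function(k) {
        y2 <- yy + ring_offsets[k, 1L]; x2 <- xx + ring_offsets[k, 2L]
        y2 >= 1L && y2 <= h && x2 >= 1L && x2 <= w && m[y2, x2]
      }, logical(1L))
      if (is_redundant_pixel(nbv)) {
        m[yy, xx] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  m
}

#' @export
print.Skeleton <- function(x, ...) {
  cat(sprintf("<Skeleton> %d pixels on a %d x %d grid\n", sum(x$pixels),
              x$source_shape[2L], x$source_shape[1L]))
  invisible(x)
}

#' Classify skeleton pixels by neighborhood
#'
#' Each skeleton pixel is classified by its count `n` of 8-neighbors in
#' the skeleton: `n <= 1` end point, `n == 2` tubule, `n >= 3` junction
#' (the standard morphological definitions; isolated pixels count as end
#' points).
#'
#' @param skel A [skeletonize_mask()] result.
#' @return An object of class `SkeletonLabels`: list with integer matrix
#'   `label_map` (0 background, 1 end point, 2 tubule, 3 junction) and a
#'   named `counts` vector.
#' @export
classify_pixels <- function(skel) {
  stopifnot(inherits(skel, "Skeleton"))
  m <- skel$pixels
  nb <- neighbor_counts(m)
  lab <- matrix(0L, nrow(m), ncol(m))
  lab[m & nb <= 1L] <- 1L
  lab[m & nb == 2L] <- 2L
  lab[m & nb >= 3L] <- 3L
  counts <- c(ENDPOINT = sum(lab == 1L), TUBULE = sum(lab == 2L),
              JUNCTION = sum(lab == 3L))
  structure(list(label_map = lab, counts = counts),
            class = "SkeletonLabels")
}

#' @export
print.SkeletonLabels <- function(x, ...) {
  cat(sprintf("<SkeletonLabels> %d end points, %d tubule px, %d junction px\n",
              x$counts["ENDPOINT"], x$counts["TUBULE"], x$counts["JUNCTION"]))
  invisible(x)
}

#' Junction-to-tubule ratio of a labeled skeleton
#'
#' The paper-style network-density readout: junction pixels over tubule
#' pixels (`mode = "pixels"`), or junction connected components over
#' tubule branch segments (`mode = "objects"`).
#'
#' @param labels A [classify_pixels()] result.
#' @param mode `"pixels"` (default) or `"objects"`.
#' @param pixel_size_um Pixel size, only needed for `mode = "objects"`
#'   (branch segmentation); ignored otherwise.
#' @return The dimensionless ratio.
#' @export
junction_tubule_ratio <- function(labels, mode = c("pixels", "objects"),
                                  pixel_size_um = 1) {
  stopifnot(inherits(labels, "SkeletonLabels"))
  mode <- match.arg(mode)
  if (labels$counts["TUBULE"] == 0L) {
    stop("undefined ratio: skeleton has no tubule pixels", call. = FALSE)
  }
  if (mode == "pixels") {
    return(unname(labels$counts["JUNCTION"] / labels$counts["TUBULE"]))
  }
  n_j <- max(label_components(labels$label_map == 3L, 8L))
  skel <- structure(list(pixels = labels$label_map > 0L, connectivity = 8L,
                         source_shape = dim(labels$label_map)),
                    class = "Skeleton")
  n_t <- length(branch_lengths(skel, labels, pixel_size_um))
  if (n_t == 0L) stop("undefined ratio: no tubule segments", call. = FALSE)
  n_j / n_t
}
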