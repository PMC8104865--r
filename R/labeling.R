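# Connected-component labeling with selectable connectivity and small
# raster helpers. EBImage::bwlabel is 4-connected; 8-connectivity is
# obtained by merging labels across diagonal adjacencies with a
# union-find over label ids (cheap: one entry per label, not per pixel).

uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, a, b) {
  ra <- uf_find(parent, a)
  rb <- uf_find(parent, b)
  if (ra != rb) parent[rb] <- ra
  parent
}

#' Label connected components of a binary image
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of labels, 0 for background, components
#'   numbered from 1 in raster order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)  # 4-connected base labeling
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  k <- max(lab)
  if (connectivity == 8L && k > 1L) {
    h <- nrow(lab); w <- ncol(lab)
    # diagonal adjacencies: (dy, dx) = (1, 1) and (1, -1)
    pairs <- rbind(
      cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),
      cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))
    )
    pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                     pairs[, 1L] != pairs[, 2L], , drop = FALSE]
    if (nrow(pairs) > 0L) {
      pairs <- unique(pairs)
      parent <- uf_new(k)
      for (r in seq_len(nrow(pairs))) {
        parent <- uf_union(parent, pairs[r, 1L], pairs[r, 2L])
      }
      root <- vapply(seq_len(k), function(i) uf_find(parent, i), integer(1L))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  # renumber compactly in raster order of first appearance
  ids <- unique(lab[lab > 0L])
  if (length(ids) > 0L) {
    remap <- integer(max(ids))
    remap[ids] <- seq_along(ids)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

# Count of 8-neighbors set in `mask` for every pixel (matrix of counts).
neighbor_counts <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0L, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  acc <- matrix(0L, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    acc <- acc + p[(2L + dy):(h + 1L + dy), (2L + dx):(w + 1L + dx)]
  }
  acc
}

# Logical matrix: does each pixel lie on the image border?
border_mask <- function(h, w) {
  b <- matrix(FALSE, h, w)
  b[1L, ] <- TRUE; b[h, ] <- TRUE; b[, 1L] <- TRUE; b[, w] <- TRUE
  b
}
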