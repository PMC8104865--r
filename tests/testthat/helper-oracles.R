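# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles are deliberately naive (enumeration, per-pixel
# loops) and share no code with the implementation paths they check.

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# Exhaustive minimum of a square assignment problem.
brute_lap_cost <- function(cost) {
  n <- nrow(cost)
  min(vapply(all_perms(n), function(p) sum(cost[cbind(seq_len(n), p)]),
             numeric(1L)))
}

# Exhaustive minimum-cost partial matching with birth/death alternatives:
# cost of a solution = sum of matched link costs + alt per unmatched
# particle (source or target). Inf cells are forbidden links.
brute_link_cost <- function(cost, alt) {
  n <- nrow(cost); m <- ncol(cost)
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return(invisible())
    if (i > n) {
      best <<- min(best, acc + alt * sum(!used))
      return(invisible())
    }
    rec(i + 1L, used, acc + alt)          # source i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && is.finite(cost[i, j])) {
        u <- used; u[j] <- TRUE
        rec(i + 1L, u, acc + cost[i, j])
      }
    }
  }
  rec(1L, rep(FALSE, m), 0)
  best
}

# Equivalent total cost of a solve_linking() result under the same
# objective as brute_link_cost().
linking_cost <- function(res, cost, alt) {
  n <- nrow(cost); m <- ncol(cost)
  sum(cost[res$links]) + alt * (n - nrow(res$links)) +
    alt * (m - nrow(res$links))
}

# Exhaustive Otsu threshold over histogram counts/edges: for every
# candidate split, between-class variance computed by the plain
# two-class definition; first maximum wins.
brute_otsu <- function(counts, edges) {
  k <- length(counts)
  mids <- edges - (edges[2L] - edges[1L]) / 2
  n <- sum(counts)
  best_v <- -Inf
  best_t <- NA_real_
  for (s in seq_len(k - 1L)) {
    c0 <- counts[seq_len(s)]; c1 <- counts[(s + 1L):k]
    w0 <- sum(c0); w1 <- sum(c1)
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(c0 * mids[seq_len(s)]) / w0
    mu1 <- sum(c1 * mids[(s + 1L):k]) / w1
    v <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    if (v > best_v) { best_v <- v; best_t <- edges[s] }
  }
  best_t
}

# Per-pixel neighbor-count classification oracle (plain double loop).
classify_oracle <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    if (!m[y, x]) next
    cnt <- 0L
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      y2 <- y + dy; x2 <- x + dx
      if (y2 >= 1L && y2 <= h && x2 >= 1L && x2 <= w && m[y2, x2]) {
        cnt <- cnt + 1L
      }
    }
    lab[y, x] <- if (cnt <= 1L) 1L else if (cnt == 2L) 2L else 3L
  }
  lab
}

# Random small skeleton: a few random strokes and blobs, thinned.
random_skeleton <- function(seed, size = 24L) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  for (k in seq_len(sample(2:4, 1L))) {
    x0 <- sample(size, 1L); y0 <- sample(size, 1L)
    x1 <- sample(size, 1L); y1 <- sample(size, 1L)
    n <- max(abs(x1 - x0), abs(y1 - y0)) + 1L
    xs <- round(seq(x0, x1, length.out = n))
    ys <- round(seq(y0, y1, length.out = n))
    m[cbind(ys, xs)] <- TRUE
  }
  if (runif(1L) < 0.5) {
    cx <- sample(5:(size - 5L), 1L); cy <- sample(5:(size - 5L), 1L)
    r <- sample(2:4, 1L)
    idx <- which((row(m) - cy)^2 + (col(m) - cx)^2 <= r^2)
    m[idx] <- TRUE
  }
  skeletonize_mask(binary_mask(m))
}

# Wrap a matrix (padded to the 16-px minimum) as a calibrated frame.
as_frame <- function(m, pixel_size_um = 0.1) {
  if (nrow(m) < 16L || ncol(m) < 16L) {
    p <- matrix(0, max(nrow(m), 16L), max(ncol(m), 16L))
    p[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    m <- p
  }
  image_frame(m, pixel_size_um)
}

# Skeleton object from a bare logical matrix (bypasses thinning; for
# fixtures that are already single-pixel-wide).
as_skeleton <- function(m) {
  structure(list(pixels = m != 0, connectivity = 8L, source_shape = dim(m)),
            class = "Skeleton")
}

# SkeletonLabels from a bare label matrix.
as_labels <- function(lab) {
  structure(list(label_map = lab,
                 counts = c(ENDPOINT = sum(lab == 1L),
                            TUBULE = sum(lab == 2L),
                            JUNCTION = sum(lab == 3L))),
            class = "SkeletonLabels")
}

# Pixel-exact area conservation check: polygon pixels + structure
# (skeleton union cisterna) pixels + border-touching background pixels
# must tile the image.
check_area_conservation <- function(skel, cisternae = NULL) {
  fg <- skel$pixels
  if (!is.null(cisternae)) {
    for (cis in cisternae) {
      fg[cbind(cis$pixels[, 2L] + 1L, cis$pixels[, 1L] + 1L)] <- TRUE
    }
  }
  polys <- extract_polygons(skel, cisternae, 1)
  poly_px <- sum(vapply(polys, function(p) nrow(p$pixels), integer(1L)))
  lab <- ernetdyn:::label_components(!fg, 4L)
  border_ids <- setdiff(unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L],
                                 lab[, ncol(lab)])), 0L)
  border_px <- sum(lab %in% border_ids)
  poly_px + sum(fg) + border_px == length(fg)
}

# Brownian tracks directly in pixel coordinates (no imaging), as Track
# objects; used to feed the diffusion estimator a known D.
brownian_tracks <- function(n_tracks, n_frames, D_um2_s, dt_s, px_um, seed) {
  set.seed(seed)
  sdpx <- sqrt(2 * D_um2_s * dt_s) / px_um
  lapply(seq_len(n_tracks), function(i) {
    x <- cumsum(c(runif(1L, 50, 200), rnorm(n_frames - 1L, sd = sdpx)))
    y <- cumsum(c(runif(1L, 50, 200), rnorm(n_frames - 1L, sd = sdpx)))
    structure(list(spots = data.frame(frame = seq_len(n_frames) - 1L,
                                      x = x, y = y, intensity = 1),
                   gaps = list()),
              class = "Track")
  })
}
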