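# Skeletonization, pixel classification, polygon morphometry, branch
# lengths, colocalization.

thinness_violated <- function(p) {
  any(p[-nrow(p), -ncol(p)] & p[-1, -ncol(p)] & p[-nrow(p), -1] & p[-1, -1])
}

test_that("skeletonization thins a wide bar to a single 1-px line and is idempotent", {
  m <- matrix(FALSE, 20, 40); m[8:12, 5:35] <- TRUE
  sk <- skeletonize_mask(binary_mask(m))
  rows <- unique(which(sk$pixels, arr.ind = TRUE)[, 1])
  expect_length(rows, 1L)
  expect_false(thinness_violated(sk$pixels))
  sk2 <- skeletonize_mask(binary_mask(sk$pixels))
  expect_identical(sk2$pixels, sk$pixels)
  expect_error(skeletonize_mask(binary_mask(matrix(FALSE, 8, 8))), "empty")
})

test_that("skeletonization preserves components and holes (annulus)", {
  g <- expand.grid(x = 1:60, y = 1:60)
  d <- sqrt((g$x - 30)^2 + (g$y - 30)^2)
  ann <- matrix(d >= 10 & d <= 18, 60, 60)
  sk <- skeletonize_mask(binary_mask(ann))
  # Euler oracle: 8-connected foreground components, 4-connected holes
  comps <- function(m) max(ernetdyn:::label_components(m, 8L))
  holes <- function(m) max(ernetdyn:::label_components(!m, 4L)) - 1L
  expect_identical(comps(sk$pixels), comps(ann))
  expect_identical(holes(sk$pixels), holes(ann))
  expect_false(thinness_violated(sk$pixels))
})

test_that("thinness and topology hold on random blobs", {
  for (s in 1:10) {
    sk <- random_skeleton(s)
    expect_false(thinness_violated(sk$pixels))
  }
})

test_that("pixel classification matches the spec patterns", {
  line <- matrix(0L, 5, 7); line[3, 3:5] <- 1L
  lab <- classify_pixels(as_skeleton(line))
  expect_identical(lab$label_map[3, 3:5], c(1L, 2L, 1L))
  plus <- matrix(0L, 9, 9); plus[5, 3:7] <- 1L; plus[3:7, 5] <- 1L
  labp <- classify_pixels(as_skeleton(plus))
  expect_identical(labp$label_map[5, 5], 3L)                # 4 neighbors
  expect_identical(labp$label_map[cbind(c(3, 7, 5, 5), c(5, 5, 3, 7))],
                   rep(1L, 4))                              # arm tips
  iso <- matrix(0L, 5, 5); iso[3, 3] <- 1L
  expect_identical(classify_pixels(as_skeleton(iso))$label_map[3, 3], 1L)
})

test_that("classification equals the neighbor-count oracle and partitions the skeleton", {
  for (s in 1:40) {
    sk <- random_skeleton(s)
    lab <- classify_pixels(sk)
    expect_identical(lab$label_map, classify_oracle(sk$pixels))
    expect_identical(sum(lab$counts), sum(sk$pixels))
  }
})

test_that("junction/tubule ratio follows the label counts", {
  line <- matrix(0L, 5, 16); line[3, 2:15] <- 1L
  expect_identical(junction_tubule_ratio(classify_pixels(as_skeleton(line))), 0)
  lab <- matrix(0L, 10, 10)
  lab[1, 1:5] <- 3L          # 5 junction pixels
  lab[3:7, 1:10] <- 2L       # 50 tubule pixels
  expect_equal(junction_tubule_ratio(as_labels(lab)), 0.1)
  only_j <- matrix(0L, 4, 4); only_j[2, 2] <- 3L
  expect_error(junction_tubule_ratio(as_labels(only_j)), "tubule")
})

test_that("polygons: flood-fill area oracle, circle shape limits, open curves", {
  sq <- matrix(FALSE, 20, 20)
  sq[5, 5:14] <- TRUE; sq[14, 5:14] <- TRUE
  sq[5:14, 5] <- TRUE; sq[5:14, 14] <- TRUE
  polys <- extract_polygons(as_skeleton(sq), NULL, 0.1)
  expect_length(polys, 1L)
  # flood-fill oracle for the interior pixel count
  flood <- function(m, start) {
    seen <- matrix(FALSE, nrow(m), ncol(m))
    stack <- list(start); seen[start[1], start[2]] <- TRUE
    while (length(stack)) {
      p <- stack[[1]]; stack <- stack[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(m) && q[2] >= 1 && q[2] <= ncol(m) &&
            !m[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    sum(seen)
  }
  expect_equal(polys[[1]]$area_um2, flood(sq, c(9, 9)) * 0.01)
  # discretized circle: near-unit circularity and elongation
  g <- expand.grid(x = 1:48, y = 1:48)
  d <- sqrt((g$x - 24)^2 + (g$y - 24)^2)
  ring <- skeletonize_mask(binary_mask(matrix(d >= 14 & d <= 16, 48, 48)))
  pc <- extract_polygons(ring, NULL, 0.1)
  expect_length(pc, 1L)
  expect_gte(pc[[1]]$circularity, 0.9)
  expect_lte(pc[[1]]$circularity, 1.05)
  expect_lte(pc[[1]]$elongation, 1.15)
  # an open curve encloses nothing
  open_c <- matrix(FALSE, 20, 20); open_c[5:15, 10] <- TRUE
  expect_length(extract_polygons(as_skeleton(open_c), NULL, 0.1), 0L)
})

test_that("area conservation is pixel-exact on diverse fixtures", {
  sq <- matrix(FALSE, 20, 20)
  sq[5, 5:14] <- TRUE; sq[14, 5:14] <- TRUE
  sq[5:14, 5] <- TRUE; sq[5:14, 14] <- TRUE
  expect_true(check_area_conservation(as_skeleton(sq)))
  for (s in 1:6) expect_true(check_area_conservation(random_skeleton(s)))
  net <- generate_network(128, 128, 8, seed = 2)
  fr <- render_network(net, noise = "none")
  sk <- skeletonize_mask(otsu_threshold(normalize_frame(fr)))
  expect_true(check_area_conservation(sk))
})

test_that("branch lengths use the axial/diagonal step metric", {
  line <- matrix(0L, 5, 16); line[3, 3:13] <- 1L  # 11 px straight
  sk <- as_skeleton(line)
  expect_equal(branch_lengths(sk, classify_pixels(sk), 0.1), 1.0)
  diag_m <- matrix(0L, 16, 16); diag_m[cbind(3:13, 3:13)] <- 1L
  skd <- as_skeleton(diag_m)
  expect_equal(branch_lengths(skd, classify_pixels(skd), 0.1),
               10 * sqrt(2) * 0.1)
})

test_that("branch count equals the graph-theoretic segment count on rendered networks", {
  for (s in c(3, 8)) {
    net <- generate_network(192, 192, 14, seed = s)
    fr <- render_network(net, noise = "none")
    sk <- skeletonize_mask(otsu_threshold(normalize_frame(fr)))
    lab <- classify_pixels(sk)
    bl <- branch_lengths(sk, lab, 0.1)
    # oracle: each maximal tubule path is one 8-connected component of
    # tubule-class pixels (plus pure loops, also one component each)
    n_seg <- max(ernetdyn:::label_components(lab$label_map == 2L, 8L))
    expect_identical(length(bl), as.integer(n_seg))
    expect_true(all(bl > 0))
  }
})

test_that("Pearson colocalization handles identity, inversion and independence", {
  set.seed(4)
  a <- matrix(runif(100 * 100), 100, 100)
  fa <- image_frame(a, 0.1)
  mask <- binary_mask(matrix(TRUE, 100, 100))
  expect_equal(pearson_colocalization(fa, fa, mask), 1.0)
  expect_equal(pearson_colocalization(fa, image_frame(max(a) - a, 0.1), mask),
               -1.0)
  b <- image_frame(matrix(runif(100 * 100), 100, 100), 0.1)
  expect_lt(abs(pearson_colocalization(fa, b, mask)), 0.05)
  expect_error(pearson_colocalization(fa, image_frame(matrix(1, 100, 100), 0.1),
                                      mask), "constant")
})
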