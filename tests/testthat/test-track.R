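# Junction tracking: spot images, detection, linking, gap closing,
# filtering, velocities, diffusion.

make_labels_cluster <- function(h, w, px) {
  lab <- matrix(0L, h, w)
  lab[px] <- 3L
  as_labels(lab)
}

test_that("spot image applies the size filter and preserves masked intensity", {
  fr <- image_frame(matrix(7, 32, 32), 0.1)
  two_px <- make_labels_cluster(32, 32, cbind(10, 10:11))
  expect_warning(img <- make_spot_image(two_px, fr, 3, 0), "size filter")
  expect_true(all(img$pixels == 0))
  five_px <- make_labels_cluster(32, 32, cbind(c(10, 10, 10, 11, 11),
                                               c(10, 11, 12, 10, 11)))
  img5 <- make_spot_image(five_px, fr, 3, 0)
  expect_identical(sum(img5$pixels == 7), 5L)
  expect_identical(sum(img5$pixels != 0), 5L)
})

test_that("Gaussian blur of interior clusters conserves total intensity", {
  fr <- image_frame(matrix(3, 64, 64), 0.1)
  five_px <- make_labels_cluster(64, 64, cbind(c(30, 30, 30, 31, 31),
                                               c(30, 31, 32, 30, 31)))
  raw <- make_spot_image(five_px, fr, 3, 0)
  blurred <- make_spot_image(five_px, fr, 3, 2.5)
  expect_equal(sum(blurred$pixels), sum(raw$pixels), tolerance = 1e-3)
})

test_that("spot detection finds sub-pixel centers and suppresses close maxima", {
  m <- matrix(0, 64, 64)
  g <- exp(-((row(m) - 31) ^ 2 + (col(m) - 21)^2) / (2 * 2^2))  # (x=20, y=30)
  sp <- detect_spots(image_frame(10 * g, 0.1), 5, 0.5)
  expect_identical(nrow(sp), 1L)
  expect_lt(abs(sp$x - 20), 0.25)
  expect_lt(abs(sp$y - 30), 0.25)
  # two blobs 3 px apart with min_distance 5: one spot survives
  m2 <- 10 * exp(-((row(m) - 31)^2 + (col(m) - 21)^2) / 4) +
    9 * exp(-((row(m) - 31)^2 + (col(m) - 24)^2) / 4)
  sp2 <- detect_spots(image_frame(m2, 0.1), 5, 0.5)
  expect_identical(nrow(sp2), 1L)
  expect_identical(nrow(detect_spots(image_frame(matrix(0, 32, 32), 0.1),
                                     5, 0)), 0L)
})

test_that("linking follows a moving spot and splits on over-limit jumps", {
  frames_at <- function(xs) lapply(seq_along(xs), function(i) {
    data.frame(x = xs[i], y = 10, intensity = 1)
  })
  one <- link_spots(frames_at(seq(5, 14)), 7)
  expect_length(one, 1L)
  expect_identical(nrow(one[[1]]), 10L)
  split <- link_spots(frames_at(c(5, 6, 7, 15, 16)), 7)  # 8-px jump
  expect_length(split, 2L)
})

test_that("frame-pair links equal the brute-force assignment optimum", {
  set.seed(7)
  for (trial in 1:20) {
    a <- data.frame(x = runif(4, 0, 30), y = runif(4, 0, 30), intensity = 1)
    b <- data.frame(x = a$x + rnorm(4, sd = 3), y = a$y + rnorm(4, sd = 3),
                    intensity = 1)
    tr <- link_spots(list(a, b), 7)
    d <- ernetdyn:::cross_dist(cbind(a$x, a$y), cbind(b$x, b$y))
    cost <- d^2; cost[d > 7] <- Inf
    got <- sum(vapply(tr, function(t) {
      if (nrow(t) == 2) (t$x[2] - t$x[1])^2 + (t$y[2] - t$y[1])^2 else 0
    }, numeric(1)))
    n_link <- sum(vapply(tr, nrow, integer(1)) == 2)
    expect_equal(got + 49 * (8 - 2 * n_link),
                 brute_link_cost(cost, 49), tolerance = 1e-9)
  }
})

test_that("gap closing merges within limits, records gaps, refuses long gaps", {
  t1 <- data.frame(frame = 0:5, x = 1:6, y = 0, intensity = 1)
  t2 <- data.frame(frame = 8:12, x = 9:13, y = 0, intensity = 1)  # gap 2, 3 px
  merged <- close_gaps(list(t1, t2), 10, 3)
  expect_length(merged, 1L)
  expect_identical(merged[[1]]$gaps, list(6:7))
  expect_true(all(diff(merged[[1]]$spots$frame) > 0))
  t3 <- data.frame(frame = 10:14, x = 9:13, y = 0, intensity = 1)  # gap 4
  expect_length(close_gaps(list(t1, t3), 10, 3), 2L)
})

test_that("gap-closing assignment equals the exhaustive matching optimum", {
  set.seed(8)
  for (trial in 1:15) {
    ends <- lapply(1:3, function(i) {
      data.frame(frame = 0:3, x = runif(1, 0, 40) + 0:3, y = runif(1, 0, 40),
                 intensity = 1)
    })
    starts <- lapply(1:3, function(i) {
      data.frame(frame = 6:9, x = runif(1, 0, 40) + 0:3, y = runif(1, 0, 40),
                 intensity = 1)
    })
    tracks <- close_gaps(c(ends, starts), 10, 3)
    e_xy <- do.call(rbind, lapply(ends, function(t) c(t$x[4], t$y[4])))
    s_xy <- do.call(rbind, lapply(starts, function(t) c(t$x[1], t$y[1])))
    d <- ernetdyn:::cross_dist(e_xy, s_xy)
    cost <- d^2; cost[d > 10] <- Inf
    n_merge <- 6L - length(tracks)
    got <- sum(vapply(tracks, function(tr) {
      s <- tr$spots
      jumps <- which(diff(s$frame) > 1)
      sum((s$x[jumps + 1] - s$x[jumps])^2 + (s$y[jumps + 1] - s$y[jumps])^2)
    }, numeric(1)))
    expect_equal(got + 100 * (6 - 2 * n_merge),
                 brute_link_cost(cost, 100), tolerance = 1e-9)
  }
})

test_that("track filtering is strict at the 10-frame default", {
  mk <- function(n) structure(list(
    spots = data.frame(frame = seq_len(n) - 1, x = 0, y = 0, intensity = 1),
    gaps = list()), class = "Track")
  kept <- filter_tracks(list(mk(10), mk(11), mk(3)))
  expect_length(kept, 1L)
  expect_identical(nrow(kept[[1]]$spots), 11L)
  expect_length(filter_tracks(list()), 0L)
})

test_that("velocities convert pixels and frames to um/s, CDF is a proper CDF", {
  tr <- structure(list(spots = data.frame(frame = 0:9, x = 0:9, y = 0,
                                          intensity = 1), gaps = list()),
                  class = "Track")
  vs <- velocity_stats(list(tr), 0.1, 0.1)
  expect_true(all(vs$instantaneous_velocities == 1.0))
  expect_true(all(diff(vs$cdf$fraction) >= 0))
  expect_identical(vs$cdf$fraction[nrow(vs$cdf)], 1)
  still <- structure(list(spots = data.frame(frame = 0:9, x = 1, y = 1,
                                             intensity = 1), gaps = list()),
                     class = "Track")
  expect_true(all(velocity_stats(list(still), 0.1,
                                 0.1)$instantaneous_velocities == 0))
  expect_error(velocity_stats(list(), 0.1, 0.1), "2 spots")
})

test_that("filtered tracks follow true junction trajectories on a resolvable network", {
  # hexagonal seed lattice: uniform Voronoi edge lengths, so no
  # sub-resolution junction pairs that would merge under the PSF
  hex_seeds <- function(w, h, spacing, jitter, seed) {
    set.seed(seed)
    ys <- seq(spacing / 2, h - 1 - spacing / 2, by = spacing * sqrt(3) / 2)
    pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
      off <- if (i %% 2 == 0) spacing / 2 else 0
      xs <- seq(spacing / 2 + off, w - 1 - spacing / 2, by = spacing)
      cbind(xs, ys[i])
    }))
    pts + matrix(runif(length(pts), -0.5, 0.5) * jitter * spacing, ncol = 2)
  }
  sp <- hex_seeds(640, 640, 52, 0.12, 7)
  net <- generate_network(640, 640, nrow(sp), pixel_size_um = 0.1,
                          seed_points = sp)
  sim <- simulate_dynamics(net, 0.05, 0.1, 50, noise = "poisson_gauss",
                           seed = 7)
  res <- run_dynamics(default_config(), tl = sim$timelapse)
  tts <- sim$truth$true_tracks
  match_frac <- mean(vapply(res$tracks, function(tr) {
    f <- tr$spots$frame + 1L
    dmean <- min(vapply(tts, function(tt) {
      mean(sqrt((tt[f, 1] - tr$spots$x)^2 + (tt[f, 2] - tr$spots$y)^2))
    }, numeric(1)))
    dmean < 2
  }, logical(1)))
  expect_gte(match_frac, 0.9)
  expect_equal(res$diffusion$D, 0.05, tolerance = 0.25)
})

test_that("diffusion estimation recovers known D, scales linearly, clips at zero", {
  tr1 <- brownian_tracks(200, 50, 0.05, 0.1, 0.1, seed = 9)
  est1 <- estimate_diffusion(tr1, 0.1, 0.1)
  expect_equal(est1$D, 0.05, tolerance = 0.15)
  tr2 <- brownian_tracks(200, 50, 0.10, 0.1, 0.1, seed = 10)
  est2 <- estimate_diffusion(tr2, 0.1, 0.1)
  expect_equal(est2$D / est1$D, 2, tolerance = 0.2)
  still <- lapply(1:10, function(i) structure(list(
    spots = data.frame(frame = 0:10, x = i, y = i, intensity = 1),
    gaps = list()), class = "Track"))
  est0 <- estimate_diffusion(still, 0.1, 0.1)
  expect_identical(est0$D, 0)
  expect_error(estimate_diffusion(still[1:3], 0.1, 0.1), "at least")
})
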