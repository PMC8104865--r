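# Kinetic trace quantification: ROI traces, normalizations, radial
# photoactivation read-outs.

blob_stack <- function(masses, h = 64, w = 64, cx = 32, cy = 32, r = 5) {
  idx <- which((row(matrix(0, h, w)) - (cy + 1))^2 +
                 (col(matrix(0, h, w)) - (cx + 1))^2 <= r^2)
  n_px <- length(idx)
  frames <- lapply(masses, function(M) {
    m <- matrix(0, h, w)
    m[idx] <- M / n_px
    image_frame(m, 0.1)
  })
  time_lapse(frames, 0.5)
}

test_that("integrated ROI traces subtract background and track known mass", {
  tl <- time_lapse(lapply(1:4, function(i) image_frame(matrix(2, 64, 64), 0.1)),
                   0.5)
  roi <- roi_disc(20, 20, 5)
  bg <- roi_disc(45, 45, 5)
  tr <- integrated_roi_trace(tl, roi, bg)
  expect_true(all(tr$raw == 0))                      # identical content
  masses <- c(10, 55, 120, 200, 260)
  tlb <- blob_stack(masses)
  trb <- integrated_roi_trace(tlb, roi_disc(32, 32, 10))
  expect_equal(trb$raw, masses, tolerance = 5e-3)     # generator bookkeeping
  expect_equal(trb$times_s, (0:4) * 0.5)
  # constant blob of mass M with empty background region
  trc <- integrated_roi_trace(blob_stack(c(42, 42)), roi_disc(32, 32, 10),
                              roi_disc(10, 10, 10))
  expect_true(all(trc$raw == 42))
})

test_that("ROI traces are linear in the image and strict about geometry", {
  set.seed(11)
  a <- lapply(1:3, function(i) image_frame(matrix(runif(64^2), 64, 64), 0.1))
  b <- lapply(1:3, function(i) image_frame(matrix(runif(64^2), 64, 64), 0.1))
  comb <- lapply(1:3, function(i) {
    image_frame(2 * a[[i]]$pixels + 3 * b[[i]]$pixels, 0.1)
  })
  roi <- roi_disc(30, 30, 6)
  tr <- function(fl) integrated_roi_trace(time_lapse(fl, 1), roi)$raw
  expect_equal(tr(comb), 2 * tr(a) + 3 * tr(b), tolerance = 1e-12)
  tl <- time_lapse(a, 1)
  expect_error(integrated_roi_trace(tl, roi_disc(2, 2, 6)), "outside")
  expect_error(integrated_roi_trace(tl, roi, roi_disc(30, 30, 3)),
               "sizes differ")
})

test_that("normalization modes match their definitions and are idempotent", {
  tr <- kinetic_trace(0:2, c(5, 7, 10))
  mm <- normalize_trace(tr, "minmax")
  expect_equal(mm$normalized, c(0, 0.4, 1))
  expect_identical(mm$normalized[1], 0)
  expect_identical(max(mm$normalized), 1)
  expect_equal(normalize_trace(mm, "minmax")$normalized, mm$normalized)
  mx <- normalize_trace(kinetic_trace(0:2, c(2, 4, 8)), "max")
  expect_equal(mx$normalized, c(0.25, 0.5, 1))
  expect_equal(normalize_trace(mx, "max")$normalized, mx$normalized)
  expect_error(normalize_trace(kinetic_trace(0:2, rep(3, 3)), "minmax"),
               "initial value")
  expect_error(normalize_trace(kinetic_trace(0:2, c(0, 0, 0)), "max"),
               "non-positive")
})

test_that("radial traces sit at the requested distances and fail loudly off-image", {
  # a uniformly brightening blob: every ROI trace rises monotonically
  base <- matrix(0, 200, 200)
  base[80:120, 80:120] <- 1
  tl <- time_lapse(lapply(1:5, function(i) image_frame(i * base, 0.1)), 0.5)
  tr0 <- radial_traces(tl, c(99.5, 99.5), distances_um = 0,
                       roi_radius_px = 5, bearing_deg = 0)
  expect_identical(tr0[["0um"]]$roi_descriptor$center,
                   c(x = 99.5, y = 99.5))
  expect_equal(tr0[["0um"]]$normalized, (0:4) / 4)
  expect_error(radial_traces(tl, c(99.5, 99.5), distances_um = 30,
                             roi_radius_px = 5, bearing_deg = 0),
               "30")
  static <- time_lapse(lapply(1:3, function(i) {
    image_frame(matrix(5, 64, 64), 0.1)
  }), 0.5)
  expect_error(radial_traces(static, c(31, 31), 1, 3, 0), "initial value")
})

test_that("diffusive-front half-rise times order strictly with distance", {
  for (s in 1:2) {
    tl <- simulate_photoactivation(400, 400, 2.5, pixel_size_um = 0.1,
                                   frame_interval_s = 0.5, n_frames = 120,
                                   center_px = c(60, 199.5),
                                   init_radius_px = 10, amplitude = 1000,
                                   noise_sd = 0.2, seed = s)
    hr <- vapply(radial_traces(tl, c(60, 199.5), c(8, 12, 16), 6, 0),
                 half_rise_time, numeric(1))
    expect_true(all(diff(hr) > 0))
  }
})
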