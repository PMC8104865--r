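# Synthetic generator: network geometry, rendering, Brownian dynamics,
# kinetic traces.

test_that("jittered-Voronoi networks have three-way interior vertices and exact area bookkeeping", {
  for (s in 1:4) {
    net <- generate_network(256, 256, 30, jitter = 0.4, pixel_size_um = 0.1,
                            seed = s)
    expect_true(all(net$node_degrees[net$interior] == 3))
    expect_true(all(net$node_degrees[!net$interior] %in% 1:2))
    expect_true(all(net$polygon_cells > 0))
    # cells tile the field rectangle exactly
    expect_equal(sum(net$cell_areas_px2), (256 - 1)^2, tolerance = 1e-9)
    # edges reference existing nodes, no self-loops
    expect_true(all(net$edges >= 1 & net$edges <= nrow(net$node_positions)))
    expect_true(all(net$edges[, 1] != net$edges[, 2]))
  }
})

test_that("generate_network is deterministic in its seed", {
  a <- generate_network(128, 128, 12, seed = 42)
  b <- generate_network(128, 128, 12, seed = 42)
  expect_identical(a$node_positions, b$node_positions)
  expect_identical(a$edges, b$edges)
  c <- generate_network(128, 128, 12, seed = 43)
  expect_false(identical(a$seed_points, c$seed_points))
})

test_that("four corner seeds plus center give one bounded diamond cell of known area", {
  sp <- rbind(c(100, 100), c(300, 100), c(300, 300), c(100, 300), c(200, 200))
  net <- generate_network(401, 401, 5, pixel_size_um = 0.1, seed_points = sp)
  expect_length(net$polygon_cells, 1L)
  # center cell is the square rotated 45 degrees: area = 200^2 / 2 px^2
  expect_equal(net$polygon_cells, 200^2 / 2 * 0.01, tolerance = 1e-6)
  expect_true(all(net$node_degrees[net$interior] == 3))
})

test_that("bounded-cell count matches an independent computational-geometry oracle", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  for (s in c(7, 19)) {
    net <- generate_network(512, 512, 50, jitter = 0.4, seed = s)
    csv <- tempfile(fileext = ".csv")
    write.csv(net$seed_points, csv, row.names = FALSE)
    py <- tempfile(fileext = ".py")
    writeLines(c(
      "import numpy as np",
      "from scipy.spatial import Voronoi",
      sprintf("pts = np.loadtxt(%s, delimiter=',', skiprows=1)", deparse(csv)),
      "w1 = 511.0; eps = 1e-6; vor = Voronoi(pts); count = 0",
      "for reg_i in vor.point_region:",
      "    reg = vor.regions[reg_i]",
      "    if -1 in reg or len(reg) == 0: continue",
      "    v = vor.vertices[reg]",
      "    if (v > eps).all() and (v < w1 - eps).all(): count += 1",
      "print(count)"), py)
    oracle <- as.integer(system2("python", py, stdout = TRUE))
    expect_identical(length(net$polygon_cells), oracle)
  }
})

test_that("degenerate geometry is rejected", {
  expect_error(generate_network(64, 64, 200, seed = 1), "degenerate")
  expect_error(generate_network(128, 128, 5,
                                seed_points = rbind(c(1, 1), c(1.5, 1),
                                                    c(50, 50), c(90, 90))),
               "degenerate")
})

test_that("render_network draws exact 1-px lines and background-only frames", {
  net <- generate_network(128, 128, 6, seed = 1)
  net$edges <- matrix(integer(0), 0, 2)
  expect_warning(fr <- render_network(net, psf_sigma_px = 0, background = 10,
                                      noise = "none"), "background-only")
  expect_true(all(fr$pixels == 10))
  # single horizontal edge at psf 0: exactly the line over background
  net2 <- generate_network(128, 128, 6, seed = 1)
  net2$node_positions <- rbind(c(20, 64), c(100, 64))
  net2$edges <- matrix(c(1L, 2L), 1, 2)
  fr2 <- render_network(net2, psf_sigma_px = 0, tubule_intensity = 50,
                        background = 2, noise = "none")
  expect_equal(sum(fr2$pixels == 50), 81)            # 81 px from x=20..100
  expect_true(all(fr2$pixels[65, 21:101] == 50))     # row y=64 (1-based 65)
  expect_true(all(fr2$pixels[-65, ] == 2))
  # with a PSF and no noise the global maximum lies on a drawn structure
  fr3 <- render_network(net2, psf_sigma_px = 1.5, tubule_intensity = 50,
                        background = 2, noise = "none")
  peak <- which(fr3$pixels == max(fr3$pixels), arr.ind = TRUE)
  expect_true(all(peak[, 1] == 65))
})

test_that("Poisson-Gaussian noise matches its moment formula", {
  net <- generate_network(256, 256, 6, seed = 2)
  net$edges <- matrix(integer(0), 0, 2)  # background-only: one clean patch
  suppressWarnings({
    fr <- render_network(net, psf_sigma_px = 0, tubule_intensity = 100,
                         background = 50, noise = "poisson_gauss",
                         read_noise_sd = 3, seed = 9)
  })
  patch <- fr$pixels[11:150, 11:150]  # 19600 px, away from any structure
  expect_gt(length(patch), 1e4)
  expect_equal(mean(patch), 50, tolerance = 0.02)
  expect_equal(var(as.vector(patch)), 50 + 9, tolerance = 0.1)
})

test_that("Brownian dynamics: D = 0 freezes, MSD matches 4 D t, determinism holds", {
  net <- generate_network(256, 256, 20, seed = 3)
  still <- simulate_dynamics(net, 0, 0.1, 12, noise = "none", seed = 1)
  expect_identical(still$timelapse$frames[[1]]$pixels,
                   still$timelapse$frames[[12]]$pixels)
  expect_true(all(vapply(still$truth$true_tracks,
                         function(m) all(m[1, ] == m[nrow(m), ]),
                         logical(1))))
  # same seed => byte-identical stack
  a <- simulate_dynamics(net, 0.05, 0.1, 11, noise = "poisson_gauss", seed = 5)
  b <- simulate_dynamics(net, 0.05, 0.1, 11, noise = "poisson_gauss", seed = 5)
  expect_identical(lapply(a$timelapse$frames, `[[`, "pixels"),
                   lapply(b$timelapse$frames, `[[`, "pixels"))
  # MSD of true tracks: big ensemble, no rendering
  big <- generate_network(640, 640, 140, seed = 4)
  sim <- simulate_dynamics(big, 0.05, 0.1, 50, render = FALSE, seed = 4)
  expect_gte(length(sim$truth$true_tracks), 200)
  for (lag in c(1, 4)) {
    msd_px2 <- mean(unlist(lapply(sim$truth$true_tracks, function(m) {
      rowSums((m[-seq_len(lag), , drop = FALSE] -
                 m[seq_len(nrow(m) - lag), , drop = FALSE])^2)
    })))
    expect_equal(msd_px2 * 0.1^2, 4 * 0.05 * 0.1 * lag, tolerance = 0.1)
  }
  # per-axis increment variance within 5% over >= 1e4 increments
  incs <- unlist(lapply(sim$truth$true_tracks, function(m) diff(m[, 1])))
  expect_gte(length(incs), 1e4)
  expect_equal(var(incs), 2 * 0.05 * 0.1 / 0.1^2, tolerance = 0.05)
})

test_that("a step SD above a quarter edge length warns", {
  net <- generate_network(128, 128, 8, seed = 6)
  expect_warning(simulate_dynamics(net, 5, 0.5, 11, render = FALSE, seed = 1),
                 "self-intersection")
})

test_that("transport traces follow the saturating form", {
  tr <- simulate_transport_trace(t0_s = 5, rate_k_per_s = 0.2, n_points = 400,
                                 frame_interval_s = 0.1, noise_sd = 0)
  expect_true(all(tr$raw[tr$times_s < 5] == 0))
  expect_equal(tr$raw[length(tr$raw)], 1 - exp(-0.2 * (39.9 - 5)),
               tolerance = 1e-12)
  expect_lt(abs(tr$raw[400] - 1), 0.001)
  # time to half saturation inverts to t0 + ln(2)/k
  t_half <- approx(tr$raw[tr$times_s >= 5], tr$times_s[tr$times_s >= 5],
                   xout = 0.5)$y
  expect_equal(t_half, 5 + log(2) / 0.2, tolerance = 0.01)
})

test_that("photoactivation spread conserves signal and is deterministic", {
  tl1 <- simulate_photoactivation(128, 128, 1, n_frames = 20, amplitude = 100,
                                  noise_sd = 0, seed = 1)
  tl2 <- simulate_photoactivation(128, 128, 1, n_frames = 20, amplitude = 100,
                                  noise_sd = 0, seed = 1)
  expect_identical(lapply(tl1$frames, `[[`, "pixels"),
                   lapply(tl2$frames, `[[`, "pixels"))
  m0 <- sum(tl1$frames[[1]]$pixels)
  m19 <- sum(tl1$frames[[20]]$pixels)
  expect_equal(m19, m0, tolerance = 0.05)  # edge-renormalized kernel
})
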