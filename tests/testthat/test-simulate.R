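test_that("equal seeds give bit-identical simulations", {
  cfg <- simulation_config(seed = 7, duration = 1, frame_interval = 3,
                           n_clusters = 3, gelation_time = 0.8)
  s1 <- simulate_particle_field(cfg)
  s2 <- simulate_particle_field(cfg)
  expect_identical(s1$series$trajectories, s2$series$trajectories)
  expect_identical(s1$truth$fusion_events, s2$truth$fusion_events)
  s3 <- simulate_particle_field(simulation_config(seed = 8, duration = 1,
                                                  frame_interval = 3,
                                                  n_clusters = 3,
                                                  gelation_time = 0.8))
  expect_false(identical(s1$series$trajectories, s3$series$trajectories))
})

test_that("an empty configuration yields an empty series and no events", {
  cfg <- simulation_config(seed = 1, n_clusters = 0)
  sim <- simulate_particle_field(cfg)
  expect_equal(nrow(sim$series$trajectories), 0)
  expect_equal(nrow(sim$truth$fusion_events), 0)
})

test_that("aggregates accumulate: per-frame particle count is non-decreasing", {
  cfg <- simulation_config(seed = 3, duration = 4, frame_interval = 3,
                           nucleation_rate = 6, gelation_time = 3.5)
  tr <- simulate_particle_field(cfg)$series$trajectories
  counts <- table(factor(tr$frame, levels = min(tr$frame):max(tr$frame)))
  expect_true(all(diff(as.integer(counts)) >= 0))
  expect_gt(max(counts), min(counts))  # nucleation actually happened
})

test_that("with zero jitter every cluster member shares the exact drift", {
  cfg <- simulation_config(seed = 5, duration = 1, frame_interval = 3,
                           jitter_sd = 0, gelation_time = Inf,
                           nucleation_rate = 0, n_clusters = 4)
  sim <- simulate_particle_field(cfg)
  tr <- sim$series$trajectories
  for (cl in unique(tr$cluster_id)) {
    sub <- tr[tr$cluster_id == cl, ]
    for (f in 0:(max(sub$frame) - 1)) {
      a <- sub[sub$frame == f, ]; b <- sub[sub$frame == f + 1, ]
      dx <- b$x_um[match(a$particle_id, b$particle_id)] - a$x_um
      dy <- b$y_um[match(a$particle_id, b$particle_id)] - a$y_um
      # all members move identically...
      expect_lt(max(dx) - min(dx), 1e-9)
      expect_lt(max(dy) - min(dy), 1e-9)
      # ...by the configured flow amplitude per frame
      expect_equal(sqrt(mean(dx)^2 + mean(dy)^2),
                   cfg$flow_amplitude * cfg$frame_interval, tolerance = 1e-9)
    }
  }
})

test_that("arrest at the configured gelation time freezes all displacements", {
  cfg <- simulation_config(seed = 2, duration = 7, frame_interval = 3,
                           jitter_sd = 0, gelation_time = 4.29)
  tr <- simulate_particle_field(cfg)$series$trajectories
  post <- tr[tr$time_h >= 4.29, ]
  moved <- tapply(seq_len(nrow(post)), post$particle_id, function(i)
    max(abs(diff(post$x_um[i]))) + max(abs(diff(post$y_um[i]))))
  expect_identical(max(unlist(moved)), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(gelation_time = 10, duration = 7),
               "gelation_time")
  expect_error(simulation_config(
    n_clusters = 2,
    fusion_schedule = data.frame(cluster_a = 1, cluster_b = 5,
                                 onset_min = 5, duration_min = 1)),
    "unknown clusters")
  expect_error(simulation_config(
    n_clusters = 4,
    fusion_schedule = data.frame(cluster_a = c(1, 3), cluster_b = c(2, 4),
                                 onset_min = c(10, 5),
                                 duration_min = c(1, 1))),
    "strictly increasing")
  expect_error(simulation_config(regime_mixture = 1.4), "probability")
})

test_that("rheology traces are deterministic and validated", {
  t1 <- simulate_rheology_trace(2, 0.28, 3.6, noise_sd = 0.1, seed = 4)
  t2 <- simulate_rheology_trace(2, 0.28, 3.6, noise_sd = 0.1, seed = 4)
  expect_identical(t1$g_prime_pa, t2$g_prime_pa)
  n1 <- simulate_rheology_trace(2, 0.28, 3.6, noise_sd = 0, seed = 1)
  n2 <- simulate_rheology_trace(2, 0.28, 3.6, noise_sd = 0, seed = 99)
  expect_identical(n1$g_prime_pa, n2$g_prime_pa)  # noiseless: seed-free
  expect_error(simulate_rheology_trace(20, 0.28, 3.6, duration = 24),
               "plateau")
  expect_error(simulate_rheology_trace(2, -1, 3.6), "rate_gp")
})

test_that("rendering places the intensity maximum at the spot centre", {
  traj <- data.frame(frame = 0L, particle_id = 1L, x_um = 100, y_um = 50)
  ser <- make_series(traj, frame_interval = 1, field = c(200, 200))
  st <- render_image_stack(ser, spot_sigma_px = 2, pixel_size_um = 2,
                           noise_sd = 0)
  m <- st[[1]]
  peak <- which(m == max(m), arr.ind = TRUE)
  # pixel centres are at (index - 0.5) * pixel size
  expect_lt(abs((peak[1, 2] - 0.5) * 2 - 100), 2 + 1e-9)
  expect_lt(abs((peak[1, 1] - 0.5) * 2 - 50), 2 + 1e-9)
  expect_error(render_image_stack(ser, pixel_size_um = 0), "pixel_size")
})

test_that("an empty frame renders as uniform background", {
  traj <- data.frame(frame = integer(), particle_id = integer(),
                     x_um = numeric(), y_um = numeric())
  ser <- make_series(traj, frame_interval = 1, field = c(60, 60))
  st <- render_image_stack(ser, pixel_size_um = 2, noise_sd = 0,
                           baseline = 0.1)
  expect_equal(length(unique(as.vector(st[[1]]))), 1L)
  expect_equal(st[[1]][1, 1], round(0.1 * 65535) / 65535)
})

test_that("image stacks round-trip through multi-page TIFF", {
  sim <- simulate_particle_field(simulation_config(
    seed = 9, duration = 0.1, frame_interval = 3, n_clusters = 1,
    n_initial = 3, field_size = c(100, 100), nucleation_rate = 0,
    gelation_time = Inf))
  st <- render_image_stack(sim$series, pixel_size_um = 2, noise_sd = 0.02,
                           seed = 5)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(st, path)
  back <- read_image_stack(path, pixel_size_um = 2, frame_interval = 3)
  expect_equal(length(back), length(st))
  expect_equal(back[[1]], st[[1]], tolerance = 1 / 65535)
})
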