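test_that("detection recovers rendered spots to sub-pixel accuracy", {
  traj <- data.frame(frame = 0L, particle_id = 1L, x_um = 100, y_um = 50)
  ser <- make_series(traj, frame_interval = 1, field = c(200, 200))
  st <- render_image_stack(ser, spot_sigma_px = 2, pixel_size_um = 2,
                           noise_sd = 0)
  det <- detect_particles(st, min_intensity = 0.2)
  expect_equal(nrow(det), 1L)
  expect_lt(sqrt((det$x_um - 100)^2 + (det$y_um - 50)^2) / 2, 0.5)

  # blank stack: zero detections per frame is a valid outcome
  blank <- make_series(data.frame(frame = integer(), particle_id = integer(),
                                  x_um = numeric(), y_um = numeric()),
                       frame_interval = 1, field = c(60, 60))
  stb <- render_image_stack(blank, pixel_size_um = 2, noise_sd = 0)
  expect_equal(nrow(detect_particles(stb, min_intensity = 0.2)), 0L)
  expect_error(detect_particles(structure(list(), class = "image_stack")),
               "empty")
})

test_that("a 25-spot grid at SNR 10 is detected and matches 1:1", {
  set.seed(81)
  g <- expand.grid(x = seq(20, 180, length = 5), y = seq(20, 180, length = 5))
  traj <- data.frame(frame = 0L, particle_id = 1:25,
                     x_um = g$x + runif(25, -3, 3),
                     y_um = g$y + runif(25, -3, 3))
  ser <- make_series(traj, frame_interval = 1, field = c(200, 200))
  # amplitude 0.6 over baseline, noise sd 0.06 -> peak SNR 10
  st <- render_image_stack(ser, spot_sigma_px = 2, pixel_size_um = 2,
                           noise_sd = 0.06, seed = 7)
  det <- detect_particles(st, min_intensity = 0.4)
  expect_equal(nrow(det), 25L)
  # nearest-neighbour bipartite match: every truth spot claims a distinct
  # detection within one pixel
  claimed <- sapply(seq_len(25), function(i)
    which.min((det$x_um - traj$x_um[i])^2 + (det$y_um - traj$y_um[i])^2))
  expect_equal(sort(claimed), 1:25)

  # noiseless: all centroids within 0.5 px of the rendered ground truth
  st0 <- render_image_stack(ser, spot_sigma_px = 2, pixel_size_um = 2,
                            noise_sd = 0)
  det0 <- detect_particles(st0, min_intensity = 0.2)
  expect_equal(nrow(det0), 25L)
  errs <- sapply(seq_len(25), function(i)
    min(sqrt((det0$x_um - traj$x_um[i])^2 + (det0$y_um - traj$y_um[i])^2)))
  expect_lt(max(errs) / 2, 0.5)
})

test_that("linking follows single particles and respects max_disp", {
  det <- data.frame(frame = 0:9, x_um = 10 + 2 * (0:9), y_um = 50)
  ser <- link_trajectories(det, max_disp = 5, frame_interval = 1,
                           field_size = c(200, 200))
  expect_equal(length(unique(ser$trajectories$particle_id)), 1L)
  expect_equal(nrow(ser$trajectories), 10L)

  two <- rbind(data.frame(frame = 0:4, x_um = 10 + 2 * (0:4), y_um = 10),
               data.frame(frame = 0:4, x_um = 510 + 2 * (0:4), y_um = 510))
  ser2 <- link_trajectories(two, max_disp = 5, frame_interval = 1,
                            field_size = c(600, 600))
  expect_equal(length(unique(ser2$trajectories$particle_id)), 2L)
  # both tracks span all five frames (no cross-links)
  spans <- tapply(ser2$trajectories$frame, ser2$trajectories$particle_id,
                  length)
  expect_true(all(spans == 5))
  expect_error(link_trajectories(det, max_disp = 0), "max_disp")
})

test_that("linking agrees with an exhaustive optimal-assignment oracle", {
  set.seed(19)
  n <- 8; n_frames <- 5; step <- 1.5
  x <- matrix(0, n_frames, n); y <- matrix(0, n_frames, n)
  x[1, ] <- runif(n, 0, 400); y[1, ] <- runif(n, 0, 400)
  for (f in 2:n_frames) {
    x[f, ] <- x[f - 1, ] + rnorm(n, 0, step)
    y[f, ] <- y[f - 1, ] + rnorm(n, 0, step)
  }
  det <- do.call(rbind, lapply(seq_len(n_frames), function(f)
    data.frame(frame = f - 1L, x_um = x[f, ], y_um = y[f, ], truth = 1:n)))
  # shuffle within frames so input order carries no information
  det <- det[order(det$frame, runif(nrow(det))), ]
  ser <- link_trajectories(det[, 1:3], max_disp = 20, frame_interval = 1,
                           field_size = c(400, 400))
  # oracle: frame-by-frame optimal assignment by brute-force enumeration
  tr <- ser$trajectories
  for (f in 1:(n_frames - 1)) {
    a <- det[det$frame == f - 1, ]; b <- det[det$frame == f, ]
    p <- brute_assignment(a$x_um, a$y_um, b$x_um, b$y_um)
    la <- tr$particle_id[match(paste(f - 1, a$x_um), paste(tr$frame, tr$x_um))]
    lb <- tr$particle_id[match(paste(f, b$x_um[p]), paste(tr$frame, tr$x_um))]
    expect_identical(la, lb)
  }
})

test_that("gap closing bridges missed frames", {
  det <- data.frame(frame = c(0, 1, 3, 4), x_um = c(0, 2, 6, 8), y_um = 0)
  ser <- link_trajectories(det, max_disp = 3, gap_frames = 1,
                           frame_interval = 1, field_size = c(50, 50))
  expect_equal(length(unique(ser$trajectories$particle_id)), 1L)
  ser0 <- link_trajectories(det, max_disp = 3, gap_frames = 0,
                            frame_interval = 1, field_size = c(50, 50))
  expect_equal(length(unique(ser0$trajectories$particle_id)), 2L)
})

test_that("speed profile implements mean-flow subtraction exactly", {
  # common drift, no jitter: flow-subtracted speeds are identically zero
  traj <- do.call(rbind, lapply(1:4, function(p)
    data.frame(frame = 0:5, particle_id = p,
               x_um = 10 * p + 3 * (0:5), y_um = 20 + 2 * (0:5))))
  prof <- compute_speed_profile(make_series(traj, frame_interval = 1))
  expect_equal(max(prof$profile$mean_speed_um_min), 0)

  # equal and opposite velocities: zero mean flow, each speed = |v|
  tr2 <- rbind(data.frame(frame = 0:5, particle_id = 1,
                          x_um = 100 + 4 * (0:5), y_um = 50),
               data.frame(frame = 0:5, particle_id = 2,
                          x_um = 300 - 4 * (0:5), y_um = 50))
  p2 <- compute_speed_profile(make_series(tr2, frame_interval = 1))
  expect_equal(p2$profile$flow_x_um_min, rep(0, 5))
  expect_equal(p2$speeds$speed_um_min, rep(4, 10))
})

test_that("replicate mean speed matches a direct recomputation", {
  sim <- simulate_particle_field(simulation_config(
    seed = 23, duration = 1, frame_interval = 3, n_clusters = 4,
    gelation_time = Inf))
  prof <- compute_speed_profile(sim$series)
  tr <- sim$series$trajectories
  # independent oracle straight off the displacement table
  for (f in c(0, 7, 15)) {
    a <- tr[tr$frame == f, ]; b <- tr[tr$frame == f + 1, ]
    ids <- intersect(a$particle_id, b$particle_id)
    dx <- b$x_um[match(ids, b$particle_id)] - a$x_um[match(ids, a$particle_id)]
    dy <- b$y_um[match(ids, b$particle_id)] - a$y_um[match(ids, a$particle_id)]
    sp <- sqrt((dx - mean(dx))^2 + (dy - mean(dy))^2) / 3
    expect_equal(prof$profile$mean_speed_um_min[prof$profile$frame_a == f],
                 mean(sp))
  }
})

test_that("flow-subtraction residuals sum to zero every frame pair", {
  sim <- simulate_particle_field(simulation_config(
    seed = 31, duration = 2, frame_interval = 3, n_clusters = 5,
    gelation_time = 1.5))
  tr <- sim$series$trajectories
  for (f in unique(tr$frame)[-length(unique(tr$frame))]) {
    a <- tr[tr$frame == f, ]; b <- tr[tr$frame == f + 1, ]
    ids <- intersect(a$particle_id, b$particle_id)
    if (length(ids) < 1) next
    dx <- b$x_um[match(ids, b$particle_id)] - a$x_um[match(ids, a$particle_id)]
    dy <- b$y_um[match(ids, b$particle_id)] - a$y_um[match(ids, a$particle_id)]
    scale <- max(1, max(abs(c(dx, dy))))
    expect_lt(abs(sum(dx - mean(dx))) / scale, 1e-9)
    expect_lt(abs(sum(dy - mean(dy))) / scale, 1e-9)
  }
})

test_that("gelation time is recovered within one frame on noiseless arrest", {
  cfg <- simulation_config(seed = 11, duration = 7, frame_interval = 3,
                           jitter_sd = 0, gelation_time = 4.29)
  est <- estimate_gelation_time(
    compute_speed_profile(simulate_particle_field(cfg)$series))
  expect_true(est$gelled)
  expect_lt(abs(est$gelation_time_h - 4.29), 3 / 60 + 1e-9)
})

test_that("degenerate mobility records are classified correctly", {
  # always stationary: gelation time 0
  tr <- do.call(rbind, lapply(1:3, function(p)
    data.frame(frame = 0:30, particle_id = p, x_um = 10 * p, y_um = 5)))
  est0 <- estimate_gelation_time(
    compute_speed_profile(make_series(tr, frame_interval = 3)))
  expect_true(est0$gelled)
  expect_identical(est0$gelation_time_h, 0)

  # never arrested: not gelled
  sim <- simulate_particle_field(simulation_config(
    seed = 4, duration = 3, frame_interval = 3, gelation_time = Inf))
  estInf <- estimate_gelation_time(compute_speed_profile(sim$series))
  expect_false(estInf$gelled)
  expect_true(is.na(estInf$gelation_time_h))

  # record shorter than the persistence window is an error
  short <- tr[tr$frame <= 3, ]
  expect_error(estimate_gelation_time(
    compute_speed_profile(make_series(short, frame_interval = 3)),
    persistence_h = 0.5), "persistence")
})

test_that("delaying the simulated arrest never decreases the estimate", {
  est_at <- function(g) {
    cfg <- simulation_config(seed = 13, duration = 7, frame_interval = 3,
                             jitter_sd = 0, gelation_time = g)
    estimate_gelation_time(
      compute_speed_profile(simulate_particle_field(cfg)$series))$gelation_time_h
  }
  ests <- vapply(c(2, 3, 4, 5, 6), est_at, numeric(1))
  expect_true(all(diff(ests) >= 0))
})

test_that("gelation recovery holds across 20 seeds at default noise", {
  rel_err <- vapply(1:20, function(s) {
    g <- 4
    cfg <- simulation_config(seed = s, duration = 6.5, frame_interval = 3,
                             gelation_time = g)
    est <- estimate_gelation_time(
      compute_speed_profile(simulate_particle_field(cfg)$series))
    abs(est$gelation_time_h - g) / g
  }, numeric(1))
  expect_gte(mean(rel_err <= 0.1), 0.9)
})
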