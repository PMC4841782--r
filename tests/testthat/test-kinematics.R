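test_that("smoothing preserves stationary and constant-velocity motion", {
  fr <- 100
  t <- seq(0, 10, by = 1 / fr)
  still <- swim_trajectory(t, rep(3, length(t)), rep(-2, length(t)),
                           frame_rate = fr)
  sv <- smooth_and_velocity(still)
  expect_true(all(sv$speed == 0))
  # constant velocity: linear-phase FIR preserves linear trends
  mov <- swim_trajectory(t, 1.5 * t, -2 * t, frame_rate = fr)
  sp <- smooth_and_velocity(mov)$speed
  interior <- 30:(length(t) - 30)
  expect_equal(sp[interior], rep(sqrt(1.5^2 + 2^2), length(interior)),
               tolerance = 1e-9)
})

test_that("per-bout peak speed matches the kernel-convolved analytic profile", {
  fr <- 100
  traj <- make_bout_train(c(2, 5, 8), c(0.4, -0.6, 0.2), frame_rate = fr)
  sv <- smooth_and_velocity(traj)
  # oracle: convolve the analytic speed profile with the same FIR taps
  w <- slalom:::gaussian_kernel(400, 70, fr)
  tt <- seq(0, 1.5, by = 1 / fr)
  prof <- 20 * exp(-tt / 0.15)
  expected_peak <- max(stats::convolve(c(rep(0, 100), prof), rev(w), type = "open"))
  peaks <- detect_bouts(sv$speed, fr)
  expect_length(peaks, 3)
  for (p in peaks) {
    expect_equal(sv$speed[p], expected_peak, tolerance = 0.1)
  }
})

test_that("bout detection crossings, refractory merge, and empty input", {
  fr <- 100
  cfg <- kinematics_config()
  expect_length(detect_bouts(rep(1, 1000), fr, cfg), 0)
  # two well-separated humps
  t <- seq(0, 10, by = 1 / fr)
  sp <- 10 * exp(-((t - 3)^2) / 0.01) + 8 * exp(-((t - 7)^2) / 0.01)
  pk <- detect_bouts(sp, fr, cfg)
  expect_length(pk, 2)
  expect_equal(t[pk], c(3, 7), tolerance = 1.5 / fr)
  # double-humped supra-threshold epoch within the refractory window
  sp2 <- 10 * exp(-((t - 3)^2) / 0.002) + 9 * exp(-((t - 3.1)^2) / 0.002)
  expect_length(detect_bouts(sp2, fr, cfg), 1)
  bad_cfg <- kinematics_config()
  bad_cfg$velocity_threshold <- -1
  expect_error(detect_bouts(sp, fr, bad_cfg), "positive")
})

test_that("turn angles difference the heading across the 250 ms window", {
  fr <- 100
  n <- 1001
  t <- (seq_len(n) - 1) / fr
  # heading steps from 0.2 to 0.5 exactly at the peak
  heading <- ifelse(t < 5, 0.2, 0.5)
  traj <- swim_trajectory(t, cos(t), sin(t), heading = heading, frame_rate = fr,
                          arena_radius = 1000)
  ev <- compute_turn_angles(traj, peaks = 501L)
  expect_equal(ev$turn_angle, 0.3, tolerance = 1e-12)
  expect_true(ev$is_turn)
  # wrap: -3.0 before, +3.0 after crosses the branch cut
  heading2 <- ifelse(t < 5, -3.0, 3.0)
  traj2 <- swim_trajectory(t, cos(t), sin(t), heading = heading2,
                           frame_rate = fr, arena_radius = 1000)
  ev2 <- compute_turn_angles(traj2, peaks = 501L)
  expect_equal(ev2$turn_angle, 6 - 2 * pi, tolerance = 1e-12)
  # sub-threshold heading change is not a turn
  heading3 <- ifelse(t < 5, 0, 0.10)
  traj3 <- swim_trajectory(t, cos(t), sin(t), heading = heading3,
                           frame_rate = fr, arena_radius = 1000)
  expect_false(compute_turn_angles(traj3, peaks = 501L)$is_turn)
  # events too close to the record edge are dropped and counted
  ev4 <- compute_turn_angles(traj, peaks = c(10L, 501L))
  expect_equal(nrow(ev4), 1)
  expect_equal(attr(ev4, "n_edge_dropped"), 1)
})

test_that("wall exclusion uses distance from the dish edge", {
  ev <- data.frame(t_peak = c(1, 2, 3), turn_angle = 0.3, magnitude = 0.3,
                   is_turn = TRUE, displacement = 1,
                   distance_from_wall = c(46, 6, 12))
  cfg <- kinematics_config() # 10 mm exclusion
  kept <- filter_wall_events(ev, cfg)
  # dish radius 46: center kept, 6 mm from wall excluded, 12 mm kept
  expect_equal(kept$distance_from_wall, c(46, 12))
  cfg0 <- kinematics_config(wall_exclusion = 0)
  expect_equal(nrow(filter_wall_events(ev, cfg0)), 3)
})

test_that("turn angles are odd under mirror reflection and |turn| is rotation invariant", {
  sim <- generate_free_swim(swim_gen_params(duration = 60, seed = 21,
                                            centroid_noise_sd = 0))
  tr <- sim$trajectory
  ev <- suppressWarnings(extract_bouts(tr, exclude_wall = FALSE))
  # mirror: y -> -y flips every heading sign
  tr_m <- swim_trajectory(tr$data$t, tr$data$x, -tr$data$y,
                          heading = -tr$data$heading,
                          frame_rate = tr$frame_rate,
                          arena_center = tr$arena_center,
                          arena_radius = tr$arena_radius)
  ev_m <- suppressWarnings(extract_bouts(tr_m, exclude_wall = FALSE))
  expect_equal(ev_m$turn_angle, -ev$turn_angle, tolerance = 1e-9)
  # global rotation: total |turn| unchanged
  phi <- 1.1
  tr_r <- swim_trajectory(tr$data$t,
                          tr$data$x * cos(phi) - tr$data$y * sin(phi),
                          tr$data$x * sin(phi) + tr$data$y * cos(phi),
                          heading = tr$data$heading + phi,
                          frame_rate = tr$frame_rate,
                          arena_center = tr$arena_center,
                          arena_radius = tr$arena_radius)
  ev_r <- suppressWarnings(extract_bouts(tr_r, exclude_wall = FALSE))
  expect_equal(sum(ev_r$magnitude), sum(ev$magnitude), tolerance = 1e-9)
})

test_that("zero-noise synthetic bouts are recovered with small angle error", {
  traj <- make_bout_train(seq(2, 20, by = 1.5), rep(c(0.5, -0.3), length.out = 13))
  ev <- extract_bouts(traj, exclude_wall = FALSE)
  expect_equal(nrow(ev), 13)
  expect_equal(ev$turn_angle, rep(c(0.5, -0.3), length.out = 13),
               tolerance = 2 * pi / 180)
})

test_that("trajectory validation rejects non-uniform sampling", {
  expect_error(swim_trajectory(c(0, 0.01, 0.5), 1:3, 1:3), "non-uniform")
  expect_error(swim_trajectory(c(0, 0, 0.01), 1:3, 1:3), "increasing")
})
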