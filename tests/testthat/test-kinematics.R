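test_that("central differences are exact for linear and uniformly accelerated motion", {
  fr <- 1000
  t <- (0:199) / fr
  # straight line at 0.2 m/s (x in mm)
  pos <- cbind(200 * t, 0, 0)
  ka <- compute_speed_acceleration(pos, fr)
  expect_equal(ka$speed, rep(0.2, 200), tolerance = 1e-9)
  # stationary hover
  kh <- compute_speed_acceleration(matrix(3, 100, 3), fr)
  expect_equal(kh$speed, rep(0, 100), tolerance = 1e-12)
  expect_equal(kh$accel, rep(0, 100), tolerance = 1e-12)
  # 5 m/s^2 from rest over 0.1 s -> 0.5 m/s at the end, within 1%
  t2 <- (0:100) / fr
  pos2 <- cbind(0.5 * 5000 * t2^2, 0, 0) # mm
  ka2 <- compute_speed_acceleration(pos2, fr)
  expect_equal(ka2$speed[101], 0.5, tolerance = 0.01)
  expect_equal(median(ka2$accel), 5, tolerance = 0.01)
})

test_that("the attack window starts after the final hover", {
  # programmed hover then sharp dart, no digitization noise
  p <- attack_gen_params(hover_duration = 100, hover_jitter_sd = 0.01,
                         digitization_noise_sd = 0, peak_speed = 0.25,
                         onset_ramp_ms = 0)
  tr <- gen_attack(p, outcome = "capture", end_distance = 2, seed = 7)
  kin <- attack_kinematics(tr)
  truth <- attr(tr, "truth")
  expect_true(kin$window$hover_found)
  expect_lte(abs(kin$window$start - truth$dart_onset_frame), 5)

  # monotone approach with no hover falls back to the full series
  p2 <- attack_gen_params(hover_duration = 0, onset_ramp_ms = 0,
                          profile = "constant_speed", peak_speed = 0.2,
                          digitization_noise_sd = 0)
  tr2 <- gen_attack(p2, outcome = "capture", end_distance = 2, seed = 1)
  sp2 <- compute_speed_acceleration(tr2$points$damselfly_head, 1000)$speed
  expect_warning(w2 <- detect_attack_window(sp2, 1000), "no hover")
  expect_false(w2$hover_found)
  expect_equal(w2$start, 1L)

  # an all-stationary series has no attack at all
  expect_error(detect_attack_window(rep(0.001, 300), 1000),
               class = "loomstrike_no_attack")
})

test_that("prey-centred angles handle the axis cases and stay in range", {
  # damselfly approaching along +x at the fly's height
  tr <- make_line_traj(c(30, 0, 0), c(3, 0, 0), n = 20)
  ang <- elevation_azimuth(tr)
  expect_equal(ang$mean_elevation, 0)
  expect_equal(ang$mean_azimuth, 0)
  # directly above: elevation 90, azimuth undefined
  up <- make_line_traj(c(0, 0, 30), c(0, 0, 3), n = 20)
  angu <- elevation_azimuth(up)
  expect_equal(angu$mean_elevation, 90)
  expect_true(all(is.na(angu$azimuth)))
  expect_equal(angu$n_undefined, 20L)
  # behind the fly: folded azimuth is 180
  back <- make_line_traj(c(-30, 0, 0), c(-3, 0, 0), n = 20)
  expect_equal(elevation_azimuth(back)$mean_azimuth, 180)
  # lateral symmetry: +y and -y approaches fold onto the same azimuth
  left <- make_line_traj(c(10, 20, 5), c(2, 4, 1), n = 20)
  right <- make_line_traj(c(10, -20, 5), c(2, -4, 1), n = 20)
  expect_equal(elevation_azimuth(left)$azimuth,
               elevation_azimuth(right)$azimuth)
})

test_that("angles stay in [0,180] x [-90,90] for random geometries", {
  set.seed(42)
  n <- 1e4
  head <- matrix(runif(3 * n, -50, 50), n, 3)
  tr <- tracked_trajectory(head, head + 1, matrix(0, n, 3))
  ang <- elevation_azimuth(tr, reference = "per_frame")
  ok <- !is.na(ang$azimuth)
  expect_true(all(ang$azimuth[ok] >= 0 & ang$azimuth[ok] <= 180))
  expect_true(all(ang$elevation >= -90 & ang$elevation <= 90, na.rm = TRUE))
})

test_that("peak metrics break ties to the latest frame", {
  speed <- c(0.1, 0.3, 0.3, 0.2, 0.3, 0.1)
  accel <- rep(0, 6)
  pk <- peak_metrics(speed, accel, list(start = 1, end = 6), 1000, 6)
  expect_equal(pk$peak_speed, 0.3)
  expect_equal(pk$time_of_peak_speed_ms, (5 - 6) / 1000 * 1000) # frame 5
  # constant speed: tie broken to the very last frame (t = 0)
  pk2 <- peak_metrics(rep(0.2, 10), rep(0, 10), list(start = 1, end = 10),
                      1000, 10)
  expect_equal(pk2$time_of_peak_speed_ms, 0)
})

test_that("retinal angular size at the event end matches the half-angle oracle", {
  tr <- make_line_traj(c(30, 0, 0), c(3, 0, 0), n = 20)
  expect_equal(angular_size_at_end(tr, head_width = 2.2),
               oracle_retinal_deg(1.1, 3), tolerance = 1e-12)
  expect_equal(round(angular_size_at_end(tr, head_width = 2.2), 1), 40.3)
  # head width equal to twice the distance subtends 90 degrees
  tr2 <- make_line_traj(c(30, 0, 0), c(1.1, 0, 0), n = 20)
  expect_equal(angular_size_at_end(tr2, head_width = 2.2), 90,
               tolerance = 1e-12)
  # far away the angle vanishes
  tr3 <- make_line_traj(c(5000, 0, 0), c(4000, 0, 0), n = 20)
  expect_lt(angular_size_at_end(tr3, head_width = 2.2), 0.1)
})

test_that("retinal size agrees with the looming law at matched geometry", {
  # (head_width/2)/d == (r/v)/|t|  =>  identical angles
  tr <- make_line_traj(c(30, 0, 0), c(3, 0, 0), n = 20)
  stim <- loom_stimulus(11, theta_onset = 0.1, theta_max = 180)
  expect_equal(angular_size_at_end(tr, head_width = 2.2),
               angular_size(stim, 30), tolerance = 1e-12)
})

test_that("speed and acceleration are invariant to rigid motions of the scene", {
  p <- attack_gen_params(digitization_noise_sd = 0, hover_jitter_sd = 0)
  tr <- gen_attack(p, outcome = "capture", end_distance = 2, seed = 3)
  shift <- c(17, -8, 4)
  rot <- matrix(c(cos(0.5), -sin(0.5), 0, sin(0.5), cos(0.5), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  translated <- tr
  rotated <- tr
  for (lab in names(tr$points)) {
    translated$points[[lab]] <- sweep(tr$points[[lab]], 2, shift, `+`)
    rotated$points[[lab]] <- tr$points[[lab]] %*% t(rot)
  }
  k0 <- attack_kinematics(tr)
  kt <- attack_kinematics(translated)
  kr <- attack_kinematics(rotated)
  expect_equal(kt$table$speed, k0$table$speed, tolerance = 1e-8)
  expect_equal(kt$table$accel, k0$table$accel, tolerance = 1e-6)
  expect_equal(kr$table$speed, k0$table$speed, tolerance = 1e-8)
  # rotation about z leaves elevation untouched
  expect_equal(kr$table$elevation, k0$table$elevation, tolerance = 1e-6)
})

test_that("events align at t = 0 and average with per-timepoint coverage", {
  p <- attack_gen_params(digitization_noise_sd = 0, hover_jitter_sd = 0,
                         profile = "constant_speed", peak_speed = 0.25,
                         hover_distance = 20)
  k1 <- attack_kinematics(gen_attack(p, outcome = "capture",
                                     end_distance = 2, seed = 1))
  avg_same <- align_and_average(list(k1, k1), "speed")
  expect_equal(avg_same$sd, rep(0, nrow(avg_same)))
  expect_true(all(avg_same$n == 2))
  expect_equal(max(avg_same$t_ms), 0)

  p_long <- attack_gen_params(digitization_noise_sd = 0, hover_jitter_sd = 0,
                              profile = "constant_speed", peak_speed = 0.125,
                              hover_distance = 20)
  k2 <- attack_kinematics(gen_attack(p_long, outcome = "capture",
                                     end_distance = 2, seed = 1))
  avg <- align_and_average(list(k1, k2), "speed")
  expect_setequal(unique(avg$n), c(1L, 2L))
  # the short event only covers late timepoints
  expect_true(all(avg$n[avg$t_ms < min(k1$table$t_ms[k1$window$start])] == 1))
  expect_error(align_and_average(list()), "empty")
})

test_that("averaged speed tracks generator truth across many draws", {
  p <- attack_gen_params(profile = "constant_speed", peak_speed = 0.25,
                         hover_distance = 20, hover_duration = 60,
                         onset_ramp_ms = 20)
  kins <- lapply(1:30, function(s)
    attack_kinematics(gen_attack(p, outcome = "capture", end_distance = 2,
                                 seed = s)))
  avg <- align_and_average(kins, "speed")
  steady <- avg[avg$n == 30 & avg$t_ms > -40 & avg$t_ms < -5, ]
  expect_gt(nrow(steady), 5)
  # mean within 2 sd/sqrt(n) of the programmed speed per timepoint
  expect_true(all(abs(steady$mean - 0.25) <=
                    pmax(2 * steady$sd / sqrt(steady$n), 0.005)))
})
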