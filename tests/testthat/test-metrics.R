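test_that("directionality endpoints and simple mixtures are exact", {
  expect_equal(directionality(uniform_field(1, 0)), 1)
  expect_equal(directionality(uniform_field(-1, 0)), -1)
  expect_equal(directionality(uniform_field(0, 2.5)), 0)
  expect_equal(directionality(vectors_field(list(c(1, 0), c(0, 1)))), 0.5)
  # magnitude-invariant: cos(theta) only
  expect_equal(directionality(uniform_field(3, 4)), 3 / 5)
})

test_that("coordination endpoints and simple mixtures are exact", {
  # any common direction, any magnitudes -> 1
  expect_equal(coordination(vectors_field(list(c(1, 1), c(2, 2), c(0.5, 0.5)))), 1)
  expect_equal(coordination(vectors_field(list(c(1, 0), c(-1, 0)))), 0)
  expect_equal(coordination(vectors_field(list(c(1, 0), c(0, 1)))), sqrt(2) / 2)
})

test_that("mean speed and x-velocity match arithmetic", {
  expect_equal(mean_speed(vectors_field(list(c(3, 4)))), 5)
  expect_equal(mean_speed(vectors_field(list(c(1, 0), c(-1, 0)))), 1)
  expect_equal(mean_x_velocity(uniform_field(2, 7)), 2)
  expect_equal(mean_x_velocity(vectors_field(list(c(1, 0), c(-1, 0)))), 0)
})

test_that("metrics are undefined, not zero, without valid nonzero vectors", {
  empty <- velocity_field(matrix(1, 3, 3), matrix(0, 3, 3),
                          valid = matrix(FALSE, 3, 3))
  zeros <- uniform_field(0, 0)
  for (f in list(empty)) {
    expect_error(mean_speed(f), class = "collmigr_undefined_metric")
    expect_error(mean_x_velocity(f), class = "collmigr_undefined_metric")
  }
  for (f in list(empty, zeros)) {
    expect_error(directionality(f), class = "collmigr_undefined_metric")
    expect_error(coordination(f), class = "collmigr_undefined_metric")
  }
})

test_that("scalar metrics agree with brute-force re-summation to 1e-12", {
  for (seed in 1:20) {
    f <- random_field(seed)
    expect_equal(directionality(f), bf_directionality(f), tolerance = 1e-12)
    expect_equal(coordination(f), bf_coordination(f), tolerance = 1e-12)
    expect_equal(mean_speed(f), bf_mean_speed(f), tolerance = 1e-12)
    expect_equal(mean_x_velocity(f), bf_mean_x_velocity(f), tolerance = 1e-12)
    expect_equal(neighbor_correlation(f), bf_neighbor_correlation(f),
                 tolerance = 1e-12)
  }
})

test_that("order parameters respect bounds, rotation and scale invariance", {
  for (seed in 1:10) {
    f <- random_field(seed + 100)
    d <- directionality(f); cc <- coordination(f)
    expect_true(d >= -1 && d <= 1)
    expect_true(cc >= 0 && cc <= 1)
    # coordination invariant under global rotation; directionality flips
    # sign under rotation by pi
    phi <- runif(1, -pi, pi)
    expect_equal(coordination(rotate_field(f, phi)), cc, tolerance = 1e-12)
    expect_equal(directionality(rotate_field(f, pi)), -d, tolerance = 1e-12)
    # both invariant to scaling all magnitudes
    g <- velocity_field(f$u * 7.3, f$v * 7.3, valid = f$valid,
                        pixel_size = f$pixel_size,
                        frame_interval = f$frame_interval)
    expect_equal(directionality(g), d, tolerance = 1e-12)
    expect_equal(coordination(g), cc, tolerance = 1e-12)
  }
})

test_that("for x-axis-only fields coordination equals |directionality|", {
  set.seed(7)
  for (k in 1:5) {
    u <- matrix(runif(64, -2, 2), 8, 8)
    f <- velocity_field(u, matrix(0, 8, 8))
    expect_equal(coordination(f), abs(directionality(f)), tolerance = 1e-12)
  }
})

test_that("neighbor correlation hits its fixed points and isotropic null", {
  expect_equal(neighbor_correlation(uniform_field(1.5, -0.3, 6, 6)), 1)
  chk <- outer(1:8, 1:8, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  f <- velocity_field(chk, matrix(0, 8, 8))
  expect_equal(neighbor_correlation(f), -1)
  # large isotropic field: |value| < 0.05
  set.seed(11)
  th <- matrix(runif(64 * 64, -pi, pi), 64, 64)
  iso <- velocity_field(cos(th), sin(th))
  expect_lt(abs(neighbor_correlation(iso)), 0.05)
})

test_that("angle distribution is normalized and localizes aligned motion", {
  h <- angle_distribution(uniform_field(1, 0), n_bins = 12)
  expect_equal(sum(h$frequency), 1, tolerance = 1e-9)
  expect_equal(max(h$frequency), 1)
  zero_bin <- findInterval(0, h$bin_edges, left.open = TRUE)
  expect_equal(h$frequency[zero_bin], 1)
  expect_error(angle_distribution(uniform_field(1, 0), n_bins = 1))
  # isotropic sample: each bin near 1/n_bins within the multinomial bound
  set.seed(5)
  th <- matrix(runif(120 * 120, -pi, pi), 120, 120)
  iso <- velocity_field(cos(th), sin(th))
  h2 <- angle_distribution(iso, n_bins = 12)
  expect_equal(sum(h2$frequency), 1, tolerance = 1e-9)
  p <- 1 / 12; M <- 120 * 120
  expect_lt(max(abs(h2$frequency - p)), 3 * sqrt(p * (1 - p) / M))
})

test_that("metric time series carries constants, missing frames and summaries", {
  f <- uniform_field(2, 0, 6, 6, pixel_size = 1.3, frame_interval = 5,
                     units = "um_min")
  fields <- replicate(7, f, simplify = FALSE)
  s <- metric_timeseries(fields, smoothing_window = 3)
  expect_equal(nrow(s), 7)
  expect_equal(s$time, (0:6) * 5)
  expect_equal(s$speed, rep(mean_speed(f), 7))
  expect_equal(s$directionality, rep(1, 7))
  expect_equal(max_migration_speed(s), 2)
  # a frame with no valid vectors is NA, never zero
  dead <- velocity_field(f$u, f$v, valid = matrix(FALSE, 6, 6),
                         pixel_size = 1.3, frame_interval = 5)
  s2 <- metric_timeseries(list(f, dead, f), smoothing_window = 1)
  expect_true(is.na(s2$directionality[2]))
  expect_equal(s2$n_valid[2], 0)
  # nearest-frame lookup
  expect_equal(metric_at_time(s, 11, "speed"), s$speed[3])
})

test_that("directionality rises after a mid-run field switch", {
  bias <- c(rep(0, 30), rep(4, 30))
  cfg <- sim_config(n_agents = 200, box_width = 300, box_height = 300,
                    coupling = 1, noise = 0.6, field_bias = bias,
                    n_frames = 61, seed = 9)
  fields <- trajectory_fields(simulate_monolayer(cfg), grid_spacing = 30)
  s <- metric_timeseries(fields, smoothing_window = 3)
  n <- nrow(s)
  first_q <- mean(s$directionality[1:floor(n / 4)], na.rm = TRUE)
  last_q <- mean(s$directionality[(n - floor(n / 4) + 1):n], na.rm = TRUE)
  expect_gt(last_q, first_q)
})
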