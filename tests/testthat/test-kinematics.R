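test_that("preprocessing: DC passthrough, interpolation, jump removal", {
  # constant-position trace passes unchanged (unit DC gain, zero phase)
  traj <- make_traj(rep(12.5, 200))
  out <- preprocess_trajectory(traj)
  expect_equal(out$x, rep(12.5, 200), tolerance = 1e-9)
  expect_true(all(abs(out$speed) < 1e-9))

  # NaN between (t=1, x=0) and (t=3, x=2) interpolates to x=1 at t=2;
  # use an unfiltered check by setting a high cutoff relative to content
  # interpolation happens before filtering; on a linear ramp the
  # interpolated point recovers its true value
  raw2 <- data.frame(time = 0:10, x = c(0:4, NA, 6:10), y = rep(0, 11))
  out2 <- preprocess_trajectory(raw2, cutoff = 0.45, order = 1)
  expect_equal(out2$x[6], 5, tolerance = 0.2)

  # a tracking jump is removed and re-interpolated
  raw3 <- make_traj(c(seq(0, 5, length.out = 50), 40,
                      seq(5.2, 10, length.out = 49)))
  out3 <- preprocess_trajectory(raw3, jump_threshold = 5)
  expect_lt(max(out3$x), 12)

  expect_error(preprocess_trajectory(
    data.frame(time = 0:3, x = rep(NA_real_, 4), y = 0)), "missing")
  expect_error(preprocess_trajectory(
    data.frame(time = 0, x = 1, y = 0)), "2 samples")
})

test_that("Butterworth filter attenuates above cutoff as designed", {
  fs <- 100
  tt <- seq(0, 10, by = 1 / fs)
  x5 <- sin(2 * pi * 25 * tt)  # 5x the 5 Hz cutoff
  y <- butter_filtfilt(x5, cutoff = 5, fs = fs, order = 2)
  interior <- seq(2 * fs, 8 * fs)
  expect_lt(max(abs(y[interior])), 0.05)
  # passband: 0.5 Hz sine essentially untouched
  x_lo <- sin(2 * pi * 0.5 * tt)
  y_lo <- butter_filtfilt(x_lo, cutoff = 5, fs = fs, order = 2)
  expect_gt(max(abs(y_lo[interior])), 0.95)
  expect_error(butter_filtfilt(x5, cutoff = 60, fs = fs), "cutoff")
})

test_that("stop detection finds maximal sub-threshold intervals", {
  const <- preprocess_trajectory(make_traj(rep(3, 100)))
  st <- detect_stops(const)
  expect_identical(nrow(st), 1L)
  expect_equal(st$t_start, const$time[1])
  expect_equal(st$t_end, const$time[100])
  expect_equal(st$mean_x, 3, tolerance = 1e-6)

  moving <- make_traj(seq(0, 20, length.out = 200), fs = 10) # 1 mm/s
  moving$vx <- 1; moving$vy <- 0; moving$speed <- 1
  expect_identical(nrow(detect_stops(moving)), 0L)

  # default threshold is the tracking resolution, 0.01 mm/s
  expect_identical(formals(detect_stops)$threshold, 0.01)
})

test_that("turn detection equals brute-force sign-alternation count", {
  # triangle wave with 7 reversals
  tri <- c(0:10, 9:0, 1:10, 9:0, 1:10, 9:0, 1:10, 9:2)
  traj <- make_traj(tri)
  expect_identical(nrow(detect_turns(traj)), 7L)
  expect_identical(nrow(detect_turns(make_traj(0:50))), 0L)  # monotone
  expect_identical(nrow(detect_turns(make_traj(rep(4, 30)))), 0L)

  # zero-velocity run between opposite signs counts exactly once
  plateau <- c(0:5, rep(5, 10), 4:0)
  expect_identical(nrow(detect_turns(make_traj(plateau))), 1L)
  # and between same signs, zero times
  plateau2 <- c(0:5, rep(5, 10), 6:10)
  expect_identical(nrow(detect_turns(make_traj(plateau2))), 0L)

  set.seed(42)
  for (i in 1:20) {
    x <- cumsum(sample(c(-1, 0, 1), sample(10:100, 1), replace = TRUE))
    expect_identical(nrow(detect_turns(make_traj(x))),
                     as.integer(oracle_turn_count(x)))
  }
})

test_that("occupancy is a normalized, time-weighted histogram", {
  fixed <- make_traj(rep(25, 500))
  occ <- occupancy_distribution(fixed, n_bins = 50, arena_length = 50)
  expect_equal(sum(occ$prob), 1, tolerance = 1e-12)
  expect_equal(occ$prob[findInterval(25, attr(occ, "breaks"),
                                     all.inside = TRUE)], 1)

  sweep <- make_traj(seq(0.01, 49.99, length.out = 20000), fs = 100)
  occ2 <- occupancy_distribution(sweep, n_bins = 50, arena_length = 50)
  expect_equal(sum(occ2$prob), 1, tolerance = 1e-12)
  expect_lt(max(occ2$prob) / min(occ2$prob), 1.1)
  expect_error(occupancy_distribution(fixed, n_bins = 0), "integer")
})

test_that("preference index is the normalized dwell contrast", {
  expect_equal(preference_index(10, 10), 0)
  expect_equal(preference_index(10, 0), 1)
  expect_equal(preference_index(0, 10), -1)
  expect_equal(preference_index(3, 1), 0.5)
  expect_error(preference_index(0, 0), "never visited")
  set.seed(3)
  for (i in 1:20) {
    z <- runif(2, 0, 100)
    pi_val <- preference_index(z[1], z[2])
    expect_gte(pi_val, -1)
    expect_lte(pi_val, 1)
  }
})

test_that("angular entropy: straight = 0, uniform = log(n), monotone", {
  straight <- angular_entropy(seq(0, 10, by = 0.1), rep(2, 101))
  expect_equal(straight, 0)

  # headings uniform over bins -> maximum entropy log(n)
  nb <- 36
  ang <- (seq_len(720) %% nb) * 2 * pi / nb - pi + pi / nb
  x <- cumsum(cos(ang)); y <- cumsum(sin(ang))
  s_unif <- angular_entropy(c(0, x), c(0, y), n_angle_bins = nb,
                            align_orientation = FALSE)
  expect_equal(s_unif, log(nb), tolerance = 1e-9)
  s_bits <- angular_entropy(c(0, x), c(0, y), n_angle_bins = nb,
                            units = "bits", align_orientation = FALSE)
  expect_equal(s_bits, log2(nb), tolerance = 1e-9)
  # with orientation alignment the support folds to a half circle
  s_fold <- angular_entropy(c(0, x), c(0, y), n_angle_bins = nb)
  expect_lte(s_fold, log(nb / 2) + 1e-9)

  # weaving path of the same endpoints has larger entropy than straight
  t <- seq(0, 10, by = 0.05)
  s_weave <- angular_entropy(t, 0.8 * sin(2 * pi * t))
  expect_gt(s_weave, straight)

  # entropy non-decreasing in heading-noise amplitude (noise ladder,
  # amplitudes kept below the saturation regime of the folded support)
  set.seed(7)
  base <- seq(0, 200, by = 0.05)
  noise <- rnorm(length(base))
  ladder <- vapply(c(0, 0.002, 0.005, 0.01, 0.02, 0.05), function(a) {
    angular_entropy(base, a * noise)
  }, numeric(1))
  expect_true(all(diff(ladder) >= -1e-3))

  expect_error(angular_entropy(c(1, 1), c(2, 2)), "entropy")
  expect_error(angular_entropy(1, 2), "2 samples")
})

test_that("kinematics summary bundles PI, occupancy and entropy classes", {
  cfg <- test_arena(p1 = 0.8, fs = 40)
  ses <- simulate_session_trajectory(cfg, duration = 400, seed = 31)
  traj <- preprocess_trajectory(ses)
  trials <- segment_trials(ses)
  ks <- kinematics_summary(traj, cfg, trials)
  expect_s3_class(ks, "kinematics_summary")
  expect_equal(sum(ks$occupancy$prob), 1, tolerance = 1e-12)
  expect_gte(ks$pi, -1); expect_lte(ks$pi, 1)
  expect_true(all(ks$angular_entropy$entropy[
    ks$angular_entropy$n_paths > 0] >= 0, na.rm = TRUE))
})
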