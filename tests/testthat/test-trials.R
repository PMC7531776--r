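test_that("segmentation matches scripted itinerary ground truth", {
  cfg <- test_arena(p1 = 0.5, p2 = 0.5)
  for (seed in 1:25) {
    it <- make_itinerary_session(3 + seed %% 10, cfg,
                                 p_reward = 0.2 + 0.6 * (seed %% 4) / 4,
                                 seed = seed)
    tr <- segment_trials(it$session)
    expect_identical(nrow(tr), nrow(it$truth))
    expect_identical(tr$zone, it$truth$zone)
    expect_identical(tr$rewarded, it$truth$rewarded)
    expect_identical(tr$returned, it$truth$returned)
    expect_true(all(tr$t_enter_reset <= tr$t_enter_reward))
    expect_true(all(tr$t_enter_reward < tr$t_end))
  }
})

test_that("segmentation returns an empty table when no zone is visited", {
  cfg <- test_arena()
  path <- scripted_trajectory(c(25, 20, 30, 22, 28), cfg)
  ses <- foragefly:::session_record(path, data.frame(time = numeric(0),
                                                     zone = integer(0)),
                                    cfg, 1)
  tr <- segment_trials(ses)
  expect_identical(nrow(tr), 0L)
})

test_that("full-crossing oscillation yields returned = 0 everywhere", {
  cfg <- test_arena()
  wp <- c(25, rep(c(2, 48), 5), 25)
  path <- scripted_trajectory(wp, cfg)
  ses <- foragefly:::session_record(path, data.frame(time = numeric(0),
                                                     zone = integer(0)),
                                    cfg, 1)
  tr <- segment_trials(ses)
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$returned == 0L))
})

test_that("returns stay on the same side short of the far reset boundary", {
  cfg <- test_arena()
  # centre -> zone1 -> short excursion (never past x = 41) -> zone1 again
  path <- scripted_trajectory(c(25, 2, 30, 2, 48, 2, 25), cfg)
  ses <- foragefly:::session_record(path, data.frame(time = numeric(0),
                                                     zone = integer(0)),
                                    cfg, 1)
  tr <- segment_trials(ses)
  z1 <- tr[tr$zone == 1, ]
  expect_identical(z1$returned, c(1L, 0L))
})

test_that("session filter excludes below 50 trials, boundary inclusive", {
  mk <- function(n) data.frame(zone = rep(1L, n), rewarded = rep(0L, n),
                               returned = rep(0L, n))
  expect_true(filter_sessions(mk(49))$excluded)
  expect_false(filter_sessions(mk(50))$excluded)
  expect_true(filter_sessions(mk(0))$excluded)
  expect_false(filter_sessions(mk(10), min_trials = 5)$excluded)
})

test_that("return statistics: probabilities, undefined sets, moving average", {
  tr <- data.frame(zone = 1L, rewarded = rep(c(1L, 0L), 10),
                   returned = rep(1L, 20))
  rs <- return_statistics(tr)
  expect_equal(rs$overall, 1)
  expect_true(all(rs$by_zone_outcome$p_return == 1))

  tr2 <- data.frame(zone = 1L, rewarded = 0L,
                    returned = rep(c(1L, 0L), 15))
  rs2 <- return_statistics(tr2)
  expect_equal(rs2$overall, 0.5)
  ma <- rs2$moving_average$ma
  ma <- ma[!is.na(ma)]
  expect_true(all(abs(ma - 0.4) < 1e-9 | abs(ma - 0.6) < 1e-9))
  # rewarded conditioning set empty -> undefined, not zero
  expect_true(is.na(
    rs2$by_zone_outcome$p_return[rs2$by_zone_outcome$rewarded == 1]))
  expect_error(return_statistics(tr2[0, ]), "at least one")
})

test_that("run-length histogram enumerates blocks of consecutive returns", {
  h <- run_length_histogram(c(1, 1, 0, 1))
  expect_identical(h$length, c(1L, 2L))
  expect_identical(h$count, c(1L, 1L))
  expect_identical(nrow(run_length_histogram(rep(0, 10))), 0L)

  # sum over histogram of length x count equals the number of returns
  set.seed(5)
  for (i in 1:10) {
    v <- rbinom(200, 1, runif(1, 0.2, 0.8))
    h <- run_length_histogram(v)
    expect_identical(sum(h$length * h$count), as.integer(sum(v)))
  }

  # i.i.d. Bernoulli(0.5): geometric runs with mean length 2
  set.seed(6)
  v <- rbinom(1e5, 1, 0.5)
  h <- run_length_histogram(v)
  m <- sum(h$length * h$count) / sum(h$count)
  se <- sqrt(2) / sqrt(sum(h$count))   # geometric(0.5) sd = sqrt(2)
  expect_lt(abs(m - 2), 3 * se)
})

test_that("first-reward summary bins delays and splits by first response", {
  mk_seq <- function(first_reward_trial, returned, n = 40) {
    r <- integer(n); r[first_reward_trial] <- 1L
    r[seq(first_reward_trial + 5, n, by = 5)] <- 1L
    ch <- integer(n); ch[first_reward_trial] <- returned
    choice_sequence(r, ch, times = (seq_len(n) - 1) * 10)
  }
  seqs <- c(lapply(1:4, function(i) mk_seq(1, 1L)),
            lapply(1:4, function(i) mk_seq(12, 0L)))
  fr <- first_reward_summary(seqs, trial_breaks = c(1, 2, 13, Inf))
  expect_identical(fr$by_trial$fraction_returned, c(1, 0))
  expect_identical(fr$by_trial$n_flies, c(4L, 4L))
  expect_true(!is.null(fr$by_time))
  # flies with no rewarded trial are excluded
  seqs2 <- c(seqs, list(choice_sequence(integer(10), integer(10))))
  fr2 <- first_reward_summary(seqs2, trial_breaks = c(1, 2, 13, Inf))
  expect_identical(sum(fr2$by_trial$n_flies), 8L)
  expect_error(first_reward_summary(
    list(choice_sequence(integer(5), integer(5)))), "rewarded")
})

test_that("per-zone choice sequences interleave independently", {
  cfg <- test_arena(p1 = 1, p2 = 1)
  it <- make_itinerary_session(12, cfg, p_reward = 1, seed = 9)
  tr <- segment_trials(it$session)
  for (z in 1:2) {
    cs <- trials_to_choice_sequence(tr, zone = z, p_reward = 1)
    expect_identical(length(cs), sum(tr$zone == z))
    expect_true(all(cs$rewards == tr$rewarded[tr$zone == z]))
  }
})
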