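test_that("sequence likelihood: beta=0, tiny-instance and perfect-fit", {
  s <- choice_sequence(c(1, 0, 1, 0), c(1, 1, 0, 0))
  p0 <- rl_params("FQ", alpha = 0.7, beta = 0, bias = 0.5)
  expect_equal(sequence_log_likelihood(p0, s), log(0.5), tolerance = 1e-12)

  # tiny instance against hand-evaluated forward pass
  p <- rl_params("FQ", alpha = 0.5, beta = 4, bias = 0.3, q0 = 0)
  # Q trace: 0 -> (c=1,R=1) 0.5 -> (c=1,R=0) 0.25 -> (c=0) 0.125 -> (c=0)
  q <- c(0, 0.5, 0.25, 0.125)
  pr <- 1 / (1 + exp(4 * (0.3 - q)))
  by_hand <- mean(c(log(pr[1]), log(pr[2]), log(1 - pr[3]), log(1 - pr[4])))
  expect_equal(sequence_log_likelihood(p, s), by_hand, tolerance = 1e-12)
  expect_equal(sequence_log_likelihood(p, s),
               oracle_rl_forward(0.5, 4, 0.3, 0.5, 0, s$rewards,
                                 s$choices)$logL_mean, tolerance = 1e-12)

  # P -> 1 on all-return data: L -> 0 from below
  all1 <- choice_sequence(rep(1, 20), rep(1, 20))
  strong <- rl_params("FQ", alpha = 0.5, beta = 50, bias = -1)
  ll <- sequence_log_likelihood(strong, all1)
  expect_lt(ll, 0)
  expect_gt(ll, -1e-6)
  expect_error(sequence_log_likelihood(p, choice_sequence(integer(0),
                                                          integer(0))),
               "empty")
})

test_that("MLE matches a dense grid search on short sequences", {
  set.seed(12)
  for (rep in 1:3) {
    s <- choice_sequence(rbinom(6, 1, 0.5), rbinom(6, 1, 0.5))
    if (length(unique(s$choices)) < 2) next
    f <- fit_mle_multistart("FQ", s, n_init = 60, seed = rep, min_trials = 4)
    g <- oracle_grid_search_rl("FQ", s$rewards, s$choices)
    # optimizer must be at least as good as the best grid point
    expect_gte(f$logL_mean, g$logL - 1e-8)
    # and the grid cannot beat it by more than its own resolution allows
    expect_lt(g$logL - f$logL_mean, 0.05)
  }
})

test_that("multistart fitting is deterministic and beats the generator", {
  gen <- rl_params("FQ", alpha = 0.4, beta = 6, bias = 0.5)
  s <- simulate_rl_agent(gen, 0.3, 3000, seed = 77)$seq
  f1 <- fit_mle_multistart("FQ", s, n_init = 30, seed = 5)
  f2 <- fit_mle_multistart("FQ", s, n_init = 30, seed = 5)
  expect_identical(f1, f2)
  # the optimum dominates the generator's own parameters
  expect_gte(f1$logL_mean, sequence_log_likelihood(gen, s))
  # and recovers them reasonably at this N
  expect_lt(abs(f1$params$alpha - 0.4), 0.1)
  expect_lt(abs(f1$params$bias - 0.5), 0.1)
  expect_error(fit_mle_multistart("FQ", choice_sequence(c(0, 1), c(0, 1))),
               "trials")
})

test_that("AIC arithmetic and model selection tie-breaking", {
  expect_equal(aic_score(-100, k = 3), 206)
  expect_equal(aic_score(-100, k = 4), 208)
  expect_equal(aic_score(0, k = 0), 0)
  mk_fit <- function(model, k, ll) {
    structure(list(model = model, k = as.integer(k), logL_total = ll,
                   AIC = 2 * k - 2 * ll, converged = TRUE),
              class = "fit_result")
  }
  fits <- list(RW = mk_fit("RW", 3, -100), FQ = mk_fit("FQ", 3, -98),
               FQaF = mk_fit("FQaF", 4, -98))
  sel <- select_model(fits)
  expect_identical(sel$winner, "FQ")
  # identical AIC for RW and FQaF -> fewer parameters wins
  fits2 <- list(RW = mk_fit("RW", 3, -100), FQaF = mk_fit("FQaF", 4, -99))
  expect_identical(select_model(fits2)$winner, "RW")
  expect_error(select_model(fits2[1]), "at least 2")
  expect_error(aic_score(mk_fit("RW", 3, -1e4)), NA)
})

test_that("adding the forgetting parameter never lowers the likelihood", {
  gen <- rl_params("RW", alpha = 0.3, beta = 5, bias = 0.4)
  s <- simulate_rl_agent(gen, 0.3, 1500, seed = 9)$seq
  f_rw <- fit_mle_multistart("RW", s, n_init = 40, seed = 2)
  f_faf <- fit_mle_multistart("FQaF", s, n_init = 40, seed = 2)
  expect_gte(f_faf$logL_total, f_rw$logL_total - 1e-6)
  expect_gt(f_faf$AIC, 2 * 4 - 2 * f_faf$logL_total - 1e-9)
})

test_that("predictive F1 components follow the stated conventions", {
  # predictions identical to choices -> all scores 1
  s <- choice_sequence(rep(1, 10), c(1, 1, 0, 1, 0, 1, 1, 0, 1, 1))
  # beta huge, bias between 0 and 1: predicts P>0.5 iff Q high; instead use
  # a synthetic exact case by scoring a model that always predicts returns
  always <- rl_params("FQ", alpha = 0, beta = 50, bias = -1, q0 = 0)
  all_ret <- choice_sequence(rep(1, 8), rep(1, 8))
  ps <- predictive_f1(always, all_ret)
  expect_equal(ps$precision, 1)
  expect_equal(ps$recall, 1)
  expect_equal(ps$f1, 1)

  # never predicts on data containing returns -> TP=0, F1=0 by convention
  never <- rl_params("FQ", alpha = 0, beta = 50, bias = 2, q0 = 0)
  ps0 <- predictive_f1(never, all_ret)
  expect_equal(ps0$tp, 0)
  expect_equal(ps0$f1, 0)
  expect_error(predictive_f1(always, choice_sequence(integer(0),
                                                     integer(0))), "empty")
})

test_that("F1 arithmetic at given TP/FP/FN rates", {
  # construct data where rates are exactly TP=0.25, FP=0.25, FN=0.25:
  # threshold model predicting returns on half the trials
  # simpler: verify the formulas directly on a crafted prediction pattern
  s <- choice_sequence(rep(0, 4), c(1, 0, 1, 0))
  # alpha=0, q0 chosen so P constant > 0.5: predicts return every trial
  m <- rl_params("FQ", alpha = 0, beta = 50, bias = 0.25, q0 = 0.5)
  ps <- predictive_f1(m, s)
  expect_equal(ps$tp, 0.5)
  expect_equal(ps$fp, 0.5)
  expect_equal(ps$fn, 0)
  expect_equal(ps$precision, 0.5)
  expect_equal(ps$recall, 1)
  expect_equal(ps$f1, 2 * 0.5 * 1 / 1.5)
  # the Eq-style identity precision = recall = F1 = 0.5 at equal rates
  pr <- 0.25 / (0.25 + 0.25)
  rc <- 0.25 / (0.25 + 0.25)
  expect_equal(2 * pr * rc / (pr + rc), 0.5)
})

test_that("chronological halves split preserves order and lengths", {
  s <- choice_sequence(rep(c(1, 0), 25), rep(c(0, 1), 25),
                       times = seq_len(50))
  h <- split_halves(s)
  expect_identical(length(h$train), 25L)
  expect_identical(length(h$test), 25L)
  expect_identical(h$train$rewards, s$rewards[1:25])
  expect_identical(h$test$times, s$times[26:50])
})

test_that("generative test separates RL, deterministic and random agents", {
  conditions <- c(0.15, 0.6)
  rnd <- generative_test(agent_spec("random"), conditions, n_seq = 60,
                         n_trials = 400, seed = 4)
  for (i in 1:2) {
    expect_lt(abs(rnd$summary$p_return_rewarded[i] - 0.5), 0.05)
    expect_lt(abs(rnd$summary$p_return_unrewarded[i] - 0.5), 0.05)
  }
  det <- generative_test(agent_spec("deterministic"), conditions, n_seq = 60,
                         n_trials = 400, seed = 5)
  expect_true(all(det$summary$p_return_unrewarded == 0))

  fq <- rl_params("FQ", alpha = 0.4, beta = 6, bias = 0.4)
  gen <- generative_test(fq, conditions, n_seq = 60, n_trials = 400,
                         seed = 6)
  # reward-rich recent history raises the return probability
  expect_true(all(gen$summary$p_return_after_rewarded_return >
                  gen$summary$p_return_unrewarded))
  # run-length histograms carry across-sequence SEMs and positive support
  expect_true(all(gen$run_lengths$mean_count >= 0))
  expect_true(all(is.finite(gen$run_lengths$sem_count)))
})
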