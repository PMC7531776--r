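test_that("value updates follow the chosen/unchosen branches", {
  fq <- rl_params("FQ", alpha = 0.5, beta = 1, bias = 0)
  expect_equal(update_value(fq, 0, 1, 1), 0.5)     # 0 + 0.5 * (1 - 0)
  expect_equal(update_value(fq, 0.5, 0, 0), 0.25)  # 0.5 - 0.5 * 0.5
  rw <- rl_params("RW", alpha = 0.5, beta = 1, bias = 0)
  expect_equal(update_value(rw, 0.7, 0, 0), 0.7)   # frozen when unchosen
  faf <- rl_params("FQaF", alpha = 0.5, beta = 1, bias = 0, alpha_f = 0.2)
  expect_equal(update_value(faf, 0.5, 0, 0), 0.4)  # 0.5 * (1 - 0.2)
  expect_equal(forgetting_rate(rw), 0)
  expect_equal(forgetting_rate(fq), 0.5)
  expect_equal(forgetting_rate(faf), 0.2)
  expect_error(update_value(fq, Inf, 1, 1), "finite")
  expect_error(update_value(fq, 0, 2, 1), "choice")
  expect_error(update_value(fq, 0, 1, -1), "reward")
})

test_that("choice probability is the shifted logistic in Q", {
  p <- rl_params("FQ", alpha = 0.3, beta = 4, bias = 0.6)
  expect_equal(choice_probability(p, 0.6), 0.5)    # Q = bias
  p0 <- rl_params("FQ", alpha = 0.3, beta = 0, bias = 0.6)
  expect_equal(choice_probability(p0, -3), 0.5)    # beta = 0
  expect_equal(choice_probability(p0, 5), 0.5)
  p1 <- rl_params("RW", alpha = 0.3, beta = 1, bias = 0)
  expect_equal(choice_probability(p1, 1), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  qs <- seq(-1, 2, by = 0.1)
  expect_true(all(diff(choice_probability(p, qs)) > 0))  # increasing in Q
})

test_that("parameter validation enforces bounds and model fields", {
  expect_error(rl_params("FQ", alpha = 1.2, beta = 1, bias = 0), "alpha")
  expect_error(rl_params("FQ", alpha = 0.5, beta = -1, bias = 0), "beta")
  expect_error(rl_params("FQaF", alpha = 0.5, beta = 1, bias = 0), "alpha_f")
  expect_error(rl_params("FQ", alpha = 0.5, beta = 1, bias = 0,
                         alpha_f = 0.1), "FQaF")
  expect_error(rl_params("FQ", alpha = 0.5, beta = 1, bias = 0, q0 = -1),
               "q0")
})

test_that("agent simulation matches the plain-R forward oracle", {
  params <- rl_params("FQaF", alpha = 0.4, beta = 5, bias = 0.3,
                      alpha_f = 0.15, q0 = 0.5)
  sim <- simulate_rl_agent(params, 0.4, 300, seed = 17)
  oracle <- oracle_rl_forward(0.4, 5, 0.3, 0.15, 0.5,
                              sim$values$reward, sim$values$choice)
  expect_equal(sim$values$Q, oracle$Q, tolerance = 1e-12)
  expect_equal(sim$values$P, oracle$P, tolerance = 1e-12)
})

test_that("no-learning agent has constant value and choice probability", {
  params <- rl_params("RW", alpha = 0, beta = 3, bias = 0.5, q0 = 0)
  sim <- simulate_rl_agent(params, 1, 500, seed = 3)
  expect_true(all(sim$values$Q == 0))
  expect_equal(unique(sim$values$P), 1 / (1 + exp(3 * 0.5)))
})

test_that("forced returns drive Q to the reward-rate fixed point", {
  # beta large, bias very negative -> P ~ 1, c = 1 every trial
  params <- rl_params("FQ", alpha = 0.5, beta = 50, bias = -1)
  sim <- simulate_rl_agent(params, 1, 200, seed = 5)
  expect_true(all(sim$values$choice == 1L))
  expect_true(all(diff(sim$values$Q) >= 0))       # monotone to 1
  expect_gt(sim$values$Q[200], 0.999)

  # p < 1: long-run mean of Q converges to p (leaky-integrator fixed point)
  for (p in c(0.3, 0.6)) {
    sim2 <- simulate_rl_agent(rl_params("FQ", alpha = 0.2, beta = 50,
                                        bias = -1), p, 20000,
                              seed = round(100 * p))
    q_bar <- mean(sim2$values$Q[-(1:500)])
    # MC error of the mean of an AR(1)-like value trace
    expect_lt(abs(q_bar - p), 0.02)
  }
})

test_that("positive initial value decays toward the baseline", {
  params <- rl_params("FQ", alpha = 0.4, beta = 6, bias = 0.4, q0 = 0.9)
  sim <- simulate_rl_agent(params, 0, 400, seed = 11)
  expect_true(all(diff(sim$values$Q) <= 1e-12))   # no rewards: decay only
  expect_lt(sim$values$Q[400], 1e-6)
  expect_equal(sim$values$P[400], choice_probability(params, 0),
               tolerance = 1e-6)
})

test_that("model nesting: FQaF reduces to FQ and RW bit-identically", {
  base <- list(alpha = 0.35, beta = 7, bias = 0.2)
  p_fq <- rl_params("FQ", base$alpha, base$beta, base$bias)
  p_rw <- rl_params("RW", base$alpha, base$beta, base$bias)
  p_as_fq <- rl_params("FQaF", base$alpha, base$beta, base$bias,
                       alpha_f = base$alpha)
  p_as_rw <- rl_params("FQaF", base$alpha, base$beta, base$bias,
                       alpha_f = 0)
  s1 <- simulate_rl_agent(p_fq, 0.3, 1000, seed = 42)
  s2 <- simulate_rl_agent(p_as_fq, 0.3, 1000, seed = 42)
  expect_identical(s1$values, s2$values)
  s3 <- simulate_rl_agent(p_rw, 0.3, 1000, seed = 42)
  s4 <- simulate_rl_agent(p_as_rw, 0.3, 1000, seed = 42)
  expect_identical(s3$values, s4$values)
})

test_that("values stay in [0, max(q0, 1)] for binary rewards", {
  set.seed(23)
  for (i in 1:15) {
    model <- sample(c("RW", "FQ", "FQaF"), 1)
    q0 <- runif(1, 0, 1.5)
    params <- rl_params(model, alpha = runif(1), beta = runif(1, 0, 20),
                        bias = runif(1, -1, 2),
                        alpha_f = if (model == "FQaF") runif(1) else NULL,
                        q0 = q0)
    sim <- simulate_rl_agent(params, runif(1), 500, seed = i)
    expect_gte(min(sim$values$Q), 0)
    expect_lte(max(sim$values$Q), max(q0, 1))
  }
})

test_that("reference agents behave as quoted", {
  det0 <- simulate_reference_agents("deterministic", 0, 1000, seed = 1)
  expect_true(all(det0$choices == 0L))
  det1 <- simulate_reference_agents("deterministic", 1, 1e5, seed = 2)
  expect_lt(abs(mean(det1$choices) - 0.5), 3 * sqrt(0.25 / 1e5))
  rnd <- simulate_reference_agents("random", 0.3, 1e5, seed = 3)
  expect_lt(abs(mean(rnd$choices) - 0.5), 3 * sqrt(0.25 / 1e5))
  # random agent's choices independent of rewards
  expect_lt(abs(mean(rnd$choices[rnd$rewards == 1]) -
                mean(rnd$choices[rnd$rewards == 0])), 0.02)
})
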