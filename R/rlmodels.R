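#' Reinforcement-learning model parameters
#'
#' The three single-option RL models differ only in how the value of the
#' *unchosen* outcome (no return) is treated: the Rescorla-Wagner model
#' (`"RW"`) freezes it, the forgetting-Q model (`"FQ"`) decays it at the
#' learning rate `alpha`, and `"FQaF"` decays it at an independent forgetting
#' rate `alpha_f`.  The chosen branch always applies a reward-prediction-error
#' update `Q + alpha * (R - Q)`.
#'
#' @param model one of `"RW"`, `"FQ"`, `"FQaF"`.
#' @param alpha learning rate in `[0, 1]`.
#' @param beta inverse temperature (>= 0) weighting the value in the logistic
#'   choice rule.
#' @param bias value-scale offset in the choice rule; accounts for baseline
#'   return probabilities below 0.5.
#' @param alpha_f forgetting rate in `[0, 1]`; required for (and only used by)
#'   the FQaF model.
#' @param q0 initial value (>= 0, default 0).  A positive `q0` encodes initial
#'   attraction to the arena ends that decays over unchosen trials.
#' @return an object of class `rl_params`.
#' @export
rl_params <- function(model = c("RW", "FQ", "FQaF"), alpha, beta, bias,
                      alpha_f = NULL, q0 = 0) {
  model <- match.arg(model)
  stopifnot_prob(alpha, "alpha")
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0) {
    stop("'beta' must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(bias) || length(bias) != 1L || is.na(bias)) {
    stop("'bias' must be a single number", call. = FALSE)
  }
  if (model == "FQaF") {
    if (is.null(alpha_f)) stop("FQaF requires 'alpha_f'", call. = FALSE)
    stopifnot_prob(alpha_f, "alpha_f")
  } else if (!is.null(alpha_f)) {
    stop("'alpha_f' is only meaningful for the FQaF model", call. = FALSE)
  }
  if (!is.numeric(q0) || length(q0) != 1L || is.na(q0) || q0 < 0) {
    stop("'q0' must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(model = model, alpha = alpha, beta = beta, bias = bias,
         alpha_f = if (model == "FQaF") alpha_f else NULL, q0 = q0),
    class = "rl_params"
  )
}

#' @export
print.rl_params <- function(x, ...) {
  cat(sprintf("<rl_params> %s: alpha=%.3g beta=%.3g bias=%.3g%s q0=%.3g\n",
              x$model, x$alpha, x$beta, x$bias,
              if (!is.null(x$alpha_f)) sprintf(" alpha_f=%.3g", x$alpha_f)
              else "",
              x$q0))
  invisible(x)
}

#' Forgetting rate implied by a parameter set
#'
#' Resolves the unchosen-branch decay rate: 0 for RW, `alpha` for FQ and
#' `alpha_f` for FQaF.
#'
#' @param params an [rl_params] object.
#' @return a single numeric decay rate.
#' @export
forgetting_rate <- function(params) {
  stopifnot(inherits(params, "rl_params"))
  switch(params$model, RW = 0, FQ = params$alpha, FQaF = params$alpha_f)
}

#' Number of free parameters of an RL model
#'
#' RW and FQ have three (alpha, beta, bias); FQaF adds the forgetting rate.
#' `q0`, when fitted rather than fixed, adds one more.
#'
#' @param model model name.
#' @param fit_q0 whether the initial value is a fitted parameter.
#' @return integer parameter count.
#' @export
n_params <- function(model = c("RW", "FQ", "FQaF"), fit_q0 = FALSE) {
  model <- match.arg(model)
  k <- if (model == "FQaF") 4L else 3L
  k + as.integer(fit_q0)
}

#' Single-trial value update
#'
#' Applies the per-trial value update: on chosen trials (`c = 1`) the value
#' moves toward the reward by the learning rate, `Q + alpha * (R - Q)`; on
#' unchosen trials it decays multiplicatively, `Q - phi * Q`, with `phi`
#' resolved per model by [forgetting_rate()].
#'
#' @param params an [rl_params] object.
#' @param q current value (finite numeric scalar or vector).
#' @param choice 0/1 return choice on this trial.
#' @param reward 0/1 reward on this trial.
#' @return updated value, same shape as `q`.
#' @export
update_value <- function(params, q, choice, reward) {
  stopifnot(inherits(params, "rl_params"))
  if (!all(is.finite(q))) stop("'q' must be finite", call. = FALSE)
  if (!choice %in% c(0, 1)) stop("'choice' must be 0 or 1", call. = FALSE)
  if (!reward %in% c(0, 1)) stop("'reward' must be 0 or 1", call. = FALSE)
  if (choice == 1) {
    q + params$alpha * (reward - q)
  } else {
    q - forgetting_rate(params) * q
  }
}

#' Logistic choice rule
#'
#' Probability of a return choice given the current value:
#' `P(c = 1) = 1 / (1 + exp(beta * (bias - Q)))`.  Strictly increasing in `Q`
#' for `beta > 0`; equal to 0.5 at `Q = bias` and for `beta = 0`.
#'
#' @param params an [rl_params] object.
#' @param q value (scalar or vector).
#' @return choice probability, same shape as `q`.
#' @export
choice_probability <- function(params, q) {
  stopifnot(inherits(params, "rl_params"))
  1 / (1 + exp(params$beta * (params$bias - q)))
}

rl_forward <- function(params, rewards, choices) {
  cpp_rl_forward(params$alpha, params$beta, params$bias,
                 forgetting_rate(params), params$q0,
                 as.integer(rewards), as.integer(choices))
}

# internal: simulate an RL agent using the *current* RNG stream
rl_simulate_stream <- function(params, p_reward, n_trials) {
  u_r <- runif(n_trials)
  u_c <- runif(n_trials)
  cpp_rl_simulate(params$alpha, params$beta, params$bias,
                  forgetting_rate(params), params$q0,
                  p_reward, n_trials, u_r, u_c)
}

#' Simulate a reinforcement-learning agent
#'
#' Sequentially draws a Bernoulli reward per trial (the reward available at
#' the zone visit), computes the return probability from the current value,
#' draws the return choice, then updates the value with the observed
#' (choice, reward) pair.  The value is initialised at `q0`.
#'
#' @param params an [rl_params] object.
#' @param p_reward stimulation probability of the zone.
#' @param n_trials number of trials (>= 1).
#' @param seed integer seed; identical seeds give identical output.
#' @return a list with `seq` (a [choice_sequence]) and `values`, a data frame
#'   with per-trial `trial`, `Q` (pre-trial value), `P` (return probability),
#'   `reward` and `choice`.
#' @export
simulate_rl_agent <- function(params, p_reward, n_trials, seed) {
  stopifnot(inherits(params, "rl_params"))
  stopifnot_prob(p_reward, "p_reward")
  n_trials <- stopifnot_count(n_trials, "n_trials")
  set.seed(seed)
  sim <- rl_simulate_stream(params, p_reward, n_trials)
  seq <- choice_sequence(sim$rewards, sim$choices, p_reward = p_reward)
  values <- data.frame(trial = seq_len(n_trials), Q = sim$Q, P = sim$P,
                       reward = sim$rewards, choice = sim$choices)
  list(seq = seq, values = values)
}

#' Simulate the reference (non-learning) agents
#'
#' The deterministic reference agent returns with probability `response_prob`
#' only on rewarded trials and never on unrewarded trials; the random agent
#' returns with probability `response_prob` independent of rewards.
#'
#' @param kind `"deterministic"` or `"random"`.
#' @param p_reward per-trial reward probability.
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @param response_prob response probability (default 0.5, the reference
#'   value).
#' @return a [choice_sequence].
#' @export
simulate_reference_agents <- function(kind = c("deterministic", "random"),
                                      p_reward, n_trials, seed,
                                      response_prob = 0.5) {
  kind <- match.arg(kind)
  stopifnot_prob(p_reward, "p_reward")
  stopifnot_prob(response_prob, "response_prob")
  n_trials <- stopifnot_count(n_trials, "n_trials")
  set.seed(seed)
  reference_stream(kind, p_reward, n_trials, response_prob)
}

# internal: reference agents on the current RNG stream
reference_stream <- function(kind, p_reward, n_trials, response_prob) {
  rewards <- as.integer(runif(n_trials) < p_reward)
  u <- runif(n_trials)
  choices <- if (kind == "deterministic") {
    as.integer(rewards == 1L & u < response_prob)
  } else {
    as.integer(u < response_prob)
  }
  choice_sequence(rewards, choices, p_reward = p_reward)
}
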