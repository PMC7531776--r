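# Maximum-likelihood fitting, AIC model comparison, predictive F1 and
# generative testing of the RL models.

#' Per-trial mean log-likelihood of a choice sequence
#'
#' Runs the model forward over the observed sequence (values updated with the
#' observed choices and rewards) and evaluates
#' `L = (1/N) * sum((1 - c) log(1 - P) + c log P)`, with choice probabilities
#' clamped to `[1e-12, 1 - 1e-12]` before taking logs.
#'
#' @param params an [rl_params] object.
#' @param seq a [choice_sequence].
#' @return the mean log-likelihood (<= 0).
#' @export
sequence_log_likelihood <- function(params, seq) {
  stopifnot(inherits(params, "rl_params"), inherits(seq, "choice_sequence"))
  if (length(seq$rewards) == 0) stop("empty sequence", call. = FALSE)
  rl_forward(params, seq$rewards, seq$choices)$logL_mean
}

#' Parameter bounds used by the multistart fitter
#'
#' @param model model name.
#' @param fit_q0 whether q0 is fitted.
#' @return a data frame `param`, `lower`, `upper`.
#' @export
rl_param_bounds <- function(model = c("RW", "FQ", "FQaF"), fit_q0 = FALSE) {
  model <- match.arg(model)
  b <- data.frame(param = c("alpha", "beta", "bias"),
                  lower = c(0, 0, -1), upper = c(1, 50, 2))
  if (model == "FQaF") {
    b <- rbind(b, data.frame(param = "alpha_f", lower = 0, upper = 1))
  }
  if (fit_q0) b <- rbind(b, data.frame(param = "q0", lower = 0, upper = 2))
  b
}

vec_to_params <- function(model, v, q0 = 0, fit_q0 = FALSE) {
  alpha_f <- if (model == "FQaF") unname(v["alpha_f"]) else NULL
  q0v <- if (fit_q0) unname(v["q0"]) else q0
  rl_params(model, alpha = unname(v["alpha"]), beta = unname(v["beta"]),
            bias = unname(v["bias"]), alpha_f = alpha_f, q0 = q0v)
}

#' Multistart maximum-likelihood fit of an RL model
#'
#' Bounded quasi-Newton (L-BFGS-B, numerical gradients) maximisation of the
#' per-trial mean log-likelihood from `n_init` uniform random starts inside
#' the parameter bounds; the best converged start wins.  Deterministic under
#' `seed`.
#'
#' @param model `"RW"`, `"FQ"` or `"FQaF"`.
#' @param seq a [choice_sequence] (at least `min_trials` trials).
#' @param n_init number of random initialisations (default 100).
#' @param seed integer seed.
#' @param q0 fixed initial value (default 0).
#' @param fit_q0 estimate q0 as a free parameter instead (adds one parameter
#'   to the AIC count).
#' @param min_trials minimum usable sequence length (default 10).
#' @return an object of class `fit_result`: `model`, `params` ([rl_params]),
#'   `logL_mean`, `logL_total` (= N * logL_mean), `AIC`, `k`, `n_trials`,
#'   `n_init`, `best_init`, `converged`.
#' @export
fit_mle_multistart <- function(model = c("RW", "FQ", "FQaF"), seq,
                               n_init = 100, seed = 1, q0 = 0,
                               fit_q0 = FALSE, min_trials = 10) {
  model <- match.arg(model)
  stopifnot(inherits(seq, "choice_sequence"))
  n <- length(seq$rewards)
  if (n < min_trials) {
    stop(sprintf("sequence has %d trials; need >= %d", n, min_trials),
         call. = FALSE)
  }
  bounds <- rl_param_bounds(model, fit_q0)
  npar <- nrow(bounds)
  rewards <- as.integer(seq$rewards)
  choices <- as.integer(seq$choices)
  # parameter layout: alpha, beta, bias [, alpha_f] [, q0]
  q0_idx <- if (fit_q0) nrow(bounds) else 0L
  negL <- switch(model,
    RW = function(v) cpp_rl_negll(v[1], v[2], v[3], 0,
                                  if (q0_idx) v[q0_idx] else q0,
                                  rewards, choices),
    FQ = function(v) cpp_rl_negll(v[1], v[2], v[3], v[1],
                                  if (q0_idx) v[q0_idx] else q0,
                                  rewards, choices),
    FQaF = function(v) cpp_rl_negll(v[1], v[2], v[3], v[4],
                                    if (q0_idx) v[q0_idx] else q0,
                                    rewards, choices))
  set.seed(seed)
  starts <- matrix(runif(n_init * npar, rep(bounds$lower, each = n_init),
                         rep(bounds$upper, each = n_init)),
                   nrow = n_init)
  best <- NULL
  best_val <- Inf
  best_init <- NA_integer_
  any_conv <- FALSE
  for (i in seq_len(n_init)) {
    res <- tryCatch(
      optim(starts[i, ], negL, method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper,
            control = list(factr = 1e7, maxit = 100)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    conv <- res$convergence == 0
    any_conv <- any_conv || conv
    if (res$value < best_val) {
      best_val <- res$value
      best <- res$par
      best_init <- i
    }
  }
  if (is.null(best)) {
    return(structure(list(model = model, params = NULL,
                          logL_mean = NA_real_, logL_total = NA_real_,
                          AIC = NA_real_, k = n_params(model, fit_q0),
                          n_trials = n, n_init = n_init,
                          best_init = NA_integer_, converged = FALSE),
                     class = "fit_result"))
  }
  names(best) <- bounds$param
  params <- vec_to_params(model, best, q0 = q0, fit_q0 = fit_q0)
  l_mean <- -best_val
  k <- n_params(model, fit_q0)
  structure(list(model = model, params = params, logL_mean = l_mean,
                 logL_total = n * l_mean, AIC = 2 * k - 2 * n * l_mean,
                 k = k, n_trials = n, n_init = n_init, best_init = best_init,
                 converged = any_conv),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: logL=%.4f (total %.1f) AIC=%.1f k=%d%s\n",
              x$model, x$logL_mean, x$logL_total, x$AIC, x$k,
              if (!x$converged) " [not converged]" else ""))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Akaike information criterion
#'
#' `AIC = 2k - 2 logL_total`, with `logL_total = N * L` (the mean per-trial
#' log-likelihood scaled back to the sequence; an AIC on the per-trial mean
#' would not be scale-consistent across flies).
#'
#' @param fit a `fit_result`, or a total log-likelihood.
#' @param k parameter count (taken from the fit when omitted).
#' @return the AIC score.
#' @export
aic_score <- function(fit, k = NULL) {
  if (inherits(fit, "fit_result")) {
    if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
    ll <- fit$logL_total
    k <- k %||% fit$k
  } else {
    ll <- fit
    if (is.null(k)) stop("'k' required", call. = FALSE)
  }
  2 * k - 2 * ll
}

#' Select the best model by AIC
#'
#' Minimum-AIC model; ties are broken toward the model with fewer parameters.
#'
#' @param fits named list of `fit_result` objects for the same sequence
#'   (>= 2 models).
#' @return a list with `winner` (model name), `table` (data frame `model`,
#'   `k`, `logL_total`, `AIC`, `dAIC`).
#' @export
select_model <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 models to compare",
                             call. = FALSE)
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    k = vapply(fits, `[[`, integer(1), "k"),
    logL_total = vapply(fits, `[[`, numeric(1), "logL_total"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"))
  tab$dAIC <- tab$AIC - min(tab$AIC)
  ord <- order(tab$AIC, tab$k)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  list(winner = tab$model[1], table = tab)
}

#' Chronological train/test split
#'
#' First half of the trials for fitting, second half held out for prediction.
#'
#' @param seq a [choice_sequence].
#' @return list with `train` and `test` choice sequences.
#' @export
split_halves <- function(seq) {
  n <- length(seq$rewards)
  h <- floor(n / 2)
  idx1 <- seq_len(h)
  idx2 <- (h + 1L):n
  sub <- function(i) choice_sequence(seq$rewards[i], seq$choices[i],
                                     zone = seq$zone, p_reward = seq$p_reward,
                                     fly = seq$fly,
                                     times = seq$times[i])
  list(train = sub(idx1), test = sub(idx2))
}

#' Predictive F1 score on held-out trials
#'
#' The fitted model is run forward on the held-out half with the observed
#' choices and rewards driving its value updates; a return is predicted
#' whenever the model's choice probability exceeds `threshold`.  TP, FP and
#' FN are rates (fractions of held-out trials); precision, recall and F1
#' follow, with F1 = 0 by convention when TP = 0.
#'
#' @param params fitted [rl_params].
#' @param heldout held-out [choice_sequence].
#' @param threshold decision threshold on the choice probability
#'   (default 0.5).
#' @return an object of class `predictive_score`: `tp`, `fp`, `fn` (rates),
#'   `precision`, `recall`, `f1`, `n`.
#' @export
predictive_f1 <- function(params, heldout, threshold = 0.5) {
  stopifnot(inherits(params, "rl_params"),
            inherits(heldout, "choice_sequence"))
  n <- length(heldout$rewards)
  if (n == 0) stop("held-out sequence is empty", call. = FALSE)
  stopifnot_prob(threshold, "threshold")
  fw <- rl_forward(params, heldout$rewards, heldout$choices)
  pred <- as.integer(fw$P > threshold)
  act <- heldout$choices
  tp <- mean(pred == 1L & act == 1L)
  fp <- mean(pred == 1L & act == 0L)
  fn <- mean(pred == 0L & act == 1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (tp == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, n = n),
            class = "predictive_score")
}

#' @export
print.predictive_score <- function(x, ...) {
  cat(sprintf(
    "<predictive_score> F1=%.3f precision=%.3f recall=%.3f (n=%d)\n",
    x$f1, x$precision, x$recall, x$n))
  invisible(x)
}

#' Fit, compare and score one sequence end to end
#'
#' Convenience wrapper: fits all requested models on the chronological first
#' half, selects by AIC (fit on the full sequence) and scores predictive F1
#' of each model on the second half.
#'
#' @param seq a [choice_sequence].
#' @param models models to fit.
#' @param n_init random initialisations per model.
#' @param seed integer seed.
#' @param threshold F1 decision threshold.
#' @return list with `fits` (full-sequence fits), `selection`, `f1`
#'   (named numeric), `half_fits`.
#' @export
fit_and_score <- function(seq, models = c("RW", "FQ", "FQaF"), n_init = 100,
                          seed = 1, threshold = 0.5) {
  halves <- split_halves(seq)
  fits <- list()
  half_fits <- list()
  f1 <- numeric(0)
  for (m in models) {
    fits[[m]] <- fit_mle_multistart(m, seq, n_init = n_init,
                                    seed = derive_seed(seed, m, "full"))
    half_fits[[m]] <- fit_mle_multistart(m, halves$train, n_init = n_init,
                                         seed = derive_seed(seed, m, "half"))
    f1[m] <- if (is.null(half_fits[[m]]$params)) NA_real_ else
      predictive_f1(half_fits[[m]]$params, halves$test, threshold)$f1
  }
  list(fits = fits, selection = select_model(fits), f1 = f1,
       half_fits = half_fits)
}

#' Generative test of a model or reference agent
#'
#' Simulates `n_seq` fresh sequences of `n_trials` trials per condition and
#' summarises, per condition: the return probability on rewarded and on
#' unrewarded trials, the return probability immediately after a rewarded
#' return (reward-rich recent history), the mean run length of consecutive
#' returns, and the run-length histogram, each with across-sequence SEM.
#'
#' @param agent an [rl_params] (simulated as an RL agent) or an [agent_spec]
#'   (for the deterministic/random reference agents).
#' @param conditions vector of reward probabilities.
#' @param n_seq sequences per condition (default 1000).
#' @param n_trials trials per sequence (default 1000).
#' @param seed integer seed.
#' @param max_run_length histogram support cap.
#' @return a list with `summary` (data frame per condition) and `run_lengths`
#'   (data frame `p_reward`, `length`, `mean_count`, `sem_count`).
#' @export
generative_test <- function(agent, conditions, n_seq = 1000, n_trials = 1000,
                            seed = 1, max_run_length = 30) {
  is_rl <- inherits(agent, "rl_params")
  if (!is_rl) stopifnot(inherits(agent, "agent_spec"))
  summ <- NULL
  runs <- NULL
  for (p in conditions) {
    stopifnot_prob(p, "condition")
    stat <- matrix(NA_real_, n_seq, 4)
    hist_mat <- matrix(0, n_seq, max_run_length)
    set.seed(derive_seed(seed, round(p * 1000)))
    for (s in seq_len(n_seq)) {
      cs <- if (is_rl) {
        sim <- rl_simulate_stream(agent, p, n_trials)
        choice_sequence(sim$rewards, sim$choices, p_reward = p)
      } else if (agent$kind == "rl") {
        sim <- rl_simulate_stream(agent$rl_params, p, n_trials)
        choice_sequence(sim$rewards, sim$choices, p_reward = p)
      } else {
        reference_stream(agent$kind, p, n_trials, agent$response_prob)
      }
      R <- cs$rewards
      C <- cs$choices
      stat[s, 1] <- if (any(R == 1L)) mean(C[R == 1L]) else NA
      stat[s, 2] <- if (any(R == 0L)) mean(C[R == 0L]) else NA
      rich <- which(R[-n_trials] == 1L & C[-n_trials] == 1L) + 1L
      stat[s, 3] <- if (length(rich)) mean(C[rich]) else NA
      rl_hist <- run_length_histogram(C)
      stat[s, 4] <- if (nrow(rl_hist)) {
        sum(rl_hist$length * rl_hist$count) / sum(rl_hist$count)
      } else NA
      if (nrow(rl_hist)) {
        lens <- pmin(rl_hist$length, max_run_length)
        for (r in seq_len(nrow(rl_hist))) {
          hist_mat[s, lens[r]] <- hist_mat[s, lens[r]] + rl_hist$count[r]
        }
      }
    }
    sem <- function(v) sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
    summ <- rbind(summ, data.frame(
      p_reward = p,
      p_return_rewarded = mean(stat[, 1], na.rm = TRUE),
      sem_rewarded = sem(stat[, 1]),
      p_return_unrewarded = mean(stat[, 2], na.rm = TRUE),
      sem_unrewarded = sem(stat[, 2]),
      p_return_after_rewarded_return = mean(stat[, 3], na.rm = TRUE),
      mean_run_length = mean(stat[, 4], na.rm = TRUE),
      sem_run_length = sem(stat[, 4])))
    occupied <- which(colSums(hist_mat) > 0)
    if (length(occupied)) {
      runs <- rbind(runs, data.frame(
        p_reward = p, length = occupied,
        mean_count = colMeans(hist_mat[, occupied, drop = FALSE]),
        sem_count = apply(hist_mat[, occupied, drop = FALSE], 2, sd) /
          sqrt(n_seq)))
    }
  }
  rownames(summ) <- NULL
  list(summary = summ,
       run_lengths = runs %||% data.frame(p_reward = numeric(0),
                                          length = integer(0),
                                          mean_count = numeric(0),
                                          sem_count = numeric(0)))
}
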