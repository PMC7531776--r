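# Independent oracles used by the tests.  These deliberately re-derive the
# quantities with plain R (no calls into the package's computational path).

# forward pass of the RL models in plain R: choice probability on trial t
# uses the value held before the trial's outcome
oracle_rl_forward <- function(alpha, beta, bias, phi, q0, rewards, choices) {
  n <- length(rewards)
  q <- q0
  ll <- 0
  Q <- numeric(n)
  P <- numeric(n)
  for (t in seq_len(n)) {
    Q[t] <- q
    p <- 1 / (1 + exp(beta * (bias - q)))
    p <- min(max(p, 1e-12), 1 - 1e-12)
    P[t] <- p
    ll <- ll + if (choices[t] == 1) log(p) else log(1 - p)
    q <- if (choices[t] == 1) q + alpha * (rewards[t] - q) else q - phi * q
  }
  list(Q = Q, P = P, logL_mean = ll / n)
}

# dense grid search of the RL likelihood over (alpha, beta, bias)
oracle_grid_search_rl <- function(model, rewards, choices,
                                  alpha_grid = seq(0, 1, by = 0.05),
                                  beta_grid = seq(0, 20, by = 1),
                                  bias_grid = seq(-1, 2, by = 0.1)) {
  best <- -Inf
  best_par <- NULL
  for (a in alpha_grid) for (b in beta_grid) for (bi in bias_grid) {
    phi <- switch(model, RW = 0, FQ = a, stop("grid oracle covers RW/FQ"))
    ll <- oracle_rl_forward(a, b, bi, phi, 0, rewards, choices)$logL_mean
    if (ll > best) {
      best <- ll
      best_par <- c(alpha = a, beta = b, bias = bi)
    }
  }
  list(logL = best, par = best_par)
}

# Bernoulli log-likelihood of a logistic model
oracle_logistic_ll <- function(beta, X1, y) {
  p <- 1 / (1 + exp(-drop(X1 %*% beta)))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# grid search of the logistic likelihood (intercept + up to 2 columns),
# vectorised over the grid in chunks
oracle_grid_search_logistic <- function(X, y, lo = -5, hi = 5, by = 0.1) {
  X1 <- cbind(1, X)
  grid <- as.matrix(expand.grid(rep(list(seq(lo, hi, by = by)), ncol(X1))))
  best <- -Inf
  best_par <- NULL
  chunk <- 2e5
  for (start in seq(1, nrow(grid), by = chunk)) {
    g <- grid[start:min(start + chunk - 1, nrow(grid)), , drop = FALSE]
    eta <- g %*% t(X1)                       # chunk x n
    p <- 1 / (1 + exp(-eta))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- log(p) %*% y + log(1 - p) %*% (1 - y)
    i <- which.max(ll)
    if (ll[i] > best) {
      best <- ll[i]
      best_par <- as.numeric(g[i, ])
    }
  }
  list(logL = best, par = best_par)
}

# brute-force turn count: sign alternations of the displacement sequence,
# zeros dropped
oracle_turn_count <- function(x) {
  s <- sign(diff(x))
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

# simple trajectory data frame at a fixed sampling rate
make_traj <- function(x, fs = 50, y = NULL) {
  n <- length(x)
  data.frame(time = (seq_len(n) - 1) / fs, x = x,
             y = y %||% rep(0, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_arena <- function(p1 = 0, p2 = 0, fs = 30) {
  arena_config(stim_probability_zone1 = p1, stim_probability_zone2 = p2,
               sampling_rate = fs)
}
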