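# Reward-history logistic regression (choice kernels).

#' Regression specification
#'
#' @param m history depth in trials (default 10).
#' @param include_choice_history also regress on the fly's own past choices
#'   (decision inertia); default TRUE.
#' @param regularization ridge strength (0 = plain maximum likelihood; a
#'   small ridge of 1e-4 is applied automatically when separation is
#'   detected).
#' @return an object of class `regression_spec`.
#' @export
regression_spec <- function(m = 10, include_choice_history = TRUE,
                            regularization = 0) {
  m <- stopifnot_count(m, "m")
  if (regularization < 0) stop("regularization must be >= 0", call. = FALSE)
  structure(list(m = m, include_choice_history = include_choice_history,
                 regularization = regularization),
            class = "regression_spec")
}

#' Build the history design matrix
#'
#' Row `t` (for `t > M`) contains the current reward `R(t)` (lag 0), the
#' lagged rewards `R(t-1) ... R(t-M)` and, when enabled, the lagged choices
#' `c(t-1) ... c(t-M)`; the response is the current choice `c(t)`.  The first
#' `M` trials are dropped.
#'
#' @param seq a [choice_sequence].
#' @param spec a [regression_spec].
#' @return a list with `X` (design matrix with named columns `reward_lag0`,
#'   `reward_lag1`, ..., `choice_lag1`, ...), `y` (response) and `spec`.
#' @export
build_history_design <- function(seq, spec = regression_spec()) {
  stopifnot(inherits(seq, "choice_sequence"),
            inherits(spec, "regression_spec"))
  R <- seq$rewards
  C <- seq$choices
  n <- length(R)
  m <- spec$m
  if (n <= m) stop("sequence too short for the requested history depth",
                   call. = FALSE)
  rows <- (m + 1L):n
  X <- sapply(0:m, function(lag) R[rows - lag])
  colnames(X) <- paste0("reward_lag", 0:m)
  if (spec$include_choice_history) {
    Xc <- sapply(1:m, function(lag) C[rows - lag])
    if (m == 1L) Xc <- matrix(Xc, ncol = 1)
    colnames(Xc) <- paste0("choice_lag", 1:m)
    X <- cbind(X, Xc)
  }
  if (is.vector(X)) X <- matrix(X, ncol = 1,
                                dimnames = list(NULL, "reward_lag0"))
  list(X = X, y = C[rows], spec = spec)
}

# penalized IRLS for logistic ridge (intercept unpenalized)
ridge_logistic <- function(X, y, lambda, max_iter = 100, tol = 1e-10) {
  X1 <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X1, X1 * w) + 2 * pen
    g <- crossprod(X1, y - mu) - 2 * pen %*% beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X1 %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(X1, X1 * w) + 2 * pen
  se <- sqrt(diag(solve(H)))
  ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  list(coef = setNames(beta, colnames(X1)), se = se, logLik = ll,
       converged = converged)
}

parse_terms <- function(terms) {
  fam <- ifelse(grepl("^reward_lag", terms), "reward",
                ifelse(grepl("^choice_lag", terms), "choice", "intercept"))
  lag <- suppressWarnings(as.integer(sub("^(reward|choice)_lag", "", terms)))
  data.frame(term = terms, family = fam, lag = lag)
}

#' Fit the history logistic regression
#'
#' Maximum-likelihood logistic fit (IRLS via `stats::glm`) of the current
#' return choice on the reward/choice history, with Wald standard errors and
#' p-values.  When (quasi-)separation is detected — glm's
#' fitted-probabilities warning, non-convergence, or divergent coefficients —
#' the fit is flagged and automatically refit with a small ridge penalty
#' (1e-4), as unpenalized estimates are infinite in that case.
#'
#' @param design output of [build_history_design()], or a design matrix.
#' @param response response vector (only when `design` is a matrix).
#' @param spec a [regression_spec] (defaults to the design's).
#' @return an object of class `regression_result`: list with `coefficients`
#'   (data frame `term`, `family`, `lag`, `estimate`, `se`, `statistic`,
#'   `p_value`), `logLik`, `null_logLik`, `n`, and flags `converged`,
#'   `separation`, `regularized`.
#' @export
fit_logistic <- function(design, response = NULL, spec = NULL) {
  if (is.list(design) && !is.data.frame(design) && !is.matrix(design)) {
    X <- design$X
    y <- design$y
    spec <- spec %||% design$spec
  } else {
    X <- as.matrix(design)
    y <- response
  }
  spec <- spec %||% regression_spec(m = 1)
  if (length(unique(y)) < 2) {
    stop("response is constant; nothing to fit", call. = FALSE)
  }
  qrX <- qr(cbind(1, X))
  rank_deficient <- qrX$rank < ncol(X) + 1L
  if (rank_deficient && spec$regularization <= 0) {
    stop("design is rank deficient; enable ridge regularization",
         call. = FALSE)
  }
  separation <- FALSE
  fit <- NULL
  if (spec$regularization <= 0) {
    dat <- data.frame(y = y, X)
    fit <- withCallingHandlers(
      glm(y ~ ., data = dat, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w)) ||
            grepl("algorithm did not converge", conditionMessage(w))) {
          separation <<- TRUE
        }
        invokeRestart("muffleWarning")
      })
    if (!separation && max(abs(coef(fit)), na.rm = TRUE) > 15) {
      separation <- TRUE
    }
  }
  regularized <- separation || spec$regularization > 0
  if (regularized) {
    lambda <- if (spec$regularization > 0) spec$regularization else 1e-4
    rf <- ridge_logistic(X, y, lambda)
    est <- rf$coef
    se <- rf$se
    ll <- rf$logLik
    converged <- rf$converged
  } else {
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    ll <- as.numeric(logLik(fit))
    converged <- fit$converged
  }
  z <- est / se
  pv <- 2 * pnorm(-abs(z))
  terms <- c("(Intercept)", colnames(X))
  meta <- parse_terms(terms)
  coefs <- cbind(meta, data.frame(estimate = unname(est), se = unname(se),
                                  statistic = unname(z),
                                  p_value = unname(pv)))
  p1 <- mean(y)
  null_ll <- sum(y) * log(p1) + sum(1 - y) * log(1 - p1)
  structure(list(coefficients = coefs, logLik = ll, null_logLik = null_ll,
                 n = length(y), converged = converged,
                 separation = separation, regularized = regularized),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n=%d logLik=%.2f%s%s\n", x$n, x$logLik,
              if (x$separation) " [separation]" else "",
              if (x$regularized) " [ridge]" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Population-average kernel
#'
#' Per-lag mean and SEM of the fitted coefficients across flies, with a
#' one-sample t-test of the population mean against zero.  Lags whose
#' population mean misses the significance threshold are masked
#' (`mean_masked = NA`) in the report, mirroring significance-masked kernel
#' plots.
#'
#' @param results list of `regression_result` objects (>= 2 flies) fitted
#'   with the same specification.
#' @param sig_threshold significance threshold (default 0.01).
#' @return a data frame `term`, `family`, `lag`, `mean`, `sem`, `statistic`,
#'   `p_value`, `significant`, `mean_masked`.
#' @export
population_kernel <- function(results, sig_threshold = 0.01) {
  if (length(results) < 2) stop("need at least 2 flies", call. = FALSE)
  terms <- results[[1]]$coefficients$term
  mat <- vapply(results, function(r) {
    stopifnot(identical(r$coefficients$term, terms))
    r$coefficients$estimate
  }, numeric(length(terms)))
  mu <- rowMeans(mat)
  sem <- apply(mat, 1, sd) / sqrt(ncol(mat))
  tstat <- ifelse(sem > 0, mu / sem, ifelse(mu == 0, 0, Inf))
  pv <- 2 * pt(-abs(tstat), df = ncol(mat) - 1L)
  meta <- parse_terms(terms)
  out <- cbind(meta, data.frame(mean = mu, sem = sem, statistic = tstat,
                                p_value = pv,
                                significant = pv < sig_threshold))
  out$mean_masked <- ifelse(out$significant, out$mean, NA_real_)
  rownames(out) <- NULL
  out
}
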