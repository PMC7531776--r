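#' Derive a reproducible sub-seed from a master seed
#'
#' Folds the master seed and any number of extra components (integers or
#' strings, e.g. fly index and stage name) into a new 31-bit seed, so that
#' stages and flies get decoupled but fully deterministic RNG streams.
#'
#' @param master integer master seed.
#' @param ... additional components (numeric or character).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  mod <- 2147483647
  h <- as.numeric(master) %% mod
  for (part in list(...)) {
    if (is.character(part)) {
      vals <- as.numeric(utf8ToInt(paste(part, collapse = "|")))
    } else {
      vals <- as.numeric(part)
    }
    for (v in vals) {
      h <- (h * 69069 + abs(v) + 1) %% mod
    }
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_prob <- function(p, what = "probability") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", what),
         call. = FALSE)
  }
  invisible(p)
}

stopifnot_count <- function(n, what = "count", min = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < min ||
      n != floor(n)) {
    stop(sprintf("'%s' must be an integer >= %d", what, min), call. = FALSE)
  }
  invisible(as.integer(n))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
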