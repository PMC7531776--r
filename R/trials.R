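# Trial segmentation and trial-level statistics.

#' Segment a session into discrete trials
#'
#' A trial on zone z spans the time between two successive visits of that
#' zone, where a visit is an entry into the reset zone from outside the
#' combined reward+reset band followed by an entry into the reward zone (the
#' reset -> reward order of the trigger rule).  The trial starts at the reset
#' entry, records the reward-zone entry time, and ends when the fly next
#' enters the same reset zone en route to the next visit.  `rewarded` is read
#' from the stimulation log (an event on this zone within
#' `[t_enter_reward, t_end]`); `returned` is 1 iff, between the two visits,
#' the fly never reached the opposite side's reset-zone boundary.  A trial
#' still in progress at session end is dropped.
#'
#' @param session a `session_record`, or a preprocessed trajectory carrying
#'   `stim_log`/`config` attributes.
#' @param config an [arena_config] (defaults to the session's).
#' @return a data frame of class `trial_table`, one row per trial in
#'   chronological order: `index`, `zone`, `t_enter_reset`, `t_enter_reward`,
#'   `t_end`, `rewarded`, `returned`, `max_excursion_x` (mm from the zone's
#'   wall).  Empty (zero-row) when the fly never completes two visits.
#' @export
segment_trials <- function(session, config = NULL) {
  if (inherits(session, "session_record")) {
    traj <- session$trajectory
    stim <- session$stim_log
    config <- config %||% session$config
  } else {
    traj <- session
    stim <- attr(session, "stim_log") %||%
      data.frame(time = numeric(0), zone = integer(0))
    config <- config %||% attr(session, "config")
  }
  stopifnot(inherits(config, "arena_config"))
  x <- traj$x
  tt <- traj$time
  reg <- arena_region(x, config)
  # visits per zone: reset entry from outside the band, then reward entry
  ch <- which(diff(reg) != 0) + 1L        # indices where the region changes
  anchors <- list(`1` = NULL, `2` = NULL)
  armed <- c(FALSE, FALSE)
  t_reset <- c(NA_real_, NA_real_)
  prev <- reg[1]
  for (i in ch) {
    g <- reg[i]
    band1 <- prev %in% c(1L, 2L)
    band2 <- prev %in% c(3L, 4L)
    if (g == 2L && !band1) { armed[1] <- TRUE; t_reset[1] <- tt[i] }
    if (g == 3L && !band2) { armed[2] <- TRUE; t_reset[2] <- tt[i] }
    # direct jump from outside into the reward zone (fast crossing of the
    # 3 mm reset band within one sample) counts as reset + reward in order
    if (g == 1L && !band1 && !armed[1]) { armed[1] <- TRUE; t_reset[1] <- tt[i] }
    if (g == 4L && !band2 && !armed[2]) { armed[2] <- TRUE; t_reset[2] <- tt[i] }
    z <- if (g == 1L) 1L else if (g == 4L) 2L else 0L
    if (z > 0L && armed[z]) {
      anchors[[z]] <- rbind(anchors[[z]],
                            data.frame(t_enter_reset = t_reset[z],
                                       t_enter_reward = tt[i]))
      armed[z] <- FALSE
    }
    prev <- g
  }
  band <- config$reward_zone_depth + config$reset_zone_depth
  far_bound <- config$length - band
  rows <- NULL
  for (z in 1:2) {
    a <- anchors[[as.character(z)]]
    if (is.null(a) || nrow(a) < 2) next
    for (j in seq_len(nrow(a) - 1L)) {
      t0 <- a$t_enter_reward[j]
      t_end <- a$t_enter_reset[j + 1L]
      t1 <- a$t_enter_reward[j + 1L]
      seg <- x[tt >= t0 & tt <= t1]
      exc <- if (z == 1L) max(seg) else config$length - min(seg)
      returned <- as.integer(exc < far_bound)
      stim_z <- stim$time[stim$zone == z]
      rewarded <- as.integer(any(stim_z >= t0 & stim_z <= t_end))
      rows <- rbind(rows, data.frame(
        zone = z, t_enter_reset = a$t_enter_reset[j], t_enter_reward = t0,
        t_end = t_end, rewarded = rewarded, returned = returned,
        max_excursion_x = exc))
    }
  }
  if (is.null(rows)) {
    rows <- data.frame(zone = integer(0), t_enter_reset = numeric(0),
                       t_enter_reward = numeric(0), t_end = numeric(0),
                       rewarded = integer(0), returned = integer(0),
                       max_excursion_x = numeric(0))
  } else {
    rows <- rows[order(rows$t_enter_reward), ]
  }
  rows <- cbind(index = seq_len(nrow(rows)), rows)
  rownames(rows) <- NULL
  class(rows) <- c("trial_table", "data.frame")
  rows
}

#' Extract the per-zone choice sequence from a trial table
#'
#' Two-sided sessions produce one interleaved sequence per zone; each is
#' analysed independently.
#'
#' @param trials a trial table from [segment_trials()].
#' @param zone zone label (1 or 2).
#' @param p_reward nominal condition probability carried into the sequence.
#' @param fly fly identifier.
#' @return a [choice_sequence] with trial timestamps.
#' @export
trials_to_choice_sequence <- function(trials, zone = 1L,
                                      p_reward = NA_real_,
                                      fly = NA_character_) {
  tz <- trials[trials$zone == zone, ]
  choice_sequence(tz$rewarded, tz$returned, zone = zone, p_reward = p_reward,
                  fly = fly, times = tz$t_enter_reward)
}

#' Minimum-trial exclusion filter
#'
#' Sessions with fewer than `min_trials` trials are excluded from further
#' analysis (boundary inclusive: exactly `min_trials` is retained).
#'
#' @param trials a trial table.
#' @param min_trials exclusion threshold (default 50).
#' @return a list with `trials` (unchanged), `n_trials` and logical
#'   `excluded`.
#' @export
filter_sessions <- function(trials, min_trials = 50) {
  n <- if (is.data.frame(trials)) nrow(trials) else length(trials)
  list(trials = trials, n_trials = n, excluded = n < min_trials)
}

#' Return statistics of a trial table
#'
#' Overall and conditioned return probabilities plus a centred 5-trial moving
#' average of the return series per zone.  Conditioning sets that are empty
#' are reported as `NA` (undefined), not zero.
#'
#' @param trials a trial table (needs `zone`, `rewarded`, `returned`).
#' @param window moving-average window (default 5, centred).
#' @return a list with `overall`, `by_zone_outcome` (data frame `zone`,
#'   `rewarded`, `p_return`, `n`) and `moving_average` (data frame `zone`,
#'   `trial`, `ma`).
#' @export
return_statistics <- function(trials, window = 5) {
  if (nrow(trials) < 1) stop("need at least one trial", call. = FALSE)
  p_if <- function(mask) if (any(mask)) mean(trials$returned[mask]) else
    NA_real_
  grid <- expand.grid(zone = sort(unique(trials$zone)), rewarded = c(0L, 1L))
  grid$p_return <- mapply(function(z, r) {
    p_if(trials$zone == z & trials$rewarded == r)
  }, grid$zone, grid$rewarded)
  grid$n <- mapply(function(z, r) {
    sum(trials$zone == z & trials$rewarded == r)
  }, grid$zone, grid$rewarded)
  ma <- NULL
  for (z in sort(unique(trials$zone))) {
    r <- trials$returned[trials$zone == z]
    if (length(r) >= window) {
      m <- stats::filter(r, rep(1 / window, window), sides = 2)
      ma <- rbind(ma, data.frame(zone = z, trial = seq_along(r),
                                 ma = as.numeric(m)))
    }
  }
  list(overall = mean(trials$returned), by_zone_outcome = grid,
       moving_average = ma %||% data.frame(zone = integer(0),
                                           trial = integer(0),
                                           ma = numeric(0)))
}

#' Run-length histogram of return choices
#'
#' Lengths of maximal blocks of consecutive returns (`c = 1`); the
#' generative-test statistic.  For two-sided data, pass each zone's sequence
#' separately.
#'
#' @param choices binary vector (or a [choice_sequence]).
#' @return a data frame `length`, `count`; zero rows when there are no
#'   returns.
#' @export
run_length_histogram <- function(choices) {
  if (inherits(choices, "choice_sequence")) choices <- choices$choices
  if (length(choices) == 0) return(data.frame(length = integer(0),
                                              count = integer(0)))
  r <- rle(as.integer(choices))
  lens <- r$lengths[r$values == 1L]
  if (length(lens) == 0) return(data.frame(length = integer(0),
                                           count = integer(0)))
  tab <- table(lens)
  data.frame(length = as.integer(names(tab)), count = as.integer(tab))
}

#' Default time bins for the first-reward analysis
#'
#' Fine bins early (0.03 s up to 1 s), 0.1 s up to 9 s, 50 s steps from 10 to
#' 200 s and 100 s steps from 300 to 1000 s.
#'
#' @return numeric vector of bin breaks (s).
#' @export
first_reward_time_bins <- function() {
  sort(unique(c(seq(0, 1, by = 0.03), seq(1, 9, by = 0.1),
                seq(10, 200, by = 50), seq(300, 1000, by = 100), Inf)))
}

#' First-reward return summary across flies
#'
#' For each fly the first rewarded trial is located; the summary reports the
#' fraction of flies that returned on that trial, binned by the delay of the
#' first reward (trial index, and wall-clock time when timestamps are
#' available), plus the split of subsequent rewarded-trial return probability
#' by whether the fly returned on its first reward.  Flies that never
#' received a reward are excluded.
#'
#' @param seqs list of [choice_sequence] objects (with `times` for the
#'   time-binned output).
#' @param trial_breaks breaks for trial-index bins.
#' @param time_breaks breaks for time bins (default
#'   [first_reward_time_bins()]).
#' @return a list with `by_trial`, `by_time` (data frames `bin_lo`, `bin_hi`,
#'   `n_flies`, `fraction_returned`) and `split` (subsequent rewarded-trial
#'   return probability by first-reward response).
#' @export
first_reward_summary <- function(seqs,
                                 trial_breaks = c(1, 2, 3, 4, 6, 11, 31, Inf),
                                 time_breaks = first_reward_time_bins()) {
  first <- lapply(seqs, function(s) {
    t1 <- which(s$rewards == 1L)[1]
    if (is.na(t1)) return(NULL)
    later <- s$rewards == 1L & seq_along(s$rewards) > t1
    list(trial = t1,
         time = if (!is.null(s$times)) s$times[t1] else NA_real_,
         returned = s$choices[t1],
         p_later = if (any(later)) mean(s$choices[later]) else NA_real_)
  })
  first <- first[!vapply(first, is.null, logical(1))]
  if (length(first) == 0) {
    stop("no fly with a rewarded trial", call. = FALSE)
  }
  df <- data.frame(trial = vapply(first, `[[`, numeric(1), "trial"),
                   time = vapply(first, `[[`, numeric(1), "time"),
                   returned = vapply(first, `[[`, numeric(1), "returned"),
                   p_later = vapply(first, `[[`, numeric(1), "p_later"))
  bin_frame <- function(v, returned, breaks) {
    b <- findInterval(v, breaks, rightmost.closed = FALSE)
    keep <- b >= 1 & b < length(breaks)
    out <- NULL
    for (k in sort(unique(b[keep]))) {
      m <- b == k & keep
      out <- rbind(out, data.frame(bin_lo = breaks[k], bin_hi = breaks[k + 1],
                                   n_flies = sum(m),
                                   fraction_returned = mean(returned[m])))
    }
    out %||% data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                        n_flies = integer(0), fraction_returned = numeric(0))
  }
  by_trial <- bin_frame(df$trial, df$returned, trial_breaks)
  ok_t <- !is.na(df$time)
  by_time <- if (!any(ok_t)) NULL else
    bin_frame(df$time[ok_t], df$returned[ok_t], time_breaks)
  split <- data.frame(
    returned_on_first = c(1L, 0L),
    p_return_later = c(mean(df$p_later[df$returned == 1L], na.rm = TRUE),
                       mean(df$p_later[df$returned == 0L], na.rm = TRUE)),
    n_flies = c(sum(df$returned == 1L), sum(df$returned == 0L)))
  list(by_trial = by_trial, by_time = by_time, split = split,
       per_fly = df)
}
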