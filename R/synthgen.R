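#' Arena configuration
#'
#' Geometry and stimulation settings of the virtual linear-track arena.  The
#' track is `length` x `width` mm; at each end a reward zone of depth
#' `reward_zone_depth` sits against the wall with a reset zone of depth
#' `reset_zone_depth` immediately adjacent (toward the centre).  A Bernoulli
#' stimulation opportunity arises only when the fly crosses a reset zone and
#' then enters the adjoining reward zone, in that order; dwelling inside the
#' reward zone never re-triggers.
#'
#' @param length arena length (mm, default 50).
#' @param width arena width (mm, default 5).
#' @param reward_zone_depth reward-zone depth from the wall (mm, default 6).
#' @param reset_zone_depth reset-zone depth adjacent to the reward zone
#'   (mm, default 3).
#' @param stim_probability_zone1,stim_probability_zone2 stimulation
#'   probabilities per armed reward-zone entry for zones 1 (x = 0 wall) and 2.
#' @param stim_duration stimulation flash duration (s, default 0.05).
#' @param sampling_rate trajectory sampling rate (Hz, default 30).
#' @return an object of class `arena_config`.
#' @export
arena_config <- function(length = 50, width = 5, reward_zone_depth = 6,
                         reset_zone_depth = 3,
                         stim_probability_zone1 = 0,
                         stim_probability_zone2 = 0,
                         stim_duration = 0.05, sampling_rate = 30) {
  if (reward_zone_depth + reset_zone_depth >= length / 2) {
    stop("reward + reset zone depth must be < length/2", call. = FALSE)
  }
  stopifnot_prob(stim_probability_zone1, "stim_probability_zone1")
  stopifnot_prob(stim_probability_zone2, "stim_probability_zone2")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  if (width <= 0 || length <= 0) stop("arena sides must be > 0",
                                      call. = FALSE)
  structure(
    list(length = length, width = width,
         reward_zone_depth = reward_zone_depth,
         reset_zone_depth = reset_zone_depth,
         stim_probability_zone1 = stim_probability_zone1,
         stim_probability_zone2 = stim_probability_zone2,
         stim_duration = stim_duration, sampling_rate = sampling_rate),
    class = "arena_config"
  )
}

# Region code for x positions: 1 = zone-1 reward, 2 = zone-1 reset,
# 0 = centre, 3 = zone-2 reset, 4 = zone-2 reward.  Zone membership is
# half-open in the distance from the wall: reward = [0, rd), reset =
# [rd, rd + rs).
arena_region <- function(x, config) {
  rd <- config$reward_zone_depth
  rs <- config$reset_zone_depth
  L <- config$length
  out <- integer(length(x))
  d2 <- L - x # distance from zone-2 wall
  out[x < rd] <- 1L
  out[x >= rd & x < rd + rs] <- 2L
  out[d2 >= rd & d2 < rd + rs] <- 3L
  out[d2 < rd] <- 4L
  out
}

#' Agent specification
#'
#' Describes the trial-level behavioural rule of a simulated fly: an RL agent
#' (driven by [rl_params]), the deterministic reference agent (returns with
#' `response_prob` only when rewarded) or the random reference agent (returns
#' with `response_prob` regardless of reward).
#'
#' @param kind `"rl"`, `"deterministic"` or `"random"`.
#' @param rl_params an [rl_params] object; required iff `kind = "rl"`.
#' @param response_prob response probability of the reference agents
#'   (default 0.5).
#' @return an object of class `agent_spec`.
#' @export
agent_spec <- function(kind = c("rl", "deterministic", "random"),
                       rl_params = NULL, response_prob = 0.5) {
  kind <- match.arg(kind)
  stopifnot_prob(response_prob, "response_prob")
  if (kind == "rl") {
    if (!inherits(rl_params, "rl_params")) {
      stop("kind = 'rl' requires an rl_params object", call. = FALSE)
    }
  } else if (!is.null(rl_params)) {
    stop("'rl_params' is only meaningful for kind = 'rl'", call. = FALSE)
  }
  structure(list(kind = kind, rl_params = rl_params,
                 response_prob = response_prob),
            class = "agent_spec")
}

#' Binary reward/choice sequence for one fly and zone
#'
#' The trial-level representation every regression and model-fitting stage
#' consumes: per-trial binary rewards `R(t)` and return choices `c(t)`.
#'
#' @param rewards 0/1 vector of per-trial rewards.
#' @param choices 0/1 vector of per-trial return choices (same length).
#' @param zone zone label (1 or 2).
#' @param p_reward nominal stimulation probability of the condition (NA if
#'   unknown).
#' @param fly fly identifier.
#' @param times optional per-trial timestamps (s, time of reward-zone entry).
#' @return an object of class `choice_sequence`.
#' @export
choice_sequence <- function(rewards, choices, zone = 1L, p_reward = NA_real_,
                            fly = NA_character_, times = NULL) {
  rewards <- as.integer(rewards)
  choices <- as.integer(choices)
  if (length(rewards) != length(choices)) {
    stop("rewards and choices must have equal length", call. = FALSE)
  }
  if (any(!rewards %in% c(0L, 1L)) || any(!choices %in% c(0L, 1L))) {
    stop("rewards and choices must be binary", call. = FALSE)
  }
  if (!is.null(times) && length(times) != length(rewards)) {
    stop("times must match the number of trials", call. = FALSE)
  }
  structure(list(rewards = rewards, choices = choices, zone = as.integer(zone),
                 p_reward = p_reward, fly = fly, times = times),
            class = "choice_sequence")
}

#' @export
print.choice_sequence <- function(x, ...) {
  cat(sprintf(
    "<choice_sequence> fly=%s zone=%d n=%d reward rate=%.3f return rate=%.3f\n",
    x$fly, x$zone, length(x$rewards), mean(x$rewards), mean(x$choices)))
  invisible(x)
}

#' @export
length.choice_sequence <- function(x) length(x$rewards)

#' Simulate a trial-level choice sequence
#'
#' Rewards are i.i.d. Bernoulli(`p_reward`) per trial; choices follow the
#' agent rule (RL agents use the logistic choice rule on their running value;
#' the deterministic reference agent returns with `response_prob` only on
#' rewarded trials; the random agent ignores rewards).
#'
#' @param agent an [agent_spec].
#' @param p_reward per-trial reward probability.
#' @param n_trials number of trials (>= 1).
#' @param seed integer seed.
#' @return a [choice_sequence].
#' @export
simulate_choice_sequence <- function(agent, p_reward, n_trials, seed) {
  stopifnot(inherits(agent, "agent_spec"))
  stopifnot_prob(p_reward, "p_reward")
  n_trials <- stopifnot_count(n_trials, "n_trials")
  set.seed(seed)
  if (agent$kind == "rl") {
    sim <- rl_simulate_stream(agent$rl_params, p_reward, n_trials)
    choice_sequence(sim$rewards, sim$choices, p_reward = p_reward)
  } else {
    reference_stream(agent$kind, p_reward, n_trials, agent$response_prob)
  }
}

#' Regression control fixture
#'
#' Generates the simulated-fly control for the reward-history regression: a
#' long i.i.d. Bernoulli reward vector and choices that follow a reward with
#' probability `responsiveness` and otherwise occur at a small baseline rate.
#' Such a memoryless responder has a true reward kernel that is zero at every
#' lag >= 1.
#'
#' @param p_reward reward probability.
#' @param n number of trials.
#' @param responsiveness probability of a return choice on rewarded trials.
#' @param seed integer seed.
#' @param baseline choice probability on unrewarded trials (default 0.01; a
#'   strict 0 induces perfect separation in the logistic fit and remains
#'   selectable).
#' @return a [choice_sequence].
#' @export
make_regression_fixture <- function(p_reward, n, responsiveness, seed,
                                    baseline = 0.01) {
  stopifnot_prob(p_reward, "p_reward")
  stopifnot_prob(responsiveness, "responsiveness")
  stopifnot_prob(baseline, "baseline")
  n <- stopifnot_count(n, "n")
  set.seed(seed)
  rewards <- as.integer(runif(n) < p_reward)
  u <- runif(n)
  p_choice <- ifelse(rewards == 1L, responsiveness, baseline)
  choices <- as.integer(u < p_choice)
  choice_sequence(rewards, choices, p_reward = p_reward)
}

#' Default walk parameters for the virtual fly
#'
#' The walking model is an Ornstein-Uhlenbeck velocity process along the
#' track with reflecting walls and small transverse jitter; it is a
#' statistical stand-in, not fly biomechanics.  After each delivered
#' stimulation the walk enters a transient "local search" state with an
#' elevated turn hazard and reduced speed.
#'
#' @param speed_sd stationary SD of the x-velocity (mm/s).
#' @param relax_rate OU relaxation rate (1/s).
#' @param y_sd SD of the transverse jitter (mm).
#' @param search_duration duration of the post-stimulation local-search state
#'   (s).
#' @param search_turn_hazard extra velocity-reversal hazard during local
#'   search (1/s).
#' @param search_slow multiplicative speed factor during local search.
#' @param search_stop_hazard extra stop hazard during local search (1/s).
#' @return a list of walk parameters.
#' @export
walk_params <- function(speed_sd = 8, relax_rate = 1.5, y_sd = 0.6,
                        search_duration = 3, search_turn_hazard = 1.5,
                        search_slow = 0.35, search_stop_hazard = 1) {
  list(speed_sd = speed_sd, relax_rate = relax_rate, y_sd = y_sd,
       search_duration = search_duration,
       search_turn_hazard = search_turn_hazard,
       search_slow = search_slow, search_stop_hazard = search_stop_hazard)
}

#' Simulate a closed-loop session at trajectory level
#'
#' Runs the stochastic walk inside the arena and applies the trigger rule
#' exactly: each zone arms when the fly enters its reset zone and, on the next
#' entry into that zone's reward zone while armed, a Bernoulli(`p_zone`)
#' stimulation opportunity is consumed.  Re-arming requires re-entering the
#' same side's reset zone.  Delivered stimulations transiently elevate the
#' stop and turn hazard (local-search emulation).
#'
#' @param config an [arena_config].
#' @param agent an [agent_spec] (reserved for behavioural coupling; the walk
#'   itself is agent-independent apart from local search).
#' @param duration session duration (s, > 0).
#' @param seed integer seed.
#' @param walk walk parameters from [walk_params()].
#' @return a `session_record`: list with `trajectory` (data frame `time`,
#'   `x`, `y`), `stim_log` (data frame `time`, `zone`), `config`, `seed`.
#' @export
simulate_session_trajectory <- function(config, agent = agent_spec("random"),
                                        duration, seed,
                                        walk = walk_params()) {
  stopifnot(inherits(config, "arena_config"))
  if (!is.numeric(duration) || duration <= 0) {
    stop("'duration' must be > 0", call. = FALSE)
  }
  fs <- config$sampling_rate
  if (fs <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  set.seed(seed)
  dt <- 1 / fs
  n <- max(2L, as.integer(round(duration * fs)))
  L <- config$length
  W <- config$width
  sigma <- walk$speed_sd * sqrt(2 * walk$relax_rate)
  noise <- rnorm(n) * sigma * sqrt(dt)
  y_noise <- rnorm(n) * walk$y_sd
  u_turn <- runif(n)
  u_stop <- runif(n)
  x <- numeric(n); y <- numeric(n)
  x[1] <- L / 2
  y[1] <- W / 2
  vx <- rnorm(1) * walk$speed_sd
  armed <- c(FALSE, FALSE)
  search_until <- -Inf
  stim_time <- numeric(0)
  stim_zone <- integer(0)
  p_zone <- c(config$stim_probability_zone1, config$stim_probability_zone2)
  region_prev <- arena_region(x[1], config)
  t_now <- 0
  for (i in 2:n) {
    t_now <- (i - 1) * dt
    searching <- t_now < search_until
    vx <- vx + walk$relax_rate * (0 - vx) * dt + noise[i]
    v_eff <- if (searching) vx * walk$search_slow else vx
    if (searching && u_turn[i] < walk$search_turn_hazard * dt) {
      vx <- -vx
      v_eff <- -v_eff
    }
    if (searching && u_stop[i] < walk$search_stop_hazard * dt) {
      v_eff <- 0
    }
    xi <- x[i - 1] + v_eff * dt
    if (xi < 0) { xi <- -xi; vx <- abs(vx) }
    if (xi > L) { xi <- 2 * L - xi; vx <- -abs(vx) }
    xi <- clamp(xi, 0, L)
    x[i] <- xi
    y[i] <- clamp(y[i - 1] + y_noise[i] * dt, 0, W)
    reg <- arena_region(xi, config)
    if (reg != region_prev) {
      if (reg == 2L) armed[1] <- TRUE
      if (reg == 3L) armed[2] <- TRUE
      zone <- if (reg == 1L) 1L else if (reg == 4L) 2L else 0L
      if (zone > 0L && armed[zone]) {
        armed[zone] <- FALSE
        if (runif(1) < p_zone[zone]) {
          stim_time <- c(stim_time, t_now)
          stim_zone <- c(stim_zone, zone)
          search_until <- t_now + walk$search_duration
        }
      }
      region_prev <- reg
    }
  }
  traj <- data.frame(time = (seq_len(n) - 1) * dt, x = x, y = y)
  session_record(traj, data.frame(time = stim_time, zone = stim_zone),
                 config, seed)
}

#' Replay the stimulation trigger rule over a given trajectory
#'
#' Applies the closed-loop trigger state machine to an existing path: each
#' zone arms when the fly enters its reset zone, and the next entry into that
#' zone's reward zone while armed consumes one Bernoulli(`p_zone`)
#' stimulation opportunity.  Dwelling inside a reward zone never
#' re-triggers.  Useful for scripted paths and for re-deriving stimulation
#' logs from recorded trajectories.
#'
#' @param traj data frame with `time` and `x`.
#' @param config an [arena_config] carrying the zone probabilities.
#' @param seed integer seed for the Bernoulli draws.
#' @return a stimulation log data frame (`time`, `zone`).
#' @export
replay_trigger <- function(traj, config, seed = 1) {
  stopifnot(inherits(config, "arena_config"))
  set.seed(seed)
  reg <- arena_region(traj$x, config)
  p_zone <- c(config$stim_probability_zone1, config$stim_probability_zone2)
  armed <- c(FALSE, FALSE)
  stim_time <- numeric(0)
  stim_zone <- integer(0)
  prev <- reg[1]
  for (i in which(diff(reg) != 0) + 1L) {
    g <- reg[i]
    if (g == 2L) armed[1] <- TRUE
    if (g == 3L) armed[2] <- TRUE
    z <- if (g == 1L) 1L else if (g == 4L) 2L else 0L
    if (z > 0L && armed[z]) {
      armed[z] <- FALSE
      if (runif(1) < p_zone[z]) {
        stim_time <- c(stim_time, traj$time[i])
        stim_zone <- c(stim_zone, z)
      }
    }
    prev <- g
  }
  data.frame(time = stim_time, zone = stim_zone)
}

session_record <- function(trajectory, stim_log, config, seed,
                           agent = NULL) {
  structure(list(trajectory = trajectory, stim_log = stim_log,
                 config = config, seed = seed, agent = agent),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %d samples, %.1f s, %d stim events\n",
              nrow(x$trajectory), max(x$trajectory$time), nrow(x$stim_log)))
  invisible(x)
}

#' Build a trajectory from scripted x waypoints
#'
#' Interpolates a constant-speed piecewise-linear path through the given x
#' waypoints (y is held at mid-width) and samples it at the arena sampling
#' rate.  Used to construct ground-truth itineraries for segmentation tests.
#'
#' @param waypoints_x numeric vector of x positions (mm).
#' @param config an [arena_config].
#' @param speed walking speed between waypoints (mm/s).
#' @return a data frame with `time`, `x`, `y`.
#' @export
scripted_trajectory <- function(waypoints_x, config, speed = 20) {
  stopifnot(length(waypoints_x) >= 2, speed > 0)
  waypoints_x <- waypoints_x[c(TRUE, diff(waypoints_x) != 0)]
  seg_len <- abs(diff(waypoints_x))
  seg_t <- seg_len / speed
  t_way <- c(0, cumsum(seg_t))
  fs <- config$sampling_rate
  tt <- seq(0, t_way[length(t_way)], by = 1 / fs)
  x <- approx(t_way, waypoints_x, xout = tt, rule = 2)$y
  data.frame(time = tt, x = x, y = rep(config$width / 2, length(tt)))
}

#' Generate a scripted itinerary session with known ground truth
#'
#' Builds a session whose fly visits the zones according to a scripted
#' itinerary, together with the ground-truth trial table implied by the
#' script (independent of the trial-segmentation code).  Each visit enters
#' the reset zone, dips into the reward zone, and then either "returns"
#' (excursion that stays short of the far reset boundary before revisiting
#' the same zone) or travels on (to the far zone, or a far excursion that
#' reaches the opposite reset boundary before coming back).  Rewards are
#' Bernoulli draws per visit placed in the stimulation log at the visit's
#' deepest point.
#'
#' @param n_visits number of zone visits to script (>= 2).
#' @param config an [arena_config].
#' @param p_reward probability that a visit is rewarded.
#' @param seed integer seed.
#' @param speed scripted walking speed (mm/s).
#' @return a list with `session` (a `session_record`) and `truth`, a data
#'   frame of ground-truth trials (`zone`, `rewarded`, `returned`) in
#'   chronological order.
#' @export
make_itinerary_session <- function(n_visits, config, p_reward = 0.5, seed = 1,
                                   speed = 20) {
  n_visits <- stopifnot_count(n_visits, "n_visits", min = 2L)
  stopifnot_prob(p_reward, "p_reward")
  set.seed(seed)
  rd <- config$reward_zone_depth
  rs <- config$reset_zone_depth
  L <- config$length
  deep <- rd / 3                       # depth of the reward dip
  short_exc <- rd + rs + (L / 2 - rd - rs) / 2  # stays short of far reset
  zone_x <- function(zone, d) if (zone == 1L) d else L - d

  wp <- c(L / 2)                      # start at the centre
  visit_zone <- integer(n_visits)
  visit_move <- character(n_visits)   # how the visit ends
  zone <- sample(1:2, 1)
  for (k in seq_len(n_visits)) {
    visit_zone[k] <- zone
    # enter reset band midpoint, then the reward dip
    wp <- c(wp, zone_x(zone, rd + rs / 2), zone_x(zone, deep))
    move <- sample(c("return", "switch", "far_and_back"), 1,
                   prob = c(0.45, 0.35, 0.20))
    if (k == n_visits) move <- "end"
    visit_move[k] <- move
    if (move == "return") {
      wp <- c(wp, zone_x(zone, short_exc))           # short excursion
    } else if (move == "switch") {
      zone <- 3L - zone                               # next visit: far zone
    } else if (move == "far_and_back") {
      wp <- c(wp, zone_x(3L - zone, rd + rs / 2),     # touch far reset band
              zone_x(3L - zone, deep),                # and its reward zone
              zone_x(zone, L / 2))
      zone <- 3L - zone                               # counts as a far visit
    } else {
      wp <- c(wp, L / 2)                              # end at the centre
    }
  }
  # "far_and_back" dips into the far reward zone, so it is itself a visit of
  # the far zone; expand the visit list accordingly.
  zones <- integer(0)
  moves <- character(0)
  for (k in seq_len(n_visits)) {
    zones <- c(zones, visit_zone[k])
    moves <- c(moves, visit_move[k])
    if (visit_move[k] == "far_and_back") {
      zones <- c(zones, 3L - visit_zone[k])
      moves <- c(moves, "mid")  # the far dip then heads back to the centre
    }
  }
  rewarded <- as.integer(runif(length(zones)) < p_reward)

  traj <- scripted_trajectory(wp, config, speed = speed)
  # stim events at the deepest point of each rewarded visit: locate the k-th
  # entry time into each zone's reward dip from the waypoint schedule
  seg_t <- c(0, cumsum(abs(diff(wp)) / speed))
  dip_times <- seg_t[which(wp[-1] %in% c(deep, L - deep)) + 1]
  dip_zone <- ifelse(wp[wp %in% c(deep, L - deep)] == deep, 1L, 2L)
  stopifnot(length(dip_times) == length(zones))
  keep <- rewarded == 1L
  stim_log <- data.frame(time = dip_times[keep], zone = zones[keep])

  # ground truth trials: one per consecutive pair of same-zone visits;
  # returned iff no intermediate other-zone visit (a "return" move).
  truth <- NULL
  for (z in 1:2) {
    idx <- which(zones == z)
    if (length(idx) >= 2) {
      for (j in seq_len(length(idx) - 1)) {
        i0 <- idx[j]; i1 <- idx[j + 1]
        returned <- as.integer(i1 == i0 + 1L)  # no far-zone visit between
        truth <- rbind(truth, data.frame(
          zone = z, t_order = dip_times[i0],
          rewarded = rewarded[i0], returned = returned))
      }
    }
  }
  if (!is.null(truth)) {
    truth <- truth[order(truth$t_order), c("zone", "rewarded", "returned")]
    rownames(truth) <- NULL
  } else {
    truth <- data.frame(zone = integer(0), rewarded = integer(0),
                        returned = integer(0))
  }
  list(session = session_record(traj, stim_log, config, seed), truth = truth)
}

#' Write / read session and sequence tables
#'
#' CSV round-trips for the package's external formats: trajectories
#' (`time_s`, `x_mm`, `y_mm`), stimulation logs (`time_s`, `zone`) and choice
#' sequences (`trial`, `zone`, `reward`, `choice`).
#'
#' @param session a `session_record`.
#' @param path_traj,path_stim output CSV paths.
#' @return `write_session_csv` invisibly returns the paths written.
#' @export
write_session_csv <- function(session, path_traj, path_stim) {
  traj <- data.frame(time_s = session$trajectory$time,
                     x_mm = session$trajectory$x,
                     y_mm = session$trajectory$y)
  write.csv(traj, path_traj, row.names = FALSE)
  stim <- data.frame(time_s = session$stim_log$time,
                     zone = session$stim_log$zone)
  write.csv(stim, path_stim, row.names = FALSE)
  invisible(c(path_traj, path_stim))
}

#' @rdname write_session_csv
#' @param config an [arena_config] attached to the session on read.
#' @export
read_session_csv <- function(path_traj, path_stim, config) {
  traj <- read.csv(path_traj)
  stim <- read.csv(path_stim)
  session_record(
    data.frame(time = traj$time_s, x = traj$x_mm, y = traj$y_mm),
    data.frame(time = stim$time_s, zone = stim$zone),
    config, seed = NA_integer_)
}

#' @rdname write_session_csv
#' @param seq a [choice_sequence].
#' @param path output/input CSV path.
#' @export
write_choice_sequence_csv <- function(seq, path) {
  df <- data.frame(trial = seq_along(seq$rewards), zone = seq$zone,
                   reward = seq$rewards, choice = seq$choices)
  if (!is.null(seq$times)) df$time_s <- seq$times
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_choice_sequence_csv <- function(path) {
  df <- read.csv(path)
  choice_sequence(df$reward, df$choice, zone = df$zone[1],
                  times = if ("time_s" %in% names(df)) df$time_s else NULL)
}
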