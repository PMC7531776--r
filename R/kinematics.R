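# Kinematic observables: preprocessing, stops, turns, occupancy, preference
# index and angular-distribution entropy.

# ---- zero-phase Butterworth low-pass -----------------------------------

# Digital Butterworth low-pass design via the bilinear transform.
# Returns list(b, a) with a[1] == 1 and unit DC gain.
butter_lowpass <- function(order, cutoff, fs) {
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop("cutoff must lie in (0, fs/2)", call. = FALSE)
  }
  warped <- 2 * fs * tan(pi * cutoff / fs)
  k <- seq_len(order)
  poles_a <- warped * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  poles_d <- (2 * fs + poles_a) / (2 * fs - poles_a)
  # polynomial with the given roots (monic, ascending powers of z^-1)
  a <- 1
  for (p in poles_d) a <- c(a, 0) - c(0, a * p)
  a <- Re(a)
  b <- choose(order, 0:order)            # zeros at z = -1
  b <- b * sum(a) / sum(b)               # unit gain at DC
  list(b = b, a = a)
}

# Steady-state filter state for a unit-step input (scipy's lfilter_zi),
# direct-form II transposed.
iir_steady_state <- function(b, a) {
  m <- max(length(a), length(b)) - 1L
  bb <- c(b, rep(0, m + 1L - length(b)))
  aa <- c(a, rep(0, m + 1L - length(a)))
  ss <- sum(bb) / sum(aa)
  z <- numeric(m)
  if (m > 0) {
    z[m] <- bb[m + 1L] - aa[m + 1L] * ss
    if (m > 1) {
      for (j in (m - 1L):1L) {
        z[j] <- bb[j + 1L] - aa[j + 1L] * ss + z[j + 1L]
      }
    }
  }
  z
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering with odd-reflection
#' edge padding and steady-state initial conditions, so a constant signal
#' passes through unchanged and the effective magnitude response is the
#' squared Butterworth response `1 / (1 + (f/fc)^(2 * order))`.
#'
#' @param x numeric signal sampled at `fs` Hz.
#' @param cutoff cutoff frequency (Hz).
#' @param fs sampling rate (Hz).
#' @param order filter order (default 2).
#' @return filtered signal, same length as `x`.
#' @export
butter_filtfilt <- function(x, cutoff, fs, order = 2) {
  n <- length(x)
  if (n < 2) return(x)
  ba <- butter_lowpass(order, cutoff, fs)
  zi <- iir_steady_state(ba$b, ba$a)
  padlen <- min(3L * (max(length(ba$a), length(ba$b)) - 1L) * 3L, n - 1L)
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  y <- cpp_iir_filter(ba$b, ba$a, ext, zi * ext[1])
  y <- rev(y)
  y <- cpp_iir_filter(ba$b, ba$a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

# ---- preprocessing ------------------------------------------------------

#' Preprocess a raw trajectory
#'
#' Cleans and filters a raw tracked trajectory: missing samples (NA) are
#' linearly interpolated, implausible jumps (inter-sample displacement above
#' `jump_threshold` mm) are removed and re-interpolated, and both coordinates
#' are low-pass filtered with a zero-phase Butterworth filter.  Speed is then
#' derived by central differences.
#'
#' @param raw a data frame with `time`, `x`, `y` (a `session_record`
#'   trajectory) or a `session_record`.
#' @param cutoff Butterworth cutoff (Hz, default 5; in the real assay this is
#'   set from camera jitter).
#' @param order filter order (default 2).
#' @param jump_threshold displacement (mm) above which a sample is treated as
#'   a tracking jump (default 5).
#' @param config optional [arena_config]; positions are clamped to the arena
#'   after filtering when provided.
#' @return a data frame `time`, `x`, `y`, `vx`, `vy`, `speed` of class
#'   `fly_trajectory`, with the stimulation log preserved in
#'   `attr(, "stim_log")` when `raw` is a `session_record`.
#' @export
preprocess_trajectory <- function(raw, cutoff = 5, order = 2,
                                  jump_threshold = 5, config = NULL) {
  stim_log <- NULL
  if (inherits(raw, "session_record")) {
    stim_log <- raw$stim_log
    config <- config %||% raw$config
    raw <- raw$trajectory
  }
  stopifnot(all(c("time", "x", "y") %in% names(raw)))
  if (nrow(raw) < 2) stop("need at least 2 samples", call. = FALSE)
  tt <- raw$time
  if (is.unsorted(tt, strictly = TRUE)) {
    ord <- order(tt)
    raw <- raw[ord, ]
    tt <- raw$time
    if (anyDuplicated(tt)) stop("duplicate timestamps", call. = FALSE)
  }
  x <- raw$x
  y <- raw$y
  if (all(is.na(x))) stop("all samples missing", call. = FALSE)
  # tracking jumps: displacement over one sample interval above threshold
  ok <- !is.na(x) & !is.na(y)
  dx <- c(0, abs(diff(ifelse(ok, x, NA))))
  dy <- c(0, abs(diff(ifelse(ok, y, NA))))
  jump <- !is.na(dx) & sqrt(dx^2 + dy^2) > jump_threshold
  x[jump] <- NA
  y[jump] <- NA
  x <- approx(tt[!is.na(x)], x[!is.na(x)], xout = tt, rule = 2)$y
  y_ok <- !is.na(y)
  y <- if (sum(y_ok) >= 2) approx(tt[y_ok], y[y_ok], xout = tt, rule = 2)$y
       else rep(ifelse(any(y_ok), y[y_ok][1], 0), length(tt))
  fs <- 1 / median(diff(tt))
  x <- butter_filtfilt(x, cutoff, fs, order)
  y <- butter_filtfilt(y, cutoff, fs, order)
  if (!is.null(config)) {
    x <- clamp(x, 0, config$length)
    y <- clamp(y, 0, config$width)
  }
  vx <- central_gradient(x, tt)
  vy <- central_gradient(y, tt)
  out <- data.frame(time = tt, x = x, y = y, vx = vx, vy = vy,
                    speed = sqrt(vx^2 + vy^2))
  attr(out, "stim_log") <- stim_log
  attr(out, "config") <- config
  class(out) <- c("fly_trajectory", "data.frame")
  out
}

central_gradient <- function(x, t) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  g <- numeric(n)
  g[1] <- (x[2] - x[1]) / (t[2] - t[1])
  g[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  g
}

# ---- observables --------------------------------------------------------

#' Detect stops
#'
#' Maximal intervals during which the planar speed stays at or below the
#' threshold (default 0.01 mm/s, the tracking resolution: less than one pixel
#' of movement between two timestamps).
#'
#' @param traj a preprocessed trajectory (from [preprocess_trajectory()]).
#' @param threshold speed threshold (mm/s).
#' @return a data frame with one row per stop: `t_start`, `t_end`,
#'   `duration`, `mean_x`.
#' @export
detect_stops <- function(traj, threshold = 0.01) {
  stopped <- abs(traj$speed) <= threshold
  r <- rle(stopped)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    t_start = traj$time[starts[keep]],
    t_end = traj$time[ends[keep]],
    duration = traj$time[ends[keep]] - traj$time[starts[keep]],
    mean_x = vapply(which(keep), function(i) {
      mean(traj$x[starts[i]:ends[i]])
    }, numeric(1))
  )
}

#' Detect turns
#'
#' One event per sign change of the x-velocity (the track is effectively
#' one-dimensional).  Velocity signs are taken from inter-sample
#' displacements; zero-displacement runs between opposite-sign segments
#' collapse to exactly one turn, and a constant trace yields no turns.
#'
#' @param traj a preprocessed trajectory.
#' @return a data frame with `time` and `x` of each turn.
#' @export
detect_turns <- function(traj) {
  s <- sign(diff(traj$x))
  idx <- which(s != 0)
  if (length(idx) < 2) {
    return(data.frame(time = numeric(0), x = numeric(0)))
  }
  flips <- idx[-1][s[idx[-1]] != s[idx[-length(idx)]]]
  data.frame(time = traj$time[flips], x = traj$x[flips])
}

#' Time-weighted occupancy distribution
#'
#' Histogram of x positions weighted by the time spent at each sample,
#' normalised to sum to 1.
#'
#' @param traj a preprocessed trajectory.
#' @param n_bins number of bins over the arena length (default 50).
#' @param arena_length track length (mm); taken from the attached config when
#'   present.
#' @return a data frame `mid`, `prob` with `attr(, "breaks")`; `prob` sums
#'   to 1.
#' @export
occupancy_distribution <- function(traj, n_bins = 50, arena_length = NULL) {
  n_bins <- stopifnot_count(n_bins, "n_bins")
  cfg <- attr(traj, "config")
  arena_length <- arena_length %||% (if (!is.null(cfg)) cfg$length else
                                       max(traj$x))
  breaks <- seq(0, arena_length, length.out = n_bins + 1)
  dt <- diff(traj$time)
  w <- c(dt, median(dt))
  bin <- findInterval(traj$x, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  prob <- vapply(seq_len(n_bins), function(b) sum(w[bin == b]), numeric(1))
  prob <- prob / sum(prob)
  out <- data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    prob = prob)
  attr(out, "breaks") <- breaks
  out
}

#' Preference index from zone dwell times
#'
#' `PI = (Z1 - Z2) / (Z1 + Z2)` of the dwell times inside the two end zones
#' (measured within the reset-zone boundaries, i.e. the outer
#' reward+reset band): +1 is exclusive zone-1 preference, -1 exclusive
#' zone-2 preference, 0 indifference.
#'
#' @param occ_zone1,occ_zone2 dwell times (s, >= 0).
#' @return the preference index in `[-1, 1]`.
#' @export
preference_index <- function(occ_zone1, occ_zone2) {
  if (occ_zone1 < 0 || occ_zone2 < 0) {
    stop("occupancies must be non-negative", call. = FALSE)
  }
  if (occ_zone1 + occ_zone2 <= 0) {
    stop("undefined preference index: fly never visited either zone",
         call. = FALSE)
  }
  (occ_zone1 - occ_zone2) / (occ_zone1 + occ_zone2)
}

#' Dwell time within each end zone
#'
#' Time spent within the reset-zone boundaries of each arena end (the
#' reward+reset band).
#'
#' @param traj a preprocessed trajectory.
#' @param config an [arena_config] (defaults to the attached one).
#' @return named numeric `c(zone1 = , zone2 = )` in seconds.
#' @export
zone_occupancy <- function(traj, config = NULL) {
  config <- config %||% attr(traj, "config")
  stopifnot(inherits(config, "arena_config"))
  band <- config$reward_zone_depth + config$reset_zone_depth
  dt <- diff(traj$time)
  w <- c(dt, median(dt))
  c(zone1 = sum(w[traj$x < band]),
    zone2 = sum(w[traj$x > config$length - band]))
}

#' Angular-distribution entropy of a path
#'
#' Per-step headings are the arctangent of consecutive displacements; when
#' the trajectory's x orientation reverses, angles are shifted by pi so all
#' headings share one reference vector.  The entropy
#' `S = -sum(q_k log q_k)` of the normalised heading histogram is 0 for a
#' perfectly straight path and `log(n_angle_bins)` for uniform headings;
#' curvier paths have broader distributions and larger S.
#'
#' Note that the orientation alignment folds all headings into the
#' half-circle around the travel direction, so with `align_orientation = TRUE`
#' the attainable maximum is `log(n_angle_bins / 2)`; set it to `FALSE` for
#' raw headings (whose uniform distribution attains `log(n_angle_bins)`).
#'
#' @param x,y coordinate vectors (or pass a trajectory data frame as `x`).
#' @param n_angle_bins number of histogram bins over `[-pi, pi)` (default 36).
#' @param units `"nats"` (natural log, default) or `"bits"`.
#' @param align_orientation shift angles by pi when the travel orientation
#'   reverses, so in- and out-bound path segments share one reference vector
#'   (default TRUE).
#' @return entropy S (>= 0).
#' @export
angular_entropy <- function(x, y = NULL, n_angle_bins = 36,
                            units = c("nats", "bits"),
                            align_orientation = TRUE) {
  units <- match.arg(units)
  if (is.data.frame(x)) {
    y <- x$y
    x <- x$x
  }
  n_angle_bins <- stopifnot_count(n_angle_bins, "n_angle_bins")
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  dx <- diff(x)
  dy <- diff(y)
  nz <- dx != 0 | dy != 0
  dx <- dx[nz]
  dy <- dy[nz]
  if (length(dx) < 1) {
    stop("undefined entropy: no nonzero displacement", call. = FALSE)
  }
  ang <- atan2(dy, dx)
  if (align_orientation) {
    # orientation of travel along the track; carry the last nonzero sign so
    # zero-x steps do not flip the reference
    sx <- sign(dx)
    for (i in seq_along(sx)) {
      if (sx[i] == 0) sx[i] <- if (i > 1) sx[i - 1] else 1
    }
    flip <- sx < 0
    ang[flip] <- ang[flip] + pi
    ang <- ((ang + pi) %% (2 * pi)) - pi   # wrap to [-pi, pi)
  }
  breaks <- seq(-pi, pi, length.out = n_angle_bins + 1)
  bin <- findInterval(ang, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  q <- tabulate(bin, nbins = n_angle_bins)
  q <- q / sum(q)
  q <- q[q > 0]
  s <- -sum(q * log(q))
  if (units == "bits") s <- s / log(2)
  s
}

#' Per-bin stop and turn rate histograms
#'
#' Normalised spatial distributions of stop and turn events along the track.
#'
#' @param traj a preprocessed trajectory.
#' @param n_bins number of x bins.
#' @param arena_length track length (mm).
#' @param threshold stop speed threshold (mm/s).
#' @return a data frame `mid`, `stop_rate`, `turn_rate` (each sums to 1 when
#'   events exist).
#' @export
event_histograms <- function(traj, n_bins = 50, arena_length = NULL,
                             threshold = 0.01) {
  cfg <- attr(traj, "config")
  arena_length <- arena_length %||% (if (!is.null(cfg)) cfg$length else
                                       max(traj$x))
  breaks <- seq(0, arena_length, length.out = n_bins + 1)
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  hist_of <- function(v) {
    if (length(v) == 0) return(rep(0, n_bins))
    b <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    h <- tabulate(b, nbins = n_bins)
    h / sum(h)
  }
  data.frame(mid = mid,
             stop_rate = hist_of(detect_stops(traj, threshold)$mean_x),
             turn_rate = hist_of(detect_turns(traj)$x))
}

#' Kinematics summary of a session
#'
#' Bundles the kinematic observables of one preprocessed session: occupancy
#' distribution, preference index, stop/turn/speed histograms and (when a
#' trial table is supplied) angular-distribution entropy per path class
#' (in-/out-walking x rewarded/unrewarded).
#'
#' @param traj a preprocessed trajectory.
#' @param config an [arena_config].
#' @param trials optional trial table from [segment_trials()].
#' @param n_bins spatial bins.
#' @param n_angle_bins heading bins.
#' @param units entropy units.
#' @return a list of class `kinematics_summary`.
#' @export
kinematics_summary <- function(traj, config = NULL, trials = NULL,
                               n_bins = 50, n_angle_bins = 36,
                               units = "nats") {
  config <- config %||% attr(traj, "config")
  occ <- occupancy_distribution(traj, n_bins,
                                if (!is.null(config)) config$length else NULL)
  zo <- if (!is.null(config)) zone_occupancy(traj, config) else
    c(zone1 = NA_real_, zone2 = NA_real_)
  pi_val <- if (!is.null(config) && sum(zo) > 0)
    preference_index(zo[["zone1"]], zo[["zone2"]]) else NA_real_
  ev <- event_histograms(traj, n_bins,
                         if (!is.null(config)) config$length else NULL)
  sp <- traj$speed
  sp_breaks <- seq(0, max(sp) + 1e-9, length.out = n_bins + 1)
  sp_hist <- tabulate(findInterval(sp, sp_breaks, rightmost.closed = TRUE,
                                   all.inside = TRUE), nbins = n_bins)
  ent <- if (!is.null(trials) && nrow(trials) > 0 && !is.null(config)) {
    path_class_entropy(traj, trials, config, n_angle_bins, units)
  } else NULL
  structure(list(occupancy = occ, zone_occupancy = zo, pi = pi_val,
                 events = ev,
                 speed_histogram = data.frame(
                   mid = (sp_breaks[-1] + sp_breaks[-n_bins - 1]) / 2,
                   count = sp_hist),
                 angular_entropy = ent),
            class = "kinematics_summary")
}

#' @export
print.kinematics_summary <- function(x, ...) {
  cat(sprintf("<kinematics_summary> PI=%.3f dwell z1=%.1fs z2=%.1fs\n",
              x$pi, x$zone_occupancy[["zone1"]], x$zone_occupancy[["zone2"]]))
  invisible(x)
}

# Angular entropy per path class.  Out-walking: from the reward-zone entry to
# the trial's maximal excursion; in-walking: from the excursion peak back
# until the trial ends at the reset zone.  Classes split by the trial's
# rewarded flag; per-trial entropies are averaged within class.
path_class_entropy <- function(traj, trials, config, n_angle_bins = 36,
                               units = "nats") {
  res <- expand.grid(direction = c("out", "in"), rewarded = c(0L, 1L))
  res$entropy <- NA_real_
  res$n_paths <- 0L
  vals <- list()
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    idx <- which(traj$time >= tr$t_enter_reward & traj$time <= tr$t_end)
    if (length(idx) < 4) next
    seg_x <- traj$x[idx]
    peak <- if (tr$zone == 1L) which.max(seg_x) else which.min(seg_x)
    if (peak < 3 || peak > length(idx) - 2) next
    out_i <- idx[1:peak]
    in_i <- idx[peak:length(idx)]
    for (d in c("out", "in")) {
      ii <- if (d == "out") out_i else in_i
      s <- tryCatch(angular_entropy(traj$x[ii], traj$y[ii], n_angle_bins,
                                    units),
                    error = function(e) NA_real_)
      key <- paste(d, tr$rewarded)
      vals[[key]] <- c(vals[[key]], s)
    }
  }
  for (j in seq_len(nrow(res))) {
    key <- paste(res$direction[j], res$rewarded[j])
    v <- vals[[key]]
    if (!is.null(v)) {
      res$entropy[j] <- mean(v, na.rm = TRUE)
      res$n_paths[j] <- sum(!is.na(v))
    }
  }
  res
}
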