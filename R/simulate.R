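#' Configuration for a synthetic controlled exposure experiment
#'
#' Bundles every parameter of the synthetic CEE generator.  Defaults mirror
#' the field design the analysis targets: 30-min experiments split into
#' 10-min pre-exposure / exposure / post-exposure phases, 24 sonar pings of
#' 1.6 s every 25 s, baseline vocal-state switching of about one mean change
#' per minute and one variance change per 3.5 min, and a short multiplicative
#' burst of whistling after each ping that abates within about 10 s.
#'
#' @param duration_s total experiment duration in seconds.
#' @param phase_bounds strictly increasing phase boundaries in seconds
#'   (pre-exposure / exposure / post-exposure); the last bound must equal
#'   `duration_s`.
#' @param n_states number of vocal states (>= 1).
#' @param state_intensities mean whistle-detection rate (whistles/s) in each
#'   state; length `n_states`, all >= 0.
#' @param mean_switch_rate,variance_switch_rate vocal state switching rates,
#'   in switches per minute, for the mean-type and variance-type processes.
#' @param response_fold multiplicative factor (>= 0) applied to whistle
#'   intensity in the response window after each ping.
#' @param response_duration_s length (s) of the flat response window, which
#'   starts when the ping transmission ends.
#' @param response_decay_s nominal decay span (s) of the excess intensity
#'   after the flat window; the excess decays exponentially with time
#'   constant `response_decay_s / 3`.
#' @param suppress_during_ping if `TRUE`, whistle intensity is zero during
#'   the 1.6-s transmission itself.
#' @param ping_start_s,n_pings,ping_interval_s,ping_dur_s exposure schedule:
#'   first onset (defaults to the start of the exposure phase), number of
#'   pings, onset spacing and transmission duration, all in seconds.
#' @param n_buoys number of drifting recording buoys.
#' @param group_speed_mps,buoy_speed_mps nominal speeds (m/s) of the focal
#'   group and of the buoys' own drift.
#' @param group_size estimated number of individuals in the focal group.
#' @param subspecies subspecies label, `"Dd"` (short-beaked) or `"Db"`
#'   (long-beaked common dolphin).
#' @param cee_type `"mfas"` for an active-sonar experiment, `"control"` for a
#'   silent control with pseudo-pings at the same time stamps.
#' @param track_scenario `"near"` keeps all buoys within detection range;
#'   `"crossing"` launches one buoy on a trajectory whose distance to the
#'   group crosses the 1.6-km exclusion threshold.
#' @param nb_dispersion optional negative-binomial size parameter; when
#'   `NULL` (default) per-second counts are Poisson given the state, else
#'   overdispersed with variance `mu + mu^2 / nb_dispersion`.
#' @param cee_id identifier used in emitted tables.
#' @param seed optional integer seed consumed by [simulate_cee()].
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cee()]
#' @export
sim_config <- function(duration_s = 1800,
                       phase_bounds = c(0, 600, 1200, 1800),
                       n_states = 2,
                       state_intensities = c(0.5, 3),
                       mean_switch_rate = 1,
                       variance_switch_rate = 1 / 3.5,
                       response_fold = 4,
                       response_duration_s = 5,
                       response_decay_s = 10,
                       suppress_during_ping = TRUE,
                       ping_start_s = phase_bounds[2],
                       n_pings = 24,
                       ping_interval_s = 25,
                       ping_dur_s = 1.6,
                       n_buoys = 3,
                       group_speed_mps = 1.5,
                       buoy_speed_mps = 0.25,
                       group_size = 150,
                       subspecies = c("Db", "Dd"),
                       cee_type = c("mfas", "control"),
                       track_scenario = c("near", "crossing"),
                       nb_dispersion = NULL,
                       cee_id = "sim_01",
                       seed = NULL) {
  cee_type <- match.arg(cee_type)
  subspecies <- match.arg(subspecies)
  track_scenario <- match.arg(track_scenario)
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("`duration_s` must be a single positive number", call. = FALSE)
  if (any(diff(phase_bounds) <= 0))
    stop("`phase_bounds` must be strictly increasing", call. = FALSE)
  if (phase_bounds[length(phase_bounds)] != duration_s)
    stop("last phase bound must equal `duration_s`", call. = FALSE)
  if (n_states < 1) stop("`n_states` must be >= 1", call. = FALSE)
  if (length(state_intensities) != n_states)
    stop("`state_intensities` must have length `n_states`", call. = FALSE)
  if (any(state_intensities < 0))
    stop("state intensities must be >= 0", call. = FALSE)
  if (response_fold < 0) stop("`response_fold` must be >= 0", call. = FALSE)
  if (mean_switch_rate < 0 || variance_switch_rate < 0)
    stop("switch rates must be >= 0", call. = FALSE)
  structure(
    list(
      duration_s = duration_s, phase_bounds = phase_bounds,
      n_states = n_states, state_intensities = state_intensities,
      mean_switch_rate = mean_switch_rate,
      variance_switch_rate = variance_switch_rate,
      response_fold = response_fold,
      response_duration_s = response_duration_s,
      response_decay_s = response_decay_s,
      suppress_during_ping = suppress_during_ping,
      ping_start_s = ping_start_s, n_pings = n_pings,
      ping_interval_s = ping_interval_s, ping_dur_s = ping_dur_s,
      n_buoys = n_buoys, group_speed_mps = group_speed_mps,
      buoy_speed_mps = buoy_speed_mps, group_size = group_size,
      subspecies = subspecies, cee_type = cee_type,
      track_scenario = track_scenario, nb_dispersion = nb_dispersion,
      cee_id = cee_id, seed = seed
    ),
    class = "sim_config"
  )
}

#' Simulate a vocal-state sequence
#'
#' Continuous-time Markov switching between vocal states (exponential holding
#' times at the configured rate, jumps to a uniformly chosen different
#' state), discretized to 1-s resolution.  Under the defaults this emulates
#' baseline behavior in which the mean whistle rate changes about once per
#' minute and its variance about once per 3.5 minutes.
#'
#' @param config a [sim_config()].
#' @param which `"mean"` uses `mean_switch_rate`, `"variance"` uses
#'   `variance_switch_rate`.
#' @return A list of class `vocal_states` with elements `states` (integer
#'   state label for each second, length `duration_s`), `switch_times`
#'   (continuous event times in seconds), `rate` (switches/min) and `which`.
#' @export
simulate_vocal_states <- function(config, which = c("mean", "variance")) {
  which <- match.arg(which)
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(config$duration_s)
  if (n <= 0) stop("duration must be positive", call. = FALSE)
  rate_min <- if (which == "mean") config$mean_switch_rate else
    config$variance_switch_rate
  if (rate_min == 0) {
    out <- list(states = rep(1L, n), switch_times = numeric(0),
                rate = 0, which = which)
    class(out) <- "vocal_states"
    return(out)
  }
  if (config$n_states < 2)
    stop("switching requires `n_states` >= 2", call. = FALSE)
  rate_s <- rate_min / 60
  # draw event times until the horizon is passed
  times <- numeric(0)
  t <- 0
  repeat {
    t <- t + stats::rexp(1, rate_s)
    if (t >= n) break
    times <- c(times, t)
  }
  state0 <- sample.int(config$n_states, 1L)
  states_at_events <- integer(length(times))
  cur <- state0
  for (i in seq_along(times)) {
    cur <- if (config$n_states == 2L) 3L - cur else
      sample(setdiff(seq_len(config$n_states), cur), 1L)
    states_at_events[i] <- cur
  }
  sec_states <- c(state0, states_at_events)[findInterval(seq_len(n) - 1L,
                                                         times) + 1L]
  out <- list(states = sec_states, switch_times = times,
              rate = rate_min, which = which)
  class(out) <- "vocal_states"
  out
}

#' Simulate a whistle train conditional on a state sequence
#'
#' Per-second whistle counts are drawn conditionally independently given the
#' state: Poisson with mean equal to the state intensity (or negative
#' binomial when `nb_dispersion` is set).  Each counted detection receives a
#' uniform start time within its second and a lognormal fragment duration,
#' emulating whistle-detector exports.
#'
#' @param states a `vocal_states` object or an integer vector of per-second
#'   state labels.
#' @param config a [sim_config()].
#' @param buoy_id buoy identifier written into the detection table.
#' @return A list of class `whistle_train`: `counts` (per-second counts),
#'   `lambda` (per-second intensity), `detections` (data frame with columns
#'   `cee_id`, `buoy_id`, `start_s`, `duration_s`), and `response_windows`
#'   (empty until [inject_ping_response()] is applied).
#' @export
simulate_whistle_train <- function(states, config, buoy_id = "B1") {
  if (inherits(states, "vocal_states")) states <- states$states
  stopifnot(inherits(config, "sim_config"))
  if (any(states < 1L | states > config$n_states))
    stop("state labels must index `state_intensities`", call. = FALSE)
  lambda <- config$state_intensities[states]
  counts <- draw_counts(lambda, config$nb_dispersion)
  det <- detections_from_counts(counts, config$cee_id, buoy_id)
  out <- list(counts = counts, lambda = lambda, detections = det,
              response_windows = empty_response_windows(),
              cee_id = config$cee_id, buoy_id = buoy_id)
  class(out) <- "whistle_train"
  out
}

draw_counts <- function(lambda, nb_dispersion = NULL) {
  n <- length(lambda)
  if (is.null(nb_dispersion)) stats::rpois(n, lambda)
  else stats::rnbinom(n, mu = lambda, size = nb_dispersion)
}

detections_from_counts <- function(counts, cee_id, buoy_id,
                                   seconds = seq_along(counts) - 1L) {
  tot <- sum(counts)
  if (tot == 0L) {
    return(data.frame(cee_id = character(0), buoy_id = character(0),
                      start_s = numeric(0), duration_s = numeric(0)))
  }
  sec <- rep(seconds, counts)
  start <- sec + stats::runif(tot)
  dur <- stats::rlnorm(tot, meanlog = log(0.3), sdlog = 0.4)
  out <- data.frame(cee_id = cee_id, buoy_id = buoy_id,
                    start_s = start, duration_s = dur)
  out[order(out$start_s), , drop = FALSE]
}

empty_response_windows <- function() {
  data.frame(ping_index = integer(0), onset_s = numeric(0),
             window_start_s = numeric(0), window_end_s = numeric(0))
}

#' Build a regular ping schedule
#'
#' Pings start at `start_s` and repeat every `interval_s`; ping `k` has onset
#' `start_s + (k - 1) * interval_s`.  The schedule must fit inside the
#' exposure phase.
#'
#' @param start_s onset of the first ping (s).
#' @param n_pings number of pings (>= 1).
#' @param interval_s onset-to-onset spacing (s); must exceed `ping_dur_s`.
#' @param ping_dur_s transmission duration (s).
#' @param phase_end_s end of the exposure phase (s); the last ping must end
#'   at or before it.
#' @param cee_id identifier.
#' @param is_pseudo `TRUE` for control experiments, where the time stamps
#'   mark when pings would have occurred but nothing was transmitted.
#' @return A data frame of class `ping_schedule` with columns `ping_index`,
#'   `onset_s`, `duration_s`, and attributes `cee_id` and `is_pseudo`.
#' @export
make_ping_schedule <- function(start_s, n_pings = 24, interval_s = 25,
                               ping_dur_s = 1.6,
                               phase_end_s = start_s + 600,
                               cee_id = "sim_01", is_pseudo = FALSE) {
  if (n_pings < 1) stop("`n_pings` must be >= 1", call. = FALSE)
  if (interval_s <= ping_dur_s)
    stop("`interval_s` must exceed `ping_dur_s`", call. = FALSE)
  onsets <- start_s + (seq_len(n_pings) - 1) * interval_s
  if (onsets[n_pings] + ping_dur_s > phase_end_s)
    stop("ping schedule overruns the exposure phase", call. = FALSE)
  out <- data.frame(ping_index = seq_len(n_pings), onset_s = onsets,
                    duration_s = ping_dur_s)
  attr(out, "cee_id") <- cee_id
  attr(out, "is_pseudo") <- is_pseudo
  class(out) <- c("ping_schedule", "data.frame")
  out
}

# Average of the ping response multiplier over [a, b), for one ping with
# transmission [onset, end), flat fold window [end, end + D), and excess
# decaying as (fold - 1) * exp(-(t - end - D) / tau) afterwards.
# `s` is the multiplier during transmission (0 when suppressed, 1 otherwise).
profile_value <- function(t, onset, end, D, fold, tau, s) {
  ifelse(t < onset, 1,
         ifelse(t < end, s,
                ifelse(t < end + D, fold,
                       1 + (fold - 1) * exp(-(t - end - D) / tau))))
}

profile_integral <- function(a, b, onset, end, D, fold, tau, s) {
  seg <- function(lo, hi) max(0, min(b, hi) - max(a, lo))
  total <- seg(-Inf, onset) * 1 + seg(onset, end) * s +
    seg(end, end + D) * fold
  lo <- max(a, end + D)
  if (b > lo) {
    len <- b - lo
    total <- total + len
    if (fold != 1 && tau > 0) {
      e0 <- exp(-(lo - end - D) / tau)
      e1 <- exp(-(b - end - D) / tau)
      total <- total + (fold - 1) * tau * (e0 - e1)
    }
  }
  total
}

#' Inject ping-triggered responses into a whistle train
#'
#' After each ping the whistle intensity is multiplied by `response_fold` in
#' a flat window of `response_duration_s` starting when the transmission
#' ends; the excess then decays exponentially (time constant
#' `response_decay_s / 3`).  During the transmission itself the intensity is
#' multiplied by zero when `suppress_during_ping` is set.  Affected seconds
#' are re-drawn from the count distribution at the modified intensity (the
#' per-second multiplier is the exact time average of the continuous
#' profile); seconds outside all windows, and the whole train when
#' `response_fold = 1` with suppression off, are left untouched.  Each
#' ping's profile is truncated at the next ping's onset.
#'
#' @param train a `whistle_train`.
#' @param schedule a `ping_schedule`.
#' @param config the [sim_config()] used to build the train.
#' @return The modified `whistle_train`, with `response_windows` describing
#'   the injected flat windows and a `multiplier` element giving the
#'   per-second intensity multiplier actually applied.
#' @export
inject_ping_response <- function(train, schedule, config) {
  stopifnot(inherits(train, "whistle_train"),
            inherits(schedule, "ping_schedule"),
            inherits(config, "sim_config"))
  n <- length(train$counts)
  onsets <- schedule$onset_s
  ends <- onsets + schedule$duration_s
  D <- config$response_duration_s
  fold <- config$response_fold
  tau <- config$response_decay_s / 3
  sup <- isTRUE(config$suppress_during_ping)
  if (any(onsets < 0) || any(ends > n))
    stop("counts do not cover the ping schedule", call. = FALSE)
  nxt <- c(onsets[-1], Inf)
  if (any(ends + D > nxt))
    stop("response windows of consecutive pings overlap", call. = FALSE)

  mult <- rep(1, n)
  if (fold != 1 || sup) {
    for (p in seq_along(onsets)) {
      dom_lo <- onsets[p]
      dom_hi <- min(nxt[p], n)
      k0 <- floor(dom_lo)
      k1 <- ceiling(dom_hi) - 1
      for (k in k0:k1) {
        a <- max(k, dom_lo)
        b <- min(k + 1, dom_hi)
        if (b <= a) next
        mult[k + 1L] <- mult[k + 1L] - (b - a) +
          profile_integral(a, b, dom_lo, ends[p], D, fold, tau,
                           s = if (sup) 0 else 1)
      }
    }
    touched <- which(abs(mult - 1) > 1e-12)
    if (length(touched)) {
      train$counts[touched] <- draw_counts(train$lambda[touched] *
                                             mult[touched],
                                           config$nb_dispersion)
      # detection start times in modified seconds follow the within-second
      # intensity profile (thinning), so e.g. no detection starts during a
      # suppressed transmission
      prof <- function(t) {
        out <- rep(1, length(t))
        p <- findInterval(t, onsets)
        in_dom <- p >= 1L & t < nxt[pmax(p, 1L)]
        if (any(in_dom)) {
          pp <- p[in_dom]
          out[in_dom] <- profile_value(t[in_dom], onsets[pp], ends[pp], D,
                                       fold, tau, s = if (sup) 0 else 1)
        }
        out
      }
      m_max <- max(1, fold, if (sup) 0 else 1)
      starts <- unlist(lapply(touched, function(k) {
        c <- train$counts[k]
        if (c == 0L) return(numeric(0))
        acc <- numeric(0)
        while (length(acc) < c) {
          u <- stats::runif(c, k - 1L, k)
          acc <- c(acc, u[stats::runif(c) * m_max <= prof(u)])
        }
        acc[seq_len(c)]
      }))
      keep_sec <- floor(train$detections$start_s)
      keep <- !(keep_sec %in% (touched - 1L))
      new_det <- if (length(starts)) {
        data.frame(cee_id = train$cee_id, buoy_id = train$buoy_id,
                   start_s = starts,
                   duration_s = stats::rlnorm(length(starts),
                                              meanlog = log(0.3),
                                              sdlog = 0.4))
      } else train$detections[0, , drop = FALSE]
      det <- rbind(train$detections[keep, , drop = FALSE], new_det)
      train$detections <- det[order(det$start_s), , drop = FALSE]
      rownames(train$detections) <- NULL
    }
  }
  train$multiplier <- mult
  train$response_windows <- data.frame(
    ping_index = schedule$ping_index, onset_s = onsets,
    window_start_s = ends, window_end_s = ends + D)
  train
}

#' Simulate GPS tracks for the focal group and drifting buoys
#'
#' Fixes are emitted every 60 s (inclusive endpoints, so a 30-min experiment
#' yields 31 fixes per platform).  Each platform follows a smooth random
#' walk: heading evolves by small Gaussian increments while speed is held at
#' its configured value.  The `"crossing"` scenario launches the last buoy
#' from ~1 km behind a steadily moving group so that their separation crosses
#' the 1.6-km exclusion threshold during the experiment.
#'
#' @param config a [sim_config()].
#' @param origin_lat,origin_lon start coordinates (decimal degrees).
#' @return A named list of track data frames (`group`, `B1`, ...), each with
#'   columns `platform_id`, `t_s`, `lat_deg`, `lon_deg`.
#' @export
simulate_tracks <- function(config, origin_lat = 33.3, origin_lon = -118.45) {
  stopifnot(inherits(config, "sim_config"))
  crossing <- config$track_scenario == "crossing"
  times <- seq(0, config$duration_s, by = 60)
  nt <- length(times)
  R <- 6371000

  walk <- function(lat0, lon0, speed, heading0, wiggle) {
    lat <- numeric(nt); lon <- numeric(nt)
    lat[1] <- lat0; lon[1] <- lon0
    h <- heading0
    for (i in seq_len(nt - 1L)) {
      h <- h + stats::rnorm(1, 0, wiggle)
      step <- speed * 60
      dlat <- step * cos(h) / (pi / 180 * R)
      dlon <- step * sin(h) / (pi / 180 * R * cos(lat[i] * pi / 180))
      lat[i + 1] <- lat[i] + dlat
      lon[i + 1] <- lon[i] + dlon
    }
    list(lat = lat, lon = lon)
  }
  offset_point <- function(lat, lon, dist, bearing) {
    c(lat + dist * cos(bearing) / (pi / 180 * R),
      lon + dist * sin(bearing) / (pi / 180 * R * cos(lat * pi / 180)))
  }

  g_heading <- stats::runif(1, 0, 2 * pi)
  g <- walk(origin_lat, origin_lon, config$group_speed_mps, g_heading,
            wiggle = if (crossing) 0.02 else 0.15)
  tracks <- list(group = data.frame(platform_id = "group", t_s = times,
                                    lat_deg = g$lat, lon_deg = g$lon))
  for (b in seq_len(config$n_buoys)) {
    id <- paste0("B", b)
    if (crossing && b == config$n_buoys) {
      # buoy dropped ~1 km behind the group's path, drifting slowly: the
      # group sails away and the separation crosses 1.6 km
      start <- offset_point(origin_lat, origin_lon, 1000, g_heading + pi)
      bt <- walk(start[1], start[2], min(config$buoy_speed_mps, 0.1),
                 g_heading + pi, wiggle = 0.1)
    } else {
      start <- offset_point(origin_lat, origin_lon,
                            stats::runif(1, 200, 700),
                            stats::runif(1, 0, 2 * pi))
      bt <- walk(start[1], start[2], config$buoy_speed_mps,
                 g_heading + stats::rnorm(1, 0, 0.3), wiggle = 0.2)
    }
    tracks[[id]] <- data.frame(platform_id = id, t_s = times,
                               lat_deg = bt$lat, lon_deg = bt$lon)
  }
  tracks
}

#' Simulate a complete controlled exposure experiment
#'
#' Composes [simulate_vocal_states()], [simulate_whistle_train()],
#' [make_ping_schedule()], [inject_ping_response()] (MFAS experiments only)
#' and [simulate_tracks()] into one bundle with known ground truth.  Control
#' experiments carry a pseudo-ping schedule — identical time stamps, no
#' injected response, no suppression.  Detections are attributed to the buoy
#' closest to the group during their minute, so the geometry and stitching
#' stages of the analysis see realistic inputs.
#'
#' @param config a [sim_config()]; `config$seed` (when non-`NULL`) makes the
#'   bundle bit-reproducible.
#' @return A list of class `simulated_cee`: `detections`, `tracks`,
#'   `schedule`, `selection` (per-minute closest-buoy table used to label
#'   detections), `counts` (true per-second counts), `truth` (state
#'   sequence, switch times, response windows, intensity multiplier), and
#'   `meta` (a one-row data frame with `cee_id`, `cee_type`, `subspecies`,
#'   `group_size`, and `rl_max_db` / `rl_min_db` for MFAS experiments).
#' @export
simulate_cee <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  states <- simulate_vocal_states(config, "mean")
  train <- simulate_whistle_train(states, config)
  schedule <- make_ping_schedule(
    config$ping_start_s, config$n_pings, config$ping_interval_s,
    config$ping_dur_s, phase_end_s = config$phase_bounds[3],
    cee_id = config$cee_id, is_pseudo = config$cee_type == "control")
  if (config$cee_type == "mfas") {
    train <- inject_ping_response(train, schedule, config)
  }
  tracks <- simulate_tracks(config)
  sel <- select_closest_buoy(tracks$group, tracks[-1],
                             duration_s = config$duration_s)
  # attribute each detection to the buoy closest to the group in its minute
  det <- train$detections
  if (nrow(det)) {
    minute <- pmin(floor(det$start_s / 60), nrow(sel) - 1L)
    det$buoy_id <- sel$closest_buoy_id[minute + 1L]
    det <- det[!is.na(det$buoy_id), , drop = FALSE]
  }
  rl <- if (config$cee_type == "mfas") round(stats::runif(1, 142, 159)) else NA_real_
  meta <- data.frame(
    cee_id = config$cee_id, cee_type = config$cee_type,
    subspecies = config$subspecies, group_size = config$group_size,
    rl_max_db = rl,
    rl_min_db = if (is.na(rl)) NA_real_ else rl - round(stats::runif(1, 3, 11)))
  out <- list(detections = det, tracks = tracks, schedule = schedule,
              selection = sel, counts = train$counts,
              truth = list(states = states$states,
                           switch_times = states$switch_times,
                           response_windows = train$response_windows,
                           multiplier = train$multiplier),
              meta = meta, config = config)
  class(out) <- "simulated_cee"
  out
}

#' @export
print.simulated_cee <- function(x, ...) {
  cat(sprintf("<simulated_cee %s: %s, %d s, %d detections, %d pings%s>\n",
              x$meta$cee_id, x$meta$cee_type, x$config$duration_s,
              nrow(x$detections), nrow(x$schedule),
              if (attr(x$schedule, "is_pseudo")) " (pseudo)" else ""))
  invisible(x)
}
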