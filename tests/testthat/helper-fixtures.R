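# Shared fixture builders for the test suite.  Everything is generated in
# code; no data files beyond the packaged CEE summary table.

# A stationary track at a fixed offset (meters north/east) from an origin.
stationary_track <- function(id, north_m = 0, east_m = 0,
                             times = seq(0, 1800, by = 60),
                             lat0 = 33.3, lon0 = -118.45) {
  R <- 6371000
  data.frame(platform_id = id, t_s = times,
             lat_deg = lat0 + north_m / (pi / 180 * R),
             lon_deg = lon0 + east_m / (pi / 180 * R * cos(lat0 * pi / 180)))
}

# Detection table with given start times on one buoy.
det_table <- function(starts, durations = rep(0.3, length(starts)),
                      buoy = "B1", cee = "cee") {
  data.frame(cee_id = rep_len(cee, length(starts)),
             buoy_id = rep_len(buoy, length(starts)),
             start_s = starts, duration_s = durations)
}

# A buoy_selection marking every minute as buoy `id` at distance `d`.
flat_selection <- function(n_min = 30, id = "B1", d = 500,
                           included = rep(TRUE, n_min)) {
  out <- data.frame(minute_index = seq_len(n_min) - 1L,
                    closest_buoy_id = id, distance_m = d,
                    included = included)
  attr(out, "threshold_m") <- 1600
  class(out) <- c("buoy_selection", "data.frame")
  out
}

# Zero-inflated Gaussian sample: exact zero w.p. pi, else N(mu, sd).
rzigauss <- function(n, pi0, mu, sd) {
  z <- runif(n) < pi0
  ifelse(z, 0, rnorm(n, mu, sd))
}

# Grouped AR(1) zero-inflated Gaussian records on a regular ping grid.
rzigauss_ar1 <- function(n_groups, n_per, pi0, mu, sd, phi) {
  do.call(rbind, lapply(seq_len(n_groups), function(g) {
    e <- as.numeric(arima.sim(list(ar = phi), n_per, sd = sd *
                                sqrt(1 - phi^2)))
    y <- mu + e
    y[runif(n_per) < pi0] <- 0
    data.frame(ceeNum = sprintf("g%02d", g), times = seq_len(n_per),
               pingChange = y)
  }))
}
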