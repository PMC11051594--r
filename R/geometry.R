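#' Great-circle distance between coordinate pairs
#'
#' Haversine great-circle distance on a sphere of radius `radius_m`
#' (default: mean Earth radius, 6,371,000 m).  Vectorized over points.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @param radius_m sphere radius in meters (> 0).
#' @return Distance(s) in meters.
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2, radius_m = 6371000) {
  if (radius_m <= 0) stop("`radius_m` must be > 0", call. = FALSE)
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE))
    stop("latitudes must lie in [-90, 90]", call. = FALSE)
  if (any(abs(c(lon1, lon2)) > 180, na.rm = TRUE))
    stop("longitudes must lie in [-180, 180]", call. = FALSE)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = radius_m)
}

#' Interpolate a GPS track at arbitrary times
#'
#' Coordinate-wise linear interpolation in time, independently on latitude
#' and longitude in degrees (no projection; adequate at the sub-km scales of
#' buoy/group separation).  No extrapolation: every requested time must lie
#' within the span of the fixes.
#'
#' @param track data frame with columns `platform_id`, `t_s`, `lat_deg`,
#'   `lon_deg`; timestamps strictly increasing.
#' @param times numeric vector of query times (s).
#' @return A data frame with one row per query time, same columns as `track`.
#' @export
interpolate_positions <- function(track, times) {
  check_track(track)
  if (nrow(track) < 2) stop("need >= 2 fixes to interpolate", call. = FALSE)
  if (any(times < min(track$t_s) | times > max(track$t_s)))
    stop("requested times outside the track span (no extrapolation)",
         call. = FALSE)
  data.frame(
    platform_id = track$platform_id[1],
    t_s = times,
    lat_deg = stats::approx(track$t_s, track$lat_deg, xout = times)$y,
    lon_deg = stats::approx(track$t_s, track$lon_deg, xout = times)$y)
}

check_track <- function(track) {
  need <- c("platform_id", "t_s", "lat_deg", "lon_deg")
  if (!all(need %in% names(track)))
    stop("track must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(track$t_s, strictly = TRUE))
    stop("track timestamps must be strictly increasing", call. = FALSE)
  if (any(abs(track$lat_deg) > 90) || any(abs(track$lon_deg) > 180))
    stop("track coordinates out of range", call. = FALSE)
  invisible(track)
}

#' Select the closest buoy per minute and build the exclusion mask
#'
#' For every minute of the experiment (minute `k` covers the half-open
#' interval `[60k, 60(k+1))`, evaluated at its start), all tracks are
#' linearly interpolated, the buoy with the minimal great-circle distance to
#' the group is selected, and the minute is marked excluded when that
#' minimal distance exceeds `threshold_m` (whistles cannot be reliably
#' detected much beyond 1.6 km).  Exact distance ties are broken by the
#' lowest `platform_id`.  Minutes not covered by any buoy track are excluded
#' with a warning.
#'
#' @param group group track (data frame, see [interpolate_positions()]).
#' @param buoys list of buoy tracks.
#' @param threshold_m exclusion threshold in meters (default 1600).
#' @param duration_s experiment duration; defaults to the group track span.
#' @param radius_m sphere radius for [haversine_distance()].
#' @return A data frame of class `buoy_selection` with one row per minute:
#'   `minute_index` (0-based), `closest_buoy_id`, `distance_m`, `included`.
#' @export
select_closest_buoy <- function(group, buoys, threshold_m = 1600,
                                duration_s = NULL, radius_m = 6371000) {
  check_track(group)
  if (!length(buoys)) stop("need at least one buoy track", call. = FALSE)
  if (is.null(duration_s)) duration_s <- max(group$t_s)
  minutes <- seq_len(max(1L, floor(duration_s / 60))) - 1L
  t_eval <- minutes * 60

  gpos <- interpolate_positions(group, t_eval)
  ids <- vapply(buoys, function(b) as.character(b$platform_id[1]), "")
  ord <- order(ids)
  buoys <- buoys[ord]; ids <- ids[ord]

  dist <- matrix(NA_real_, nrow = length(t_eval), ncol = length(buoys),
                 dimnames = list(NULL, ids))
  for (j in seq_along(buoys)) {
    b <- buoys[[j]]
    check_track(b)
    ok <- t_eval >= min(b$t_s) & t_eval <= max(b$t_s)
    if (any(ok)) {
      bp <- interpolate_positions(b, t_eval[ok])
      dist[ok, j] <- haversine_distance(gpos$lat_deg[ok], gpos$lon_deg[ok],
                                        bp$lat_deg, bp$lon_deg,
                                        radius_m = radius_m)
    }
  }
  any_cov <- rowSums(!is.na(dist)) > 0
  if (!all(any_cov))
    warning(sum(!any_cov), " minute(s) not covered by any buoy track; ",
            "excluded", call. = FALSE)
  best_j <- apply(dist, 1L, function(d) {
    if (all(is.na(d))) NA_integer_ else which.min(d)  # ties -> lowest id
  })
  best_d <- dist[cbind(seq_along(best_j), best_j)]
  out <- data.frame(
    minute_index = minutes,
    closest_buoy_id = ifelse(is.na(best_j), NA_character_, ids[best_j]),
    distance_m = best_d,
    included = !is.na(best_d) & best_d <= threshold_m)
  attr(out, "threshold_m") <- threshold_m
  class(out) <- c("buoy_selection", "data.frame")
  out
}

#' Mean group-to-buoy distance over a CEE
#'
#' The per-CEE mean of the selected closest-buoy distance, the `buoyDist`
#' covariate of the response models.  Computed over included minutes.
#'
#' @param sel a `buoy_selection`.
#' @return Mean distance in meters (NA if no minute is included).
#' @export
mean_buoy_distance <- function(sel) {
  stopifnot(inherits(sel, "buoy_selection"))
  d <- sel$distance_m[sel$included]
  if (!length(d)) NA_real_ else mean(d)
}
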