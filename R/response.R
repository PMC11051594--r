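#' Absolute pre-exposure vs exposure difference in median whistle count
#'
#' The broad-scale (10-min) response variable: the absolute difference
#' between the median per-second whistle count of the exposure period and
#' that of the pre-exposure period, over unmasked seconds.
#'
#' @param cs a `count_series`.
#' @param meta optional one-row data frame (or list) of CEE covariates
#'   (`cee_id`, `cee_type`, `subspecies`, `group_size`); copied into the
#'   record.
#' @param buoy_dist_m mean closest-buoy distance for the CEE (covariate).
#' @param quantile_type quantile convention, see [summarize_cee()].
#' @return A one-row data frame (`ceeNum`, `ceeType`, `periodDiff`,
#'   `subSpecies`, `groupSize`, `buoyDist`, `medWhist`), or `NULL` with a
#'   warning when either period is fully masked.
#' @export
period_median_difference <- function(cs, meta = NULL, buoy_dist_m = NA_real_,
                                     quantile_type = 7) {
  stopifnot(inherits(cs, "count_series"))
  med <- function(p) {
    x <- cs$counts[cs$mask & cs$phase == p]
    if (!length(x)) NA_real_ else
      stats::quantile(x, 0.5, type = quantile_type, names = FALSE)
  }
  m_pre <- med("pre"); m_exp <- med("exposure")
  if (is.na(m_pre) || is.na(m_exp)) {
    warning("a period is fully masked; record dropped for ", cs$cee_id,
            call. = FALSE)
    return(NULL)
  }
  all_x <- cs$counts[cs$mask]
  data.frame(
    ceeNum = meta_field(meta, "cee_id", cs$cee_id),
    ceeType = meta_field(meta, "cee_type", NA_character_),
    periodDiff = abs(m_exp - m_pre),
    subSpecies = meta_field(meta, "subspecies", NA_character_),
    groupSize = meta_field(meta, "group_size", NA_real_),
    buoyDist = buoy_dist_m,
    medWhist = if (length(all_x))
      stats::quantile(all_x, 0.5, type = quantile_type, names = FALSE)
    else NA_real_)
}

meta_field <- function(meta, name, default) {
  if (!is.null(meta) && !is.null(meta[[name]])) meta[[name]] else default
}

#' Before/after analysis windows around each ping
#'
#' For window length `w` and alignment `"offset"` (default) the before
#' window is `[onset - w, onset)` and the after window `[end, end + w)`,
#' i.e. the after window opens when the transmission ends — responses are
#' expected once the signal has been transmitted, and the transmission
#' second itself (where whistling may be suppressed) is kept out of both
#' windows.  With `"onset"` both windows abut the ping onset.
#'
#' Validity checks: with `check = "pings"` (default) no window may contain
#' an adjacent ping's transmission.  `check = "strict"` additionally
#' requires consecutive ping cycles' windows to be disjoint; note that at
#' the standard design (25-s spacing, 1.6-s pings) strict tiling admits only
#' `w <= (25 - 1.6) / 2 = 11.7` s, so 20-s windows necessarily share time
#' across cycles and pass only the default check.
#'
#' @param schedule a `ping_schedule`.
#' @param window_s window length in seconds.
#' @param align `"offset"` or `"onset"`.
#' @param check `"pings"`, `"strict"`, or `"none"`.
#' @return Data frame: `ping_index`, `before_start`, `before_end`,
#'   `after_start`, `after_end` (continuous times, s).
#' @export
ping_windows <- function(schedule, window_s,
                         align = c("offset", "onset"),
                         check = c("pings", "strict", "none")) {
  stopifnot(inherits(schedule, "ping_schedule"))
  align <- match.arg(align)
  check <- match.arg(check)
  if (window_s <= 0) stop("`window_s` must be > 0", call. = FALSE)
  onset <- schedule$onset_s
  end <- onset + schedule$duration_s
  after_start <- if (align == "offset") end else onset
  w <- data.frame(ping_index = schedule$ping_index,
                  before_start = onset - window_s, before_end = onset,
                  after_start = after_start,
                  after_end = after_start + window_s)
  overlap <- function(a1, a2, b1, b2) a1 < b2 - 1e-9 & b1 < a2 - 1e-9
  if (check != "none" && nrow(w) > 1L) {
    for (i in seq_len(nrow(w))) {
      adj <- setdiff(seq_len(nrow(w)), i)
      if (any(overlap(w$before_start[i], w$before_end[i], onset[adj],
                      end[adj])) ||
          any(overlap(w$after_start[i], w$after_end[i], onset[adj],
                      end[adj])))
        stop("window of ping ", i, " overlaps an adjacent ping's ",
             "transmission; `window_s` too large", call. = FALSE)
    }
  }
  if (check == "strict" && nrow(w) > 1L) {
    for (i in seq_len(nrow(w) - 1L)) {
      if (overlap(w$after_start[i], w$after_end[i],
                  w$before_start[i + 1L], w$before_end[i + 1L]))
        stop("after-window of ping ", i, " overlaps the next cycle's ",
             "before-window; `window_s` too large for strict tiling",
             call. = FALSE)
    }
  }
  w
}

# whole 1-s bins (0-based seconds) covered by the snapped window
window_seconds <- function(start, width, snap = c("down", "up")) {
  snap <- match.arg(snap)
  s0 <- if (snap == "down") floor(start) else ceiling(start)
  seq.int(s0, s0 + width - 1L)
}

#' Per-ping change in mean whistle count
#'
#' For each ping, `pingChange` is the mean per-second whistle count in the
#' after window minus the mean in the before window (after − before), over
#' unmasked whole seconds.  Windows are snapped to whole 1-s bins: the
#' before window is the `window_s` whole seconds ending at the ping onset,
#' the after window the `window_s` whole seconds starting at the first full
#' second after the reference point (transmission end under `"offset"`
#' alignment).  Pseudo-ping schedules from control experiments are treated
#' identically.  Pings with a fully masked window are dropped with a
#' message.
#'
#' @inheritParams ping_windows
#' @param cs a `count_series`.
#' @return Data frame of class `ping_change`: `ceeNum`, `ping_index`,
#'   `times` (the ping order index used by the AR(1) correlation),
#'   `pingChange`, `window_s`, `n_before`, `n_after`.
#' @export
ping_change_series <- function(cs, schedule, window_s = 5,
                               align = c("offset", "onset"),
                               check = c("pings", "strict", "none")) {
  stopifnot(inherits(cs, "count_series"))
  w <- ping_windows(schedule, window_s, align, check)
  n <- length(cs$counts)
  rows <- lapply(seq_len(nrow(w)), function(i) {
    bs <- window_seconds(w$before_start[i], window_s, "down")
    as_ <- window_seconds(w$after_start[i], window_s, "up")
    if (any(c(bs, as_) < 0) || any(c(bs, as_) >= n))
      stop("ping windows fall outside the count series", call. = FALSE)
    bu <- bs[cs$mask[bs + 1L]]
    au <- as_[cs$mask[as_ + 1L]]
    if (!length(bu) || !length(au)) {
      message("ping ", w$ping_index[i], " of ", cs$cee_id,
              ": window fully masked; record dropped")
      return(NULL)
    }
    data.frame(ceeNum = cs$cee_id, ping_index = w$ping_index[i],
               times = w$ping_index[i],
               pingChange = mean(cs$counts[au + 1L]) -
                 mean(cs$counts[bu + 1L]),
               window_s = window_s, n_before = length(bu),
               n_after = length(au))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(
    ceeNum = character(0), ping_index = integer(0), times = integer(0),
    pingChange = numeric(0), window_s = numeric(0), n_before = integer(0),
    n_after = integer(0))
  class(out) <- c("ping_change", "data.frame")
  out
}

#' Fold change in whistle count across the first ping
#'
#' Total whistle count in the 5 s (or `window_s`) after the first ping
#' divided by the total in the equal window before it.  A zero before-count
#' makes the ratio undefined (`NA` with the `undefined` flag), never
#' infinite.
#'
#' @inheritParams ping_change_series
#' @param window_s window length in seconds (default 5).
#' @return A list: `before_total`, `after_total`, `ratio`, `undefined`.
#' @export
first_ping_fold_change <- function(cs, schedule, window_s = 5,
                                   align = c("offset", "onset")) {
  stopifnot(inherits(cs, "count_series"), inherits(schedule, "ping_schedule"))
  w <- ping_windows(schedule, window_s, align, check = "none")[1L, ]
  bs <- window_seconds(w$before_start, window_s, "down")
  as_ <- window_seconds(w$after_start, window_s, "up")
  if (!all(cs$mask[c(bs, as_) + 1L]))
    warning("first-ping windows partially masked", call. = FALSE)
  before <- sum(cs$counts[bs + 1L])
  after <- sum(cs$counts[as_ + 1L])
  if (before == 0) {
    list(before_total = before, after_total = after, ratio = NA_real_,
         undefined = TRUE)
  } else {
    list(before_total = before, after_total = after,
         ratio = after / before, undefined = FALSE)
  }
}

#' Is the first-ping response pronounced?
#'
#' `TRUE` when the first ping's `pingChange` exceeds the 75th percentile of
#' the per-ping `pingChange` distribution of the same CEE (linear
#' interpolation percentile convention).
#'
#' @param records a `ping_change` data frame for one CEE, or a numeric
#'   vector of per-ping changes in ping order.
#' @param prob percentile threshold (default 0.75).
#' @param quantile_type passed to [stats::quantile()].
#' @return Logical.
#' @export
flag_pronounced_first_ping <- function(records, prob = 0.75,
                                       quantile_type = 7) {
  x <- if (is.data.frame(records)) {
    records$pingChange[order(records$ping_index)]
  } else as.numeric(records)
  if (length(x) < 4) stop("need >= 4 pings", call. = FALSE)
  x[1] > stats::quantile(x, prob, type = quantile_type, names = FALSE)
}
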