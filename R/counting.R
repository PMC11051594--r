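#' Remove detections overlapping annotated sonar-harmonic intervals
#'
#' High source levels leave sonar harmonics in the 5-20 kHz detection band;
#' these are annotated manually and must be dropped before counting.  A
#' detection is dropped when its half-open extent `[start_s, start_s +
#' duration_s)` overlaps any annotation interval `[start_s, end_s)` on the
#' same CEE and buoy; touching endpoints do not overlap.
#'
#' @param det detection table: data frame with `cee_id`, `buoy_id`,
#'   `start_s`, `duration_s` (`start_s >= 0`, `duration_s > 0`).
#' @param ann annotation table: data frame with `cee_id`, `buoy_id`,
#'   `start_s`, `end_s` (`end_s > start_s`).
#' @return The detection table with overlapping rows removed.
#' @export
remove_annotated_detections <- function(det, ann) {
  check_detections(det)
  if (is.null(ann) || nrow(ann) == 0L) return(det)
  if (any(ann$end_s <= ann$start_s))
    stop("annotation intervals must have `end_s` > `start_s`", call. = FALSE)
  drop <- rep(FALSE, nrow(det))
  d_end <- det$start_s + det$duration_s
  for (i in seq_len(nrow(ann))) {
    same <- det$cee_id == ann$cee_id[i] & det$buoy_id == ann$buoy_id[i]
    drop <- drop | (same & det$start_s < ann$end_s[i] &
                      d_end > ann$start_s[i])
  }
  det[!drop, , drop = FALSE]
}

check_detections <- function(det) {
  need <- c("cee_id", "buoy_id", "start_s", "duration_s")
  if (!all(need %in% names(det)))
    stop("detection table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(det) && (any(det$start_s < 0) || any(det$duration_s <= 0)))
    stop("detections need `start_s` >= 0 and `duration_s` > 0",
         call. = FALSE)
  invisible(det)
}

#' Keep only detections recorded on the selected closest buoy
#'
#' Analyses use the buoy closest to the focal group at 1-min resolution.  A
#' detection survives when its start falls in a minute where its buoy is the
#' selected buoy and the minute is included (within the 1.6-km threshold).
#'
#' @param det detection table.
#' @param sel a `buoy_selection` from [select_closest_buoy()].
#' @return The filtered detection table.
#' @export
stitch_closest_buoy <- function(det, sel) {
  check_detections(det)
  stopifnot(inherits(sel, "buoy_selection"))
  if (!nrow(det)) return(det)
  minute <- floor(det$start_s / 60)
  if (any(minute >= nrow(sel)))
    stop("buoy selection does not cover the detection span", call. = FALSE)
  row <- match(minute, sel$minute_index)
  keep <- !is.na(row) & sel$included[row] &
    !is.na(sel$closest_buoy_id[row]) &
    det$buoy_id == sel$closest_buoy_id[row]
  det[keep, , drop = FALSE]
}

#' Bin detections into a masked per-second count series
#'
#' The whistle-activity metric is the number of detections *starting* within
#' each 1-s bin: a whistle longer than 1 s still contributes only to its
#' start bin.  The per-minute exclusion mask from the buoy selection is
#' expanded to seconds (all seconds of an excluded minute are masked), and
#' each second is labelled with its experimental phase.
#'
#' @param det detection table (already harmonic-filtered and stitched).
#' @param duration_s series length in seconds.
#' @param sel optional `buoy_selection` providing the mask; `NULL` leaves
#'   every second usable.
#' @param phase_bounds phase boundaries in seconds.
#' @param cee_id identifier stored on the series.
#' @return An object of class `count_series`: list with integer `counts`
#'   (length `duration_s`), logical `mask` (`TRUE` = usable), factor `phase`
#'   (`pre`/`exposure`/`post`), plus `phase_bounds` and `cee_id`.
#' @export
bin_per_second <- function(det, duration_s, sel = NULL,
                           phase_bounds = c(0, 600, 1200, duration_s),
                           cee_id = if (nrow(det)) det$cee_id[1] else "cee") {
  check_detections(det)
  duration_s <- as.integer(duration_s)
  if (nrow(det) && any(det$start_s >= duration_s))
    stop("detection beyond the series duration", call. = FALSE)
  counts <- tabulate(floor(det$start_s) + 1L, nbins = duration_s)
  mask <- rep(TRUE, duration_s)
  if (!is.null(sel)) {
    stopifnot(inherits(sel, "buoy_selection"))
    minute <- pmin(floor((seq_len(duration_s) - 1L) / 60), nrow(sel) - 1L)
    mask <- sel$included[match(minute, sel$minute_index)]
    mask[is.na(mask)] <- FALSE
  }
  labs <- c("pre", "exposure", "post")[seq_len(length(phase_bounds) - 1L)]
  phase <- cut(seq_len(duration_s) - 1L, breaks = phase_bounds,
               right = FALSE, labels = labs)
  out <- list(counts = counts, mask = mask, phase = phase,
              phase_bounds = phase_bounds, cee_id = cee_id)
  class(out) <- "count_series"
  out
}

#' Construct a count series directly
#'
#' Builds a `count_series` from a per-second count vector, for simulated
#' counts or counts imported from other tooling.  [bin_per_second()] is the
#' usual constructor from a detection table.
#'
#' @param counts non-negative integer vector of per-second whistle counts.
#' @param mask logical vector (`TRUE` = usable), recycled from `TRUE`.
#' @param phase_bounds phase boundaries in seconds.
#' @param cee_id identifier.
#' @return A `count_series`.
#' @export
count_series <- function(counts, mask = rep(TRUE, length(counts)),
                         phase_bounds = c(0, 600, 1200, length(counts)),
                         cee_id = "cee") {
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (length(mask) != length(counts))
    stop("`mask` must match `counts` in length", call. = FALSE)
  labs <- c("pre", "exposure", "post")[seq_len(length(phase_bounds) - 1L)]
  phase <- cut(seq_along(counts) - 1L, breaks = phase_bounds,
               right = FALSE, labels = labs)
  structure(list(counts = counts, mask = as.logical(mask), phase = phase,
                 phase_bounds = phase_bounds, cee_id = cee_id),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series %s: %d s, %d whistles, %d s masked>\n",
              x$cee_id, length(x$counts), sum(x$counts[x$mask]),
              sum(!x$mask)))
  invisible(x)
}

#' Summary statistics of a count series
#'
#' Mean, SD, median and IQR of the per-second whistle counts over unmasked
#' seconds, overall and per experimental phase.  Quantiles use linear
#' interpolation between order statistics (`stats::quantile` type 7, the R
#' default); IQR is the 75th minus the 25th percentile.  The overall median
#' is the `medWhist` covariate of the response models.
#'
#' @param cs a `count_series`.
#' @param quantile_type passed to [stats::quantile()].
#' @return A list with `overall` and `by_phase` data frames (columns `n`,
#'   `mean`, `sd`, `median`, `iqr`) and `med_whist`.  If every second is
#'   masked the summary is missing (`NA` rows) and a warning is raised.
#' @export
summarize_cee <- function(cs, quantile_type = 7) {
  stopifnot(inherits(cs, "count_series"))
  stat <- function(x) {
    if (!length(x)) {
      return(data.frame(n = 0L, mean = NA_real_, sd = NA_real_,
                        median = NA_real_, iqr = NA_real_))
    }
    q <- stats::quantile(x, c(.25, .5, .75), type = quantile_type,
                         names = FALSE)
    data.frame(n = length(x), mean = mean(x), sd = stats::sd(x),
               median = q[2], iqr = q[3] - q[1])
  }
  use <- cs$mask
  if (!any(use)) warning("all seconds masked; summary is missing",
                         call. = FALSE)
  overall <- stat(cs$counts[use])
  phases <- levels(cs$phase)
  by_phase <- do.call(rbind, lapply(phases, function(p) {
    cbind(phase = p, stat(cs$counts[use & cs$phase == p]))
  }))
  list(overall = overall, by_phase = by_phase, med_whist = overall$median)
}
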