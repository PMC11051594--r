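#' Serialize a simulated CEE to plain-text files
#'
#' Writes the bundle the analysis consumes: `detections.csv` (`cee_id`,
#' `buoy_id`, `start_s`, `duration_s`), `tracks.csv` (`platform_id`, `t_s`,
#' `lat_deg`, `lon_deg`), and `meta.json` holding the ping schedule, CEE
#' metadata and generator configuration.  Output is deterministic: the same
#' seeded bundle serializes byte-identically.
#'
#' @param cee a `simulated_cee`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cee_bundle <- function(cee, dir) {
  stopifnot(inherits(cee, "simulated_cee"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cee$detections, file.path(dir, "detections.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, cee$tracks), file.path(dir, "tracks.csv"),
                   row.names = FALSE)
  meta <- list(
    meta = cee$meta,
    schedule = list(cee_id = attr(cee$schedule, "cee_id"),
                    is_pseudo = attr(cee$schedule, "is_pseudo"),
                    onset_s = cee$schedule$onset_s,
                    duration_s = cee$schedule$duration_s),
    config = unclass(cee$config))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null", dataframe = "columns"),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' Read a serialized CEE bundle
#'
#' Inverse of [write_cee_bundle()]: reconstructs the detection table, the
#' named track list, the ping schedule and the metadata so the bundle can be
#' fed to [analyze_cee()].
#'
#' @param dir directory written by [write_cee_bundle()].
#' @return A list with `detections`, `tracks`, `schedule`, `meta`.
#' @export
read_cee_bundle <- function(dir) {
  det <- utils::read.csv(file.path(dir, "detections.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c(cee_id = "character",
                                        buoy_id = "character"))
  tr <- utils::read.csv(file.path(dir, "tracks.csv"),
                        stringsAsFactors = FALSE)
  tracks <- split(tr, tr$platform_id)
  tracks <- tracks[c("group", setdiff(sort(names(tracks)), "group"))]
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  sched <- make_ping_schedule(
    start_s = meta$schedule$onset_s[1],
    n_pings = length(meta$schedule$onset_s),
    interval_s = if (length(meta$schedule$onset_s) > 1)
      diff(meta$schedule$onset_s)[1] else 25,
    ping_dur_s = meta$schedule$duration_s[1],
    phase_end_s = Inf,
    cee_id = meta$schedule$cee_id, is_pseudo = meta$schedule$is_pseudo)
  list(detections = det, tracks = tracks, schedule = sched,
       meta = as.data.frame(meta$meta))
}

#' Write the study report tables
#'
#' Emits the per-CEE summary table, the model-input record tables, the
#' model-comparison table (when selection was run) and the manifest of a
#' [run_full_analysis()] result as headered UTF-8 CSV / JSON files.
#'
#' @param study a `cee_study`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(study, dir) {
  stopifnot(inherits(study, "cee_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$summary_table,
                   file.path(dir, "cee_summary_table.csv"),
                   row.names = FALSE)
  if (!is.null(study$period_records))
    utils::write.csv(study$period_records,
                     file.path(dir, "period_records.csv"),
                     row.names = FALSE)
  for (w in names(study$ping_records)) {
    utils::write.csv(study$ping_records[[w]],
                     file.path(dir, paste0("ping_records_", w, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(study$selections)) {
    tab <- do.call(rbind, lapply(names(study$selections), function(nm) {
      cbind(scale = nm, study$selections[[nm]]$table)
    }))
    utils::write.csv(tab, file.path(dir, "model_comparison.csv"),
                     row.names = FALSE)
  }
  writeLines(jsonlite::toJSON(study$manifest, auto_unbox = TRUE,
                              digits = NA, null = "null"),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
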