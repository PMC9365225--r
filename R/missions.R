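#' Write / read mission and patient tables as CSV
#'
#' Missions and the per-patient sidecar are stored as two CSV files with
#' ISO-8601 UTC timestamps (`YYYY-MM-DDTHH:MM:SSZ`) and WGS84 decimal-degree
#' coordinates; the sidecar is keyed by `mission_id`. `read_missions()`
#' parses and re-derives the `month` and (given an intervention date) the
#' `period` columns, and rejects unparseable timestamps.
#'
#' @param sim A `hems_sim` object, or a list with `missions`/`patients`
#'   data frames.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix; files are `<prefix>_missions.csv` and
#'   `<prefix>_patients.csv`.
#' @return `write_missions()` returns the two paths invisibly;
#'   `read_missions()` returns a list with `missions` and `patients`.
#' @export
write_missions <- function(sim, dir, prefix = "hems") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- sim$missions
  for (col in c("alarm_time", "takeoff_time", "on_scene_time"))
    m[[col]] <- format_iso8601(m[[col]])
  mp <- file.path(dir, paste0(prefix, "_missions.csv"))
  pp <- file.path(dir, paste0(prefix, "_patients.csv"))
  utils::write.csv(m, mp, row.names = FALSE, na = "")
  p <- sim$patients
  if (!is.null(p)) {
    p$contact_time <- format_iso8601(p$contact_time)
    utils::write.csv(p, pp, row.names = FALSE, na = "")
  }
  invisible(c(missions = mp, patients = pp))
}

#' @rdname write_missions
#' @param missions_path,patients_path CSV paths; `patients_path` may be
#'   `NULL`.
#' @param intervention POSIXct intervention date used to derive `period`;
#'   `NULL` leaves any existing column untouched.
#' @export
read_missions <- function(missions_path, patients_path = NULL,
                          intervention = NULL) {
  m <- utils::read.csv(missions_path, stringsAsFactors = FALSE)
  for (col in c("alarm_time", "takeoff_time", "on_scene_time"))
    if (col %in% names(m)) m[[col]] <- parse_iso8601(m[[col]], col)
  m$month <- format(m$alarm_time, "%Y-%m")
  if (!is.null(intervention))
    m$period <- ifelse(m$alarm_time >= intervention, "post", "pre")
  p <- NULL
  if (!is.null(patients_path) && file.exists(patients_path)) {
    p <- utils::read.csv(patients_path, stringsAsFactors = FALSE)
    if ("contact_time" %in% names(p))
      p$contact_time <- parse_iso8601(p$contact_time, "contact_time")
  }
  list(missions = m, patients = p)
}

format_iso8601 <- function(x) {
  out <- format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out[is.na(x)] <- NA_character_
  out
}

parse_iso8601 <- function(x, what) {
  x[!nzchar(x)] <- NA_character_
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    stop(sprintf("unparseable %s timestamp(s), e.g. '%s'", what,
                 x[which(bad)[1]]), call. = FALSE)
  out
}

# fixed priority order in which exclusion reasons are assigned
EXCLUSION_ORDER <- c("cancelled/aborted", "rapid-response car",
                     "SAR mission", "secondary mission", "not acute",
                     "no patient contact", "missing timeline")

#' Apply the study's inclusion and exclusion criteria
#'
#' Retains completed, primary, acute missions with patient contact and a
#' usable timeline. Every dropped record is tallied under its first matching
#' reason in the fixed priority order: cancelled/aborted, rapid-response
#' car, SAR mission, secondary mission, not acute, no patient contact,
#' missing timeline. Records with unknown categorical values are rejected
#' (tallied under the relevant reason's slot as unparseable, never silently
#' dropped). Missions without GPS positions remain included — they are only
#' dropped later from the service-area analysis — but their count is
#' reported in the tally for audit.
#'
#' @param missions Mission table (see [generate_missions()] /
#'   [read_missions()]).
#' @return A list of class `inclusion_result`: `included` (filtered table),
#'   `tally` (an `exclusion_tally`: named counts per reason plus `included`,
#'   `total` and the informational `missing_gps`).
#' @export
apply_inclusion_criteria <- function(missions) {
  n <- nrow(missions)
  if (n == 0L) {
    tally <- structure(
      list(counts = stats::setNames(integer(length(EXCLUSION_ORDER)),
                                    EXCLUSION_ORDER),
           included = 0L, total = 0L, missing_gps = 0L),
      class = "exclusion_tally")
    return(structure(list(included = missions, tally = tally),
                     class = "inclusion_result"))
  }
  known_types <- c("primary", "secondary", "sar", "car")
  bad_type <- !(missions$mission_type %in% known_types)
  if (any(bad_type))
    stop(sprintf("unknown mission_type value(s): %s",
                 paste(unique(missions$mission_type[bad_type]),
                       collapse = ", ")), call. = FALSE)
  bad_urg <- !(missions$urgency %in% c("acute", "other"))
  if (any(bad_urg))
    stop(sprintf("unknown urgency value(s): %s",
                 paste(unique(missions$urgency[bad_urg]), collapse = ", ")),
         call. = FALSE)

  reason <- rep(NA_character_, n)
  hit <- function(cond, label) {
    sel <- is.na(reason) & cond
    reason[sel] <<- label
  }
  hit(!missions$completed, "cancelled/aborted")
  hit(missions$mission_type == "car", "rapid-response car")
  hit(missions$mission_type == "sar", "SAR mission")
  hit(missions$mission_type == "secondary", "secondary mission")
  hit(missions$urgency != "acute", "not acute")
  hit(!missions$patient_contact, "no patient contact")
  hit(is.na(missions$alarm_time) | is.na(missions$on_scene_time),
      "missing timeline")

  included <- missions[is.na(reason), , drop = FALSE]
  rownames(included) <- NULL
  counts <- stats::setNames(integer(length(EXCLUSION_ORDER)), EXCLUSION_ORDER)
  tab <- table(reason)
  counts[names(tab)] <- as.integer(tab)
  tally <- structure(
    list(counts = counts, included = nrow(included), total = n,
         missing_gps = sum(is.na(included$latitude) |
                             is.na(included$longitude))),
    class = "exclusion_tally")
  structure(list(included = included, tally = tally),
            class = "inclusion_result")
}

#' @export
print.exclusion_tally <- function(x, ...) {
  cat(sprintf("Inclusion filter: %d of %d records retained\n",
              x$included, x$total))
  for (r in names(x$counts))
    if (x$counts[[r]] > 0) cat(sprintf("  excluded, %-20s %6d\n", r,
                                       x$counts[[r]]))
  cat(sprintf("  retained without GPS    %6d (kept; dropped from map analyses)\n",
              x$missing_gps))
  invisible(x)
}

#' @export
as.data.frame.exclusion_tally <- function(x, ...) {
  data.frame(reason = c(names(x$counts), "included", "missing GPS (retained)"),
             n = c(unname(x$counts), x$included, x$missing_gps),
             stringsAsFactors = FALSE)
}

#' Response time of a mission
#'
#' The interval from the alarm (local dispatch centre alarming the crew
#' before the intervention; the HEMS coordinator being alarmed after) to the
#' crew's arrival on scene, in decimal minutes. A missing timestamp yields
#' `NA`; a non-positive interval is a data error and also yields `NA`, with
#' the record flagged for review via the `flag` attribute
#' (`"ok"`, `"missing"`, `"nonpositive"`).
#'
#' @param missions Mission table with `alarm_time` and `on_scene_time`.
#' @return Numeric vector of minutes with attribute `flag`.
#' @export
response_time <- function(missions) {
  mins <- as.numeric(difftime(missions$on_scene_time, missions$alarm_time,
                              units = "mins"))
  flag <- rep("ok", length(mins))
  flag[is.na(mins)] <- "missing"
  bad <- !is.na(mins) & mins <= 0
  flag[bad] <- "nonpositive"
  mins[bad] <- NA_real_
  structure(mins, flag = flag)
}

#' In-flight scramble classifier
#'
#' A mission is an in-flight scramble when the helicopter was already
#' airborne at the alarm, operationalised as an abnormally short interval —
#' strictly less than 2 minutes — between the alarm and takeoff. Exactly 2
#' minutes is not a scramble. Missing takeoff yields `NA`.
#'
#' @param missions Mission table with `alarm_time` and `takeoff_time`.
#' @param threshold_min Threshold in minutes (default 2).
#' @return Logical vector.
#' @export
is_inflight_scramble <- function(missions, threshold_min = 2) {
  iv <- as.numeric(difftime(missions$takeoff_time, missions$alarm_time,
                            units = "mins"))
  iv < threshold_min
}

#' Collapse multi-patient missions to a single mission row
#'
#' Missions transporting several patients are registered once; when patient
#' contact times differ, the earliest patient contact defines the mission's
#' on-scene time. All patients remain in the sidecar for descriptive
#' analyses. Missions with no patients in the sidecar are marked as having
#' no patient contact (and are then dropped by the inclusion filter).
#'
#' @param missions Mission table.
#' @param patients Patient sidecar with `mission_id` and `contact_time`.
#' @return Mission table with updated `on_scene_time` and `patient_contact`.
#' @export
collapse_multipatient <- function(missions, patients) {
  if (is.null(patients) || nrow(patients) == 0L) {
    missions$patient_contact <- FALSE
    return(missions)
  }
  ct <- patients[!is.na(patients$contact_time), , drop = FALSE]
  first <- tapply(as.numeric(ct$contact_time), ct$mission_id, min)
  idx <- match(missions$mission_id, names(first))
  has <- !is.na(idx)
  missions$on_scene_time[has] <- as.POSIXct(unname(first[idx[has]]),
                                            origin = "1970-01-01", tz = "UTC")
  known <- missions$mission_id %in% patients$mission_id
  missions$patient_contact <- known & missions$patient_contact
  missions
}
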