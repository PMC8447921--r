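# Cohort serialization: observations.csv (patient_id, timestamp_iso8601,
# feature_name, value) and events.csv (patient_id, timestamp_iso8601,
# event_type, code). Timestamps are absolute UTC; internally everything is
# hours relative to the admission event, and pre-admission ICD history keeps
# negative times. Generated times sit on a whole-second grid, so the round
# trip is exact.

.EVENT_TYPES <- c("icd", "antibiotics", "supplemental_o2", "mech_vent",
                  "admission", "discharge")
.T0 <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

.fmt_time <- function(hours, origin) {
  format(origin + round(hours * 3600), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Write a cohort to observations.csv / events.csv
#'
#' Each patient is assigned an absolute admission timestamp (a fixed origin
#' staggered by patient index); all event and observation times are emitted
#' as ISO-8601 UTC timestamps.
#'
#' @param cohort an `ards_cohort` or list of encounters.
#' @param obs_path,events_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, obs_path, events_path) {
  obs <- vector("list", length(cohort))
  evs <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    enc <- cohort[[i]]
    origin <- .T0 + (i - 1) * 86400
    obs[[i]] <- data.table::data.table(
      patient_id = enc$patient_id,
      timestamp_iso8601 = .fmt_time(enc$observations$time, origin),
      feature_name = enc$observations$feature,
      value = enc$observations$value)
    evs[[i]] <- data.table::data.table(
      patient_id = enc$patient_id,
      timestamp_iso8601 = .fmt_time(enc$events$time, origin),
      event_type = enc$events$event_type,
      code = enc$events$code)
  }
  data.table::fwrite(data.table::rbindlist(obs), obs_path)
  data.table::fwrite(data.table::rbindlist(evs), events_path)
  invisible(c(obs_path, events_path))
}

.parse_times <- function(x, file) {
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  bad <- which(is.na(t))
  if (length(bad))
    stop("unparseable timestamp in ", file, " at data row ", bad[1],
         ": '", x[bad[1]], "'")
  t
}

#' Read a cohort from observations.csv / events.csv
#'
#' Every patient must have an `admission` event, which anchors hour 0;
#' pre-admission events get negative times. Discharge time falls back to the
#' latest observed time when no discharge event is present.
#'
#' @param obs_path,events_path input CSV paths.
#' @return an `ards_cohort` (hospital ids are not part of the serialized
#'   schema and come back as `NA`).
#' @export
read_cohort <- function(obs_path, events_path) {
  ob <- data.table::fread(obs_path, colClasses = list(character = 1:3))
  ev <- data.table::fread(events_path, colClasses = list(character = 1:4))
  need_ob <- c("patient_id", "timestamp_iso8601", "feature_name", "value")
  need_ev <- c("patient_id", "timestamp_iso8601", "event_type", "code")
  if (!identical(names(ob), need_ob))
    stop("observations file must have columns: ",
         paste(need_ob, collapse = ", "))
  if (!identical(names(ev), need_ev))
    stop("events file must have columns: ", paste(need_ev, collapse = ", "))
  if (nrow(ev) && any(!ev$event_type %in% .EVENT_TYPES))
    stop("unknown event_type in ", events_path, " at data row ",
         which(!ev$event_type %in% .EVENT_TYPES)[1])
  ob$t <- .parse_times(ob$timestamp_iso8601, obs_path)
  ev$t <- .parse_times(ev$timestamp_iso8601, events_path)
  ev$code <- ifelse(is.na(ev$code), "", ev$code)
  pids <- unique(c(ob$patient_id, ev$patient_id))
  obs_sp <- split(ob, ob$patient_id)
  ev_sp <- split(ev, ev$patient_id)
  out <- vector("list", length(pids))
  for (i in seq_along(pids)) {
    pid <- pids[i]
    e <- ev_sp[[pid]]
    adm <- e$t[e$event_type == "admission"]
    if (is.null(e) || !length(adm))
      stop("patient ", pid, " has no admission event")
    adm <- min(adm)
    o <- obs_sp[[pid]]
    observations <- if (is.null(o)) {
      data.frame(feature = character(0), value = numeric(0),
                 time = numeric(0), stringsAsFactors = FALSE)
    } else {
      data.frame(feature = o$feature_name, value = as.numeric(o$value),
                 time = as.numeric(difftime(o$t, adm, units = "hours")),
                 stringsAsFactors = FALSE)
    }
    observations <- observations[order(observations$time,
                                       observations$feature), , drop = FALSE]
    rownames(observations) <- NULL
    events <- data.frame(event_type = e$event_type, code = e$code,
                         time = as.numeric(difftime(e$t, adm, units = "hours")),
                         stringsAsFactors = FALSE)
    events <- events[order(events$time, events$event_type), , drop = FALSE]
    rownames(events) <- NULL
    dis <- events$time[events$event_type == "discharge"]
    discharge <- if (length(dis)) max(dis)
                 else max(c(0, observations$time, events$time))
    out[[i]] <- structure(list(patient_id = pid, hospital_id = NA_integer_,
                               admission_time = 0, discharge_time = discharge,
                               observations = observations, events = events),
                          class = "ards_encounter")
  }
  structure(out, class = "ards_cohort")
}

#' Write a labeled cohort to labels.csv
#' @param labels data.frame from [label_cohort()].
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  data.table::fwrite(labels, path)
  invisible(path)
}
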