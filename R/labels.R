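# Gold-standard labelling from ICD-coded events plus physiologic criteria.
#
# Seven binary outcomes per encounter. The primary outcome (ARDS leading to
# respiratory failure) requires a *new* ARDS ICD code — absent during the
# 1000 hours before admission — together with physiologic respiratory
# failure (SpO2 < 92% or PaO2/FiO2 < 300), both at or after the prediction
# time (first SpO2 < 97%). All threshold comparisons are strict and the
# 1000-hour code-novelty rule applies to every ICD-defined outcome.

# ICD code lists, dot-stripped; matching is dot-insensitive prefix matching
# so e.g. "J960" matches "J96.00".
.ICD_CODES <- list(
  ards = c("J80", "J960", "J962", "J969", "51881"),
  covid19 = c("U071", "B9721", "B9729", "J1281", "B342"),
  aki = c("N17", "N19", "R34"),
  thrombosis = c("I12", "I26", "I63", "I67", "I74", "I80", "I81", "I82"),
  sepsis = c("A40", "A41", "R652", "T8112", "T8144", "O85", "O8604")
)

.LOOKBACK_HOURS <- 1000

#' Canonical outcome order used throughout the package
#'
#' The primary outcome (ARDS with verified respiratory failure) is first;
#' validation checkpointing, pseudolabelling and AUROC reporting all key on
#' this column.
#' @return character vector of the 7 outcome names.
#' @export
outcome_names <- function() {
  c("primary_ards_resp_failure", "ards_icd", "covid19", "aki",
    "thrombosis", "sepsis", "mech_vent_after_drop")
}

.feature_obs <- function(enc, name) {
  o <- enc$observations
  o[o$feature == name & o$time >= 0, , drop = FALSE]
}

#' Prediction time: first SpO2 strictly below 97%
#'
#' @param enc an `ards_encounter`.
#' @return time in hours since admission, or `NA_real_` if the SpO2 never
#'   drops below 97%.
#' @export
prediction_time <- function(enc) {
  o <- .feature_obs(enc, "spo2")
  t <- o$time[o$value < 97]
  if (length(t)) min(t) else NA_real_
}

#' Respiratory-failure onset: first SpO2 < 92% or PaO2/FiO2 < 300
#'
#' The FiO2 paired with a PaO2 measurement is the last FiO2 recorded at or
#' before that time (0.21, room air, if none was ever recorded).
#'
#' @param enc an `ards_encounter`.
#' @return onset time in hours, or `NA_real_`.
#' @export
respiratory_failure_onset <- function(enc) {
  spo2 <- .feature_obs(enc, "spo2")
  cand <- spo2$time[spo2$value < 92]
  pao2 <- .feature_obs(enc, "pao2")
  if (nrow(pao2)) {
    fio2 <- .feature_obs(enc, "fio2")
    if (any(fio2$value <= 0)) stop("recorded FiO2 must be positive")
    fio2 <- fio2[order(fio2$time), , drop = FALSE]
    for (i in seq_len(nrow(pao2))) {
      f <- fio2$value[fio2$time <= pao2$time[i]]
      f <- if (length(f)) f[length(f)] else 0.21
      if (pao2$value[i] / f < 300) cand <- c(cand, pao2$time[i])
    }
  }
  if (length(cand)) min(cand) else NA_real_
}

# earliest post-admission time of a new code from `codes`; NA if the code
# family appeared in the pre-admission look-back window or never after
.new_code_onset <- function(enc, codes) {
  ev <- enc$events
  ev <- ev[ev$event_type == "icd", , drop = FALSE]
  if (!nrow(ev)) return(NA_real_)
  bare <- gsub(".", "", ev$code, fixed = TRUE)
  hit <- rep(FALSE, nrow(ev))
  for (cd in codes) hit <- hit | startsWith(bare, cd)
  prior <- hit & ev$time >= -.LOOKBACK_HOURS & ev$time < 0
  if (any(prior)) return(NA_real_)
  t <- ev$time[hit & ev$time >= 0]
  if (length(t)) min(t) else NA_real_
}

#' ARDS ICD onset under the 1000-hour novelty rule
#'
#' Earliest post-admission ARDS code (J80, J96.0, J96.2, J96.9, 518.81 —
#' dot-insensitive prefix match), unless any such code already appears in
#' the 1000 hours leading up to admission.
#'
#' @param enc an `ards_encounter`.
#' @return onset time in hours, or `NA_real_`.
#' @export
ards_icd_onset <- function(enc) .new_code_onset(enc, .ICD_CODES$ards)

#' Label the 7 gold-standard outcomes for one encounter
#'
#' @param enc an `ards_encounter`.
#' @return an `ards_outcomes` list: 7 booleans (see [outcome_names()]) plus
#'   `prediction_time`, `resp_failure_onset`, `ards_icd_onset`.
#' @export
label_outcomes <- function(enc) {
  tp <- prediction_time(enc)
  tf <- respiratory_failure_onset(enc)
  ti <- ards_icd_onset(enc)
  ev <- enc$events
  mech <- !is.na(tp) &&
    any(ev$event_type == "mech_vent" & ev$time > tp)
  primary <- !is.na(tp) && !is.na(ti) && !is.na(tf) && ti >= tp && tf >= tp
  structure(list(
    primary_ards_resp_failure = primary,
    ards_icd = !is.na(ti),
    covid19 = !is.na(.new_code_onset(enc, .ICD_CODES$covid19)),
    aki = !is.na(.new_code_onset(enc, .ICD_CODES$aki)),
    thrombosis = !is.na(.new_code_onset(enc, .ICD_CODES$thrombosis)),
    sepsis = !is.na(.new_code_onset(enc, .ICD_CODES$sepsis)),
    mech_vent_after_drop = mech,
    prediction_time = tp, resp_failure_onset = tf, ards_icd_onset = ti),
    class = "ards_outcomes")
}

#' Inclusion filter: stay of at least 3 hours with a prediction time
#'
#' @param enc an `ards_encounter`.
#' @return logical.
#' @export
inclusion_filter <- function(enc) {
  (enc$discharge_time - enc$admission_time) >= 3 &&
    !is.na(prediction_time(enc))
}

#' Label every encounter in a cohort
#'
#' @param cohort an `ards_cohort` or list of encounters.
#' @return data.frame with `patient_id`, the 7 outcome columns and the 3
#'   timestamp columns.
#' @export
label_cohort <- function(cohort) {
  rows <- lapply(cohort, function(enc) {
    lb <- label_outcomes(enc)
    data.frame(patient_id = enc$patient_id,
               as.data.frame(lb[outcome_names()]),
               prediction_time = lb$prediction_time,
               resp_failure_onset = lb$resp_failure_onset,
               ards_icd_onset = lb$ards_icd_onset,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Look-ahead intervals from prediction time to ICD and failure onsets
#'
#' @param labels a labeled cohort data.frame from [label_cohort()].
#' @return list with `ards_icd` and `resp_failure`: hours from prediction
#'   time to each onset, over encounters where both are present; negative
#'   differences excluded.
#' @export
lookahead_intervals <- function(labels) {
  keep_pos <- function(x) x[!is.na(x) & x >= 0]
  list(ards_icd = keep_pos(labels$ards_icd_onset - labels$prediction_time),
       resp_failure = keep_pos(labels$resp_failure_onset -
                                 labels$prediction_time))
}
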