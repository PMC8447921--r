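# Synthetic EHR cohort generator. A latent deterioration indicator drawn at
# the configured prevalence drives, for positive patients, an SpO2 trace that
# crosses 97% (the prediction time) and later 92% (respiratory failure),
# followed by a lognormally lagged ARDS ICD code; respiratory rate and heart
# rate (and other features) drift ahead of the failure in proportion to
# deterioration_signal_strength. Everything is seeded and deterministic.

# 21 time-varying model features: baseline mean/SD, relative sampling rate
# (vitals ~ obs_rate_per_hour, labs 12x sparser), and the mean shift reached
# at full deterioration (scaled by deterioration_signal_strength).
.SYNTH_FEATURES <- data.frame(
  name = c("sysbp", "diasbp", "hr", "temp", "resprate", "spo2",
           "creatinine", "bun", "bilirubin", "glucose", "inr", "wbc", "rbc",
           "platelets", "neutrophil_pct", "lymphocyte_pct", "monocyte_pct",
           "hematocrit", "lactate", "ast", "alt"),
  mean = c(120, 72, 82, 36.9, 17, 97.8, 1.0, 16, 0.7, 115, 1.1, 8.5, 4.5,
           230, 62, 25, 7, 39, 1.3, 32, 30),
  sd = c(15, 10, 13, 0.5, 3.2, 1.3, 0.4, 7, 0.4, 35, 0.2, 3.0, 0.6,
         70, 10, 8, 3, 5, 0.6, 18, 16),
  rel_rate = c(rep(1, 6), rep(1 / 12, 15)),
  drift = c(-8, -4, 18, 0.6, 7, 0, 0.3, 4, 0.2, 15, 0.1, 3, -0.3,
            -40, 8, -7, -1, -2, 1.2, 25, 22),
  stringsAsFactors = FALSE
)

.ARDS_SIM_CODES <- c("J80", "J96.00", "J96.20", "J96.90")

# ARDS presentation subtypes: which feature groups drift, and how strongly.
# Heterogeneous presentations keep the task learnable while making a small
# labeled set genuinely undersample the positive class (columns follow
# .SYNTH_FEATURES order).
.SUBTYPE_PATTERNS <- rbind(
  c(1.0, 1.0, 1.2, 0.0, 1.2, 1, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0,
    0.0, 0.0, 0.0, 0.0, 0.0, 0.8, 0.0, 0.0),   # cardiorespiratory
  c(0.0, 0.0, 0.4, 1.2, 1.0, 1, 0.0, 0.0, 0.0, 1.0, 0.0, 1.4, 0.0,
    0.0, 1.2, 1.2, 1.0, 0.0, 0.0, 0.0, 0.0),   # febrile / inflammatory
  c(0.6, 0.6, 0.0, 0.0, 0.6, 1, 1.3, 1.3, 1.0, 0.0, 1.0, 0.0, 1.0,
    1.2, 0.0, 0.0, 0.0, 1.0, 1.0, 0.0, 0.0),   # renal / coagulopathic
  c(0.0, 0.0, 0.8, 0.5, 0.8, 1, 0.0, 0.0, 1.2, 0.0, 0.8, 0.0, 0.0,
    0.0, 0.0, 0.0, 0.0, 0.0, 0.6, 1.3, 1.3))   # hepatic / hypoxemic
.BENIGN_HISTORY_CODES <- c("I10", "E11.9", "J44.9", "K21.9", "Z87.891", "E78.5")
.PRIOR_OUTCOME_CODES <- c("N17.9", "A41.9", "I26.99", "U07.1")

#' Synthetic cohort configuration
#'
#' @param n_patients number of encounters to generate.
#' @param n_hospitals number of hospital systems (uniform assignment with a
#'   per-hospital, per-feature mean shift).
#' @param ards_prevalence probability that an encounter is ARDS-destined.
#' @param deterioration_signal_strength nonnegative scale on the pre-failure
#'   drift of respiratory rate, heart rate and the other drifting features;
#'   0 removes all informative drift.
#' @param icd_lag_hours length-2 vector `(median, dispersion)` of the
#'   lognormal lag (hours) from respiratory-failure onset to the ARDS ICD
#'   code. The default median of 38 h, combined with the median 21 h
#'   prediction-to-failure gap, puts the prediction-to-ICD median near 59 h.
#' @param fail_gap_hours `(median, dispersion)` of the lognormal gap from the
#'   prediction time (first SpO2 < 97) to respiratory failure (first < 92).
#' @param aux_outcome_probs 6 x 2 matrix of conditional probabilities
#'   (columns: given ARDS, given no ARDS) for the auxiliary outcomes in order
#'   ards_icd, covid19, aki, thrombosis, sepsis, mech_vent.
#' @param obs_rate_per_hour mean vital-sign sampling rate (labs are 12x
#'   sparser).
#' @param history_fraction fraction of patients with pre-admission ICD
#'   history in the 1000-hour look-back window.
#' @param hospital_shift_sd per-hospital mean shift, in units of each
#'   feature's SD.
#' @param seed integer seed; same config + seed gives identical cohorts.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_patients, n_hospitals = 7L,
                          ards_prevalence = 0.02,
                          deterioration_signal_strength = 1,
                          icd_lag_hours = c(38, 0.45),
                          fail_gap_hours = c(21, 0.5),
                          aux_outcome_probs = NULL,
                          obs_rate_per_hour = 0.5,
                          history_fraction = 0.3,
                          hospital_shift_sd = 0.15,
                          seed = 1L) {
  if (is.null(aux_outcome_probs))
    aux_outcome_probs <- cbind(pos = c(1, 0.30, 0.40, 0.25, 0.50, 0.75),
                               neg = c(0, 0.05, 0.08, 0.05, 0.08, 0.03))
  rownames(aux_outcome_probs) <-
    c("ards_icd", "covid19", "aki", "thrombosis", "sepsis", "mech_vent")
  if (n_patients < 0) stop("n_patients must be nonnegative")
  if (ards_prevalence <= 0 || ards_prevalence >= 1)
    stop("ards_prevalence must be in (0, 1)")
  if (deterioration_signal_strength < 0)
    stop("deterioration_signal_strength must be nonnegative")
  if (icd_lag_hours[1] <= 0) stop("icd lag median must be positive")
  if (any(aux_outcome_probs < 0 | aux_outcome_probs > 1))
    stop("aux_outcome_probs must lie in [0, 1]")
  if (history_fraction < 0 || history_fraction > 1)
    stop("history_fraction must lie in [0, 1]")
  structure(list(n_patients = as.integer(n_patients),
                 n_hospitals = as.integer(n_hospitals),
                 ards_prevalence = ards_prevalence,
                 deterioration_signal_strength = deterioration_signal_strength,
                 icd_lag_hours = icd_lag_hours,
                 fail_gap_hours = fail_gap_hours,
                 aux_outcome_probs = aux_outcome_probs,
                 obs_rate_per_hour = obs_rate_per_hour,
                 history_fraction = history_fraction,
                 hospital_shift_sd = hospital_shift_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# times are kept on a whole-second grid so that CSV round trips through
# ISO-8601 timestamps are exact
.snap <- function(hours) round(hours * 3600) / 3600

# Poisson-process observation times on (0, los]
.obs_times <- function(rate, los) {
  n <- rpois(1L, rate * los)
  if (n == 0L) return(numeric(0))
  sort(.snap(runif(n, 0, los)))
}

.sim_encounter <- function(pid, hosp, ards, cfg, hshift) {
  sig <- cfg$deterioration_signal_strength
  fb <- .SYNTH_FEATURES
  vit_rate <- cfg$obs_rate_per_hour

  t_pred <- t_fail <- t_icd <- NA_real_
  if (ards) {
    t_pred <- .snap(rlnorm(1, log(12), 0.5))
    t_fail <- .snap(t_pred + rlnorm(1, log(cfg$fail_gap_hours[1]),
                                    cfg$fail_gap_hours[2]))
    t_icd <- .snap(t_fail + rlnorm(1, log(cfg$icd_lag_hours[1]),
                                   cfg$icd_lag_hours[2]))
    los <- .snap(max(rlnorm(1, log(60), 0.7), t_icd + 24))
  } else {
    los <- .snap(if (runif(1) < 0.03) runif(1, 1, 6) else rlnorm(1, log(60), 0.7))
  }
  # prodromal drift begins a day before the planned sub-97 crossing, so
  # vital-sign changes are visible even when an earlier noise dip sets the
  # realized prediction time
  ramp0 <- if (ards) max(0, t_pred - 24) else NA_real_

  # deterioration fraction in [0, 1.3]: 0 before ramp0, 1 at failure onset
  dfrac <- function(t) {
    if (!ards) return(rep(0, length(t)))
    pmin(pmax((t - ramp0) / max(t_fail - ramp0, 1e-9), 0), 1.3)
  }
  # heterogeneous presentation: a latent subtype selects which features
  # drift, with per-patient magnitude jitter
  subtype <- sample.int(nrow(.SUBTYPE_PATTERNS), 1L)
  drift_scale <- .SUBTYPE_PATTERNS[subtype, ] * rlnorm(1, 0, 0.3)

  feat <- vector("list", nrow(fb) + 5L)
  k <- 0L
  add_obs <- function(name, time, value) {
    k <<- k + 1L
    feat[[k]] <<- list(feature = rep(name, length(time)), value = value,
                       time = time)
  }

  age <- round(min(max(rnorm(1, 67, 16), 18), 100))
  male <- rbinom(1, 1, 0.49)
  add_obs("age", 0, age)
  add_obs("male", 0, male)
  add_obs("female", 0, 1 - male)

  for (i in seq_len(nrow(fb))) {
    nm <- fb$name[i]
    tt <- .obs_times(vit_rate * fb$rel_rate[i], los)
    if (nm == "spo2") {
      # the SpO2 trajectory carries the label structure: ARDS-destined
      # patients are held at >= 97 before t_pred, between (92, 97) before
      # t_fail, and decline below 92 afterwards; crossings are inserted
      # explicitly so the labeler's strict scans find t_pred and t_fail.
      if (ards) {
        # same baseline as controls before the decline (the prediction time
        # may therefore be an earlier noise dip, as in real cohorts); the
        # decline stays in (92, 97] until t_fail and crossings of 97 and 92
        # are inserted explicitly so both onsets are guaranteed to exist
        v <- numeric(length(tt))
        pre <- tt < t_pred
        mid <- tt >= t_pred & tt < t_fail
        post <- tt >= t_fail
        v[pre] <- pmin(pmax(rnorm(sum(pre), fb$mean[i] + hshift[i],
                                  fb$sd[i]), 50), 100)
        frac <- (tt[mid] - t_pred) / max(t_fail - t_pred, 1e-9)
        v[mid] <- pmin(pmax(96.5 - 4 * frac + rnorm(sum(mid), 0, 0.8),
                            92.05), 97.9)
        v[post] <- pmax(pmin(91 - 2.5 * pmin((tt[post] - t_fail) / 24, 1) +
                               rnorm(sum(post), 0, 1), 96.9), 50)
        tt <- c(tt, t_pred, t_fail)
        v <- c(v, runif(1, 95.5, 96.9), runif(1, 90.6, 91.8))
        o <- order(tt)
        tt <- tt[o]; v <- round(v[o], 1)
        t_pred <- min(tt[v < 97])           # realized prediction time
        t_fail <- min(tt[v < 92])           # realized failure onset
        add_obs(nm, tt, v)
      } else {
        v <- pmin(pmax(rnorm(length(tt), fb$mean[i] + hshift[i], fb$sd[i]),
                       50), 100)
        add_obs(nm, tt, round(v, 1))
      }
    } else {
      mu <- fb$mean[i] + hshift[i] + rnorm(1, 0, 0.3 * fb$sd[i])
      v <- rnorm(length(tt),
                 mu + sig * drift_scale[i] * fb$drift[i] * dfrac(tt),
                 fb$sd[i])
      add_obs(nm, tt, round(v, 2))
    }
  }

  # blood-gas features used only by the labeler (PaO2/FiO2 ratio)
  tt <- .obs_times(vit_rate / 12, los)
  if (length(tt)) {
    fio2 <- ifelse(ards & tt >= t_fail, 0.4, 0.21)
    pao2 <- ifelse(ards & tt >= t_fail, rnorm(length(tt), 70, 8),
                   rnorm(length(tt), 95, 10))
    add_obs("fio2", tt, fio2)
    add_obs("pao2", tt, round(pmax(pao2, 30), 1))
  }

  feat <- feat[seq_len(k)]
  obs <- data.frame(
    feature = unlist(lapply(feat, `[[`, "feature"), use.names = FALSE),
    value = unlist(lapply(feat, `[[`, "value"), use.names = FALSE),
    time = unlist(lapply(feat, `[[`, "time"), use.names = FALSE),
    stringsAsFactors = FALSE)
  obs <- obs[order(obs$time, obs$feature), , drop = FALSE]
  rownames(obs) <- NULL

  ev_type <- character(0); ev_code <- character(0); ev_time <- numeric(0)
  add_ev <- function(type, code, time) {
    ev_type <<- c(ev_type, type); ev_code <<- c(ev_code, code)
    ev_time <<- c(ev_time, .snap(time))
  }
  add_ev("admission", "", 0)
  aux <- cfg$aux_outcome_probs[, if (ards) 1L else 2L]
  if (runif(1) < aux[["ards_icd"]] && ards && t_icd < los)
    add_ev("icd", sample(.ARDS_SIM_CODES, 1L), t_icd)
  draw_code <- function(p, codes) {
    if (runif(1) < p) add_ev("icd", sample(codes, 1L), runif(1, 0.1, 0.9) * los)
  }
  draw_code(aux[["covid19"]], c("U07.1", "B97.21", "J12.81"))
  draw_code(aux[["aki"]], c("N17.9", "N19", "R34"))
  draw_code(aux[["thrombosis"]], c("I26.99", "I63.9", "I80.2", "I82.40"))
  draw_code(aux[["sepsis"]], c("A41.9", "R65.20", "A40.3"))
  if (runif(1) < aux[["mech_vent"]]) {
    vt <- if (ards) min(t_pred + runif(1, 2, 20), los * 0.95) else 0.7 * los
    add_ev("mech_vent", "", vt)
  }
  p_abx <- if (ards) 0.35 else 0.25
  if (runif(1) < p_abx)
    add_ev("antibiotics", "", runif(1, 0, if (ards) t_pred else los / 2))
  p_o2 <- if (ards) 0.45 else 0.25
  if (runif(1) < p_o2)
    add_ev("supplemental_o2", "", runif(1, 0, if (ards) t_pred else los / 2))
  if (runif(1) < cfg$history_fraction) {
    nh <- sample(1:4, 1L)
    for (cd in sample(.BENIGN_HISTORY_CODES, nh))
      add_ev("icd", cd, runif(1, -1000, -1))
    if (runif(1) < 0.12) add_ev("icd", "I50.9", runif(1, -1000, -1))
    if (runif(1) < 0.05)
      add_ev("icd", sample(.PRIOR_OUTCOME_CODES, 1L), runif(1, -1000, -1))
  }
  add_ev("discharge", "", los)
  events <- data.frame(event_type = ev_type, code = ev_code, time = ev_time,
                       stringsAsFactors = FALSE)
  events <- events[order(events$time, events$event_type), , drop = FALSE]
  rownames(events) <- NULL

  structure(list(patient_id = pid, hospital_id = hosp, admission_time = 0,
                 discharge_time = los, observations = obs, events = events,
                 sim_truth = list(ards = ards, t_pred = t_pred,
                                  t_fail = t_fail, t_icd = t_icd)),
            class = "ards_encounter")
}

#' Generate a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @return an `ards_cohort`: a list of `ards_encounter` objects. Each
#'   encounter carries `sim_truth` (the generator's latent state) for
#'   oracle-style testing; the labeler never reads it.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  fb <- .SYNTH_FEATURES
  hshift <- matrix(rnorm(config$n_hospitals * nrow(fb), 0,
                         config$hospital_shift_sd * fb$sd),
                   config$n_hospitals, nrow(fb), byrow = TRUE)
  n <- config$n_patients
  out <- vector("list", n)
  if (n > 0) {
    ards <- runif(n) < config$ards_prevalence
    hosp <- sample.int(config$n_hospitals, n, replace = TRUE)
    for (i in seq_len(n))
      out[[i]] <- .sim_encounter(sprintf("P%06d", i), hosp[i], ards[i],
                                 config, hshift[hosp[i], ])
  }
  structure(out, class = "ards_cohort", config = config)
}
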