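# Fixed-layout feature encoding. Each encounter becomes a 49 x 32 matrix:
# 6 constant rows (z-scored age, male, female, antibiotics before the
# prediction time, supplemental O2 before the prediction time, heart-failure
# history), then a (mask, value) row pair for each of the 21 time-varying
# features, then one inter-step time-delta row (minutes, z-scored). Columns
# are update steps — distinct observation times up to and including the
# prediction time — capped at the 32 most recent, left-padded with all-zero
# columns when fewer.

.TIMEVARYING <- c("sysbp", "diasbp", "hr", "temp", "resprate", "spo2",
                  "creatinine", "bun", "bilirubin", "glucose", "inr", "wbc",
                  "rbc", "platelets", "neutrophil_pct", "lymphocyte_pct",
                  "monocyte_pct", "hematocrit", "lactate", "ast", "alt")
.CONSTANT_ROWS <- c("age", "male", "female", "antibiotics_before_prediction",
                    "supplemental_o2_before_prediction",
                    "heart_failure_history")
# features that may appear in observations.csv but are not encoded
.NONENCODED <- c("age", "male", "female", "pao2", "fio2")
.N_STEPS <- 32L
.SD_FLOOR <- 1e-6

#' Row layout of the model feature matrix
#'
#' @return list with `constants` (6 names), `features` (21 time-varying
#'   names), `rows` (all 49 row names in order) and `n_steps` (32).
#' @export
feature_layout <- function() {
  rows <- c(.CONSTANT_ROWS,
            as.vector(rbind(paste0(.TIMEVARYING, "_mask"),
                            paste0(.TIMEVARYING, "_value"))),
            "time_delta")
  list(constants = .CONSTANT_ROWS, features = .TIMEVARYING, rows = rows,
       n_steps = .N_STEPS)
}

#' Fit training-set normalization statistics
#'
#' Unbiased mean/SD per time-varying feature and for age over all
#' observations at or before each encounter's prediction time, plus pooled
#' inter-step minutes (gaps between distinct update times). SDs are floored
#' at 1e-6.
#'
#' @param encounters list of `ards_encounter` (the training set). Encounters
#'   without a prediction time are skipped.
#' @return an `ards_norm_stats` list with `features` (data.frame name, mean,
#'   sd), `age` and `delta_minutes` (length-2 mean/sd vectors).
#' @export
fit_stats <- function(encounters) {
  if (!length(encounters)) stop("empty training set")
  vals <- lapply(.TIMEVARYING, function(x) numeric(0))
  names(vals) <- .TIMEVARYING
  ages <- numeric(0)
  deltas <- numeric(0)
  for (enc in encounters) {
    tp <- prediction_time(enc)
    if (is.na(tp)) next
    o <- enc$observations
    o <- o[o$time >= 0 & o$time <= tp, , drop = FALSE]
    tv <- o[o$feature %in% .TIMEVARYING, , drop = FALSE]
    sp <- split(tv$value, factor(tv$feature, levels = .TIMEVARYING))
    for (nm in .TIMEVARYING)
      if (length(sp[[nm]])) vals[[nm]] <- c(vals[[nm]], sp[[nm]])
    a <- o$value[o$feature == "age"]
    if (length(a)) ages <- c(ages, a[1])
    ut <- sort(unique(tv$time))
    if (length(ut) > 1) deltas <- c(deltas, diff(ut) * 60)
  }
  if (!length(unlist(vals, use.names = FALSE)))
    stop("no pre-prediction-time observations in the training set")
  msd <- function(x) {
    if (length(x) < 2) c(if (length(x)) mean(x) else 0, .SD_FLOOR)
    else c(mean(x), max(sd(x), .SD_FLOOR))
  }
  fm <- t(vapply(vals, msd, numeric(2)))
  structure(list(
    features = data.frame(name = .TIMEVARYING, mean = fm[, 1], sd = fm[, 2],
                          stringsAsFactors = FALSE, row.names = NULL),
    age = msd(ages), delta_minutes = msd(deltas)),
    class = "ards_norm_stats")
}

#' Build the 49 x 32 feature matrix for one encounter
#'
#' @param enc an `ards_encounter` with a prediction time.
#' @param stats an `ards_norm_stats` from [fit_stats()].
#' @return numeric matrix (49 rows, 32 columns) with the [feature_layout()]
#'   row names. Padded columns (oldest positions) are entirely zero.
#' @export
build_matrix <- function(enc, stats) {
  tp <- prediction_time(enc)
  if (is.na(tp)) stop("encounter has no prediction time (SpO2 never < 97)")
  o <- enc$observations
  unknown <- setdiff(unique(o$feature), c(.TIMEVARYING, .NONENCODED))
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  o <- o[o$time >= 0 & o$time <= tp & o$feature %in% .TIMEVARYING, ,
         drop = FALSE]
  lay <- feature_layout()
  M <- matrix(0, length(lay$rows), .N_STEPS,
              dimnames = list(lay$rows, NULL))
  times <- sort(unique(o$time))
  if (length(times) > .N_STEPS) times <- tail(times, .N_STEPS)
  n_real <- length(times)
  if (!n_real) return(M)
  cols <- (.N_STEPS - n_real + 1L):.N_STEPS

  # constants, replicated over real columns
  allobs <- enc$observations
  aval <- allobs$value[allobs$feature == "age"]
  age_z <- if (length(aval)) (aval[1] - stats$age[1]) / stats$age[2] else 0
  male <- if (length(v <- allobs$value[allobs$feature == "male"])) v[1] else 0
  female <- if (length(v <- allobs$value[allobs$feature == "female"])) v[1] else 0
  ev <- enc$events
  abx <- any(ev$event_type == "antibiotics" & ev$time <= tp)
  o2 <- any(ev$event_type == "supplemental_o2" & ev$time <= tp)
  icd <- ev[ev$event_type == "icd" & ev$time <= tp, , drop = FALSE]
  bare <- gsub(".", "", icd$code, fixed = TRUE)
  hf <- any(startsWith(bare, "I50") | startsWith(bare, "428"))
  M["age", cols] <- age_z
  M["male", cols] <- male
  M["female", cols] <- female
  M["antibiotics_before_prediction", cols] <- as.numeric(abx)
  M["supplemental_o2_before_prediction", cols] <- as.numeric(o2)
  M["heart_failure_history", cols] <- as.numeric(hf)

  fs <- stats$features
  step_of <- match(o$time, times)           # NA for dropped (oldest) steps
  keep <- !is.na(step_of)
  val <- o$value[keep]
  step_of <- step_of[keep]
  fidx <- match(o$feature[keep], .TIMEVARYING)
  key <- (fidx - 1L) * .N_STEPS + step_of
  if (anyDuplicated(key)) {                 # same feature, same timestamp
    agg <- vapply(split(val, key), mean, numeric(1))
    key <- as.integer(names(agg))
    val <- unname(agg)
    fidx <- (key - 1L) %/% .N_STEPS + 1L
    step_of <- (key - 1L) %% .N_STEPS + 1L
  }
  z <- (val - fs$mean[fidx]) / fs$sd[fidx]
  M[cbind(2L * fidx + 5L, cols[step_of])] <- 1      # mask rows
  M[cbind(2L * fidx + 6L, cols[step_of])] <- z      # value rows
  if (n_real > 1) {
    dmin <- diff(times) * 60
    M["time_delta", cols[-1]] <-
      (dmin - stats$delta_minutes[1]) / stats$delta_minutes[2]
  }
  M
}

#' Save / load a built dataset keyed by patient
#'
#' Persists the feature tensor, labels and metadata as a single-file
#' container with per-patient keys. (An HDF5 carrier would be the natural
#' choice; no HDF5-capable R package is available in the supported
#' environment, so the container is RDS.)
#'
#' @param ds dataset list from [build_dataset()].
#' @param path file path.
#' @return `save_dataset` returns `path` invisibly; `load_dataset` the
#'   dataset list.
#' @export
save_dataset <- function(ds, path) {
  stopifnot(is.array(ds$X), length(ds$ids) == dim(ds$X)[1])
  saveRDS(c(ds, list(format = "ardssl-dataset-1")), path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  ds <- readRDS(path)
  if (!identical(ds$format, "ardssl-dataset-1"))
    stop("not an ardssl dataset container: ", path)
  ds$format <- NULL
  ds
}

#' Build a model-ready dataset from encounters
#'
#' Applies the inclusion filter (stay >= 3 h and a prediction time), builds
#' each feature matrix, and collects labels and metadata.
#'
#' @param encounters list of `ards_encounter`.
#' @param stats an `ards_norm_stats`.
#' @return list with `X` (array N x 49 x 32), `Y` (N x 7 outcome matrix in
#'   [outcome_names()] order), `M` (all-ones loss-mask matrix), `ids`,
#'   `hospital`.
#' @export
build_dataset <- function(encounters, stats) {
  keep <- vapply(encounters, inclusion_filter, logical(1))
  encounters <- encounters[keep]
  n <- length(encounters)
  lay <- feature_layout()
  X <- array(0, c(n, length(lay$rows), .N_STEPS))
  Y <- matrix(0, n, 7L, dimnames = list(NULL, outcome_names()))
  ids <- character(n)
  hosp <- integer(n)
  for (i in seq_len(n)) {
    enc <- encounters[[i]]
    X[i, , ] <- build_matrix(enc, stats)
    lb <- label_outcomes(enc)
    Y[i, ] <- as.numeric(unlist(lb[outcome_names()]))
    ids[i] <- enc$patient_id
    hosp[i] <- if (is.null(enc$hospital_id)) NA_integer_ else enc$hospital_id
  }
  list(X = X, Y = Y, M = matrix(1, n, 7L), ids = ids, hospital = hosp)
}
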