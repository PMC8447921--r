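test_that("prediction time is the first strict SpO2 < 97 crossing", {
  enc <- spo2_trace(c(1, 2, 3), c(98, 96, 91))
  expect_equal(prediction_time(enc), 2)
  expect_true(is.na(prediction_time(spo2_trace(c(1, 5), c(98, 97)))))
  # a value of exactly 97 does not trigger
  expect_equal(prediction_time(spo2_trace(c(1, 4), c(97, 95))), 4)
})

test_that("respiratory-failure onset uses SpO2 < 92 or PaO2/FiO2 < 300", {
  expect_equal(respiratory_failure_onset(spo2_trace(c(2, 5), c(93, 91))), 5)
  # 80 / 0.30 = 266.7 < 300 with the last-known FiO2 rule
  enc <- spo2_trace(c(1, 6), c(95, 94), extra_obs = data.frame(
    feature = c("fio2", "pao2"), value = c(0.30, 80), time = c(1, 3)))
  expect_equal(respiratory_failure_onset(enc), 3)
  # default FiO2 0.21 when never recorded: 80/0.21 = 381 >= 300
  enc2 <- spo2_trace(c(1, 6), c(95, 94), extra_obs = data.frame(
    feature = "pao2", value = 80, time = 3))
  expect_true(is.na(respiratory_failure_onset(enc2)))
  expect_true(is.na(respiratory_failure_onset(spo2_trace(1, 95))))
  bad <- spo2_trace(1, 95, extra_obs = data.frame(
    feature = c("fio2", "pao2"), value = c(0, 80), time = c(1, 2)))
  expect_error(respiratory_failure_onset(bad), "FiO2")
})

test_that("ARDS ICD onset applies the 1000-hour novelty rule", {
  expect_equal(ards_icd_onset(make_encounter(events = icd_event("J80", 59))),
               59)
  pre <- rbind(icd_event("J80", 59), icd_event("J96.0", -200))
  expect_true(is.na(ards_icd_onset(make_encounter(events = pre))))
  two <- rbind(icd_event("J96.2", 30), icd_event("J80", 10))
  expect_equal(ards_icd_onset(make_encounter(events = two)), 10)
  # codes older than the 1000-hour window do not block
  old <- rbind(icd_event("J80", 59), icd_event("J96.0", -1500))
  expect_equal(ards_icd_onset(make_encounter(events = old)), 59)
  # dot-insensitive prefix matching: J96.01 matches J96.0
  expect_equal(ards_icd_onset(make_encounter(events = icd_event("J96.01", 7))),
               7)
})

test_that("label_outcomes composes the pieces with no event leakage", {
  enc <- spo2_trace(c(1, 2, 8), c(98, 96, 90),
                    events = icd_event("J80", 59))
  lb <- label_outcomes(enc)
  expect_true(lb$primary_ards_resp_failure)
  expect_true(lb$ards_icd)
  expect_false(any(unlist(lb[c("covid19", "aki", "thrombosis", "sepsis",
                               "mech_vent_after_drop")])))
  expect_equal(lb$prediction_time, 2)
  expect_equal(lb$resp_failure_onset, 8)

  # respiratory failure without an ARDS code is not a primary positive
  lb2 <- label_outcomes(spo2_trace(c(1, 2, 8), c(98, 96, 90)))
  expect_false(lb2$primary_ards_resp_failure)

  # an ARDS code before the prediction time must not count
  early <- spo2_trace(c(10, 12, 15), c(98, 96, 90),
                      events = icd_event("J80", 5))
  expect_false(label_outcomes(early)$primary_ards_resp_failure)

  # mechanical ventilation only counts strictly after the SpO2 drop
  vent_before <- spo2_trace(c(1, 2), c(98, 96), events = data.frame(
    event_type = "mech_vent", code = "", time = 2))
  expect_false(label_outcomes(vent_before)$mech_vent_after_drop)
  vent_after <- spo2_trace(c(1, 2), c(98, 96), events = data.frame(
    event_type = "mech_vent", code = "", time = 2.5))
  expect_true(label_outcomes(vent_after)$mech_vent_after_drop)
})

test_that("inclusion filter requires 3-hour stay and a prediction time", {
  expect_false(inclusion_filter(spo2_trace(1, 96, los = 2.9)))
  expect_false(inclusion_filter(spo2_trace(c(1, 50), c(98, 99), los = 100)))
  expect_true(inclusion_filter(spo2_trace(1, 96, los = 3.0)))
})

test_that("lookahead intervals subtract the prediction time", {
  lb <- data.frame(prediction_time = c(2, 5, NA, 1),
                   resp_failure_onset = c(23, 4, 7, NA),
                   ards_icd_onset = c(61, NA, 9, 3))
  iv <- lookahead_intervals(lb)
  expect_equal(iv$resp_failure, 21)     # negative difference excluded
  expect_equal(iv$ards_icd, c(59, 2))
  empty <- lookahead_intervals(lb[0, ])
  expect_length(empty$ards_icd, 0)
  expect_length(empty$resp_failure, 0)
})

test_that("labeler agrees with a brute-force rescan on a synthetic cohort", {
  co <- test_cohort(300)
  lb <- label_cohort(co)
  for (i in seq_along(co)) {
    o <- oracle_label(co[[i]])
    for (nm in outcome_names())
      expect_identical(lb[[nm]][i], o[[nm]],
                       label = sprintf("%s of encounter %d", nm, i))
    expect_equal(lb$prediction_time[i], o$prediction_time)
    expect_equal(lb$resp_failure_onset[i], o$resp_failure_onset)
    expect_equal(lb$ards_icd_onset[i], o$ards_icd_onset)
  }
})

test_that("labeling invariants hold on a synthetic cohort", {
  co <- test_cohort(300)
  lb <- label_cohort(co)
  both <- !is.na(lb$prediction_time) & !is.na(lb$resp_failure_onset)
  expect_true(all(lb$prediction_time[both] <= lb$resp_failure_onset[both]))
  # idempotence: relabeling changes nothing
  expect_identical(lb, label_cohort(co))
  # monotonicity: removing the ARDS ICD event never turns primary on
  for (i in which(lb$ards_icd)) {
    enc <- co[[i]]
    ev <- enc$events
    bare <- gsub(".", "", ev$code, fixed = TRUE)
    drop_row <- ev$event_type == "icd" &
      (startsWith(bare, "J80") | startsWith(bare, "J96") |
         startsWith(bare, "51881"))
    enc$events <- ev[!drop_row, , drop = FALSE]
    expect_false(label_outcomes(enc)$primary_ards_resp_failure)
  }
})
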