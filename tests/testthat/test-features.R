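test_that("fit_stats computes unbiased moments with a floored SD", {
  enc <- spo2_trace(2, 96, extra_obs = data.frame(
    feature = "hr", value = c(1, 2, 3), time = c(0.5, 1, 1.5)))
  st <- fit_stats(list(enc))
  hr <- st$features[st$features$name == "hr", ]
  expect_equal(hr$mean, 2)
  expect_equal(hr$sd, 1)
  # constant feature: SD floored
  enc2 <- spo2_trace(1, 96, extra_obs = data.frame(
    feature = "glucose", value = c(5, 5, 5), time = c(0.2, 0.4, 0.6)))
  st2 <- fit_stats(list(enc2))
  expect_equal(st2$features$sd[st2$features$name == "glucose"], 1e-6)
  expect_error(fit_stats(list()), "empty")
})

test_that("fit_stats matches a flat recomputation over the raw tables", {
  co <- Filter(inclusion_filter, test_cohort(300))[1:80]
  st <- fit_stats(co)
  flat <- do.call(rbind, lapply(co, function(enc) {
    o <- enc$observations
    sp <- o[o$feature == "spo2", ]
    tp <- min(sp$time[sp$value < 97])
    cbind(o[o$time <= tp & o$time >= 0, c("feature", "value", "time")],
          pid = enc$patient_id)
  }))
  for (nm in c("hr", "spo2", "lactate")) {
    v <- flat$value[flat$feature == nm]
    row <- st$features[st$features$name == nm, ]
    expect_equal(row$mean, mean(v))
    expect_equal(row$sd, sd(v))
  }
  # pooled inter-step minutes over distinct update times
  deltas <- unlist(lapply(split(flat, flat$pid), function(d) {
    tv <- d[d$feature %in% feature_layout()$features, ]
    ut <- sort(unique(tv$time))
    if (length(ut) > 1) diff(ut) * 60 else numeric(0)
  }))
  expect_equal(st$delta_minutes, c(mean(deltas), sd(deltas)))
})

test_that("build_matrix keeps the 32 most recent steps and left-pads", {
  # 41 distinct update times: only the 32 most recent are kept
  times <- seq(0.5, 20, by = 0.5)     # 40 steps before the crossing
  enc <- spo2_trace(c(times, 21), c(rep(98, 40), 96), extra_obs = NULL)
  m <- build_matrix(enc, tiny_stats())
  expect_equal(dim(m), c(49, 32))
  expect_equal(sum(m["spo2_mask", ]), 32)
  # most recent step is the prediction-time measurement itself
  expect_equal(unname(m["spo2_value", 32]), 96)
  # the first kept step has no predecessor inside the window: delta is 0
  expect_equal(unname(m["time_delta", 1]), 0)
  expect_equal(unname(m["time_delta", 2]), 30)   # 0.5 h with mean 0 / sd 1 stats

  # single update step: 31 left-padded all-zero columns
  one <- build_matrix(spo2_trace(1, 96), tiny_stats())
  expect_true(all(one[, 1:31] == 0))
  expect_equal(unname(one["spo2_mask", 32]), 1)
  expect_equal(unname(one["time_delta", 32]), 0)
  expect_error(build_matrix(spo2_trace(1, 99), tiny_stats()),
               "prediction time")
})

test_that("a hand-built 3-step encounter reproduces the documented layout", {
  obs <- data.frame(
    feature = c("age", "male", "female", "hr", "resprate", "hr", "spo2"),
    value = c(60, 1, 0, 80, 22, 90, 95),
    time = c(0, 0, 0, 1, 1, 2, 3))
  events <- data.frame(event_type = c("antibiotics", "icd"),
                       code = c("", "I50.9"), time = c(0.5, -10))
  enc <- make_encounter(obs, events, los = 50)
  m <- build_matrix(enc, tiny_stats())

  expected <- matrix(0, 49, 32, dimnames = list(feature_layout()$rows, NULL))
  cols <- 30:32                       # 3 update steps: hours 1, 2, 3
  expected["age", cols] <- 60         # stats mean 0 / sd 1
  expected["male", cols] <- 1
  expected["antibiotics_before_prediction", cols] <- 1
  expected["heart_failure_history", cols] <- 1
  expected["hr_mask", c(30, 31)] <- 1
  expected["hr_value", c(30, 31)] <- c(80, 90)
  expected["resprate_mask", 30] <- 1
  expected["resprate_value", 30] <- 22
  expected["spo2_mask", 32] <- 1
  expected["spo2_value", 32] <- 95
  expected["time_delta", c(31, 32)] <- 60
  expect_equal(m, expected)
})

test_that("matrix invariants hold across a random cohort", {
  co <- Filter(inclusion_filter, test_cohort(300))[1:60]
  st <- fit_stats(co)
  lay <- feature_layout()
  mask_rows <- paste0(lay$features, "_mask")
  value_rows <- paste0(lay$features, "_value")
  for (enc in co) {
    m <- build_matrix(enc, st)
    expect_equal(dim(m), c(49, 32))
    expect_true(all(m[mask_rows, ] %in% c(0, 1)))
    expect_true(all(m[value_rows, ][m[mask_rows, ] == 0] == 0))
    # padded columns are entirely zero
    real <- colSums(abs(m)) > 0
    if (any(!real)) expect_true(all(which(!real) < min(which(real))))
  }
  # permuting observation rows changes nothing
  enc <- co[[5]]
  perm <- enc
  set.seed(1)
  perm$observations <- perm$observations[sample(nrow(perm$observations)), ]
  expect_equal(build_matrix(enc, st), build_matrix(perm, st))
  # unknown feature names are rejected
  bad <- enc
  bad$observations <- rbind(bad$observations,
                            data.frame(feature = "blood_moxie", value = 1,
                                       time = 1))
  expect_error(build_matrix(bad, st), "unknown feature")
})

test_that("built datasets persist with per-patient keys", {
  co <- Filter(inclusion_filter, test_cohort(300))[1:15]
  ds <- build_dataset(co, fit_stats(co))
  f <- withr::local_tempfile(fileext = ".rds")
  save_dataset(ds, f)
  back <- load_dataset(f)
  expect_identical(back$X, ds$X)
  expect_identical(back$ids, ds$ids)
  expect_identical(back$Y, ds$Y)
  expect_error(load_dataset(system.file("extdata", "feature_layout.json",
                                        package = "ardssl")), "")
})
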