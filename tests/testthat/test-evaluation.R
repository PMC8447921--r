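test_that("AUROC: closed forms, errors and the pair-counting oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.1, 0.9), c(1, 0)), 0)
  expect_equal(auroc(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  set.seed(21)
  for (i in 1:10) {
    s <- round(runif(200), 2)          # rounded scores force ties
    y <- rbinom(200, 1, 0.3)
    expect_equal(auroc(s, y), oracle_auroc(s, y))
  }
})

test_that("AUPRC: closed forms and the threshold-sweep oracle", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  n <- 10
  s <- seq(1, 0.1, length.out = n)
  y <- c(rep(0, n - 1), 1)             # single positive ranked last
  expect_equal(auprc(s, y), 1 / n)
  expect_error(auprc(1:3, c(0, 0, 0)), "positive")
  set.seed(22)
  for (i in 1:10) {
    s <- round(runif(150), 2)
    y <- rbinom(150, 1, 0.2)
    if (sum(y) == 0) y[1] <- 1
    expect_equal(auprc(s, y), oracle_auprc(s, y))
  }
  # constant scores give AUPRC equal to prevalence
  expect_equal(auprc(rep(0.3, 100), rep(c(1, 0), c(20, 80))), 0.2)
})

test_that("confusion metrics at an operating point", {
  s <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.15, 0.1, 0.05)
  y <- c(1, 1, 0, 1, 1, 0, 0, 0, 0, 0)
  # threshold 0.5: TP=3, FP=1, FN=1, TN=5
  cm <- confusion_metrics(s, y, 0.5)
  expect_equal(unname(cm["sensitivity"]), 0.75)
  expect_equal(unname(cm["specificity"]), 5 / 6)
  expect_equal(unname(cm["ppv"]), 0.75)
  expect_equal(unname(cm["npv"]), 5 / 6)
  # threshold below every score: everything predicted positive
  cm2 <- confusion_metrics(s, y, 0)
  expect_equal(unname(cm2["sensitivity"]), 1)
  expect_equal(unname(cm2["specificity"]), 0)
})

test_that("validation-chosen threshold transfers its sensitivity", {
  set.seed(23)
  draw <- function(n) {
    y <- rbinom(n, 1, 0.3)
    list(s = rnorm(n, mean = y), y = y)
  }
  vl <- draw(4000); te <- draw(4000)
  thr <- threshold_for_sensitivity(vl$s, vl$y, target = 0.78)
  expect_gte(unname(confusion_metrics(vl$s, vl$y, thr)["sensitivity"]), 0.78)
  test_sens <- unname(confusion_metrics(te$s, te$y, thr)["sensitivity"])
  expect_lt(abs(test_sens - 0.78), 0.05)   # Monte-Carlo transfer tolerance
  rep <- evaluation_report(te$s, te$y, thr)
  expect_equal(rep$n_pos + rep$n_neg, 4000)
  expect_true(all(unlist(rep[c("auroc", "auprc", "sensitivity",
                               "specificity", "ppv", "npv")]) >= 0))
})

test_that("attention heat map accumulates only mask-1 cells at focus steps", {
  lay <- feature_layout()
  mc <- model_config(hidden = 8L)
  m <- init_model_params(mc, seed = 2)
  spo2_mask <- match("spo2_mask", lay$rows)
  spo2_val <- match("spo2_value", lay$rows)
  hr_val <- match("hr_value", lay$rows)
  mk_sample <- function(z) {
    x <- matrix(0, 49, 32)
    x[spo2_mask, 32] <- 1
    x[spo2_val, 32] <- z
    x[hr_val, 32] <- 5       # mask 0: must be ignored
    x[2, 32] <- 1            # male flag marks the column as real
    x
  }
  X <- array(0, c(1, 49, 32)); X[1, , ] <- mk_sample(-2)
  hm <- attention_heatmap(m, X)
  expect_equal(unname(hm$mean_z["spo2"]), -2)
  expect_true(is.na(hm$mean_z["hr"]))
  expect_true(all(is.na(hm$mean_z[setdiff(lay$features, "spo2")])))
  # two encounters with opposite inflections cancel
  X2 <- array(0, c(2, 49, 32))
  X2[1, , ] <- mk_sample(-2); X2[2, , ] <- mk_sample(2)
  hm2 <- attention_heatmap(m, X2)
  expect_equal(unname(hm2$mean_z["spo2"]), 0)
  expect_equal(unname(hm2$n_obs["spo2"]), 2L)
})

test_that("embedding projection matches an eigendecomposition oracle", {
  mc <- model_config(hidden = 8L)
  m <- init_model_params(mc, seed = 3)
  set.seed(24)
  X <- array(rnorm(10 * 49 * 32), c(10, 49, 32))
  pj <- embed_project(m, X)
  emb <- model_forward(m, X)$penultimate
  ev <- eigen(cov(emb), symmetric = TRUE)
  centered <- sweep(emb, 2, colMeans(emb))
  ref <- centered %*% ev$vectors[, 1:2]
  for (k in 1:2) {
    err <- min(max(abs(pj$coords[, k] - ref[, k])),   # sign of a PC is
               max(abs(pj$coords[, k] + ref[, k])))   # arbitrary
    expect_lt(err, 1e-8)
  }
  expect_gte(pj$sdev[1], pj$sdev[2])
  expect_equal(crossprod(pj$rotation), diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(embed_project(m, X[1:2, , , drop = FALSE]), "at least 3")
})
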