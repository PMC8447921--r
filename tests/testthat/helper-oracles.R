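# Independent reference implementations used as oracles. These deliberately
# use scalar loops and naive algorithms, never the package's vectorized /
# compiled code paths.

# hand encounter builder ----------------------------------------------------

make_encounter <- function(obs = NULL, events = NULL, los = 100,
                           pid = "T001", hospital = 1L) {
  if (is.null(obs))
    obs <- data.frame(feature = character(0), value = numeric(0),
                      time = numeric(0), stringsAsFactors = FALSE)
  if (is.null(events))
    events <- data.frame(event_type = character(0), code = character(0),
                         time = numeric(0), stringsAsFactors = FALSE)
  structure(list(patient_id = pid, hospital_id = hospital,
                 admission_time = 0, discharge_time = los,
                 observations = obs, events = events),
            class = "ards_encounter")
}

spo2_trace <- function(times, values, extra_obs = NULL, events = NULL,
                       los = 100) {
  obs <- data.frame(feature = "spo2", value = values, time = times,
                    stringsAsFactors = FALSE)
  if (!is.null(extra_obs)) obs <- rbind(obs, extra_obs)
  make_encounter(obs, events, los = los)
}

icd_event <- function(code, time)
  data.frame(event_type = "icd", code = code, time = time,
             stringsAsFactors = FALSE)

# metric oracles -------------------------------------------------------------

# O(n^2) pair-counting AUROC, ties counted half
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
  tot / (length(pos) * length(neg))
}

# exhaustive threshold sweep AUPRC: precision step function over recall at
# every distinct score cut, integrated piecewise
oracle_auprc <- function(scores, labels) {
  cuts <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_rec <- 0; area <- 0
  for (cut in cuts) {
    pred <- scores >= cut
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / n_pos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# model oracles ---------------------------------------------------------------

# scalar-loop learned normalization
oracle_normalize <- function(v, norm) {
  out <- numeric(length(v))
  for (i in seq_along(v))
    out[i] <- norm$a[i] * ((v[i] - norm$mu[i]) / (norm$sigma[i] + norm$eps)) +
      norm$b[i]
  out
}

# full forward pass of the attention-GRU, written as explicit per-step
# loops over vectors (independent of the compiled implementation)
oracle_forward <- function(model, m) {
  cfg <- model$config
  H <- cfg$hidden; T_ <- cfg$n_steps
  blk <- function(nm) param_block(model, nm)
  sig <- function(x) 1 / (1 + exp(-x))
  nrm <- function(v, mu, sg, a, b) a * ((v - mu) / (sg + cfg$eps)) + b
  gru_cell <- function(x, h, W, U, bw, bu) {
    pw <- drop(W %*% x) + bw
    pu <- drop(U %*% h) + bu
    r <- sig(pw[1:H] + pu[1:H])
    z <- sig(pw[(H + 1):(2 * H)] + pu[(H + 1):(2 * H)])
    n <- tanh(pw[(2 * H + 1):(3 * H)] + r * pu[(2 * H + 1):(3 * H)])
    (1 - z) * n + z * h
  }
  h1 <- numeric(H); h2 <- numeric(H)
  H2s <- matrix(0, H, T_)
  for (t in seq_len(T_)) {
    xn <- nrm(m[, t], blk("mu_in"), blk("sg_in"), blk("a_in"), blk("b_in"))
    h1 <- gru_cell(xn, h1, blk("W1"), blk("U1"), blk("bw1"), blk("bu1"))
    h2 <- gru_cell(h1, h2, blk("W2"), blk("U2"), blk("bw2"), blk("bu2"))
    H2s[, t] <- h2
  }
  l <- H2s[, T_]
  att <- attention_params(model)
  s <- vapply(seq_len(T_), function(t) attention_score(l, H2s[, t], att),
              numeric(1))
  w <- exp(s - max(s)); w <- w / sum(w)
  ctx <- drop(H2s %*% w)
  f <- c(l, ctx)
  pen <- pmax(drop(blk("Wc1") %*% f) + blk("bc1"), 0)
  logits <- drop(blk("Wc2") %*% pen) + blk("bc2")
  list(logits = logits, attention_weights = w, penultimate = pen,
       context = ctx)
}

# labeling oracle -------------------------------------------------------------

# brute-force relabeling straight off the raw tables, organized completely
# differently from the labels module (flat scans, no helper reuse)
oracle_label <- function(enc) {
  o <- enc$observations; e <- enc$events
  first_below <- function(feat, cut) {
    best <- Inf
    for (i in seq_len(nrow(o)))
      if (o$feature[i] == feat && o$time[i] >= 0 && o$value[i] < cut &&
          o$time[i] < best) best <- o$time[i]
    best
  }
  tp <- first_below("spo2", 97)
  tf <- first_below("spo2", 92)
  for (i in seq_len(nrow(o))) {
    if (o$feature[i] != "pao2" || o$time[i] < 0) next
    f <- 0.21
    ft <- -Inf
    for (j in seq_len(nrow(o)))
      if (o$feature[j] == "fio2" && o$time[j] <= o$time[i] &&
          o$time[j] >= ft) { f <- o$value[j]; ft <- o$time[j] }
    if (o$value[i] / f < 300 && o$time[i] < tf) tf <- o$time[i]
  }
  code_onset <- function(codes) {
    best <- Inf; blocked <- FALSE
    for (i in seq_len(nrow(e))) {
      if (e$event_type[i] != "icd") next
      bare <- gsub(".", "", e$code[i], fixed = TRUE)
      m <- any(vapply(codes, function(cd) startsWith(bare, cd), logical(1)))
      if (!m) next
      if (e$time[i] >= -1000 && e$time[i] < 0) blocked <- TRUE
      if (e$time[i] >= 0 && e$time[i] < best) best <- e$time[i]
    }
    if (blocked) Inf else best
  }
  ards <- code_onset(c("J80", "J960", "J962", "J969", "51881"))
  mech <- FALSE
  for (i in seq_len(nrow(e)))
    if (e$event_type[i] == "mech_vent" && is.finite(tp) && e$time[i] > tp)
      mech <- TRUE
  list(primary_ards_resp_failure =
         is.finite(tp) && is.finite(ards) && is.finite(tf) &&
         ards >= tp && tf >= tp,
       ards_icd = is.finite(ards),
       covid19 = is.finite(code_onset(c("U071", "B9721", "B9729", "J1281",
                                        "B342"))),
       aki = is.finite(code_onset(c("N17", "N19", "R34"))),
       thrombosis = is.finite(code_onset(c("I12", "I26", "I63", "I67",
                                           "I74", "I80", "I81", "I82"))),
       sepsis = is.finite(code_onset(c("A40", "A41", "R652", "T8112",
                                       "T8144", "O85", "O8604"))),
       mech_vent_after_drop = mech,
       prediction_time = if (is.finite(tp)) tp else NA_real_,
       resp_failure_onset = if (is.finite(tf)) tf else NA_real_,
       ards_icd_onset = if (is.finite(ards)) ards else NA_real_)
}

# shared small fixtures -------------------------------------------------------

# a tiny cached cohort for tests that need realistic encounters
test_cohort <- local({
  cache <- NULL
  function(n = 300, seed = 42, ...) {
    key <- paste(n, seed, ...)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$co)
    co <- generate_cohort(cohort_config(n, ards_prevalence = 0.08,
                                        seed = seed, ...))
    cache <<- list(key = key, co = co)
    co
  }
})

tiny_stats <- function() {
  lay <- feature_layout()
  structure(list(
    features = data.frame(name = lay$features, mean = 0, sd = 1,
                          stringsAsFactors = FALSE),
    age = c(0, 1), delta_minutes = c(0, 1)),
    class = "ards_norm_stats")
}
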