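# Teacher-student semisupervised loop. The teacher scores the unlabeled
# pool on the ARDS outcome; samples above twice the pool-mean probability
# become pseudo-positives, samples below the mean pseudo-negatives, the band
# in between is "unconfident" and unused. Each cycle trains a freshly
# initialized student on labeled + confident-pseudolabeled data (auxiliary
# losses masked for pseudolabeled samples), fine-tunes it on the labeled set,
# records validation AUROC, and promotes the student to teacher.

#' Confidence-banded pseudolabel partition
#'
#' With `m` the mean predicted ARDS probability over the pool: probability
#' strictly above `2m` is positive, strictly below `m` negative, and the
#' closed band `[m, 2m]` unconfident.
#'
#' @param probs numeric vector of predicted probabilities.
#' @return list with integer index vectors `positive`, `negative`,
#'   `unconfident` plus the thresholds `m` and `m2`.
#' @export
pseudolabel_partition <- function(probs) {
  if (!length(probs)) stop("empty unlabeled pool")
  m <- mean(probs)
  list(positive = which(probs > 2 * m),
       negative = which(probs < m),
       unconfident = which(probs >= m & probs <= 2 * m),
       m = m, m2 = 2 * m)
}

#' Pseudolabel an unlabeled pool with a teacher model
#'
#' @param teacher trained `ards_model`.
#' @param pool an `ards_guarded` pool (features only).
#' @return as [pseudolabel_partition()], with `probs` attached.
#' @export
pseudolabel <- function(teacher, pool) {
  if (!pool$n) stop("empty unlabeled pool")
  probs <- model_predict(teacher, pool$X)[, 1L]
  out <- pseudolabel_partition(probs)
  out$probs <- probs
  out
}

.bind_sets <- function(a, b) {
  list(X = {
    d <- dim(a$X)
    X <- array(0, c(d[1] + dim(b$X)[1], d[2], d[3]))
    X[seq_len(d[1]), , ] <- a$X
    X[d[1] + seq_len(dim(b$X)[1]), , ] <- b$X
    X
  },
  Y = rbind(a$Y, b$Y), M = rbind(a$M, b$M))
}

#' Teacher-student semisupervised training
#'
#' Cycle 0 trains the initial teacher on the labeled set only. Each
#' subsequent cycle pseudolabels the pool with the current teacher,
#' initializes a new student, trains it on labeled plus confident
#' pseudolabeled samples (ARDS loss only for the latter), fine-tunes on the
#' labeled set, records validation AUROC on the ARDS outcome, and promotes
#' the student. The checkpoint with the best cycle validation AUROC is
#' returned; with `n_cycles = 0` that is the initial teacher.
#'
#' @param labeled,val dataset lists (`X`, `Y`, `M`).
#' @param pool an `ards_guarded` unlabeled pool; true labels are never read.
#' @param cfg a [train_config()].
#' @param n_cycles number of teacher-student cycles (reference setup: 4,
#'   best validation on cycle 3).
#' @param model_cfg a [model_config()].
#' @param finetune_lr_factor learning-rate multiplier for the fine-tuning
#'   phase (default 0.1): fine-tuning the combined-trained student on the
#'   small labeled set at the full rate largely overwrites what was learned
#'   from the pool.
#' @param verbose log per-cycle JSON lines to stderr.
#' @return list with `model` (best checkpoint), `teacher` (initial teacher),
#'   `history` (per-cycle data.frame: cycle, n_positive, n_negative,
#'   n_unconfident, m, val_auroc), `best_cycle`, `teacher_auroc`.
#' @export
ssl_train <- function(labeled, pool, val, cfg = train_config(),
                      n_cycles = 4L, model_cfg = model_config(),
                      finetune_lr_factor = 0.1, verbose = FALSE) {
  stopifnot(inherits(pool, "ards_guarded"))
  val_auroc <- function(mdl)
    auroc(model_predict(mdl, val$X)[, 1L], val$Y[, 1L])
  teacher <- train_supervised(init_model_params(model_cfg, seed = cfg$seed),
                              labeled, val, cfg, verbose = verbose)$model
  t_auroc <- val_auroc(teacher)
  if (verbose)
    message(sprintf('{"stage":"ssl","cycle":0,"val_auroc":%.4f}', t_auroc))
  if (n_cycles == 0L)
    return(list(model = teacher, teacher = teacher,
                history = data.frame(), best_cycle = 0L,
                teacher_auroc = t_auroc))
  hist <- vector("list", n_cycles)
  best <- list(auroc = -Inf, model = NULL, cycle = 0L)
  current <- teacher
  for (cyc in seq_len(n_cycles)) {
    ps <- pseudolabel(current, pool)
    conf <- c(ps$positive, ps$negative)
    student <- init_model_params(model_cfg, seed = cfg$seed + 1000L * cyc)
    cfg_c <- cfg; cfg_c$seed <- cfg$seed + 7L * cyc
    if (length(conf)) {
      np <- length(ps$positive)
      pseudo <- list(
        X = pool$X[conf, , , drop = FALSE],
        Y = cbind(c(rep(1, np), rep(0, length(ps$negative))),
                  matrix(0, length(conf), 6L)),
        M = .ards_mask(length(conf)))
      combined <- .bind_sets(labeled, pseudo)
      student <- train_supervised(student, combined, val, cfg_c)$model
    } else {
      warning("cycle ", cyc, ": no confident pseudolabels; ",
              "training on the labeled set only")
      student <- train_supervised(student, labeled, val, cfg_c)$model
    }
    a_comb <- val_auroc(student)
    cfg_f <- cfg
    cfg_f$seed <- cfg$seed + 7L * cyc + 3L
    cfg_f$lr0 <- cfg$lr0 * finetune_lr_factor
    student <- train_supervised(student, labeled, val, cfg_f,
                                init_output_bias = FALSE)$model
    a <- val_auroc(student)
    hist[[cyc]] <- data.frame(cycle = cyc, n_positive = length(ps$positive),
                              n_negative = length(ps$negative),
                              n_unconfident = length(ps$unconfident),
                              m = ps$m, val_auroc_combined = a_comb,
                              val_auroc = a)
    if (verbose)
      message(sprintf(
        '{"stage":"ssl","cycle":%d,"n_pos":%d,"n_neg":%d,"n_unconf":%d,"m":%.4f,"val_auroc":%.4f}',
        cyc, length(ps$positive), length(ps$negative),
        length(ps$unconfident), ps$m, a))
    if (a > best$auroc) best <- list(auroc = a, model = student, cycle = cyc)
    current <- student
  }
  list(model = best$model, teacher = teacher,
       history = do.call(rbind, hist), best_cycle = best$cycle,
       teacher_auroc = t_auroc, best_auroc = best$auroc)
}

#' Performance-ceiling model trained on all true labels
#'
#' Opens the label guard (with the explicit ceiling purpose), joins the
#' labeled set with the unlabeled pool under its gold-standard labels, and
#' runs one supervised training.
#'
#' @param labeled,val dataset lists.
#' @param pool an `ards_guarded` pool.
#' @param cfg a [train_config()].
#' @param model_cfg a [model_config()].
#' @return list as returned by [train_supervised()].
#' @export
train_all_data_ceiling <- function(labeled, pool, val, cfg = train_config(),
                                   model_cfg = model_config()) {
  Y_true <- unlabeled_true_labels(pool, purpose = "all_data_ceiling")
  all_data <- .bind_sets(labeled,
                         list(X = pool$X, Y = Y_true,
                              M = matrix(1, nrow(Y_true), 7L)))
  train_supervised(init_model_params(model_cfg, seed = cfg$seed),
                   all_data, val, cfg)
}
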