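# Synthetic SSL benchmark: the package's own test bed for the claim that
# teacher-student pseudolabelling recovers part of the gap between a model
# trained on a small labeled set and the all-data ceiling.

#' Teacher / SSL / all-data benchmark on a synthetic cohort
#'
#' For each seed: generates a synthetic cohort, carves out labeled /
#' unlabeled / validation / test sets of the requested sizes, trains the
#' initial teacher, runs the SSL loop, trains the all-data ceiling (labels
#' unsealed through the guard), and evaluates test AUROC on the primary
#' outcome for all three models.
#'
#' @param seeds integer vector; one full run per seed.
#' @param n_labeled,n_unlabeled,n_val,n_test set sizes (default 1500 / 4000
#'   / 500 / 1000).
#' @param prevalence ARDS prevalence of the generated cohort.
#' @param signal_strength deterioration signal strength.
#' @param n_cycles SSL cycles.
#' @param hidden GRU hidden size (32 keeps the benchmark desk-sized).
#' @param max_epochs epoch cap per training run.
#' @param batch_size minibatch size. The benchmark defaults to 64 rather
#'   than the general-purpose 256: with only 1500 labeled encounters and a
#'   15-epoch cap, 256-sized batches give the teacher too few optimizer
#'   steps to converge at the reference learning rate.
#' @param stop_patience early-stopping patience (epochs).
#' @return list with `runs` (per-seed data.frame: seed, auroc_teacher,
#'   auroc_ssl, auroc_all_data, best_cycle, guard_accesses_during_ssl) and
#'   `mean` (named means of the three AUROCs).
#' @export
ssl_benchmark <- function(seeds = 1:5, n_labeled = 1500L,
                          n_unlabeled = 4000L, n_val = 500L, n_test = 1000L,
                          prevalence = 0.05, signal_strength = 1.0,
                          n_cycles = 4L, hidden = 32L, max_epochs = 15L,
                          batch_size = 64L, stop_patience = 6L) {
  n_total <- n_labeled + n_unlabeled + n_val + n_test
  mc <- model_config(hidden = hidden)
  rows <- vector("list", length(seeds))
  take <- function(ds, idx)
    list(X = ds$X[idx, , , drop = FALSE], Y = ds$Y[idx, , drop = FALSE],
         M = ds$M[idx, , drop = FALSE], ids = ds$ids[idx])
  for (k in seq_along(seeds)) {
    seed <- as.integer(seeds[k])
    # oversample so that >= n_total encounters survive the inclusion filter
    cc <- cohort_config(ceiling(n_total / 0.9),
                        ards_prevalence = prevalence,
                        deterioration_signal_strength = signal_strength,
                        seed = seed)
    cohort <- generate_cohort(cc)
    included <- Filter(inclusion_filter, cohort)
    if (length(included) < n_total)
      stop("synthetic cohort too small after inclusion filtering")
    stats <- fit_stats(included[seq_len(n_labeled + n_unlabeled)])
    ds <- build_dataset(included[seq_len(n_total)], stats)
    labeled <- take(ds, seq_len(n_labeled))
    pool <- guard_labels(take(ds, n_labeled + seq_len(n_unlabeled)))
    val <- take(ds, n_labeled + n_unlabeled + seq_len(n_val))
    test <- take(ds, n_labeled + n_unlabeled + n_val + seq_len(n_test))
    cfg <- train_config(max_epochs = max_epochs, batch_size = batch_size,
                        stop_patience = stop_patience, seed = seed)
    fit <- ssl_train(labeled, pool, val, cfg, n_cycles = n_cycles,
                     model_cfg = mc)
    ssl_accesses <- guard_accesses(pool)
    ceiling_fit <- train_all_data_ceiling(labeled, pool, val, cfg, mc)
    tauc <- function(mdl) auroc(model_predict(mdl, test$X)[, 1L],
                                test$Y[, 1L])
    rows[[k]] <- data.frame(
      seed = seed,
      auroc_teacher = tauc(fit$teacher),
      auroc_ssl = tauc(fit$model),
      auroc_all_data = tauc(ceiling_fit$model),
      best_cycle = fit$best_cycle,
      guard_accesses_during_ssl = ssl_accesses)
  }
  runs <- do.call(rbind, rows)
  list(runs = runs,
       mean = c(teacher = mean(runs$auroc_teacher),
                ssl = mean(runs$auroc_ssl),
                all_data = mean(runs$auroc_all_data)))
}
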