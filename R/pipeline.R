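# Top-level orchestration: simulate -> label -> split -> features ->
# teacher -> ssl -> all-data ceiling -> evaluate, with file-based artifacts
# in an output directory so any stage can be resumed, plus a small CLI.

#' Pipeline run configuration
#'
#' @param out_dir artifact directory.
#' @param cohort a [cohort_config()] (used by the simulate stage).
#' @param split a [split_spec()].
#' @param train a [train_config()].
#' @param model a [model_config()].
#' @param n_cycles SSL cycles.
#' @param target_sensitivity validation sensitivity used to pick the
#'   operating threshold.
#' @param obs_path,events_path input CSVs; defaults point inside `out_dir`
#'   (written there by the simulate stage).
#' @param seed master seed; stage seeds derive from it.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, cohort = cohort_config(2000),
                       split = split_spec(test_hospitals = c(1L, 2L, 3L)),
                       train = train_config(max_epochs = 10L),
                       model = model_config(hidden = 32L),
                       n_cycles = 2L, target_sensitivity = 0.78,
                       obs_path = file.path(out_dir, "observations.csv"),
                       events_path = file.path(out_dir, "events.csv"),
                       seed = 1L) {
  structure(list(out_dir = out_dir, cohort = cohort, split = split,
                 train = train, model = model, n_cycles = n_cycles,
                 target_sensitivity = target_sensitivity,
                 obs_path = obs_path, events_path = events_path,
                 seed = as.integer(seed)),
            class = "run_config")
}

.log_stage <- function(stage, ...) {
  extra <- list(...)
  msg <- jsonlite::toJSON(c(list(stage = stage), extra), auto_unbox = TRUE)
  message(msg)
}

.subset_ds <- function(ds, ids) {
  i <- match(ids, ds$ids)
  i <- i[!is.na(i)]
  list(X = ds$X[i, , , drop = FALSE], Y = ds$Y[i, , drop = FALSE],
       M = ds$M[i, , drop = FALSE], ids = ds$ids[i],
       hospital = ds$hospital[i])
}

#' Run the full pipeline
#'
#' Executes every stage, writing artifacts into `config$out_dir`
#' (observations/events CSVs, labels.csv, split.json, model checkpoints,
#' evaluation.json, heatmap.csv, projection.csv). A stage whose artifact
#' already exists is loaded instead of recomputed, so deleting one artifact
#' re-runs that stage and those after it that depend on it.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the evaluation reports and artifact paths.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(config$out_dir, f)

  # simulate
  if (!file.exists(config$obs_path) || !file.exists(config$events_path)) {
    .log_stage("simulate", n = config$cohort$n_patients,
               seed = config$cohort$seed)
    cohort <- generate_cohort(config$cohort)
    write_cohort(cohort, config$obs_path, config$events_path)
    hosp <- data.frame(
      patient_id = vapply(cohort, `[[`, character(1), "patient_id"),
      hospital_id = vapply(cohort, `[[`, integer(1), "hospital_id"))
    data.table::fwrite(hosp, pth("hospitals.csv"))
  } else {
    cohort <- NULL
  }

  # label
  if (!file.exists(pth("labels.csv"))) {
    if (is.null(cohort))
      cohort <- read_cohort(config$obs_path, config$events_path)
    .log_stage("label", n = length(cohort))
    labels <- label_cohort(cohort)
    write_labels(labels, pth("labels.csv"))
  }

  if (is.null(cohort))
    cohort <- read_cohort(config$obs_path, config$events_path)
  if (file.exists(pth("hospitals.csv"))) {
    hosp <- data.table::fread(pth("hospitals.csv"))
    hmap <- setNames(hosp$hospital_id, hosp$patient_id)
    for (i in seq_along(cohort))
      if (is.na(cohort[[i]]$hospital_id))
        cohort[[i]]$hospital_id <- unname(hmap[cohort[[i]]$patient_id])
  }

  # split
  if (!file.exists(pth("split.json"))) {
    .log_stage("split", seed = config$split$seed)
    sp <- split_cohort(cohort, config$split)
    jsonlite::write_json(sp, pth("split.json"))
  } else {
    sp <- lapply(jsonlite::read_json(pth("split.json")),
                 function(x) unlist(x, use.names = FALSE))
  }

  # features: stats fitted on the labeled + unlabeled development patients
  included <- Filter(inclusion_filter, cohort)
  dev_ids <- c(sp$labeled, sp$unlabeled)
  stats <- fit_stats(Filter(function(e) e$patient_id %in% dev_ids, included))
  ds <- build_dataset(included, stats)
  labeled <- .subset_ds(ds, sp$labeled)
  val <- .subset_ds(ds, sp$validation)
  test <- .subset_ds(ds, sp$test)
  pool <- guard_labels(.subset_ds(ds, sp$unlabeled))
  .log_stage("features", n_labeled = length(labeled$ids),
             n_unlabeled = pool$n, n_val = length(val$ids),
             n_test = length(test$ids))

  # ssl (includes the initial teacher)
  if (!file.exists(pth("ssl.rds"))) {
    .log_stage("ssl", cycles = config$n_cycles)
    fit <- ssl_train(labeled, pool, val, config$train,
                     n_cycles = config$n_cycles, model_cfg = config$model,
                     verbose = TRUE)
    saveRDS(fit[c("model", "teacher", "history", "best_cycle",
                  "teacher_auroc")], pth("ssl.rds"))
    if (is.data.frame(fit$history) && nrow(fit$history))
      data.table::fwrite(fit$history, pth("ssl_history.csv"))
  } else {
    fit <- readRDS(pth("ssl.rds"))
  }

  # ceiling
  if (!file.exists(pth("ceiling.rds"))) {
    .log_stage("ceiling")
    ceiling_fit <- train_all_data_ceiling(labeled, pool, val, config$train,
                                          config$model)
    saveRDS(ceiling_fit$model, pth("ceiling.rds"))
    data.table::fwrite(ceiling_fit$trace, pth("ceiling_trace.csv"))
  } else {
    ceiling_fit <- list(model = readRDS(pth("ceiling.rds")))
  }

  # evaluate
  .log_stage("evaluate")
  reports <- list()
  for (nm in c("teacher", "ssl", "all_data")) {
    mdl <- switch(nm, teacher = fit$teacher, ssl = fit$model,
                  all_data = ceiling_fit$model)
    sv <- model_predict(mdl, val$X)[, 1L]
    thr <- threshold_for_sensitivity(sv, val$Y[, 1L],
                                     config$target_sensitivity)
    st <- model_predict(mdl, test$X)[, 1L]
    reports[[nm]] <- evaluation_report(st, test$Y[, 1L], thr)
  }
  jsonlite::write_json(lapply(reports, unclass), pth("evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  hm <- attention_heatmap(fit$model, test$X)
  data.table::fwrite(data.frame(feature = names(hm$mean_z),
                                mean_z = hm$mean_z, heat = hm$heat,
                                n_obs = hm$n_obs),
                     pth("heatmap.csv"))
  grDevices::png(pth("heatmap.png"), width = 900, height = 500)
  op <- graphics::par(mar = c(9, 4, 2, 1))
  graphics::barplot(hm$mean_z, las = 2, col = "steelblue",
                    ylab = "mean z-score at attention focus",
                    main = "Feature inflections at maximally attended steps")
  graphics::par(op)
  grDevices::dev.off()
  pj <- embed_project(fit$model, test$X)
  data.table::fwrite(data.frame(patient_id = test$ids, pj$coords),
                     pth("projection.csv"))
  invisible(list(reports = reports, ssl = fit, out_dir = config$out_dir))
}

.cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      out[[substring(args[i], 3)]] <- args[i + 1L]
      i <- i + 2L
    } else i <- i + 1L
  }
  out
}

.cli_config <- function(opts) {
  cj <- if (!is.null(opts$config)) jsonlite::read_json(opts$config) else list()
  seed <- as.integer(opts$seed %||% cj$seed %||% 1L)
  out_dir <- opts$out %||% cj$out_dir %||% "ards_run"
  co <- do.call(cohort_config,
                c(list(n_patients = as.integer(cj$cohort$n_patients %||% 2000L),
                       seed = seed),
                  cj$cohort[setdiff(names(cj$cohort),
                                    c("n_patients", "seed"))]))
  sp <- do.call(split_spec,
                c(list(test_hospitals =
                         unlist(cj$split$test_hospitals %||% list(1L, 2L, 3L)),
                       seed = seed),
                  cj$split[setdiff(names(cj$split),
                                   c("test_hospitals", "seed"))]))
  tr <- do.call(train_config,
                c(list(seed = seed),
                  cj$train[setdiff(names(cj$train), "seed")]))
  md <- do.call(model_config, cj$model %||% list(hidden = 32L))
  run_config(out_dir = out_dir, cohort = co, split = sp, train = tr,
             model = md,
             n_cycles = as.integer(opts$cycles %||% cj$n_cycles %||% 2L),
             target_sensitivity = cj$target_sensitivity %||% 0.78,
             seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands: `simulate`, `label`, `run-all` (full pipeline; `split`,
#' `train`, `ssl-train`, `train-ceiling`, `evaluate`, `heatmap` and
#' `project` run as resumable stages of it — delete a stage artifact to
#' re-run it). Options: `--config <json>`, `--out <dir>`, `--seed <int>`,
#' `--cycles <int>`.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return invisibly, the subcommand's result.
#' @export
ards_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: ards_cli <command> [--config file.json] ",
                          "[--out dir] [--seed n] [--cycles n]")
  cmd <- args[1]
  opts <- .cli_args(args[-1])
  config <- .cli_config(opts)
  res <- switch(cmd,
    "simulate" = {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      cohort <- generate_cohort(config$cohort)
      write_cohort(cohort, config$obs_path, config$events_path)
      invisible(config$out_dir)
    },
    "label" = {
      cohort <- read_cohort(config$obs_path, config$events_path)
      write_labels(label_cohort(cohort),
                   file.path(config$out_dir, "labels.csv"))
    },
    "run-all" = ,
    "split" = , "train" = , "ssl-train" = , "train-ceiling" = ,
    "evaluate" = , "heatmap" = , "project" = run_pipeline(config),
    stop("unknown command: ", cmd))
  invisible(res)
}
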