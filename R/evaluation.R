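# Threshold-free discrimination metrics, operating-point statistics, the
# attention-focus feature heat map, and PCA projection of the penultimate
# embeddings.

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, ties counted half.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise integral of precision over recall with a cut at every distinct
#' score (equivalently, average precision with tied scores grouped).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("at least one positive is required to compute AUPRC")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)   # last index within each tie group
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Confusion-matrix metrics at an operating threshold
#'
#' Scores at or above the threshold are predicted positive.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (both classes present).
#' @param threshold operating threshold.
#' @return named vector: `sensitivity`, `specificity`, `ppv`, `npv`
#'   (undefined ratios are `NaN`).
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  labels <- as.numeric(labels)
  stopifnot(sum(labels == 1) > 0, sum(labels == 0) > 0)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
  fp <- sum(pred & labels == 0); tn <- sum(!pred & labels == 0)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = tp / (tp + fp), npv = tn / (tn + fn))
}

#' Choose a threshold achieving a target sensitivity
#'
#' Returns the largest threshold whose sensitivity on the given (validation)
#' data is at least `target`: the k-th largest positive score with
#' `k = ceiling(target * n_pos)`.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param target desired sensitivity (default 0.78, the reference SSL
#'   operating point).
#' @return threshold value.
#' @export
threshold_for_sensitivity <- function(scores, labels, target = 0.78) {
  pos <- sort(scores[labels == 1], decreasing = TRUE)
  if (!length(pos)) stop("no positives")
  pos[min(length(pos), max(1L, ceiling(target * length(pos))))]
}

#' Full evaluation report
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param threshold operating threshold (e.g. from
#'   [threshold_for_sensitivity()] on validation data).
#' @return an `ards_evaluation` list: `auroc`, `auprc`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `threshold`, `n_pos`, `n_neg`.
#' @export
evaluation_report <- function(scores, labels, threshold) {
  cm <- confusion_metrics(scores, labels, threshold)
  structure(c(list(auroc = auroc(scores, labels),
                   auprc = auprc(scores, labels)),
              as.list(cm),
              list(threshold = threshold, n_pos = sum(labels == 1),
                   n_neg = sum(labels == 0))),
            class = "ards_evaluation")
}

#' Attention-focus feature heat map
#'
#' For each encounter, the non-padded time step with the greatest attention
#' weight (earliest wins ties) is the focus step; every time-varying
#' feature measured at that step (mask 1) contributes its z-scored value.
#' Reported are per-feature means over focus steps and a min-max-normalized
#' rendering.
#'
#' @param model trained `ards_model`.
#' @param X batch array N x 49 x 32 (feature matrices already carry z-scored
#'   values and masks).
#' @return list with `mean_z` (named per-feature means, `NA` when a feature
#'   was never measured at a focus step), `heat` (min-max normalized),
#'   `n_obs` (contribution counts), `n_skipped`.
#' @export
attention_heatmap <- function(model, X) {
  lay <- feature_layout()
  nf <- length(lay$features)
  mask_rows <- 2 * seq_len(nf) + 5L
  value_rows <- mask_rows + 1L
  fw <- model_forward(model, X)
  W <- fw$attention_weights
  sums <- numeric(nf); counts <- integer(nf); skipped <- 0L
  n <- dim(X)[1]
  for (i in seq_len(n)) {
    padded <- colSums(abs(X[i, , ])) == 0
    if (all(padded)) {
      skipped <- skipped + 1L
      message("encounter ", i, ": all columns padded; skipped")
      next
    }
    w <- W[i, ]
    w[padded] <- -Inf
    j <- which.max(w)                        # earliest index on ties
    measured <- X[i, mask_rows, j] == 1
    sums[measured] <- sums[measured] + X[i, value_rows, j][measured]
    counts[measured] <- counts[measured] + 1L
  }
  mean_z <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  names(mean_z) <- lay$features
  rng <- range(mean_z, na.rm = TRUE)
  heat <- if (diff(rng) > 0) (mean_z - rng[1]) / diff(rng) else mean_z * 0
  list(mean_z = mean_z, heat = heat, n_obs = setNames(counts, lay$features),
       n_skipped = skipped)
}

#' Project penultimate embeddings to two principal components
#'
#' @param model trained `ards_model`.
#' @param X batch array N x 49 x 32 with N >= 3.
#' @return list with `coords` (N x 2 scores), `rotation` (orthonormal
#'   loadings), `sdev` (component standard deviations).
#' @export
embed_project <- function(model, X) {
  if (dim(X)[1] < 3) stop("at least 3 encounters are required")
  emb <- model_forward(model, X)$penultimate
  pr <- prcomp(emb, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pr$x))
  list(coords = pr$x[, seq_len(k), drop = FALSE],
       rotation = pr$rotation[, seq_len(k), drop = FALSE],
       sdev = pr$sdev)
}
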