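#' @useDynLib ardssl, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm rbinom rpois rlnorm quantile sd median prcomp setNames
#' @importFrom utils head tail
NULL

#' Model architecture configuration
#'
#' Describes the attention-GRU classifier: a learned elementwise input
#' normalization, a 2-layer GRU, a soft-attention scorer
#' `score(l, h) = K . tanh(A . prelu(B . n([l, h])))` over the deepest layer's
#' hidden states, and a 2-layer feed-forward classifier that consumes the
#' concatenation of the final deepest hidden state `l` and the attention
#' context vector.
#'
#' @param hidden GRU hidden size per layer (64 in the reference setup).
#' @param input_dim number of feature-matrix rows (49 for the standard layout).
#' @param n_steps number of time-step columns (32).
#' @param attn_dim inner width of the attention scorer; defaults to `hidden`.
#' @param clf_hidden penultimate embedding size (64).
#' @param n_out number of sigmoid outputs (7 outcomes).
#' @param eps division-by-zero guard in the normalization layers (1e-7).
#' @param prelu_init initial slope of the prelu nonlinearity.
#' @return a `model_config` list.
#' @export
model_config <- function(hidden = 64L, input_dim = 49L, n_steps = 32L,
                         attn_dim = hidden, clf_hidden = 64L, n_out = 7L,
                         eps = 1e-7, prelu_init = 0.25) {
  stopifnot(hidden >= 1, input_dim >= 1, n_steps >= 1, n_out >= 1, eps > 0)
  structure(list(input_dim = as.integer(input_dim), hidden = as.integer(hidden),
                 n_steps = as.integer(n_steps), attn_dim = as.integer(attn_dim),
                 clf_hidden = as.integer(clf_hidden), n_out = as.integer(n_out),
                 eps = eps, prelu_init = prelu_init),
            class = "ards_model_config")
}

cfg_dims <- function(cfg) {
  as.integer(c(cfg$input_dim, cfg$hidden, cfg$n_steps, cfg$attn_dim,
               cfg$clf_hidden, cfg$n_out))
}

#' Initialize model parameters
#'
#' GRU, attention and classifier weights are drawn uniformly in
#' `[-1/sqrt(fan), 1/sqrt(fan)]`; both learned normalization layers start as
#' the identity z-score (`mu = 0`, `sigma = 1`, `a = 1`, `b = 0`), which is a
#' plain z-score when composed with inputs already standardized by the
#' training-set statistics.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed controlling the draw.
#' @return an `ards_model` object (flat parameter vector plus config).
#' @export
init_model_params <- function(cfg = model_config(), seed = 1L) {
  lay <- cpp_param_layout(cfg_dims(cfg))
  par <- numeric(cpp_n_params(cfg_dims(cfg)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  put <- function(name, x) {
    i <- match(name, lay$name)
    par[seq(lay$offset[i], length.out = lay$nrow[i] * lay$ncol[i])] <<- x
  }
  unif <- function(n, fan) runif(n, -1 / sqrt(fan), 1 / sqrt(fan))
  H <- cfg$hidden
  put("sg_in", rep(1, cfg$input_dim)); put("a_in", rep(1, cfg$input_dim))
  for (nm in c("W1", "U1", "bw1", "bu1", "W2", "U2", "bw2", "bu2")) {
    i <- match(nm, lay$name)
    put(nm, unif(lay$nrow[i] * lay$ncol[i], H))
  }
  put("sg_at", rep(1, 2 * H)); put("a_at", rep(1, 2 * H))
  put("B", unif(cfg$attn_dim * 2 * H, 2 * H))
  put("slope", cfg$prelu_init)
  put("A", unif(cfg$attn_dim^2, cfg$attn_dim))
  put("K", unif(cfg$attn_dim, cfg$attn_dim))
  put("Wc1", unif(cfg$clf_hidden * 2 * H, 2 * H))
  put("bc1", unif(cfg$clf_hidden, 2 * H))
  put("Wc2", unif(cfg$n_out * cfg$clf_hidden, cfg$clf_hidden))
  put("bc2", unif(cfg$n_out, cfg$clf_hidden))
  structure(list(par = par, config = cfg), class = "ards_model")
}

# RNG bookkeeping so seeded constructors do not disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Extract a named parameter block from a model
#'
#' @param model an `ards_model`.
#' @param name block name as listed by the internal parameter layout
#'   (e.g. `"W1"`, `"K"`, `"mu_in"`).
#' @return the block as a matrix (or vector for 1-column blocks).
#' @export
param_block <- function(model, name) {
  lay <- cpp_param_layout(cfg_dims(model$config))
  i <- match(name, lay$name)
  if (is.na(i)) stop("unknown parameter block: ", name)
  x <- model$par[seq(lay$offset[i], length.out = lay$nrow[i] * lay$ncol[i])]
  if (lay$ncol[i] == 1L) x else matrix(x, lay$nrow[i], lay$ncol[i])
}

`param_block<-` <- function(model, name, value) {
  lay <- cpp_param_layout(cfg_dims(model$config))
  i <- match(name, lay$name)
  if (is.na(i)) stop("unknown parameter block: ", name)
  idx <- seq(lay$offset[i], length.out = lay$nrow[i] * lay$ncol[i])
  stopifnot(length(value) == length(idx))
  model$par[idx] <- as.numeric(value)
  model
}

#' Learned normalization layer
#'
#' Computes `a * (v - mu) / (sigma + eps) + b` elementwise — a z-score with
#' learnable location, scale, gain and shift.
#'
#' @param v numeric vector.
#' @param norm list with elements `mu`, `sigma`, `a`, `b` (same length as `v`)
#'   and `eps`.
#' @return normalized vector.
#' @export
normalize <- function(v, norm) {
  if (length(norm$mu) != length(v) || length(norm$sigma) != length(v) ||
      length(norm$a) != length(v) || length(norm$b) != length(v))
    stop("normalization parameter length mismatch")
  norm$a * ((v - norm$mu) / (norm$sigma + norm$eps)) + norm$b
}

prelu <- function(x, slope) ifelse(x > 0, x, slope * x)

#' Attention score for one (l, h) pair
#'
#' `score(l, h) = K . tanh(A . prelu(B . n([l, h])))` where `l` is the final
#' deepest-layer GRU hidden state, `h` any deepest-layer hidden state, and
#' `n` an independent learned normalization over the length-2H concatenation.
#'
#' @param l,h numeric vectors of the hidden size.
#' @param attn list with `K` (vector), `A`, `B` (matrices), `slope` (scalar),
#'   and `norm` (as in [normalize()]).
#' @return scalar score.
#' @export
attention_score <- function(l, h, attn) {
  if (length(l) != length(h)) stop("l and h must have equal length")
  c_vec <- c(l, h)
  if (ncol(attn$B) != length(c_vec)) stop("attention dimension mismatch")
  u <- normalize(c_vec, attn$norm)
  drop(attn$K %*% tanh(attn$A %*% prelu(attn$B %*% u, attn$slope)))
}

#' Attention parameters of a model, in [attention_score()] form
#' @param model an `ards_model`.
#' @return list with `K`, `A`, `B`, `slope`, `norm`.
#' @export
attention_params <- function(model) {
  list(K = param_block(model, "K"), A = param_block(model, "A"),
       B = param_block(model, "B"), slope = param_block(model, "slope"),
       norm = list(mu = param_block(model, "mu_at"),
                   sigma = param_block(model, "sg_at"),
                   a = param_block(model, "a_at"),
                   b = param_block(model, "b_at"),
                   eps = model$config$eps))
}

#' Forward pass of the attention-GRU classifier
#'
#' @param model an `ards_model`.
#' @param x either one feature matrix (`input_dim` x `n_steps`) or a batch
#'   array `N x input_dim x n_steps`.
#' @return for one matrix: list with `logits` (length `n_out`), `probs`,
#'   `attention_weights` (length `n_steps`), `penultimate`, `context`;
#'   for a batch: the same fields as matrices with one row per sample.
#' @export
model_forward <- function(model, x) {
  cfg <- model$config
  single <- is.matrix(x)
  if (single) {
    if (nrow(x) != cfg$input_dim || ncol(x) != cfg$n_steps)
      stop("feature matrix must be ", cfg$input_dim, " x ", cfg$n_steps)
    x <- aperm(array(x, c(cfg$input_dim, cfg$n_steps, 1L)), c(3L, 1L, 2L))
  }
  if (length(dim(x)) != 3L || dim(x)[2] != cfg$input_dim ||
      dim(x)[3] != cfg$n_steps)
    stop("batch array must be N x ", cfg$input_dim, " x ", cfg$n_steps)
  out <- cpp_forward(model$par, cfg_dims(cfg), cfg$eps, x)
  res <- list(logits = out$logits, probs = out$probs,
              attention_weights = out$attention, penultimate = out$penultimate,
              context = out$context, l = out$l)
  if (single) res <- lapply(res, drop)
  res
}

#' Predicted outcome probabilities for a batch
#'
#' Runs the forward pass in minibatches to bound memory.
#'
#' @param model an `ards_model`.
#' @param X batch array `N x input_dim x n_steps`.
#' @param batch_size minibatch size.
#' @return matrix `N x n_out` of sigmoid probabilities.
#' @export
model_predict <- function(model, X, batch_size = 1024L) {
  n <- dim(X)[1]
  out <- matrix(NA_real_, n, model$config$n_out)
  for (i in seq(1L, n, by = batch_size)) {
    j <- min(i + batch_size - 1L, n)
    out[i:j, ] <- model_forward(model, X[i:j, , , drop = FALSE])$probs
  }
  out
}

#' Masked multitask binary cross-entropy
#'
#' Mean, over outcomes with `loss_mask == 1`, of the binary cross-entropy
#' between `sigmoid(logits)` and `labels`. Used with all-ones masks for
#' gold-labeled samples and an ARDS-only mask for pseudolabeled samples.
#'
#' @param logits numeric vector of logits.
#' @param labels 0/1 vector, same length.
#' @param loss_mask 0/1 vector, same length; at least one 1.
#' @return scalar loss.
#' @export
multitask_loss <- function(logits, labels,
                           loss_mask = rep(1, length(logits))) {
  stopifnot(length(labels) == length(logits),
            length(loss_mask) == length(logits),
            all(labels %in% c(0, 1)), all(loss_mask %in% c(0, 1)))
  if (sum(loss_mask) == 0) stop("all outcomes are masked")
  bce <- pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits)))
  sum(bce * loss_mask) / sum(loss_mask)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file container holding the flat parameter
#' vector, the architecture configuration and a hash of that configuration;
#' loading verifies the hash so a checkpoint cannot silently be read into a
#' mismatched architecture.
#'
#' @param model an `ards_model`.
#' @param path file path (RDS container).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ards_model"))
  saveRDS(list(par = model$par, config = unclass(model$config),
               config_hash = .config_hash(model$config),
               format = "ardssl-checkpoint-1"), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "ardssl-checkpoint-1"))
    stop("not an ardssl checkpoint: ", path)
  cfg <- structure(ck$config, class = "ards_model_config")
  if (!identical(.config_hash(cfg), ck$config_hash))
    stop("checkpoint config hash mismatch in ", path)
  structure(list(par = ck$par, config = cfg), class = "ards_model")
}

# order-sensitive polynomial hash of the serialized config fields
.config_hash <- function(cfg) {
  chars <- utf8ToInt(paste(names(unlist(unclass(cfg))),
                           format(unlist(unclass(cfg)), digits = 17),
                           collapse = "|"))
  sum(chars * (seq_along(chars) %% 997)) %% 2147483647
}

batch_loss_grad <- function(model, X, Y, M) {
  cfg <- model$config
  cpp_loss_grad(model$par, cfg_dims(cfg), cfg$eps, X, Y, M)
}

batch_loss <- function(model, X, Y, M) {
  cfg <- model$config
  cpp_loss(model$par, cfg_dims(cfg), cfg$eps, X, Y, M)
}
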