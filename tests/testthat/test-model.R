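tiny_cfg <- model_config(hidden = 6L, input_dim = 5L, n_steps = 4L,
                         attn_dim = 6L, clf_hidden = 8L)

rand_norm <- function(n, seed) {
  set.seed(seed)
  list(mu = rnorm(n), sigma = abs(rnorm(n)) + 0.5, a = rnorm(n),
       b = rnorm(n), eps = 1e-7)
}

test_that("the learned normalization layer matches its closed form", {
  nm <- rand_norm(4, 1)
  # v = mu collapses to b regardless of a
  expect_equal(normalize(nm$mu, nm), nm$b)
  # the documented epsilon guard: a=1, b=0, mu=0, sigma=1, v=2
  id <- list(mu = 0, sigma = 1, a = 1, b = 0, eps = 1e-7)
  expect_equal(normalize(2, id), 2 / (1 + 1e-7))
  # random case against the scalar-loop oracle
  set.seed(2)
  v <- rnorm(4)
  expect_equal(normalize(v, nm), oracle_normalize(v, nm))
  expect_error(normalize(1:3, nm), "length mismatch")
})

test_that("attention_score matches hand evaluation", {
  H <- 3
  set.seed(3)
  l <- rnorm(H); h <- rnorm(H)
  id_norm <- list(mu = rep(0, 2 * H), sigma = rep(1, 2 * H),
                  a = rep(1, 2 * H), b = rep(0, 2 * H), eps = 0)
  # K of zeros kills the score for any input
  attn0 <- list(K = rep(0, 2 * H), A = diag(2 * H), B = diag(2 * H),
                slope = 0.25, norm = id_norm)
  expect_equal(attention_score(l, h, attn0), 0)
  # identity-like A, B with K = e1: tanh(prelu(n([l,h])))[1]
  attn1 <- list(K = c(1, rep(0, 2 * H - 1)), A = diag(2 * H),
                B = diag(2 * H), slope = 0.25, norm = id_norm)
  x1 <- c(l, h)[1]
  expect_equal(attention_score(l, h, attn1),
               tanh(ifelse(x1 > 0, x1, 0.25 * x1)))
  # scores over a 3-step sequence match a step-by-step scalar oracle
  set.seed(4)
  nm <- rand_norm(2 * H, 5)
  attn <- list(K = rnorm(2 * H), A = matrix(rnorm(4 * H * H), 2 * H),
               B = matrix(rnorm(4 * H * H), 2 * H), slope = 0.3, norm = nm)
  hs <- matrix(rnorm(3 * H), H, 3)
  for (t in 1:3) {
    u <- oracle_normalize(c(l, hs[, t]), nm)
    bu <- as.vector(attn$B %*% u)
    pr <- ifelse(bu > 0, bu, 0.3 * bu)
    manual <- sum(attn$K * tanh(as.vector(attn$A %*% pr)))
    expect_equal(attention_score(l, hs[, t], attn), manual)
  }
  expect_error(attention_score(l, rnorm(2), attn), "equal length")
})

test_that("compiled forward pass agrees with the scalar-loop oracle", {
  for (seed in 1:3) {
    m <- init_model_params(tiny_cfg, seed = seed)
    set.seed(seed + 100)
    x <- matrix(rnorm(5 * 4), 5, 4)
    got <- model_forward(m, x)
    ref <- oracle_forward(m, x)
    expect_equal(got$logits, ref$logits, tolerance = 1e-10)
    expect_equal(got$attention_weights, ref$attention_weights,
                 tolerance = 1e-10)
    expect_equal(got$penultimate, ref$penultimate, tolerance = 1e-10)
    expect_equal(got$context, ref$context, tolerance = 1e-10)
  }
})

test_that("forward output contracts and determinism", {
  m <- init_model_params(tiny_cfg, seed = 1)
  set.seed(7)
  X <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  fw1 <- model_forward(m, X)
  fw2 <- model_forward(m, X)
  expect_identical(fw1, fw2)
  expect_equal(dim(fw1$logits), c(6L, 7L))
  expect_equal(rowSums(fw1$attention_weights), rep(1, 6), tolerance = 1e-9)
  expect_true(all(fw1$attention_weights >= 0))
  # all-zero GRU weights give identical (zero) hidden states at every step,
  # so attention is uniform by symmetry
  z <- m
  set_block <- ardssl:::`param_block<-`
  for (nm in c("W1", "U1", "bw1", "bu1", "W2", "U2", "bw2", "bu2"))
    z <- set_block(z, nm, 0 * param_block(z, nm))
  fwz <- model_forward(z, X)
  expect_equal(fwz$attention_weights,
               matrix(1 / 4, 6, 4), tolerance = 1e-12)
  expect_error(model_forward(m, matrix(0, 3, 3)), "must be")
})

test_that("multitask loss has its closed forms and masks correctly", {
  expect_equal(multitask_loss(0, 1), log(2))
  expect_equal(multitask_loss(c(0, 0), c(1, 0)), log(2))
  expect_lt(multitask_loss(c(30, -30), c(1, 0)), 1e-10)
  # random case against an elementwise hand sum
  set.seed(8)
  lg <- rnorm(7); y <- rbinom(7, 1, 0.5); mk <- c(1, 1, 0, 1, 0, 1, 1)
  p <- 1 / (1 + exp(-lg))
  hand <- -mean((y * log(p) + (1 - y) * log(1 - p))[mk == 1])
  expect_equal(multitask_loss(lg, y, mk), hand)
  expect_error(multitask_loss(lg, y, rep(0, 7)), "masked")
})

test_that("analytic gradients match finite differences on a tiny model", {
  m <- init_model_params(tiny_cfg, seed = 5)
  set.seed(11)
  N <- 3
  X <- array(rnorm(N * 5 * 4), c(N, 5, 4))
  Y <- matrix(rbinom(N * 7, 1, 0.5), N, 7)
  Mk <- matrix(1, N, 7)
  g <- ardssl:::batch_loss_grad(m, X, Y, Mk)$grad
  h <- 1e-4
  par0 <- m$par
  num <- vapply(seq_along(par0), function(i) {
    p1 <- par0; p1[i] <- p1[i] + h
    p2 <- par0; p2[i] <- p2[i] - h
    m1 <- m; m1$par <- p1
    m2 <- m; m2$par <- p2
    (ardssl:::batch_loss(m1, X, Y, Mk) -
       ardssl:::batch_loss(m2, X, Y, Mk)) / (2 * h)
  }, numeric(1))
  rel <- abs(num - g) / pmax(abs(num) + abs(g), 1e-6)
  expect_lt(max(rel), 1e-4)
})

test_that("architecture dimensions follow the configuration", {
  m <- init_model_params(model_config(), seed = 1)
  expect_equal(dim(param_block(m, "Wc1")), c(64L, 128L))
  expect_equal(dim(param_block(m, "Wc2")), c(7L, 64L))
  expect_length(param_block(m, "mu_at"), 128L)
  expect_error(param_block(m, "nope"), "unknown parameter block")
})

test_that("checkpoints round-trip and verify their config hash", {
  m <- init_model_params(tiny_cfg, seed = 9)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  back <- load_model(f)
  expect_identical(back$par, m$par)
  expect_equal(unclass(back$config), unclass(m$config))
  # a checkpoint cannot be loaded into a silently different architecture
  ck <- readRDS(f)
  ck$config$hidden <- 12L
  saveRDS(ck, f)
  expect_error(load_model(f), "hash mismatch")
  saveRDS(list(a = 1), f)
  expect_error(load_model(f), "not an ardssl checkpoint")
})
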