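# Brute-force loop oracles for each network operation, kept deliberately
# naive and independent of the vectorized implementations.

conv_oracle <- function(X, W_c, b_c, activation = "identity") {
  k <- dim(W_c)[1]; d_c <- dim(W_c)[3]; n <- ncol(X)
  pl <- (k - 1) %/% 2
  H <- matrix(0, d_c, n)
  for (pos in seq_len(n)) {
    for (f in seq_len(d_c)) {
      acc <- b_c[f]
      for (t in seq_len(k)) {
        src <- pos - pl + t - 1
        if (src >= 1 && src <= n) acc <- acc + sum(W_c[t, , f] * X[, src])
      }
      H[f, pos] <- switch(activation, identity = acc, tanh = tanh(acc),
                          relu = max(acc, 0))
    }
  }
  H
}

softmax_oracle <- function(s) exp(s) / sum(exp(s))

test_that("conv_forward matches a nested-loop oracle on random instances", {
  set.seed(101)
  for (rep in 1:40) {
    k <- sample(1:5, 1); d_e <- sample(1:4, 1); d_c <- sample(1:5, 1)
    n <- sample(1:8, 1)
    X <- matrix(rnorm(d_e * n), d_e, n)
    W <- array(rnorm(k * d_e * d_c), c(k, d_e, d_c))
    b <- rnorm(d_c)
    act <- sample(c("identity", "tanh", "relu"), 1)
    expect_lt(max(abs(conv_forward(X, W, b, act) - conv_oracle(X, W, b, act))),
              1e-6)
  }
})

test_that("identity filter reproduces the input and length is conserved", {
  X <- matrix(c(1, 2, 3), 1, 3)
  W <- array(1, c(1, 1, 1))
  expect_equal(conv_forward(X, W, 0, "identity"), X)
  set.seed(5)
  Xr <- matrix(rnorm(4 * 7), 4, 7)
  for (k in 1:10) {
    W <- array(rnorm(k * 4 * 3), c(k, 4, 3))
    expect_equal(ncol(conv_forward(Xr, W, rnorm(3))), 7)
  }
  Xbad <- Xr; Xbad[1, 1] <- NaN
  expect_error(conv_forward(Xbad, W, rnorm(3)), class = "swam_numeric_error")
})

test_that("per-label attention matches closed forms and the exp-normalize oracle", {
  H <- matrix(rnorm(12), 3, 4)
  # zero attention vector: uniform weights by symmetry
  expect_equal(perlabel_attention(H, c(0, 0, 0)), rep(0.25, 4))
  # closed-form softmax of [ln 2, 0]
  H2 <- matrix(c(log(2), 0), 1, 2)
  expect_equal(perlabel_attention(H2, 1), c(2 / 3, 1 / 3))
  set.seed(77)
  for (rep in 1:40) {
    d_c <- sample(1:6, 1); n <- sample(1:9, 1)
    H <- matrix(rnorm(d_c * n, sd = 2), d_c, n)
    u <- rnorm(d_c)
    expect_lt(max(abs(perlabel_attention(H, u) -
                        softmax_oracle(as.vector(t(H) %*% u)))), 1e-6)
  }
})

test_that("masked positions get weight exactly zero and all-masked errors", {
  H <- matrix(rnorm(8), 2, 4)
  u <- rnorm(2)
  a <- perlabel_attention(H, u, mask = c(TRUE, TRUE, FALSE, TRUE))
  expect_identical(a[3], 0)
  expect_equal(sum(a), 1)
  expect_error(perlabel_attention(H, u, mask = rep(FALSE, 4)),
               class = "swam_data_error")
})

test_that("attend_pool matches selection, convexity and the loop oracle", {
  H <- matrix(rnorm(15), 3, 5)
  onehot <- c(0, 0, 1, 0, 0)
  expect_equal(attend_pool(H, onehot), H[, 3])
  Hsame <- matrix(rep(c(1, -2, 0.5), 5), 3, 5)
  expect_equal(attend_pool(Hsame, rep(0.2, 5)), c(1, -2, 0.5))
  set.seed(12)
  for (rep in 1:40) {
    d_c <- sample(1:6, 1); n <- sample(1:9, 1)
    H <- matrix(rnorm(d_c * n), d_c, n)
    a <- softmax_oracle(rnorm(n))
    v_loop <- numeric(d_c)
    for (pos in seq_len(n)) v_loop <- v_loop + a[pos] * H[, pos]
    expect_lt(max(abs(attend_pool(H, a) - v_loop)), 1e-6)
  }
  expect_error(attend_pool(H, c(0.5, 0.5)), class = "swam_shape_error")
})

test_that("max_pool takes per-filter maxima with earliest-tie argmax", {
  H <- matrix(c(-1, 5, 2), 1, 3)
  mp <- max_pool(H)
  expect_equal(mp$v, 5)
  expect_equal(mp$argmax, 2)
  Hc <- matrix(c(3, -1), 2, 1)
  expect_equal(max_pool(Hc)$v, c(3, -1))
  # earliest position wins ties
  Ht <- matrix(c(7, 1, 7, 1), 1, 4)
  expect_equal(max_pool(Ht)$argmax, 1)
  set.seed(9)
  for (rep in 1:40) {
    d_c <- sample(1:6, 1); n <- sample(1:9, 1)
    H <- matrix(rnorm(d_c * n), d_c, n)
    mp <- max_pool(H)
    v_loop <- apply(H, 1, max)
    expect_identical(mp$v, v_loop)
  }
  # mask excludes positions from both max and argmax
  Hm <- matrix(c(10, 1, 2), 1, 3)
  mpm <- max_pool(Hm, mask = c(FALSE, TRUE, TRUE))
  expect_equal(mpm$v, 2)
  expect_equal(mpm$argmax, 3)
  expect_error(max_pool(Hm, mask = rep(FALSE, 3)), class = "swam_data_error")
})

test_that("classify matches sigmoid closed forms and is monotone in the offset", {
  expect_equal(classify(c(1, 1), c(0, 0), 0), 0.5)
  # beta'v + b = ln 3  ->  sigma = 3/4
  expect_equal(classify(1, log(3), 0), 0.75)
  v <- rnorm(4); beta <- rnorm(4)
  ys <- vapply(seq(-2, 2, by = 0.5),
               function(b) classify(v, beta, b), numeric(1))
  expect_true(all(diff(ys) > 0))
})

test_that("bce_loss matches closed forms and the elementwise loop oracle", {
  expect_equal(bce_loss(rep(0.5, 50), rbinom(50, 1, 0.5)), 50 * log(2))
  y <- c(1, 0, 1)
  expect_lt(bce_loss(c(0.999999, 1e-6, 0.999999), y), 1e-4)
  expect_warning(bce_loss(c(1, 0.5), c(1, 0)), "clamped")
  set.seed(3)
  for (rep in 1:40) {
    L <- sample(1:8, 1)
    yh <- runif(L, 0.01, 0.99)
    y <- rbinom(L, 1, 0.5)
    loop <- 0
    for (l in seq_len(L)) {
      loop <- loop - (y[l] * log(yh[l]) + (1 - y[l]) * log(1 - yh[l]))
    }
    expect_lt(abs(bce_loss(yh, y) - loop), 1e-6)
  }
})

test_that("a micro-model forward pass matches a full hand trace", {
  # one label, one filter of width 1 over 1-d embeddings: every step has a
  # closed form.  Vocabulary rows: pad=0, unk=0.5, t001=1, t002=2.
  E <- matrix(c(0, 0.5, 1, 2), ncol = 1,
              dimnames = list(c("<pad>", "<unk>", "t001", "t002"), NULL))
  cfg <- swam_config(k = 1, d_c = 1, d_e = 1, n_labels = 1, dropout = 0,
                     activation = "tanh")
  p <- swam_init_params(cfg, E, seed = 1)
  p$W[1, 1] <- 1; p$b_c <- 0; p$U[1, 1] <- 1; p$B[1, 1] <- 2; p$b <- 0.1
  ids <- c(3L, 4L)  # embeddings 1, 2
  st <- swam_forward(ids, p, cfg)
  h <- tanh(c(1, 2))
  a <- softmax_oracle(h)
  v <- sum(a * h)
  yhat <- plogis(2 * v + 0.1)
  expect_lt(max(abs(st$H - matrix(h, 1))), 1e-12)
  expect_lt(max(abs(st$A - matrix(a, 1))), 1e-12)
  expect_lt(abs(st$yhat - yhat), 1e-12)
})

test_that("forward pass is deterministic without dropout and rejects all-pad docs", {
  cfg <- swam_config(k = 3, d_c = 4, d_e = 5, n_labels = 3, dropout = 0)
  p <- random_params(cfg, v = 15, seed = 2)
  ids <- c(3L, 7L, 9L, 4L)
  s1 <- swam_forward(ids, p, cfg)
  s2 <- swam_forward(ids, p, cfg)
  expect_identical(s1$yhat, s2$yhat)
  expect_error(swam_forward(c(1L, 1L), p, cfg), class = "swam_data_error")
})

test_that("max-pool predictions are invariant to token permutation and
           per-label attention is position-equivariant", {
  cfg <- swam_config(k = 1, d_c = 4, d_e = 5, n_labels = 3, dropout = 0,
                     attention = "max_pool")
  p <- random_params(cfg, v = 15, seed = 3)
  ids <- c(3L, 7L, 9L, 4L, 11L, 5L)
  set.seed(8)
  for (rep in 1:5) {
    perm <- sample(length(ids))
    expect_equal(swam_forward(ids[perm], p, cfg)$yhat,
                 swam_forward(ids, p, cfg)$yhat)
  }
  # with k=1 the attention weights permute exactly with the tokens
  cfg2 <- swam_config(k = 1, d_c = 4, d_e = 5, n_labels = 3, dropout = 0)
  p2 <- random_params(cfg2, v = 15, seed = 4)
  base <- swam_forward(ids, p2, cfg2)
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  permuted <- swam_forward(ids[perm], p2, cfg2)
  expect_equal(permuted$A, base$A[, perm])
  expect_equal(permuted$yhat, base$yhat)
})

test_that("batched forward agrees with the single-document composition", {
  cfg <- swam_config(k = 4, d_c = 6, d_e = 5, n_labels = 3, dropout = 0)
  p <- random_params(cfg, v = 30, seed = 5)
  set.seed(21)
  docs <- lapply(c(9, 4, 12, 1), function(n) sample(3:30, n, replace = TRUE))
  batch <- swam:::swam_batch_forward(docs, p, cfg)
  for (i in seq_along(docs)) {
    expect_lt(max(abs(batch$yhat[i, ] - swam_forward(docs[[i]], p, cfg)$yhat)),
              1e-10)
  }
  cfgm <- swam_config(k = 4, d_c = 6, d_e = 5, n_labels = 3, dropout = 0,
                      attention = "max_pool")
  pm <- random_params(cfgm, v = 30, seed = 6)
  batchm <- swam:::swam_batch_forward(docs, pm, cfgm)
  for (i in seq_along(docs)) {
    expect_lt(max(abs(batchm$yhat[i, ] -
                        swam_forward(docs[[i]], pm, cfgm)$yhat)), 1e-10)
  }
})

test_that("checkpoints reload bit-exactly", {
  cfg <- swam_config(k = 2, d_c = 3, d_e = 4, n_labels = 2, dropout = 0)
  p <- random_params(cfg, v = 10, seed = 7)
  fit <- structure(list(params = p, model_config = cfg,
                        best_epoch = 1L), class = "swam_fit")
  tf <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(fit, tf)
  back <- read_checkpoint(tf)
  expect_identical(back$params, fit$params)
})
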