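# Architecture contracts: attention algebra, generator geometry, encoder
# routing, discriminator and classifier heads.

test_that("scaled attention obeys its closed-form special cases", {
  set.seed(1)
  # single token: softmax of a scalar is 1, output is V exactly
  Q <- matrix(rnorm(3), 1, 3); K <- matrix(rnorm(3), 1, 3)
  V <- matrix(rnorm(3), 1, 3)
  expect_identical(scaled_attention(Q, K, V, 2), V)

  # identical keys: uniform weights, every output row is the mean of V
  K2 <- matrix(1, 4, 3)
  Q2 <- matrix(rnorm(2 * 3), 2, 3)
  V2 <- matrix(rnorm(4 * 3), 4, 3)
  out <- scaled_attention(Q2, K2, V2, 1.7)
  expect_equal(out, matrix(colMeans(V2), 2, 3, byrow = TRUE),
               tolerance = 1e-12)

  # worked example against independent arithmetic
  Q3 <- rbind(c(1, 0), c(0, 1)); K3 <- diag(2)
  V3 <- rbind(c(1, 0), c(0, 2))
  S <- Q3 %*% t(K3) / 1
  P <- exp(S) / rowSums(exp(S))
  expect_equal(scaled_attention(Q3, K3, V3, 1), P %*% V3, tolerance = 1e-12)

  # attention weights form a row-stochastic matrix (probe with V = I)
  for (i in 1:20) {
    tq <- sample(1:5, 1); tk <- sample(1:5, 1); d <- sample(1:4, 1)
    W <- scaled_attention(matrix(rnorm(tq * d), tq, d),
                          matrix(rnorm(tk * d), tk, d),
                          diag(tk), sqrt(d))
    expect_equal(rowSums(W), rep(1, tq), tolerance = 1e-6)
    expect_true(all(W >= 0))
  }
  expect_error(scaled_attention(Q3, K3, V3, 0), "positive")
})

test_that("multi-head attention equals per-slice attention, any head count", {
  set.seed(2)
  x <- matrix(rnorm(5 * 8), 5, 8)
  # h = 1 is plain scaled attention over the full width
  expect_equal(multi_head_attention(x, 1), scaled_attention(x, x, x, sqrt(8)),
               tolerance = 1e-12)
  # h = 2 equals manually slicing, attending and concatenating
  man <- cbind(scaled_attention(x[, 1:4], x[, 1:4], x[, 1:4], 2),
               scaled_attention(x[, 5:8], x[, 5:8], x[, 5:8], 2))
  expect_equal(multi_head_attention(x, 2), man, tolerance = 1e-12)
  # shape contract for every valid h
  for (h in c(1, 2, 4, 8)) {
    expect_equal(dim(multi_head_attention(x, h)), dim(x))
  }
  expect_error(multi_head_attention(x, 3), "divisible")
})

test_that("tape attention equals the plain multi-head implementation", {
  mc <- tiny_model_config(h = 2)
  m <- ccan_model(mc, seed = 3)
  set.seed(4)
  x <- array(rnorm(3 * mc$t * mc$D), c(3, mc$t, mc$D))
  tape <- ccan:::ad_tape()
  lv <- ccan:::param_leaves(tape, m$params, track = FALSE)
  xn <- ccan:::ad_const(tape, x)
  got <- ccan:::adv(ccan:::attention_t(tape, lv, "enc.self_t", xn, xn, xn,
                                       mc$h, mc$d, mc$k))
  w <- list(Wq = m$params[["enc.self_t.Wq"]], Wk = m$params[["enc.self_t.Wk"]],
            Wv = m$params[["enc.self_t.Wv"]], bq = m$params[["enc.self_t.bq"]],
            bk = m$params[["enc.self_t.bk"]], bv = m$params[["enc.self_t.bv"]])
  want <- multi_head_attention(x, mc$h, weights = w, k = mc$k)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("generator emits the token geometry given by the pooling arithmetic", {
  # published-scale case: C=22, T=1000, L=25, pool 75/15
  mc <- model_config(C = 22, T = 1000, M = 4, L = 25, n_kernels = 40, h = 8,
                     pool_len = 75, pool_stride = 15, dropout_p = 0)
  t_expect <- floor((1000 - 25 + 1 - 75) / 15) + 1
  expect_equal(mc$t, t_expect)
  m <- ccan_model(mc, seed = 5)
  set.seed(6)
  X <- array(rnorm(4 * 22 * 1000), c(4, 22, 1000))
  tok <- generator_forward(m, X)
  expect_equal(dim(tok), c(4, t_expect, 80))

  # zero input stays finite in eval mode
  z <- generator_forward(m, array(0, c(2, 22, 1000)))
  expect_true(all(is.finite(z)))

  # batch equivariance with frozen statistics
  tok2 <- generator_forward(m, X[c(3, 1, 4, 2), , ])
  expect_equal(tok2, tok[c(3, 1, 4, 2), , ], tolerance = 1e-12)

  expect_error(model_config(C = 4, T = 20, M = 2, L = 25), "L")
})

test_that("cross-encoder target stream is blind to the source stream", {
  mc <- tiny_model_config()
  m <- ccan_model(mc, seed = 7)
  set.seed(8)
  tok <- function() array(rnorm(3 * mc$t * mc$D), c(3, mc$t, mc$D))
  tgt <- tok()
  a <- cross_encoder_forward(m, tok(), tgt)
  b <- cross_encoder_forward(m, tok(), tgt)
  expect_identical(a$tgt, b$tgt)
  expect_false(identical(a$src, b$src))
  expect_equal(dim(a$src), c(3, mc$t, mc$D))
  expect_equal(dim(a$tgt), c(3, mc$t, mc$D))
  # target-only path (test time) gives the same target output
  c0 <- cross_encoder_forward(m, NULL, tgt)
  expect_identical(c0$tgt, a$tgt)
  expect_null(c0$src)
  expect_error(cross_encoder_forward(m, tok()[, , 1:4], tgt), "width")
})

test_that("with identity projections the target self-attention reduces to scaled attention", {
  mc <- tiny_model_config(h = 1)
  m <- ccan_model(mc, seed = 9)
  D <- mc$D
  # identity-equivalent weights: unit projections, zero FFN, plain LN
  for (nm in c("Wq", "Wk", "Wv")) m$params[[paste0("enc.self_t.", nm)]] <- diag(D)
  for (nm in c("bq", "bk", "bv")) m$params[[paste0("enc.self_t.", nm)]] <- numeric(D)
  m$params[["enc.ffn_t.W1"]] <- matrix(0, D, 4 * D)
  m$params[["enc.ffn_t.W2"]] <- matrix(0, 4 * D, D)
  m$params[["enc.ffn_t.b1"]] <- numeric(4 * D)
  m$params[["enc.ffn_t.b2"]] <- numeric(D)
  m$params[["enc.ffn_t.g"]] <- rep(1, D)
  m$params[["enc.ffn_t.b"]] <- numeric(D)
  set.seed(10)
  x <- array(rnorm(1 * mc$t * D), c(1, mc$t, D))
  got <- cross_encoder_forward(m, NULL, x)$tgt[1, , ]
  att <- scaled_attention(x[1, , ], x[1, , ], x[1, , ], mc$k)
  ln <- t(apply(att, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)))
  expect_equal(got, ln, tolerance = 1e-10)
})

test_that("discriminator applies layer norm then an affine map to r units", {
  for (r in 2:5) {
    mc <- tiny_model_config(r = r)
    m <- ccan_model(mc, seed = r)
    f <- matrix(rnorm(6 * mc$feat_dim), 6)
    expect_equal(dim(discriminator_forward(m, f)), c(6, r))
  }
  mc <- tiny_model_config(r = 3)
  m <- ccan_model(mc, seed = 11)
  m$params[["disc.bW"]] <- c(0.3, -0.2, 0.9)
  # constant feature vector -> LN output zero -> output equals the bias
  cst <- matrix(5, 2, mc$feat_dim)
  out <- discriminator_forward(m, cst)
  expect_equal(out, matrix(c(0.3, -0.2, 0.9), 2, 3, byrow = TRUE),
               tolerance = 1e-10)
  # a batch of one is valid: layer norm is per sample
  expect_equal(dim(discriminator_forward(m, cst[1, , drop = FALSE])), c(1, 3))
})

test_that("dual classifiers are independent softmax heads", {
  mc <- tiny_model_config(M = 3)
  m <- ccan_model(mc, seed = 12)
  f <- matrix(rnorm(5 * mc$feat_dim), 5)
  ps <- classifier_forward(m, f)
  expect_equal(rowSums(ps$probs1), rep(1, 5), tolerance = 1e-6)
  expect_equal(rowSums(ps$probs2), rep(1, 5), tolerance = 1e-6)
  # freshly initialised heads disagree
  expect_false(isTRUE(all.equal(ps$probs1, ps$probs2)))
  # identical head parameters give identical outputs
  m$params[["cls.h2.W"]] <- m$params[["cls.h1.W"]]
  m$params[["cls.h2.b"]] <- m$params[["cls.h1.b"]]
  ps2 <- classifier_forward(m, f)
  expect_identical(ps2$probs1, ps2$probs2)
})

test_that("average_predict takes the argmax of the mean with low-index ties", {
  expect_equal(average_predict(matrix(c(0.6, 0.4), 1), matrix(c(0.2, 0.8), 1)),
               1L)
  p <- matrix(c(0.3, 0.7, 0.9, 0.1), 2, byrow = TRUE)
  expect_equal(average_predict(p, p), max.col(p) - 1L)
  expect_equal(average_predict(matrix(c(0.5, 0.5), 1), matrix(c(0.5, 0.5), 1)),
               0L)
  expect_error(average_predict(matrix(0.5, 1, 2), matrix(0.5, 2, 2)),
               "shapes")
})

test_that("non-shared generators emit matching token geometry", {
  mc <- model_config(C = 8, T = 250, M = 2, L = 10, n_kernels = 8, h = 2,
                     pool_len = 30, pool_stride = 12,
                     shared_generator = FALSE,
                     source_C = 12, source_T = 400, source_L = 25)
  expect_equal(mc$geom_s$t, mc$geom_t$t)
  m <- ccan_model(mc, seed = 13)
  expect_true(any(grepl("^gens\\.", names(m$params))))
  tok_t <- generator_forward(m, array(rnorm(2 * 8 * 250), c(2, 8, 250)),
                             domain = "target")
  tok_s <- generator_forward(m, array(rnorm(2 * 12 * 400), c(2, 12, 400)),
                             domain = "source")
  expect_equal(dim(tok_t), dim(tok_s))
})

test_that("model checkpoints round-trip and reject mismatched manifests", {
  mc <- tiny_model_config()
  m <- ccan_model(mc, seed = 14)
  m$bn[["t.p1"]] <- list(mean = rnorm(4), var = runif(4))
  dir <- file.path(tempdir(), "ckpt-test")
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_equal(m2$params, m$params)
  expect_equal(m2$bn[["t.p1"]], m$bn[["t.p1"]])
  # corrupt the manifest: drop a parameter
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  meta$shapes[["disc.W"]] <- NULL
  jsonlite::write_json(meta, file.path(dir, "config.json"), auto_unbox = TRUE)
  expect_error(load_model(dir), "manifest")
})
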