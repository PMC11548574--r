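# Reverse-mode autodiff engine: every op's analytic gradient is checked
# against central finite differences on small random inputs.

ad <- function(name) get(name, asNamespace("ccan"))

check_op <- function(build, x0, tol = 1e-5, extra = NULL) {
  # build(tape, xnode, extra_nodes) must return a node; the loss is a fixed
  # random projection of its output so every entry matters.
  tape <- ad("ad_tape")()
  xn <- ad("ad_leaf")(tape, x0)
  out <- build(tape, xn, extra)
  set.seed(99)
  wproj <- array(rnorm(length(ad("adv")(out))), dim(ad("adv")(out)))
  loss <- ad("ad_sum_all")(tape, ad("ad_mul")(tape, out,
                                              ad("ad_const")(tape, wproj)))
  grads <- ad("ad_backward")(tape, loss)
  ag <- grads[[xn$id]]
  f <- function(x) {
    tape <- ad("ad_tape")()
    xn <- ad("ad_const")(tape, x)
    out <- build(tape, xn, extra)
    sum(ad("adv")(out) * wproj)
  }
  ng <- num_grad(f, x0)
  expect_lt(max(abs(ag - ng)) / (max(abs(ng)) + 1e-10), tol)
}

test_that("elementwise and linear-algebra ops differentiate correctly", {
  set.seed(1)
  W <- matrix(rnorm(12), 4, 3)
  check_op(function(tp, x, e) ad("ad_matmul")(tp, x, ad("ad_const")(tp, W)),
           matrix(rnorm(8), 2, 4))
  check_op(function(tp, x, e) ad("ad_matmul")(tp, ad("ad_const")(tp, W), x),
           matrix(rnorm(6), 3, 2))
  check_op(function(tp, x, e) ad("ad_elu")(tp, x), matrix(rnorm(20), 4, 5))
  check_op(function(tp, x, e) ad("ad_sqrt")(tp, ad("ad_mul")(tp, x, x), 1e-3),
           matrix(runif(6) + 0.5, 2, 3))
  check_op(function(tp, x, e) ad("ad_log_clamp")(tp, x),
           matrix(runif(6) + 0.1, 2, 3))
  denom <- matrix(runif(4) + 1, 2, 2)
  check_op(function(tp, x, e) {
    ad("ad_div")(tp, x, ad("ad_const")(tp, denom))
  }, matrix(rnorm(4), 2, 2))
  base <- matrix(rnorm(12), 3, 4)
  check_op(function(tp, x, e) {
    ad("ad_add_bias")(tp, ad("ad_const")(tp, base), x, tile = 2L)
  }, rnorm(2))
})

test_that("shape ops differentiate correctly", {
  set.seed(2)
  check_op(function(tp, x, e) ad("ad_aperm")(tp, x, c(2, 1, 3),
                                             dims = c(3, 8)),
           array(rnorm(24), c(2, 3, 4)))
  check_op(function(tp, x, e) ad("ad_reshape")(tp, x, c(6, 4)),
           array(rnorm(24), c(2, 3, 4)))
  other <- array(rnorm(12), c(2, 3, 2))
  check_op(function(tp, x, e) {
    ad("ad_concat_last")(tp, x, ad("ad_const")(tp, other))
  }, array(rnorm(18), c(2, 3, 3)))
  other2 <- matrix(rnorm(6), 2, 3)
  check_op(function(tp, x, e) {
    ad("ad_rbind")(tp, x, ad("ad_const")(tp, other2))
  }, matrix(rnorm(9), 3, 3))
  check_op(function(tp, x, e) ad("ad_slice_first")(tp, x, c(3, 1)),
           array(rnorm(36), c(4, 3, 3)))
  check_op(function(tp, x, e) ad("ad_unfold_time")(tp, x, 3L),
           array(rnorm(2 * 7 * 2), c(2, 7, 2)))
})

test_that("batched matmuls differentiate correctly", {
  set.seed(3)
  B <- array(rnorm(3 * 2 * 4), c(3, 2, 4))
  for (ta in c(FALSE, TRUE)) for (tb in c(FALSE, TRUE)) {
    Bv <- if (tb) aperm(B, c(2, 1, 3)) else B
    Av <- if (ta) array(rnorm(3 * 2 * 4), c(3, 2, 4)) else
                  array(rnorm(2 * 3 * 4), c(2, 3, 4))
    check_op(function(tp, x, e) {
      ad("ad_bmm")(tp, x, ad("ad_const")(tp, Bv), ta, tb)
    }, Av)
  }
  # shared-weight form, gradient w.r.t. the slices, the weight and the bias
  W <- matrix(rnorm(3 * 2), 3, 2)
  bias <- rnorm(2)
  check_op(function(tp, x, e) {
    ad("ad_bmm_sharedB")(tp, x, ad("ad_const")(tp, W),
                         b = ad("ad_const")(tp, bias),
                         r = 4, c = 3, n = 2)
  }, array(rnorm(4 * 3 * 2), c(4, 3, 2)))
  A <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
  check_op(function(tp, x, e) {
    ad("ad_bmm_sharedB")(tp, ad("ad_const")(tp, A), x, r = 4, c = 3, n = 2)
  }, W)
  check_op(function(tp, x, e) {
    ad("ad_bmm_sharedB")(tp, ad("ad_const")(tp, A), ad("ad_const")(tp, W),
                         b = x, r = 4, c = 3, n = 2)
  }, bias)
})

test_that("softmax and normalisation layers differentiate correctly", {
  set.seed(4)
  check_op(function(tp, x, e) ad("ad_softmax_rows")(tp, x),
           matrix(rnorm(12), 3, 4), tol = 1e-4)
  g <- rnorm(4); b <- rnorm(4)
  check_op(function(tp, x, e) {
    ad("ad_layernorm_rows")(tp, x, ad("ad_const")(tp, g), ad("ad_const")(tp, b))
  }, matrix(rnorm(20), 5, 4), tol = 1e-4)
  xfix <- matrix(rnorm(20), 5, 4)
  check_op(function(tp, x, e) {
    ad("ad_layernorm_rows")(tp, ad("ad_const")(tp, xfix),
                            x, ad("ad_const")(tp, b))
  }, g)
  bnenv <- new.env()
  check_op(function(tp, x, e) {
    ad("ad_batchnorm_cols")(tp, x, ad("ad_const")(tp, g), ad("ad_const")(tp, b),
                            bnenv, "k", training = TRUE)
  }, matrix(rnorm(24), 6, 4), tol = 1e-4)
})

test_that("softmax rows sum to one and batch-norm tracks running stats", {
  set.seed(5)
  tape <- ad("ad_tape")()
  p <- ad("adv")(ad("ad_softmax_rows")(tape, ad("ad_const")(tape,
        matrix(rnorm(40), 8, 5))))
  expect_equal(rowSums(p), rep(1, 8), tolerance = 1e-12)

  bnenv <- new.env()
  x <- matrix(rnorm(300, mean = 3, sd = 2), 100, 3)
  g1 <- rep(1, 3); b0 <- rep(0, 3)
  tape <- ad("ad_tape")()
  y <- ad("adv")(ad("ad_batchnorm_cols")(tape, ad("ad_const")(tape, x),
        ad("ad_const")(tape, g1), ad("ad_const")(tape, b0), bnenv, "k", TRUE))
  expect_lt(max(abs(colMeans(y))), 1e-10)
  # first training pass seeds the running statistics with the batch stats
  expect_equal(bnenv$k$mean, colMeans(x), tolerance = 1e-10)
  # eval mode uses the stored statistics and is deterministic
  tape <- ad("ad_tape")()
  y2 <- ad("adv")(ad("ad_batchnorm_cols")(tape, ad("ad_const")(tape, x),
        ad("ad_const")(tape, g1), ad("ad_const")(tape, b0), bnenv, "k", FALSE))
  tape <- ad("ad_tape")()
  y3 <- ad("adv")(ad("ad_batchnorm_cols")(tape, ad("ad_const")(tape, x),
        ad("ad_const")(tape, g1), ad("ad_const")(tape, b0), bnenv, "k", FALSE))
  expect_identical(y2, y3)
})

test_that("gradients flow correctly through a full composite network", {
  mc <- tiny_model_config()
  m <- ccan_model(mc, seed = 7)
  set.seed(8)
  Xs <- array(rnorm(4 * 3 * 60), c(4, 3, 60))
  Xt <- array(rnorm(4 * 3 * 60), c(4, 3, 60))
  loss_at <- function(params, track = FALSE) {
    tape <- ad("ad_tape")()
    lv <- ad("param_leaves")(tape, params, track = track)
    fe <- ad("features_t")(tape, lv, mc, Xs, Xt, training = FALSE, bn = m$bn)
    ds <- ad("discriminator_t")(tape, lv, fe$src)
    dt <- ad("discriminator_t")(tape, lv, fe$tgt)
    ls <- ad("dis_loss_t")(tape, ds, dt, c(0, 1, 0, 1), c(0, 1, 1, 0), 1e-8)
    list(tape = tape, lv = lv, node = ls$dis)
  }
  r <- loss_at(m$params, track = TRUE)
  grads <- ad("ad_backward")(r$tape, r$node)
  for (nm in c("gen.p1.Wt", "gen.p1.Ws", "gen.p2.Wt", "enc.self_s.Wk",
               "enc.cross1.Wv", "enc.cross3.Wq", "enc.ffn_s.W2", "disc.g")) {
    ag <- grads[[r$lv[[nm]]$id]]
    pv <- m$params[[nm]]
    set.seed(match(nm, names(m$params)))
    idx <- sample(length(pv), min(4, length(pv)))
    ng <- vapply(idx, function(i) {
      pp <- m$params; pp[[nm]][i] <- pv[i] + 1e-6
      pm <- m$params; pm[[nm]][i] <- pv[i] - 1e-6
      (ad("adv")(loss_at(pp)$node) - ad("adv")(loss_at(pm)$node)) / 2e-6
    }, numeric(1))
    denom <- max(abs(ng), 1e-6)
    expect_lt(max(abs(ag[idx] - ng)) / denom, 1e-3, label = nm)
  }
})
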