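# Two-step training: batching policy, parameter partition, optimisation
# smoke tests, determinism and evaluation arithmetic.

test_that("batches mix the domains half and half, deterministically", {
  sd <- tiny_scenario_data(n_per_class = 20)
  bs <- make_batches(sd, 8, seed = 1)
  expect_equal(length(bs), ceiling(dim(sd$target_train$X)[1] / 4))
  expect_equal(dim(bs[[1]]$Xs)[1], 4)
  expect_equal(dim(bs[[1]]$Xt)[1], 4)
  bs2 <- make_batches(sd, 8, seed = 1)
  expect_identical(bs, bs2)
  expect_false(identical(bs, make_batches(sd, 8, seed = 2)))

  # ablation: both halves come from the target-train pool
  bo <- make_batches(sd, 8, seed = 1, use_source = FALSE)
  tgt_vals <- sd$target_train$X[, 1, 1]
  expect_true(all(bo[[1]]$Xs[, 1, 1] %in% tgt_vals))

  # recycling message when the pool is smaller than a half-batch
  small <- tiny_scenario_data(n_per_class = 2)
  expect_message(make_batches(small, 64, seed = 1), "recycles")
})

test_that("step 1 never touches classifiers; step 2 never touches the discriminator", {
  mc <- tiny_model_config()
  tc <- train_config(epochs = 1, batch = 8, seed = 1)
  m0 <- ccan_model(mc, seed = 1)
  b <- tiny_batch(mc, n = 4)
  opt <- ccan:::adam_state()
  r1 <- train_step1(m0, b, opt, tc)
  expect_false(r1$skipped)
  cls_names <- grep("^cls\\.", names(m0$params), value = TRUE)
  for (nm in cls_names) expect_identical(r1$model$params[[nm]], m0$params[[nm]])
  gen_names <- grep("^(gen|enc|disc)\\.", names(m0$params), value = TRUE)
  expect_true(any(vapply(gen_names, function(nm) {
    !identical(r1$model$params[[nm]], m0$params[[nm]])
  }, logical(1))))

  opt2 <- ccan:::adam_state()
  r2 <- train_step2(m0, b, opt2, tc)
  disc_names <- grep("^disc\\.", names(m0$params), value = TRUE)
  for (nm in disc_names) expect_identical(r2$model$params[[nm]], m0$params[[nm]])
  expect_false(identical(r2$model$params[["cls.h1.W"]], m0$params[["cls.h1.W"]]))
})

test_that("a batch with fewer than two shared classes is skipped untouched", {
  mc <- tiny_model_config()
  m0 <- ccan_model(mc, seed = 2)
  b <- tiny_batch(mc, n = 4)
  b$ys <- rep(0L, 4); b$yt <- rep(1L, 4)      # no shared class
  opt <- ccan:::adam_state()
  r <- train_step1(m0, b, opt, train_config(batch = 8))
  expect_true(r$skipped)
  expect_identical(r$model$params, m0$params)
  expect_true(is.na(r$report$L_dis))
})

test_that("repeated step-1 updates shrink the alignment ratio loss", {
  mc <- tiny_model_config()
  tc <- train_config(epochs = 1, batch = 8, seed = 3)
  m <- ccan_model(mc, seed = 3)
  b <- tiny_batch(mc, n = 6, separation = 2)
  opt <- ccan:::adam_state()
  first <- NULL
  set.seed(3)
  for (i in 1:50) {
    r <- train_step1(m, b, opt, tc)
    m <- r$model
    if (is.null(first)) first <- r$report$L_dis
  }
  expect_lt(r$report$L_dis, first)
})

test_that("repeated step-2 updates drive the classification loss below chance", {
  mc <- tiny_model_config()
  tc <- train_config(epochs = 1, batch = 8, seed = 4, lr = 2e-3)
  m <- ccan_model(mc, seed = 4)
  b <- tiny_batch(mc, n = 6, separation = 4)  # linearly separable classes
  opt <- ccan:::adam_state()
  set.seed(4)
  for (i in 1:50) {
    r <- train_step2(m, b, opt, tc)
    m <- r$model
  }
  expect_lt(r$report$L_cls, log(2))
  # with w_cen = 0 the joint loss is the classification loss
  tc0 <- train_config(batch = 8, w_cen = 0)
  r0 <- train_step2(m, b, ccan:::adam_state(), tc0)
  expect_equal(r0$report$L_joint, r0$report$L_cls)
})

test_that("fit is deterministic, honours epochs = 0 and records history", {
  sd <- tiny_scenario_data(n_per_class = 6)
  mc <- model_config(C = 4, T = 80, M = 2, L = 5, n_kernels = 4, h = 2,
                     pool_len = 10, pool_stride = 5, r = 3, dropout_p = 0.25)
  tc <- train_config(epochs = 2, batch = 8, seed = 11)
  a <- fit(sd, mc, tc)
  b <- fit(sd, mc, tc)
  expect_identical(a$history, b$history)
  expect_identical(a$accuracy, b$accuracy)
  expect_identical(a$model$params, b$model$params)
  expect_equal(nrow(a$history), 2 * ceiling(6 / 4))
  expect_true(all(c("L_corr", "L_dis", "L_cls", "L_cen", "L_joint")
                  %in% names(a$history)))

  z <- fit(sd, mc, train_config(epochs = 0, batch = 8, seed = 11))
  expect_identical(z$model$params, ccan_model(mc, seed = 11)$params)
  expect_equal(nrow(z$history), 0)
})

test_that("ablation switches train without source data or cross-encoder", {
  sd <- tiny_scenario_data(n_per_class = 6)
  mc <- model_config(C = 4, T = 80, M = 2, L = 5, n_kernels = 4, h = 2,
                     pool_len = 10, pool_stride = 5, r = 3, dropout_p = 0)
  r1 <- fit(sd, mc, train_config(epochs = 1, batch = 8, seed = 5,
                                 use_source = FALSE))
  expect_length(r1$accuracy, 1)
  r2 <- fit(sd, mc, train_config(epochs = 1, batch = 8, seed = 5,
                                 use_cross_encoder = FALSE))
  expect_length(r2$accuracy, 1)
  # without the cross-encoder, encoder parameters receive no updates
  m0 <- ccan_model(mc, seed = 5)
  enc_names <- grep("^enc\\.", names(m0$params), value = TRUE)
  for (nm in enc_names) {
    expect_identical(r2$model$params[[nm]], m0$params[[nm]])
  }
  r3 <- fit(sd, mc, train_config(epochs = 1, batch = 8, seed = 5,
                                 use_discriminator = FALSE))
  expect_true(all(is.na(r3$history$L_dis)))
})

test_that("accuracy is the confusion-matrix trace over the total", {
  a <- matrix(c(3, 2, 1, 4), 2)           # rows = truth
  expect_equal(accuracy_from_confusion(a), 0.7)
  expect_equal(accuracy_from_confusion(diag(c(5, 7, 2))), 1)
  expect_equal(accuracy_from_confusion(matrix(c(0, 3, 3, 0), 2)), 0)
  cm <- confusion_matrix(c(0L, 0L, 1L, 1L), c(0L, 1L, 1L, 1L), 2)
  expect_equal(cm, matrix(c(1L, 0L, 1L, 2L), 2))
  expect_error(evaluate(ccan_model(tiny_model_config(), 1),
                        trial_set(array(0, c(0, 3, 60)), integer(0), 10)),
               "empty")
})
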