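# Two-step training: step 1 updates generator + cross-encoder + class
# discriminator under the alignment ratio loss; step 2 updates generator +
# cross-encoder + both classifier heads under the joint loss.  Both steps
# use ADAM, with one optimiser state per step.

#' Training configuration
#'
#' Defaults follow the published optimisation settings: ADAM with learning
#' rate 2e-4, beta1 = 0.5, beta2 = 0.999, batch size 64.
#'
#' @param lr learning rate.
#' @param beta1,beta2 ADAM moment decay rates.
#' @param batch total batch size; each batch mixes `ceiling(batch/2)`
#'   source and `floor(batch/2)` target-train samples.
#' @param epochs training epochs (one epoch sweeps the target-train set).
#' @param w_cen weight of the centre loss in the joint objective.
#' @param seed master seed for initialisation, batching and dropout.
#' @param use_source if `FALSE`, the source half of every batch is drawn
#'   from the target-train pool instead (source-ablation experiment).
#' @param use_cross_encoder if `FALSE`, generator tokens feed the heads
#'   directly.
#' @param use_discriminator if `FALSE`, step 1 is skipped entirely.
#' @param split_fraction default target train fraction, used by pipeline
#'   helpers.
#' @param warmup_epochs epochs during which step 1 is skipped (ratio-loss
#'   gradients can be unstable at random initialisation); default 0.
#' @param eps_dis denominator floor of the ratio loss.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 2e-4, beta1 = 0.5, beta2 = 0.999, batch = 64,
                         epochs = 500, w_cen = 0.1, seed = 1,
                         use_source = TRUE, use_cross_encoder = TRUE,
                         use_discriminator = TRUE, split_fraction = 0.5,
                         warmup_epochs = 0, eps_dis = 1e-8) {
  if (lr <= 0 || beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1) {
    stop("invalid ADAM hyperparameters")
  }
  if (batch < 2) stop("batch must be >= 2")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 batch = as.integer(batch), epochs = as.integer(epochs),
                 w_cen = w_cen, seed = as.integer(seed),
                 use_source = use_source,
                 use_cross_encoder = use_cross_encoder,
                 use_discriminator = use_discriminator,
                 split_fraction = split_fraction,
                 warmup_epochs = as.integer(warmup_epochs),
                 eps_dis = eps_dis),
            class = "train_config")
}

# --- ADAM ------------------------------------------------------------------

adam_state <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

adam_update <- function(params, grads, st, lr, b1, b2, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - b1^st$t
  c2 <- 1 - b2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- st$m[[nm]]; v <- st$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    st$m[[nm]] <- m; st$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / c1) / (sqrt(v / c2) + eps)
  }
  params
}

# --- batching --------------------------------------------------------------

#' Build one epoch of mixed-domain batches
#'
#' Each batch holds `ceiling(batch/2)` source and `floor(batch/2)`
#' target-train samples; the number of batches covers the target-train set
#' once.  When a pool is smaller than its half-batch, sampling recycles the
#' shuffled pool (with a one-time message).  Deterministic given `seed`.
#'
#' @param data a [assemble_scenario()] result.
#' @param batch total batch size.
#' @param seed integer seed.
#' @param use_source draw the source half from the source domain (`TRUE`)
#'   or from the target-train pool (ablation).
#' @return List of batches, each a list `Xs, ys, Xt, yt`.
#' @export
make_batches <- function(data, batch, seed = 1, use_source = TRUE) {
  half_t <- batch %/% 2L
  half_s <- batch - half_t
  src <- if (use_source) data$source else data$target_train
  tgt <- data$target_train
  n_t <- dim(tgt$X)[1]
  n_s <- dim(src$X)[1]
  if (n_t < 1 || n_s < 1) stop("both domains must be nonempty")
  old <- rng_snapshot()
  on.exit(rng_restore(old))
  set.seed(as.integer(seed))
  n_batches <- max(1L, ceiling(n_t / half_t))
  if (n_s < half_s || n_t < half_t) {
    message("pool smaller than a half-batch; sampling recycles the pool")
  }
  recycle <- function(n, need) {
    idx <- integer(0)
    while (length(idx) < need) idx <- c(idx, sample(n))
    idx[seq_len(need)]
  }
  ti <- recycle(n_t, n_batches * half_t)
  si <- recycle(n_s, n_batches * half_s)
  lapply(seq_len(n_batches), function(b) {
    ts <- ti[((b - 1L) * half_t + 1L):(b * half_t)]
    ss <- si[((b - 1L) * half_s + 1L):(b * half_s)]
    list(Xs = src$X[ss, , , drop = FALSE], ys = src$y[ss],
         Xt = tgt$X[ts, , , drop = FALSE], yt = tgt$y[ts])
  })
}

# --- tape losses -----------------------------------------------------------

# Mean features per shared class via constant averaging matrices, then the
# corresponding / non-corresponding distances and their ratio.
dis_loss_t <- function(tape, disc_s, disc_t, ys, yt, eps) {
  shared <- sort(intersect(unique(ys), unique(yt)))
  Mt <- length(shared)
  if (Mt < 2) return(NULL)
  avg_mat <- function(y, n) {
    A <- matrix(0, Mt, n)
    for (j in seq_len(Mt)) {
      rows <- which(y == shared[j])
      A[j, rows] <- 1 / length(rows)
    }
    A
  }
  r <- ncol(adv(disc_s))
  ones <- matrix(1, r, 1)
  mean_s <- ad_matmul(tape, ad_const(tape, avg_mat(ys, length(ys))), disc_s)
  mean_t <- ad_matmul(tape, ad_const(tape, avg_mat(yt, length(yt))), disc_t)
  rowdist <- function(a, b) {
    df <- ad_sub(tape, a, b)
    rs <- ad_matmul(tape, ad_mul(tape, df, df), ad_const(tape, ones))
    ad_sqrt(tape, rs, 1e-12)
  }
  l_corr <- ad_scale(tape, ad_sum_all(tape, rowdist(mean_s, mean_t)), 1 / Mt)
  pairs <- expand.grid(m = seq_len(Mt), m2 = seq_len(Mt))
  pairs <- pairs[pairs$m != pairs$m2, ]
  sel <- function(rows) {
    S <- matrix(0, nrow(pairs), Mt)
    S[cbind(seq_len(nrow(pairs)), rows)] <- 1
    S
  }
  ms <- ad_matmul(tape, ad_const(tape, sel(pairs$m)), mean_s)
  mt <- ad_matmul(tape, ad_const(tape, sel(pairs$m2)), mean_t)
  l_ncorr <- ad_scale(tape, ad_sum_all(tape, rowdist(ms, mt)),
                      1 / (Mt * (Mt - 1)))
  l_dis <- if (adv(l_ncorr) > eps) ad_div(tape, l_corr, l_ncorr)
           else ad_scale(tape, l_corr, 1 / eps)
  list(corr = l_corr, ncorr = l_ncorr, dis = l_dis)
}

ce_loss_t <- function(tape, probs, labels, M) {
  n <- nrow(adv(probs))
  onehot <- matrix(0, n, M)
  onehot[cbind(seq_len(n), labels + 1L)] <- 1
  lp <- ad_log_clamp(tape, probs, 1e-12)
  ad_scale(tape, ad_sum_all(tape, ad_mul(tape, lp, ad_const(tape, onehot))),
           -1 / n)
}

center_loss_t <- function(tape, feat_all, labels_all, feat_t_value, yt) {
  centers <- lapply(sort(unique(yt)), function(m) {
    colMeans(feat_t_value[yt == m, , drop = FALSE])
  })
  names(centers) <- sort(unique(yt))
  rows <- which(labels_all %in% as.integer(names(centers)))
  if (!length(rows)) return(ad_const(tape, 0))
  Cm <- do.call(rbind, lapply(rows, function(i) {
    centers[[as.character(labels_all[i])]]
  }))
  counts <- table(labels_all[rows])
  w <- matrix(1 / as.numeric(counts[as.character(labels_all[rows])]),
              ncol = 1)
  df <- ad_sub(tape, ad_slice_first(tape, feat_all, rows),
               ad_const(tape, Cm))
  rs <- ad_matmul(tape, ad_mul(tape, df, df),
                  ad_const(tape, matrix(1, ncol(feat_t_value), 1)))
  dist <- ad_sqrt(tape, rs, 1e-12)
  ad_sum_all(tape, ad_mul(tape, dist, ad_const(tape, w)))
}

# --- training steps --------------------------------------------------------

step_param_names <- function(model, step) {
  nms <- names(model$params)
  pat <- if (step == 1L) "^(gen\\.|gens\\.|enc\\.|disc\\.)"
         else "^(gen\\.|gens\\.|enc\\.|cls\\.)"
  nms[grepl(pat, nms)]
}

#' One update of generator + cross-encoder + discriminator (step 1)
#'
#' Minimises the alignment ratio loss on the discriminator outputs of a
#' mixed batch.  Classifier parameters are untouched.  If fewer than two
#' corresponding classes are present in both halves of the batch, the
#' batch is skipped and the model returned unchanged.
#'
#' @param model a [ccan_model()].
#' @param batch a batch from [make_batches()].
#' @param opt optimiser state from `adam_state()` (created by [fit()]).
#' @param tcfg a [train_config()].
#' @return List `model`, `report` (losses), `skipped`.
#' @export
train_step1 <- function(model, batch, opt, tcfg = train_config()) {
  cfg <- model$cfg
  tape <- ad_tape()
  lv <- param_leaves(tape, model$params, track = TRUE)
  fe <- features_t(tape, lv, cfg, batch$Xs, batch$Xt, training = TRUE,
                   bn = model$bn, use_cross_encoder = tcfg$use_cross_encoder)
  disc_s <- discriminator_t(tape, lv, fe$src)
  disc_t <- discriminator_t(tape, lv, fe$tgt)
  ls <- dis_loss_t(tape, disc_s, disc_t, batch$ys, batch$yt, tcfg$eps_dis)
  if (is.null(ls)) {
    return(list(model = model,
                report = list(L_corr = NA_real_, L_ncorr = NA_real_,
                              L_dis = NA_real_),
                skipped = TRUE))
  }
  grads <- ad_backward(tape, ls$dis)
  upd <- step_param_names(model, 1L)
  g <- stats::setNames(lapply(upd, function(nm) grads[[lv[[nm]]$id]]), upd)
  model$params <- adam_update(model$params, g, opt, tcfg$lr, tcfg$beta1,
                              tcfg$beta2)
  list(model = model,
       report = list(L_corr = adv(ls$corr), L_ncorr = adv(ls$ncorr),
                     L_dis = adv(ls$dis)),
       skipped = FALSE)
}

#' One update of generator + cross-encoder + classifiers (step 2)
#'
#' Minimises `L_joint = L_cls + w_cen * L_cen`, with `L_cls` averaged over
#' the two classifier heads and computed on both domains of the batch, and
#' the centre loss pulling all features towards the (detached) target class
#' centres.  Discriminator parameters are untouched.
#'
#' @inheritParams train_step1
#' @return List `model`, `report`.
#' @export
train_step2 <- function(model, batch, opt, tcfg = train_config()) {
  cfg <- model$cfg
  tape <- ad_tape()
  lv <- param_leaves(tape, model$params, track = TRUE)
  fe <- features_t(tape, lv, cfg, batch$Xs, batch$Xt, training = TRUE,
                   bn = model$bn, use_cross_encoder = tcfg$use_cross_encoder)
  feat_all <- ad_rbind(tape, fe$src, fe$tgt)
  labels_all <- c(batch$ys, batch$yt)
  ps <- classifier_t(tape, lv, feat_all)
  l1 <- ce_loss_t(tape, ps[[1]], labels_all, cfg$M)
  l2 <- ce_loss_t(tape, ps[[2]], labels_all, cfg$M)
  l_cls <- ad_scale(tape, ad_add(tape, l1, l2), 0.5)
  l_cen <- center_loss_t(tape, feat_all, labels_all, adv(fe$tgt), batch$yt)
  l_joint <- ad_add(tape, l_cls, ad_scale(tape, l_cen, tcfg$w_cen))
  grads <- ad_backward(tape, l_joint)
  upd <- step_param_names(model, 2L)
  g <- stats::setNames(lapply(upd, function(nm) grads[[lv[[nm]]$id]]), upd)
  model$params <- adam_update(model$params, g, opt, tcfg$lr, tcfg$beta1,
                              tcfg$beta2)
  list(model = model,
       report = list(L_cls = adv(l_cls), L_cen = adv(l_cen),
                     L_joint = adv(l_joint)))
}

# --- fitting and evaluation ------------------------------------------------

#' Train a model on an assembled scenario
#'
#' Runs the two-step schedule: per batch, one discriminator-path update
#' (step 1) followed by one classifier-path update (step 2), both with
#' ADAM.  Records per-iteration losses, per-epoch target-test accuracy and
#' the corresponding-class alignment distance (in discriminator space) at
#' initialisation and after training.
#'
#' @param data a [assemble_scenario()] result.
#' @param mcfg a [model_config()]; its `shared_generator` flag should match
#'   `data$shared_generator`.
#' @param tcfg a [train_config()].
#' @return List with `model`, `history` (data.frame of per-iteration
#'   losses), `accuracy` (per-epoch target-test accuracy) and `alignment`
#'   (`init` / `final` mean corresponding-class distances).
#' @export
fit <- function(data, mcfg, tcfg = train_config()) {
  stopifnot(inherits(data, "scenario_data"), inherits(mcfg, "model_config"))
  if (mcfg$shared_generator != data$shared_generator) {
    warning("model and scenario disagree about generator sharing")
  }
  old <- rng_snapshot()
  on.exit(rng_restore(old))
  set.seed(tcfg$seed)
  model <- ccan_model(mcfg, seed = tcfg$seed)
  opt1 <- adam_state()
  opt2 <- adam_state()
  hist <- list()
  accs <- numeric(0)
  align0 <- alignment_distance(model, data, tcfg)
  it <- 0L
  for (epoch in seq_len(tcfg$epochs)) {
    batches <- make_batches(data, tcfg$batch, seed = tcfg$seed + epoch,
                            use_source = tcfg$use_source)
    for (b in batches) {
      it <- it + 1L
      rep1 <- list(L_corr = NA_real_, L_ncorr = NA_real_, L_dis = NA_real_)
      if (tcfg$use_discriminator && epoch > tcfg$warmup_epochs) {
        s1 <- train_step1(model, b, opt1, tcfg)
        model <- s1$model
        rep1 <- s1$report
      }
      s2 <- train_step2(model, b, opt2, tcfg)
      model <- s2$model
      vals <- c(unlist(rep1), unlist(s2$report))
      if (any(is.nan(vals) | is.infinite(vals))) {
        stop(sprintf("divergence at epoch %d: non-finite loss (%s)",
                     epoch, paste(names(vals), round(vals, 4),
                                  collapse = ", ")))
      }
      hist[[it]] <- c(epoch = epoch, iter = it, vals)
    }
    ev <- evaluate(model, data$target_test, mcfg$M)
    accs <- c(accs, ev$accuracy)
  }
  align1 <- alignment_distance(model, data, tcfg)
  history <- as.data.frame(do.call(rbind, hist))
  list(model = model, history = history, accuracy = accs,
       alignment = list(init = align0, final = align1))
}

# Mean L2 distance between corresponding-class mean features in
# discriminator space, over the full source + target-train sets.  The
# cross-attention path pairs source and target samples positionally, so
# source trials are processed in target-train-sized chunks, each paired
# with the (repeated) target-train stream.
alignment_distance <- function(model, data, tcfg = train_config()) {
  Xt <- data$target_train$X
  nt <- dim(Xt)[1]
  ns <- dim(data$source$X)[1]
  srcf <- list()
  tgtf <- NULL
  i <- 1L
  while (i <= ns) {
    j <- min(i + nt - 1L, ns)
    len <- j - i + 1L
    fe <- eval_features(model, data$source$X[i:j, , , drop = FALSE],
                        Xt = Xt[seq_len(len), , , drop = FALSE],
                        use_cross_encoder = tcfg$use_cross_encoder)
    srcf[[length(srcf) + 1L]] <- fe$src
    if (is.null(tgtf) && len == nt) tgtf <- fe$tgt
    i <- j + 1L
  }
  if (is.null(tgtf)) {
    tgtf <- eval_features(model, NULL, Xt = Xt,
                          use_cross_encoder = tcfg$use_cross_encoder)$tgt
  }
  feats <- rbind(do.call(rbind, srcf), tgtf)
  cm <- class_means(discriminator_forward(model, feats),
                    c(data$source$y, data$target_train$y),
                    c(rep("source", ns), rep("target", nt)))
  loss_corr(cm)
}

# Eval-mode encoder features for source and/or target arrays.
eval_features <- function(model, Xs, domain = "source", Xt = NULL,
                          use_cross_encoder = TRUE) {
  tape <- ad_tape()
  lv <- param_leaves(tape, model$params, track = FALSE)
  fe <- features_t(tape, lv, model$cfg, Xs, Xt, training = FALSE,
                   bn = model$bn, use_cross_encoder = use_cross_encoder)
  list(src = if (is.null(fe$src)) NULL else adv(fe$src),
       tgt = if (is.null(fe$tgt)) NULL else adv(fe$tgt))
}

#' Evaluate a model on a test trial set
#'
#' Test trials traverse the generator and the target self-attention path
#' only (no source batch exists at test time), then both classifier heads;
#' predictions average the heads.  Accuracy is the trace of the confusion
#' matrix over its total.
#'
#' @param model a [ccan_model()].
#' @param test a [trial_set()] with labels remapped to `[0, M)`.
#' @param M class count.
#' @param use_cross_encoder must match the flag the model was trained with.
#' @return List with `confusion` (`M x M` matrix, rows = true class) and
#'   `accuracy`.
#' @export
evaluate <- function(model, test, M = model$cfg$M,
                     use_cross_encoder = TRUE) {
  if (dim(test$X)[1] == 0) stop("empty test set")
  fe <- eval_features(model, Xs = NULL, Xt = test$X,
                      use_cross_encoder = use_cross_encoder)
  ps <- classifier_forward(model, fe$tgt)
  pred <- average_predict(ps$probs1, ps$probs2)
  cm <- confusion_matrix(test$y, pred, M)
  list(confusion = cm, accuracy = accuracy_from_confusion(cm))
}

#' Confusion matrix and its accuracy
#'
#' `a[i, j]` counts test samples truly of class `i - 1` predicted as class
#' `j - 1`; accuracy is `sum(diag(a)) / sum(a)`.
#'
#' @param truth,pred integer 0-based class vectors.
#' @param M class count.
#' @return `confusion_matrix`: an `M x M` integer matrix.
#' @export
confusion_matrix <- function(truth, pred, M) {
  a <- matrix(0L, M, M)
  for (i in seq_along(truth)) {
    a[truth[i] + 1L, pred[i] + 1L] <- a[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  a
}

#' @rdname confusion_matrix
#' @param a an `M x M` confusion matrix.
#' @export
accuracy_from_confusion <- function(a) sum(diag(a)) / sum(a)
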