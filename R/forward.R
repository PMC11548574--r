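# Forward passes.  Internal *_t functions operate on autodiff tape nodes
# and are shared between training (with gradients) and evaluation (constant
# leaves); the exported operations wrap them for plain arrays.

# --- generator -------------------------------------------------------------

# X node: (B, C, T) -> tokens (B, t, K) for one pathway pair; returns the
# fused (B, t, 2K) token node.
generator_t <- function(tape, lv, pfx, x, g, training, bn, bnpfx,
                        dropout_p) {
  B <- dim(adv(x))[1]
  P <- pool_matrix(g)
  Pc <- ad_const(tape, P)

  pool_drop <- function(z) {             # z: (B, T1, K)
    zp <- ad_aperm(tape, z, c(2, 1, 3), dims = c(g$T1, B * g$K))
    zp <- ad_matmul(tape, ad_const(tape, t(P)), zp)  # (t, B*K)
    zp <- ad_reshape(tape, zp, c(g$t, B, g$K))
    zp <- ad_aperm(tape, zp, c(2, 1, 3))             # (B, t, K)
    ad_dropout(tape, zp, dropout_p, training)
  }

  xt <- ad_aperm(tape, x, c(1, 3, 2))                 # (B, T, C)

  # pathway 1: temporal conv (per channel, shared kernels), then spatial
  # conv across the C x K feature maps.  The per-channel convolution runs
  # as a batched matmul over channel slices so the (k, c)-ordered feature
  # block never needs a large permutation.
  w1 <- ad_unfold_time(tape, xt, g$L, dims = c(B * g$T1, g$L, g$C))
  c1 <- ad_bmm_sharedB(tape, w1, lv[[paste0(pfx, ".p1.Wt")]],
                       b = lv[[paste0(pfx, ".p1.bt")]],
                       dims = c(B * g$T1, g$K * g$C),
                       r = B * g$T1, c = g$L, n = g$C)
  c1 <- ad_add_bias(tape, ad_matmul(tape, c1, lv[[paste0(pfx, ".p1.Ws")]]),
                    lv[[paste0(pfx, ".p1.bs")]])      # (B*T1, K)
  c1 <- ad_batchnorm_cols(tape, c1, lv[[paste0(pfx, ".p1.bn.gamma")]],
                          lv[[paste0(pfx, ".p1.bn.beta")]], bn,
                          paste0(bnpfx, ".p1"), training)
  c1 <- ad_elu(tape, c1)
  c1 <- ad_reshape(tape, c1, c(B, g$T1, g$K))
  t1 <- pool_drop(c1)

  # pathway 2: spatial conv first, then temporal conv across K maps
  x2 <- ad_reshape(tape, xt, c(B * g$T, g$C))
  c2 <- ad_add_bias(tape, ad_matmul(tape, x2, lv[[paste0(pfx, ".p2.Ws")]]),
                    lv[[paste0(pfx, ".p2.bs")]])      # (B*T, K)
  c2 <- ad_reshape(tape, c2, c(B, g$T, g$K))
  w2 <- ad_unfold_time(tape, c2, g$L, dims = c(B * g$T1, g$L * g$K))
  c2 <- ad_add_bias(tape, ad_matmul(tape, w2, lv[[paste0(pfx, ".p2.Wt")]]),
                    lv[[paste0(pfx, ".p2.bt")]])      # (B*T1, K)
  c2 <- ad_batchnorm_cols(tape, c2, lv[[paste0(pfx, ".p2.bn.gamma")]],
                          lv[[paste0(pfx, ".p2.bn.beta")]], bn,
                          paste0(bnpfx, ".p2"), training)
  c2 <- ad_elu(tape, c2)
  c2 <- ad_reshape(tape, c2, c(B, g$T1, g$K))
  t2 <- pool_drop(c2)

  ad_concat_last(tape, t1, t2)                        # (B, t, 2K)
}

pool_matrix <- function(g) {
  P <- matrix(0, g$T1, g$t)
  for (tt in seq_len(g$t)) {
    i0 <- (tt - 1L) * g$pool_stride
    P[(i0 + 1):(i0 + g$pool_len), tt] <- 1 / g$pool_len
  }
  P
}

# --- attention -------------------------------------------------------------

# One multi-head attention block on tape.  q_in/k_in/v_in: (B, t, D) nodes
# feeding the three learned projections of block `pfx`.
attention_t <- function(tape, lv, pfx, q_in, k_in, v_in, h, d, kscale) {
  B <- dim(adv(q_in))[1]
  t <- dim(adv(q_in))[2]
  D <- h * d

  to_heads <- function(x, W, b) {
    xf <- ad_reshape(tape, x, c(B * t, D))
    xf <- ad_add_bias(tape, ad_matmul(tape, xf, lv[[paste0(pfx, ".", W)]]),
                      lv[[paste0(pfx, ".", b)]])
    xf <- ad_reshape(tape, xf, c(B, t, d, h))
    xf <- ad_aperm(tape, xf, c(2, 3, 1, 4))           # (t, d, B, h)
    ad_reshape(tape, xf, c(t, d, B * h))
  }
  Q <- to_heads(q_in, "Wq", "bq")
  K <- to_heads(k_in, "Wk", "bk")
  V <- to_heads(v_in, "Wv", "bv")

  S <- ad_scale(tape, ad_bmm(tape, Q, K, transB = TRUE), 1 / kscale)
  S <- ad_aperm(tape, S, c(1, 3, 2))                  # (t, B*h, t)
  S <- ad_reshape(tape, S, c(t * B * h, t))
  P <- ad_softmax_rows(tape, S)
  P <- ad_reshape(tape, P, c(t, B * h, t))
  P <- ad_aperm(tape, P, c(1, 3, 2))                  # (t, t, B*h)
  O <- ad_bmm(tape, P, V)                             # (t, d, B*h)
  O <- ad_reshape(tape, O, c(t, d, B, h))
  O <- ad_aperm(tape, O, c(3, 1, 2, 4))               # (B, t, d, h)
  ad_reshape(tape, O, c(B, t, D))
}

# Feed-forward sublayer with residual connection and layer normalisation:
# y = LN(x + W2 ELU(W1 x + b1) + b2).
ffn_ln_t <- function(tape, lv, pfx, x) {
  dms <- dim(adv(x))
  B <- dms[1]; t <- dms[2]; D <- dms[3]
  xf <- ad_reshape(tape, x, c(B * t, D))
  hmid <- ad_elu(tape, ad_add_bias(tape,
                                   ad_matmul(tape, xf, lv[[paste0(pfx, ".W1")]]),
                                   lv[[paste0(pfx, ".b1")]]))
  out <- ad_add_bias(tape, ad_matmul(tape, hmid, lv[[paste0(pfx, ".W2")]]),
                     lv[[paste0(pfx, ".b2")]])
  res <- ad_add(tape, xf, out)
  y <- ad_layernorm_rows(tape, res, lv[[paste0(pfx, ".g")]],
                         lv[[paste0(pfx, ".b")]])
  ad_reshape(tape, y, c(B, t, D))
}

# Cross-encoder on tape.  The target stream is self-attention + FFN/LN and
# never sees the source; the source stream is self-attention followed by
# three cross-attention operations fed by the target stream
# ((i) V from source, Q,K from target; (ii) Q from source, K,V from target;
# (iii) K from source, Q,V from target), computed in parallel from the
# self-attended source stream and summed, then FFN/LN.  The parallel sum
# keeps operation (i)'s value path open, so source-sample information
# survives into the aligned features; a purely sequential chain ends on
# target-value mixtures and erases it.
encoder_t <- function(tape, lv, tok_s, tok_t, cfg) {
  h <- cfg$h; d <- cfg$d; k <- cfg$k
  tg <- attention_t(tape, lv, "enc.self_t", tok_t, tok_t, tok_t, h, d, k)
  tg <- ffn_ln_t(tape, lv, "enc.ffn_t", tg)
  if (is.null(tok_s)) return(list(src = NULL, tgt = tg))
  s <- attention_t(tape, lv, "enc.self_s", tok_s, tok_s, tok_s, h, d, k)
  c1 <- attention_t(tape, lv, "enc.cross1", tg, tg, s, h, d, k)
  c2 <- attention_t(tape, lv, "enc.cross2", s, tg, tg, h, d, k)
  c3 <- attention_t(tape, lv, "enc.cross3", tg, s, tg, h, d, k)
  s <- ad_add(tape, ad_add(tape, c1, c2), c3)
  s <- ffn_ln_t(tape, lv, "enc.ffn_s", s)
  list(src = s, tgt = tg)
}

# Flatten tokens (B, t, D) -> (B, t*D)
flatten_t <- function(tape, x) {
  dms <- dim(adv(x))
  ad_reshape(tape, ad_aperm(tape, x, c(1, 3, 2)), c(dms[1], dms[2] * dms[3]))
}

discriminator_t <- function(tape, lv, feats) {
  z <- ad_layernorm_rows(tape, feats, lv[["disc.g"]], lv[["disc.b"]])
  ad_add_bias(tape, ad_matmul(tape, z, lv[["disc.W"]]), lv[["disc.bW"]])
}

classifier_t <- function(tape, lv, feats) {
  p1 <- ad_softmax_rows(tape, ad_add_bias(tape,
        ad_matmul(tape, feats, lv[["cls.h1.W"]]), lv[["cls.h1.b"]]))
  p2 <- ad_softmax_rows(tape, ad_add_bias(tape,
        ad_matmul(tape, feats, lv[["cls.h2.W"]]), lv[["cls.h2.b"]]))
  list(p1, p2)
}

# Leaves for all parameters on a fresh tape (tracked when training).
param_leaves <- function(tape, params, track) {
  if (track) lapply(params, function(p) ad_leaf(tape, p))
  else lapply(params, function(p) ad_const(tape, p))
}

# --- exported operations ---------------------------------------------------

#' Generator forward pass
#'
#' Runs a batch of trials through the two-pathway convolutional generator
#' and returns the fused token sequence.
#'
#' @param model a [ccan_model()].
#' @param X numeric array `batch x C x T` (or a [trial_set()]).
#' @param domain `"target"` or `"source"`; with a shared generator both use
#'   the same parameters, otherwise the source generator is selected.
#' @param training logical; enables dropout and batch-statistics updates.
#' @return Numeric array `batch x t x D` of token features.
#' @export
generator_forward <- function(model, X, domain = "target",
                              training = FALSE) {
  if (inherits(X, "trial_set")) X <- X$X
  cfg <- model$cfg
  use_src <- !cfg$shared_generator && domain == "source"
  g <- if (use_src) cfg$geom_s else cfg$geom_t
  if (dim(X)[2] != g$C) stop("channel count does not match the model")
  if (dim(X)[3] < g$L) stop("trial shorter than the temporal kernel")
  if (dim(X)[3] != g$T) stop("trial length does not match the model")
  tape <- ad_tape()
  lv <- param_leaves(tape, model$params, track = FALSE)
  pfx <- if (use_src) "gens" else "gen"
  bnpfx <- if (use_src) "s" else "t"
  tok <- generator_t(tape, lv, pfx, ad_const(tape, X), g, training,
                     model$bn, bnpfx, cfg$dropout_p)
  adv(tok)
}

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K' / k) V`, the core operation of the
#' cross-encoder; every row of the softmax weights sums to one.
#'
#' @param Q,K,V numeric matrices with compatible shapes (`Q`: `tq x d`,
#'   `K`: `tk x d`, `V`: `tk x dv`).
#' @param k positive scaling factor (commonly `sqrt(d)`).
#' @return Matrix `tq x dv`.
#' @export
scaled_attention <- function(Q, K, V, k = sqrt(ncol(Q))) {
  if (k <= 0) stop("scaling factor k must be positive")
  S <- Q %*% t(K) / k
  m <- apply(S, 1, max)
  E <- exp(S - m)
  P <- E / rowSums(E)
  P %*% V
}

#' Multi-head attention on a token matrix
#'
#' Splits the feature axis into `h` contiguous slices of width `d = D/h`,
#' projects each slice's tokens into queries, keys and values, applies
#' [scaled_attention()] per head and concatenates the heads in index order.
#'
#' @param x token matrix `t x D` or array `batch x t x D`.
#' @param h head count; `D` must be divisible by `h`.
#' @param weights optional list with `D x D` projection matrices
#'   `Wq, Wk, Wv` and length-`D` biases `bq, bk, bv`; identity projections
#'   by default.
#' @param k scaling factor, default `sqrt(d)`.
#' @return Same shape as `x`.
#' @export
multi_head_attention <- function(x, h, weights = NULL, k = NULL) {
  one <- function(xm) {
    D <- ncol(xm)
    if (D %% h != 0) stop("token width D must be divisible by h")
    d <- D %/% h
    ks <- if (is.null(k)) sqrt(d) else k
    w <- weights
    if (is.null(w)) {
      I <- diag(D); z <- numeric(D)
      w <- list(Wq = I, Wk = I, Wv = I, bq = z, bk = z, bv = z)
    }
    Qf <- xm %*% w$Wq + rep(w$bq, each = nrow(xm))
    Kf <- xm %*% w$Wk + rep(w$bk, each = nrow(xm))
    Vf <- xm %*% w$Wv + rep(w$bv, each = nrow(xm))
    out <- matrix(0, nrow(xm), D)
    for (l in seq_len(h)) {
      sl <- ((l - 1) * d + 1):(l * d)
      out[, sl] <- scaled_attention(Qf[, sl, drop = FALSE],
                                    Kf[, sl, drop = FALSE],
                                    Vf[, sl, drop = FALSE], ks)
    }
    out
  }
  if (length(dim(x)) == 2L) return(one(x))
  out <- x
  for (b in seq_len(dim(x)[1])) out[b, , ] <- one(x[b, , ])
  out
}

#' Cross-encoder forward pass
#'
#' Applies within-domain self-attention to each token stream; the target
#' stream additionally passes a feed-forward/layer-norm sublayer, and the
#' source stream is refined by three cross-attention operations driven by
#' the target stream before its own feed-forward/layer-norm.  The target
#' output never depends on the source input.
#'
#' @param model a [ccan_model()].
#' @param src source tokens `batch x t x D`, or `NULL` for the target-only
#'   path used at test time.
#' @param tgt target tokens `batch x t x D`.
#' @return List with arrays `src` (or `NULL`) and `tgt`.
#' @export
cross_encoder_forward <- function(model, src, tgt) {
  cfg <- model$cfg
  if (!is.null(src) && dim(src)[3] != dim(tgt)[3]) {
    stop("source and target token widths differ")
  }
  if (dim(tgt)[3] != cfg$D) stop("token width does not match the model")
  tape <- ad_tape()
  lv <- param_leaves(tape, model$params, track = FALSE)
  sn <- if (is.null(src)) NULL else ad_const(tape, src)
  out <- encoder_t(tape, lv, sn, ad_const(tape, tgt), cfg)
  list(src = if (is.null(out$src)) NULL else adv(out$src),
       tgt = adv(out$tgt))
}

#' Class-discriminator forward pass
#'
#' Layer normalisation over the flattened features followed by an affine
#' map to `r` dimensions, the space in which the class-alignment ratio
#' loss is computed.
#'
#' @param model a [ccan_model()].
#' @param features matrix `n x feat_dim` of flattened encoder features.
#' @return Matrix `n x r`.
#' @export
discriminator_forward <- function(model, features) {
  tape <- ad_tape()
  lv <- param_leaves(tape, model$params, track = FALSE)
  adv(discriminator_t(tape, lv, ad_const(tape, features)))
}

#' Dual-classifier forward pass
#'
#' Two independently initialised affine-plus-softmax heads; each row of
#' each output sums to one.
#'
#' @param model a [ccan_model()].
#' @param features matrix `n x feat_dim`.
#' @return List of two `n x M` probability matrices.
#' @export
classifier_forward <- function(model, features) {
  tape <- ad_tape()
  lv <- param_leaves(tape, model$params, track = FALSE)
  ps <- classifier_t(tape, lv, ad_const(tape, features))
  list(probs1 = adv(ps[[1]]), probs2 = adv(ps[[2]]))
}

#' Average the two classifier heads into a prediction
#'
#' Takes the argmax of the elementwise mean of the two probability
#' matrices; ties break towards the lowest class index.
#'
#' @param probs1,probs2 `n x M` probability matrices.
#' @return Integer vector of 0-based class indices.
#' @export
average_predict <- function(probs1, probs2) {
  if (!identical(dim(probs1), dim(probs2))) stop("probability shapes differ")
  m <- (probs1 + probs2) / 2
  max.col(m, ties.method = "first") - 1L
}

# Full trials -> flattened encoder features, on tape (shared by training
# and evaluation).  Either stream may be NULL.
features_t <- function(tape, lv, cfg, Xs, Xt, training, bn,
                       use_cross_encoder = TRUE) {
  tok_s <- tok_t <- NULL
  if (cfg$shared_generator && !is.null(Xs) && !is.null(Xt)) {
    # one pass through the shared generator so batch-norm pools the domains
    ns <- dim(Xs)[1]
    xall <- ad_const(tape, abind_first(Xs, Xt))
    tok <- generator_t(tape, lv, "gen", xall, cfg$geom_t, training, bn, "t",
                       cfg$dropout_p)
    tok_s <- ad_slice_first(tape, tok, seq_len(ns))
    tok_t <- ad_slice_first(tape, tok, ns + seq_len(dim(Xt)[1]))
  } else {
    if (!is.null(Xt)) {
      tok_t <- generator_t(tape, lv, "gen", ad_const(tape, Xt), cfg$geom_t,
                           training, bn, "t", cfg$dropout_p)
    }
    if (!is.null(Xs)) {
      pfx <- if (cfg$shared_generator) "gen" else "gens"
      bnp <- if (cfg$shared_generator) "t" else "s"
      tok_s <- generator_t(tape, lv, pfx, ad_const(tape, Xs), cfg$geom_s,
                           training, bn, bnp, cfg$dropout_p)
    }
  }
  if (use_cross_encoder) {
    enc <- encoder_t(tape, lv, tok_s, tok_t, cfg)
  } else {
    enc <- list(src = tok_s, tgt = tok_t)
  }
  list(src = if (is.null(enc$src)) NULL else flatten_t(tape, enc$src),
       tgt = if (is.null(enc$tgt)) NULL else flatten_t(tape, enc$tgt))
}

abind_first <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[-1], db[-1]))
  am <- a; dim(am) <- c(da[1], prod(da[-1]))
  bm <- b; dim(bm) <- c(db[1], prod(db[-1]))
  out <- rbind(am, bm)
  dim(out) <- c(da[1] + db[1], da[-1])
  out
}
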