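# Model configuration, geometry arithmetic and parameter initialisation for
# the four-component network: two-pathway convolutional generator,
# self+cross attention cross-encoder, class discriminator, dual classifiers.

#' Model configuration
#'
#' @param C,T channel count and samples per trial of the target domain.
#' @param M number of (remapped) classes.
#' @param L temporal kernel length in samples (25 suits 250 Hz recordings,
#'   10 suits 100 Hz).
#' @param n_kernels convolutional kernels per stage (40).
#' @param h attention heads; the fused token width `D = 2 * n_kernels` must
#'   be divisible by `h`, giving per-head dimension `d = D / h`.
#' @param k attention scaling factor; default `sqrt(d)`.
#' @param r output width of the class discriminator.
#' @param dropout_p dropout probability in the generator.
#' @param pool_len,pool_stride average-pooling window and stride (samples)
#'   applied along time after each pathway; they fix the token count
#'   `t = floor((T - L + 1 - pool_len) / pool_stride) + 1`.
#' @param shared_generator if `FALSE`, source and target domains get
#'   independent generators (heterogeneous feature spaces); the source
#'   geometry is then taken from `source_C`, `source_T`, `source_L` and its
#'   pooling is adjusted so both emit the same token count.
#' @param source_C,source_T,source_L source-domain geometry when
#'   `shared_generator = FALSE`.
#'
#' @return An object of class `model_config` with derived fields `D`, `d`
#'   and per-domain geometries.
#' @export
model_config <- function(C, T, M, L = 25, n_kernels = 40, h = 8, k = NULL,
                         r = 3, dropout_p = 0.5, pool_len = 75,
                         pool_stride = 15, shared_generator = TRUE,
                         source_C = C, source_T = T, source_L = L) {
  D <- 2L * n_kernels
  if (D %% h != 0) stop("fused width D = 2*n_kernels must be divisible by h")
  d <- D %/% h
  if (r < 2) stop("discriminator width r must be >= 2")
  if (L > T) stop("temporal kernel length L must not exceed T")
  if (is.null(k)) k <- sqrt(d)
  if (k <= 0) stop("scaling factor k must be positive")
  geom_t <- gen_geometry(C, T, L, n_kernels, pool_len, pool_stride)
  if (shared_generator) {
    geom_s <- geom_t
  } else {
    geom_s <- gen_geometry_matched(source_C, source_T, source_L, n_kernels,
                                   pool_len, geom_t$t)
  }
  structure(list(C = as.integer(C), T = as.integer(T), M = as.integer(M),
                 L = as.integer(L), n_kernels = as.integer(n_kernels),
                 h = as.integer(h), d = as.integer(d), D = as.integer(D),
                 k = k, r = as.integer(r), dropout_p = dropout_p,
                 pool_len = as.integer(pool_len),
                 pool_stride = as.integer(pool_stride),
                 shared_generator = shared_generator,
                 geom_t = geom_t, geom_s = geom_s,
                 t = geom_t$t, feat_dim = geom_t$t * D),
            class = "model_config")
}

# Convolution/pooling arithmetic for one generator; both pathways end on the
# same time length T1 = T - L + 1, pooled down to t tokens.
gen_geometry <- function(C, T, L, n_kernels, pool_len, pool_stride) {
  T1 <- T - L + 1L
  if (T1 < pool_len) stop("pooling window longer than the convolved signal")
  t <- (T1 - pool_len) %/% pool_stride + 1L
  list(C = as.integer(C), T = as.integer(T), L = as.integer(L),
       K = as.integer(n_kernels), T1 = as.integer(T1),
       pool_len = as.integer(pool_len), pool_stride = as.integer(pool_stride),
       t = as.integer(t))
}

# Source-domain geometry with pooling solved so the token count matches the
# target's (needed when the two domains use separate generators).
gen_geometry_matched <- function(C, T, L, n_kernels, pool_len_pref, t_target) {
  T1 <- T - L + 1L
  if (T1 < t_target) stop("source trials too short for the target token count")
  if (t_target == 1L) {
    pl <- T1; ps <- 1L
  } else {
    ps <- max(1L, (T1 - min(pool_len_pref, T1 - t_target + 1L)) %/%
                (t_target - 1L))
    pl <- T1 - ps * (t_target - 1L)
    if (pl < 1L) {
      ps <- (T1 - 1L) %/% (t_target - 1L)
      pl <- T1 - ps * (t_target - 1L)
    }
  }
  g <- gen_geometry(C, T, L, n_kernels, pl, ps)
  stopifnot(g$t == t_target)
  g
}

glorot <- function(nin, nout, dims = c(nin, nout)) {
  lim <- sqrt(6 / (nin + nout))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

init_generator <- function(g) {
  K <- g$K
  list(
    "p1.Wt" = glorot(g$L, K),                 # temporal conv, 1 in-channel
    "p1.bt" = numeric(K),
    "p1.Ws" = glorot(g$C * K, K),             # spatial conv over C x K maps
    "p1.bs" = numeric(K),
    "p1.bn.gamma" = rep(1, K),
    "p1.bn.beta" = numeric(K),
    "p2.Ws" = glorot(g$C, K),                 # spatial conv first
    "p2.bs" = numeric(K),
    "p2.Wt" = glorot(g$L * K, K),             # temporal conv over K maps
    "p2.bt" = numeric(K),
    "p2.bn.gamma" = rep(1, K),
    "p2.bn.beta" = numeric(K)
  )
}

init_attention <- function(D) {
  list(Wq = glorot(D, D), Wk = glorot(D, D), Wv = glorot(D, D),
       bq = numeric(D), bk = numeric(D), bv = numeric(D))
}

init_ffn <- function(D) {
  list(W1 = glorot(D, 4 * D), b1 = numeric(4 * D),
       W2 = glorot(4 * D, D), b2 = numeric(D),
       g = rep(1, D), b = numeric(D))
}

prefix_names <- function(lst, pfx) {
  stats::setNames(lst, paste0(pfx, ".", names(lst)))
}

#' Initialise a model
#'
#' Draws all parameters (Glorot-uniform weights, zero biases, unit
#' batch/layer-norm gains) from the given seed.  The two classifier heads
#' receive independent draws, so a fresh model's heads disagree by design.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for the initialisation.
#' @return An object of class `ccan_model`: list with the flat named
#'   parameter list `params`, the config `cfg`, and an environment `bn`
#'   holding batch-norm running statistics.
#' @export
ccan_model <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "model_config"))
  old <- rng_snapshot()
  on.exit(rng_restore(old))
  set.seed(as.integer(seed))
  D <- cfg$D
  F <- cfg$feat_dim
  p <- c(
    prefix_names(init_generator(cfg$geom_t), "gen"),
    if (!cfg$shared_generator) prefix_names(init_generator(cfg$geom_s), "gens"),
    prefix_names(init_attention(D), "enc.self_s"),
    prefix_names(init_attention(D), "enc.self_t"),
    prefix_names(init_ffn(D), "enc.ffn_t"),
    prefix_names(init_attention(D), "enc.cross1"),
    prefix_names(init_attention(D), "enc.cross2"),
    prefix_names(init_attention(D), "enc.cross3"),
    prefix_names(init_ffn(D), "enc.ffn_s"),
    list("disc.g" = rep(1, F), "disc.b" = numeric(F),
         "disc.W" = glorot(F, cfg$r), "disc.bW" = numeric(cfg$r),
         "cls.h1.W" = glorot(F, cfg$M), "cls.h1.b" = numeric(cfg$M),
         "cls.h2.W" = glorot(F, cfg$M), "cls.h2.b" = numeric(cfg$M))
  )
  structure(list(params = p, cfg = cfg, bn = new.env(parent = emptyenv())),
            class = "ccan_model")
}

#' @export
print.ccan_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<ccan_model> %d parameters | C=%d T=%d -> t=%d tokens x D=%d (h=%d heads), M=%d classes, r=%d, %s generator\n",
              np, x$cfg$C, x$cfg$T, x$cfg$t, x$cfg$D, x$cfg$h, x$cfg$M,
              x$cfg$r, if (x$cfg$shared_generator) "shared" else "non-shared"))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory with a JSON echo of the configuration, a
#' manifest of parameter names and shapes, the flat little-endian binary
#' parameter array, and the batch-norm running statistics.  `load_model`
#' fails loudly if the manifest and config do not agree.
#'
#' @param model a [ccan_model()].
#' @param dir checkpoint directory (created if missing).
#' @return `save_model` returns `dir` invisibly; `load_model` the restored
#'   [ccan_model()].
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfgl <- unclass(model$cfg)
  shapes <- lapply(model$params, function(p) {
    if (is.null(dim(p))) length(p) else dim(p)
  })
  jsonlite::write_json(list(config = cfgl, shapes = shapes),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(file.path(dir, "params.bin"), "wb")
  writeBin(unlist(lapply(model$params, as.vector), use.names = FALSE),
           con, size = 8, endian = "little")
  close(con)
  bn <- as.list(model$bn)
  jsonlite::write_json(bn, file.path(dir, "bn.json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  cl <- meta$config
  cfg <- model_config(C = cl$C, T = cl$T, M = cl$M, L = cl$L,
                      n_kernels = cl$n_kernels, h = cl$h, k = cl$k,
                      r = cl$r, dropout_p = cl$dropout_p,
                      pool_len = cl$pool_len, pool_stride = cl$pool_stride,
                      shared_generator = cl$shared_generator,
                      source_C = cl$geom_s$C, source_T = cl$geom_s$T,
                      source_L = cl$geom_s$L)
  model <- ccan_model(cfg, seed = 1)
  if (!identical(names(meta$shapes), names(model$params))) {
    stop("checkpoint manifest does not match the model configuration")
  }
  con <- file(file.path(dir, "params.bin"), "rb")
  on.exit(close(con))
  for (nm in names(model$params)) {
    sh <- as.integer(meta$shapes[[nm]])
    expected <- model$params[[nm]]
    if (prod(sh) != length(expected)) {
      stop("checkpoint shape mismatch for parameter ", nm)
    }
    v <- readBin(con, "double", n = prod(sh), size = 8, endian = "little")
    if (length(v) != prod(sh)) stop("checkpoint truncated at parameter ", nm)
    if (length(sh) > 1) dim(v) <- sh
    model$params[[nm]] <- v
  }
  bnp <- file.path(dir, "bn.json")
  if (file.exists(bnp)) {
    bn <- jsonlite::read_json(bnp, simplifyVector = TRUE)
    for (nm in names(bn)) model$bn[[nm]] <- bn[[nm]]
  }
  model
}
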