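# Independent brute-force oracles and small shared fixtures.  Everything
# here is deliberately written as naive loops, separate from the package's
# vectorised implementations.

# --- losses, by direct evaluation of their definitions ---------------------

bf_l2 <- function(a, b) sqrt(sum((a - b)^2))

bf_means <- function(features, labels, domains, domain) {
  out <- list()
  for (m in sort(unique(labels[domains == domain]))) {
    rows <- which(labels == m & domains == domain)
    v <- rep(0, ncol(features))
    for (i in rows) v <- v + features[i, ]
    out[[as.character(m)]] <- v / length(rows)
  }
  out
}

bf_losses <- function(features, labels, domains) {
  sm <- bf_means(features, labels, domains, "source")
  tm <- bf_means(features, labels, domains, "target")
  shared <- intersect(names(sm), names(tm))
  Mt <- length(shared)
  corr <- ncorr <- NA_real_
  if (Mt >= 1) {
    s <- 0
    for (m in shared) s <- s + bf_l2(sm[[m]], tm[[m]])
    corr <- s / Mt
  }
  if (Mt >= 2) {
    s <- 0
    for (m in shared) for (m2 in shared) {
      if (m != m2) s <- s + bf_l2(sm[[m]], tm[[m2]])
    }
    ncorr <- s / (Mt * (Mt - 1))
  }
  list(corr = corr, ncorr = ncorr,
       dis = if (Mt >= 2) corr / max(ncorr, 1e-8) else NA_real_,
       M_tilde = Mt)
}

bf_cls <- function(probs, labels) {
  s <- 0
  for (i in seq_len(nrow(probs))) {
    s <- s - log(max(probs[i, labels[i] + 1], 1e-12))
  }
  s / nrow(probs)
}

bf_center <- function(features, labels, centers) {
  tot <- 0
  for (m in names(centers)) {
    rows <- which(labels == as.integer(m))
    if (!length(rows)) next
    s <- 0
    for (i in rows) s <- s + bf_l2(features[i, ], centers[[m]])
    tot <- tot + s / length(rows)
  }
  tot
}

random_loss_batch <- function(M = 2, dim = 4, n = 10) {
  features <- matrix(rnorm(n * dim), n, dim)
  labels <- sample(0:(M - 1), n, replace = TRUE)
  domains <- sample(c("source", "target"), n, replace = TRUE)
  # guarantee at least two shared classes
  labels[1:4] <- c(0L, 1L, 0L, 1L)
  domains[1:4] <- c("source", "source", "target", "target")
  list(features = features, labels = labels, domains = domains)
}

# --- numerical gradients ---------------------------------------------------

num_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# --- small shared model/data fixtures --------------------------------------

tiny_model_config <- function(M = 2, r = 3, h = 2, dropout_p = 0, ...) {
  model_config(C = 3, T = 60, M = M, L = 5, n_kernels = 4, h = h,
               pool_len = 10, pool_stride = 5, r = r,
               dropout_p = dropout_p, ...)
}

tiny_batch <- function(mc, n = 4, seed = 3, separation = 0) {
  set.seed(seed)
  mk <- function(labels) {
    X <- array(rnorm(length(labels) * mc$C * mc$T), c(length(labels), mc$C, mc$T))
    if (separation > 0) {
      for (i in seq_along(labels)) {
        f <- if (labels[i] == 0) 6 else 14
        s <- sin(2 * pi * f * seq_len(mc$T) / 60)
        X[i, 1, ] <- X[i, 1, ] + separation * s
        X[i, 2, ] <- X[i, 2, ] + separation * (labels[i] * 2 - 1) * s
      }
    }
    X
  }
  ys <- rep(0:(mc$M - 1), length.out = n)
  yt <- rep(0:(mc$M - 1), length.out = n)
  list(Xs = mk(ys), ys = ys, Xt = mk(yt), yt = yt)
}

tiny_scenario_data <- function(n_per_class = 6, seed = 5, C = 4, T = 80,
                               fs = 40) {
  cfg <- synthetic_config(n_trials_per_class = n_per_class, classes = 1:4,
                          C = C, T = T, fs = fs,
                          class_freqs = c(`1` = 5, `2` = 9, `3` = 13, `4` = 17),
                          snr = 4, subject_shift = 0.05, seed = seed)
  pair <- generate_domain_pair(cfg, cfg, 2)
  assemble_scenario(parse_spec("1,2->1,3", 1), pair$source, pair$target,
                    split = 0.5, seed = seed)
}
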