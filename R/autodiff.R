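#' @useDynLib ccan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal reverse-mode automatic differentiation on R arrays.
#
# A tape is an environment holding a list of nodes in creation order.  Each
# node carries its value, the ids of its parents and a backward closure that
# maps the node's output gradient to gradients for its parents.  Gradients
# are propagated once, in reverse creation order, which is a valid
# topological order for any DAG built by calling the ops below.
#
# Nodes with `track = FALSE` (data constants) prune gradient computation:
# a backward closure receives a `needs` logical vector and may return NULL
# for parents whose gradient nobody wants.
# ---------------------------------------------------------------------------

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

ad_push <- function(tape, value, parents = integer(0), backward = NULL,
                    track = NA) {
  # force all promises before claiming a slot: argument expressions may
  # themselves push nodes onto the tape
  force(value)
  parents <- as.integer(parents)
  force(backward)
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  if (is.na(track)) {
    track <- any(vapply(parents, function(p) tape$nodes[[p]]$track, TRUE))
  }
  tape$nodes[[n]] <- list(id = n, value = value, parents = as.integer(parents),
                          backward = backward, track = track)
  tape$n <- n
  tape$nodes[[n]]
}

# Leaf holding a trainable value (gradient wanted).
ad_leaf <- function(tape, value) ad_push(tape, value, track = TRUE)

# Leaf holding data / constants (no gradient).
ad_const <- function(tape, value) ad_push(tape, value, track = FALSE)

adv <- function(node) node$value

# Runs the reverse sweep from a scalar node; returns the full gradient list
# indexed by node id (leaves keep their accumulated gradients, interior
# gradients are freed as soon as they have been consumed).
ad_backward <- function(tape, loss) {
  if (length(adv(loss)) != 1L) stop("loss must be scalar")
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- 1
  for (i in seq(loss$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tape$nodes[[i]]
    if (is.null(nd$backward)) next
    needs <- vapply(nd$parents, function(p) tape$nodes[[p]]$track,
                    logical(1))
    pg <- nd$backward(g, needs)
    for (j in seq_along(nd$parents)) {
      if (!needs[[j]] || is.null(pg[[j]])) next
      p <- nd$parents[[j]]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
    grads[i] <- list(NULL)
  }
  grads
}

# --- elementwise / arithmetic ---------------------------------------------

ad_add <- function(tape, a, b) {
  ad_push(tape, adv(a) + adv(b), c(a$id, b$id),
          function(g, needs) list(g, g))
}

ad_sub <- function(tape, a, b) {
  ad_push(tape, adv(a) - adv(b), c(a$id, b$id),
          function(g, needs) list(g, -g))
}

ad_mul <- function(tape, a, b) {
  va <- adv(a); vb <- adv(b)
  ad_push(tape, va * vb, c(a$id, b$id),
          function(g, needs) list(if (needs[1]) g * vb,
                                  if (needs[2]) g * va))
}

ad_scale <- function(tape, a, s) {
  ad_push(tape, adv(a) * s, a$id, function(g, needs) list(g * s))
}

ad_div <- function(tape, a, b) {
  va <- adv(a); vb <- adv(b)
  ad_push(tape, va / vb, c(a$id, b$id),
          function(g, needs) list(if (needs[1]) g / vb,
                                  if (needs[2]) -g * va / (vb * vb)))
}

ad_elu <- function(tape, a) {
  x <- adv(a)
  v <- x
  neg <- x <= 0
  v[neg] <- expm1(x[neg])
  ad_push(tape, v, a$id, function(g, needs) {
    d <- g
    d[neg] <- g[neg] * (v[neg] + 1)
    list(d)
  })
}

ad_sqrt <- function(tape, a, eps = 0) {
  v <- sqrt(adv(a) + eps)
  ad_push(tape, v, a$id, function(g, needs) list(g * 0.5 / v))
}

ad_log_clamp <- function(tape, a, lo = 1e-12) {
  x <- adv(a)
  xc <- pmax(x, lo)
  if (!is.null(dim(x))) dim(xc) <- dim(x)
  v <- log(xc)
  ad_push(tape, v, a$id, function(g, needs) {
    d <- g / xc
    d[x < lo] <- 0
    list(d)
  })
}

ad_sum_all <- function(tape, a) {
  dims <- dim(adv(a))
  ad_push(tape, sum(adv(a)), a$id,
          function(g, needs) list(array(g, if (is.null(dims)) length(adv(a)) else dims)))
}

# --- linear algebra --------------------------------------------------------

ad_matmul <- function(tape, a, b) {
  va <- adv(a); vb <- adv(b)
  ad_push(tape, va %*% vb, c(a$id, b$id),
          function(g, needs) list(
            if (needs[1]) g %*% t(vb),
            if (needs[2]) crossprod(va, g)))
}

# b is a vector added to every row of the 2-d matrix a; with `tile` > 1 the
# bias is recycled `tile` times across the columns (for fused layouts whose
# column blocks share one bias).
ad_add_bias <- function(tape, a, b, tile = 1L) {
  va <- adv(a); vb <- adv(b)
  bias <- if (tile > 1L) rep(vb, times = tile) else vb
  v <- va + rep(bias, each = nrow(va))
  ad_push(tape, v, c(a$id, b$id),
          function(g, needs) list(g, if (needs[2]) {
            cs <- colSums(g)
            if (tile > 1L) rowSums(matrix(cs, length(vb), tile)) else cs
          }))
}

# Batched matmul of `n` cube slices (r x c) against one shared weight
# matrix, with a fused per-output-column bias and a fused output reshape
# (the fresh result is re-dimensioned without a copy).  `a` may be stored
# flat; its cube view is (r, c, n).
ad_bmm_sharedB <- function(tape, a, w, b = NULL, dims = NULL,
                           r, c, n) {
  va <- adv(a); vw <- adv(w)
  k <- ncol(vw)
  v <- cpp_bmm_sharedB(va, vw, FALSE, r, c, n,
                       if (is.null(b)) NULL else adv(b))
  dim(v) <- if (is.null(dims)) c(r, k, n) else dims
  parents <- c(a$id, w$id, if (!is.null(b)) b$id)
  ad_push(tape, v, parents, function(g, needs) {
    out <- list(
      if (needs[1]) {
        da <- cpp_bmm_sharedB(g, vw, TRUE, r, k, n)
        dim(da) <- dim(va)
        da
      },
      if (needs[2]) cpp_accum_AtG(va, g, r, c, k, n))
    if (!is.null(b)) {
      out[[3]] <- if (needs[3]) as.vector(cpp_slice_colsums(g, r, k, n))
    }
    out
  })
}

# Batched matmul over cubes (r x c x n).
ad_bmm <- function(tape, a, b, transA = FALSE, transB = FALSE) {
  va <- adv(a); vb <- adv(b)
  v <- cpp_bmm(va, vb, transA, transB)
  ad_push(tape, v, c(a$id, b$id), function(g, needs) {
    da <- db <- NULL
    if (!transA && !transB) {
      if (needs[1]) da <- cpp_bmm(g, vb, FALSE, TRUE)
      if (needs[2]) db <- cpp_bmm(va, g, TRUE, FALSE)
    } else if (!transA && transB) {
      if (needs[1]) da <- cpp_bmm(g, vb, FALSE, FALSE)
      if (needs[2]) db <- cpp_bmm(g, va, TRUE, FALSE)
    } else if (transA && !transB) {
      if (needs[1]) da <- cpp_bmm(vb, g, FALSE, TRUE)
      if (needs[2]) db <- cpp_bmm(va, g, FALSE, FALSE)
    } else {
      if (needs[1]) da <- cpp_bmm(vb, g, TRUE, TRUE)
      if (needs[2]) db <- cpp_bmm(g, va, TRUE, TRUE)
    }
    list(da, db)
  })
}

# --- shape ops -------------------------------------------------------------

ad_reshape <- function(tape, a, dims) {
  old <- dim(adv(a))
  v <- adv(a)
  dim(v) <- dims
  ad_push(tape, v, a$id, function(g, needs) {
    dim(g) <- old
    list(g)
  })
}

ad_aperm <- function(tape, a, perm, dims = NULL) {
  inv <- order(perm)
  pdim <- dim(adv(a))[perm]
  v <- aperm(adv(a), perm)
  if (!is.null(dims)) dim(v) <- dims
  ad_push(tape, v, a$id, function(g, needs) {
    dim(g) <- pdim
    list(aperm(g, inv))
  })
}

# Concatenate along the last axis (slowest-varying in column-major order).
ad_concat_last <- function(tape, a, b) {
  va <- adv(a); vb <- adv(b)
  da <- dim(va); db <- dim(vb)
  stopifnot(identical(da[-length(da)], db[-length(db)]))
  v <- c(va, vb)
  dim(v) <- c(da[-length(da)], da[length(da)] + db[length(db)])
  na <- length(va)
  ad_push(tape, v, c(a$id, b$id), function(g, needs) {
    ga <- g[seq_len(na)]
    gb <- g[-seq_len(na)]
    dim(ga) <- da; dim(gb) <- db
    list(ga, gb)
  })
}

ad_rbind <- function(tape, a, b) {
  va <- adv(a); vb <- adv(b)
  na <- nrow(va)
  ad_push(tape, rbind(va, vb), c(a$id, b$id), function(g, needs) {
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE])
  })
}

# Subset along the first axis of a 2-d or 3-d array (idx must be unique).
ad_slice_first <- function(tape, a, idx) {
  va <- adv(a)
  nd <- length(dim(va))
  v <- if (nd == 2L) va[idx, , drop = FALSE] else va[idx, , , drop = FALSE]
  ad_push(tape, v, a$id, function(g, needs) {
    z <- array(0, dim(va))
    if (nd == 2L) z[idx, ] <- g else z[idx, , ] <- g
    list(z)
  })
}

# --- sliding windows (im2col along the time axis) --------------------------

.ccan_cache <- new.env(parent = emptyenv())

unfold_index <- function(B, T, F, L) {
  key <- paste(B, T, F, L, sep = "x")
  idx <- .ccan_cache[[key]]
  if (is.null(idx)) {
    T1 <- T - L + 1L
    # out[b, t1, j, f] = x[b, t1 + j - 1, f]; linear index into (B, T, F)
    tmp <- outer(seq_len(T1), 0:(L - 1L), "+")       # T1 x L time positions
    v2 <- (as.vector(tmp) - 1L) * B                  # offsets for (t1, j)
    v3 <- (seq_len(F) - 1L) * (B * T)                # offsets for f
    idx <- rep(v3, each = B * T1 * L) +
      rep(rep(v2, each = B), times = F) +
      rep(seq_len(B), times = T1 * L * F)
    .ccan_cache[[key]] <- idx
  }
  idx
}

# x: (B, T, F) -> windows (B, T1, L, F) with T1 = T - L + 1; `dims` fuses a
# reshape of the (fresh) output without a copy.
ad_unfold_time <- function(tape, a, L, dims = NULL) {
  va <- adv(a)
  d <- dim(va)
  B <- d[1]; T <- d[2]; F <- d[3]
  if (T < L) stop("time axis shorter than kernel length")
  T1 <- T - L + 1L
  idx <- unfold_index(B, T, F, L)
  v <- va[idx]
  dim(v) <- if (is.null(dims)) c(B, T1, L, F) else dims
  ad_push(tape, v, a$id, function(g, needs) {
    dim(g) <- c(B, T1, L, F)
    z <- array(0, c(B, T, F))
    for (j in seq_len(L)) {
      z[, j:(j + T1 - 1L), ] <- z[, j:(j + T1 - 1L), ] + g[, , j, ]
    }
    list(z)
  })
}

# --- normalisation, softmax, dropout ---------------------------------------

ad_softmax_rows <- function(tape, a) {
  x <- adv(a)
  m <- as.vector(do.call(pmax, c(lapply(asplit(x, 2), as.vector),
                                 list(-Inf))))
  e <- exp(x - m)
  p <- e / rowSums(e)
  ad_push(tape, p, a$id, function(g, needs) {
    list(p * (g - rowSums(g * p)))
  })
}

# Layer normalisation across columns, independently per row.
ad_layernorm_rows <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- adv(a)
  n <- nrow(x); f <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gm <- rep(adv(gamma), each = n); dim(gm) <- c(n, f)
  y <- xhat * gm + rep(adv(beta), each = n)
  dim(y) <- c(n, f)
  ad_push(tape, y, c(a$id, gamma$id, beta$id), function(g, needs) {
    dxhat <- g * gm
    dx <- NULL
    if (needs[1]) {
      dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    }
    list(dx,
         if (needs[2]) colSums(g * xhat),
         if (needs[3]) colSums(g))
  })
}

# Batch normalisation per column (feature map) over all rows.  `stats` is an
# environment storing running means/vars under `key` for evaluation mode.
ad_batchnorm_cols <- function(tape, a, gamma, beta, stats, key,
                              training, momentum = 0.1, eps = 1e-5) {
  x <- adv(a)
  n <- nrow(x); f <- ncol(x)
  if (training) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = n)
    v <- colMeans(xc * xc)
    run <- stats[[key]]
    if (is.null(run)) {
      stats[[key]] <- list(mean = mu, var = v)
    } else {
      stats[[key]] <- list(mean = (1 - momentum) * run$mean + momentum * mu,
                           var  = (1 - momentum) * run$var + momentum * v)
    }
  } else {
    run <- stats[[key]]
    if (is.null(run)) run <- list(mean = numeric(f), var = rep(1, f))
    mu <- run$mean
    v <- run$var
    xc <- x - rep(mu, each = n)
  }
  inv <- 1 / sqrt(v + eps)
  invm <- rep(inv, each = n); dim(invm) <- c(n, f)
  xhat <- xc * invm
  gm <- rep(adv(gamma), each = n); dim(gm) <- c(n, f)
  y <- xhat * gm + rep(adv(beta), each = n)
  dim(y) <- c(n, f)
  ad_push(tape, y, c(a$id, gamma$id, beta$id), function(g, needs) {
    dxhat <- g * gm
    dx <- NULL
    if (needs[1]) {
      if (training) {
        mh <- rep(colMeans(dxhat), each = n); dim(mh) <- c(n, f)
        mx <- rep(colMeans(dxhat * xhat), each = n); dim(mx) <- c(n, f)
        dx <- invm * (dxhat - mh - xhat * mx)
      } else {
        dx <- dxhat * invm
      }
    }
    list(dx,
         if (needs[2]) colSums(g * xhat),
         if (needs[3]) colSums(g))
  })
}

# Inverted dropout; draws its mask from the current R RNG stream.
ad_dropout <- function(tape, a, p, training) {
  if (!training || p <= 0) return(a)
  x <- adv(a)
  mask <- (stats::runif(length(x)) >= p) / (1 - p)
  dim(mask) <- dim(x)
  ad_push(tape, x * mask, a$id, function(g, needs) list(g * mask))
}
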