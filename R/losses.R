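# Loss functions: the class-alignment ratio loss computed on per-class mean
# features in discriminator space, the shared cross-entropy of the dual
# classifiers, and the centre loss that pulls batch features towards the
# target-domain class centres.  All distances are unsquared Euclidean
# (L2-norm) distances.

l2dist <- function(a, b) sqrt(sum((a - b)^2))

#' Per-domain per-class mean features
#'
#' Splits a feature batch by domain and class and averages.  `M_tilde`
#' counts the classes present in both domains of the batch; classes seen in
#' only one domain are kept in the per-domain lists but excluded from
#' `M_tilde`.
#'
#' @param features numeric matrix `n x F`, one flattened feature vector per
#'   sample.
#' @param labels integer class indices (remapped correspondence indices).
#' @param domain_tags character vector of `"source"` / `"target"`, one per
#'   sample.
#' @return An object of class `class_means`: list with named lists
#'   `source_means` and `target_means` (class index -> mean vector) and the
#'   shared-class count `M_tilde`.
#' @export
class_means <- function(features, labels, domain_tags) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) == 0) stop("empty batch")
  stopifnot(nrow(features) == length(labels),
            length(labels) == length(domain_tags))
  mean_by <- function(rows) {
    cls <- sort(unique(labels[rows]))
    out <- lapply(cls, function(m) {
      colMeans(features[rows[labels[rows] == m], , drop = FALSE])
    })
    names(out) <- cls
    out
  }
  s_rows <- which(domain_tags == "source")
  t_rows <- which(domain_tags == "target")
  sm <- if (length(s_rows)) mean_by(s_rows) else list()
  tm <- if (length(t_rows)) mean_by(t_rows) else list()
  shared <- intersect(names(sm), names(tm))
  structure(list(source_means = sm, target_means = tm,
                 M_tilde = length(shared), shared = shared),
            class = "class_means")
}

#' Class-alignment losses
#'
#' `loss_corr` averages the L2 distance between the source and target mean
#' features of each shared class; `loss_ncorr` averages the distances over
#' all ordered non-corresponding pairs of shared classes; `loss_dis` is
#' their ratio, which shrinks as corresponding classes align and
#' non-corresponding classes separate.  When the batch holds fewer shared
#' classes than a term needs, the term is undefined and `NA` is returned as
#' a skip-batch signal.
#'
#' @param cm a [class_means()] object.
#' @param eps floor applied to the denominator of the ratio.
#' @return A scalar, or `NA` when the batch must be skipped.
#' @export
loss_corr <- function(cm) {
  if (cm$M_tilde < 1) return(NA_real_)
  mean(vapply(cm$shared, function(m) {
    l2dist(cm$source_means[[m]], cm$target_means[[m]])
  }, numeric(1)))
}

#' @rdname loss_corr
#' @export
loss_ncorr <- function(cm) {
  if (cm$M_tilde < 2) return(NA_real_)
  tot <- 0
  for (m in cm$shared) for (m2 in cm$shared) {
    if (m != m2) tot <- tot + l2dist(cm$source_means[[m]], cm$target_means[[m2]])
  }
  tot / (cm$M_tilde * (cm$M_tilde - 1))
}

#' @rdname loss_corr
#' @export
loss_dis <- function(cm, eps = 1e-8) {
  if (cm$M_tilde < 2) return(NA_real_)
  loss_corr(cm) / max(loss_ncorr(cm), eps)
}

#' Classification loss
#'
#' Mean one-hot cross-entropy over the batch; predicted probabilities are
#' clamped at `1e-12` before the log so a confident wrong prediction stays
#' finite.
#'
#' @param probs `n x M` matrix of predicted class probabilities (rows sum
#'   to one).
#' @param labels integer class indices in `[0, M)`.
#' @param M class count (defaults to `ncol(probs)`).
#' @param Bn batch size used for the mean (defaults to `nrow(probs)`).
#' @return Nonnegative scalar.
#' @export
loss_cls <- function(probs, labels, M = ncol(probs), Bn = nrow(probs)) {
  if (any(labels < 0 | labels >= M)) stop("label outside [0, M)")
  p <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  -sum(log(pmax(p, 1e-12))) / Bn
}

#' Centre loss
#'
#' Sum over classes of the mean L2 distance between every batch feature of
#' class m (from either domain) and the target-domain centre of class m.
#' Classes without a target centre are skipped; centres are treated as
#' constants (no gradient flows through them during training).
#'
#' @param features `n x F` feature matrix.
#' @param labels integer class indices per row.
#' @param target_centers named list (class index -> centre vector), e.g.
#'   the `target_means` of [class_means()].
#' @return Nonnegative scalar.
#' @export
loss_center <- function(features, labels, target_centers) {
  if (!is.matrix(features)) features <- as.matrix(features)
  tot <- 0
  for (m in names(target_centers)) {
    rows <- which(labels == as.integer(m))
    if (!length(rows)) next
    dd <- vapply(rows, function(i) l2dist(features[i, ], target_centers[[m]]),
                 numeric(1))
    tot <- tot + sum(dd) / length(rows)
  }
  tot
}

#' Joint loss
#'
#' `L_joint = L_cls + w_cen * L_cen`.
#'
#' @param l_cls,l_cen scalar losses.
#' @param w_cen nonnegative weight of the centre term.
#' @return Scalar.
#' @export
loss_joint <- function(l_cls, l_cen, w_cen) {
  if (w_cen < 0) stop("w_cen must be nonnegative")
  l_cls + w_cen * l_cen
}

#' Six-loss report for one batch
#'
#' Convenience wrapper evaluating all losses on given discriminator
#' features, classifier probabilities and encoder features.
#'
#' @param disc_features `n x r` discriminator outputs.
#' @param probs averaged (or single-head) classifier probabilities.
#' @param enc_features `n x F` encoder features for the centre loss.
#' @param labels integer class indices per sample.
#' @param domain_tags `"source"`/`"target"` per sample.
#' @param w_cen centre-loss weight.
#' @return List with `L_corr`, `L_ncorr`, `L_dis`, `L_cls`, `L_cen`,
#'   `L_joint` and `Bn`.
#' @export
loss_report <- function(disc_features, probs, enc_features, labels,
                        domain_tags, w_cen = 0.1) {
  cm <- class_means(disc_features, labels, domain_tags)
  lc <- loss_cls(probs, labels)
  tc <- class_means(enc_features, labels, domain_tags)$target_means
  lcen <- loss_center(enc_features, labels, tc)
  list(L_corr = loss_corr(cm), L_ncorr = loss_ncorr(cm),
       L_dis = loss_dis(cm), L_cls = lc, L_cen = lcen,
       L_joint = loss_joint(lc, lcen, w_cen), Bn = length(labels))
}
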