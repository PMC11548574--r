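# Heterogeneous domain-adaptation scenarios: a source->target label
# correspondence in arrow notation ("1,2->1,3"), its enumeration over a
# label universe, and the assembly of remapped source/target data sets.
#
# The arrow notation pairs labels positionally: under "1,2->1,3" source
# label 1 corresponds to target label 1 and source label 2 to target
# label 3.  Reordered writings of the same pairing (e.g. "2,1->3,1") are
# equivalent, so enumeration fixes the source labels in ascending order.

#' Scenario specification
#'
#' @param scenario_id integer 1--5; the five scenario families are
#'   1: binary, one shared label; 2: ternary, two shared labels;
#'   3: binary, completely distinct label sets; 4: ternary, completely
#'   different matched labels; 5: cross-dataset binary with heterogeneous
#'   feature spaces.
#' @param source_labels,target_labels ordered integer labels; equal length,
#'   no duplicates within a list.  Position m of each list forms the m-th
#'   corresponding class pair.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario_id, source_labels, target_labels) {
  scenario_id <- as.integer(scenario_id)
  if (!scenario_id %in% 1:5) stop("scenario_id must be 1..5")
  source_labels <- as.integer(source_labels)
  target_labels <- as.integer(target_labels)
  if (length(source_labels) != length(target_labels)) {
    stop("source and target label lists must have equal length")
  }
  if (anyDuplicated(source_labels) || anyDuplicated(target_labels)) {
    stop("duplicate labels within a domain are not allowed")
  }
  structure(list(scenario_id = scenario_id,
                 source_labels = source_labels,
                 target_labels = target_labels,
                 correspondence = stats::setNames(target_labels,
                                                  source_labels)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec %d> %s\n", x$scenario_id, format_spec(x)))
  invisible(x)
}

#' Parse / format arrow notation
#'
#' `parse_spec` reads `"a,b,...->c,d,..."` (both `->` and the arrow glyph
#' are accepted; `+`/`-` denote the labels +1/-1 of the cross-dataset
#' scenario).  `format_spec` renders a spec back into the notation.
#'
#' @param text specification text such as `"1,2->1,3"`.
#' @param scenario_id scenario family the spec belongs to.
#' @return `parse_spec`: a [scenario_spec()]; `format_spec`: a string.
#' @export
parse_spec <- function(text, scenario_id) {
  parts <- strsplit(gsub("→", "->", text), "->", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("malformed spec: expected one arrow in ", text)
  lab <- function(s) {
    s <- trimws(s)
    s[s == "+"] <- "1"
    s[s %in% c("-", "−")] <- "-1"
    v <- suppressWarnings(as.integer(s))
    if (anyNA(v)) stop("malformed label in spec: ", text)
    v
  }
  src <- lab(strsplit(parts[1], ",")[[1]])
  tgt <- lab(strsplit(parts[2], ",")[[1]])
  scenario_spec(scenario_id, src, tgt)
}

#' @rdname parse_spec
#' @param spec a [scenario_spec()].
#' @export
format_spec <- function(spec) {
  fmt <- function(v) {
    if (spec$scenario_id == 5L && all(sort(v) == c(-1L, 1L))) {
      return(paste(ifelse(v > 0, "+", "-"), collapse = ","))
    }
    paste(v, collapse = ",")
  }
  paste0(fmt(spec$source_labels), "->", fmt(spec$target_labels))
}

#' Enumerate all admissible specs of a scenario
#'
#' Reproduces the classification counts of the five scenario families over
#' the default four-label universe: 24, 12, 6, 12 and 1.
#'
#' Scenario 1 keeps the shared label in its source position and replaces
#' the other source label by any label outside the source pair; scenario 2
#' replaces one position of a source triple by a label outside the triple;
#' scenario 3 pairs each ascending source pair with its ascending
#' complement pair; scenario 4 takes every scenario-2 spec and swaps the
#' first two target labels; scenario 5 is the single cross-dataset spec
#' `+,- -> 3,4`.
#'
#' @param scenario_id integer 1--5.
#' @param label_universe integer labels to enumerate over (default 1:4).
#' @return List of [scenario_spec()] objects.
#' @export
enumerate_specs <- function(scenario_id, label_universe = 1:4) {
  scenario_id <- as.integer(scenario_id)
  U <- sort(as.integer(label_universe))
  specs <- list()
  add <- function(src, tgt) {
    specs[[length(specs) + 1L]] <<- scenario_spec(scenario_id, src, tgt)
  }
  if (scenario_id == 1L) {
    if (length(U) >= 3L) {
      for (a in U) for (b in U[U > a]) {
        rest <- setdiff(U, c(a, b))
        for (x in rest) {
          add(c(a, b), c(a, x))   # shared label in first position
          add(c(a, b), c(x, b))   # shared label in second position
        }
      }
    }
  } else if (scenario_id == 2L || scenario_id == 4L) {
    if (length(U) >= 4L) {
      triples <- utils::combn(U, 3, simplify = FALSE)
      for (s in triples) {
        rest <- setdiff(U, s)
        for (u in rest) for (p in 1:3) {
          tgt <- s
          tgt[p] <- u
          if (scenario_id == 4L) tgt[1:2] <- tgt[2:1]
          add(s, tgt)
        }
      }
    }
  } else if (scenario_id == 3L) {
    if (length(U) >= 4L) {
      pairs <- utils::combn(U, 2, simplify = FALSE)
      for (s in pairs) {
        comp <- setdiff(U, s)
        for (tg in utils::combn(comp, 2, simplify = FALSE)) {
          add(s, sort(tg))
        }
      }
    }
  } else if (scenario_id == 5L) {
    add(c(1L, -1L), c(3L, 4L))
  } else {
    stop("unknown scenario_id")
  }
  specs
}

#' Assembled scenario data
#'
#' Filters the given trial sets down to the spec's labels, remaps each
#' label to its correspondence index `0..M-1` (the source label at position
#' m and the target label at position m both become `m - 1`), concatenates
#' the source subjects, and splits the target subject's trials into train
#' and test halves, stratified by class.
#'
#' @param spec a [scenario_spec()].
#' @param source_sets list of source-subject [trial_set()] objects; each
#'   must contain every source label.
#' @param target_set the target subject's [trial_set()].
#' @param split fraction of target trials (per class) assigned to training.
#' @param seed integer seed for the stratified split.
#' @return An object of class `scenario_data`: list with `source`,
#'   `target_train`, `target_test` ([trial_set()]s with remapped labels),
#'   `spec` and `shared_generator` (FALSE only for scenario 5).
#' @export
assemble_scenario <- function(spec, source_sets, target_set, split = 0.5,
                              seed = 1) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (inherits(source_sets, "trial_set")) source_sets <- list(source_sets)

  remap <- function(ts, labels, tag) {
    pos <- match(ts$y, labels)
    keep <- which(!is.na(pos))
    miss <- setdiff(labels, ts$y)
    if (length(miss)) {
      stop(sprintf("label %s missing from %s set of subject %s",
                   paste(miss, collapse = ","), tag, ts$subject_id))
    }
    trial_set(ts$X[keep, , , drop = FALSE], pos[keep] - 1L, ts$fs,
              ts$subject_id, tag, ts$channel_names)
  }

  src <- lapply(source_sets, remap, labels = spec$source_labels,
                tag = "source")
  dims <- vapply(src, function(s) dim(s$X)[2:3], numeric(2))
  if (length(src) > 1 && any(apply(dims, 1, function(r) length(unique(r)) > 1))) {
    stop("source subjects must share channel count and trial length")
  }
  Xs <- do.call(rbind, lapply(src, function(s) {
    x <- s$X; dim(x) <- c(dim(x)[1], prod(dim(x)[2:3])); x
  }))
  dim(Xs) <- c(nrow(Xs), dim(src[[1]]$X)[2:3])
  source <- trial_set(Xs, unlist(lapply(src, `[[`, "y")), src[[1]]$fs,
                      "pooled-source", "source", src[[1]]$channel_names)

  tgt <- remap(target_set, spec$target_labels, "target")
  old <- rng_snapshot()
  on.exit(rng_restore(old))
  set.seed(as.integer(seed))
  tr_idx <- integer(0)
  for (m in sort(unique(tgt$y))) {
    idx <- which(tgt$y == m)
    idx <- sample(idx)
    tr_idx <- c(tr_idx, idx[seq_len(round(split * length(idx)))])
  }
  tr_idx <- sort(tr_idx)
  te_idx <- setdiff(seq_along(tgt$y), tr_idx)
  take <- function(idx) trial_set(tgt$X[idx, , , drop = FALSE], tgt$y[idx],
                                  tgt$fs, tgt$subject_id, "target",
                                  tgt$channel_names)
  structure(list(source = source,
                 target_train = take(tr_idx),
                 target_test = take(te_idx),
                 spec = spec,
                 shared_generator = spec$scenario_id != 5L),
            class = "scenario_data")
}

#' @export
print.scenario_data <- function(x, ...) {
  cat(sprintf("<scenario_data> %s | source %d trials, target %d train / %d test, shared generator: %s\n",
              format_spec(x$spec), dim(x$source$X)[1],
              dim(x$target_train$X)[1], dim(x$target_test$X)[1],
              x$shared_generator))
  invisible(x)
}
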