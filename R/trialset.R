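#' Epoched EEG trials
#'
#' The basic data unit consumed and produced by every stage of the package:
#' an array of epoched trials together with integer class labels, the
#' sampling rate and bookkeeping identifiers.
#'
#' @param X numeric array `n trials x C channels x T samples`.
#' @param y integer class labels, one per trial.
#' @param fs sampling rate in Hz.
#' @param subject_id character identifier of the recorded subject.
#' @param domain_tag `"source"` or `"target"`.
#' @param channel_names optional character vector of length `C`.
#'
#' @return An object of class `trial_set`: a list with elements `X`, `y`,
#'   `fs`, `subject_id`, `domain_tag`, `channel_names`.
#' @export
#' @examples
#' ts <- trial_set(array(rnorm(2 * 3 * 10), c(2, 3, 10)), c(1L, 2L), fs = 100)
#' ts
trial_set <- function(X, y, fs, subject_id = "S1", domain_tag = "target",
                      channel_names = NULL) {
  if (length(dim(X)) != 3L) stop("X must be a 3-d array (trials x channels x samples)")
  if (dim(X)[1] != length(y)) stop("first dimension of X must equal length(y)")
  if (dim(X)[1] > 0 && dim(X)[3] < 1L) stop("T must be positive")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate")
  domain_tag <- match.arg(domain_tag, c("source", "target"))
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(dim(X)[2]))
  }
  if (length(channel_names) != dim(X)[2]) {
    stop("channel_names length must equal the channel count")
  }
  structure(list(X = X, y = as.integer(y), fs = fs,
                 subject_id = as.character(subject_id),
                 domain_tag = domain_tag,
                 channel_names = as.character(channel_names)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<trial_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  subject %s (%s); labels: %s\n", x$subject_id, x$domain_tag,
              paste(names(table(x$y)), table(x$y), sep = ":", collapse = " ")))
  invisible(x)
}

#' Continuous EEG recording
#'
#' Container for a continuous multi-channel recording with event markers,
#' the return type expected from any external-file adapter (e.g. readers of
#' BCI Competition IV GDF or MAT files).  Adapters themselves are out of
#' scope: any function producing this structure satisfies the contract.
#'
#' @param signal numeric matrix `channels x samples`.
#' @param fs sampling rate in Hz.
#' @param channel_names character labels, one per channel.
#' @param events data.frame with integer columns `sample` (0-based sample
#'   index of each event) and `label`.
#'
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(signal, fs, channel_names = NULL, events = NULL) {
  if (!is.matrix(signal)) stop("signal must be a channels x samples matrix")
  if (fs <= 0) stop("fs must be positive")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(signal)))
  if (length(channel_names) != nrow(signal)) {
    stop("channel_names length must equal the channel count")
  }
  if (is.null(events)) {
    events <- data.frame(sample = integer(0), label = integer(0))
  }
  if (nrow(events) > 0 &&
      (min(events$sample) < 0 || max(events$sample) >= ncol(signal))) {
    stop("event sample indices must lie within the recording")
  }
  structure(list(signal = signal, fs = fs,
                 channel_names = as.character(channel_names),
                 events = events),
            class = "raw_recording")
}

#' Cut fixed-length trials out of a continuous recording
#'
#' @param rec a [raw_recording()].
#' @param tmin,tmax epoch window in seconds relative to each event marker.
#' @param subject_id,domain_tag forwarded to the resulting [trial_set()].
#'
#' @return A [trial_set()] with one trial per event.
#' @export
epoch_recording <- function(rec, tmin, tmax, subject_id = "S1",
                            domain_tag = "target") {
  stopifnot(inherits(rec, "raw_recording"), tmin < tmax)
  n0 <- round(tmin * rec$fs)
  n1 <- round(tmax * rec$fs)
  len <- n1 - n0
  ev <- rec$events
  X <- array(0, c(nrow(ev), nrow(rec$signal), len))
  for (i in seq_len(nrow(ev))) {
    s <- ev$sample[i] + n0
    if (s < 0 || s + len > ncol(rec$signal)) {
      stop(sprintf("epoch window for event %d falls outside the recording", i))
    }
    X[i, , ] <- rec$signal[, (s + 1):(s + len)]
  }
  trial_set(X, ev$label, rec$fs, subject_id, domain_tag, rec$channel_names)
}

#' Save / load a trial set
#'
#' The on-disk container is one flat binary array file (`<stem>.dat`,
#' little-endian IEEE 754 doubles, column-major in trial-fastest order,
#' i.e. the R array `n x C x T` written as-is) plus a JSON sidecar
#' (`<stem>.json`) holding `dims`, `fs`, `subject_id`, `domain_tag`,
#' `labels` and `channel_names`.
#'
#' @param trials a [trial_set()].
#' @param stem path stem; `.dat` and `.json` are appended.
#' @return `save_trials` returns `stem` invisibly; `load_trials` returns
#'   the reconstructed [trial_set()].
#' @export
save_trials <- function(trials, stem) {
  stopifnot(inherits(trials, "trial_set"))
  meta <- list(format = "ccan-trials-v1",
               dims = dim(trials$X),
               byte_order = "little",
               dtype = "float64",
               fs = trials$fs,
               subject_id = trials$subject_id,
               domain_tag = trials$domain_tag,
               labels = trials$y,
               channel_names = trials$channel_names)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(trials$X), con, size = 8, endian = "little")
  invisible(stem)
}

#' @rdname save_trials
#' @export
load_trials <- function(stem) {
  jpath <- paste0(stem, ".json")
  dpath <- paste0(stem, ".dat")
  if (!file.exists(jpath)) stop("sidecar not found: ", jpath)
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  for (fld in c("dims", "fs", "subject_id", "domain_tag", "labels",
                "channel_names")) {
    if (is.null(meta[[fld]])) {
      stop(sprintf("trial container is missing field '%s'", fld))
    }
  }
  dims <- as.integer(meta$dims)
  n <- prod(dims)
  con <- file(dpath, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(x) != n) stop("array file truncated: expected ", n, " values")
  dim(x) <- dims
  trial_set(x, as.integer(meta$labels), as.numeric(meta$fs), meta$subject_id,
            meta$domain_tag, meta$channel_names)
}
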