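# Preprocessing: band-pass filtering, window cropping and per-position
# z-score normalisation of epoched trials.

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel of every trial independently along time with a
#' Butterworth band-pass applied forward and backward (`signal::filtfilt`),
#' so the net phase response is zero and the effective magnitude response is
#' the squared one-pass response.  Defaults restrict motor-imagery EEG to
#' the 4--38 Hz band with a 3rd-order design.
#'
#' @param trials a [trial_set()].
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs / 2`.
#' @param order Butterworth order of the one-pass prototype.
#'
#' @return A [trial_set()] of identical shape.
#' @export
bandpass_filter <- function(trials, low = 4, high = 38, order = 3) {
  stopifnot(inherits(trials, "trial_set"))
  fs <- trials$fs
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  X <- trials$X
  d <- dim(X)
  for (i in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      X[i, c, ] <- signal::filtfilt(bf, X[i, c, ])
    }
  }
  out <- trials
  out$X <- X
  out
}

#' Crop a time window out of every trial
#'
#' Restricts the time axis to the half-open sample interval
#' `[round(start_s * fs), round(end_s * fs))`, e.g. the 2--6 s window of a
#' 250 Hz trial keeps exactly 1000 samples.  Labels are unchanged.
#'
#' @param trials a [trial_set()].
#' @param start_s,end_s window in seconds from trial onset.
#' @return A cropped [trial_set()].
#' @export
crop_window <- function(trials, start_s, end_s) {
  stopifnot(inherits(trials, "trial_set"))
  T <- dim(trials$X)[3]
  fs <- trials$fs
  if (!(start_s >= 0 && start_s < end_s && end_s <= T / fs)) {
    stop("window must satisfy 0 <= start_s < end_s <= T/fs")
  }
  a <- round(start_s * fs)
  b <- round(end_s * fs)
  out <- trials
  out$X <- trials$X[, , (a + 1):b, drop = FALSE]
  out
}

#' Fit / apply per-position z-score normalisation
#'
#' `fit_normalizer` computes, across the trial axis, the mean and the
#' population standard deviation (divide-by-n) of the values at every
#' `(channel, time)` position.  `apply_normalizer` standardises a trial set
#' with a fitted state: `x~ = (x - mean) / (std + epsilon)`.  Fitting on
#' training trials only and applying the frozen state to test trials avoids
#' test-set leakage.
#'
#' @param trials a [trial_set()] with at least 2 trials.
#' @param epsilon guard added to the standard deviation so zero-variance
#'   positions map to 0.
#' @return `fit_normalizer`: an object of class `norm_state` with `C x T`
#'   matrices `mean` and `std`.  `apply_normalizer`: a standardised
#'   [trial_set()].
#' @export
fit_normalizer <- function(trials, epsilon = 1e-8) {
  stopifnot(inherits(trials, "trial_set"))
  n <- dim(trials$X)[1]
  if (n < 2) stop("need at least 2 trials to fit normalisation statistics")
  m <- apply(trials$X, c(2, 3), mean)
  v <- apply(trials$X, c(2, 3), function(x) mean((x - mean(x))^2))
  structure(list(mean = m, std = sqrt(v), epsilon = epsilon),
            class = "norm_state")
}

#' @rdname fit_normalizer
#' @param state a `norm_state` from [fit_normalizer()].
#' @export
apply_normalizer <- function(trials, state) {
  stopifnot(inherits(trials, "trial_set"), inherits(state, "norm_state"))
  d <- dim(trials$X)
  if (!identical(dim(state$mean), d[2:3])) {
    stop("normaliser shape does not match the trial set")
  }
  X <- trials$X
  denom <- state$std + state$epsilon
  for (i in seq_len(d[1])) {
    X[i, , ] <- (trials$X[i, , ] - state$mean) / denom
  }
  out <- trials
  out$X <- X
  out
}
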