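# Synthetic multi-subject EEG with class-conditional oscillatory structure.
#
# Signal model: each class has a fixed spatial loading vector (a smooth bump
# centred on a class-specific channel) that is perturbed per subject; each
# trial projects a Hann-enveloped sinusoid at the class centre frequency
# (random phase) through that loading and adds white Gaussian noise.  The
# oscillation is scaled so that the ratio of average signal power to noise
# power equals `snr`; `snr = 0` degenerates to pure noise.

#' Configuration for the synthetic EEG generator
#'
#' @param n_trials_per_class trials generated per class (default 72,
#'   the session size of a standard four-class motor-imagery recording).
#' @param classes integer class labels.
#' @param C channel count.
#' @param T samples per trial.
#' @param fs sampling rate in Hz.
#' @param class_freqs named numeric vector mapping each label to a centre
#'   frequency in Hz (defaults spread over the mu/beta range); every
#'   frequency must lie below the Nyquist rate.
#' @param snr linear signal-to-noise power ratio.
#' @param subject_shift nonnegative scale of the per-subject perturbation of
#'   the class spatial patterns.
#' @param seed integer seed; generation is deterministic given
#'   `(seed, subject_id)`.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_trials_per_class = 72, classes = 1:4,
                             C = 22, T = 1000, fs = 250,
                             class_freqs = NULL, snr = 1,
                             subject_shift = 0.1, seed = 1) {
  if (is.null(class_freqs)) {
    base <- c(10, 13, 21, 27)
    class_freqs <- stats::setNames(
      rep(base, length.out = length(classes)) +
        0.5 * (seq_along(classes) - 1) %/% length(base),
      classes)
  }
  classes <- as.integer(classes)
  if (!all(as.character(classes) %in% names(class_freqs))) {
    stop("class_freqs must be defined for every label")
  }
  if (any(class_freqs[as.character(classes)] >= fs / 2)) {
    stop("every class frequency must be below the Nyquist rate fs/2")
  }
  if (n_trials_per_class < 1 || C < 1 || T < 1 || fs <= 0) {
    stop("all counts must be positive")
  }
  if (snr < 0 || subject_shift < 0) stop("snr and subject_shift must be >= 0")
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 classes = classes, C = as.integer(C), T = as.integer(T),
                 fs = fs, class_freqs = class_freqs, snr = snr,
                 subject_shift = subject_shift, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Stable small integer derived from (seed, subject_id); kept below 2^31.
subject_seed <- function(seed, subject_id) {
  h <- sum(utf8ToInt(as.character(subject_id)) *
             (seq_along(utf8ToInt(as.character(subject_id))) + 16L))
  as.integer((as.numeric(seed) * 100003 + h) %% 2147483629)
}

# Deterministic class spatial patterns shared by all subjects of a cohort.
class_patterns <- function(cfg) {
  centres <- ((seq_along(cfg$classes) - 1L) %% cfg$C) *
    max(1, floor(cfg$C / length(cfg$classes))) + 1L
  pats <- lapply(centres, function(cc) {
    a <- exp(-((seq_len(cfg$C) - cc) / 2)^2)
    a / sqrt(sum(a^2))
  })
  names(pats) <- as.character(cfg$classes)
  pats
}

#' Generate one subject's synthetic trial set
#'
#' @param cfg a [synthetic_config()].
#' @param subject_id character id; combined with `cfg$seed` it fixes the
#'   random stream, so repeated calls are bit-identical.
#' @param domain_tag `"source"` or `"target"`.
#' @return A [trial_set()] with `n_trials_per_class` trials of every class.
#' @export
generate_subject <- function(cfg, subject_id, domain_tag = "target") {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- rng_snapshot()
  on.exit(rng_restore(old))
  set.seed(subject_seed(cfg$seed, subject_id))

  base <- class_patterns(cfg)
  n_cls <- length(cfg$classes)
  n <- cfg$n_trials_per_class * n_cls
  X <- array(0, c(n, cfg$C, cfg$T))
  y <- rep(cfg$classes, each = cfg$n_trials_per_class)
  tt <- seq_len(cfg$T) / cfg$fs
  env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(cfg$T) - 1) / (cfg$T - 1)) # Hann

  # subject-specific perturbation of every class pattern
  pats <- lapply(base, function(a) {
    a2 <- a + cfg$subject_shift * stats::rnorm(cfg$C)
    a2 / sqrt(sum(a2^2))
  })

  amp <- sqrt(cfg$snr)
  for (i in seq_len(n)) {
    lab <- as.character(y[i])
    f <- cfg$class_freqs[[lab]]
    phase <- stats::runif(1, 0, 2 * pi)
    s <- env * sin(2 * pi * f * tt + phase)
    # unit average power per channel-sample over the whole trial array
    s <- s / sqrt(mean(s^2) + 1e-12)
    sig <- outer(pats[[lab]] * sqrt(cfg$C), s)   # C x T, mean power 1
    noise <- matrix(stats::rnorm(cfg$C * cfg$T), cfg$C, cfg$T)
    X[i, , ] <- amp * sig + noise
  }
  trial_set(X, y, cfg$fs, subject_id, domain_tag)
}

#' Generate a source-subject cohort plus one target subject
#'
#' Source subjects share the class structure of `source_cfg` but receive
#' independent spatial-mixing perturbations; the target subject is drawn
#' from `target_cfg`, which may differ in channel count and sampling rate
#' to emulate heterogeneous feature spaces.
#'
#' @param source_cfg,target_cfg [synthetic_config()] objects.
#' @param n_source_subjects number of source subjects.
#' @return A list with `source` (list of [trial_set()]) and `target`
#'   (one [trial_set()]).
#' @export
generate_domain_pair <- function(source_cfg, target_cfg, n_source_subjects) {
  stopifnot(n_source_subjects >= 1)
  src <- lapply(seq_len(n_source_subjects), function(i) {
    generate_subject(source_cfg, sprintf("src%02d", i), "source")
  })
  tgt <- generate_subject(target_cfg, "tgt01", "target")
  list(source = src, target = tgt)
}

# Save/restore the global RNG state so seeded generators do not disturb the
# caller's stream.
rng_snapshot <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

rng_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Band power of every trial around a centre frequency
#'
#' Utility used by tests and examples: mean periodogram power in
#' `centre +/- half_bw` Hz, averaged over the given channels.
#'
#' @param trials a [trial_set()].
#' @param centre centre frequency in Hz.
#' @param half_bw half bandwidth in Hz.
#' @param channels channel indices to average over (default all).
#' @return Numeric vector with one band-power value per trial.
#' @export
band_power <- function(trials, centre, half_bw = 2, channels = NULL) {
  d <- dim(trials$X)
  if (is.null(channels)) channels <- seq_len(d[2])
  T <- d[3]
  freqs <- (0:(T - 1)) * trials$fs / T
  sel <- which(freqs >= centre - half_bw & freqs <= centre + half_bw &
                 freqs <= trials$fs / 2)
  vapply(seq_len(d[1]), function(i) {
    p <- 0
    for (c in channels) {
      sp <- abs(stats::fft(trials$X[i, c, ]))^2 / T
      p <- p + mean(sp[sel])
    }
    p / length(channels)
  }, numeric(1))
}
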