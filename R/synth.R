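# Synthetic six-channel sEMG generator. Each trial is amplitude-modulated
# band-limited (10-450 Hz) Gaussian noise per channel: a trapezoidal
# activation envelope (rest -> ramp -> hold -> ramp -> rest) scaled by a
# muscle-by-motion synergy matrix modulates unit-variance band-limited
# noise, with an additive band-limited baseline noise floor set by an SNR in
# dB. Labels follow the envelope (motion while above 50% of peak, relax
# otherwise). Everything is deterministic given the trial seed.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Band-limited Gaussian noise
#'
#' Unit-variance Gaussian noise whose spectrum is confined to
#' `[band[1], band[2]]` Hz (hard FFT mask), emulating the hardware band-pass
#' of an sEMG acquisition chain.
#'
#' @param n number of samples.
#' @param rate_hz sampling rate; must be at least twice the upper band edge.
#' @param band two-element frequency band in Hz (default `c(10, 450)`).
#' @return numeric series of length `n`, mean ~0, sd 1.
#' @export
bandlimited_noise <- function(n, rate_hz = 1000, band = c(10, 450)) {
  if (rate_hz < 2 * band[2]) {
    stop("rate_hz must be at least twice the upper band edge", call. = FALSE)
  }
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  freq <- (seq_len(n) - 1) * rate_hz / n
  freq <- pmin(freq, rate_hz - freq)  # fold to [0, rate/2]
  sp[freq < band[1] | freq > band[2]] <- 0
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x <- x / s
  x
}

#' Muscle-by-motion synergy matrix
#'
#' Validates a 6x9 matrix of peak activation levels (fraction of MVC) per
#' muscle (rows, canonical order) and motion (columns, codes 1..9). The
#' relax column must stay at or below `baseline`, and every pair of columns
#' must differ by at least `margin` in some muscle so that motions are
#' separable in principle.
#'
#' @param activation_levels 6x9 numeric matrix with entries in \[0, 1\].
#' @param baseline maximum relax-column activation (default 0.02).
#' @param margin minimum max-row difference between any two columns
#'   (default 0.15).
#' @return a validated `synergy_matrix`.
#' @export
synergy_matrix <- function(activation_levels, baseline = 0.02,
                           margin = 0.15) {
  m <- as.matrix(activation_levels)
  if (!all(dim(m) == c(6, 9))) stop("synergy matrix must be 6 x 9",
                                    call. = FALSE)
  if (any(m < 0) || any(m > 1)) stop("activation levels must lie in [0, 1]",
                                     call. = FALSE)
  if (any(m[, 9] > baseline)) {
    stop("relax column must not exceed the baseline level ", baseline,
         call. = FALSE)
  }
  for (i in 1:8) for (j in (i + 1):9) {
    if (max(abs(m[, i] - m[, j])) < margin) {
      stop("motion columns ", i, " and ", j, " differ by less than the ",
           "separability margin ", margin, call. = FALSE)
    }
  }
  rownames(m) <- EMG_CHANNELS
  colnames(m) <- names(MOTION_LABELS)
  structure(m, class = c("synergy_matrix", "matrix"))
}

#' Default synergy matrix
#'
#' A fixed, documented muscle-synergy pattern: wrist flexion/adduction load
#' the wrist flexors (FCR, FCU), extension/abduction the extensors (ECR,
#' ECU), the elbow pair loads biceps vs. triceps, and forearm
#' pronation/supination -- whose prime movers are too deep for surface
#' electrodes -- are distinct mixtures of the six recorded muscles rather
#' than a dedicated channel. Relax sits at the 0.02 baseline.
#'
#' @return a [synergy_matrix()].
#' @export
default_synergy <- function() {
  m <- rbind(
    #        EF    EE    PRO   SUP   WF    WE    WAB   WAD   RLX
    FCR = c(0.05, 0.05, 0.55, 0.10, 0.70, 0.05, 0.60, 0.10, 0.02),
    FCU = c(0.05, 0.05, 0.10, 0.15, 0.60, 0.05, 0.10, 0.65, 0.02),
    ECR = c(0.10, 0.05, 0.25, 0.20, 0.05, 0.70, 0.65, 0.10, 0.02),
    ECU = c(0.05, 0.10, 0.15, 0.50, 0.05, 0.60, 0.10, 0.60, 0.02),
    BB  = c(0.80, 0.10, 0.30, 0.55, 0.05, 0.05, 0.05, 0.05, 0.02),
    TB  = c(0.10, 0.75, 0.10, 0.10, 0.05, 0.05, 0.05, 0.05, 0.02)
  )
  synergy_matrix(m)
}

#' Trial specification
#'
#' @param motion motion code 1..9.
#' @param ramp_s envelope rise/fall time in seconds (default 0.5).
#' @param hold_s plateau duration in seconds (default 2, the protocol's
#'   held-contraction time).
#' @param rest_s rest before and after the movement in seconds
#'   (default 0.5).
#' @param snr_db ratio, in dB, of peak modulated signal power to the
#'   baseline noise floor (default 15).
#' @param seed RNG seed for this trial.
#' @return a `trial_spec` list.
#' @export
trial_spec <- function(motion, ramp_s = 0.5, hold_s = 2, rest_s = 0.5,
                       snr_db = 15, seed = 1) {
  motion <- as.integer(motion)
  if (motion < 1 || motion > 9) stop("motion must be a code in 1..9",
                                     call. = FALSE)
  if (ramp_s <= 0 || hold_s <= 0 || rest_s <= 0) {
    stop("parameter error: all durations must be positive", call. = FALSE)
  }
  structure(list(motion = motion, ramp_s = ramp_s, hold_s = hold_s,
                 rest_s = rest_s, snr_db = snr_db, seed = as.integer(seed)),
            class = "trial_spec")
}

trial_envelope <- function(spec, rate_hz) {
  n_rest <- round(spec$rest_s * rate_hz)
  n_ramp <- round(spec$ramp_s * rate_hz)
  n_hold <- round(spec$hold_s * rate_hz)
  c(numeric(n_rest),
    seq_len(n_ramp) / n_ramp,
    rep(1, n_hold),
    rev(seq_len(n_ramp) / n_ramp),
    numeric(n_rest))
}

#' Generate one synthetic trial
#'
#' @param spec a [trial_spec()].
#' @param synergy a [synergy_matrix()] (default [default_synergy()]).
#' @param rate_hz sampling rate, >= 900 Hz (default 1000).
#' @return a labeled [emg_recording()] (MVC-normalized amplitudes,
#'   `mvc = 1`); labels are the trial motion while the envelope exceeds 50%
#'   of its peak and relax (9) elsewhere.
#' @export
generate_trial <- function(spec, synergy = default_synergy(),
                           rate_hz = 1000) {
  if (!inherits(spec, "trial_spec")) stop("spec must be a trial_spec()",
                                          call. = FALSE)
  if (rate_hz < 900) stop("rate_hz must be >= 900 (Nyquist for the 450 Hz ",
                          "band)", call. = FALSE)
  env <- trial_envelope(spec, rate_hz)
  n <- length(env)
  amp <- as.numeric(synergy[, spec$motion])
  base_sd <- max(amp) * 10^(-spec$snr_db / 20)
  samples <- with_seed(spec$seed, {
    t(vapply(seq_along(amp), function(ch) {
      amp[ch] * env * bandlimited_noise(n, rate_hz) +
        base_sd * bandlimited_noise(n, rate_hz)
    }, numeric(n)))
  })
  labels <- ifelse(env > 0.5, spec$motion, 9L)
  emg_recording(samples, rate_hz = rate_hz, labels = labels)
}

#' Generate a dataset of synthetic trials
#'
#' One recording per motion and trial index, with the trial seed derived as
#' `base_seed + running trial index`, so recordings are distinct but the
#' whole dataset is reproducible. Splitting into train and test sets should
#' always be done by whole trials (as in a 5-train + 5-test protocol), never
#' within a trial.
#'
#' @param motions motion codes to generate (default 1:8).
#' @param trials_per_motion trials per motion (default 5).
#' @param base_seed integer seed offset.
#' @param synergy a [synergy_matrix()].
#' @param rate_hz sampling rate.
#' @param ... further arguments passed to [trial_spec()] (e.g. `snr_db`).
#' @return list of [emg_recording()]s with attributes `motion` and `trial`.
#' @export
generate_dataset <- function(motions = 1:8, trials_per_motion = 5,
                             base_seed = 1, synergy = default_synergy(),
                             rate_hz = 1000, ...) {
  if (trials_per_motion < 1) stop("trials_per_motion must be >= 1",
                                  call. = FALSE)
  out <- list()
  idx <- 0L
  for (m in motions) {
    for (tr in seq_len(trials_per_motion)) {
      idx <- idx + 1L
      spec <- trial_spec(m, seed = base_seed + idx, ...)
      rec <- generate_trial(spec, synergy, rate_hz)
      attr(rec, "motion") <- m
      attr(rec, "trial") <- tr
      out[[idx]] <- rec
    }
  }
  out
}

#' Optional 60 Hz notch filter
#'
#' Biquad notch removing narrowband line interference; provided for parity
#' with hardware acquisition chains (the generator itself injects no line
#' interference).
#'
#' @param x an `emg_recording` or numeric series.
#' @param notch_hz notch center frequency (default 60).
#' @param rate_hz sampling rate (taken from the recording when given one).
#' @param q quality factor, bandwidth = notch_hz / q (default 30).
#' @return filtered object of the same type.
#' @export
notch_filter <- function(x, notch_hz = 60, rate_hz = 1000, q = 30) {
  design <- function(rate) {
    w0 <- 2 * pi * notch_hz / rate
    alpha <- sin(w0) / (2 * q)
    a0 <- 1 + alpha
    list(b = c(1, -2 * cos(w0), 1) / a0,
         a = c(1, -2 * cos(w0) / a0, (1 - alpha) / a0))
  }
  if (inherits(x, "emg_recording")) {
    coefs <- design(x$rate_hz)
    x$samples <- t(apply(x$samples, 1, function(ch) biquad_filter(coefs, ch)))
    x
  } else {
    biquad_filter(design(rate_hz), x)
  }
}
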