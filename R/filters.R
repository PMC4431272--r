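# Minimal IIR filtering support: 2nd-order Butterworth biquad design via the
# bilinear transform, a causal direct-form pass built on stats::filter, and a
# forward-backward zero-phase pass with odd-symmetric edge padding.

#' Design a 2nd-order Butterworth biquad
#'
#' Bilinear-transform design of a digital 2nd-order Butterworth low- or
#' high-pass filter.
#'
#' @param cutoff_hz cutoff frequency in Hz, strictly inside (0, rate/2).
#' @param rate_hz sampling rate in Hz.
#' @param type `"low"` or `"high"`.
#' @return list with numerator `b` (length 3) and denominator `a`
#'   (length 3, `a[1] == 1`).
#' @export
butter2 <- function(cutoff_hz, rate_hz, type = c("low", "high")) {
  type <- match.arg(type)
  if (cutoff_hz <= 0 || cutoff_hz >= rate_hz / 2) {
    stop("cutoff must lie strictly inside (0, Nyquist)", call. = FALSE)
  }
  k <- tan(pi * cutoff_hz / rate_hz)
  norm <- 1 / (1 + sqrt(2) * k + k^2)
  a <- c(1, 2 * (k^2 - 1) * norm, (1 - sqrt(2) * k + k^2) * norm)
  b <- if (type == "low") {
    c(k^2, 2 * k^2, k^2) * norm
  } else {
    c(1, -2, 1) * norm
  }
  list(b = b, a = a)
}

#' Causal biquad filtering
#'
#' Direct-form single-pass IIR filtering with zero initial conditions, as a
#' streaming (causal) implementation would apply it sample by sample.
#'
#' @param coefs list with `b` and `a` as returned by [butter2()].
#' @param x numeric series.
#' @return filtered series, same length.
#' @export
biquad_filter <- function(coefs, x) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  xp <- c(0, 0, x)
  v <- coefs$b[1] * xp[3:(n + 2)] + coefs$b[2] * xp[2:(n + 1)] +
    coefs$b[3] * xp[1:n]
  as.numeric(stats::filter(v, -coefs$a[2:3], method = "recursive"))
}

#' Zero-phase biquad filtering
#'
#' Forward-backward application of a biquad with odd-symmetric extension at
#' both ends to suppress start-up transients (batch mode only).
#'
#' @inheritParams biquad_filter
#' @return filtered series, same length as `x`.
#' @export
filtfilt2 <- function(coefs, x) {
  n <- length(x)
  pad <- min(n - 1, 12L)
  if (pad > 0) {
    left <- 2 * x[1] - x[(pad + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - pad)]
    xe <- c(left, x, right)
  } else {
    xe <- x
  }
  y <- biquad_filter(coefs, xe)
  y <- rev(biquad_filter(coefs, rev(y)))
  y[(pad + 1):(pad + n)]
}
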