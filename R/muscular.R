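# Hill-type muscular-model (MM) feature extraction. Rectified MVC-normalized
# EMG e(t) is mapped to muscle activation u(t) by a second-order recursive
# filter with an electromechanical delay,
#   u(t) = alpha * e(t - d) - beta1 * u(t-1) - beta2 * u(t-2),
# whose coefficients derive from two stable roots gamma1, gamma2:
#   beta1 = gamma1 + gamma2,  beta2 = gamma1 * gamma2,  |gamma| < 1,
#   alpha - beta1 - beta2 = 1  (unit DC gain, so constant input is
# recovered). The contractile-element force F_CE = F_max * u * f_l * f_v is
# evaluated under the model's simplifications (length change held constant,
# contraction velocity zero, series/parallel elastic forces ignored), and a
# causal low-pass mimics the muscle's own mechanical filtering.

#' Activation-filter parameters
#'
#' Derives the recursion coefficients of the EMG-to-activation filter from
#' its two poles. Stability requires both pole magnitudes below 1; unit DC
#' gain fixes `alpha = 1 + beta1 + beta2`.
#'
#' @param gamma1,gamma2 filter poles, `|gamma| < 1`.
#' @param delay_d electromechanical delay in samples (default 0; a
#'   physiological 30--50 ms at 1000 Hz would be 30--50 samples).
#' @param lowpass_hz cutoff of the force-like post-filter in Hz; must lie in
#'   \[3, 10\] (default 4).
#' @return an `activation_params` list with `gamma1`, `gamma2`, `alpha`,
#'   `beta1`, `beta2`, `delay_d`, `lowpass_hz`.
#' @export
make_activation_params <- function(gamma1 = -0.5, gamma2 = -0.5,
                                   delay_d = 0, lowpass_hz = 4) {
  if (abs(gamma1) >= 1 || abs(gamma2) >= 1) {
    stop("stability error: |gamma1| and |gamma2| must be < 1", call. = FALSE)
  }
  if (delay_d < 0) stop("delay_d must be >= 0", call. = FALSE)
  if (lowpass_hz < 3 || lowpass_hz > 10) {
    stop("lowpass_hz must lie in [3, 10]", call. = FALSE)
  }
  beta1 <- gamma1 + gamma2
  beta2 <- gamma1 * gamma2
  structure(list(gamma1 = gamma1, gamma2 = gamma2,
                 alpha = 1 + beta1 + beta2, beta1 = beta1, beta2 = beta2,
                 delay_d = as.integer(delay_d), lowpass_hz = lowpass_hz),
            class = "activation_params")
}

#' EMG-to-activation recursive filter
#'
#' Applies `u(t) = alpha * e(t - d) - beta1 * u(t-1) - beta2 * u(t-2)` with
#' zero initial conditions (`u(-1) = u(-2) = 0`, `e(t - d) = 0` for
#' `t <= d`). Because `alpha / (1 + beta1 + beta2) = 1`, a constant input
#' `e0` converges to activation `e0`.
#'
#' @param e rectified, MVC-normalized series (values in \[0, 1\]).
#' @param params an [make_activation_params()] object.
#' @return activation series `u`, same length as `e` (not yet low-passed or
#'   clipped; see [mm_features()] for the full chain).
#' @export
activation_dynamics <- function(e, params) {
  if (!inherits(params, "activation_params")) {
    stop("params must come from make_activation_params()", call. = FALSE)
  }
  n <- length(e)
  if (n == 0) return(numeric(0))
  d <- params$delay_d
  ed <- if (d > 0) c(numeric(min(d, n)), e[seq_len(max(n - d, 0))]) else e
  as.numeric(stats::filter(params$alpha * ed,
                           c(-params$beta1, -params$beta2),
                           method = "recursive"))
}

#' Force-velocity factor
#'
#' `f_v = 0.1433 / (0.1074 + exp(-1.3 * sinh(2.8 * V_CE / V_CE0 + 1.64)))`,
#' the asymmetric force-velocity dependence of the contractile element.
#' Positive everywhere and monotone in the velocity ratio, saturating near
#' 1.33 on the lengthening side (eccentric force enhancement) and falling
#' toward 0 for fast shortening. At `V_CE = 0` it evaluates to approximately
#' 0.9737.
#'
#' @param v_ce contraction velocity.
#' @param v_ce0 scaled velocity reference, nonzero; for full activation
#'   (`u = 1`), `V_CE0 = 0.5 * (u + 1) * V_CEmax = V_CEmax`.
#' @return scalar factor `f_v > 0`.
#' @export
fv_factor <- function(v_ce = 0, v_ce0 = 1) {
  if (v_ce0 == 0) stop("parameter error: v_ce0 must be nonzero",
                       call. = FALSE)
  0.1433 / (0.1074 + exp(-1.3 * sinh(2.8 * v_ce / v_ce0 + 1.64)))
}

#' Scaled velocity reference
#'
#' `V_CE0 = 0.5 * (u + 1) * V_CEmax`.
#'
#' @param u activation level in \[0, 1\].
#' @param v_ce_max maximum contraction velocity.
#' @return scalar `V_CE0`.
#' @export
vce0_reference <- function(u, v_ce_max = 1) 0.5 * (u + 1) * v_ce_max

#' Hill-model constants
#'
#' @param f_max maximum isometric force (default 1, so features are relative
#'   activations rather than Newtons).
#' @param shape_s exponential shape parameter of the passive elements
#'   (default 2), nonzero.
#' @param delta_l element length change, held constant (default 0).
#' @param delta_l_max length change at which the passive force reaches
#'   `f_max` (default 1), positive.
#' @param f_l force-length factor, constant while `delta_l` is constant
#'   (default 1).
#' @param v_ce_max maximum contraction velocity (default 1); the contraction
#'   velocity itself is fixed at 0 under the model simplifications.
#' @return a `hill_params` list.
#' @export
hill_params <- function(f_max = 1, shape_s = 2, delta_l = 0,
                        delta_l_max = 1, f_l = 1, v_ce_max = 1) {
  if (f_max <= 0) stop("f_max must be positive", call. = FALSE)
  if (delta_l_max <= 0) stop("delta_l_max must be positive", call. = FALSE)
  if (shape_s == 0) stop("parameter error: shape_s must be nonzero",
                         call. = FALSE)
  structure(list(f_max = f_max, shape_s = shape_s, delta_l = delta_l,
                 delta_l_max = delta_l_max, f_l = f_l,
                 v_ce_max = v_ce_max),
            class = "hill_params")
}

#' Passive series/parallel elastic force
#'
#' `F_PE,SE = F_max * (exp(S * dL / dL_max) - 1) / (exp(S) - 1)`: zero at
#' zero length change, `F_max` at `dL_max`, monotone increasing for `S > 0`.
#' Excluded from [mm_features()] (the model ignores the passive elements)
#' but exposed for completeness.
#'
#' @param delta_l element length change.
#' @param params a [hill_params()] object.
#' @return scalar passive force.
#' @export
passive_force <- function(delta_l, params = hill_params()) {
  params$f_max * (exp(params$shape_s * delta_l / params$delta_l_max) - 1) /
    (exp(params$shape_s) - 1)
}

#' Muscular-model features
#'
#' Per channel of a conditioned recording: EMG-to-activation recursion,
#' causal 2nd-order Butterworth low-pass at `act$lowpass_hz` (the muscle
#' acts as a mechanical low-pass; this also keeps activation from exceeding
#' 1), clipping to \[0, 1\], and scaling by the simplified contractile-element
#' force `F_max * f_l * f_v(V_CE = 0)`. One feature per sample: 1000
#' features per second per channel at 1000 Hz.
#'
#' @param recording conditioned [emg_recording()] (rectified,
#'   MVC-normalized).
#' @param act [make_activation_params()] parameters.
#' @param hill [hill_params()] constants.
#' @return multichannel [feature_stream()], method `"MM"`, one tick per
#'   sample, labels carried over from the recording.
#' @export
mm_features <- function(recording, act = make_activation_params(),
                        hill = hill_params()) {
  scale <- hill$f_max * hill$f_l * fv_factor(0, vce0_reference(1, hill$v_ce_max))
  coefs <- butter2(act$lowpass_hz, recording$rate_hz, type = "low")
  vals <- t(apply(recording$samples, 1, function(e) {
    u <- activation_dynamics(e, act)
    u <- biquad_filter(coefs, u)
    pmin(pmax(u, 0), 1) * scale
  }))
  feature_stream(vals, seq_len(ncol(vals)), "MM",
                 labels = recording$labels, channels = recording$channels)
}
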