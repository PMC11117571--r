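## EMG-driven activation dynamics: a recursive second-order discrete filter
## maps normalized EMG e_n(t) to neural activation u_n(t); an exponential
## shape function maps u_n(t) to muscle activation a_n(t).

#' Activation model parameters
#'
#' The recursion u(t) = alpha e(t - d) - beta1 u(t-1) - beta2 u(t-2) is
#' parameterized through the stability coefficients C1, C2 with
#' beta1 = C1 + C2, beta2 = C1 * C2 and the gain constrained to
#' alpha = 1 + beta1 + beta2, which fixes unit DC gain (a sustained 100%
#' EMG drives u to 1). Stability requires |C1| < 1 and |C2| < 1.
#'
#' @param C1,C2 recursion coefficients, magnitudes < 1. The defaults
#'   C1 = C2 = -0.5 give beta1 = -1, beta2 = 0.25, alpha = 0.25: a
#'   critically-damped-like, unit-gain smoothing filter with a
#'   non-negative impulse response.
#' @param dMs electromechanical delay in milliseconds (default 10).
#' @param An nonlinear shape factor of the exponential map (default 1.5);
#'   must be non-zero.
#' @return A list with class `"ActivationParams"`: C1, C2, dMs, An and the
#'   derived beta1, beta2, alpha.
#' @examples
#' p <- activationParams()
#' p$alpha - p$beta1 - p$beta2  # 1 by construction
#' @export
activationParams <- function(C1 = -0.5, C2 = -0.5, dMs = 10, An = 1.5) {
  if (abs(C1) >= 1 || abs(C2) >= 1)
    stop("unstable recursion: |C1| and |C2| must be < 1")
  if (An == 0) stop("An must be non-zero")
  if (dMs < 0) stop("delay must be non-negative")
  beta1 <- C1 + C2
  beta2 <- C1 * C2
  structure(list(C1 = C1, C2 = C2, dMs = dMs, An = An,
                 beta1 = beta1, beta2 = beta2, alpha = 1 + beta1 + beta2),
            class = "ActivationParams")
}

#' Neural activation from normalized EMG
#'
#' Runs the second-order recursion with zero initial conditions:
#' u(t) = alpha e(t - d) - beta1 u(t-1) - beta2 u(t-2), where d is the
#' electromechanical delay rounded to whole samples. Because alpha is tied
#' to 1 + beta1 + beta2, the filter has unit DC gain for every admissible
#' (C1, C2). Output is clipped to `[0, 1]` by default since the downstream
#' shape function assumes that range.
#'
#' @param e numeric vector, normalized EMG in `[0, 1]`.
#' @param params an [activationParams()] object.
#' @param fs sampling rate in Hz.
#' @param clip clip the output to `[0, 1]` (default TRUE).
#' @return Numeric vector u(t), same length as `e`.
#' @export
neuralActivation <- function(e, params = activationParams(), fs = 1000,
                             clip = TRUE) {
  stopifnot(inherits(params, "ActivationParams"), fs > 0)
  d <- as.integer(round(params$dMs * fs / 1000))
  ed <- c(rep(0, d), e)[seq_along(e)]
  # direct-form recursion: numerator alpha * z^-d, denominator (1, b1, b2)
  u <- as.numeric(signal::filter(params$alpha, c(1, params$beta1, params$beta2), ed))
  if (clip) u <- pmin(pmax(u, 0), 1)
  u
}

#' Nonlinear activation shape function
#'
#' Maps neural activation to muscle activation through
#' a = (exp(An u) - 1) / (exp(An) - 1), a monotone bijection of `[0, 1]`
#' onto itself with a(0) = 0 and a(1) = 1.
#'
#' @param u numeric vector in `[0, 1]`.
#' @param An nonlinear shape factor, non-zero.
#' @return Numeric vector a(t).
#' @examples
#' nonlinearActivation(0.5, An = 1.5)  # 0.3208...
#' @export
nonlinearActivation <- function(u, An = 1.5) {
  if (An == 0) stop("An must be non-zero (linear limit not supported)")
  (exp(An * u) - 1) / (exp(An) - 1)
}

#' Inverse of the nonlinear activation map
#'
#' @param a muscle activation in `[0, 1]`.
#' @param An nonlinear shape factor.
#' @return u such that `nonlinearActivation(u, An) == a`.
#' @export
inverseNonlinearActivation <- function(a, An = 1.5) {
  if (An == 0) stop("An must be non-zero")
  log1p(a * (exp(An) - 1)) / An
}

#' Muscle activation matrix from a normalized EMG trial
#'
#' Per muscle: neural activation at the native sampling rate (preserving the
#' physical electromechanical delay), then the nonlinear shape function,
#' then time normalization to `nPoints` phase points. The result is
#' transposed to muscles x points, the orientation taken by the synergy
#' factorization.
#'
#' @param rec normalized-stage [EMGRecording-class].
#' @param params an [activationParams()] object.
#' @param nPoints phase grid size (default 101).
#' @return An [ActivationMatrix-class] (muscles x nPoints).
#' @export
activationFromEMG <- function(rec, params = activationParams(), nPoints = 101) {
  stopifnot(is(rec, "EMGRecording"))
  if (rec@stage != "normalized")
    stop("activationFromEMG expects a normalized-stage recording")
  a <- apply(rec@samples, 2, function(e) {
    nonlinearActivation(neuralActivation(e, params, rec@fs), params$An)
  })
  a <- timeNormalize(a, nPoints)
  ActivationMatrix(t(a), muscleNames = rec@muscleNames,
                   subjectId = rec@subjectId, group = rec@group,
                   trialIndex = rec@trialIndex)
}
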