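## Envelope preprocessing: notch -> zero-phase high-pass -> full-wave
## rectification -> zero-phase low-pass, then MVC normalization and
## time normalization to the landing phase.

#' Zero-phase IIR notch filter
#'
#' Second-order (biquad) notch at `f0` Hz with quality factor `Q`
#' (bandwidth = f0/Q), applied forward and backward so the net filter has
#' zero phase.
#'
#' @param x numeric vector or matrix (one column per channel).
#' @param fs sampling rate in Hz.
#' @param f0 notch centre frequency in Hz (default 50, mains).
#' @param Q quality factor (default 30).
#' @return Filtered signal, same shape as `x`.
#' @export
notchFilter <- function(x, fs, f0 = 50, Q = 30) {
  if (f0 <= 0 || f0 >= fs / 2)
    stop("notch frequency must lie in (0, fs/2)")
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + al, -2 * cos(w0), 1 - al)
  .applyFiltfilt(b / a[1], a / a[1], x)
}

.zeroPhaseButter <- function(x, fs, cutoff, type, order = 4) {
  wn <- cutoff / (fs / 2)
  if (any(wn <= 0) || any(wn >= 1))
    stop(sprintf("filter corner (%s Hz) incompatible with fs = %g Hz",
                 paste(cutoff, collapse = "-"), fs))
  bf <- signal::butter(order, wn, type = type)
  .applyFiltfilt(bf$b, bf$a, x)
}

.applyFiltfilt <- function(b, a, x) {
  if (is.matrix(x)) apply(x, 2, function(col) signal::filtfilt(b, a, col))
  else signal::filtfilt(b, a, x)
}

#' Preprocess raw sEMG into a linear envelope
#'
#' Applies, per channel and in order: 50 Hz notch (mains interference),
#' zero-phase 30 Hz high-pass (motion artifacts), full-wave rectification,
#' and a zero-phase 5 Hz low-pass emulating the muscle's own low-pass
#' characteristic. All IIR stages are Butterworth (the notch a biquad) run
#' forward-backward, so the envelope is not delayed relative to the signal.
#' Tiny negative values from filter ringing are clipped to zero.
#'
#' @param rec raw-stage [EMGRecording-class].
#' @param notchHz,highpassHz,lowpassHz filter corners in Hz.
#' @param notchQ notch quality factor.
#' @param order Butterworth order for the high/low-pass stages (each is
#'   effectively doubled by the forward-backward pass).
#' @return An envelope-stage [EMGRecording-class] of the same shape.
#' @examples
#' rec <- EMGRecording(matrix(rnorm(2000), 1000, 2), fs = 1000)
#' env <- preprocessEMG(rec)
#' @export
preprocessEMG <- function(rec, notchHz = 50, highpassHz = 30, lowpassHz = 5,
                          notchQ = 30, order = 4) {
  stopifnot(is(rec, "EMGRecording"))
  if (rec@stage != "raw")
    stop("preprocessEMG expects a raw-stage recording")
  fs <- rec@fs
  if (fs <= 2 * max(notchHz, highpassHz, lowpassHz))
    stop("sampling rate too low for the requested filter corners")
  x <- rec@samples
  if (any(!is.finite(x))) stop("raw samples contain NA/NaN/Inf")
  x <- notchFilter(x, fs, notchHz, notchQ)
  x <- .zeroPhaseButter(x, fs, highpassHz, "high", order)
  x <- abs(x)
  x <- .zeroPhaseButter(x, fs, lowpassHz, "low", order)
  x <- pmax(x, 0)
  initialize(rec, samples = x, stage = "envelope")
}

#' Per-muscle MVC peak from a maximal-contraction trial
#'
#' The MVC recording is processed exactly like a task trial; the peak of
#' each muscle's envelope defines 100% activation for that muscle.
#'
#' @param mvcRec raw-stage [EMGRecording-class] of the MVC trial.
#' @param ... passed to [preprocessEMG()].
#' @return An [MVCReference-class].
#' @export
computeMVCPeak <- function(mvcRec, ...) {
  env <- preprocessEMG(mvcRec, ...)
  peaks <- apply(env@samples, 2, max)
  if (any(peaks <= 0))
    stop("MVC envelope peak is zero for muscle(s): ",
         paste(names(peaks)[peaks <= 0], collapse = ", "))
  MVCReference(peaks, source = mvcRec@subjectId)
}

#' Normalize an envelope by MVC peaks
#'
#' Divides each channel of an envelope-stage recording by the corresponding
#' MVC peak, expressing the signal as a fraction of maximal activation
#' (e_n(t)). Task EMG can transiently exceed MVC; because the downstream
#' activation model maps `[0, 1]` to `[0, 1]`, values are capped at 1 by
#' default.
#'
#' @param env envelope-stage [EMGRecording-class].
#' @param ref [MVCReference-class] covering all muscles in `env`.
#' @param clip cap normalized values at 1 (default TRUE).
#' @return A normalized-stage [EMGRecording-class].
#' @export
mvcNormalize <- function(env, ref, clip = TRUE) {
  stopifnot(is(env, "EMGRecording"), is(ref, "MVCReference"))
  if (env@stage != "envelope")
    stop("mvcNormalize expects an envelope-stage recording")
  missing <- setdiff(env@muscleNames, names(ref@peaks))
  if (length(missing))
    stop("MVC reference lacks muscle(s): ", paste(missing, collapse = ", "))
  x <- sweep(env@samples, 2, ref@peaks[env@muscleNames], "/")
  if (clip) x <- pmin(x, 1)
  initialize(env, samples = x, stage = "normalized")
}

#' Time-normalize curves to a fixed number of phase points
#'
#' Linearly interpolates each channel onto a uniform grid spanning the first
#' to last sample, the standard 0-100% phase normalization (101 points).
#' Endpoints are preserved exactly.
#'
#' @param x numeric vector or matrix (samples x channels) with >= 2 rows.
#' @param nPoints grid size (default 101).
#' @return Matrix `nPoints x channels` (or vector for vector input).
#' @examples
#' timeNormalize(seq(0, 1, length.out = 500))[51]  # 0.5 at 50% phase
#' @export
timeNormalize <- function(x, nPoints = 101) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 2) stop("time normalization needs at least 2 samples")
  if (nPoints < 2) stop("nPoints must be >= 2")
  grid <- seq(1, n, length.out = nPoints)
  out <- apply(x, 2, function(col) approx(seq_len(n), col, xout = grid)$y)
  out <- matrix(out, nrow = nPoints, dimnames = list(NULL, colnames(x)))
  if (vec) drop(out) else out
}
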