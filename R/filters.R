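# Minimal IIR filter design + zero-phase filtering. No DSP dependency:
# Butterworth poles via bilinear transform, RBJ biquad notch, and a
# reflection-padded forward-backward pass (filtfilt) built on stats::filter.

# polynomial coefficients (descending powers) from roots, complex-safe
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Butterworth low-pass coefficients
#'
#' Digital Butterworth low-pass design (bilinear transform with frequency
#' pre-warping), returning transfer-function coefficients `b` (numerator) and
#' `a` (denominator, `a[1] = 1`).
#'
#' @param order Filter order (default 4).
#' @param cutoff -3 dB cutoff in Hz; must be below Nyquist.
#' @param fs Sampling rate in Hz.
#' @return List with numeric vectors `b` and `a`.
#' @export
butter_lowpass <- function(order = 4L, cutoff, fs) {
  stopifnot(order >= 1L, cutoff > 0, fs > 0)
  if (cutoff >= fs / 2) {
    stop("cutoff (", cutoff, " Hz) must be below Nyquist (", fs / 2, " Hz)",
         call. = FALSE)
  }
  Wn <- cutoff / (fs / 2)
  k <- seq_len(order)
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  fs2 <- 2
  wa <- 2 * fs2 * tan(pi * Wn / 2)
  p_a <- wa * p_proto
  p_z <- (1 + p_a / (2 * fs2)) / (1 - p_a / (2 * fs2))
  a <- Re(poly_from_roots(p_z))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  b <- b * sum(a) / sum(b)  # unit DC gain
  list(b = b, a = a)
}

#' Biquad notch coefficients
#'
#' Second-order notch (band-reject) filter centered at `freq` with quality
#' factor `q` (bandwidth `freq/q`). Unit gain away from the notch.
#'
#' @param freq Notch center frequency in Hz; below Nyquist.
#' @param fs Sampling rate in Hz.
#' @param q Quality factor (default 30).
#' @return List with numeric vectors `b` and `a`.
#' @export
notch_coefs <- function(freq, fs, q = 30) {
  stopifnot(freq > 0, fs > 0, q > 0)
  if (freq >= fs / 2) {
    stop("notch frequency (", freq, " Hz) must be below Nyquist (",
         fs / 2, " Hz)", call. = FALSE)
  }
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# single-pass IIR filter. init = "zero" starts from rest; "step" matches the
# steady state for a constant input x[1] (no startup transient on DC), the
# analogue of scipy's lfilter_zi conditioning used inside filtfilt.
iir_filter <- function(x, b, a, init = c("zero", "step")) {
  init <- match.arg(init)
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  x1 <- if (init == "step") x[1] else 0
  xp <- c(rep(x1, nb - 1), x)
  fb <- stats::filter(xp, b, method = "convolution", sides = 1)
  fb <- as.numeric(fb)[-seq_len(nb - 1)]
  if (length(a) > 1L) {
    y0 <- if (init == "step") rep(x1 * sum(b) / sum(a), length(a) - 1L)
          else rep(0, length(a) - 1L)
    fb <- as.numeric(stats::filter(fb, -a[-1], method = "recursive",
                                   init = y0))
  }
  fb
}

#' Zero-phase forward-backward filtering
#'
#' Applies the filter `(b, a)` forward and backward with odd-reflection edge
#' padding, canceling phase distortion and squaring the magnitude response.
#' The pad length adapts to the filter's slowest pole (about six decay time
#' constants, capped by the signal length), so narrow high-Q filters do not
#' leak edge transients into the retained segment.
#'
#' @param x Numeric signal.
#' @param b,a Transfer-function coefficients.
#' @param npad Edge pad length in samples; default as described above.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(x, b, a, npad = NULL) {
  n <- length(x)
  if (is.null(npad)) {
    npad <- 3L * (max(length(a), length(b)) - 1L)
    if (length(a) > 1L) {
      r <- max(Mod(polyroot(rev(a / a[1]))))
      if (r < 1) npad <- max(npad, ceiling(-6 / log(r)))
    }
    npad <- min(npad, n - 2L)
  }
  if (n <= npad + 1L) {
    stop("signal too short (", n, " samples) for edge padding of ", npad,
         call. = FALSE)
  }
  front <- 2 * x[1] - x[(npad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - npad)]
  xe <- c(front, x, back)
  y <- iir_filter(xe, b, a, init = "step")
  y <- rev(iir_filter(rev(y), b, a, init = "step"))
  y[(npad + 1):(npad + n)]
}
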