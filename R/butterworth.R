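# Butterworth band-pass design and application.
#
# The design follows the classical zero-pole-gain route: analog low-pass
# prototype -> low-pass-to-band-pass transform -> bilinear transform with
# frequency prewarping. Coefficients agree with standard DSP toolboxes to
# ~1e-10 (see the frozen-coefficient test).

# polynomial coefficients (descending powers) from roots
.poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (root in r) p <- c(p, 0) - c(0, p) * root
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' @param low,high band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param order analog prototype order (the digital filter has `2 * order`
#'   poles).
#' @return list with numerator `b` and denominator `a` coefficients
#'   (`a[1] == 1`), usable with [filter_signal()].
#' @export
butter_bandpass <- function(low = 20, high = 495, fs = 1000, order = 4) {
  .assert(low > 0 && high > low, "need 0 < low < high")
  if (high >= fs / 2) {
    stop("invalid configuration: high cutoff must be below the Nyquist frequency",
         call. = FALSE)
  }
  n <- as.integer(order)
  # analog low-pass prototype poles on the unit circle, left half plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # prewarped band edges
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # low-pass -> band-pass: each pole splits in two; n zeros appear at s = 0
  ph <- p * bw / 2
  pb <- c(ph + sqrt(ph^2 - w0^2), ph - sqrt(ph^2 - w0^2))
  zb <- rep(0 + 0i, n)
  kb <- bw^n
  # bilinear transform; degree deficit adds zeros at z = -1
  pd <- (fs2 + pb) / (fs2 - pb)
  zd <- c((fs2 + zb) / (fs2 - zb), rep(-1 + 0i, length(pb) - length(zb)))
  kd <- kb * Re(prod(fs2 - zb) / prod(fs2 - pb))
  b <- Re(.poly_from_roots(zd)) * kd
  a <- Re(.poly_from_roots(pd))
  list(b = b, a = a / a[1])
}

#' Frequency response magnitude of a digital filter
#'
#' Evaluates `|B(e^{-i w}) / A(e^{-i w})|` at the requested frequencies —
#' the analytic steady-state gain for a sinusoid at `f` Hz.
#'
#' @param filt list with `b`, `a` as returned by [butter_bandpass()].
#' @param f frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @export
filter_gain <- function(filt, f, fs = 1000) {
  w <- 2 * pi * f / fs
  resp <- vapply(w, function(wi) {
    e <- exp(-1i * wi * (seq_along(filt$b) - 1))
    num <- sum(filt$b * e)
    e <- exp(-1i * wi * (seq_along(filt$a) - 1))
    Mod(num / sum(filt$a * e))
  }, numeric(1))
  resp
}

# single-channel IIR application, zero initial conditions
.apply_iir <- function(x, b, a) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  w <- stats::filter(xp, b, method = "convolution", sides = 1)
  w <- as.numeric(w)[nb:length(xp)]
  as.numeric(stats::filter(w, -a[-1], method = "recursive"))
}

#' Apply a designed filter to a multi-channel signal
#'
#' @param signal numeric matrix, channels x samples.
#' @param filt list with `b`, `a`.
#' @param zero_phase if `TRUE`, apply forward and backward (doubling the
#'   effective order and cancelling phase); the default is a causal forward
#'   pass, matching real-time myoelectric-control use.
#' @export
filter_signal <- function(signal, filt, zero_phase = FALSE) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1)
  out <- t(apply(signal, 1, function(ch) {
    y <- .apply_iir(ch, filt$b, filt$a)
    if (zero_phase) y <- rev(.apply_iir(rev(y), filt$b, filt$a))
    y
  }))
  if (nrow(signal) == 1) dim(out) <- dim(signal)
  out
}

#' Band-pass filter a multi-channel EMG signal
#'
#' Fourth-order Butterworth band-pass between `low` and `high` Hz applied
#' independently to each channel.
#'
#' @inheritParams filter_signal
#' @inheritParams butter_bandpass
#' @export
bandpass_filter <- function(signal, low = 20, high = 495, fs = 1000,
                            order = 4, zero_phase = FALSE) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1)
  .assert(ncol(signal) > 3 * order, "signal too short for the filter order")
  filt <- butter_bandpass(low = low, high = high, fs = fs, order = order)
  filter_signal(signal, filt, zero_phase = zero_phase)
}
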