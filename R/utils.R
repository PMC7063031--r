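#' @keywords internal
#' @useDynLib emglens, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Numerical floor used throughout to guard logs and divisions.
.EPS <- 1e-12

#' One-sided periodogram of a signal window
#'
#' Rectangular-window periodogram with resolution `fs/N`. The DC bin is
#' returned but flagged so that spectral peak and moment computations can
#' exclude it (a band-passed EMG window carries no useful DC information).
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @return list with `freq` (Hz) and `power` vectors of length
#'   `floor(N/2) + 1`, including the 0 Hz bin at position 1.
#' @export
periodogram <- function(x, fs = 1000) {
  n <- length(x)
  sp <- stats::fft(x)
  nh <- floor(n / 2)
  p <- Mod(sp[seq_len(nh + 1)])^2 / n
  # fold the energy of the discarded conjugate half into bins 2..nh(+1)
  if (n %% 2 == 0) {
    if (nh >= 2) p[2:nh] <- 2 * p[2:nh]
  } else {
    p[2:(nh + 1)] <- 2 * p[2:(nh + 1)]
  }
  list(freq = (0:nh) * fs / n, power = p)
}

# Spectral moment m_k = sum f^k P(f), excluding the DC bin.
.spectral_moment <- function(pg, k) {
  sum(pg$freq[-1]^k * pg$power[-1])
}

# Band power between lo and hi Hz (inclusive), DC excluded unless lo <= 0.
.band_power <- function(pg, lo, hi) {
  idx <- pg$freq >= lo & pg$freq <= hi
  if (lo > 0) idx[1] <- FALSE
  sum(pg$power[idx])
}

# Centered moving average with window w (truncated at the edges).
.moving_average <- function(x, w) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- floor(w / 2)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + (w - half - 1), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Least-squares slope of y on x (used by the fractal / scaling estimators).
.ls_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}
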