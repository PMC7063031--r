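# Handcrafted EMG feature implementations.
#
# Every function maps a single-channel window (numeric vector, typically
# 151 samples) to one or more scalars. Division and logarithm are guarded
# with a 1e-12 floor so that degenerate windows (e.g. all-zero) still
# produce finite values. Frequency-domain features use the one-sided
# rectangular-window periodogram (see periodogram()); the 0 Hz bin is
# excluded from spectral peaks and moments.

## ---- signal amplitude and power (SAP) ----

fe_iemg <- function(x, p) sum(abs(x))
fe_mav  <- function(x, p) mean(abs(x))

fe_mmav1 <- function(x, p) {
  n <- length(x); i <- seq_len(n)
  w <- ifelse(i >= 0.25 * n & i <= 0.75 * n, 1, 0.5)
  mean(w * abs(x))
}

fe_mmav2 <- function(x, p) {
  n <- length(x); i <- seq_len(n)
  w <- ifelse(i < 0.25 * n, 4 * i / n,
              ifelse(i > 0.75 * n, 4 * (n - i) / n, 1))
  mean(w * abs(x))
}

fe_rms <- function(x, p) sqrt(mean(x^2))
fe_var <- function(x, p) sum(x^2) / (length(x) - 1)
fe_ssi <- function(x, p) sum(x^2)
fe_v   <- function(x, p) mean(x^p$v)^(1 / p$v)
fe_ld  <- function(x, p) exp(mean(log(pmax(abs(x), .EPS))))
fe_max <- function(x, p) max(abs(x))
fe_wl  <- function(x, p) sum(abs(diff(x)))
fe_tm  <- function(x, p) abs(mean(x^3))
fe_m2  <- function(x, p) sum(diff(x)^2)

fe_sm  <- function(x, p) .spectral_moment(periodogram(x, p$fs), 2)
fe_mnp <- function(x, p) mean(periodogram(x, p$fs)$power)
fe_ttp <- function(x, p) sum(periodogram(x, p$fs)$power)

# three half-overlapping windowed segments; energy of the windowed signal
.windowed_energies <- function(x, winfun) {
  n <- length(x)
  len <- floor(n / 2)
  starts <- round(c(1, n / 4, n / 2))
  w <- winfun(len)
  vapply(starts, function(s) {
    seg <- x[s:(s + len - 1)]
    sum((w * seg)^2)
  }, numeric(1))
}

fe_mhw <- function(x, p) {
  hamming <- function(l) 0.54 - 0.46 * cos(2 * pi * (seq_len(l) - 1) / (l - 1))
  .windowed_energies(x, hamming)
}

fe_mtw <- function(x, p) {
  trapez <- function(l) {
    q <- floor(l / 4)
    c(seq(0, 1, length.out = q), rep(1, l - 2 * q), seq(1, 0, length.out = q))
  }
  .windowed_energies(x, trapez)
}

fe_afb <- function(x, p) {
  ma <- .moving_average(abs(x), 32)
  n <- length(ma)
  for (i in 2:(n - 1)) {
    if (ma[i - 1] < ma[i] && ma[i] >= ma[i + 1]) return(ma[i])
  }
  max(ma)
}

# difference-series variants: base feature applied to the first difference
fe_damv  <- function(x, p) fe_mav(diff(x), p)
fe_dasdv <- function(x, p) sqrt(mean(diff(x)^2))
fe_dld   <- function(x, p) fe_ld(diff(x), p)
fe_dtm   <- function(x, p) fe_tm(diff(x), p)
fe_dvarv <- function(x, p) fe_var(diff(x), p)
fe_dv    <- function(x, p) fe_v(diff(x), p)

## ---- frequency information (FI) ----

fe_zc <- function(x, p) {
  a <- x[-length(x)]; b <- x[-1]
  sum(a * b < 0 & abs(a - b) >= p$threshold)
}

fe_ssc <- function(x, p) {
  n <- length(x)
  d1 <- x[2:(n - 1)] - x[1:(n - 2)]
  d2 <- x[2:(n - 1)] - x[3:n]
  sum(d1 * d2 > 0 & pmax(abs(d1), abs(d2)) >= p$threshold)
}

fe_mnf <- function(x, p) {
  pg <- periodogram(x, p$fs)
  .spectral_moment(pg, 1) / max(.spectral_moment(pg, 0), .EPS)
}

fe_mdf <- function(x, p) {
  pg <- periodogram(x, p$fs)
  pw <- pg$power[-1]
  cs <- cumsum(pw)
  tot <- cs[length(cs)]
  if (tot < .EPS) return(0)
  pg$freq[-1][which(cs >= tot / 2)[1]]
}

fe_fr <- function(x, p) {
  pg <- periodogram(x, p$fs)
  .band_power(pg, p$low_band[1], p$low_band[2]) /
    max(.band_power(pg, p$high_band[1], p$high_band[2]), .EPS)
}

## ---- non-linear complexity (NLC) ----

fe_wamp <- function(x, p) sum(abs(diff(x)) > p$threshold)

# Chebyshev distances between all template pairs of length m
.template_cheb <- function(x, m) {
  n <- length(x) - m + 1
  d <- abs(outer(x[seq_len(n)], x[seq_len(n)], "-"))
  if (m > 1) {
    for (k in 2:m) {
      v <- x[k:(k + n - 1)]
      d <- pmax(d, abs(outer(v, v, "-")))
    }
  }
  d
}

# counts of Chebyshev-close template pairs of length m (i < j)
.template_matches <- function(x, m, r) {
  n <- length(x) - m + 1
  if (n < 2) return(0)
  d <- .template_cheb(x, m)
  (sum(d <= r) - n) / 2
}

fe_sampen <- function(x, p) {
  s <- stats::sd(x)
  if (s < .EPS) return(0)
  r <- p$r_frac * s
  b <- .template_matches(x[seq_len(length(x) - 1)], p$m, r)
  a <- .template_matches(x, p$m + 1, r)
  -log(max(a, .EPS) / max(b, .EPS))
}

fe_apen <- function(x, p) {
  s <- stats::sd(x)
  if (s < .EPS) return(0)
  r <- p$r_frac * s
  phi <- function(m) {
    n <- length(x) - m + 1
    cm <- colSums(.template_cheb(x, m) <= r) / n   # self-matches included
    mean(log(pmax(cm, .EPS)))
  }
  phi(p$m) - phi(p$m + 1)
}

# box counts of a polyline normalised to the unit square, grids 2^(1..5)
.box_count_dim <- function(y) {
  n <- length(y)
  rng <- range(y)
  if (diff(rng) < .EPS) return(1)
  yn <- (y - rng[1]) / diff(rng)
  tn <- (seq_len(n) - 1) / (n - 1)
  scales <- 2^(1:5)
  counts <- vapply(scales, function(s) {
    col <- pmin(floor(tn * s), s - 1)
    tot <- 0
    for (cc in unique(col)) {
      yy <- yn[col == cc]
      lo <- pmin(floor(min(yy) * s), s - 1)
      hi <- pmin(floor(max(yy) * s), s - 1)
      tot <- tot + (hi - lo + 1)
    }
    tot
  }, numeric(1))
  .ls_slope(log(scales), log(counts))
}

fe_bc <- function(x, p) .box_count_dim(x)

fe_katz <- function(x, p) {
  n <- length(x) - 1
  l <- max(sum(abs(diff(x))), .EPS)
  d <- max(max(abs(x - x[1])), .EPS)
  log10(n) / (log10(n) + log10(max(d / l, .EPS)))
}

fe_mfl <- function(x, p) log10(max(sqrt(sum(diff(x)^2)), .EPS))

## ---- time-series modelling (TSM) ----

# Levinson-Durbin on the biased autocorrelation; returns predictor
# coefficients phi so that x_t ~ sum_k phi_k x_{t-k}
ar_coefficients <- function(x, order = 4) {
  n <- length(x)
  r <- vapply(0:order, function(k) sum(x[seq_len(n - k)] * x[(k + 1):n]) / n,
              numeric(1))
  if (r[1] < .EPS) return(rep(0, order))
  phi <- numeric(order)
  e <- r[1]
  for (k in seq_len(order)) {
    if (e < .EPS) break
    acc <- r[k + 1] - if (k > 1) sum(phi[seq_len(k - 1)] * r[k:2]) else 0
    kk <- acc / e
    prev <- phi
    phi[k] <- kk
    if (k > 1) phi[seq_len(k - 1)] <- prev[seq_len(k - 1)] - kk * prev[(k - 1):1]
    e <- e * (1 - kk^2)
  }
  phi
}

# LPC cepstrum recursion from AR polynomial a_k = -phi_k; c_1 = -a_1
cepstral_from_ar <- function(phi) {
  a <- -phi
  p <- length(a)
  cc <- numeric(p)
  cc[1] <- -a[1]
  if (p > 1) {
    for (n in 2:p) {
      m <- seq_len(n - 1)
      cc[n] <- -a[n] - sum((m / n) * cc[m] * a[n - m])
    }
  }
  cc
}

fe_ar  <- function(x, p) ar_coefficients(x, p$order)
fe_cc  <- function(x, p) cepstral_from_ar(ar_coefficients(x, p$order))
fe_dar <- function(x, p) ar_coefficients(diff(x), p$order)
fe_dcc <- function(x, p) cepstral_from_ar(ar_coefficients(diff(x), p$order))

fe_dfa <- function(x, p) {
  n <- length(x)
  y <- cumsum(x - mean(x))
  sizes <- unique(round(exp(seq(log(4), log(n / 4), length.out = 8))))
  fl <- vapply(sizes, function(s) {
    nseg <- floor(n / s)
    res <- 0
    t <- seq_len(s)
    for (k in seq_len(nseg)) {
      seg <- y[((k - 1) * s + 1):(k * s)]
      fit <- stats::lm.fit(cbind(1, t), seg)
      res <- res + sum(fit$residuals^2)
    }
    sqrt(res / (nseg * s))
  }, numeric(1))
  .ls_slope(log(sizes), log(pmax(fl, .EPS)))
}

fe_psr <- function(x, p) {
  pg <- periodogram(x, p$fs)
  pw <- pg$power[-1]; fr <- pg$freq[-1]
  tot <- sum(pw)
  if (tot < .EPS) return(0)
  fp <- fr[which.max(pw)]
  sum(pw[fr >= fp - p$width & fr <= fp + p$width]) / tot
}

fe_snr <- function(x, p) {
  pg <- periodogram(x, p$fs)
  pw <- sort(pg$power[-1])
  noise <- mean(pw[seq_len(max(1, floor(length(pw) / 10)))])
  10 * log10(max(mean(pw), .EPS) / max(noise, .EPS))
}

## ---- unique (UNI) ----

fe_kurt <- function(x, p) {
  s <- stats::sd(x)
  if (s < .EPS) return(0)
  mean((x - mean(x))^4) / s^4
}

fe_skew <- function(x, p) {
  s <- stats::sd(x)
  if (s < .EPS) return(0)
  mean((x - mean(x))^3) / s^3
}

fe_pkf <- function(x, p) {
  pg <- periodogram(x, p$fs)
  pg$freq[-1][which.max(pg$power[-1])]
}

fe_vcf <- function(x, p) {
  pg <- periodogram(x, p$fs)
  m0 <- max(.spectral_moment(pg, 0), .EPS)
  m1 <- .spectral_moment(pg, 1)
  m2 <- .spectral_moment(pg, 2)
  m2 / m0 - (m1 / m0)^2
}

fe_ohm <- function(x, p) {
  pg <- periodogram(x, p$fs)
  m0 <- max(.spectral_moment(pg, 0), .EPS)
  m1 <- max(.spectral_moment(pg, 1), .EPS)
  m2 <- .spectral_moment(pg, 2)
  sqrt(m2 / m0) / (m1 / m0)
}

fe_dpr <- function(x, p) {
  pg <- periodogram(x, p$fs)
  sm <- .moving_average(pg$power[-1], 20)
  max(sm) / max(min(sm), .EPS)
}

fe_smr <- function(x, p) {
  pg <- periodogram(x, p$fs)
  .band_power(pg, 35, p$fs / 2) / max(.band_power(pg, 0, 35), .EPS)
}

fe_mavs <- function(x, p) {
  n <- length(x)
  h <- floor(n / 2)
  mean(abs(x[(h + 1):n])) - mean(abs(x[seq_len(h)]))
}

fe_hist <- function(x, p) {
  s <- stats::sd(x)
  if (s < .EPS) return(c(0, length(x), 0)[seq_len(p$bins)])
  lim <- 3 * s
  xc <- pmin(pmax(x - mean(x), -lim), lim)
  bin <- pmin(floor((xc + lim) / (2 * lim) * p$bins), p$bins - 1)
  tabulate(bin + 1, nbins = p$bins)
}

# scaling exponent H of the lag-k increment variance, k = 1..8
.increment_exponent <- function(x) {
  ks <- 1:8
  v <- vapply(ks, function(k) {
    n <- length(x)
    mean((x[(k + 1):n] - x[seq_len(n - k)])^2)
  }, numeric(1))
  .ls_slope(log(ks), log(pmax(v, .EPS)))
}

fe_ce  <- function(x, p) .increment_exponent(x)
fe_vfd <- function(x, p) 2 - .increment_exponent(x) / 2

fe_psdfd <- function(x, p) {
  pg <- periodogram(x, p$fs)
  .box_count_dim(pg$power[-1])
}

fe_tspsd <- function(x, p) {
  lg <- function(v) log(max(abs(v), .EPS))
  d1 <- diff(x); d2 <- diff(d1)
  m0 <- sqrt(sum(x^2))^0.1 / 0.1
  m2 <- sqrt(sum(d1^2))^0.1 / 0.1
  m4 <- sqrt(sum(d2^2))^0.1 / 0.1
  sparseness <- m0 / max(sqrt(abs((m0 - m2) * (m0 - m4))), .EPS)
  irregularity <- m2 / max(sqrt(abs(m0 * m4)), .EPS)
  wl_ratio <- sum(abs(d1)) / max(sum(abs(d2)), .EPS)
  c(lg(m0), lg(m0 - m2), lg(m0 - m4), lg(sparseness), lg(irregularity),
    lg(wl_ratio))
}
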