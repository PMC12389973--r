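# IIR filter design and application.
#
# Butterworth designs are obtained the classical way: analog lowpass
# prototype poles on the unit circle, frequency transform
# (lp2lp/lp2hp/lp2bp/lp2bs), then the bilinear transform at fs = 2 so
# that critical frequencies are expressed as fractions of Nyquist.

#' Butterworth IIR filter design
#'
#' Designs a digital Butterworth filter and returns transfer-function
#' coefficients, following the standard analog-prototype + bilinear
#' transform construction.
#'
#' @param n filter order of the analog prototype (band-pass and band-stop
#'   designs have final order `2 * n`).
#' @param Wn critical frequency (fraction of Nyquist, in (0, 1)); a
#'   length-2 vector for `"pass"`/`"stop"` types.
#' @param type one of `"low"`, `"high"`, `"pass"`, `"stop"`.
#' @return list with numerator `b` and denominator `a` coefficients
#'   (`a[1] == 1`).
#' @export
butter_design <- function(n, Wn, type = c("low", "high", "pass", "stop")) {
  type <- match.arg(type)
  if (n < 1) stop("filter order must be >= 1")
  if (any(Wn <= 0) || any(Wn >= 1)) {
    stop("critical frequencies must lie strictly inside (0, 1) of Nyquist")
  }
  if (type %in% c("pass", "stop")) {
    if (length(Wn) != 2 || Wn[1] >= Wn[2]) {
      stop("band filters need Wn = c(low, high) with low < high")
    }
  } else if (length(Wn) != 1) {
    stop("low/high filters take a scalar Wn")
  }

  fs <- 2
  warped <- 2 * fs * tan(pi * Wn / fs)

  # analog lowpass prototype: unit-cutoff Butterworth poles
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  z <- complex(0)
  gain <- 1

  zpk <- switch(type,
    low  = .lp2lp(z, p, gain, warped),
    high = .lp2hp(z, p, gain, warped),
    pass = .lp2bp(z, p, gain, sqrt(warped[1] * warped[2]), diff(warped)),
    stop = .lp2bs(z, p, gain, sqrt(warped[1] * warped[2]), diff(warped))
  )
  zpk <- .bilinear_zpk(zpk$z, zpk$p, zpk$k, fs)

  b <- Re(.poly_from_roots(zpk$z)) * zpk$k
  a <- Re(.poly_from_roots(zpk$p))
  list(b = b, a = a)
}

.poly_from_roots <- function(r) {
  out <- complex(real = 1)
  for (ri in r) out <- c(out, 0) - c(0, out) * ri
  out
}

.lp2lp <- function(z, p, k, wo) {
  list(z = z * wo, p = p * wo, k = k * wo^(length(p) - length(z)))
}

.lp2hp <- function(z, p, k, wo) {
  d <- length(p) - length(z)
  zn <- if (length(z)) wo / z else complex(0)
  pn <- wo / p
  num <- if (length(z)) prod(-z) else complex(real = 1)
  list(z = c(zn, rep(0 + 0i, d)), p = pn, k = k * Re(num / prod(-p)))
}

.lp2bp <- function(z, p, k, wo, bw) {
  d <- length(p) - length(z)
  shift <- function(r) {
    s <- r * bw / 2
    rt <- sqrt(s^2 - wo^2)
    c(s + rt, s - rt)
  }
  zn <- if (length(z)) shift(z) else complex(0)
  list(z = c(zn, rep(0 + 0i, d)), p = shift(p), k = k * bw^d)
}

.lp2bs <- function(z, p, k, wo, bw) {
  d <- length(p) - length(z)
  shift <- function(r) {
    s <- (bw / 2) / r
    rt <- sqrt(s^2 - wo^2)
    c(s + rt, s - rt)
  }
  zn <- if (length(z)) shift(z) else complex(0)
  pn <- shift(p)
  num <- if (length(z)) prod(-z) else complex(real = 1)
  zext <- c(zn, rep(1i * wo, d), rep(-1i * wo, d))
  list(z = zext, p = pn, k = k * Re(num / prod(-p)))
}

.bilinear_zpk <- function(z, p, k, fs) {
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  d <- length(p) - length(z)
  num <- if (length(z)) prod(fs2 - z) else complex(real = 1)
  list(
    z = c(zd, rep(-1 + 0i, d)),
    p = pd,
    k = k * Re(num / prod(fs2 - p))
  )
}

# Single-pass IIR difference equation
#   y[t] = sum_j b[j] x[t-j+1] - sum_j a[j+1] y[t-j]
# implemented with stats::filter (FIR convolution + recursive AR part).
# The filter is started in the steady state it would reach if the input
# had been constant at x[1] forever (removes start-up transients).
.iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  na <- length(a)
  dc <- sum(b) / sum(a)

  xp <- if (nb > 1) c(rep(x[1], nb - 1), x) else x
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v[nb:length(v)])
  if (na > 1) {
    y <- stats::filter(v, -a[-1], method = "recursive",
                       init = rep(x[1] * dc, na - 1))
    as.numeric(y)
  } else {
    v
  }
}

#' Zero-phase forward-backward IIR filtering
#'
#' Applies the filter twice, forward and reversed, so the net phase
#' response is zero (amplitude response is squared). Edges are handled
#' by odd extension of the signal before filtering.
#'
#' @param b,a transfer-function coefficients from [butter_design()].
#' @param x numeric vector.
#' @return filtered vector, same length as `x`.
#' @export
filtfilt_iir <- function(b, a, x) {
  n <- length(x)
  padlen <- min(3 * max(length(a), length(b)), n - 1)
  if (padlen < 1) stop("signal too short to filter")
  head_ext <- 2 * x[1] - x[(padlen + 1):2]
  tail_ext <- 2 * x[n] - x[(n - 1):(n - padlen)]
  ext <- c(head_ext, x, tail_ext)
  y <- .iir_filter(b, a, ext)
  y <- rev(.iir_filter(b, a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Analytic signal via the discrete Hilbert transform
#'
#' @param x real numeric vector.
#' @return complex vector `x + i * H(x)`; `Arg()` of it is the
#'   instantaneous phase, `Mod()` the instantaneous amplitude.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Welch power spectral density
#'
#' Hann-tapered, mean-detrended overlapping segments; one-sided density
#' scaling so that `sum(psd) * df` approximates the signal variance.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples (default 1 s of data, capped
#'   at the signal length).
#' @param overlap fractional overlap between segments.
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(round(fs), n)
  nperseg <- min(nperseg, n)
  step <- max(1, floor(nperseg * (1 - overlap)))
  starts <- seq(1, n - nperseg + 1, by = step)

  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / nperseg)  # periodic Hann
  scale <- fs * sum(w^2)
  nfreq <- nperseg %/% 2 + 1

  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    S <- stats::fft(seg)[seq_len(nfreq)]
    acc <- acc + (Mod(S)^2) / scale
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when present)
  if (nperseg %% 2 == 0) {
    psd[2:(nfreq - 1)] <- 2 * psd[2:(nfreq - 1)]
  } else if (nfreq > 1) {
    psd[2:nfreq] <- 2 * psd[2:nfreq]
  }
  list(freq = (seq_len(nfreq) - 1) * fs / nperseg, psd = psd)
}
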