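# Digital filter primitives: Butterworth band-pass design, zero-phase
# application, and Savitzky-Golay polynomial smoothing. These are kept
# internal; user-facing wrappers live in ppg.R.

# Polynomial coefficients (descending powers) from complex roots.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' Classical pole placement on the analog Butterworth circle, low-pass to
#' band-pass transformation, and bilinear mapping to the z-plane with
#' frequency pre-warping. Gain is normalized to unity at the geometric
#' center of the pass band.
#'
#' @param low,high Pass-band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @param order Order of the low-pass prototype (the band-pass filter has
#'   twice this many poles). Default 4.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @keywords internal
#' @noRd
butter_bandpass <- function(low, high, fs, order = 4) {
  stopifnot(low > 0, high > low, fs > 2 * high, order >= 1)
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order)
  p_proto <- complex(real = -sin(theta), imaginary = cos(theta))

  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  w0sq <- w1 * w2
  bw <- w2 - w1

  # low-pass prototype -> band-pass: each pole splits into two
  p_lp <- p_proto * bw / 2
  disc <- sqrt(p_lp^2 - w0sq)
  p_s <- c(p_lp + disc, p_lp - disc)
  z_s <- rep(0 + 0i, order)          # n zeros at s = 0 (plus n at infinity)
  k_s <- bw^order

  # bilinear transform
  p_z <- (fs2 + p_s) / (fs2 - p_s)
  z_z <- c((fs2 + z_s) / (fs2 - z_s), rep(-1 + 0i, order))
  k_z <- k_s * Re(prod(fs2 - z_s) / prod(fs2 - p_s))

  b <- Re(poly_from_roots(z_z)) * k_z
  a <- Re(poly_from_roots(p_z))

  # exact unity gain at the geometric band center
  wc <- 2 * pi * sqrt(low * high) / fs
  ejw <- exp(complex(imaginary = -wc * (seq_along(a) - 1)))
  g <- abs(sum(b * ejw[seq_along(b)]) / sum(a * ejw))
  list(b = b / g, a = a)
}

# Largest pole magnitude; controls how long filter transients persist.
max_pole_radius <- function(a) {
  if (length(a) < 2) return(0)
  max(Mod(polyroot(rev(a))))
}

# Causal IIR filtering with zero initial state, via an FIR convolution
# stage followed by the recursive stage (both run in C by stats::filter).
iir_filter <- function(b, a, x) {
  v <- as.numeric(stats::filter(c(rep(0, length(b) - 1), x), b / a[1],
                                method = "convolution", sides = 1))
  v <- v[-seq_len(length(b) - 1)]
  if (length(a) > 1) {
    as.numeric(stats::filter(v, -a[-1] / a[1], method = "recursive"))
  } else {
    v
  }
}

#' Zero-phase filtering (forward-backward application)
#'
#' Applies the filter forward and then time-reversed so the net phase
#' response is zero. Edge transients are controlled by odd-symmetric
#' signal extension long enough for the slowest pole to decay below 1e-9.
#'
#' @keywords internal
#' @noRd
filtfilt <- function(b, a, x) {
  n <- length(x)
  r <- max_pole_radius(a)
  padlen <- 3 * (max(length(a), length(b)) - 1)
  if (r > 0 && r < 1) {
    padlen <- max(padlen, ceiling(log(1e-9) / log(r)))
  }
  padlen <- min(padlen, n - 1)
  if (padlen < 1) stop("signal too short for zero-phase filtering")
  head_ext <- 2 * x[1] - x[(padlen + 1):2]
  tail_ext <- 2 * x[n] - x[(n - 1):(n - padlen)]
  xe <- c(head_ext, x, tail_ext)
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with a centered window.
#' Interior samples use the standard convolution kernel; the first and
#' last half-windows are smoothed by evaluating the polynomial fitted to
#' the first/last full window (so polynomials of degree <= `order` are
#' reproduced exactly everywhere).
#'
#' @keywords internal
#' @noRd
savgol <- function(x, order = 3, window = 35) {
  stopifnot(window %% 2 == 1, window > order, order >= 0)
  n <- length(x)
  if (n < window) stop("signal shorter than the Savitzky-Golay window")
  h <- (window - 1L) / 2L
  A <- outer(seq(-h, h), 0:order, `^`)
  G <- solve(crossprod(A), t(A))           # (order+1) x window projector
  kern <- G[1, ]
  y <- as.numeric(stats::filter(x, rev(kern), method = "convolution",
                                sides = 2))
  # edge handling: evaluate the boundary-window polynomials
  Phead <- outer(seq(-h, -1), 0:order, `^`) %*% G  # h x window
  Ptail <- outer(seq(1, h), 0:order, `^`) %*% G
  y[1:h] <- as.numeric(Phead %*% x[1:window])
  y[(n - h + 1):n] <- as.numeric(Ptail %*% x[(n - window + 1):n])
  y
}

#' Dominant frequency of a signal by zero-padded periodogram peak
#'
#' Hann-windowed, zero-padded FFT power spectrum restricted to
#' `[fmin, fmax]`; the peak bin is refined by parabolic interpolation on
#' log power, giving resolution far below one bin.
#'
#' @return Frequency in Hz, or `NA_real_` when the signal is flat.
#' @keywords internal
#' @noRd
dominant_frequency <- function(x, fs, fmin, fmax) {
  x <- x - mean(x)
  n <- length(x)
  if (n < 4 || max(abs(x)) < .Machine$double.eps * 1e3) return(NA_real_)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  nfft <- 2^ceiling(log2(max(16 * n, 4096)))
  spec <- Mod(stats::fft(c(x * w, rep(0, nfft - n))))^2
  freqs <- (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft
  keep <- which(freqs >= fmin & freqs <= fmax)
  if (length(keep) == 0) return(NA_real_)
  pk <- keep[which.max(spec[keep])]
  f <- freqs[pk]
  if (pk > 1 && pk < length(freqs)) {
    lp <- log(pmax(spec[(pk - 1):(pk + 1)], .Machine$double.xmin))
    denom <- lp[1] - 2 * lp[2] + lp[3]
    if (is.finite(denom) && denom < 0) {
      delta <- 0.5 * (lp[1] - lp[3]) / denom
      if (abs(delta) <= 1) f <- f + delta * fs / nfft
    }
  }
  f
}
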