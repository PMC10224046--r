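# IIR filter design and zero-phase application.
#
# No signal-processing package is assumed: Butterworth designs are derived
# from the analog prototype (poles on the unit circle), frequency-transformed
# (lowpass/highpass/bandpass), mapped to z via the bilinear transform with
# pre-warping, and emitted as second-order sections (SOS). Zero-phase
# filtering is forward-backward with odd-reflection edge padding and
# steady-state initial conditions per section, so step offsets at the edges
# do not leak transients into the output.

#' Butterworth filter design as second-order sections
#'
#' Designs a digital Butterworth filter by bilinear transform of the analog
#' prototype, returned as a cascade of second-order sections.
#'
#' @param order filter design order (the analog prototype order; a bandpass
#'   design of order `n` has `2 n` poles).
#' @param wn normalized cutoff(s) as a fraction of the Nyquist frequency,
#'   in (0, 1); length 2 (low, high) for `type = "pass"`.
#' @param type `"pass"`, `"low"` or `"high"`.
#' @return numeric matrix with one row per section, columns
#'   `b0 b1 b2 a0 a1 a2` (`a0` always 1).
#' @examples
#' sos <- butter_sos(4, c(7, 30) / 500, "pass")
#' @export
butter_sos <- function(order, wn, type = c("pass", "low", "high")) {
  type <- match.arg(type)
  if (order < 1 || order != round(order))
    scg_stop("filter order must be a positive integer", "scg_config_error")
  if (any(wn <= 0) || any(wn >= 1))
    scg_stop("normalized cutoffs must lie strictly inside (0, 1)",
             "scg_config_error")
  fs2 <- 4  # 2 * fs on the normalized (fs = 2) design grid
  # analog lowpass prototype: poles on the unit circle, no zeros, unit gain
  p <- exp(1i * pi * (2 * seq_len(order) + order - 1) / (2 * order))
  k <- 1
  warped <- fs2 * tan(pi * wn / 2)
  if (type == "pass") {
    if (length(wn) != 2 || wn[1] >= wn[2])
      scg_stop("bandpass design needs wn = c(low, high) with low < high",
               "scg_config_error")
    wo <- sqrt(prod(warped))
    bw <- diff(warped)
    s <- p * bw / 2
    p <- c(s + sqrt(s^2 - wo^2), s - sqrt(s^2 - wo^2))
    z <- rep(0 + 0i, order)
    k <- bw^order
  } else if (type == "low") {
    p <- warped[1] * p
    z <- complex(0)
    k <- warped[1]^order
  } else { # high
    p <- warped[1] / p
    z <- rep(0 + 0i, order)
  }
  # bilinear transform with matched degree (extra zeros at z = -1)
  k <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  pd <- (fs2 + p) / (fs2 - p)
  zd <- if (length(z)) (fs2 + z) / (fs2 - z) else complex(0)
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  zpk_to_sos(zd, pd, k)
}

# Convert zeros/poles/gain to SOS. Tailored to the designs above: all zeros
# are real (at z = +1 / z = -1), poles come in conjugate pairs plus at most
# one real pair or singleton.
zpk_to_sos <- function(z, p, k) {
  tol <- 1e-9
  cplx <- p[Im(p) > tol]
  realp <- Re(p[abs(Im(p)) <= tol])
  zr <- Re(z)
  n_sec2 <- length(cplx) + length(realp) %/% 2
  odd <- length(realp) %% 2 == 1
  n_sec <- n_sec2 + as.integer(odd)
  sos <- matrix(0, n_sec, 6)
  # denominators
  row <- 1
  for (q in cplx) {
    sos[row, 4:6] <- c(1, -2 * Re(q), Mod(q)^2)
    row <- row + 1
  }
  if (length(realp) >= 2) {
    for (i in seq(1, 2 * (length(realp) %/% 2), by = 2)) {
      sos[row, 4:6] <- c(1, -(realp[i] + realp[i + 1]), realp[i] * realp[i + 1])
      row <- row + 1
    }
  }
  if (odd) sos[n_sec, 4:6] <- c(1, -realp[length(realp)], 0)
  # numerators: hand out zeros two per full section, preferring one +1 and
  # one -1 each (keeps every bandpass section itself a small bandpass)
  n_p1 <- sum(abs(zr - 1) < 1e-6)
  n_m1 <- sum(abs(zr + 1) < 1e-6)
  if (n_p1 + n_m1 != length(zr))
    scg_stop("internal: unexpected zero locations in design", "scg_config_error")
  take <- function(n_needed) {
    zz <- numeric(0)
    for (i in seq_len(n_needed)) {
      if (n_p1 > 0 && (n_m1 == 0 || n_p1 >= n_m1)) {
        zz <- c(zz, 1); n_p1 <<- n_p1 - 1
      } else if (n_m1 > 0) {
        zz <- c(zz, -1); n_m1 <<- n_m1 - 1
      }
    }
    zz
  }
  g <- k^(1 / n_sec)
  for (row in seq_len(n_sec)) {
    first_order <- odd && row == n_sec
    zz <- take(if (first_order) 1 else 2)
    b <- if (length(zz) == 2) c(1, -(zz[1] + zz[2]), zz[1] * zz[2])
         else if (length(zz) == 1) c(1, -zz[1], 0)
         else c(1, 0, 0)
    sos[row, 1:3] <- g * b
  }
  sos
}

#' Second-order IIR notch design
#'
#' Single-biquad notch at a normalized center frequency, standard
#' constant-Q audio-EQ parameterization.
#'
#' @param w0 normalized center frequency (fraction of Nyquist, in (0, 1)).
#' @param q quality factor (center frequency / -3 dB bandwidth).
#' @return 1 x 6 SOS matrix.
#' @export
notch_sos <- function(w0, q = 30) {
  if (w0 <= 0 || w0 >= 1)
    scg_stop("notch center must lie strictly inside (0, 1) of Nyquist",
             "scg_config_error")
  th <- pi * w0
  alpha <- sin(th) / (2 * q)
  a0 <- 1 + alpha
  matrix(c(1 / a0, -2 * cos(th) / a0, 1 / a0,
           1, -2 * cos(th) / a0, (1 - alpha) / a0), 1, 6)
}

# Steady-state (unit-step) initial conditions for each DF2T section.
sos_zi <- function(sos) {
  t(apply(sos, 1, function(s) {
    b0 <- s[1]; b1 <- s[2]; b2 <- s[3]; a1 <- s[5]; a2 <- s[6]
    h <- (b0 + b1 + b2) / (1 + a1 + a2)
    c(h - b0, b2 - a2 * h)
  }))
}

#' Zero-phase filtering with a second-order-section cascade
#'
#' Applies the cascade forward and backward (squared magnitude response,
#' zero net phase). The signal is extended at both ends by odd reflection
#' and each pass starts from steady-state initial conditions scaled to the
#' first sample, which suppresses edge transients even for high-Q sections.
#'
#' @param x numeric signal.
#' @param sos SOS matrix as returned by [butter_sos()] / [notch_sos()].
#' @param padlen reflection padding length in samples; the default is
#'   derived from the slowest pole radius of the cascade (long enough for
#'   its transient to decay below 1e-12) and is clipped to `length(x) - 1`.
#' @return filtered signal, same length as `x`.
#' @export
sosfiltfilt <- function(x, sos, padlen = NULL) {
  n <- length(x)
  ns <- nrow(sos)
  if (n < 4) scg_stop("signal too short to filter", "scg_length_error")
  if (is.null(padlen)) {
    r <- max(vapply(seq_len(ns), function(s)
      max(Mod(polyroot(c(sos[s, 6], sos[s, 5], 1)))), numeric(1)))
    padlen <- if (r >= 1) n - 1L
      else min(20000L, max(27L, as.integer(ceiling(log(1e-12) / log(r)))))
  }
  padlen <- min(as.integer(padlen), n - 1L)
  ext <- if (padlen > 0) {
    c(2 * x[1] - x[seq(padlen + 1, 2)], x, 2 * x[n] - x[seq(n - 1, n - padlen)])
  } else x
  zib <- sos_zi(sos)
  dc <- apply(sos, 1, function(s) (s[1] + s[2] + s[3]) / (1 + s[5] + s[6]))
  cumg <- c(1, cumprod(dc))[seq_len(ns)]
  y <- sosfilt_cpp(sos, ext, zib * (cumg * ext[1]))
  y <- rev(y)
  y <- sosfilt_cpp(sos, y, zib * (cumg * y[1]))
  y <- rev(y)
  y[seq(padlen + 1, padlen + n)]
}

#' Frequency response of an SOS cascade
#'
#' @param sos SOS matrix.
#' @param f frequencies in Hz.
#' @param fs sampling frequency in Hz.
#' @return complex response `H(f)` (single pass; zero-phase application
#'   realizes `|H|^2`).
#' @export
sos_freqz <- function(sos, f, fs) {
  zi1 <- exp(-2i * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (r in seq_len(nrow(sos))) {
    h <- h * (sos[r, 1] + sos[r, 2] * zi1 + sos[r, 3] * zi1^2) /
      (1 + sos[r, 5] * zi1 + sos[r, 6] * zi1^2)
  }
  h
}
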