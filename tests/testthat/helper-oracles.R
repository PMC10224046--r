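# Independent oracles and small fixture builders used across the suite.

# Literal NCC definition: loop over lags, zero-mean dot product over the
# product of zero-mean norms. Deliberately naive; the reference against
# which the vectorized implementation is checked.
ncc_oracle <- function(s, t) {
  L <- length(t)
  mu_t <- mean(t)
  vapply(0:(length(s) - L), function(k) {
    w <- s[(k + 1):(k + L)]
    mu_s <- mean(w)
    num <- sum((w - mu_s) * (t - mu_t))
    den <- sqrt(sum((w - mu_s)^2) * sum((t - mu_t)^2))
    if (den > 0) num / den else 0
  }, numeric(1))
}

# Brute-force topographic prominence of every strict local maximum.
prominence_oracle <- function(x) {
  n <- length(x)
  peaks <- which(vapply(2:(n - 1), function(i)
    x[i] > x[i - 1] && x[i] > x[i + 1], logical(1))) + 1L
  prom <- vapply(peaks, function(p) {
    higher_l <- which(x[seq_len(p - 1)] > x[p])
    lo_l <- if (length(higher_l)) max(higher_l) + 1L else 1L
    higher_r <- which(x[(p + 1):n] > x[p]) + p
    hi_r <- if (length(higher_r)) min(higher_r) - 1L else n
    x[p] - max(min(x[lo_l:p]), min(x[p:hi_r]))
  }, numeric(1))
  list(peaks = peaks, prominence = prom)
}

# Analytic squared-magnitude of the bilinear-transformed Butterworth
# bandpass at frequency f (single pass). Warping maps the digital
# frequency back onto the analog prototype axis.
butter_bp_mag <- function(f, fs, low, high, order) {
  wf <- function(g) 4 * tan(pi * g / fs)   # matches the fs = 2 design grid
  w <- wf(f); w1 <- wf(low); w2 <- wf(high)
  wo2 <- w1 * w2; bw <- w2 - w1
  1 / sqrt(1 + ((w^2 - wo2) / (bw * w))^(2 * order))
}

# Default quick synthetic record shared by several tests.
quick_synth <- function(duration_s = 40, snr_db = 40, seed = 101, ...) {
  generate_record(synth_config(duration_s = duration_s, snr_db = snr_db,
                               seed = seed, ...))
}
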