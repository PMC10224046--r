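# Local-maximum detection with topographic prominence.
#
# Semantics follow the usual peak-finding convention: a peak is a sample
# strictly higher than its neighbours (plateaus collapse to their middle
# sample); its prominence is its height above the higher of the two minima
# separating it from the nearest higher ground (or the series edge).

# Indices (1-based) of local maxima of x; plateau -> floor of the middle.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2) return(integer(0))
  s <- sign(d[nz])
  j <- which(s[-length(s)] == 1 & s[-1] == -1)
  if (!length(j)) return(integer(0))
  left <- nz[j] + 1L          # first sample of the (possible) plateau
  right <- nz[j + 1L]         # last sample of the plateau
  as.integer(floor((left + right) / 2))
}

# Topographic prominence of each peak index.
peak_prominences <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(p) {
    h <- x[p]
    lmin <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) {
      if (x[i] < lmin) lmin <- x[i]
      i <- i - 1L
    }
    rmin <- h
    i <- p + 1L
    while (i <= n && x[i] <= h) {
      if (x[i] < rmin) rmin <- x[i]
      i <- i + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

# Peaks with prominence >= min_prominence, then greedy minimum-distance
# selection: candidates sorted by height descending (ties: earlier index),
# accepted unless within min_distance samples of an accepted peak.
# Returns sorted (increasing) 1-based indices.
select_peaks <- function(x, min_prominence = 0, min_distance = 1) {
  pk <- local_maxima(x)
  if (!length(pk)) return(integer(0))
  if (min_prominence > 0) {
    pk <- pk[peak_prominences(x, pk) >= min_prominence]
    if (!length(pk)) return(integer(0))
  }
  if (min_distance > 1) {
    ord <- pk[order(-x[pk], pk)]
    acc <- integer(0)
    for (p in ord) {
      if (!length(acc) || all(abs(acc - p) >= min_distance)) acc <- c(acc, p)
    }
    pk <- sort(acc)
  }
  pk
}
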