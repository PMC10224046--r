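# Reference R-peak detection with the Pan-Tompkins algorithm.
#
# Classic stage sequence: band-pass (about 5-15 Hz) to isolate QRS energy,
# five-point derivative, squaring, 150 ms moving-window integration, then
# dual adaptive thresholds with search-back, a 200 ms refractory period and
# T-wave rejection for candidates closer than 360 ms. Because the whole
# pipeline here is offline and zero-phase, the derivative and the
# integration window are centered, so the integrator fiducial falls on the
# QRS itself and the final refinement to the local ECG maximum only needs a
# +/- 40 ms window. Published constants are adopted wholesale; the first
# 2 s serve as the learning phase for the signal/noise levels.

#' Detect R-peaks in an ECG with the Pan-Tompkins algorithm
#'
#' @param ecg numeric ECG samples (pre-processed: band-passed, notch
#'   filtered), R-wave positive.
#' @param fs sampling frequency in Hz (>= 100).
#' @param refine_s half-width of the final refinement window around the
#'   integrator fiducial, seconds (default 0.040).
#' @return object of class `scg_rpeaks`: `peaks` ([beat_annotations()]
#'   labelled `"R"`), `thresholds_trace` (adaptive threshold at each
#'   accepted peak, diagnostic).
#' @export
detect_r_peaks <- function(ecg, fs, refine_s = 0.040) {
  if (fs < 100)
    scg_stop("detect_r_peaks requires fs >= 100 Hz", "scg_config_error")
  n <- length(ecg)
  if (n < 2 * fs)
    scg_stop("ECG shorter than the 2 s learning phase", "scg_length_error")

  bp <- sosfiltfilt(ecg, butter_sos(3, c(5, 15) / (fs / 2), "pass"))
  # centered five-point derivative (zero phase)
  der <- stats::filter(bp, c(2, 1, 0, -1, -2) / 8, sides = 2)
  der[is.na(der)] <- 0
  der <- as.numeric(der)
  sq <- der^2
  w <- max(3L, as.integer(round(0.150 * fs)))
  mwi <- stats::filter(sq, rep(1 / w, w), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  cand <- local_maxima(mwi)
  if (!length(cand))
    return(structure(list(peaks = beat_annotations(numeric(0), "R"),
                          thresholds_trace = numeric(0)),
                     class = "scg_rpeaks"))

  # learning phase: first 2 s
  learn <- mwi[seq_len(min(n, as.integer(2 * fs)))]
  spki <- max(learn) / 3
  npki <- mean(learn) / 2
  refr <- 0.200 * fs
  twin <- 0.360 * fs

  acc <- integer(0)
  thr_trace <- numeric(0)
  slope_at <- function(i) {
    lo <- max(1L, i - as.integer(round(0.075 * fs)))
    hi <- min(n, i + as.integer(round(0.075 * fs)))
    max(abs(der[lo:hi]))
  }
  rr_avg <- function() {
    if (length(acc) < 2) return(NA_real_)
    mean(diff(tail(acc, 9)))
  }

  i <- 1L
  while (i <= length(cand)) {
    p <- cand[i]
    v <- mwi[p]
    thr1 <- npki + 0.25 * (spki - npki)
    accept <- FALSE
    if (v >= thr1) {
      if (length(acc)) {
        gap <- p - acc[length(acc)]
        if (gap < refr) {
          # refractory: keep the taller of the two
          if (v > mwi[acc[length(acc)]]) {
            acc[length(acc)] <- p
            thr_trace[length(thr_trace)] <- thr1
            spki <- 0.125 * v + 0.875 * spki
          }
          i <- i + 1L
          next
        }
        if (gap < twin && slope_at(p) < 0.5 * slope_at(acc[length(acc)])) {
          # T wave: slope markedly smaller than the previous QRS
          npki <- 0.125 * v + 0.875 * npki
          i <- i + 1L
          next
        }
      }
      accept <- TRUE
    } else {
      npki <- 0.125 * v + 0.875 * npki
      # search-back: no beat for 166% of the running RR average
      ra <- rr_avg()
      if (!is.na(ra) && length(acc) &&
          (p - acc[length(acc)]) > 1.66 * ra) {
        seg <- cand[cand > acc[length(acc)] + refr & cand <= p]
        if (length(seg)) {
          vb <- mwi[seg]
          j <- which(vb >= 0.5 * thr1)
          if (length(j)) {
            pb <- seg[j[which.max(vb[j])]]
            acc <- c(acc, pb)
            thr_trace <- c(thr_trace, 0.5 * thr1)
            spki <- 0.25 * mwi[pb] + 0.75 * spki
          }
        }
      }
    }
    if (accept) {
      acc <- c(acc, p)
      thr_trace <- c(thr_trace, thr1)
      spki <- 0.125 * v + 0.875 * spki
    }
    i <- i + 1L
  }
  ord <- order(acc)
  acc <- acc[ord]
  thr_trace <- thr_trace[ord]
  dup <- duplicated(acc)
  acc <- acc[!dup]
  thr_trace <- thr_trace[!dup]

  # refine to the local ECG maximum around the integrator fiducial
  rw <- as.integer(round(refine_s * fs))
  ref <- vapply(acc, function(p) {
    lo <- max(1L, p - rw); hi <- min(n, p + rw)
    lo + which.max(ecg[lo:hi]) - 1L
  }, integer(1))
  keep <- rep(TRUE, length(ref))
  if (length(ref) > 1) {
    last <- ref[1]
    for (k in 2:length(ref)) {
      if (ref[k] - last < refr || ref[k] <= last) keep[k] <- FALSE
      else last <- ref[k]
    }
  }
  ref <- ref[keep]
  structure(
    list(peaks = beat_annotations((ref - 1) / fs, "R"),
         thresholds_trace = thr_trace[keep]),
    class = "scg_rpeaks"
  )
}

#' @export
print.scg_rpeaks <- function(x, ...) {
  nb <- length(x$peaks$times_s)
  cat(sprintf("<scg_rpeaks: %d R-peaks%s>\n", nb,
              if (nb > 1) sprintf(", mean RR %.0f ms",
                                  1000 * mean(diff(x$peaks$times_s))) else ""))
  invisible(x)
}
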