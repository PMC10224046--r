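# Scoring SCG detections against reference R-peaks.
#
# Each cardiac cycle is the half-open interval [R_i, R_{i+1}); detections
# before the first or after the last R-peak belong to no cycle and are
# ignored. Cycles overlapping a motion-artifact interval are EXCLUDED and
# their peaks discarded before any counting. In every remaining cycle the
# detection nearest to R_i + expected_offset (the median systolic latency
# across peak-bearing cycles) is the candidate heartbeat: within the
# tolerance it is a true positive (TP), outside it a detection error (DE);
# any other peaks in the cycle are false positives (FP); a cycle without
# peaks is a false negative (FN). A DE counts against both sensitivity and
# PPV because it simultaneously marks a false beat and misses the real one.

#' Construct a detection report from counts
#'
#' Mostly used internally by [classify_detections()]; exposed so that
#' published count tables can be fed straight into [sensitivity()] and
#' [ppv()].
#'
#' @param tp,fp,fn,de non-negative counts.
#' @param n_reference number of scored (non-excluded) reference cycles;
#'   must equal `tp + fn + de`.
#' @param cycle_labels,matched_pairs,expected_offset_s,tolerance_s optional
#'   per-cycle detail as produced by [classify_detections()].
#' @return object of class `scg_report`.
#' @export
detection_report <- function(tp, fp, fn, de, n_reference = tp + fn + de,
                             cycle_labels = NULL, matched_pairs = NULL,
                             expected_offset_s = NA_real_,
                             tolerance_s = NA_real_) {
  counts <- c(tp, fp, fn, de, n_reference)
  if (any(counts < 0) || any(counts != round(counts)))
    scg_stop("counts must be non-negative integers", "scg_config_error")
  if (tp + fn + de != n_reference)
    scg_stop("invariant violated: tp + fn + de must equal n_reference",
             "scg_config_error")
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         de = as.integer(de), n_reference = as.integer(n_reference),
         cycle_labels = cycle_labels, matched_pairs = matched_pairs,
         expected_offset_s = expected_offset_s, tolerance_s = tolerance_s),
    class = "scg_report"
  )
}

#' @export
print.scg_report <- function(x, ...) {
  cat(sprintf("<scg_report: %d cycles | TP %d  FP %d  FN %d  DE %d | Se %.1f%%  PPV %.1f%%>\n",
              x$n_reference, x$tp, x$fp, x$fn, x$de,
              tryCatch(sensitivity(x), error = function(e) NA),
              tryCatch(ppv(x), error = function(e) NA)))
  invisible(x)
}

#' Classify SCG detections against reference R-peaks
#'
#' @param r_peaks [beat_annotations()] of reference R-peaks (>= 2), or a
#'   numeric vector of times in seconds.
#' @param ncc_beats [beat_annotations()] of detected beats, or numeric
#'   times in seconds.
#' @param artifact_intervals optional data.frame with `start_s`, `end_s`
#'   columns; cycles overlapping any interval are excluded.
#' @param tolerance_s half-width of the acceptance window around the
#'   expected systolic latency (default 0.150 s, half the 500 ms minimum
#'   peak distance floor). This is the main reproducibility knob of the
#'   scoring scheme.
#' @return [detection_report()] with per-cycle labels (`TP`, `FN`, `DE`,
#'   `EXCLUDED`), per-cycle extra-peak (FP) counts, matched `(r_time_s,
#'   ncc_time_s)` pairs and the estimated `expected_offset_s`.
#' @export
classify_detections <- function(r_peaks, ncc_beats, artifact_intervals = NULL,
                                tolerance_s = 0.150) {
  rt <- if (inherits(r_peaks, "scg_annotations")) r_peaks$times_s
        else as.numeric(r_peaks)
  nt <- if (inherits(ncc_beats, "scg_annotations")) ncc_beats$times_s
        else as.numeric(ncc_beats)
  if (length(rt) < 2)
    scg_stop("classification needs at least 2 reference beats",
             "scg_insufficient_data_error")
  m <- length(rt) - 1L  # number of cycles

  excluded <- rep(FALSE, m)
  if (!is.null(artifact_intervals) && nrow(artifact_intervals) > 0) {
    for (i in seq_len(nrow(artifact_intervals))) {
      excluded <- excluded |
        (rt[seq_len(m)] < artifact_intervals$end_s[i] &
           rt[seq_len(m) + 1L] > artifact_intervals$start_s[i])
    }
  }

  # assign each detection to its cycle [R_i, R_{i+1})
  cyc <- findInterval(nt, rt)
  in_cyc <- cyc >= 1 & cyc <= m & nt < rt[length(rt)]
  peaks_by_cycle <- split(nt[in_cyc], factor(cyc[in_cyc], levels = seq_len(m)))

  # expected systolic latency: median first-peak offset over non-excluded,
  # peak-bearing cycles
  offs <- vapply(seq_len(m), function(i) {
    if (excluded[i]) return(NA_real_)
    p <- peaks_by_cycle[[i]]
    if (!length(p)) return(NA_real_)
    min(p) - rt[i]
  }, numeric(1))
  if (all(is.na(offs)))
    scg_stop("no non-excluded cycle contains a detection; cannot estimate the systolic latency",
             "scg_insufficient_data_error")
  expected_offset <- stats::median(offs, na.rm = TRUE)

  labels <- character(m)
  fp_per_cycle <- integer(m)
  matched <- list()
  tp <- fp <- fn <- de <- 0L
  for (i in seq_len(m)) {
    if (excluded[i]) {
      labels[i] <- "EXCLUDED"
      next
    }
    p <- peaks_by_cycle[[i]]
    if (!length(p)) {
      labels[i] <- "FN"
      fn <- fn + 1L
      next
    }
    target <- rt[i] + expected_offset
    j <- which.min(abs(p - target))
    extra <- length(p) - 1L
    fp <- fp + extra
    fp_per_cycle[i] <- extra
    if (abs(p[j] - target) <= tolerance_s) {
      labels[i] <- "TP"
      tp <- tp + 1L
      matched[[length(matched) + 1L]] <- c(rt[i], p[j])
    } else {
      labels[i] <- "DE"
      de <- de + 1L
    }
  }
  mp <- if (length(matched)) do.call(rbind, matched) else
    matrix(numeric(0), 0, 2)
  colnames(mp) <- c("r_time_s", "ncc_time_s")
  detection_report(
    tp = tp, fp = fp, fn = fn, de = de,
    n_reference = sum(!excluded),
    cycle_labels = data.frame(cycle = seq_len(m), r_time_s = rt[seq_len(m)],
                              label = labels, fp_count = fp_per_cycle),
    matched_pairs = mp,
    expected_offset_s = expected_offset,
    tolerance_s = tolerance_s
  )
}

#' Heartbeat-detection sensitivity
#'
#' `100 * TP / (TP + FN + DE)`: the percentage of reference heartbeats
#' correctly recovered, with detection errors counting as misses.
#'
#' @param report [detection_report()].
#' @return sensitivity in percent, in `[0, 100]`.
#' @export
sensitivity <- function(report) {
  den <- report$tp + report$fn + report$de
  if (den <= 0)
    scg_stop("sensitivity undefined: tp + fn + de = 0", "scg_metric_error")
  100 * report$tp / den
}

#' Positive predictive value of the detection
#'
#' `100 * TP / (TP + FP + DE)`: the percentage of detected peaks that are
#' true heartbeats, with detection errors counting as false detections.
#'
#' @param report [detection_report()].
#' @return PPV in percent, in `[0, 100]`.
#' @export
ppv <- function(report) {
  den <- report$tp + report$fp + report$de
  if (den <= 0)
    scg_stop("PPV undefined: tp + fp + de = 0", "scg_metric_error")
  100 * report$tp / den
}

#' Matched inter-beat-interval pairs
#'
#' One (ECG, SCG) interval pair per pair of adjacent TP cycles; intervals
#' touching an FN, DE or excluded cycle are dropped, as are intervals
#' outside the (0.25, 3.0) s sanity range.
#'
#' @param report [detection_report()] from [classify_detections()].
#' @param r_peaks,ncc_beats the annotations that produced `report`
#'   (unused directly -- the matched pairs in the report carry the times --
#'   but accepted for interface symmetry).
#' @return object of class `scg_ibi_pairs`: `ecg_ibi_ms`, `scg_ibi_ms`
#'   (equal-length vectors, milliseconds) and `n`.
#' @export
extract_ibi_pairs <- function(report, r_peaks = NULL, ncc_beats = NULL) {
  if (is.null(report$cycle_labels))
    scg_stop("report lacks per-cycle labels; run classify_detections()",
             "scg_insufficient_data_error")
  lab <- report$cycle_labels$label
  mp <- report$matched_pairs
  # map TP cycles to their matched detection times, in cycle order
  tp_cycles <- which(lab == "TP")
  ecg_ms <- numeric(0)
  scg_ms <- numeric(0)
  if (length(tp_cycles) >= 2) {
    r_by_cycle <- stats::setNames(mp[, "r_time_s"], tp_cycles)
    n_by_cycle <- stats::setNames(mp[, "ncc_time_s"], tp_cycles)
    adj <- tp_cycles[which(diff(tp_cycles) == 1)]
    for (c0 in adj) {
      e <- 1000 * (r_by_cycle[[as.character(c0 + 1)]] -
                     r_by_cycle[[as.character(c0)]])
      s <- 1000 * (n_by_cycle[[as.character(c0 + 1)]] -
                     n_by_cycle[[as.character(c0)]])
      ecg_ms <- c(ecg_ms, e)
      scg_ms <- c(scg_ms, s)
    }
  }
  ok <- ecg_ms > 250 & ecg_ms < 3000 & scg_ms > 250 & scg_ms < 3000
  if (any(!ok))
    message(sprintf("extract_ibi_pairs: dropped %d interval pair(s) outside the 0.25-3.0 s sanity range",
                    sum(!ok)))
  ibi_pairs(ecg_ms[ok], scg_ms[ok])
}

#' Construct an inter-beat-interval pair set
#'
#' @param ecg_ibi_ms,scg_ibi_ms paired intervals in milliseconds, equal
#'   length, all positive.
#' @return object of class `scg_ibi_pairs`.
#' @export
ibi_pairs <- function(ecg_ibi_ms, scg_ibi_ms) {
  ecg_ibi_ms <- as.numeric(ecg_ibi_ms)
  scg_ibi_ms <- as.numeric(scg_ibi_ms)
  if (length(ecg_ibi_ms) != length(scg_ibi_ms))
    scg_stop("paired interval lists must have equal length",
             "scg_format_error")
  if (length(ecg_ibi_ms) && (any(ecg_ibi_ms <= 0) || any(scg_ibi_ms <= 0)))
    scg_stop("inter-beat intervals must be positive", "scg_format_error")
  structure(list(ecg_ibi_ms = ecg_ibi_ms, scg_ibi_ms = scg_ibi_ms,
                 n = length(ecg_ibi_ms)),
            class = "scg_ibi_pairs")
}

#' @export
print.scg_ibi_pairs <- function(x, ...) {
  cat(sprintf("<scg_ibi_pairs: %d pairs%s>\n", x$n,
              if (x$n) sprintf(", ECG IBI %.0f-%.0f ms",
                               min(x$ecg_ibi_ms), max(x$ecg_ibi_ms)) else ""))
  invisible(x)
}
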