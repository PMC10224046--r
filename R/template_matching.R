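# Template matching: heartbeat template selection, normalized
# cross-correlation (NCC) over all lags, and NCC-peak localization.
#
# The NCC at lag k is the zero-mean cosine similarity between the template
# and the signal window starting at sample k:
#
#   NCC(k) = sum_n (s[n] - mu_s(k)) (t[n-k] - mu_t)
#            / sqrt( sum_n (s[n] - mu_s(k))^2 * sum_n (t[n] - mu_t)^2 )
#
# with sums over the full template support (valid lags only), mu_t the
# template mean and mu_s(k) the signal mean over the shifted window.
# Windows of zero variance get NCC = 0 (no similarity evidence).

#' Select a heartbeat template from a record
#'
#' Cuts a single-heartbeat snippet out of the (band-passed) SCG channel.
#' Case 1 templates span both the systolic and the diastolic complex
#' (recommended: start 2-3 oscillations before the systolic peak, end just
#' after the last diastolic oscillation); case 2 templates cover only the
#' systolic complex (about 1-2 oscillations either side of the systolic
#' peak), for records without a clear diastolic complex.
#'
#' @param record [signal_record()] whose `scg` channel is already
#'   band-passed.
#' @param bounds numeric `c(start_s, end_s)` in seconds from record start.
#' @param case_label 1 (systolic + diastolic) or 2 (systolic only).
#' @return object of class `scg_template` with fields `samples`,
#'   `case_label`, `start_index` (0-based), `systolic_peak_offset`
#'   (0-based samples from template start to its highest sample),
#'   `fs`, `source_record_id`.
#' @export
select_template <- function(record, bounds, case_label = 1) {
  if (!case_label %in% c(1, 2))
    scg_stop("case_label must be 1 or 2", "scg_config_error")
  n <- length(record$scg)
  fs <- record$fs
  if (length(bounds) != 2 || bounds[1] < 0 || bounds[2] > (n - 1) / fs ||
      bounds[1] >= bounds[2])
    scg_stop("template bounds outside record", "scg_range_error")
  i0 <- as.integer(round(bounds[1] * fs))        # 0-based
  i1 <- as.integer(round(bounds[2] * fs))
  snip <- record$scg[(i0 + 1):(i1 + 1)]
  if (length(snip) < 2 || stats::sd(snip) == 0 || !all(is.finite(snip)))
    scg_stop("degenerate template: constant or invalid snippet",
             "scg_degenerate_error")
  structure(
    list(samples = snip, case_label = as.integer(case_label),
         start_index = i0,
         systolic_peak_offset = which.max(snip) - 1L,
         fs = fs, source_record_id = record$record_id),
    class = "scg_template"
  )
}

#' @export
print.scg_template <- function(x, ...) {
  cat(sprintf("<scg_template case %d: %d samples (%.0f ms) @ %g Hz, systolic peak at +%.0f ms>\n",
              x$case_label, length(x$samples),
              1000 * length(x$samples) / x$fs, x$fs,
              1000 * x$systolic_peak_offset / x$fs))
  invisible(x)
}

#' Suggest a heartbeat template automatically
#'
#' Automates the otherwise manual template choice: candidate single-beat
#' snippets are cut around reference beats, each is matched against the
#' whole record, and the candidate whose detected NCC peaks have the
#' highest median height wins (ties: earliest candidate). Deterministic
#' given identical input.
#'
#' @param record [signal_record()] with band-passed `scg`.
#' @param r_peaks [beat_annotations()] of reference beats (>= 10 required).
#' @param case_label 1 or 2; a case 1 candidate spans most of the cardiac
#'   cycle (systolic + diastolic complexes), a case 2 candidate only the
#'   systolic complex.
#' @param max_candidates cap on the number of candidate beats tried
#'   (evenly spaced across the record).
#' @param min_prominence prominence used when scoring candidates.
#' @return `scg_template` with an extra logical field `low_confidence`
#'   (`TRUE` when the best median NCC peak height is below 0.5).
#' @export
suggest_template <- function(record, r_peaks, case_label = 1,
                             max_candidates = 12, min_prominence = 0.5) {
  rt <- r_peaks$times_s
  if (length(rt) < 10)
    scg_stop("suggest_template needs at least 10 reference beats",
             "scg_insufficient_data_error")
  fs <- record$fs
  dur <- (length(record$scg) - 1) / fs
  rr <- stats::median(diff(rt))
  span <- if (case_label == 1) 0.85 * rr else min(0.30, 0.45 * rr)
  # interior beats only, evenly spaced
  usable <- which(rt + span < dur & rt > 0.05)
  usable <- usable[rt[usable] + span <= dur]
  if (!length(usable))
    scg_stop("no usable candidate beats inside the record",
             "scg_insufficient_data_error")
  cand_idx <- usable[unique(as.integer(round(
    seq(1, length(usable), length.out = min(max_candidates, length(usable)))
  )))]
  best <- NULL
  best_score <- -Inf
  for (ci in cand_idx) {
    tpl <- tryCatch(
      select_template(record, c(rt[ci], rt[ci] + span), case_label),
      scg_error = function(e) NULL
    )
    if (is.null(tpl)) next
    ncc <- compute_ncc(record$scg, tpl, fs = fs)
    ncc <- find_ncc_peaks(ncc, min_prominence = min_prominence,
                          min_distance_s = 0.5)
    # drop the candidate's self-match (NCC = 1 at its own source lag),
    # which would otherwise mask a record with no repeating morphology
    lags <- ncc$peak_lags[abs(ncc$peak_lags - tpl$start_index) >=
                            length(tpl$samples)]
    score <- if (length(lags)) stats::median(ncc$values[lags + 1]) else 0
    if (score > best_score + 1e-12) {
      best_score <- score
      best <- tpl
    }
  }
  if (is.null(best))
    scg_stop("no usable candidate template could be cut from the record",
             "scg_insufficient_data_error")
  best$low_confidence <- best_score < 0.5
  if (best$low_confidence)
    warning("suggest_template: best median NCC peak height ",
            sprintf("%.3f", best_score),
            " is below 0.5; template confidence is low")
  best$median_peak_ncc <- best_score
  best
}

#' Normalized cross-correlation of a template against a signal
#'
#' One NCC value per valid lag `k = 0 ... N - L` (template fully inside the
#' signal). Values lie in `[-1, 1]`; windows with zero variance yield 0.
#'
#' @param scg numeric signal samples (band-passed SCG), or a
#'   [signal_record()] whose `scg` channel is used.
#' @param template `scg_template` (or bare numeric template vector).
#' @param fs sampling frequency of `scg`; defaults to the template's.
#' @return object of class `scg_ncc` with fields `values`,
#'   `lag_zero_time_s`, `fs`, `peak_lags` (`NULL` until
#'   [find_ncc_peaks()]), `min_prominence`, `min_distance_s`.
#' @export
compute_ncc <- function(scg, template, fs = NULL) {
  if (inherits(scg, "scg_record")) {
    fs <- fs %||% scg$fs
    scg <- scg$scg
  }
  tpl <- if (inherits(template, "scg_template")) template$samples
         else as.numeric(template)
  if (is.null(fs))
    fs <- if (inherits(template, "scg_template")) template$fs else
      scg_stop("fs required when scg is a bare vector", "scg_config_error")
  if (length(tpl) > length(scg))
    scg_stop("template longer than signal", "scg_length_error")
  if (length(tpl) < 2)
    scg_stop("template must have length >= 2", "scg_length_error")
  structure(
    list(values = ncc_cpp(as.numeric(scg), tpl),
         lag_zero_time_s = 0, fs = fs, peak_lags = NULL,
         min_prominence = NA_real_, min_distance_s = NA_real_),
    class = "scg_ncc"
  )
}

#' @export
print.scg_ncc <- function(x, ...) {
  cat(sprintf("<scg_ncc: %d lags @ %g Hz, range [%.3f, %.3f]%s>\n",
              length(x$values), x$fs, min(x$values), max(x$values),
              if (!is.null(x$peak_lags)) sprintf(", %d peaks",
                                                 length(x$peak_lags)) else ""))
  invisible(x)
}

#' Localize NCC peaks
#'
#' Retains local maxima of the NCC series with topographic prominence of at
#' least `min_prominence`, then enforces the minimum peak distance greedily:
#' candidates are taken by decreasing NCC value (ties: earlier lag) and
#' rejected when within `min_distance_s` of an already accepted peak.
#'
#' The defaults mirror the published operating point: prominence 0.5
#' (a 0.3-0.7 range is legitimate for systolic-only, case 2 templates) and
#' a 500 ms minimum peak distance for all signals.
#'
#' @param ncc `scg_ncc` object from [compute_ncc()].
#' @param min_prominence minimum topographic prominence (NCC units).
#' @param min_distance_s minimum distance between accepted peaks, seconds.
#' @return the `scg_ncc` object with `peak_lags` (0-based lags, strictly
#'   increasing) and the thresholds filled in.
#' @export
find_ncc_peaks <- function(ncc, min_prominence = 0.5, min_distance_s = 0.5) {
  if (!inherits(ncc, "scg_ncc"))
    scg_stop("ncc must come from compute_ncc()", "scg_config_error")
  idx <- select_peaks(ncc$values, min_prominence = min_prominence,
                      min_distance = min_distance_s * ncc$fs)
  ncc$peak_lags <- as.integer(idx - 1L)
  ncc$min_prominence <- min_prominence
  ncc$min_distance_s <- min_distance_s
  ncc
}

#' Beat annotations from NCC peaks
#'
#' Each NCC peak lag marks where the template start aligns with the signal;
#' the beat timestamp adds the template's systolic-peak offset so that
#' annotations fall on the systolic peak itself. Inter-beat intervals are
#' unaffected by this constant shift.
#'
#' @param ncc `scg_ncc` with `peak_lags` filled by [find_ncc_peaks()].
#' @param template the `scg_template` used for [compute_ncc()].
#' @return [beat_annotations()] labelled `"NCC"`.
#' @export
beats_from_peaks <- function(ncc, template) {
  if (is.null(ncc$peak_lags))
    scg_stop("run find_ncc_peaks() before beats_from_peaks()",
             "scg_config_error")
  off <- if (inherits(template, "scg_template"))
    template$systolic_peak_offset else as.numeric(template)
  beat_annotations(
    (ncc$peak_lags + off) / ncc$fs + ncc$lag_zero_time_s,
    label = "NCC"
  )
}
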