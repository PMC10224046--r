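# Pre-processing: oversampling to a common 1 kHz grid by linear
# interpolation, then zero-phase band-pass filtering per channel
# (SCG: 7-30 Hz high-frequency component; ECG: 0.5-40 Hz) and powerline
# notch removal on the ECG.

#' Filter specification
#'
#' @param kind `"bandpass"` or `"notch"`.
#' @param order design order (bandpass; the zero-phase application squares
#'   the magnitude response of this design).
#' @param low_hz,high_hz band edges in Hz (bandpass).
#' @param center_hz notch center in Hz.
#' @param q notch quality factor.
#' @param zero_phase apply forward-backward (default `TRUE`).
#' @return object of class `scg_filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "notch"), order = 4,
                        low_hz = NULL, high_hz = NULL,
                        center_hz = NULL, q = 30, zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (kind == "bandpass") {
    if (is.null(low_hz) || is.null(high_hz) || low_hz <= 0 ||
        high_hz <= low_hz)
      scg_stop("bandpass needs 0 < low_hz < high_hz", "scg_config_error")
  } else {
    if (is.null(center_hz) || center_hz <= 0)
      scg_stop("notch needs center_hz > 0", "scg_config_error")
  }
  structure(list(kind = kind, order = order, low_hz = low_hz,
                 high_hz = high_hz, center_hz = center_hz, q = q,
                 zero_phase = isTRUE(zero_phase)),
            class = "scg_filter_spec")
}

#' Oversample a record by linear interpolation
#'
#' Resamples both channels onto the grid `k / fs_out` by linear
#' interpolation of the input samples at times `i / fs`. The artifact mask
#' is resampled by nearest neighbor. Downsampling is out of scope.
#'
#' @param record [signal_record()] object.
#' @param fs_out target sampling frequency in Hz (>= `record$fs`).
#' @return resampled [signal_record()].
#' @export
resample_linear <- function(record, fs_out) {
  fs_in <- record$fs
  if (fs_out < fs_in)
    scg_stop("downsampling is not supported (fs_out < fs)",
             "scg_config_error")
  n <- length(record$scg)
  if (fs_out == fs_in) return(record)
  t_in <- (seq_len(n) - 1) / fs_in
  # duration preserved within one input sample period
  m <- floor(t_in[n] * fs_out) + 1
  t_out <- (seq_len(m) - 1) / fs_out
  scg <- stats::approx(t_in, record$scg, xout = t_out, rule = 2)$y
  ecg <- stats::approx(t_in, record$ecg, xout = t_out, rule = 2)$y
  idx <- pmin(pmax(round(t_out * fs_in) + 1, 1), n)
  signal_record(scg, ecg, fs_out, record_id = record$record_id,
                artifact_mask = record$artifact_mask[idx])
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs an `order`-th order Butterworth band-pass and applies it
#' forward-backward (zero net phase shift; effective magnitude response is
#' the squared design response). DC is fully outside the passband.
#'
#' @param x numeric samples.
#' @param fs sampling frequency in Hz.
#' @param spec [filter_spec()] of kind `"bandpass"`; alternatively pass
#'   `low_hz`/`high_hz`/`order` directly.
#' @param low_hz,high_hz,order shortcut parameters used when `spec` is
#'   missing.
#' @return filtered samples, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, fs, spec = NULL, low_hz = 7, high_hz = 30,
                                order = 4) {
  if (!is.null(spec)) {
    if (!inherits(spec, "scg_filter_spec") || spec$kind != "bandpass")
      scg_stop("spec must be a bandpass filter_spec", "scg_config_error")
    low_hz <- spec$low_hz; high_hz <- spec$high_hz; order <- spec$order
  }
  if (high_hz >= fs / 2)
    scg_stop("band edge at or above Nyquist", "scg_config_error")
  if (length(x) <= 3 * (2 * order + 1))
    scg_stop("signal too short for edge padding", "scg_length_error")
  sos <- butter_sos(order, c(low_hz, high_hz) / (fs / 2), "pass")
  sosfiltfilt(x, sos)
}

#' Powerline notch filter (fundamental plus harmonics)
#'
#' Applies a zero-phase second-order IIR notch at `base_hz` and at each
#' requested harmonic strictly below Nyquist; harmonics at or above Nyquist
#' are skipped with a message.
#'
#' @param x numeric samples.
#' @param fs sampling frequency in Hz.
#' @param base_hz powerline fundamental (default 50 Hz).
#' @param harmonics number of notched lines including the fundamental
#'   (default 1).
#' @param q notch quality factor (default 30).
#' @return filtered samples, same length as `x`.
#' @export
notch_powerline <- function(x, fs, base_hz = 50, harmonics = 1, q = 30) {
  if (base_hz >= fs / 2)
    scg_stop("notch base frequency at or above Nyquist", "scg_config_error")
  y <- x
  for (h in seq_len(harmonics)) {
    f0 <- h * base_hz
    if (f0 >= fs / 2) {
      message(sprintf("notch_powerline: skipping %g Hz (at or above Nyquist %g Hz)",
                      f0, fs / 2))
      next
    }
    y <- sosfiltfilt(y, notch_sos(f0 / (fs / 2), q))
  }
  y
}

#' Standard pre-processing of a record
#'
#' Oversamples to `target_fs` (default 1 kHz) and filters each channel:
#' SCG band-pass `scg_band`, ECG band-pass `ecg_band` followed by the
#' powerline notch.
#'
#' @param record [signal_record()] object.
#' @param target_fs grid to oversample to, Hz.
#' @param scg_band,ecg_band band edges in Hz.
#' @param filter_order Butterworth design order.
#' @param powerline_hz notch fundamental, Hz.
#' @param notch_harmonics notched lines including the fundamental.
#' @return [signal_record()] with filtered channels at `target_fs`.
#' @export
preprocess_record <- function(record, target_fs = 1000,
                              scg_band = c(7, 30), ecg_band = c(0.5, 40),
                              filter_order = 4, powerline_hz = 50,
                              notch_harmonics = 1) {
  rec <- resample_linear(record, target_fs)
  rec$scg <- bandpass_zero_phase(rec$scg, rec$fs, low_hz = scg_band[1],
                                 high_hz = scg_band[2], order = filter_order)
  ecg <- bandpass_zero_phase(rec$ecg, rec$fs, low_hz = ecg_band[1],
                             high_hz = ecg_band[2], order = filter_order)
  rec$ecg <- notch_powerline(ecg, rec$fs, base_hz = powerline_hz,
                             harmonics = notch_harmonics)
  rec
}
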