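# Synthetic two-channel (SCG + ECG) record generator with ground truth.
#
# Beat times follow a quasi-periodic RR series with respiratory sinus
# arrhythmia and Gaussian jitter:
#   RR_i = 60000 / hr + rsa_depth * sin(2 pi f_resp t_i) + N(0, jitter_sd)
# The ECG is a sum of beat-locked Gaussians (small P, narrow dominant R,
# broad T); the SCG beat is a damped oscillation (the systolic complex)
# starting a fixed delay after the R wave, plus an optional weaker damped
# oscillation for the diastolic complex. Both channels are amplitude
# modulated by respiration and corrupted by additive Gaussian noise at a
# configured SNR. All randomness flows from one seeded generator and the
# global RNG state is left untouched.

#' Synthetic record configuration
#'
#' Defaults describe a resting adult measured with a chest accelerometer at
#' the paper-grade acquisition rate: 256 Hz sampling, 70 bpm with ~25 ms RR
#' jitter and 30 ms respiratory modulation at 0.25 Hz, an 18 Hz systolic
#' oscillation decaying with a 40 ms time constant 30 ms after the R wave,
#' a half-amplitude diastolic complex 380 ms after the R wave, 20%
#' respiratory amplitude modulation and 20 dB white noise.
#'
#' @param duration_s record length, seconds.
#' @param fs sampling frequency, Hz (>= 100).
#' @param mean_hr_bpm mean heart rate, beats per minute (20-240).
#' @param rr_jitter_sd_ms SD of the Gaussian RR jitter, ms.
#' @param resp_rate_hz respiration rate, Hz.
#' @param rsa_depth_ms respiratory RR modulation amplitude, ms.
#' @param sys_freq_hz systolic oscillation frequency, Hz.
#' @param sys_decay_ms systolic decay time constant, ms.
#' @param sys_delay_ms systolic-complex onset after the R wave, ms.
#' @param dia_delay_ms diastolic-complex onset after the R wave, ms.
#' @param dia_amp_ratio diastolic/systolic amplitude ratio in `[0, 1]`
#'   (0 produces systolic-only, "case 2"-like records).
#' @param resp_am_depth respiratory amplitude-modulation depth in `[0, 1)`.
#' @param snr_db clean-signal-to-noise power ratio, dB.
#' @param noise_band optional `c(low, high)` Hz: band-limit the SCG noise
#'   (stresses the matcher inside its own passband); `NULL` = white.
#' @param seed integer seed.
#' @return object of class `scg_synth_config`.
#' @export
synth_config <- function(duration_s = 60, fs = 256, mean_hr_bpm = 70,
                         rr_jitter_sd_ms = 25, resp_rate_hz = 0.25,
                         rsa_depth_ms = 30, sys_freq_hz = 18,
                         sys_decay_ms = 40, sys_delay_ms = 30,
                         dia_delay_ms = 380, dia_amp_ratio = 0.5,
                         resp_am_depth = 0.2, snr_db = 20,
                         noise_band = NULL, seed = 1L) {
  if (duration_s <= 0)
    scg_stop("duration_s must be positive", "scg_config_error")
  if (fs < 100)
    scg_stop("fs must be >= 100 Hz", "scg_config_error")
  if (mean_hr_bpm <= 20 || mean_hr_bpm >= 240)
    scg_stop("mean_hr_bpm must lie in (20, 240)", "scg_config_error")
  if (dia_amp_ratio < 0 || dia_amp_ratio > 1)
    scg_stop("dia_amp_ratio must lie in [0, 1]", "scg_config_error")
  if (resp_am_depth < 0 || resp_am_depth >= 1)
    scg_stop("resp_am_depth must lie in [0, 1)", "scg_config_error")
  structure(
    list(duration_s = duration_s, fs = fs, mean_hr_bpm = mean_hr_bpm,
         rr_jitter_sd_ms = rr_jitter_sd_ms, resp_rate_hz = resp_rate_hz,
         rsa_depth_ms = rsa_depth_ms, sys_freq_hz = sys_freq_hz,
         sys_decay_ms = sys_decay_ms, sys_delay_ms = sys_delay_ms,
         dia_delay_ms = dia_delay_ms, dia_amp_ratio = dia_amp_ratio,
         resp_am_depth = resp_am_depth, snr_db = snr_db,
         noise_band = noise_band, seed = as.integer(seed)),
    class = "scg_synth_config"
  )
}

# run fn with a private RNG stream, restoring global state afterwards
with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# add a localized waveform to sig (modified in place semantics via return)
add_local <- function(sig, tt, fs, center, half_s, shape) {
  i0 <- max(1L, as.integer(floor((center - half_s) * fs)) + 1L)
  i1 <- min(length(sig), as.integer(ceiling((center + half_s) * fs)) + 1L)
  if (i1 < i0) return(sig)
  idx <- i0:i1
  sig[idx] <- sig[idx] + shape(tt[idx])
  sig
}

#' Generate a synthetic SCG + ECG record with ground truth
#'
#' @param config [synth_config()] object (or arguments forwarded to it).
#' @param ... forwarded to [synth_config()] when `config` is missing.
#' @return object of class `scg_synth_record`: `record`
#'   ([signal_record()]), `truth_r` and `truth_sys_peak`
#'   ([beat_annotations()], equal counts).
#' @export
generate_record <- function(config = NULL, ...) {
  cfg <- config %||% synth_config(...)
  if (!inherits(cfg, "scg_synth_config"))
    scg_stop("config must come from synth_config()", "scg_config_error")
  with_seed(cfg$seed, function() {
    n <- as.integer(round(cfg$duration_s * cfg$fs))
    tt <- (seq_len(n) - 1) / cfg$fs
    rr0 <- 60000 / cfg$mean_hr_bpm

    # beat schedule; the record extends ~one cycle past the last beat so
    # that the full beat waveform (and a full-beat template aligned to it)
    # fits inside the record
    beats <- numeric(0)
    t_i <- 0.1
    margin <- 0.9 * 60 / cfg$mean_hr_bpm
    while (t_i <= cfg$duration_s - margin) {
      beats <- c(beats, t_i)
      rr_ms <- rr0 +
        cfg$rsa_depth_ms * sin(2 * pi * cfg$resp_rate_hz * t_i) +
        stats::rnorm(1, 0, cfg$rr_jitter_sd_ms)
      rr_ms <- min(max(rr_ms, 300), 2500)
      t_i <- t_i + rr_ms / 1000
    }
    if (length(beats) < 2)
      scg_stop("configuration yields fewer than 2 beats", "scg_config_error")

    # ECG: beat-locked P, Q, R, S, T waves
    gauss <- function(tc, amp, sd) function(t) amp * exp(-((t - tc)^2) / (2 * sd^2))
    ecg <- numeric(n)
    for (tb in beats) {
      ecg <- add_local(ecg, tt, cfg$fs, tb - 0.18, 0.1, gauss(tb - 0.18, 0.12, 0.025))
      ecg <- add_local(ecg, tt, cfg$fs, tb - 0.025, 0.05, gauss(tb - 0.025, -0.10, 0.008))
      ecg <- add_local(ecg, tt, cfg$fs, tb, 0.06, gauss(tb, 1.0, 0.010))
      ecg <- add_local(ecg, tt, cfg$fs, tb + 0.025, 0.05, gauss(tb + 0.025, -0.15, 0.008))
      ecg <- add_local(ecg, tt, cfg$fs, tb + 0.30, 0.2, gauss(tb + 0.30, 0.25, 0.05))
    }

    # SCG: damped oscillatory complexes
    tau <- cfg$sys_decay_ms / 1000
    f_sys <- cfg$sys_freq_hz
    burst <- function(t0, amp) function(t) {
      u <- t - t0
      ifelse(u >= 0, amp * exp(-u / tau) * sin(2 * pi * f_sys * u), 0)
    }
    span <- min(0.4, 8 * tau)
    scg <- numeric(n)
    for (tb in beats) {
      t_sys <- tb + cfg$sys_delay_ms / 1000
      scg <- add_local(scg, tt, cfg$fs, t_sys + span / 2, span / 2 + 2 / cfg$fs,
                       burst(t_sys, 1.0))
      if (cfg$dia_amp_ratio > 0) {
        t_dia <- tb + cfg$dia_delay_ms / 1000
        scg <- add_local(scg, tt, cfg$fs, t_dia + span / 2, span / 2 + 2 / cfg$fs,
                         burst(t_dia, cfg$dia_amp_ratio))
      }
    }

    am <- 1 + cfg$resp_am_depth * sin(2 * pi * cfg$resp_rate_hz * tt)
    scg <- scg * am
    ecg <- ecg * am

    add_noise <- function(x, band = NULL) {
      p_sig <- mean(x^2)
      if (!is.finite(cfg$snr_db)) return(x)
      sd_n <- sqrt(p_sig / 10^(cfg$snr_db / 10))
      e <- stats::rnorm(length(x), 0, sd_n)
      if (!is.null(band)) {
        e <- bandpass_zero_phase(e, cfg$fs, low_hz = band[1],
                                 high_hz = band[2], order = 4)
        e <- e * sd_n / stats::sd(e)  # keep the configured noise power
      }
      x + e
    }
    scg <- add_noise(scg, cfg$noise_band)
    ecg <- add_noise(ecg)

    # analytic systolic-peak instant of exp(-u/tau) sin(2 pi f u)
    u_star <- atan(2 * pi * f_sys * tau) / (2 * pi * f_sys)
    structure(
      list(record = signal_record(scg, ecg, cfg$fs, record_id = sprintf(
             "synth-hr%g-snr%g-seed%d", cfg$mean_hr_bpm, cfg$snr_db, cfg$seed)),
           truth_r = beat_annotations(beats, "R"),
           truth_sys_peak = beat_annotations(
             beats + cfg$sys_delay_ms / 1000 + u_star, "SYS"),
           config = cfg),
      class = "scg_synth_record"
    )
  })
}

#' @export
print.scg_synth_record <- function(x, ...) {
  cat(sprintf("<scg_synth_record: %d beats, %.0f s @ %g Hz, SNR %g dB, seed %d>\n",
              length(x$truth_r$times_s), x$config$duration_s, x$config$fs,
              x$config$snr_db, x$config$seed))
  invisible(x)
}

#' Ground-truth inter-beat intervals of a synthetic record
#'
#' @param synth `scg_synth_record` from [generate_record()].
#' @return consecutive differences of the true R times, in milliseconds.
#' @export
truth_ibis <- function(synth) {
  tr <- synth$truth_r$times_s
  if (length(tr) < 2)
    scg_stop("need at least 2 beats for intervals",
             "scg_insufficient_data_error")
  1000 * diff(tr)
}
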