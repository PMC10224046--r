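# Record and annotation I/O.
#
# Records are two-channel (SCG dorso-ventral acceleration + ECG lead II)
# uniformly sampled series. Readers never resample: N and fs come from the
# file alone. Sample index i (0-based) maps to time i/fs seconds.

#' Construct a two-channel signal record
#'
#' @param scg numeric SCG (acceleration) samples.
#' @param ecg numeric ECG samples, same length as `scg`.
#' @param fs sampling frequency in Hz (> 0).
#' @param record_id identifier string.
#' @param artifact_mask logical per-sample mask (`TRUE` = motion-artifact
#'   region); default all `FALSE`.
#' @return object of class `scg_record` with fields `record_id`, `fs`,
#'   `scg`, `ecg`, `artifact_mask`.
#' @export
signal_record <- function(scg, ecg, fs, record_id = "record",
                          artifact_mask = NULL) {
  scg <- as.numeric(scg); ecg <- as.numeric(ecg)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    scg_stop("fs must be a single positive number", "scg_config_error")
  n <- length(scg)
  if (n < 2 || length(ecg) != n)
    scg_stop("scg and ecg must have equal length >= 2", "scg_format_error")
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, n)
  if (length(artifact_mask) != n || !is.logical(artifact_mask))
    scg_stop("artifact_mask must be logical of signal length",
             "scg_format_error")
  structure(
    list(record_id = as.character(record_id), fs = as.numeric(fs),
         scg = scg, ecg = ecg, artifact_mask = artifact_mask),
    class = "scg_record"
  )
}

#' @export
print.scg_record <- function(x, ...) {
  cat(sprintf("<scg_record '%s': %d samples @ %g Hz (%.1f s), %d artifact samples>\n",
              x$record_id, length(x$scg), x$fs, length(x$scg) / x$fs,
              sum(x$artifact_mask)))
  invisible(x)
}

#' Construct beat annotations
#'
#' @param times_s strictly increasing beat timestamps in seconds (>= 0).
#' @param label annotation label, e.g. `"R"` (ECG R-peaks) or `"NCC"`
#'   (template-matching detections).
#' @return object of class `scg_annotations` with fields `times_s`, `label`.
#' @export
beat_annotations <- function(times_s, label = "R") {
  times_s <- as.numeric(times_s)
  if (length(times_s) > 0) {
    if (any(!is.finite(times_s)) || any(times_s < 0))
      scg_stop("annotation times must be finite and non-negative",
               "scg_format_error")
    if (length(times_s) > 1 && any(diff(times_s) <= 0))
      scg_stop("annotation times must be strictly increasing",
               "scg_format_error")
  }
  structure(list(times_s = times_s, label = as.character(label)[1]),
            class = "scg_annotations")
}

#' @export
print.scg_annotations <- function(x, ...) {
  cat(sprintf("<scg_annotations '%s': %d beats%s>\n", x$label,
              length(x$times_s),
              if (length(x$times_s)) sprintf(" spanning %.2f-%.2f s",
                                             min(x$times_s), max(x$times_s))
              else ""))
  invisible(x)
}

#' Read a two-channel record from CSV
#'
#' Expects a comma-separated file with a header; column names are matched
#' case-insensitively. Columns `scg` and `ecg` are required; an optional
#' time column (`t` or `time`, seconds) must be uniformly spaced within
#' `1e-6` relative tolerance and determines `fs` unless `fs` is given
#' explicitly.
#'
#' @param path CSV file path.
#' @param fs sampling frequency in Hz; required when the file has no time
#'   column, and takes precedence over it otherwise.
#' @param artifact_path optional sidecar CSV of artifact intervals with
#'   columns `start_s,end_s`.
#' @param record_id identifier; defaults to the file name.
#' @return [signal_record()] object.
#' @export
read_record_csv <- function(path, fs = NULL, artifact_path = NULL,
                            record_id = NULL) {
  if (!file.exists(path))
    scg_stop(sprintf("record file not found: %s", path), "scg_io_error")
  dt <- data.table::fread(path, header = TRUE, sep = ",")
  nm <- tolower(names(dt))
  i_scg <- match("scg", nm); i_ecg <- match("ecg", nm)
  if (is.na(i_scg) || is.na(i_ecg))
    scg_stop("CSV must contain 'scg' and 'ecg' columns", "scg_format_error")
  i_t <- match(c("t", "time"), nm)
  i_t <- i_t[!is.na(i_t)][1]
  if (!is.na(i_t)) {
    tt <- as.numeric(dt[[i_t]])
    d <- diff(tt)
    if (length(d) < 1 || any(d <= 0))
      scg_stop("time column must be strictly increasing", "scg_sampling_error")
    dt0 <- stats::median(d)
    if (max(abs(d - dt0)) > 1e-6 * dt0)
      scg_stop("time column is not uniformly spaced (1e-6 relative tolerance)",
               "scg_sampling_error")
    if (is.null(fs)) fs <- 1 / dt0
  }
  if (is.null(fs))
    scg_stop("sampling frequency unresolvable: no time column and no fs given",
             "scg_config_error")
  n <- nrow(dt)
  mask <- rep(FALSE, n)
  if (!is.null(artifact_path) && file.exists(artifact_path)) {
    iv <- read_artifact_intervals(artifact_path)
    mask <- artifact_mask_from_intervals(iv, n, fs)
  }
  signal_record(dt[[i_scg]], dt[[i_ecg]], fs,
                record_id = record_id %||% basename(path),
                artifact_mask = mask)
}

#' Write a record to CSV
#'
#' Columns `t,scg,ecg` with `t = i/fs` (0-based). Round-trips through
#' [read_record_csv()].
#'
#' @param record [signal_record()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  n <- length(record$scg)
  dt <- data.table::data.table(
    t = (seq_len(n) - 1) / record$fs,
    scg = record$scg, ecg = record$ecg
  )
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read artifact intervals from a sidecar CSV
#'
#' @param path CSV with columns `start_s,end_s` (seconds from record start).
#' @return data.frame with columns `start_s`, `end_s`.
#' @export
read_artifact_intervals <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = ",")
  nm <- tolower(names(dt))
  i1 <- match("start_s", nm); i2 <- match("end_s", nm)
  if (is.na(i1) || is.na(i2))
    scg_stop("artifact sidecar needs 'start_s' and 'end_s' columns",
             "scg_format_error")
  out <- data.frame(start_s = as.numeric(dt[[i1]]), end_s = as.numeric(dt[[i2]]))
  if (any(out$end_s <= out$start_s))
    scg_stop("artifact intervals must have end_s > start_s", "scg_format_error")
  out
}

#' Build a per-sample artifact mask from intervals
#'
#' @param intervals data.frame with `start_s`, `end_s` columns (may have 0
#'   rows).
#' @param n number of samples.
#' @param fs sampling frequency in Hz.
#' @return logical vector of length `n`.
#' @export
artifact_mask_from_intervals <- function(intervals, n, fs) {
  mask <- rep(FALSE, n)
  tt <- (seq_len(n) - 1) / fs
  for (i in seq_len(nrow(intervals))) {
    mask <- mask | (tt >= intervals$start_s[i] & tt < intervals$end_s[i])
  }
  mask
}

# ---- WFDB (subset: format 16, little-endian, interleaved) -----------------

#' Read a WFDB record (.hea/.dat pair)
#'
#' Supports the common single-segment layout with all signals in one
#' format-16 (16-bit little-endian integer) `.dat` file. Physical units are
#' reconstructed as `(adc - baseline) / gain` per channel.
#'
#' @param path record name, with or without the `.hea` extension.
#' @param channels optional named integer vector `c(scg = i, ecg = j)`
#'   (1-based channel indices). Without it, channels are inferred from
#'   signal descriptions (names containing "scg"/"acc"/"z" and "ecg").
#' @param record_id identifier; defaults to the record name.
#' @return [signal_record()] object with `fs` from the header.
#' @export
read_record_wfdb <- function(path, channels = NULL, record_id = NULL) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea))
    scg_stop(sprintf("header not found: %s", hea), "scg_io_error")
  lines <- readLines(hea)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(head_tok[2])
  fs <- if (length(head_tok) >= 3) as.numeric(head_tok[3]) else 250
  if (is.na(nsig) || nsig < 2)
    scg_stop("WFDB record must have at least 2 signals", "scg_format_error")
  sig_lines <- lines[2:(1 + nsig)]
  parse_sig <- function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    fmt <- sub("x.*$", "", tok[2])
    gain_tok <- if (length(tok) >= 3) tok[3] else "200"
    gain <- 200; baseline <- 0
    m <- regmatches(gain_tok, regexec("^([-0-9.eE+]+)(\\(([-0-9]+)\\))?", gain_tok))[[1]]
    if (length(m) && nzchar(m[2])) gain <- as.numeric(m[2])
    if (length(m) >= 4 && nzchar(m[4])) baseline <- as.numeric(m[4])
    if (gain == 0) gain <- 200
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ") else ""
    list(file = tok[1], fmt = fmt, gain = gain, baseline = baseline,
         desc = desc)
  }
  sigs <- lapply(sig_lines, parse_sig)
  if (any(vapply(sigs, function(s) s$fmt != "16", logical(1))))
    scg_stop("only WFDB format 16 is supported", "scg_format_error")
  datf <- file.path(dirname(hea), sigs[[1]]$file)
  if (!file.exists(datf))
    scg_stop(sprintf("signal file not found: %s", datf), "scg_io_error")
  raw <- readBin(datf, integer(), n = file.size(datf) / 2, size = 2,
                 signed = TRUE, endian = "little")
  nsamp <- length(raw) %/% nsig
  adc <- matrix(raw[seq_len(nsamp * nsig)], nrow = nsig)
  phys <- lapply(seq_len(nsig), function(i)
    (adc[i, ] - sigs[[i]]$baseline) / sigs[[i]]$gain)
  if (is.null(channels)) {
    desc <- tolower(vapply(sigs, `[[`, character(1), "desc"))
    i_scg <- which(grepl("scg|acc|z[_ -]?axis|^z$", desc))[1]
    i_ecg <- which(grepl("ecg", desc))[1]
    if (is.na(i_scg) || is.na(i_ecg))
      scg_stop("cannot infer scg/ecg channels from signal names; pass 'channels'",
               "scg_config_error")
    channels <- c(scg = i_scg, ecg = i_ecg)
  }
  if (!all(c("scg", "ecg") %in% names(channels)))
    scg_stop("'channels' must name both scg and ecg", "scg_config_error")
  signal_record(phys[[channels[["scg"]]]], phys[[channels[["ecg"]]]], fs,
                record_id = record_id %||% basename(base))
}

#' Write a WFDB record (.hea/.dat pair, format 16)
#'
#' Samples are scaled to ADC units as `round(x * gain)` with baseline 0;
#' the round trip through [read_record_wfdb()] is exact whenever
#' `x * gain` is integral (and within 1/(2 gain) otherwise).
#'
#' @param record [signal_record()] object.
#' @param path output record name (without extension).
#' @param gain ADC gain (units per physical unit) applied to both channels.
#' @return `path`, invisibly.
#' @export
write_record_wfdb <- function(record, path, gain = 1000) {
  base <- sub("\\.hea$", "", path)
  n <- length(record$scg)
  adc <- rbind(round(record$scg * gain), round(record$ecg * gain))
  if (any(abs(adc) > 32767))
    scg_stop("samples overflow 16-bit range at this gain; lower 'gain'",
             "scg_range_error")
  datname <- paste0(basename(base), ".dat")
  hea <- c(
    sprintf("%s 2 %.10g %d", basename(base), record$fs, n),
    sprintf("%s 16 %g(0)/au 16 0 0 0 0 SCG z-axis", datname, gain),
    sprintf("%s 16 %g(0)/au 16 0 0 0 0 ECG II", datname, gain)
  )
  writeLines(hea, paste0(base, ".hea"))
  con <- file(file.path(dirname(base), datname), "wb")
  on.exit(close(con))
  writeBin(as.integer(adc), con, size = 2, endian = "little")
  invisible(base)
}

# ---- annotations ----------------------------------------------------------

#' Write beat annotations to CSV or JSON
#'
#' CSV has columns `time_s,label`; JSON is a list of `{time_s, label}`
#' objects. Both round-trip exactly through [read_annotations()] (times
#' written with full double precision).
#'
#' @param ann [beat_annotations()] object.
#' @param path output file path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  df <- data.frame(time_s = ann$times_s,
                   label = rep(ann$label, length(ann$times_s)))
  ok <- tryCatch({
    if (format == "csv") {
      lines <- c("time_s,label",
                 if (nrow(df)) sprintf("%.17g,%s", df$time_s, df$label))
      writeLines(lines, path)
    } else {
      # numbers formatted with %.17g so the round trip is bit-exact
      items <- if (nrow(df))
        sprintf("  {\"time_s\": %.17g, \"label\": \"%s\"}", df$time_s, df$label)
      else character(0)
      writeLines(c("[", paste(items, collapse = ",\n"), "]"), path)
    }
    TRUE
  }, error = function(e) FALSE)
  if (!ok) scg_stop(sprintf("cannot write annotations to %s", path),
                    "scg_io_error")
  invisible(path)
}

#' Read beat annotations written by [write_annotations()]
#'
#' @param path CSV or JSON annotation file.
#' @return [beat_annotations()] object.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path))
    scg_stop(sprintf("annotation file not found: %s", path), "scg_io_error")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0 || is.null(dim(df)))
      return(beat_annotations(numeric(0)))
    return(beat_annotations(as.numeric(df$time_s), df$label[1]))
  }
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = list(numeric = "time_s"))
  if (nrow(dt) == 0) return(beat_annotations(numeric(0)))
  beat_annotations(as.numeric(dt$time_s), as.character(dt$label[1]))
}
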