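# Readers and writers: CSV records (time_s, ecg_mv), plain-text R-peak
# annotation files, a minimal read-only WFDB signal reader (formats 16 and
# 212, enough for MIT-BIH records), and single-file model checkpoints.

#' Write an ECG record to CSV
#'
#' Comma-separated, header `time_s,ecg_mv`, full double precision (17
#' significant digits), '.' decimal separator. An optional sidecar
#' annotation file holds one R-peak sample index per line.
#'
#' @param samples numeric series (mV).
#' @param fs sampling rate in Hz.
#' @param path output CSV path.
#' @param r_peaks optional integer annotation indices; written to
#'   `<path>.rpeaks` when provided.
#' @return `path`, invisibly.
#' @export
write_record <- function(samples, fs, path, r_peaks = NULL) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  samples <- as.numeric(samples)
  t <- (seq_along(samples) - 1) / fs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,ecg_mv", con)
  if (length(samples) > 0L) {
    writeLines(paste(sprintf("%.17g", t), sprintf("%.17g", samples), sep = ","),
               con)
  }
  if (!is.null(r_peaks)) {
    write_annotations(r_peaks, paste0(path, ".rpeaks"))
  }
  invisible(path)
}

#' Read an ECG record
#'
#' CSV records must have a `time_s,ecg_mv` header; the sampling rate is
#' recovered from the time column (or taken from `fs` if given). A sidecar
#' `<path>.rpeaks` annotation file is loaded when present. WFDB records
#' (`format = "wfdb"`, `path` without extension) are read with
#' [read_wfdb()].
#'
#' @param path file path.
#' @param format `"csv"` (default) or `"wfdb"`.
#' @param fs optional sampling rate override in Hz.
#' @param channel channel selector for multi-channel WFDB records.
#' @return an `ecg_record` (annotations empty if no sidecar file exists).
#' @export
read_record <- function(path, format = c("csv", "wfdb"), fs = NULL,
                        channel = 1L) {
  format <- match.arg(format)
  if (format == "wfdb") {
    w <- read_wfdb(path, channel = channel)
    return(new_ecg_record(w$samples, w$fs, integer(0)))
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L || trimws(lines[1]) != "time_s,ecg_mv") {
    stop(sprintf("%s: expected header 'time_s,ecg_mv'", path), call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  n <- length(body)
  tvals <- numeric(n); xvals <- numeric(n)
  if (n > 0L) {
    parts <- strsplit(body, ",", fixed = TRUE)
    for (i in seq_len(n)) {
      p <- parts[[i]]
      if (length(p) != 2L) {
        stop(sprintf("%s: row %d has %d fields, expected 2", path, i + 1L,
                     length(p)), call. = FALSE)
      }
      tv <- suppressWarnings(as.numeric(p[1]))
      xv <- suppressWarnings(as.numeric(p[2]))
      if (is.na(tv) || is.na(xv)) {
        stop(sprintf("%s: non-numeric value in row %d", path, i + 1L),
             call. = FALSE)
      }
      tvals[i] <- tv; xvals[i] <- xv
    }
  }
  if (is.null(fs)) {
    if (n >= 2L) {
      dt <- stats::median(diff(tvals))
      if (!is.finite(dt) || dt <= 0) {
        stop(sprintf("%s: cannot infer sampling rate from time column", path),
             call. = FALSE)
      }
      fs <- 1 / dt
      if (abs(fs - round(fs)) < 1e-6) fs <- round(fs)
    } else {
      stop(sprintf("%s: too few rows to infer fs; pass `fs` explicitly", path),
           call. = FALSE)
    }
  }
  ann_path <- paste0(path, ".rpeaks")
  ann <- if (file.exists(ann_path)) read_annotations(ann_path) else integer(0)
  new_ecg_record(xvals, fs, ann)
}

#' Write R-peak annotations (one sample index per line)
#'
#' @param r_peaks integer indices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(r_peaks, path) {
  writeLines(as.character(as.integer(r_peaks)), path)
  invisible(path)
}

#' Read R-peak annotations written by [write_annotations()]
#'
#' @param path annotation file path.
#' @return integer vector of sample indices.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(integer(0))
  v <- suppressWarnings(as.integer(lines))
  if (anyNA(v)) stop(sprintf("%s: non-integer annotation entry", path), call. = FALSE)
  v
}

#' Read a WFDB record (formats 16 and 212)
#'
#' Minimal reader for the WFDB header (`.hea`) and signal (`.dat`) pair:
#' supports single-segment records in format 16 (16-bit little-endian) and
#' format 212 (pairs of 12-bit samples in 3 bytes), the formats used by the
#' MIT-BIH arrhythmia database. Values are converted to physical units with
#' `(raw - baseline) / gain`.
#'
#' @param record path to the record without extension (e.g. `"100"` for
#'   `100.hea` + `100.dat`).
#' @param channel 1-based channel to extract.
#' @return list with `samples` (physical units), `fs` (Hz), `n_channels`,
#'   and `units`.
#' @export
read_wfdb <- function(record, channel = 1L) {
  hea <- paste0(record, ".hea")
  if (!file.exists(hea)) stop(sprintf("header not found: %s", hea), call. = FALSE)
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  head_f <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  n_sig <- as.integer(head_f[2])
  fs <- if (length(head_f) >= 3L) as.numeric(sub("/.*$", "", head_f[3])) else 250
  n_samp <- if (length(head_f) >= 4L) as.integer(head_f[4]) else NA_integer_
  if (is.na(n_sig) || n_sig < 1L) stop(sprintf("%s: bad signal count", hea), call. = FALSE)
  if (channel < 1L || channel > n_sig) {
    stop(sprintf("channel %d out of range (record has %d)", channel, n_sig),
         call. = FALSE)
  }
  sig <- vector("list", n_sig)
  for (i in seq_len(n_sig)) {
    f <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1]]
    gain_field <- if (length(f) >= 3L) f[3] else "200"
    gain <- as.numeric(sub("^([0-9.eE+-]+).*$", "\\1", gain_field))
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    } else 0
    units <- if (grepl("/", gain_field)) sub("^.*/", "", gain_field) else "mV"
    sig[[i]] <- list(file = f[1], fmt = as.integer(sub("[x:+].*$", "", f[2])),
                     gain = if (is.na(gain) || gain == 0) 200 else gain,
                     baseline = baseline, units = units)
  }
  want <- sig[[channel]]
  fmts <- unique(vapply(sig, `[[`, 0L, "fmt"))
  files <- unique(vapply(sig, `[[`, "", "file"))
  if (length(files) != 1L) {
    stop("multi-file WFDB records are not supported", call. = FALSE)
  }
  if (length(fmts) != 1L || !fmts %in% c(16L, 212L)) {
    stop(sprintf("unsupported WFDB format(s): %s (only 16 and 212)",
                 paste(fmts, collapse = ", ")), call. = FALSE)
  }
  dat <- file.path(dirname(hea), files)
  if (!file.exists(dat)) stop(sprintf("signal file not found: %s", dat), call. = FALSE)
  raw <- readBin(dat, "raw", n = file.info(dat)$size)
  if (fmts == 16L) {
    v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little")
    mat <- matrix(v[seq_len((length(v) %/% n_sig) * n_sig)], nrow = n_sig)
  } else {
    v <- decode_wfdb_212(raw)
    mat <- matrix(v[seq_len((length(v) %/% n_sig) * n_sig)], nrow = n_sig)
  }
  x <- as.numeric(mat[channel, ])
  if (!is.na(n_samp) && n_samp > 0L && n_samp <= length(x)) x <- x[seq_len(n_samp)]
  list(samples = (x - want$baseline) / want$gain, fs = fs,
       n_channels = n_sig, units = want$units)
}

# format 212: two 12-bit two's-complement samples packed into 3 bytes
decode_wfdb_212 <- function(raw) {
  n3 <- (length(raw) %/% 3L) * 3L
  b <- as.integer(raw[seq_len(n3)])
  b1 <- b[seq(1L, n3, by = 3L)]
  b2 <- b[seq(2L, n3, by = 3L)]
  b3 <- b[seq(3L, n3, by = 3L)]
  s1 <- bitwAnd(b2, 15L) * 256L + b1
  s2 <- bitwAnd(bitwShiftR(b2, 4L), 15L) * 256L + b3
  fix <- function(s) ifelse(s > 2047L, s - 4096L, s)
  out <- numeric(2L * length(s1))
  out[seq(1L, length(out), by = 2L)] <- fix(s1)
  out[seq(2L, length(out), by = 2L)] <- fix(s2)
  out
}

#' Save a trained model checkpoint
#'
#' Single-file container holding the network weights, architecture
#' configuration, normalization statistics, and training history
#' (serialized with `saveRDS`).
#'
#' @param model a trained `rced_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  if (!inherits(model, "rced_model")) stop("not an rced_model", call. = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint path.
#' @return the `rced_model`.
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rced_model")) {
    stop(sprintf("%s does not contain an rced_model", path), call. = FALSE)
  }
  model
}
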