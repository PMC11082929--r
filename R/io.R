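#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed PCM (8/16/32-bit integer)
#' audio, sufficient for stimulus waveforms. Samples are returned scaled
#' to `[-1, 1]`.
#'
#' @param path file path.
#' @return list with `wave` (channel x sample matrix), `fs`,
#'   `bits_per_sample`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!length(id) || nchar(id) < 4) stop("corrupt WAV: no data chunk")
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, 2,
                               endian = "little"),
        n_channels = readBin(raw_fmt[3:4], "integer", 1, 2,
                             endian = "little"),
        fs = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("corrupt WAV: data before fmt")
      if (fmt$audio_format != 1) stop("only PCM WAV is supported")
      bytes <- fmt$bits / 8
      n <- size / bytes
      raw <- readBin(con, "integer", n, bytes, signed = fmt$bits > 8,
                     endian = "little")
      full <- 2^(fmt$bits - 1)
      x <- if (fmt$bits == 8) (raw - 128) / 128 else raw / full
      wave_m <- matrix(x, nrow = fmt$n_channels)
      return(list(wave = wave_m, fs = fmt$fs, bits_per_sample = fmt$bits))
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
}

#' Write a 16-bit PCM WAV file
#'
#' @param wave numeric vector or channel x sample matrix in `[-1, 1]`.
#' @param fs sampling rate in Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, fs, path) {
  wave <- if (is.null(dim(wave))) matrix(wave, nrow = 1) else as.matrix(wave)
  pcm <- as.integer(round(pmin(pmax(wave, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(nrow(wave), con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * nrow(wave) * 2), con, 4, endian = "little")
  writeBin(as.integer(nrow(wave) * 2), con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

.edf_pad <- function(x, width) {
  formatC(as.character(x), width = width, flag = "-")
}

#' Write a continuous recording as EDF
#'
#' European Data Format writer (16-bit integer samples, one-second data
#' records). Physical units are microvolts; the physical range is set
#' per channel from the data. The sampling rate must be an integer.
#'
#' @param rec an `eeg_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export needs an integer rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one data record")
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  span <- pmax(pmax_ - pmin_, 1e-6)
  pmin_ <- pmin_ - 0.001 * span
  pmax_ <- pmax_ + 0.001 * span
  dmin <- -32768L
  dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad("X X X X", 80),
    .edf_pad("Startdate X X X X", 80),
    "01.01.0001.00.00",
    .edf_pad(256 * (1 + ns), 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad(1, 8),
    .edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, .edf_pad, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(rec$channels, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(sprintf("%.6g", pmin_), 8)
  field(sprintf("%.6g", pmax_), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (c in seq_len(ns)) {
      seg <- x[c, ((r - 1) * fs + 1):(r * fs)]
      dig <- as.integer(round((seg - pmin_[c]) / gain[c]) + dmin)
      writeBin(pmin(pmax(dig, dmin), dmax), con, 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a BioSemi BDF or EDF recording with trigger events
#'
#' Reads continuous EDF (16-bit) and BDF (BioSemi 24-bit) files into an
#' `eeg_recording`, converting to physical units (µV as stored). Event
#' onsets are detected as rising edges on a trigger channel (label
#' containing "Status" or "Trigger", case-insensitive), thresholded at
#' half its maximum excursion; the trigger channel is dropped from the
#' data. Unknown extensions and corrupt headers are explicit errors.
#'
#' @param path file path ending in `.edf` or `.bdf`.
#' @param trigger_threshold optional absolute threshold for the trigger
#'   channel (default half of its maximum).
#' @return list with `recording` (an `eeg_recording`) and `events`
#'   (rising-edge onsets in samples).
#' @export
read_bdf_edf <- function(path, trigger_threshold = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("edf", "bdf")) {
    stop("unsupported format: .", ext, " (expected .edf or .bdf)")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  is_bdf <- magic[1] == as.raw(255)
  if (ext == "bdf" && !is_bdf) stop("corrupt BDF header")
  if (ext == "edf" && is_bdf) stop("corrupt EDF header (BDF magic found)")
  rd <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  invisible(rd(80)) # patient
  invisible(rd(80)) # recording
  invisible(rd(8))  # date
  invisible(rd(8))  # time
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  invisible(rd(44))
  n_rec <- suppressWarnings(as.integer(rd(8)))
  dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(header_bytes, n_rec, dur, ns)) || ns < 1 || n_rec < 1) {
    stop("corrupt header")
  }
  rdv <- function(width) {
    vapply(seq_len(ns), function(i) rd(width), character(1))
  }
  labels <- rdv(16)
  invisible(rdv(80))
  units <- rdv(8)
  pmin_ <- as.numeric(rdv(8))
  pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  invisible(rdv(80))
  spr <- as.integer(rdv(8))
  invisible(rdv(32))
  if (length(unique(spr)) != 1) {
    stop("mixed per-channel sampling rates are not supported")
  }
  fs <- spr[1] / dur
  bytes <- if (is_bdf) 3L else 2L
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  dat <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (c in seq_len(ns)) {
      if (is_bdf) {
        raw3 <- readBin(con, "raw", spr[c] * 3L)
        m <- matrix(as.integer(raw3), nrow = 3)
        v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        v <- ifelse(v >= 2^23, v - 2^24, v)
      } else {
        v <- readBin(con, "integer", spr[c], 2, endian = "little")
      }
      dat[c, ((r - 1) * spr[c] + 1):(r * spr[c])] <-
        pmin_[c] + gain[c] * (v - dmin[c])
    }
  }
  trig_i <- grep("status|trigger", labels, ignore.case = TRUE)
  events <- integer(0)
  if (length(trig_i)) {
    trig <- dat[trig_i[1], ]
    thr <- if (is.null(trigger_threshold)) max(abs(trig)) / 2 else
      trigger_threshold
    high <- abs(trig) > thr
    events <- which(high & !c(FALSE, high[-length(high)]))
    dat <- dat[-trig_i[1], , drop = FALSE]
    labels <- labels[-trig_i[1]]
  }
  list(
    recording = eeg_recording(dat, fs = fs, channels = labels),
    events = events
  )
}

#' Write a feature series as a single-column file with a JSON sidecar
#'
#' @param feature a [feature_series()].
#' @param path output path; the sidecar gets `.json` appended.
#' @return `path`, invisibly.
#' @export
write_feature_file <- function(feature, path) {
  stopifnot(inherits(feature, "feature_series"))
  writeLines(formatC(feature$values, format = "g", digits = 10), path)
  jsonlite::write_json(
    list(fs = feature$fs, segment_id = feature$segment_id,
         polarity = feature$polarity, n = length(feature$values)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature series written by [write_feature_file()] (or an
#' externally computed firing-rate series with a compatible sidecar)
#'
#' @param path data file path (sidecar at `paste0(path, ".json")`).
#' @param fs sampling rate, required when no sidecar exists.
#' @return a [feature_series()].
#' @export
read_feature_file <- function(path, fs = NULL) {
  vals <- as.numeric(readLines(path))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    feature_series(vals, fs = meta$fs,
                   segment_id = meta$segment_id %||% NA_character_,
                   polarity = meta$polarity %||% "original")
  } else {
    if (is.null(fs)) stop("`fs` required without a sidecar")
    feature_series(vals, fs = fs)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a tidy peak table (schema-validated)
#'
#' @param tab data.frame as produced by [peak_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(tab, path) {
  need <- c("participant", "group", "response_type", "component",
            "latency_ms", "amplitude")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
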