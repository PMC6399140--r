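# File formats: delimited EEG matrices (with JSON sidecar), 16-bit EDF,
# BrainVision triplets, and integer-per-line label files. No installed R
# package reads EDF or BrainVision, so minimal readers live here.

#' Read an EEG recording
#'
#' Supported formats: `delimited` (comma-separated; header row of channel
#' labels, then one row per channel; sampling rate from a `<path>.json`
#' sidecar or the `sampling_rate` argument), `edf` (16-bit EDF), and
#' `brainvision` (`.vhdr` + binary `.eeg`). `auto` sniffs from the file
#' extension. A missing sampling rate is an error, never a guessed default.
#'
#' @param path input file (`.vhdr` for BrainVision).
#' @param format one of `auto`, `delimited`, `edf`, `brainvision`.
#' @param sampling_rate required for delimited files without a sidecar.
#' @param subject_id identifier; defaults to the file stem.
#' @return An [eeg_recording].
#' @export
read_eeg <- function(path, format = c("auto", "delimited", "edf",
                                      "brainvision"),
                     sampling_rate = NULL, subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", vhdr = "brainvision",
                     csv = "delimited", txt = "delimited",
                     stop("cannot sniff format from extension '.", ext, "'"))
  }
  subject_id <- subject_id %||% tools::file_path_sans_ext(basename(path))
  switch(format,
         delimited = read_eeg_delimited(path, sampling_rate, subject_id),
         edf = read_eeg_edf(path, subject_id),
         brainvision = read_eeg_brainvision(path, subject_id))
}

read_eeg_delimited <- function(path, sampling_rate, subject_id) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("parse error: delimited EEG needs a header row ",
                              "and at least 2 channel rows")
  labels <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  rows <- lapply(seq_along(lines)[-1], function(i) {
    v <- suppressWarnings(as.numeric(strsplit(lines[i], ",", fixed = TRUE)[[1]]))
    if (anyNA(v)) stop("parse error at line ", i, ": non-numeric field")
    v
  })
  if (length(rows) != length(labels))
    stop("parse error: header names ", length(labels), " channels but file ",
         "has ", length(rows), " data rows")
  ns <- lengths(rows)
  if (length(unique(ns)) != 1)
    stop("parse error: ragged rows (file truncated?)")
  sidecar <- paste0(path, ".json")
  if (is.null(sampling_rate) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    sampling_rate <- meta$sampling_rate
    subject_id <- meta$subject_id %||% subject_id
  }
  if (is.null(sampling_rate))
    stop("sampling rate unknown: pass sampling_rate= or provide a ",
         basename(sidecar), " sidecar")
  eeg_recording(do.call(rbind, rows), sampling_rate,
                channel_labels = labels, subject_id = subject_id)
}

#' Write an EEG recording as a delimited matrix
#'
#' Comma-separated, header row of channel labels, one row per channel, plus a
#' `<path>.json` sidecar holding the sampling rate and subject id.
#'
#' @param rec an [eeg_recording].
#' @param path output file.
#' @param digits significant digits to print.
#' @return `path`, invisibly.
#' @export
write_eeg_delimited <- function(rec, path, digits = 8) {
  stopifnot(inherits(rec, "eeg_recording"))
  body <- apply(rec$data, 1, function(ch)
    paste(formatC(ch, digits = digits, format = "g"), collapse = ","))
  writeLines(c(paste(rec$channel_labels, collapse = ","), body), path)
  jsonlite::write_json(list(sampling_rate = rec$sampling_rate,
                            subject_id = rec$subject_id,
                            n_channels = nrow(rec$data),
                            n_samples = ncol(rec$data)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write an EEG recording as 16-bit EDF
#'
#' Minimal EDF writer (one data record per second; per-channel symmetric
#' physical range). The sample count must be a multiple of the sampling rate.
#'
#' @param rec an [eeg_recording]; sampling rate must be integral.
#' @param path output `.edf` file.
#' @return `path`, invisibly.
#' @export
write_eeg_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer needs an integer Hz rate")
  fs <- as.integer(round(fs))
  C <- nrow(rec$data); n <- ncol(rec$data)
  if (n %% fs != 0) stop("sample count must be a multiple of the rate")
  n_rec <- n %/% fs
  # integer physical range and symmetric digital range keep the header
  # fields exactly representable, so quantization is the only loss
  pmax_ <- pmax(ceiling(apply(abs(rec$data), 1, max)), 1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad_field("0", 8), pad_field(rec$subject_id, 80), pad_field("", 80),
    pad_field("01.01.20", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + C), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(C, 4)),
    con, eos = NULL)
  fields <- list(c(rec$channel_labels, 16), c(rep("", C), 80),
                 c(rep("uV", C), 8),
                 c(formatC(-pmax_, format = "d"), 8),
                 c(formatC(pmax_, format = "d"), 8),
                 c(rep("-32767", C), 8), c(rep("32767", C), 8),
                 c(rep("", C), 80), c(rep(fs, C), 8), c(rep("", C), 32))
  for (f in fields) {
    w <- as.integer(f[length(f)])
    for (v in f[-length(f)]) writeChar(pad_field(v, w), con, eos = NULL)
  }
  scale <- pmax_ / 32767
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    dig <- round(rec$data[, cols, drop = FALSE] / scale)
    for (c_i in seq_len(C))
      writeBin(as.integer(dig[c_i, ]), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_eeg_edf <- function(path, subject_id) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    raw <- readChar(con, w, useBytes = TRUE)
    if (length(raw) == 0 || nchar(raw, type = "bytes") < w)
      stop("parse error: truncated EDF header")
    trimws(raw)
  }
  rd(8)                              # version
  pid <- rd(80); rd(80); rd(8); rd(8)
  rd(8)                              # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  C <- as.integer(rd(4))
  if (is.na(n_rec) || is.na(C) || C < 1) stop("parse error: bad EDF header")
  sig <- function(w) vapply(seq_len(C), function(i) rd(w), character(1))
  labels <- sig(16); sig(80); sig(8)
  phys_min <- as.numeric(sig(8)); phys_max <- as.numeric(sig(8))
  dig_min <- as.numeric(sig(8)); dig_max <- as.numeric(sig(8))
  sig(80)
  spr <- as.integer(sig(8))          # samples per record, per signal
  sig(32)
  if (length(unique(spr)) != 1)
    stop("EDF reader supports a common sampling rate only")
  total <- n_rec * spr[1]
  data <- matrix(0, C, total)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (c_i in seq_len(C)) {
      d <- readBin(con, integer(), n = spr[1], size = 2, endian = "little")
      if (length(d) < spr[1]) stop("parse error: truncated EDF data record")
      data[c_i, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (d - dig_min[c_i]) * scale[c_i] + phys_min[c_i]
    }
  }
  fs <- spr[1] / rec_dur
  eeg_recording(data, fs, channel_labels = labels,
                subject_id = if (nzchar(pid)) pid else subject_id)
}

parse_vhdr <- function(lines) {
  out <- list(channels = character(), resolution = numeric())
  section <- ""
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[", ln)) { section <- tolower(ln); next }
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3) next
    key <- trimws(kv[2]); val <- trimws(kv[3])
    if (section == "[common infos]" || section == "[binary infos]") {
      out[[tolower(key)]] <- val
    } else if (section == "[channel infos]") {
      parts <- strsplit(val, ",", fixed = TRUE)[[1]]
      out$channels <- c(out$channels, parts[1])
      res <- suppressWarnings(as.numeric(parts[3]))
      out$resolution <- c(out$resolution, if (is.na(res)) 1 else res)
    }
  }
  out
}

read_eeg_brainvision <- function(path, subject_id) {
  hdr <- parse_vhdr(readLines(path, warn = FALSE))
  for (need in c("datafile", "numberofchannels", "samplinginterval"))
    if (is.null(hdr[[need]])) stop("parse error: missing ", need, " in .vhdr")
  if (!is.null(hdr$dataorientation) &&
      toupper(hdr$dataorientation) != "MULTIPLEXED")
    stop("only MULTIPLEXED BrainVision data supported")
  C <- as.integer(hdr$numberofchannels)
  fs <- 1e6 / as.numeric(hdr$samplinginterval)   # interval is in microseconds
  fmt <- toupper(hdr$binaryformat %||% "IEEE_FLOAT_32")
  datafile <- file.path(dirname(path), hdr$datafile)
  if (!file.exists(datafile)) stop("data file not found: ", datafile)
  sz <- file.info(datafile)$size
  bytes <- if (fmt == "INT_16") 2 else 4
  if (sz %% (bytes * C) != 0) stop("parse error: truncated BrainVision data")
  n <- sz / (bytes * C)
  con <- file(datafile, "rb")
  on.exit(close(con))
  raw <- if (fmt == "INT_16")
    readBin(con, integer(), n = n * C, size = 2, endian = "little")
  else readBin(con, numeric(), n = n * C, size = 4, endian = "little")
  data <- matrix(raw, nrow = C)                   # multiplexed: channel-fastest
  if (length(hdr$resolution) == C) data <- data * hdr$resolution
  labels <- if (length(hdr$channels) == C) hdr$channels else NULL
  eeg_recording(data, fs, channel_labels = labels, subject_id = subject_id)
}

#' Write a label sequence as an integer-per-line file
#'
#' External contract: 0-based state indices, `-1` for unassigned samples,
#' with a `<path>.json` sidecar carrying the sampling rate and state names.
#'
#' @param seq an [ms_labels].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_labels <- function(seq, path) {
  stopifnot(inherits(seq, "ms_labels"))
  writeLines(as.character(ifelse(is.na(seq$labels), -1L, seq$labels - 1L)),
             path)
  jsonlite::write_json(list(sampling_rate = seq$sampling_rate,
                            state_names = seq$state_names),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a label sequence written by [write_labels()]
#'
#' @param path label file (integer per line, 0-based, `-1` = unassigned).
#' @param sampling_rate required if no sidecar is present.
#' @param state_names optional state names.
#' @return An [ms_labels].
#' @export
read_labels <- function(path, sampling_rate = NULL, state_names = NULL) {
  v <- suppressWarnings(as.integer(readLines(path)))
  if (anyNA(v)) stop("parse error: non-integer label line")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    sampling_rate <- sampling_rate %||% meta$sampling_rate
    state_names <- state_names %||% unlist(meta$state_names)
  }
  if (is.null(sampling_rate)) stop("sampling rate unknown for label file")
  labels <- ifelse(v < 0, NA_integer_, v + 1L)
  ms_labels(labels, sampling_rate, state_names = state_names,
            k = if (is.null(state_names)) max(labels, na.rm = TRUE) else NULL)
}
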