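# Minimal EDF (European Data Format) writer/reader: 16-bit samples,
# 1-second data records, one scaling per channel. The true sample count is
# kept in the reserved header field so padded final records round-trip.

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Samples are quantised to 16 bits against a symmetric per-channel physical
#' range, in 1-second data records (the final record is zero-padded; the
#' true length is recorded in the header and honoured by [read_edf()]).
#'
#' @param rec an `eeg_recording`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  validate_recording(rec)
  ns <- ncol(rec$data)
  nsamp <- nrow(rec$data)
  spr <- as.integer(round(rec$fs))           # samples per 1-s record
  if (abs(spr - rec$fs) > 1e-9) stopf("EDF writer requires integer fs")
  nrec <- ceiling(nsamp / spr)
  phys_max <- apply(abs(rec$data), 2, max)
  phys_max[phys_max == 0] <- 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    pad_ascii("0", 8),
    pad_ascii(rec$meta$patient_id %||% "X", 80),
    pad_ascii(rec$meta$contact_id %||% "X", 80),
    pad_ascii("01.01.20", 8), pad_ascii("00.00.00", 8),
    pad_ascii(hdr_bytes, 8),
    pad_ascii(sprintf("NSAMP=%d REGION=%s MONTAGE=%s", nsamp,
                      rec$meta$region_label %||% "unknown",
                      rec$meta$montage_id %||% "NA"), 44),
    pad_ascii(nrec, 8),
    pad_ascii(1, 8),
    pad_ascii(ns, 4)), con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste(vapply(vals, pad_ascii, "", width = width),
                    collapse = ""), con, eos = NULL)
  }
  field(rec$channel_names, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(sprintf("%.6g", -phys_max), 8)
  field(sprintf("%.6g", phys_max), 8)
  field(rep(-32767L, ns), 8)
  field(rep(32767L, ns), 8)
  field(rep("", ns), 80)
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)
  scale <- 32767 / phys_max
  padded <- nrec * spr
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):min(r * spr, nsamp)
    block <- matrix(0L, spr, ns)
    dig <- round(sweep(rec$data[idx, , drop = FALSE], 2L, scale, "*"))
    block[seq_along(idx), ] <- dig
    storage.mode(block) <- "integer"
    writeBin(as.vector(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file written by [write_edf()] or any single-rate 16-bit
#'   EDF with identical samples-per-record across channels.
#' @return An `eeg_recording` without events (attach via [read_recording()]).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    out <- readChar(con, w, useBytes = TRUE)
    if (nchar(out, type = "bytes") < w) stopf("malformed EDF header in %s", path)
    trimws(out)
  }
  rd(8)                                   # version
  patient <- rd(80); contact <- rd(80)
  rd(8); rd(8); rd(8)
  reserved <- rd(44)
  nrec <- suppressWarnings(as.integer(rd(8)))
  dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(nrec) || is.na(dur) || is.na(ns) || ns < 1L || dur <= 0) {
    stopf("malformed EDF header in %s", path)
  }
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin_ <- as.numeric(rdv(8)); dmax_ <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  if (length(unique(spr)) != 1L) stopf("EDF reader requires one rate per file")
  spr <- spr[1]
  fs <- spr / dur
  raw <- readBin(con, "integer", n = nrec * ns * spr, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < nrec * ns * spr) stopf("EDF data truncated in %s", path)
  arr <- array(raw, c(spr, ns, nrec))
  data <- matrix(aperm(arr, c(1, 3, 2)), spr * nrec, ns)
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  data <- sweep(data, 2L, scale, "*")
  data <- sweep(data, 2L, pmin_ - dmin_ * scale, "+")
  meta <- list(patient_id = patient, contact_id = contact)
  m <- regmatches(reserved, regexec("NSAMP=(\\d+) REGION=(\\S+) MONTAGE=(\\S+)",
                                    reserved))[[1]]
  if (length(m) == 4L) {
    data <- data[seq_len(as.integer(m[2])), , drop = FALSE]
    meta$region_label <- m[3]
    if (m[4] != "NA") meta$montage_id <- m[4]
  }
  recording(data, fs, labels, NULL, meta)
}

#' Read / write a signal matrix as plain CSV (test convenience)
#'
#' One column per channel, one row per sample; header row gives channel
#' names. Metadata beyond `fs` is not stored.
#'
#' @param rec an `eeg_recording` (for writing).
#' @param path file path.
#' @param fs sampling rate to assume when reading.
#' @return `read_signal_csv` returns an `eeg_recording`.
#' @export
write_signal_csv <- function(rec, path) {
  df <- as.data.frame(rec$data)
  names(df) <- rec$channel_names
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path, fs = 1000) {
  df <- utils::read.csv(path, check.names = FALSE)
  recording(as.matrix(df), fs, names(df))
}
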