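#' Read / write stimulus event tables
#'
#' Tab-separated with columns `onset_sample` (0-based, authoritative),
#' `onset_ms` (informative) and `label`. When `onset_sample` is absent the
#' millisecond column is converted at the stated sampling rate.
#'
#' @param path TSV file.
#' @param fs sampling rate used to convert `onset_ms` when needed.
#' @return A data frame with columns `onset_sample` and `label`.
#' @export
read_events <- function(path, fs = 1000) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(df$onset_sample)) {
    if (is.null(df$onset_ms)) stopf("event table needs onset_sample or onset_ms")
    df$onset_sample <- ms_to_samples(df$onset_ms, fs)
  }
  bad <- which(is.na(df$onset_sample) | df$onset_sample < 0 |
                 df$onset_sample != floor(df$onset_sample))
  if (length(bad)) {
    stopf("event onsets must be non-negative integers; offending rows: %s",
          paste(utils::head(bad, 10L), collapse = ", "))
  }
  data.frame(onset_sample = as.integer(df$onset_sample),
             label = as.character(df$label %||% "stim"),
             stringsAsFactors = FALSE)
}

#' @param events event data frame (`onset_sample`, `label`).
#' @rdname read_events
#' @export
write_events <- function(events, path, fs = 1000) {
  out <- data.frame(onset_sample = events$onset_sample,
                    onset_ms = samples_to_ms(events$onset_sample, fs),
                    label = events$label)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a recording plus its event table
#'
#' Dispatches on extension: `.edf` via [read_edf()], `.csv` via
#' [read_signal_csv()]. Events whose onsets fall outside the signal span
#' raise a validation error listing the offenders, or are dropped with a
#' warning when `drop_out_of_range = TRUE`.
#'
#' @param path signal file (`.edf` or `.csv`).
#' @param events_path optional event TSV.
#' @param fs sampling rate assumed for CSV signals.
#' @param drop_out_of_range drop (with a warning count) rather than error on
#'   events beyond the recording end.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, events_path = NULL, fs = 1000,
                           drop_out_of_range = FALSE) {
  rec <- if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    read_edf(path)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    read_signal_csv(path, fs = fs)
  } else {
    stopf("unsupported signal format: %s", path)
  }
  if (!is.null(events_path)) {
    ev <- read_events(events_path, fs = rec$fs)
    out <- ev$onset_sample >= nrow(rec$data)
    if (any(out)) {
      if (drop_out_of_range) {
        warnf("dropped %d event(s) beyond the recording end", sum(out))
        ev <- ev[!out, , drop = FALSE]
      } else {
        stopf("event(s) beyond recording end at rows: %s",
              paste(utils::head(which(out), 10L), collapse = ", "))
      }
    }
    rec$events <- ev
    validate_recording(rec)
  }
  rec
}

#' @param rec an `eeg_recording`.
#' @rdname read_recording
#' @export
write_recording <- function(rec, path, events_path = NULL) {
  write_edf(rec, path)
  if (!is.null(events_path)) write_events(rec$events, events_path, fs = rec$fs)
  invisible(path)
}

#' Read / write the session x feature table
#'
#' CSV with identifier columns `session_id`, `region`, `seed` followed by
#' one column per engineered feature, named `<location>.<window>.<kind>`.
#'
#' @param table feature table data frame.
#' @param path CSV path.
#' @return `read_feature_table` returns the data frame with `region` as
#'   character.
#' @export
write_feature_table <- function(table, path) {
  if (!nrow(table)) stopf("feature table is empty")
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
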