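#' Construct a continuous multichannel EEG recording
#'
#' The basic container moved through the pipeline: a samples x channels
#' matrix in microvolts (time-major: one column per channel, which keeps
#' every heavy operation contiguous in R's column-major storage), its
#' sampling rate, stimulus events and session metadata. Stimulus onsets
#' are stored as 0-based sample indices; all user-facing times are
#' milliseconds relative to stimulus onset.
#'
#' @param data numeric matrix, samples x channels (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one unique name per column of
#'   `data`.
#' @param events data frame with columns `onset_sample` (0-based integer)
#'   and `label`, or `NULL` for none.
#' @param meta named list of session metadata. Recognised entries:
#'   `patient_id`, `contact_id`, `region_label` (one of `"ZI"`, `"DLR"`,
#'   `"VMR"`, `"unknown"`), `montage_id` (`"EGI64"` or `"EGI128"`).
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs, channel_names = colnames(data),
                      events = NULL, meta = list()) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stopf("`data` must be a numeric samples x channels matrix")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("E", seq_len(ncol(data)))
  }
  if (is.null(events)) {
    events <- data.frame(onset_sample = integer(0), label = character(0))
  }
  meta$region_label <- meta$region_label %||% "unknown"
  rec <- structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         events = events, meta = meta),
    class = "eeg_recording"
  )
  validate_recording(rec)
  rec
}

#' Validate recording invariants
#'
#' Checks sampling rate, channel-name uniqueness and that every event onset
#' falls inside the signal span. Called by every constructor/reader.
#'
#' @param rec an `eeg_recording`.
#' @param pipeline_entry if `TRUE`, additionally require 64 or 128 channels
#'   (the montages the pipeline accepts).
#' @return `rec`, invisibly; errors describe the offending invariant.
#' @export
validate_recording <- function(rec, pipeline_entry = FALSE) {
  if (!inherits(rec, "eeg_recording")) stopf("not an eeg_recording")
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || rec$fs <= 0) {
    stopf("sampling rate must be a single positive number")
  }
  if (length(rec$channel_names) != ncol(rec$data)) {
    stopf("channel_names length (%d) != channel count (%d)",
          length(rec$channel_names), ncol(rec$data))
  }
  if (anyDuplicated(rec$channel_names)) stopf("channel names must be unique")
  n <- nrow(rec$data)
  ev <- rec$events
  if (nrow(ev)) {
    bad <- which(ev$onset_sample < 0 | ev$onset_sample >= n)
    if (length(bad)) {
      stopf("events outside recording span [0, %d): offending rows %s",
            n, paste(utils::head(bad, 10L), collapse = ", "))
    }
  }
  if (pipeline_entry && !ncol(rec$data) %in% c(64L, 128L)) {
    stopf("pipeline entry requires 64 or 128 channels, got %d", ncol(rec$data))
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
    ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs, nrow(x$events)))
  cat(sprintf("  region: %s  montage: %s\n",
              x$meta$region_label %||% "unknown",
              x$meta$montage_id %||% "?"))
  invisible(x)
}

n_channels <- function(rec) ncol(rec$data)
n_samples <- function(rec) nrow(rec$data)
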