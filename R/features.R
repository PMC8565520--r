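#' The seven engineered ERP features
#'
#' Per (location, window): max/min peak amplitude, max/min peak latency
#' (ms, first occurrence on ties), peak-to-peak (max - min), signed area
#' under the curve (trapezoidal, uV.ms) and energy. `energy` defaults to
#' the trapezoidal integral of the squared trace (signal energy, uV^2.ms);
#' the literal "square of the window integral" reading is available via
#' `energy_mode = "square_of_integral"`.
#'
#' @return Character vector of the 7 feature kinds.
#' @export
feature_kinds <- function() {
  c("max_amp", "min_amp", "max_latency", "min_latency",
    "peak_to_peak", "auc", "energy")
}

feature_key <- function(location, window, kind) {
  paste(location, window, kind, sep = ".")
}

#' Engineered features of one ERP
#'
#' Computes the seven feature kinds for every (location, window) pair.
#' Locations are the ERP's channels plus, when a `roi_map` is given, the
#' nine ROI averages. Windows are half-open in ms.
#'
#' @param erp an `eeg_erp`.
#' @param windows named list of half-open windows (ms), see
#'   [default_windows()].
#' @param roi_map optional ROI map to append the 9 virtual channels.
#' @param energy_mode `"integral_of_square"` (default) or
#'   `"square_of_integral"`.
#' @return Named numeric vector with `7 x |windows| x |locations|` entries,
#'   keys `<location>.<window>.<kind>`.
#' @export
extract_features <- function(erp, windows = default_windows(),
                             roi_map = NULL,
                             energy_mode = "integral_of_square") {
  traces <- erp$data
  locs <- erp$channel_names
  if (!is.null(roi_map)) {
    re <- roi_average(erp, roi_map)
    traces <- rbind(traces, re$data)
    locs <- c(locs, re$channel_names)
  }
  times <- erp$times_ms
  out <- numeric(0)
  for (wname in names(windows)) {
    w <- windows[[wname]]
    sel <- which(times >= w[1] & times < w[2])
    if (!length(sel)) stopf("window %s lies outside the ERP span", wname)
    seg <- traces[, sel, drop = FALSE]
    t_sel <- times[sel]
    imax <- max.col(seg, ties.method = "first")
    imin <- max.col(-seg, ties.method = "first")
    mx <- seg[cbind(seq_len(nrow(seg)), imax)]
    mn <- seg[cbind(seq_len(nrow(seg)), imin)]
    auc <- apply(seg, 1, function(x) pracma::trapz(t_sel, x))
    energy <- if (energy_mode == "square_of_integral") {
      auc^2
    } else {
      apply(seg, 1, function(x) pracma::trapz(t_sel, x^2))
    }
    vals <- cbind(max_amp = mx, min_amp = mn,
                  max_latency = t_sel[imax], min_latency = t_sel[imin],
                  peak_to_peak = mx - mn, auc = auc, energy = energy)
    keys <- outer(locs, feature_kinds(),
                  function(l, k) feature_key(l, wname, k))
    v <- as.vector(vals)
    names(v) <- as.vector(keys)
    out <- c(out, v)
  }
  out
}

#' Assemble the cohort feature table
#'
#' One row per session: identifier columns (`session_id`, `region`, `seed`)
#' followed by the engineered features. With 64 channels, 9 ROIs, 4 windows
#' and 7 kinds this is 2,044 feature columns.
#'
#' @param rows list of per-session results, each a list with `features`
#'   (from [extract_features()]), `session_id`, `region` and optionally
#'   `seed`.
#' @return Data frame feature table.
#' @export
build_feature_table <- function(rows) {
  if (!length(rows)) stopf("no sessions")
  keys <- names(rows[[1]]$features)
  for (r in rows) {
    if (!identical(names(r$features), keys)) {
      stopf("inconsistent feature sets across sessions")
    }
  }
  feat <- do.call(rbind, lapply(rows, function(r) unname(r$features)))
  colnames(feat) <- keys
  df <- data.frame(
    session_id = vapply(rows, function(r) r$session_id, ""),
    region = vapply(rows, function(r) r$region, ""),
    seed = vapply(rows, function(r) as.integer(r$seed %||% NA_integer_), 1L),
    stringsAsFactors = FALSE)
  cbind(df, as.data.frame(feat, check.names = FALSE))
}

# Identifier (non-feature) columns of a feature table.
id_columns <- function() c("session_id", "region", "seed")

feature_columns <- function(table) setdiff(names(table), id_columns())

feature_matrix <- function(table) {
  as.matrix(table[, feature_columns(table), drop = FALSE])
}
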