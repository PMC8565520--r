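#' The four predefined post-stimulus analysis windows
#'
#' Half-open millisecond intervals relative to stimulus onset: very early
#' 5-25 ms, early 45-55 ms, middle 50-100 ms, late 100-149 ms. The early
#' and middle windows overlap by construction; they are independent
#' features, not a partition.
#'
#' @return Named list of `c(start, end)` vectors (ms).
#' @export
default_windows <- function() {
  list(very_early = c(5, 25), early = c(45, 55),
       middle = c(50, 100), late = c(100, 149))
}

#' Analysis configuration for the full pipeline
#'
#' Collects every tunable of the cleaning, epoching, feature and
#' classification stages with the study defaults.
#'
#' @param artifact_threshold_sd detection threshold in SDs of the
#'   channel-mean signal (default 3).
#' @param artifact_margin_ms extension of each detected artifact run on both
#'   sides before merging (ms).
#' @param filter_band band-pass edges in Hz (default 0.5-40).
#' @param epoch_window_ms epoch span in ms relative to onset, half-open
#'   (default -50 to +150).
#' @param windows named list of half-open feature windows (ms).
#' @param energy_mode `"integral_of_square"` (signal energy, default) or
#'   `"square_of_integral"`.
#' @param features_on compute features on `"raw"` (default) or `"zscore"`d
#'   ERPs.
#' @param mrmr_k number of MRMR-selected features fed to the SVM (default 25).
#' @param mrmr_k_grid candidate feature-count grid.
#' @param svm_c_grid linear-SVM regularisation grid.
#' @param cv_folds cross-validation folds (default 5).
#' @param select_within_folds run MRMR inside each training fold (leakage
#'   safe, default) rather than once on the full table.
#' @param rng_seed seed consumed by every stochastic stage.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(artifact_threshold_sd = 3,
                            artifact_margin_ms = 2,
                            filter_band = c(0.5, 40),
                            epoch_window_ms = c(-50, 150),
                            windows = default_windows(),
                            energy_mode = c("integral_of_square",
                                            "square_of_integral"),
                            features_on = c("raw", "zscore"),
                            mrmr_k = 25,
                            mrmr_k_grid = c(5, 10, 15, 20, 25, 30, 40, 60, 80),
                            svm_c_grid = c(0.001, 0.01, 0.1, 0.5, 1, 2),
                            cv_folds = 5,
                            select_within_folds = TRUE,
                            rng_seed = 1) {
  cfg <- list(artifact_threshold_sd = artifact_threshold_sd,
              artifact_margin_ms = artifact_margin_ms,
              filter_band = filter_band,
              epoch_window_ms = epoch_window_ms,
              windows = windows,
              energy_mode = match.arg(energy_mode),
              features_on = match.arg(features_on),
              mrmr_k = mrmr_k,
              mrmr_k_grid = mrmr_k_grid,
              svm_c_grid = svm_c_grid,
              cv_folds = cv_folds,
              select_within_folds = isTRUE(select_within_folds),
              rng_seed = rng_seed)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (cfg$artifact_threshold_sd < 0) stopf("artifact threshold must be >= 0")
  ew <- cfg$epoch_window_ms
  if (!(ew[1] < 0 && ew[2] > 0)) stopf("epoch window must contain 0")
  for (nm in names(cfg$windows)) {
    w <- cfg$windows[[nm]]
    if (w[1] >= w[2]) stopf("window %s: start must precede end", nm)
    if (w[1] < 0 || w[2] > ew[2]) {
      stopf("window %s must lie in the post-stimulus epoch span [0, %g)",
            nm, ew[2])
    }
  }
  if (!length(cfg$svm_c_grid) || !length(cfg$mrmr_k_grid)) {
    stopf("parameter grids must be non-empty")
  }
  if (any(cfg$svm_c_grid <= 0)) stopf("SVM C values must be positive")
  if (cfg$filter_band[1] >= cfg$filter_band[2]) stopf("invalid filter band")
  invisible(cfg)
}

#' Read / write configurations (YAML or JSON by extension)
#'
#' @param cfg a `pipeline_config` or `simulation_config`.
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return `read_config` returns the restored object (class from the
#'   stored `config_class` field).
#' @export
write_config <- function(cfg, path) {
  lst <- unclass(cfg)
  # named atomic vectors become maps (YAML sequences would drop the names)
  lst <- lapply(lst, function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  lst$config_class <- class(cfg)[1]
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cls <- lst$config_class %||% "pipeline_config"
  lst$config_class <- NULL
  maker <- if (cls == "simulation_config") simulation_config else pipeline_config
  # restore (possibly named) numeric vectors that YAML/JSON split into lists
  lst <- lapply(lst, function(x) {
    if (is.list(x) && length(x) &&
        all(vapply(x, function(e) is.numeric(e) && length(e) == 1L, TRUE))) {
      unlist(x)
    } else {
      x
    }
  })
  if (!is.null(lst$windows)) lst$windows <- lapply(lst$windows, unlist)
  if (!is.null(lst$templates)) lst$templates <- as.data.frame(lst$templates)
  for (nm in c("artifact", "noise")) {
    if (!is.null(lst[[nm]])) lst[[nm]] <- as.list(unlist(lst[[nm]]))
  }
  do.call(maker, lst)
}
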