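#' The nine scalp regions of interest
#'
#' ROI names follow the left/medial/right x frontal/fronto-central/
#' occipital-parietal grid used throughout the analysis.
#'
#' @return Character vector of the 9 ROI names, in fixed order.
#' @export
roi_names <- function() {
  c("left_frontal", "medial_frontal", "right_frontal",
    "left_fronto_central", "medial_fronto_central", "right_fronto_central",
    "left_occipital_parietal", "medial_occipital_parietal",
    "right_occipital_parietal")
}

golden_angle <- pi * (3 - sqrt(5))

# Deterministic sensor layout: golden-angle spiral over a spherical cap,
# head-centred unit sphere, +x right, +y anterior, +z up. A synthetic
# stand-in for the proprietary geodesic net geometries.
spiral_layout <- function(n, z_top = 0.95, z_bot = -0.05) {
  i <- seq_len(n)
  z <- z_top - (i - 0.5) / n * (z_top - z_bot)
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * golden_angle
  data.frame(name = paste0("E", i),
             x = r * cos(phi), y = r * sin(phi), z = z,
             stringsAsFactors = FALSE)
}

# Sector-based ROI assignment from electrode positions. Vertex electrodes
# (z > 0.8) join the medial fronto-central strip. Electrodes between the
# fronto-central and occipital-parietal bands stay unassigned; ROIs need
# not cover the whole montage.
assign_rois <- function(pos) {
  r <- sqrt(pos$x^2 + pos$y^2)
  u <- pos$x / pmax(r, 1e-9)
  v <- pos$y / pmax(r, 1e-9)
  vertex <- pos$z > 0.80
  ap <- ifelse(vertex | (v > -0.15 & v <= 0.55), "fronto_central",
        ifelse(v > 0.55, "frontal",
        ifelse(v < -0.45, "occipital_parietal", NA)))
  lr <- ifelse(vertex, "medial",
        ifelse(u < -0.4, "left", ifelse(u > 0.4, "right", "medial")))
  ifelse(is.na(ap), NA, paste(lr, ap, sep = "_"))
}

#' Build a montage (electrode positions + ROI map)
#'
#' Positions lie on the unit sphere (golden-angle spiral over the scalp
#' cap); the ROI map groups channels into the nine named scalp regions by
#' angular sector. The layout is a documented synthetic convention, not the
#' manufacturer's proprietary net geometry.
#'
#' @param n_channels 64 or 128.
#' @return An object of class `eeg_montage` with `positions` (data frame
#'   name/x/y/z), `roi_map` (named list of character vectors) and
#'   `montage_id`.
#' @export
make_montage <- function(n_channels = 64) {
  if (!n_channels %in% c(64L, 128L)) stopf("n_channels must be 64 or 128")
  pos <- spiral_layout(n_channels)
  roi <- assign_rois(pos)
  roi_map <- lapply(roi_names(), function(r) pos$name[which(roi == r)])
  names(roi_map) <- roi_names()
  m <- structure(
    list(positions = pos, roi_map = roi_map,
         montage_id = paste0("EGI", n_channels)),
    class = "eeg_montage"
  )
  validate_montage(m)
  m
}

validate_montage <- function(m) {
  if (!setequal(names(m$roi_map), roi_names()) ||
      length(m$roi_map) != 9L) {
    stopf("montage must define exactly the 9 named ROIs")
  }
  empty <- names(m$roi_map)[lengths(m$roi_map) == 0L]
  if (length(empty)) stopf("empty ROI(s): %s", paste(empty, collapse = ", "))
  unknown <- setdiff(unlist(m$roi_map), m$positions$name)
  if (length(unknown)) {
    stopf("ROI channels missing from positions: %s",
          paste(unknown, collapse = ", "))
  }
  invisible(m)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %s: %d electrodes, 9 ROIs (%s channels)\n",
              x$montage_id, nrow(x$positions),
              paste(range(lengths(x$roi_map)), collapse = "-")))
  invisible(x)
}

#' Read / write electrode positions in .sfp-style format
#'
#' Whitespace-separated `name x y z`, one electrode per line.
#'
#' @param path file path.
#' @return For `read_montage_sfp`, a data frame name/x/y/z.
#' @export
read_montage_sfp <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("name", "x", "y", "z"),
                          stringsAsFactors = FALSE)
  df
}

#' @param positions data frame with columns name, x, y, z.
#' @rdname read_montage_sfp
#' @export
write_montage_sfp <- function(positions, path) {
  utils::write.table(positions, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Interpolate a 128-channel recording onto a 64-channel montage
#'
#' Each target channel is the inverse-distance-weighted average of its `k`
#' nearest source electrodes (3D Euclidean distance on the shared unit
#' sphere). A target coincident with a source copies that source exactly.
#'
#' @param rec an `eeg_recording` whose channels match `montage_from`.
#' @param montage_from source `eeg_montage` (e.g. the 128-channel net).
#' @param montage_to target `eeg_montage` (the 64-channel net).
#' @param k number of nearest sources per target.
#' @return A recording on the target montage; events and metadata carried
#'   over, `montage_id` updated.
#' @export
unify_montage <- function(rec, montage_from, montage_to, k = 3) {
  if (!identical(rec$meta$montage_id %||% montage_from$montage_id,
                 montage_from$montage_id)) {
    stopf("recording montage (%s) does not match source montage (%s)",
          rec$meta$montage_id, montage_from$montage_id)
  }
  if (!setequal(rec$channel_names, montage_from$positions$name)) {
    stopf("recording channels do not match the source montage")
  }
  src <- montage_from$positions
  src <- src[match(rec$channel_names, src$name), ]
  tgt <- montage_to$positions
  ns <- nrow(src); nt <- nrow(tgt)
  W <- matrix(0, nt, ns)
  sp <- as.matrix(src[, c("x", "y", "z")])
  tp <- as.matrix(tgt[, c("x", "y", "z")])
  for (i in seq_len(nt)) {
    d2 <- colSums((t(sp) - tp[i, ])^2)
    nn <- order(d2)[seq_len(k)]
    d <- sqrt(d2[nn])
    if (d[1] < 1e-9) {
      W[i, nn[1]] <- 1
    } else {
      w <- 1 / d
      W[i, nn] <- w / sum(w)
    }
  }
  out <- rec$data %*% t(W)
  meta <- rec$meta
  meta$montage_id <- montage_to$montage_id
  recording(out, rec$fs, tgt$name, rec$events, meta)
}
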