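# File formats: volumes as multi-page TIFF + JSON sidecar, recordings as
# two-column CSV + JSON sidecar, study tables as plain CSV.

.sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Write a whisker volume as a multi-page TIFF stack
#'
#' Pages run along the shaft (z), rows are y, columns are x; a JSON sidecar
#' next to the stack records the voxel size and axis order.
#'
#' @param x a `whisker_phantom` or a 3-D array with a `voxel_size_um`
#'   attribute.
#' @param path output `.tif` path; the sidecar goes to the same path with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_phantom_tiff <- function(x, path) {
  vol <- if (inherits(x, "whisker_phantom")) x$volume else x
  vox <- attr(vol, "voxel_size_um")
  stopifnot(length(dim(vol)) == 3L, !is.null(vox))
  pages <- lapply(seq_len(dim(vol)[3]), function(i) {
    m <- vol[, , i]
    if (max(m) > 1) m <- m / max(m)
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(list(voxel_size_um = vox, axis_order = "zyx"),
                       .sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a whisker volume from a multi-page TIFF stack
#'
#' @param path path to a `.tif` stack written by [write_phantom_tiff()] (or
#'   a scanner export with a matching JSON sidecar).
#' @param voxel_size_um override for the voxel size when no sidecar exists.
#' @return A 3-D array `[y, x, slice]` with attribute `voxel_size_um`.
#' @export
read_volume_tiff <- function(path, voxel_size_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- .sidecar_path(path)
  if (is.null(voxel_size_um)) {
    if (!file.exists(side)) {
      stop("no JSON sidecar found and voxel_size_um not given", call. = FALSE)
    }
    voxel_size_um <- jsonlite::read_json(side)$voxel_size_um
  }
  vol <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) vol[, , i] <- pages[[i]]
  attr(vol, "voxel_size_um") <- as.numeric(voxel_size_um)
  vol
}

#' Write / read a vibration recording as CSV plus JSON sidecar
#'
#' Two columns, `time_s` and `velocity_m_per_s`; the sidecar stores the
#' sample rate (and angle, when annotated).
#'
#' @param recording a [vibration_recording()].
#' @param path output `.csv` path.
#' @return `path` invisibly (write) or a `vibration_recording` (read).
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "vibration_recording"))
  n <- length(recording$samples)
  utils::write.csv(
    data.frame(time_s = (seq_len(n) - 1) / recording$sample_rate,
               velocity_m_per_s = recording$samples),
    path, row.names = FALSE)
  side <- list(sample_rate = recording$sample_rate)
  if (!is.null(recording$angle_deg)) side$angle_deg <- recording$angle_deg
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  d <- utils::read.csv(path)
  side <- jsonlite::read_json(.sidecar_path(path))
  vibration_recording(d$velocity_m_per_s, as.numeric(side$sample_rate),
                      angle_deg = if (!is.null(side$angle_deg))
                        as.numeric(side$angle_deg))
}

#' Write / read a study table as CSV
#'
#' Header: `subject_id,species,angle_deg,peak_freq_hz,peak_vel_m_s,length_cm`.
#'
#' @param table a study table data.frame.
#' @param path `.csv` path.
#' @return `path` invisibly (write) or the table (read).
#' @export
write_study_table_csv <- function(table, path) {
  cols <- c("subject_id", "species", "angle_deg", "peak_freq_hz",
            "peak_vel_m_s", "length_cm")
  stopifnot(all(cols %in% names(table)))
  utils::write.csv(table[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_table_csv
#' @export
read_study_table_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("study_table", class(out))
  out
}
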