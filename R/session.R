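#' BOLD sessions
#'
#' One scanning session: a `n_regions x n_volumes` real signal matrix for a
#' single subject at a single timepoint, with the sampling interval (seconds
#' per volume, the TR). Row `i` is the time series of atlas `node_id i`.
#'
#' @param signals Numeric matrix, regions in rows, volumes in columns.
#' @param subject_id Subject label.
#' @param timepoint Timepoint label (e.g. `"pre"`, `"1wpi"`).
#' @param sampling_interval Seconds per volume (default 1).
#' @return A `bold_session` object.
#' @export
bold_session <- function(signals, subject_id, timepoint, sampling_interval = 1) {
  if (!is.matrix(signals) || !is.numeric(signals)) {
    stop_hubshift("signals must be a numeric matrix", "shape_error")
  }
  if (ncol(signals) < 3) {
    stop_hubshift("a session needs at least 3 volumes", "validation_error")
  }
  if (any(!is.finite(signals))) {
    stop_hubshift("signals contain non-finite values; inputs are rejected, not imputed",
                  "data_error")
  }
  if (!is.numeric(sampling_interval) || sampling_interval <= 0) {
    stop_hubshift("sampling_interval must be > 0", "validation_error")
  }
  structure(
    list(signals = unname(signals),
         subject_id = as.character(subject_id),
         timepoint = as.character(timepoint),
         sampling_interval = as.numeric(sampling_interval)),
    class = "bold_session"
  )
}

#' @export
print.bold_session <- function(x, ...) {
  cat(sprintf("<bold_session> subject %s, timepoint %s: %d regions x %d volumes, TR %g s\n",
              x$subject_id, x$timepoint, nrow(x$signals), ncol(x$signals),
              x$sampling_interval))
  invisible(x)
}

#' @export
dim.bold_session <- function(x) dim(x$signals)

#' Read and write session matrices
#'
#' Session files are CSV matrices: one row per region (atlas order), one
#' column per volume, with a single header row of volume indices
#' `v0,v1,...`. Writing then reading reproduces the matrix bit-exactly.
#'
#' @param path CSV file path.
#' @param atlas A `region_atlas`; the file's row count must equal its size.
#' @param subject_id,timepoint Labels for the session; when `NULL` they are
#'   parsed from a `sub-<id>_tp-<label>.csv` filename.
#' @param sampling_interval Seconds per volume (default 1).
#' @return `load_session()` returns a `bold_session`; `write_session()`
#'   returns `path` invisibly.
#' @export
load_session <- function(path, atlas, subject_id = NULL, timepoint = NULL,
                         sampling_interval = 1) {
  if (!file.exists(path)) {
    stop_hubshift(paste0("session file not found: ", path), "io_error")
  }
  atlas <- validate_atlas(atlas)
  # base strtod parsing round-trips the 17-digit writer bit-exactly
  raw <- utils::read.csv(path, header = TRUE, colClasses = "numeric")
  mat <- unname(as.matrix(raw))
  if (nrow(mat) != nrow(atlas)) {
    stop_hubshift(sprintf("session has %d rows but atlas has %d regions",
                          nrow(mat), nrow(atlas)), "shape_error")
  }
  if (any(!is.finite(mat))) {
    stop_hubshift("session file contains missing or non-finite cells", "data_error")
  }
  fn <- basename(path)
  if (is.null(subject_id)) {
    subject_id <- sub("^.*sub-([^_\\.]+).*$", "\\1", fn)
    if (identical(subject_id, fn)) subject_id <- "unknown"
  }
  if (is.null(timepoint)) {
    timepoint <- sub("^.*tp-([^_\\.]+).*$", "\\1", fn)
    if (identical(timepoint, fn)) timepoint <- "unknown"
  }
  bold_session(mat, subject_id, timepoint, sampling_interval)
}

#' @rdname load_session
#' @param session A `bold_session`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "bold_session"))
  mat <- session$signals
  write_matrix_csv(mat, path, paste0("v", seq_len(ncol(mat)) - 1))
}

#' Extract region time series from a 4-D NIfTI volume
#'
#' Averages voxels label-wise per volume: the signal of atlas node `i` is
#' the mean, at each volume, of all voxels carrying integer label `i + 1`
#' in the 3-D label image (label 0 is background). This stands in for the
#' region-extraction step of standard fMRI toolboxes, applied after the
#' upstream registration which is out of scope here.
#'
#' @param volume_path 4-D NIfTI file (`.nii`/`.nii.gz`).
#' @param label_path 3-D integer-valued NIfTI label image on the same grid.
#' @param atlas A `region_atlas`; every `node_id + 1` must occur as a label.
#' @param subject_id,timepoint,sampling_interval Session metadata.
#' @return A `bold_session`.
#' @export
extract_from_nifti <- function(volume_path, label_path, atlas,
                               subject_id = "unknown", timepoint = "unknown",
                               sampling_interval = 1) {
  atlas <- validate_atlas(atlas)
  vol <- as.array(RNifti::readNifti(volume_path))
  lab <- as.array(RNifti::readNifti(label_path))
  if (length(dim(vol)) != 4) {
    stop_hubshift("volume must be 4-D (x, y, z, time)", "shape_error")
  }
  if (length(dim(lab)) != 3 || !all(dim(lab) == dim(vol)[1:3])) {
    stop_hubshift("label image grid does not match the volume's spatial grid",
                  "shape_error")
  }
  if (max(abs(lab - round(lab))) > 1e-6) {
    stop_hubshift("label image must be integer-valued", "validation_error")
  }
  lab <- as.integer(round(lab))
  n <- nrow(atlas)
  nt <- dim(vol)[4]
  vmat <- matrix(vol, ncol = nt)   # voxels x time
  signals <- matrix(NA_real_, n, nt)
  for (i in seq_len(n)) {
    idx <- which(lab == i)         # node_id i-1 carries label i
    if (length(idx) == 0) {
      stop_hubshift(sprintf("label %d (node_id %d) missing from label image",
                            i, i - 1), "coverage_error")
    }
    signals[i, ] <- colMeans(vmat[idx, , drop = FALSE])
  }
  bold_session(signals, subject_id, timepoint, sampling_interval)
}
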