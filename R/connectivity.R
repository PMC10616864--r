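#' Temporal bandpass filter specification
#'
#' The connectivity analysis restricts BOLD signals to the conventional
#' resting-state band, 0.009–0.1 Hz by default. Two designs are offered:
#' a zero-phase Butterworth (order `order`, applied forward–backward so no
#' phase lag is introduced; the default) and a hard FFT mask that zeroes
#' every Fourier bin outside the band exactly.
#'
#' @param low_hz,high_hz Passband edges in Hz; must satisfy
#'   `0 < low < high < Nyquist` for the session they are applied to.
#' @param design `"butterworth_zero_phase"` or `"fft_hard"`.
#' @param order Butterworth order (default 2; ignored by `fft_hard`).
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(low_hz = 0.009, high_hz = 0.1,
                        design = c("butterworth_zero_phase", "fft_hard"),
                        order = 2L) {
  design <- match.arg(design)
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      low_hz <= 0 || high_hz <= low_hz) {
    stop_hubshift("need 0 < low_hz < high_hz", "parameter_error")
  }
  structure(list(low_hz = low_hz, high_hz = high_hz, design = design,
                 order = as.integer(order)),
            class = "filter_spec")
}

#' Bandpass-filter a BOLD session
#'
#' Demeans each region series and applies the band limit of `spec`
#' independently per region. The Butterworth design uses
#' [signal::filtfilt()] (zero phase, squared magnitude response); the FFT
#' design zeroes out-of-band bins, including DC, so a constant series maps
#' to (numerically) zero under either design.
#'
#' @param session A `bold_session`.
#' @param spec A `filter_spec`.
#' @return A filtered `bold_session` of identical shape.
#' @export
bandpass <- function(session, spec = filter_spec()) {
  stopifnot(inherits(session, "bold_session"), inherits(spec, "filter_spec"))
  dt <- session$sampling_interval
  nyq <- 1 / (2 * dt)
  if (spec$high_hz >= nyq) {
    stop_hubshift(sprintf("high cutoff %g Hz is not below Nyquist %g Hz",
                          spec$high_hz, nyq), "parameter_error")
  }
  x <- session$signals
  nt <- ncol(x)
  if (spec$design == "butterworth_zero_phase") {
    if (nt <= 6 * spec$order) {
      stop_hubshift("too few volumes for the requested filter order",
                    "length_error")
    }
    bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq,
                         type = "pass")
    filt <- x
    for (i in seq_len(nrow(x))) {
      v <- x[i, ]
      filt[i, ] <- signal::filtfilt(bf, v - mean(v))
    }
  } else {
    xm <- t(x - rowMeans(x))                  # volumes x regions
    freqs <- (seq_len(nt) - 1) / (nt * dt)
    freqs <- pmin(freqs, 1 / dt - freqs)      # fold to [0, Nyquist]
    keep <- freqs >= spec$low_hz & freqs <= spec$high_hz
    xf <- mvfft(xm)
    xf[!keep, ] <- 0
    filt <- t(Re(mvfft(xf, inverse = TRUE)) / nt)
  }
  out <- session
  out$signals <- filt
  out$filter <- spec
  out
}

#' Connectivity matrices
#'
#' A connectivity matrix holds the pairwise Pearson correlations of a
#' session's (filtered) region series: symmetric, off-diagonal entries in
#' `[-1, 1]`, diagonal excluded (stored as `NA` and never counted by
#' strength, density or edge rules).
#'
#' @param values Symmetric numeric matrix; the diagonal is overwritten
#'   with `NA`.
#' @param subject_id,timepoint Session labels carried as metadata.
#' @param filter A `filter_spec` or `NULL`.
#' @return A `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(values, subject_id = "unknown",
                                timepoint = "unknown", filter = NULL) {
  check_square_symmetric(values, what = "connectivity")
  off <- values
  diag(off) <- 0
  if (max(abs(off)) > 1 + 1e-8) {
    stop_hubshift("off-diagonal connectivities must lie in [-1, 1]",
                  "validation_error")
  }
  diag(values) <- NA_real_
  structure(list(values = unname(values), n = nrow(values),
                 subject_id = as.character(subject_id),
                 timepoint = as.character(timepoint),
                 filter = filter),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d, subject %s, timepoint %s\n",
              x$n, x$n, x$subject_id, x$timepoint))
  invisible(x)
}

#' Pearson functional connectivity of a session
#'
#' Computes the full region-by-region Pearson correlation matrix, the
#' package's edge definition. Every region series must have nonzero
#' variance (after filtering); degenerate series are reported by node id
#' rather than propagated as `NA` edges.
#'
#' @param session A `bold_session`, normally already bandpassed.
#' @return A `connectivity_matrix`.
#' @export
pearson_connectivity <- function(session) {
  stopifnot(inherits(session, "bold_session"))
  x <- session$signals
  sds <- apply(x, 1, sd)
  bad <- which(sds < .Machine$double.eps^0.5 * (1 + max(abs(x))))
  if (length(bad) > 0) {
    stop_hubshift(paste0("zero-variance region series at node_id ",
                         paste(bad - 1, collapse = ", ")),
                  "degenerate_series_error")
  }
  r <- cor(t(x))
  r <- (r + t(r)) / 2
  r[r > 1] <- 1; r[r < -1] <- -1
  connectivity_matrix(r, session$subject_id, session$timepoint,
                      session$filter)
}

#' Filter and correlate a whole cohort
#'
#' Batch driver: bandpass each session, then compute its Pearson
#' connectivity, preserving input order. All sessions must share one
#' region count. The returned list carries a `log` attribute (a tibble of
#' subject, timepoint and filter settings per session).
#'
#' @param sessions List of `bold_session` objects.
#' @param spec A `filter_spec` applied to every session.
#' @return List of `connectivity_matrix` objects, one per session.
#' @export
cohort_connectivity <- function(sessions, spec = filter_spec()) {
  if (length(sessions) == 0) {
    warn("cohort_connectivity called with an empty session list")
    return(structure(list(), log = tibble()))
  }
  ns <- vapply(sessions, function(s) nrow(s$signals), integer(1))
  if (length(unique(ns)) != 1) {
    stop_hubshift("sessions have mixed region counts", "shape_error")
  }
  cms <- map(sessions, function(s) pearson_connectivity(bandpass(s, spec)))
  log <- tibble(
    subject = vapply(sessions, `[[`, "", "subject_id"),
    timepoint = vapply(sessions, `[[`, "", "timepoint"),
    low_hz = spec$low_hz, high_hz = spec$high_hz,
    design = spec$design, order = spec$order
  )
  structure(cms, log = log)
}

#' Read and write connectivity matrices
#'
#' Connectivity files are full square CSV matrices with `NaN` on the
#' diagonal (self-describing; symmetry is re-checked on load).
#'
#' @param cm A `connectivity_matrix`.
#' @param path CSV file path.
#' @param subject_id,timepoint Metadata for the loaded matrix; parsed from
#'   a `sub-<id>_tp-<label>` filename when `NULL`.
#' @return `load_connectivity()` returns a `connectivity_matrix`;
#'   `write_connectivity()` returns `path` invisibly.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  write_matrix_csv(cm$values, path, paste0("n", seq_len(cm$n) - 1))
}

#' @rdname write_connectivity
#' @export
load_connectivity <- function(path, subject_id = NULL, timepoint = NULL) {
  if (!file.exists(path)) {
    stop_hubshift(paste0("connectivity file not found: ", path), "io_error")
  }
  mat <- unname(as.matrix(utils::read.csv(path, header = TRUE,
                                          colClasses = "numeric")))
  diag(mat) <- NA_real_
  fn <- basename(path)
  if (is.null(subject_id)) {
    subject_id <- sub("^.*sub-([^_\\.]+).*$", "\\1", fn)
    if (identical(subject_id, fn)) subject_id <- "unknown"
  }
  if (is.null(timepoint)) {
    timepoint <- sub("^.*tp-([^_\\.]+).*$", "\\1", fn)
    if (identical(timepoint, fn)) timepoint <- "unknown"
  }
  vals <- mat
  diag(vals) <- 0
  check_square_symmetric(vals, what = "connectivity file")
  connectivity_matrix(mat, subject_id, timepoint)
}
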