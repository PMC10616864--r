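#' Canonical timepoint labels
#'
#' The default longitudinal design: one pre-injury scan and four post-injury
#' scans at 1, 3, 7 and 14 weeks post-injury (wpi). Any character vector of
#' labels is accepted throughout the package; these are the defaults the
#' synthetic cohorts use.
#'
#' @return Character vector of ordered timepoint labels.
#' @export
default_timepoints <- function() c("pre", "1wpi", "3wpi", "7wpi", "14wpi")

# Ordered factor over the label set actually present, respecting a canonical
# ordering when the labels are a subset of it.
as_timepoint <- function(x, levels = NULL) {
  if (is.null(levels)) {
    canon <- default_timepoints()
    levels <- if (all(unique(x) %in% canon)) {
      canon[canon %in% unique(x)]
    } else {
      unique(x)
    }
  }
  factor(as.character(x), levels = levels, ordered = TRUE)
}

# Deterministic per-(subject, timepoint) seed stream derived from a cohort
# seed. Linear mix modulo the Mersenne prime 2^31 - 1 keeps every derived
# seed a valid 32-bit R integer; documented as the package's stable hash.
derive_seed <- function(seed, subject_index, timepoint_index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 1000003 %% m
  s <- (s + subject_index * 98893 + timepoint_index * 10007) %% m
  as.integer(s)
}

stop_hubshift <- function(msg, class) {
  abort(msg, class = c(class, "hubshift_error"))
}

check_square_symmetric <- function(values, tol = 1e-8, what = "matrix") {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop_hubshift(sprintf("%s must be a square matrix", what), "shape_error")
  }
  off <- values
  diag(off) <- 0
  if (any(!is.finite(off))) {
    stop_hubshift(sprintf("%s has non-finite off-diagonal entries", what),
                  "data_error")
  }
  if (max(abs(off - t(off))) > tol) {
    stop_hubshift(sprintf("%s is not symmetric", what), "validation_error")
  }
  invisible(TRUE)
}

upper_pairs <- function(n) n * (n - 1) / 2

# CSV writer for numeric matrices that round-trips doubles bit-exactly
# (17 significant digits; shortest-representation writers can lose the
# final bit).
write_matrix_csv <- function(mat, path, col_names) {
  txt <- apply(mat, 1, function(row) {
    paste(sprintf("%.17g", row), collapse = ",")
  })
  writeLines(c(paste(col_names, collapse = ","), txt), path)
  invisible(path)
}

sem <- function(x) sd(x) / sqrt(length(x))
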