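#' Whole-network strength
#'
#' Strength is the total functional coupling of the network: the sum of
#' the `n(n-1)/2` unique off-diagonal connectivities, each pair counted
#' once. For the 244-region parcellation that is a sum over 29,646 pairs.
#'
#' @param cm A `connectivity_matrix`.
#' @return A single number.
#' @export
strength <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  sum(cm$values[upper.tri(cm$values)])
}

#' Weighted density
#'
#' The mean connectivity over all unique pairs:
#' `strength / (n(n-1)/2)`.
#'
#' @param cm A `connectivity_matrix`.
#' @return A single number in `[-1, 1]`.
#' @export
weighted_density <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (cm$n < 2) stop_hubshift("density needs n >= 2 nodes", "degenerate_error")
  strength(cm) / upper_pairs(cm$n)
}

#' Threshold a connectivity matrix into a binary network
#'
#' The classical network-analysis step: a pair is connected iff its signed
#' correlation withstands the threshold, `r >= threshold` (inclusive).
#' Negative correlations never become edges at the conventional threshold
#' of 0.10. The threshold is recorded in the result.
#'
#' @param cm A `connectivity_matrix`.
#' @param threshold Finite real cutoff (default 0.10).
#' @return A `binary_network`: logical symmetric adjacency (no self-edges),
#'   with `threshold`, `subject_id` and `timepoint` fields.
#' @export
binarize <- function(cm, threshold = 0.10) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (!is.numeric(threshold) || !is.finite(threshold)) {
    stop_hubshift("threshold must be finite", "parameter_error")
  }
  adj <- cm$values >= threshold
  diag(adj) <- FALSE
  structure(list(adjacency = adj, n = cm$n, threshold = threshold,
                 subject_id = cm$subject_id, timepoint = cm$timepoint),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges at threshold %g (subject %s, %s)\n",
              x$n, edge_count(x), x$threshold, x$subject_id, x$timepoint))
  invisible(x)
}

#' Edge count of a binary network
#'
#' @param bn A `binary_network`.
#' @return Number of (undirected) edges.
#' @export
edge_count <- function(bn) {
  stopifnot(inherits(bn, "binary_network"))
  sum(bn$adjacency[upper.tri(bn$adjacency)])
}

#' Binary density
#'
#' The fraction of possible connections present:
#' `edges / (n(n-1)/2)`, in `[0, 1]`.
#'
#' @param bn A `binary_network`.
#' @return A single number.
#' @export
binary_density <- function(bn) {
  stopifnot(inherits(bn, "binary_network"))
  if (bn$n < 2) stop_hubshift("density needs n >= 2 nodes", "degenerate_error")
  edge_count(bn) / upper_pairs(bn$n)
}

#' Degree centrality
#'
#' The number of edges incident to each node — the hub-function index of
#' the analysis. For an `n`-node network the attainable range is
#' `0..n-1` (0 to 243 at the 244-region parcellation). The correlation
#' graph is undirected, so in- and out-degree coincide.
#'
#' @param bn A `binary_network`.
#' @return Integer vector of length `n`, element `i` for `node_id i-1`.
#' @export
degree_centrality <- function(bn) {
  stopifnot(inherits(bn, "binary_network"))
  as.integer(rowSums(bn$adjacency))
}

#' Build a centrality panel across a cohort
#'
#' Binarizes every connectivity matrix at one common threshold and stacks
#' the degree centralities into the long node x subject x timepoint table
#' that all longitudinal statistics consume. Duplicate
#' (subject, timepoint) inputs are an error; the panel is complete by
#' construction for the sessions supplied.
#'
#' @param cms List of `connectivity_matrix` objects sharing one `n`.
#' @param threshold Binarization threshold (default 0.10).
#' @return A `centrality_panel`: a tibble with columns `node_id`,
#'   `subject`, `timepoint` (ordered factor) and `degree`, plus
#'   `n_nodes` and `threshold` attributes.
#' @export
build_centrality_panel <- function(cms, threshold = 0.10) {
  if (length(cms) == 0) stop_hubshift("no connectivity matrices", "shape_error")
  ns <- vapply(cms, `[[`, integer(1), "n")
  if (length(unique(ns)) != 1) {
    stop_hubshift("connectivity matrices have inconsistent n", "shape_error")
  }
  keys <- vapply(cms, function(cm) paste(cm$subject_id, cm$timepoint, sep = "\r"),
                 character(1))
  if (anyDuplicated(keys)) {
    stop_hubshift("duplicate (subject, timepoint) connectivity inputs",
                  "validation_error")
  }
  rows <- map(cms, function(cm) {
    deg <- degree_centrality(binarize(cm, threshold))
    tibble(node_id = seq_along(deg) - 1L,
           subject = cm$subject_id,
           timepoint = cm$timepoint,
           degree = deg)
  })
  panel <- bind_rows(rows)
  panel$timepoint <- as_timepoint(panel$timepoint)
  new_centrality_panel(panel, n_nodes = ns[1], threshold = threshold)
}

new_centrality_panel <- function(panel, n_nodes, threshold) {
  panel <- as_tibble(panel)
  attr(panel, "n_nodes") <- as.integer(n_nodes)
  attr(panel, "threshold") <- threshold
  class(panel) <- c("centrality_panel", class(tibble()))
  panel
}

#' @export
print.centrality_panel <- function(x, ...) {
  cat(sprintf("<centrality_panel> %d nodes x %d subjects x %d timepoints (threshold %g)\n",
              attr(x, "n_nodes"), length(unique(x$subject)),
              length(unique(x$timepoint)), attr(x, "threshold")))
  NextMethod()
}

#' Edge counts across a grid of thresholds
#'
#' Diagnostic sweep used to choose a working threshold: edge count and
#' binary density of one matrix at each candidate cutoff. Edge count is
#' non-increasing in the threshold.
#'
#' @param cm A `connectivity_matrix`.
#' @param thresholds Numeric vector of cutoffs.
#' @return Tibble with `threshold`, `edges`, `density`.
#' @export
threshold_sweep <- function(cm, thresholds = seq(0, 0.5, by = 0.05)) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  res <- map(thresholds, function(th) {
    bn <- binarize(cm, th)
    tibble(threshold = th, edges = edge_count(bn),
           density = binary_density(bn))
  })
  bind_rows(res)
}
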