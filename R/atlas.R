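#' Region atlas tables
#'
#' A region atlas is the node universe of every network in the package: one
#' row per functional area ("node"), with a contiguous zero-based `node_id`,
#' a nonempty `name`, a `hemisphere` label (`left`, `right` or `midline`) and
#' stereotaxic `x`, `y`, `z` coordinates in mm. The reference design uses 244
#' whole-brain areas, 122 per hemisphere.
#'
#' @param node_id Integer vector, contiguous ids `0..n-1`.
#' @param name Character vector of nonempty region names.
#' @param hemisphere Character vector over `left`, `right`, `midline`.
#' @param x,y,z Numeric coordinates (mm, atlas space).
#' @return A `region_atlas` tibble.
#' @examples
#' region_atlas(0:1, c("M1_L", "M1_R"), c("left", "right"),
#'              x = c(-1.5, 1.5), y = c(0.5, 0.5), z = c(-1, -1))
#' @export
region_atlas <- function(node_id, name, hemisphere, x, y, z) {
  atlas <- tibble(
    node_id = as.integer(node_id),
    name = as.character(name),
    hemisphere = as.character(hemisphere),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)
  )
  validate_atlas(atlas)
}

validate_atlas <- function(atlas) {
  req <- c("node_id", "name", "hemisphere", "x", "y", "z")
  missing_cols <- setdiff(req, names(atlas))
  if (length(missing_cols) > 0) {
    stop_hubshift(paste0("atlas is missing column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "format_error")
  }
  n <- nrow(atlas)
  if (n < 2) stop_hubshift("atlas needs at least 2 regions", "validation_error")
  if (anyDuplicated(atlas$node_id)) {
    stop_hubshift("duplicate node_id in atlas", "validation_error")
  }
  if (!identical(sort(as.integer(atlas$node_id)), 0:(n - 1L))) {
    stop_hubshift("node_ids must be contiguous 0..n-1", "validation_error")
  }
  if (any(is.na(atlas$name)) || any(!nzchar(atlas$name))) {
    stop_hubshift("every region name must be nonempty", "validation_error")
  }
  if (!all(atlas$hemisphere %in% c("left", "right", "midline"))) {
    stop_hubshift("hemisphere must be one of left/right/midline",
                  "validation_error")
  }
  atlas <- arrange(atlas, .data$node_id)
  class(atlas) <- c("region_atlas", class(tibble()))
  atlas
}

#' Read and write atlas tables
#'
#' Atlas files are UTF-8 CSV with one header row and columns
#' `node_id,name,hemisphere,x,y,z`. Loading validates ids (contiguous,
#' unique, zero-based), names and hemisphere labels, and never reorders:
#' row `i` of every downstream matrix corresponds to `node_id i`.
#'
#' @param path Path to the CSV file.
#' @return `load_atlas()` returns a validated `region_atlas`;
#'   `write_atlas()` returns `path` invisibly.
#' @export
load_atlas <- function(path) {
  if (!file.exists(path)) {
    stop_hubshift(paste0("atlas file not found: ", path), "io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_atlas(as_tibble(raw))
}

#' @rdname load_atlas
#' @param atlas A `region_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  atlas <- validate_atlas(atlas)
  readr::write_csv(as_tibble(atlas), path, progress = FALSE)
  invisible(path)
}

#' Per-hemisphere region counts
#'
#' @param atlas A `region_atlas`.
#' @return Named integer vector with counts for left, right and midline.
#' @export
hemisphere_counts <- function(atlas) {
  atlas <- validate_atlas(atlas)
  vapply(c(left = "left", right = "right", midline = "midline"),
         function(h) sum(atlas$hemisphere == h), integer(1))
}

#' Build a synthetic bilateral atlas
#'
#' Generates an `n_nodes`-region atlas split evenly between hemispheres
#' (`n_nodes` must be even), mirroring the 244-area / 122-per-hemisphere
#' whole-brain parcellation. The first six bilateral pairs carry the region
#' names the hub scenarios anchor on: primary and secondary motor cortex
#' (M1, M2), cingulate area A24b, caudate-putamen (Cpu), corpus
#' callosum/external capsule (ccec) and olfactory tubercle (Tu); remaining
#' regions are numbered. Coordinates are drawn reproducibly inside a
#' mouse-brain-sized bounding box (x mirrored across the midline).
#'
#' @param n_nodes Even region count (default 244).
#' @param seed Integer seed for the coordinate draw.
#' @return A `region_atlas` with `n_nodes` rows.
#' @export
synthetic_atlas <- function(n_nodes = 244, seed = 1L) {
  if (n_nodes %% 2 != 0 || n_nodes < 12) {
    stop_hubshift("n_nodes must be even and >= 12", "validation_error")
  }
  half <- n_nodes / 2
  base_names <- c("M1", "M2", "A24b", "Cpu", "ccec", "Tu")
  nm <- c(base_names, sprintf("region_%03d", seq_len(half - length(base_names))))
  set.seed(as.integer(seed))
  # one hemisphere's coordinates, mirrored in x for the other
  xs <- runif(half, 0.3, 4.5)
  ys <- runif(half, -8, 4)
  zs <- runif(half, -6, 0)
  region_atlas(
    node_id = 0:(n_nodes - 1),
    name = c(paste0(nm, "_L"), paste0(nm, "_R")),
    hemisphere = rep(c("left", "right"), each = half),
    x = c(-xs, xs), y = c(ys, ys), z = c(zs, zs)
  )
}

# Node ids of a named region (both hemispheres unless suffixed _L/_R).
atlas_node_id <- function(atlas, name) {
  hits <- atlas$node_id[atlas$name %in% name]
  if (length(hits) == 0) {
    stop_hubshift(paste0("region not in atlas: ", paste(name, collapse = ", ")),
                  "validation_error")
  }
  as.integer(hits)
}
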