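#' Node color maps
#'
#' The figure convention for node maps: hue interpolates linearly from
#' blue (240 deg) at the low end of the domain to red (0 deg) at the high
#' end, at full saturation and value; out-of-domain values clamp to the
#' endpoints. Two modes are used: `absolute` for raw degree centrality
#' (domain 0 to `n - 1`, 0–243 at full scale) and `ratio` for change
#' relative to baseline (domain 0.6–1.5).
#'
#' @param mode `"absolute"` or `"ratio"`.
#' @param domain Length-2 numeric `[lo, hi]`; defaults 0–243 (absolute)
#'   or 0.6–1.5 (ratio).
#' @return A `color_map` object.
#' @export
color_map <- function(mode = c("absolute", "ratio"), domain = NULL) {
  mode <- match.arg(mode)
  if (is.null(domain)) {
    domain <- if (mode == "absolute") c(0, 243) else c(0.6, 1.5)
  }
  if (length(domain) != 2 || domain[1] >= domain[2]) {
    stop_hubshift("domain must be [lo, hi] with lo < hi", "parameter_error")
  }
  structure(list(mode = mode, domain = domain), class = "color_map")
}

#' Map values to RGB node colors
#'
#' @param value Numeric vector.
#' @param cmap A [color_map()].
#' @return Tibble with `value`, clamped `clamped`, `hue` (degrees) and
#'   integer `r`, `g`, `b` in 0–255 plus `hex`.
#' @examples
#' color_of(c(0, 121.5, 243), color_map("absolute"))
#' @export
color_of <- function(value, cmap = color_map()) {
  stopifnot(inherits(cmap, "color_map"))
  lo <- cmap$domain[1]; hi <- cmap$domain[2]
  clamped <- pmin(pmax(value, lo), hi)
  frac <- (clamped - lo) / (hi - lo)
  hue <- 240 * (1 - frac)
  hex <- grDevices::hsv(h = hue / 360, s = 1, v = 1)
  rgb <- t(grDevices::col2rgb(hex))
  tibble(value = value, clamped = clamped, hue = hue,
         r = as.integer(rgb[, 1]), g = as.integer(rgb[, 2]),
         b = as.integer(rgb[, 3]), hex = hex)
}

matrix_long <- function(values) {
  n <- nrow(values)
  tibble(row = rep(0:(n - 1), times = n),
         col = rep(0:(n - 1), each = n),
         value = as.vector(values))
}

#' Heatmap of a connectivity matrix
#'
#' Fixed symmetric scale over `[-1, 1]`, blue for negative and red for
#' positive correlations; the excluded diagonal is blank.
#'
#' @param object A `connectivity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.connectivity_matrix <- function(object, ...) {
  df <- matrix_long(object$values)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         limits = c(-1, 1), na.value = "grey90",
                         name = "r") +
    scale_y_reverse() +
    coord_fixed() +
    labs(title = sprintf("Connectivity: subject %s, %s",
                         object$subject_id, object$timepoint),
         x = "node", y = "node") +
    theme_minimal()
}

#' Heatmap of a change matrix
#'
#' Diverging scale symmetric about zero: red for increased edges, blue
#' for decreased edges.
#'
#' @param object A `change_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.change_matrix <- function(object, ...) {
  df <- matrix_long(object$values)
  lim <- max(abs(df$value), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1e-12
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         limits = c(-lim, lim), na.value = "grey90",
                         name = "Δr") +
    scale_y_reverse() +
    coord_fixed() +
    labs(title = sprintf("Change: %s vs %s", object$timepoint,
                         object$ref_timepoint),
         x = "node", y = "node") +
    theme_minimal()
}

#' Strength / delta trajectories with SEM bars
#'
#' @param summary_df Tibble with a `timepoint` column, a value column and
#'   a `sem` column (e.g. from [strength_delta_series()] or
#'   [mean_centrality_comparison()]).
#' @param value Name of the value column (default auto-detected among
#'   `mean_delta`, `mean_centrality`, `mean_degree`).
#' @return A ggplot object.
#' @export
plot_trajectory <- function(summary_df, value = NULL) {
  if (is.null(value)) {
    value <- intersect(c("mean_delta", "mean_centrality", "mean_degree"),
                       names(summary_df))[1]
    if (is.na(value)) stop_hubshift("no value column found", "parameter_error")
  }
  ggplot(summary_df, aes(x = .data$timepoint, y = .data[[value]], group = 1)) +
    geom_line() +
    geom_point(size = 2) +
    geom_errorbar(aes(ymin = .data[[value]] - .data$sem,
                      ymax = .data[[value]] + .data$sem), width = 0.15) +
    labs(x = "timepoint", y = value) +
    theme_minimal()
}

#' Export a 3-D node scene
#'
#' Writes the authoritative, bit-stable record of a node map: a CSV of
#' `node_id, name, x, y, z, value, r, g, b, hex`. An optional static
#' rendering (two orthogonal scatter projections) is written only when an
#' image path is supplied; the CSV is always the record.
#'
#' @param atlas A `region_atlas`.
#' @param values Per-node numeric vector (length `n`).
#' @param cmap A [color_map()].
#' @param csv_path Output CSV path.
#' @param image_path Optional PNG path for the convenience rendering.
#' @return The scene tibble, invisibly.
#' @export
export_node_scene <- function(atlas, values, cmap = color_map(),
                              csv_path, image_path = NULL) {
  atlas <- validate_atlas(atlas)
  if (length(values) != nrow(atlas)) {
    stop_hubshift("values length must equal atlas size", "shape_error")
  }
  cols <- color_of(values, cmap)
  scene <- tibble(node_id = atlas$node_id, name = atlas$name,
                  x = atlas$x, y = atlas$y, z = atlas$z,
                  value = values, r = cols$r, g = cols$g, b = cols$b,
                  hex = cols$hex)
  readr::write_csv(scene, csv_path, progress = FALSE)
  if (!is.null(image_path)) {
    p <- ggplot(scene, aes(x = .data$x, y = .data$y, color = .data$hex)) +
      geom_point(size = 3) +
      scale_color_identity() +
      coord_fixed() +
      labs(title = "axial projection") +
      theme_minimal()
    ggsave(image_path, p, width = 6, height = 6, dpi = 120)
  }
  invisible(scene)
}

default_pipeline_config <- function() {
  list(
    simulate = list(n_nodes = 244, n_subjects = 10, n_volumes = 600,
                    seed = 1L),
    filter = list(low_hz = 0.009, high_hz = 0.1,
                  design = "butterworth_zero_phase", order = 2L),
    graph = list(threshold = 0.10),
    stats = list(alpha = 0.05, baseline = "pre", fdr = FALSE),
    hubs = list(k = 2, final = NULL, seeds = c("M1_L", "M1_R")),
    report = list(write_figures = FALSE)
  )
}

#' Run the whole pipeline from a configuration
#'
#' End-to-end driver: simulate (or load) a cohort, bandpass, correlate,
#' compute strength/density and the centrality panel, run the
#' longitudinal statistics, extract the motor subnetwork and the
#' hub-shift report, and write every artifact plus a manifest with full
#' parameter provenance into `out_dir`. Deterministic given the
#' configuration (including its seed).
#'
#' The configuration is a YAML file or a nested list with sections
#' `simulate` (passed to [scenario()]; alternatively `io$cohort_dir`
#' pointing at a written cohort), `filter`, `graph` (must contain
#' `threshold`), `stats`, `hubs` and `report`.
#'
#' @param config Path to a YAML file, or a list.
#' @param out_dir Output directory.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) {
    stop_hubshift("config must be a YAML path or a list", "config_error")
  }
  cfg <- modifyList(default_pipeline_config(), config)
  if (is.null(config$graph) || is.null(config$graph$threshold)) {
    stop_hubshift("config key missing: graph.threshold", "config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_hubshift(sprintf("pipeline stage '%s' failed: %s", name,
                            conditionMessage(e)), "pipeline_error")
    })
  }

  scn <- stage("simulate", do.call(scenario, cfg$simulate))
  cohort <- stage("simulate", simulate_cohort(scn))
  atlas <- cohort$atlas
  write_atlas(atlas, file.path(out_dir, "atlas.csv"))

  spec <- stage("filter", do.call(filter_spec, cfg$filter))
  cms <- stage("connectivity", cohort_connectivity(cohort$sessions, spec))
  cm_dir <- file.path(out_dir, "connectivity")
  dir.create(cm_dir, showWarnings = FALSE)
  for (cm in cms) {
    write_connectivity(cm, file.path(cm_dir, sprintf(
      "sub-%s_tp-%s.csv", sub("^sub-", "", cm$subject_id), cm$timepoint)))
  }

  th <- cfg$graph$threshold
  strengths <- strength_table(cms)
  readr::write_csv(strengths, file.path(out_dir, "strength.csv"),
                   progress = FALSE)
  baseline <- cfg$stats$baseline
  deltas_base <- strength_delta_series(strengths, "baseline", baseline)
  deltas_prev <- strength_delta_series(strengths, "previous")
  readr::write_csv(deltas_base, file.path(out_dir, "strength_delta_vs_baseline.csv"),
                   progress = FALSE)
  readr::write_csv(deltas_prev, file.path(out_dir, "strength_delta_vs_previous.csv"),
                   progress = FALSE)

  # group-mean change matrices vs baseline and vs previous
  tps <- scn$timepoints
  by_tp <- split(cms, vapply(cms, `[[`, "", "timepoint"))[tps]
  means <- lapply(by_tp, mean_connectivity)
  chg_dir <- file.path(out_dir, "change_matrices")
  dir.create(chg_dir, showWarnings = FALSE)
  for (i in seq_along(tps)) {
    tp <- tps[i]
    if (tp != baseline) {
      ch <- change_matrix(means[[tp]], means[[baseline]], "vs_baseline")
      readr::write_csv(as.data.frame(ch$values),
                       file.path(chg_dir, sprintf("tp-%s_vs_baseline.csv", tp)),
                       progress = FALSE)
    }
    if (i > 1) {
      ch <- change_matrix(means[[tp]], means[[tps[i - 1]]], "vs_previous")
      readr::write_csv(as.data.frame(ch$values),
                       file.path(chg_dir, sprintf("tp-%s_vs_previous.csv", tp)),
                       progress = FALSE)
    }
  }

  panel <- stage("metrics", build_centrality_panel(cms, th))
  readr::write_csv(as_tibble(panel), file.path(out_dir, "centrality.csv"),
                   progress = FALSE)

  meanc <- stage("stats", mean_centrality_comparison(panel, baseline))
  readr::write_csv(meanc, file.path(out_dir, "mean_centrality.csv"),
                   progress = FALSE)
  node_tests <- bind_rows(lapply(setdiff(tps, baseline), function(tp) {
    nt <- nodewise_paired_test(panel, tp, baseline, alpha = cfg$stats$alpha,
                               fdr = isTRUE(cfg$stats$fdr))
    mutate(tidy(nt), timepoint = tp)
  }))
  readr::write_csv(node_tests, file.path(out_dir, "nodewise_tests.csv"),
                   progress = FALSE)

  final <- cfg$hubs$final %||% tps[length(tps)]
  seed_ids <- atlas_node_id(atlas, cfg$hubs$seeds)
  pre_cms <- by_tp[[baseline]]
  mask <- stage("hubs", extract_motor_nodes(pre_cms, seed_ids[1:2], th))
  motor_panel <- stage("hubs", build_masked_panel(cms, mask, th))
  readr::write_csv(as_tibble(motor_panel),
                   file.path(out_dir, "motor_centrality.csv"),
                   progress = FALSE)
  report <- stage("hubs", hub_shift_report(panel, baseline, final,
                                           k = cfg$hubs$k,
                                           alpha = cfg$stats$alpha))
  write_hub_report(report, file.path(out_dir, "hub_shift_report.json"))

  # node scenes: absolute centrality at baseline/final, ratio at final
  mean_deg <- function(tp) {
    df <- filter(as_tibble(panel), as.character(.data$timepoint) == tp)
    df %>% group_by(.data$node_id) %>%
      summarise(v = mean(.data$degree), .groups = "drop") %>%
      arrange(.data$node_id) %>% pull(.data$v)
  }
  cmap_abs <- color_map("absolute", c(0, scn$n_nodes - 1))
  export_node_scene(atlas, mean_deg(baseline), cmap_abs,
                    file.path(out_dir, sprintf("scene_centrality_%s.csv", baseline)))
  export_node_scene(atlas, mean_deg(final), cmap_abs,
                    file.path(out_dir, sprintf("scene_centrality_%s.csv", final)))
  ratios <- centrality_ratio(panel, baseline) %>%
    filter(as.character(.data$timepoint) == final, !.data$undefined) %>%
    group_by(.data$node_id) %>%
    summarise(v = mean(.data$ratio), .groups = "drop")
  rv <- rep(NA_real_, scn$n_nodes)
  rv[ratios$node_id + 1] <- ratios$v
  rv[is.na(rv)] <- 1
  export_node_scene(atlas, rv, color_map("ratio"),
                    file.path(out_dir, sprintf("scene_ratio_%s.csv", final)))

  if (isTRUE(cfg$report$write_figures) && capabilities("png")) {
    fig_dir <- file.path(out_dir, "figures")
    dir.create(fig_dir, showWarnings = FALSE)
    ggsave(file.path(fig_dir, "strength_delta.png"),
           plot_trajectory(deltas_base), width = 6, height = 4, dpi = 120)
    ggsave(file.path(fig_dir, "mean_centrality.png"),
           plot_trajectory(meanc), width = 6, height = 4, dpi = 120)
  }

  manifest <- list(
    parameters = cfg,
    seed = scn$seed,
    n_sessions = length(cms),
    timepoints = tps,
    motor_mask_union_size = sum(mask$group_union),
    outputs = sort(list.files(out_dir, recursive = TRUE))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
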