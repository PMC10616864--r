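#' Extract the motor-related node set from pre-injury connectivity
#'
#' Seeds the subnetwork on the left and right primary motor cortex: a node
#' belongs to a subject's motor mask iff its pre-injury connectivity to at
#' least one of the two M1 seeds withstands the threshold
#' (`max(r(j, seedL), r(j, seedR)) >= threshold`, inclusive, consistent
#' with [binarize()]). Seeds always belong to their own mask. The group
#' mask is the union over subjects: a node is excluded only when it is
#' sub-threshold to both seeds in every individual.
#'
#' @param pre_cms List of per-subject pre-injury `connectivity_matrix`
#'   objects.
#' @param seed_ids Integer pair of node ids (left and right M1).
#' @param threshold Seed-connectivity cutoff (default 0.10).
#' @return A `motor_node_mask`: logical `subject_masks` matrix
#'   (nodes x subjects), `group_union` vector, `seed_ids`, `threshold`.
#' @export
extract_motor_nodes <- function(pre_cms, seed_ids, threshold = 0.10) {
  if (length(pre_cms) == 0) stop_hubshift("no pre-injury matrices", "shape_error")
  n <- pre_cms[[1]]$n
  seed_ids <- as.integer(seed_ids)
  if (length(seed_ids) != 2 || any(seed_ids < 0) || any(seed_ids >= n)) {
    stop_hubshift("seed_ids must be two node ids in 0..n-1", "validation_error")
  }
  masks <- vapply(pre_cms, function(cm) {
    if (cm$n != n) stop_hubshift("matrices of mixed size", "shape_error")
    r_seed <- pmax(cm$values[seed_ids[1] + 1, ], cm$values[seed_ids[2] + 1, ])
    m <- !is.na(r_seed) & r_seed >= threshold
    m[seed_ids + 1] <- TRUE
    m
  }, logical(n))
  masks <- matrix(masks, nrow = n,
                  dimnames = list(NULL, vapply(pre_cms, `[[`, "", "subject_id")))
  structure(list(subject_masks = masks,
                 group_union = rowSums(masks) > 0,
                 seed_ids = seed_ids, threshold = threshold, n = n),
            class = "motor_node_mask")
}

#' @export
print.motor_node_mask <- function(x, ...) {
  cat(sprintf("<motor_node_mask> seeds %d/%d at threshold %g: %d of %d nodes in group union\n",
              x$seed_ids[1], x$seed_ids[2], x$threshold,
              sum(x$group_union), x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.motor_node_mask <- function(x, ...) {
  m <- x$subject_masks
  tibble(node_id = rep(0:(x$n - 1), ncol(m)),
         subject = rep(colnames(m), each = x$n),
         included = as.vector(m))
}

#' Degree centrality on a masked subgraph
#'
#' Degree computed on the subgraph induced by the masked-in nodes;
#' masked-out nodes are reported as `NA` (missing, not zero). With a full
#' mask this is exactly [degree_centrality()].
#'
#' @param bn A `binary_network`.
#' @param mask Logical vector of length `n` (`TRUE` = keep).
#' @return Numeric vector of length `n`, `NA` where masked out.
#' @export
masked_degree_centrality <- function(bn, mask) {
  stopifnot(inherits(bn, "binary_network"))
  mask <- as.logical(mask)
  if (length(mask) != bn$n) {
    stop_hubshift("mask length must equal node count", "shape_error")
  }
  if (!any(mask)) stop_hubshift("mask excludes every node", "degenerate_error")
  adj <- bn$adjacency
  adj[!mask, ] <- FALSE
  adj[, !mask] <- FALSE
  deg <- rowSums(adj)
  deg[!mask] <- NA_real_
  deg
}

#' Build a centrality panel restricted to each subject's motor mask
#'
#' Like [build_centrality_panel()] but degree is computed on each
#' subject's own induced motor subgraph (that subject's pre-injury mask),
#' so a node's centrality counts only edges to nodes motor-related in
#' that individual. Masked-out nodes carry `NA` degree.
#'
#' @param cms List of `connectivity_matrix` objects.
#' @param mask A `motor_node_mask` whose subject columns cover the
#'   matrices' subjects.
#' @param threshold Binarization threshold (default 0.10).
#' @return A `centrality_panel` (with possible `NA` degrees).
#' @export
build_masked_panel <- function(cms, mask, threshold = 0.10) {
  stopifnot(inherits(mask, "motor_node_mask"))
  rows <- map(cms, function(cm) {
    subj <- cm$subject_id
    if (!subj %in% colnames(mask$subject_masks)) {
      stop_hubshift(paste0("no motor mask for subject ", subj),
                    "validation_error")
    }
    deg <- masked_degree_centrality(binarize(cm, threshold),
                                    mask$subject_masks[, subj])
    tibble(node_id = seq_along(deg) - 1L, subject = subj,
           timepoint = cm$timepoint, degree = deg)
  })
  panel <- bind_rows(rows)
  panel$timepoint <- as_timepoint(panel$timepoint)
  new_centrality_panel(panel, n_nodes = cms[[1]]$n, threshold = threshold)
}

#' Centrality ratio against baseline
#'
#' Per node per subject, degree at each timepoint divided by degree at
#' the baseline (so the baseline column is identically 1). Ratios are
#' undefined where the baseline degree is 0; these are flagged
#' (`undefined = TRUE`, ratio `NA`) and excluded from summaries rather
#' than treated as errors.
#'
#' @param panel A `centrality_panel`.
#' @param baseline Baseline timepoint label (default `"pre"`).
#' @return Tibble with `node_id`, `subject`, `timepoint`, `degree`,
#'   `baseline_degree`, `ratio`, `undefined`.
#' @export
centrality_ratio <- function(panel, baseline = "pre") {
  stopifnot(inherits(panel, "centrality_panel"))
  df <- as_tibble(panel)
  base <- df %>%
    filter(as.character(.data$timepoint) == !!baseline) %>%
    select("node_id", "subject", baseline_degree = "degree")
  if (nrow(base) == 0) {
    stop_hubshift(paste0("baseline timepoint not present: ", baseline),
                  "validation_error")
  }
  out <- left_join(df, base, by = c("node_id", "subject")) %>%
    mutate(undefined = is.na(.data$baseline_degree) | .data$baseline_degree == 0,
           ratio = ifelse(.data$undefined, NA_real_,
                          .data$degree / .data$baseline_degree))
  as_tibble(out)
}

#' High-centrality (hub) nodes at one timepoint
#'
#' The hub rule: average each node's degree across subjects at the chosen
#' timepoint, then keep nodes whose mean degree exceeds the cross-node
#' grand mean by more than `k` cross-node standard deviations
#' (`mean + k*SD`, `k = 2` by default — "approximately 2 SD above
#' average"). Invariant under node relabeling.
#'
#' @param panel A `centrality_panel`.
#' @param timepoint Timepoint label at which hubs are assessed.
#' @param k SD multiplier (> 0; default 2).
#' @return A `hub_set`: `node_ids`, `cutoff`, `k`, `timepoint` and the
#'   per-node mean degrees the cutoff was derived from.
#' @export
high_centrality_nodes <- function(panel, timepoint, k = 2) {
  stopifnot(inherits(panel, "centrality_panel"))
  if (!is.numeric(k) || k <= 0) stop_hubshift("k must be > 0", "parameter_error")
  df <- filter(as_tibble(panel),
               as.character(.data$timepoint) == !!timepoint)
  if (nrow(df) == 0) {
    stop_hubshift(paste0("timepoint not in panel: ", timepoint),
                  "validation_error")
  }
  node_means <- df %>%
    filter(!is.na(.data$degree)) %>%
    group_by(.data$node_id) %>%
    summarise(mean_degree = mean(.data$degree), .groups = "drop")
  s <- sd(node_means$mean_degree)
  if (!is.finite(s) || s == 0) {
    warn("degenerate cross-node SD; empty hub set")
    cutoff <- Inf
  } else {
    cutoff <- mean(node_means$mean_degree) + k * s
  }
  ids <- node_means$node_id[node_means$mean_degree > cutoff]
  structure(list(node_ids = as.integer(ids), cutoff = cutoff, k = k,
                 timepoint = timepoint, node_means = node_means),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("<hub_set> %d node(s) above mean + %g*SD (= %.3f) at %s: %s\n",
              length(x$node_ids), x$k, x$cutoff, x$timepoint,
              paste(x$node_ids, collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hub_set <- function(x, ...) {
  mutate(x$node_means, is_hub = .data$node_id %in% x$node_ids,
         cutoff = x$cutoff, timepoint = x$timepoint)
}

hub_trajectory <- function(panel, node_ids, baseline) {
  if (length(node_ids) == 0) {
    tps <- levels(panel$timepoint)
    return(tibble(timepoint = as_timepoint(tps, levels = tps),
                  mean_degree = NA_real_, sem = NA_real_,
                  statistic = NA_real_, p_value = NA_real_))
  }
  df <- as_tibble(panel) %>%
    filter(.data$node_id %in% node_ids, !is.na(.data$degree)) %>%
    group_by(.data$subject, .data$timepoint) %>%
    summarise(mean_degree = mean(.data$degree), .groups = "drop")
  tps <- levels(df$timepoint)
  wide <- tidyr::pivot_wider(df, names_from = "timepoint",
                             values_from = "mean_degree")
  res <- map(tps, function(tp) {
    v <- wide[[tp]]
    row <- tibble(timepoint = tp, mean_degree = mean(v), sem = sem(v),
                  statistic = NA_real_, p_value = NA_real_)
    if (tp != baseline) {
      ht <- paired_t(v, wide[[baseline]])
      row$statistic <- ht$statistic
      row$p_value <- ht$p_value
    }
    row
  })
  out <- bind_rows(res)
  out$timepoint <- as_timepoint(out$timepoint, levels = tps)
  out
}

#' Hub-shift report
#'
#' The package's summary of where hub function sits before injury and
#' where it has moved by the final timepoint: the baseline hub set (high
#' centrality at `baseline`) with its full trajectory and paired tests
#' vs. baseline, the final hub set (high centrality at `final`) likewise,
#' the overlap between the two sets, and the significance calls at the
#' final timepoint. A cortical-to-subcortical shift appears as a
#' significant decline of the baseline set with no decline of the final
#' set.
#'
#' @param panel A `centrality_panel`.
#' @param baseline,final Timepoint labels (defaults `"pre"`, `"14wpi"`).
#' @param k SD multiplier for the hub rule (default 2).
#' @param alpha Significance level for the decline calls (default 0.05).
#' @return A `hub_shift_report` list: `baseline_hubs`, `final_hubs`
#'   (`hub_set`s), `baseline_trajectory`, `final_trajectory` (tibbles),
#'   `overlap` (ids, Jaccard), `calls` (decline/non-decline logicals),
#'   `params`.
#' @export
hub_shift_report <- function(panel, baseline = "pre", final = "14wpi",
                             k = 2, alpha = 0.05) {
  stopifnot(inherits(panel, "centrality_panel"))
  base_hubs <- high_centrality_nodes(panel, baseline, k)
  final_hubs <- high_centrality_nodes(panel, final, k)
  traj_b <- hub_trajectory(panel, base_hubs$node_ids, baseline)
  traj_f <- hub_trajectory(panel, final_hubs$node_ids, baseline)
  at_final <- function(traj) traj[as.character(traj$timepoint) == final, ]
  fb <- at_final(traj_b); ff <- at_final(traj_f)
  base_at_base <- traj_b$mean_degree[as.character(traj_b$timepoint) == baseline]
  final_at_base <- traj_f$mean_degree[as.character(traj_f$timepoint) == baseline]
  inter <- intersect(base_hubs$node_ids, final_hubs$node_ids)
  uni <- union(base_hubs$node_ids, final_hubs$node_ids)
  calls <- list(
    baseline_hubs_decline =
      isTRUE(fb$p_value < alpha && fb$mean_degree < base_at_base),
    final_hubs_decline =
      isTRUE(ff$p_value < alpha && ff$mean_degree < final_at_base)
  )
  structure(
    list(baseline_hubs = base_hubs, final_hubs = final_hubs,
         baseline_trajectory = traj_b, final_trajectory = traj_f,
         overlap = list(node_ids = inter,
                        jaccard = if (length(uni)) length(inter) / length(uni) else NA_real_),
         calls = calls,
         params = list(baseline = baseline, final = final, k = k,
                       alpha = alpha)),
    class = "hub_shift_report"
  )
}

#' @export
print.hub_shift_report <- function(x, ...) {
  cat("<hub_shift_report>\n")
  cat(sprintf("  baseline (%s) hubs: %s\n", x$params$baseline,
              paste(x$baseline_hubs$node_ids, collapse = ", ")))
  cat(sprintf("  final (%s) hubs:    %s\n", x$params$final,
              paste(x$final_hubs$node_ids, collapse = ", ")))
  cat(sprintf("  overlap Jaccard: %.3f\n", x$overlap$jaccard))
  cat(sprintf("  baseline hubs decline at %s: %s; final hubs decline: %s\n",
              x$params$final, x$calls$baseline_hubs_decline,
              x$calls$final_hubs_decline))
  invisible(x)
}

#' Serialize and restore hub-shift reports
#'
#' JSON round trip for the report (hub memberships, cutoffs, trajectories,
#' calls); `read_hub_report(write_hub_report(x, p))` reproduces every
#' reported number.
#'
#' @param report A `hub_shift_report`.
#' @param path JSON file path.
#' @return `write_hub_report()` returns `path` invisibly;
#'   `read_hub_report()` the restored `hub_shift_report`.
#' @export
write_hub_report <- function(report, path) {
  stopifnot(inherits(report, "hub_shift_report"))
  ser_hub <- function(h) list(node_ids = h$node_ids, cutoff = h$cutoff,
                              k = h$k, timepoint = h$timepoint,
                              node_means = h$node_means)
  ser_traj <- function(tr) mutate(tr, timepoint = as.character(.data$timepoint))
  payload <- list(
    baseline_hubs = ser_hub(report$baseline_hubs),
    final_hubs = ser_hub(report$final_hubs),
    baseline_trajectory = ser_traj(report$baseline_trajectory),
    final_trajectory = ser_traj(report$final_trajectory),
    overlap = report$overlap,
    calls = report$calls,
    params = report$params
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_hub_report
#' @export
read_hub_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_hub <- function(h) {
    structure(list(node_ids = as.integer(h$node_ids %||% integer(0)),
                   cutoff = h$cutoff, k = h$k, timepoint = h$timepoint,
                   node_means = as_tibble(h$node_means)),
              class = "hub_set")
  }
  de_traj <- function(tr) {
    tr <- as_tibble(tr)
    tr$timepoint <- as_timepoint(tr$timepoint)
    tr
  }
  structure(
    list(baseline_hubs = de_hub(p$baseline_hubs),
         final_hubs = de_hub(p$final_hubs),
         baseline_trajectory = de_traj(p$baseline_trajectory),
         final_trajectory = de_traj(p$final_trajectory),
         overlap = list(node_ids = as.integer(p$overlap$node_ids %||% integer(0)),
                        jaccard = p$overlap$jaccard),
         calls = lapply(p$calls, isTRUE),
         params = p$params),
    class = "hub_shift_report"
  )
}
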