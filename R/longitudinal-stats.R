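#' Per-session strength table
#'
#' Tabulates whole-network strength for every matrix of a cohort; the
#' substrate of the longitudinal strength trajectories.
#'
#' @param cms List of `connectivity_matrix` objects.
#' @return Tibble with `subject`, `timepoint` (ordered factor), `strength`.
#' @export
strength_table <- function(cms) {
  res <- bind_rows(map(cms, function(cm) {
    tibble(subject = cm$subject_id, timepoint = cm$timepoint,
           strength = strength(cm))
  }))
  res$timepoint <- as_timepoint(res$timepoint)
  res
}

#' Connectivity change matrix
#'
#' Entrywise difference between two (typically cohort-mean) connectivity
#' matrices: positive entries are edges that strengthened relative to the
#' reference, negative entries edges that weakened. Linear, so
#' `strength(change) == strength(cm_t) - strength(cm_ref)` and differences
#' chain across timepoints.
#'
#' @param cm_t,cm_ref `connectivity_matrix` objects of equal size, the
#'   reference typically pre-injury (`vs_baseline`) or the previous
#'   timepoint (`vs_previous`).
#' @param reference Which comparison this difference represents.
#' @return A `change_matrix`: symmetric `values` plus the timepoint pair.
#' @export
change_matrix <- function(cm_t, cm_ref,
                          reference = c("vs_baseline", "vs_previous")) {
  stopifnot(inherits(cm_t, "connectivity_matrix"),
            inherits(cm_ref, "connectivity_matrix"))
  reference <- match.arg(reference)
  if (cm_t$n != cm_ref$n) {
    stop_hubshift("change_matrix: operand sizes differ", "shape_error")
  }
  vals <- cm_t$values - cm_ref$values
  structure(list(values = vals, n = cm_t$n, reference = reference,
                 timepoint = cm_t$timepoint, ref_timepoint = cm_ref$timepoint),
            class = "change_matrix")
}

#' @export
print.change_matrix <- function(x, ...) {
  cat(sprintf("<change_matrix> %d x %d: %s minus %s (%s)\n",
              x$n, x$n, x$timepoint, x$ref_timepoint, x$reference))
  invisible(x)
}

#' Mean connectivity matrix of a group
#'
#' Entrywise cross-subject mean of per-subject matrices at one timepoint,
#' the aggregation used for group-level matrices and change matrices.
#'
#' @param cms List of `connectivity_matrix` objects (one per subject).
#' @return A `connectivity_matrix` with subject id `"group-mean"`.
#' @export
mean_connectivity <- function(cms) {
  if (length(cms) == 0) stop_hubshift("no matrices to average", "shape_error")
  ns <- vapply(cms, `[[`, integer(1), "n")
  if (length(unique(ns)) != 1) {
    stop_hubshift("matrices of mixed size", "shape_error")
  }
  acc <- Reduce(`+`, map(cms, function(cm) {
    v <- cm$values; diag(v) <- 0; v
  })) / length(cms)
  diag(acc) <- NA_real_
  connectivity_matrix(acc, "group-mean", cms[[1]]$timepoint)
}

#' Strength change trajectory
#'
#' Per-subject strength differences against a reference — either the fixed
#' baseline timepoint or, for `reference = "previous"`, each timepoint's
#' predecessor — summarised across subjects as mean and SEM. Differences
#' are taken within subject first; the cross-subject summary comes second.
#'
#' @param strengths Tibble from [strength_table()] (columns `subject`,
#'   `timepoint`, `strength`); every subject must be present at every
#'   timepoint (missing cells are dropped pairwise with a warning).
#' @param reference `"pre"`-style baseline label, or `"previous"`.
#' @param baseline Baseline label used when `reference != "previous"`.
#' @return Tibble with `timepoint`, `reference_timepoint`, `mean_delta`,
#'   `sem`, `n_subjects`.
#' @export
strength_delta_series <- function(strengths, reference = "baseline",
                                  baseline = "pre") {
  stopifnot(all(c("subject", "timepoint", "strength") %in% names(strengths)))
  strengths <- mutate(strengths, timepoint = as_timepoint(.data$timepoint))
  tps <- levels(strengths$timepoint)
  tab <- tidyr::pivot_wider(strengths, names_from = "timepoint",
                            values_from = "strength")
  if (anyNA(tab)) {
    warn("subjects missing at some timepoints; affected pairs are masked")
  }
  is_prev <- identical(reference, "previous")
  if (!is_prev && !baseline %in% tps) {
    stop_hubshift(paste0("baseline timepoint not present: ", baseline),
                  "validation_error")
  }
  targets <- if (is_prev) tps[-1] else tps
  res <- map(targets, function(tp) {
    ref_tp <- if (is_prev) tps[match(tp, tps) - 1] else baseline
    d <- tab[[tp]] - tab[[ref_tp]]
    d <- d[is.finite(d)]
    tibble(timepoint = tp, reference_timepoint = ref_tp,
           mean_delta = mean(d), sem = sem(d), n_subjects = length(d))
  })
  out <- bind_rows(res)
  out$timepoint <- as_timepoint(out$timepoint, levels = tps)
  out
}

# Closed-form-compatible paired t via stats::t.test, with the degenerate
# (zero-variance-difference) case flagged instead of thrown.
paired_t <- function(x, y) {
  d <- x - y
  if (length(d) < 2 || sd(d) < .Machine$double.eps^0.5 * (1 + max(abs(d)))) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                mean_diff = mean(d), n = length(d), degenerate = TRUE))
  }
  ht <- t.test(x, y, paired = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       mean_diff = mean(d), n = length(d), degenerate = FALSE)
}

#' Node-wise paired tests of degree centrality
#'
#' For every node, a two-sided paired t-test of degree at `timepoint`
#' against `baseline` across subjects. A node's direction is `increase`
#' (`decrease`) when its mean paired difference is positive (negative) and
#' its p-value clears `alpha`; nodes with zero-variance differences are
#' flagged `none` with an undefined statistic. Raw p-values are used by
#' default, matching the convention of reporting per-node significance
#' counts without correction; `fdr = TRUE` switches the significance calls
#' to Benjamini–Hochberg-adjusted p-values (reported in `p_adjusted`).
#'
#' @param panel A `centrality_panel`.
#' @param timepoint,baseline Timepoint labels to compare.
#' @param alpha Two-sided significance level (default 0.05).
#' @param fdr Apply Benjamini–Hochberg correction to the calls.
#' @return A `nodewise_test` tibble: `node_id`, `statistic`, `p_value`,
#'   (`p_adjusted` when `fdr`), `mean_diff`, `direction`, `n_pairs`;
#'   significant increase/decrease counts are in `glance()`.
#' @export
nodewise_paired_test <- function(panel, timepoint, baseline, alpha = 0.05,
                                 fdr = FALSE) {
  stopifnot(inherits(panel, "centrality_panel"))
  wide <- panel_pairs(panel, timepoint, baseline)
  if (length(unique(wide$subject)) < 3) {
    stop_hubshift("node-wise tests need >= 3 subjects with both timepoints",
                  "insufficient_data_error")
  }
  res <- wide %>%
    group_by(.data$node_id) %>%
    summarise(test = list(paired_t(.data$at_t, .data$at_ref)), .groups = "drop")
  out <- tibble(
    node_id = res$node_id,
    statistic = map_dbl(res$test, "statistic"),
    p_value = map_dbl(res$test, "p_value"),
    mean_diff = map_dbl(res$test, "mean_diff"),
    n_pairs = as.integer(map_dbl(res$test, "n"))
  )
  p_eff <- out$p_value
  if (fdr) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    p_eff <- out$p_adjusted
  }
  out$direction <- dplyr::case_when(
    is.na(p_eff) ~ "none",
    p_eff < alpha & out$mean_diff > 0 ~ "increase",
    p_eff < alpha & out$mean_diff < 0 ~ "decrease",
    TRUE ~ "none"
  )
  attr(out, "timepoint") <- timepoint
  attr(out, "baseline") <- baseline
  attr(out, "alpha") <- alpha
  attr(out, "fdr") <- fdr
  class(out) <- c("nodewise_test", class(tibble()))
  out
}

panel_pairs <- function(panel, timepoint, baseline) {
  tps <- as.character(unique(panel$timepoint))
  for (tp in c(timepoint, baseline)) {
    if (!tp %in% tps) {
      stop_hubshift(paste0("timepoint not in panel: ", tp), "validation_error")
    }
  }
  a <- filter(panel, as.character(.data$timepoint) == !!timepoint) %>%
    select("node_id", "subject", at_t = "degree")
  b <- filter(panel, as.character(.data$timepoint) == !!baseline) %>%
    select("node_id", "subject", at_ref = "degree")
  inner <- dplyr::inner_join(as_tibble(a), as_tibble(b),
                             by = c("node_id", "subject"))
  inner[stats::complete.cases(inner), ]
}

#' @exportS3Method generics::tidy
tidy.nodewise_test <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @exportS3Method generics::glance
glance.nodewise_test <- function(x, ...) {
  tibble(
    timepoint = attr(x, "timepoint"),
    baseline = attr(x, "baseline"),
    alpha = attr(x, "alpha"),
    n_nodes = nrow(x),
    n_increase = sum(x$direction == "increase"),
    n_decrease = sum(x$direction == "decrease"),
    n_flagged_degenerate = sum(is.na(x$statistic))
  )
}

#' Mean centrality per timepoint with paired tests vs. baseline
#'
#' Collapses the panel to one mean degree per subject per timepoint (mean
#' over all nodes), then summarises across subjects (mean, SEM) and runs a
#' paired t-test of every timepoint against the baseline. The grand mean
#' of the panel equals the mean of these subject means at each timepoint.
#'
#' @param panel A complete `centrality_panel`.
#' @param baseline Baseline timepoint label (default `"pre"`).
#' @return Tibble with `timepoint`, `mean_centrality`, `sem`, `statistic`,
#'   `p_value` (`NA` statistic at the baseline itself and for degenerate
#'   differences).
#' @export
mean_centrality_comparison <- function(panel, baseline = "pre") {
  stopifnot(inherits(panel, "centrality_panel"))
  per_subject <- panel %>%
    as_tibble() %>%
    group_by(.data$subject, .data$timepoint) %>%
    summarise(mean_degree = mean(.data$degree), .groups = "drop")
  if (length(unique(per_subject$subject)) < 2) {
    stop_hubshift("mean-centrality comparison needs >= 2 subjects",
                  "insufficient_data_error")
  }
  tps <- levels(per_subject$timepoint)
  if (!baseline %in% tps) {
    stop_hubshift(paste0("baseline timepoint not present: ", baseline),
                  "validation_error")
  }
  wide <- tidyr::pivot_wider(per_subject, names_from = "timepoint",
                             values_from = "mean_degree")
  res <- map(tps, function(tp) {
    v <- wide[[tp]]
    row <- tibble(timepoint = tp, mean_centrality = mean(v), sem = sem(v),
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

#' Mixed repeated-measures comparison of two cohorts
#'
#' Two-way mixed ANOVA on node-set mean centrality: `group` is the
#' between-subject factor (e.g. two injury models), `timepoint` the
#' within-subject factor. Each panel is first collapsed to one value per
#' subject per timepoint (mean degree over `node_ids`, or all nodes).
#' Uses the classical `aov` decomposition with
#' `Error(subject/timepoint)` and no sphericity correction.
#'
#' @param panel_a,panel_b `centrality_panel` objects for the two groups;
#'   timepoint label sets must match and designs must be balanced.
#' @param node_ids_a,node_ids_b Optional node subsets (default all nodes).
#' @param group_labels Length-2 character vector naming the groups.
#' @return An `rm_anova` object; `tidy()` gives one row per term
#'   (`group`, `timepoint`, `group:timepoint`) with `df`, `statistic` (F)
#'   and `p_value`.
#' @export
group_rm_comparison <- function(panel_a, panel_b,
                                node_ids_a = NULL, node_ids_b = NULL,
                                group_labels = c("A", "B")) {
  stopifnot(inherits(panel_a, "centrality_panel"),
            inherits(panel_b, "centrality_panel"))
  collapse <- function(panel, ids, grp) {
    df <- as_tibble(panel)
    if (!is.null(ids)) df <- filter(df, .data$node_id %in% ids)
    df %>%
      group_by(.data$subject, .data$timepoint) %>%
      summarise(value = mean(.data$degree), .groups = "drop") %>%
      mutate(group = grp)
  }
  a <- collapse(panel_a, node_ids_a, group_labels[1])
  b <- collapse(panel_b, node_ids_b, group_labels[2])
  tps_a <- sort(as.character(unique(a$timepoint)))
  tps_b <- sort(as.character(unique(b$timepoint)))
  if (!identical(tps_a, tps_b)) {
    stop_hubshift("the two panels must share identical timepoint labels",
                  "validation_error")
  }
  if (length(tps_a) < 2) {
    stop_hubshift("repeated-measures comparison needs >= 2 timepoints",
                  "validation_error")
  }
  dat <- bind_rows(a, b)
  # distinct subjects across groups, by construction of the uid
  dat$subject_uid <- factor(paste(dat$group, dat$subject, sep = ":"))
  dat$group <- factor(dat$group)
  dat$time_f <- factor(as.character(dat$timepoint))
  cells <- table(dat$subject_uid, dat$time_f)
  if (any(cells != 1)) {
    stop_hubshift("unbalanced design: every subject needs exactly one value per timepoint",
                  "validation_error")
  }
  fit <- aov(value ~ group * time_f + Error(subject_uid / time_f), data = dat)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject_uid"]][[1]])
  within <- as.data.frame(sm[["Error: subject_uid:time_f"]][[1]])
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    tibble(term = term, df = tab$Df[i], statistic = tab$`F value`[i],
           p_value = tab$`Pr(>F)`[i])
  }
  out <- bind_rows(pick(between, "group"),
                   pick(within, "time_f"),
                   pick(within, "group:time_f"))
  out$term <- c("group", "timepoint", "group:timepoint")
  structure(list(table = out, fit = fit, data = dat,
                 group_labels = group_labels),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("<rm_anova> mixed two-way (between: group; within: timepoint)\n")
  print(x$table)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rm_anova <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.rm_anova <- function(x, ...) {
  tibble(
    n_subjects = length(unique(x$data$subject_uid)),
    n_timepoints = length(unique(x$data$time_f)),
    group_p = x$table$p_value[x$table$term == "group"],
    interaction_p = x$table$p_value[x$table$term == "group:timepoint"]
  )
}
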