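test_that("change matrices are entrywise differences and linear in strength", {
  a <- random_cm(10, seed = 1, timepoint = "1wpi")
  b <- random_cm(10, seed = 2, timepoint = "pre")
  ch <- change_matrix(a, b)
  expect_equal(ch$values[2, 5], a$values[2, 5] - b$values[2, 5])
  expect_equal(ch$values, t(ch$values))

  zero <- change_matrix(a, a)
  expect_true(all(zero$values[!diag(10)] == 0))

  # strength linearity
  str_ch <- sum(ch$values[upper.tri(ch$values)])
  expect_equal(str_ch, strength(a) - strength(b), tolerance = 1e-10)

  # chaining: delta(a, c) = delta(a, b) + delta(b, c)
  c3 <- random_cm(10, seed = 3, timepoint = "3wpi")
  lhs <- change_matrix(a, c3)$values
  rhs <- change_matrix(a, b)$values + change_matrix(b, c3)$values
  expect_equal(lhs[!diag(10)], rhs[!diag(10)], tolerance = 1e-12)

  expect_error(change_matrix(a, random_cm(9, seed = 4)), class = "shape_error")
})

test_that("group mean connectivity averages entrywise", {
  cms <- lapply(1:4, function(i) random_cm(6, seed = i, subject = paste0("s", i)))
  m <- mean_connectivity(cms)
  manual <- Reduce(`+`, lapply(cms, function(cm) {
    v <- cm$values; diag(v) <- 0; v
  })) / 4
  got <- m$values; diag(got) <- 0
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("strength delta series summarises within-subject differences", {
  strengths <- tibble::tibble(
    subject = rep(c("s1", "s2"), each = 2),
    timepoint = rep(c("pre", "1wpi"), 2),
    strength = c(10, 11, 20, 23)
  )
  out <- strength_delta_series(strengths, baseline = "pre")
  row <- out[out$timepoint == "1wpi", ]
  expect_equal(row$mean_delta, 2)   # deltas +1, +3
  expect_equal(row$sem, 1)
  expect_equal(out$mean_delta[out$timepoint == "pre"], 0)

  prev <- strength_delta_series(strengths, reference = "previous")
  expect_equal(prev$mean_delta, 2)
  expect_equal(prev$reference_timepoint, "pre")
})

test_that("the paired t statistic matches its closed form", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    x <- rnorm(n, 5, 2); y <- rnorm(n, 4, 2)
    d <- x - y
    t_closed <- mean(d) / (sd(d) / sqrt(n))
    p_closed <- 2 * stats::pt(-abs(t_closed), df = n - 1)
    got <- hubshift:::paired_t(x, y)
    expect_equal(got$statistic, t_closed, tolerance = 1e-10)
    expect_equal(got$p_value, p_closed, tolerance = 1e-10)
  }
})

test_that("node-wise paired tests flag planted declines and nothing under no change", {
  # 8 nodes x 5 subjects x 2 timepoints; node 2 declines by ~10, others vary
  set.seed(32)
  base <- matrix(sample(30:60, 8 * 5, TRUE), 8, 5)
  deg <- array(0, c(8, 5, 2))
  deg[, , 1] <- base
  noise <- matrix(sample(-2:2, 8 * 5, TRUE), 8, 5)
  deg[, , 2] <- base + noise
  deg[3, , 2] <- base[3, ] + c(-10, -12, -9, -11, -10)
  panel <- panel_from_array(deg, c("pre", "14wpi"))
  res <- nodewise_paired_test(panel, "14wpi", "pre", alpha = 0.05)
  expect_equal(res$direction[res$node_id == 2], "decrease")
  expect_lt(res$p_value[res$node_id == 2], 0.01)
  # hand check of that node's t statistic
  d <- c(-10, -12, -9, -11, -10)
  expect_equal(res$statistic[res$node_id == 2],
               mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-10)
  g <- glance(res)
  expect_equal(g$n_decrease, 1L)

  # identical panels: nothing significant, degenerate nodes flagged "none"
  same <- array(base, c(8, 5, 2))
  panel0 <- panel_from_array(same, c("pre", "14wpi"))
  res0 <- nodewise_paired_test(panel0, "14wpi", "pre")
  expect_true(all(res0$direction == "none"))
  expect_equal(glance(res0)$n_increase + glance(res0)$n_decrease, 0L)

  # BH-corrected calls are never more numerous than raw calls
  res_fdr <- nodewise_paired_test(panel, "14wpi", "pre", fdr = TRUE)
  expect_lte(sum(res_fdr$direction != "none"), sum(res$direction != "none"))
  expect_true(all(res_fdr$p_adjusted >= res_fdr$p_value, na.rm = TRUE))
})

test_that("mean centrality comparison works subject-first", {
  set.seed(33)
  base <- matrix(sample(40:80, 10 * 6, TRUE), 10, 6)
  deg <- array(0, c(10, 6, 2))
  deg[, , 1] <- base
  deg[, , 2] <- round(base / 2)   # halved at the final timepoint
  panel <- panel_from_array(deg, c("pre", "14wpi"))
  out <- mean_centrality_comparison(panel, "pre")
  expect_equal(out$mean_centrality[out$timepoint == "pre"], mean(base))
  final <- out[out$timepoint == "14wpi", ]
  expect_lt(final$p_value, 0.01)
  expect_lt(final$mean_centrality, out$mean_centrality[out$timepoint == "pre"])

  # grand-mean identity: mean of subject means equals the panel grand mean
  expect_equal(final$mean_centrality, mean(round(base / 2)))

  # constant panel: difference degenerate, flagged undefined
  const <- array(50, c(4, 5, 2))
  panelc <- panel_from_array(const, c("pre", "14wpi"))
  outc <- mean_centrality_comparison(panelc, "pre")
  expect_true(is.na(outc$p_value[outc$timepoint == "14wpi"]))
})

test_that("mixed repeated-measures ANOVA matches a textbook SS decomposition", {
  # 2 groups x 2 timepoints x 3 subjects, hand-checkable
  deg_a <- array(c(10, 12, 14,   11, 13, 18), c(1, 3, 2))
  deg_b <- array(c(9, 11, 13,    20, 24, 25), c(1, 3, 2))
  pa <- panel_from_array(deg_a, c("pre", "14wpi"))
  pb <- panel_from_array(deg_b, c("pre", "14wpi"))
  fit <- group_rm_comparison(pa, pb)
  tab <- tidy(fit)

  # independent decomposition from explicit sums of squares
  y <- array(NA_real_, c(2, 3, 2))    # group x subject x time
  y[1, , ] <- deg_a[1, , ]
  y[2, , ] <- deg_b[1, , ]
  gm <- mean(y)
  subj_m <- apply(y, c(1, 2), mean)
  grp_m <- apply(y, 1, mean)
  time_m <- apply(y, 3, mean)
  cell_m <- apply(y, c(1, 3), mean)
  n_s <- 3; n_t <- 2; n_g <- 2
  ss_group <- n_s * n_t * sum((grp_m - gm)^2)
  ss_subj_within <- n_t * sum((subj_m - grp_m[row(subj_m)])^2)
  ss_time <- n_s * n_g * sum((time_m - gm)^2)
  # interaction SS via cell means: sum over cells of (cell - group - time + grand)^2
  ss_int <- n_s * sum((cell_m - matrix(grp_m, n_g, n_t) -
                         matrix(time_m, n_g, n_t, byrow = TRUE) + gm)^2)
  ss_total <- sum((y - gm)^2)
  ss_err_within <- ss_total - ss_group - ss_subj_within - ss_time - ss_int
  f_group <- (ss_group / (n_g - 1)) / (ss_subj_within / (n_g * (n_s - 1)))
  f_time <- (ss_time / (n_t - 1)) /
    (ss_err_within / (n_g * (n_s - 1) * (n_t - 1)))
  f_int <- (ss_int / ((n_g - 1) * (n_t - 1))) /
    (ss_err_within / (n_g * (n_s - 1) * (n_t - 1)))

  expect_equal(tab$statistic[tab$term == "group"], f_group, tolerance = 1e-8)
  expect_equal(tab$statistic[tab$term == "timepoint"], f_time, tolerance = 1e-8)
  expect_equal(tab$statistic[tab$term == "group:timepoint"], f_int,
               tolerance = 1e-8)
})

test_that("identical cohorts yield a null group effect and designs are validated", {
  set.seed(34)
  deg <- array(sample(20:60, 5 * 4 * 3, TRUE), c(5, 4, 3))
  p1 <- panel_from_array(deg, c("pre", "1wpi", "14wpi"))
  fit <- group_rm_comparison(p1, p1)
  tab <- tidy(fit)
  expect_lt(tab$statistic[tab$term == "group"], 1e-10)
  expect_gt(tab$p_value[tab$term == "group"], 0.99)

  single <- panel_from_array(deg[, , 1, drop = FALSE], "pre")
  expect_error(group_rm_comparison(p1, single), class = "validation_error")

  mismatched <- panel_from_array(deg[, , 1:2], c("pre", "7wpi"))
  expect_error(group_rm_comparison(p1, mismatched), class = "validation_error")
})

test_that("opposite planted trends produce a strong interaction", {
  set.seed(35)
  n_node <- 6; n_sub <- 10
  base <- matrix(rnorm(n_node * n_sub, 50, 3), n_node, n_sub)
  declining <- array(c(base, base - 12 + rnorm(n_node * n_sub, 0, 2)),
                     c(n_node, n_sub, 2))
  rising <- array(c(base, base + 12 + rnorm(n_node * n_sub, 0, 2)),
                  c(n_node, n_sub, 2))
  pa <- panel_from_array(declining, c("pre", "14wpi"))
  pb <- panel_from_array(rising, c("pre", "14wpi"))
  tab <- tidy(group_rm_comparison(pa, pb))
  expect_lt(tab$p_value[tab$term == "group:timepoint"], 0.001)
})
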