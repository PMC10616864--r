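test_that("target matrices reduce to identity at zero levels and respect hub geometry", {
  scn0 <- scenario(n_nodes = 20, timepoints = "pre",
                   motor_hub_ids = c(0, 1), subcortical_hub_ids = c(3, 4),
                   motor_corr = 0, subcortical_corr = 0,
                   background_corr = 0, global_burst = 0, seed = 1)
  expect_equal(build_target_matrix(scn0, "pre"), diag(20),
               ignore_attr = TRUE)

  # star correlation matrix: one hub at level c over zero background is PSD
  # iff c <= 1/sqrt(n - 1); the analytic minimal eigenvalue is 1 - c*sqrt(n-1)
  star_scn <- function(c) {
    scenario(n_nodes = 20, timepoints = "pre", motor_hub_ids = 5L,
             subcortical_hub_ids = integer(0),
             motor_corr = c, subcortical_corr = numeric(0),
             background_corr = 0, global_burst = 0, psd_tol = 1, seed = 1)
  }
  c_crit <- 1 / sqrt(19)
  below <- build_target_matrix(star_scn(c_crit - 0.02), "pre")
  expect_equal(attr(below, "psd_max_shift"), 0)
  raw_star <- diag(20); raw_star[6, ] <- raw_star[, 6] <- c_crit - 0.02
  diag(raw_star) <- 1
  expect_equal(min(eigen(raw_star, symmetric = TRUE)$values),
               1 - (c_crit - 0.02) * sqrt(19), tolerance = 1e-10)
  above <- build_target_matrix(star_scn(c_crit + 0.05), "pre")
  expect_gt(attr(above, "psd_max_shift"), 0)
})

test_that("default hub schedules shift row means from motor to subcortical", {
  scn <- desk_scenario(seed = 2)
  pre <- build_target_matrix(scn, "pre")
  fin <- build_target_matrix(scn, "14wpi")
  rm_pre <- rowMeans(pre - diag(diag(pre)))
  rm_fin <- rowMeans(fin - diag(diag(fin)))
  mo <- scn$motor_hub_ids + 1
  sc <- scn$subcortical_hub_ids + 1
  expect_true(all(rm_fin[mo] < rm_pre[mo]))
  expect_true(all(rm_fin[sc] > rm_pre[sc]))
  # the burst raises the background at 1wpi
  burst <- build_target_matrix(scn, "1wpi")
  bg <- setdiff(seq_len(scn$n_nodes), c(mo, sc))
  expect_gt(mean(burst[bg, bg][upper.tri(burst[bg, bg])]),
            mean(pre[bg, bg][upper.tri(pre[bg, bg])]))
})

test_that("PSD repair stays within tolerance at desk and full scale", {
  for (n in c(60, 244)) {
    scn <- scenario(n_nodes = n, seed = 3)
    for (tp in scn$timepoints) {
      m <- build_target_matrix(scn, tp)
      expect_lte(attr(m, "psd_max_shift"), scn$psd_tol)
      ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-8)
      expect_equal(diag(m), rep(1, n))
    }
  }
})

test_that("sessions are bit-deterministic given seeds", {
  scn <- scenario(n_nodes = 20, n_volumes = 100, timepoints = "pre",
                  motor_corr = 0.2, subcortical_corr = 0.15,
                  motor_hub_ids = c(0, 1), subcortical_hub_ids = c(3, 4),
                  seed = 5)
  tg <- build_target_matrix(scn, "pre")
  s1 <- simulate_session(tg, scn, 123)
  s2 <- simulate_session(tg, scn, 123)
  expect_identical(s1$signals, s2$signals)
  s3 <- simulate_session(tg, scn, 124)
  expect_false(identical(s1$signals, s3$signals))
})

test_that("simulated correlations converge to the target", {
  # single planted pair at r = 0.5, no noise, no autocorrelation
  scn <- scenario(n_nodes = 12, n_volumes = 5000, timepoints = "pre",
                  motor_hub_ids = integer(0), subcortical_hub_ids = integer(0),
                  motor_corr = numeric(0), subcortical_corr = numeric(0),
                  background_corr = 0, global_burst = 0,
                  ar_coeff = 0, noise_sd = 0, seed = 6)
  tg <- diag(12)
  tg[1, 2] <- tg[2, 1] <- 0.5
  s <- simulate_session(tg, scn, 99)
  r <- cor(s$signals[1, ], s$signals[2, ])
  expect_lt(abs(r - 0.5), 0.05)   # ~3 Fisher-z SEs at 5000 samples

  # identity target: null correlations at the 3/sqrt(T) scale
  s0 <- simulate_session(diag(12), scn, 100)
  c0 <- cor(t(s0$signals))
  expect_lt(mean(abs(c0[upper.tri(c0)])), 3 / sqrt(5000))
})

test_that("cross-subject mean correlation approaches the repaired target matrix", {
  scn <- scenario(n_nodes = 20, n_subjects = 3, n_volumes = 5000,
                  timepoints = "pre",
                  motor_hub_ids = c(0, 1), subcortical_hub_ids = c(3, 4),
                  motor_corr = 0.25, subcortical_corr = 0.15,
                  background_corr = 0.10, global_burst = 0,
                  ar_coeff = 0.3, noise_sd = 0, seed = 7)
  tg <- build_target_matrix(scn, "pre")
  cms <- lapply(1:3, function(i) {
    s <- simulate_session(tg, scn, 200 + i, subject_id = paste0("s", i))
    pearson_connectivity(s)$values
  })
  avg <- Reduce(`+`, lapply(cms, function(m) { diag(m) <- 0; m })) / 3
  ref <- tg; diag(ref) <- 0
  expect_lt(max(abs(avg - ref)), 0.05)
})

test_that("cohorts are reproducible and carry their ground truth", {
  scn <- scenario(n_nodes = 16, n_subjects = 2, n_volumes = 50,
                  timepoints = c("pre", "14wpi"),
                  motor_hub_ids = c(0, 1), subcortical_hub_ids = c(3, 4),
                  motor_corr = c(0.2, 0.1), subcortical_corr = c(0.1, 0.2),
                  seed = 8)
  c1 <- simulate_cohort(scn)
  c2 <- simulate_cohort(scn)
  expect_length(c1$sessions, 4)
  expect_equal(dim(c1$sessions[[1]]$signals), c(16, 50))
  expect_identical(lapply(c1$sessions, `[[`, "signals"),
                   lapply(c2$sessions, `[[`, "signals"))
  expect_named(c1$ground_truth$targets, c("pre", "14wpi"))
  expect_equal(c1$ground_truth$motor_hub_ids, c(0L, 1L))

  # different cohort seed changes the data
  c3 <- simulate_cohort(scenario(n_nodes = 16, n_subjects = 2, n_volumes = 50,
                                 timepoints = c("pre", "14wpi"),
                                 motor_hub_ids = c(0, 1),
                                 subcortical_hub_ids = c(3, 4),
                                 motor_corr = c(0.2, 0.1),
                                 subcortical_corr = c(0.1, 0.2), seed = 9))
  expect_false(identical(c1$sessions[[1]]$signals, c3$sessions[[1]]$signals))
})

test_that("written cohorts reload into identical session matrices", {
  scn <- scenario(n_nodes = 12, n_subjects = 2, n_volumes = 30,
                  timepoints = c("pre", "14wpi"),
                  motor_hub_ids = c(0, 1), subcortical_hub_ids = c(3, 4),
                  motor_corr = c(0.2, 0.1), subcortical_corr = c(0.1, 0.2),
                  seed = 10)
  cohort <- simulate_cohort(scn)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  atlas <- load_atlas(file.path(dir, "atlas.csv"))
  expect_equal(nrow(atlas), 12)
  s <- load_session(file.path(dir, "sub-01_tp-pre.csv"), atlas)
  expect_identical(s$signals, cohort$sessions[["sub-01_pre"]]$signals)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$motor_hub_ids, c(0L, 1L))
})

test_that("scenario validation rejects inconsistent inputs", {
  expect_error(scenario(motor_hub_ids = c(0, 1), subcortical_hub_ids = c(1, 2)),
               class = "scenario_error")
  expect_error(scenario(motor_corr = c(0.2, 0.1)), class = "scenario_error")
  expect_error(scenario(background_corr = c(0.1, 0.2)),
               class = "scenario_error")
  expect_error(scenario(ar_coeff = 1.2), class = "scenario_error")
  expect_error(scenario(motor_hub_ids = c(0, 500)), class = "scenario_error")
  # infeasible levels beyond the repair tolerance are refused
  scn_bad <- scenario(n_nodes = 60, timepoints = "pre",
                      motor_hub_ids = 0:5, subcortical_hub_ids = 6:11,
                      motor_corr = 0.6, subcortical_corr = 0.5,
                      background_corr = 0.05, seed = 11)
  expect_error(build_target_matrix(scn_bad, "pre"), class = "scenario_error")
})
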