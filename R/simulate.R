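#' Synthetic cohort scenario
#'
#' Describes a multi-subject, multi-timepoint synthetic BOLD cohort with a
#' planted, time-shifting hub structure: a motor-cortical hub set whose
#' hub-to-network correlation declines over the post-injury timepoints and
#' a subcortical hub set whose correlation rises, on a weak positive
#' background with a transient global elevation ("burst") at the first
#' post-injury scan. The default scale matches the reference acquisition:
#' 244 regions, 600 volumes at 1 s sampling, 10 subjects, five timepoints
#' (pre, 1, 3, 7, 14 wpi).
#'
#' @param n_nodes Region count (even; default 244).
#' @param n_subjects Subjects per cohort (default 10).
#' @param timepoints Ordered timepoint labels.
#' @param n_volumes Volumes per session (default 600).
#' @param sampling_interval Seconds per volume (default 1).
#' @param motor_hub_ids,subcortical_hub_ids Disjoint node-id sets; defaults
#'   are the bilateral M1/M2 and Cpu/ccec nodes of [synthetic_atlas()].
#' @param motor_corr,subcortical_corr Hub-to-network correlation per
#'   timepoint (same length as `timepoints`); defaults decline
#'   0.23 to 0.12 (motor) and rise 0.13 to 0.22 (subcortical). Raising a
#'   node's correlation to the whole network is geometrically limited —
#'   too high a hub-to-all level over a weak background cannot be
#'   embedded in any valid correlation matrix — so the defaults sit just
#'   inside what the PSD repair tolerance `psd_tol` admits at full
#'   (244-node) scale, making the planted effect as large as the
#'   geometry allows.
#' @param background_corr Baseline pairwise correlation: a scalar, or one
#'   value per timepoint. The default (for the default timepoints)
#'   declines slightly late after injury, `0.12, 0.12, 0.12, 0.11, 0.10`,
#'   so whole-network strength ends below its pre-injury level;
#'   otherwise a flat 0.12.
#' @param global_burst Added to the background at `burst_timepoint`
#'   (default +0.08 at `"1wpi"`), the transient post-injury
#'   hyperconnectivity.
#' @param ar_coeff AR(1) temporal autocorrelation of the latent signal
#'   (default 0.3).
#' @param noise_sd White measurement-noise SD on unit-variance signals
#'   (default 0.3).
#' @param psd_tol Maximum entry change tolerated when repairing a target
#'   matrix to positive semi-definiteness (default 0.05).
#' @param seed Integer cohort seed; fully determines the cohort.
#' @return A `scenario` object (includes the generated atlas).
#' @export
scenario <- function(n_nodes = 244, n_subjects = 10,
                     timepoints = default_timepoints(),
                     n_volumes = 600, sampling_interval = 1,
                     motor_hub_ids = NULL, subcortical_hub_ids = NULL,
                     motor_corr = c(0.23, 0.20, 0.17, 0.14, 0.12),
                     subcortical_corr = c(0.13, 0.15, 0.18, 0.20, 0.22),
                     background_corr = NULL, global_burst = 0.08,
                     burst_timepoint = "1wpi", ar_coeff = 0.3,
                     noise_sd = 0.3, psd_tol = 0.05, seed = 1L) {
  atlas <- synthetic_atlas(n_nodes, seed = seed)
  half <- n_nodes / 2
  if (is.null(motor_hub_ids)) {
    motor_hub_ids <- c(0:1, half + 0:1)            # M1, M2 bilaterally
  }
  if (is.null(subcortical_hub_ids)) {
    subcortical_hub_ids <- c(3:4, half + 3:4)      # Cpu, ccec bilaterally
  }
  motor_hub_ids <- as.integer(motor_hub_ids)
  subcortical_hub_ids <- as.integer(subcortical_hub_ids)
  nt <- length(timepoints)
  if (length(motor_hub_ids) > 0 && length(motor_corr) != nt ||
      length(subcortical_hub_ids) > 0 && length(subcortical_corr) != nt) {
    stop_hubshift("hub correlation schedules must have one level per timepoint",
                  "scenario_error")
  }
  if (is.null(background_corr)) {
    background_corr <- if (identical(as.character(timepoints),
                                     default_timepoints())) {
      c(0.12, 0.12, 0.12, 0.11, 0.10)
    } else {
      0.12
    }
  }
  if (length(background_corr) == 1) background_corr <- rep(background_corr, nt)
  if (length(background_corr) != nt) {
    stop_hubshift("background_corr must be a scalar or one value per timepoint",
                  "scenario_error")
  }
  background_corr <- setNames(background_corr, timepoints)
  if (length(intersect(motor_hub_ids, subcortical_hub_ids)) > 0) {
    stop_hubshift("hub sets must be disjoint", "scenario_error")
  }
  all_ids <- c(motor_hub_ids, subcortical_hub_ids)
  if (length(all_ids) > 0 && (min(all_ids) < 0 || max(all_ids) >= n_nodes)) {
    stop_hubshift("hub ids out of range", "scenario_error")
  }
  lv <- c(motor_corr, subcortical_corr, background_corr,
          max(background_corr) + global_burst)
  if (any(abs(lv) >= 1)) {
    stop_hubshift("all target correlation levels must lie in (-1, 1)",
                  "scenario_error")
  }
  if (!is.numeric(ar_coeff) || abs(ar_coeff) >= 1) {
    stop_hubshift("ar_coeff must lie in (-1, 1)", "scenario_error")
  }
  structure(
    list(n_nodes = as.integer(n_nodes), n_subjects = as.integer(n_subjects),
         timepoints = as.character(timepoints),
         n_volumes = as.integer(n_volumes),
         sampling_interval = sampling_interval,
         motor_hub_ids = motor_hub_ids,
         subcortical_hub_ids = subcortical_hub_ids,
         motor_corr = setNames(motor_corr, timepoints[seq_along(motor_corr)]),
         subcortical_corr = setNames(subcortical_corr,
                                     timepoints[seq_along(subcortical_corr)]),
         background_corr = background_corr, global_burst = global_burst,
         burst_timepoint = burst_timepoint, ar_coeff = ar_coeff,
         noise_sd = noise_sd, psd_tol = psd_tol, seed = as.integer(seed),
         atlas = atlas),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %d nodes x %d volumes, %d subjects x %d timepoints (seed %d)\n",
              x$n_nodes, x$n_volumes, x$n_subjects, length(x$timepoints),
              x$seed))
  cat(sprintf("  motor hubs (%d): %s | subcortical hubs (%d): %s\n",
              length(x$motor_hub_ids), paste(x$motor_hub_ids, collapse = ","),
              length(x$subcortical_hub_ids),
              paste(x$subcortical_hub_ids, collapse = ",")))
  invisible(x)
}

#' Desk-scale and null scenario presets
#'
#' `desk_scenario()` is the default hub-shift scenario at the reduced
#' scale used for fast simulation studies (60 nodes, 300 volumes; all
#' other settings as in [scenario()]). `null_scenario()` plants no change
#' at all — flat background correlation, no hub sets, no burst — and is
#' the reference for type-I-error calibration of the node-wise tests.
#'
#' @param seed Integer cohort seed.
#' @param n_nodes,n_volumes,n_subjects Scale overrides.
#' @param timepoints Timepoint labels (`null_scenario()` defaults to a
#'   pre/final pair).
#' @param ... Passed on to [scenario()].
#' @return A `scenario`.
#' @export
desk_scenario <- function(seed = 1L, n_nodes = 60, n_volumes = 300, ...) {
  scenario(n_nodes = n_nodes, n_volumes = n_volumes, seed = seed, ...)
}

#' @rdname desk_scenario
#' @export
null_scenario <- function(seed = 1L, n_nodes = 60, n_volumes = 300,
                          n_subjects = 10, timepoints = c("pre", "14wpi"),
                          ...) {
  scenario(n_nodes = n_nodes, n_volumes = n_volumes, n_subjects = n_subjects,
           timepoints = timepoints,
           motor_hub_ids = integer(0), subcortical_hub_ids = integer(0),
           motor_corr = numeric(0), subcortical_corr = numeric(0),
           global_burst = 0, seed = seed, ...)
}

#' Target correlation matrix of a scenario at one timepoint
#'
#' Entry (i, j) is the background level (plus the global burst at the
#' burst timepoint), raised to the motor or subcortical hub level wherever
#' node i or j belongs to that hub set; where several levels apply, the
#' maximum wins. The unit-diagonal matrix is then projected to the nearest
#' positive semi-definite correlation matrix by eigenvalue clipping and
#' diagonal rescaling; the largest entry shift of that repair is recorded
#' in the `"psd_max_shift"` attribute and must not exceed the scenario's
#' `psd_tol`.
#'
#' @param scn A `scenario`.
#' @param timepoint One of the scenario's timepoint labels.
#' @return An `n x n` correlation matrix (PSD, unit diagonal).
#' @export
build_target_matrix <- function(scn, timepoint) {
  stopifnot(inherits(scn, "scenario"))
  if (!timepoint %in% scn$timepoints) {
    stop_hubshift(paste0("unknown timepoint: ", timepoint), "scenario_error")
  }
  n <- scn$n_nodes
  b <- scn$background_corr[[timepoint]] +
    if (identical(timepoint, scn$burst_timepoint)) scn$global_burst else 0
  node_level <- rep(-Inf, n)
  if (length(scn$motor_hub_ids) > 0) {
    node_level[scn$motor_hub_ids + 1] <- scn$motor_corr[[timepoint]]
  }
  if (length(scn$subcortical_hub_ids) > 0) {
    node_level[scn$subcortical_hub_ids + 1] <-
      pmax(node_level[scn$subcortical_hub_ids + 1],
           scn$subcortical_corr[[timepoint]])
  }
  m <- pmax(outer(node_level, node_level, pmax), b)
  diag(m) <- 1
  repaired <- nearest_psd_correlation(m)
  shift <- attr(repaired, "psd_max_shift")
  if (shift > scn$psd_tol) {
    stop_hubshift(sprintf(
      "infeasible correlation levels: PSD repair moved an entry by %.3f (> %.3f)",
      shift, scn$psd_tol), "scenario_error")
  }
  repaired
}

#' Project a symmetric matrix to the nearest PSD correlation matrix
#'
#' Eigenvalue clipping: negative eigenvalues are raised to a small
#' positive floor, the matrix is reconstructed and rescaled to unit
#' diagonal. Already-PSD inputs are returned unchanged (shift 0). The
#' maximum absolute entry change is attached as `"psd_max_shift"`.
#'
#' @param m Symmetric matrix with unit diagonal.
#' @param eig_floor Eigenvalue floor (default `1e-6`).
#' @return PSD correlation matrix with a `"psd_max_shift"` attribute.
#' @export
nearest_psd_correlation <- function(m, eig_floor = 1e-6) {
  check_square_symmetric(m, what = "target")
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= 0) {
    attr(m, "psd_max_shift") <- 0
    return(m)
  }
  vals <- pmax(e$values, eig_floor)
  rep_m <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(rep_m))
  rep_m <- rep_m / tcrossprod(d)
  rep_m <- (rep_m + t(rep_m)) / 2
  diag(rep_m) <- 1
  attr(rep_m, "psd_max_shift") <- max(abs(rep_m - m))
  rep_m
}

#' Simulate one BOLD session from a target correlation matrix
#'
#' Draws a stationary zero-mean Gaussian AR(1) process whose
#' cross-sectional covariance is exactly `target` (innovations shaped by
#' the Cholesky factor of `target`, AR coefficient from the scenario),
#' then adds white measurement noise of SD `noise_sd`. Bit-deterministic
#' given `subject_seed`.
#'
#' @param target PSD correlation matrix (`n_nodes` square).
#' @param scn A `scenario` (supplies `n_volumes`, `ar_coeff`, `noise_sd`,
#'   `sampling_interval`).
#' @param subject_seed Integer seed for this session's draw.
#' @param subject_id,timepoint Session labels.
#' @return A `bold_session`.
#' @export
simulate_session <- function(target, scn, subject_seed,
                             subject_id = "sim", timepoint = "pre") {
  stopifnot(inherits(scn, "scenario"))
  n <- nrow(target)
  ch <- tryCatch(chol(target + diag(1e-10, n)),
                 error = function(e) stop_hubshift(
                   "target matrix is not positive semi-definite", "scenario_error"))
  nt <- scn$n_volumes
  phi <- scn$ar_coeff
  set.seed(as.integer(subject_seed))
  innov <- matrix(rnorm(nt * n), nt, n) %*% ch      # rows ~ N(0, target)
  x <- matrix(0, nt, n)
  x[1, ] <- innov[1, ]
  if (nt > 1) {
    sc <- sqrt(1 - phi^2)
    for (t in 2:nt) x[t, ] <- phi * x[t - 1, ] + sc * innov[t, ]
  }
  y <- x + scn$noise_sd * matrix(rnorm(nt * n), nt, n)
  bold_session(t(y), subject_id, timepoint, scn$sampling_interval)
}

#' Simulate a full cohort with ground truth
#'
#' One session per subject x timepoint, each drawn with a seed derived
#' reproducibly from the scenario seed, plus the ground truth needed to
#' score recovery: the per-timepoint (repaired) target matrices, planted
#' hub memberships, and the expected direction of the strength trajectory.
#'
#' @param scn A `scenario`.
#' @return A `synthetic_cohort` list: `sessions` (subject-major list of
#'   `bold_session`s), `atlas`, `ground_truth`, `scenario`.
#' @export
simulate_cohort <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  targets <- lapply(setNames(scn$timepoints, scn$timepoints),
                    function(tp) build_target_matrix(scn, tp))
  subjects <- sprintf("sub-%02d", seq_len(scn$n_subjects))
  sessions <- list()
  for (si in seq_along(subjects)) {
    for (ti in seq_along(scn$timepoints)) {
      tp <- scn$timepoints[ti]
      s <- simulate_session(targets[[tp]], scn,
                            derive_seed(scn$seed, si, ti),
                            subject_id = subjects[si], timepoint = tp)
      sessions[[paste(subjects[si], tp, sep = "_")]] <- s
    }
  }
  gt <- list(
    targets = targets,
    motor_hub_ids = scn$motor_hub_ids,
    subcortical_hub_ids = scn$subcortical_hub_ids,
    psd_max_shift = vapply(targets, function(m) attr(m, "psd_max_shift"),
                           numeric(1)),
    expected_strength_trend = list(
      burst_timepoint = scn$burst_timepoint,
      rises_at_burst = scn$global_burst > 0,
      final_below_baseline = length(scn$motor_hub_ids) > 0
    )
  )
  structure(list(sessions = sessions, atlas = scn$atlas,
                 ground_truth = gt, scenario = scn),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d sessions (%d subjects x %d timepoints), %d nodes\n",
              length(x$sessions), x$scenario$n_subjects,
              length(x$scenario$timepoints), x$scenario$n_nodes))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Emits the atlas CSV, one session CSV per subject x timepoint
#' (`sub-XX_tp-<label>.csv`) and `ground_truth.json` into a directory.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.csv"))
  for (s in cohort$sessions) {
    write_session(s, file.path(dir, sprintf("sub-%s_tp-%s.csv",
                                            sub("^sub-", "", s$subject_id),
                                            s$timepoint)))
  }
  gt <- cohort$ground_truth
  gt$targets <- lapply(gt$targets, function(m) {
    attr(m, "psd_max_shift") <- NULL
    unname(m)
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
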