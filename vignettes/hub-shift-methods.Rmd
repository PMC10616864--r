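---
title: "Methods: longitudinal connectivity networks and the hub-shift analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal connectivity networks and the hub-shift analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hubshift)
```

## The model and its assumptions

The pipeline treats each scanning session as an `n × T` matrix of
region-wise BOLD signals (one row per atlas node, one column per
volume). Analysis proceeds in four stages.

**1. Temporal bandpass.** Each region series is demeaned and restricted
to 0.009–0.1 Hz, the conventional resting-state band. The default
design is a second-order Butterworth applied forward–backward
(`signal::filtfilt`), which is zero-phase: a causal filter would lag
every series and the lag would leak into the pairwise correlations. A
hard FFT mask (`design = "fft_hard"`) is provided as an exact
alternative for response tests. The band-edge behaviour differs
slightly between the two (the Butterworth's squared magnitude rolls
off smoothly; the mask is brick-wall); both pass a 0.05 Hz tone at
≥ 90 % amplitude and attenuate 0.2 Hz to ≤ 20 %, which the test suite
verifies against an FFT amplitude oracle. Filtering assumes a uniform
sampling interval (TR; 1 s by default) and a Nyquist frequency above
the upper cutoff.

**2. Pearson connectivity.** The edge weight between two nodes is the
plain Pearson correlation of their filtered series — *not* Fisher-z
transformed, so every value lies in [−1, 1] and whole-network sums are
directly interpretable. The diagonal is excluded (stored as `NA`) and
never enters strength, density, or edge counts. Zero-variance series
are an error that names the offending node: silently propagating `NA`
edges would corrupt every downstream panel. No global-signal or
nuisance regression is applied; the pipeline starts from
already-preprocessed region series.

**3. Graph measures.** `strength()` sums the `n(n−1)/2` unique pairs
(29,646 at `n = 244`); `weighted_density()` is their mean;
`binarize()` keeps signed correlations with `r ≥ θ` (inclusive, see
below); `degree_centrality()` counts incident edges per node, so its
range is 0 to `n − 1` (0–243 at full scale). Correlation matrices are
symmetric, so degree is undirected.

**4. Longitudinal statistics.** All comparisons aggregate
within-subject first: per-subject strength deltas, per-subject mean
degree, per-subject hub-set means. Cross-subject summaries are mean ±
SEM, significance is a two-sided paired t-test against the baseline
timepoint, and the between-cohort comparison is a classical two-way
mixed ANOVA (`aov` with `Error(subject/time)`; between-subject factor
group, within-subject factor time) without sphericity correction.
Node-wise tests are *uncorrected* by default because the analysis
reports raw per-node significance counts; a Benjamini–Hochberg flag
(`fdr = TRUE`) is available.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `filter.low_hz`, `filter.high_hz` | 0.009, 0.1 | Hz | analysis band |
| `filter.order` | 2 | — | Butterworth order (doubled by filtfilt) |
| `threshold` (θ) | 0.10 | r | binarization and seed-connectivity cutoff |
| `alpha` | 0.05 | — | two-sided significance level |
| `k` | 2 | SD | hub rule `mean + k·SD` |
| `sampling_interval` | 1 | s | TR |

θ = 0.10 is the conventional working point of this analysis family;
`threshold_sweep()` exposes the edge-count/density curve for choosing a
different one, with no reference values attached. The hub rule's
"approximately 2 SD above average" is implemented as exactly `k = 2`
with `k` configurable, since "approximately" marks the cutoff as a
parameter, not a constant.

## Decisions taken where the design was open

- **Inclusive, signed thresholding.** An edge exists iff `r ≥ θ`.
  Equality is kept (the tie-break is arbitrary but must be fixed and
  documented); negative correlations never become edges at a positive
  θ. The motor-seed rule uses the same inclusive ≥ on
  `max(r(j, M1_L), r(j, M1_R))`.
- **Motor-subnetwork masks.** A node joins a *subject's* mask if its
  pre-injury connectivity to either M1 seed clears θ in that subject;
  the *group* set is the union (a node is excluded only if
  sub-threshold in every individual). Per-subject centrality uses the
  subject's own mask (`build_masked_panel()`); both readings of the
  extraction rule are thereby honoured.
- **Group-level matrices** (figures, change matrices) are entrywise
  cross-subject means of per-subject matrices — the conventional
  aggregation when a single matrix per timepoint is displayed for a
  cohort.
- **Ratio summaries** average per-subject ratios (degree at t over
  degree at baseline), not ratios of means; zero baselines are flagged
  undefined and excluded from summaries rather than fatal.
- **Degenerate statistics.** Zero-variance paired differences yield an
  undefined t statistic: the node is flagged `direction = "none"`
  instead of erroring, and a uniform panel yields an empty hub set
  with a warning (the `mean + k·SD` cutoff is meaningless at zero SD).

## What the synthetic generator emulates — and what it does not

`scenario()` describes a cohort by its *target correlation structure*
per timepoint: a weak positive background `b(t)` (default 0.12,
declining slightly to 0.10 by the final timepoint), a transient global
burst (+0.08) at 1 wpi, and two disjoint planted hub sets whose
correlation-to-network levels move in opposite directions — motor
(bilateral M1/M2) declining 0.23 → 0.12, subcortical (bilateral
Cpu/cc-ec) rising 0.13 → 0.22. Where several levels apply to a pair
the maximum wins. Sessions are drawn from a stationary Gaussian AR(1)
process whose cross-sectional covariance equals the target (innovations
shaped by its Cholesky factor, `ar_coeff = 0.3`), plus white
measurement noise (`noise_sd = 0.3` on unit-variance signals, a
moderate-SNR convention that attenuates observed correlations by
roughly 8 %). Every draw is a deterministic function of the scenario
seed via a documented integer hash, so cohorts are bit-reproducible.

Two geometric facts shaped the defaults. First, a node cannot be
correlated at an arbitrary level with *all* other nodes: over a mutual
background `b`, hub-to-network levels are bounded near
`sqrt(b + (1 − b)/(n − 1))` (≈ 0.35 for `b = 0.12`), and raising
several whole rows at once tightens the bound further. Target matrices
are therefore projected to the nearest positive semi-definite
correlation matrix by eigenvalue clipping and rescaling; the projection
may move an entry by at most `psd_tol` (default 0.05) or the scenario
is refused as infeasible. The default schedules sit just inside that
tolerance at full 244-node scale (maximum observed repair shift
≈ 0.037), which is why they are lower than the nominal-looking "hub
correlations" of empirical reports: they are *row* levels, not
within-block levels. Second, the hub construction raises whole rows
because degree centrality counts edges to all nodes — row elevation is
the direct generative analogue of "hub"; a within-block construction
would plant a module, not a hub.

The generator does **not** model haemodynamics, motion or physiological
artifacts, spatial autocorrelation between neighbouring regions, or
awake-animal arousal effects. Passing tests on synthetic cohorts
therefore demonstrates that the *pipeline* recovers structure the
generative model plants at realistic SNR — not that real data contain
such structure, nor that preprocessing upstream of the package is
adequate.

The null scenario (`null_scenario()`) plants nothing: flat background,
no hubs, no burst, two timepoints. It calibrates the node-wise tests'
type-I rate at the nominal α.

## Numerical choices

- **PSD repair**: eigenvalues are floored at 10⁻⁶, the matrix is
  reconstructed and rescaled to unit diagonal; the maximum entry shift
  is recorded on the result (`"psd_max_shift"`) and checked against
  `psd_tol`. A 10⁻¹⁰ ridge precedes the Cholesky factorisation.
- **Bit-exact I/O**: session and connectivity CSVs are written with 17
  significant digits and read with base-R `strtod` parsing, so a
  write–read round trip reproduces matrices exactly. Connectivity
  files are full square matrices with a `NaN` diagonal; symmetry is
  re-checked on load (tolerance 10⁻⁸). Atlas and session loading never
  reorders nodes: row *i* is always `node_id i`.
- **Seed derivation**: subject *s* at timepoint index *t* draws with
  seed `(seed·1000003 + s·98893 + t·10007) mod (2³¹ − 1)`.
- **Correlations** are symmetrised (`(r + rᵀ)/2`) and clamped to
  [−1, 1] to absorb floating-point overshoot before validation.

## Problem sizes used by the test suite

The suite exercises the full 244-node geometry where the quantity is
analytic (pair counts, degree range, PSD feasibility) and a reduced
60-node / 300-volume / 10-subject profile for simulation studies —
20 replicate cohorts for hub-shift recovery, 10 null cohorts (600
node-tests) for type-I calibration, and 5,000-volume draws for
generator-fidelity checks on 12–20 nodes. These sizes were chosen so a
full run completes in about a minute while keeping the Monte-Carlo
margins (binomial SE of a 5 % rate over 600 tests ≈ 0.9 %) well inside
the asserted bands.

## Known limitations

- The RM-ANOVA applies no sphericity correction; with more than two
  within-subject levels and strong non-sphericity its time and
  interaction p-values are anticonservative.
- Degree panels assume a complete subject × timepoint design; missing
  cells are masked with warnings, not modelled (no mixed-effects
  longitudinal model is fitted).
- The hub rule compares each node to the cross-node distribution at a
  single timepoint; it does not correct for the number of nodes, by
  design (it is a descriptive cutoff, not a test).
- NIfTI extraction is plain label-wise averaging; no partial-volume
  weighting.
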