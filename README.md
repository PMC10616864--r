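# hubshift

Longitudinal resting-state functional-connectivity network analysis:
from region-wise BOLD time series to thresholded graphs, degree-centrality
hub maps, change matrices, and motor-subnetwork hub-shift statistics.

## The problem

After spinal cord injury, the brain — though not directly damaged —
reorganises. Longitudinal resting-state fMRI in rodent injury models
tracks this as changes in *functional connectivity*: the Pearson
correlation `r ∈ [−1, 1]` between the band-limited (0.009–0.1 Hz) BOLD
signals of every pair of atlas-defined brain regions ("nodes"; 244
whole-brain areas, 122 per hemisphere, in the reference design, giving
244·243/2 = 29,646 unique edges). Thresholding the correlation matrix at
`r ≥ 0.10` yields a binary graph, and each node's **degree centrality**

```
k_i = Σ_j  1[ r_ij ≥ 0.10 ],        k_i ∈ {0, …, n − 1}
```

indexes its hub function. Tracked over timepoints (pre-injury and 1, 3,
7, 14 weeks post-injury) across subjects, these graphs answer: where do
the network's hubs sit before injury, and where do they move afterwards?
The characteristic finding this pipeline quantifies is a *hub shift*:
motor-cortical nodes (M1/M2) lose centrality over the weeks after a
thoracic contusion while subcortical nodes (caudate-putamen, corpus
callosum/external capsule) comparatively gain it, on top of a transient
global hyperconnectivity in the first week and a mild late global
decline.

`hubshift` implements the whole analysis as composable, pipe-friendly
functions — whole-network **strength** (sum of the unique pairwise
connectivities) and **density** (their mean, or the binary edge
fraction), per-node degree panels, node-wise paired t-tests and
mean-centrality comparisons against baseline, mixed repeated-measures
ANOVA between cohorts, M1-seeded motor-subnetwork extraction, and
`mean + k·SD` hub identification — plus a deterministic synthetic-cohort
generator with planted, time-shifting hub structure, so every stage is
testable without any scanner data.

## Worked example

Simulate the default hub-shift cohort at desk scale (60 nodes, 10
subjects, 5 timepoints, 300 volumes at TR 1 s), run the pipeline, and
ask where the hubs are:

```r
library(hubshift)

scn    <- desk_scenario(seed = 42)
cohort <- simulate_cohort(scn)
cms    <- cohort_connectivity(cohort$sessions)      # bandpass + Pearson r
panel  <- build_centrality_panel(cms, threshold = 0.10)

mean_centrality_comparison(panel, baseline = "pre")
#> # A tibble: 5 × 5
#>   timepoint mean_centrality   sem statistic   p_value
#>   <ord>               <dbl> <dbl>     <dbl>     <dbl>
#> 1 pre                  35.9 0.921    NA     NA
#> 2 1wpi                 45.0 1.20      6.16   0.000167
#> 3 3wpi                 36.2 1.38      0.205  0.842
#> 4 7wpi                 32.7 0.920    -1.90   0.0899
#> 5 14wpi                33.2 1.21     -2.61   0.0281

hub_shift_report(panel, baseline = "pre", final = "14wpi", k = 2)
#> <hub_shift_report>
#>   baseline (pre) hubs: 0, 1, 30, 31
#>   final (14wpi) hubs:    3, 4, 33, 34
#>   overlap Jaccard: 0.000
#>   baseline hubs decline at 14wpi: TRUE; final hubs decline: FALSE
```

Mean centrality rises transiently at 1 wpi, then falls significantly
below baseline by 14 wpi. The pre-injury hubs are exactly the planted
bilateral motor nodes (`scn$motor_hub_ids` = 0, 1, 30, 31 — M1/M2 left
and right), they decline significantly by the final timepoint, and the
14-wpi hubs are the planted subcortical nodes (3, 4, 33, 34 — Cpu and
cc/ec) with no decline: the cortical-to-subcortical hub shift. The
whole-network strength trajectory shows the same shape:

```r
strength_table(cms) |> strength_delta_series(baseline = "pre")
#> # A tibble: 5 × 5
#>   timepoint reference_timepoint mean_delta   sem n_subjects
#>   <ord>     <chr>                    <dbl> <dbl>      <int>
#> 1 pre       pre                       0      0           10
#> 2 1wpi      pre                     101.    16.9         10
#> 3 3wpi      pre                       1.55  15.4         10
#> 4 7wpi      pre                     -34.0   17.0         10
#> 5 14wpi     pre                     -26.4   11.1         10
```

`run_pipeline(config, out_dir)` drives the same steps end-to-end from a
YAML/list configuration and writes every artifact (connectivity and
change matrices, centrality panel, node-wise tests, hub-shift report,
3-D node-scene CSVs, manifest) into a directory. `autoplot()` methods
and `plot_trajectory()` render connectivity/change heatmaps and
SEM-barred trajectories; `tidy()`/`glance()` give broom-style access to
test results.

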