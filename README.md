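# statefc

Brain states govern resting-state functional connectivity: cortical
activity under deep anesthesia alternates between silent *down* periods and
brief *up* states (slow-wave activity, with population *down-up transitions*
propagating as travelling waves), while light sedation yields sustained,
desynchronized *persistent activity*. `statefc` is an R package plus
analysis workflow that quantifies how these two regimes shape BOLD
functional connectivity, and whether down-up transitions — detected
directly in fiber-photometry calcium recordings — drive connectivity
strength. A synthetic-data module with known ground truth stands in for the
animal recordings, so the entire pipeline is testable end to end.

The pipeline implements:

- **Connectivity**: pairwise partial correlation of 96 cortical ROI series
  with nuisance covariables (breathing, ventricle/white-matter means,
  optionally a cortex-wide slow-wave regressor or its time-reversed
  control); per-matrix FDR cutoffs (Storey q-values, with
  Benjamini–Hochberg as the simpler option) on the positive correlations:
  a pair is a connection iff `r >= cutoff` where q < 0.05 via
  `t = r√((n−2)/(1−r²))`.
- **Spectral statistics**: fALFF — the ratio of summed amplitude-spectrum
  magnitude in 0.01–0.1 Hz to 0–0.25 Hz per ROI — and the regression of
  significant pairs' r on inter-ROI Euclidean distance.
- **Brain graphs**: weighted undirected networks from thresholded matrices;
  Newman modularity Q (Louvain, 100 seeded restarts), global/local
  efficiency, geometric-mean weighted clustering, characteristic path
  length (edge length 1/w).
- **Matrix similarity**: the Frobenius norm of the difference between the
  sorted eigenvalue spectra of two connectivity matrices (0 = isospectral),
  and sliding-window dynamic connectivity against the initial 5-min window.
- **Photometry**: 2 kHz→1 kHz downsampling by pairwise averaging,
  quantile-anchored baseline correction in shifted 2500-sample windows,
  ΔF/F, slow-wave detection via fast-minus-slow exponential moving averages
  (onset at 70% of a robust amplitude scale, termination at 50% of the
  threshold; merge < 0.5 s, discard < 0.3 s, discard peaks below the 90th
  amplitude percentile — in that order), dual-site cross-correlation,
  band-stop controls and propagation speed (separation/lag).
- **Statistics**: 10,000-surrogate permutation tests for window
  correlations, repeated-measures correlation (ANCOVA formulation,
  `df = N − k − 1`), paired t contrasts.

## Worked example

Simulate one subject per state and compare them:

```r
library(statefc)

sw <- gen_bold_state_dataset("slow_wave", seed = 1)   # 96 ROIs, 30 min
pa <- gen_bold_state_dataset("persistent", seed = 2)

fc_sw <- partial_corr_matrix(sw$ts, c("breathing", "vwm"))
fc_pa <- partial_corr_matrix(pa$ts, c("breathing", "vwm"))
fc_sw
#> <fc_result> 96 ROIs, 1200 timepoints; FDR cutoff r = 0.030; 3794 significant pairs
#>   covariables: breathing, vwm
fc_pa
#> <fc_result> 96 ROIs, 1200 timepoints; FDR cutoff r = 0.064; 1257 significant pairs
#>   covariables: breathing, vwm

falff(sw$ts)$fitted_mean   # 0.415  (long quiescent periods: low fALFF)
falff(pa$ts)$fitted_mean   # 0.712

g <- build_adjacency(fc_pa)
graph_metrics(g, n_restarts = 100, seed = 5)$modularity_q   # 0.58
```

Slow-wave activity yields about three times as many significant
connections but lower fALFF and much lower modularity — connectivity is
cortex-wide and distance-governed rather than compartmentalized into
networks.

The full analysis sequence lives in `analysis/01`–`06` (each writes its
tables under `results/`): cohort simulation, state connectivity contrasts,
graph metrics, matrix-similarity dynamics, transition↔connectivity linkage,
and dual-site wave propagation. Running them prints, among others:

```
Significant pairs: slow-wave 3796 vs persistent 1160 (t(9) = 31.65, p = 1.5e-10)
fALFF: slow-wave 0.410 vs persistent 0.726 (t(9) = -51.34, p = 2e-12)
modularity_q       slow-wave 0.154  persistent 0.624  t(9) = -46.53  p = 4.9e-12
global_efficiency  slow-wave 0.177  persistent 0.182  t(9) =  -0.89  p = 0.398
Repeated-measures correlation: r(35) = 0.894, p = 9.26e-14
Cross-correlation peak r = 0.65 at lag 40 ms -> 51.2 mm/s (truth 51.2 mm/s)
```

i.e. the two states separate on pair counts, fALFF and modularity but not
on global efficiency or path length (the small-world contrast), window
transition counts predict window connectivity within and across subjects,
and the dual-site lag recovers the generator's wave propagation speed.

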