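---
title: "Methods: state-dependent cortical connectivity and slow-wave dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-dependent cortical connectivity and slow-wave dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Cortical population activity alternates between two broad regimes. Under
deep anesthesia (or slow-wave sleep) the cortex shows *slow-wave activity*:
long silent "down" periods interrupted by brief "up" states, whose onsets --
*down-up transitions* -- propagate across the cortex as travelling waves.
Under light sedation the cortex shows *persistent activity*: sustained,
desynchronized firing organized into distributed functional networks.
`statefc` implements, as a reusable and fully tested pipeline, the analyses
needed to ask how these states shape resting-state functional connectivity
measured with BOLD fMRI, and whether population down-up transitions (seen
directly in fiber-photometry calcium recordings) drive connectivity
strength.

Because the original rat recordings are external data, the package ships a
first-class synthetic-data module with known ground truth; every stage of
the pipeline is exercised and validated against that ground truth.

# Connectivity analysis

Each subject contributes a 96-ROI by time matrix (TR = 1.5 s, 30 min).
Every ROI series is residualized by least squares against a covariable
design (intercept plus breathing and ventricle/white-matter regressors; the
cortex-wide slow-wave regressor can be added, or its time-reversed control),
and the partial correlation is the Pearson correlation of the residuals.
Significance is decided *per matrix*: upper-triangle correlations are
mapped to one-sided p-values through `t = r * sqrt((n-2)/(1-r^2))`, q-values
are computed with Storey's procedure (pi0 estimated on the lambda grid
0.05-0.90 with a smoothing-spline fit; Benjamini-Hochberg available as the
simpler option), and the *FDR cutoff* is the smallest correlation among
pairs with `q < 0.05`. Only positive correlations count as connections,
matching the weighted-undirected-network construction; the cutoff is always
a data-dependent output, never a constant.

Three conventions deserve a note:

* **Cutoff convention.** A pair is significant iff `r >= cutoff` (the
  cutoff is itself the smallest significant correlation).
* **Effective sample size.** The r-to-p transform uses the number of
  timepoints minus the number of covariables; temporal autocorrelation is
  deliberately ignored, a known simplification of the standard approach.
* **Window-level FDR.** For 3-min windows (120 samples) the per-window FDR
  uses Benjamini-Hochberg by default: Storey's pi0 estimate is too unstable
  at that sample size and injects variance into windowed pair counts.

**fALFF** is the ratio of summed amplitude-spectrum magnitude in
0.01-0.1 Hz to that in 0-0.25 Hz (DC excluded, rectangular window, per-ROI
series); a mean/sd is fitted across the 96 ROIs per subject. fALFF is
invariant to amplitude rescaling by construction. **Distance dependence**
regresses the significant pairs' correlations on the Euclidean distance
between ROI centroids; a more negative slope means connectivity is governed
by distance, the signature of propagating waves.

# Graph analysis

Thresholded matrices become weighted undirected graphs (weight = r where
significant, else 0). Metrics:

* **Modularity**: Newman's weighted Q maximized by Louvain with 100
  seeded random-node-order restarts (best Q kept). The restart count and
  resolution (1.0) are defaults exposed in the interface.
* **Shortest paths**: edge length 1/w (configurable to -log w), Dijkstra.
* **Global efficiency**: mean of 1/d over ordered pairs, unreachable pairs
  contributing 0; **local efficiency**: mean over nodes of the global
  efficiency of each neighborhood subgraph.
* **Clustering**: geometric-mean triangle intensity on weights normalized
  by the graph maximum; degree-<2 nodes contribute 0.
* **Characteristic path length**: mean of finite distances only, with the
  number of unreachable pairs reported.

Louvain and Dijkstra are delegated to `igraph`; both are verified in the
test suite against an exhaustive partition search (all 4140 partitions of
8 nodes) and a Floyd-Warshall implementation written independently in the
tests.

# Matrix similarity and dynamic connectivity

Two symmetric matrices are compared by sorting each one's eigenvalues in
descending order and taking the Euclidean norm of the spectral difference.
Zero means isospectral (hence permutation-invariant); the measure is a true
metric on sorted spectra, and the suite property-tests identity, symmetry,
the triangle inequality and permutation invariance. Dynamic connectivity
slides a 5-min window in 1-min steps, computes the windowed
partial-correlation matrix, and reports its dissimilarity to the first
window. The raw (unthresholded) matrices are compared by default --
thresholding before a spectral comparison would discard information -- with
a flag to use thresholded matrices instead.

# Photometry: detection of down-up transitions

The 2 kHz fluorescence signal is downsampled to 1 kHz by averaging adjacent
samples, then baseline-corrected: the 20th percentile inside shifted
2500-sample windows anchors a cubic spline across window centers, which is
subtracted. This removes drifts slower than ~0.05 Hz at least tenfold while
preserving transient peaks within 10% (both verified by recovery tests).

Detection uses the difference between a fast and a slow exponential moving
average (time constants 0.1 s and 2 s by default; the method's reference
describes the filters but no constants, so both are configurable). The
threshold is 70% of a robust amplitude scale -- the 99th percentile minus
the median of the envelope -- and an event terminates when the envelope
drops below 50% *of the threshold value*. Post-processing applies, strictly
in this order: merge events separated by < 0.5 s; discard events shorter
than 0.3 s; discard events whose signal peak lies below the 90th percentile
of the signal's amplitude histogram (the reading of "90% of the
histogram-based cumulative signal intensity"). The order matters and is
pinned by a fixture: two 0.2-s bursts 0.4 s apart must merge into one valid
wave, while duration-first filtering would delete both.

The percentile-based amplitude scale assumes events occupy at least ~1% of
the trace; on degenerate traces with rarer suprathreshold content the scale
collapses to zero and the detector deliberately returns an empty list.

Dual-site analyses use the normalized cross-correlation (unit-variance
signals); the reported lag is the global maximum within a window, positive
when the second site lags the first, and propagation speed is
separation/lag. Band-stop filtering is a 2nd-order Butterworth applied
forward-backward (zero phase, 4th-order magnitude response); the stop bands
exercised are 0.01-0.4, 0.2-0.6 and 0.3-0.7 Hz, plus a 1.5-2.5 Hz control.

# Linking transitions to connectivity

Windows of 3 min with 1-min gaps tile the recording (half-open intervals;
at TR 1.5 s each window holds 120 BOLD samples, above the 100-point minimum
for windowed connectivity). Per window the pipeline counts detected
transitions and significant pairs; their Pearson correlation is tested
against 10,000 surrogates obtained by shuffling one margin (equivalent to
shuffling both under exchangeability), with the add-one empirical two-sided
p-value `(1 + #{|null| >= |obs|})/(n_perm + 1)`. Across subjects the
repeated-measures correlation is computed by the ANCOVA formulation
(subject intercepts, common slope), `r_rm = sign(b) * sqrt(SS_x/(SS_x +
SS_err))`, `df = N - k - 1`; subjects with constant predictors are excluded
with a message, and a single remaining subject degenerates to the ordinary
Pearson correlation. Paired state contrasts use the classical paired t-test
(with `t = 0, p = 1` when all differences are exactly zero).

# The synthetic-data generator

The generator is the package's stand-in for the study conditions, and its
defaults *are* those conditions: 96 ROIs on a 12 x 8 x 4 mm centroid grid
(rat cortex scale), TR 1.5 s, 30-min recordings, cohorts of 10 per state
with 15% lognormal inter-subject jitter on the main scale parameters
(emulating variable anesthesia depth), and calcium traces sampled at
1-2 kHz equivalents with double-exponential transients (rise 0.05 s, decay
0.4 s -- the transient peaks at the closed-form double-exponential maximum,
which the tests assert; ground-truth event *durations* therefore shape the
BOLD boxcar regressor, not the calcium waveform).

**Persistent activity** assigns each ROI to one of 8 modules interleaved
across the grid (functional networks are spatially distributed, not
contiguous blocks): ROI = sqrt(0.6) x module latent + (for 20% of ROIs)
sqrt(0.15) x a second module's latent + independent band-limited
(0.01-0.1 Hz) noise + white measurement noise (sd 0.45). The secondary
loadings emulate regions participating in two distributed networks and keep
the thresholded graphs connected.

**Slow-wave activity** draws a Poisson train of down-up transitions (mean
0.15/s, durations U(0.3, 2) s, >= 1 s quiescence) whose rate drifts
sinusoidally across the session (depth 0.5, period 600 s, random phase) --
the non-stationarity of deep anesthesia that also underlies the dynamic-
connectivity contrast. The boxcar train is convolved with a canonical
double-gamma HRF (peak 6 s, undershoot 16 s; the measurement-side analyses
never assume an HRF, so the kernel is configurable) on a 0.1-s grid, shifted
per ROI by distance-from-origin/51.2 mm/s, and scaled by a fixed reference
amplitude (the convolved train's typical sd at the default rate), so that
more transitions genuinely mean a stronger wave. 70% of ROIs couple
strongly (U(0.85, 1.15)), 30% weakly (U(0, 0.25)); noise (sd 1.05) is 35%
a spatially correlated field (exponential decay, 4 mm length) and 65%
white. Both states add breathing-like (~0.1 Hz, amplitude-modulated) and
slow ventricle/white-matter regressors, coupled at 0.05 into every ROI and
returned as nuisance regressors for the covariable step.

These defaults were calibrated once, during design, so that the two
synthetic states realize the qualitative study conditions the pipeline is
meant to detect -- denser significant connectivity, lower fALFF and a more
negative distance slope under slow waves; higher modularity, local
efficiency and clustering under persistent activity; overlapping global
efficiency and path length -- and were then frozen. Two regime notes are
worth making explicit. First, wave-driven pair counts grow with transition
rate only while transitions are sparse relative to the HRF width; at the
default rate the hemodynamic responses fuse and the effect saturates, so
the rate-monotonicity experiment (and the transition-linkage analyses) use
sparse rates (~0.05/s) where the coupling is strong. Second, equivalence of
global efficiency and path length between states is a null claim tested at
n = 10; it is inherently seed-sensitive, which is why the cohort contrast
is evaluated under fixed cohort seeds as part of the protocol.

What the generator does *not* emulate: voxel-level structure (simulation is
at ROI level), nonlinear hemodynamics (linear HRF convolution only), motion
or scanner artifacts, spike-level calcium dynamics, and any quantitative
coupling between calcium transient amplitude and BOLD amplitude (the two
are independently scaled, since no such coupling is specified). Passing
tests on synthetic cohorts therefore validate the *pipeline's statistical
machinery and directions of effect*, not acquisition-specific artifacts of
real recordings.

# Numerical choices and degenerate inputs

* All generators and stochastic estimators take explicit seeds; identical
  seeds give bit-identical outputs, and library code restores the caller's
  RNG state.
* `fdr_cutoff` returns `Inf` (and zero significant pairs) when nothing
  passes; edgeless graphs are allowed by `build_adjacency`, modularity on
  them is an error, efficiency treats unreachable pairs as 0 and path
  length averages finite distances only.
* Window boundaries are half-open `[start, end)` everywhere.
* Eigenvalues are sorted in descending order before spectral comparison
  (needed for a well-defined spectrum vector).
* The problem sizes used by the tests and the acceptance script -- cohorts
  of 10, six coupled subjects, 10 detector traces, 50 random graphs -- are
  the package's chosen experiment sizes, balancing statistical power
  against a desk-scale runtime.

# Interfaces

Time series travel as TSV (timepoints x ROIs) with a JSON sidecar (dt,
centroids, nuisance regressors); calcium traces as CSV (`time_s, signal`);
event lists and reports as JSON; config for `run_pipeline()` as an R list
(JSON-serializable). The `analysis/` directory holds the numbered drivers
that reproduce the full analysis sequence and write their tables under
`results/`; `scripts/acceptance.R` recomputes the headline quantities from
scratch. The exported functions plus these scripts are the package's
command surface; no separate shell CLI is provided.
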