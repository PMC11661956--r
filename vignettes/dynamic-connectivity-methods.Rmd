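---
title: "Static and dynamic functional network connectivity: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic functional network connectivity: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynconn)
```

## The analysis in one paragraph

`dynconn` analyses multi-subject *component time courses* — the per-network
signals produced by a group spatial ICA of resting-state fMRI — and asks two
questions. First, the **static** one: how strongly is each pair of networks
coupled over the whole scan, and does that coupling differ between a patient
group and controls once age and head motion are accounted for? Second, the
**dynamic** one: how does network coupling *move* over the scan — which
recurring connectivity states does the brain visit, how long does it dwell in
each, how often does it switch, and how far does it travel through
connectivity space — and do those dynamism measures relate to symptoms?

The pipeline is: condition the time courses (detrend, despike, low-pass
filter); compute static FNC (Fisher-z correlations) and a covariate-adjusted
multivariate group analysis; compute windowed connectivity with a tapered
sliding window and graphical-LASSO regularization; cluster the pooled windows
into recurring states (city-block k-means) and summarize each subject's state
sequence by dwell time, fraction time, and number of transitions (NT);
decompose the same windows into a few maximally independent connectivity
patterns, discretize the per-window pattern weights into signed quartiles
("meta-states"), and summarize each subject's meta-state trajectory by four
dynamism metrics; finally, run the group statistics: gated two-sample tests,
Box–Cox-normalized partial correlations with medication dose as nuisance, and
an effective-number-of-tests Bonferroni correction.

## Conditioning the time courses

Each component series is processed as `detrend → despike → low-pass`.

**Detrending** projects out six regressors: intercept, linear trend, and
sine/cosine pairs with one half cycle and one full cycle over the record. The
"half/full cycle" reading of the period-π/2π basis is the only
dimensionally coherent one: it removes the slowest drifts that the later
filter cannot reach.

**Despiking** follows the MAD convention of AFNI's 3dDespike: residuals from
the smooth (detrend-basis) fit are scaled by `σ = sqrt(π/2)·median|r|`;
residuals within `c1 = 2.5` σ pass untouched, larger ones are compressed to
`c1 + (c2−c1)·tanh((s−c1)/(c2−c1))` with `c2 = 4`, sign preserved. The
compression is monotone and bounded by `c2` σ, so a spike of any size ends up
at most 4 MAD-units from the smooth fit. The operation is not a projection —
repeated application keeps shrinking values in the (c1, c2) band toward c1 —
and the tests assert exactly that contraction.

**Low-pass filtering** is a fifth-order Butterworth with a 0.15 Hz cutoff
applied forward–backward (zero phase), so the effective magnitude response is
the squared single-pass response. Zero-phase filtering matters here: a causal
pass would shift each component by a frequency-dependent lag and bias the
windowed correlations. The implementation pads the series with an odd
(antisymmetric) reflection long enough for the filter transient to decay
below 1e-9, because `signal::filtfilt` does not estimate initial conditions.

One property the composite does **not** have is strict idempotence: a
Butterworth is not a projection, so a second conditioning pass changes a
typical series by 10–15% RMS (the change halves with each further pass as
transition-band power decays geometrically). The test suite asserts the
attainable property — per-stage idempotence and geometric contraction of the
composite — rather than a fictional exact one.

**Multitaper spectra** (time–bandwidth 3, 5 Slepian tapers, the standard
Chronux settings) are provided for per-component spectral comparisons; tapers
come from the classical tridiagonal eigenproblem and the integrated spectrum
matches the series variance to a few percent.

**Motion QC** removes subjects whose maximum absolute translation exceeds
3.0 mm or rotation exceeds 3.0° — *strictly* greater; a value exactly at the
ceiling is kept, reading the criterion as a ceiling rather than an open
bound. Framewise displacement uses the Power convention (sum of absolute
parameter differences, rotations mapped to arc length on a 50 mm sphere).

## Static FNC and the multivariate group analysis

Static FNC is the Fisher-z-transformed correlation matrix of the conditioned
time courses (correlations clipped to ±(1−1e−7) so every z is finite;
diagonal fixed at 0). The group analysis mirrors the backward step-wise
multivariate selection of the MANCOVA toolboxes, re-scoped to FNC features:
features are standardized, reduced to principal axes keeping 95% of variance
(capped so the residual degrees of freedom stay positive), each predictor
(age, diagnosis, mean FD, RMS motion) receives a partial Pillai-trace
F-test adjusting for the others, and the least significant predictor is
removed until all survivors pass BH-FDR at α = 0.05. Follow-up univariate
partial-F tests per feature give effect directions, BH-corrected across
features. The Pillai implementation is cross-checked in the tests against
`car::Manova` on the same fits.

The number of principal dimensions the original toolbox used is not
recoverable; 95% retained variance is the package default and a free
parameter.

## Windowed connectivity

Windows are 30 TRs wide (60 s at TR = 0.72 s), slid by 1 TR; the weight
vector is a boxcar convolved with a Gaussian of σ = 3 TRs, truncated and
renormalized. The window count is exactly `floor((T−width)/step)+1`, and
window starts are 0-based inclusive TR ranges.

Each window's taper-weighted covariance is converted to correlation and
regularized with the **graphical LASSO** — L1-penalized maximum-likelihood
inverse covariance — written for this package as Armadillo block coordinate
descent with the diagonal unpenalized, so a correlation input keeps its unit
diagonal. The regularized correlation (from the implied covariance) is the
window's connectivity measure, Fisher-z transformed; negative partial
correlations from the precision matrix are available as an option.

The per-subject penalty is selected from a grid of 10 log-spaced values in
[1e−3, 1] by held-out Gaussian log-likelihood over 10 random window splits.
Each repetition fits the candidate penalties to a *single* randomly drawn
window and scores held-out windows: this matches how the penalty is used
downstream (regularizing single, often rank-deficient windows). Fitting to
the average of many training windows instead looks attractive but degenerates
— the averaged covariance is always well-conditioned, the likelihood then
always prefers a vanishing penalty, and single windows are left
under-regularized; with more components than effective samples per window
they can even be singular.

Motion is regressed *from the windowed connectivity* (the taper-weighted
window-mean FD and the taper-weighted mean absolute derivative of each of the
six motion parameters, OLS with the intercept restored), following the
pipeline's published order of operations; constant regressors are dropped.

## Cluster states and their metrics

All subjects' windows are pooled and clustered by k-means with **city-block
distance and median centroid updates** — the geometry consistent with the
meta-state metrics — keeping the best of `n_replicates` seeded random
restarts (100 by default; empty clusters are re-seeded at the worst-fitted
point). All windows are clustered; no exemplar pre-pass. The headline state
count is k = 5 with an exploratory sweep over k ∈ {4, 5, 6} (`sweep_k`).

Per subject: **dwell time** is the mean length of maximal constant runs per
state, in windows; **fraction time** is the share of windows per state; and
**NT** counts adjacent unequal pairs. Unvisited states contribute dwell 0
with a visited flag and are excluded from that state's group test. Group
contrasts of within-state connectivity use subject-level mean z per pair and
Welch two-sample t-tests at a raw α = 0.05 (per-state BH-FDR available).

## Meta-states

The pooled window-by-pair matrix is reduced to `model_order = 5` principal
axes and rotated by FastICA (`ica::icafast`) so the *patterns* — loadings
over component pairs — are maximally independent: spatial group ICA on group
dFNC. Patterns are unit-norm with the largest-magnitude entry positive;
per-window weights are least-squares projections onto the patterns, so
held-out subjects can be projected onto a fitted model. Identifiability is
tested on synthetic mixtures of sparse (spatially non-Gaussian) patterns —
the structure this decomposition is actually able to identify.

Weights are discretized to signed quartiles: per pattern, quartile
boundaries of |weight| pooled over all subjects' windows, each weight mapped
to `sign(w)·quartile(|w|) ∈ {±1..±4}` (zero weights to +1; tied boundaries
collapsed with a message). Global pooling is the convention of the
originating meta-state literature; per-subject quartiles are an option. The
four dynamism metrics per subject are the number of distinct meta-states
occupied, the number of meta-state changes, the span (largest city-block
distance between occupied vectors), and the total distance traveled; the
tests verify `total_distance ≥ span` and `n_changes ≥ n_meta_states − 1` on
random trajectories, against brute-force enumeration.

## Group statistics

`choose_and_run_test` makes the "as appropriate" test choice explicit:
Shapiro–Wilk p < .05 in either group → Mann–Whitney U; otherwise an F-test of
variance homogeneity decides Welch vs Student t; categorical tables get
Pearson χ² without continuity correction (the uncorrected statistic is what
reproduces the published sex table value of 0.483). `summary_stat_tests`
computes the same t statistics from printed means/SDs/ns, which is how the
demographic-table values are recomputed to within rounding of the printed
summaries.

Correlation analyses use partial correlations (Pearson or Spearman via rank
transformation of all variables) with chlorpromazine-equivalent dose as the
nuisance, after a Shapiro–Wilk-gated Box–Cox transformation of the score
(shift `1 − min` when values are non-positive; λ by profile maximum
likelihood over [−3, 3]).

Multiplicity over the four inter-correlated dynamism endpoints uses the
Dubey/Armitage–Parmar correction: `m_eff_j = m^(1−r̄_j)` with `r̄_j` the mean
absolute correlation of endpoint j with the others (clamped to [0, 1]), and
`p_corr = 1 − (1−p)^m_eff` computed via `expm1`/`log1p` so tiny p-values
survive. It equals the raw p at r̄ = 1 and the Šidák correction at r̄ = 0.
The separately cited "unadjusted FWE correction" is read as plain Bonferroni
(`m·p`), the only coherent reading of that phrase.

## The synthetic cohort: what it emulates and what it does not

Because the motivating dataset is access-restricted, every stage is validated
against a generator with known ground truth:

* **States**: three block-structured correlation matrices over the components
  — a *hyperconnected/segregated* motif (within-block +0.75, between −0.35),
  a *globally integrated* motif (+0.55 / +0.40), and a *weakly connected*
  motif (+0.10 / 0) — the three canonical patterns recurring in dFNC
  literature, mutually separated by ≥ 14 in city-block distance over pairs.
* **Switching**: a hidden Markov chain at TR resolution (so analysis windows
  genuinely mix states near boundaries). Default self-transition
  probabilities give dwell times of roughly 0.7–2.4 minutes, with the
  patient-like group stickiest in the strong state and controls in the weak
  one. Each subject's stay probabilities are additionally jittered by
  N(0, 1) on the logit scale: subjects genuinely differ in switching rate,
  and this heterogeneity is the dynamism signal that brain–behavior coupling
  acts on.
* **Signal**: the state signal is AR(1) with coefficient 0.7 at TR = 0.72 s,
  reproducing the band-limited character of hemodynamic network time courses
  (the stationary cross-component correlation remains exactly the planted
  matrix). A temporally white signal would be mostly destroyed by the
  0.15 Hz low-pass that real pipelines apply.
* **Artifacts**: linear drift, a slow sinusoidal trend, sparse spikes in MAD
  units (so despiking efficacy is directly assertable), white observation
  noise (SD 0.3 against a unit-variance signal), and mean-reverting
  six-parameter motion traces with higher innovation scale in the patient
  group.
* **Clinical coupling**: `score = 15 − 1·z(true NT) + N(0, 1)`, a strong
  planted coupling (true r ≈ −0.7) so that recovery failures indicate
  pipeline attenuation rather than a weak plant; dose (chlorpromazine
  equivalents) is lognormal in a medicated subset of patients and zero
  elsewhere.

Not emulated: hemodynamic response convolution, spatial maps or voxel data,
scanner-specific noise spectra, physiological (cardiac/respiratory)
components. Passing recovery tests therefore demonstrates that the *pipeline*
recovers planted temporal structure through realistic conditioning, not that
it would behave identically on raw scanner data.

## Validation scale and observed behavior

The validation experiments (tests and `scripts/acceptance.R`) use: a
20+20-subject, 10-component, 300-TR cohort for cluster-state recovery;
10 seeds of a 10+10-subject cohort for the dwell-difference direction check;
and 10 seeds of a 96/56-subject, 15-component, 250-TR cohort for
brain–behavior recovery — sizes chosen so each experiment completes in
minutes on one core while keeping the group sizes of the motivating study
where they matter (96/56 for the correlation power).

Three observations deserve honesty.

First, matched cluster centroids correlate with the planted state matrices
at ~0.96 and the planted dwell-time group difference is detected in 9 of 10
seeds, but **window-level assignment agreement saturates near 0.75**: with
TR-resolution switching, a 60-s window, and a 0.15 Hz low-pass, each window
retains only ~6–7 effective samples, which caps single-window state
discrimination regardless of the clustering algorithm; roughly a quarter of
windows also straddle a transition and have no unambiguous true label. This
is a measurement-physics ceiling of the windowed design itself, and it is
reported as such rather than hidden by easing the simulation.

Second, **meta-state dynamism metrics are heavily attenuated**: the
planted score–dynamism coupling of r ≈ −0.7 (on true transition counts)
emerges from the full pipeline as a partial correlation of about −0.15 ±
0.10 with computed `n_changes`/`total_distance` — strikingly close to the
magnitudes such studies report in real cohorts. The attenuation has two
sources: the discretized weight trajectories change at almost every window
through quartile-boundary churn of the noisy window estimates (tens of
spurious changes against a planted signal of a handful of true
transitions), and the per-subject glasso penalty adds a subject-level scale
confound under global quartiles. Per-subject quartiles remove the confound
but also the genuine between-subject scale signal, and are therefore only
an option, not the default. The practical consequence: at n = 96 the
corrected joint detection of both fluidity metrics succeeds in only ~30–50%
of simulated cohorts at this effect size, so a single-cohort finding at
this magnitude should be read as fragile.

Third, these two attenuation phenomena mean recovery-rate checks that
presume near-lossless metric estimation will fail here by design, and the
corresponding validation outputs report the honestly measured rates.

## Numerical choices

* Correlations are clipped to ±(1−1e−7) before `atanh`; Fisher round trips
  are exact to 1e−12 for |r| ≤ 0.999.
* The glasso solver converges when the largest single-sweep change falls
  below `tol` × mean |off-diagonal| (default 1e−4, 2000-iteration cap); at
  penalty 0 it reproduces the input correlation to 1e−4 and it matches an
  independent sparse-covariance implementation to ~1e−6 on a frozen fixture.
* k-means ties in assignment break to the lowest state index; restarts are
  seeded from a master seed, making every fit reproducible.
* Degenerate inputs are handled explicitly: constant components give zero
  correlations with a warning, zero-variance windows are guarded in the
  correlation conversion, constant motion regressors are dropped, tied
  quartile boundaries are collapsed with a message, and σ_MAD = 0 returns
  the series unchanged.

## Limitations

* The backward-selection MANCOVA operates on FNC features only; voxelwise
  spatial-map statistics are out of scope.
* Meta-state weights at low component counts are noisy — with 45–105 pairs
  the per-window weight estimates average over far fewer loadings than the
  1378 pairs of a full 53-component analysis, attenuating
  computed-vs-true dynamism correlations; validation uses ≥ 15 components
  for the brain–behavior experiment for exactly this reason.
* No hidden-Markov or change-point state estimation; the state count is
  fixed (with the k ∈ {4,5,6} sweep) rather than selected.
* The window-assignment ceiling discussed above.
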