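---
title: "Source-space PLV connectivity and cluster-based permutation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-space PLV connectivity and cluster-based permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plvfc)
```

## The analysis

plvfc implements a resting-state source-space functional-connectivity
analysis of the kind used to compare clinical groups — here motivated by the
comparison of frail and robust older adults, where frailty-related
hypoconnectivity is expected in the upper beta band between parietal seed
regions and fronto-parietal targets. Continuous source time series (sources
x samples at 1000 Hz, on a regular 1-cm grid in an MNI-like millimetre
frame) pass through:

1. **Epoching** — consecutive non-overlapping 4-s windows from the start of
   the recording; trailing partial windows are discarded.
2. **Band-pass filtering** — alpha-mu 8–13 Hz, low beta 12–20 Hz, upper
   beta 20–30 Hz by default. Each epoch is filtered on a window padded with
   2 s of real neighbouring signal on both sides to avoid edge effects;
   where the recording ends inside the pad, the remainder is
   reflection-padded and a warning is raised.
3. **Instantaneous phase** — the angle of the analytic signal
   (Hilbert-transform method), wrapped to (−pi, pi].
4. **Phase-locking value** — for sources *k*, *l* and an epoch of *T*
   samples,
   PLV = | (1/T) Σ_t exp(−i(φ_k(t) − φ_l(t))) |,
   computed per epoch and averaged across epochs. PLV is 1 for a perfectly
   constant phase relation and falls to the sampling floor (≈ √π/2·T^−1/2
   for independent uniform phases) when none exists.
5. **Reductions** — a *seed* analysis averages PLV from all sources of a
   seed region to each distant source (intra-seed pairs never contribute),
   giving one vector per subject; an *RSN* analysis averages PLV over pairs
   of sources inside a resting-state network defined as the union of
   1.5-cm spheres around MNI coordinates.
6. **Group inference** — independent-samples t-tests per source or network.
   Seed maps are corrected over sources by a cluster-based Monte-Carlo
   permutation test (CBPT); RSN and clinical tests are reported
   uncorrected, and seed × band × laterality analyses are tested separately
   without cross-analysis correction (a note to this effect is embedded in
   every report).

## Filtering: design and numerical choices

The filter is a type-I FIR band-pass designed with a Kaiser window
(`design_bandpass_fir()`), applied through its *squared magnitude response*
in the frequency domain. This is the transfer function a forward–backward
("filtfilt") application would have, realised exactly: the phase response is
identically zero, which matters because PLV measures phase relations. The
single-pass design attenuation is 26 dB over a transition of half the low
band edge, so the applied |H|² response reaches ≈ 52 dB one octave below the
band; the contract checked by the tests is ≥ 20 dB there, unit gain (±5%)
at band centre, and < 5% of white-noise output power outside the band.
Shorter filters would leak out-of-band power; longer ones smooth the phase
dynamics the coupling simulation relies on (below), and this design is the
measured compromise. The FFT application is circular, which is why windows
are padded with real signal first — a test verifies that boundary errors at
epoch edges are below 1% of signal RMS with padding honoured and visibly
larger without.

`band_phases()` / `band_phases_multi()` provide the production path: one
forward FFT of the whole padded recording per source, shared across bands,
with band filtering and the analytic-signal step fused into the same
transform. Interior epochs are thereby padded with *all* available real
signal (a superset of the 2-s contract); only the two boundary epochs fall
back to reflection. The modular route
(`bandpass_epochs()` then `instantaneous_phase()`) keeps the literal
per-epoch 2-s-pad mechanics; a test pins the two paths to each other.

## The synthetic cohort generator

No real recordings ship with the package, so the generator *is* the study
bed. Its defaults are the emulated study conditions: 34 robust and 20 frail
subjects; per-subject epoch counts drawn as round(N(81.0, 13.1)) (robust)
and round(N(77.5, 12.1)) (frail), clipped at 20; fs = 1000 Hz; 4-s epochs; a
desk-scale MNI-like grid of 315 sources at 10-mm spacing (a full-scale
2,459-source grid is just a larger `build_regular_grid()` call).

Each source carries a main oscillator
x(t) = cos(2π f t + θ + w(t)) + ε_obs,
with f uniform in the source's assigned band, θ uniform, w a random walk
with per-sample SD 0.05 rad (≈ 0.4 Hz Lorentzian linewidth), and Gaussian
observation noise σ_obs = 0.2 relative to unit carrier amplitude. σ_obs and
the walk SD were chosen once: the walk width is a realistic spectral width
well inside a 10-Hz band, and σ_obs = 0.2 keeps end-to-end PLV recovery
inside its ±0.05 contract while remaining non-trivial. In addition, every
source carries an independent *background* oscillator (amplitude 0.5,
`background_amp`) in each analysis band other than its own: resting-state
sources are broadband, and without background activity the faint spectral
tails of a coupled carrier would be the only out-of-band content a filter
sees. That matters because a phase-jitter coupling necessarily places its
incoherent power (1 − ρ²) into spectral sidebands that leak beyond the
coupling band, and that leak differs between groups whenever ρ does; with
background activity present, out-of-band content is dominated by
group-independent oscillators and the measured cross-band leak of an
implanted Δρ = 0.15 effect is statistically invisible at cohort size
(verified by the band-confinement acceptance check).

**Coupling** uses a driven-source model: for a coupled pair (i → j, target
PLV ρ), the driven phase is φ_j = φ_i + δ + ε(t) with ε von Mises
distributed with concentration κ solved from the Bessel-ratio map
ρ = I₁(κ)/I₀(κ) (`kappa_for_plv()`, inverted to 1e-10). This gives a
closed-form expected PLV — the oracle every recovery test uses. A source
may be driven by at most one pair; implanted group effects force the pair's
carriers into the effect band (upper beta by default) and reduce ρ by Δρ in
the frail group only, so the deficit is band-confined by construction.

**Why the jitter is block-stratified, not white.** A white (per-sample)
jitter sequence has its power spread to the Nyquist frequency; any filter
meeting the stop-band contract removes almost all of it, and the estimated
PLV collapses towards 1 regardless of ρ. The jitter must therefore live
inside the band: ε(t) is piecewise constant over 160-sample (0.16-s)
blocks. Holding blocks introduces a second bias — the modulus of a mean of
N phasors overestimates ρ by ≈ √(ρ² + (1−ρ²)/N) with only N = 25 blocks per
epoch — so within each epoch the block values are the von Mises *quantiles*,
rescaled so that the block set's mean phasor equals ρ exactly, in fresh
random order per epoch (outside epoch boundaries plain i.i.d. von Mises
blocks are used). This stratification removes the small-sample inflation
while keeping the marginal von Mises and the Bessel-ratio oracle exact;
measured end-to-end bias is ≤ +0.01 across ρ = 0.2…0.9. Block length is the
measured compromise between surviving the filter (slow jitter) and
averaging within an epoch (fast jitter); it must divide the epoch length in
samples.

Two caveats the generator makes explicit rather than hiding: (a) uncoupled
same-band sources whose carriers happen to fall within the oscillator
linewidth (≲ 0.4 Hz apart) phase-lock genuinely — free-running oscillators
at near-identical frequencies do — so "uncoupled implies null PLV" holds
only for separated carriers, and the tests select on ground-truth carrier
separation; (b) band-filtered signals have autocorrelated phases, so the
null PLV for independent sources (~0.14 at 20–30 Hz, T = 4000) sits well
above the i.i.d.-phase floor of 0.014. Neither effect is an artifact: both
appear in real narrowband electrophysiology.

What the generator does *not* emulate: volume conduction / field spread,
1/f background spectra, artifacts (the emulated pipeline assumes artifact
rejection happened upstream), inter-subject anatomical variability, and
inter-network coupling. Passing tests therefore demonstrate correctness of
the estimators and inference under controlled phase dynamics, not
robustness to those real-data complications.

## Cluster-based permutation testing

Per-source two-sample t-tests (pooled-variance Student by default, Welch by
configuration — the conventional reading of an unqualified
"independent-samples t-test" is pooled) are thresholded at a two-sided
cluster-forming α = 0.05. Suprathreshold sources are split by t-sign and
joined into clusters via spatial adjacency; each cluster is scored by its
summed t (the *T-statsum*). The null distribution of the maximum |mass|
over both signs is built from random relabelings of subjects preserving
group sizes (5000 by default, seeded; per-sign nulls are a config option),
and each observed cluster gets p = (1 + #{perm max ≥ |mass|}) / (N + 1) —
an estimator that can never return 0 and is a valid Monte-Carlo p. An
exhaustive mode enumerates all distinct relabelings for tiny groups; a test
pins the Monte-Carlo p to the exhaustive p at n₁ = n₂ = 4. The default
relabeling floor (≥ 100 distinct relabelings) is a config field so that
such tiny exhaustive analyses remain possible deliberately rather than
accidentally.

Adjacency defaults to face connectivity (neighbour distance ≤ 1.1 × grid
spacing) — the most conservative notion of "spatially contiguous" — and is
configurable, as is the sphere-boundary convention: all ball memberships
are closed (≤ radius), so boundary sources never silently vanish. Group
sign convention: group 1 is the first factor level (the pipeline puts
*robust* first), so frail hypoconnectivity appears as *positive* clusters
in pipeline reports, matching how such results are conventionally printed;
the sign flips symmetrically if groups are passed frail-first, with
identical p-values.

Operating characteristics are measured, not assumed: on null cohorts
(12 vs 8 subjects, 315 sources, 500 relabelings) the fraction of analyses
reporting any p < 0.05 cluster must land in [0.02, 0.10]; with a Δρ = 0.15
deficit implanted between a 2-source seed and a contiguous 6-source target,
the best frail-deficit cluster must overlap the truth (Jaccard ≥ 0.5) in
≥ 80% of 50 cohorts while the alpha-mu band stays clean in ≥ 90%.

## Clinical table statistics

Categorical variables use Fisher's exact test with the probability-mass
two-sided convention (sum of all margin-preserving tables whose probability
does not exceed the observed one) — the convention is confirmed by
reproducing p = 0.381 from the worked gender example (21/34 vs 15/20
female). Continuous variables use the Mann-Whitney U test: exact
enumeration of all splits (ties handled by mid-ranks) for m + n ≤ 14,
normal approximation with tie and continuity corrections above. Summaries
are "median [25th, 75th percentile]" with linear interpolation between
order statistics (R's default quantile type 7; the convention is fixed for
reproducibility and config-exposed, since published tables rarely state
theirs) and "n [%]" for categorical variables.

## Problem sizes and reproducibility

All statistical machinery is exact at any scale; simulation-based checks
run at desk scale by choice: 315-source grids for null calibration,
18-source grids with 10 vs 6 subjects and 20 epochs for the repeated power
studies, 500 relabelings where the default is 5000. These sizes keep the
whole property suite to minutes while leaving every estimator and code path
identical to full-scale runs; the full-size cohort is one
`cohort_spec()` call away and streams one subject at a time (a 2,459-source
PLV matrix is O(n²) memory, and the connectivity stage computes only the
PLV rows the enabled analyses need).

Every random draw in a pipeline run derives from the single `rng_seed` in
the configuration: subject streams are child seeds of the cohort seed, the
CBPT relabeling stream is seeded separately, and reports echo all of them.
Identical configuration + seed reproduces a report bit-for-bit, including
across processes. On-disk interchange uses TSV manifests, JSON
(ROI/RSN definitions, ground truth, reports) and per-subject RDS blobs
written at run time.

## Known limitations

- The RSN coordinate file shipped under `inst/extdata/` contains generic,
  editable placeholder coordinates; real analyses must supply their own.
- Filter family/order and the phase-extraction method are stated defaults,
  not inferred from any reference implementation; both are config-exposed.
- The choice of averaging *within-sphere* pairs into RSN means
  (`all_pairs`, the literal reading) versus only *between-sphere* pairs is
  ambiguous in the literature; both policies are implemented and the
  default is flagged in results.
- No correction is applied across the seed × band × laterality analysis
  family, mirroring the emulated design; the report says so explicitly.
- The generator's coupling is unidirectional phase-copying; symmetric or
  delayed coupling, amplitude dynamics and field spread are out of scope.
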