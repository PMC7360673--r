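# plvfc

Source-space functional-connectivity analysis for resting-state
electrophysiology, built around the phase-locking value (PLV) and
cluster-based permutation inference — the analysis style used to compare
clinical groups such as frail versus robust older adults, where coupling
deficits are expected in specific frequency bands (classically the upper
beta band, 20–30 Hz, for motor-relevant networks).

For sources *k* and *l* with instantaneous phases φ_k(t), φ_l(t) over an
epoch of *T* samples,

    PLV_kl = | (1/T) Σ_t exp(−i (φ_k(t) − φ_l(t))) |

computed per 4-s epoch and averaged across epochs. The package covers the
full chain:

- **Source space** — regular 1-cm grids in an MNI-like mm frame, seed ROIs
  (explicit index sets, spheres, or NIfTI atlas labels), resting-state
  networks as unions of 1.5-cm spheres around MNI coordinates, and the
  spatial adjacency used for clustering.
- **Preprocessing** — 4-s epoching, zero-phase FIR band-pass (alpha-mu
  8–13, low beta 12–20, upper beta 20–30 Hz) on windows padded with 2 s of
  real signal, analytic-signal instantaneous phase.
- **Connectivity** — per-subject PLV matrices (streamed; only the rows an
  analysis needs are ever computed), seed-to-brain FC vectors (intra-seed
  pairs excluded), per-network mean FC.
- **Group inference** — per-source independent-samples t-tests corrected by
  a cluster-based Monte-Carlo permutation test (clusters scored by summed
  t, the *T-statsum*, referenced to the permutation null of the maximum
  cluster mass); per-network uncorrected t-tests.
- **Clinical tables** — Fisher's exact test (probability-mass two-sided
  convention), exact / approximate Mann-Whitney U, "median [IQR]" and
  "n [%]" summaries.
- **Synthetic cohorts** — a two-group coupled-oscillator generator with a
  closed-form coupling oracle (target PLV ρ maps to von Mises concentration
  via ρ = I₁(κ)/I₀(κ)), controllable group-specific coupling deficits, and
  full per-subject seeded reproducibility. This is first-class, tested
  functionality: it defines the conditions under which every statistical
  property of the package is verified.

See the vignette `vignettes/plv-connectivity-methods.Rmd` for the model,
the numerical design choices and their rationale.

## Worked example

Simulate a 16-subject cohort on an 18-source grid with a coupling deficit
(PLV 0.50 → 0.35) implanted between a 2-source seed and a contiguous
6-source target in the upper beta band only, then run the full pipeline:

```r
library(plvfc)

report <- run_pipeline(list(
  rng_seed = 7,
  simulate = list(
    n_robust = 10, n_frail = 6, epochs_fixed = 20,
    grid = list(lower = c(0, 0, 0), upper = c(20, 20, 10), spacing = 10),
    effect = list(seed_indices = c(1, 2), target_indices = 13:18,
                  band = "upper_beta", rho_robust = 0.5, delta_rho = 0.15)),
  bands = list(alpha_mu = c(8, 13), upper_beta = c(20, 30)),
  seeds = list(list(name = "parietal_seed", source_indices = c(1, 2))),
  rsns  = list(list(name = "target_network",
                    centers = list(c(20, 0, 0), c(20, 20, 10)), radius = 11)),
  cbpt  = list(n_permutations = 500)))
print(report)
#> plvfc run report
#>   cohort: 16 subjects on 18 sources
#>   connectivity: PLV rows for 10 sources x 2 bands
#>   seed analysis: 2 seed x band combinations (tested separately, no cross-analysis correction)
#>   rsn analysis: 2 network x band combinations
#>   clinical: 3 variables
#>   seed-based clusters:
#>     parietal_seed.alpha_mu       2 cluster(s), 0 with p < 0.05
#>     parietal_seed.upper_beta     2 cluster(s), 1 with p < 0.05
#>       positive, 6 sources, T-statsum 20.54, p = 0.0020
#>   RSN tests (uncorrected):
#>     target_network.alpha_mu      t = +0.35, p = 0.7314
#>     target_network.upper_beta    t = +1.19, p = 0.2535
#>   clinical summary:
#>    variable        type      p
#>      gender categorical 0.3024
#>         age  continuous 0.1158
#>  gait_speed  continuous 0.0448
```

Reading the output: the permutation test recovers exactly the six implanted
target sources as a significant cluster (T-statsum 20.54, the sum of the
per-source t-values; p = 0.002 against 500 relabelings) in the upper beta
band, with a *positive* sign because group 1 (robust) has the higher
coupling. The control band (alpha-mu) shows no significant cluster. The RSN
mean for the network covering the target region moves in the expected
direction (robust > frail) in upper beta only, but does not reach
significance at this cohort size — a network mean averages many pairs the
implanted seed-target deficit never touches, which is exactly why the
seed-based cluster analysis is the sensitive instrument here. The simulated
clinical table behaves like a real one (the gender difference is
non-significant at these group sizes). Re-running with the same `rng_seed`
reproduces every number bit-for-bit.

The clinical machinery on a worked example — a gender-by-group table of
21/34 vs 15/20 female:

```r
fisher_exact_2x2(matrix(c(21, 13, 15, 5), 2, byrow = TRUE))
#> [1] 0.3814933   # 0.381 at 3 d.p.
```

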