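# Shared fixtures and independent brute-force oracles used across test files.

# Brute-force closed-ball membership.
bf_in_sphere <- function(grid, center, radius) {
  which(apply(grid$positions, 1, function(p) sqrt(sum((p - center)^2)) <=
                radius + 1e-9))
}

# Brute-force adjacency by pairwise distance thresholding.
bf_adjacency <- function(grid, max_dist) {
  n <- grid$n_sources
  lapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(grid$positions) - grid$positions[i, ])^2))
    setdiff(which(d <= max_dist + 1e-9), i)
  })
}

# Flood-fill connected components of `nodes` under neighbour lists.
bf_components <- function(nodes, neighbors) {
  remaining <- nodes
  comps <- list()
  while (length(remaining)) {
    comp <- remaining[1]
    repeat {
      grow <- unique(unlist(neighbors[comp]))
      grow <- intersect(grow, setdiff(remaining, comp))
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    comps[[length(comps) + 1]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

# Exhaustive two-sided Fisher p for a 2x2 table by enumerating all tables
# with the observed margins.
bf_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(a_range, function(a)
    exp(lchoose(r1, a) + lchoose(n - r1, c1 - a) - lchoose(n, c1)),
    numeric(1))
  p_obs <- probs[a_range == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exhaustive two-sided Mann-Whitney p over all splits of the pooled sample.
bf_mwu <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  splits <- combn(m + n, m)
  Us <- colSums(matrix(r[splits], nrow = m)) - m * (m + 1) / 2
  mean(abs(Us - m * n / 2) >= abs(U_obs - m * n / 2) - 1e-9)
}

# A tiny phase container for connectivity tests without running the
# preprocessing chain.
make_phase_set <- function(data, fs = 1000, band = "test") {
  structure(list(data = data, fs = fs, epoch_len = dim(data)[3] / fs,
                 band = band, subject_id = "test",
                 n_sources = dim(data)[1], n_epochs = dim(data)[2],
                 n_samples = dim(data)[3]),
            class = "plv_phase")
}

# Naive per-pair PLV loop (the oracle for plv_matrix).
bf_plv_matrix <- function(phases) {
  n <- phases$n_sources
  m <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- plv_pair(matrix(phases$data[i, , ], phases$n_epochs),
                  matrix(phases$data[j, , ], phases$n_epochs))
    m[i, j] <- m[j, i] <- v
  }
  m
}

# Von Mises sampler for oracle use (kept independent of the package's
# internal sampler: inversion from the CDF on a dense grid).
oracle_rvm <- function(n, kappa) {
  if (kappa == 0) return(runif(n, -pi, pi))
  th <- seq(-pi, pi, length.out = 32768)
  cdf <- cumsum(exp(kappa * (cos(th) - 1)))
  cdf <- cdf / cdf[length(cdf)]
  approx(cdf, th, xout = runif(n), rule = 2, ties = "ordered")$y
}

# Seed-FC subject matrices for a simulated cohort: simulate each subject
# once, band-filter/phase all requested bands in one FFT pass, PLV rows of
# the seed, reduce. Returns per band a subjects x (n_sources - |seed|)
# matrix, plus the distant-source index map.
cohort_seed_fc <- function(cohort, seed, bands, pad = 2) {
  if (inherits(bands, "plv_band")) bands <- setNames(list(bands), bands$name)
  spec <- cohort$spec
  firs <- lapply(bands, design_bandpass_fir, fs = spec$fs)
  n_sub <- nrow(cohort$manifest)
  distant <- setdiff(seq_len(spec$grid$n_sources), seed$source_indices)
  fc <- lapply(bands, function(b) matrix(NA_real_, n_sub, length(distant)))
  for (k in seq_len(n_sub)) {
    sub <- cohort_subject(cohort, k)
    phs <- suppressWarnings(band_phases_multi(
      sub$data, spec$fs, bands, epoch_len = spec$epoch_len, pad = pad,
      firs = firs, phase_array = FALSE))
    for (bn in names(bands)) {
      rows <- plv_rows(phs[[bn]], seed$source_indices)
      fc[[bn]][k, ] <- seed_fc(rows, seed)$values
    }
  }
  list(fc = fc, distant = distant)
}

# Compact grid + implanted-effect cohort used by the power checks: 4 x 3 x 2
# sources at 10-mm spacing; 2-source seed at one end drives a contiguous
# 6-source slab at the other, upper beta only.
power_cohort_spec <- function(rng_seed, n_robust = 10, n_frail = 6,
                              delta_rho = 0.15, rho_robust = 0.5,
                              n_epochs = 20) {
  grid <- build_regular_grid(c(0, 0, 0), c(20, 20, 10), 10)  # 18 sources
  seed <- seed_roi("driver", c(1L, 2L), grid = grid)
  target <- 13:18                                            # the x = 20 slab
  adj <- build_adjacency(grid)
  eff <- effect_spec(seed, target, band = band_spec("upper_beta", 20, 30),
                     rho_robust = rho_robust, delta_rho = delta_rho,
                     adjacency = adj)
  cohort_spec(n_robust = n_robust, n_frail = n_frail, grid = grid,
              epochs_fixed = n_epochs, effect = eff,
              rng_seed = rng_seed)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
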