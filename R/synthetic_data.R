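#' Synthetic source-space cohorts with controllable phase coupling
#'
#' Generates two-group cohorts of band-limited oscillatory source time
#' series on a regular grid. Every source carries a noisy oscillator
#' (uniformly drawn carrier frequency within its assigned band, random
#' starting phase, slow random-walk phase wander, additive observation
#' noise). Coupling between a driver i and a driven source j replaces j's
#' phase by `phi_i + delta_ij + eps(t)` where `eps` is a von Mises jitter
#' process whose concentration kappa is chosen so that the expected phasor
#' mean equals the target PLV rho via the Bessel-ratio map
#' `rho = I1(kappa) / I0(kappa)`. A frailty-like effect implants a
#' group-specific coupling reduction between a seed region and a contiguous
#' target region in one band only.
#'
#' The jitter is piecewise-constant (hold `jitter_hold` samples). Within
#' each epoch the block values are a stratified sample of the von Mises
#' distribution (its quantiles, rescaled so the block set's mean phasor
#' equals rho exactly, in random order); this keeps the jitter slow enough
#' to survive band-pass filtering while removing the small-sample upward
#' bias of the modulus estimator, so the pipeline recovers rho without
#' systematic error. White per-sample jitter would be removed by any
#' spec-compliant band-pass filter and is therefore not offered.
#'
#' @name synthetic_data
NULL

bessel_ratio <- function(kappa)
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)

#' Von Mises concentration for a target PLV
#'
#' Inverts the Bessel-ratio map `rho = I1(kappa)/I0(kappa)` by bisection to
#' `|I1/I0 - rho| < 1e-10`.
#'
#' @param rho target PLV in `[0, 1)`.
#' @return concentration kappa (0 when `rho = 0`).
#' @export
kappa_for_plv <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0)
    stop("rho must be a scalar in [0, 1)")
  if (rho >= 1) stop("rho >= 1 is unattainable (kappa diverges)")
  if (rho == 0) return(0)
  ub <- 1 / (1 - rho) + 5
  while (bessel_ratio(ub) < rho) ub <- ub * 2
  lo <- 0; hi <- ub
  best <- ub; best_err <- abs(bessel_ratio(ub) - rho)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    err <- bessel_ratio(mid) - rho
    if (abs(err) < best_err) { best <- mid; best_err <- abs(err) }
    if (err < 0) lo <- mid else hi <- mid
    if (best_err < 1e-13) break
  }
  best
}

# Best & Fisher (1979) rejection sampler for von Mises(0, kappa).
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

# Von Mises(0, kappa) quantiles by CDF inversion on a dense grid.
qvonmises <- function(p, kappa) {
  th <- seq(-pi, pi, length.out = 65536)
  d <- exp(kappa * (cos(th) - 1))
  cdf <- cumsum(d) / sum(d)
  approx(cdf, th, xout = p, rule = 2, ties = "ordered")$y
}

# Stratified von Mises block values whose mean phasor equals rho exactly.
stratified_vm <- function(n_blocks, rho) {
  kap <- kappa_for_plv(rho)
  q <- qvonmises((seq_len(n_blocks) - 0.5) / n_blocks, kap)
  if (rho == 0) return(q)
  g <- function(s) Mod(mean(exp(1i * s * q))) - rho
  s <- uniroot(g, c(0.25, 4), tol = 1e-12)$root
  s * q
}

#' Implanted group-difference effect
#'
#' @param seed_region a `plv_seed`: the driver region.
#' @param target_region integer vector of driven source indices (should be
#'   contiguous under the analysis adjacency; validated when `adjacency` is
#'   given).
#' @param band a [band_spec()]; default upper beta 20-30 Hz.
#' @param rho_robust coupling PLV in the robust group.
#' @param delta_rho coupling reduction in the frail group
#'   (`rho_frail = rho_robust - delta_rho`).
#' @param adjacency optional `plv_adjacency` used to check target
#'   contiguity.
#' @return object of class `plv_effect`.
#' @export
effect_spec <- function(seed_region, target_region,
                        band = band_spec("upper_beta", 20, 30),
                        rho_robust = 0.5, delta_rho = 0.15,
                        adjacency = NULL) {
  stopifnot(inherits(seed_region, "plv_seed"), inherits(band, "plv_band"))
  target_region <- as.integer(target_region)
  if (length(target_region) == 0) stop("target region is empty")
  if (rho_robust - delta_rho < 0)
    stop("rho_robust - delta_rho must be >= 0")
  if (rho_robust >= 1) stop("rho_robust must be < 1")
  if (length(intersect(seed_region$source_indices, target_region)))
    stop("seed and target regions overlap")
  if (!is.null(adjacency)) {
    nbr_local <- local_neighbors(adjacency, target_region)
    comps <- connected_components(seq_along(target_region), nbr_local)
    if (length(comps) != 1)
      stop("target region is not connected under the given adjacency")
  }
  structure(list(seed_region = seed_region, target_region = target_region,
                 band = band, rho_robust = rho_robust,
                 delta_rho = delta_rho),
            class = "plv_effect")
}

#' Cohort specification
#'
#' Defaults mirror the study conditions this generator emulates: 34 robust
#' and 20 frail subjects, 4-s epochs at 1000 Hz with per-subject epoch
#' counts drawn from round(Normal(81.0, 13.1)) (robust) and
#' round(Normal(77.5, 12.1)) (frail), clipped at 20, on a desk-scale
#' MNI-like 1-cm grid of ~300 sources.
#'
#' @param n_robust,n_frail group sizes (>= 2).
#' @param grid a `plv_grid`; default 7 x 9 x 5 box at 10-mm spacing
#'   (315 sources) centred on the origin in x/y.
#' @param fs sampling rate, Hz.
#' @param epoch_len epoch length, s.
#' @param epochs_mean,epochs_sd named per-group means / SDs of the epoch
#'   count.
#' @param epochs_min lower clip for drawn epoch counts.
#' @param epochs_fixed set to an integer to give every subject the same
#'   epoch count (overrides the draw).
#' @param bands named list of [band_spec()]s.
#' @param band_assignment character vector (length = grid sources) of band
#'   names assigning each source's carrier band; default cycles through
#'   `bands`.
#' @param base_coupling data.frame with columns `i`, `j`, `rho`: coupled
#'   pairs applying to all subjects (driver i, driven j).
#' @param effect a [effect_spec()] or `NULL`.
#' @param sigma_obs additive observation-noise SD (unit carrier amplitude).
#' @param background_amp amplitude of the independent background oscillators
#'   every source carries in each band other than its own (default 0.5;
#'   0 disables). Resting-state sources are broadband: without background
#'   activity, the faint spectral tails of a coupled carrier would be the
#'   only out-of-band content and coupling strength would leak into other
#'   bands' connectivity.
#' @param walk_sd per-sample SD of the random-walk phase wander (rad).
#' @param jitter_hold coupling-jitter hold time in samples; must divide the
#'   epoch length in samples.
#' @param rng_seed top-level seed; all subject streams derive from it.
#' @return object of class `plv_cohort_spec`.
#' @export
cohort_spec <- function(n_robust = 34, n_frail = 20,
                        grid = build_regular_grid(c(-30, -40, 0), c(30, 40, 40),
                                                  spacing = 10),
                        fs = 1000, epoch_len = 4,
                        epochs_mean = c(robust = 81.0, frail = 77.5),
                        epochs_sd = c(robust = 13.1, frail = 12.1),
                        epochs_min = 20, epochs_fixed = NULL,
                        bands = default_bands(),
                        band_assignment = NULL,
                        base_coupling = NULL,
                        effect = NULL,
                        sigma_obs = 0.2, background_amp = 0.5,
                        walk_sd = 0.05,
                        jitter_hold = 160, rng_seed = 1L) {
  if (n_robust < 2 || n_frail < 2) stop("group sizes must be >= 2")
  stopifnot(inherits(grid, "plv_grid"))
  spp <- round(epoch_len * fs)
  if (spp %% jitter_hold != 0)
    stop("jitter_hold must divide the epoch length in samples")
  if (is.null(band_assignment)) {
    band_assignment <- rep(names(bands), length.out = grid$n_sources)
  }
  if (length(band_assignment) != grid$n_sources)
    stop("band_assignment must name a band per source")
  if (!all(band_assignment %in% names(bands)))
    stop("band_assignment refers to unknown bands")
  if (!is.null(base_coupling)) {
    stopifnot(all(c("i", "j", "rho") %in% names(base_coupling)))
    if (any(base_coupling$rho < 0 | base_coupling$rho >= 1))
      stop("coupling rho must lie in [0, 1)")
  }
  if (!is.null(effect)) stopifnot(inherits(effect, "plv_effect"))
  structure(list(n_robust = n_robust, n_frail = n_frail, grid = grid,
                 fs = fs, epoch_len = epoch_len, spp = spp,
                 epochs_mean = epochs_mean, epochs_sd = epochs_sd,
                 epochs_min = epochs_min, epochs_fixed = epochs_fixed,
                 bands = bands, band_assignment = band_assignment,
                 base_coupling = base_coupling, effect = effect,
                 sigma_obs = sigma_obs, background_amp = background_amp,
                 walk_sd = walk_sd,
                 jitter_hold = jitter_hold, rng_seed = rng_seed),
            class = "plv_cohort_spec")
}

# Resolve the coupling pair list effective for one group:
# data.frame(i, j, rho, band).
effective_coupling <- function(spec, group) {
  pairs <- NULL
  if (!is.null(spec$base_coupling)) {
    pairs <- data.frame(i = spec$base_coupling$i, j = spec$base_coupling$j,
                        rho = spec$base_coupling$rho,
                        band = spec$band_assignment[spec$base_coupling$i],
                        stringsAsFactors = FALSE)
  }
  if (!is.null(spec$effect)) {
    ef <- spec$effect
    rho <- if (group == "robust") ef$rho_robust else
      ef$rho_robust - ef$delta_rho
    drivers <- rep(ef$seed_region$source_indices,
                   length.out = length(ef$target_region))
    pairs <- rbind(pairs,
                   data.frame(i = drivers, j = ef$target_region, rho = rho,
                              band = ef$band$name, stringsAsFactors = FALSE))
  }
  if (!is.null(pairs) && anyDuplicated(pairs$j))
    stop("conflicting coupling: a source may be driven by at most one pair")
  pairs
}

#' Simulate one subject's continuous source time series
#'
#' @param spec a [cohort_spec()].
#' @param group `"robust"` or `"frail"`.
#' @param rng_seed subject-level seed (bit-identical output for identical
#'   seed and spec).
#' @param n_epochs number of 4-s epochs to generate (default: the group's
#'   clipped-normal draw, using the subject stream).
#' @return list: `data` (sources x samples matrix), `n_epochs`, `pairs`
#'   (the effective coupling table), `carrier_freq` per source.
#' @export
simulate_subject <- function(spec, group = c("robust", "frail"),
                             rng_seed = 1L, n_epochs = NULL) {
  group <- match.arg(group)
  stopifnot(inherits(spec, "plv_cohort_spec"))
  pairs <- effective_coupling(spec, group)
  with_seed(rng_seed, {
    # the epoch-count draw is always consumed so that the stream is identical
    # whether or not the caller passes n_epochs (cohort manifests do)
    drawn <- if (!is.null(spec$epochs_fixed)) as.integer(spec$epochs_fixed) else
      max(spec$epochs_min,
          as.integer(round(rnorm(1, spec$epochs_mean[[group]],
                                 spec$epochs_sd[[group]]))))
    if (is.null(n_epochs)) n_epochs <- drawn
    S <- spec$grid$n_sources
    N <- n_epochs * spec$spp
    tt <- (0:(N - 1)) / spec$fs
    driven <- if (is.null(pairs)) integer(0) else pairs$j
    band_of <- spec$band_assignment
    if (!is.null(pairs)) band_of[pairs$i] <- pairs$band
    phases <- matrix(0, S, N)
    carrier <- numeric(S)
    for (s in seq_len(S)) {
      if (s %in% driven) next
      b <- spec$bands[[band_of[s]]]
      carrier[s] <- runif(1, b$lo, b$hi)
      phases[s, ] <- 2 * pi * carrier[s] * tt + runif(1, -pi, pi) +
        cumsum(rnorm(N, 0, spec$walk_sd))
    }
    if (!is.null(pairs)) {
      L <- spec$jitter_hold
      nb <- spec$spp / L
      for (r in seq_len(nrow(pairs))) {
        strata <- stratified_vm(nb, pairs$rho[r])
        eps <- as.vector(vapply(seq_len(n_epochs),
                                function(e) rep(sample(strata), each = L),
                                numeric(spec$spp)))
        delta <- runif(1, -pi, pi)
        j <- pairs$j[r]
        phases[j, ] <- phases[pairs$i[r], ] + delta + eps
        carrier[j] <- carrier[pairs$i[r]]
        band_of[j] <- pairs$band[r]   # the driven carrier lives in this band
      }
    }
    data <- cos(phases) + matrix(rnorm(S * N, 0, spec$sigma_obs), S, N)
    if (spec$background_amp > 0) {
      # independent background oscillator per source in every other band
      for (s in seq_len(S)) {
        for (bn in setdiff(names(spec$bands), band_of[s])) {
          b <- spec$bands[[bn]]
          fb <- runif(1, b$lo, b$hi)
          data[s, ] <- data[s, ] + spec$background_amp *
            cos(2 * pi * fb * tt + runif(1, -pi, pi) +
                  cumsum(rnorm(N, 0, spec$walk_sd)))
        }
      }
    }
    list(data = data, n_epochs = n_epochs, pairs = pairs,
         carrier_freq = carrier, group = group)
  })
}

#' Simulate a two-group cohort
#'
#' Every subject gets an independent child RNG stream derived from the
#' spec's `rng_seed`, so any subject can be re-generated deterministically
#' without materialising the others; [cohort_subject()] does exactly that.
#' With `out_dir` set, per-subject data are also written to disk (RDS)
#' together with a TSV manifest and a JSON ground-truth record.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional output directory.
#' @return object of class `plv_cohort`: `spec`, `manifest` (data.frame:
#'   subject_id, group, n_epochs, rng_seed), `truth` (coupling tables per
#'   group incl. expected PLV via the Bessel-ratio map, effect membership,
#'   all seeds).
#' @export
simulate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "plv_cohort_spec"))
  n <- spec$n_robust + spec$n_frail
  groups <- c(rep("robust", spec$n_robust), rep("frail", spec$n_frail))
  seeds <- with_seed(spec$rng_seed, sample.int(.Machine$integer.max - 1L, n))
  n_epochs <- vapply(seq_len(n), function(k) {
    if (!is.null(spec$epochs_fixed)) return(as.integer(spec$epochs_fixed))
    with_seed(seeds[k],
              as.integer(max(spec$epochs_min,
                             round(rnorm(1, spec$epochs_mean[[groups[k]]],
                                         spec$epochs_sd[[groups[k]]])))))
  }, integer(1))
  manifest <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = groups, n_epochs = n_epochs, rng_seed = seeds,
    stringsAsFactors = FALSE)
  truth <- list(
    rng_seed = spec$rng_seed,
    coupling = list(robust = effective_coupling(spec, "robust"),
                    frail = effective_coupling(spec, "frail")),
    effect = if (is.null(spec$effect)) NULL else list(
      seed_sources = spec$effect$seed_region$source_indices,
      target_sources = spec$effect$target_region,
      band = spec$effect$band$name,
      rho_robust = spec$effect$rho_robust,
      delta_rho = spec$effect$delta_rho),
    subject_seeds = seeds)
  for (g in names(truth$coupling))
    if (!is.null(truth$coupling[[g]]))
      truth$coupling[[g]]$expected_plv <-
        vapply(truth$coupling[[g]]$rho,
               function(r) bessel_ratio(kappa_for_plv(r)), numeric(1))
  cohort <- structure(list(spec = spec, manifest = manifest, truth = truth,
                           dir = out_dir),
                      class = "plv_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    saveRDS(spec, file.path(out_dir, "spec.rds"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    for (k in seq_len(n)) {
      sub <- simulate_subject(spec, groups[k], seeds[k],
                              n_epochs = n_epochs[k])
      saveRDS(sub, file.path(out_dir,
                             paste0(manifest$subject_id[k], ".rds")))
    }
  }
  cohort
}

#' Materialise one subject of a cohort
#'
#' @param cohort a `plv_cohort`.
#' @param k subject number (row of the manifest).
#' @return as [simulate_subject()].
#' @export
cohort_subject <- function(cohort, k) {
  stopifnot(inherits(cohort, "plv_cohort"))
  m <- cohort$manifest[k, ]
  if (!is.null(cohort$dir) &&
      file.exists(file.path(cohort$dir, paste0(m$subject_id, ".rds"))))
    return(readRDS(file.path(cohort$dir, paste0(m$subject_id, ".rds"))))
  simulate_subject(cohort$spec, m$group, m$rng_seed, n_epochs = m$n_epochs)
}

#' @export
print.plv_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d robust / %d frail, %d sources, fs %g Hz\n",
              x$spec$n_robust, x$spec$n_frail, x$spec$grid$n_sources,
              x$spec$fs))
  cat(sprintf("  epochs per subject: %s\n",
              paste(range(x$manifest$n_epochs), collapse = "-")))
  if (!is.null(x$spec$effect))
    cat(sprintf("  implanted effect: band %s, rho %g -> %g, %d target sources\n",
                x$spec$effect$band$name, x$spec$effect$rho_robust,
                x$spec$effect$rho_robust - x$spec$effect$delta_rho,
                length(x$spec$effect$target_region)))
  invisible(x)
}

#' Simulate a clinical table
#'
#' @param n_robust,n_frail group sizes.
#' @param variable_specs list of variable specifications. Categorical:
#'   `list(name=, type="categorical", levels=c(...), p_robust=, p_frail=)`
#'   where the probabilities refer to the first level (binary) or are
#'   per-level vectors. Continuous:
#'   `list(name=, type="continuous", robust=c(mean, sd), frail=c(mean, sd))`.
#' @param rng_seed seed.
#' @return a [clinical_table()] with groups "robust"/"frail".
#' @export
simulate_clinical <- function(n_robust, n_frail, variable_specs,
                              rng_seed = 1L) {
  if (length(variable_specs) == 0) stop("need at least one variable spec")
  n <- n_robust + n_frail
  groups <- c(rep("robust", n_robust), rep("frail", n_frail))
  with_seed(rng_seed, {
    cols <- list(subject_id = sprintf("sub-%03d", seq_len(n)),
                 group = groups)
    types <- character(0)
    for (vs in variable_specs) {
      if (vs$type == "categorical") {
        draw <- function(p, size, levels) {
          if (length(p) == 1) p <- c(p, 1 - p)
          if (any(p < 0 | p > 1)) stop("probabilities outside [0, 1]")
          sample(levels, size, replace = TRUE, prob = p)
        }
        cols[[vs$name]] <- c(draw(vs$p_robust, n_robust, vs$levels),
                             draw(vs$p_frail, n_frail, vs$levels))
      } else if (vs$type == "continuous") {
        cols[[vs$name]] <- c(rnorm(n_robust, vs$robust[1], vs$robust[2]),
                             rnorm(n_frail, vs$frail[1], vs$frail[2]))
      } else stop("unknown variable type: ", vs$type)
      types[vs$name] <- vs$type
    }
    clinical_table(as.data.frame(cols, stringsAsFactors = FALSE), types)
  })
}
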