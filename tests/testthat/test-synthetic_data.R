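ub <- band_spec("upper_beta", 20, 30)

test_that("kappa_for_plv inverts the Bessel-ratio map to 1e-10", {
  expect_equal(kappa_for_plv(0), 0)
  k5 <- kappa_for_plv(0.5)
  expect_equal(k5, 1.1595, tolerance = 1e-3)
  expect_lt(abs(besselI(k5, 1, TRUE) / besselI(k5, 0, TRUE) - 0.5), 1e-10)
  set.seed(30)
  for (rho in runif(50, 0, 0.99)) {
    k <- kappa_for_plv(rho)
    expect_lt(abs(besselI(k, 1, TRUE) / besselI(k, 0, TRUE) - rho), 1e-10)
  }
  expect_error(kappa_for_plv(1), "unattainable")
  expect_error(kappa_for_plv(-0.1), "scalar in")
})

two_source_spec <- function(rho, nep = 20) {
  cohort_spec(n_robust = 2, n_frail = 2,
              grid = build_regular_grid(c(0, 0, 0), c(10, 0, 0), 10),
              epochs_fixed = nep,
              base_coupling = data.frame(i = 1, j = 2, rho = rho),
              band_assignment = rep("upper_beta", 2))
}

pipeline_pair_plv <- function(sub, spec, band = ub) {
  ph <- suppressWarnings(band_phases(sub$data, spec$fs, band,
                                     epoch_len = spec$epoch_len))
  plv_pair(matrix(ph$data[1, , ], sub$n_epochs),
           matrix(ph$data[2, , ], sub$n_epochs))
}

test_that("simulated subjects are deterministic and respect the coupling graph", {
  sp <- two_source_spec(0.6)
  s1 <- simulate_subject(sp, "robust", rng_seed = 77)
  s2 <- simulate_subject(sp, "robust", rng_seed = 77)
  expect_identical(s1$data, s2$data)               # bit-identical
  s3 <- simulate_subject(sp, "robust", rng_seed = 78)
  expect_false(identical(s1$data, s3$data))
  expect_equal(dim(s1$data), c(2, 20 * 4000))

  bad <- cohort_spec(n_robust = 2, n_frail = 2,
                     grid = build_regular_grid(c(0, 0, 0), c(20, 0, 0), 10),
                     epochs_fixed = 20,
                     base_coupling = data.frame(i = c(1, 3), j = c(2, 2),
                                                rho = c(0.5, 0.5)),
                     band_assignment = rep("upper_beta", 3))
  expect_error(simulate_subject(bad, "robust", 1), "at most one pair")
})

test_that("the pipeline recovers implanted coupling at high PLV and rejects none", {
  sp <- two_source_spec(0.9)
  est <- mean(vapply(1:4, function(k)
    pipeline_pair_plv(simulate_subject(sp, "robust", 200 + k), sp),
    numeric(1)))
  expect_lt(abs(est - 0.9), 0.05)

  # Uncoupled pairs stay below the narrowband null's 95th percentile,
  # provided the two carriers are separated by more than the oscillator
  # linewidth (~0.4 Hz at walk_sd = 0.05): two free-running oscillators at
  # near-identical frequency genuinely phase-lock, which is oscillator
  # physics, not spurious coupling. Subjects are selected a priori on the
  # ground-truth carrier separation, never on the measured PLV.
  sp0 <- cohort_spec(n_robust = 2, n_frail = 2,
                     grid = build_regular_grid(c(0, 0, 0), c(10, 0, 0), 10),
                     epochs_fixed = 20,
                     band_assignment = rep("upper_beta", 2))
  subs <- lapply(301:312, function(k) simulate_subject(sp0, "robust", k))
  sep <- vapply(subs, function(s) abs(diff(s$carrier_freq)), numeric(1))
  subs <- subs[sep > 1][1:6]
  est0 <- vapply(subs, function(s) pipeline_pair_plv(s, sp0), numeric(1))
  # Monte-Carlo null: independent band-filtered noise, same T and epochs
  set.seed(31)
  null_plv <- replicate(30, {
    x <- rbind(rnorm(80000), rnorm(80000))
    ph <- suppressWarnings(band_phases(x, 1000, ub))
    plv_pair(matrix(ph$data[1, , ], 20), matrix(ph$data[2, , ], 20))
  })
  expect_true(all(est0 < unname(quantile(null_plv, 0.95)) + 0.02))
})

test_that("cohort manifests follow the study conditions and carry ground truth", {
  sp <- cohort_spec(rng_seed = 5)     # full defaults; manifest only, no data
  co <- simulate_cohort(sp)
  expect_equal(nrow(co$manifest), 54)
  expect_equal(sum(co$manifest$group == "robust"), 34)
  expect_equal(sum(co$manifest$group == "frail"), 20)
  expect_true(all(co$manifest$n_epochs >= 20))
  expect_equal(anyDuplicated(co$manifest$rng_seed), 0)

  sp2 <- power_cohort_spec(rng_seed = 8)
  co2 <- simulate_cohort(sp2)
  tr <- co2$truth
  expect_equal(tr$coupling$robust$rho, rep(0.5, 6))
  expect_equal(tr$coupling$frail$rho, rep(0.35, 6))
  expect_equal(tr$coupling$robust$expected_plv, tr$coupling$robust$rho,
               tolerance = 1e-9)                    # Bessel-ratio round trip
  expect_equal(tr$effect$target_sources, 13:18)

  # same seed -> identical manifest and identical first subject
  co3 <- simulate_cohort(power_cohort_spec(rng_seed = 8))
  expect_identical(co2$manifest, co3$manifest)
  expect_identical(cohort_subject(co2, 1)$data, cohort_subject(co3, 1)$data)
})

test_that("cohort serialisation writes manifest, truth and per-subject data", {
  dir <- withr::local_tempdir()
  sp <- two_source_spec(0.4, nep = 20)
  co <- simulate_cohort(sp, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "sub-001.rds")))
  tr <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(tr$coupling$robust$rho, 0.4)
  # reading from disk equals regenerating from the seed
  on_disk <- cohort_subject(co, 2)
  regen <- simulate_subject(sp, co$manifest$group[2], co$manifest$rng_seed[2],
                            n_epochs = co$manifest$n_epochs[2])
  expect_identical(on_disk$data, regen$data)
})

test_that("implanted effects shift group-mean PLV by the Bessel-ratio prediction", {
  sp <- power_cohort_spec(rng_seed = 42, n_robust = 6, n_frail = 6)
  co <- simulate_cohort(sp)
  seed <- sp$effect$seed_region
  fir <- design_bandpass_fir(ub, sp$fs)
  mean_target_plv <- function(k) {
    sub <- cohort_subject(co, k)
    ph <- suppressWarnings(band_phases(sub$data, sp$fs, ub, fir = fir))
    rows <- plv_rows(ph, seed$source_indices)
    drv <- rep(seed$source_indices, length.out = length(13:18))
    mean(rows[cbind(match(drv, seed$source_indices), 13:18)])
  }
  v <- vapply(seq_len(nrow(co$manifest)), mean_target_plv, numeric(1))
  rob <- v[co$manifest$group == "robust"]; fra <- v[co$manifest$group == "frail"]
  expect_lt(abs((mean(rob) - mean(fra)) - 0.15), 0.03)
})

test_that("simulate_clinical honours probabilities, types and seeds", {
  specs <- list(
    list(name = "sex", type = "categorical", levels = c("female", "male"),
         p_robust = 1, p_frail = 1),
    list(name = "gait", type = "continuous", robust = c(1, 0.1),
         frail = c(0.7, 0.1)))
  t1 <- simulate_clinical(10, 8, specs, rng_seed = 3)
  expect_true(all(t1$data$sex == "female"))        # deterministic draw
  t2 <- simulate_clinical(10, 8, specs, rng_seed = 3)
  expect_identical(t1$data, t2$data)
  expect_equal(t1$types, c(sex = "categorical", gait = "continuous"))

  bad <- list(list(name = "x", type = "categorical",
                   levels = c("a", "b"), p_robust = 1.4, p_frail = 0.5))
  expect_error(simulate_clinical(5, 5, bad, 1), "outside")
  expect_error(simulate_clinical(5, 5, list(), 1), "at least one")
})
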