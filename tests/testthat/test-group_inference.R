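line_grid <- function(n) build_regular_grid(c(0, 0, 0), c((n - 1) * 10, 0, 0), 10)

test_that("pointwise_t matches hand computation and the reference implementation", {
  X0 <- matrix(rep(c(1, 2, 3, 1, 2, 3), 2), 6)
  t0 <- pointwise_t(X0, rep(c("a", "b"), each = 3))
  expect_equal(t0$t, c(0, 0))

  X <- matrix(c(1, 2, 3, 4, 5, 6), 6)
  tm <- pointwise_t(X, rep(c("g1", "g2"), each = 3))
  expect_equal(round(tm$t, 3), -3.674)    # pooled two-sample t by hand
  expect_equal(tm$df, 4)

  set.seed(10)
  Xr <- matrix(rnorm(12 * 7), 12)
  gr <- rep(c("g1", "g2"), c(7, 5))
  tp <- pointwise_t(Xr, gr, "pooled")
  tw <- pointwise_t(Xr, gr, "welch")
  for (j in 1:7) {
    ref_p <- t.test(Xr[1:7, j], Xr[8:12, j], var.equal = TRUE)
    ref_w <- t.test(Xr[1:7, j], Xr[8:12, j], var.equal = FALSE)
    expect_equal(tp$t[j], unname(ref_p$statistic), tolerance = 1e-10)
    expect_equal(tw$t[j], unname(ref_w$statistic), tolerance = 1e-10)
    expect_equal(tw$df[j], unname(ref_w$parameter), tolerance = 1e-10)
  }
  expect_warning(pointwise_t(matrix(1, 6, 2), rep(c("a", "b"), each = 3)),
                 "zero variance")
  expect_error(pointwise_t(Xr, rep("a", 12)), "two levels")
})

test_that("find_clusters splits suprathreshold sources by sign into components", {
  g <- line_grid(5)
  adj <- build_adjacency(g)
  mk_tmap <- function(t) structure(
    list(t = t, df = rep(1e6, length(t)), n1 = 10, n2 = 10,
         group_levels = c("a", "b"), t_variant = "pooled",
         source_index = seq_along(t)), class = "plv_tmap")

  expect_length(find_clusters(mk_tmap(rep(0, 5)), adj, 0.05), 0)

  # chain t = (0, 4, 4, 0, 4) with threshold |t| > ~1.96: masses 8 and 4
  cl <- find_clusters(mk_tmap(c(0, 4, 4, 0, 4)), adj, 0.05)
  expect_length(cl, 2)
  expect_setequal(vapply(cl, `[[`, numeric(1), "mass"), c(8, 4))
  expect_equal(sort(cl[[which.max(vapply(cl, `[[`, numeric(1), "mass"))]]$source_index),
               c(2, 3))

  # mixed signs never merge
  cl2 <- find_clusters(mk_tmap(c(4, -4, 4, -4, 4)), adj, 0.05)
  expect_length(cl2, 5)

  # random t-maps on a random partial grid match the flood-fill oracle
  set.seed(12)
  gr <- build_regular_grid(c(0, 0, 0), c(40, 30, 10), 10)
  adjr <- build_adjacency(gr)
  for (r in 1:10) {
    t_vals <- rnorm(gr$n_sources, sd = 2)
    cl <- find_clusters(mk_tmap(t_vals), adjr, 0.05)
    thr <- qt(1 - 0.025, 1e6)
    for (sgn in c(1, -1)) {
      nodes <- which(sgn * t_vals > thr)
      want <- bf_components(nodes, adjr$neighbors)
      got <- lapply(Filter(function(c.)
        c.$sign == if (sgn > 0) "positive" else "negative", cl),
        function(c.) sort(c.$source_index))
      got <- got[order(vapply(got, min, numeric(1)))]
      expect_equal(got, want)
    }
  }
})

test_that("cluster permutation p-values are valid, deterministic and label-symmetric", {
  set.seed(13)
  g <- build_regular_grid(c(0, 0, 0), c(40, 30, 0), 10)
  adj <- build_adjacency(g)
  X <- matrix(rnorm(14 * g$n_sources), 14)
  X[1:8, 5:8] <- X[1:8, 5:8] + 2.5
  gr <- rep(c("g1", "g2"), c(8, 6))
  cfg <- cbpt_config(n_permutations = 400, rng_seed = 99)

  r1 <- cluster_permutation_test(X, gr, adj, cfg)
  r2 <- cluster_permutation_test(X, gr, adj, cfg)
  expect_identical(r1$clusters, r2$clusters)       # determinism contract
  expect_gt(length(r1$clusters), 0)
  for (cl in r1$clusters) {
    expect_equal(cl$mass, sum(r1$tmap$t[cl$members]))  # exact mass
    expect_gt(cl$p_value, 0); expect_lte(cl$p_value, 1)
  }
  expect_lte(r1$clusters[[1]]$p_value, min(vapply(r1$clusters, `[[`,
                                                  numeric(1), "p_value")))

  # relabeling the groups flips t and cluster signs, p unchanged
  gr_flip <- factor(gr, levels = c("g2", "g1"))
  r_flip <- cluster_permutation_test(X, gr_flip, adj, cfg)
  expect_equal(r_flip$tmap$t, -r1$tmap$t)
  expect_equal(vapply(r_flip$clusters, `[[`, numeric(1), "p_value"),
               vapply(r1$clusters, `[[`, numeric(1), "p_value"))
  expect_equal(vapply(r_flip$clusters, `[[`, character(1), "sign"),
               c(negative = "positive", positive = "negative")[
                 vapply(r1$clusters, `[[`, character(1), "sign")],
               ignore_attr = TRUE)

  expect_error(cluster_permutation_test(X[1:5, ], rep(c("a", "b"), c(3, 2)),
                                        adj, cfg),
               "distinct relabelings")
})

test_that("Monte-Carlo CBPT converges to the exact permutation distribution", {
  set.seed(14)
  g <- line_grid(8)
  adj <- build_adjacency(g)
  X <- matrix(rnorm(8 * 8), 8)
  X[1:4, 3:5] <- X[1:4, 3:5] + 2
  gr <- rep(c("a", "b"), each = 4)

  cfg_ex <- cbpt_config(n_permutations = "exhaustive", rng_seed = 1,
                        min_relabelings = 70)
  r_ex <- cluster_permutation_test(X, gr, adj, cfg_ex)
  expect_equal(r_ex$n_permutations, choose(8, 4))

  # independent exact oracle: enumerate all 70 relabelings by brute force
  thr <- qt(1 - 0.025, 6)
  splits <- combn(8, 4, simplify = FALSE)
  max_masses <- vapply(splits, function(s) {
    tv <- vapply(1:8, function(j)
      unname(t.test(X[s, j], X[-s, j], var.equal = TRUE)$statistic),
      numeric(1))
    best <- 0
    for (sgn in c(1, -1)) {
      nodes <- which(sgn * tv > thr)
      for (cp in bf_components(nodes, adj$neighbors))
        best <- max(best, abs(sum(tv[cp])))
    }
    best
  }, numeric(1))
  for (cl in r_ex$clusters) {
    p_oracle <- mean(max_masses >= abs(cl$mass) - 1e-12)
    expect_equal(cl$p_value, p_oracle, tolerance = 1e-12)
  }

  # Monte-Carlo estimate approaches the exact p
  cfg_mc <- cbpt_config(n_permutations = 4000, rng_seed = 5,
                        min_relabelings = 70)
  r_mc <- cluster_permutation_test(X, gr, adj, cfg_mc)
  expect_equal(vapply(r_mc$clusters, `[[`, numeric(1), "p_value"),
               vapply(r_ex$clusters, `[[`, numeric(1), "p_value"),
               tolerance = 0.05)
})

test_that("rsn_group_test is a two-sided independent-samples t-test", {
  v <- c(1, 2, 3, 4, 1, 2, 3, 4)
  gr <- rep(c("a", "b"), each = 4)
  r <- rsn_group_test(v, gr, network = "FPN", band = "upper_beta")
  expect_equal(r$p, 1, tolerance = 1e-12)
  expect_equal(r$t, 0, tolerance = 1e-12)

  set.seed(15)
  x <- rnorm(10); y <- rnorm(8, 1)
  r2 <- rsn_group_test(c(x, y), rep(c("a", "b"), c(10, 8)))
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(r2$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r2$p, ref$p.value, tolerance = 1e-10)
  expect_error(rsn_group_test(1:3, c("a", "a", "b")), "2 subjects")
})

test_that("two-sample t power matches the noncentral-t closed form", {
  # shifted normals, delta = 1 SD, n = 34 vs 20: rejection rate within 5
  # percentage points of the analytic power at alpha = 0.05
  n1 <- 34; n2 <- 20; delta <- 1
  ncp <- delta / sqrt(1 / n1 + 1 / n2)
  df <- n1 + n2 - 2
  crit <- qt(0.975, df)
  power <- pt(-crit, df, ncp) + 1 - pt(crit, df, ncp)
  set.seed(16)
  rej <- mean(replicate(500, {
    r <- rsn_group_test(c(rnorm(n1, delta), rnorm(n2)),
                        rep(c("r", "f"), c(n1, n2)))
    r$p < 0.05
  }))
  expect_lt(abs(rej - power), 0.05)
})
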