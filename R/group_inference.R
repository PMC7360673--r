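#' Group inference: pointwise t-tests and cluster-based permutation testing
#'
#' Seed connectivity vectors are compared between two groups with an
#' independent-samples t-test at every source. Family-wise control over
#' sources uses cluster-based permutation testing (CBPT): sources with
#' two-sided p below the cluster-forming alpha are grouped by t-sign into
#' spatially contiguous clusters scored by their summed t ("cluster mass",
#' the T-statsum); observed masses are referred to the Monte-Carlo null of
#' the maximum absolute cluster mass under random relabelings of subjects.
#'
#' @name group_inference
NULL

#' Configuration for the cluster-based permutation test
#'
#' @param cluster_forming_alpha two-sided pointwise alpha that admits a
#'   source into a cluster (default 0.05).
#' @param n_permutations Monte-Carlo relabelings (default 5000), or
#'   `"exhaustive"` to enumerate all distinct relabelings (tiny groups only).
#' @param rng_seed seed for the relabeling stream (mandatory for
#'   reproducibility).
#' @param t_variant `"pooled"` (Student, default) or `"welch"`.
#' @param null_statistic `"max_abs_mass"` (default; two-sided family control
#'   over both cluster signs) or `"per_sign"` (separate negative/positive
#'   nulls).
#' @param min_relabelings smallest number of distinct relabelings the group
#'   sizes must admit (default 100).
#' @return list of class `plv_cbpt_config`.
#' @export
cbpt_config <- function(cluster_forming_alpha = 0.05, n_permutations = 5000,
                        rng_seed = 1L,
                        t_variant = c("pooled", "welch"),
                        null_statistic = c("max_abs_mass", "per_sign"),
                        min_relabelings = 100) {
  t_variant <- match.arg(t_variant)
  null_statistic <- match.arg(null_statistic)
  if (!(is.numeric(cluster_forming_alpha) && cluster_forming_alpha > 0 &&
        cluster_forming_alpha < 1))
    stop("cluster_forming_alpha must lie in (0, 1)")
  if (!identical(n_permutations, "exhaustive")) {
    if (!(is.numeric(n_permutations) && n_permutations >= 100))
      stop("n_permutations must be >= 100 (or \"exhaustive\")")
    n_permutations <- as.integer(n_permutations)
  }
  structure(list(cluster_forming_alpha = cluster_forming_alpha,
                 n_permutations = n_permutations, rng_seed = rng_seed,
                 t_variant = t_variant, null_statistic = null_statistic,
                 min_relabelings = min_relabelings),
            class = "plv_cbpt_config")
}

# Vectorised two-sample t for one grouping over columns of X (subjects x k).
# Returns list(t, df); zero variance in both groups at a column -> t = 0.
two_sample_t_cols <- function(X, g1, variant = "pooled", warn_zero = TRUE) {
  n <- nrow(X); n1 <- length(g1); n2 <- n - n1
  X1 <- X[g1, , drop = FALSE]; X2 <- X[-g1, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  ss1 <- colSums(X1^2) - n1 * m1^2
  ss2 <- colSums(X2^2) - n2 * m2^2
  if (variant == "pooled") {
    sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, ncol(X))
  } else {
    v1 <- ss1 / (n1 - 1); v2 <- ss2 / (n2 - 1)
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      (pmax(v1 / n1, 0)^2 / (n1 - 1) + pmax(v2 / n2, 0)^2 / (n2 - 1))
  }
  zero <- !is.finite(se) | se <= 0
  t <- (m1 - m2) / se
  if (any(zero)) {
    if (warn_zero)
      warning(sprintf("%d source(s) with zero variance in both groups; t set to 0",
                      sum(zero)), call. = FALSE)
    t[zero] <- 0
    df[!is.finite(df)] <- n1 + n2 - 2
  }
  list(t = t, df = df)
}

#' Pointwise independent-samples t-map
#'
#' Two-sample t statistic at every source. Positive t means the first group
#' level (by convention the robust group) has the larger mean.
#'
#' @param values matrix, subjects x sources (e.g. stacked [seed_fc()]
#'   values).
#' @param groups factor/character of length `nrow(values)` with exactly two
#'   levels; the first level is "group 1".
#' @param t_variant `"pooled"` or `"welch"`.
#' @param source_index optional grid indices of the columns (carried to
#'   clustering).
#' @return object of class `plv_tmap`: `t`, `df`, `n1`, `n2`,
#'   `source_index`.
#' @export
pointwise_t <- function(values, groups, t_variant = c("pooled", "welch"),
                        source_index = seq_len(ncol(values))) {
  t_variant <- match.arg(t_variant)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  g1 <- which(groups == levels(groups)[1])
  if (length(g1) < 2 || nrow(values) - length(g1) < 2)
    stop("both groups need at least 2 subjects")
  r <- two_sample_t_cols(values, g1, variant = t_variant)
  structure(list(t = r$t, df = r$df, n1 = length(g1),
                 n2 = nrow(values) - length(g1),
                 group_levels = levels(groups), t_variant = t_variant,
                 source_index = as.integer(source_index)),
            class = "plv_tmap")
}

# Connected components of `nodes` (local column positions) under local
# neighbour lists; returns list of integer vectors.
connected_components <- function(nodes, nbr_local) {
  comps <- list()
  seen <- logical(length(nbr_local))
  inset <- logical(length(seen))
  inset[nodes] <- TRUE
  for (s in nodes) {
    if (seen[s]) next
    stack <- s; seen[s] <- TRUE; comp <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      comp <- c(comp, v)
      nb <- nbr_local[[v]]
      nb <- nb[inset[nb] & !seen[nb]]
      if (length(nb)) { seen[nb] <- TRUE; stack <- c(stack, nb) }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# Remap a grid adjacency to local column positions given source_index.
local_neighbors <- function(adjacency, source_index) {
  pos <- integer(adjacency$n_sources)
  pos[source_index] <- seq_along(source_index)
  lapply(source_index, function(g) {
    nb <- adjacency$neighbors[[g]]
    p <- pos[nb]
    p[p > 0L]
  })
}

#' Find suprathreshold spatial clusters in a t-map
#'
#' Sources with two-sided p below `alpha` are split by the sign of t;
#' connected components (under the grid adjacency) within each sign form
#' proto-clusters whose mass is the sum of member t-values.
#'
#' @param tmap a `plv_tmap`.
#' @param adjacency a `plv_adjacency` over the full grid.
#' @param alpha cluster-forming two-sided alpha.
#' @return list of clusters, each `list(members, source_index, mass, sign)`;
#'   empty list when nothing is suprathreshold. Members are column positions
#'   into the t-map; `source_index` the corresponding grid indices.
#' @export
find_clusters <- function(tmap, adjacency, alpha = 0.05) {
  stopifnot(inherits(tmap, "plv_tmap"), inherits(adjacency, "plv_adjacency"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  nbr_local <- local_neighbors(adjacency, tmap$source_index)
  crit <- qt(1 - alpha / 2, tmap$df)
  clusters_from_t(tmap$t, crit, nbr_local, tmap$source_index)
}

clusters_from_t <- function(t, crit, nbr_local, source_index) {
  out <- list()
  for (sgn in c(1, -1)) {
    nodes <- which(sgn * t > crit)
    if (length(nodes) == 0) next
    for (comp in connected_components(nodes, nbr_local)) {
      out[[length(out) + 1]] <- list(
        members = comp,
        source_index = source_index[comp],
        mass = sum(t[comp]),
        sign = if (sgn > 0) "positive" else "negative")
    }
  }
  out
}

# Max |mass| (and per-sign maxima) for one permutation t row.
max_cluster_mass <- function(t, crit, nbr_local) {
  mx <- c(abs = 0, pos = 0, neg = 0)
  for (sgn in c(1, -1)) {
    nodes <- which(sgn * t > crit)
    if (length(nodes) == 0) next
    for (comp in connected_components(nodes, nbr_local)) {
      m <- abs(sum(t[comp]))
      mx["abs"] <- max(mx["abs"], m)
      if (sgn > 0) mx["pos"] <- max(mx["pos"], m) else
        mx["neg"] <- max(mx["neg"], m)
    }
  }
  mx
}

#' Cluster-based Monte-Carlo permutation test
#'
#' Observed clusters are formed with [find_clusters()]. For each random
#' relabeling of subjects (preserving group sizes) the t-map is recomputed
#' and the maximum absolute cluster mass recorded (0 when no cluster forms).
#' Each observed cluster's p-value is `(1 + #(perm max >= |mass|)) /
#' (n_permutations + 1)`; with `n_permutations = "exhaustive"` all distinct
#' relabelings are enumerated and `p = #(max >= |mass|) / N`.
#'
#' @inheritParams pointwise_t
#' @param adjacency a `plv_adjacency`.
#' @param config a [cbpt_config()].
#' @return object of class `plv_cbpt`: `clusters` (sorted by p; each with
#'   `members`, `source_index`, `mass`, `sign`, `p_value`, `n_permutations`),
#'   the observed `tmap`, and the `config` echo.
#' @export
cluster_permutation_test <- function(values, groups, adjacency,
                                     config = cbpt_config(),
                                     source_index = seq_len(ncol(values))) {
  stopifnot(inherits(config, "plv_cbpt_config"))
  groups <- as.factor(groups)
  tmap <- pointwise_t(values, groups, t_variant = config$t_variant,
                      source_index = source_index)
  n <- nrow(values); n1 <- tmap$n1
  n_distinct <- choose(n, n1)
  if (n_distinct < config$min_relabelings)
    stop(sprintf("group sizes admit only %d distinct relabelings (< %d)",
                 n_distinct, config$min_relabelings))
  alpha <- config$cluster_forming_alpha
  nbr_local <- local_neighbors(adjacency, tmap$source_index)
  crit <- qt(1 - alpha / 2, tmap$df)
  observed <- clusters_from_t(tmap$t, crit, nbr_local, tmap$source_index)

  exhaustive <- identical(config$n_permutations, "exhaustive")
  if (exhaustive) {
    perms <- combn(n, n1, simplify = FALSE)
  } else {
    perms <- with_seed(config$rng_seed,
                       replicate(config$n_permutations,
                                 sort(sample.int(n, n1)), simplify = FALSE))
  }
  welch <- config$t_variant == "welch"
  nulls <- matrix(0, length(perms), 3,
                  dimnames = list(NULL, c("abs", "pos", "neg")))
  X <- as.matrix(values)
  for (i in seq_along(perms)) {
    r <- two_sample_t_cols(X, perms[[i]],
                           variant = if (welch) "welch" else "pooled",
                           warn_zero = FALSE)
    ci <- if (welch) qt(1 - alpha / 2, r$df) else crit
    nulls[i, ] <- max_cluster_mass(r$t, ci, nbr_local)
  }
  npsz <- length(perms)
  clusters <- lapply(observed, function(cl) {
    stat <- switch(config$null_statistic,
                   max_abs_mass = nulls[, "abs"],
                   per_sign = if (cl$sign == "positive") nulls[, "pos"]
                              else nulls[, "neg"])
    k <- sum(stat >= abs(cl$mass) - 1e-12)
    cl$p_value <- if (exhaustive) k / npsz else (1 + k) / (npsz + 1)
    cl$n_permutations <- npsz
    cl
  })
  ord <- order(vapply(clusters, `[[`, numeric(1), "p_value"),
               -abs(vapply(clusters, `[[`, numeric(1), "mass")))
  structure(list(clusters = clusters[ord], tmap = tmap, config = config,
                 n_permutations = npsz, exhaustive = exhaustive),
            class = "plv_cbpt")
}

#' @export
print.plv_cbpt <- function(x, ...) {
  cat(sprintf("Cluster-based permutation test: %d cluster(s), %d relabelings%s\n",
              length(x$clusters), x$n_permutations,
              if (x$exhaustive) " (exhaustive)" else ""))
  for (cl in x$clusters)
    cat(sprintf("  %s cluster, %d sources, T-statsum %.2f, p = %.4f\n",
                cl$sign, length(cl$members), cl$mass, cl$p_value))
  invisible(x)
}

#' Per-network group comparison
#'
#' Two-sided independent-samples t-test on per-subject RSN mean connectivity
#' (uncorrected across networks and bands, mirroring the seed/RSN analysis
#' design).
#'
#' @param values numeric vector of per-subject scalar FC.
#' @param groups two-level factor/character, first level = group 1.
#' @param network,band labels carried into the result.
#' @param var_equal pooled-variance t when `TRUE` (default).
#' @return object of class `plv_rsn_test`: group means, `t`, `df`, `p`.
#' @export
rsn_group_test <- function(values, groups, network = NA_character_,
                           band = NA_character_, var_equal = TRUE) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  x <- values[groups == levels(groups)[1]]
  y <- values[groups == levels(groups)[2]]
  if (length(x) < 2 || length(y) < 2)
    stop("both groups need at least 2 subjects")
  tt <- t.test(x, y, var.equal = var_equal)
  structure(list(network = network, band = band,
                 mean_group1 = mean(x), mean_group2 = mean(y),
                 group_levels = levels(groups),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value),
            class = "plv_rsn_test")
}
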