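#' Phase-locking values and their reductions
#'
#' The phase-locking value between sources k and l is the modulus of the mean
#' unit phasor of their phase difference over the T samples of an epoch,
#'
#'   PLV_kl = | (1/T) sum_t exp(-i (phi_k(t) - phi_l(t))) |,
#'
#' computed per epoch and then averaged across epochs (trials). A PLV of 1
#' means a perfectly constant phase relation; values near 0 mean no
#' consistent relation. Per-subject source-by-source PLV matrices are reduced
#' to seed connectivity vectors (mean PLV of all seed members to each distant
#' source) and to resting-state-network means.
#'
#' @name connectivity
NULL

#' PLV between two phase series
#'
#' @param phase_k,phase_l numeric matrices, epochs x samples, of
#'   instantaneous phases (radians). Equal shapes required.
#' @return scalar in `[0, 1]`: per-epoch PLV averaged across epochs.
#' @export
plv_pair <- function(phase_k, phase_l) {
  if (is.vector(phase_k)) phase_k <- matrix(phase_k, nrow = 1)
  if (is.vector(phase_l)) phase_l <- matrix(phase_l, nrow = 1)
  if (!identical(dim(phase_k), dim(phase_l)))
    stop("phase arrays must have identical shapes")
  if (ncol(phase_k) < 2) stop("need at least T = 2 samples per epoch")
  d <- phase_k - phase_l
  mean(Mod(rowMeans(exp(-1i * d))))
}

# Per-epoch complex phasor cross-products between row blocks, accumulated
# into a PLV block; phases: plv_phase. rows/cols are source index vectors.
plv_block <- function(phases, rows, cols) {
  d <- phases$data
  E <- phases$n_epochs; Tn <- phases$n_samples
  # unit phasors, sources x (samples grouped by epoch); taken directly from
  # the analytic signal when available, else from the phase array
  same <- identical(rows, cols)
  if (!is.null(phases$phasor)) {
    ur <- phases$phasor[rows, , drop = FALSE]
    Cr <- Re(ur); Sr <- Im(ur)
    if (same) { Cc <- Cr; Sc <- Sr } else {
      uc <- phases$phasor[cols, , drop = FALSE]
      Cc <- Re(uc); Sc <- Im(uc)
    }
  } else {
    flat <- function(ix) matrix(aperm(d[ix, , , drop = FALSE], c(1, 3, 2)),
                                length(ix))
    pr <- flat(rows)
    Cr <- cos(pr); Sr <- sin(pr)
    if (same) { Cc <- Cr; Sc <- Sr } else {
      pc <- flat(cols)
      Cc <- cos(pc); Sc <- sin(pc)
    }
  }
  acc <- matrix(0, length(rows), length(cols))
  for (e in seq_len(E)) {
    idx <- ((e - 1) * Tn + 1):(e * Tn)
    re <- tcrossprod(Cr[, idx, drop = FALSE], Cc[, idx, drop = FALSE]) +
      tcrossprod(Sr[, idx, drop = FALSE], Sc[, idx, drop = FALSE])
    im <- tcrossprod(Sr[, idx, drop = FALSE], Cc[, idx, drop = FALSE]) -
      tcrossprod(Cr[, idx, drop = FALSE], Sc[, idx, drop = FALSE])
    acc <- acc + sqrt(re^2 + im^2) / Tn
  }
  acc / E
}

#' Per-subject PLV matrix
#'
#' Computes all unordered source pairs (per-epoch PLV averaged over epochs).
#' The diagonal is fixed at 1 and is excluded from every downstream
#' averaging. The computation streams across epochs, so memory is
#' O(sources^2) regardless of recording length.
#'
#' @param phases a `plv_phase` (sources x epochs x samples).
#' @return an object of class `plv_matrix`: `values` (symmetric n x n in
#'   `[0, 1]`, unit diagonal), `subject_id`, `band`.
#' @export
plv_matrix <- function(phases) {
  stopifnot(inherits(phases, "plv_phase"))
  n <- phases$n_sources
  if (n < 2) stop("need at least 2 sources")
  v <- plv_block(phases, seq_len(n), seq_len(n))
  # tcrossprod makes re exactly symmetric and im exactly antisymmetric, so v
  # is symmetric bit-for-bit; clamp rounding excursions above 1.
  v[v > 1] <- 1
  diag(v) <- 1
  structure(list(values = v, subject_id = phases$subject_id,
                 band = if (inherits(phases$band, "plv_band"))
                   phases$band$name else phases$band,
                 n_sources = n),
            class = "plv_matrix")
}

#' @export
print.plv_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("PLV matrix: %d x %d (subject %s, band %s); off-diagonal mean %.3f\n",
              x$n_sources, x$n_sources, x$subject_id, x$band, mean(off)))
  invisible(x)
}

#' PLV rows for a subset of sources
#'
#' Streaming computation of selected rows of the PLV matrix (e.g. seed
#' members against all sources) without forming the full n x n matrix.
#'
#' @param phases a `plv_phase`.
#' @param rows source indices whose rows are wanted.
#' @return matrix `length(rows) x n_sources`; entries for row source r and
#'   column source s hold PLV(r, s), with 1 on self-pairs.
#' @export
plv_rows <- function(phases, rows) {
  stopifnot(inherits(phases, "plv_phase"))
  n <- phases$n_sources
  v <- plv_block(phases, rows, seq_len(n))
  v[v > 1] <- 1
  v[cbind(seq_along(rows), rows)] <- 1
  v
}

#' Seed-based connectivity vector
#'
#' For every source outside the seed, the mean PLV between that source and
#' all seed members (intra-seed pairs are never considered).
#'
#' @param plv a `plv_matrix`, or a matrix as returned by [plv_rows()] for the
#'   seed's sources (in that case `n_sources` is taken from its columns).
#' @param seed a `plv_seed`.
#' @return object of class `plv_seed_fc`: `values` (length n - |seed|),
#'   `source_index` (grid index of each entry), `seed`, plus subject/band
#'   metadata when available.
#' @export
seed_fc <- function(plv, seed) {
  stopifnot(inherits(seed, "plv_seed"))
  if (inherits(plv, "plv_matrix")) {
    rows <- plv$values[seed$source_indices, , drop = FALSE]
    n <- plv$n_sources
    meta <- plv[c("subject_id", "band")]
  } else {
    rows <- plv
    if (nrow(rows) != length(seed$source_indices))
      stop("row count does not match seed size")
    n <- ncol(rows)
    meta <- list(subject_id = NA_character_, band = NA_character_)
  }
  if (any(seed$source_indices > n)) stop("seed indices outside matrix")
  distant <- setdiff(seq_len(n), seed$source_indices)
  if (length(distant) == 0) stop("no distant sources: seed covers the grid")
  vals <- colMeans(rows[, distant, drop = FALSE])
  structure(list(values = vals, source_index = distant, seed = seed$name,
                 subject_id = meta$subject_id, band = meta$band),
            class = "plv_seed_fc")
}

#' Resting-state-network mean connectivity
#'
#' Mean PLV over pairs of distinct RSN sources. Under the default
#' `all_pairs` policy every unordered pair of distinct member sources
#' contributes; under `between_spheres` only pairs whose two members belong
#' to different centers' spheres do (sources shared by both spheres never
#' pair with themselves). The diagonal is never included.
#'
#' @param plv a `plv_matrix`.
#' @param rsn a `plv_rsn`.
#' @param pair_policy `"all_pairs"` (default) or `"between_spheres"`.
#' @return object of class `plv_rsn_fc`: `value` (scalar in `[0, 1]`),
#'   `n_pairs`, `network`, subject/band metadata.
#' @export
rsn_fc <- function(plv, rsn, pair_policy = c("all_pairs", "between_spheres")) {
  pair_policy <- match.arg(pair_policy)
  stopifnot(inherits(plv, "plv_matrix"), inherits(rsn, "plv_rsn"))
  idx <- rsn$source_indices
  if (length(idx) == 0) stop("RSN has no sources")
  if (any(idx > plv$n_sources)) stop("RSN indices outside matrix")
  pairs <- if (pair_policy == "all_pairs") {
    if (length(idx) < 2) NULL else t(combn(idx, 2))
  } else {
    keep <- list()
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (b <= a) next
      sa <- rsn$membership[[a]]; sb <- rsn$membership[[b]]
      # pair counts when the two sources can be attributed to different spheres
      if (length(unique(c(sa, sb))) >= 2)
        keep[[length(keep) + 1]] <- c(idx[a], idx[b])
    }
    if (length(keep)) do.call(rbind, keep) else NULL
  }
  if (is.null(pairs) || nrow(pairs) == 0)
    stop(sprintf("RSN '%s': selected pair set is empty under policy '%s'",
                 rsn$name, pair_policy))
  vals <- plv$values[pairs]
  structure(list(value = mean(vals), n_pairs = nrow(pairs),
                 network = rsn$name, pair_policy = pair_policy,
                 subject_id = plv$subject_id, band = plv$band),
            class = "plv_rsn_fc")
}
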