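#' Source grids, ROIs, resting-state networks and spatial adjacency
#'
#' The spatial substrate of every analysis in plvfc is a regular grid of
#' candidate sources in a right-handed, millimetre, MNI-like frame. Seeds and
#' resting-state networks (RSNs) are index sets into that grid; spatial
#' adjacency (used by the cluster-based permutation test) is a symmetric
#' neighbour structure derived from inter-source distance.
#'
#' @name source_space
NULL

REL_TOL <- 1e-9

new_source_grid <- function(positions, spacing) {
  structure(
    list(positions = positions, spacing = spacing,
         n_sources = nrow(positions)),
    class = "plv_grid")
}

#' Build a regular source grid
#'
#' Generates all lattice points with the given spacing inside an axis-aligned
#' box, optionally restricted by a mask. The lattice is anchored at `anchor`
#' (defaults to the box lower corner), i.e. points are
#' `anchor + spacing * (i, j, k)` for integer `(i, j, k)`. Points are ordered
#' lexicographically by (x, y, z).
#'
#' @param lower,upper numeric length-3, box corners in mm (inclusive).
#' @param spacing grid spacing in mm (> 0). Default 10 (a 1-cm grid).
#' @param mask optional restriction: either a predicate `function(xyz)`
#'   returning `TRUE` to keep a point (called with a length-3 numeric), or a
#'   list `list(volume = <3-D array>, affine = <4x4 voxel-to-mm matrix>)`
#'   keeping points whose nearest voxel is non-zero / `TRUE`.
#' @param anchor lattice anchor point in mm; default `lower`.
#' @return an object of class `plv_grid` with fields `positions`
#'   (n x 3 matrix, mm), `spacing` and `n_sources`.
#' @export
#' @examples
#' g <- build_regular_grid(c(0, 0, 0), c(20, 20, 20), spacing = 10)
#' g$n_sources  # 27
build_regular_grid <- function(lower, upper, spacing = 10, mask = NULL,
                               anchor = lower) {
  stopifnot(length(lower) == 3, length(upper) == 3, length(anchor) == 3)
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0)
    stop("spacing must be a positive scalar (mm)")
  if (any(upper < lower)) stop("extent contains no grid points")
  ax <- lapply(1:3, function(d) {
    i0 <- ceiling((lower[d] - anchor[d]) / spacing - REL_TOL)
    i1 <- floor((upper[d] - anchor[d]) / spacing + REL_TOL)
    if (i1 < i0) numeric(0) else anchor[d] + spacing * (i0:i1)
  })
  if (any(lengths(ax) == 0)) stop("extent contains no grid points")
  # lexicographic by (x, y, z): x slowest
  pos <- as.matrix(expand.grid(z = ax[[3]], y = ax[[2]], x = ax[[1]],
                               KEEP.OUT.ATTRS = FALSE))[, 3:1, drop = FALSE]
  colnames(pos) <- c("x", "y", "z")
  if (!is.null(mask)) {
    keep <- if (is.function(mask)) {
      vapply(seq_len(nrow(pos)), function(i) isTRUE(mask(pos[i, ])), logical(1))
    } else if (is.list(mask) && !is.null(mask$volume)) {
      in_label_volume(pos, mask$volume, mask$affine,
                      labels = NULL, warn = FALSE)
    } else stop("mask must be a predicate function or list(volume, affine)")
    pos <- pos[keep, , drop = FALSE]
  }
  if (nrow(pos) == 0) stop("extent contains no grid points")
  rownames(pos) <- NULL
  new_source_grid(pos, spacing)
}

#' @export
print.plv_grid <- function(x, ...) {
  rng <- apply(x$positions, 2, range)
  cat(sprintf("Source grid: %d sources, spacing %g mm\n", x$n_sources,
              x$spacing))
  cat(sprintf("  extent x [%g, %g]  y [%g, %g]  z [%g, %g] mm\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Sources inside a closed ball
#'
#' Returns the indices of all grid sources whose Euclidean distance to
#' `center` is at most `radius` (closed ball: boundary sources are included).
#'
#' @param grid a `plv_grid`.
#' @param center length-3 numeric, mm.
#' @param radius ball radius in mm (>= 0).
#' @return integer vector of source indices (possibly empty).
#' @export
sources_in_sphere <- function(grid, center, radius) {
  stopifnot(inherits(grid, "plv_grid"), length(center) == 3)
  if (radius < 0) stop("radius must be >= 0")
  d2 <- colSums((t(grid$positions) - center)^2)
  which(d2 <= radius^2 * (1 + REL_TOL) + REL_TOL)
}

#' Define a seed region of interest
#'
#' @param name region label (e.g. "SMG", "sensorimotor").
#' @param source_indices integer indices into the grid; unique, non-empty.
#' @param laterality one of "left", "right", "bilateral".
#' @param grid optional `plv_grid` used to validate the indices.
#' @return an object of class `plv_seed`.
#' @export
seed_roi <- function(name, source_indices,
                     laterality = c("bilateral", "left", "right"),
                     grid = NULL) {
  laterality <- match.arg(laterality)
  idx <- as.integer(source_indices)
  if (length(idx) == 0) stop("seed ROI must contain at least one source")
  if (anyDuplicated(idx)) stop("seed source indices must be unique")
  if (any(idx < 1)) stop("seed source indices must be positive")
  if (!is.null(grid) && any(idx > grid$n_sources))
    stop("seed source indices outside grid")
  structure(list(name = name, laterality = laterality, source_indices = idx),
            class = "plv_seed")
}

#' Build a resting-state network from sphere centers
#'
#' An RSN is the union of closed balls of radius `radius` around each MNI
#' center. Per-source sphere membership is recorded (a source can fall inside
#' several centers' spheres).
#'
#' @param grid a `plv_grid`.
#' @param name network label (e.g. "pDMN", "SMN").
#' @param centers numeric matrix (k x 3) or list of length-3 vectors, mm.
#' @param radius sphere radius in mm; default 15 (1.5 cm).
#' @return an object of class `plv_rsn` with `source_indices` (sorted, unique)
#'   and `membership` (list: sphere indices containing each source).
#' @export
build_rsn <- function(grid, name, centers, radius = 15) {
  stopifnot(inherits(grid, "plv_grid"))
  if (is.list(centers)) centers <- do.call(rbind, centers)
  centers <- matrix(as.numeric(centers), ncol = 3)
  if (nrow(centers) < 1) stop("RSN needs at least one center")
  if (radius < 0) stop("radius must be >= 0")  # 0 keeps the closed-ball center
  per <- lapply(seq_len(nrow(centers)), function(k)
    sources_in_sphere(grid, centers[k, ], radius))
  idx <- sort(unique(unlist(per)))
  if (length(idx) == 0) stop("RSN covers no sources")
  membership <- lapply(idx, function(s)
    which(vapply(per, function(p) s %in% p, logical(1))))
  names(membership) <- as.character(idx)
  structure(list(name = name, centers = centers, radius = radius,
                 source_indices = idx, membership = membership),
            class = "plv_rsn")
}

#' Build spatial adjacency for clustering
#'
#' Two sources are neighbours when their Euclidean distance is at most
#' `max_dist`. The default `1.1 * spacing` yields face connectivity on a
#' regular grid, the most conservative notion of spatial contiguity; pass
#' e.g. `1.5 * spacing` for face+edge connectivity.
#'
#' @param grid a `plv_grid`.
#' @param max_dist neighbour distance threshold in mm (> 0).
#' @return an object of class `plv_adjacency`: `neighbors` (list of integer
#'   vectors per source, no self-neighbours, symmetric) and `max_dist`.
#' @export
build_adjacency <- function(grid, max_dist = 1.1 * grid$spacing) {
  stopifnot(inherits(grid, "plv_grid"))
  if (max_dist <= 0) stop("max_dist must be > 0")
  p <- grid$positions
  n <- nrow(p)
  d2 <- outer(rowSums(p^2), rowSums(p^2), "+") - 2 * tcrossprod(p)
  keep <- d2 <= max_dist^2 * (1 + REL_TOL)
  diag(keep) <- FALSE
  nbr <- lapply(seq_len(n), function(i) which(keep[i, ]))
  structure(list(neighbors = nbr, max_dist = max_dist, n_sources = n),
            class = "plv_adjacency")
}

# Map mm positions to voxel subscripts of a label volume; returns, per point,
# the label value or NA when the point falls outside the volume.
lookup_labels <- function(positions, volume, affine) {
  stopifnot(is.array(volume), length(dim(volume)) == 3,
            is.matrix(affine), all(dim(affine) == c(4, 4)))
  inv <- tryCatch(solve(affine), error = function(e)
    stop("affine is not invertible"))
  xyz1 <- cbind(positions, 1)
  vox <- round(xyz1 %*% t(inv))[, 1:3, drop = FALSE]  # 0-based voxel coords
  dm <- dim(volume)
  inside <- vox[, 1] >= 0 & vox[, 1] < dm[1] &
    vox[, 2] >= 0 & vox[, 2] < dm[2] &
    vox[, 3] >= 0 & vox[, 3] < dm[3]
  out <- rep(NA_real_, nrow(positions))
  if (any(inside)) {
    sub <- vox[inside, , drop = FALSE] + 1
    out[inside] <- volume[sub]
  }
  out
}

in_label_volume <- function(positions, volume, affine, labels = NULL,
                            warn = TRUE) {
  lab <- lookup_labels(positions, volume, affine)
  if (warn && anyNA(lab))
    warning(sprintf("%d source position(s) outside label volume; excluded",
                    sum(is.na(lab))))
  if (is.null(labels)) !is.na(lab) & lab != 0 else !is.na(lab) & lab %in% labels
}

#' Seed ROI from an atlas label volume
#'
#' Maps every grid position through the inverse affine to its nearest voxel
#' and keeps sources whose voxel label is in `labels`. Positions falling
#' outside the volume are excluded with a warning.
#'
#' @param grid a `plv_grid`.
#' @param volume integer/numeric 3-D array of parcellation labels.
#' @param affine 4x4 voxel-to-mm affine (0-based voxel coordinates).
#' @param labels label values to keep.
#' @param name,laterality passed to [seed_roi()].
#' @return a `plv_seed`.
#' @export
roi_from_label_volume <- function(grid, volume, affine, labels,
                                  name = "atlas_roi",
                                  laterality = "bilateral") {
  keep <- in_label_volume(grid$positions, volume, affine, labels = labels)
  idx <- which(keep)
  if (length(idx) == 0) stop("no grid sources carry the requested label(s)")
  seed_roi(name, idx, laterality, grid = grid)
}

#' Read a NIfTI label volume
#'
#' Thin wrapper around `RNifti::readNifti()` returning the pieces
#' [roi_from_label_volume()] needs.
#'
#' @param path path to a NIfTI file.
#' @return `list(volume, affine)`.
#' @export
read_label_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI label volumes requires the RNifti package")
  img <- RNifti::readNifti(path)
  list(volume = array(as.numeric(img), dim = dim(img)),
       affine = matrix(as.numeric(RNifti::xform(img)), 4, 4))
}

#' Read ROI / RSN definitions from JSON
#'
#' The file holds an array of entries; each entry is either an explicit index
#' set `{"name", "laterality"?, "source_indices": [...]}` (1-based) or a
#' sphere set `{"name", "centers": [[x,y,z],...], "radius"?}` resolved against
#' `grid`. Sphere entries become [build_rsn()] objects, index entries become
#' [seed_roi()] objects.
#'
#' @param path JSON file path.
#' @param grid a `plv_grid` used to resolve sphere entries.
#' @param default_radius radius (mm) used when an entry omits it.
#' @return named list of `plv_seed` / `plv_rsn` objects.
#' @export
read_roi_definitions <- function(path, grid, default_radius = 15) {
  defs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(defs$rois)) defs <- defs$rois
  out <- lapply(defs, function(d) {
    if (!is.null(d$source_indices)) {
      seed_roi(d$name, unlist(d$source_indices),
               laterality = if (is.null(d$laterality)) "bilateral"
                            else d$laterality,
               grid = grid)
    } else if (!is.null(d$centers)) {
      r <- if (is.null(d$radius)) default_radius else d$radius
      build_rsn(grid, d$name, lapply(d$centers, unlist), radius = r)
    } else stop(sprintf("ROI entry '%s' has neither source_indices nor centers",
                        if (is.null(d$name)) "?" else d$name))
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}
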