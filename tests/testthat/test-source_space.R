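test_that("regular grids enumerate exactly the lattice points in the extent", {
  g <- build_regular_grid(c(0, 0, 0), c(10, 10, 10), 10)
  expect_equal(g$n_sources, 8)          # unit-cell corners
  expect_equal(g$spacing, 10)

  g3 <- build_regular_grid(c(0, 0, 0), c(20, 20, 20), 10)
  expect_equal(g3$n_sources, 27)        # 3^3 lattice
  # lexicographic (x, y, z) ordering
  expect_true(all(diff(g3$positions[, "x"]) >= 0))
  expect_equal(g3$positions[1:3, "z"], c(0, 10, 20), ignore_attr = TRUE)

  # spherical mask: brute-force integer-lattice count, radius 25, spacing 10
  gs <- build_regular_grid(c(-30, -30, -30), c(30, 30, 30), 10,
                           mask = function(p) sqrt(sum(p^2)) <= 25,
                           anchor = c(0, 0, 0))
  lattice <- as.matrix(expand.grid(x = -3:3, y = -3:3, z = -3:3)) * 10
  expect_equal(gs$n_sources, sum(sqrt(rowSums(lattice^2)) <= 25))

  expect_error(build_regular_grid(c(0, 0, 0), c(-1, 1, 1), 10),
               "no grid points")
})

test_that("grid counts are invariant under lattice translation", {
  for (k in 1:5) {
    shift <- 10 * sample(-3:3, 3, replace = TRUE)
    g1 <- build_regular_grid(c(0, 0, 0), c(30, 20, 10), 10)
    g2 <- build_regular_grid(shift, shift + c(30, 20, 10), 10)
    expect_equal(g2$n_sources, g1$n_sources)
    expect_equal(g2$positions, sweep(g1$positions, 2, -shift),
                 ignore_attr = TRUE)
  }
})

test_that("sources_in_sphere is a closed ball matching brute force", {
  g <- build_regular_grid(c(0, 0, 0), c(40, 40, 40), 10)
  center_idx <- which(colSums(abs(t(g$positions) - c(20, 20, 20))) == 0)
  expect_equal(sources_in_sphere(g, c(20, 20, 20), 0), center_idx)
  # radius exactly one spacing: the point plus its 6 face neighbours
  expect_length(sources_in_sphere(g, c(20, 20, 20), 10), 7)
  set.seed(11)
  for (k in 1:10) {
    ctr <- runif(3, -5, 45)
    expect_equal(sources_in_sphere(g, ctr, 15), bf_in_sphere(g, ctr, 15))
  }
  expect_error(sources_in_sphere(g, c(0, 0, 0), -1), ">= 0")
  expect_length(sources_in_sphere(g, c(500, 0, 0), 5), 0)  # empty is legal
})

test_that("build_rsn takes the deduplicated union of spheres and records membership", {
  g <- build_regular_grid(c(0, 0, 0), c(50, 50, 20), 10)
  r0 <- build_rsn(g, "one", matrix(c(10, 10, 10), 1), radius = 0)
  expect_length(r0$source_indices, 1)

  r2 <- build_rsn(g, "two", rbind(c(10, 10, 10), c(15, 10, 10)), radius = 15)
  expect_false(anyDuplicated(r2$source_indices) > 0)
  expect_lte(length(r2$source_indices),
             length(bf_in_sphere(g, c(10, 10, 10), 15)) +
               length(bf_in_sphere(g, c(15, 10, 10), 15)))
  # sources in both spheres carry both memberships
  both <- intersect(bf_in_sphere(g, c(10, 10, 10), 15),
                    bf_in_sphere(g, c(15, 10, 10), 15))
  expect_equal(r2$membership[[as.character(both[1])]], c(1L, 2L))

  set.seed(7)
  ctrs <- cbind(runif(4, 0, 50), runif(4, 0, 50), runif(4, 0, 20))
  rr <- build_rsn(g, "rand", ctrs, radius = 12)
  expect_equal(rr$source_indices,
               sort(unique(unlist(lapply(1:4, function(k)
                 bf_in_sphere(g, ctrs[k, ], 12))))))
  expect_error(build_rsn(g, "far", matrix(c(900, 900, 900), 1), radius = 5),
               "covers no sources")
})

test_that("adjacency is symmetric, irreflexive, and matches brute force", {
  g <- build_regular_grid(c(0, 0, 0), c(40, 40, 40), 10)
  interior <- which(colSums(abs(t(g$positions) - c(20, 20, 20))) == 0)
  a_face <- build_adjacency(g, 10.5)
  expect_length(a_face$neighbors[[interior]], 6)
  a_edge <- build_adjacency(g, 14.5)
  expect_length(a_edge$neighbors[[interior]], 18)

  for (a in list(a_face, a_edge)) {
    for (i in seq_along(a$neighbors)) {
      expect_false(i %in% a$neighbors[[i]])
      for (j in a$neighbors[[i]]) expect_true(i %in% a$neighbors[[j]])
    }
  }
  set.seed(3)
  gr <- build_regular_grid(c(0, 0, 0), c(30, 30, 10), 10,
                           mask = function(p) runif(1) < 0.8)
  ar <- build_adjacency(gr, 17)
  expect_equal(ar$neighbors, bf_adjacency(gr, 17))
})

test_that("label volumes map to seed ROIs through their affine", {
  g <- build_regular_grid(c(0, 0, 0), c(30, 30, 30), 10)
  vol <- array(0L, c(8, 8, 8))
  aff <- diag(c(5, 5, 5, 1))  # voxel k -> 5k mm
  expect_error(roi_from_label_volume(g, vol, aff, labels = 1),
               "no grid sources")

  # label one octant: x,y,z in [0,15] mm -> voxels 0..3
  vol[1:4, 1:4, 1:4] <- 1L
  roi <- roi_from_label_volume(g, vol, aff, labels = 1, name = "octant")
  in_oct <- which(apply(g$positions, 1, function(p) all(p <= 15)))
  expect_equal(roi$source_indices, in_oct)

  # identity affine, single labelled voxel on a grid point
  vol2 <- array(0L, c(32, 32, 32)); vol2[11, 11, 11] <- 7L
  roi2 <- roi_from_label_volume(g, vol2, diag(4), labels = 7)
  expect_length(roi2$source_indices, 1)
  expect_equal(g$positions[roi2$source_indices, ], c(x = 10, y = 10, z = 10))

  # positions outside the volume are excluded with a warning
  vol3 <- array(1L, c(2, 2, 2))
  expect_warning(roi3 <- roi_from_label_volume(g, vol3, diag(4), labels = 1),
                 "outside")
  expect_true(all(g$positions[roi3$source_indices, ] <= 1.5))
})

test_that("ROI definition files round-trip seeds and sphere RSNs", {
  g <- build_regular_grid(c(0, 0, 0), c(50, 50, 20), 10)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(rois = list(
      list(name = "seedA", laterality = "left", source_indices = c(1, 2, 3)),
      list(name = "netB", centers = list(c(20, 20, 10)), radius = 15))),
    path, auto_unbox = TRUE)
  defs <- read_roi_definitions(path, g)
  expect_s3_class(defs$seedA, "plv_seed")
  expect_equal(defs$seedA$source_indices, 1:3)
  expect_equal(defs$seedA$laterality, "left")
  expect_s3_class(defs$netB, "plv_rsn")
  expect_equal(defs$netB$source_indices, bf_in_sphere(g, c(20, 20, 10), 15))

  # bundled default coordinates parse (desk grids may not cover them)
  f <- system.file("extdata", "rsn_default_coords.json", package = "plvfc")
  raw <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_length(raw$rois, 6)
})
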