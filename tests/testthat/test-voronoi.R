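test_that("periodic Voronoi areas tile the box exactly", {
  set.seed(8)
  L <- 6
  pts <- cbind(runif(50, 0, L), runif(50, 0, L))
  vor <- periodic_voronoi(pts, c(L, L))
  expect_equal(sum(vor$areas), L^2, tolerance = 1e-9)
  expect_true(all(vor$areas > 0))
  ## Euler on the torus: 2n triangles, 3n edges
  expect_equal(nrow(vor$triangles), 2L * nrow(pts))
  expect_equal(nrow(vor$adjacency), 3L * nrow(pts))
  ## adjacency is symmetric-unique with i < j
  expect_true(all(vor$adjacency[, 1L] < vor$adjacency[, 2L]))
})

test_that("exactly regular lattices are tessellated correctly", {
  ## degenerate case: collinear rows put triangle circumcenters exactly on
  ## the domain boundary; every cell must still get 6 neighbors
  a <- sqrt(2 / sqrt(3)); nx <- 8L; ny <- 8L
  box <- c(nx * a, ny * a * sqrt(3) / 2)
  ix <- rep(0:(nx - 1L), times = ny); iy <- rep(0:(ny - 1L), each = nx)
  pts <- cbind((ix + 0.5 * (iy %% 2)) * a, iy * a * sqrt(3) / 2)
  vor <- periodic_voronoi(pts, box)
  expect_equal(nrow(vor$adjacency), 3L * nrow(pts))
  deg <- tabulate(c(vor$adjacency), nbins = nrow(pts))
  expect_true(all(deg == 6L))
  expect_equal(sum(vor$areas), prod(box), tolerance = 1e-9)
  ## all Voronoi cells of the triangular lattice are congruent hexagons
  expect_lt(diff(range(vor$areas)), 1e-9)
})

test_that("invalid point sets are rejected", {
  expect_error(periodic_voronoi(cbind(1:2, 1:2), c(5, 5)), "at least 4")
  dup <- rbind(c(1, 1), c(1, 1), c(2, 3), c(4, 2))
  expect_error(periodic_voronoi(dup, c(5, 5)), "duplicate")
  bad <- rbind(c(1, 1), c(NA, 2), c(2, 3), c(4, 2))
  expect_error(periodic_voronoi(bad, c(5, 5)), "non-finite")
})

test_that("voronoi_areas separates narrow and bimodal area distributions", {
  set.seed(21)
  L <- 10
  ## jittered lattice: narrow, unimodal area distribution
  g <- as.matrix(expand.grid(x = seq(0.5, 9.5, 1), y = seq(0.5, 9.5, 1)))
  lat <- (g + matrix(runif(200, -0.15, 0.15), ncol = 2)) %% L
  va_lat <- voronoi_areas(lat, c(L, L))
  expect_equal(sum(va_lat$areas), L^2, tolerance = 1e-9)
  expect_lt(sd(va_lat$areas) / mean(va_lat$areas), 0.2)
  ## half the box at 4x the density: bimodal areas
  dense <- rbind(cbind(runif(80, 0, 5), runif(80, 0, L)),
                 cbind(runif(20, 5, 10), runif(20, 0, L)))
  va_mix <- voronoi_areas(dense, c(L, L))
  expect_gt(sd(va_mix$areas) / mean(va_mix$areas),
            2 * sd(va_lat$areas) / mean(va_lat$areas))
  ## model-based clustering prefers >= 2 components for the mixture
  bic <- mclust::mclustBIC(va_mix$areas, G = 1:3, verbose = FALSE)
  best <- as.integer(sub("^.*,", "", names(summary(bic))[1]))
  expect_gt(best, 1L)
})
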