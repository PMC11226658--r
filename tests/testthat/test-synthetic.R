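test_that("map_chirality converts cell chirality to rotation rates", {
  expect_equal(map_chirality(0)$omega, 0)
  expect_equal(map_chirality(1, omega_max = 2)$omega, 2)
  expect_equal(map_chirality(-0.5, omega_max = 2)$omega, -1)
  expect_error(map_chirality(1.5), "domain error")
})

test_that("deterministic chiral cells trace circles of radius v0/|omega|", {
  p <- chiral_cell_params(v0 = 0.5, chi_cell = 1, omega_max = 0.8, D_r = 0)
  tr <- chiral_abp_trajectory(p, n_cells = 4L, n_frames = 2000L, dt = 0.005,
                              box = c(50, 50), seed = 9, chi_sys = 1)
  u <- shapejam:::.unwrap(tr)
  for (i in 1:4) {
    x <- u[, i, 1L]; y <- u[, i, 2L]
    cx <- (max(x) + min(x)) / 2; cy <- (max(y) + min(y)) / 2
    r <- sqrt((x - cx)^2 + (y - cy)^2)
    expect_equal(mean(r), 0.5 / 0.8, tolerance = 0.02)
    expect_lt(sd(r) / mean(r), 0.02)
  }
})

test_that("chiral ABP MSD matches the Green-Kubo oracle within 3 SE", {
  p <- chiral_cell_params(v0 = 1, chi_cell = 0.6, omega_max = 1.5, D_r = 0.3)
  n_cells <- 600L
  tr <- chiral_abp_trajectory(p, n_cells = n_cells, n_frames = 400L,
                              dt = 0.05, box = c(40, 40), seed = 10,
                              chi_sys = 1)
  ## compare beyond the ballistic regime (t >~ 1/max(D_r, omega)): at
  ## shorter lags all cells move near-identically, the standard error
  ## vanishes faster than the O(dt) integrator bias, and the 3 SE band is
  ## bias-dominated rather than noise-dominated
  lags <- c(20L, 60L, 150L)
  mc <- msd(tr, lags = lags)
  ## per-cell displacement spread gives the standard error of the MSD mean
  u <- shapejam:::.unwrap(tr)
  for (j in seq_along(lags)) {
    l <- lags[j]
    d <- shapejam:::.lag_disp(u, l)
    per_cell <- colMeans(d$dx^2 + d$dy^2)
    se <- sd(per_cell) / sqrt(n_cells)
    theory <- chiral_abp_msd_theory(l * tr$dt, p)
    expect_lt(abs(mc$msd[j] - theory), 3 * se + 1e-12)
  }
})

test_that("persistence time decreases monotonically with |omega|", {
  taus <- vapply(c(0, 0.6, 1.5, 3), function(om) {
    p <- chiral_cell_params(v0 = 1, chi_cell = 1, omega_max = om, D_r = 0.05)
    ## span far past 1/D_r = 20 so the slowest case reaches its diffusive
    ## regime
    tt <- exp(seq(log(0.02), log(1000), length.out = 80))
    pt <- persistence_time(data.frame(time = tt,
                                      msd = chiral_abp_msd_theory(tt, p)))
    pt$tau_p
  }, numeric(1L))
  expect_true(all(diff(taus) < 0))
})

test_that("system chirality controls the handedness composition", {
  p <- chiral_cell_params(v0 = 1, chi_cell = 1, omega_max = 1, D_r = 0.1)
  h0 <- attr(chiral_abp_trajectory(p, 10L, 3L, 0.01, c(10, 10),
                                   chi_sys = 0), "handedness")
  expect_equal(sum(h0 > 0), 5L)
  h1 <- attr(chiral_abp_trajectory(p, 10L, 3L, 0.01, c(10, 10),
                                   chi_sys = 1), "handedness")
  expect_equal(sum(h1 > 0), 10L)
  expect_error(chiral_abp_trajectory(p, 9L, 3L, 0.01, c(10, 10),
                                     chi_sys = 0), "even")
  expect_error(chiral_abp_trajectory(p, 10L, 3L, 0.5, c(10, 10)),
               "dt")
})

test_that("polygons_with_ar hits requested aspect ratios at unit area", {
  targets <- c(1.05, 1.4, 2.2, 3.0)
  pe <- polygons_with_ar(targets, n_vertices = 48L, seed = 3)
  tab <- ensemble_aspect_ratios(pe)
  expect_equal(sort(tab$ar), sort(targets), tolerance = 2e-3)
  for (p in pe$frames[[1L]]) {
    expect_equal(abs(polygon_area(p)), 1, tolerance = 1e-6)
  }
})

test_that("shape pipeline recovers alpha end to end from polygons", {
  ## draw ARs from the mean-field law, realize them as polygons, re-measure
  ## the ARs geometrically and fit alpha
  ar <- sample_meanfield(2e4, alpha = 2, seed = 11)
  keep <- seq(1, length(ar), by = 40)  # 500 polygons is enough geometry
  pe <- polygons_with_ar(ar[keep], n_vertices = 32L, seed = 4)
  measured <- ensemble_aspect_ratios(pe)$ar
  expect_equal(mean(measured), mean(ar[keep]), tolerance = 1e-3)
  ## full-sample fit on the law's own draws: the headline recovery bound
  fit <- fit_meanfield(ar)
  expect_equal(fit$alpha, 2, tolerance = 0.1 / 2)
})
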