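## shared Brownian reference trajectory: D = 0.05, dt = 0.5, 400 cells
D <- 0.05
brown <- brownian_trajectory(n_frames = 200L, n_cells = 400L, D = D,
                             dt = 0.5, L = 20, seed = 301)

test_that("Brownian MSD is linear with slope 4D", {
  mc <- msd(brown)
  fit <- lm(msd ~ 0 + time, data = mc)
  expect_equal(unname(coef(fit)), 4 * D, tolerance = 0.03)
  ## invariance under a uniform periodic shift of all positions
  shifted <- brown
  shifted$positions[, , 1L] <- (shifted$positions[, , 1L] + 7.3) %% 20
  expect_equal(msd(shifted)$msd, mc$msd, tolerance = 1e-12)
})

test_that("F_s matches exp(-q^2 D t) and tau_alpha matches 1/(q^2 D)", {
  q <- 1
  fs <- self_intermediate_scattering(brown, q)
  expect_equal(fs$fs[1L], 1)
  theory <- exp(-q^2 * D * fs$time)
  expect_lt(max(abs(fs$fs - theory)), 0.02)
  ta <- relaxation_time(fs)
  expect_false(ta$censored)
  expect_equal(ta$tau_alpha, 1 / (q^2 * D), tolerance = 0.05)
})

test_that("relaxation time is censored when F_s never reaches 1/e", {
  short <- brownian_trajectory(40L, 100L, D = 0.002, dt = 0.1, L = 10,
                               seed = 302)
  ta <- relaxation_time(self_intermediate_scattering(short, q = 1))
  expect_true(ta$censored)
  expect_true(is.na(ta$tau_alpha))
  expect_equal(ta$lower_bound, 2, tolerance = 1e-12)
})

test_that("persistence time tracks the ballistic-diffusive crossover", {
  p <- chiral_cell_params(v0 = 1, chi_cell = 0, omega_max = 0, D_r = 0.2)
  tt <- exp(seq(log(0.05), log(200), length.out = 80))
  curve <- data.frame(time = tt, msd = chiral_abp_msd_theory(tt, p))
  pt <- persistence_time(curve)
  ## crossover at the scale of the persistence time 1/D_r = 5
  expect_gt(pt$tau_p, 5 / 3)
  expect_lt(pt$tau_p, 5 * 3)
  expect_equal(pt$v, 1, tolerance = 0.05)
  expect_equal(pt$l_p, pt$v * pt$tau_p)
  ## pure diffusion has no ballistic regime
  diffu <- data.frame(time = tt, msd = 4 * 0.1 * tt)
  expect_error(persistence_time(diffu), "no-crossover")
})

test_that("alpha2 is flat for Gaussian dynamics and boundary peaks warn", {
  ## Brownian displacements are Gaussian at every lag: alpha2 stays near 0
  ct <- suppressWarnings(cage_time(brown, lags = 1:60))
  expect_lt(max(abs(ct$alpha2$alpha2)), 0.2)
  ## deterministic bimodal ballistic motion: alpha2 is constant in lag, so
  ## the argmax sits at the first lag and must be flagged
  nf <- 20L; nc <- 100L
  v <- rep(c(0.01, 0.1), times = c(90L, 10L))
  pos <- array(0, c(nf, nc, 2L))
  pos[, , 1L] <- outer(seq_len(nf) - 1L, v)
  pos[, , 2L] <- 5
  traj <- trajectory(pos %% 1000, dt = 1,
                     box = list(type = "periodic", Lx = 1000, Ly = 1000))
  expect_warning(ctb <- cage_time(traj), "boundary-peak")
  expect_true(ctb$boundary)
  expect_equal(ctb$t_star_lag, 1L)
})

test_that("a planted two-population mixture yields a positive alpha2 peak", {
  set.seed(305)
  nf <- 150L; nc <- 200L; dt <- 0.1
  ## 20% fast cells (D x 25): strongly non-Gaussian displacement field
  Ds <- rep(c(0.01, 0.25), times = c(160L, 40L))
  pos <- array(0, c(nf, nc, 2L))
  pos[1L, , ] <- matrix(runif(2L * nc, 0, 10), nc, 2L)
  for (f in 2:nf) {
    pos[f, , ] <- pos[f - 1L, , ] +
      matrix(rnorm(2L * nc, sd = rep(sqrt(2 * Ds * dt), 2L)), nc, 2L)
  }
  traj <- trajectory(pos %% 10, dt = dt,
                     box = list(type = "periodic", Lx = 10, Ly = 10))
  ct <- cage_time(traj)
  expect_gt(max(ct$alpha2$alpha2), 0.5)

  dh <- mobility_subsets(traj, ct$t_star_lag, fraction = 0.10)
  ## >= 80% of the selected fast cells are genuinely fast (planted ids 161+)
  expect_gte(mean(as.integer(dh$fast_ids) > 160L), 0.8)
  expect_gte(mean(as.integer(dh$slow_ids) <= 160L), 0.8)
  expect_false(dh$degenerate)
})

test_that("mobility subsets have deterministic size and tie-breaking", {
  pos <- array(rep(seq_len(20L), each = 2L), c(2L, 20L, 2L))
  pos[2L, , ] <- pos[2L, , ] + 1  # all displacements equal
  traj <- trajectory(pos %% 100, dt = 1,
                     box = list(type = "periodic", Lx = 100, Ly = 100))
  dh <- mobility_subsets(traj, 1L, fraction = 0.10)
  expect_length(dh$fast_ids, 2L)   # 20 cells, fraction 0.10 -> 2 fast
  expect_length(dh$slow_ids, 2L)
  expect_true(dh$degenerate)
  expect_equal(dh$slow_ids, c(1L, 2L))  # ties broken by cell order
  expect_error(mobility_subsets(traj, 1L, fraction = 0.8), "fraction")
})

test_that("subset shape statistics demand full polygon coverage", {
  fr <- list("1" = regular_polygon(6L), "2" = ellipse_polygon(2, 1, 32L))
  pe <- polygon_ensemble(list(fr))
  dh <- structure(list(fast_ids = c("1"), slow_ids = c("3"),
                       displacement = c("1" = 1, "2" = 0, "3" = 0.5)),
                  class = "dh_result")
  expect_error(subset_shape_stats(dh, pe), "coverage error")
  dh$slow_ids <- "2"
  ss <- subset_shape_stats(dh, pe)
  expect_equal(unname(ss$fast["mean_ar"]), 1, tolerance = 1e-9)
  expect_equal(unname(ss$slow["mean_ar"]), 2, tolerance = 0.01)
})

test_that("unwrapping rejects frame-to-frame jumps beyond half the box", {
  pos <- array(c(1, 6, 1, 1), c(2L, 1L, 2L))
  traj <- trajectory(pos, dt = 1, box = list(type = "periodic",
                                             Lx = 10, Ly = 10))
  expect_error(msd(traj), "jump|half")
})
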