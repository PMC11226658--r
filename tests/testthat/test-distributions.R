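test_that("the k-gamma law has unit mass, unit mean and variance 1/k", {
  for (k in c(0.7, 1, 2.6, 8)) {
    expect_equal(integrate(dkgamma, 0, Inf, k = k, rel.tol = 1e-10)$value,
                 1, tolerance = 1e-7)
    m1 <- integrate(function(x) x * dkgamma(x, k), 0, Inf,
                    rel.tol = 1e-10)$value
    m2 <- integrate(function(x) x^2 * dkgamma(x, k), 0, Inf,
                    rel.tol = 1e-10)$value
    expect_equal(m1, 1, tolerance = 1e-7)
    expect_equal(m2 - m1^2, 1 / k, tolerance = 1e-6)
  }
  expect_error(dkgamma(1, k = -1), "parameter-domain")
  expect_error(dkgamma(1, k = c(1, 2)), "parameter-domain")
})

test_that("the mean-field density is normalized and vanishes at AR = 1", {
  for (alpha in c(0.9, 2, 15, 200)) {
    expect_equal(integrate(dmeanfield, 1, Inf, alpha = alpha,
                           rel.tol = 1e-10)$value,
                 1, tolerance = 1e-7)
  }
  expect_equal(dmeanfield(1, 2), 0)
  expect_error(dmeanfield(0.5, 2), "parameter-domain")
  expect_error(dmeanfield(1.5, -2), "parameter-domain")
})

test_that("meanfield moments and mean_h agree with direct quadrature", {
  for (alpha in c(1.2, 5, 50)) {
    mm <- meanfield_moments(alpha)
    m1 <- integrate(function(a) a * dmeanfield(a, alpha), 1, Inf,
                    rel.tol = 1e-10)$value
    m2 <- integrate(function(a) a^2 * dmeanfield(a, alpha), 1, Inf,
                    rel.tol = 1e-10)$value
    expect_equal(unname(mm["mean_ar"]), m1, tolerance = 1e-7)
    expect_equal(unname(mm["sd_ar"]), sqrt(m2 - m1^2), tolerance = 1e-6)
    h <- integrate(function(a) (a + 1 / a) * dmeanfield(a, alpha), 1, Inf,
                   rel.tol = 1e-10)$value
    expect_equal(meanfield_mean_h(alpha), h, tolerance = 1e-7)
  }
  ## mean_h is strictly decreasing in alpha (exponential-family monotonicity)
  hs <- vapply(c(0.5, 1, 2, 4, 8, 16), meanfield_mean_h, numeric(1))
  expect_true(all(diff(hs) < 0))
})

test_that("samplers reproduce their target laws", {
  x <- sample_kgamma(2e4, k = 2.6, seed = 101)
  expect_equal(mean(x), 1, tolerance = 0.02)
  expect_equal(var(x), 1 / 2.6, tolerance = 0.03)

  y <- sample_meanfield(2e4, alpha = 2, seed = 102)
  expect_true(all(y > 1))
  mm <- meanfield_moments(2)
  expect_equal(mean(y), unname(mm["mean_ar"]), tolerance = 0.01)
  expect_equal(sd(y), unname(mm["sd_ar"]), tolerance = 0.02)
  expect_gt(attr(y, "acceptance_rate"), 0.05)
  ## one-sample KS against the model CDF
  cdf <- function(q) vapply(q, function(z) {
    integrate(dmeanfield, 1, z, alpha = 2, rel.tol = 1e-9)$value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(y[1:2000], cdf))
  expect_gt(ks$p.value, 0.001)
})

test_that("sampling is reproducible by seed", {
  expect_identical(sample_kgamma(50, 2, seed = 7), sample_kgamma(50, 2, seed = 7))
  expect_identical(as.numeric(sample_meanfield(50, 3, seed = 7)),
                   as.numeric(sample_meanfield(50, 3, seed = 7)))
})
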