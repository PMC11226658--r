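curve <- universal_line()

test_that("the universal line has the predicted coefficients", {
  expect_equal(curve$slope, 0.71, tolerance = 0.03 / 0.71)
  expect_equal(curve$intercept, -0.75, tolerance = 0.05 / 0.75)
  ## the parametric curve is monotone: mean AR decreases with alpha
  expect_true(all(diff(curve$mean_ar) < 0))
})

test_that("the line is stable under halving and doubling the alpha grid", {
  ## the halved grid legitimately warns about its own coarseness
  co_half <- suppressWarnings(universal_line(n_grid = 200L))
  co_dbl <- universal_line(n_grid = 800L)
  expect_equal(co_half$slope, curve$slope, tolerance = 0.01)
  expect_equal(co_dbl$slope, curve$slope, tolerance = 0.01)
  expect_equal(co_half$intercept, curve$intercept, tolerance = 0.01)
  expect_equal(co_dbl$intercept, curve$intercept, tolerance = 0.01)
})

test_that("window sensitivity is reported and sparse grids are rejected", {
  expect_true(all(c("nominal", "narrower", "wider") %in%
                    rownames(curve$sensitivity)))
  expect_lt(max(abs(curve$sensitivity$slope - curve$slope), na.rm = TRUE),
            0.05)
  expect_error(suppressWarnings(universal_line(alpha_grid = c(1, 2, 40))),
               "insufficient-grid|coarser")
})

test_that("rescaled PDFs collapse across alpha but not across k", {
  sams <- list(a = sample_meanfield(8000, 1.5, seed = 1),
               b = sample_meanfield(8000, 4, seed = 2),
               c = sample_meanfield(8000, 10, seed = 3))
  cp <- collapse_pdfs(sams)
  expect_lt(cp$score, 0.25)
  ## distributions of genuinely different shape do not collapse
  far <- list(x = 1 + rgamma(8000, shape = 0.4, rate = 2),
              y = 1 + rgamma(8000, shape = 30, rate = 40))
  expect_gt(collapse_pdfs(far)$score, 2 * cp$score)
  expect_equal(collapse_pdfs(sams[1])$score, 0)
})

test_that("assess_scaling_deviation detects points below the line", {
  ms <- seq(1.2, 1.8, length.out = 8)
  on_line <- data.frame(mean_ar = ms,
                        sd_ar = curve$slope * ms + curve$intercept +
                          c(-1, 1) * 0.004)
  below <- data.frame(mean_ar = ms,
                      sd_ar = curve$slope * ms + curve$intercept - 0.06 +
                        c(-1, 1) * 0.004)
  a_on <- assess_scaling_deviation(on_line, curve)
  a_below <- assess_scaling_deviation(below, curve)
  expect_false(a_on$below)
  expect_true(a_below$below)
  expect_lt(a_below$p_value, 0.01)
  expect_error(assess_scaling_deviation(1:5, curve), "input error")
  expect_error(assess_scaling_deviation(on_line[1:2, ], curve), "3 points")
})
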