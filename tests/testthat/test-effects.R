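test_that("cohens_d matches hand arithmetic and its invariances", {
  expect_equal(cohens_d(c(2, 4), c(1, 3)), 1 / sqrt(2))
  expect_equal(cohens_d(c(1, 3), c(2, 4)), -1 / sqrt(2))  # antisymmetry
  expect_equal(cohens_d(c(5, 6, 7), c(5, 7, 6)), 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), class = "warmsoil_validation_error")
  expect_error(cohens_d(1, c(1, 2)), class = "warmsoil_validation_error")
  # location invariance / scale equivariance: d(a + bX, a + bY) = sign(b) d(X, Y)
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(6); a <- rnorm(1); b <- rnorm(1)
    expect_equal(cohens_d(a + b * x, a + b * y),
                 sign(b) * cohens_d(x, y), tolerance = 1e-10)
  }
  # Hedges correction shrinks toward zero
  expect_lt(abs(cohens_d(c(2, 4), c(1, 3), hedges = TRUE)),
            abs(cohens_d(c(2, 4), c(1, 3))))
})

test_that("trend_ols matches the closed-form normal equations", {
  f <- trend_ols(1:5, 2 * (1:5) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2_adjusted, 1)
  expect_equal(trend_ols(c(1, 2, 3), c(1, 3, 2))$slope, 0.5)
  f0 <- trend_ols(1:5, rep(3, 5))
  expect_equal(f0$slope, 0)
  expect_equal(f0$p, 1)
  expect_error(trend_ols(rep(1, 4), 1:4), class = "warmsoil_validation_error")
  # oracle: agree with lm() on random inputs to 1e-10
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    f <- trend_ols(x, y)
    m <- summary(lm(y ~ x))
    expect_equal(f$slope, unname(coef(m)[2, 1]), tolerance = 1e-10)
    expect_equal(f$p, unname(coef(m)[2, 4]), tolerance = 1e-10)
    expect_equal(f$r2_adjusted, m$adj.r.squared, tolerance = 1e-10)
  }
})

test_that("trend_sma is the sign-corrected SD ratio with SMA symmetry", {
  expect_equal(trend_sma(1:4, 2 * (1:4)), 2)
  expect_equal(trend_sma(c(1, 2, 3), c(1, 3, 2)), 1.0)
  expect_error(trend_sma(1:3, rep(2, 3)), class = "warmsoil_validation_error")
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(7); y <- rnorm(7)
    s <- trend_sma(x, y)
    expect_equal(trend_sma(y, x), 1 / s, tolerance = 1e-12)
    # |SMA| >= |OLS|, equality iff |corr| = 1
    expect_gte(abs(s) + 1e-12, abs(trend_ols(x, y)$slope))
  }
})

test_that("response_ratio is the log ratio with exact antisymmetry", {
  expect_equal(response_ratio(5, 5), 0)
  expect_equal(response_ratio(exp(1) * 4, 4), 1)
  expect_equal(response_ratio(2, 8), log(0.25))
  expect_identical(response_ratio(2, 8), -response_ratio(8, 2))
  expect_error(response_ratio(0, 1), class = "warmsoil_validation_error")
  expect_error(response_ratio(1, -2), class = "warmsoil_validation_error")
})

test_that("effect_size_series recovers injected per-year effects", {
  cfg <- generator_config(seed = 21, noise_sd = zero_noise())
  d <- generate_design(cfg)
  tr <- generate_truth(cfg, d)
  mm <- generate_measurements(cfg, d, tr)
  es <- suppressMessages(effect_size_series(mm$measurements, d, "soc",
                                            "conservation"))
  # step multiplier from the 2016 onset: zero effect before, positive after
  expect_equal(es$per_year$d[es$per_year$year < 2016], rep(0, 3))
  expect_true(all(es$per_year$d[es$per_year$year >= 2016] > 0))
  # sign convention: warmed > ambient <=> d > 0
  expect_gt(es$trend_slope, 0)
  es2 <- suppressMessages(effect_size_series(mm$measurements, d, "soc",
                                             "conventional"))
  expect_equal(es2$per_year$d, rep(0, 6))
  expect_error(effect_size_series(mm$measurements, d, "nope", "conservation"),
               class = "warmsoil_validation_error")
})

test_that("single-year input yields NA trend with a message", {
  cfg <- generator_config(seed = 22, years = c(2010, 2012))
  d <- generate_design(cfg)
  tr <- generate_truth(cfg, d)
  mm <- generate_measurements(cfg, d, tr)
  expect_message(es <- effect_size_series(mm$measurements, d, "soc",
                                          "conservation"),
                 "trend not fit")
  expect_true(is.na(es$trend_slope))
})

test_that("stage_contrast splits and averages the trajectory", {
  series <- structure(list(
    variable = "x", management = "conservation",
    per_year = data.frame(year = seq(2010, 2020, 2),
                          d = c(-1, -1, -1, 1, 1, 1))),
    class = "effect_size_series")
  sc <- stage_contrast(series)
  expect_equal(sc$early_mean_d, -1)
  expect_equal(sc$late_mean_d, 1)
  expect_equal(sc$difference, 2)
  series$per_year$d <- rep(0.4, 6)
  expect_equal(stage_contrast(series)$difference, 0)
  series$per_year$d[series$per_year$year > 2015] <- NA
  expect_error(stage_contrast(series), class = "warmsoil_validation_error")
})
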