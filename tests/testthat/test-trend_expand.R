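test_that("annual multiplier matches the closed form and composes", {
  expect_equal(annual_multiplier(1, 7), 1)
  expect_equal(annual_multiplier(2, 10), exp(log(2) / 10), tolerance = 1e-12)
  expect_equal(annual_multiplier(0.5, 10) * annual_multiplier(2, 10), 1,
               tolerance = 1e-12)
  expect_error(annual_multiplier(-1, 10), "mean_trend")
  expect_error(annual_multiplier(1.2, 0), "trend_period")
})

test_that("reconstruction anchors at the estimate year and is reversible", {
  rec <- list(mean_trend = 1.05^10, trend_period = 10, mean_pop = 1000,
              mean_estimate_year = 2005)
  out <- reconstruct_series(rec, 2000:2010)
  expect_equal(out$population[out$year == 2005], 1000)
  expect_equal(out$population[out$year == 2007], 1102.5, tolerance = 1e-9)
  ## flat trend
  flat <- reconstruct_series(list(mean_trend = 1, trend_period = 5,
                                  mean_pop = 77, mean_estimate_year = 2003),
                             2000:2010)
  expect_equal(flat$population, rep(77, 11))
  ## reversibility on random records: re-anchoring at any year i* of the
  ## reconstructed series reproduces the same series
  set.seed(21)
  for (r in 1:50) {
    rec <- list(mean_trend = exp(runif(1, -1, 1)),
                trend_period = sample(5:20, 1),
                mean_pop = exp(runif(1, 4, 12)),
                mean_estimate_year = sample(1995:2010, 1))
    yrs <- 1990:2015
    a <- reconstruct_series(rec, yrs)
    istar <- sample(yrs, 1)
    rec2 <- rec
    rec2$mean_pop <- a$population[a$year == istar]
    rec2$mean_estimate_year <- istar
    b <- reconstruct_series(rec2, yrs)
    expect_equal(b$population, a$population, tolerance = 1e-9)
  }
})

test_that("regional point estimate follows the geometric-mean/span rules", {
  pe <- eu_point_estimate(60, 120)
  expect_equal(pe$point, sqrt(60 * 120), tolerance = 1e-12)
  expect_equal(pe$se, 10)
  best <- eu_point_estimate(500)
  expect_equal(best$point, 500)
  expect_equal(best$se, 0)
  expect_error(eu_point_estimate(10, 5), "exceeds")
  set.seed(3)
  for (r in 1:100) {
    mn <- exp(runif(1, 0, 10)); mx <- mn * runif(1, 1, 5)
    expect_equal(eu_point_estimate(mn, mx)$point^2, mn * mx,
                 tolerance = 1e-12)
  }
})

test_that("summing national series is linear and grid-checked", {
  a <- data.frame(year = 2000:2004, population = rep(100, 5))
  b <- data.frame(year = 2000:2004, population = rep(200, 5))
  expect_equal(sum_national_series(list(a, b))$population, rep(300, 5))
  expect_equal(sum_national_series(list(a)), a)
  k <- 4
  expect_equal(sum_national_series(rep(list(a), k))$population,
               k * a$population)
  bad <- data.frame(year = 2001:2005, population = 1)
  expect_error(sum_national_series(list(a, bad)), "common year grid")
})

test_that("summed series inherit year-on-year monotonicity", {
  set.seed(14)
  mk <- function() {
    lam <- runif(1, 1.001, 1.1)
    reconstruct_series(list(mean_trend = lam^10, trend_period = 10,
                            mean_pop = exp(runif(1, 5, 10)),
                            mean_estimate_year = 2000), 2000:2015)
  }
  tot <- sum_national_series(lapply(1:5, function(i) mk()))
  expect_true(all(diff(tot$population) > 0))
})

test_that("bootstrap interval is degenerate, calibrated and reproducible", {
  ## zero-variance inputs -> width 0
  ci0 <- bootstrap_ci(function(x) x, function() 5, n = 100, seed = 1)
  expect_equal(ci0$lcl, ci0$ucl)
  ## mean of m standard normals: percentile interval approaches the
  ## analytic +/- 1.96/sqrt(m) interval around the sample mean
  m <- 100
  set.seed(2)
  ci <- bootstrap_ci(function(x) mean(x),
                     function() rnorm(m, 0, 1), n = 1e5)
  half_width <- (ci$ucl - ci$lcl) / 2
  expect_equal(half_width, 1.96 / sqrt(m), tolerance = 0.02)
  ## fixed seed -> bit-identical
  s1 <- bootstrap_ci(sum, function() rnorm(3), n = 50, seed = 99)
  s2 <- bootstrap_ci(sum, function() rnorm(3), n = 50, seed = 99)
  expect_identical(s1, s2)
})

test_that("bootstrap intervals for expanded trends achieve nominal coverage", {
  ## 1000 simulated datasets with known truth; lognormal estimate error;
  ## each interval from a 1000-replicate bootstrap. Nominal 95% coverage
  ## should land between 93% and 97%.
  set.seed(77)
  n_sim <- 1000
  sdlog <- 0.2
  lam <- 1.02
  truth <- 5e4 * lam^7        # population 7 years after the estimate year
  cover <- 0L
  for (i in seq_len(n_sim)) {
    obs <- 5e4 * exp(rnorm(1, 0, sdlog))
    ci <- bootstrap_ci(function(p) p * lam^7,
                       function() stats::rlnorm(1, log(obs), sdlog),
                       n = 1000)
    if (truth >= ci$lcl && truth <= ci$ucl) cover <- cover + 1L
  }
  expect_gte(cover, 930)
  expect_lte(cover, 970)
})

test_that("reconstruct_with_ci brackets the point estimate", {
  recs <- data.frame(species_id = "s", country = c("AT", "BE"),
                     mean_trend = c(1.3, 0.8), trend_period = 10,
                     mean_pop = c(1e4, 2e4), mean_estimate_year = 2005,
                     pop_se = c(1e3, 3e3))
  out <- reconstruct_with_ci(recs, 2000:2010, n = 500, seed = 8)
  expect_true(all(out$lcl <= out$population & out$population <= out$ucl))
  ## zero se -> zero-width intervals
  recs$pop_se <- 0
  out0 <- reconstruct_with_ci(recs, 2000:2010, n = 200, seed = 8)
  expect_equal(out0$lcl, out0$population, tolerance = 1e-12)
  expect_equal(out0$ucl, out0$population, tolerance = 1e-12)
})
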