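test_that("missing-year variance inflation follows the squared-gap rule", {
  years <- 1990:2000
  obs_var <- rep(0.04, 11)
  out <- inflate_missing_variance(obs_var, first_data_year = 1995,
                                  years = years, c = 1)
  expect_equal(out[years == 1994], 0.04 + 1)
  expect_equal(out[years == 1990], 0.04 + 25)
  expect_equal(out[years >= 1995], rep(0.04, 6))
  out2 <- inflate_missing_variance(obs_var, 1995, years, c = 0.5)
  expect_equal(out2[years == 1990], 0.04 + 0.25 * 25)
  ## trailing gap treated symmetrically
  out3 <- inflate_missing_variance(obs_var, 1990, years, c = 1,
                                   last_data_year = 1998)
  expect_equal(out3[years == 2000], 0.04 + 4)
})

test_that("a noiseless single species collapses to its scaled trajectory", {
  years <- 2000:2010
  lam <- 0.05 * (years - 2005)
  sm <- list(spA = make_smoothed(years, log_index = 3 + lam,
                                 se_log = rep(1e-6, 11)))
  est <- data.frame(species_id = "spA", point = 1e4, se = 0,
                    ref_year_start = 2005, ref_year_end = 2005)
  sp <- data.frame(species_id = "spA", habitat = "forest",
                   migration = "resident")
  fit <- suppressWarnings(
    fit_abundance_model(sm, est, sp, chains = 2, warmup = 100, iter = 100,
                        thin = 1, seed = 2))
  tt <- total_trajectory(fit)
  expect_equal(tt$summary$median, 1e4 * exp(lam), tolerance = 1e-3)
  rel_width <- (tt$summary$ucl - tt$summary$lcl) / tt$summary$median
  expect_lt(max(rel_width), 1e-3)
})

test_that("totals are additive over any species partition, draw by draw", {
  fit <- shared_small_fit()$fit
  S <- length(fit$species_id)
  idx1 <- seq_len(floor(S / 2)); idx2 <- setdiff(seq_len(S), idx1)
  N <- species_trajectories(fit)
  tot <- total_trajectory(fit)$draws
  t1 <- apply(N[, idx1, , drop = FALSE], c(1, 3), sum)
  t2 <- apply(N[, idx2, , drop = FALSE], c(1, 3), sum)
  expect_equal(t1 + t2, tot, tolerance = 1e-9)
  expect_true(all(is.finite(tot)) && all(tot > 0))
})

test_that("weighted totals equal mass-weighted sums draw by draw", {
  fit <- shared_small_fit()$fit
  w <- stats::setNames(runif(length(fit$species_id), 5, 500),
                       fit$species_id)
  tw <- total_trajectory(fit, weights = w)$draws
  N <- species_trajectories(fit)
  for (s in seq_along(fit$species_id)) N[, s, ] <- N[, s, ] * w[s]
  manual <- apply(N, c(1, 3), sum)
  expect_equal(tw, manual, tolerance = 1e-9)
})

test_that("uncertain species are shrunk towards their group mean", {
  set.seed(99)
  years <- 2000:2019
  d <- years - 2010
  group_slope <- -0.04
  sms <- list()
  for (i in 1:6) {
    sms[[sprintf("dec%02d", i)]] <- make_smoothed(
      years, log_index = (group_slope + rnorm(1, 0, 0.002)) * d,
      se_log = rep(0.02, 20), species_id = sprintf("dec%02d", i))
  }
  ## one species with a wildly uncertain, flat observed trend
  noisy_obs <- 0.0 * d + rnorm(20, 0, 0.3)
  noisy_obs <- noisy_obs - noisy_obs[d == 0]
  sms[["noisy"]] <- make_smoothed(years, log_index = noisy_obs,
                                  se_log = rep(0.5, 20),
                                  species_id = "noisy")
  ids <- names(sms)
  est <- data.frame(species_id = ids, point = 1e4, se = 1e3,
                    ref_year_start = 2010, ref_year_end = 2010)
  sp <- data.frame(species_id = ids, habitat = "grassland",
                   migration = "resident")
  fit <- suppressWarnings(
    fit_abundance_model(sms, est, sp, chains = 2, warmup = 400, iter = 400,
                        thin = 2, seed = 31))
  i_noisy <- match("noisy", fit$species_id)
  theta_post <- colMeans(fit$draws$theta)
  group_mean <- mean(theta_post[-i_noisy])
  ## WLS estimate for the noisy species alone
  w <- rep(1 / 0.5^2, 20)
  theta_wls <- sum(w * d * noisy_obs) / sum(w * d^2)
  expect_lt(abs(theta_post[i_noisy] - group_mean),
            abs(theta_wls - group_mean))
})

test_that("with one diffuse group, trends match independent fits", {
  set.seed(12)
  years <- 2000:2019
  d <- years - 2010
  slopes <- c(-0.05, 0, 0.04)
  sms <- list()
  for (i in seq_along(slopes)) {
    id <- sprintf("sp%d", i)
    obs <- slopes[i] * d + rnorm(20, 0, 0.01)
    obs <- obs - obs[d == 0]
    sms[[id]] <- make_smoothed(years, obs, se_log = rep(0.01, 20),
                               species_id = id)
  }
  ids <- names(sms)
  est <- data.frame(species_id = ids, point = 1e5, se = 1e4,
                    ref_year_start = 2010, ref_year_end = 2010)
  sp <- data.frame(species_id = ids, habitat = "forest",
                   migration = "resident")
  fit <- suppressWarnings(
    fit_abundance_model(sms, est, sp, interaction = FALSE, chains = 2,
                        warmup = 400, iter = 400, thin = 2, seed = 13))
  theta_post <- colMeans(fit$draws$theta)
  for (i in seq_along(slopes)) {
    obs <- sms[[i]]$log_index
    wls <- sum(d * obs) / sum(d^2)
    expect_equal(theta_post[i], wls, tolerance = 0.004)
  }
})

test_that("species without estimates are dropped with a message", {
  sim <- simulate_assemblage(n_species = 6, years = 2000:2014, seed = 21,
                             p_zero = 0, p_missing_start = 0)
  sm <- smooth_all_series(sim$bundle$index)
  est <- sim$bundle$estimates[-2, ]
  expect_message(
    fit <- suppressWarnings(
      fit_abundance_model(sm, est, sim$bundle$species, chains = 1,
                          warmup = 50, iter = 50, thin = 1, seed = 1)),
    "dropping 1 species")
  expect_equal(length(fit$species_id), 5)
})

test_that("reference year outside the smoothed span is an error", {
  years <- 2000:2012
  sm <- list(spA = make_smoothed(years, rnorm(13, 0, 0.01),
                                 se_log = rep(0.02, 13)))
  est <- data.frame(species_id = "spA", point = 100, se = 10,
                    ref_year_start = 2020, ref_year_end = 2020)
  sp <- data.frame(species_id = "spA", habitat = "forest",
                   migration = "resident")
  expect_error(fit_abundance_model(sm, est, sp, chains = 1, warmup = 10,
                                   iter = 10, thin = 1),
               "reference year")
})
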