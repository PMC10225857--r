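test_that("z-transform uses the population convention and inverts", {
  z <- z_transform(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean((as.numeric(z))^2)), 1, tolerance = 1e-12)
  ## idempotence on already-standardized input
  z2 <- z_transform(as.numeric(z))
  expect_equal(as.numeric(z2), as.numeric(z), tolerance = 1e-12)
  ## round trip
  set.seed(1)
  x <- rnorm(50, 10, 3)
  expect_equal(inverse_z(z_transform(x)), x, tolerance = 1e-12)
  expect_error(z_transform(rep(4, 5), "mass"), "mass.*zero variance")
})

test_that("the linear model recovers a known mass effect", {
  set.seed(2)
  n <- 300
  dat <- data.frame(body_mass_z = rnorm(n),
                    migration = factor(sample(migration_classes, n, TRUE)))
  dat$growth_rate <- 0.5 * dat$body_mass_z + rnorm(n, 0, 1)
  fit <- fit_trend_lm(growth_rate ~ body_mass_z + migration, dat)
  co <- summary(fit$fit)$coefficients
  expect_lt(abs(co["body_mass_z", 1] - 0.5), 2 * co["body_mass_z", 2])
  expect_equal(fit$aic, AIC(fit$fit))
})

test_that("rank-deficient designs report aliased terms", {
  dat <- data.frame(growth_rate = rnorm(20), a = rnorm(20))
  dat$b <- dat$a
  expect_message(fit <- fit_trend_lm(growth_rate ~ a + b, dat), "aliased")
  expect_identical(fit$aliased, "b")
})

test_that("coefficients are invariant to row order", {
  set.seed(3)
  dat <- data.frame(growth_rate = rnorm(40), x = rnorm(40))
  f1 <- fit_trend_lm(growth_rate ~ x, dat)
  f2 <- fit_trend_lm(growth_rate ~ x, dat[sample(40), ])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
})

make_pgls_data <- function(tree, beta = 0, sigma = 1, phylo = TRUE,
                           seed = 1) {
  set.seed(seed)
  n <- length(tree$tip.label)
  x <- rnorm(n)
  resid <- if (phylo) {
    V <- ape::vcv(tree)
    drop(crossprod(chol(V / mean(diag(V))), rnorm(n))) * sigma
  } else rnorm(n, 0, sigma)
  data.frame(species_id = tree$tip.label, x = x,
             growth_rate = beta * x + resid)
}

test_that("PGLS at lambda = 0 equals OLS exactly on an ultrametric tree", {
  set.seed(4)
  tree <- ape::rphylo(40, birth = 0.1, death = 0)
  dat <- make_pgls_data(tree, beta = 0.4, phylo = FALSE, seed = 5)
  pg <- fit_pgls(growth_rate ~ x, dat, tree, lambda = 0)
  ols <- lm(growth_rate ~ x, dat)
  expect_equal(pg$coefficients[, "Estimate"], coef(ols), tolerance = 1e-10)
  expect_equal(pg$coefficients[, "Std. Error"],
               summary(ols)$coefficients[, 2], tolerance = 1e-10)
})

test_that("a star phylogeny is flagged unidentifiable and equals OLS", {
  n <- 25
  star <- ape::stree(n, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  star$tip.label <- sprintf("t%02d", 1:n)
  dat <- make_pgls_data(star, beta = 0.3, phylo = FALSE, seed = 6)
  expect_message(pg <- fit_pgls(growth_rate ~ x, dat, star), "unidentifiable")
  expect_true(pg$unidentifiable)
  expect_equal(pg$coefficients[, "Estimate"],
               coef(lm(growth_rate ~ x, dat)), tolerance = 1e-10)
})

test_that("GLS pieces match an independent implementation at fixed lambda", {
  skip_if_not_installed("nlme")
  set.seed(7)
  tree <- ape::rphylo(60, birth = 0.1, death = 0)
  dat <- make_pgls_data(tree, beta = 0.5, phylo = TRUE, seed = 8)
  for (lam in c(0.3, 0.8)) {
    pg <- fit_pgls(growth_rate ~ x, dat, tree, lambda = lam)
    gl <- nlme::gls(growth_rate ~ x, data = dat,
                    correlation = ape::corPagel(lam, tree, fixed = TRUE,
                                                form = ~species_id),
                    method = "ML")
    expect_equal(pg$coefficients[, "Estimate"], coef(gl), tolerance = 1e-6)
    expect_equal(pg$loglik, as.numeric(logLik(gl)), tolerance = 1e-6)
  }
})

test_that("lambda ML agrees with an independent estimator", {
  skip_if_not_installed("nlme")
  set.seed(7)
  tree <- ape::rphylo(60, birth = 0.1, death = 0)
  dat <- make_pgls_data(tree, beta = 0.5, phylo = TRUE, seed = 8)
  pg <- fit_pgls(growth_rate ~ x, dat, tree)
  gl <- nlme::gls(growth_rate ~ x, data = dat,
                  correlation = ape::corPagel(0.5, tree, fixed = FALSE,
                                              form = ~species_id),
                  method = "ML")
  lam_nlme <- coef(gl$modelStruct$corStruct, unconstrained = FALSE)
  ## nlme profiles lambda with a generic optimizer; agreement is expected
  ## to optimizer precision, and the likelihoods must agree at each other's
  ## optimum
  expect_equal(pg$lambda, unname(lam_nlme), tolerance = 0.05)
  expect_gte(pg$loglik + 1e-6, pg$profile(min(max(unname(lam_nlme), 0), 1)))
})

test_that("profile likelihood peaks at the estimate and CI brackets it", {
  set.seed(9)
  tree <- ape::rphylo(50, birth = 0.1, death = 0)
  dat <- make_pgls_data(tree, beta = 0, phylo = TRUE, seed = 10)
  pg <- fit_pgls(growth_rate ~ x, dat, tree)
  grid <- seq(0, 1, by = 0.1)
  lls <- vapply(grid, pg$profile, 0)
  expect_true(all(pg$loglik >= lls - 1e-8))
  expect_true(pg$lambda_ci[1] <= pg$lambda && pg$lambda <= pg$lambda_ci[2])
  expect_equal(pg$aic, 2 * pg$k - 2 * pg$loglik)
})

test_that("species missing from the tree are dropped with a message", {
  set.seed(11)
  tree <- ape::rphylo(20, birth = 0.1, death = 0)
  dat <- make_pgls_data(tree, seed = 12)
  dat <- rbind(dat, data.frame(species_id = "ghost", x = 0,
                               growth_rate = 0))
  expect_message(pg <- fit_pgls(growth_rate ~ x, dat, tree),
                 "dropping 1 species")
  expect_equal(pg$n, 20)
})

test_that("boundary LR test behaves at and away from the null", {
  set.seed(13)
  tree <- ape::rphylo(60, birth = 0.1, death = 0)
  ## independent residuals: lambda near 0 -> test vs 0 is non-significant,
  ## test vs 1 rejects
  dat <- make_pgls_data(tree, beta = 0, phylo = FALSE, seed = 14)
  pg <- fit_pgls(growth_rate ~ x, dat, tree)
  t0 <- lr_test_lambda(pg, 0)
  t1 <- lr_test_lambda(pg, 1)
  expect_gte(t0$statistic, 0)
  expect_gte(t1$statistic, 0)
  if (pg$lambda < 1e-6) expect_gte(t0$p_value, 0.5)
  expect_lt(t1$p_value, 0.05)
})

test_that("dredge enumerates marginality-respecting candidates", {
  set.seed(15)
  dat <- data.frame(x1 = rnorm(60), x2 = rnorm(60))
  dat$growth_rate <- 0.8 * dat$x1 + rnorm(60)
  sel <- dredge_models(growth_rate ~ x1 + x2, dat)
  expect_equal(nrow(sel$table), 4)          # {1, x1, x2, x1+x2}
  expect_true(all(sel$retained$delta <= 6))
  expect_true("x1" %in% sel$best_terms)
  ## with an interaction: x1:x2 only alongside both parents
  sel2 <- dredge_models(growth_rate ~ x1 + x2 + x1:x2, dat)
  expect_equal(nrow(sel2$table), 5)
  has_int <- grepl("x1:x2", sel2$table$model)
  expect_true(all(grepl("x1 \\+ x2", sel2$table$model[has_int])))
  ## determinism
  sel3 <- dredge_models(growth_rate ~ x1 + x2, dat)
  expect_identical(sel$table, sel3$table)
})

test_that("no retained model nests a retained model with lower AIC", {
  set.seed(16)
  n <- 80
  dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  dat$growth_rate <- 0.5 * dat$x1 + rnorm(n)
  sel <- dredge_models(growth_rate ~ x1 + x2 + x3, dat)
  terms_of <- function(m) if (m == "1") character(0) else
    strsplit(m, " \\+ ")[[1]]
  ret <- sel$retained
  expect_gte(nrow(ret), 1)
  expect_true(all(ret$delta <= 6))
  for (i in seq_len(nrow(ret))) {
    for (j in seq_len(nrow(ret))) {
      if (i == j) next
      ti <- terms_of(ret$model[i]); tj <- terms_of(ret$model[j])
      nested <- length(ti) < length(tj) && all(ti %in% tj)
      if (nested) expect_gt(ret$aic[i], ret$aic[j])
    }
  }
})

test_that("dredge finds the generating predictor at its theoretical rate", {
  set.seed(17)
  has_x1 <- 0L; no_x2 <- 0L
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    n <- 300
    dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    dat$growth_rate <- 1.0 * dat$x1 + rnorm(n)   # 1 sd effect
    sel <- dredge_models(growth_rate ~ x1 + x2, dat)
    if ("x1" %in% sel$best_terms) has_x1 <- has_x1 + 1L
    if (!"x2" %in% sel$best_terms) no_x2 <- no_x2 + 1L
  }
  ## the true 1-sd predictor is always selected at n = 300
  expect_equal(has_x1, n_rep)
  ## AIC admits an irrelevant extra term with probability
  ## P(chisq_1 > 2) ~ 0.157, so x2 is (correctly) excluded ~84% of the
  ## time; 72 is the 99.9% binomial lower bound on that rate
  expect_gte(no_x2, 72)
})

test_that("pure-noise responses rarely promote either term", {
  set.seed(18)
  inc1 <- 0L; n_rep <- 200
  for (r in seq_len(n_rep)) {
    dat <- data.frame(x1 = rnorm(100), x2 = rnorm(100))
    dat$growth_rate <- rnorm(100)
    sel <- dredge_models(growth_rate ~ x1 + x2, dat)
    if ("x1" %in% sel$best_terms) inc1 <- inc1 + 1L
  }
  ## AIC admits a noise term with probability P(chisq_1 > 2) ~ 0.157
  expect_lte(inc1 / n_rep, 0.25)
})

test_that("trait model data applies the marine and missing-CST exclusions", {
  sp <- random_species_table(30, seed = 19)
  sp$habitat <- rep(c("forest", "grassland", "wetland"), 10)
  sp$habitat[1:3] <- "marine"
  gr <- data.frame(species_id = sp$species_id, growth_rate = rnorm(30))
  cst <- data.frame(species_id = sp$species_id, cst = rnorm(30, 0, 0.02))
  cst$cst[4] <- NA
  cls <- assign_quartiles(data.frame(species_id = sp$species_id,
                                     point = rlnorm(30, 8, 2)))
  expect_message(dat <- trait_model_data(sp, gr, cst, cls),
                 "3 marine species and 1 species without CST")
  expect_equal(nrow(dat), 26)
  expect_equal(mean(dat$body_mass_z), 0, tolerance = 1e-10)
})
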