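## Bayesian hierarchical model converting smoothed log index series and
## absolute population estimates into posterior trajectories of total
## abundance.
##
## Generative model (the package's canonical variant):
##   observation  x[s,y] ~ Normal(lambda[s,y], v[s,y])
##     x[s,y] = smoothed log index in year y minus its value in the species'
##     reference year, so lambda[s,ref] = 0 by construction;
##     v[s,y] = se_log[s,y]^2 with se_log the larger of the smoother's SE
##     and the raw index SE for that year (a penalized smoother's reported
##     SE excludes smoothing bias, so the observation layer never claims
##     less uncertainty than the data themselves carry); inflated for years
##     outside the observed span by the squared number of years since
##     non-missing data.
##   latent       lambda[s,y] ~ Normal(theta[s] * (y - ref[s]), sigma_dev[s]^2)
##     with sigma_dev[s]^2 ~ InvGamma(a_dev, b_dev) and a Gamma hyperprior
##     on b_dev: per-species smooth-deviation variances, pooled
##     hierarchically across species
##   species      theta[s] ~ Normal(mu + a[habitat] + b[migration]
##                                  + g[habitat,migration], tau^2)
##   groups       a ~ N(0, sigma_h^2), b ~ N(0, sigma_m^2),
##                g ~ N(0, sigma_hm^2) (interaction with its own precision)
##   anchor       P[s] ~ Lognormal(log point[s], (se[s]/point[s])^2)
## All full conditionals are conjugate, so the posterior is explored with a
## plain Gibbs sampler. Totals are T[y] = sum_s w[s] P[s] exp(lambda[s,y])
## per draw.

#' Variance inflation for years without data
#'
#' Years before the first (or after the last) year with data are filled with
#' the nearest observed value, and their variance is the nearest observed
#' variance plus the squared number of years since non-missing data, scaled
#' by \code{c}. As the gap grows, the filled value loses all influence on
#' the fit.
#'
#' @param obs_var named or positional per-year observation variances aligned
#'   with \code{years}; entries for unobserved years are ignored.
#' @param first_data_year first year with data.
#' @param years full integer year grid.
#' @param c scale of the inflation (same units as the observation SD).
#' @param last_data_year last year with data (defaults to \code{max(years)},
#'   i.e. no trailing inflation).
#' @return Per-year variances over \code{years}.
#' @export
inflate_missing_variance <- function(obs_var, first_data_year, years,
                                     c = 1, last_data_year = max(years)) {
  stopifnot(c > 0, length(obs_var) == length(years))
  out <- obs_var
  i_first <- match(first_data_year, years)
  i_last <- match(last_data_year, years)
  if (is.na(i_first) || is.na(i_last))
    stop("first/last data year not on the year grid", call. = FALSE)
  lead <- which(years < first_data_year)
  out[lead] <- obs_var[i_first] + c^2 * (first_data_year - years[lead])^2
  trail <- which(years > last_data_year)
  out[trail] <- obs_var[i_last] + c^2 * (years[trail] - last_data_year)^2
  out
}

.midpoint_year <- function(start, end) floor((start + end) / 2)

## split-Rhat on a chains x draws matrix
.rhat <- function(mat) {
  half <- floor(ncol(mat) / 2)
  if (half < 2L) return(NA_real_)
  sub <- rbind(mat[, seq_len(half), drop = FALSE],
               mat[, ncol(mat) - half + seq_len(half), drop = FALSE])
  m <- nrow(sub); n <- ncol(sub)
  means <- rowMeans(sub)
  B <- n * stats::var(means)
  W <- mean(apply(sub, 1L, stats::var))
  if (W < 1e-300) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the hierarchical total-abundance model
#'
#' Combines smoothed log index series (with their standard errors) and
#' absolute population estimates anchored at per-species reference years in
#' a Bayesian hierarchical model that shrinks uncertain species growth rates
#' towards the mean of their habitat-by-migration group and propagates
#' uncertainty from both the index series and the population estimates. The
#' posterior is sampled by a conjugate Gibbs sampler.
#'
#' @param smoothed named list of \code{smoothed_series} (see
#'   [smooth_all_series()]).
#' @param estimates population-estimate data.frame with \code{species_id},
#'   \code{point}, \code{se}, \code{ref_year_start}, \code{ref_year_end}.
#'   The reference year used is the midpoint of the range, rounded down.
#' @param species species trait data.frame with \code{species_id},
#'   \code{habitat}, \code{migration}.
#' @param years integer model year grid; defaults to the union of the
#'   smoothed spans.
#' @param missing_c scale of the missing-year variance inflation; default
#'   (\code{NULL}) is each species' mean observed log-scale SE.
#' @param interaction include the habitat-by-migration interaction term
#'   (with its own precision) in the group structure.
#' @param obs_layer \code{"raw"} (default) anchors the reference year at
#'   the smoothed value but takes the raw log index with its reported SE as
#'   the observation layer, which is unbiased at the series endpoints;
#'   \code{"smoothed"} uses the smoothed values with the larger of the
#'   smoother's and the raw SEs (a penalized smoother attenuates genuine
#'   fluctuations near the endpoints, so this layer is slightly
#'   conservative in level but can understate endpoint change).
#' @param chains,warmup,iter,thin,seed MCMC settings: number of chains,
#'   warmup iterations discarded per chain, retained iterations per chain,
#'   thinning interval applied to retained iterations, integer seed.
#' @return An object of class \code{abundance_fit} holding posterior draws
#'   of the per-species log relative abundances, growth rates and reference
#'   populations, plus convergence diagnostics (split-Rhat; a warning is
#'   issued above 1.05).
#' @export
fit_abundance_model <- function(smoothed, estimates, species,
                                years = NULL, missing_c = NULL,
                                interaction = TRUE,
                                obs_layer = c("raw", "smoothed"),
                                chains = 4, warmup = 1000, iter = 1000,
                                thin = 4, seed = 1L) {
  obs_layer <- match.arg(obs_layer)
  est <- as.data.frame(estimates)
  spdf <- as.data.frame(species)
  ids <- intersect(names(smoothed), intersect(est$species_id,
                                              spdf$species_id))
  dropped <- setdiff(names(smoothed), ids)
  if (length(dropped))
    message("dropping ", length(dropped),
            " species without estimate or traits: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  if (!length(ids)) stop("no species with complete inputs", call. = FALSE)
  smoothed <- smoothed[ids]
  est <- est[match(ids, est$species_id), ]
  spdf <- spdf[match(ids, spdf$species_id), ]
  S <- length(ids)

  if (is.null(years)) {
    years <- seq(min(vapply(smoothed, function(s) min(s$year), 0)),
                 max(vapply(smoothed, function(s) max(s$year), 0)))
  }
  Yg <- length(years)
  ref_year <- .midpoint_year(est$ref_year_start, est$ref_year_end)

  x <- matrix(0, S, Yg)           # relative smoothed log index
  v <- matrix(0, S, Yg)           # observation variance
  d <- matrix(0, S, Yg)           # years since reference
  for (s in seq_len(S)) {
    sm <- smoothed[[s]]
    if (ref_year[s] < min(sm$year) || ref_year[s] > max(sm$year))
      stop("reference year ", ref_year[s], " outside smoothed span for ",
           ids[s], call. = FALSE)
    i_ref <- match(ref_year[s], sm$year)
    ## the smoothed value anchors the reference year (it is far less noisy
    ## than a single raw observation; a shared anchor error cancels from
    ## every ratio-based quantity)
    ref_val <- sm$log_index[i_ref]
    use_raw <- obs_layer == "raw" && !is.null(sm$log_index_obs) &&
      any(!is.na(sm$log_index_obs))
    if (use_raw) {
      keep <- !is.na(sm$log_index_obs)
      obs_years <- sm$year[keep]
      obs_x <- sm$log_index_obs[keep] - ref_val
      obs_se <- sm$se_log_obs[keep]
    } else {
      obs_years <- sm$year
      obs_x <- sm$log_index - ref_val
      obs_se <- sm$se_log
      ## a penalized smoother's SE excludes smoothing bias; never claim
      ## less uncertainty than the data themselves carry
      if (!is.null(sm$se_log_obs))
        obs_se <- pmax(obs_se, sm$se_log_obs, na.rm = TRUE)
    }
    idx <- match(obs_years, years)
    if (anyNA(idx))
      stop("series of ", ids[s], " extends beyond the model years",
           call. = FALSE)
    xs <- rep(NA_real_, Yg); vs <- rep(NA_real_, Yg)
    xs[idx] <- obs_x
    vs[idx] <- obs_se^2
    ## fill unobserved years (leading, trailing or interior) with the
    ## nearest observed value; variance grows with the squared gap
    c_s <- if (is.null(missing_c)) max(mean(obs_se), 1e-3) else missing_c
    un <- which(is.na(xs))
    if (length(un)) {
      ob <- which(!is.na(xs))
      for (j in un) {
        nb <- ob[which.min(abs(years[ob] - years[j]))]
        xs[j] <- xs[nb]
        vs[j] <- vs[nb] + c_s^2 * (years[j] - years[nb])^2
      }
    }
    x[s, ] <- xs
    v[s, ] <- vs
    d[s, ] <- years - ref_year[s]
  }
  v <- pmax(v, 1e-12)
  ref_col <- match(ref_year, years)
  obs_mask <- matrix(TRUE, S, Yg)
  obs_mask[cbind(seq_len(S), ref_col)] <- FALSE   # lambda fixed at 0 there

  hab <- factor(spdf$habitat, levels = intersect(habitat_classes,
                                                 unique(spdf$habitat)))
  mig <- factor(spdf$migration, levels = intersect(migration_classes,
                                                   unique(spdf$migration)))
  H <- nlevels(hab); M <- nlevels(mig)
  hm <- interaction(hab, mig, drop = TRUE)
  G <- nlevels(hm)
  h_i <- as.integer(hab); m_i <- as.integer(mig); g_i <- as.integer(hm)

  sdlog <- ifelse(est$point > 0, est$se / est$point, 0)
  logP0 <- log(est$point)

  ## weighted least-squares slope per species as initial value
  theta_init <- vapply(seq_len(S), function(s) {
    ws <- 1 / v[s, obs_mask[s, ]]
    ds <- d[s, obs_mask[s, ]]
    xs <- x[s, obs_mask[s, ]]
    sum(ws * ds * xs) / max(sum(ws * ds^2), 1e-12)
  }, 0)

  keep_per_chain <- floor(iter / thin)
  D <- keep_per_chain * chains
  lam_draws <- array(NA_real_, c(D, S, Yg))
  theta_draws <- matrix(NA_real_, D, S)
  P_draws <- matrix(NA_real_, D, S)
  tau_draws <- numeric(D)
  mu_draws <- numeric(D)
  chain_of <- rep(seq_len(chains), each = keep_per_chain)

  a0 <- 0.001; b0 <- 0.001          # diffuse IG for tau^2, sigma_dev^2
  ag <- 1; bg <- 0.01               # weakly informative IG for group scales

  for (ch in seq_len(chains)) {
    set.seed(seed + 1000L * (ch - 1L))
    theta <- theta_init + stats::rnorm(S, 0, 0.002 * ch)
    lambda <- x
    lambda[cbind(seq_len(S), ref_col)] <- 0
    mu <- mean(theta)
    a <- rep(0, H); b <- rep(0, M); g <- rep(0, G)
    tau2 <- max(c(stats::var(theta), 1e-6), na.rm = TRUE)  # var is NA at S = 1
    sig_h2 <- 1e-4; sig_m2 <- 1e-4; sig_hm2 <- 1e-4
    ## per-species trajectory-deviation variances, hierarchically pooled:
    ## sig_dev2[s] ~ IG(a_dev, b_dev) with a Gamma hyperprior on b_dev, so
    ## species with strong smooth deviations can widen without starving
    ## near-linear species of variance
    sig_dev2 <- rep(0.01, S)
    a_dev <- 2
    b_dev <- 0.01
    n_obs_s <- rowSums(obs_mask)
    n_obs <- sum(obs_mask)
    kept <- 0L
    for (it in seq_len(warmup + iter)) {
      gs <- mu + a[h_i] + b[m_i] + if (interaction) g[g_i] else 0
      ## theta | x (lambda marginalized out -- blocked update; the
      ## one-at-a-time conditional couples theta to the filled-year
      ## lambdas, which sit at the largest |y - ref| and mix far too
      ## slowly otherwise). Marginally x ~ N(theta d, sig_dev2 + v).
      vm <- sig_dev2 + v
      Sd2 <- rowSums((d^2 / vm) * obs_mask)
      Sxd <- rowSums((x * d / vm) * obs_mask)
      prec_t <- 1 / tau2 + Sd2
      mean_t <- (gs / tau2 + Sxd) / prec_t
      theta <- stats::rnorm(S, mean_t, sqrt(1 / prec_t))
      ## lambda | theta (elementwise conjugate update)
      prec_l <- 1 / sig_dev2 + 1 / v
      mean_l <- (theta * d / sig_dev2 + x / v) / prec_l
      lambda <- mean_l + matrix(stats::rnorm(S * Yg), S, Yg) / sqrt(prec_l)
      lambda[cbind(seq_len(S), ref_col)] <- 0
      ## group structure | theta
      resid <- theta - a[h_i] - b[m_i] - (if (interaction) g[g_i] else 0)
      prec_mu <- S / tau2 + 0.01
      mu <- stats::rnorm(1L, sum(resid) / tau2 / prec_mu, sqrt(1 / prec_mu))
      resid <- theta - mu - b[m_i] - (if (interaction) g[g_i] else 0)
      sums <- tapply(resid, h_i, sum); ns <- tabulate(h_i, H)
      prec_a <- ns / tau2 + 1 / sig_h2
      a <- stats::rnorm(H, as.numeric(sums) / tau2 / prec_a,
                        sqrt(1 / prec_a))
      resid <- theta - mu - a[h_i] - (if (interaction) g[g_i] else 0)
      sums <- tapply(resid, m_i, sum); ns <- tabulate(m_i, M)
      prec_b <- ns / tau2 + 1 / sig_m2
      b <- stats::rnorm(M, as.numeric(sums) / tau2 / prec_b,
                        sqrt(1 / prec_b))
      if (interaction) {
        resid <- theta - mu - a[h_i] - b[m_i]
        sums <- tapply(resid, g_i, sum); ns <- tabulate(g_i, G)
        prec_g <- ns / tau2 + 1 / sig_hm2
        g <- stats::rnorm(G, as.numeric(sums) / tau2 / prec_g,
                          sqrt(1 / prec_g))
      }
      ## variance components
      gs <- mu + a[h_i] + b[m_i] + if (interaction) g[g_i] else 0
      tau2 <- 1 / stats::rgamma(1L, a0 + S / 2,
                                b0 + sum((theta - gs)^2) / 2)
      sig_h2 <- 1 / stats::rgamma(1L, ag + H / 2, bg + sum(a^2) / 2)
      sig_m2 <- 1 / stats::rgamma(1L, ag + M / 2, bg + sum(b^2) / 2)
      if (interaction)
        sig_hm2 <- 1 / stats::rgamma(1L, ag + G / 2, bg + sum(g^2) / 2)
      rss_s <- rowSums(((lambda - theta * d)^2) * obs_mask)
      sig_dev2 <- 1 / stats::rgamma(S, a_dev + n_obs_s / 2,
                                    b_dev + rss_s / 2)
      b_dev <- stats::rgamma(1L, a0 + S * a_dev, a0 + sum(1 / sig_dev2))
      ## store
      if (it > warmup && (it - warmup) %% thin == 0L) {
        kept <- kept + 1L
        row <- (ch - 1L) * keep_per_chain + kept
        lam_draws[row, , ] <- lambda
        theta_draws[row, ] <- theta
        P_draws[row, ] <- stats::rlnorm(S, logP0, sdlog)
        tau_draws[row] <- sqrt(tau2)
        mu_draws[row] <- mu
      }
    }
  }

  ## convergence diagnostics on scalar summaries
  total_first <- rowSums(P_draws * exp(lam_draws[, , 1L, drop = TRUE]))
  total_last <- rowSums(P_draws * exp(lam_draws[, , Yg, drop = TRUE]))
  if (S == 1L) {
    total_first <- P_draws[, 1L] * exp(lam_draws[, 1L, 1L])
    total_last <- P_draws[, 1L] * exp(lam_draws[, 1L, Yg])
  }
  ## Rhat is computed on identified quantities: mu and the group effects
  ## are additively confounded (only their sums enter theta), so their
  ## individual chains mix slowly without affecting any reported output.
  as_chain_mat <- function(z) matrix(z, nrow = chains, byrow = TRUE)
  rhat <- c(log_total_first = .rhat(as_chain_mat(log(total_first))),
            log_total_last = .rhat(as_chain_mat(log(total_last))),
            mean_theta = .rhat(as_chain_mat(rowMeans(theta_draws))),
            tau = .rhat(as_chain_mat(tau_draws)))
  if (any(rhat > 1.05, na.rm = TRUE))
    warning("possible non-convergence: max split-Rhat = ",
            round(max(rhat, na.rm = TRUE), 3),
            "; consider more iterations")

  structure(list(species_id = ids, years = years, ref_year = ref_year,
                 groups = data.frame(species_id = ids,
                                     habitat = as.character(hab),
                                     migration = as.character(mig)),
                 draws = list(lambda = lam_draws, theta = theta_draws,
                              P = P_draws, mu = mu_draws, tau = tau_draws),
                 chain = chain_of,
                 estimates = est,
                 diagnostics = list(rhat = rhat),
                 settings = list(chains = chains, warmup = warmup,
                                 iter = iter, thin = thin, seed = seed,
                                 interaction = interaction)),
            class = "abundance_fit")
}

#' Posterior draws of per-species absolute abundance trajectories
#'
#' @param fit an \code{abundance_fit}.
#' @param weights optional per-species multiplier, named by species_id or in
#'   species order (e.g. body mass in tonnes for biomass trajectories).
#' @return Array \code{[draw, species, year]} of
#'   \code{w_s * P_s * exp(lambda)}.
#' @export
species_trajectories <- function(fit, weights = NULL) {
  S <- length(fit$species_id)
  w <- .resolve_weights(fit, weights)
  N <- exp(fit$draws$lambda)
  scale <- fit$draws$P * rep(w, each = nrow(fit$draws$P))
  for (y in seq_along(fit$years)) N[, , y] <- N[, , y] * scale
  dimnames(N) <- list(NULL, fit$species_id, fit$years)
  N
}

.resolve_weights <- function(fit, weights) {
  S <- length(fit$species_id)
  if (is.null(weights)) return(rep(1, S))
  if (!is.null(names(weights))) {
    if (!all(fit$species_id %in% names(weights)))
      stop("weights missing for some species", call. = FALSE)
    weights <- weights[fit$species_id]
  }
  stopifnot(length(weights) == S)
  as.numeric(weights)
}

#' Posterior trajectory of assemblage total abundance (or biomass)
#'
#' Per posterior draw, the total in year y is the weighted sum over species
#' of the reference population times the exponentiated log relative
#' abundance. Summaries are the pointwise median and 2.5/97.5 percentiles.
#'
#' @inheritParams species_trajectories
#' @return An object of class \code{total_trajectory}: list with
#'   \code{years}, \code{draws} (draw x year matrix), and a \code{summary}
#'   data.frame (\code{year}, \code{median}, \code{lcl}, \code{ucl}).
#' @export
total_trajectory <- function(fit, weights = NULL) {
  N <- species_trajectories(fit, weights)
  draws <- apply(N, c(1L, 3L), sum)
  qs <- apply(draws, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE)
  structure(list(years = fit$years, draws = draws,
                 summary = data.frame(year = fit$years, median = qs[1L, ],
                                      lcl = qs[2L, ], ucl = qs[3L, ])),
            class = "total_trajectory")
}

#' @export
print.abundance_fit <- function(x, ...) {
  cat(sprintf("Hierarchical abundance fit: %d species, years %d-%d, %d draws\n",
              length(x$species_id), min(x$years), max(x$years),
              nrow(x$draws$theta)))
  cat("  split-Rhat:",
      paste(names(x$diagnostics$rhat),
            round(x$diagnostics$rhat, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.total_trajectory <- function(x, ...) {
  s <- x$summary
  n <- nrow(s)
  cat(sprintf("Total trajectory %d-%d: %0.4g (%0.4g-%0.4g) -> %0.4g (%0.4g-%0.4g)\n",
              s$year[1L], s$year[n], s$median[1L], s$lcl[1L], s$ucl[1L],
              s$median[n], s$lcl[n], s$ucl[n]))
  invisible(x)
}
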