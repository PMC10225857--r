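## Reconstruction of annual national population series from a mean trend
## and a mean population estimate, aggregation across countries, and
## bootstrap uncertainty.

#' Annual multiplier from a multiplicative trend over a period
#'
#' \eqn{\lambda = \bar{T}^{1/\mathrm{period}}}: the constant per-year factor
#' that compounds to the reported multiplicative change \eqn{\bar{T}} over
#' the trend period.
#'
#' @param mean_trend multiplicative change over the period (> 0); a
#'   "+20% over 10 years" trend is supplied as 1.2.
#' @param trend_period length of the period in years (> 0).
#' @return The per-year multiplier \eqn{\lambda}.
#' @export
annual_multiplier <- function(mean_trend, trend_period) {
  if (any(!is.finite(mean_trend)) || any(mean_trend <= 0))
    stop("mean_trend must be > 0", call. = FALSE)
  if (any(!is.finite(trend_period)) || any(trend_period <= 0))
    stop("trend_period must be > 0", call. = FALSE)
  mean_trend^(1 / trend_period)
}

#' Reconstruct an annual population series from a national trend record
#'
#' Population in year \eqn{i} is \eqn{\bar{E}N_i = \bar{E}N_{\bar{y}}
#' \lambda^{(i - \bar{y})}}, anchored exactly at the mean estimate year
#' \eqn{\bar{y}}. Extrapolation far beyond the trend period is permitted but
#' reported via the \code{extrapolated} attribute, since long extrapolations
#' are the least accurate part of trend expansion.
#'
#' @param record one-row data.frame (or list) with \code{mean_trend},
#'   \code{trend_period}, \code{mean_pop}, \code{mean_estimate_year}.
#' @param years integer vector of years to reconstruct.
#' @return data.frame with \code{year} and \code{population}.
#' @export
reconstruct_series <- function(record, years) {
  lam <- annual_multiplier(record$mean_trend, record$trend_period)
  pop <- record$mean_pop * lam^(years - record$mean_estimate_year)
  out <- data.frame(year = years, population = pop)
  over <- abs(years - record$mean_estimate_year) > record$trend_period
  attr(out, "extrapolated") <- years[over]
  out
}

#' Regional point estimate and standard error from summed bounds
#'
#' The point estimate is the geometric mean of the summed minimum and
#' maximum national estimates; the standard error is approximated as a
#' sixth of the span between them. A best-only value is passed as both
#' bounds and yields a standard error of zero.
#'
#' @param min_sum,max_sum summed minimum and maximum estimates
#'   (0 < min_sum <= max_sum).
#' @return list with \code{point} and \code{se}.
#' @export
eu_point_estimate <- function(min_sum, max_sum = min_sum) {
  if (!is.finite(min_sum) || !is.finite(max_sum) || min_sum < 0)
    stop("estimates must be finite and non-negative", call. = FALSE)
  if (min_sum > max_sum)
    stop("min_sum exceeds max_sum", call. = FALSE)
  list(point = sqrt(min_sum * max_sum), se = (max_sum - min_sum) / 6)
}

#' Sum reconstructed national series into one regional series
#'
#' @param series_list list of data.frames as returned by
#'   [reconstruct_series()], all on an identical year grid.
#' @return data.frame with \code{year} and \code{population}.
#' @export
sum_national_series <- function(series_list) {
  stopifnot(length(series_list) >= 1L)
  years <- series_list[[1L]]$year
  for (s in series_list)
    if (!identical(s$year, years))
      stop("national series are not on a common year grid", call. = FALSE)
  pop <- Reduce(`+`, lapply(series_list, `[[`, "population"))
  data.frame(year = years, population = pop)
}

#' Percentile bootstrap interval for an estimator with uncertain inputs
#'
#' Draws \code{n} replicate input sets with \code{sampler}, evaluates
#' \code{estimator} on each, and returns the empirical 2.5% and 97.5%
#' percentiles. With zero-variance inputs every replicate is identical and
#' the interval has width zero. Results are bit-reproducible under a fixed
#' seed.
#'
#' @param estimator function mapping one input set to a numeric vector.
#' @param sampler zero-argument function drawing one perturbed input set.
#' @param n number of bootstrap replicates (default 1000).
#' @param seed optional integer seed.
#' @param probs interval percentiles.
#' @return list with \code{lcl}, \code{ucl} (numeric, the length of the
#'   estimator output) and \code{replicates} (n x length matrix).
#' @export
bootstrap_ci <- function(estimator, sampler, n = 1000, seed = NULL,
                         probs = c(0.025, 0.975)) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  first <- as.numeric(estimator(sampler()))
  reps <- matrix(NA_real_, nrow = n, ncol = length(first))
  reps[1L, ] <- first
  for (i in seq_len(n)[-1L]) reps[i, ] <- as.numeric(estimator(sampler()))
  qs <- apply(reps, 2L, stats::quantile, probs = probs, names = FALSE,
              type = 7)
  list(lcl = qs[1L, ], ucl = qs[2L, ], replicates = reps)
}

#' Reconstruct and aggregate national series with bootstrap intervals
#'
#' For one species, reconstructs each country's annual series from its mean
#' trend and mean population estimate, sums across countries, and attaches
#' 95% bootstrap intervals. Replicates redraw each country's mean population
#' estimate from a lognormal with median equal to the reported estimate and
#' log-sd matched to its standard error by the delta method
#' (\code{sdlog = pop_se / mean_pop}), independently across countries.
#'
#' @param records data.frame of national trend records for one species
#'   (see [read_national_trends()]).
#' @param years integer vector of years.
#' @param n bootstrap replicates.
#' @param seed optional integer seed.
#' @return data.frame with \code{year}, \code{population}, \code{lcl},
#'   \code{ucl}.
#' @export
reconstruct_with_ci <- function(records, years, n = 1000, seed = NULL) {
  records <- as.data.frame(records)
  if (!"pop_se" %in% names(records)) records$pop_se <- 0
  point <- sum_national_series(
    lapply(seq_len(nrow(records)),
           function(i) reconstruct_series(records[i, ], years)))
  sdlog <- records$pop_se / records$mean_pop
  sampler <- function() {
    r <- records
    r$mean_pop <- stats::rlnorm(nrow(r), meanlog = log(records$mean_pop),
                                sdlog = sdlog)
    r
  }
  estimator <- function(r) {
    sum_national_series(
      lapply(seq_len(nrow(r)),
             function(i) reconstruct_series(r[i, ], years)))$population
  }
  ci <- bootstrap_ci(estimator, sampler, n = n, seed = seed)
  data.frame(year = years, population = point$population,
             lcl = pmin(ci$lcl, point$population),
             ucl = pmax(ci$ucl, point$population))
}
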