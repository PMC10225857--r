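## Climate suitability trends: a logistic-GLM suitability model and the
## logit-slope statistic (CST).

#' Fit a climate suitability model to occurrence data
#'
#' Logistic regression of presence/absence on the supplied climate
#' covariates with linear and quadratic terms per covariate. This single-GLM
#' suitability model stands behind the suitability stage of the pipeline;
#' any externally modelled annual suitability series can be supplied to
#' [cst_slope()] directly instead. Complete separation triggers a
#' ridge-penalized refit with a warning.
#'
#' @param occurrence 0/1 vector of presences per cell.
#' @param climate data.frame of climate covariates per cell (typically
#'   four).
#' @param min_presences minimum number of presences required.
#' @param ridge penalty used only on separation (L2 on coefficients).
#' @return An object of class \code{sdm_fit} with \code{coefficients},
#'   \code{model} (the glm, or NULL for the penalized path) and
#'   \code{terms} metadata.
#' @export
fit_sdm <- function(occurrence, climate, min_presences = 20, ridge = 1e-4) {
  occurrence <- as.numeric(occurrence)
  stopifnot(all(occurrence %in% c(0, 1)))
  if (sum(occurrence) < min_presences)
    stop("need at least ", min_presences, " presences", call. = FALSE)
  climate <- as.data.frame(climate)
  if (!all(vapply(climate, function(z) all(is.finite(z)), TRUE)))
    stop("climate covariates must be finite", call. = FALSE)
  X <- .sdm_design(climate)
  keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L,
                        function(z) stats::sd(z) > 0))
  Xk <- X[, keep, drop = FALSE]
  dat <- data.frame(y = occurrence, Xk[, -1L, drop = FALSE])
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  separated <- !fit$converged ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (separated) {
    warning("possible complete separation; using a ridge-penalized fit")
    beta <- .ridge_logistic(Xk, occurrence, ridge)
    coefs <- stats::setNames(beta, colnames(Xk))
    model <- NULL
  } else {
    coefs <- stats::coef(fit)
    names(coefs) <- colnames(Xk)
    model <- fit
  }
  full <- stats::setNames(rep(0, ncol(X)), colnames(X))
  full[names(coefs)] <- coefs
  structure(list(coefficients = full, model = model,
                 variables = names(climate), separated = separated),
            class = "sdm_fit")
}

.sdm_design <- function(climate) {
  mats <- lapply(names(climate), function(v) {
    cbind(stats::setNames(data.frame(climate[[v]], climate[[v]]^2),
                          c(v, paste0(v, "_sq"))))
  })
  X <- as.matrix(cbind(data.frame(`(Intercept)` = 1, check.names = FALSE),
                       do.call(cbind, mats)))
  X
}

.ridge_logistic <- function(X, y, ridge) {
  beta <- rep(0, ncol(X))
  for (it in 1:100) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    H <- crossprod(X, X * W) + diag(ridge, ncol(X))
    g <- crossprod(X, y - p) - ridge * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  drop(beta)
}

#' Predict suitability from a fitted SDM
#'
#' @param object an \code{sdm_fit}.
#' @param climate data.frame of covariates (same variables as at fit time).
#' @param ... unused.
#' @return Vector of occurrence probabilities.
#' @export
predict.sdm_fit <- function(object, climate, ...) {
  X <- .sdm_design(as.data.frame(climate)[, object$variables, drop = FALSE])
  stats::plogis(drop(X %*% object$coefficients[colnames(X)]))
}

#' Annual mean suitability series from an SDM and annual climate
#'
#' Applies the fitted suitability model to each year's climate surface and
#' averages the predicted occurrence probability across cells in the
#' species' range.
#'
#' @param object an \code{sdm_fit}.
#' @param annual_climate data.frame with a \code{year} column plus the
#'   model's climate covariates, one row per cell x year.
#' @return data.frame with \code{year} and \code{suitability}.
#' @export
suitability_series <- function(object, annual_climate) {
  stopifnot("year" %in% names(annual_climate))
  p <- predict.sdm_fit(object, annual_climate)
  agg <- tapply(p, annual_climate$year, mean)
  data.frame(year = as.integer(names(agg)), suitability = as.numeric(agg))
}

#' Climate suitability trend: slope of logit suitability on year
#'
#' Ordinary least squares of \code{logit(suitability)} against calendar
#' year. Suitability values outside (0, 1) are clamped to
#' \code{[1e-6, 1 - 1e-6]} with a warning before the logit. Positive values
#' indicate improving climatic conditions for the species.
#'
#' @param series data.frame with \code{year} and \code{suitability}.
#' @param min_years minimum number of years required (default 5).
#' @return list of class \code{cst} with \code{slope} (logit units per
#'   year), \code{se}, \code{r2}, \code{p_value} and \code{n}.
#' @export
cst_slope <- function(series, min_years = 5) {
  stopifnot(all(c("year", "suitability") %in% names(series)))
  if (nrow(series) < min_years)
    stop("need at least ", min_years, " years for a CST", call. = FALSE)
  p <- series$suitability
  if (any(p <= 0 | p >= 1)) {
    warning("suitability values clamped into (0, 1) before logit")
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  }
  fit <- stats::lm(qlogis(p) ~ year, data = data.frame(p = p,
                                                       year = series$year))
  ## an exactly logistic input gives a perfect fit; that is not a problem
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 se = sm$coefficients[2L, 2L],
                 r2 = sm$r.squared,
                 p_value = sm$coefficients[2L, 4L],
                 n = nrow(series)),
            class = "cst")
}

#' @export
print.cst <- function(x, ...) {
  cat(sprintf("CST: %.5f logit/yr (se %.5f, R2 %.3f, n = %d)\n",
              x$slope, x$se, x$r2, x$n))
  invisible(x)
}
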