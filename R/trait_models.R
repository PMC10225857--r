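## Correlates of species trends: global linear model, phylogenetic
## generalized least squares with Pagel's lambda, and all-subsets AIC
## selection with nested-model removal.

#' z-transform a continuous variable
#'
#' Centres to mean zero and scales to unit standard deviation using the
#' population convention (divisor n). The centre and scale are stored as
#' attributes so the transform can be inverted.
#'
#' @param x numeric vector.
#' @param name column name used in error messages.
#' @return Standardized vector with attributes \code{center} and
#'   \code{scale}.
#' @export
z_transform <- function(x, name = deparse(substitute(x))) {
  mu <- mean(x, na.rm = TRUE)
  sdev <- sqrt(mean((x - mu)^2, na.rm = TRUE))
  if (!is.finite(sdev) || sdev == 0)
    stop("cannot z-transform '", name, "': zero variance", call. = FALSE)
  structure((x - mu) / sdev, center = mu, scale = sdev)
}

#' @rdname z_transform
#' @param z a vector produced by [z_transform()].
#' @export
inverse_z <- function(z) {
  as.numeric(z) * attr(z, "scale") + attr(z, "center")
}

#' The default global model for species-trend correlates
#'
#' Log annual rate of change per species against migration strategy,
#' habitat, (z-scored) body mass, (z-scored) climate suitability trend,
#' trophic niche and abundance class, with the six two-way interactions of
#' the factors with the continuous variables.
#'
#' @return A formula.
#' @export
trend_global_formula <- function() {
  growth_rate ~ migration + habitat + body_mass_z + cst_z + trophic_niche +
    abundance_class +
    migration:body_mass_z + migration:cst_z +
    habitat:body_mass_z + habitat:cst_z +
    trophic_niche:body_mass_z + trophic_niche:cst_z
}

#' Assemble the trait-model data frame
#'
#' Merges species traits, growth rates, CST values and abundance classes,
#' z-transforms the continuous predictors, and applies the stated
#' exclusions: marine-habitat species (their CST values are not meaningful)
#' and species without a CST value. Exclusion counts are reported via a
#' message.
#'
#' @param species species trait data.frame (see [read_species_table()]).
#' @param growth_rates data.frame with \code{species_id}, \code{growth_rate}.
#' @param cst data.frame with \code{species_id}, \code{cst} (slope values).
#' @param classes data.frame with \code{species_id}, \code{abundance_class}.
#' @return data.frame ready for [fit_trend_lm()] / [fit_pgls()], with
#'   \code{body_mass_z} and \code{cst_z} columns.
#' @export
trait_model_data <- function(species, growth_rates, cst, classes) {
  df <- merge(species, growth_rates, by = "species_id")
  df <- merge(df, cst, by = "species_id", all.x = TRUE)
  df <- merge(df, classes, by = "species_id")
  n0 <- nrow(df)
  marine <- df$habitat == "marine"
  no_cst <- is.na(df$cst)
  df <- df[!marine & !no_cst, , drop = FALSE]
  message(sum(marine), " marine species and ", sum(no_cst & !marine),
          " species without CST excluded (", n0, " -> ", nrow(df), ")")
  df$body_mass_z <- as.numeric(z_transform(log(df$body_mass), "body_mass"))
  df$cst_z <- as.numeric(z_transform(df$cst, "cst"))
  df$migration <- factor(df$migration)
  df$habitat <- factor(df$habitat)
  df$trophic_niche <- factor(df$trophic_niche)
  rownames(df) <- NULL
  df
}

#' Ordinary least squares fit of a trend-correlate model
#'
#' Wraps \code{lm} with empty factor levels dropped and aliased
#' (rank-deficient) terms reported. The AIC is the Gaussian AIC including
#' the residual-variance parameter.
#'
#' @param formula model formula.
#' @param data data.frame.
#' @return list of class \code{trend_lm}: \code{fit}, \code{coefficients},
#'   \code{aic}, \code{loglik}, \code{aliased} (character vector).
#' @export
fit_trend_lm <- function(formula, data) {
  data <- droplevels(as.data.frame(data))
  fit <- stats::lm(formula, data = data)
  co <- stats::coef(fit)
  aliased <- names(co)[is.na(co)]
  if (length(aliased))
    message("aliased terms dropped: ", paste(aliased, collapse = ", "))
  structure(list(fit = fit, coefficients = co[!is.na(co)],
                 aic = stats::AIC(fit),
                 loglik = as.numeric(stats::logLik(fit)),
                 aliased = aliased, formula = formula),
            class = "trend_lm")
}

## Profile (over beta, sigma2) ML log-likelihood of a GLS model with
## covariance V; returns loglik and the fitted pieces.
.gls_profile <- function(y, X, V) {
  n <- length(y)
  U <- chol(V)
  yt <- backsolve(U, y, transpose = TRUE)
  Xt <- backsolve(U, X, transpose = TRUE)
  qrx <- qr(Xt)
  beta <- qr.coef(qrx, yt)
  r <- yt - Xt %*% beta
  rss <- sum(r^2)
  s2_ml <- rss / n
  ll <- -n / 2 * log(2 * pi) - n / 2 * log(s2_ml) -
    sum(log(diag(U))) - n / 2
  XtX_inv <- chol2inv(qr.R(qrx))
  list(loglik = ll, beta = drop(beta), rss = rss, xtx_inv = XtX_inv,
       df_resid = n - ncol(X))
}

.pagel_v <- function(V, lambda) {
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' GLS regression whose residual covariance is the Brownian-motion
#' covariance of the tree with off-diagonal entries multiplied by Pagel's
#' lambda. Lambda is estimated by maximum likelihood on a [0, 1] grid
#' refined by golden-section search (or fixed via \code{lambda}); a profile
#' confidence interval is taken at a 1.92 log-likelihood drop. Species in
#' the data but absent from the tree are dropped with a message. On a star
#' phylogeny the likelihood is flat in lambda; the fit is then the ordinary
#' least squares fit and is flagged unidentifiable.
#'
#' @param formula model formula; the data must carry a \code{species_id}
#'   column matching tree tip labels.
#' @param data data.frame.
#' @param tree a \code{phylo} with branch lengths.
#' @param lambda optional fixed lambda in [0, 1]; \code{NULL} estimates it.
#' @return list of class \code{pgls_fit}: \code{coefficients} (matrix with
#'   estimates and SEs), \code{lambda}, \code{lambda_ci}, \code{loglik},
#'   \code{aic}, \code{n}, \code{unidentifiable}, \code{profile} (function
#'   lambda -> profile loglik).
#' @export
fit_pgls <- function(formula, data, tree, lambda = NULL) {
  data <- droplevels(as.data.frame(data))
  if (!"species_id" %in% names(data))
    stop("data must contain species_id matching tree tips", call. = FALSE)
  keep <- data$species_id %in% tree$tip.label
  if (!all(keep)) {
    message("dropping ", sum(!keep), " species not in the phylogeny")
    data <- data[keep, , drop = FALSE]
  }
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths", call. = FALSE)
  tree <- ape::keep.tip(tree, data$species_id)
  Vfull <- ape::vcv(tree)
  V <- Vfull[data$species_id, data$species_id]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  profile <- function(lam) .gls_profile(y, X, .pagel_v(V, lam))$loglik

  estimated <- is.null(lambda)
  unident <- FALSE
  if (estimated) {
    grid <- seq(0, 1, by = 0.05)
    ll_grid <- vapply(grid, profile, 0)
    if (max(ll_grid) - min(ll_grid) < 1e-8) {
      unident <- TRUE
      lambda <- 0
    } else {
      i <- which.max(ll_grid)
      lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
      opt <- stats::optimize(profile, c(lo, hi), maximum = TRUE,
                             tol = 1e-8)
      cand <- c(opt$maximum, 0, 1)
      lambda <- cand[which.max(vapply(cand, profile, 0))]
    }
  }
  best <- .gls_profile(y, X, .pagel_v(V, lambda))
  ll_max <- best$loglik

  ci <- c(NA_real_, NA_real_)
  if (estimated && !unident) {
    thresh <- ll_max - 1.92
    f <- function(l) profile(l) - thresh
    ci[1L] <- if (f(0) >= 0) 0 else
      stats::uniroot(f, c(0, lambda), tol = 1e-6)$root
    ci[2L] <- if (f(1) >= 0) 1 else
      stats::uniroot(f, c(lambda, 1), tol = 1e-6)$root
  }
  if (unident) {
    ci <- c(0, 1)
    message("lambda unidentifiable (flat likelihood, e.g. star phylogeny); ",
            "fit equals ordinary least squares")
  }
  s2 <- best$rss / best$df_resid
  se <- sqrt(diag(best$xtx_inv) * s2)
  coefs <- cbind(Estimate = best$beta, `Std. Error` = se)
  rownames(coefs) <- colnames(X)
  k <- ncol(X) + 1L + as.integer(estimated && !unident)
  structure(list(coefficients = coefs, lambda = lambda, lambda_ci = ci,
                 loglik = ll_max, aic = 2 * k - 2 * ll_max, k = k,
                 n = length(y), unidentifiable = unident,
                 estimated_lambda = estimated, profile = profile,
                 formula = formula),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit: n = %d, lambda = %.3f (%.3f, %.3f), logLik = %.2f, AIC = %.2f\n",
              x$n, x$lambda, x$lambda_ci[1L], x$lambda_ci[2L], x$loglik,
              x$aic))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Likelihood-ratio test of Pagel's lambda against a boundary value
#'
#' Compares the profile likelihood at the estimated lambda with the profile
#' likelihood at \code{null_lambda} (0 or 1). Because the null lies on the
#' boundary of the parameter space, the statistic is referred to a 50:50
#' mixture of a point mass at zero and a chi-squared with one degree of
#' freedom.
#'
#' @param fit a \code{pgls_fit} with estimated lambda.
#' @param null_lambda the null value, 0 or 1.
#' @return list with \code{statistic} (non-negative), \code{p_value} and
#'   \code{null_lambda}.
#' @export
lr_test_lambda <- function(fit, null_lambda = 0) {
  stopifnot(inherits(fit, "pgls_fit"), null_lambda %in% c(0, 1))
  ll0 <- fit$profile(null_lambda)
  stat <- max(0, 2 * (fit$loglik - ll0))
  p <- if (stat < 1e-12) 1 else 0.5 * stats::pchisq(stat, df = 1,
                                                    lower.tail = FALSE)
  list(statistic = stat, p_value = p, null_lambda = null_lambda)
}

## Enumerate marginality-respecting term subsets of a global model.
.candidate_term_sets <- function(formula, max_models) {
  labels <- attr(stats::terms(formula), "term.labels")
  mains <- labels[!grepl(":", labels)]
  inters <- labels[grepl(":", labels)]
  parents <- lapply(inters, function(tt) strsplit(tt, ":", fixed = TRUE)[[1L]])
  sets <- list()
  n_main <- length(mains)
  for (code in 0:(2^n_main - 1L)) {
    inc <- mains[bitwAnd(code, 2^(seq_len(n_main) - 1L)) > 0]
    ok_int <- which(vapply(parents, function(p) all(p %in% inc), TRUE))
    n_i <- length(ok_int)
    for (icode in 0:(2^n_i - 1L)) {
      ii <- ok_int[bitwAnd(icode, 2^(seq_len(n_i) - 1L)) > 0]
      sets[[length(sets) + 1L]] <- c(inc, inters[ii])
      if (length(sets) > max_models)
        stop("more than ", max_models, " candidate models; prune the ",
             "global model before dredging", call. = FALSE)
    }
  }
  sets
}

.is_nested <- function(smaller, larger) {
  length(smaller) < length(larger) && all(smaller %in% larger)
}

#' All-subsets model selection with nested-model removal
#'
#' Enumerates every marginality-respecting simplification of the global
#' model (interactions only alongside both parent terms), ranks candidates
#' by AIC, removes any model within the AIC window that contains a simpler
#' retained model with lower AIC (nested-model removal), and retains all
#' remaining models within \code{delta_max} AIC units of the minimum. The
#' procedure is deterministic given the data.
#'
#' @param formula the global model formula.
#' @param data data.frame.
#' @param fitter fitting backend: \code{"lm"} (default) or \code{"pgls"}.
#' @param tree phylogeny, required when \code{fitter = "pgls"}.
#' @param delta_max AIC window (default 6).
#' @param max_models refuse to enumerate more candidates than this.
#' @return An object of class \code{selection_result}: list with
#'   \code{table} (all candidates with AIC, delta, retained flag),
#'   \code{retained} (data.frame of the retained set), \code{best}
#'   (refitted best model) and \code{n_dropped_nested}.
#' @export
dredge_models <- function(formula, data, fitter = c("lm", "pgls"),
                          tree = NULL, delta_max = 6, max_models = 1e5) {
  fitter <- match.arg(fitter)
  response <- as.character(formula)[2L]
  sets <- .candidate_term_sets(formula, max_models)
  fit_one <- function(terms) {
    f <- stats::reformulate(if (length(terms)) terms else "1",
                            response = response)
    if (fitter == "lm") fit_trend_lm(f, data) else
      fit_pgls(f, data, tree)
  }
  aics <- vapply(sets, function(tt) suppressMessages(fit_one(tt)$aic), 0)
  labels <- vapply(sets, function(tt)
    if (length(tt)) paste(tt, collapse = " + ") else "1", "")
  o <- order(aics)
  delta <- aics - min(aics)
  retained_idx <- integer(0)
  dropped_nested <- 0L
  for (i in o) {
    if (delta[i] > delta_max) break
    nested_in_i <- vapply(retained_idx, function(j)
      .is_nested(sets[[j]], sets[[i]]), TRUE)
    if (any(nested_in_i)) { dropped_nested <- dropped_nested + 1L; next }
    retained_idx <- c(retained_idx, i)
  }
  tab <- data.frame(model = labels, df = lengths(sets), aic = aics,
                    delta = delta,
                    retained = seq_along(sets) %in% retained_idx)
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  best_terms <- sets[[o[1L]]]
  structure(list(table = tab,
                 retained = tab[tab$retained, , drop = FALSE],
                 best = suppressMessages(fit_one(best_terms)),
                 best_terms = best_terms,
                 n_dropped_nested = dropped_nested),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("All-subsets selection:", nrow(x$table), "candidates,",
      nrow(x$retained), "retained,", x$n_dropped_nested,
      "nested models removed\n")
  print(utils::head(x$retained, 10L))
  invisible(x)
}
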