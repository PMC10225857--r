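## Two-segment continuous breakpoint regression on log total-abundance
## series. Slopes are reported as 100 x per-year change in log total
## (percent-per-annum convention, natural logs).

.quiet_summary <- function(fit) {
  withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Continuous two-segment regression on a log total series
#'
#' For every candidate breakpoint (interior years with at least three
#' points on each side), fits the continuous hinge model
#' \eqn{y = b_0 + b_1 x + b_2 (x - c)_+} by least squares and keeps the
#' breakpoint with the smallest residual sum of squares; ties go to the
#' earliest year. Segment slopes are \eqn{100 b_1} and
#' \eqn{100 (b_1 + b_2)} percent per annum with t-based 95% confidence
#' intervals from the segment-wise standard errors. When no admissible
#' breakpoint exists, a single-slope fit is returned and flagged. A fit
#' whose hinge term does not reduce the error of the best straight line is
#' flagged degenerate.
#'
#' @param years integer years.
#' @param log_totals log-scale totals (natural log), same length.
#' @return An object of class \code{piecewise_fit}: list with
#'   \code{breakpoint_year}, \code{slope1}, \code{slope1_ci},
#'   \code{slope2}, \code{slope2_ci} (percent per annum), \code{r2},
#'   \code{sse}, \code{single_line}, \code{degenerate}, \code{log_base}
#'   ("natural").
#' @export
fit_piecewise <- function(years, log_totals) {
  stopifnot(length(years) == length(log_totals))
  o <- order(years)
  x <- as.numeric(years[o]); y <- as.numeric(log_totals[o])
  n <- length(x)
  if (n < 7L) stop("need at least 7 observations", call. = FALSE)

  single <- stats::lm(y ~ x)
  sse_single <- sum(stats::resid(single)^2)

  candidates <- x[vapply(x, function(b)
    sum(x <= b) >= 3L && sum(x >= b) >= 3L && b > min(x) && b < max(x),
    TRUE)]
  if (!length(candidates)) {
    ci <- 100 * stats::confint(single)["x", ]
    s <- 100 * stats::coef(single)[["x"]]
    return(structure(list(breakpoint_year = NA_integer_,
                          slope1 = s, slope1_ci = unname(ci),
                          slope2 = s, slope2_ci = unname(ci),
                          r2 = .quiet_summary(single)$r.squared,
                          sse = sse_single, single_line = TRUE,
                          degenerate = TRUE, log_base = "natural"),
                     class = "piecewise_fit"))
  }
  best <- NULL
  best_sse <- Inf
  for (b in candidates) {
    h <- pmax(x - b, 0)
    fit <- stats::lm(y ~ x + h)
    sse <- sum(stats::resid(fit)^2)
    if (sse < best_sse - 1e-12) {       # strict improvement; ties -> earliest
      best_sse <- sse
      best <- list(b = b, fit = fit)
    }
  }
  fit <- best$fit
  co <- stats::coef(fit)
  vc <- withCallingHandlers(stats::vcov(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  df <- fit$df.residual
  tq <- stats::qt(0.975, df)
  s1 <- co[["x"]]
  se1 <- sqrt(vc["x", "x"])
  s2 <- co[["x"]] + co[["h"]]
  se2 <- sqrt(vc["x", "x"] + vc["h", "h"] + 2 * vc["x", "h"])
  r2 <- 1 - best_sse / sum((y - mean(y))^2)
  structure(list(breakpoint_year = as.integer(best$b),
                 slope1 = 100 * s1,
                 slope1_ci = 100 * c(s1 - tq * se1, s1 + tq * se1),
                 slope2 = 100 * s2,
                 slope2_ci = 100 * c(s2 - tq * se2, s2 + tq * se2),
                 r2 = r2, sse = best_sse,
                 single_line = FALSE,
                 degenerate = best_sse > sse_single - 1e-10,
                 log_base = "natural"),
            class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  if (x$single_line) {
    cat(sprintf("Single-slope fit (no admissible breakpoint): %.2f %%/yr, R2 = %.3f\n",
                x$slope1, x$r2))
  } else {
    cat(sprintf("Breakpoint %d: slope %.2f (%.2f, %.2f) -> %.2f (%.2f, %.2f) %%/yr, R2 = %.3f%s\n",
                x$breakpoint_year, x$slope1, x$slope1_ci[1L], x$slope1_ci[2L],
                x$slope2, x$slope2_ci[1L], x$slope2_ci[2L], x$r2,
                if (x$degenerate) " [degenerate: straight line]" else ""))
  }
  invisible(x)
}
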