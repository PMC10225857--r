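## Derived covariates: abundance quartile classes and the collinearity
## screen used before trait modelling.

#' Assign species to abundance quartile classes
#'
#' Species are sorted ascending by their population point estimate (ties
#' broken by species_id for a stable, deterministic assignment) and split
#' into four contiguous classes, rarest first, labelled rare, scarce,
#' common and abundant. Class sizes differ by at most one; when the species
#' count is not a multiple of four, the spare species go to the rarer
#' classes so that "abundant" is always exactly the top quartile.
#'
#' @param estimates data.frame with \code{species_id} and \code{point}.
#' @param labels class labels, rarest first.
#' @return data.frame with \code{species_id} and \code{abundance_class}
#'   (ordered factor).
#' @export
assign_quartiles <- function(estimates,
                             labels = c("rare", "scarce", "common",
                                        "abundant")) {
  est <- as.data.frame(estimates)
  stopifnot(length(labels) == 4L)
  if (nrow(est) < 4L) stop("need at least 4 species", call. = FALSE)
  if (anyDuplicated(est$species_id))
    stop("duplicate species_id in estimates", call. = FALSE)
  if (any(est$point <= 0)) stop("point estimates must be positive",
                                call. = FALSE)
  o <- order(est$point, est$species_id)
  n <- nrow(est)
  base <- n %/% 4L
  extra <- n %% 4L
  sizes <- base + (seq_len(4L) <= extra)
  cls <- rep(labels, times = sizes)
  out <- data.frame(species_id = est$species_id[o],
                    abundance_class = factor(cls, levels = labels,
                                             ordered = TRUE))
  out <- out[match(est$species_id, out$species_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise association screen for a covariate table
#'
#' For every pair of covariates, computes the statistic appropriate to the
#' pair: Pearson's correlation for two continuous variables, Cramer's V for
#' two nominal variables, and the R-squared of a single-term linear
#' regression for a continuous-nominal pair. Constant columns yield NA with
#' the reason recorded.
#'
#' @param table data.frame of covariates (numeric columns are treated as
#'   continuous, character/factor columns as nominal).
#' @return An object of class \code{collinearity_screen}: list with
#'   \code{statistic} (symmetric numeric matrix) and \code{type} (matrix of
#'   statistic names: "pearson", "cramers_v", "r_squared" or "undefined").
#' @export
collinearity_screen <- function(table) {
  table <- as.data.frame(table)
  if (nrow(table) < 3L) stop("need at least 3 rows", call. = FALSE)
  vars <- names(table)
  p <- length(vars)
  is_num <- vapply(table, is.numeric, TRUE)
  stat <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  type <- matrix("", p, p, dimnames = list(vars, vars))
  diag(stat) <- 1
  diag(type) <- "self"
  constant <- vapply(seq_len(p), function(j) {
    z <- table[[j]]
    length(unique(z[!is.na(z)])) < 2L
  }, TRUE)
  for (i in seq_len(p - 1L)) {
    for (j in seq(i + 1L, p)) {
      if (constant[i] || constant[j]) {
        type[i, j] <- type[j, i] <- "undefined"
        next
      }
      xi <- table[[i]]; xj <- table[[j]]
      if (is_num[i] && is_num[j]) {
        s <- stats::cor(xi, xj, use = "complete.obs")
        t <- "pearson"
      } else if (!is_num[i] && !is_num[j]) {
        s <- cramers_v(xi, xj)
        t <- "cramers_v"
      } else {
        num <- if (is_num[i]) xi else xj
        nom <- if (is_num[i]) xj else xi
        s <- summary(stats::lm(num ~ factor(nom)))$r.squared
        t <- "r_squared"
      }
      stat[i, j] <- stat[j, i] <- s
      type[i, j] <- type[j, i] <- t
    }
  }
  structure(list(statistic = stat, type = type),
            class = "collinearity_screen")
}

#' Cramer's V for two nominal variables
#'
#' \eqn{V = \sqrt{\chi^2 / (n (\min(r, c) - 1))}} from the (uncorrected)
#' chi-squared statistic of the contingency table.
#'
#' @param x,y vectors coercible to factors.
#' @return V in [0, 1].
#' @export
cramers_v <- function(x, y) {
  tab <- table(x, y)
  chi2 <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic)
  n <- sum(tab)
  k <- min(nrow(tab), ncol(tab)) - 1L
  if (k < 1L) return(NA_real_)
  v <- sqrt(as.numeric(chi2) / (n * k))
  min(v, 1)
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat("Pairwise association screen\n")
  print(round(x$statistic, 3))
  invisible(x)
}
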