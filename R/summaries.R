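## Change decompositions and headline metrics from posterior trajectories.
## All decompositions are computed per posterior draw so the accounting
## identities (group nets sum to the assemblage net; increases plus
## decreases equal the net) hold exactly, draw by draw.

.cri <- function(z) stats::quantile(z, c(0.5, 0.025, 0.975), names = FALSE)

.summarize_N <- function(N, years, year_start, year_end) {
  i0 <- match(year_start, years)
  i1 <- match(year_end, years)
  if (is.na(i0) || is.na(i1) || i1 <= i0)
    stop("year_start/year_end must be distinct years on the grid",
         call. = FALSE)
  span <- year_end - year_start
  N0 <- N[, , i0, drop = FALSE][, , 1L, drop = TRUE]
  N1 <- N[, , i1, drop = FALSE][, , 1L, drop = TRUE]
  if (is.null(dim(N0))) {
    N0 <- cbind(N0); N1 <- cbind(N1)
    colnames(N0) <- colnames(N1) <- dimnames(N)[[2L]]
  }
  change <- N1 - N0
  T0 <- rowSums(N0); T1 <- rowSums(N1)
  net <- rowSums(change)
  inc <- rowSums(change * (change > 0))
  dec <- rowSums(change * (change < 0))
  pct <- 100 * (T1 - T0) / T0
  pa <- 100 * ((T1 / T0)^(1 / span) - 1)
  per_species <- data.frame(
    species_id = colnames(N0),
    change = apply(change, 2L, stats::median),
    start = apply(N0, 2L, stats::median),
    end = apply(N1, 2L, stats::median))
  per_species$direction <- ifelse(per_species$change >= 0, "increasing",
                                  "decreasing")
  list(draws = list(net = net, increase = inc, decrease = dec,
                    pct = pct, per_annum = pa, start = T0, end = T1,
                    change = change),
       per_species = per_species, span = span,
       year_start = year_start, year_end = year_end)
}

.change_summary <- function(parts) {
  d <- parts$draws
  tab <- rbind(start = .cri(d$start), end = .cri(d$end),
               net_change = .cri(d$net),
               total_increase = .cri(d$increase),
               total_decrease = .cri(d$decrease),
               pct_change = .cri(d$pct),
               pct_per_annum = .cri(d$per_annum))
  colnames(tab) <- c("estimate", "lcl", "ucl")
  structure(list(summary = as.data.frame(tab),
                 per_species = parts$per_species,
                 draws = d,
                 year_start = parts$year_start, year_end = parts$year_end,
                 span = parts$span),
            class = "change_summary")
}

#' Summarize assemblage change from a fitted abundance model
#'
#' Per posterior draw, computes the net change in the weighted total between
#' the start and end year, splits it into the summed increases of species
#' with positive change and the summed decreases of species with negative
#' change (classified per draw, so the decomposition is exact draw by
#' draw), the percent change \eqn{100 (T_{end} - T_{start}) / T_{start}}
#' and the geometric per-annum rate
#' \eqn{100 ((T_{end}/T_{start})^{1/\mathrm{span}} - 1)} with the span in
#' calendar years. Summaries are posterior medians with 2.5/97.5
#' percentiles; a species' headline direction is the sign of its posterior
#' median change.
#'
#' @param fit an \code{abundance_fit}.
#' @param weights optional per-species multipliers (see
#'   [total_trajectory()]).
#' @param year_start,year_end summary window; default full model span.
#' @return An object of class \code{change_summary} with \code{summary}
#'   (estimate/lcl/ucl rows), \code{per_species} and raw \code{draws}.
#' @export
summarize_change <- function(fit, weights = NULL, year_start = NULL,
                             year_end = NULL) {
  if (is.null(year_start)) year_start <- min(fit$years)
  if (is.null(year_end)) year_end <- max(fit$years)
  N <- species_trajectories(fit, weights)
  .change_summary(.summarize_N(N, fit$years, year_start, year_end))
}

#' Percent change and per-annum rate from two totals
#'
#' The deterministic arithmetic behind the headline table:
#' \code{pct = 100 * (end - start) / start} and
#' \code{per_annum = 100 * ((end/start)^(1/span) - 1)}. Compounding the
#' per-annum rate over the span reproduces the percent change exactly.
#'
#' @param start,end totals in the first and last year.
#' @param span number of calendar years between them.
#' @return list with \code{change}, \code{pct_change}, \code{pct_per_annum}.
#' @export
change_metrics <- function(start, end, span) {
  stopifnot(start > 0, span > 0)
  list(change = end - start,
       pct_change = 100 * (end - start) / start,
       pct_per_annum = 100 * ((end / start)^(1 / span) - 1))
}

#' Concentration of change in the top k species
#'
#' The share of the total same-sign change accounted for by the k species
#' with the largest changes of that sign, e.g. the fraction of the total
#' decline contributed by the eight steepest-declining species. With fewer
#' than k species of that sign the share is 1 and the result is flagged.
#'
#' @param changes per-species changes (positive and negative).
#' @param k number of species (default 8).
#' @param direction \code{"decline"} (default) or \code{"increase"}.
#' @return Share in [0, 1] with attributes \code{n_species} (species of
#'   that sign) and \code{flagged}.
#' @export
concentration <- function(changes, k = 8, direction = c("decline",
                                                        "increase")) {
  direction <- match.arg(direction)
  stopifnot(k >= 1)
  z <- if (direction == "decline") -changes[changes < 0] else
    changes[changes > 0]
  if (!length(z))
    return(structure(NA_real_, n_species = 0L, flagged = TRUE))
  flagged <- length(z) < k
  share <- sum(sort(z, decreasing = TRUE)[seq_len(min(k, length(z)))]) /
    sum(z)
  structure(share, n_species = length(z), flagged = flagged)
}

#' Change decomposition by species group
#'
#' Applies [summarize_change()] within each level of a grouping (abundance
#' class, habitat or migration strategy). Group net changes sum to the
#' assemblage net change in every posterior draw; empty groups are omitted
#' with a message.
#'
#' @inheritParams summarize_change
#' @param grouping named character vector mapping species_id to a group
#'   label, or a data.frame with \code{species_id} and a group column.
#' @return Named list of \code{change_summary}, one per group, with the
#'   assemblage summary attached as attribute \code{assemblage}.
#' @export
group_breakdown <- function(fit, grouping, weights = NULL,
                            year_start = NULL, year_end = NULL) {
  if (is.data.frame(grouping)) {
    gcol <- setdiff(names(grouping), "species_id")[1L]
    grouping <- stats::setNames(as.character(grouping[[gcol]]),
                                grouping$species_id)
  }
  if (!all(fit$species_id %in% names(grouping)))
    stop("grouping undefined for some fitted species", call. = FALSE)
  if (is.null(year_start)) year_start <- min(fit$years)
  if (is.null(year_end)) year_end <- max(fit$years)
  g <- grouping[fit$species_id]
  N <- species_trajectories(fit, weights)
  out <- list()
  for (lev in unique(g)) {
    idx <- which(g == lev)
    if (!length(idx)) { message("empty group omitted: ", lev); next }
    Ng <- N[, idx, , drop = FALSE]
    out[[lev]] <- .change_summary(.summarize_N(Ng, fit$years, year_start,
                                               year_end))
  }
  attr(out, "assemblage") <- .change_summary(
    .summarize_N(N, fit$years, year_start, year_end))
  out
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf("Change %d-%d (span %d yr):\n", x$year_start, x$year_end,
              x$span))
  print(round(x$summary, 3))
  invisible(x)
}

#' Export a change summary as CSV and JSON
#'
#' @param x a \code{change_summary}.
#' @param csv,json output paths (either may be NULL).
#' @return Invisibly, the summary data.frame written.
#' @export
write_change_summary <- function(x, csv = NULL, json = NULL) {
  tab <- cbind(quantity = rownames(x$summary), x$summary)
  rownames(tab) <- NULL
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(tab, json, dataframe = "rows", digits = NA)
  invisible(tab)
}
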