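## Inclusion, zero-handling and coverage rules applied to raw index series.
## A "series" here is one species' slice of the long index table: a
## data.frame with columns year, index, se and (optionally) coverage.

.empty_prep_report <- function() {
  data.frame(species_id = character(0), rule = character(0),
             detail = character(0), stringsAsFactors = FALSE)
}

.report_row <- function(species_id, rule, detail = "") {
  data.frame(species_id = species_id, rule = rule,
             detail = as.character(detail), stringsAsFactors = FALSE)
}

#' Truncate a series at its first positive count and offset zeros
#'
#' The series is retained from the year of the first positive index value.
#' If any zero remains in the retained window, 1% of the mean of the
#' retained raw values is added to every retained value, so that all outputs
#' are strictly positive. An all-zero series is an exclusion (reason
#' \code{all_zero}), not an error.
#'
#' @param series data.frame with columns \code{year}, \code{index},
#'   \code{se} (and optionally \code{coverage}) for one species.
#' @param species_id label used in the report.
#' @return A list with \code{series} (the prepared data.frame, or \code{NULL}
#'   on exclusion), \code{report} (rule rows), \code{offset} (the value
#'   added, 0 when no zero was present) and \code{excluded} (logical).
#' @export
truncate_and_offset <- function(series, species_id = "species") {
  stopifnot(all(c("year", "index", "se") %in% names(series)))
  series <- series[order(series$year), , drop = FALSE]
  pos <- which(series$index > 0)
  if (!length(pos)) {
    return(list(series = NULL,
                report = .report_row(species_id, "excluded", "all_zero"),
                offset = 0, excluded = TRUE))
  }
  report <- .empty_prep_report()
  if (pos[1L] > 1L) {
    series <- series[pos[1L]:nrow(series), , drop = FALSE]
    report <- rbind(report, .report_row(species_id,
                                        "truncated_to_first_positive",
                                        series$year[1L]))
  }
  offset <- 0
  if (any(series$index == 0)) {
    offset <- 0.01 * mean(series$index)
    series$index <- series$index + offset
    report <- rbind(report, .report_row(species_id, "zero_offset_added",
                                        format(offset, digits = 12)))
  }
  rownames(series) <- NULL
  list(series = series, report = report, offset = offset, excluded = FALSE)
}

#' Apply population-coverage filters
#'
#' A species is excluded outright when the most recent year of its series
#' covers less than \code{min_final} (default 50%) of the regional
#' population; individual years covering less than \code{min_year}
#' (default 5%) are dropped. Years with missing coverage are kept.
#'
#' @inheritParams truncate_and_offset
#' @param min_final minimum coverage fraction required in the final year.
#' @param min_year minimum coverage fraction required to keep a year.
#' @return As [truncate_and_offset()].
#' @export
apply_coverage_filters <- function(series, species_id = "species",
                                   min_final = 0.5, min_year = 0.05) {
  if (!"coverage" %in% names(series) || all(is.na(series$coverage)))
    return(list(series = series, report = .empty_prep_report(),
                excluded = FALSE))
  series <- series[order(series$year), , drop = FALSE]
  final_cov <- series$coverage[nrow(series)]
  if (!is.na(final_cov) && final_cov < min_final) {
    return(list(series = NULL,
                report = .report_row(species_id, "excluded",
                                     "low_final_coverage"),
                excluded = TRUE))
  }
  report <- .empty_prep_report()
  drop <- !is.na(series$coverage) & series$coverage < min_year
  if (any(drop)) {
    report <- rbind(report, .report_row(species_id,
                                        "years_dropped_low_coverage",
                                        paste(series$year[drop],
                                              collapse = ";")))
    series <- series[!drop, , drop = FALSE]
  }
  rownames(series) <- NULL
  list(series = series, report = report, excluded = FALSE)
}

#' Enforce the minimum span rule
#'
#' A series is excluded when its first and last years are less than
#' \code{min_span_years} apart (default 10): a span of exactly 10 years,
#' e.g. 2000--2010, is retained.
#'
#' @inheritParams truncate_and_offset
#' @param min_span_years minimum difference between last and first year.
#' @return As [truncate_and_offset()].
#' @export
enforce_span_rule <- function(series, species_id = "species",
                              min_span_years = 10) {
  if (is.null(series) || nrow(series) == 0L ||
      max(series$year) - min(series$year) < min_span_years) {
    return(list(series = NULL,
                report = .report_row(species_id, "excluded", "span_lt_min"),
                excluded = TRUE))
  }
  list(series = series, report = .empty_prep_report(), excluded = FALSE)
}

#' Prepare all index series for analysis
#'
#' Applies, per species and in order: named exclusions, truncation at the
#' first positive count with zero offsetting, coverage filters, and the
#' minimum span rule. The full preparation is idempotent: running it on its
#' own output changes nothing.
#'
#' @param index_df long-format index table (see [read_index_series()]).
#' @param exclude_species species_ids removed a priori (e.g. species with
#'   imprecise, strongly negative trends flagged by the analyst).
#' @param min_final,min_year,min_span_years rule thresholds; see
#'   [apply_coverage_filters()] and [enforce_span_rule()].
#' @return A list with \code{series} (prepared long data.frame of retained
#'   species) and \code{report} (one row per rule application, with
#'   machine-readable reasons for every exclusion).
#' @export
prepare_series <- function(index_df, exclude_species = character(),
                           min_final = 0.5, min_year = 0.05,
                           min_span_years = 10) {
  index_df <- validate_index_series(index_df, file = "index input")
  out <- list()
  reports <- list()
  for (sp in unique(index_df$species_id)) {
    s <- index_df[index_df$species_id == sp,
                  c("year", "index", "se", "coverage"), drop = FALSE]
    if (sp %in% exclude_species) {
      reports[[sp]] <- .report_row(sp, "excluded", "excluded_by_name")
      next
    }
    r1 <- truncate_and_offset(s, sp)
    if (r1$excluded) { reports[[sp]] <- r1$report; next }
    r2 <- apply_coverage_filters(r1$series, sp, min_final, min_year)
    if (r2$excluded) { reports[[sp]] <- rbind(r1$report, r2$report); next }
    r3 <- enforce_span_rule(r2$series, sp, min_span_years)
    reports[[sp]] <- rbind(r1$report, r2$report, r3$report)
    if (r3$excluded) next
    s_out <- r3$series
    s_out$species_id <- sp
    out[[sp]] <- s_out[c("species_id", "year", "index", "se", "coverage")]
  }
  series <- if (length(out)) do.call(rbind, out) else index_df[0, ]
  rownames(series) <- NULL
  report <- if (length(reports)) do.call(rbind, reports) else
    .empty_prep_report()
  rownames(report) <- NULL
  list(series = series, report = report)
}
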