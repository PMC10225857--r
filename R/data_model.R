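#' avitrend: trends in total abundance and biomass of bird assemblages
#'
#' Tools to take per-species annual abundance index series and absolute
#' population estimates through inclusion filters, GAM smoothing, a Bayesian
#' hierarchical total-abundance model, biomass weighting, climate-suitability
#' trends, trait-correlate regression (ordinary and phylogenetic least
#' squares) and change decompositions, together with a synthetic-assemblage
#' simulator with known ground truth.
#'
#' @keywords internal
#' @aliases avitrend-package
"_PACKAGE"

#' Closed vocabularies for species traits
#'
#' Habitat classes follow the nine breeding-habitat categories used for
#' assemblage breakdowns plus a catch-all \code{"other"}; migration classes
#' are the four standard strategies. Unknown tokens in input tables are
#' errors, never coerced.
#'
#' @format Character vectors.
#' @export
habitat_classes <- c(
  "human-modified", "grassland", "forest", "woodland/parkland",
  "wetland", "riverine", "coastal", "marine", "other"
)

#' @rdname habitat_classes
#' @export
migration_classes <- c("resident", "partial", "short-distance", "long-distance")

## row-addressed validation error
.row_error <- function(file, rows, msg) {
  stop(sprintf("%s: %s (row%s %s)", file, msg,
               if (length(rows) > 1L) "s" else "",
               paste(rows, collapse = ", ")), call. = FALSE)
}

.require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Read and validate a species trait table
#'
#' Expects a UTF-8 CSV with header and columns \code{species_id},
#' \code{body_mass} (grams), \code{habitat}, \code{migration},
#' \code{trophic_niche} and optionally \code{native} (logical, default
#' \code{TRUE}). Habitat and migration values must come from
#' [habitat_classes] and [migration_classes].
#'
#' @param path path to a CSV file.
#' @return A validated data.frame, one row per species.
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  validate_species_table(df, file = basename(path))
}

#' @rdname read_species_table
#' @param df a data.frame to validate in place of a file.
#' @param file label used in error messages.
#' @export
validate_species_table <- function(df, file = "species table") {
  .require_columns(df, c("species_id", "body_mass", "habitat", "migration",
                         "trophic_niche"), file)
  if (!"native" %in% names(df)) df$native <- TRUE
  dup <- which(duplicated(df$species_id))
  if (length(dup)) .row_error(file, dup, "duplicate species_id")
  bad <- which(!is.finite(df$body_mass) | df$body_mass <= 0)
  if (length(bad)) .row_error(file, bad, "body_mass must be > 0")
  bad <- which(!df$habitat %in% habitat_classes)
  if (length(bad))
    .row_error(file, bad, paste0("unknown habitat token '",
                                 df$habitat[bad[1L]], "'"))
  bad <- which(!df$migration %in% migration_classes)
  if (length(bad))
    .row_error(file, bad, paste0("unknown migration token '",
                                 df$migration[bad[1L]], "'"))
  df$native <- as.logical(df$native)
  df
}

#' @rdname read_species_table
#' @export
write_species_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a long-format index series table
#'
#' Columns: \code{species_id}, \code{year}, \code{index}, \code{se} and
#' optionally \code{coverage} (fraction of the regional population covered
#' by the monitoring data in that year). Index values may be zero on input;
#' the preparation rules in [prepare_series()] remove or offset them.
#'
#' @param path path to a CSV file.
#' @return A validated long data.frame ordered by species then year.
#' @export
read_index_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  validate_index_series(df, file = basename(path))
}

#' @rdname read_index_series
#' @param df a data.frame to validate in place of a file.
#' @param file label used in error messages.
#' @export
validate_index_series <- function(df, file = "index series") {
  .require_columns(df, c("species_id", "year", "index", "se"), file)
  if (!"coverage" %in% names(df)) df$coverage <- NA_real_
  bad <- which(!is.finite(df$year) | df$year != round(df$year))
  if (length(bad)) .row_error(file, bad, "year must be an integer")
  bad <- which(!is.finite(df$index) | df$index < 0)
  if (length(bad)) .row_error(file, bad, "index must be >= 0")
  bad <- which(!is.finite(df$se) | df$se < 0)
  if (length(bad)) .row_error(file, bad, "se must be >= 0")
  bad <- which(!is.na(df$coverage) & (df$coverage < 0 | df$coverage > 1))
  if (length(bad)) .row_error(file, bad, "coverage must lie in [0, 1]")
  df <- df[order(df$species_id, df$year), , drop = FALSE]
  dup <- which(duplicated(df[c("species_id", "year")]))
  if (length(dup)) .row_error(file, dup, "duplicate species_id x year")
  rownames(df) <- NULL
  df
}

#' @rdname read_index_series
#' @export
write_index_series <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and validate population estimates
#'
#' Columns: \code{species_id}, \code{min_est}, \code{max_est} (individuals;
#' a best-only value is supplied as \code{min_est == max_est}),
#' \code{ref_year_start}, \code{ref_year_end}. If \code{point} and \code{se}
#' are absent they are derived with [eu_point_estimate()]: the point is the
#' geometric mean of the minimum and maximum and the standard error a sixth
#' of their span.
#'
#' @param path path to a CSV file.
#' @return A validated data.frame with \code{point} and \code{se} filled in.
#' @export
read_population_estimates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  validate_population_estimates(df, file = basename(path))
}

#' @rdname read_population_estimates
#' @param df a data.frame to validate in place of a file.
#' @param file label used in error messages.
#' @export
validate_population_estimates <- function(df, file = "population estimates") {
  .require_columns(df, c("species_id", "min_est", "max_est",
                         "ref_year_start", "ref_year_end"), file)
  dup <- which(duplicated(df$species_id))
  if (length(dup)) .row_error(file, dup, "duplicate species_id")
  bad <- which(!is.finite(df$min_est) | !is.finite(df$max_est) |
                 df$min_est < 0 | df$max_est < df$min_est)
  if (length(bad)) .row_error(file, bad, "need 0 <= min_est <= max_est")
  bad <- which(df$ref_year_end < df$ref_year_start)
  if (length(bad)) .row_error(file, bad, "ref_year_end < ref_year_start")
  if (!all(c("point", "se") %in% names(df))) {
    ps <- mapply(function(mn, mx) unlist(eu_point_estimate(mn, mx)),
                 df$min_est, df$max_est)
    df$point <- ps["point", ]
    df$se <- ps["se", ]
  }
  bad <- which(df$point < df$min_est | df$point > df$max_est | df$se < 0)
  if (length(bad))
    .row_error(file, bad, "point outside [min_est, max_est] or se < 0")
  df
}

#' @rdname read_population_estimates
#' @export
write_population_estimates <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and validate a per-country mean-trend table
#'
#' Used by the trend-expansion engine. Columns: \code{species_id},
#' \code{country}, \code{mean_trend} (multiplicative change over
#' \code{trend_period}; values reported as percent change must be converted
#' to multiplicative form before this table is written), \code{trend_period}
#' (years), \code{mean_pop} (individuals), \code{mean_estimate_year}, and
#' optionally \code{pop_se} (individuals, used for bootstrap resampling;
#' defaults to 0).
#'
#' @param path path to a CSV file.
#' @return A validated data.frame.
#' @export
read_national_trends <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  validate_national_trends(df, file = basename(path))
}

#' @rdname read_national_trends
#' @param df a data.frame to validate in place of a file.
#' @param file label used in error messages.
#' @export
validate_national_trends <- function(df, file = "national trends") {
  .require_columns(df, c("species_id", "country", "mean_trend", "trend_period",
                         "mean_pop", "mean_estimate_year"), file)
  if (!"pop_se" %in% names(df)) df$pop_se <- 0
  bad <- which(!is.finite(df$mean_trend) | df$mean_trend <= 0)
  if (length(bad)) .row_error(file, bad, "mean_trend must be > 0")
  bad <- which(!is.finite(df$trend_period) | df$trend_period < 1)
  if (length(bad)) .row_error(file, bad, "trend_period must be >= 1")
  bad <- which(!is.finite(df$mean_pop) | df$mean_pop <= 0)
  if (length(bad)) .row_error(file, bad, "mean_pop must be > 0")
  dup <- which(duplicated(df[c("species_id", "country")]))
  if (length(dup)) .row_error(file, dup, "duplicate species_id x country")
  df
}

#' @rdname read_national_trends
#' @export
write_national_trends <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that additionally rejects
#' duplicated tip labels and warns (without failing) when the tree is not
#' ultrametric, since the phylogenetic regression assumes branch lengths
#' proportional to expected trait covariance.
#'
#' @param path path to a Newick file.
#' @return An object of class \code{phylo}.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("cannot parse Newick file ", path,
                                            ": ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) stop("cannot parse Newick file ", path, call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in ", path, call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths: ", path, call. = FALSE)
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    warning("tree is not ultrametric; phylogenetic regression assumes ",
            "branch lengths proportional to expected covariance")
  tree
}

#' @rdname read_phylogeny
#' @param tree a \code{phylo} object.
#' @export
write_phylogeny <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Compare tree tips with a species table
#'
#' @param tree a \code{phylo} object.
#' @param species_ids character vector of species identifiers.
#' @return A list with \code{in_both}, \code{only_tree}, \code{only_table}.
#' @export
match_tree_species <- function(tree, species_ids) {
  list(in_both = intersect(tree$tip.label, species_ids),
       only_tree = setdiff(tree$tip.label, species_ids),
       only_table = setdiff(species_ids, tree$tip.label))
}

#' Analysis configuration
#'
#' Bundles the run-level constants: the year range analysed, bootstrap
#' replicate count, MCMC settings, abundance-class labels, optional region
#' areas (km^2, user supplied; only used to express change per unit area)
#' and named species exclusions applied during series preparation.
#'
#' @param year_start,year_end calendar years bounding the analysis.
#' @param bootstrap_n bootstrap replicates for trend-expansion intervals.
#' @param mcmc list of MCMC settings; see [fit_abundance_model()].
#' @param quartile_labels labels for the four abundance classes, rarest first.
#' @param area_km2 optional named numeric of region areas.
#' @param exclude_species species_ids removed before analysis.
#' @param cst_variables names of the climate covariates used by the SDM stage.
#' @return An object of class \code{analysis_config}.
#' @export
analysis_config <- function(year_start, year_end,
                            bootstrap_n = 1000,
                            mcmc = list(chains = 4, warmup = 1000,
                                        iter = 1000, thin = 4, seed = 1L),
                            quartile_labels = c("rare", "scarce",
                                                "common", "abundant"),
                            area_km2 = NULL,
                            exclude_species = character(),
                            cst_variables = character()) {
  stopifnot(year_start < year_end, bootstrap_n >= 1,
            length(quartile_labels) == 4L)
  structure(list(year_start = year_start, year_end = year_end,
                 bootstrap_n = bootstrap_n, mcmc = mcmc,
                 quartile_labels = quartile_labels, area_km2 = area_km2,
                 exclude_species = exclude_species,
                 cst_variables = cst_variables),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param path path to a YAML file with fields matching the arguments.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(analysis_config)))]
  do.call(analysis_config, args)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat("  years:      ", x$year_start, "-", x$year_end, "\n", sep = "")
  cat("  bootstrap_n:", x$bootstrap_n, "\n")
  cat("  mcmc:       ", x$mcmc$chains, "chains,", x$mcmc$warmup, "warmup +",
      x$mcmc$iter, "draws, thin", x$mcmc$thin, "\n")
  if (length(x$exclude_species))
    cat("  excluded:   ", paste(x$exclude_species, collapse = ", "), "\n")
  invisible(x)
}
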