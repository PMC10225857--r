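## Biomass accounting: body-mass scaling of population estimates and
## mass-weighted total trajectories.

#' Convert a population estimate to a biomass estimate
#'
#' Multiplies the point estimate and its standard error by the species'
#' average body mass and converts grams to tonnes (x 1e-6). Mass is treated
#' as time-invariant per species.
#'
#' @param estimates population-estimate data.frame with \code{species_id},
#'   \code{point}, \code{se}.
#' @param masses named numeric of body masses in grams (names are
#'   species_ids); species without a mass are dropped with a message.
#' @return data.frame with \code{species_id}, \code{biomass_point} and
#'   \code{biomass_se} in tonnes, plus the original columns.
#' @export
to_biomass <- function(estimates, masses) {
  est <- as.data.frame(estimates)
  if (any(masses <= 0, na.rm = TRUE))
    stop("body masses must be positive", call. = FALSE)
  m <- masses[est$species_id]
  drop <- is.na(m)
  if (any(drop)) {
    message("dropping ", sum(drop), " species without body mass: ",
            paste(utils::head(est$species_id[drop], 5L), collapse = ", "))
    est <- est[!drop, , drop = FALSE]
    m <- m[!drop]
  }
  est$biomass_point <- est$point * m * 1e-6
  est$biomass_se <- est$se * m * 1e-6
  est
}

#' Posterior biomass trajectory
#'
#' The assemblage biomass trajectory is the total-abundance trajectory with
#' each species weighted by its body mass in tonnes; per posterior draw the
#' two are identical up to the weighting, so all accounting identities carry
#' over.
#'
#' @param fit an \code{abundance_fit}.
#' @param masses named numeric of body masses in grams.
#' @return A \code{total_trajectory} in tonnes.
#' @export
biomass_trajectory <- function(fit, masses) {
  if (!all(fit$species_id %in% names(masses)))
    stop("body mass missing for some fitted species", call. = FALSE)
  total_trajectory(fit, weights = masses[fit$species_id] * 1e-6)
}
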