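# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk unless a test writes it first.

make_series <- function(values, years = seq_along(values) + 1999,
                        se = pmax(0.05 * values, 1e-3), coverage = NA_real_) {
  data.frame(year = years, index = values, se = se, coverage = coverage)
}

random_species_table <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    species_id = sprintf("sp%03d", seq_len(n)),
    body_mass = rlnorm(n, log(50), 1),
    habitat = sample(habitat_classes, n, replace = TRUE),
    migration = sample(migration_classes, n, replace = TRUE),
    trophic_niche = sample(c("invertivore", "granivore", "omnivore"), n,
                           replace = TRUE),
    native = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.9, 0.1)))
}

# Hand-built smoothed series object, bypassing the GAM, for model tests
# where exact control of the inputs matters.
make_smoothed <- function(years, log_index, se_log, species_id = "spA") {
  out <- data.frame(year = years, log_index = log_index, se_log = se_log)
  structure(out, class = c("smoothed_series", "data.frame"),
            species_id = species_id,
            growth_rate = annual_growth_rate(out),
            method = "gam")
}

# Minimal hand-built abundance_fit for accounting-identity tests: known
# lambda draws and reference populations, no MCMC involved.
make_fake_fit <- function(lambda, P, years, species_id = NULL) {
  D <- dim(lambda)[1]; S <- dim(lambda)[2]
  if (is.null(species_id)) species_id <- sprintf("sp%02d", seq_len(S))
  dimnames(lambda) <- list(NULL, species_id, years)
  colnames(P) <- species_id
  structure(list(species_id = species_id, years = years,
                 ref_year = rep(years[1], S),
                 groups = data.frame(species_id = species_id,
                                     habitat = "forest",
                                     migration = "resident"),
                 draws = list(lambda = lambda,
                              theta = matrix(0, D, S), P = P),
                 chain = rep(1L, D),
                 diagnostics = list(rhat = c()),
                 settings = list()),
            class = "abundance_fit")
}

# Small end-to-end fitted model shared by several test files (computed once).
shared_small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_assemblage(n_species = 12, years = 2000:2014,
                                 seed = 42, p_missing_start = 0.25,
                                 p_zero = 0)
      prep <- prepare_series(sim$bundle$index)
      sm <- smooth_all_series(prep$series)
      fit <- suppressWarnings(
        fit_abundance_model(sm, sim$bundle$estimates, sim$bundle$species,
                            years = sim$truth$years, chains = 2,
                            warmup = 200, iter = 200, thin = 2, seed = 5))
      cache <<- list(sim = sim, fit = fit)
    }
    cache
  }
})
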