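# Shared fixtures, built in code. Expensive fits are cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small single-ecosystem simulation with informative traits
small_sim_config <- function(n_species = 10, n_individuals = 12,
                             sigma_obs = 0.2, re_sd = c(alpha = 0.2, b = 0.15, c = 0.2)) {
  simulation_config(
    ecosystem_config("eco1",
      n_species = n_species,
      n_individuals = n_individuals, age_range = c(0, 20)
    ),
    re_sd = re_sd, sigma_obs = sigma_obs
  )
}

quick_mcmc <- function(seed = 11, chains = 3, iterations = 2000) {
  mcmc_config(
    chains = chains, iterations = iterations,
    burnin = iterations / 2, thin = 2, seed = seed
  )
}

# one moderately sized trait-model fit shared across evaluation tests
shared_sim <- function() {
  cached("shared_sim", generate_multi_ecosystem(small_sim_config(), seed = 301))
}

shared_trait_fit <- function() {
  cached("shared_trait_fit", suppressWarnings(sample_posterior(
    shared_sim()$data,
    structure = trait_structure(alpha = "sla", b = "leaf_n", c = "seed_mass"),
    config = quick_mcmc(seed = 302, iterations = 3000)
  )))
}

shared_baseline_fit <- function() {
  cached("shared_baseline_fit", suppressWarnings(sample_posterior(
    shared_sim()$data,
    structure = trait_structure(),
    config = quick_mcmc(seed = 303, iterations = 3000)
  )))
}

# hand-buildable posterior object for arithmetic oracles (dic, pooling, ...)
fake_fit <- function(draw_tbl, species, structure = trait_structure(),
                     chains = 1) {
  qn <- names(draw_tbl)
  n <- nrow(draw_tbl)
  draws <- array(NA_real_, dim = c(n / chains, chains, length(qn)),
    dimnames = list(NULL, NULL, qn)
  )
  for (q in qn) draws[, , q] <- matrix(draw_tbl[[q]], ncol = chains)
  structure(
    list(
      draws = draws, species = species, species_eco = rep("e", length(species)),
      ecosystems = "e", structure = structure, stats = NULL,
      config = NULL, log_traits = character(0), ensemble = FALSE,
      fixed = list(), init = NULL,
      rhat = tibble::tibble(quantity = qn, rhat = NA_real_), converged = TRUE
    ),
    class = "growth_draws"
  )
}

# minimal valid trait table for n species
toy_traits <- function(species, ecosystem = "e", sla = NULL) {
  n <- length(species)
  tibble::tibble(
    species = species, ecosystem = ecosystem,
    sla = if (is.null(sla)) seq(8, 16, length.out = n) else sla,
    wood_density = seq(0.5, 0.8, length.out = n),
    seed_mass = seq(1, 4, length.out = n),
    leaf_n = seq(10, 20, length.out = n)
  )
}
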