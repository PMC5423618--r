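#' Configure one simulated ecosystem
#'
#' Describes a chronosequence of time-since-fire sites for a single
#' ecosystem: how many species and individuals are sampled, the age range
#' covered by the sites, and the (log-scale) distribution its species traits
#' are drawn from. Traits are simulated on log scales and exponentiated, so
#' they are always positive and right-skewed like real trait data.
#'
#' @param name Ecosystem identifier.
#' @param n_species Number of species (the field studies span roughly 9-23).
#' @param n_individuals Individuals measured per species.
#' @param age_range Range of site ages (years since fire), length 2.
#' @param n_sites Number of discrete chronosequence sites spanning
#'   `age_range`; individuals are spread across sites. Set `continuous_ages =
#'   TRUE` to draw ages uniformly instead.
#' @param continuous_ages Draw ages from a continuous uniform instead of the
#'   discrete site list.
#' @param trait_logmeans,trait_logsds Named numeric vectors (names from
#'   [trait_names()]) giving the mean and sd of each log trait. Shifting the
#'   log-means between ecosystems creates the partially or fully
#'   non-overlapping trait ranges seen across real ecosystems.
#' @param trait_corr 4x4 trait correlation matrix (log scale); must be
#'   positive definite.
#' @param log_mean_offsets Named vector `c(alpha=, b=, c=)` added to the
#'   global sub-model intercepts for this ecosystem (log scale). Use these to
#'   build ecosystems whose growth regimes genuinely differ.
#' @param re_sd Optional named vector overriding the global between-species
#'   random-effect sds for this ecosystem.
#' @return A list of class `ecosystem_config`.
#' @export
ecosystem_config <- function(name,
                             n_species = 14,
                             n_individuals = 40,
                             age_range = c(0, 25),
                             n_sites = 8,
                             continuous_ages = FALSE,
                             trait_logmeans = c(
                               sla = 2.3, wood_density = -0.45,
                               seed_mass = 0.7, leaf_n = 2.7
                             ),
                             trait_logsds = c(
                               sla = 0.4, wood_density = 0.15,
                               seed_mass = 0.6, leaf_n = 0.3
                             ),
                             trait_corr = diag(4),
                             log_mean_offsets = c(alpha = 0, b = 0, c = 0),
                             re_sd = NULL) {
  stopifnot(is.character(name), length(name) == 1, n_species >= 0, n_individuals >= 1)
  if (length(age_range) != 2 || diff(age_range) <= 0) {
    stop("`age_range` must be an increasing length-2 vector.", call. = FALSE)
  }
  trait_logmeans <- trait_logmeans[trait_names()]
  trait_logsds <- trait_logsds[trait_names()]
  if (anyNA(trait_logmeans) || anyNA(trait_logsds) || any(trait_logsds <= 0)) {
    stop("trait_logmeans/trait_logsds must cover all four traits with positive sds.",
      call. = FALSE
    )
  }
  trait_corr <- as.matrix(trait_corr)
  ok <- tryCatch(
    {
      chol(trait_corr)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok || nrow(trait_corr) != 4) {
    stop("`trait_corr` must be a positive-definite 4x4 matrix.", call. = FALSE)
  }
  structure(
    list(
      name = name, n_species = n_species, n_individuals = n_individuals,
      age_range = age_range, n_sites = n_sites, continuous_ages = continuous_ages,
      trait_logmeans = trait_logmeans, trait_logsds = trait_logsds,
      trait_corr = trait_corr,
      log_mean_offsets = log_mean_offsets[c("alpha", "b", "c")],
      re_sd = re_sd
    ),
    class = "ecosystem_config"
  )
}

#' Configure a multi-ecosystem growth simulation
#'
#' Holds the shared generating process: sub-model intercepts `beta0` and
#' trait slopes on the log scale (the trait -> growth-parameter map),
#' between-species random-effect sds, and the lognormal observation noise.
#' Defaults describe a single mixed-stature sclerophyll-forest-like system:
#' asymptotic heights around 200 cm, peak relative growth near 1.2
#' cm cm^-1 yr^-1 at about 3 years, with SLA lowering achievable height,
#' leaf nitrogen raising growth rate, and seed mass delaying peak growth.
#'
#' @param ecosystems A list of [ecosystem_config()] objects (unique names).
#' @param beta0 Named vector `c(alpha=, b=, c=)`: sub-model intercepts on the
#'   log scale (so `exp(beta0)` is the growth parameter of a species with
#'   average traits and zero random effect).
#' @param slopes A tibble with columns `parameter` (`alpha`/`b`/`c`), `trait`
#'   and `value`: the true trait slopes per standardized trait unit.
#' @param re_sd Named vector of between-species random-effect sds (log scale).
#' @param sigma_obs Lognormal observation sd (log scale).
#' @param log_traits Traits to log-transform before standardizing in the
#'   generating sub-models (the generator standardizes with the simulated
#'   species' own trait statistics and records them as ground truth).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(ecosystems = list(ecosystem_config("eco1")),
                              beta0 = c(alpha = 5.3, b = 0.15, c = 1.2),
                              slopes = default_slopes(),
                              re_sd = c(alpha = 0.4, b = 0.25, c = 0.35),
                              sigma_obs = 0.2,
                              log_traits = character(0)) {
  if (inherits(ecosystems, "ecosystem_config")) ecosystems <- list(ecosystems)
  nms <- purrr::map_chr(ecosystems, "name")
  if (anyDuplicated(nms)) stop("Duplicate ecosystem names in `ecosystems`.", call. = FALSE)
  beta0 <- beta0[c("alpha", "b", "c")]
  re_sd <- re_sd[c("alpha", "b", "c")]
  stopifnot(!anyNA(beta0), !anyNA(re_sd), all(re_sd >= 0), sigma_obs >= 0)
  slopes <- tibble::as_tibble(slopes)
  if (nrow(slopes) > 0) {
    stopifnot(all(c("parameter", "trait", "value") %in% names(slopes)))
    stopifnot(
      all(slopes$parameter %in% c("alpha", "b", "c")),
      all(slopes$trait %in% trait_names())
    )
  }
  structure(
    list(
      ecosystems = stats::setNames(ecosystems, nms), beta0 = beta0,
      slopes = slopes, re_sd = re_sd, sigma_obs = sigma_obs,
      log_traits = log_traits
    ),
    class = "simulation_config"
  )
}

#' Default generating trait -> growth-parameter map
#'
#' Low SLA raises achievable height, high leaf nitrogen raises maximum
#' relative growth rate, and high seed mass delays the age of peak growth.
#'
#' @return A tibble with columns `parameter`, `trait`, `value`.
#' @export
default_slopes <- function() {
  tibble::tibble(
    parameter = c("alpha", "b", "c"),
    trait = c("sla", "leaf_n", "seed_mass"),
    value = c(-0.3, 0.3, 0.3)
  )
}

#' Preset three-ecosystem configuration spanning contrasting growth regimes
#'
#' A trio of ecosystems echoing the qualitative regimes seen across
#' south-eastern Australian fire chronosequences: a semi-arid "fast-short-
#' early" system, an intermediate mixed-stature system, and a wet-forest
#' "slow-tall-late" system. Grand means of the log growth-rate parameter are
#' set near +1.35, +0.15 and -1.13 respectively, with correspondingly
#' ordered asymptotic heights and ages at peak growth; the trait ranges are
#' shifted so they only partially overlap between systems.
#'
#' @param n_species,n_individuals Per-ecosystem sampling effort.
#' @param sigma_obs Observation sd (log scale).
#' @return A [simulation_config()] with ecosystems `fast_short_early`,
#'   `intermediate`, `slow_tall_late`.
#' @export
preset_three_ecosystems <- function(n_species = 14, n_individuals = 40,
                                    sigma_obs = 0.2) {
  base_means <- c(sla = 2.3, wood_density = -0.45, seed_mass = 0.7, leaf_n = 2.7)
  mk <- function(name, off_a, off_b, off_c, ages, sla_shift, re_sd) {
    ecosystem_config(
      name = name, n_species = n_species, n_individuals = n_individuals,
      age_range = ages,
      trait_logmeans = base_means + c(sla = sla_shift, wood_density = 0, seed_mass = 0, leaf_n = 0),
      log_mean_offsets = c(alpha = off_a, b = off_b, c = off_c),
      re_sd = re_sd
    )
  }
  simulation_config(
    ecosystems = list(
      # short, fast, early-peaking; species growth rates nearly uniform
      mk("fast_short_early", -0.3, 1.20, -0.75, c(0, 12), -0.8,
        re_sd = c(alpha = 0.55, b = 0.03, c = 0.12)
      ),
      mk("intermediate", 0, 0, 0, c(0, 25), 0,
        re_sd = c(alpha = 0.6, b = 0.32, c = 0.6)
      ),
      # tall, slow, late-peaking
      mk("slow_tall_late", 1.0, -1.28, 1.20, c(0, 45), 0.3,
        re_sd = c(alpha = 0.43, b = 0.38, c = 0.32)
      )
    ),
    beta0 = c(alpha = 5.3, b = 0.15, c = 1.2),
    sigma_obs = sigma_obs
  )
}

#' Simulate species traits for one ecosystem
#'
#' Draws `n_species` trait vectors from the ecosystem's multivariate normal
#' on the log-trait scale and exponentiates. Uses the current RNG state;
#' call `set.seed()` (or use [generate_multi_ecosystem()]) for
#' reproducibility.
#'
#' @param config A [simulation_config()].
#' @param ecosystem Name of the ecosystem to simulate.
#' @return A validated trait tibble.
#' @export
simulate_traits <- function(config, ecosystem) {
  eco <- get_eco(config, ecosystem)
  n <- eco$n_species
  sp <- species_ids(eco$name, n)
  sds <- eco$trait_logsds
  cov <- diag(sds) %*% eco$trait_corr %*% diag(sds)
  z <- matrix(stats::rnorm(n * 4), n, 4) %*% chol(cov)
  logt <- sweep(z, 2, eco$trait_logmeans, "+")
  colnames(logt) <- trait_names()
  out <- tibble::tibble(species = sp, ecosystem = eco$name)
  for (tr in trait_names()) out[[tr]] <- exp(logt[, tr])
  validate_traits(out)
}

#' Simulate species growth parameters from traits
#'
#' Standardizes the supplied traits (with their own sample statistics, which
#' are recorded as ground truth), then forms each species' log growth
#' parameters as intercept + trait slopes + a Normal(0, re_sd) species random
#' effect, and exponentiates — exactly the trait sub-models the hierarchical
#' model assumes.
#'
#' @param traits A validated trait tibble for one ecosystem.
#' @param config A [simulation_config()].
#' @param ecosystem Ecosystem name (for intercept offsets and re_sd
#'   overrides).
#' @return A list with `params` (tibble `species`, `ecosystem`, `alpha`,
#'   `b`, `c`) and `truth` (list: `eps` long tibble, `stats`, `beta0`,
#'   `slopes`, `re_sd`).
#' @export
simulate_species_params <- function(traits, config, ecosystem) {
  eco <- get_eco(config, ecosystem)
  traits <- validate_traits(traits)
  st <- trait_stats(traits, log_traits = config$log_traits)
  z <- standardize_traits(traits, st)
  re_sd <- if (is.null(eco$re_sd)) config$re_sd else eco$re_sd[c("alpha", "b", "c")]
  beta0 <- config$beta0 + eco$log_mean_offsets
  n <- nrow(traits)
  params <- tibble::tibble(species = traits$species, ecosystem = traits$ecosystem)
  eps_tbl <- NULL
  for (p in c("alpha", "b", "c")) {
    lin <- rep(beta0[[p]], n)
    sl <- config$slopes[config$slopes$parameter == p, , drop = FALSE]
    if (nrow(sl) > 0) {
      for (i in seq_len(nrow(sl))) lin <- lin + sl$value[i] * z[[sl$trait[i]]]
    }
    eps <- stats::rnorm(n, 0, re_sd[[p]])
    params[[p]] <- exp(lin + eps)
    eps_tbl <- dplyr::bind_rows(eps_tbl, tibble::tibble(
      species = traits$species, parameter = p, eps = eps, linpred = lin
    ))
  }
  list(
    params = params,
    truth = list(
      eps = eps_tbl, stats = st, beta0 = beta0,
      slopes = config$slopes, re_sd = re_sd
    )
  )
}

#' Simulate individual height observations
#'
#' Assigns each individual an age from the ecosystem's chronosequence sites
#' (balanced across sites, in random order) or from a continuous uniform,
#' then draws its height from a lognormal centred (in the median sense) on
#' the Hillslope curve. `sigma_obs = 0` returns the exact curve heights.
#'
#' @param params A tibble `species`, `ecosystem`, `alpha`, `b`, `c`.
#' @param config A [simulation_config()].
#' @param ecosystem Ecosystem name.
#' @return A validated height tibble.
#' @export
simulate_heights <- function(params, config, ecosystem) {
  eco <- get_eco(config, ecosystem)
  n_ind <- eco$n_individuals
  site_ages <- seq(eco$age_range[1], eco$age_range[2], length.out = eco$n_sites)
  # keep age 0 off the chronosequence: a just-burned site has no measurable plants
  site_ages[site_ages == 0] <- diff(eco$age_range) / (10 * eco$n_sites)
  rows <- purrr::map_dfr(seq_len(nrow(params)), function(j) {
    ages <- if (eco$continuous_ages) {
      stats::runif(n_ind, max(eco$age_range[1], 1e-3), eco$age_range[2])
    } else {
      sample(rep_len(site_ages, n_ind))
    }
    mu <- hillslope_height(params$alpha[j], params$b[j], params$c[j], ages)
    h <- if (config$sigma_obs > 0) {
      stats::rlnorm(n_ind, meanlog = log(mu), sdlog = config$sigma_obs)
    } else {
      mu
    }
    tibble::tibble(
      individual_id = sprintf("%s_i%03d", params$species[j], seq_len(n_ind)),
      species = params$species[j], ecosystem = eco$name,
      age_yrs = ages, height_cm = h
    )
  })
  validate_heights(rows)
}

#' Generate a complete multi-ecosystem dataset with ground truth
#'
#' Composes [simulate_traits()], [simulate_species_params()] and
#' [simulate_heights()] for every configured ecosystem under a single seed.
#' Regenerating with the same `(config, seed)` reproduces the dataset and
#' ground truth exactly.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list with `data` (a [growth_data()] object) and `truth` (a list
#'   per ecosystem as in [simulate_species_params()], each with the species'
#'   true `params` added).
#' @export
generate_multi_ecosystem <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(config$ecosystems) < 1) stop("No ecosystems configured.", call. = FALSE)
  set.seed(seed)
  heights <- NULL
  traits <- NULL
  truth <- list()
  for (nm in names(config$ecosystems)) {
    eco <- config$ecosystems[[nm]]
    if (eco$n_species == 0) {
      warning(sprintf("Ecosystem '%s' has n_species = 0; excluded.", nm))
      next
    }
    tr <- simulate_traits(config, nm)
    sp <- simulate_species_params(tr, config, nm)
    h <- simulate_heights(sp$params, config, nm)
    heights <- dplyr::bind_rows(heights, h)
    traits <- dplyr::bind_rows(traits, tr)
    truth[[nm]] <- c(sp["truth"][[1]], list(params = sp$params))
  }
  if (is.null(heights)) stop("All ecosystems were empty.", call. = FALSE)
  list(data = growth_data(heights, traits), truth = truth, seed = seed)
}

#' Trait structure matching a simulation's generating slopes
#' @param config A [simulation_config()].
#' @return A [trait_structure()] with exactly the generating slopes active.
#' @export
generating_structure <- function(config) {
  sl <- config$slopes
  trait_structure(
    alpha = sl$trait[sl$parameter == "alpha"],
    b = sl$trait[sl$parameter == "b"],
    c = sl$trait[sl$parameter == "c"]
  )
}

#' Preset configuration for parameter-recovery validation
#'
#' The standard recovery benchmark used throughout the package: one
#' ecosystem of 15 species with 40 individuals each over a 0-25 year
#' chronosequence, trait slopes of -0.3 (SLA on asymptotic height), +0.3
#' (leaf nitrogen on maximum relative growth rate) and +0.3 (seed mass on
#' age at maximum growth), between-species random-effect sds of
#' 0.2/0.15/0.2 and lognormal observation sd 0.2.
#'
#' @return A [simulation_config()].
#' @export
preset_recovery_config <- function() {
  simulation_config(
    ecosystem_config("train", n_species = 15, n_individuals = 40, age_range = c(0, 25)),
    slopes = tibble::tibble(
      parameter = c("alpha", "b", "c"),
      trait = c("sla", "leaf_n", "seed_mass"),
      value = c(-0.3, 0.3, 0.3)
    ),
    re_sd = c(alpha = 0.2, b = 0.15, c = 0.2), sigma_obs = 0.2
  )
}

#' Preset strong-signal configuration for structure-selection experiments
#'
#' A deliberately favourable regime for detecting which traits drive which
#' growth parameters: few, noisy observations per species (so hierarchical
#' pooling matters), large trait slopes, tiny residual species scatter, and
#' a chronosequence confined to the rising phase of the curves (so the
#' growth-rate and timing sub-models leave a visible imprint on heights).
#'
#' @return A [simulation_config()].
#' @export
preset_selection_config <- function() {
  simulation_config(
    ecosystem_config("train", n_species = 14, n_individuals = 5, age_range = c(0, 12)),
    slopes = tibble::tibble(
      parameter = c("alpha", "b", "c"),
      trait = c("sla", "leaf_n", "seed_mass"),
      value = c(-0.8, 1.0, 0.8)
    ),
    re_sd = c(alpha = 0.05, b = 0.05, c = 0.05), sigma_obs = 0.15
  )
}

#' Backward-selection recovery experiment
#'
#' Repeatedly simulates a dataset whose generating trait structure is known,
#' runs [backward_selection()] from the full candidate structure, and
#' records whether the chosen structure matches the generating one exactly.
#'
#' @param config A single-ecosystem [simulation_config()] with a non-empty
#'   slope table.
#' @param mcmc [mcmc_config()] for every refit.
#' @param n_replicates Number of simulate-select cycles.
#' @param tolerance Selection tolerance (see [backward_selection()]).
#' @param seed Base seed; replicate r simulates with `seed + r`.
#' @return A tibble: `replicate`, `chosen` (list-column of structures),
#'   `n_slopes`, `exact` (recovered the generating structure exactly).
#' @export
selection_recovery_experiment <- function(config, mcmc = mcmc_config(),
                                          n_replicates = 10, tolerance = 0.03,
                                          seed = 1L) {
  stopifnot(inherits(config, "simulation_config"), length(config$ecosystems) == 1)
  target <- generating_structure(config)
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    sim <- generate_multi_ecosystem(config, seed = seed + r)
    cfg <- mcmc
    cfg$seed <- seed + 5000L + r
    sel <- backward_selection(sim$data,
      full = full_trait_structure(),
      config = cfg, tolerance = tolerance
    )
    tibble::tibble(
      replicate = r, chosen = list(sel$chosen),
      n_slopes = nrow(structure_slopes(sel$chosen)),
      exact = identical(unclass(sel$chosen), unclass(target))
    )
  })
}

#' Parameter-recovery experiment
#'
#' The standard validation loop for a hierarchical generative model:
#' repeatedly simulate a dataset with known coefficients, refit, and compare.
#' Reports, per sub-model coefficient, the mean posterior-mean bias, RMSE,
#' and empirical coverage of the 95% credible intervals, plus per-replicate
#' detail (non-convergent replicates are flagged, never dropped).
#'
#' @param config A single-ecosystem [simulation_config()].
#' @param mcmc An [mcmc_config()] used for each refit.
#' @param n_replicates Number of simulate-fit cycles.
#' @param seed Base seed; replicate r uses `seed + r` for data generation.
#' @return A list with `summary` (tibble: coefficient, true value, bias,
#'   rmse, coverage) and `detail` (per replicate x coefficient), of class
#'   `recovery_experiment`.
#' @export
parameter_recovery_experiment <- function(config, mcmc = mcmc_config(),
                                          n_replicates = 10, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(config$ecosystems) != 1) {
    stop("Use a single-ecosystem config for recovery experiments.", call. = FALSE)
  }
  structure_fit <- generating_structure(config)
  truth_beta <- c(
    stats::setNames(
      as.numeric(config$beta0),
      paste0("beta0_", c("alpha", "b", "c"))
    ),
    stats::setNames(
      config$slopes$value,
      paste0("beta_", config$slopes$parameter, "_", config$slopes$trait)
    )
  )
  detail <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    sim <- generate_multi_ecosystem(config, seed = seed + r)
    fit_cfg <- mcmc
    fit_cfg$seed <- seed + 1000L + r
    fit <- sample_posterior(sim$data,
      structure = structure_fit, config = fit_cfg,
      log_traits = config$log_traits
    )
    td <- tidy(fit)
    td <- td[td$term %in% names(truth_beta), ]
    tibble::tibble(
      replicate = r, coefficient = td$term,
      true = truth_beta[td$term], estimate = td$estimate,
      conf.low = td$conf.low, conf.high = td$conf.high,
      covered = td$conf.low <= truth_beta[td$term] &
        truth_beta[td$term] <= td$conf.high,
      converged = fit$converged
    )
  })
  summary <- detail |>
    dplyr::group_by(.data$coefficient) |>
    dplyr::summarise(
      true = .data$true[1],
      bias = mean(.data$estimate - .data$true),
      rmse = sqrt(mean((.data$estimate - .data$true)^2)),
      coverage = mean(.data$covered),
      n_converged = sum(.data$converged),
      .groups = "drop"
    )
  structure(list(summary = summary, detail = detail), class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat("<recovery_experiment>", max(x$detail$replicate), "replicates\n")
  print(x$summary)
  invisible(x)
}

get_eco <- function(config, ecosystem) {
  stopifnot(inherits(config, "simulation_config"))
  eco <- config$ecosystems[[ecosystem]]
  if (is.null(eco)) stop(sprintf("Unknown ecosystem '%s'.", ecosystem), call. = FALSE)
  eco
}

species_ids <- function(eco, n) sprintf("%s_sp%02d", eco, seq_len(n))
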