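#' Define which traits predict which growth parameters
#'
#' A trait structure maps each Hillslope growth parameter (`alpha`, `b`,
#' `c`) to the (possibly empty) set of traits whose standardized values
#' enter its log-linear sub-model. An empty structure everywhere is the
#' no-trait baseline model, in which each species' log parameter is a grand
#' mean plus a species random effect.
#'
#' @param alpha,b,c Character vectors of trait names (subset of
#'   [trait_names()]).
#' @return An object of class `trait_structure`.
#' @examples
#' trait_structure(alpha = "sla", b = "leaf_n", c = "seed_mass")
#' trait_structure() # no-trait baseline
#' @export
trait_structure <- function(alpha = character(0), b = character(0), c = character(0)) {
  parts <- list(alpha = alpha, b = b, c = c)
  for (p in names(parts)) {
    parts[[p]] <- sort(unique(as.character(parts[[p]])))
    bad <- setdiff(parts[[p]], trait_names())
    if (length(bad)) {
      stop(sprintf(
        "Unknown trait(s) for %s: %s", p, paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
  }
  structure(parts, class = "trait_structure")
}

#' The full candidate structure: every trait on every growth parameter
#' @return A `trait_structure` with all 4 traits predicting all 3 parameters.
#' @export
full_trait_structure <- function() {
  trait_structure(alpha = trait_names(), b = trait_names(), c = trait_names())
}

#' @export
print.trait_structure <- function(x, ...) {
  cat("<trait_structure>\n")
  for (p in c("alpha", "b", "c")) {
    cat(sprintf(
      "  %s ~ %s\n", p,
      if (length(x[[p]])) paste(x[[p]], collapse = " + ") else "1 (intercept only)"
    ))
  }
  invisible(x)
}

#' Enumerate the active slopes of a trait structure
#' @param structure A `trait_structure`.
#' @return A tibble with columns `parameter`, `trait` (zero rows if empty).
#' @export
structure_slopes <- function(structure) {
  stopifnot(inherits(structure, "trait_structure"))
  purrr::map_dfr(c("alpha", "b", "c"), function(p) {
    if (length(structure[[p]]) == 0) {
      return(tibble::tibble(parameter = character(0), trait = character(0)))
    }
    tibble::tibble(parameter = p, trait = structure[[p]])
  })
}

#' Remove one trait slope from a structure
#' @param structure A `trait_structure`.
#' @param parameter One of `"alpha"`, `"b"`, `"c"`.
#' @param trait A trait name currently active for that parameter.
#' @return The reduced `trait_structure`.
#' @export
drop_slope <- function(structure, parameter, trait) {
  stopifnot(inherits(structure, "trait_structure"))
  if (!trait %in% structure[[parameter]]) {
    stop(sprintf("Slope %s -> %s is not in the structure.", trait, parameter),
      call. = FALSE
    )
  }
  structure[[parameter]] <- setdiff(structure[[parameter]], trait)
  trait_structure(
    alpha = structure$alpha, b = structure$b,
    c = structure$c
  )
}

is_empty_structure <- function(structure) {
  nrow(structure_slopes(structure)) == 0
}

#' MCMC run settings
#'
#' @param chains Number of chains (at least 2; 3 by default so the
#'   between-chain diagnostic is well supported).
#' @param iterations Total iterations per chain, including burn-in.
#' @param burnin Iterations discarded as burn-in (default half).
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param seed Integer seed; the entire run is reproducible from it.
#' @param jitter_sd Log-scale sd of the multiplicative over-dispersion noise
#'   applied to each chain's initial values.
#' @param prior_beta_sd Prior sd of the sub-model coefficients. The default
#'   100 corresponds to a vague Normal prior with precision 1e-4.
#' @param prior_scale_cauchy Half-Cauchy prior scale for all standard
#'   deviations (observation, random effects, ecosystem offsets).
#' @param adapt_batch Proposal step sizes adapt every this many iterations
#'   during burn-in (frozen afterwards).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3, iterations = 20000, burnin = floor(iterations / 2),
                        thin = 10, seed = 1L, jitter_sd = 0.2,
                        prior_beta_sd = 100, prior_scale_cauchy = 25,
                        adapt_batch = 50) {
  stopifnot(
    chains >= 2, iterations > burnin, burnin >= 0, thin >= 1,
    jitter_sd >= 0, prior_beta_sd > 0, prior_scale_cauchy > 0
  )
  structure(
    list(
      chains = as.integer(chains), iterations = as.integer(iterations),
      burnin = as.integer(burnin), thin = as.integer(thin),
      seed = as.integer(seed), jitter_sd = jitter_sd,
      prior_beta_sd = prior_beta_sd, prior_scale_cauchy = prior_scale_cauchy,
      adapt_batch = as.integer(adapt_batch)
    ),
    class = "mcmc_config"
  )
}
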