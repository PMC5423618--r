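# Internal representation of one model fit: observation vectors aligned to a
# sorted species index, plus the per-parameter design matrices implied by a
# trait structure (and, for the ensemble model, ecosystem offset columns).

gp_names <- c("alpha", "b", "c")

build_model_frame <- function(data, structure, log_traits = character(0),
                              ensemble = FALSE) {
  stopifnot(inherits(data, "growth_data"), inherits(structure, "trait_structure"))
  if (length(data$underidentified)) {
    stop(sprintf(
      "Cannot fit: species with fewer than 2 distinct ages present (%s). Remove them first.",
      paste(data$underidentified, collapse = ", ")
    ), call. = FALSE)
  }
  heights <- data$heights
  # fit only species that have height observations, in sorted order
  # (with no observations at all — prior-only evaluation — use the traits)
  sp_src <- if (nrow(heights) > 0) heights else data$traits
  sp_eco <- sp_src |>
    dplyr::distinct(.data$species, .data$ecosystem) |>
    dplyr::arrange(.data$species, .data$ecosystem)
  if (anyDuplicated(sp_eco$species)) {
    stop("The same species identifier appears in more than one ecosystem; make identifiers ecosystem-unique before fitting.",
      call. = FALSE
    )
  }
  species <- sp_eco$species
  traits <- data$traits |>
    dplyr::semi_join(sp_eco, by = c("species", "ecosystem")) |>
    dplyr::arrange(.data$species)
  stats <- trait_stats(traits, log_traits = log_traits)
  z <- standardize_traits(traits, stats)
  ecosystems <- sort(unique(sp_eco$ecosystem))
  jidx <- match(heights$species, species)
  X <- list()
  prior_kind <- list() # "beta" or "delta" per column, for prior precision
  for (p in gp_names) {
    cols <- list(rep(1, length(species)))
    nms <- paste0("beta0_", p)
    for (tr in structure[[p]]) {
      cols <- c(cols, list(z[[tr]]))
      nms <- c(nms, paste0("beta_", p, "_", tr))
    }
    kind <- rep("beta", length(nms))
    if (ensemble) {
      for (eco in ecosystems) {
        cols <- c(cols, list(as.numeric(sp_eco$ecosystem == eco)))
        nms <- c(nms, paste0("delta_", p, "_", eco))
        kind <- c(kind, "delta")
      }
    }
    Xp <- do.call(cbind, cols)
    colnames(Xp) <- nms
    X[[p]] <- Xp
    prior_kind[[p]] <- kind
  }
  list(
    species = species, species_eco = sp_eco$ecosystem, ecosystems = ecosystems,
    n_species = length(species), n_obs = nrow(heights),
    logH = log(heights$height_cm), T = heights$age_yrs, jidx = jidx,
    X = X, prior_kind = prior_kind, stats = stats, z = z,
    structure = structure, ensemble = ensemble, heights = heights
  )
}

# log-median height for every observation given log-scale species parameters
compute_logmu <- function(u_alpha, b_nat, c_nat, jidx, T) {
  u_alpha[jidx] + stats::plogis(b_nat[jidx] * (T - c_nat[jidx]), log.p = TRUE)
}

# half-Cauchy(0, scale) log density for x > 0
lhalf_cauchy <- function(x, scale) {
  ifelse(x > 0, log(2) + stats::dcauchy(x, 0, scale, log = TRUE), -Inf)
}

#' Joint log-posterior density of the hierarchical growth model
#'
#' Assembles, term by term, the unnormalised log-posterior: the lognormal
#' observation log-likelihood summed over individuals, Normal log-densities
#' of the species random effects, vague Normal priors on all sub-model
#' coefficients, and half-Cauchy priors on every standard deviation. Useful
#' for testing and for diagnostics; the sampler targets the same density (up
#' to an additive constant).
#'
#' @param data A [growth_data()] object (a single ecosystem unless
#'   `ensemble = TRUE`).
#' @param structure A [trait_structure()].
#' @param state A named list with elements `log_alpha`, `log_b`, `log_c`
#'   (numeric vectors over species, sorted by species name), `beta` (list
#'   `alpha`/`b`/`c` of coefficient vectors matching the design: intercept,
#'   then one slope per structure trait in sorted order, then — for ensemble
#'   fits — one offset per ecosystem), `re_sd` (named vector), `sigma`
#'   (scalar), and for ensemble fits `sd_site` (named vector).
#' @param log_traits Traits log-transformed before standardization.
#' @param ensemble Include per-ecosystem intercept offsets.
#' @param prior_beta_sd,prior_scale_cauchy Prior settings (see
#'   [mcmc_config()]).
#' @return A single finite number for any interior state.
#' @export
log_posterior <- function(data, structure, state, log_traits = character(0),
                          ensemble = FALSE, prior_beta_sd = 100,
                          prior_scale_cauchy = 25) {
  mf <- build_model_frame(data, structure, log_traits, ensemble)
  J <- mf$n_species
  for (nm in c("log_alpha", "log_b", "log_c")) {
    if (length(state[[nm]]) != J) {
      stop(sprintf("`state$%s` must have length %d (one per species).", nm, J),
        call. = FALSE
      )
    }
  }
  lp <- 0
  u <- list(
    alpha = state$log_alpha, b = state$log_b, c = state$log_c
  )
  for (p in gp_names) {
    beta <- state$beta[[p]]
    if (length(beta) != ncol(mf$X[[p]])) {
      stop(sprintf(
        "`state$beta$%s` must have length %d (columns: %s).",
        p, ncol(mf$X[[p]]), paste(colnames(mf$X[[p]]), collapse = ", ")
      ), call. = FALSE)
    }
    m <- drop(mf$X[[p]] %*% beta)
    eps <- u[[p]] - m
    lp <- lp + sum(stats::dnorm(eps, 0, state$re_sd[[p]], log = TRUE))
    is_beta <- mf$prior_kind[[p]] == "beta"
    lp <- lp + sum(stats::dnorm(beta[is_beta], 0, prior_beta_sd, log = TRUE))
    if (ensemble) {
      lp <- lp + sum(stats::dnorm(beta[!is_beta], 0, state$sd_site[[p]], log = TRUE))
      lp <- lp + lhalf_cauchy(state$sd_site[[p]], prior_scale_cauchy)
    }
    lp <- lp + lhalf_cauchy(state$re_sd[[p]], prior_scale_cauchy)
  }
  if (mf$n_obs > 0) {
    logmu <- compute_logmu(u$alpha, exp(u$b), exp(u$c), mf$jidx, mf$T)
    lp <- lp + sum(lognormal_loglik(exp(mf$logH), exp(logmu), state$sigma))
  }
  lp + lhalf_cauchy(state$sigma, prior_scale_cauchy)
}

#' Deterministic initial values from single-species curve fits
#'
#' Fits the Hillslope curve to each species' log heights by least squares
#' (Nelder-Mead over the log-scale parameters). Species with fewer than 3
#' observations or fewer than 2 distinct ages fall back to a heuristic:
#' `alpha = 1.1 * max height`, `c = median age`, `b = 4 * max height /
#' (alpha * age range)`. The result is deterministic given the dataset.
#'
#' @param data A [growth_data()] object.
#' @return A tibble `species`, `alpha`, `b`, `c`, `method`
#'   (`"ls"` or `"heuristic"`).
#' @export
init_from_single_species <- function(data) {
  stopifnot(inherits(data, "growth_data"))
  heights <- data$heights
  species <- sort(unique(heights$species))
  purrr::map_dfr(species, function(sp) {
    obs <- heights[heights$species == sp, ]
    h <- obs$height_cm
    t <- obs$age_yrs
    maxh <- max(h)
    rng <- diff(range(t))
    alpha0 <- 1.1 * maxh
    c0 <- max(stats::median(t), 0.1)
    b0 <- min(max(4 * maxh / (alpha0 * max(rng, 1)), 0.01), 20)
    method <- "heuristic"
    par <- log(c(alpha0, b0, c0))
    if (nrow(obs) >= 3 && length(unique(t)) >= 2) {
      ssr <- function(q) {
        lm <- q[1] + stats::plogis(exp(q[2]) * (t - exp(q[3])), log.p = TRUE)
        sum((log(h) - lm)^2)
      }
      fit <- stats::optim(par, ssr,
        method = "Nelder-Mead",
        control = list(maxit = 2000, reltol = 1e-12)
      )
      # polish: a second restart from the first solution tightens convergence
      fit <- stats::optim(fit$par, ssr,
        method = "Nelder-Mead",
        control = list(maxit = 2000, reltol = 1e-12)
      )
      if (is.finite(fit$value)) {
        par <- fit$par
        method <- "ls"
      }
    } else {
      warning(sprintf(
        "Species '%s' has too few observations/ages for a curve fit; using heuristic initial values.",
        sp
      ))
    }
    tibble::tibble(
      species = sp, alpha = exp(par[1]), b = exp(par[2]), c = exp(par[3]),
      method = method
    )
  })
}
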