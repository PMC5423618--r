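# Adaptive random-walk Metropolis-within-Gibbs for the hierarchical growth
# model. Species-level log parameters are updated jointly across species in
# one vectorised Metropolis step per growth parameter (species are
# conditionally independent given the hyperparameters), the sub-model
# coefficients get an exact conjugate multivariate-normal Gibbs draw, and the
# standard deviations get log-scale random-walk steps. Proposal scales adapt
# in batches during burn-in only, then freeze.

#' Draw posterior samples for the hierarchical growth model
#'
#' Fits the full hierarchical model to a single ecosystem: lognormal heights
#' around species Hillslope curves whose log parameters are log-linear in
#' standardized traits plus species random effects (the no-trait baseline is
#' the empty [trait_structure()]). Chains start from over-dispersed jitter
#' around [init_from_single_species()] and the whole run is reproducible
#' from `config$seed`.
#'
#' @param data A [growth_data()] object containing exactly one ecosystem.
#' @param structure A [trait_structure()] (default: no traits).
#' @param config An [mcmc_config()].
#' @param log_traits Traits to log-transform before standardization.
#' @param fixed Named list pinning quantities at fixed values instead of
#'   sampling them: any of `sigma`, `re_sd` (named, possibly partial),
#'   `beta` (list per parameter, full coefficient vectors), `log_alpha`,
#'   `log_b`, `log_c` (per-species vectors or scalars). Intended for
#'   degenerate-case testing and conditional analyses.
#' @return A `growth_draws` object: an `iterations x chains x quantities`
#'   array of retained draws, plus standardization statistics, the
#'   structure, the per-quantity Brooks-Gelman-Rubin diagnostic, and a
#'   `converged` flag (all monitored R-hat at or below 1.1). A
#'   non-converged fit is returned with a prominent warning, never silently.
#' @export
sample_posterior <- function(data, structure = trait_structure(),
                             config = mcmc_config(), log_traits = character(0),
                             fixed = list()) {
  stopifnot(inherits(data, "growth_data"))
  if (length(unique(data$heights$ecosystem)) != 1) {
    stop("`sample_posterior()` fits a single ecosystem; use `fit_ensemble()` for several.",
      call. = FALSE
    )
  }
  fit_hierarchical(data, structure, config, log_traits, fixed, ensemble = FALSE)
}

#' Fit the ensemble model across several ecosystems
#'
#' The same hierarchical model fitted jointly to two or more ecosystems,
#' with each growth parameter's intercept allowed to vary by ecosystem:
#' `beta0` becomes `beta0 + delta_s` with `delta_s ~ Normal(0, sd_site)` and
#' a half-Cauchy prior on each `sd_site`. Traits are standardized on the
#' pooled trait table.
#'
#' @inheritParams sample_posterior
#' @param data A [growth_data()] covering at least two ecosystems.
#' @return A `growth_draws` object (with `delta_*` and `sd_site_*`
#'   quantities).
#' @export
fit_ensemble <- function(data, structure = trait_structure(),
                         config = mcmc_config(), log_traits = character(0),
                         fixed = list()) {
  stopifnot(inherits(data, "growth_data"))
  if (length(unique(data$heights$ecosystem)) < 2) {
    stop("`fit_ensemble()` needs at least two ecosystems; use `sample_posterior()` for one.",
      call. = FALSE
    )
  }
  fit_hierarchical(data, structure, config, log_traits, fixed, ensemble = TRUE)
}

fit_hierarchical <- function(data, structure, config, log_traits, fixed, ensemble) {
  stopifnot(inherits(config, "mcmc_config"))
  mf <- build_model_frame(data, structure, log_traits, ensemble)
  if (mf$n_obs == 0) stop("No height observations to fit.", call. = FALSE)
  init <- suppressWarnings(init_from_single_species(data))
  init <- init[match(mf$species, init$species), ]
  base <- base_state(mf, init, config)

  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$chains)
  qn <- quantity_names(mf)
  n_keep <- length(kept_iterations(config))
  draws <- array(NA_real_, dim = c(n_keep, config$chains, length(qn)),
    dimnames = list(NULL, NULL, qn)
  )
  for (k in seq_len(config$chains)) {
    draws[, k, ] <- run_chain(mf, base, config, fixed, chain_seeds[k])
  }
  rh <- rhat_table_array(draws)
  converged <- all(rh$rhat <= 1.1, na.rm = TRUE)
  fit <- structure(
    list(
      draws = draws, species = mf$species, species_eco = mf$species_eco,
      ecosystems = mf$ecosystems, structure = structure, stats = mf$stats,
      config = config, log_traits = log_traits, ensemble = ensemble,
      fixed = fixed, init = init, rhat = rh, converged = converged,
      chain_seeds = chain_seeds
    ),
    class = "growth_draws"
  )
  if (!converged) {
    warning(sprintf(
      "MCMC did not converge: max R-hat = %.3f (threshold 1.1). Inspect `$rhat` and rerun longer.",
      max(rh$rhat, na.rm = TRUE)
    ), call. = FALSE)
  }
  fit
}

kept_iterations <- function(config) {
  it <- seq_len(config$iterations)
  it[it > config$burnin & (it - config$burnin) %% config$thin == 0]
}

quantity_names <- function(mf) {
  qn <- character(0)
  for (p in gp_names) qn <- c(qn, sprintf("%s[%s]", p, mf$species))
  for (p in gp_names) qn <- c(qn, sprintf("eps_%s[%s]", p, mf$species))
  for (p in gp_names) qn <- c(qn, colnames(mf$X[[p]]))
  qn <- c(qn, paste0("sd_eps_", gp_names))
  if (mf$ensemble) qn <- c(qn, paste0("sd_site_", gp_names))
  c(qn, "sigma")
}

# deterministic (pre-jitter) starting state shared by all chains
base_state <- function(mf, init, config) {
  u <- list(alpha = log(init$alpha), b = log(init$b), c = log(init$c))
  beta <- list()
  re_sd <- c(alpha = NA_real_, b = NA_real_, c = NA_real_)
  for (p in gp_names) {
    X <- mf$X[[p]]
    # ridge-regularised LS keeps the init well-defined when ensemble offset
    # columns make X rank deficient
    bt <- solve(crossprod(X) + diag(0.01, ncol(X)), crossprod(X, u[[p]]))
    beta[[p]] <- drop(bt)
    names(beta[[p]]) <- colnames(X)
    re_sd[[p]] <- max(stats::sd(u[[p]] - drop(X %*% bt)), 0.05)
  }
  logmu <- compute_logmu(u$alpha, exp(u$b), exp(u$c), mf$jidx, mf$T)
  sigma <- max(stats::sd(mf$logH - logmu), 0.05)
  list(u = u, beta = beta, re_sd = re_sd, sigma = sigma, sd_site = c(alpha = 0.5, b = 0.5, c = 0.5))
}

run_chain <- function(mf, base, config, fixed, chain_seed) {
  set.seed(chain_seed)
  J <- mf$n_species
  u <- base$u
  beta <- base$beta
  re_sd <- base$re_sd
  sigma <- base$sigma
  sd_site <- base$sd_site

  fix_u <- list(
    alpha = fixed$log_alpha, b = fixed$log_b, c = fixed$log_c
  )
  for (p in gp_names) {
    if (!is.null(fix_u[[p]])) u[[p]] <- rep_len(as.numeric(fix_u[[p]]), J)
    if (!is.null(fixed$beta[[p]])) {
      if (length(fixed$beta[[p]]) != ncol(mf$X[[p]])) {
        stop(sprintf("fixed$beta$%s must have length %d.", p, ncol(mf$X[[p]])), call. = FALSE)
      }
      beta[[p]] <- as.numeric(fixed$beta[[p]])
    }
    if (!is.null(fixed$re_sd) && !is.na(fixed$re_sd[p])) re_sd[[p]] <- fixed$re_sd[[p]]
    if (!is.null(fixed$sd_site) && !is.na(fixed$sd_site[p])) sd_site[[p]] <- fixed$sd_site[[p]]
  }
  if (!is.null(fixed$sigma)) sigma <- fixed$sigma

  upd_u <- purrr::map_lgl(fix_u, is.null)
  upd_beta <- purrr::map_lgl(gp_names, ~ is.null(fixed$beta[[.x]]))
  names(upd_beta) <- gp_names
  upd_re <- purrr::map_lgl(gp_names, ~ is.null(fixed$re_sd) || is.na(fixed$re_sd[.x]))
  names(upd_re) <- gp_names
  upd_sig <- is.null(fixed$sigma)
  upd_site <- mf$ensemble &
    stats::setNames(purrr::map_lgl(
      gp_names,
      ~ is.null(fixed$sd_site) || is.na(fixed$sd_site[.x])
    ), gp_names)

  # over-dispersed jitter (only on quantities that are actually sampled)
  jit <- config$jitter_sd
  for (p in gp_names) {
    if (upd_u[[p]]) u[[p]] <- u[[p]] + stats::rnorm(J, 0, jit)
    if (upd_beta[[p]]) beta[[p]] <- beta[[p]] + stats::rnorm(length(beta[[p]]), 0, jit)
    if (upd_re[[p]]) re_sd[[p]] <- re_sd[[p]] * exp(stats::rnorm(1, 0, jit))
  }
  if (upd_sig) sigma <- sigma * exp(stats::rnorm(1, 0, jit))

  bn <- exp(u$b)
  cn <- exp(u$c)
  logmu <- compute_logmu(u$alpha, bn, cn, mf$jidx, mf$T)
  ssr_j <- drop(rowsum((mf$logH - logmu)^2, mf$jidx))
  m <- purrr::map(gp_names, ~ drop(mf$X[[.x]] %*% beta[[.x]]))
  names(m) <- gp_names

  prior_prec <- purrr::map(gp_names, function(p) {
    pp <- ifelse(mf$prior_kind[[p]] == "beta",
      1 / config$prior_beta_sd^2, 1 / sd_site[[p]]^2
    )
    pp
  })
  names(prior_prec) <- gp_names
  XtX <- purrr::map(mf$X, crossprod)

  step_u <- purrr::map(gp_names, ~ rep(0.15, J))
  names(step_u) <- gp_names
  step_sc <- c(
    sd_eps_alpha = 0.4, sd_eps_b = 0.4, sd_eps_c = 0.4, sigma = 0.15,
    sd_site_alpha = 0.6, sd_site_b = 0.6, sd_site_c = 0.6
  )
  acc_u <- purrr::map(gp_names, ~ numeric(J))
  names(acc_u) <- gp_names
  acc_sc <- step_sc * 0
  batch <- 0L

  kept <- kept_iterations(config)
  out <- matrix(NA_real_, length(kept), length(quantity_names(mf)))
  keep_row <- 0L
  scale25 <- config$prior_scale_cauchy

  for (it in seq_len(config$iterations)) {
    # --- species-level log parameters, one vectorised MH step per parameter
    for (p in gp_names) {
      if (!upd_u[[p]]) next
      prop <- u[[p]] + step_u[[p]] * stats::rnorm(J)
      up <- u
      up[[p]] <- prop
      logmu_p <- compute_logmu(
        up$alpha,
        if (p == "b") exp(prop) else bn,
        if (p == "c") exp(prop) else cn,
        mf$jidx, mf$T
      )
      ssr_p <- drop(rowsum((mf$logH - logmu_p)^2, mf$jidx))
      dlp <- -0.5 / sigma^2 * (ssr_p - ssr_j) +
        stats::dnorm(prop, m[[p]], re_sd[[p]], log = TRUE) -
        stats::dnorm(u[[p]], m[[p]], re_sd[[p]], log = TRUE)
      acc <- log(stats::runif(J)) < dlp
      if (any(acc)) {
        u[[p]][acc] <- prop[acc]
        if (p == "b") bn <- exp(u$b)
        if (p == "c") cn <- exp(u$c)
        logmu <- compute_logmu(u$alpha, bn, cn, mf$jidx, mf$T)
        ssr_j <- drop(rowsum((mf$logH - logmu)^2, mf$jidx))
      }
      acc_u[[p]] <- acc_u[[p]] + acc
    }
    # --- sub-model coefficients: exact conjugate Gibbs draw
    for (p in gp_names) {
      if (!upd_beta[[p]]) next
      Q <- XtX[[p]] / re_sd[[p]]^2 + diag(prior_prec[[p]], ncol(mf$X[[p]]))
      ch <- chol(Q)
      rhs <- crossprod(mf$X[[p]], u[[p]]) / re_sd[[p]]^2
      mean_b <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
      beta[[p]] <- drop(mean_b + backsolve(ch, stats::rnorm(ncol(mf$X[[p]]))))
      m[[p]] <- drop(mf$X[[p]] %*% beta[[p]])
    }
    # --- random-effect sds, log-scale random walk with half-Cauchy prior
    for (p in gp_names) {
      if (!upd_re[[p]]) next
      eps <- u[[p]] - m[[p]]
      nm <- paste0("sd_eps_", p)
      prop <- re_sd[[p]] * exp(step_sc[[nm]] * stats::rnorm(1))
      dlp <- sum(stats::dnorm(eps, 0, prop, log = TRUE)) -
        sum(stats::dnorm(eps, 0, re_sd[[p]], log = TRUE)) +
        lhalf_cauchy(prop, scale25) - lhalf_cauchy(re_sd[[p]], scale25) +
        log(prop) - log(re_sd[[p]])
      if (log(stats::runif(1)) < dlp) {
        re_sd[[p]] <- prop
        acc_sc[[nm]] <- acc_sc[[nm]] + 1
      }
    }
    # --- ecosystem-offset sds (ensemble only)
    if (mf$ensemble) {
      for (p in gp_names) {
        if (!upd_site[[p]]) next
        is_delta <- mf$prior_kind[[p]] == "delta"
        delta <- beta[[p]][is_delta]
        nm <- paste0("sd_site_", p)
        prop <- sd_site[[p]] * exp(step_sc[[nm]] * stats::rnorm(1))
        dlp <- sum(stats::dnorm(delta, 0, prop, log = TRUE)) -
          sum(stats::dnorm(delta, 0, sd_site[[p]], log = TRUE)) +
          lhalf_cauchy(prop, scale25) - lhalf_cauchy(sd_site[[p]], scale25) +
          log(prop) - log(sd_site[[p]])
        if (log(stats::runif(1)) < dlp) {
          sd_site[[p]] <- prop
          acc_sc[[nm]] <- acc_sc[[nm]] + 1
        }
        prior_prec[[p]][is_delta] <- 1 / sd_site[[p]]^2
      }
    }
    # --- observation sd
    if (upd_sig) {
      prop <- sigma * exp(step_sc[["sigma"]] * stats::rnorm(1))
      stot <- sum(ssr_j)
      N <- mf$n_obs
      dlp <- (-N * log(prop) - stot / (2 * prop^2)) -
        (-N * log(sigma) - stot / (2 * sigma^2)) +
        lhalf_cauchy(prop, scale25) - lhalf_cauchy(sigma, scale25) +
        log(prop) - log(sigma)
      if (log(stats::runif(1)) < dlp) {
        sigma <- prop
        acc_sc[["sigma"]] <- acc_sc[["sigma"]] + 1
      }
    }
    # --- batch adaptation during burn-in
    if (it <= config$burnin && it %% config$adapt_batch == 0) {
      batch <- batch + 1L
      d <- min(0.1, 1 / sqrt(batch))
      for (p in gp_names) {
        rate <- acc_u[[p]] / config$adapt_batch
        step_u[[p]] <- step_u[[p]] * exp(ifelse(rate > 0.44, d, -d))
        acc_u[[p]][] <- 0
      }
      rate_sc <- acc_sc / config$adapt_batch
      step_sc <- step_sc * exp(ifelse(rate_sc > 0.44, d, -d))
      acc_sc[] <- 0
    }
    # --- storage
    if (it > config$burnin && (it - config$burnin) %% config$thin == 0) {
      keep_row <- keep_row + 1L
      row <- c(
        exp(u$alpha), exp(u$b), exp(u$c),
        u$alpha - m$alpha, u$b - m$b, u$c - m$c,
        beta$alpha, beta$b, beta$c,
        re_sd[["alpha"]], re_sd[["b"]], re_sd[["c"]]
      )
      if (mf$ensemble) row <- c(row, sd_site[["alpha"]], sd_site[["b"]], sd_site[["c"]])
      out[keep_row, ] <- c(row, sigma)
    }
  }
  out
}
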