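# Model checking and comparison: DIC, observed-vs-predicted R^2, multilevel
# (Gelman) R^2 and pooling factors for the trait sub-models, backward
# selection over trait->parameter maps, and CI-overlap screening.

# align a dataset's observations with a fit's species index
obs_index <- function(fit, data) {
  stopifnot(inherits(data, "growth_data"))
  heights <- data$heights
  jidx <- match(heights$species, fit$species)
  if (anyNA(jidx)) {
    stop("Dataset contains species absent from the fit.", call. = FALSE)
  }
  list(heights = heights, jidx = jidx)
}

# lognormal observation log-likelihood for every retained draw (vector, one
# element per draw, summed over observations)
obs_loglik_draws <- function(fit, data) {
  oi <- obs_index(fit, data)
  A <- species_param_draws(fit, "alpha")
  B <- species_param_draws(fit, "b")
  C <- species_param_draws(fit, "c")
  sig <- sigma_draws(fit)
  D <- nrow(A)
  ll <- rep(0, D)
  logH <- log(oi$heights$height_cm)
  for (j in seq_along(fit$species)) {
    idx <- which(oi$jidx == j)
    if (!length(idx)) next
    tj <- oi$heights$age_yrs[idx]
    lh <- logH[idx]
    M <- log(A[, j]) + stats::plogis(outer(B[, j], tj) - B[, j] * C[, j], log.p = TRUE)
    R <- sweep(M, 2, lh)
    nj <- length(idx)
    ll <- ll - nj * log(sig) - rowSums(R^2) / (2 * sig^2) -
      nj * 0.5 * log(2 * pi) - sum(lh)
  }
  ll
}

obs_loglik_point <- function(fit, data, a_bar, b_bar, c_bar, sig_bar) {
  oi <- obs_index(fit, data)
  mu <- hillslope_height(
    a_bar[oi$jidx], b_bar[oi$jidx], c_bar[oi$jidx], oi$heights$age_yrs
  )
  sum(lognormal_loglik(oi$heights$height_cm, mu, sig_bar))
}

#' Deviance Information Criterion for a fitted growth model
#'
#' Spiegelhalter's form: with deviance \eqn{D(\theta) = -2 \log L(\theta)},
#' `DIC = Dbar + pD` where `Dbar` is the posterior mean deviance and
#' `pD = Dbar - D(theta_bar)` the effective number of parameters. The
#' plug-in point `theta_bar` is the posterior mean on the log scale of the
#' species growth parameters and of the observation sd.
#'
#' @param fit A `growth_draws` object.
#' @param data The [growth_data()] the model was fitted to.
#' @return A one-row tibble: `dic`, `p_d`, `d_bar`, `d_hat`.
#' @export
dic <- function(fit, data) {
  stopifnot(inherits(fit, "growth_draws"))
  ll <- obs_loglik_draws(fit, data)
  d_bar <- mean(-2 * ll)
  a_bar <- exp(colMeans(species_param_draws(fit, "alpha", log_scale = TRUE)))
  b_bar <- exp(colMeans(species_param_draws(fit, "b", log_scale = TRUE)))
  c_bar <- exp(colMeans(species_param_draws(fit, "c", log_scale = TRUE)))
  sig_bar <- exp(mean(log(sigma_draws(fit))))
  d_hat <- -2 * obs_loglik_point(fit, data, a_bar, b_bar, c_bar, sig_bar)
  p_d <- d_bar - d_hat
  tibble::tibble(dic = d_bar + p_d, p_d = p_d, d_bar = d_bar, d_hat = d_hat)
}

#' Observed vs predicted heights per individual
#'
#' @param fit A `growth_draws` object.
#' @param data The fitted [growth_data()].
#' @return A tibble `individual_id`, `species`, `age_yrs`, `observed`,
#'   `predicted` (posterior-median expected height).
#' @export
predicted_heights <- function(fit, data) {
  oi <- obs_index(fit, data)
  A <- species_param_draws(fit, "alpha")
  B <- species_param_draws(fit, "b")
  C <- species_param_draws(fit, "c")
  pred <- numeric(nrow(oi$heights))
  for (j in seq_along(fit$species)) {
    idx <- which(oi$jidx == j)
    if (!length(idx)) next
    tj <- oi$heights$age_yrs[idx]
    M <- log(A[, j]) + stats::plogis(outer(B[, j], tj) - B[, j] * C[, j], log.p = TRUE)
    pred[idx] <- exp(apply(M, 2, stats::median))
  }
  tibble::tibble(
    individual_id = oi$heights$individual_id,
    species = oi$heights$species,
    age_yrs = oi$heights$age_yrs,
    observed = oi$heights$height_cm,
    predicted = pred
  )
}

#' Squared Pearson correlation between observed and predicted heights
#'
#' @inheritParams predicted_heights
#' @return A single number in `[0, 1]`.
#' @export
obs_pred_r2 <- function(fit, data) {
  ph <- predicted_heights(fit, data)
  if (nrow(ph) < 3) stop("Need at least 3 individuals for R^2.", call. = FALSE)
  stats::cor(ph$observed, ph$predicted)^2
}

#' Trait-level R-squared: what the traits alone explain
#'
#' Like [obs_pred_r2()], but the predicted height for each individual is the
#' posterior-median of the curve implied by the *trait sub-models only* —
#' species random effects set to zero — so the statistic measures how much
#' of the observed height variation the traits themselves account for. The
#' correlation is computed on the log scale, the model's residual scale, so
#' short fast-growing species weigh as much as tall ones.
#'
#' This is the default score for [backward_selection()]: unlike the full
#' posterior-median predictions (whose in-sample correlation is dominated by
#' the species-level fit and therefore insensitive to the trait structure),
#' it falls sharply when an informative trait slope is removed.
#'
#' @inheritParams predicted_heights
#' @return A single number in `[0, 1]`.
#' @export
trait_level_r2 <- function(fit, data) {
  oi <- obs_index(fit, data)
  if (nrow(oi$heights) < 3) stop("Need at least 3 individuals for R^2.", call. = FALSE)
  z <- standardize_traits(
    data$traits[match(fit$species, data$traits$species), ], fit$stats
  )
  lp <- list()
  for (p in gp_names) {
    bd <- beta_draws(fit, p)
    X <- cbind(1, as.matrix(z[fit$structure[[p]]]))
    lp[[p]] <- bd %*% t(X) # D x J log-parameters at eps = 0
  }
  pred <- numeric(nrow(oi$heights))
  for (j in seq_along(fit$species)) {
    idx <- which(oi$jidx == j)
    if (!length(idx)) next
    tj <- oi$heights$age_yrs[idx]
    Bj <- exp(lp$b[, j])
    M <- lp$alpha[, j] + stats::plogis(outer(Bj, tj) - Bj * exp(lp$c[, j]), log.p = TRUE)
    pred[idx] <- apply(M, 2, stats::median)
  }
  stats::cor(log(oi$heights$height_cm), pred)^2
}

#' Multilevel (Gelman) R-squared for one trait sub-model
#'
#' The proportion of species-level variance in a log growth parameter
#' explained by its trait predictors:
#' \deqn{R^2 = 1 - E_d[V_j(\epsilon_{j})] / E_d[V_j(\log \theta_j)],}
#' averaging the finite-sample variances across species over posterior
#' draws. Defined only when the sub-model has at least one trait.
#'
#' @param fit A `growth_draws` object from a trait model.
#' @param parameter One of `"alpha"`, `"b"`, `"c"`.
#' @return A number, near 1 when traits explain almost all between-species
#'   variation (can dip slightly outside `[0, 1]` through Monte Carlo
#'   error).
#' @export
gelman_r2_submodel <- function(fit, parameter) {
  check_submodel(fit, parameter)
  E <- eps_draws(fit, parameter)
  U <- species_param_draws(fit, parameter, log_scale = TRUE)
  1 - mean(apply(E, 1, stats::var)) / mean(apply(U, 1, stats::var))
}

#' Pooling factor for one trait sub-model
#'
#' \deqn{\lambda = 1 - V_j(E_d[\epsilon_j]) / E_d[V_j(\epsilon_j)]:}
#' near 1 means the species random effects are strongly pooled toward the
#' trait-mean line (estimates dominated by the population model), near 0
#' means they are dominated by each species' own data.
#'
#' @inheritParams gelman_r2_submodel
#' @return A number (in `[0, 1]` up to Monte Carlo error).
#' @export
pooling_factor <- function(fit, parameter) {
  check_submodel(fit, parameter)
  E <- eps_draws(fit, parameter)
  1 - stats::var(colMeans(E)) / mean(apply(E, 1, stats::var))
}

check_submodel <- function(fit, parameter) {
  stopifnot(inherits(fit, "growth_draws"))
  parameter <- match.arg(parameter, gp_names)
  if (length(fit$structure[[parameter]]) == 0) {
    stop(sprintf(
      "No trait sub-model for '%s' (no-trait model): statistic undefined.", parameter
    ), call. = FALSE)
  }
  invisible(parameter)
}

#' Backward selection over trait -> growth-parameter slopes
#'
#' Starting from the full candidate structure, repeatedly refits the model
#' with each remaining slope removed and drops the slope whose removal
#' costs the least R^2; stops when any further drop would lower R^2 by more
#' than `tolerance`. The first trace entry is the full structure; with
#' `tolerance = Inf` selection runs to the no-trait model.
#'
#' By default candidates are scored with [trait_level_r2()] (species random
#' effects zeroed), which is sensitive to the trait structure;
#' `score = "full"` scores with [obs_pred_r2()] instead, whose in-sample
#' value is dominated by the species-level fit and barely distinguishes
#' structures.
#'
#' @param data A single-ecosystem [growth_data()].
#' @param full The starting [trait_structure()] (default: all traits on all
#'   parameters).
#' @param config An [mcmc_config()] used for every refit (the same seed is
#'   reused so candidate comparisons are paired).
#' @param tolerance Maximum acceptable R^2 loss per dropped slope
#'   (absolute; non-negative).
#' @param score `"trait"` (default, [trait_level_r2()]) or `"full"`
#'   ([obs_pred_r2()]).
#' @param log_traits Traits to log-transform before standardization.
#' @return A `selection_trace`: list with `trace` (tibble: step, dropped
#'   slope, R^2, number of slopes, structure list-column, convergence flag)
#'   and `chosen` (the selected `trait_structure`).
#' @export
backward_selection <- function(data, full = full_trait_structure(),
                               config = mcmc_config(), tolerance = 0.005,
                               score = c("trait", "full"),
                               log_traits = character(0)) {
  if (!is.numeric(tolerance) || length(tolerance) != 1 || is.na(tolerance) ||
    tolerance < 0) {
    stop("`tolerance` must be a single non-negative number.", call. = FALSE)
  }
  score <- match.arg(score)
  score_fun <- if (score == "trait") trait_level_r2 else obs_pred_r2
  fit_r2 <- function(st) {
    fit <- suppressWarnings(
      sample_posterior(data, structure = st, config = config, log_traits = log_traits)
    )
    list(r2 = score_fun(fit, data), converged = fit$converged)
  }
  cur <- full
  cur_fit <- fit_r2(cur)
  trace <- tibble::tibble(
    step = 0L, parameter = NA_character_, trait = NA_character_,
    obs_pred_r2 = cur_fit$r2, n_slopes = nrow(structure_slopes(cur)),
    structure = list(cur), converged = cur_fit$converged
  )
  step <- 0L
  repeat {
    cands <- structure_slopes(cur)
    if (nrow(cands) == 0) break
    cands <- dplyr::arrange(cands, .data$parameter, .data$trait)
    res <- purrr::map(seq_len(nrow(cands)), function(i) {
      fit_r2(drop_slope(cur, cands$parameter[i], cands$trait[i]))
    })
    r2s <- purrr::map_dbl(res, "r2")
    best <- which.max(r2s)
    drop_cost <- trace$obs_pred_r2[nrow(trace)] - r2s[best]
    if (drop_cost > tolerance) break
    step <- step + 1L
    cur <- drop_slope(cur, cands$parameter[best], cands$trait[best])
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step, parameter = cands$parameter[best], trait = cands$trait[best],
      obs_pred_r2 = r2s[best], n_slopes = nrow(structure_slopes(cur)),
      structure = list(cur), converged = res[[best]]$converged
    ))
  }
  structure(list(trace = trace, chosen = cur), class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace>\n")
  print(dplyr::select(x$trace, -"structure"))
  cat("chosen structure:\n")
  print(x$chosen)
  invisible(x)
}

#' Approximate hypothesis test from the overlap of two 95% intervals
#'
#' Compares the overlap of two 95% credible (or confidence) intervals to
#' half of the mean of their lengths: disjoint or just-touching intervals
#' reject the null of no difference at p < 0.01; an overlap shorter than
#' half the mean length rejects at p < 0.05; otherwise the difference is
#' not significant.
#'
#' @param interval_a,interval_b Numeric length-2 vectors `(lower, upper)`.
#' @return One of `"p<0.01"`, `"p<0.05"`, `"not significant"`.
#' @export
ci_overlap_test <- function(interval_a, interval_b) {
  for (iv in list(interval_a, interval_b)) {
    if (length(iv) != 2 || !all(is.finite(iv)) || iv[1] >= iv[2]) {
      stop("Each interval must be a finite length-2 vector with lower < upper.",
        call. = FALSE
      )
    }
  }
  overlap <- min(interval_a[2], interval_b[2]) - max(interval_a[1], interval_b[1])
  half_mean_len <- (diff(interval_a) + diff(interval_b)) / 4
  if (overlap <= 0) {
    "p<0.01"
  } else if (overlap < half_mean_len) {
    "p<0.05"
  } else {
    "not significant"
  }
}

#' Pairwise R-squared among species-level growth parameters
#'
#' For each fitted group (ecosystem fits and/or an ensemble fit), the
#' squared Pearson correlations between posterior-mean species-level log
#' parameters, pairwise among (alpha, b), (alpha, c) and (b, c). Pooling
#' ecosystems with contrasting parameter levels can induce cross-ecosystem
#' correlations absent within any single ecosystem.
#'
#' @param fits A named list of `growth_draws` objects.
#' @return A tibble `group`, `pair`, `r2`, `n_species`.
#' @export
parameter_pairwise_r2 <- function(fits) {
  if (inherits(fits, "growth_draws")) fits <- list(fit = fits)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("fit", seq_along(fits))
  }
  purrr::imap_dfr(fits, function(fit, nm) {
    stopifnot(inherits(fit, "growth_draws"))
    J <- length(fit$species)
    if (J < 3) stop("Need at least 3 species per group for pairwise R^2.", call. = FALSE)
    means <- purrr::map(gp_names, function(p) {
      colMeans(species_param_draws(fit, p, log_scale = TRUE))
    })
    names(means) <- gp_names
    pairs <- list(c("alpha", "b"), c("alpha", "c"), c("b", "c"))
    purrr::map_dfr(pairs, function(pr) {
      tibble::tibble(
        group = nm, pair = paste(pr, collapse = "_"),
        r2 = stats::cor(means[[pr[1]]], means[[pr[2]]])^2,
        n_species = J
      )
    })
  })
}
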