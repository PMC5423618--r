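# Out-of-sample prediction of growth trajectories for species the model has
# never seen, from their traits alone, and RMSD / mean-deviance scoring
# against reference trajectories.

#' Predict growth trajectories for new species from their traits
#'
#' For each posterior draw, the new species' traits are standardized with
#' the *training* statistics, fresh species random effects are drawn from
#' the fitted random-effect distribution (`epsilon = "draw"`, equivalent to
#' Monte Carlo imputation of the missing heights within the model), the
#' three growth parameters are formed through the trait sub-models, and the
#' Hillslope curve is evaluated on the age grid. Summaries are the
#' posterior median and central 95% band per age. `epsilon = "zero"` gives
#' the point prediction at the trait-mean line instead.
#'
#' Trait values far outside the training distribution are allowed — the
#' z-scores are never clipped — but extrapolation beyond |z| > 3 is
#' reported via a message.
#'
#' @param fit A `growth_draws` object from a trait (or no-trait) model.
#' @param new_traits Trait records for the target species (typically a
#'   different ecosystem).
#' @param ages Numeric age grid (years).
#' @param stats Training [trait_stats()]; defaults to the statistics stored
#'   in the fit (always from the training data).
#' @param epsilon `"draw"` (integrate over new-species random effects) or
#'   `"zero"` (set them to zero).
#' @param seed Optional seed for the random-effect draws.
#' @return A tibble of class `predicted_trajectory`: `species`, `age`,
#'   `height_cm` (median), `lower`, `upper`.
#' @export
predict_new_species <- function(fit, new_traits, ages, stats = fit$stats,
                                epsilon = c("draw", "zero"), seed = NULL) {
  stopifnot(inherits(fit, "growth_draws"))
  epsilon <- match.arg(epsilon)
  new_traits <- validate_traits(new_traits)
  if (!is.null(seed)) set.seed(seed)
  z <- standardize_traits(new_traits, stats)
  zmat <- as.matrix(z[trait_names()])
  if (any(abs(zmat) > 3)) {
    message(sprintf(
      "Extrapolating: %d standardized trait value(s) beyond |z| > 3 of the training data.",
      sum(abs(zmat) > 3)
    ))
  }
  S <- nrow(new_traits)
  out <- vector("list", S)
  par_draws <- vector("list", S)
  for (s in seq_len(S)) {
    logpar <- list()
    for (p in gp_names) {
      bd <- beta_draws(fit, p) # D x (1 + n_traits); excludes ensemble offsets
      x <- c(1, zmat[s, fit$structure[[p]]])
      lp <- drop(bd %*% x)
      if (epsilon == "draw") {
        lp <- lp + stats::rnorm(length(lp), 0, re_sd_draws(fit, p))
      }
      logpar[[p]] <- lp
    }
    A <- exp(logpar$alpha)
    B <- exp(logpar$b)
    C <- exp(logpar$c)
    M <- log(A) + stats::plogis(outer(B, ages) - B * C, log.p = TRUE)
    H <- exp(M)
    out[[s]] <- tibble::tibble(
      species = new_traits$species[s],
      age = ages,
      height_cm = apply(H, 2, stats::median),
      lower = apply(H, 2, stats::quantile, probs = 0.025),
      upper = apply(H, 2, stats::quantile, probs = 0.975)
    )
    par_draws[[s]] <- tibble::tibble(species = new_traits$species[s], alpha = A, b = B, c = C)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "param_draws") <- dplyr::bind_rows(par_draws)
  class(res) <- c("predicted_trajectory", class(res))
  res
}

#' Root mean squared deviance between aligned height vectors
#'
#' `sqrt(mean((predicted - reference)^2))`: a measure of prediction
#' accuracy in cm (lower is closer).
#'
#' @param predicted,reference Numeric vectors of heights (cm), aligned on
#'   the same ages.
#' @return RMSD in cm.
#' @export
rmsd <- function(predicted, reference) {
  check_aligned(predicted, reference)
  sqrt(mean((predicted - reference)^2))
}

#' Mean deviance (bias) between aligned height vectors
#'
#' `mean(predicted - reference)`: positive values report systematic
#' over-prediction, negative values under-prediction.
#'
#' @inheritParams rmsd
#' @return Signed mean deviance in cm.
#' @export
mean_deviance <- function(predicted, reference) {
  check_aligned(predicted, reference)
  mean(predicted - reference)
}

check_aligned <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stop("`predicted` and `reference` must have the same length.", call. = FALSE)
  }
  if (length(predicted) == 0) stop("Empty height vectors.", call. = FALSE)
  invisible(TRUE)
}

#' Score out-of-sample growth predictions against target-data references
#'
#' The transferability test: trait-based predictions for every target
#' species (from the training-ecosystem trait model) are scored with RMSD
#' and mean deviance against reference trajectories, and compared with the
#' predictions of the no-trait baseline model trained on the same data. By
#' default the reference per species is the posterior-median trajectory of
#' a hierarchical no-trait model fitted to the *target* data; set
#' `reference = "observed"` to score against the raw target heights at
#' their observed ages instead.
#'
#' @param trait_fit `growth_draws` from the trait model on the training
#'   ecosystem.
#' @param baseline_fit `growth_draws` from the no-trait model on the same
#'   training data.
#' @param target A [growth_data()] with the target ecosystem(s).
#' @param stats Training [trait_stats()] (default: stored in `trait_fit`).
#' @param n_ages Number of evenly spaced evaluation ages spanning each
#'   target ecosystem's observed age range (used when
#'   `reference = "fitted"`).
#' @param target_config [mcmc_config()] for the reference fits to the
#'   target data.
#' @param reference `"fitted"` (default) or `"observed"`.
#' @param seed Seed for the prediction random effects.
#' @return A tibble of class `transfer_report`: `species`, `ecosystem`,
#'   `model` (`"trait"`/`"baseline"`), `rmsd_cm`, `md_cm`, `n_eval`.
#'   Per-ecosystem aggregates are attached as attribute `by_ecosystem`.
#' @export
transfer_report <- function(trait_fit, baseline_fit, target,
                            stats = trait_fit$stats, n_ages = 50,
                            target_config = mcmc_config(),
                            reference = c("fitted", "observed"), seed = NULL) {
  stopifnot(
    inherits(trait_fit, "growth_draws"), inherits(baseline_fit, "growth_draws"),
    inherits(target, "growth_data")
  )
  reference <- match.arg(reference)
  if (nrow(target$traits) == 0) {
    return(empty_transfer_report())
  }
  rows <- list()
  for (eco in sort(unique(target$traits$ecosystem))) {
    tgt <- filter_ecosystem(target, eco)
    tr <- tgt$traits
    if (length(tgt$underidentified)) {
      warning(sprintf(
        "Skipping species without identifiable target fits in '%s': %s",
        eco, paste(tgt$underidentified, collapse = ", ")
      ))
      keep <- !tr$species %in% tgt$underidentified
      tr <- tr[keep, , drop = FALSE]
      tgt <- suppressWarnings(growth_data(
        tgt$heights[!tgt$heights$species %in% tgt$underidentified, ], tr
      ))
    }
    if (nrow(tr) == 0) next
    if (reference == "fitted") {
      rng <- range(tgt$heights$age_yrs)
      ages <- seq(rng[1], rng[2], length.out = n_ages)
      ref_fit <- suppressWarnings(sample_posterior(
        tgt,
        structure = trait_structure(), config = target_config
      ))
      ref_tbl <- median_trajectories(ref_fit, ages)
    } else {
      ref_tbl <- tgt$heights |>
        dplyr::transmute(
          species = .data$species, age = .data$age_yrs,
          ref_height = .data$height_cm
        )
      ages <- NULL
    }
    for (model in c("trait", "baseline")) {
      fit <- if (model == "trait") trait_fit else baseline_fit
      sp_rows <- purrr::map_dfr(tr$species, function(sp) {
        ref_sp <- ref_tbl[ref_tbl$species == sp, ]
        if (nrow(ref_sp) == 0) {
          warning(sprintf("No reference trajectory for species '%s'; skipped.", sp))
          return(tibble::tibble())
        }
        pred <- predict_new_species(
          fit, tr[tr$species == sp, ], ref_sp$age,
          stats = stats, epsilon = "draw",
          seed = if (is.null(seed)) NULL else seed + match(sp, tr$species)
        )
        tibble::tibble(
          species = sp, ecosystem = eco, model = model,
          rmsd_cm = rmsd(pred$height_cm, ref_sp$ref_height),
          md_cm = mean_deviance(pred$height_cm, ref_sp$ref_height),
          n_eval = nrow(ref_sp)
        )
      })
      rows <- c(rows, list(sp_rows))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(empty_transfer_report())
  }
  agg <- out |>
    dplyr::group_by(.data$ecosystem, .data$model) |>
    dplyr::summarise(
      mean_rmsd_cm = mean(.data$rmsd_cm),
      mean_md_cm = mean(.data$md_cm),
      n_species = dplyr::n(), .groups = "drop"
    )
  attr(out, "by_ecosystem") <- agg
  class(out) <- c("transfer_report", class(out))
  out
}

empty_transfer_report <- function() {
  out <- tibble::tibble(
    species = character(0), ecosystem = character(0), model = character(0),
    rmsd_cm = numeric(0), md_cm = numeric(0), n_eval = integer(0)
  )
  attr(out, "by_ecosystem") <- tibble::tibble(
    ecosystem = character(0), model = character(0),
    mean_rmsd_cm = numeric(0), mean_md_cm = numeric(0), n_species = integer(0)
  )
  class(out) <- c("transfer_report", class(out))
  out
}

# posterior-median trajectories of a fitted model's own species
median_trajectories <- function(fit, ages) {
  A <- species_param_draws(fit, "alpha")
  B <- species_param_draws(fit, "b")
  C <- species_param_draws(fit, "c")
  purrr::map_dfr(seq_along(fit$species), function(j) {
    M <- log(A[, j]) + stats::plogis(outer(B[, j], ages) - B[, j] * C[, j], log.p = TRUE)
    tibble::tibble(
      species = fit$species[j], age = ages,
      ref_height = exp(apply(M, 2, stats::median))
    )
  })
}
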