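#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
print.growth_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf(
    "<growth_draws> %d retained iterations x %d chains x %d quantities\n",
    d[1], d[2], d[3]
  ))
  cat(sprintf(
    "  %d species, ecosystem(s): %s%s\n", length(x$species),
    paste(x$ecosystems, collapse = ", "),
    if (x$ensemble) " (ensemble fit)" else ""
  ))
  sl <- structure_slopes(x$structure)
  cat(sprintf(
    "  trait structure: %s\n",
    if (nrow(sl)) paste(sprintf("%s->%s", sl$trait, sl$parameter), collapse = ", ") else "no traits"
  ))
  mx <- suppressWarnings(max(x$rhat$rhat, na.rm = TRUE))
  cat(sprintf(
    "  max R-hat = %.3f — %s\n", mx,
    if (x$converged) "converged" else "NOT CONVERGED"
  ))
  invisible(x)
}

#' Posterior draws in long (tidy) format
#'
#' @param fit A `growth_draws` object.
#' @param quantities Optional character vector or regular expression
#'   (`regex = TRUE`) selecting quantities.
#' @param regex Treat `quantities` as a regular expression.
#' @return A tibble with columns `chain`, `iteration`, `quantity`, `value`.
#' @export
posterior_long <- function(fit, quantities = NULL, regex = FALSE) {
  stopifnot(inherits(fit, "growth_draws"))
  qn <- dimnames(fit$draws)[[3]]
  sel <- select_quantities(qn, quantities, regex)
  d <- dim(fit$draws)
  purrr::map_dfr(sel, function(q) {
    tibble::tibble(
      chain = rep(seq_len(d[2]), each = d[1]),
      iteration = rep(seq_len(d[1]), times = d[2]),
      quantity = q,
      value = as.vector(fit$draws[, , q])
    )
  })
}

#' Posterior draws as a matrix (chains stacked)
#'
#' @inheritParams posterior_long
#' @return A numeric matrix, one column per quantity, chains concatenated
#'   row-wise in chain order.
#' @export
posterior_matrix <- function(fit, quantities = NULL, regex = FALSE) {
  stopifnot(inherits(fit, "growth_draws"))
  qn <- dimnames(fit$draws)[[3]]
  sel <- select_quantities(qn, quantities, regex)
  d <- dim(fit$draws)
  out <- matrix(NA_real_, d[1] * d[2], length(sel), dimnames = list(NULL, sel))
  for (q in sel) out[, q] <- as.vector(fit$draws[, , q])
  out
}

select_quantities <- function(qn, quantities, regex) {
  if (is.null(quantities)) {
    return(qn)
  }
  if (regex) {
    return(qn[grepl(quantities, qn)])
  }
  missing <- setdiff(quantities, qn)
  if (length(missing)) {
    stop(sprintf("Unknown quantities: %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  quantities
}

#' @rdname sample_posterior
#' @param x,object A `growth_draws` object.
#' @param conf_level Credible-interval mass for `tidy()`.
#' @param ... Unused.
#' @export
tidy.growth_draws <- function(x, conf_level = 0.95, ...) {
  m <- posterior_matrix(x)
  a <- (1 - conf_level) / 2
  rh <- stats::setNames(x$rhat$rhat, x$rhat$quantity)
  tibble::tibble(
    term = colnames(m),
    estimate = colMeans(m),
    std.error = apply(m, 2, stats::sd),
    median = apply(m, 2, stats::median),
    conf.low = apply(m, 2, stats::quantile, probs = a),
    conf.high = apply(m, 2, stats::quantile, probs = 1 - a),
    rhat = unname(rh[colnames(m)])
  )
}

#' @rdname sample_posterior
#' @export
glance.growth_draws <- function(x, ...) {
  d <- dim(x$draws)
  tibble::tibble(
    n_species = length(x$species),
    n_chains = d[2],
    n_retained = d[1],
    n_slopes = nrow(structure_slopes(x$structure)),
    max_rhat = suppressWarnings(max(x$rhat$rhat, na.rm = TRUE)),
    converged = x$converged,
    ensemble = x$ensemble
  )
}

#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' Computes \eqn{\hat R = \sqrt{((n-1)/n \cdot W + B/n) / W}} where `W` is
#' the mean within-chain variance and `B` is `n` times the variance of the
#' chain means. Values near 1 indicate the chains agree; the package flags a
#' fit as converged when all monitored quantities satisfy R-hat <= 1.1.
#'
#' @param draws A `growth_draws` object, or a numeric matrix with one column
#'   per chain.
#' @param quantity Quantity name (required for `growth_draws` input).
#' @return The scale reduction factor. `NA` (with a warning) when the
#'   within-chain variance is zero and the chains agree; `Inf` (with a
#'   warning) when the within-chain variance is zero but the chains differ.
#' @export
rhat <- function(draws, quantity = NULL) {
  if (inherits(draws, "growth_draws")) {
    if (is.null(quantity)) stop("Supply a `quantity` name.", call. = FALSE)
    qn <- dimnames(draws$draws)[[3]]
    if (!quantity %in% qn) {
      stop(sprintf("Unknown quantity '%s'.", quantity), call. = FALSE)
    }
    x <- draws$draws[, , quantity, drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, ncol = dim(draws$draws)[2])
  } else {
    x <- as.matrix(draws)
  }
  if (ncol(x) < 2) stop("R-hat needs at least 2 chains.", call. = FALSE)
  if (nrow(x) < 2) stop("R-hat needs at least 2 retained iterations.", call. = FALSE)
  rhat_core(x)
}

rhat_core <- function(x) {
  n <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  if (W == 0) {
    if (B == 0) {
      warning("R-hat undefined: zero variance within and between chains.")
      return(NA_real_)
    }
    warning("R-hat infinite: chains are constant but disagree.")
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

rhat_table_array <- function(draws_array) {
  qn <- dimnames(draws_array)[[3]]
  n <- dim(draws_array)[1]
  vals <- purrr::map_dbl(qn, function(q) {
    x <- matrix(draws_array[, , q], nrow = n)
    suppressWarnings(rhat_core(x))
  })
  tibble::tibble(quantity = qn, rhat = vals)
}

#' Export posterior draws and a run manifest
#'
#' Writes the retained draws as a tidy long CSV (`chain`, `iteration`,
#' `quantity`, `value`) and a JSON manifest recording the seed, run
#' configuration and the R-hat table.
#'
#' @param fit A `growth_draws` object.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Invisibly, the paths written.
#' @export
write_draws <- function(fit, dir, prefix = "fit") {
  stopifnot(inherits(fit, "growth_draws"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(prefix, "_draws.csv"))
  manifest <- file.path(dir, paste0(prefix, "_manifest.json"))
  readr::write_csv(posterior_long(fit), csv)
  jsonlite::write_json(
    list(
      seed = fit$config$seed,
      config = unclass(fit$config),
      ecosystems = fit$ecosystems,
      structure = unclass(fit$structure),
      converged = fit$converged,
      rhat = fit$rhat
    ),
    manifest,
    auto_unbox = TRUE, digits = 10, pretty = TRUE
  )
  invisible(c(draws = csv, manifest = manifest))
}

# --- internal extraction helpers used by evaluation and transfer ---------

# D x J matrix of species-level draws for one growth parameter
species_param_draws <- function(fit, parameter, log_scale = FALSE) {
  m <- posterior_matrix(fit, sprintf("%s[%s]", parameter, fit$species))
  if (log_scale) log(m) else m
}

eps_draws <- function(fit, parameter) {
  posterior_matrix(fit, sprintf("eps_%s[%s]", parameter, fit$species))
}

beta_draws <- function(fit, parameter) {
  qn <- dimnames(fit$draws)[[3]]
  cols <- qn[grepl(paste0("^beta0?_", parameter, "($|_)"), qn)]
  posterior_matrix(fit, cols)
}

sigma_draws <- function(fit) drop(posterior_matrix(fit, "sigma"))

re_sd_draws <- function(fit, parameter) {
  drop(posterior_matrix(fit, paste0("sd_eps_", parameter)))
}
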