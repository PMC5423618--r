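#' Hillslope growth curve: expected height at a given age
#'
#' The Hillslope equation is a three-parameter re-parameterisation of the
#' logistic curve,
#' \deqn{\mu(T) = \frac{\alpha}{1 + \exp[-b (T - c)]},}
#' where `alpha` is the asymptotic height (cm), `b` the maximum relative
#' growth rate (cm cm^-1 yr^-1) and `c` the age (years) at which absolute
#' growth peaks (the inflection point, where the curve reaches `alpha / 2`).
#'
#' The implementation routes through [stats::plogis()] so that extreme values
#' of `b * (age - c)` (up to several hundred in magnitude) neither overflow
#' nor produce `NaN`.
#'
#' @param alpha Asymptotic height, cm. Strictly positive.
#' @param b Maximum relative growth rate, cm cm^-1 yr^-1. Strictly positive.
#' @param c Age at maximum growth, years. Strictly positive.
#' @param age Age (time since fire), years. Non-negative, finite.
#'
#' @return Expected height in cm, vectorised over the inputs.
#' @seealso [absolute_growth_rate()], [relative_growth_rate()]
#' @examples
#' hillslope_height(100, 1, 5, 5) # == 50, the inflection
#' hillslope_height(100, 1, 5, 7) # 100 / (1 + exp(-2))
#' @export
hillslope_height <- function(alpha, b, c, age) {
  check_growth_params(alpha, b, c)
  if (any(!is.finite(age))) {
    stop("`age` must be finite (NA/NaN/Inf not allowed).", call. = FALSE)
  }
  alpha * stats::plogis(b * (age - c))
}

#' Absolute growth rate of the Hillslope curve
#'
#' The derivative of [hillslope_height()] with respect to age,
#' \eqn{d\mu/dT = \alpha b p (1 - p)} with \eqn{p = \mathrm{logit}^{-1}(b(T - c))}.
#' It attains its maximum \eqn{\alpha b / 4} exactly at `age = c`.
#'
#' @inheritParams hillslope_height
#' @return Absolute growth rate, cm yr^-1.
#' @export
absolute_growth_rate <- function(alpha, b, c, age) {
  check_growth_params(alpha, b, c)
  p <- stats::plogis(b * (age - c))
  alpha * b * p * (1 - p)
}

#' Relative growth rate of the Hillslope curve
#'
#' Growth per unit size, \eqn{(1/\mu) d\mu/dT = b (1 - \mu/\alpha)}. It
#' decreases monotonically with age; its supremum as the plant becomes
#' vanishingly small is `b` itself, which is why `b` is interpreted as the
#' maximum relative growth rate. At the inflection (`age = c`) it equals `b/2`.
#'
#' @inheritParams hillslope_height
#' @return Relative growth rate, cm cm^-1 yr^-1.
#' @export
relative_growth_rate <- function(alpha, b, c, age) {
  check_growth_params(alpha, b, c)
  b * (1 - stats::plogis(b * (age - c)))
}

#' Lognormal observation log-density for heights
#'
#' The observation model treats a measured height as lognormal around the
#' Hillslope expectation: the log-scale location is `log(mu_cm)`, so `mu_cm`
#' is the *median* height, and `sigma_log` is the log-scale standard
#' deviation. Summing the returned vector over a dataset gives the model
#' log-likelihood.
#'
#' @param height_cm Observed height(s), cm, strictly positive.
#' @param mu_cm Median height(s) from the growth curve, cm, strictly positive.
#' @param sigma_log Log-scale standard deviation, strictly positive.
#' @return Log-density, vectorised (one value per observation).
#' @export
lognormal_loglik <- function(height_cm, mu_cm, sigma_log) {
  if (any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    stop("`height_cm` must be finite and strictly positive.", call. = FALSE)
  }
  if (any(!is.finite(mu_cm)) || any(mu_cm <= 0)) {
    stop("`mu_cm` must be finite and strictly positive.", call. = FALSE)
  }
  if (any(!is.finite(sigma_log)) || any(sigma_log <= 0)) {
    stop("`sigma_log` must be finite and strictly positive.", call. = FALSE)
  }
  stats::dlnorm(height_cm, meanlog = log(mu_cm), sdlog = sigma_log, log = TRUE)
}

#' Evaluate a growth trajectory on an age grid
#'
#' @inheritParams hillslope_height
#' @param ages Numeric vector of ages (years).
#' @return A tibble with columns `age` and `height_cm`.
#' @export
hillslope_trajectory <- function(alpha, b, c, ages) {
  tibble::tibble(age = ages, height_cm = hillslope_height(alpha, b, c, ages))
}

# shared validation for the (alpha, b, c) triplet
check_growth_params <- function(alpha, b, c) {
  for (nm in c("alpha", "b", "c")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("Growth parameter `%s` must be finite and strictly positive.", nm),
        call. = FALSE
      )
    }
  }
  invisible(TRUE)
}
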