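#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot trait-coefficient estimates with credible intervals
#'
#' Point estimates and 95% credible intervals for every trait slope in the
#' fitted sub-models (the analogue of a coefficient forest plot). For a
#' no-trait fit, shows the species-level growth parameters instead.
#'
#' @param object A `growth_draws` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growth_draws <- function(object, ...) {
  td <- tidy(object)
  slopes <- td[grepl("^beta_", td$term), ]
  if (nrow(slopes) > 0) {
    slopes <- slopes |>
      tidyr::separate_wider_delim("term",
        delim = "_", names = c("kind", "parameter", "trait"),
        too_many = "merge"
      )
    ggplot2::ggplot(slopes, ggplot2::aes(
      x = .data$estimate, y = .data$trait,
      xmin = .data$conf.low, xmax = .data$conf.high
    )) +
      ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
      ggplot2::geom_pointrange() +
      ggplot2::facet_wrap(~ .data$parameter, scales = "free_y") +
      ggplot2::labs(
        x = "coefficient (log scale, per standardized trait unit)", y = NULL,
        title = "Trait effects on growth parameters"
      )
  } else {
    pars <- td[grepl("^(alpha|b|c)\\[", td$term), ] |>
      tidyr::separate_wider_regex("term",
        patterns = c(parameter = "^[a-z]+", "\\[", species = "[^\\]]+", "\\]")
      )
    ggplot2::ggplot(pars, ggplot2::aes(
      x = .data$estimate, y = .data$species,
      xmin = .data$conf.low, xmax = .data$conf.high
    )) +
      ggplot2::geom_pointrange() +
      ggplot2::facet_wrap(~ .data$parameter, scales = "free_x") +
      ggplot2::labs(
        x = "posterior mean and 95% CrI", y = NULL,
        title = "Species growth parameters"
      )
  }
}

#' Plot fitted growth trajectories over the observations
#'
#' Posterior-median Hillslope curves per species with the raw height
#' observations overlaid.
#'
#' @param fit A `growth_draws` object.
#' @param data The fitted [growth_data()].
#' @param n_ages Grid resolution.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(fit, data, n_ages = 60) {
  rng <- range(data$heights$age_yrs)
  ages <- seq(rng[1], rng[2], length.out = n_ages)
  traj <- median_trajectories(fit, ages)
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$age, y = .data$ref_height)) +
    ggplot2::geom_point(
      data = data$heights,
      ggplot2::aes(x = .data$age_yrs, y = .data$height_cm),
      alpha = 0.35, size = 0.8
    ) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::facet_wrap(~ .data$species, scales = "free_y") +
    ggplot2::labs(
      x = "age since fire (years)", y = "height (cm)",
      title = "Posterior-median growth trajectories"
    )
}

#' @rdname predict_new_species
#' @param object A `predicted_trajectory` tibble.
#' @param ... Unused.
#' @export
autoplot.predicted_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$height_cm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::facet_wrap(~ .data$species, scales = "free_y") +
    ggplot2::labs(
      x = "age since fire (years)", y = "predicted height (cm)",
      title = "Trait-based out-of-sample growth predictions (median and 95% band)"
    )
}

#' @rdname transfer_report
#' @param object A `transfer_report`.
#' @param ... Unused.
#' @export
autoplot.transfer_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$rmsd_cm, y = .data$species, colour = .data$model
  )) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$ecosystem, scales = "free_y") +
    ggplot2::labs(
      x = "RMSD (cm)", y = NULL, colour = "model",
      title = "Out-of-sample prediction error by species"
    )
}
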