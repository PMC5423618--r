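# hand-buildable one-species fits for arithmetic oracles
one_species_data <- function() {
  growth_data(
    tibble::tibble(
      individual_id = c("i1", "i2"), species = "s1", ecosystem = "e",
      age_yrs = c(2, 10), height_cm = c(15, 70)
    ),
    toy_traits(c("s1", "s2"))[1, ]
  )
}

test_that("DIC is D(theta_hat) with pD = 0 for point-mass draws", {
  gd <- one_species_data()
  draws <- tibble::tibble(
    `alpha[s1]` = rep(100, 12), `b[s1]` = rep(0.5, 12), `c[s1]` = rep(5, 12),
    sigma = rep(0.3, 12)
  )
  fit <- fake_fit(draws, "s1")
  out <- dic(fit, gd)
  mu <- 100 * plogis(0.5 * (c(2, 10) - 5))
  d_hand <- -2 * sum(dlnorm(c(15, 70), log(mu), 0.3, log = TRUE))
  expect_equal(out$p_d, 0, tolerance = 1e-10)
  expect_equal(out$dic, d_hand, tolerance = 1e-10)
})

test_that("DIC on three hand-written draws matches a by-hand computation", {
  gd <- one_species_data()
  a <- c(90, 100, 110)
  b <- c(0.4, 0.5, 0.6)
  cc <- c(4, 5, 6)
  s <- c(0.25, 0.3, 0.35)
  fit <- fake_fit(
    tibble::tibble(`alpha[s1]` = a, `b[s1]` = b, `c[s1]` = cc, sigma = s),
    "s1"
  )
  ll <- vapply(1:3, function(d) {
    mu <- a[d] * plogis(b[d] * (c(2, 10) - cc[d]))
    sum(dlnorm(c(15, 70), log(mu), s[d], log = TRUE))
  }, numeric(1))
  d_bar <- mean(-2 * ll)
  # plug-in point: posterior mean on the log scale
  mu_hat <- exp(mean(log(a))) *
    plogis(exp(mean(log(b))) * (c(2, 10) - exp(mean(log(cc)))))
  d_hat <- -2 * sum(dlnorm(c(15, 70), log(mu_hat), exp(mean(log(s))), log = TRUE))
  out <- dic(fit, gd)
  expect_equal(out$d_bar, d_bar, tolerance = 1e-10)
  expect_equal(out$p_d, d_bar - d_hat, tolerance = 1e-10)
  expect_equal(out$dic, 2 * d_bar - d_hat, tolerance = 1e-10)
})

test_that("DIC prefers (or ties with) the generating structure on strong signal", {
  sim <- shared_sim()
  right <- shared_trait_fit()
  wrong <- suppressWarnings(sample_posterior(
    sim$data,
    structure = trait_structure(alpha = "wood_density"),
    config = quick_mcmc(seed = 771, iterations = 3000)
  ))
  expect_lte(dic(right, sim$data)$dic, dic(wrong, sim$data)$dic + 5)
})

test_that("observed-vs-predicted R2 behaves at its extremes", {
  # noiseless data, exact point-mass parameter draws -> R2 = 1
  cfg <- simulation_config(
    ecosystem_config("e", n_species = 3, n_individuals = 8),
    sigma_obs = 0
  )
  sim <- generate_multi_ecosystem(cfg, seed = 4)
  p <- sim$truth$e$params
  n_draw <- 12
  draws <- tibble::tibble(sigma = rep(0.1, n_draw))
  for (j in seq_len(nrow(p))) {
    draws[[sprintf("alpha[%s]", p$species[j])]] <- rep(p$alpha[j], n_draw)
    draws[[sprintf("b[%s]", p$species[j])]] <- rep(p$b[j], n_draw)
    draws[[sprintf("c[%s]", p$species[j])]] <- rep(p$c[j], n_draw)
  }
  fit <- fake_fit(draws, sort(p$species))
  expect_equal(obs_pred_r2(fit, sim$data), 1, tolerance = 1e-9)

  # permuting the observations against the predictions kills the correlation
  perm <- sim$data
  set.seed(1)
  perm$heights$height_cm <- sample(perm$heights$height_cm)
  expect_lt(obs_pred_r2(fit, perm), 0.3)

  # matches a direct correlation on the exported predictions
  ph <- predicted_heights(fit, sim$data)
  expect_equal(obs_pred_r2(fit, sim$data), cor(ph$observed, ph$predicted)^2)
})

test_that("obs_pred_r2 needs at least 3 individuals", {
  gd <- one_species_data()
  fit <- fake_fit(
    tibble::tibble(
      `alpha[s1]` = rep(100, 12), `b[s1]` = rep(0.5, 12),
      `c[s1]` = rep(5, 12), sigma = rep(0.3, 12)
    ),
    "s1"
  )
  expect_error(obs_pred_r2(fit, gd), "3 individuals")
})

test_that("trait-level R2 rewards informative trait structures", {
  sim <- shared_sim()
  r2_trait <- trait_level_r2(shared_trait_fit(), sim$data)
  r2_none <- trait_level_r2(shared_baseline_fit(), sim$data)
  # the no-trait model predicts one common curve: only age structure scores
  expect_gt(r2_trait, r2_none)
  expect_true(r2_trait > 0 && r2_trait <= 1)
})

test_that("Gelman R2 and pooling factor are undefined without a sub-model", {
  fit <- shared_baseline_fit()
  expect_error(gelman_r2_submodel(fit, "alpha"), "no-trait")
  expect_error(pooling_factor(fit, "alpha"), "no-trait")
})

test_that("Gelman R2 hits its analytic extremes under pinned parameters", {
  sim <- shared_sim()
  st <- trait_structure(alpha = "sla")
  # random effects forced to (almost) zero with a non-zero slope: all
  # species-level variance is explained by the trait line -> R2 ~ 1
  fit_tight <- suppressWarnings(sample_posterior(
    sim$data, st,
    config = quick_mcmc(seed = 61, iterations = 1500),
    fixed = list(re_sd = c(alpha = 1e-4, b = NA, c = NA))
  ))
  expect_gt(gelman_r2_submodel(fit_tight, "alpha"), 0.97)

  # slope pinned at zero: the trait explains nothing
  fit_null <- suppressWarnings(sample_posterior(
    sim$data, st,
    config = quick_mcmc(seed = 62, iterations = 1500),
    fixed = list(beta = list(alpha = c(5.3, 0)))
  ))
  expect_lt(abs(gelman_r2_submodel(fit_null, "alpha")), 0.15)
})

test_that("Gelman R2 recovers a known variance partition", {
  # slope variance : random-effect variance = 3 : 1 -> R2 ~ 0.75
  cfg <- simulation_config(
    ecosystem_config("e", n_species = 40, n_individuals = 10),
    slopes = tibble::tibble(parameter = "alpha", trait = "sla", value = sqrt(3) * 0.2),
    re_sd = c(alpha = 0.2, b = 0.15, c = 0.2), sigma_obs = 0.15
  )
  sim <- generate_multi_ecosystem(cfg, seed = 55)
  fit <- suppressWarnings(sample_posterior(
    sim$data, trait_structure(alpha = "sla"),
    config = quick_mcmc(seed = 56, iterations = 2500)
  ))
  expect_equal(gelman_r2_submodel(fit, "alpha"), 0.75, tolerance = 0.12)
})

test_that("pooling factor matches a direct two-pass computation and its limits", {
  fit <- shared_trait_fit()
  E <- posterior_matrix(fit, "^eps_alpha\\[", regex = TRUE)
  direct <- 1 - var(colMeans(E)) / mean(apply(E, 1, var))
  expect_equal(pooling_factor(fit, "alpha"), direct, tolerance = 1e-12)

  # identical posterior-mean effects -> complete pooling (lambda = 1)
  draws <- tibble::tibble(
    `eps_alpha[s1]` = c(-0.1, 0.1, -0.2, 0.2), `eps_alpha[s2]` = c(0.1, -0.1, 0.2, -0.2),
    `eps_alpha[s3]` = c(0.2, -0.2, 0.1, -0.1)
  )
  fk <- fake_fit(draws, c("s1", "s2", "s3"),
    structure = trait_structure(alpha = "sla")
  )
  expect_equal(pooling_factor(fk, "alpha"), 1, tolerance = 1e-12)
})

test_that("pooling factor falls with overwhelming per-species data", {
  cfg_big <- simulation_config(
    ecosystem_config("e", n_species = 8, n_individuals = 500),
    re_sd = c(alpha = 0.4, b = 0.2, c = 0.2), sigma_obs = 0.3
  )
  sim_big <- generate_multi_ecosystem(cfg_big, seed = 71)
  fit_big <- suppressWarnings(sample_posterior(
    sim_big$data, trait_structure(alpha = "sla"),
    config = quick_mcmc(seed = 72, iterations = 1500)
  ))
  # with 500 observations per species the likelihood dominates the sub-model
  expect_lt(pooling_factor(fit_big, "alpha"), 0.5)
})

test_that("ci_overlap_test implements the half-length screening rule", {
  expect_equal(ci_overlap_test(c(0, 1), c(2, 3)), "p<0.01") # disjoint
  expect_equal(ci_overlap_test(c(0, 1), c(1, 2)), "p<0.01") # just touching
  expect_equal(ci_overlap_test(c(0, 1), c(0.8, 1.8)), "p<0.05") # overlap 0.2 < 0.5
  expect_equal(ci_overlap_test(c(0, 1), c(0.1, 1.1)), "not significant")
  expect_error(ci_overlap_test(c(1, 0), c(0, 1)), "lower < upper")
})

test_that("pairwise parameter R2 reflects generated correlations", {
  # construct species parameters with corr(log b, log c) = -0.9 by hand
  set.seed(33)
  J <- 60
  zb <- rnorm(J)
  zc <- -0.9 * zb + sqrt(1 - 0.81) * rnorm(J)
  species <- sprintf("s%02d", seq_len(J))
  n_draw <- 10
  draws <- tibble::tibble(sigma = rep(0.1, n_draw))
  la <- rnorm(J, 5, 0.3)
  for (j in seq_len(J)) {
    draws[[sprintf("alpha[%s]", species[j])]] <- rep(exp(la[j]), n_draw)
    draws[[sprintf("b[%s]", species[j])]] <- rep(exp(0.3 * zb[j]), n_draw)
    draws[[sprintf("c[%s]", species[j])]] <- rep(exp(1 + 0.3 * zc[j]), n_draw)
  }
  fit <- fake_fit(draws, species)
  r2 <- parameter_pairwise_r2(list(sim = fit))
  bc <- r2$r2[r2$pair == "b_c"]
  expect_equal(bc, cor(zb, zc)^2, tolerance = 1e-10)
  expect_equal(bc, 0.81, tolerance = 0.12)
  expect_lt(r2$r2[r2$pair == "alpha_b"], 0.2)
})

test_that("pairwise R2 refuses groups with fewer than 3 species", {
  draws <- tibble::tibble(
    `alpha[s1]` = 1:10, `b[s1]` = 1:10, `c[s1]` = 1:10,
    `alpha[s2]` = 1:10, `b[s2]` = 1:10, `c[s2]` = 1:10, sigma = rep(0.1, 10)
  )
  fit <- fake_fit(draws, c("s1", "s2"))
  expect_error(parameter_pairwise_r2(list(f = fit)), "3 species")
})

test_that("backward selection obeys its degenerate limits", {
  expect_error(
    backward_selection(shared_sim()$data, tolerance = -1),
    "non-negative"
  )
  # infinite tolerance strips every slope, returning the no-trait model
  sel <- backward_selection(
    shared_sim()$data,
    full = trait_structure(alpha = "sla", b = "leaf_n"),
    config = mcmc_config(
      chains = 2, iterations = 400, burnin = 200,
      thin = 2, seed = 13
    ),
    tolerance = Inf
  )
  expect_true(is_empty_structure(sel$chosen))
  expect_equal(sel$trace$n_slopes[1], 2) # first entry is the full structure
  expect_equal(sel$trace$n_slopes[nrow(sel$trace)], 0)
})

test_that("backward selection is invariant to species ordering", {
  sim <- generate_multi_ecosystem(
    small_sim_config(n_species = 6, n_individuals = 8),
    seed = 19
  )
  shuffled <- growth_data(
    sim$data$heights[rev(seq_len(nrow(sim$data$heights))), ],
    sim$data$traits[sample(nrow(sim$data$traits)), ]
  )
  cfg <- mcmc_config(chains = 2, iterations = 400, burnin = 200, thin = 2, seed = 23)
  s1 <- backward_selection(sim$data,
    full = trait_structure(alpha = c("sla", "wood_density")),
    config = cfg, tolerance = 0.005
  )
  s2 <- backward_selection(shuffled,
    full = trait_structure(alpha = c("sla", "wood_density")),
    config = cfg, tolerance = 0.005
  )
  expect_identical(unclass(s1$chosen), unclass(s2$chosen))
  expect_equal(s1$trace$obs_pred_r2, s2$trace$obs_pred_r2, tolerance = 1e-12)
})
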