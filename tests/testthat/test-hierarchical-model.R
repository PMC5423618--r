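make_toy_data <- function() {
  # 2 species, 4 observations each, fixed numbers for hand-checkable oracles
  h <- tibble::tibble(
    individual_id = sprintf("i%d", 1:8),
    species = rep(c("s1", "s2"), each = 4),
    ecosystem = "e",
    age_yrs = c(1, 4, 8, 15, 2, 5, 9, 14),
    height_cm = c(12, 45, 80, 95, 8, 20, 33, 40)
  )
  growth_data(h, toy_traits(c("s1", "s2")))
}

toy_state <- function() {
  list(
    log_alpha = c(4.6, 3.7), log_b = c(-0.7, -0.9), log_c = c(1.6, 1.7),
    beta = list(
      alpha = c(4.2, -0.25), # intercept + sla slope
      b = -0.8, c = 1.65
    ),
    re_sd = c(alpha = 0.4, b = 0.3, c = 0.35),
    sigma = 0.25
  )
}

test_that("log_posterior matches a hand-assembled term-by-term oracle", {
  gd <- make_toy_data()
  st <- trait_structure(alpha = "sla")
  state <- toy_state()

  # --- independent assembly using nothing but base R densities
  z_sla <- scale(gd$traits$sla)[, 1] # species sorted s1, s2 already
  mu1 <- exp(4.6) * plogis(exp(-0.7) * (c(1, 4, 8, 15) - exp(1.6)))
  mu2 <- exp(3.7) * plogis(exp(-0.9) * (c(2, 5, 9, 14) - exp(1.7)))
  obs <- sum(dlnorm(c(12, 45, 80, 95), log(mu1), 0.25, log = TRUE)) +
    sum(dlnorm(c(8, 20, 33, 40), log(mu2), 0.25, log = TRUE))
  eps_a <- c(4.6, 3.7) - (4.2 + -0.25 * z_sla)
  eps_b <- c(-0.7, -0.9) - (-0.8)
  eps_c <- c(1.6, 1.7) - 1.65
  res <- sum(dnorm(eps_a, 0, 0.4, log = TRUE)) +
    sum(dnorm(eps_b, 0, 0.3, log = TRUE)) +
    sum(dnorm(eps_c, 0, 0.35, log = TRUE))
  priors <- sum(dnorm(c(4.2, -0.25, -0.8, 1.65), 0, 100, log = TRUE)) +
    sum(log(2) + dcauchy(c(0.4, 0.3, 0.35, 0.25), 0, 25, log = TRUE))
  expect_equal(
    log_posterior(gd, st, state),
    obs + res + priors,
    tolerance = 1e-10
  )
})

test_that("log_posterior with zero observations reduces to the prior", {
  gd0 <- suppressWarnings(growth_data(
    tibble::tibble(
      individual_id = character(0), species = character(0),
      ecosystem = character(0), age_yrs = numeric(0), height_cm = numeric(0)
    ),
    toy_traits(c("s1", "s2"))
  ))
  st <- trait_structure(alpha = "sla")
  state <- toy_state()
  z_sla <- scale(toy_traits(c("s1", "s2"))$sla)[, 1]
  eps_a <- c(4.6, 3.7) - (4.2 + -0.25 * z_sla)
  prior_only <- sum(dnorm(eps_a, 0, 0.4, log = TRUE)) +
    sum(dnorm(c(-0.7, -0.9) + 0.8, 0, 0.3, log = TRUE)) +
    sum(dnorm(c(1.6, 1.7) - 1.65, 0, 0.35, log = TRUE)) +
    sum(dnorm(c(4.2, -0.25, -0.8, 1.65), 0, 100, log = TRUE)) +
    sum(log(2) + dcauchy(c(0.4, 0.3, 0.35, 0.25), 0, 25, log = TRUE))
  expect_equal(log_posterior(gd0, st, state), prior_only, tolerance = 1e-10)
})

test_that("log_posterior decreases as sigma shrinks under an imperfect fit", {
  gd <- make_toy_data()
  st <- trait_structure(alpha = "sla")
  lp <- vapply(c(0.05, 0.02, 0.01, 0.005), function(s) {
    state <- toy_state()
    state$sigma <- s
    log_posterior(gd, st, state)
  }, numeric(1))
  expect_true(all(diff(lp) < 0))
})

test_that("log_posterior rejects dimension mismatches", {
  gd <- make_toy_data()
  st <- trait_structure(alpha = "sla")
  state <- toy_state()
  state$log_alpha <- c(4.6, 3.7, 2)
  expect_error(log_posterior(gd, st, state), "length 2")
  state <- toy_state()
  state$beta$alpha <- 4.2 # missing the sla slope
  expect_error(log_posterior(gd, st, state), "beta")
})

test_that("single-species initialization recovers noiseless parameters", {
  cfg <- simulation_config(
    ecosystem_config("e", n_species = 4, n_individuals = 16, age_range = c(0, 25)),
    re_sd = c(alpha = 0.3, b = 0.2, c = 0.3), sigma_obs = 0
  )
  sim <- generate_multi_ecosystem(cfg, seed = 8)
  init <- init_from_single_species(sim$data)
  truth <- sim$truth$e$params[match(init$species, sim$truth$e$params$species), ]
  expect_true(all(init$method == "ls"))
  expect_equal(init$alpha, truth$alpha, tolerance = 1e-4)
  expect_equal(init$b, truth$b, tolerance = 1e-4)
  expect_equal(init$c, truth$c, tolerance = 1e-4)
})

test_that("initialization falls back to the heuristic for degenerate species", {
  h <- tibble::tibble(
    individual_id = c("a", "b", "c", "d", "e"),
    species = c("deg", "deg", "ok", "ok", "ok"),
    ecosystem = "e", age_yrs = c(3, 3, 1, 5, 9), height_cm = c(10, 12, 5, 30, 50)
  )
  gd <- suppressWarnings(growth_data(h, toy_traits(c("deg", "ok"))))
  expect_warning(init <- init_from_single_species(gd), "deg")
  expect_equal(init$method[init$species == "deg"], "heuristic")
  expect_equal(init$alpha[init$species == "deg"], 1.1 * 12)
  # deterministic given the dataset
  i2 <- suppressWarnings(init_from_single_species(gd))
  expect_identical(init, i2)
})

test_that("rhat reproduces hand-computed values", {
  # identical chains [1,2,3,4]: B = 0, W = var -> sqrt(3/4)
  expect_equal(rhat(cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))), sqrt(3 / 4))
  # by the formula with distinct chains
  x <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 6))
  n <- 4
  W <- mean(c(var(x[, 1]), var(x[, 2])))
  B <- n * var(colMeans(x))
  expect_equal(rhat(x), sqrt(((n - 1) / n * W + B / n) / W))
  # long well-mixed chains approach 1
  set.seed(2)
  y <- matrix(rnorm(20000), ncol = 2)
  expect_equal(rhat(y), 1, tolerance = 0.01)
  # constant disagreeing chains are flagged
  expect_warning(r <- rhat(cbind(rep(0, 12), rep(10, 12))), "disagree")
  expect_identical(r, Inf)
  expect_warning(r0 <- rhat(cbind(rep(3, 12), rep(3, 12))), "undefined")
  expect_true(is.na(r0))
  expect_error(rhat(matrix(1:20, ncol = 1)), "2 chains")
  expect_error(rhat(matrix(1:2, ncol = 2)), "2 retained")
})

test_that("same seed and config give identical draws", {
  gd <- shared_sim()$data
  cfg <- mcmc_config(chains = 2, iterations = 300, burnin = 150, thin = 3, seed = 44)
  f1 <- suppressWarnings(sample_posterior(gd, trait_structure(alpha = "sla"), cfg))
  f2 <- suppressWarnings(sample_posterior(gd, trait_structure(alpha = "sla"), cfg))
  expect_identical(f1$draws, f2$draws)
  cfg2 <- cfg
  cfg2$seed <- 45L
  f3 <- suppressWarnings(sample_posterior(gd, trait_structure(alpha = "sla"), cfg2))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("species parameters reconstruct exactly from coefficients and effects", {
  fit <- shared_trait_fit()
  z <- standardize_traits(shared_sim()$data$traits, fit$stats)
  z <- z[match(fit$species, z$species), ]
  m <- posterior_matrix(fit)
  for (p in c("alpha", "b", "c")) {
    tr <- fit$structure[[p]]
    # rebuild: beta0 + slope * z + eps, species by species
    for (j in seq_along(fit$species)) {
      rebuilt <- m[, paste0("beta0_", p)]
      for (t in tr) rebuilt <- rebuilt + m[, paste0("beta_", p, "_", t)] * z[[t]][j]
      rebuilt <- rebuilt + m[, sprintf("eps_%s[%s]", p, fit$species[j])]
      expect_equal(m[, sprintf("%s[%s]", p, fit$species[j])], exp(rebuilt),
        tolerance = 1e-10
      )
    }
    # positivity from the log link
    expect_true(all(m[, sprintf("%s[%s]", p, fit$species)] > 0))
  }
})

test_that("conjugate reduction matches the analytic normal posterior", {
  # all non-location parameters pinned: the model reduces to estimating the
  # log-asymptote of each species under a Normal prior -> conjugate posterior
  ages <- c(1, 3, 5, 8, 12, 20)
  hts1 <- c(14, 38, 60, 82, 95, 101)
  hts2 <- c(6, 15, 26, 33, 41, 44)
  gd <- growth_data(
    tibble::tibble(
      individual_id = sprintf("i%d", 1:12),
      species = rep(c("s1", "s2"), each = 6), ecosystem = "e",
      age_yrs = rep(ages, 2), height_cm = c(hts1, hts2)
    ),
    toy_traits(c("s1", "s2"))
  )
  b0 <- 0.8
  c0 <- 4
  sig <- 0.3
  m0 <- 4
  tau0 <- 0.5
  fit <- suppressWarnings(sample_posterior(
    gd, trait_structure(),
    config = mcmc_config(
      chains = 3, iterations = 2000, burnin = 1000,
      thin = 2, seed = 31
    ),
    fixed = list(
      log_b = log(b0), log_c = log(c0), sigma = sig,
      re_sd = c(alpha = tau0, b = 0.1, c = 0.1),
      beta = list(alpha = m0, b = log(b0), c = log(c0))
    )
  ))
  k <- plogis(b0 * (ages - c0), log.p = TRUE)
  for (sp in c("s1", "s2")) {
    y <- log(gd$heights$height_cm[gd$heights$species == sp]) - k
    prec <- length(y) / sig^2 + 1 / tau0^2
    m_post <- (sum(y) / sig^2 + m0 / tau0^2) / prec
    draws <- log(posterior_matrix(fit, sprintf("alpha[%s]", sp))[, 1])
    expect_equal(mean(draws), m_post, tolerance = 0.04)
    expect_equal(sd(draws), sqrt(1 / prec), tolerance = 0.03)
  }
})

test_that("sample_posterior insists on one ecosystem, fit_ensemble on several", {
  cfg <- simulation_config(list(
    ecosystem_config("e1", n_species = 4, n_individuals = 6),
    ecosystem_config("e2", n_species = 4, n_individuals = 6)
  ))
  sim <- generate_multi_ecosystem(cfg, seed = 12)
  expect_error(
    sample_posterior(sim$data, config = quick_mcmc()),
    "fit_ensemble"
  )
  expect_error(
    fit_ensemble(filter_ecosystem(sim$data, "e1"), config = quick_mcmc()),
    "sample_posterior"
  )
})

test_that("ensemble model recovers opposed ecosystem intercept offsets", {
  cfg <- simulation_config(
    list(
      ecosystem_config("hi",
        n_species = 8, n_individuals = 10,
        log_mean_offsets = c(alpha = 1, b = 0, c = 0)
      ),
      ecosystem_config("lo",
        n_species = 8, n_individuals = 10,
        log_mean_offsets = c(alpha = -1, b = 0, c = 0)
      )
    ),
    slopes = tibble::tibble(
      parameter = character(0), trait = character(0),
      value = numeric(0)
    ),
    re_sd = c(alpha = 0.15, b = 0.1, c = 0.15), sigma_obs = 0.15
  )
  sim <- generate_multi_ecosystem(cfg, seed = 88)
  fit <- suppressWarnings(fit_ensemble(
    sim$data, trait_structure(),
    config = mcmc_config(
      chains = 3, iterations = 3000, burnin = 1500,
      thin = 3, seed = 90
    )
  ))
  m <- posterior_matrix(fit, c("delta_alpha_hi", "delta_alpha_lo"))
  diff_post <- mean(m[, "delta_alpha_hi"] - m[, "delta_alpha_lo"])
  expect_equal(diff_post, 2, tolerance = 0.4)
})

test_that("tidy and glance summarise a fit", {
  fit <- shared_trait_fit()
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high", "rhat") %in% names(td)))
  expect_true("beta_alpha_sla" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$n_species, 10)
  expect_equal(gl$n_chains, 3)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("draws export writes a tidy CSV and manifest", {
  dir <- withr::local_tempdir()
  fit <- shared_trait_fit()
  paths <- write_draws(fit, dir)
  long <- readr::read_csv(paths["draws"], show_col_types = FALSE)
  expect_equal(sort(unique(long$chain)), 1:3)
  expect_true("sigma" %in% long$quantity)
  man <- jsonlite::read_json(paths["manifest"])
  expect_equal(man$seed, fit$config$seed)
})
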