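test_that("log prior sums its closed-form component densities", {
  p <- model_params(b0 = c(s1 = 0, s2 = 0), eps = c(a = 0, b = 0),
                    sd_eps = 5)
  pr <- prior_spec()   # Normal(0, 1000) coefficients, Uniform(0, 10) sd
  # 7 fixed effects at 0, uniform sd density 1/10, two N(0, 5) at 0
  expected <- 7 * (-log(1000) - 0.5 * log(2 * pi)) - log(10) +
    2 * (-log(5) - 0.5 * log(2 * pi))
  expect_equal(log_prior(p, pr), expected, tolerance = 1e-12)

  # outside the sd support
  p$sd_eps <- 11
  expect_identical(log_prior(p, pr), -Inf)
  p$sd_eps <- -0.1
  expect_identical(log_prior(p, pr), -Inf)

  # a wider coefficient prior shrinks the quadratic penalty of a nonzero
  # coefficient toward zero (density relative to the all-zero vector)
  p2 <- model_params(b0 = c(s1 = 500, s2 = 0), eps = c(a = 0, b = 0),
                     sd_eps = 5)
  p0 <- model_params(b0 = c(s1 = 0, s2 = 0), eps = c(a = 0, b = 0),
                     sd_eps = 5)
  pen <- function(sd) log_prior(p2, prior_spec(coef_sd = sd)) -
    log_prior(p0, prior_spec(coef_sd = sd))
  expect_gt(pen(2000), pen(1000))
  expect_lt(pen(2000), 0)

  # sd_eps = 0 only supports all-zero random effects
  p3 <- model_params(b0 = c(s1 = 0), eps = c(a = 0.2), sd_eps = 0)
  expect_identical(log_prior(p3, pr), -Inf)
})

test_that("Gelman-Rubin R-hat matches its defining formula", {
  # duplicate chains: B = 0, R-hat = sqrt((n-1)/n) = sqrt(3/4)
  ch <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(gelman_rubin_rhat(ch), sqrt(3 / 4), tolerance = 1e-12)

  # iid chains from one distribution: R-hat ~ 1
  set.seed(11)
  iid <- matrix(rnorm(3 * 10000), 3, 10000)
  expect_gt(gelman_rubin_rhat(iid), 0.99)
  expect_lt(gelman_rubin_rhat(iid), 1.01)

  # chains stuck at different levels: far above 1.1
  set.seed(12)
  apart <- rbind(rnorm(500, 0, 1), rnorm(500, 100, 1))
  expect_gt(gelman_rubin_rhat(apart), 10)

  # constant chains: undefined
  expect_warning(r <- gelman_rubin_rhat(rbind(rep(2, 5), rep(2, 5))),
                 "undefined")
  expect_true(is.na(r))
  expect_error(gelman_rubin_rhat(matrix(1:4, 1)), "at least 2 chains")
})

test_that("posterior summaries use pooled draws and type-7 quantiles", {
  # constant parameter
  s <- summarize_posterior(list(theta = rbind(rep(3, 10), rep(3, 10))))
  expect_equal(s$mean, 3)
  expect_equal(s$sd, 0)
  expect_equal(s$q2.5, 3)
  expect_equal(s$q97.5, 3)
  expect_true(is.na(s$rhat))

  # pooled 1..100: linear-interpolation 2.5% quantile = 1 + 0.025*99
  ch <- list(x = rbind(1:50, 51:100))
  s2 <- summarize_posterior(ch)
  expect_equal(s2$q2.5, 3.475)
  expect_equal(s2$q97.5, 97.525)
  expect_equal(s2$mean, 50.5)
  expect_equal(s2$sd, sd(1:100))

  # rhat column equals the diagnostic applied per parameter
  set.seed(4)
  two <- list(a = matrix(rnorm(400), 2), b = matrix(rnorm(400, 5), 2))
  s3 <- summarize_posterior(two)
  expect_equal(s3$rhat[1], gelman_rubin_rhat(two$a))
  expect_equal(s3$rhat[2], gelman_rubin_rhat(two$b))
})

test_that("MLE recovers a known sigma and shifts with the intercept", {
  truth <- single_species_truth(sigma = 3, N = 12000, seed = 21)
  rec <- simulate_survey(truth)
  expect_gt(nrow(rec), 4000)
  cfg <- survey_config(10, "site1")
  ct <- center_covariates(truth$traits)
  fit <- fit_mle(rec, ct, cfg)
  expect_equal(fit$convergence, 0)
  expect_false(fit$boundary)
  expect_equal(unname(fit$par["b0[site1]"]), log(3), tolerance = 0.05)

  # equivariance: scaling the generating sigma by e^0.4 shifts b0 by 0.4
  truth2 <- single_species_truth(sigma = 3 * exp(0.4), N = 12000, seed = 21)
  rec2 <- simulate_survey(truth2)
  fit2 <- fit_mle(rec2, ct, cfg)
  expect_equal(unname(fit2$par["b0[site1]"] - fit$par["b0[site1]"]), 0.4,
               tolerance = 0.06)

  # near-uniform distances leave sigma unidentified: flagged, not silent
  set.seed(22)
  unif_rec <- data.frame(species_id = "spA", site_id = "site1",
                         distance_m = runif(400, 0, 10))
  expect_warning(fitu <- fit_mle(unif_rec, ct, cfg), "not identified")
  expect_true(fitu$boundary)
})

test_that("the sampler is seed-deterministic and agrees with the MLE", {
  truth <- single_species_truth(sigma = 3, N = 1500, seed = 31)
  rec <- simulate_survey(truth)
  cfg <- survey_config(10, "site1")
  ct <- center_covariates(truth$traits)
  mc <- mcmc_config(n_chains = 2, n_iter = 1500, n_burnin = 750, seed = 9)

  ch1 <- run_mcmc(rec, ct, cfg, mcmc = mc)
  ch2 <- run_mcmc(rec, ct, cfg, mcmc = mc)
  expect_identical(ch1$draws, ch2$draws)

  # posterior mean of b0 within 3 posterior sd of the ML estimate
  mle <- fit_mle(rec, ct, cfg)
  s <- summarize_posterior(ch1)
  b0row <- s[s$parameter == "b0[site1]", ]
  expect_lt(abs(b0row$mean - mle$par["b0[site1]"]), 3 * b0row$sd)
})

test_that("with no data the sampler returns the prior", {
  tr <- simulate_traits(2, seed = 3)
  cfg <- survey_config(10, c("A", "B"))
  ct <- center_covariates(tr)
  empty <- data.frame(species_id = character(0), site_id = character(0),
                      distance_m = numeric(0))
  ch <- run_mcmc(empty, ct, cfg,
                 mcmc = mcmc_config(n_chains = 3, n_iter = 8000,
                                    n_burnin = 4000, seed = 5))
  s <- summarize_posterior(ch)
  fixed <- s[grepl("^b", s$parameter), ]
  expect_equal(nrow(fixed), 7L)   # 2 intercepts + 5 coefficients
  # prior recovery: Normal(0, 1000) marginals
  expect_true(all(abs(fixed$sd - 1000) / 1000 < 0.10))
  # sd_eps covers its Uniform(0, 10) prior
  sdrow <- s[s$parameter == "sd_eps", ]
  expect_equal(sdrow$mean, 5, tolerance = 0.2)
})

test_that("configuration objects validate their inputs", {
  expect_error(mcmc_config(n_iter = 100, n_burnin = 100), "smaller")
  expect_error(prior_spec(coef_sd = -1), "positive")
  expect_error(survey_config(0, "a"), "positive")
  expect_error(survey_config(10, c("a", "a")), "unique")
})
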