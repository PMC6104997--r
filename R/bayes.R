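#' Prior specification
#'
#' Uninformative priors: every fixed effect (site intercepts and trait
#' coefficients) gets an independent Normal(0, coef_sd) prior with
#' \code{coef_sd = 1000} (precision 1e-6); the random-effect standard
#' deviation gets a Uniform(0, sd_eps_upper) prior with upper bound 10.
#'
#' @param coef_sd prior standard deviation for fixed effects.
#' @param sd_eps_upper upper bound of the uniform prior on the
#'   random-effect standard deviation.
#' @return A \code{prior_spec} list.
#' @export
prior_spec <- function(coef_sd = 1000, sd_eps_upper = 10) {
  if (!is.numeric(coef_sd) || coef_sd <= 0) stop("'coef_sd' must be positive")
  if (!is.numeric(sd_eps_upper) || sd_eps_upper <= 0) {
    stop("'sd_eps_upper' must be positive")
  }
  structure(list(coef_sd = coef_sd, sd_eps_upper = sd_eps_upper),
            class = "prior_spec")
}

#' MCMC settings
#'
#' Defaults mirror a standard three-chain run: 10,000 iterations per chain
#' with the first 5,000 discarded as burn-in, no thinning. Proposal scales
#' adapt during burn-in only (Robbins-Monro on acceptance rate, empirical
#' per-coordinate scaling for the fixed-effect block) and are frozen
#' afterwards so the kept draws target the exact posterior.
#'
#' @param n_chains number of chains.
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burnin burn-in iterations discarded from each chain.
#' @param seed integer seed; chain c uses stream \code{seed + c}.
#' @return An \code{mcmc_config} list.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 10000, n_burnin = 5000,
                        seed = 1) {
  stopifnot(n_chains >= 1, n_iter >= 2, n_burnin >= 0)
  if (n_burnin >= n_iter) stop("'n_burnin' must be smaller than 'n_iter'")
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Log prior density of the model parameters
#'
#' Sum of Normal(0, coef_sd) log densities over all fixed effects, the
#' Normal(0, sd_eps) log densities of the species random effects, and the
#' Uniform(0, sd_eps_upper) log density of sd_eps. Returns \code{-Inf} when
#' sd_eps falls outside its support (or is 0 with nonzero random effects).
#'
#' @param params a \code{\link{model_params}}.
#' @param priors a \code{\link{prior_spec}}.
#' @return Log prior density.
#' @export
log_prior <- function(params, priors = prior_spec()) {
  fixed <- c(params$b0, params$bS, params$bS2, params$bH, params$bA,
             params$bA2)
  if (params$sd_eps < 0 || params$sd_eps > priors$sd_eps_upper) return(-Inf)
  lp <- sum(stats::dnorm(fixed, 0, priors$coef_sd, log = TRUE)) -
    log(priors$sd_eps_upper)
  if (length(params$eps) > 0L) {
    if (params$sd_eps == 0) {
      return(if (all(params$eps == 0)) lp else -Inf)
    }
    lp <- lp + sum(stats::dnorm(params$eps, 0, params$sd_eps, log = TRUE))
  }
  lp
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF on post-burn-in draws: with W the mean within-chain sample
#' variance and B/n the sample variance of the chain means,
#' R-hat = sqrt(((n-1)/n * W + B/n) / W). No rank normalisation, no chain
#' splitting and no (m+1)/m inflation; values below 1.1 are conventionally
#' taken as converged.
#'
#' @param chains numeric matrix of draws, one row per chain.
#' @return R-hat, or \code{NA} (with a warning) when the within-chain
#'   variance is zero.
#' @export
gelman_rubin_rhat <- function(chains) {
  chains <- as.matrix(chains)
  m <- nrow(chains); n <- ncol(chains)
  if (m < 2L || n < 2L) stop("need at least 2 chains of length >= 2")
  W <- mean(apply(chains, 1L, stats::var))
  if (W == 0) {
    warning("within-chain variance is zero; R-hat undefined")
    return(NA_real_)
  }
  B_over_n <- stats::var(rowMeans(chains))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Posterior summary table
#'
#' Pooled-across-chains posterior mean, standard deviation, 2.5% and 97.5%
#' quantiles (linear-interpolation empirical quantiles, R type 7) and
#' per-parameter Gelman-Rubin R-hat. Rows are ordered site intercepts
#' first, then the five trait coefficients, then the random-effect sd,
#' then species random effects.
#'
#' @param chains a \code{posterior_chains} object from
#'   \code{\link{run_mcmc}}, or a named list of per-parameter chain
#'   matrices (rows = chains).
#' @return Data frame with columns \code{parameter}, \code{mean},
#'   \code{sd}, \code{q2.5}, \code{q97.5}, \code{rhat}.
#' @export
summarize_posterior <- function(chains) {
  draws <- if (inherits(chains, "posterior_chains")) chains$draws else chains
  if (length(draws) == 0L) stop("no parameters to summarise")
  rows <- lapply(names(draws), function(p) {
    x <- as.matrix(draws[[p]])
    pooled <- as.numeric(t(x))
    rhat <- if (nrow(x) >= 2L && ncol(x) >= 2L) {
      if (stats::var(pooled) == 0) NA_real_ else gelman_rubin_rhat(x)
    } else NA_real_
    q <- stats::quantile(pooled, c(0.025, 0.975), names = FALSE)
    data.frame(parameter = p, mean = mean(pooled), sd = stats::sd(pooled),
               q2.5 = q[1L], q97.5 = q[2L], rhat = rhat,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# canonical parameter name ordering for reports
.param_order <- function(sites, species) {
  c(paste0("b0[", sites, "]"), "bS", "bS2", "bH", "bA", "bA2", "sd_eps",
    if (length(species)) paste0("eps[", species, "]"))
}

# split a flat parameter vector into the pieces the likelihood consumes
.theta_split <- function(theta, n_sites, n_species) {
  list(b0 = theta[seq_len(n_sites)],
       beta = theta[n_sites + 1:5],
       eps = if (n_species) theta[n_sites + 5L + seq_len(n_species)]
             else numeric(0),
       sd_eps = theta[length(theta)])
}

#' Maximum-likelihood fit of the fixed effects
#'
#' Deterministic point estimation used for chain initialisation and for
#' fast tests: maximises the conditional distance-sampling likelihood over
#' the site intercepts and trait coefficients with all species random
#' effects held at zero. Site intercepts are initialised at the log of the
#' per-site moment estimate of sigma.
#'
#' @inheritParams dataset_loglik
#' @return List with \code{par} (named fixed-effect estimates),
#'   \code{loglik}, \code{convergence} (0 = optimiser converged) and
#'   \code{boundary} (TRUE when an intercept ran to an implausibly large
#'   sigma, i.e. the uniform-density limit where sigma is unidentified).
#' @export
fit_mle <- function(records, ctraits, config) {
  if (nrow(records) == 0L) stop("cannot fit an empty record set")
  ss <- .suffstats(records, ctraits, config)
  n_sites <- length(config$sites)
  eps0 <- numeric(length(ss$species_ids))
  # moment init: for half-normal with generous w, E[d^2] ~ sigma^2
  b0_init <- vapply(seq_len(n_sites), function(j) {
    rows <- ss$site == j
    if (!any(rows)) return(0)
    0.5 * log(sum(ss$sumd2[rows]) / sum(ss$n[rows]) + 1e-8)
  }, numeric(1))
  par0 <- c(b0_init, rep(0, 5))
  negll <- function(p) {
    val <- -.loglik_ss(ss, p[seq_len(n_sites)], p[n_sites + 1:5], eps0)
    if (!is.finite(val)) 1e10 else val
  }
  opt <- stats::optim(par0, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  if (opt$convergence != 0 && opt$convergence != 1) {
    stop("MLE optimisation failed (code ", opt$convergence, ")")
  }
  par <- opt$par
  names(par) <- c(paste0("b0[", config$sites, "]"),
                  "bS", "bS2", "bH", "bA", "bA2")
  boundary <- any(par[seq_len(n_sites)] > log(100 * config$truncation_w_m))
  if (boundary) {
    warning("a site intercept ran to the uniform-density limit; ",
            "sigma is not identified there")
  }
  list(par = par, loglik = -opt$value, convergence = opt$convergence,
       boundary = boundary)
}

#' Sample the posterior by adaptive Metropolis-within-Gibbs
#'
#' Blocked random-walk Metropolis sampler for the hierarchical detection
#' model: the fixed effects (site intercepts + 5 trait coefficients) are
#' proposed jointly, each species random effect singly (its likelihood
#' contribution only touches that species' records), and the random-effect
#' sd singly with reflection at its [0, upper] support. Because each trait
#' coefficient trades off against the species random effects along a flat
#' likelihood ridge, the sampler adds likelihood-invariant recentering
#' moves (coefficient shifted, every random effect compensated so all log
#' sigma stay fixed) whose acceptance depends only on the priors.
#' Proposal scales
#' adapt towards standard acceptance targets (0.25 joint, 0.44 scalar)
#' during burn-in and are frozen afterwards. Chains start from the
#' maximum-likelihood fixed effects (zero on failure) with seeded
#' per-chain jitter so they are over-dispersed.
#'
#' @inheritParams dataset_loglik
#' @param priors a \code{\link{prior_spec}}.
#' @param mcmc an \code{\link{mcmc_config}}.
#' @param init optional named numeric vector of fixed-effect starting
#'   values (as returned in \code{fit_mle()$par}); computed internally
#'   when NULL.
#' @param verbose print per-chain acceptance rates.
#' @return A \code{posterior_chains} object: \code{draws} is a named list
#'   (canonical parameter order) of chains x kept-iterations matrices;
#'   \code{acceptance} holds per-chain acceptance rates per block.
#' @export
run_mcmc <- function(records, ctraits, config, priors = prior_spec(),
                     mcmc = mcmc_config(), init = NULL, verbose = FALSE) {
  n_sites <- length(config$sites)
  if (nrow(records) > 0L) {
    ss <- .suffstats(records, ctraits, config)
  } else {
    # prior-only run: no likelihood contribution, random effects for every
    # species in the trait table
    ss <- list(n = integer(0), sumd2 = numeric(0),
               X = matrix(0, 0, 5), site = integer(0), spec = integer(0),
               species_ids = as.character(ctraits$species_id),
               w = config$truncation_w_m, n_total = 0L)
  }
  species <- ss$species_ids
  n_species <- length(species)
  # row indices of each species' sufficient-statistic rows
  sp_rows <- lapply(seq_len(n_species), function(i) which(ss$spec == i))
  # per-species covariate matrix (for likelihood-invariant ridge moves)
  Xs <- {
    ti <- match(species, ctraits$species_id)
    cbind(ctraits$S[ti], ctraits$S2[ti], ctraits$H[ti], ctraits$L[ti],
          ctraits$L2[ti])
  }

  if (is.null(init)) {
    init <- if (ss$n_total > 0L) {
      tryCatch(fit_mle(records, ctraits, config)$par,
               error = function(e) NULL, warning = function(w) NULL)
    } else NULL
  }
  fixed_init <- if (is.null(init)) rep(0, n_sites + 5L) else unname(init)

  n_fixed <- n_sites + 5L
  n_kept <- mcmc$n_iter - mcmc$n_burnin
  param_names <- .param_order(config$sites, species)
  draws <- lapply(param_names, function(p) {
    matrix(NA_real_, mcmc$n_chains, n_kept)
  })
  names(draws) <- param_names
  acc_all <- vector("list", mcmc$n_chains)

  lp_fixed_prior <- function(fx) sum(stats::dnorm(fx, 0, priors$coef_sd,
                                                  log = TRUE))

  for (chain in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + chain)
    # over-dispersed but sane starting points
    fx <- fixed_init + stats::rnorm(n_fixed, 0, 0.15)
    eps <- stats::rnorm(n_species, 0, 0.05)
    sd_eps <- stats::runif(1, 0.05, 0.5)

    ll <- .loglik_ss(ss, fx[seq_len(n_sites)], fx[n_sites + 1:5], eps)
    tries <- 0L
    while (!is.finite(ll) && tries < 20L) {
      fx <- fixed_init + stats::rnorm(n_fixed, 0, 0.05)
      eps <- numeric(n_species)
      ll <- .loglik_ss(ss, fx[seq_len(n_sites)], fx[n_sites + 1:5], eps)
      tries <- tries + 1L
    }
    if (!is.finite(ll)) stop("could not find finite starting log-posterior")

    # adaptive proposal state
    scale_f <- 2.38 / sqrt(n_fixed)
    sds_f <- rep(0.1, n_fixed)
    if (ss$n_total == 0L) sds_f <- rep(priors$coef_sd / 10, n_fixed)
    scale_e <- rep(0.3, max(n_species, 1L))
    scale_s <- 0.2
    scale_r <- rep(0.1, 6L)   # 5 coefficient ridge moves + intercept shift
    acc <- c(fixed = 0, eps = 0, sd_eps = 0, ridge = 0)
    n_prop <- c(fixed = 0, eps = 0, sd_eps = 0, ridge = 0)
    hist_f <- matrix(NA_real_, 500L, n_fixed)

    for (t in seq_len(mcmc$n_iter)) {
      adapting <- t <= mcmc$n_burnin
      gam <- if (adapting) min(0.1, 5 / sqrt(t)) else 0

      ## -- fixed-effect block --
      prop <- fx + scale_f * sds_f * stats::rnorm(n_fixed)
      ll_p <- .loglik_ss(ss, prop[seq_len(n_sites)], prop[n_sites + 1:5],
                         eps)
      lr <- (ll_p + lp_fixed_prior(prop)) - (ll + lp_fixed_prior(fx))
      a <- is.finite(lr) && log(stats::runif(1)) < lr
      if (a) { fx <- prop; ll <- ll_p }
      acc["fixed"] <- acc["fixed"] + a; n_prop["fixed"] <- n_prop["fixed"] + 1
      if (adapting) {
        scale_f <- scale_f * exp(gam * ((a * 1) - 0.25))
        hist_f[(t - 1L) %% 500L + 1L, ] <- fx
        if (t %% 250L == 0L && t >= 500L) {
          emp <- apply(hist_f, 2L, stats::sd)
          ok <- is.finite(emp) & emp > 0
          sds_f[ok] <- emp[ok]
        }
      }

      ## -- species random effects, one at a time --
      if (n_species > 0L) {
        z <- stats::rnorm(n_species)
        u <- stats::runif(n_species)
        for (i in seq_len(n_species)) {
          e_new <- eps[i] + scale_e[i] * z[i]
          rows <- sp_rows[[i]]
          eps_try <- eps; eps_try[i] <- e_new
          dll <- if (length(rows)) {
            .loglik_ss(ss, fx[seq_len(n_sites)], fx[n_sites + 1:5],
                       eps_try, rows) -
              .loglik_ss(ss, fx[seq_len(n_sites)], fx[n_sites + 1:5],
                         eps, rows)
          } else 0
          lr <- dll + stats::dnorm(e_new, 0, sd_eps, log = TRUE) -
            stats::dnorm(eps[i], 0, sd_eps, log = TRUE)
          a <- is.finite(lr) && log(u[i]) < lr
          if (a) { eps <- eps_try; ll <- ll + dll }
          acc["eps"] <- acc["eps"] + a; n_prop["eps"] <- n_prop["eps"] + 1
          if (adapting) scale_e[i] <- scale_e[i] * exp(gam * ((a * 1) - 0.44))
        }
      }

      ## -- likelihood-invariant ridge moves --
      # a trait coefficient and the random effects trade off along a flat
      # ridge of the likelihood: shifting beta_k by delta while subtracting
      # delta * x_ik from every eps_i leaves all log sigma unchanged, so
      # the acceptance ratio involves only the priors. These moves let the
      # chain traverse the ridge quickly; the eps shrinkage prior then
      # decides where along it the mass sits. Move 6 shifts all site
      # intercepts jointly against the random effects in the same way.
      if (n_species > 0L && sd_eps > 0) {
        for (k in seq_len(6L)) {
          # step size proportional to the current random-effect sd: the
          # posterior width along the ridge scales with sd_eps, and
          # sd-relative steps let excursions to large sd_eps diffuse back
          delta <- scale_r[k] * max(sd_eps, 1e-3) * stats::rnorm(1)
          if (k <= 5L) {
            bk <- fx[n_sites + k]
            eps_new <- eps - delta * Xs[, k]
            lr <- stats::dnorm(bk + delta, 0, priors$coef_sd, log = TRUE) -
              stats::dnorm(bk, 0, priors$coef_sd, log = TRUE) +
              sum(stats::dnorm(eps_new, 0, sd_eps, log = TRUE)) -
              sum(stats::dnorm(eps, 0, sd_eps, log = TRUE))
            a <- is.finite(lr) && log(stats::runif(1)) < lr
            if (a) { fx[n_sites + k] <- bk + delta; eps <- eps_new }
          } else {
            b0_new <- fx[seq_len(n_sites)] + delta
            eps_new <- eps - delta
            lr <- sum(stats::dnorm(b0_new, 0, priors$coef_sd, log = TRUE)) -
              sum(stats::dnorm(fx[seq_len(n_sites)], 0, priors$coef_sd,
                               log = TRUE)) +
              sum(stats::dnorm(eps_new, 0, sd_eps, log = TRUE)) -
              sum(stats::dnorm(eps, 0, sd_eps, log = TRUE))
            a <- is.finite(lr) && log(stats::runif(1)) < lr
            if (a) { fx[seq_len(n_sites)] <- b0_new; eps <- eps_new }
          }
          acc["ridge"] <- acc["ridge"] + a
          n_prop["ridge"] <- n_prop["ridge"] + 1
          if (adapting) scale_r[k] <- scale_r[k] * exp(gam * ((a * 1) - 0.44))
        }
      }

      ## -- random-effect sd, reflected at [0, upper] --
      s_new <- sd_eps + scale_s * stats::rnorm(1)
      up <- priors$sd_eps_upper
      # reflect into support (period 2*up)
      s_new <- abs(s_new) %% (2 * up)
      if (s_new > up) s_new <- 2 * up - s_new
      lr <- if (n_species > 0L && s_new > 0 && sd_eps > 0) {
        sum(stats::dnorm(eps, 0, s_new, log = TRUE)) -
          sum(stats::dnorm(eps, 0, sd_eps, log = TRUE))
      } else if (n_species == 0L) 0 else -Inf
      a <- is.finite(lr) && log(stats::runif(1)) < lr
      if (a) sd_eps <- s_new
      acc["sd_eps"] <- acc["sd_eps"] + a
      n_prop["sd_eps"] <- n_prop["sd_eps"] + 1
      if (adapting) scale_s <- scale_s * exp(gam * ((a * 1) - 0.44))

      ## -- record --
      if (t > mcmc$n_burnin) {
        k <- t - mcmc$n_burnin
        for (j in seq_len(n_sites)) draws[[j]][chain, k] <- fx[j]
        draws[["bS"]][chain, k] <- fx[n_sites + 1L]
        draws[["bS2"]][chain, k] <- fx[n_sites + 2L]
        draws[["bH"]][chain, k] <- fx[n_sites + 3L]
        draws[["bA"]][chain, k] <- fx[n_sites + 4L]
        draws[["bA2"]][chain, k] <- fx[n_sites + 5L]
        draws[["sd_eps"]][chain, k] <- sd_eps
        if (n_species > 0L) {
          for (i in seq_len(n_species)) {
            draws[[n_sites + 6L + i]][chain, k] <- eps[i]
          }
        }
      }
    }
    acc_all[[chain]] <- acc / pmax(n_prop, 1)
    if (verbose) {
      message(sprintf("chain %d acceptance: fixed %.2f, eps %.2f, sd %.2f",
                      chain, acc_all[[chain]]["fixed"],
                      acc_all[[chain]]["eps"], acc_all[[chain]]["sd_eps"]))
    }
  }

  structure(list(draws = draws, acceptance = acc_all,
                 sites = config$sites, species = species,
                 mcmc = mcmc, priors = priors),
            class = "posterior_chains")
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat(sprintf("Posterior draws: %d chains x %d kept iterations, %d parameters\n",
              nrow(x$draws[[1L]]), ncol(x$draws[[1L]]), length(x$draws)))
  invisible(x)
}

#' Posterior means as a model_params object
#'
#' Collapses posterior draws to their means and packs them into a
#' \code{\link{model_params}}, ready for prediction.
#'
#' @param chains a \code{posterior_chains} object.
#' @return A \code{\link{model_params}}.
#' @export
posterior_mean_params <- function(chains) {
  m <- vapply(chains$draws, function(d) mean(as.matrix(d)), numeric(1))
  b0 <- m[paste0("b0[", chains$sites, "]")]
  names(b0) <- chains$sites
  eps <- if (length(chains$species)) {
    e <- m[paste0("eps[", chains$species, "]")]
    names(e) <- chains$species
    e
  } else numeric(0)
  model_params(b0 = b0, bS = m[["bS"]], bS2 = m[["bS2"]], bH = m[["bH"]],
               bA = m[["bA"]], bA2 = m[["bA2"]], eps = eps,
               sd_eps = m[["sd_eps"]])
}
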