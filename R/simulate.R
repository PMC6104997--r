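#' Simulate species trait tables
#'
#' Draws a species-level trait table with the spread typical of exotic
#' understorey shrubs, herbs and small trees in tropical montane forest:
#' leaf sizes (square-root leaf area) roughly 2-20 cm, right-skewed leaf
#' dissection indices bounded below by the circular minimum 2*sqrt(pi), and
#' plant heights roughly 0.1-5 m.
#'
#' @param n_species number of species (default 25).
#' @param seed integer seed; the table is reproducible given the seed.
#' @return Data frame with columns \code{species_id}, \code{height_m},
#'   \code{leaf_size_cm}, \code{leaf_shape}, \code{n_samples}.
#' @export
simulate_traits <- function(n_species = 25, seed = 1) {
  stopifnot(n_species >= 1)
  set.seed(seed)
  sp <- sprintf("sp%02d", seq_len(n_species))
  leaf_size <- pmin(pmax(stats::rlnorm(n_species, log(7), 0.45), 2), 20)
  shape <- 2 * sqrt(pi) + stats::rgamma(n_species, shape = 2, scale = 1.6)
  height <- pmin(pmax(stats::rlnorm(n_species, log(1.2), 0.65), 0.1), 5)
  data.frame(species_id = sp, height_m = height, leaf_size_cm = leaf_size,
             leaf_shape = shape,
             n_samples = stats::rpois(n_species, 3) + 1L,
             stringsAsFactors = FALSE)
}

#' Ground truth for a simulated survey
#'
#' Bundles everything the forward model needs: true regression parameters,
#' true species traits, per species-by-site abundances inside the surveyed
#' strip, the truncation distance and a seed. The default parameter vector
#' uses site intercepts near 0.8-1.35, a height coefficient of 0.136 and a
#' random-effect sd of 0.168 — magnitudes typical of fitted understorey
#' detectability models — so the default fixture behaves like a realistic
#' survey.
#'
#' @param params a \code{\link{model_params}} (without \code{eps}: true
#'   random effects are drawn by \code{\link{simulate_survey}} from
#'   Normal(0, sd_eps)).
#' @param traits trait table as from \code{\link{simulate_traits}}.
#' @param abundance matrix (species x site, dimnames required) of true
#'   individual counts inside the strip.
#' @param truncation_w_m truncation distance (m).
#' @param seed integer seed for the survey draw.
#' @return A \code{simulation_truth} list.
#' @export
simulation_truth <- function(params, traits, abundance,
                             truncation_w_m = 10, seed = 1) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(rownames(abundance)) || is.null(colnames(abundance))) {
    stop("'abundance' needs species rownames and site colnames")
  }
  if (any(abundance < 0) || any(abundance != round(abundance))) {
    stop("abundances must be non-negative integers")
  }
  if (!all(rownames(abundance) %in% traits$species_id)) {
    stop("abundance rows must match trait table species")
  }
  if (!all(colnames(abundance) %in% names(params$b0))) {
    stop("abundance columns must match sites in params$b0")
  }
  structure(list(params = params, traits = traits, abundance = abundance,
                 truncation_w_m = truncation_w_m, seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Default simulation truth
#'
#' A four-site, 25-species truth with realistic parameter magnitudes and
#' right-skewed abundances calibrated to yield on the order of 1300
#' detections in total — the size of a season-long multi-garden survey.
#'
#' @param seed integer seed controlling traits, abundances and (downstream)
#'   the survey draw.
#' @param n_species number of species.
#' @param bH,bA,bA2,bS,bS2 true trait coefficients.
#' @param sd_eps true random-effect standard deviation.
#' @return A \code{\link{simulation_truth}}.
#' @export
default_truth <- function(seed = 1, n_species = 25,
                          bS = 0.012, bS2 = 0, bH = 0.136, bA = 0,
                          bA2 = 0.007, sd_eps = 0.168) {
  traits <- simulate_traits(n_species, seed = seed)
  sites <- c("Bali", "Baturraden", "Cibodas", "Kuningan")
  params <- model_params(
    b0 = c(Bali = 1.197, Baturraden = 0.989, Cibodas = 1.34,
           Kuningan = 0.804),
    bS = bS, bS2 = bS2, bH = bH, bA = bA, bA2 = bA2, sd_eps = sd_eps)
  set.seed(seed + 1L)
  ab <- matrix(stats::rnbinom(n_species * length(sites), mu = 35,
                              size = 0.9),
               n_species, length(sites),
               dimnames = list(traits$species_id, sites))
  simulation_truth(params, traits, ab, truncation_w_m = 10, seed = seed)
}

#' Simulate a line-transect survey
#'
#' Forward model of the trait-based detection analysis. For every species
#' at every site, the true number of individuals inside the strip is placed
#' at perpendicular distances uniform on [0, w] (the standard
#' distance-sampling placement assumption); each individual is detected
#' independently with probability g(d; sigma_ij), where log sigma_ij
#' follows the trait regression with a species random effect drawn from
#' Normal(0, sd_eps). Only detected individuals are returned, as in field
#' data.
#'
#' @param truth a \code{\link{simulation_truth}}.
#' @param seed optional integer overriding \code{truth$seed}.
#' @return A \code{detection records} data frame (\code{species_id},
#'   \code{site_id}, \code{distance_m}) with attributes \code{eps_true}
#'   (the drawn random effects) and \code{n_placed} (total individuals
#'   placed).
#' @export
simulate_survey <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (is.null(seed)) seed <- truth$seed
  set.seed(seed)
  w <- truth$truncation_w_m
  sites <- colnames(truth$abundance)
  species <- rownames(truth$abundance)
  ctr <- center_covariates(truth$traits, species)
  eps <- stats::rnorm(length(species), 0, truth$params$sd_eps)
  names(eps) <- species
  par_eps <- truth$params
  par_eps$eps <- eps

  out <- vector("list", length(species) * length(sites))
  k <- 0L
  n_placed <- 0L
  for (si in sites) {
    lsig <- log_sigma(species, rep(si, length(species)), par_eps, ctr)
    sig <- exp(lsig)
    for (ii in seq_along(species)) {
      N <- truth$abundance[species[ii], si]
      if (N == 0) next
      n_placed <- n_placed + N
      d <- stats::runif(N, 0, w)
      det <- stats::runif(N) < half_normal_g(d, sig[ii])
      if (any(det)) {
        k <- k + 1L
        out[[k]] <- data.frame(species_id = species[ii], site_id = si,
                               distance_m = d[det],
                               stringsAsFactors = FALSE)
      }
    }
  }
  rec <- if (k > 0L) do.call(rbind, out[seq_len(k)]) else {
    data.frame(species_id = character(0), site_id = character(0),
               distance_m = numeric(0))
  }
  rownames(rec) <- NULL
  attr(rec, "eps_true") <- eps
  attr(rec, "n_placed") <- n_placed
  rec
}

#' Parameter-recovery experiment
#'
#' Simulates \code{n_replicates} surveys from a fixed truth, refits the
#' hierarchical model to each, and scores recovery of every fixed effect
#' and the random-effect sd: bias of the posterior mean, RMSE, and the
#' coverage rate of the 95 percent credible interval.
#'
#' @param truth a \code{\link{simulation_truth}}.
#' @param n_replicates number of simulated surveys.
#' @param mcmc an \code{\link{mcmc_config}} used for every refit (replicate
#'   r shifts the seed by r).
#' @param min_detections per-species detection threshold applied before
#'   fitting, as in the field analysis.
#' @param verbose print progress.
#' @return List with \code{report} (one row per parameter: truth, mean
#'   posterior mean, bias, rmse, coverage) and \code{fits} (per-replicate
#'   posterior summaries; failed replicates recorded as NULL with the error
#'   message in \code{errors}).
#' @export
parameter_recovery_experiment <- function(truth, n_replicates = 20,
                                          mcmc = mcmc_config(n_iter = 2000,
                                                             n_burnin = 1000),
                                          min_detections = 5,
                                          verbose = FALSE) {
  stopifnot(n_replicates >= 1)
  sites <- colnames(truth$abundance)
  cfg <- survey_config(truth$truncation_w_m, sites)
  p <- truth$params
  true_vec <- c(stats::setNames(as.numeric(p$b0), paste0("b0[", names(p$b0), "]")),
                bS = p$bS, bS2 = p$bS2, bH = p$bH, bA = p$bA, bA2 = p$bA2,
                sd_eps = p$sd_eps)
  fits <- vector("list", n_replicates)
  errors <- character(n_replicates)
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      rec <- simulate_survey(truth, seed = truth$seed + 1000L * r)
      flt <- filter_min_detections(rec, min_detections)
      ctr <- center_covariates(truth$traits,
                               sort(unique(flt$kept$species_id)))
      mc <- mcmc; mc$seed <- mcmc$seed + r
      ch <- run_mcmc(flt$kept, ctr, cfg, mcmc = mc)
      summarize_posterior(ch)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errors[r] <- res
    } else {
      fits[[r]] <- res
    }
    if (verbose) message("replicate ", r, " done")
  }
  ok <- !vapply(fits, is.null, logical(1))
  report <- do.call(rbind, lapply(names(true_vec), function(pn) {
    est <- vapply(fits[ok], function(s) s$mean[s$parameter == pn], numeric(1))
    lo <- vapply(fits[ok], function(s) s$q2.5[s$parameter == pn], numeric(1))
    hi <- vapply(fits[ok], function(s) s$q97.5[s$parameter == pn], numeric(1))
    tv <- true_vec[[pn]]
    data.frame(parameter = pn, truth = tv,
               mean_estimate = mean(est), bias = mean(est) - tv,
               rmse = sqrt(mean((est - tv)^2)),
               coverage = mean(lo <= tv & tv <= hi),
               n_replicates = sum(ok), stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  list(report = report, fits = fits, errors = errors[errors != ""])
}
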