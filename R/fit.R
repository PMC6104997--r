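#' Fit the trait-based hierarchical detection model
#'
#' Central model-fitting interface. Takes detection records (one row per
#' detected individual: species, site, perpendicular distance) and a
#' species trait table, drops species with fewer than \code{min_detections}
#' detections, centers the trait covariates over the analysed species,
#' and samples the posterior of the truncated half-normal detection model
#'
#' \deqn{g_{ij}(d) = \exp(-d^2 / 2\sigma_{ij}^2)}
#' \deqn{\log \sigma_{ij} = b_{0j} + b_S S_i + b_{S2} S_i^2 + b_A L_i +
#'   b_{A2} L_i^2 + b_H H_i + \varepsilon_i}
#'
#' where S, H and L are centered species-level leaf shape (dissection
#' index), plant height (m) and leaf size (cm, square-root leaf area), and
#' the species random effects are Normal(0, sd_eps). The likelihood is the
#' conditional distance-sampling likelihood of the observed distances,
#' truncated at \code{truncation_w_m}.
#'
#' @param records data frame with columns \code{species_id},
#'   \code{site_id}, \code{distance_m}, e.g. from
#'   \code{\link{load_detections}} or \code{\link{simulate_survey}}.
#' @param traits species trait table with columns \code{species_id},
#'   \code{height_m}, \code{leaf_size_cm}, \code{leaf_shape}.
#' @param config a \code{\link{survey_config}}; defaults to truncation at
#'   10 m with the sites present in \code{records} in sorted order.
#' @param min_detections minimum detections per species (default 5).
#' @param priors a \code{\link{prior_spec}}.
#' @param mcmc an \code{\link{mcmc_config}}.
#' @param verbose print sampler progress.
#' @return An object of class \code{traitds_fit} with components
#'   \code{summary} (posterior summary table), \code{chains}
#'   (\code{posterior_chains}), \code{mle}, \code{ctraits}, \code{records}
#'   (analysed records), \code{dropped} (excluded-species report),
#'   \code{config}, \code{priors}, \code{mcmc} and \code{call}. Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{plot}, \code{simulate}.
#' @seealso \code{\link{run_pipeline}} for the file-to-file wrapper.
#' @examples
#' \donttest{
#' truth <- default_truth(seed = 7, n_species = 6)
#' rec <- simulate_survey(truth)
#' fit <- fit_detectability(rec, truth$traits,
#'                          mcmc = mcmc_config(n_iter = 400, n_burnin = 200))
#' fit
#' }
#' @export
fit_detectability <- function(records, traits, config = NULL,
                              min_detections = 5, priors = prior_spec(),
                              mcmc = mcmc_config(), verbose = FALSE) {
  cl <- match.call()
  req <- c("species_id", "site_id", "distance_m")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    stop("'records' needs columns species_id, site_id, distance_m")
  }
  if (is.null(config)) {
    config <- survey_config(10, sort(unique(as.character(records$site_id))))
  }
  if (any(records$distance_m < 0) ||
      any(records$distance_m > config$truncation_w_m)) {
    stop("record distances must lie within [0, truncation]; ",
         "use load_detections() to apply truncation")
  }
  flt <- filter_min_detections(records, min_detections)
  if (nrow(flt$kept) == 0L) {
    stop("no species reaches the detection threshold of ", min_detections)
  }
  species <- sort(unique(as.character(flt$kept$species_id)))
  ctraits <- center_covariates(traits, species)

  mle <- tryCatch(fit_mle(flt$kept, ctraits, config),
                  error = function(e) NULL, warning = function(w) NULL)
  chains <- run_mcmc(flt$kept, ctraits, config, priors = priors,
                     mcmc = mcmc, init = if (is.null(mle)) NULL else mle$par,
                     verbose = verbose)
  summ <- summarize_posterior(chains)

  structure(list(summary = summ, chains = chains, mle = mle,
                 ctraits = ctraits, records = flt$kept,
                 dropped = flt$dropped, config = config, priors = priors,
                 mcmc = mcmc, call = cl),
            class = "traitds_fit")
}

#' @export
print.traitds_fit <- function(x, ...) {
  cat("Trait-based hierarchical distance-sampling fit\n")
  cat(sprintf("  %d detections, %d species, %d sites; truncation %g m\n",
              nrow(x$records), length(x$chains$species),
              length(x$config$sites), x$config$truncation_w_m))
  cat(sprintf("  %d chains x %d iterations (burn-in %d)\n",
              x$mcmc$n_chains, x$mcmc$n_iter, x$mcmc$n_burnin))
  fixed <- x$summary[!grepl("^eps\\[", x$summary$parameter), , drop = FALSE]
  cat(sprintf("  max R-hat (fixed effects + sd): %.3f\n",
              max(fixed$rhat, na.rm = TRUE)))
  cat("\nPosterior means (fixed effects):\n")
  print(round(stats::setNames(fixed$mean, fixed$parameter), 3))
  invisible(x)
}

#' Posterior summary of a fitted detection model
#'
#' @param object a \code{traitds_fit}.
#' @param random include the per-species random-effect rows (default
#'   FALSE).
#' @param ... unused.
#' @return The posterior summary data frame (parameter, mean, sd, q2.5,
#'   q97.5, rhat).
#' @export
summary.traitds_fit <- function(object, random = FALSE, ...) {
  s <- object$summary
  if (!random) s <- s[!grepl("^eps\\[", s$parameter), , drop = FALSE]
  rownames(s) <- NULL
  class(s) <- c("summary.traitds_fit", "data.frame")
  s
}

#' @export
print.summary.traitds_fit <- function(x, ...) {
  cat("Posterior summary (mean, sd, 95% credible interval, R-hat):\n")
  print.data.frame(cbind(x["parameter"],
                         round(x[c("mean", "sd", "q2.5", "q97.5")], 3),
                         rhat = round(x$rhat, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
coef.traitds_fit <- function(object, random = FALSE, ...) {
  s <- summary(object, random = random)
  stats::setNames(s$mean, s$parameter)
}

#' Predict detectability from a fitted model
#'
#' Evaluates the fitted half-normal detection probability g(d) on a grid of
#' species, sites and distances, using posterior-mean parameters.
#'
#' @param object a \code{traitds_fit}.
#' @param newdata data frame with columns \code{species_id},
#'   \code{site_id}, \code{distance_m}; defaults to every analysed species
#'   at every site at distances 0, 2, 5 and 10 m.
#' @param include_random add the species random effect to log sigma
#'   (default TRUE; FALSE gives the trait-only prediction, also used for
#'   species outside the fitted set).
#' @param ... unused.
#' @return \code{newdata} with columns \code{sigma} and
#'   \code{detection_prob} appended.
#' @export
predict.traitds_fit <- function(object, newdata = NULL,
                                include_random = TRUE, ...) {
  pm <- posterior_mean_params(object$chains)
  if (is.null(newdata)) {
    newdata <- expand.grid(species_id = object$chains$species,
                           site_id = object$config$sites,
                           distance_m = c(0, 2, 5, 10),
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
  }
  ls <- log_sigma(newdata$species_id, newdata$site_id, pm, object$ctraits,
                  include_random = include_random)
  newdata$sigma <- exp(ls)
  newdata$detection_prob <- half_normal_g(newdata$distance_m, newdata$sigma)
  newdata
}

#' Plot fitted detectability curves
#'
#' Draws g(d) against distance for each analysed species at one site,
#' using posterior-mean parameters.
#'
#' @param x a \code{traitds_fit}.
#' @param site site to plot (default: first site).
#' @param include_random include species random effects.
#' @param ... passed to \code{matplot}.
#' @return Invisibly, the matrix of plotted curves.
#' @export
plot.traitds_fit <- function(x, site = NULL, include_random = TRUE, ...) {
  if (is.null(site)) site <- x$config$sites[1L]
  pm <- posterior_mean_params(x$chains)
  d <- seq(0, x$config$truncation_w_m, length.out = 101)
  curves <- vapply(x$chains$species, function(sp) {
    predicted_detectability_curve(sp, site, pm, x$ctraits, d,
                                  include_random = include_random)
  }, numeric(length(d)))
  graphics::matplot(d, curves, type = "l", lty = 1,
                    col = grDevices::hcl.colors(ncol(curves), "viridis"),
                    xlab = "Perpendicular distance (m)",
                    ylab = "Detection probability",
                    main = paste("Predicted detectability at", site), ...)
  invisible(curves)
}

#' Posterior-predictive distance simulation
#'
#' Simulates replicate sets of observed perpendicular distances for the
#' analysed records: each simulation draws one posterior sample of the
#' parameters and, for every record, a new distance from the truncated
#' half-normal density at that record's species/site sigma (inverse-CDF
#' sampling). Useful for posterior-predictive checks of the distance
#' histogram.
#'
#' @param object a \code{traitds_fit}.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return List of \code{nsim} data frames shaped like
#'   \code{object$records}.
#' @export
simulate.traitds_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ch <- object$chains
  n_draw <- ncol(ch$draws[[1L]])
  n_chain <- nrow(ch$draws[[1L]])
  w <- object$config$truncation_w_m
  rec <- object$records
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    ci <- sample.int(n_chain, 1L); ki <- sample.int(n_draw, 1L)
    val <- vapply(ch$draws, function(d) d[ci, ki], numeric(1))
    b0 <- val[paste0("b0[", ch$sites, "]")]
    names(b0) <- ch$sites
    eps <- val[paste0("eps[", ch$species, "]")]
    names(eps) <- ch$species
    pp <- model_params(b0 = b0, bS = val[["bS"]], bS2 = val[["bS2"]],
                       bH = val[["bH"]], bA = val[["bA"]],
                       bA2 = val[["bA2"]], eps = eps,
                       sd_eps = val[["sd_eps"]])
    sig <- exp(log_sigma(rec$species_id, rec$site_id, pp, object$ctraits))
    u <- stats::runif(nrow(rec))
    # inverse CDF of the half-normal truncated to [0, w]
    d_new <- stats::qnorm(0.5 + u * (stats::pnorm(w / sig) - 0.5)) * sig
    sim <- rec
    sim$distance_m <- d_new
    out[[s]] <- sim
  }
  out
}
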