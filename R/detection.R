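#' Half-normal detection function
#'
#' Probability of detecting an individual at perpendicular distance \code{d}
#' from the transect line, g(d) = exp(-d^2 / (2 sigma^2)). Detection on the
#' line itself is assumed perfect: g(0) = 1. The scale parameter sigma
#' controls how quickly detectability decays with distance.
#'
#' @param distance_m perpendicular distance(s) in metres, >= 0.
#' @param sigma positive scale parameter in metres.
#' @return Detection probability in (0, 1], vectorised over
#'   \code{distance_m}.
#' @export
half_normal_g <- function(distance_m, sigma) {
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("'sigma' must be positive")
  }
  if (any(distance_m < 0)) stop("'distance_m' must be non-negative")
  exp(-distance_m^2 / (2 * sigma^2))
}

# integral of g over [0, w]: sigma * sqrt(2*pi) * (Phi(w/sigma) - 1/2),
# the closed form of sigma * sqrt(pi/2) * erf(w / (sigma*sqrt(2)))
.hn_norm_const <- function(sigma, w) {
  sigma * sqrt(2 * pi) * (stats::pnorm(w / sigma) - 0.5)
}

#' Truncated half-normal distance density
#'
#' Density of an observed perpendicular distance given detection, under the
#' half-normal model truncated at \code{w}: g(d) / integral of g over
#' [0, w]. The denominator has the closed form
#' sigma * sqrt(pi/2) * erf(w / (sigma * sqrt(2))). Integrates to 1 on
#' [0, w].
#'
#' @param distance_m distance(s) in [0, w].
#' @param sigma positive scale parameter (m).
#' @param w positive truncation distance (m); detections beyond \code{w}
#'   are discarded in the field protocol.
#' @return Density value(s).
#' @export
truncated_distance_pdf <- function(distance_m, sigma, w) {
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w <= 0) {
    stop("'w' must be a positive number")
  }
  if (any(distance_m > w)) {
    stop("distances beyond the truncation distance should have been dropped at load")
  }
  half_normal_g(distance_m, sigma) / .hn_norm_const(sigma, w)
}

#' Mean detection probability within the surveyed strip
#'
#' Average detectability of an individual placed uniformly within
#' perpendicular distance \code{w} of the transect:
#' (1/w) * integral of g over [0, w]. Equals the effective strip half-width
#' divided by \code{w}; approaches 1 as sigma grows. Useful for survey
#' effort planning.
#'
#' @inheritParams truncated_distance_pdf
#' @return Probability in (0, 1], vectorised over \code{sigma}.
#' @export
mean_detection_prob <- function(sigma, w) {
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("'sigma' must be positive")
  }
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w <= 0) {
    stop("'w' must be a positive number")
  }
  .hn_norm_const(sigma, w) / w
}

#' Survey configuration
#'
#' @param truncation_w_m perpendicular truncation distance in metres
#'   (default 10: only detections within 10 m of the line are recorded).
#' @param sites character vector of site identifiers, in the order their
#'   intercepts should be reported.
#' @return A \code{survey_config} list.
#' @export
survey_config <- function(truncation_w_m = 10, sites) {
  if (!is.numeric(truncation_w_m) || truncation_w_m <= 0) {
    stop("'truncation_w_m' must be positive")
  }
  sites <- as.character(sites)
  if (length(sites) == 0L || anyDuplicated(sites)) {
    stop("'sites' must be non-empty and unique")
  }
  structure(list(truncation_w_m = truncation_w_m, sites = sites),
            class = "survey_config")
}

#' Center trait covariates
#'
#' Centers the linear trait columns (leaf shape S, height H, leaf size L) at
#' their means over the analysed species and forms quadratic terms as
#' squares of the centered values, so that linear and quadratic columns stay
#' near-orthogonal and the site intercepts refer to a species with average
#' traits. The centering constants are stored for prediction on new species.
#'
#' @param traits data frame with columns \code{species_id},
#'   \code{leaf_shape}, \code{height_m}, \code{leaf_size_cm}.
#' @param species optional character vector restricting (and ordering) the
#'   analysed species set; defaults to all species in \code{traits}.
#' @return A \code{centered_traits} data frame with columns
#'   \code{species_id}, \code{S}, \code{S2}, \code{H}, \code{L}, \code{L2}
#'   and an attribute \code{centers} (named means of S, H, L).
#' @export
center_covariates <- function(traits, species = NULL) {
  req <- c("species_id", "leaf_shape", "height_m", "leaf_size_cm")
  if (!is.data.frame(traits) || !all(req %in% names(traits))) {
    stop("'traits' needs columns species_id, leaf_shape, height_m, leaf_size_cm")
  }
  if (is.null(species)) species <- as.character(traits$species_id)
  idx <- match(species, as.character(traits$species_id))
  if (anyNA(idx)) {
    stop("missing traits for species: ",
         paste(species[is.na(idx)], collapse = ", "))
  }
  tr <- traits[idx, , drop = FALSE]
  vals <- tr[c("leaf_shape", "height_m", "leaf_size_cm")]
  if (any(!is.finite(as.matrix(vals)))) {
    stop("trait values must be finite for every analysed species")
  }
  centers <- c(S = mean(tr$leaf_shape), H = mean(tr$height_m),
               L = mean(tr$leaf_size_cm))
  S <- tr$leaf_shape - centers[["S"]]
  H <- tr$height_m - centers[["H"]]
  L <- tr$leaf_size_cm - centers[["L"]]
  out <- data.frame(species_id = species, S = S, S2 = S^2, H = H,
                    L = L, L2 = L^2, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "centers") <- centers
  class(out) <- c("centered_traits", "data.frame")
  out
}

#' Model parameter container
#'
#' Bundles every parameter of the log-sigma regression: per-site intercepts,
#' the five trait coefficients (leaf shape, shape squared, height, leaf
#' size, size squared), per-species random effects and their standard
#' deviation.
#'
#' @param b0 named numeric vector of site intercepts (names = site ids).
#' @param bS,bS2,bH,bA,bA2 trait coefficients: leaf shape, shape^2, height,
#'   leaf size, size^2.
#' @param eps named numeric vector of species random effects (names =
#'   species ids); defaults to none.
#' @param sd_eps non-negative standard deviation of the random effects.
#' @return A \code{model_params} list.
#' @export
model_params <- function(b0, bS = 0, bS2 = 0, bH = 0, bA = 0, bA2 = 0,
                         eps = numeric(0), sd_eps = 0) {
  if (is.null(names(b0)) || any(names(b0) == "")) {
    stop("'b0' must be named by site id")
  }
  if (length(eps) > 0L && (is.null(names(eps)) || any(names(eps) == ""))) {
    stop("'eps' must be named by species id")
  }
  if (!is.finite(sd_eps) || sd_eps < 0) stop("'sd_eps' must be >= 0")
  stopifnot(all(is.finite(b0)), all(is.finite(c(bS, bS2, bH, bA, bA2))),
            all(is.finite(eps)))
  structure(list(b0 = b0, bS = bS, bS2 = bS2, bH = bH, bA = bA, bA2 = bA2,
                 eps = eps, sd_eps = sd_eps),
            class = "model_params")
}

#' Log scale parameter for a species at a site
#'
#' Evaluates the log-sigma regression
#' log(sigma_ij) = b0_j + bS S_i + bS2 S_i^2 + bA L_i + bA2 L_i^2 +
#' bH H_i + eps_i for the given species/site pairs, using centered traits.
#'
#' @param species,site character vectors (recycled to common length).
#' @param params a \code{\link{model_params}}.
#' @param ctraits a \code{\link{center_covariates}} table.
#' @param include_random include the species random effect (default TRUE);
#'   a species absent from \code{params$eps} gets 0 only when
#'   \code{include_random = FALSE}.
#' @return Numeric vector of log(sigma) values.
#' @export
log_sigma <- function(species, site, params, ctraits, include_random = TRUE) {
  n <- max(length(species), length(site))
  species <- rep_len(as.character(species), n)
  site <- rep_len(as.character(site), n)
  i <- match(species, ctraits$species_id)
  if (anyNA(i)) stop("unknown species: ",
                     paste(unique(species[is.na(i)]), collapse = ", "))
  b0 <- params$b0[site]
  if (anyNA(b0)) stop("unknown site: ",
                      paste(unique(site[is.na(b0)]), collapse = ", "))
  lp <- as.numeric(b0) +
    params$bS * ctraits$S[i] + params$bS2 * ctraits$S2[i] +
    params$bA * ctraits$L[i] + params$bA2 * ctraits$L2[i] +
    params$bH * ctraits$H[i]
  if (include_random) {
    e <- params$eps[species]
    if (anyNA(e)) stop("no random effect for species: ",
                       paste(unique(species[is.na(e)]), collapse = ", "))
    lp <- lp + as.numeric(e)
  }
  lp
}

#' Predicted detectability at given distances
#'
#' Detection probability g(d) for one species at one site evaluated on a
#' grid of distances, using the species/site sigma from the fitted
#' regression. Monotone non-increasing in distance, equal to 1 at d = 0.
#'
#' @inheritParams log_sigma
#' @param distances distances (m) within [0, truncation].
#' @return Numeric vector of detection probabilities.
#' @export
predicted_detectability_curve <- function(species, site, params, ctraits,
                                          distances,
                                          include_random = TRUE) {
  sig <- exp(log_sigma(species, site, params, ctraits,
                       include_random = include_random))
  if (length(sig) != 1L) stop("give exactly one species/site pair")
  half_normal_g(distances, sig)
}

#' Conditional distance-sampling log-likelihood
#'
#' Sum over detection records of the log truncated half-normal density of
#' the observed perpendicular distance, with each record's sigma determined
#' by its species and site through the log-sigma regression. This is the
#' conditional (detected-distances-only) likelihood of classical distance
#' sampling: only detection-function parameters enter, not abundance.
#'
#' @param records data frame with columns \code{species_id}, \code{site_id},
#'   \code{distance_m}.
#' @param params a \code{\link{model_params}}.
#' @param ctraits a \code{\link{center_covariates}} table.
#' @param config a \code{\link{survey_config}}.
#' @return The log-likelihood (0 for an empty record set).
#' @export
dataset_loglik <- function(records, params, ctraits, config) {
  if (nrow(records) == 0L) return(0)
  w <- config$truncation_w_m
  if (any(records$distance_m < 0) || any(records$distance_m > w)) {
    stop("all record distances must lie in [0, truncation]")
  }
  ls <- log_sigma(records$species_id, records$site_id, params, ctraits)
  sig <- exp(ls)
  sum(-records$distance_m^2 / (2 * sig^2) - log(.hn_norm_const(sig, w)))
}

# sufficient statistics for fast repeated likelihood evaluation:
# one row per observed species x site combination
.suffstats <- function(records, ctraits, config) {
  sp <- as.character(records$species_id)
  st <- as.character(records$site_id)
  key <- paste(sp, st, sep = "\r")
  uk <- unique(key)
  m <- match(key, uk)
  n <- tabulate(m, length(uk))
  sumd2 <- as.numeric(rowsum(records$distance_m^2, m)[, 1L])
  usp <- sub("\r.*$", "", uk)
  ust <- sub("^.*\r", "", uk)
  ti <- match(usp, ctraits$species_id)
  if (anyNA(ti)) stop("species missing from trait table: ",
                      paste(unique(usp[is.na(ti)]), collapse = ", "))
  species_ids <- sort(unique(usp))
  list(
    n = n, sumd2 = sumd2,
    X = cbind(S = ctraits$S[ti], S2 = ctraits$S2[ti], H = ctraits$H[ti],
              L = ctraits$L[ti], L2 = ctraits$L2[ti]),
    site = match(ust, config$sites),
    spec = match(usp, species_ids),
    species_ids = species_ids,
    w = config$truncation_w_m,
    n_total = nrow(records)
  )
}

# log-likelihood from sufficient stats given split parameter vectors
.loglik_ss <- function(ss, b0, beta, eps, rows = NULL) {
  if (is.null(rows)) rows <- seq_along(ss$n)
  lsig <- b0[ss$site[rows]] + ss$X[rows, , drop = FALSE] %*% beta +
    eps[ss$spec[rows]]
  sig <- exp(lsig)
  sum(-ss$sumd2[rows] / (2 * sig^2) -
        ss$n[rows] * log(.hn_norm_const(sig, ss$w)))
}

#' Drop rarely detected species
#'
#' Restricts the analysis to species detected at least \code{threshold}
#' times (default 5), since the distance distribution of a species seen
#' once or twice carries almost no information about its detection scale.
#'
#' @param records detection records data frame.
#' @param threshold minimum number of detections to retain a species.
#' @return List with \code{kept} (records of retained species) and
#'   \code{dropped} (data frame of excluded species and their counts).
#' @export
filter_min_detections <- function(records, threshold = 5) {
  if (!is.numeric(threshold) || threshold < 1) stop("'threshold' must be >= 1")
  counts <- table(as.character(records$species_id))
  keep_sp <- names(counts)[counts >= threshold]
  drop_sp <- names(counts)[counts < threshold]
  kept <- records[as.character(records$species_id) %in% keep_sp, ,
                  drop = FALSE]
  rownames(kept) <- NULL
  dropped <- data.frame(species_id = drop_sp,
                        n_detections = as.integer(counts[drop_sp]),
                        stringsAsFactors = FALSE)
  dropped <- dropped[order(dropped$species_id), , drop = FALSE]
  rownames(dropped) <- NULL
  list(kept = kept, dropped = dropped)
}
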