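# shared fixtures and independent oracles, built in code at test time

# regular n-gon of radius r centred at the origin
reg_polygon <- function(n, r = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(r * cos(th), r * sin(th))
}

# random star-shaped polygon (simple by construction): sorted angles,
# radii in [0.5, 1.5]
star_polygon <- function(n, seed) {
  set.seed(seed)
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, 0.5, 1.5)
  cbind(r * cos(th), r * sin(th))
}

# filled-disk binary mask, radius in pixels
disk_mask <- function(radius_px, pad = 10L) {
  n <- 2L * (radius_px + pad)
  c0 <- n / 2 + 0.5
  outer(1:n, 1:n, function(i, j) (i - c0)^2 + (j - c0)^2 <= radius_px^2)
}

# quadrature oracle for the half-normal integral over [0, w]
quad_hn_integral <- function(sigma, w) {
  stats::integrate(function(u) exp(-u^2 / (2 * sigma^2)), 0, w,
                   rel.tol = 1e-12, abs.tol = 1e-13)$value
}

# single species/site survey at fixed sigma: trait table, truth, config
single_species_truth <- function(sigma, N, seed = 1, w = 10) {
  traits <- data.frame(species_id = "spA", height_m = 1,
                       leaf_size_cm = 5, leaf_shape = 4,
                       n_samples = 1L, stringsAsFactors = FALSE)
  params <- model_params(b0 = c(site1 = log(sigma)), sd_eps = 0)
  ab <- matrix(N, 1, 1, dimnames = list("spA", "site1"))
  simulation_truth(params, traits, ab, truncation_w_m = w, seed = seed)
}
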