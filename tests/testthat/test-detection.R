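test_that("half-normal detection function behaves analytically", {
  expect_equal(half_normal_g(0, 0.3), 1)
  expect_equal(half_normal_g(0, 50), 1)
  # half-height at d = sigma * sqrt(2 ln 2)
  for (s in c(0.5, 2, 7)) {
    expect_equal(half_normal_g(s * sqrt(2 * log(2)), s), 0.5)
  }
  expect_equal(half_normal_g(10, 1), exp(-50))
  # strictly decreasing in distance
  d <- seq(0, 10, by = 0.1)
  expect_true(all(diff(half_normal_g(d, 3)) < 0))
  expect_error(half_normal_g(1, 0), "positive")
  expect_error(half_normal_g(-1, 1), "non-negative")
})

test_that("covariate centering subtracts means and squares afterwards", {
  tr <- data.frame(species_id = c("a", "b", "c"),
                   leaf_shape = c(4, 5, 6), height_m = c(1, 2, 3),
                   leaf_size_cm = c(2, 4, 6))
  ct <- center_covariates(tr)
  expect_equal(ct$H, c(-1, 0, 1))
  expect_equal(ct$S, c(-1, 0, 1))
  expect_equal(ct$L, c(-2, 0, 2))
  expect_equal(ct$L2, c(4, 0, 4))   # squares of centered values
  expect_equal(mean(ct$S), 0, tolerance = 1e-12)
  expect_equal(attr(ct, "centers"), c(S = 5, H = 2, L = 4))

  # two-species case from first principles
  ct2 <- center_covariates(tr, c("a", "b"))
  expect_equal(ct2$L, c(-1, 1))
  expect_equal(ct2$L2, c(1, 1))

  # degenerate single species centers to zero
  ct1 <- center_covariates(tr, "b")
  expect_equal(unlist(ct1[1, c("S", "S2", "H", "L", "L2")],
                      use.names = FALSE), rep(0, 5))

  expect_error(center_covariates(tr, c("a", "zz")), "zz")
})

test_that("log-sigma regression assembles its terms correctly", {
  tr <- data.frame(species_id = c("a", "b"),
                   leaf_shape = c(2, 6), height_m = c(1, 3),
                   leaf_size_cm = c(3, 7))
  ct <- center_covariates(tr)   # centered S = -2, +2 etc.

  # intercept only: log sigma = b0, sigma = e^b0
  p0 <- model_params(b0 = c(s1 = 1.34), eps = c(a = 0, b = 0))
  ls <- log_sigma("a", "s1", p0, ct)
  expect_equal(ls, 1.34)
  expect_equal(exp(ls), 3.819044, tolerance = 1e-6)

  # quadratic shape term: centered S = 2, bS2 = 0.5 -> 2.0
  p1 <- model_params(b0 = c(s1 = 0), bS2 = 0.5, eps = c(a = 0, b = 0))
  expect_equal(log_sigma("b", "s1", p1, ct), 2)

  # all terms at once, hand-assembled
  p2 <- model_params(b0 = c(s1 = 1), bS = 0.1, bS2 = 0.01, bH = 0.2,
                     bA = 0.05, bA2 = 0.002, eps = c(a = 0.3, b = -0.3))
  expected_a <- 1 + 0.1 * (-2) + 0.01 * 4 + 0.05 * (-2) + 0.002 * 4 +
    0.2 * (-1) + 0.3
  expect_equal(log_sigma("a", "s1", p2, ct), expected_a)

  expect_error(log_sigma("zz", "s1", p0, ct), "unknown species")
  expect_error(log_sigma("a", "nowhere", p0, ct), "unknown site")
})

test_that("truncated distance density is normalised and matches quadrature", {
  w <- 10
  # closed-form erf denominator vs adaptive quadrature across sigma scales
  for (s in c(0.1, 0.5, 2, 5, 50, 1000)) {
    closed <- truncated_distance_pdf(1, s, w)
    oracle <- exp(-1 / (2 * s^2)) / quad_hn_integral(s, w)
    expect_equal(closed, oracle, tolerance = 1e-8)
  }
  # density integrates to 1
  for (s in c(0.5, 2, 5, 50)) {
    total <- stats::integrate(function(d) truncated_distance_pdf(d, s, w),
                              0, w, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
  # sigma -> infinity limit: uniform 1/w
  expect_equal(truncated_distance_pdf(7, 1e7, 10), 0.1, tolerance = 1e-9)
  expect_error(truncated_distance_pdf(11, 2, 10), "truncation")
})

test_that("mean detection probability matches quadrature and is monotone", {
  expect_equal(mean_detection_prob(5, 10), quad_hn_integral(5, 10) / 10,
               tolerance = 1e-10)
  expect_equal(mean_detection_prob(5, 10), 0.5981, tolerance = 1e-4)
  expect_equal(mean_detection_prob(1e8, 10), 1, tolerance = 1e-9)
  sig <- seq(0.2, 50, length.out = 200)
  expect_true(all(diff(mean_detection_prob(sig, 10)) > 0))
  expect_error(mean_detection_prob(-1, 10), "positive")
  expect_error(mean_detection_prob(1, 0), "positive")
})

test_that("predicted detectability curves are anchored and ordered", {
  tr <- data.frame(species_id = c("a", "b"), leaf_shape = c(4, 6),
                   height_m = c(1, 2), leaf_size_cm = c(4, 8))
  ct <- center_covariates(tr)
  p <- model_params(b0 = c(s1 = 1.34), eps = c(a = 0, b = 0))
  g <- predicted_detectability_curve("a", "s1", p, ct, c(0, 2, 5, 10))
  expect_equal(g[1], 1)
  expect_true(all(diff(g) < 0))
  # sigma = e^1.34: g(2) = exp(-4 / (2 sigma^2)) ~ 0.872
  expect_equal(g[2], exp(-4 / (2 * exp(1.34)^2)), tolerance = 1e-12)
  expect_equal(g[2], 0.872, tolerance = 1e-3)
  # doubling sigma raises detectability at any d > 0
  p2 <- model_params(b0 = c(s1 = 1.34 + log(2)), eps = c(a = 0, b = 0))
  g2 <- predicted_detectability_curve("a", "s1", p2, ct, c(2, 5, 10))
  expect_true(all(g2 > g[2:4]))
})

test_that("dataset log-likelihood equals the per-record quadrature sum", {
  set.seed(42)
  tr <- data.frame(species_id = c("a", "b", "c"),
                   leaf_shape = c(4, 5, 7), height_m = c(0.5, 1.5, 3),
                   leaf_size_cm = c(3, 6, 11))
  ct <- center_covariates(tr)
  cfg <- survey_config(10, c("s1", "s2"))
  p <- model_params(b0 = c(s1 = 1.1, s2 = 0.8), bS = 0.05, bS2 = -0.01,
                    bH = 0.15, bA = 0.02, bA2 = 0.005,
                    eps = c(a = 0.1, b = -0.2, c = 0), sd_eps = 0.2)
  rec <- data.frame(
    species_id = sample(c("a", "b", "c"), 60, replace = TRUE),
    site_id = sample(c("s1", "s2"), 60, replace = TRUE),
    distance_m = runif(60, 0, 10), stringsAsFactors = FALSE)

  ll <- dataset_loglik(rec, p, ct, cfg)
  oracle <- sum(vapply(seq_len(nrow(rec)), function(k) {
    s <- exp(log_sigma(rec$species_id[k], rec$site_id[k], p, ct))
    log(exp(-rec$distance_m[k]^2 / (2 * s^2)) / quad_hn_integral(s, 10))
  }, numeric(1)))
  expect_equal(ll, oracle, tolerance = 1e-6)

  # empty dataset and uniform limit
  expect_identical(dataset_loglik(rec[0, ], p, ct, cfg), 0)
  p_big <- model_params(b0 = c(s1 = 20, s2 = 20),
                        eps = c(a = 0, b = 0, c = 0))
  one <- rec[1, ]
  expect_equal(dataset_loglik(one, p_big, ct, cfg), -log(10),
               tolerance = 1e-6)
})

test_that("rare species are filtered at the detection threshold", {
  rec <- data.frame(
    species_id = c(rep("A", 5), rep("B", 4), rep("C", 399)),
    site_id = "s1", distance_m = 1, stringsAsFactors = FALSE)
  out <- filter_min_detections(rec, 5)
  expect_setequal(unique(out$kept$species_id), c("A", "C"))
  expect_equal(out$dropped$species_id, "B")
  expect_equal(out$dropped$n_detections, 4L)

  # threshold 1 keeps everything
  out1 <- filter_min_detections(rec, 1)
  expect_equal(nrow(out1$kept), nrow(rec))
  expect_equal(nrow(out1$dropped), 0L)

  # everything below threshold
  out2 <- filter_min_detections(rec, 1000)
  expect_equal(nrow(out2$kept), 0L)
  expect_equal(nrow(out2$dropped), 3L)
  expect_error(filter_min_detections(rec, 0), ">= 1")
})
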