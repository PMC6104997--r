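test_that("polygon area and perimeter match analytic shapes", {
  sq <- leaf_outline(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
  expect_equal(leaf_area(sq), 100)
  expect_equal(leaf_perimeter(sq), 40)

  tri <- leaf_outline(cbind(c(0, 1, 0), c(0, 0, 1)))
  expect_equal(leaf_area(tri), 0.5)

  rect <- leaf_outline(cbind(c(0, 25, 25, 0), c(0, 0, 1, 1)))
  expect_equal(leaf_area(rect), 25)
  expect_equal(leaf_perimeter(rect), 52)

  # 360-gon approximates the unit circle to within 0.1%
  gon <- leaf_outline(reg_polygon(360))
  expect_equal(leaf_area(gon), pi, tolerance = 1e-3)
  expect_equal(leaf_perimeter(gon), 2 * pi, tolerance = 1e-3)

  # vertex order (orientation) must not change the answer
  sq_cw <- leaf_outline(cbind(c(0, 0, 10, 10), c(0, 10, 10, 0)))
  expect_equal(leaf_area(sq_cw), 100)
})

test_that("degenerate and self-intersecting outlines are rejected", {
  expect_error(leaf_outline(cbind(c(0, 1), c(0, 0))), "3 distinct vertices")
  # bow-tie
  expect_error(leaf_outline(cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))),
               "self-intersecting")
  # collinear points: zero area
  expect_error(leaf_outline(cbind(c(0, 1, 2), c(0, 1, 2))), "zero area")
  expect_error(leaf_outline(), "exactly one")
  expect_error(leaf_outline(mask = matrix(c(0, 1), 1, 2)), "pixel_cm")
})

test_that("leaf size is the square root of area", {
  expect_equal(leaf_size(100), 10)
  expect_equal(leaf_size(0), 0)
  expect_equal(leaf_size(2), sqrt(2))
  expect_error(leaf_size(-1), "non-negative")
})

test_that("dissection index hits its analytic values and scale invariance", {
  # circle: isoperimetric minimum 2*sqrt(pi), approached by fine polygons
  gon <- leaf_outline(reg_polygon(720, r = 3.7))
  di_circ <- dissection_index(leaf_area(gon), leaf_perimeter(gon))
  expect_equal(di_circ, 2 * sqrt(pi), tolerance = 1e-4)

  expect_equal(dissection_index(100, 40), 4)    # any square
  expect_equal(dissection_index(25, 52), 10.4)  # 1 x 25 rectangle

  expect_error(dissection_index(0, 10), "positive")
  expect_error(dissection_index(10, 0), "positive")

  # scale invariance and isoperimetric lower bound on random simple polygons
  for (seed in 1:10) {
    v <- star_polygon(12, seed)
    m1 <- measure_leaf(leaf_outline(v))
    k <- 0.5 + seed / 3
    m2 <- measure_leaf(leaf_outline(v * k))
    expect_equal(m2$dissection_index, m1$dissection_index,
                 tolerance = 1e-9)
    expect_gte(m1$dissection_index, 2 * sqrt(pi) - 1e-9)
    expect_equal(m1$leaf_size_cm^2, m1$area_cm2, tolerance = 1e-9)
  }
})

test_that("raster masks agree with exact polygons within 2%", {
  # disk of radius 30 px, pixel 0.1 cm -> radius 3 cm
  m <- disk_mask(30)
  ras <- leaf_outline(mask = m, pixel_cm = 0.1)
  expect_equal(leaf_area(ras), pi * 9, tolerance = 0.02)
  expect_equal(leaf_perimeter(ras), 2 * pi * 3, tolerance = 0.02)

  # elongated ellipse, 120 x 50 px
  n <- 140L
  a <- 60; b <- 25
  em <- outer(1:n, 1:n, function(i, j) {
    ((i - 70.5) / a)^2 + ((j - 70.5) / b)^2 <= 1
  })
  eras <- leaf_outline(mask = em, pixel_cm = 0.05)
  # oracle: fine polygon of the same ellipse
  th <- seq(0, 2 * pi, length.out = 2001)[-2001]
  ep <- leaf_outline(cbind(a * 0.05 * cos(th), b * 0.05 * sin(th)))
  expect_equal(leaf_area(eras), leaf_area(ep), tolerance = 0.02)
  expect_equal(leaf_perimeter(eras), leaf_perimeter(ep), tolerance = 0.02)
})

test_that("species trait means use the two-level (leaf -> plant -> species) rule", {
  # one individual, one leaf: identity
  lv <- data.frame(species_id = "s1", individual_id = "i1",
                   leaf_size_cm = 5, dissection_index = 4)
  out <- species_trait_means(lv)
  expect_equal(out$leaf_size_cm, 5)
  expect_equal(out$n_samples, 1L)

  # two individuals with per-plant means 4 and 6 -> 5
  lv2 <- data.frame(species_id = "s1",
                    individual_id = c("i1", "i2"),
                    leaf_size_cm = c(4, 6), dissection_index = c(4, 4))
  expect_equal(species_trait_means(lv2)$leaf_size_cm, 5)

  # unbalanced leaf counts: A {2,4}, B {9} -> (3 + 9)/2 = 6, not 5
  lv3 <- data.frame(species_id = "s1",
                    individual_id = c("A", "A", "B"),
                    leaf_size_cm = c(2, 4, 9),
                    dissection_index = c(4, 4, 4))
  expect_equal(species_trait_means(lv3)$leaf_size_cm, 6)
  expect_equal(species_trait_means(lv3)$n_samples, 2L)

  # heights averaged per species; area/perimeter input accepted
  lv4 <- data.frame(species_id = c("s1", "s1", "s2"),
                    individual_id = c("A", "B", "C"),
                    area_cm2 = c(4, 16, 100),
                    perimeter_cm = c(8, 16, 40))
  hh <- data.frame(species_id = c("s1", "s1", "s2"),
                   individual_id = c("A", "B", "C"),
                   height_m = c(1, 3, 0.5))
  out4 <- species_trait_means(lv4, hh)
  expect_equal(out4$leaf_size_cm, c(3, 10))       # (2+4)/2 and 10
  expect_equal(out4$height_m, c(2, 0.5))
  expect_equal(out4$leaf_shape, c(4, 4))          # squares

  expect_error(species_trait_means(data.frame()), "non-empty")
})
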