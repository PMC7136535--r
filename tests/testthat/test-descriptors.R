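test_that("cutoff function matches its closed form and clamps beyond rc", {
  expect_identical(cutoff_fn(0, 99), 1)
  expect_identical(cutoff_fn(99, 99), 0)
  expect_equal(cutoff_fn(99 / 2, 99), 0.5, tolerance = 1e-12)
  expect_identical(cutoff_fn(120, 99), 0)
  r <- seq(0, 99, length.out = 200)
  expect_true(all(diff(cutoff_fn(r, 99)) <= 1e-12))  # non-increasing
  expect_error(cutoff_fn(-1, 99), class = "cac_config_error")
})

test_that("radial term reproduces hand-evaluated cases", {
  s <- structure3d(c("C", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  ## single neighbor at 1 A under defaults: exp(0) * fc(1, 99)
  expect_equal(radial_term(s, 1, "H"), 0.9997482712, tolerance = 1e-8)
  ## empty sum when the element is absent
  expect_identical(radial_term(s, 1, "Fe"), 0)
  ## two equidistant neighbors double the single-neighbor value
  s2 <- structure3d(c("C", "H", "H"),
                    rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0)))
  expect_equal(radial_term(s2, 1, "H"), 2 * radial_term(s, 1, "H"),
               tolerance = 1e-12)
})

test_that("angular term reproduces hand-evaluated cases and symmetries", {
  s <- structure3d(c("Fe", "C", "N"),
                   rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  ## single pair at 90 deg: (1 + 0) * exp(-4) * fc(1)^2 * fc(sqrt(2))
  expect_equal(angular_term(s, 1, "C", "N"), 0.0182972032, tolerance = 1e-7)
  expect_identical(angular_term(s, 1, "C", "N"), angular_term(s, 1, "N", "C"))
  ## collinear opposite neighbors: (1 + cos 180) = 0
  s180 <- structure3d(c("Fe", "C", "N"),
                      rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0)))
  expect_equal(angular_term(s180, 1, "C", "N"), 0, tolerance = 1e-15)
  ## a single Fe atom can never supply an Fe-Fe neighbor pair
  t <- heme_template()
  for (i in c(1, 2, 13)) expect_identical(angular_term(t, i, "Fe", "Fe"), 0)
})

test_that("layout enumeration follows composition, dropping impossible pairs", {
  lay <- build_layout(heme_template())
  expect_identical(lay$p, 19L)  # 5 radial + 15 pairs - Fe-Fe
  expect_identical(nrow(lay$dropped), 1L)
  expect_identical(unname(lay$dropped[1, ]), c("Fe", "Fe"))
  expect_identical(lay$names[1:5],
                   c("radial_H", "radial_C", "radial_N", "radial_O", "radial_Fe"))

  ## water H2O: the O-O pair has no possible center -> dropped, length 4
  expect_identical(build_layout(c("H", "H", "O"))$p, 4L)
  ## with two O atoms every pair is realizable -> full length 5
  expect_identical(build_layout(c("H", "H", "O", "O"))$p, 5L)
  ## single-element 3-atom molecule: 1 radial + 1 angular
  expect_identical(build_layout(c("H", "H", "H"))$p, 2L)
  ## H2 alone: no center atom for the H-H pair
  expect_identical(build_layout(c("H", "H"))$p, 1L)

  ## layout is a function of composition only
  set.seed(5)
  el <- heme_template()$elements
  expect_identical(build_layout(sample(el)), build_layout(el))
})

test_that("featurize agrees with the naive triple-loop oracle", {
  set.seed(101)
  params <- sf_params()
  for (trial in 1:25) {
    s <- random_structure(sample(3:10, 1))
    lay <- build_layout(s)
    expect_lt(max(abs(featurize(s, lay, params) - naive_featurize(s, lay, params))),
              1e-10)
  }
  ## and under non-default parameters
  params2 <- sf_params(eta = 0.4, rs = 1.7, rc = 6, lambda = -1, zeta = 2.5)
  for (trial in 1:10) {
    s <- random_structure(sample(3:10, 1))
    lay <- build_layout(s)
    expect_lt(max(abs(featurize(s, lay, params2) - naive_featurize(s, lay, params2))),
              1e-10)
  }
})

test_that("descriptors are invariant to rigid motions and covariant to swaps", {
  set.seed(202)
  for (trial in 1:20) {
    s <- random_structure(sample(4:9, 1))
    lay <- build_layout(s)
    F0 <- featurize(s, lay)
    s2 <- apply_rigid(s, random_rotation(), runif(3, -5, 5))
    expect_lt(max(abs(featurize(s2, lay) - F0)), 1e-8)
  }
  ## swapping two same-element atoms swaps their rows only
  s <- structure3d(c("C", "H", "H", "O"),
                   rbind(c(0, 0, 0), c(1.1, 0, 0), c(-0.4, 1, 0), c(0, -1.2, 0.3)))
  lay <- build_layout(s)
  F0 <- featurize(s, lay)
  sw <- structure3d(s$elements, s$coords[c(1, 3, 2, 4), ])
  Fw <- featurize(sw, lay)
  expect_lt(max(abs(Fw - F0[c(1, 3, 2, 4), ])), 1e-12)
})

test_that("cutoff radius controls which descriptors vanish", {
  s <- random_structure(6)
  lay <- build_layout(s)
  ## rc below the minimum separation zeroes everything
  rc_small <- 0.9 * min(dist(s$coords))
  expect_identical(max(abs(featurize(s, lay, sf_params(rc = rc_small)))), 0)
  ## an atom farther than rc from all others gets an all-zero vector
  far <- structure3d(c("C", "H", "H"),
                     rbind(c(0, 0, 0), c(1, 0, 0), c(50, 0, 0)))
  F <- featurize(far, build_layout(far), sf_params(rc = 10))
  expect_identical(max(abs(F[3, ])), 0)
  expect_gt(max(abs(F[1, ])), 0)
})

test_that("lambda = +1 descriptors are non-negative; zeta = 1 prefactor is 1", {
  set.seed(303)
  for (trial in 1:10) {
    s <- random_structure(sample(3:8, 1))
    expect_true(all(featurize(s, build_layout(s)) >= 0))
  }
  expect_identical(2^(1 - sf_params()$zeta), 1)
})

test_that("coincident atoms raise a degenerate-geometry error naming the pair", {
  s <- structure3d(c("C", "H", "H"),
                   rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1e-9, 0)))
  s$coords[3, ] <- s$coords[2, ]  # bypass the constructor check
  expect_error(featurize(s, build_layout(s)), "atoms 2 and 3",
               class = "cac_geometry_error")
})

test_that("featurize rejects elements outside the layout", {
  s <- random_structure(4, elements = c("H", "C"))
  lay <- build_layout(s)
  s2 <- structure3d(c(s$elements[-4], "Fe"), s$coords)
  expect_error(featurize(s2, lay), class = "cac_layout_error")
})

test_that("symmetry-function parameter validation", {
  expect_error(sf_params(rc = 0), class = "cac_config_error")
  expect_error(sf_params(zeta = -1), class = "cac_config_error")
  expect_error(sf_params(lambda = 0.5), class = "cac_config_error")
  expect_error(sf_params(eta = -0.1), class = "cac_config_error")
})
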