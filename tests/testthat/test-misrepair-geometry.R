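test_that("rejoining kernel is a unit-peak Gaussian in separation", {
  expect_identical(rejoining_kernel(0, 0.05), 1)
  expect_lt(rejoining_kernel(10, 0.05), 1e-300)
  s <- 0.0428
  expect_equal(rejoining_kernel(s, s) / rejoining_kernel(0, s), exp(-0.5))
  d <- seq(0, 1, length.out = 50)
  expect_true(all(diff(rejoining_kernel(d, 0.1)) < 0))
  expect_error(rejoining_kernel(0.1, 0), "positive")
  expect_error(rejoining_kernel(-0.1, 0.1), "non-negative")
})

test_that("pair-distance density is a proper density with the known mean", {
  norm <- integrate(pair_distance_density, 0, 2, rel.tol = 1e-10)$value
  expect_equal(norm, 1, tolerance = 1e-8)
  m <- integrate(function(r) r * pair_distance_density(r), 0, 2,
                 rel.tol = 1e-10)$value
  expect_equal(m, 36 / 35, tolerance = 1e-8)  # classic mean distance in a ball
  expect_identical(pair_distance_density(2.5), 0)
  # scaling: density for radius a is the unit density squeezed by 1/a
  expect_equal(pair_distance_density(0.3, radius = 0.5),
               pair_distance_density(0.6) / 0.5)
})

test_that("theta matches a brute-force Monte Carlo kernel average", {
  for (s in c(0.0428, 0.15)) {
    mc <- mc_theta(s, n_pairs = 4e5, seed = 71)
    expect_lt(abs(theta(s) - mc$mean), 3 * mc$se)
  }
})

test_that("theta limits and truncation behave as an averaged kernel must", {
  expect_equal(theta(1e3), 1, tolerance = 1e-5)   # kernel ~ 1 everywhere
  expect_identical(theta(0.05, max_separation = 0), 0)
  expect_lt(theta(0.05, max_separation = 0.05), theta(0.05))
  expect_error(theta(0.05, max_separation = -1), ">= 0")
  expect_error(theta(0), "positive")
  # scale-free: only sigma / radius matters
  expect_equal(theta(0.04, radius = 1), theta(0.08, radius = 2),
               tolerance = 1e-10)
})

test_that("omega correction interpolates between its small- and large-sigma limits", {
  p <- default_parameters()
  expect_equal(omega_correction(5), 1, tolerance = 1e-10)
  expect_equal(omega_correction(1e-9), p$geom_A, tolerance = 1e-6)
  s <- 10^seq(-3, 0, length.out = 20)
  o <- omega_correction(s)
  expect_true(all(o > 0 & o <= 1))
  expect_true(all(diff(o) > 0))
})

test_that("eta is linear in the number of wrong partners and zero without them", {
  expect_identical(eta(0, 0.0428), 0)
  expect_equal(eta(200, 0.0428), 2 * eta(100, 0.0428))
  expect_error(eta(-1, 0.0428), "non-negative")
})

test_that("analytic misrepair fraction matches the rejoining ensemble at the fitted range", {
  ev <- eta(99, 0.0428)
  pred <- ev / (1 + ev)
  mc <- simulate_eta_ensemble(99, 0.0428, replicates = 20000, seed = 5)
  # MC noise plus the few-percent structural accuracy of the two-constant
  # skew correction (its constants are a global fit over the sigma grid)
  expect_lt(abs(mc$mis_fraction - pred), 3 * mc$se + 0.03 * pred)
})

test_that("correct-repair probability composes fidelity with the spatial term", {
  expect_equal(p_correct(0, "NHEJ"), 0.985)
  expect_equal(p_correct(0, "MMEJ"), 0.465)
  expect_equal(p_correct(c(0, 1, 50), "HR"), rep(1, 3))
  expect_error(p_correct(-0.1, "NHEJ"), "non-negative")
  # property: in [0, 1] over random admissible inputs
  withr::with_seed(42, {
    for (i in 1:50) {
      pp <- default_parameters(mu_nhej = runif(1), mu_mmej = runif(1))
      ev <- rexp(1, 0.2)
      for (proc in c("NHEJ", "HR", "MMEJ")) {
        val <- p_correct(ev, proc, pp)
        expect_true(val >= 0 && val <= 1)
      }
    }
  })
})

test_that("intra-chromosome probability has the right limits and monotonicity", {
  expect_equal(p_intra(1, 0.0428), 1, tolerance = 1e-9)
  expect_equal(p_intra(46, 50), 1 / 46, tolerance = 1e-3)  # uniform partners
  vals <- vapply(1:50, p_intra, numeric(1), sigma = 0.0428)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals <= 1))
})

test_that("deletion-size map is monotone with an exact inverse", {
  expect_identical(deletion_size(0, 6.1), 0)
  r <- seq(0, 2, length.out = 100)
  sz <- deletion_size(r, 6.1)
  expect_true(all(diff(sz) > 0))
  expect_equal(deletion_separation(sz, 6.1), r, tolerance = 1e-9)
  # full diameter maps to the whole genome; chromosome diameter to l_c
  expect_equal(deletion_size(2, 6.1), 6.1e9)
  r_c <- 46^(-1 / 3)
  expect_equal(deletion_size(2 * r_c, 6.1), 6.1e9 / 46, tolerance = 1e-9)
  expect_error(deletion_size(2.1, 6.1), "\\[0, 2 R\\]")
  expect_error(deletion_size(-0.1, 6.1), "\\[0, 2 R\\]")
})
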