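test_that("misrepair accumulates from zero and vanishes without dose or with HR only", {
  expect_identical(misrepaired_count(0, 2, human_wt), 0)
  expect_equal(misrepaired_count(c(1, 10, Inf), 0, human_wt), rep(0, 3))
  # all breaks complex + HR available: perfect repair, no misrepair
  p_hr <- default_parameters(p_complex = 1)
  expect_equal(misrepaired_count(Inf, 4, human_wt, "G2", params = p_hr), 0)
  # non-decreasing in time
  m <- misrepaired_count(c(0.5, 1, 2, 8, 24, Inf), 4, human_wt)
  expect_true(all(diff(m) >= 0))
})

test_that("asymmetric events split between dicentrics and deletions conservatively", {
  out <- dicentrics_and_deletions(10, 0.8)
  expect_equal(out$n_dicentric + out$n_deletion_total, 0.5 * 10)
  expect_equal(dicentrics_and_deletions(7, 1)$n_dicentric, 0)  # single-chromosome limit
  z <- dicentrics_and_deletions(0, 0.5)
  expect_identical(c(z$n_dicentric, z$n_deletion_total), c(0, 0))
  # conservation at machine precision across a parameter sweep
  withr::with_seed(9, {
    for (i in 1:25) {
      nm <- rexp(1, 0.1); pi_v <- runif(1)
      s <- dicentrics_and_deletions(nm, pi_v)
      expect_equal(s$n_dicentric + s$n_deletion_total, 0.5 * nm,
                   tolerance = 1e-14)
    }
  })
})

test_that("size-thresholded deletion counts are total at zero and vanish at the chromosome length", {
  geom <- geometry_context(human_wt)
  n_del <- 4.2
  expect_equal(deletions_above(0, n_del, geom), n_del)
  l_c_bp <- 6.1e9 / 46
  expect_equal(deletions_above(l_c_bp, n_del, geom), 0, tolerance = 1e-12)
  D <- c(0, 1e4, 1e5, 1e6, 3e6, 1e7, 5e7, l_c_bp)
  v <- deletions_above(D, n_del, geom)
  expect_true(all(diff(v) <= 0))
  expect_error(deletions_above(-1, n_del, geom), "non-negative")
})

test_that("inter-arm events are a subset of intra-chromosome deletions", {
  for (pp in list(default_parameters(), default_parameters(sigma = 0.1))) {
    for (ph in list(human_wt, cho_wt)) {
      geom <- geometry_context(ph, pp)
      arm <- radrepair:::interarm_from_deletions(1, geom)
      expect_gt(arm, 0)
      expect_lt(arm, 1)  # n_del_total = 1: spanning events are a subset
    }
  }
  expect_identical(interarm_rate(Inf, 0, human_wt), 0)
  arm <- interarm_rate(Inf, 4, human_wt)
  del <- predict_aberrations(4, human_wt, "G2")$n_deletion_total
  expect_lt(arm, del)
})

test_that("mutation channels respond to gene length, nu and dose as expected", {
  g <- 34e3; bmax <- 5.8e6
  m0 <- gene_mutation_rate(0, bmax, 4, cho_wt)
  expect_identical(m0$mut_intra, 0)
  p0 <- default_parameters(nu = 0)
  expect_identical(gene_mutation_rate(g, bmax, 4, cho_wt, params = p0)$mut_point, 0)
  # intra-gene and point channels are exactly linear in gene length;
  # the spanning channel is nearly so for genes far smaller than the genome
  m1 <- gene_mutation_rate(g, bmax, 4, cho_wt)
  m2 <- gene_mutation_rate(2 * g, bmax, 4, cho_wt)
  expect_equal(m2$mut_intra, 2 * m1$mut_intra, tolerance = 1e-12)
  expect_equal(m2$mut_point, 2 * m1$mut_point, tolerance = 1e-12)
  expect_equal(m2$mut_total, 2 * m1$mut_total, tolerance = 0.02)
  expect_error(gene_mutation_rate(g, 0, 4, cho_wt), "positive")
  expect_error(gene_mutation_rate(-1, bmax, 4, cho_wt), ">= 0")
})

test_that("low-dose-rate mode linearises the dose response; acute mode is super-linear", {
  m1 <- misrepaired_count(Inf, 2, human_wt, dose_rate_mode = "low_dose_rate")
  m2 <- misrepaired_count(Inf, 4, human_wt, dose_rate_mode = "low_dose_rate")
  expect_equal(m2, 2 * m1, tolerance = 1e-12)
  a1 <- predict_aberrations(2, human_wt, dose_rate_mode = "low_dose_rate")
  a2 <- predict_aberrations(4, human_wt, dose_rate_mode = "low_dose_rate")
  for (col in c("n_mis", "n_dicentric", "n_deletion_total",
                "n_deletion_visible"))
    expect_equal(a2[[col]], 2 * a1[[col]], tolerance = 1e-10)
  # with multi-break interaction on, misrepair grows super-linearly
  s1 <- misrepaired_count(Inf, 5, human_wt)
  s2 <- misrepaired_count(Inf, 10, human_wt)
  expect_gt(s2, 2 * s1)
})

test_that("aberration tables are internally consistent", {
  tab <- predict_aberrations(c(1, 2, 4, 8), human_wt, "G2", times = Inf)
  expect_equal(tab$n_dicentric + tab$n_deletion_total, 0.5 * tab$n_mis,
               tolerance = 1e-12)
  expect_equal(tab$n_visible,
               tab$n_dicentric + tab$n_deletion_visible + tab$n_interarm)
  # G1 tables carry no inter-arm class
  tab1 <- predict_aberrations(c(2, 4), human_wt, "G1")
  expect_identical(tab1$n_interarm, c(0, 0))
  # yields increase with dose
  expect_true(all(diff(tab$n_visible) > 0))
})
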