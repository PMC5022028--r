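test_that("every survival channel is 1 at zero insult and stays in (0, 1]", {
  expect_identical(mitotic_survival(0), 1)
  expect_equal(g1_escape(0, human_wt), 1)
  conditions <- list(
    list(ph = human_wt, sc = exposure(0, "G1")),
    list(ph = human_wt, sc = exposure(0, "G1", plating = "immediate",
                                      cycling = TRUE)),
    list(ph = cho_wt, sc = exposure(0, "G2")),
    list(ph = human_nhej, sc = exposure(0, "M")))
  for (cond in conditions) {
    curve <- predict_survival(c(0, 1, 3, 6, 10), cond$ph, cond$sc)
    expect_equal(curve$surviving_fraction[1], 1)
    expect_true(all(curve$surviving_fraction > 0 &
                      curve$surviving_fraction <= 1))
    expect_true(all(diff(curve$surviving_fraction) < 0))
  }
})

test_that("exponential death channels match their closed forms", {
  expect_equal(mitotic_survival(35), exp(-0.49))
  expect_equal(mitotic_survival(35), 0.6126, tolerance = 1e-4)
  expect_equal(g1_escape(35, human_wt), exp(-0.2975))
  expect_equal(g1_escape(35, human_wt), 0.7427, tolerance = 1e-4)
  # log-survival is linear in break count
  n <- c(5, 10, 20, 40)
  expect_equal(log(mitotic_survival(n)), -0.014 * n)
  # checkpoint-defective or non-cycling cells never arrest
  expect_equal(g1_escape(50, cho_wt), 1)
  expect_equal(g1_escape(50, human_wt, cycling = FALSE), 1)
  expect_error(mitotic_survival(-1), "non-negative")
})

test_that("one expected lethal aberration gives Poisson zero-class survival", {
  # calibrate a dose at which dicentrics + visible deletions = 1 and check e^-1
  geom <- geometry_context(human_wt)
  lethal <- function(d) {
    tab <- predict_aberrations(d, human_wt, "G1")
    tab$n_dicentric + tab$n_deletion_visible
  }
  d1 <- uniroot(function(d) lethal(d) - 1, c(0.5, 15), tol = 1e-10)$root
  expect_equal(survival_g1_noncycling(d1, human_wt), exp(-1), tolerance = 1e-6)
})

test_that("condition composition selects the applicable channels", {
  d <- c(0, 2, 4, 6)
  # delayed-plating G1 is the aberration channel alone
  curve <- predict_survival(d, human_wt, exposure(0, "G1"))
  expect_equal(curve$surviving_fraction, survival_g1_noncycling(d, human_wt))
  expect_equal(curve$escape_term, rep(1, 4))
  # cycling G1 multiplies in the escape probability
  cy <- predict_survival(d, human_wt, exposure(0, "G1", plating = "immediate",
                                               cycling = TRUE))
  n0 <- initial_dsb_count(d, human_wt, "G1")
  expect_equal(cy$surviving_fraction,
               survival_g1_noncycling(d, human_wt) * exp(-0.0085 * n0))
  # mitotic irradiation uses only the mitotic channel
  m <- predict_survival(d, human_wt, exposure(0, "M"))
  expect_equal(m$surviving_fraction,
               mitotic_survival(initial_dsb_count(d, human_wt, "M")))
  expect_equal(m$aberration_term, rep(1, 4))
  # G2 couples the aberration channel with checkpoint-gated mitotic death
  g2 <- predict_survival(d, human_wt, exposure(0, "G2"))
  expect_equal(g2$surviving_fraction,
               survival_g2(d, human_wt) *
                 mitotic_survival(pmin(initial_dsb_count(d, human_wt, "G2"),
                                       20)))
})

test_that("removing a death channel never decreases survival", {
  d <- c(1, 3, 6)
  base <- predict_survival(d, human_wt,
                           exposure(0, "G1", plating = "immediate",
                                    cycling = TRUE))$surviving_fraction
  no_arrest <- predict_survival(
    d, human_wt, exposure(0, "G1", plating = "immediate", cycling = TRUE),
    default_parameters(arrest_sensitivity = 1e-6))$surviving_fraction
  expect_true(all(no_arrest >= base))
  g2 <- predict_survival(d, human_wt, exposure(0, "G2"))$surviving_fraction
  g2_soft <- predict_survival(d, human_wt, exposure(0, "G2"),
                              default_parameters(mitosis_sensitivity = 1e-6)
                              )$surviving_fraction
  expect_true(all(g2_soft >= g2))
})

test_that("phenotype contrasts reproduce the model's characteristic patterns", {
  d <- c(1, 2, 4, 6, 8)
  wt_g1 <- predict_survival(d, human_wt, exposure(0, "G1"))$surviving_fraction
  nh_g1 <- predict_survival(d, human_nhej, exposure(0, "G1"))$surviving_fraction
  nh_g2 <- predict_survival(d, human_nhej, exposure(0, "G2"))$surviving_fraction
  # NHEJ-defective cells are more sensitive than competent at every dose in G1
  expect_true(all(nh_g1 < wt_g1))
  # and regain resistance in G2, where HR absorbs the complex breaks
  expect_true(all(nh_g2 > nh_g1))
})

test_that("mean inactivation dose integrates survival with an exponential tail", {
  d <- seq(0, 10, 0.25)
  expect_equal(mean_inactivation_dose(d, exp(-0.5 * d)), 2, tolerance = 1e-9)
  # flat curve: MID equals the dose range and the degenerate case warns
  expect_warning(expect_warning(
    mid_flat <- mean_inactivation_dose(c(0, 5, 10), rep(1, 3)),
    "0.01"), "tail")
  expect_equal(mid_flat, 10)
  # linear-quadratic curve against a high-resolution quadrature oracle
  a <- 0.3; b <- 0.03
  dd <- seq(0, 12, 0.05)
  oracle <- integrate(function(x) exp(-a * x - b * x^2), 0, 12,
                      rel.tol = 1e-12)$value +
    exp(-a * 12 - b * 144) / (a + 2 * b * 12)
  expect_equal(mean_inactivation_dose(dd, exp(-a * dd - b * dd^2)), oracle,
               tolerance = 1e-4)
  expect_error(mean_inactivation_dose(c(0, 1), c(1, 1.2)), "\\(0, 1\\]")
  expect_error(mean_inactivation_dose(c(1, 0), c(1, 0.5)), "increasing")
})
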