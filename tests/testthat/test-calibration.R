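test_that("synthetic datasets sit on the model surface at zero noise and are seed-stable", {
  synth0 <- generate_synthetic_datasets(noise_relative = 0, seed = 1)
  expect_equal(synth0$value, synth0$truth)
  expect_true(all(synth0$sd > 0))
  a <- generate_synthetic_datasets(seed = 7)
  b <- generate_synthetic_datasets(seed = 7)
  expect_identical(a$value, b$value)
  c2 <- generate_synthetic_datasets(seed = 8)
  expect_false(identical(a$value, c2$value))
  empty <- synthetic_design_default()
  empty$design <- empty$design[0, ]
  expect_error(generate_synthetic_datasets(design = empty), "empty")
  expect_error(generate_synthetic_datasets(noise_relative = -0.1), ">= 0")
})

test_that("the default design exercises all six endpoint kinds", {
  d <- synthetic_design_default()
  expect_setequal(unique(d$design$endpoint),
                  c("foci_timecourse", "misrepair_fraction",
                    "aberrations_vs_dose", "aberrations_vs_time",
                    "mutations_vs_dose", "survival_vs_dose"))
  pred <- predict_endpoints(d$design, default_parameters(), d$phenotypes)
  expect_true(all(is.finite(pred)))
  expect_true(all(pred >= 0))
})

test_that("noiseless joint fit recovers the generating parameters almost exactly", {
  synth0 <- generate_synthetic_datasets(noise_relative = 0, seed = 3)
  start <- default_parameters()
  jitter <- withr::with_seed(13, {
    vals <- unlist(start[dna_parameter_names()]) * exp(stats::rnorm(9, 0, 0.15))
    vals <- pmin(vals, c(lambda_fast = 50, lambda_slow = 50, lambda_mmej = 50,
                         p_complex = 0.99, p_fail = 0.99, sigma = 0.4,
                         mu_nhej = 0.999, mu_mmej = 0.99, nu = 0.5))
    as.list(stats::setNames(vals, dna_parameter_names()))
  })
  start_j <- do.call(default_parameters, jitter)
  fit <- joint_fit(synth0, start = start_j)
  truth <- unlist(default_parameters()[dna_parameter_names()])
  expect_true(all(abs(fit$par[dna_parameter_names()] - truth) / truth < 1e-3))
  expect_true(fit$converged)
})

test_that("weighted least squares is invariant to row order and uniform weight scaling", {
  synth <- generate_synthetic_datasets(seed = 5)
  fit1 <- joint_fit(synth)
  perm <- withr::with_seed(6, sample(nrow(synth)))
  shuffled <- synth[perm, ]
  attr(shuffled, "phenotypes") <- attr(synth, "phenotypes")
  fit2 <- joint_fit(shuffled)
  expect_equal(fit2$par, fit1$par, tolerance = 1e-3)
  scaled <- synth
  scaled$sd <- scaled$sd * 10
  attr(scaled, "phenotypes") <- attr(synth, "phenotypes")
  fit3 <- joint_fit(scaled)
  expect_equal(fit3$par, fit1$par, tolerance = 1e-3)
  expect_equal(fit3$deviance, fit1$deviance / 100, tolerance = 1e-3)
})

test_that("survival-stage fit varies only the death sensitivities", {
  # cycling-G1 and mitotic-irradiation survival data generated at truth
  design <- list(
    design = dplyr::bind_rows(
      tibble::tibble(endpoint = "survival_vs_dose", phenotype_id = "human_wt",
                     phase = "G1", dose_gy = c(1, 2, 3, 4, 6), time_h = Inf,
                     plating = "immediate", cycling = TRUE),
      tibble::tibble(endpoint = "survival_vs_dose", phenotype_id = "human_wt",
                     phase = "M", dose_gy = c(0.5, 1, 2, 3), time_h = Inf,
                     plating = "immediate", cycling = TRUE)),
    phenotypes = list(human_wt = human_wt))
  synth <- generate_synthetic_datasets(design = design, noise_relative = 0.03,
                                       seed = 17)
  start <- default_parameters(mitosis_sensitivity = 0.03,
                              arrest_sensitivity = 0.02)
  fit <- joint_fit(synth, start = start, free = survival_parameter_names())
  expect_named(fit$par, survival_parameter_names())
  # DNA parameters pass through untouched
  expect_equal(fit$parameters$lambda_fast, 3.6)
  expect_equal(fit$parameters$sigma, 0.0428)
  truth <- c(mitosis_sensitivity = 0.014, arrest_sensitivity = 0.0085)
  expect_true(all(abs(fit$par - truth) / truth < 0.25))
})

test_that("per-study focus scaling factors are estimated when flagged", {
  design <- synthetic_design_default()
  design$design$scale_group[design$design$endpoint == "foci_timecourse"] <-
    "studyA"
  truth_scaled <- predict_endpoints(design$design, default_parameters(),
                                    design$phenotypes,
                                    scalings = c(studyA = 1.7))
  synth <- generate_synthetic_datasets(design = design, noise_relative = 0,
                                       seed = 19)
  synth$value <- truth_scaled
  synth$sd <- pmax(0.02 * abs(truth_scaled), 1e-8)
  fit <- joint_fit(synth, free = c("lambda_fast", "lambda_slow"))
  expect_equal(unname(fit$par["scale_studyA"]), 1.7, tolerance = 1e-3)
  expect_equal(unname(fit$par["lambda_fast"]), 3.6, tolerance = 1e-3)
})

test_that("fixing a parameter at truth still recovers the others", {
  synth <- generate_synthetic_datasets(seed = 23)
  free <- setdiff(dna_parameter_names(), "sigma")
  fit <- joint_fit(synth, free = free)
  truth <- unlist(default_parameters()[free])
  est <- fit$par[free]
  se <- fit$se[free]
  expect_true(all(abs(est - truth) <= 3 * se))
})

test_that("degenerate fit inputs are rejected with clear messages", {
  synth <- generate_synthetic_datasets(seed = 29)
  expect_error(joint_fit(synth[0, ], phenotypes = attr(synth, "phenotypes")),
               "no datasets")
  bad <- synth
  bad$sd[1] <- 0
  attr(bad, "phenotypes") <- attr(synth, "phenotypes")
  expect_error(joint_fit(bad), "positive")
  expect_error(joint_fit(synth, free = c("sigma", "nucleus_radius")),
               "cannot fit")
  st <- synth
  attr(st, "phenotypes") <- NULL
  expect_error(joint_fit(st, phenotypes = NULL), "phenotypes")
})

test_that("MID stratification summarises observed against modelled sensitivity", {
  conds <- tidyr::expand_grid(ph = c("wt", "nhej"), phase = c("G1", "G2"),
                              id = 1:3)
  curves <- purrr::pmap_dfr(conds, function(ph, phase, id) {
    phen <- if (ph == "wt") human_wt else human_nhej
    cur <- predict_survival(seq(0, 12, 0.5), phen, exposure(0, phase))
    tibble::tibble(condition = paste(ph, phase, id, sep = "_"),
                   dose_gy = cur$dose_gy,
                   surviving_fraction = cur$surviving_fraction)
  })
  # identity: slope 1, R^2 = 1
  ident <- suppressWarnings(mid_stratification(curves, curves))
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$r_squared, 1, tolerance = 1e-12)
  # 5% noisy observations over 12 conditions stay near equality
  noisy <- curves
  noisy$surviving_fraction <- withr::with_seed(31,
    pmin(1, curves$surviving_fraction *
           (1 + 0.05 * stats::rnorm(nrow(curves)))))
  strat <- suppressWarnings(mid_stratification(noisy, curves))
  expect_gt(strat$slope, 0.9); expect_lt(strat$slope, 1.1)
  expect_gt(strat$r_squared, 0.95)
  # degenerate and unmatched inputs
  one <- dplyr::filter(curves, .data$condition == curves$condition[1])
  expect_error(suppressWarnings(mid_stratification(one, one)), "two conditions")
  renamed <- dplyr::mutate(curves, condition = paste0(.data$condition, "_x"))
  expect_error(mid_stratification(curves, renamed), "unmatched")
})
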