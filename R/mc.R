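#' Stochastic break-rejoining simulator
#'
#' Full competitive pairing of DSB free ends in the unit-sphere nucleus: per
#' replicate, `n0` breaks are placed uniformly (two co-located free ends
#' each), and ends are joined sequentially — an end drawn uniformly at random
#' picks its partner among the remaining free ends with probability
#' proportional to the Gaussian kernel of their separation — until every end
#' is joined. A break is misrepaired when its ends did not rejoin with each
#' other. Misrepair events are classified intra-/inter-chromosome from
#' territory labels (nearest of `n_chromosomes` uniformly placed centres, so
#' break positions stay uniform), and the break separations of intra events
#' can be recorded as deletion-size samples.
#'
#' Exactly `2 n0` ends are joined into `n0` pairs in every replicate, and
#' results are reproducible under a fixed `seed`.
#'
#' @param n0 breaks per replicate (>= 1).
#' @param sigma rejoining range in units of the nucleus radius.
#' @param n_chromosomes chromosome territory count for classification.
#' @param replicates number of independent replicates.
#' @param seed optional integer seed (applied locally).
#' @param keep_separations record separations of intra-chromosome misrepairs.
#' @return An object of class `mc_rejoining`: a list with `n0`, `sigma`,
#'   `replicates`, `misrepair_fraction`, `misrepair_se`, `intra_fraction`,
#'   `intra_se`, `per_replicate` (tibble of per-replicate fractions),
#'   `separations` and `seed`.
#' @examples
#' sim <- simulate_rejoining(50, 0.08, replicates = 200, seed = 1)
#' sim$misrepair_fraction
#' @export
simulate_rejoining <- function(n0, sigma, n_chromosomes = 1, replicates = 1000,
                               seed = NULL, keep_separations = FALSE) {
  run <- function() rejoin_pairing_cpp(as.integer(n0), sigma,
                                       as.integer(n_chromosomes),
                                       as.integer(replicates),
                                       isTRUE(keep_separations))
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  mf <- out$mis_frac
  intra <- out$intra_frac[!is.na(out$intra_frac)]
  structure(list(
    n0 = n0, sigma = sigma, n_chromosomes = n_chromosomes,
    replicates = replicates,
    misrepair_fraction = mean(mf),
    misrepair_se = stats::sd(mf) / sqrt(length(mf)),
    intra_fraction = if (length(intra)) mean(intra) else NA_real_,
    intra_se = if (length(intra) > 1) stats::sd(intra) / sqrt(length(intra))
               else NA_real_,
    per_replicate = tibble::tibble(misrepair_fraction = mf,
                                   intra_fraction = out$intra_frac),
    separations = out$separations,
    seed = seed), class = "mc_rejoining")
}

#' @export
print.mc_rejoining <- function(x, ...) {
  cat(sprintf(paste0("<mc_rejoining> n0 = %d, sigma = %.4g, %d replicates\n",
                     "  misrepair fraction %.4g +/- %.2g\n"),
              x$n0, x$sigma, x$replicates, x$misrepair_fraction,
              x$misrepair_se))
  invisible(x)
}

#' Mean-field misrejoining ensemble
#'
#' Monte Carlo estimate of the misrepair probability of a single randomly
#' placed DSB competing against `2 * n_other` independently and uniformly
#' placed wrong free ends — the ensemble whose mean the analytic propensity
#' [eta()] describes and whose configuration-to-configuration skew the omega
#' correction absorbs. Per configuration the misrepair probability is
#' `W / (1 + W)` with `W` the summed kernel weights to the wrong ends.
#'
#' This mean-field ensemble is the matching target for the geometric
#' constants ([fit_geometry_constants()]) and for the analytic-vs-MC
#' equivalence checks; unlike [simulate_rejoining()] it shares the analytic
#' model's assumption that wrong ends are placed independently rather than in
#' co-located pairs.
#'
#' @param n_other number of other DSBs present.
#' @param sigma rejoining range in units of the nucleus radius.
#' @param replicates number of sampled configurations.
#' @param seed optional integer seed.
#' @return A list with `mis_fraction`, `se`, `n_other`, `sigma`,
#'   `replicates`.
#' @examples
#' simulate_eta_ensemble(99, 0.0428, replicates = 5000, seed = 1)$mis_fraction
#' @export
simulate_eta_ensemble <- function(n_other, sigma, replicates = 10000,
                                  seed = NULL) {
  run <- function() eta_ensemble_cpp(as.integer(n_other), sigma,
                                     as.integer(replicates))
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(mis_fraction = out$m, se = out$se, n_other = n_other, sigma = sigma,
       replicates = replicates)
}

#' Analytic-vs-Monte-Carlo validation grid
#'
#' Runs the mean-field rejoining ensemble over a `sigma x n0` grid and
#' compares the simulated misrepair fractions with the analytic prediction
#' `eta / (1 + eta)`, reporting a z score per point. On a correct
#' implementation |z| stays within ~3 across the grid.
#'
#' @param sigmas rejoining ranges (units of nucleus radius).
#' @param n0s initial break counts (each break sees `n0 - 1` others).
#' @param replicates configurations per grid point.
#' @param seed optional integer seed.
#' @param params a [default_parameters()] object.
#' @return A tibble with columns `sigma`, `n0`, `mc_fraction`, `mc_se`,
#'   `analytic_fraction`, `z`.
#' @examples
#' mc_validate(c(0.04, 0.1), c(10, 100), replicates = 2000, seed = 1)
#' @export
mc_validate <- function(sigmas = c(0.01, 0.04, 0.1, 0.3),
                        n0s = c(10, 100, 1000), replicates = 4000,
                        seed = NULL, params = default_parameters()) {
  run <- function() {
    grid <- tidyr::expand_grid(sigma = sigmas, n0 = n0s)
    purrr::pmap_dfr(grid, function(sigma, n0) {
      mc <- eta_ensemble_cpp(as.integer(n0 - 1), sigma,
                             as.integer(replicates))
      ev <- eta(n0 - 1, sigma, 1, params)
      pred <- ev / (1 + ev)
      tibble::tibble(sigma = sigma, n0 = n0,
                     mc_fraction = mc$m, mc_se = mc$se,
                     analytic_fraction = pred,
                     z = (mc$m - pred) / mc$se)
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Recover the geometric correction constants from Monte Carlo
#'
#' Reproduces the calibration that defines the omega correction's constants:
#' the mean-field rejoining ensemble is run over a `sigma x n0` grid and the
#' two constants of `omega = 1 - (1 - A) exp(-B sigma / R)` are fitted by
#' weighted nonlinear least squares so that the analytic misrepair fraction
#' `eta / (1 + eta)` matches the simulated fractions, weighting each point by
#' its Monte Carlo standard error.
#'
#' Replicates per grid point are chosen adaptively so each point resolves at
#' least `target_events` expected misrepair events (and never fewer than
#' `min_replicates` configurations), giving all points comparable relative
#' precision. Reported uncertainties come from the residual-scaled covariance
#' of the fit, which inflates honestly when the two-constant form cannot
#' fully describe the simulated surface.
#'
#' @param mc_grid optional precomputed grid: a tibble with columns `sigma`,
#'   `n0`, `mc_fraction`, `mc_se` (e.g. from an earlier run, or constructed
#'   for self-consistency checks). When `NULL` the ensemble is simulated on
#'   the default grid.
#' @param sigmas,n0s calibration grid (defaults: sigma in
#'   \{0.01, 0.02, 0.04, 0.08, 0.15\} nuclear radii, n0 in
#'   \{10, 50, 100, 500\} breaks).
#' @param target_events minimum expected misrepair events per point.
#' @param min_replicates minimum configurations per point.
#' @param max_replicates cap on configurations per point.
#' @param seed optional integer seed.
#' @return An object of class `geometry_fit`: list with `A`, `B`, `se_A`,
#'   `se_B`, `vcov`, `grid` (tibble incl. per-point MC results and fitted
#'   values) and `converged`.
#' @examples
#' \donttest{
#' fit <- fit_geometry_constants(seed = 1)
#' tidy(fit)
#' }
#' @export
fit_geometry_constants <- function(mc_grid = NULL,
                                   sigmas = c(0.01, 0.02, 0.04, 0.08, 0.15),
                                   n0s = c(10, 50, 100, 500),
                                   target_events = 300,
                                   min_replicates = 2000,
                                   max_replicates = 2e6,
                                   seed = NULL) {
  run <- function() {
    if (is.null(mc_grid)) {
      grid <- tidyr::expand_grid(sigma = sigmas, n0 = n0s)
      grid$theta <- vapply(grid$sigma, theta, numeric(1))
      # rough misrepair scale used only to size the replicate budget
      m_hat <- pmin(0.95, 0.77 * 2 * (grid$n0 - 1) * grid$theta)
      grid$replicates <- as.integer(pmax(min_replicates,
                                         pmin(max_replicates,
                                              ceiling(target_events / m_hat))))
      mc <- purrr::pmap_dfr(grid[c("sigma", "n0", "replicates")],
                            function(sigma, n0, replicates) {
        out <- eta_ensemble_cpp(as.integer(n0 - 1), sigma,
                                as.integer(replicates))
        tibble::tibble(mc_fraction = out$m, mc_se = out$se)
      })
      grid <- dplyr::bind_cols(grid, mc)
    } else {
      need <- c("sigma", "n0", "mc_fraction", "mc_se")
      missing <- setdiff(need, names(mc_grid))
      if (length(missing))
        stop("mc_grid is missing column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      grid <- tibble::as_tibble(mc_grid)
      grid$theta <- vapply(grid$sigma, theta, numeric(1))
    }
    if (length(unique(grid$sigma)) < 2)
      stop("calibration needs at least two distinct sigma values",
           call. = FALSE)
    model_m <- function(A, B) {
      om <- 1 - (1 - A) * exp(-B * grid$sigma)
      ev <- 2 * (grid$n0 - 1) * grid$theta * om
      ev / (1 + ev)
    }
    resid <- function(p) (grid$mc_fraction - model_m(p[1], p[2])) / grid$mc_se
    fit <- minpack.lm::nls.lm(par = c(0.75, 4), lower = c(0.01, 0.01),
                              upper = c(1, 50), fn = resid,
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 2, 2))
    ses <- sqrt(diag(vc))
    grid$fitted_fraction <- model_m(fit$par[1], fit$par[2])
    structure(list(A = fit$par[1], B = fit$par[2],
                   se_A = ses[1], se_B = ses[2], vcov = vc,
                   grid = grid, converged = fit$info %in% 1:4,
                   seed = seed),
              class = "geometry_fit")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.geometry_fit <- function(x, ...) {
  cat(sprintf("<geometry_fit> A = %.3f +/- %.3f, B = %.2f +/- %.2f (%d grid points)\n",
              x$A, x$se_A, x$B, x$se_B, nrow(x$grid)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.geometry_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "B"),
                 estimate = c(x$A, x$B),
                 std.error = c(x$se_A, x$se_B))
}

#' @export
glance.geometry_fit <- function(x, ...) {
  r <- (x$grid$mc_fraction - x$grid$fitted_fraction) / x$grid$mc_se
  tibble::tibble(n_points = nrow(x$grid),
                 deviance = sum(r^2),
                 df.residual = nrow(x$grid) - 2,
                 converged = x$converged)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.geometry_fit <- function(object, ...) {
  g <- object$grid
  ggplot2::ggplot(g, ggplot2::aes(.data$sigma, .data$mc_fraction,
                                  colour = factor(.data$n0))) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mc_fraction - .data$mc_se,
                                          ymax = .data$mc_fraction + .data$mc_se)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_fraction)) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sigma (nuclear radii)", y = "Misrepair fraction",
                  colour = "Breaks")
}
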