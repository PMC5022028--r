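#' Names of the jointly fitted DNA-model parameters
#'
#' The nine mechanistic constants estimated by the joint multi-endpoint fit;
#' the two death sensitivities are fitted separately from survival data with
#' the DNA parameters held fixed.
#'
#' @return Character vector of parameter names.
#' @export
dna_parameter_names <- function() {
  c("lambda_fast", "lambda_slow", "lambda_mmej", "p_complex", "p_fail",
    "sigma", "mu_nhej", "mu_mmej", "nu")
}

#' @rdname dna_parameter_names
#' @export
survival_parameter_names <- function() {
  c("mitosis_sensitivity", "arrest_sensitivity")
}

# box bounds bracketing the best-fit values by at least an order of magnitude
parameter_bounds <- function(names) {
  lower <- c(lambda_fast = 1e-4, lambda_slow = 1e-4, lambda_mmej = 1e-4,
             p_complex = 1e-6, p_fail = 0, sigma = 1e-3,
             mu_nhej = 0, mu_mmej = 0, nu = 0,
             mitosis_sensitivity = 1e-6, arrest_sensitivity = 1e-6)
  upper <- c(lambda_fast = 100, lambda_slow = 100, lambda_mmej = 100,
             p_complex = 1, p_fail = 1, sigma = 0.5,
             mu_nhej = 1, mu_mmej = 1, nu = 1,
             mitosis_sensitivity = 1, arrest_sensitivity = 1)
  list(lower = lower[names], upper = upper[names])
}

#' Joint weighted fit of the mechanistic parameters
#'
#' Minimises the weighted residual sum of squares
#' `sum(((value - model) / sd)^2)` over heterogeneous endpoint datasets with
#' bounded Levenberg-Marquardt least squares, varying any chosen subset of
#' the mechanistic parameters and holding the rest fixed (the survival-stage
#' fit, for instance, frees only the two death sensitivities with the DNA
#' parameters fixed). Per-study focus scaling factors are estimated as
#' auxiliary parameters for every distinct `scale_group` in the data.
#'
#' Multi-start optimisation guards against local minima: starts beyond the
#' first jitter the initial values lognormally within bounds and the best
#' converged solution is kept. Parameter uncertainties are one-standard-
#' deviation values from the residual-scaled covariance of the best fit.
#'
#' @param data measurement tibble as produced by
#'   [generate_synthetic_datasets()] (design columns plus `value` and `sd`).
#' @param phenotypes named phenotype list; defaults to the `"phenotypes"`
#'   attribute of `data`.
#' @param start starting [default_parameters()] object (also supplies the
#'   values of fixed parameters).
#' @param free names of parameters to vary (default: the nine DNA-model
#'   parameters).
#' @param multistart number of starts (>= 1).
#' @param jitter lognormal jitter SD applied to starts after the first.
#' @param seed optional integer seed controlling start jitter.
#' @return An object of class `dsb_fit` with elements `par` (named
#'   estimates), `se`, `vcov`, `scalings`, `deviance`, `df.residual`,
#'   `converged`, `fitted`, `data`, `start`, `free`.
#' @examples
#' \donttest{
#' synth <- generate_synthetic_datasets(seed = 1)
#' fit <- joint_fit(synth)
#' tidy(fit)
#' }
#' @export
joint_fit <- function(data, phenotypes = attr(data, "phenotypes"),
                      start = default_parameters(),
                      free = dna_parameter_names(),
                      multistart = 1, jitter = 0.2, seed = NULL) {
  if (!nrow(data)) stop("no datasets supplied", call. = FALSE)
  stopifnot(all(c("value", "sd") %in% names(data)))
  if (any(data$sd <= 0)) stop("all uncertainties must be positive", call. = FALSE)
  if (is.null(phenotypes)) stop("phenotypes must be supplied", call. = FALSE)
  bad <- setdiff(free, c(dna_parameter_names(), survival_parameter_names()))
  if (length(bad))
    stop("cannot fit parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  scale_groups <- if ("scale_group" %in% names(data))
    unique(stats::na.omit(data$scale_group)) else character(0)
  bounds <- parameter_bounds(free)
  p0 <- unlist(start[free])
  if (any(p0 < bounds$lower | p0 > bounds$upper))
    stop("starting values outside bounds", call. = FALSE)
  lower <- c(bounds$lower, rep(0.1, length(scale_groups)))
  upper <- c(bounds$upper, rep(10, length(scale_groups)))

  resid_fun <- function(p) {
    params <- start
    params[free] <- as.list(p[seq_along(free)])
    scalings <- NULL
    if (length(scale_groups)) {
      scalings <- p[length(free) + seq_along(scale_groups)]
      names(scalings) <- scale_groups
    }
    pred <- predict_endpoints(data, params, phenotypes, scalings)
    (data$value - pred) / data$sd
  }

  starts <- list(c(p0, rep(1, length(scale_groups))))
  if (multistart > 1) {
    gen <- function() {
      lapply(seq_len(multistart - 1), function(i) {
        s <- starts[[1]] * exp(stats::rnorm(length(starts[[1]]), 0, jitter))
        pmin(pmax(s, lower), upper)
      })
    }
    extra <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
    starts <- c(starts, extra)
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("optimisation failed from every start; check data and bounds",
         call. = FALSE)
  converged <- best$info %in% 1:4
  if (!converged)
    warning("fit did not formally converge (nls.lm info = ", best$info,
            "): ", best$message, call. = FALSE)
  vc <- tryCatch(stats::vcov(best), error = function(e)
    matrix(NA_real_, length(best$par), length(best$par)))
  all_names <- c(free, if (length(scale_groups))
    paste0("scale_", scale_groups))
  est <- stats::setNames(best$par, all_names)
  se <- stats::setNames(sqrt(diag(vc)), all_names)
  params_hat <- start
  params_hat[free] <- as.list(est[seq_along(free)])
  scalings <- if (length(scale_groups))
    stats::setNames(est[length(free) + seq_along(scale_groups)], scale_groups)
  structure(list(par = est, se = se, vcov = vc,
                 parameters = params_hat,
                 scalings = scalings,
                 deviance = best$deviance,
                 df.residual = nrow(data) - length(best$par),
                 converged = converged,
                 info = best$info,
                 message = best$message,
                 fitted = data$value - resid_fun(best$par) * data$sd,
                 data = data, start = start, free = free),
            class = "dsb_fit")
}

#' @export
print.dsb_fit <- function(x, ...) {
  cat(sprintf("<dsb_fit> %d parameters over %d measurements; WRSS = %.3g%s\n",
              length(x$par), nrow(x$data), x$deviance,
              if (x$converged) "" else " (NOT converged)"))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
coef.dsb_fit <- function(object, ...) object$par

#' @export
tidy.dsb_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par),
                 std.error = unname(x$se))
}

#' @export
glance.dsb_fit <- function(x, ...) {
  tibble::tibble(deviance = x$deviance, df.residual = x$df.residual,
                 n_obs = nrow(x$data), n_par = length(x$par),
                 converged = x$converged)
}

#' @export
autoplot.dsb_fit <- function(object, ...) {
  d <- dplyr::mutate(object$data, fitted = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(.data$fitted, .data$value,
                                  colour = .data$endpoint)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Fitted", y = "Measured", colour = "Endpoint")
}

#' Mean-inactivation-dose stratification
#'
#' Compares observed and modelled radiosensitivity across conditions: the
#' MID (integral of the survival curve, exponential tail beyond the last
#' dose) is computed for each observed dataset and each matching model
#' curve, and the agreement is summarised by the ordinary least-squares
#' slope of observed on modelled MID (through the origin, i.e. against the
#' equality line) and the squared Pearson correlation.
#'
#' @param observed tibble with columns `condition`, `dose_gy`,
#'   `surviving_fraction` for the measured curves.
#' @param modelled tibble with the same columns for the model curves.
#' @return A list of class `mid_stratification`: `table` (per-condition
#'   MIDs), `slope`, `r_squared`.
#' @export
mid_stratification <- function(observed, modelled) {
  need <- c("condition", "dose_gy", "surviving_fraction")
  stopifnot(all(need %in% names(observed)), all(need %in% names(modelled)))
  obs_keys <- unique(observed$condition)
  mod_keys <- unique(modelled$condition)
  unmatched <- c(setdiff(obs_keys, mod_keys), setdiff(mod_keys, obs_keys))
  if (length(unmatched))
    stop("unmatched condition key(s): ", paste(unmatched, collapse = ", "),
         call. = FALSE)
  if (length(obs_keys) < 2)
    stop("at least two conditions are needed; R^2 is undefined for one",
         call. = FALSE)
  # measured curves may carry noise; clamp into the valid survival range
  mid_of <- function(df) mean_inactivation_dose(df$dose_gy,
                                                pmin(df$surviving_fraction, 1))
  tab <- tibble::tibble(
    condition = obs_keys,
    mid_observed = vapply(obs_keys, function(k)
      mid_of(dplyr::arrange(dplyr::filter(observed, .data$condition == k),
                            .data$dose_gy)), numeric(1)),
    mid_modelled = vapply(obs_keys, function(k)
      mid_of(dplyr::arrange(dplyr::filter(modelled, .data$condition == k),
                            .data$dose_gy)), numeric(1)))
  slope <- unname(stats::coef(stats::lm(mid_observed ~ 0 + mid_modelled,
                                        data = tab)))
  r2 <- stats::cor(tab$mid_observed, tab$mid_modelled)^2
  structure(list(table = tab, slope = slope, r_squared = r2),
            class = "mid_stratification")
}

#' @export
print.mid_stratification <- function(x, ...) {
  cat(sprintf("<mid_stratification> %d conditions; slope = %.3f, R^2 = %.3f\n",
              nrow(x$table), x$slope, x$r_squared))
  print(x$table, n = Inf)
  invisible(x)
}

#' @export
autoplot.mid_stratification <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(.data$mid_modelled, .data$mid_observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Modelled MID (Gy)", y = "Observed MID (Gy)")
}
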