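#' Gaussian rejoining kernel
#'
#' Relative rate at which two free DSB ends separated by distance `d` rejoin:
#' `zeta(d) = exp(-d^2 / (2 sigma^2))`, maximal (1) at zero separation and
#' monotone decreasing. The same kernel governs correct rejoining (the two
#' ends of one break, at `d = 0`) and misrejoining between ends of different
#' breaks.
#'
#' @param d separation between ends (same units as `sigma`; vectorised).
#' @param sigma characteristic rejoining range.
#' @return Relative rate(s) in (0, 1].
#' @examples
#' rejoining_kernel(0.0428, 0.0428)  # exp(-1/2)
#' @export
rejoining_kernel <- function(d, sigma) {
  if (!is.numeric(sigma) || any(sigma <= 0))
    stop("sigma must be positive", call. = FALSE)
  if (any(d < 0)) stop("d must be non-negative", call. = FALSE)
  exp(-d^2 / (2 * sigma^2))
}

#' Pair-distance density in a sphere
#'
#' Probability density of the distance between two independent uniform points
#' in a sphere of radius `radius` (the standard closed form; for the unit
#' sphere `f(r) = 3 r^2 - (9/4) r^3 + (3/16) r^5` on `[0, 2]`). This density
#' is the measure against which the rejoining kernel is averaged.
#'
#' @param r distance(s).
#' @param radius sphere radius.
#' @return Density value(s); zero outside `[0, 2 radius]`.
#' @export
pair_distance_density <- function(r, radius = 1) {
  stopifnot(radius > 0)
  u <- r / radius
  out <- (3 * u^2 - (9 / 4) * u^3 + (3 / 16) * u^5) / radius
  out[u < 0 | u > 2] <- 0
  out
}

#' Mean rejoining rate between two random ends
#'
#' `theta` is the expectation of the Gaussian rejoining kernel over the
#' pair-distance distribution of two uniform points in a sphere: the mean
#' relative rate at which two randomly placed free ends rejoin, relative to a
#' co-located correct pair. The generalised form truncates the average at a
#' maximum separation `max_separation` (used for deletion-size-limited
#' counts): contributions from pairs further apart than the cutoff are
#' dropped, so the truncated value is bounded by the full one.
#'
#' Evaluated by adaptive quadrature (absolute tolerance 1e-10) of the
#' closed-form pair-distance density; scale-free, so only `sigma/radius`
#' matters.
#'
#' @param sigma rejoining range.
#' @param radius sphere radius (nucleus or chromosome sub-volume).
#' @param max_separation optional truncation distance; `NULL` for the full
#'   integral.
#' @return A probability-like scalar in `[0, 1]`.
#' @examples
#' theta(0.0428)
#' theta(0.0428, max_separation = 0.1) < theta(0.0428)
#' @export
theta <- function(sigma, radius = 1, max_separation = NULL) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive", call. = FALSE)
  stopifnot(radius > 0)
  upper <- 2 * radius
  if (!is.null(max_separation)) {
    if (max_separation < 0) stop("max_separation must be >= 0", call. = FALSE)
    upper <- min(upper, max_separation)
    if (upper == 0) return(0)
  }
  # scale to the unit sphere
  s <- sigma / radius
  up <- upper / radius
  stats::integrate(function(r) pair_distance_density(r) * exp(-r^2 / (2 * s^2)),
                   lower = 0, upper = up,
                   abs.tol = 1e-10, rel.tol = 1e-8)$value
}

#' Small-sigma skew correction
#'
#' The misrejoining propensity is the mean of a strongly right-skewed
#' per-configuration quantity when `sigma` is much smaller than the nucleus:
#' most breaks have no wrong end nearby while a few have one very close. The
#' multiplicative correction
#' `omega = 1 - (1 - A) exp(-B sigma / R)` absorbs this skew; it tends to `A`
#' as `sigma -> 0` and to 1 where the skew vanishes. The constants `A` and
#' `B` (defaults 0.757 and 5.39) are geometric: they are recovered by
#' matching the analytic propensity to Monte Carlo break-rejoining
#' simulations, see [fit_geometry_constants()]. The correction depends only
#' on `sigma/R` in this parameterisation.
#'
#' @param sigma rejoining range.
#' @param nucleus_radius nucleus radius R.
#' @param params a [default_parameters()] object (supplies `geom_A`, `geom_B`).
#' @return Correction factor(s) in (0, 1].
#' @export
omega_correction <- function(sigma, nucleus_radius = 1,
                             params = default_parameters()) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  1 - (1 - params$geom_A) * exp(-params$geom_B * sigma / nucleus_radius)
}

#' Misrejoining propensity eta
#'
#' The effective integral misrejoining propensity for a single randomly
#' placed DSB in a nucleus of radius `R` when `n_other` other DSBs (i.e.
#' `2 n_other` wrong free ends) are present:
#' `eta = 2 n_other * theta(sigma, R) * omega(sigma)`. The leading factor is
#' the number of wrong free ends competing with the co-located correct
#' partner; `theta` is their mean relative rejoining rate; `omega` corrects
#' the skew of the per-configuration distribution. The implied misrepair
#' fraction is `eta / (1 + eta)`, which is exact in the `sigma -> Inf` limit
#' (uniform random pairing of `2(n_other + 1)` ends).
#'
#' @param n_other number of *other* DSBs present (vectorised; need not be an
#'   integer since expected counts are carried through the analytic chain).
#' @param sigma rejoining range.
#' @param nucleus_radius nucleus radius.
#' @param params a [default_parameters()] object.
#' @return Non-negative propensity value(s); 0 when `n_other = 0`.
#' @examples
#' eta(99, 0.0428)
#' @export
eta <- function(n_other, sigma, nucleus_radius = 1,
                params = default_parameters()) {
  if (any(n_other < 0)) stop("n_other must be non-negative", call. = FALSE)
  2 * n_other * theta(sigma, nucleus_radius) *
    omega_correction(sigma, nucleus_radius, params)
}

# eta for an initial break count n0: each break sees n0 - 1 others.
eta_for_breaks <- function(n0, sigma, nucleus_radius = 1,
                           params = default_parameters()) {
  eta(pmax(n0 - 1, 0), sigma, nucleus_radius, params)
}

#' Probability of correct repair
#'
#' Combines spatial misrejoining with the base fidelity of the repair
#' process: `P_correct = mu_x / (1 + eta)` for NHEJ and MMEJ, where `mu_x` is
#' the process fidelity; homologous recombination is taken to always complete
#' successfully (`P_correct = 1`) regardless of `eta`.
#'
#' @param eta_value misrejoining propensity (from [eta()]; vectorised).
#' @param process one of "NHEJ", "HR", "MMEJ".
#' @param params a [default_parameters()] object.
#' @return Probability in `[0, 1]`.
#' @examples
#' p_correct(0, "NHEJ")  # = mu_nhej
#' p_correct(10, "HR")   # = 1
#' @export
p_correct <- function(eta_value, process = c("NHEJ", "HR", "MMEJ"),
                      params = default_parameters()) {
  process <- match.arg(process)
  if (any(eta_value < 0)) stop("eta_value must be non-negative", call. = FALSE)
  if (process == "HR") return(rep(1, length(eta_value)))
  mu <- switch(process, NHEJ = params$mu_nhej, MMEJ = params$mu_mmej)
  mu / (1 + eta_value)
}

#' Probability that a misrepair event is intra-chromosome
#'
#' Chromosomes are modelled as spherical sub-volumes of radius
#' `r_c = R n_c^(-1/3)`. The probability that a misrejoining partner lies in
#' the same chromosome is the ratio of the within-chromosome rejoining rate
#' to the whole-nucleus rate: `P_intra = theta(sigma, r_c) / (n_c theta(sigma, R))`.
#' Equal to 1 when `n_c = 1`, and tending to `1/n_c` when `sigma >> R`
#' (uniform partner choice).
#'
#' @param n_chromosomes number of chromosomes `n_c`.
#' @param sigma rejoining range.
#' @param nucleus_radius nucleus radius.
#' @return Probability in (0, 1].
#' @examples
#' p_intra(46, 0.0428)
#' @export
p_intra <- function(n_chromosomes, sigma, nucleus_radius = 1) {
  stopifnot(n_chromosomes >= 1)
  r_c <- nucleus_radius * n_chromosomes^(-1 / 3)
  theta(sigma, r_c) / (n_chromosomes * theta(sigma, nucleus_radius))
}

#' Deletion size from end separation (and inverse)
#'
#' Genomic separation along the chromosome is taken to increase monotonically
#' with the spatial distance between the two ends forming the deletion.
#' With DNA distributed uniformly through the nucleus the size in base pairs
#' is `b(r_D) = L (r_D / 2R)^3 * 1e9`, where `L` is the total genome length in
#' Gbp and `r_D` the end separation. The map is self-consistent across
#' scales: at the chromosome sub-volume diameter `r_D = 2 r_c` it returns
#' exactly the mean chromosome length `L / n_c`. `deletion_separation()` is
#' the exact inverse.
#'
#' @param r_d separation between the ends forming the deletion, in units of
#'   the nucleus radius; must lie in `[0, 2 R]`.
#' @param genome_gbp total genome length L in Gbp.
#' @param nucleus_radius nucleus radius R.
#' @return `deletion_size()`: size in base pairs; `deletion_separation()`:
#'   separation in units of R.
#' @examples
#' deletion_size(0.1, 6.1)
#' deletion_separation(deletion_size(0.1, 6.1), 6.1)  # 0.1
#' @export
deletion_size <- function(r_d, genome_gbp, nucleus_radius = 1) {
  if (any(r_d < 0) || any(r_d > 2 * nucleus_radius))
    stop("r_d must lie in [0, 2 R]", call. = FALSE)
  genome_gbp * 1e9 * (r_d / (2 * nucleus_radius))^3
}

#' @rdname deletion_size
#' @param size_bp deletion size in base pairs.
#' @export
deletion_separation <- function(size_bp, genome_gbp, nucleus_radius = 1) {
  if (any(size_bp < 0)) stop("size_bp must be non-negative", call. = FALSE)
  2 * nucleus_radius * pmin(1, (size_bp / (genome_gbp * 1e9)))^(1 / 3)
}
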