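#' Geometry context for a phenotype
#'
#' Precomputes the scale-free geometric quantities used by the aberration and
#' mutation endpoints for one phenotype and rejoining range: the
#' whole-nucleus and chromosome sub-volume `theta` integrals, the
#' intra-chromosome probability, and a tabulated truncated within-chromosome
#' integral used to resolve deletion-size distributions. Returned objects are
#' reused across doses and times.
#'
#' @param phenotype a [cell_phenotype()].
#' @param params a [default_parameters()] object.
#' @return A list of class `geometry_context` with fields `sigma`, `R`,
#'   `n_c`, `r_c`, `genome_gbp`, `l_c_gbp`, `theta_R`, `theta_c`, `p_intra`
#'   and the truncated-integral interpolator `trunc_fraction(r)` giving the
#'   fraction of within-chromosome misrejoining rate at separations `<= r`.
#' @export
geometry_context <- function(phenotype, params = default_parameters()) {
  stopifnot(inherits(phenotype, "cell_phenotype"))
  sigma <- params$sigma
  R <- phenotype$nucleus_radius
  n_c <- phenotype$n_chromosomes
  r_c <- R * n_c^(-1 / 3)
  theta_R <- theta(sigma, R)
  theta_c <- theta(sigma, r_c)
  # cumulative within-chromosome rate up to separation r, on a grid refined
  # near the origin where the kernel mass sits
  r_hi <- 2 * r_c
  r_knee <- min(8 * sigma, r_hi)
  grid <- sort(unique(c(seq(0, r_knee, length.out = 320),
                        seq(r_knee, r_hi, length.out = 120))))
  integrand <- pair_distance_density(grid, r_c) * exp(-grid^2 / (2 * sigma^2))
  cum <- cumsum(c(0, diff(grid) * (utils::head(integrand, -1) +
                                   utils::tail(integrand, -1)) / 2))
  total <- cum[length(cum)]
  trunc_fraction <- stats::approxfun(grid, cum / total, yleft = 0, yright = 1)
  structure(list(sigma = sigma, R = R, n_c = n_c, r_c = r_c,
                 genome_gbp = phenotype$genome_gbp,
                 l_c_gbp = phenotype$genome_gbp / n_c,
                 theta_R = theta_R, theta_c = theta_c,
                 p_intra = theta_c / (n_c * theta_R),
                 trunc_fraction = trunc_fraction,
                 trunc_grid = grid),
            class = "geometry_context")
}

# Misrepair bookkeeping for one exposure at time t (t may be Inf).
# Returns initial, misrepaired, correctly repaired counts and the
# dicentric/deletion split; eta is forced to zero in low-dose-rate mode.
misrepair_components <- function(dose, phenotype, phase = "G1",
                                 t = Inf, dose_rate_mode = "acute",
                                 params = default_parameters(),
                                 geometry = NULL) {
  n0 <- initial_dsb_count(dose, phenotype, phase, params)
  fr <- repair_fractions(phenotype, phase, params)
  if (is.null(geometry)) geometry <- geometry_context(phenotype, params)
  eta_v <- if (identical(dose_rate_mode, "low_dose_rate")) 0 else
    2 * max(n0 - 1, 0) * geometry$theta_R *
      omega_correction(params$sigma, phenotype$nucleus_radius, params)
  p_cor <- c(
    fast = p_correct(eta_v, "NHEJ", params),
    slow = if (fr$hr_active) 1 else p_correct(eta_v, "NHEJ", params),
    mmej = p_correct(eta_v, "MMEJ", params)
  )
  rep_x <- c(fast = repaired_increment(0, t, "fast", n0, fr, params),
             slow = repaired_increment(0, t, "slow", n0, fr, params),
             mmej = repaired_increment(0, t, "mmej", n0, fr, params))
  n_mis <- sum(rep_x * (1 - p_cor))
  n_correct <- sum(rep_x * p_cor)
  n_dic <- params$p_asym * (1 - geometry$p_intra) * n_mis
  n_del <- params$p_asym * geometry$p_intra * n_mis
  list(n0 = n0, fractions = fr, eta = eta_v, n_mis = n_mis,
       n_correct = n_correct, n_dic = n_dic, n_del_total = n_del,
       geometry = geometry)
}

#' Misrepaired DSB count
#'
#' Expected number of misrepaired breaks at time `t`: breaks repaired by each
#' kinetic class up to `t` times that class's misrepair probability
#' `1 - P_correct`, combining the spatial misrejoining propensity (computed
#' from the initial break count) with the base process fidelity. HR-repaired
#' breaks never misrepair. In `low_dose_rate` mode the spatial propensity is
#' set to zero, leaving only base-fidelity misrepair and hence a count
#' exactly linear in dose.
#'
#' @param t assay time in hours (`Inf` for complete repair).
#' @param dose dose in Gy.
#' @param phenotype a [cell_phenotype()].
#' @param phase irradiated phase.
#' @param dose_rate_mode "acute" or "low_dose_rate".
#' @param params a [default_parameters()] object.
#' @return Expected misrepaired-break count.
#' @examples
#' misrepaired_count(Inf, 2, cell_phenotype())
#' @export
misrepaired_count <- function(t, dose, phenotype, phase = "G1",
                              dose_rate_mode = "acute",
                              params = default_parameters()) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  geom <- geometry_context(phenotype, params)
  vapply(t, function(ti)
    misrepair_components(dose, phenotype, phase, ti, dose_rate_mode,
                         params, geom)$n_mis,
    numeric(1))
}

#' Split misrepairs into dicentrics and deletions
#'
#' Asymmetric exchanges occur with probability `p_asym` (0.5); inter-
#' chromosome asymmetric events are dicentrics and intra-chromosome ones
#' deletions: `n_dic = p_asym (1 - P_intra) n_mis`,
#' `n_del = p_asym P_intra n_mis`. The two outputs always sum to
#' `p_asym * n_mis`.
#'
#' @param n_mis misrepaired break count.
#' @param p_intra_value intra-chromosome probability (from [p_intra()]).
#' @param params a [default_parameters()] object.
#' @return A list with `n_dicentric` and `n_deletion_total`.
#' @export
dicentrics_and_deletions <- function(n_mis, p_intra_value,
                                     params = default_parameters()) {
  if (any(n_mis < 0)) stop("n_mis must be non-negative", call. = FALSE)
  list(n_dicentric = params$p_asym * (1 - p_intra_value) * n_mis,
       n_deletion_total = params$p_asym * p_intra_value * n_mis)
}

#' Deletions larger than a size threshold
#'
#' Counts intra-chromosome deletions larger than `D` base pairs using the
#' truncated within-chromosome rejoining integral: the fraction of deletion
#' events with end separation above the inverse deletion-size map of `D`.
#' Non-increasing in `D`; equals the total deletion count at `D = 0` and
#' zero beyond the mean chromosome length.
#'
#' @param D size threshold in base pairs.
#' @param n_del_total total deletion count (e.g. from
#'   [dicentrics_and_deletions()]).
#' @param geometry a [geometry_context()].
#' @return Expected count of deletions larger than `D`.
#' @export
deletions_above <- function(D, n_del_total, geometry) {
  if (any(D < 0)) stop("D must be non-negative", call. = FALSE)
  stopifnot(inherits(geometry, "geometry_context"))
  r_d <- deletion_separation(D, geometry$genome_gbp, geometry$R)
  n_del_total * (1 - geometry$trunc_fraction(r_d))
}

#' G2 inter-arm aberration rate
#'
#' In G2 the presence of the sister chromatid makes intra-chromosome
#' exchanges spanning the centromere visible. Treating the centromere as a
#' point (`g = 0`) at the centre of each of the `n_c` chromosomes, the rate
#' is the centromere-spanning analogue of the gene-deletion integral carried
#' over the whole mean chromosome length: the expected number of deletion
#' events whose span covers a given genomic point, integrated over the
#' chromosome and summed over chromosomes. Always bounded by the total
#' deletion count, since spanning events are a subset of intra-chromosome
#' events.
#'
#' @param t assay time in hours.
#' @param dose dose in Gy.
#' @param phenotype a [cell_phenotype()].
#' @param dose_rate_mode "acute" or "low_dose_rate".
#' @param params a [default_parameters()] object.
#' @return Expected inter-arm aberration count.
#' @export
interarm_rate <- function(t, dose, phenotype, dose_rate_mode = "acute",
                          params = default_parameters()) {
  geom <- geometry_context(phenotype, params)
  vapply(t, function(ti) {
    comp <- misrepair_components(dose, phenotype, "G2", ti, dose_rate_mode,
                                 params, geom)
    interarm_from_deletions(comp$n_del_total, geom)
  }, numeric(1))
}

# n_c / L * integral over the mean chromosome of deletions spanning a point,
# evaluated in separation space where the change of variables is exact.
interarm_from_deletions <- function(n_del_total, geometry) {
  g <- geometry
  r <- g$trunc_grid
  f_above <- 1 - g$trunc_fraction(r)
  w <- 3 * r^2 / (8 * g$R^3)
  integ <- f_above * w
  val <- sum(diff(r) * (utils::head(integ, -1) + utils::tail(integ, -1)) / 2)
  n_del_total * g$n_c * val
}

#' Gene mutation rates
#'
#' Three mutation channels for a gene of length `g` on a genome of length
#' `L`:
#' \describe{
#'   \item{deletion-spanning}{a deletion formed by two breaks outside the
#'     gene covers it entirely. For each genomic point `b` base pairs before
#'     the gene, the chance that a deletion event starting there is larger
#'     than `b + g`, integrated over `b` up to `b_max` (the largest deletion
#'     compatible with survival) and normalised by `L`.}
#'   \item{intra-gene}{every misrepair event involving a break inside the
#'     gene; expected count `n_mis * g / L`.}
#'   \item{point}{small insertions/deletions at correctly rejoined ends:
#'     `nu * n_correct * g / L`.}
#' }
#'
#' @param gene_length_bp gene length `g` in base pairs.
#' @param b_max_bp largest survivable deletion, base pairs.
#' @param dose dose in Gy (vectorised).
#' @param phenotype a [cell_phenotype()].
#' @param phase irradiated phase.
#' @param t assay time in hours (default complete repair).
#' @param dose_rate_mode "acute" or "low_dose_rate".
#' @param params a [default_parameters()] object.
#' @return A tibble with columns `dose_gy`, `mut_deletion`, `mut_intra`,
#'   `mut_point`, `mut_total`.
#' @examples
#' gene_mutation_rate(34e3, 5.8e6, dose = c(2, 4),
#'                    phenotype = cell_phenotype(4.7, 21))
#' @export
gene_mutation_rate <- function(gene_length_bp, b_max_bp, dose, phenotype,
                               phase = "G1", t = Inf,
                               dose_rate_mode = "acute",
                               params = default_parameters()) {
  if (gene_length_bp < 0) stop("gene_length_bp must be >= 0", call. = FALSE)
  if (b_max_bp <= 0) stop("b_max_bp must be positive", call. = FALSE)
  geom <- geometry_context(phenotype, params)
  L_bp <- geom$genome_gbp * 1e9
  purrr::map_dfr(dose, function(d) {
    comp <- misrepair_components(d, phenotype, phase, t, dose_rate_mode,
                                 params, geom)
    mut_del <- spanning_deletion_rate(gene_length_bp, b_max_bp,
                                      comp$n_del_total, geom)
    mut_intra <- comp$n_mis * gene_length_bp / L_bp
    mut_point <- params$nu * comp$n_correct * gene_length_bp / L_bp
    tibble::tibble(dose_gy = d, mut_deletion = mut_del,
                   mut_intra = mut_intra, mut_point = mut_point,
                   mut_total = mut_del + mut_intra + mut_point)
  })
}

# (1/L) * integral_0^{b_max} N_del>(b + g) db, evaluated in separation space.
spanning_deletion_rate <- function(g_bp, b_max_bp, n_del_total, geometry) {
  gm <- geometry
  L_bp <- gm$genome_gbp * 1e9
  r1 <- deletion_separation(g_bp, gm$genome_gbp, gm$R)
  r2 <- deletion_separation(min(g_bp + b_max_bp, L_bp), gm$genome_gbp, gm$R)
  r2 <- min(r2, 2 * gm$r_c)
  if (r2 <= r1) return(0)
  r <- seq(r1, r2, length.out = 200)
  f_above <- 1 - gm$trunc_fraction(r)
  w <- 3 * r^2 / (8 * gm$R^3)
  integ <- f_above * w
  val <- sum(diff(r) * (utils::head(integ, -1) + utils::tail(integ, -1)) / 2)
  n_del_total * val
}

#' Aberration dose/time response
#'
#' Tidy per-condition aberration yields: misrepaired breaks, dicentrics,
#' total and Giemsa-visible deletions, inter-arm events (G2 only) and the
#' visible total. First-mitosis assays correspond to `times = Inf` (complete
#' repair); supply finite times for kinetics (e.g. premature chromosome
#' condensation in G2).
#'
#' @param doses doses in Gy.
#' @param phenotype a [cell_phenotype()].
#' @param phase irradiated phase.
#' @param times assay times in hours (recycled against doses via crossing).
#' @param dose_rate_mode "acute" or "low_dose_rate".
#' @param params a [default_parameters()] object.
#' @return A tibble with one row per dose x time.
#' @examples
#' predict_aberrations(c(1, 2, 4), cell_phenotype())
#' @export
predict_aberrations <- function(doses, phenotype, phase = "G1", times = Inf,
                                dose_rate_mode = "acute",
                                params = default_parameters()) {
  geom <- geometry_context(phenotype, params)
  grid <- tidyr::expand_grid(dose_gy = doses, time_h = times)
  purrr::pmap_dfr(grid, function(dose_gy, time_h) {
    comp <- misrepair_components(dose_gy, phenotype, phase, time_h,
                                 dose_rate_mode, params, geom)
    n_vis_del <- deletions_above(params$deletion_visibility_bp,
                                 comp$n_del_total, geom)
    n_arm <- if (phase == "G2") interarm_from_deletions(comp$n_del_total, geom)
             else 0
    tibble::tibble(dose_gy = dose_gy, time_h = time_h,
                   n_mis = comp$n_mis,
                   n_dicentric = comp$n_dic,
                   n_deletion_total = comp$n_del_total,
                   n_deletion_visible = n_vis_del,
                   n_interarm = n_arm,
                   n_visible = comp$n_dic + n_vis_del + n_arm)
  })
}
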