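#' Condition-specific survival sub-models
#'
#' Survival after irradiation is composed from independent death channels,
#' each a Poisson zero-class probability on an expected count of lethal
#' events.
#'
#' `survival_g1_noncycling()` is the aberration channel for cells that do not
#' cycle through mitosis under observation (G0/G1-held, delayed plating):
#' `S = exp(-(n_dicentric + n_deletion > 3 Mbp))` evaluated at complete
#' repair.
#'
#' `survival_g2()` covers cells irradiated in G2, where lesions are
#' chromatid-type and the replicated sister buffers their impact: a large
#' deletion disrupts the cell line only when both sister chromatids of a
#' chromosome are hit (expected count `n_c (1 - exp(-n_del / (2 n_c)))^2`
#' for `n_del` visible deletions spread over `2 n_c` chromatids), while an
#' asymmetric chromatid exchange sends the aberrant chromatid to one of the
#' two daughters, halving its effective lethality. This gives
#' `S = exp(-(n_dic / 2 + n_c (1 - exp(-n_del / 2 n_c))^2))`, which
#' reproduces the characteristic behaviours of the model: repair-competent
#' cells are more radiosensitive in G2 than in G1 (twice the DNA, hence
#' twice the breaks), while NHEJ-defective cells become more resistant in G2
#' because homologous recombination absorbs the complex breaks that would
#' otherwise fail over to mutagenic MMEJ.
#'
#' `mitotic_survival()` is the exponential mitotic-death channel
#' `exp(-mitosis_sensitivity * n_m)` on the number of breaks present at
#' mitosis, and `g1_escape()` the probability
#' `exp(-arrest_sensitivity * n_g1)` of escaping G1 arrest/apoptosis, applied
#' only to cycling cells with a functional G1 checkpoint.
#'
#' @param dose dose in Gy (vectorised).
#' @param phenotype a [cell_phenotype()].
#' @param params a [default_parameters()] object.
#' @return Survival probability (in (0, 1]).
#' @examples
#' survival_g1_noncycling(2, cell_phenotype())
#' mitotic_survival(35)  # exp(-0.49)
#' @export
survival_g1_noncycling <- function(dose, phenotype,
                                   params = default_parameters()) {
  geom <- geometry_context(phenotype, params)
  vapply(dose, function(d) {
    comp <- misrepair_components(d, phenotype, "G1", Inf, "acute", params, geom)
    n_vis <- deletions_above(params$deletion_visibility_bp,
                             comp$n_del_total, geom)
    exp(-(comp$n_dic + n_vis))
  }, numeric(1))
}

#' @rdname survival_g1_noncycling
#' @export
survival_g2 <- function(dose, phenotype, params = default_parameters()) {
  geom <- geometry_context(phenotype, params)
  n_c <- phenotype$n_chromosomes
  vapply(dose, function(d) {
    comp <- misrepair_components(d, phenotype, "G2", Inf, "acute", params, geom)
    n_vis <- deletions_above(params$deletion_visibility_bp,
                             comp$n_del_total, geom)
    lethal_del <- n_c * (1 - exp(-n_vis / (2 * n_c)))^2
    exp(-(comp$n_dic / 2 + lethal_del))
  }, numeric(1))
}

#' @rdname survival_g1_noncycling
#' @param n_m DSB count present at mitosis.
#' @export
mitotic_survival <- function(n_m, params = default_parameters()) {
  if (any(n_m < 0)) stop("n_m must be non-negative", call. = FALSE)
  exp(-params$mitosis_sensitivity * n_m)
}

#' @rdname survival_g1_noncycling
#' @param n_g1 DSB count induced in G1.
#' @param cycling logical; arrest is only triggered in cycling cells.
#' @export
g1_escape <- function(n_g1, phenotype, params = default_parameters(),
                      cycling = TRUE) {
  if (any(n_g1 < 0)) stop("n_g1 must be non-negative", call. = FALSE)
  if (!cycling || !phenotype$g1_checkpoint_competent)
    return(rep(1, length(n_g1)))
  exp(-params$arrest_sensitivity * n_g1)
}

#' Survival curve for an experimental condition
#'
#' Composes the applicable death channels for a condition:
#' \itemize{
#'   \item G1, non-cycling (delayed plating): aberration channel only.
#'   \item G1, cycling (immediate plating): aberration channel times the G1
#'     escape probability (the escape term is 1 for checkpoint-defective
#'     lines such as CHO).
#'   \item G2: the G2 aberration channel times mitotic death on the breaks
#'     carried through the G2 checkpoint — cells are released when the
#'     unrepaired count first falls below the checkpoint threshold, so the
#'     mitotic term sees `min(n0, checkpoint_threshold)` breaks.
#'   \item M: mitotic death on all induced breaks (no time for repair; DNA
#'     content is replicated).
#' }
#'
#' @param doses dose grid in Gy.
#' @param phenotype a [cell_phenotype()].
#' @param scenario an [exposure()] giving phase/cycling/plating (its dose
#'   field is ignored in favour of `doses`).
#' @param params a [default_parameters()] object.
#' @return A tibble with columns `dose_gy`, `surviving_fraction` and the
#'   per-channel components `aberration_term`, `escape_term`, `mitotic_term`.
#' @examples
#' predict_survival(0:6, cell_phenotype(), exposure(0, "G1"))
#' @export
predict_survival <- function(doses, phenotype, scenario,
                             params = default_parameters()) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  phase <- scenario$phase
  cycling <- scenario$cycling || identical(scenario$plating, "immediate")
  ab <- rep(1, length(doses))
  esc <- rep(1, length(doses))
  mit <- rep(1, length(doses))
  if (phase == "G1") {
    ab <- survival_g1_noncycling(doses, phenotype, params)
    if (cycling) {
      n0 <- initial_dsb_count(doses, phenotype, "G1", params)
      esc <- g1_escape(n0, phenotype, params, cycling = TRUE)
    }
  } else if (phase == "G2") {
    ab <- survival_g2(doses, phenotype, params)
    n0 <- initial_dsb_count(doses, phenotype, "G2", params)
    mit <- mitotic_survival(pmin(n0, params$checkpoint_threshold), params)
  } else if (phase == "M") {
    n0 <- initial_dsb_count(doses, phenotype, "M", params)
    mit <- mitotic_survival(n0, params)
  } else {
    stop("unsupported phase for survival: ", phase, call. = FALSE)
  }
  tibble::tibble(dose_gy = doses,
                 surviving_fraction = ab * esc * mit,
                 aberration_term = ab, escape_term = esc, mitotic_term = mit)
}

#' Mean inactivation dose
#'
#' The integral of the surviving fraction over dose, a scalar summary of
#' radiosensitivity. The curve is refined to a grid no coarser than
#' `step` Gy and integrated piecewise-exponentially (survival is log-linear
#' between grid points, so a pure exponential curve integrates exactly);
#' beyond the last dose the curve is extrapolated exponentially from the
#' final slope. A warning is issued when the curve has not fallen below 0.01
#' at its last dose, or when it is non-decreasing there (in which case no
#' tail is added).
#'
#' @param doses dose grid in Gy (increasing, starting at or near 0).
#' @param surviving_fraction survival values on `doses`.
#' @param step maximum integration step in Gy.
#' @return Mean inactivation dose in Gy.
#' @examples
#' d <- seq(0, 10, 0.25)
#' mean_inactivation_dose(d, exp(-0.5 * d))  # 2.0
#' @export
mean_inactivation_dose <- function(doses, surviving_fraction, step = 0.05) {
  stopifnot(length(doses) == length(surviving_fraction), length(doses) >= 2)
  if (is.unsorted(doses, strictly = TRUE))
    stop("doses must be strictly increasing", call. = FALSE)
  if (any(surviving_fraction <= 0 | surviving_fraction > 1))
    stop("surviving_fraction must lie in (0, 1]", call. = FALSE)
  n <- length(doses)
  if (surviving_fraction[n] > 0.01)
    warning("survival has not fallen below 0.01 at the largest dose; ",
            "MID relies on tail extrapolation", call. = FALSE)
  # refine on a log-linear interpolation of the curve
  fine <- seq(doses[1], doses[n],
              length.out = max(n, ceiling((doses[n] - doses[1]) / step) + 1))
  ls <- stats::approx(doses, log(surviving_fraction), xout = fine)$y
  s <- exp(ls)
  h <- diff(fine)
  k <- -diff(ls) / h
  seg <- ifelse(abs(k) > 1e-12,
                (s[-length(s)] - s[-1]) / k,
                s[-length(s)] * h)
  area <- sum(seg)
  k_tail <- k[length(k)]
  tail <- if (k_tail > 0) s[length(s)] / k_tail else {
    warning("survival curve is non-decreasing at the largest dose; ",
            "no exponential tail added", call. = FALSE)
    0
  }
  area + tail + doses[1] * 1  # leading [0, doses[1]] treated as full survival
}

#' Survival curve plot
#'
#' Semi-log survival curve(s) from [predict_survival()] output (or any tibble
#' with `dose_gy` and `surviving_fraction`), optionally coloured by a
#' condition column.
#'
#' @param data tibble of survival predictions.
#' @param colour optional bare column name used for colour grouping.
#' @return A ggplot object.
#' @export
plot_survival <- function(data, colour = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(.data$dose_gy,
                                          .data$surviving_fraction))
  colour <- rlang::enquo(colour)
  if (!rlang::quo_is_null(colour)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = !!colour))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Dose (Gy)", y = "Surviving fraction")
}
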