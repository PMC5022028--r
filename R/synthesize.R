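#' Default synthetic calibration design
#'
#' A six-endpoint experimental design mirroring the kind of literature data
#' the model is calibrated against: focus time courses (0.25-300 h) across
#' repair-competent and repair-defective lines in G1 and G2, misrepair
#' fractions at 5-80 Gy, aberration yields versus dose (0-10 Gy) for human
#' and hamster-like genomes, G2 aberration kinetics, Hprt-type mutation
#' yields (total and point), and delayed-plating G1 survival — the endpoints
#' that jointly constrain the nine DNA-model parameters. Gene length (34 kbp)
#' and the largest survivable deletion (5.8 Mbp) are placeholder assay
#' constants, user-supplied in real analyses.
#'
#' @return A list with `design` (tibble of conditions, one row per
#'   measurement) and `phenotypes` (named list of [cell_phenotype()]
#'   objects).
#' @examples
#' d <- synthetic_design_default()
#' dplyr::count(d$design, endpoint)
#' @export
synthetic_design_default <- function() {
  phenotypes <- list(
    human_wt   = cell_phenotype(6.1, 46),
    human_nhej = cell_phenotype(6.1, 46, nhej_competent = FALSE),
    human_hr   = cell_phenotype(6.1, 46, hr_competent = FALSE),
    cho_wt     = cell_phenotype(4.7, 21, g1_checkpoint_competent = FALSE)
  )
  foci_times <- c(0.25, 0.5, 1, 2, 4, 8, 24, 72, 150, 300)
  foci <- tidyr::expand_grid(
    endpoint = "foci_timecourse",
    condition = c("human_wt.G1", "human_wt.G2", "human_nhej.G1",
                  "human_nhej.G2", "human_hr.G2"),
    dose_gy = 2, time_h = foci_times) |>
    tidyr::separate_wider_delim("condition", ".",
                                names = c("phenotype_id", "phase"))
  misrep <- tibble::tibble(endpoint = "misrepair_fraction",
                           phenotype_id = "human_wt", phase = "G1",
                           dose_gy = c(5, 10, 20, 40, 60, 80), time_h = Inf)
  aber_dose <- dplyr::bind_rows(
    tidyr::expand_grid(phenotype_id = "human_wt",
                       dose_gy = c(1, 2, 3, 4, 6, 8, 10)),
    tidyr::expand_grid(phenotype_id = "human_nhej", dose_gy = c(1, 2, 4, 6)),
    tidyr::expand_grid(phenotype_id = "cho_wt", dose_gy = c(2, 4, 6, 8))) |>
    dplyr::mutate(endpoint = "aberrations_vs_dose", phase = "G1",
                  time_h = Inf)
  aber_time <- tibble::tibble(endpoint = "aberrations_vs_time",
                              phenotype_id = "human_wt", phase = "G2",
                              dose_gy = 6,
                              time_h = c(0.5, 1, 2, 4, 8, 12, 24))
  mut <- tidyr::expand_grid(endpoint = "mutations_vs_dose",
                            phenotype_id = "cho_wt", phase = "G1",
                            dose_gy = c(1, 2, 4, 6, 8, 10), time_h = Inf,
                            response = c("total", "point"))
  surv <- tidyr::expand_grid(endpoint = "survival_vs_dose",
                             phenotype_id = c("human_wt", "human_nhej"),
                             phase = "G1",
                             dose_gy = c(1, 2, 3, 4, 5, 6, 8), time_h = Inf)
  design <- dplyr::bind_rows(foci, misrep, aber_dose, aber_time, mut, surv) |>
    dplyr::mutate(
      response = dplyr::coalesce(.data$response, "total"),
      dose_rate = "acute",
      plating = "delayed",
      cycling = FALSE,
      gene_length_bp = ifelse(.data$endpoint == "mutations_vs_dose", 34e3, NA),
      b_max_bp = ifelse(.data$endpoint == "mutations_vs_dose", 5.8e6, NA),
      scale_group = NA_character_) |>
    dplyr::select("endpoint", "phenotype_id", "phase", "dose_gy", "time_h",
                  "response", "dose_rate", "plating", "cycling",
                  "gene_length_bp", "b_max_bp", "scale_group")
  list(design = design, phenotypes = phenotypes)
}

#' Forward model over a design table
#'
#' Evaluates the mechanistic model at every row of a design/measurement
#' table. Endpoint kinds supported: `foci_timecourse` (focus count at
#' `time_h`, optionally times a per-study scaling factor),
#' `misrepair_fraction` (misrepaired breaks per initial break at `time_h`),
#' `aberrations_vs_dose` / `aberrations_vs_time` (visible aberrations:
#' dicentrics + deletions above the visibility threshold + inter-arm events
#' in G2), `mutations_vs_dose` (per-cell mutation rate, `response` "total"
#' or "point") and `survival_vs_dose` (surviving fraction for the row's
#' plating/cycling condition).
#'
#' @param design tibble with columns `endpoint`, `phenotype_id`, `phase`,
#'   `dose_gy`, `time_h` and optionally `response`, `dose_rate`, `plating`,
#'   `cycling`, `gene_length_bp`, `b_max_bp`, `scale_group`.
#' @param params a [default_parameters()] object.
#' @param phenotypes named list of [cell_phenotype()] objects resolving
#'   `phenotype_id`.
#' @param scalings named numeric vector of per-study focus scaling factors
#'   (names matching `scale_group`); unmatched rows use 1.
#' @return Numeric vector of model predictions, one per row.
#' @export
predict_endpoints <- function(design, params = default_parameters(),
                              phenotypes, scalings = NULL) {
  if (!nrow(design)) stop("design is empty", call. = FALSE)
  needed <- c("endpoint", "phenotype_id", "phase", "dose_gy", "time_h")
  missing <- setdiff(needed, names(design))
  if (length(missing))
    stop("design is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(unique(design$phenotype_id), names(phenotypes))
  if (length(unknown))
    stop("unresolved phenotype_id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  d <- design
  if (!"response" %in% names(d)) d$response <- "total"
  if (!"dose_rate" %in% names(d)) d$dose_rate <- "acute"
  if (!"plating" %in% names(d)) d$plating <- "delayed"
  if (!"cycling" %in% names(d)) d$cycling <- FALSE
  if (!"scale_group" %in% names(d)) d$scale_group <- NA_character_

  geoms <- lapply(phenotypes[unique(d$phenotype_id)], geometry_context,
                  params = params)
  out <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    ph <- phenotypes[[d$phenotype_id[i]]]
    geom <- geoms[[d$phenotype_id[i]]]
    ep <- d$endpoint[i]
    dose <- d$dose_gy[i]
    t_i <- d$time_h[i]
    out[i] <- switch(
      ep,
      foci_timecourse = {
        n0 <- initial_dsb_count(dose, ph, d$phase[i], params)
        fr <- repair_fractions(ph, d$phase[i], params)
        sc <- 1
        if (!is.na(d$scale_group[i]) && !is.null(scalings) &&
            d$scale_group[i] %in% names(scalings))
          sc <- scalings[[d$scale_group[i]]]
        predicted_foci(t_i, n0, fr, params, scaling = sc)
      },
      misrepair_fraction = {
        comp <- misrepair_components(dose, ph, d$phase[i], t_i,
                                     d$dose_rate[i], params, geom)
        if (comp$n0 > 0) comp$n_mis / comp$n0 else 0
      },
      aberrations_vs_dose = ,
      aberrations_vs_time = {
        comp <- misrepair_components(dose, ph, d$phase[i], t_i,
                                     d$dose_rate[i], params, geom)
        n_vis <- deletions_above(params$deletion_visibility_bp,
                                 comp$n_del_total, geom)
        arm <- if (d$phase[i] == "G2")
          interarm_from_deletions(comp$n_del_total, geom) else 0
        comp$n_dic + n_vis + arm
      },
      mutations_vs_dose = {
        comp <- misrepair_components(dose, ph, d$phase[i], t_i,
                                     d$dose_rate[i], params, geom)
        g_bp <- d$gene_length_bp[i]
        L_bp <- geom$genome_gbp * 1e9
        if (identical(d$response[i], "point")) {
          params$nu * comp$n_correct * g_bp / L_bp
        } else {
          spanning_deletion_rate(g_bp, d$b_max_bp[i], comp$n_del_total, geom) +
            comp$n_mis * g_bp / L_bp +
            params$nu * comp$n_correct * g_bp / L_bp
        }
      },
      survival_vs_dose = {
        scen <- exposure(dose, d$phase[i],
                         plating = d$plating[i],
                         cycling = isTRUE(d$cycling[i]))
        predict_survival(dose, ph, scen, params)$surviving_fraction
      },
      stop("unknown endpoint kind: ", ep, call. = FALSE)
    )
  }
  out
}

#' Generate synthetic endpoint datasets
#'
#' Evaluates the forward model over a design, perturbs each value with
#' Gaussian relative noise and attaches measurement uncertainties
#' `sd = noise_relative * |value|` (floored at a small positive constant),
#' mimicking digitised multi-endpoint literature data with a uniform added
#' relative uncertainty. With `noise_relative = 0` the data lie exactly on
#' the model surface. Deterministic under `seed`.
#'
#' @param true_params generating [default_parameters()] object.
#' @param design a design list from [synthetic_design_default()] or a
#'   compatible `list(design =, phenotypes =)`.
#' @param noise_relative relative noise level (default 0.05).
#' @param seed optional integer seed.
#' @param sd_floor lower bound on reported uncertainties.
#' @return The design tibble with columns `truth`, `value` and `sd` added;
#'   the phenotype list is attached as attribute `"phenotypes"`.
#' @examples
#' synth <- generate_synthetic_datasets(seed = 1)
#' head(synth)
#' @export
generate_synthetic_datasets <- function(true_params = default_parameters(),
                                        design = synthetic_design_default(),
                                        noise_relative = 0.05, seed = NULL,
                                        sd_floor = 1e-8) {
  if (noise_relative < 0) stop("noise_relative must be >= 0", call. = FALSE)
  if (!nrow(design$design)) stop("design is empty", call. = FALSE)
  truth <- predict_endpoints(design$design, true_params, design$phenotypes)
  perturb <- function() {
    z <- stats::rnorm(length(truth))
    tibble::tibble(value = truth * (1 + noise_relative * z),
                   sd = pmax(noise_relative * abs(truth), sd_floor))
  }
  noise <- if (is.null(seed)) perturb() else withr::with_seed(seed, perturb())
  out <- dplyr::bind_cols(design$design, tibble::tibble(truth = truth), noise)
  attr(out, "phenotypes") <- design$phenotypes
  out
}
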