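#' Mechanistic model parameters
#'
#' Container for the constants of the DSB repair/misrepair model. The eleven
#' fitted mechanistic constants (three repair rates, the complex-break and
#' repair-failure probabilities, the misrejoining range, two process
#' fidelities, the point-mutation factor, and two death sensitivities) default
#' to the joint best-fit values; the remaining entries are fixed model
#' constants (induction rate per Gbp, the geometric correction constants, the
#' asymmetric-exchange probability, the Giemsa visibility threshold, the G2
#' checkpoint release threshold and the focus-formation lag).
#'
#' @param ... named overrides for any parameter, e.g. `sigma = 0.05`.
#'
#' @details Parameters and units:
#' \describe{
#'   \item{induction_rate}{DSB Gy^-1 Gbp^-1, fixed at 5.738.}
#'   \item{lambda_fast, lambda_slow, lambda_mmej}{repair rate constants, h^-1
#'     (fast NHEJ, slow complex/HR, and MMEJ classes).}
#'   \item{p_complex}{probability that a break is complex (slow-class).}
#'   \item{p_fail}{probability that a break whose preferred pathway is
#'     defective fails over to MMEJ.}
#'   \item{sigma}{characteristic misrejoining range, units of nucleus radius.}
#'   \item{mu_nhej, mu_mmej}{base repair fidelities of NHEJ and MMEJ.}
#'   \item{nu}{point-mutation factor per correctly repaired break.}
#'   \item{mitosis_sensitivity}{per-break mitotic death rate (break^-1).}
#'   \item{arrest_sensitivity}{per-break G1 arrest/apoptosis rate (break^-1).}
#'   \item{geom_A, geom_B}{constants of the small-sigma skew correction
#'     omega = 1 - (1 - A) exp(-B sigma / R).}
#'   \item{p_asym}{probability that an exchange is asymmetric (0.5).}
#'   \item{deletion_visibility_bp}{deletion size visible/lethal in
#'     Giemsa-type assays, base pairs (3 Mbp).}
#'   \item{checkpoint_threshold}{DSB count below which the G2 checkpoint
#'     releases cells into mitosis (20).}
#'   \item{foci_lag}{lag between break formation and focus appearance,
#'     minutes (7.5).}
#' }
#'
#' @return An object of class `dsb_params` (a named list).
#' @examples
#' p <- default_parameters(sigma = 0.05)
#' p$sigma
#' @export
default_parameters <- function(...) {
  p <- list(
    induction_rate = 5.738,
    lambda_fast = 3.6,
    lambda_slow = 0.15,
    lambda_mmej = 0.0084,
    p_complex = 0.42,
    p_fail = 0.67,
    sigma = 0.0428,
    mu_nhej = 0.985,
    mu_mmej = 0.465,
    nu = 0.044,
    mitosis_sensitivity = 0.014,
    arrest_sensitivity = 0.0085,
    geom_A = 0.757,
    geom_B = 5.39,
    p_asym = 0.5,
    deletion_visibility_bp = 3e6,
    checkpoint_threshold = 20,
    foci_lag = 7.5
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    p[names(dots)] <- dots
  }
  validate_parameters(structure(p, class = "dsb_params"))
}

#' @rdname default_parameters
#' @param params object to validate.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "dsb_params"))
  probs <- c("p_complex", "p_fail", "mu_nhej", "mu_mmej", "nu", "p_asym")
  for (nm in probs) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop(nm, " must be a probability in [0, 1]", call. = FALSE)
  }
  pos <- c("induction_rate", "lambda_fast", "lambda_slow", "lambda_mmej",
           "sigma", "mitosis_sensitivity", "arrest_sensitivity", "geom_A",
           "geom_B", "deletion_visibility_bp", "checkpoint_threshold")
  for (nm in pos) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stop(nm, " must be a positive number", call. = FALSE)
  }
  if (params$foci_lag < 0) stop("foci_lag must be non-negative", call. = FALSE)
  if (!(params$lambda_fast > params$lambda_slow &&
        params$lambda_slow > params$lambda_mmej))
    warning("expected lambda_fast > lambda_slow > lambda_mmej; ",
            "rate ordering is not physical", call. = FALSE)
  params
}

#' @export
print.dsb_params <- function(x, ...) {
  cat("<dsb_params>\n")
  df <- tibble::tibble(parameter = names(x),
                       value = vapply(x, as.numeric, numeric(1)))
  print(df, n = Inf)
  invisible(x)
}

#' Cell phenotype description
#'
#' The cell-level inputs of the model: DNA content in G1 (Gbp), chromosome
#' number, competence flags for the two primary repair pathways and for the
#' G1 checkpoint, and the nucleus radius (the geometry is scale-free; all
#' lengths are expressed in units of this radius, default 1).
#'
#' @param genome_gbp G1 DNA content in Gbp (e.g. 6.1 for a diploid human cell).
#' @param n_chromosomes number of chromosomes in the nucleus.
#' @param nhej_competent,hr_competent logical pathway-competence flags.
#' @param g1_checkpoint_competent logical; cells lacking a functional G1
#'   checkpoint (e.g. CHO) neither arrest nor apoptose at the G1/S transition.
#' @param nucleus_radius nucleus radius; kept at 1 (normalised).
#' @return An object of class `cell_phenotype`.
#' @examples
#' human <- cell_phenotype(6.1, 46)
#' cho <- cell_phenotype(4.7, 21, g1_checkpoint_competent = FALSE)
#' @export
cell_phenotype <- function(genome_gbp = 6.1, n_chromosomes = 46,
                           nhej_competent = TRUE, hr_competent = TRUE,
                           g1_checkpoint_competent = TRUE,
                           nucleus_radius = 1) {
  if (!is.numeric(genome_gbp) || genome_gbp <= 0)
    stop("genome_gbp must be positive", call. = FALSE)
  if (!is.numeric(n_chromosomes) || n_chromosomes < 1)
    stop("n_chromosomes must be >= 1", call. = FALSE)
  if (nucleus_radius <= 0) stop("nucleus_radius must be positive", call. = FALSE)
  structure(list(genome_gbp = genome_gbp,
                 n_chromosomes = as.integer(n_chromosomes),
                 nhej_competent = isTRUE(nhej_competent),
                 hr_competent = isTRUE(hr_competent),
                 g1_checkpoint_competent = isTRUE(g1_checkpoint_competent),
                 nucleus_radius = nucleus_radius),
            class = "cell_phenotype")
}

#' @export
print.cell_phenotype <- function(x, ...) {
  cat("<cell_phenotype> ", x$genome_gbp, " Gbp, ", x$n_chromosomes,
      " chromosomes; NHEJ ", if (x$nhej_competent) "+" else "-",
      ", HR ", if (x$hr_competent) "+" else "-",
      ", G1 checkpoint ", if (x$g1_checkpoint_competent) "+" else "-",
      "\n", sep = "")
  invisible(x)
}

#' Exposure scenario
#'
#' Describes a single irradiation condition: dose, cell-cycle phase at
#' irradiation, assay time, dose-rate mode and plating/cycling status.
#' Phases supported are G1, G2 and M; S-phase irradiation is outside the
#' model and rejected. In `low_dose_rate` mode multi-break interaction is
#' switched off (the spatial misrejoining propensity is set to zero), leaving
#' only base-fidelity misrepair.
#'
#' @param dose absorbed dose in Gy.
#' @param phase cell-cycle phase at irradiation: "G1", "G2" or "M".
#' @param assay_time time post-exposure at which the endpoint is scored,
#'   hours; `Inf` means full repair (first-mitosis scoring).
#' @param dose_rate_mode "acute" (all breaks present at t = 0) or
#'   "low_dose_rate".
#' @param plating "delayed" (cells held before plating) or "immediate".
#' @param cycling logical; whether cells are actively cycling.
#' @return An object of class `exposure_scenario`.
#' @examples
#' exposure(2, "G1")
#' exposure(4, "G2", assay_time = 12)
#' @export
exposure <- function(dose, phase = c("G1", "G2", "M"), assay_time = Inf,
                     dose_rate_mode = c("acute", "low_dose_rate"),
                     plating = c("delayed", "immediate"), cycling = FALSE) {
  if (!is.numeric(dose) || any(dose < 0))
    stop("dose must be non-negative", call. = FALSE)
  if (is.character(phase) && length(phase) == 1 && phase == "S")
    stop("S-phase irradiation is not supported", call. = FALSE)
  phase <- match.arg(phase)
  if (!is.numeric(assay_time) || any(assay_time < 0))
    stop("assay_time must be non-negative", call. = FALSE)
  structure(list(dose = dose, phase = phase, assay_time = assay_time,
                 dose_rate_mode = match.arg(dose_rate_mode),
                 plating = match.arg(plating), cycling = isTRUE(cycling)),
            class = "exposure_scenario")
}

#' Read and write parameter configurations
#'
#' Parameter sets, phenotypes and scenarios are serialised as flat YAML
#' key-value files keyed by the field names used throughout the package, so a
#' fitted parameter set written by [joint_fit()]/[write_parameters()] can be
#' read straight back as a model configuration (round-trip guaranteed).
#'
#' @param path file path.
#' @param params a `dsb_params` object.
#' @return `read_parameters()` returns a `dsb_params`; `write_parameters()`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_parameters(default_parameters(), f)
#' identical(read_parameters(f), default_parameters())
#' @export
read_parameters <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_parameters, vals)
}

#' @rdname read_parameters
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "dsb_params"))
  yaml::write_yaml(lapply(unclass(params), as.numeric), path)
  invisible(path)
}

#' @rdname read_parameters
#' @export
read_phenotype <- function(path) {
  vals <- yaml::read_yaml(path)
  needed <- c("genome_gbp", "n_chromosomes")
  missing <- setdiff(needed, names(vals))
  if (length(missing))
    stop("phenotype config is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(cell_phenotype, vals)
}

# DNA content (Gbp) at the irradiated phase: G2 and M carry replicated DNA.
dna_content <- function(phenotype, phase) {
  stopifnot(inherits(phenotype, "cell_phenotype"))
  switch(phase,
         G1 = phenotype$genome_gbp,
         G2 = 2 * phenotype$genome_gbp,
         M  = 2 * phenotype$genome_gbp,
         stop("unsupported phase: ", phase, call. = FALSE))
}
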