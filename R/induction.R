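#' Initial DSB yield
#'
#' Expected number of double-strand breaks immediately after an acute
#' exposure: the fixed induction constant (5.738 DSB/Gy/Gbp) times dose times
#' the DNA content present at the irradiated phase (G1 content in G1; twice
#' that in G2 and M, where the genome is replicated). The yield is exactly
#' linear in both dose and DNA content; for a 6.1 Gbp human genome in G1 this
#' gives the canonical ~35 DSB/Gy. The count is carried as a real-valued
#' expectation; integer sampling only happens inside the stochastic
#' simulators.
#'
#' @param dose absorbed dose in Gy (vectorised).
#' @param phenotype a [cell_phenotype()].
#' @param phase irradiated phase, "G1", "G2" or "M".
#' @param params a [default_parameters()] object.
#' @return Expected DSB count(s), same length as `dose`.
#' @examples
#' initial_dsb_count(1, cell_phenotype(6.1, 46))  # ~35
#' @export
initial_dsb_count <- function(dose, phenotype, phase = "G1",
                              params = default_parameters()) {
  if (!is.numeric(dose) || any(is.na(dose)) || any(dose < 0))
    stop("dose must be non-negative", call. = FALSE)
  params$induction_rate * dose * dna_content(phenotype, phase)
}

#' Repair-class fractions and fidelities
#'
#' Partition of breaks between the three kinetic repair classes. Breaks are
#' complex with probability `p_complex`; simple breaks are fast-class (NHEJ)
#' and complex breaks slow-class (HR in G2 when available, otherwise slow
#' NHEJ). If the preferred pathway for a class is defective, that class's
#' breaks fail over to the MMEJ class with probability `p_fail` and otherwise
#' keep their class kinetics (repaired by the residual pathway). The fractions
#' always sum to one.
#'
#' Each class also carries the base fidelity of the pathway that actually
#' performs the repair: `mu_nhej` for NHEJ-repaired classes, 1 for HR (repair
#' by homologous recombination is taken to always complete correctly, with no
#' spatial misrejoining either), `mu_mmej` for MMEJ.
#'
#' @inheritParams initial_dsb_count
#' @return A list of class `repair_fractions` with elements `p_f`, `p_s`,
#'   `p_m` (probabilities of fast/slow/MMEJ repair), `fidelity` (named vector
#'   of base fidelities per class) and `hr_active` (whether the slow class is
#'   HR).
#' @examples
#' repair_fractions(cell_phenotype(), "G1")            # p_f 0.58, p_s 0.42
#' repair_fractions(cell_phenotype(nhej_competent = FALSE), "G2")
#' @export
repair_fractions <- function(phenotype, phase = "G1",
                             params = default_parameters()) {
  stopifnot(inherits(phenotype, "cell_phenotype"))
  if (!phase %in% c("G1", "G2", "M"))
    stop("unsupported phase: ", phase, call. = FALSE)
  pc <- params$p_complex
  pfail <- params$p_fail
  # M-phase breaks face the same pathway availability as G2 chromatin
  hr_available <- phase %in% c("G2", "M") && phenotype$hr_competent

  # preferred pathways: simple -> NHEJ; complex -> HR when available, else NHEJ
  fast_fails <- !phenotype$nhej_competent
  slow_pref_hr <- phase %in% c("G2", "M")
  # complex breaks in G2 prefer HR; with HR defective they divert with p_fail
  # and are otherwise repaired slow-class by NHEJ
  slow_fails <- if (slow_pref_hr) !phenotype$hr_competent
                else !phenotype$nhej_competent

  p_f <- (1 - pc) * (if (fast_fails) 1 - pfail else 1)
  p_s <- pc * (if (slow_fails) 1 - pfail else 1)
  p_m <- max(0, 1 - p_f - p_s)

  fidelity <- c(fast = params$mu_nhej,
                slow = if (hr_available) 1 else params$mu_nhej,
                mmej = params$mu_mmej)
  structure(list(p_f = p_f, p_s = p_s, p_m = p_m,
                 fidelity = fidelity, hr_active = hr_available),
            class = "repair_fractions")
}

#' @export
print.repair_fractions <- function(x, ...) {
  cat(sprintf("<repair_fractions> fast %.4f | slow %.4f (%s) | mmej %.4f\n",
              x$p_f, x$p_s, if (x$hr_active) "HR" else "NHEJ", x$p_m))
  invisible(x)
}
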