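# shared fixtures: phenotypes and phenotype x phase sweeps used across tests

human_wt <- cell_phenotype(6.1, 46)
human_nhej <- cell_phenotype(6.1, 46, nhej_competent = FALSE)
human_hr <- cell_phenotype(6.1, 46, hr_competent = FALSE)
human_double <- cell_phenotype(6.1, 46, nhej_competent = FALSE,
                               hr_competent = FALSE)
cho_wt <- cell_phenotype(4.7, 21, g1_checkpoint_competent = FALSE)

all_phenotypes <- list(wt = human_wt, nhej = human_nhej, hr = human_hr,
                       double = human_double, cho = cho_wt)
all_phases <- c("G1", "G2", "M")

# brute-force Monte Carlo estimate of theta: mean kernel over random point
# pairs in the unit sphere (independent oracle for the quadrature)
mc_theta <- function(sigma, n_pairs, seed) {
  withr::with_seed(seed, {
    pt <- function(n) {
      m <- matrix(stats::runif(3 * ceiling(n * 2.2), -1, 1), ncol = 3)
      m <- m[rowSums(m^2) <= 1, , drop = FALSE]
      m[seq_len(n), , drop = FALSE]
    }
    a <- pt(n_pairs); b <- pt(n_pairs)
    d2 <- rowSums((a - b)^2)
    k <- exp(-d2 / (2 * sigma^2))
    list(mean = mean(k), se = stats::sd(k) / sqrt(n_pairs))
  })
}
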