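# Shared fixtures, built in code at test time.

# Two-population toy dosage matrices used for the frozen Weir-Cockerham
# check (independent oracle values computed from the published 1984 formulas).
wc_toy <- function() {
  A <- matrix(c(0, 1, 2, 0, 1,
                1, 1, 2, 0, 0,
                0, 2, 1, 1, 0,
                2, 1, 2, 0, 1,
                1, 0, 1, 0, 0,
                0, 1, 2, 1, 1), 6, 5, byrow = TRUE)
  B <- matrix(c(2, 0, 0, 1, 1,
                1, 0, 1, 2, 0,
                2, 1, 0, 1, 1,
                2, 0, 0, 2, 0,
                1, 0, 1, 1, 1,
                2, 1, 0, 1, 0), 6, 5, byrow = TRUE)
  list(A = genotype_matrix(A), B = genotype_matrix(B))
}

# Small K-population reference world for ancestry tests.
small_world <- function(K = 3, M = 150, n_per_pop = 30, seed = 11,
                        divergence = NULL) {
  if (is.null(divergence)) {
    divergence <- stats::setNames(seq(0.08, 0.16, length.out = K),
                                  paste0("P", seq_len(K)))
  }
  model <- ancestral_model(M = M, divergence = divergence)
  panels <- simulate_reference_panels(model, n_per_pop = n_per_pop, seed = seed)
  list(model = model, panels = panels,
       panel = estimate_reference_freqs(panels$genotypes))
}

# Genotypes for individuals with known admixture, drawn from true frequencies.
admixed_genotypes <- function(panels, Q, seed = 1) {
  set.seed(seed)
  pm <- Q %*% panels$true_freqs
  genotype_matrix(
    matrix(stats::rbinom(nrow(Q) * ncol(pm), 2L, pm), nrow(Q), ncol(pm)),
    variants = panels$variants
  )
}

rdirichlet_test <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              n, length(alpha))
  x / rowSums(x)
}

subset_panel_test <- function(panel, idx) {
  reference_panel(panel$freqs[, idx, drop = FALSE], panel$n_samples,
                  panel$variants[idx, , drop = FALSE])
}

# Deterministic stage-2 response table: per-region constant standardized rate
# over `years` repeated observations.
toy_std_rates <- function(regions, rates, person_years = 1e6, years = 3,
                          icd = "X") {
  expand <- expand.grid(year = seq_len(years) + 2000, region = regions,
                        stringsAsFactors = FALSE)
  data.frame(
    region = expand$region, year = expand$year, icd = icd,
    std_rate = rates[match(expand$region, regions)],
    person_years = person_years
  )
}
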