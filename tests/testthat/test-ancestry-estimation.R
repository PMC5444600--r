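# Reference frequency estimation ---------------------------------------------

test_that("pseudocount frequencies follow the stated arithmetic", {
  # 9 samples all homozygous alt: (18 + .5) / (18 + 1) = 18.5/19
  g_all <- genotype_matrix(matrix(2L, 9, 1))
  p <- estimate_reference_freqs(list(P = g_all))
  expect_equal(unname(p$freqs[1, 1]), 18.5 / 19)
  # no alt among 9: 0.5/19
  g_none <- genotype_matrix(matrix(0L, 9, 1))
  p <- estimate_reference_freqs(list(P = g_none))
  expect_equal(unname(p$freqs[1, 1]), 0.5 / 19)
  # pseudocount 0, all called, 50% alt -> exactly 0.5
  g_half <- genotype_matrix(matrix(1L, 4, 1))
  p <- estimate_reference_freqs(list(P = g_half), pseudocount = 0)
  expect_equal(unname(p$freqs[1, 1]), 0.5)
})

test_that("zero called genotypes fall back to the pseudocount with a warning", {
  g <- genotype_matrix(matrix(NA_integer_, 3, 1))
  expect_warning(p <- estimate_reference_freqs(list(P = g)), "zero called")
  expect_equal(unname(p$freqs[1, 1]), 0.5)
})

test_that("label-vector form splits one matrix into population panels", {
  set.seed(6)
  g <- genotype_matrix(matrix(stats::rbinom(60, 2, 0.4), 10, 6))
  p <- estimate_reference_freqs(g, labels = rep(c("A", "B"), each = 5))
  expect_setequal(p$populations, c("A", "B"))
  expect_equal(unname(p$n_samples[c("A", "B")]), c(5L, 5L))
})

# Supervised estimation -------------------------------------------------------

test_that("a single decisive marker drives the estimate to the boundary", {
  pan <- reference_panel(rbind(P1 = 1 - 1e-4, P2 = 1e-4), c(P1 = 9, P2 = 9))
  e <- estimate_ancestry(2L, pan)
  expect_gt(e$q["P1"], 0.99)
  expect_true(e$converged)
  o <- grid_oracle(2L, pan, resolution = 0.01)
  expect_equal(unname(o$q), c(1, 0))
})

test_that("identical reference frequencies yield a uniform non-identifiable answer", {
  f <- matrix(rep(c(0.3, 0.6, 0.4), each = 2), 2, 3)
  pan <- reference_panel(f, c(p1 = 5, p2 = 5))
  expect_warning(e <- estimate_ancestry(c(1L, 2L, 0L), pan), "flat")
  expect_equal(unname(e$q), c(0.5, 0.5))
})

test_that("estimates live on the simplex and never fall below the grid oracle", {
  w <- small_world(K = 3, M = 120, seed = 51)
  set.seed(52)
  for (i in 1:10) {
    q <- as.numeric(rdirichlet_test(1, c(1, 1, 1)))
    g <- stats::rbinom(120, 2, as.numeric(q %*% w$panels$true_freqs))
    e <- estimate_ancestry(g, w$panel)
    expect_true(all(e$q >= 0))
    expect_equal(sum(e$q), 1, tolerance = 1e-8)
    o <- grid_oracle(g, w$panel, resolution = 0.02)
    expect_gte(e$loglik, o$loglik - 1e-6)
    expect_lte(sum(abs(e$q - o$q)), 0.04 + 1e-9)   # lattice spacing 0.02
  }
})

test_that("missing dosages are skipped in the likelihood", {
  w <- small_world(K = 2, M = 100, seed = 61, divergence = c(A = .2, B = .2))
  set.seed(62)
  g <- stats::rbinom(100, 2, as.numeric(c(0.7, 0.3) %*% w$panels$true_freqs))
  g_miss <- g; g_miss[41:100] <- NA
  e_sub <- estimate_ancestry(g[1:40], subset_panel_test(w$panel, 1:40))
  e_miss <- estimate_ancestry(g_miss, w$panel)
  expect_equal(e_miss$q, e_sub$q, tolerance = 1e-6)
  expect_equal(e_miss$loglik, e_sub$loglik, tolerance = 1e-6)
})

test_that("matrix estimator agrees with the single-individual estimator", {
  w <- small_world(K = 3, M = 150, seed = 71)
  set.seed(72)
  Q <- rdirichlet_test(6, c(2, 2, 2))
  g <- admixed_genotypes(w$panels, Q, seed = 73)
  res <- estimate_ancestry_matrix(g, w$panel, tol = 1e-10)
  for (i in 1:6) {
    e <- estimate_ancestry(g$dosage[i, ], w$panel, tol = 1e-10, max_iter = 1e5)
    expect_lt(max(abs(as.numeric(res[i, w$panel$populations]) - e$q)), 1e-3)
  }
  expect_true(all(abs(rowSums(res[, w$panel$populations]) - 1) < 1e-8))
})

test_that("recovery error shrinks as the marker count grows", {
  errs <- vapply(c(100, 1000, 5000), function(M) {
    model <- ancestral_model(M = M, divergence = c(A = .15, B = .1, C = .12))
    panels <- simulate_reference_panels(model, n_per_pop = 60, seed = 81)
    pan <- estimate_reference_freqs(panels$genotypes)
    set.seed(82)
    Q <- rdirichlet_test(25, c(2, 2, 2))
    g <- admixed_genotypes(panels, Q, seed = 83)
    res <- estimate_ancestry_matrix(g, pan)
    mean(abs(as.matrix(res[, pan$populations]) - Q))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("grid oracle lattice has the exact combinatorial size", {
  pan <- reference_panel(rbind(P1 = 0.7, P2 = 0.2), c(P1 = 4, P2 = 4))
  o <- grid_oracle(1L, pan, resolution = 0.5)
  expect_equal(o$n_evaluated, 3)        # (1,0), (.5,.5), (0,1)
  pan5 <- reference_panel(matrix(runif(5 * 3, .2, .8), 5, 3), rep(4, 5))
  expect_error(grid_oracle(c(1L, 1L, 0L), pan5, resolution = 0.01),
               "lattice too large")
})

# MAF confidence-interval filter ----------------------------------------------

dosage_with_alt <- function(n_samples, n_alt_alleles) {
  # distribute alt alleles over samples (dosage 2 then 1)
  d <- integer(n_samples)
  full <- n_alt_alleles %/% 2
  d[seq_len(full)] <- 2L
  if (n_alt_alleles %% 2) d[full + 1] <- 1L
  d
}

test_that("Wilson 80% intervals match independently computed values", {
  # 50 samples -> 100 alleles; 10 vs 20 minor alleles (frozen reference
  # values computed from the Wilson score formula at z = qnorm(0.9))
  ci_eur <- maf_confint(10, 100, level = 0.80, method = "wilson")
  ci_map <- maf_confint(20, 100, level = 0.80, method = "wilson")
  expect_equal(ci_eur, c(0.06778483, 0.14514186), tolerance = 1e-7)
  expect_equal(ci_map, c(0.15377074, 0.25592428), tolerance = 1e-7)
  # these borderline intervals are disjoint: the variant is retained
  g_eur <- genotype_matrix(matrix(dosage_with_alt(50, 10), ncol = 1))
  g_poo <- genotype_matrix(matrix(dosage_with_alt(50, 20), ncol = 1))
  g_map <- genotype_matrix(matrix(dosage_with_alt(50, 20), ncol = 1))
  out <- maf_ci_filter(g_eur, g_poo, g_map)
  expect_length(out$retained, 1)
})

test_that("identical frequencies are excluded, fixed differences retained", {
  make <- function(doses) genotype_matrix(matrix(doses, ncol = 2))
  # variant 1: identical MAF everywhere; variant 2: 0.0 vs 0.5
  eur <- make(c(dosage_with_alt(50, 30), dosage_with_alt(50, 0)))
  poo <- make(c(dosage_with_alt(50, 30), dosage_with_alt(50, 50)))
  map <- make(c(dosage_with_alt(50, 30), dosage_with_alt(50, 50)))
  out <- maf_ci_filter(eur, poo, map)
  expect_equal(out$excluded, "snp1")
  expect_equal(out$retained, "snp2")
})

test_that("the conjunction rule differs from the disjunction on one-sided overlap", {
  make <- function(doses) genotype_matrix(matrix(doses, ncol = 1))
  eur <- make(dosage_with_alt(50, 30))
  poo <- make(dosage_with_alt(50, 30))  # overlaps Europe
  map <- make(dosage_with_alt(50, 50))  # MAF 0.5, far from Europe's 0.3
  out_and <- maf_ci_filter(eur, poo, map, rule = "and")
  out_or <- maf_ci_filter(eur, poo, map, rule = "or")
  expect_length(out_and$excluded, 0)    # needs BOTH overlaps to exclude
  expect_length(out_or$excluded, 1)
})

test_that("groups with no called samples are skipped with a warning", {
  eur <- genotype_matrix(matrix(NA_integer_, 4, 1))
  poo <- genotype_matrix(matrix(1L, 4, 1))
  map <- genotype_matrix(matrix(1L, 4, 1))
  expect_warning(out <- maf_ci_filter(eur, poo, map), "zero called")
  expect_length(out$retained, 0)
  expect_length(out$excluded, 0)
})

# Pooled-reference underestimation --------------------------------------------

test_that("pooled Native references underestimate high-Mapuche individuals", {
  res <- experiment_masking(seed = 2, n_high = 80, n_snps = 1200,
                            replicates = 2)
  expect_lt(res$estimation$slope, 1)
  expect_gt(res$estimation$mean_underestimation, 0)
})
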