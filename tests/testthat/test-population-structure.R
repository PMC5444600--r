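# QC filtering ---------------------------------------------------------------

toy_qc_matrix <- function() {
  # 20 samples x 10 variants: 1 chrX, 2 with 3/20 missing, 2 with MAF 0.025,
  # 5 clean at intermediate frequency
  set.seed(77)
  n <- 20
  clean <- function() sample(0:2, n, replace = TRUE, prob = c(.25, .5, .25))
  d <- cbind(
    x1 = clean(),                                   # chrX
    m1 = {v <- clean(); v[1:3] <- NA; v},           # 15% missing
    m2 = {v <- clean(); v[5:7] <- NA; v},
    r1 = c(1L, rep(0L, n - 1)),                     # MAF 1/40 = 0.025
    r2 = c(rep(0L, n - 1), 1L),
    c1 = clean(), c2 = clean(), c3 = clean(), c4 = clean(), c5 = clean()
  )
  variants <- data.frame(
    chrom = c("X", rep("1", 9)), pos = 1:10 * 100L,
    id = colnames(d), ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  genotype_matrix(d, variants = variants)
}

test_that("qc_filter removes non-autosomal, high-missingness and rare variants", {
  g <- toy_qc_matrix()
  out <- qc_filter(g)
  r <- out$report
  expect_equal(r$variants_in, 10)
  expect_equal(r$removed_nonautosomal, 1)
  expect_equal(r$removed_missingness, 2)
  expect_equal(r$removed_maf, 2)
  expect_equal(r$variants_out, 5)
  expect_setequal(out$genotypes$variants$id, paste0("c", 1:5))
  # counts reconcile
  expect_equal(r$variants_in - r$removed_nonautosomal - r$removed_missingness -
                 r$removed_maf - r$removed_ld, r$variants_out)
})

test_that("qc_filter is the identity on clean input and idempotent", {
  g <- toy_qc_matrix()
  once <- qc_filter(g)
  expect_equal(once$report$variants_out, 5)
  twice <- qc_filter(once$genotypes)
  expect_identical(twice$genotypes$dosage, once$genotypes$dosage)
  expect_equal(twice$report$removed_missingness +
                 twice$report$removed_maf +
                 twice$report$removed_nonautosomal, 0)
})

test_that("MAF threshold is a strict inequality (exactly 5% is retained)", {
  # 20 samples, 40 alleles: 2 alt alleles -> MAF exactly 0.05
  d <- cbind(v1 = c(1L, 1L, rep(0L, 18)),
             v2 = c(1L, rep(0L, 19)))                # MAF 0.025 -> removed
  g <- genotype_matrix(d)
  out <- qc_filter(g)
  expect_equal(out$genotypes$variants$id, "v1")
  expect_equal(out$report$removed_maf, 1)
})

test_that("qc_filter with nothing left is an error", {
  g <- genotype_matrix(cbind(v1 = rep(0L, 10)))
  expect_error(qc_filter(g), "no variants survive")
})

# LD pruning ------------------------------------------------------------------

test_that("duplicated variant columns are pruned down to one", {
  set.seed(5)
  x <- sample(0:2, 50, replace = TRUE)
  g <- genotype_matrix(cbind(a = x, b = x, c = sample(0:2, 50, replace = TRUE)))
  out <- ld_prune(g, r2_max = 0.1, window = 10, step = 2)
  expect_true("a" %in% out$variants$id)
  expect_false("b" %in% out$variants$id)
})

test_that("greedy pruning keeps the endpoints of a correlation chain", {
  # construct A~B and B~C correlated, A~C nearly independent
  set.seed(1234)
  repeat {
    A <- stats::rbinom(200, 2, 0.5)
    B <- ifelse(stats::runif(200) < 0.7, A, stats::rbinom(200, 2, 0.5))
    C <- ifelse(stats::runif(200) < 0.7, B, 2L - B)
    r2 <- stats::cor(cbind(A, B, C))^2
    if (r2["A", "B"] > 0.3 && r2["B", "C"] > 0.1 && r2["A", "C"] < 0.1) break
  }
  g <- genotype_matrix(cbind(A = A, B = B, C = C))
  out <- ld_prune(g, r2_max = 0.1, window = 3, step = 1)
  expect_setequal(out$variants$id, c("A", "C"))
})

test_that("independent variants survive pruning almost entirely", {
  set.seed(8)
  n <- 600
  d <- matrix(stats::rbinom(n * 80, 2, 0.4), n, 80)
  g <- genotype_matrix(d)
  out <- ld_prune(g, r2_max = 0.1, window = 20, step = 5)
  expect_gte(nrow(out$variants), 78)   # expected r2 ~ 1/600 << 0.1
})

test_that("no retained pair violates the r2 threshold (exhaustive check)", {
  set.seed(9)
  base <- matrix(stats::rbinom(100 * 12, 2, 0.5), 100, 12)
  # add correlated copies to force pruning work
  noisy <- apply(base[, 1:6], 2, function(x)
    ifelse(stats::runif(100) < 0.8, x, stats::rbinom(100, 2, 0.5)))
  g <- genotype_matrix(cbind(base, noisy))
  out <- ld_prune(g, r2_max = 0.1, window = 6, step = 2)
  kept <- match(out$variants$id, g$variants$id)   # original positions
  r2 <- stats::cor(out$dosage)^2
  for (i in seq_along(kept)[-1]) {
    for (j in seq_len(i - 1)) {
      if (kept[i] - kept[j] < 6) {                # pair shared a window
        expect_lte(r2[i, j], 0.1 + 1e-12)
      }
    }
  }
})

test_that("window smaller than step is a parameter error", {
  g <- genotype_matrix(matrix(0:2, 3, 4))
  expect_error(ld_prune(g, window = 2, step = 5), "window")
})

# PCA -------------------------------------------------------------------------

test_that("two homogeneous clusters separate on PC1 with all the variance", {
  d <- rbind(
    matrix(rep(c(0L, 2L, 0L, 2L, 1L, 0L, 2L, 1L), each = 10), 10, 8),
    matrix(rep(c(2L, 0L, 2L, 0L, 1L, 2L, 0L, 1L), each = 10), 10, 8)
  )
  g <- genotype_matrix(d)
  res <- suppressWarnings(pca_genotypes(g, n_components = 3))
  cl <- rep(c(1, 2), each = 10)
  expect_gt(abs(mean(res$scores[cl == 1, 1]) - mean(res$scores[cl == 2, 1])), 1)
  expect_gt(res$explained[1], 0.999)
})

test_that("hierarchical four-population structure orders the principal components", {
  model <- chile_ancestral_model(M = 600)
  p <- simulate_reference_panels(model, n_per_pop = 25, seed = 42)
  g <- Reduce(bind_genotypes, p$genotypes)
  pop <- rep(names(p$genotypes), each = 25)
  res <- pca_genotypes(g, n_components = 4)
  sep <- function(a, b, k) {
    abs(mean(res$scores[pop %in% a, k]) - mean(res$scores[pop %in% b, k])) /
      stats::sd(res$scores[, k])
  }
  others <- c("European", "Mapuche", "Aymara")
  afr_pc <- which.max(vapply(1:4, function(k) sep("African", others, k), 1))
  eur_pc <- which.max(vapply(1:4, function(k)
    sep("European", c("Mapuche", "Aymara"), k), 1))
  nat_pc <- which.max(vapply(1:4, function(k) sep("Mapuche", "Aymara", k), 1))
  expect_equal(afr_pc, 1)               # African-vs-rest dominates
  expect_lt(eur_pc, nat_pc)             # Native split appears later
})

test_that("explained variance fractions are non-increasing and bounded", {
  set.seed(3)
  g <- genotype_matrix(matrix(stats::rbinom(300, 2, 0.5), 20, 15))
  res <- pca_genotypes(g, n_components = 5)
  expect_true(all(diff(res$explained) <= 1e-12))
  expect_lte(sum(res$explained), 1 + 1e-12)
  expect_true(all(res$explained >= 0))
})

test_that("PCA scores are sample-order invariant up to sign", {
  set.seed(14)
  d <- matrix(stats::rbinom(40 * 60, 2, 0.4), 40, 60)
  g <- genotype_matrix(d)
  perm <- sample(40)
  gp <- subset_genotypes(g, samples = perm)
  a <- pca_genotypes(g, n_components = 3)$scores[perm, ]
  b <- pca_genotypes(gp, n_components = 3)$scores
  for (k in 1:3) {
    expect_equal(abs(stats::cor(a[, k], b[, k])), 1, tolerance = 1e-6)
  }
})

test_that("monomorphic variants are excluded with a warning", {
  d <- cbind(v1 = rep(1L, 10), v2 = rep(0L, 10),
             v3 = sample(0:2, 10, replace = TRUE))
  d[1, 3] <- 1L; d[2, 3] <- 0L          # ensure polymorphic
  g <- genotype_matrix(d)
  expect_warning(res <- pca_genotypes(g, n_components = 1), "monomorphic")
  expect_equal(res$n_variants_used, 2)  # v1 (freq .5) kept, v2 dropped
})

# Weir-Cockerham Fst ----------------------------------------------------------

test_that("multi-locus estimate matches the independently computed reference values", {
  toy <- wc_toy()
  f <- fst_wc(toy$A, toy$B)
  # frozen values from an independent implementation of the published
  # 1984 two-sample a/b/c variance components
  expect_equal(f$fst, 0.3261083744, tolerance = 1e-9)
  expect_equal(unname(unlist(f$per_locus[1, c("a", "b", "c")])),
               c(0.1055555556, 0.0333333333, 0.1666666667), tolerance = 1e-9)
})

test_that("fst_wc is symmetric and bounded by its degenerate cases", {
  toy <- wc_toy()
  expect_equal(fst_wc(toy$A, toy$B)$fst, fst_wc(toy$B, toy$A)$fst)
  # identical allele counts in both samples: no between-population variance
  same <- fst_wc(toy$A, toy$A)
  expect_lte(same$fst, 1e-12)
  # complete fixation difference
  gA <- genotype_matrix(matrix(2L, 6, 4))
  gB <- genotype_matrix(matrix(0L, 6, 4))
  expect_equal(fst_wc(gA, gB)$fst, 1)
})

test_that("Balding-Nichols pairs reproduce their expected Fst", {
  model <- ancestral_model(M = 5000, divergence = c(A = 0.038, B = 0.038))
  p <- simulate_reference_panels(model, n_per_pop = 50, seed = 2024)
  f <- fst_wc(p$genotypes$A, p$genotypes$B)
  expect_gt(f$fst, 0.030)
  expect_lt(f$fst, 0.046)
})

test_that("disjoint variant sets are a data error", {
  a <- genotype_matrix(matrix(0:2, 4, 3),
                       variants = data.frame(chrom = "1", pos = 1:3,
                                             id = paste0("a", 1:3),
                                             ref = "A", alt = "G"))
  b <- genotype_matrix(matrix(0:2, 4, 3),
                       variants = data.frame(chrom = "2", pos = 1:3,
                                             id = paste0("b", 1:3),
                                             ref = "A", alt = "G"))
  expect_error(fst_wc(a, b), "no overlapping variants")
})
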