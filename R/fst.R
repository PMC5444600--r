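#' Weir-Cockerham Fst between two populations
#'
#' The Weir & Cockerham (1984) variance-components estimator for two samples,
#' combined across loci as a ratio of sums: `theta = sum(a) / sum(a + b + c)`
#' with `a`, `b`, `c` the among-population, among-individual-within-population
#' and within-individual components. Loci lacking called genotypes in either
#' sample are skipped. Per-locus heterozygote counts enter through the
#' observed heterozygosity, so the estimator matches the published
#' full-diploid form (not a haploid allele-count approximation).
#'
#' @param gA,gB `genotype_matrix` objects with at least two samples each;
#'   variants are matched on (chrom, pos, ref, alt).
#' @return A list with `fst` (the multi-locus estimate), `n_loci` (loci that
#'   contributed) and `per_locus` (data frame of a, b, c per locus).
#' @export
fst_wc <- function(gA, gB) {
  stopifnot(inherits(gA, "genotype_matrix"), inherits(gB, "genotype_matrix"))
  if (length(gA$samples) < 2 || length(gB$samples) < 2) {
    stop("need at least 2 samples per population", call. = FALSE)
  }
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  ka <- key(gA$variants); kb <- key(gB$variants)
  common <- intersect(ka, kb)
  if (!length(common)) stop("no overlapping variants", call. = FALSE)
  A <- gA$dosage[, match(common, ka), drop = FALSE]
  B <- gB$dosage[, match(common, kb), drop = FALSE]

  comp <- wc_components(A, B)
  ok <- comp$usable
  num <- sum(comp$a[ok])
  den <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  list(
    fst = num / den,
    n_loci = sum(ok),
    per_locus = data.frame(id = common, a = comp$a, b = comp$b, c = comp$c)
  )
}

# Weir & Cockerham (1984) a/b/c components for r = 2 samples, vectorized
# over loci. A and B are dosage matrices (samples x loci).
wc_components <- function(A, B) {
  nA <- colSums(!is.na(A)); nB <- colSums(!is.na(B))
  pA <- colMeans(A, na.rm = TRUE) / 2
  pB <- colMeans(B, na.rm = TRUE) / 2
  hA <- colMeans(A == 1, na.rm = TRUE)   # observed heterozygote proportion
  hB <- colMeans(B == 1, na.rm = TRUE)
  r <- 2
  nsum <- nA + nB
  nbar <- nsum / r
  nc <- (nsum - (nA^2 + nB^2) / nsum) / (r - 1)
  pbar <- (nA * pA + nB * pB) / nsum
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / nsum

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c <- hbar / 2
  usable <- nA >= 2 & nB >= 2 & is.finite(a) & is.finite(b) & is.finite(c)
  list(a = a, b = b, c = c, usable = usable)
}
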