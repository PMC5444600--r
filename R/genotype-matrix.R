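#' Genotype matrix container
#'
#' Holds biallelic SNP dosages (counts of the alternate allele, 0/1/2, `NA`
#' for missing) for a set of samples, together with the variant table that
#' identifies each column by (chrom, pos, ref, alt).
#'
#' @param dosage integer matrix, samples in rows, variants in columns; entries
#'   in \{0, 1, 2, NA\}.
#' @param samples character vector of sample identifiers (row order).
#' @param variants data frame with columns `chrom`, `pos`, `id`, `ref`, `alt`
#'   (column order). Coordinates are 1-based as in VCF.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, samples = rownames(dosage), variants = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  if (is.null(variants)) {
    ids <- colnames(dosage)
    if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(dosage)))
    variants <- data.frame(
      chrom = rep("1", ncol(dosage)),
      pos   = seq_len(ncol(dosage)),
      id    = ids,
      ref   = rep("A", ncol(dosage)),
      alt   = rep("G", ncol(dosage)),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(length(samples) == nrow(dosage), nrow(variants) == ncol(dosage))
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  dimnames(dosage) <- list(samples, variants$id)
  structure(
    list(dosage = dosage, samples = samples, variants = variants),
    class = "genotype_matrix"
  )
}

#' @exportS3Method print genotype_matrix
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d variants (%.2f%% missing)\n",
    length(x$samples), nrow(x$variants),
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @exportS3Method dim genotype_matrix
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param samples,variants index vectors (logical, integer or character) into
#'   the sample and variant dimensions; `NULL` keeps everything.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(x$samples) else samples
  vi <- if (is.null(variants)) seq_len(nrow(x$variants)) else variants
  if (is.character(si)) si <- match(si, x$samples)
  if (is.character(vi)) vi <- match(vi, x$variants$id)
  genotype_matrix(
    x$dosage[si, vi, drop = FALSE],
    samples = x$samples[si],
    variants = x$variants[vi, , drop = FALSE]
  )
}

#' Alternate-allele frequency per variant
#'
#' Computed over called genotypes only (missing entries are ignored).
#'
#' @param x a `genotype_matrix`.
#' @return Numeric vector of length `n_variants`, `NaN` where no genotype is
#'   called.
#' @export
allele_freq <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  colMeans(x$dosage, na.rm = TRUE) / 2
}

#' Minor allele frequency per variant
#'
#' The folded frequency `min(p, 1 - p)` of [allele_freq()].
#'
#' @param x a `genotype_matrix`.
#' @return Numeric vector of minor allele frequencies.
#' @export
minor_allele_freq <- function(x) {
  p <- allele_freq(x)
  pmin(p, 1 - p)
}

# Merge two genotype matrices sample-wise over their shared variants.
# Variant identity is (chrom, pos, ref, alt); no strand flipping is attempted.
#' Stack two genotype matrices over their common variants
#'
#' @param a,b `genotype_matrix` objects.
#' @return A `genotype_matrix` with the samples of `a` followed by those of
#'   `b`, restricted to variants shared by both (matched on chrom, pos, ref,
#'   alt).
#' @export
bind_genotypes <- function(a, b) {
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  ka <- key(a$variants); kb <- key(b$variants)
  common <- intersect(ka, kb)
  if (!length(common)) stop("no overlapping variants to merge on", call. = FALSE)
  ia <- match(common, ka); ib <- match(common, kb)
  genotype_matrix(
    rbind(a$dosage[, ia, drop = FALSE], b$dosage[, ib, drop = FALSE]),
    samples = c(a$samples, b$samples),
    variants = a$variants[ia, , drop = FALSE]
  )
}
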