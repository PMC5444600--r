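#' Genotype quality control
#'
#' Removes, in order: non-autosomal variants, variants with a missing call
#' fraction over `max_missing`, and variants with a minor allele frequency
#' under `min_maf`. Both thresholds are strict inequalities ("over" / "under"),
#' so a variant with MAF exactly equal to `min_maf` is retained.
#'
#' @param g a [genotype_matrix()].
#' @param max_missing maximum tolerated missing call fraction (default 0.05).
#' @param min_maf minimum tolerated minor allele frequency (default 0.05).
#' @return A list with `genotypes` (the filtered matrix) and `report`, a
#'   `qc_report` whose removal counts reconcile with the in/out totals.
#' @export
qc_filter <- function(g, max_missing = 0.05, min_maf = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  chrom <- sub("^chr", "", g$variants$chrom, ignore.case = TRUE)
  autosomal <- chrom %in% as.character(1:22)
  removed_nonautosomal <- sum(!autosomal)
  keep <- autosomal

  miss <- colMeans(is.na(g$dosage))
  drop_miss <- keep & miss > max_missing
  removed_missingness <- sum(drop_miss)
  keep <- keep & !drop_miss

  maf <- minor_allele_freq(g)
  maf[is.nan(maf)] <- 0
  drop_maf <- keep & maf < min_maf
  removed_maf <- sum(drop_maf)
  keep <- keep & !drop_maf

  if (!any(keep)) stop("no variants survive quality control", call. = FALSE)

  report <- structure(
    list(
      variants_in = ncol(g$dosage),
      removed_nonautosomal = removed_nonautosomal,
      removed_missingness = removed_missingness,
      removed_maf = removed_maf,
      removed_ld = 0L,
      variants_out = sum(keep)
    ),
    class = "qc_report"
  )
  list(genotypes = subset_genotypes(g, variants = which(keep)), report = report)
}

#' @exportS3Method print qc_report
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat("  variants in:          ", x$variants_in, "\n")
  cat("  removed non-autosomal:", x$removed_nonautosomal, "\n")
  cat("  removed missingness:  ", x$removed_missingness, "\n")
  cat("  removed MAF:          ", x$removed_maf, "\n")
  cat("  removed LD:           ", x$removed_ld, "\n")
  cat("  variants out:         ", x$variants_out, "\n")
  invisible(x)
}

#' Linkage-disequilibrium pruning
#'
#' Greedy left-to-right pruning within a sliding window: walking windows of
#' `window` variants advanced by `step`, every retained pair with squared
#' Pearson dosage correlation above `r2_max` loses its right-hand member
#' (keep-first tie-breaking). Deterministic given the input variant order.
#' Missing dosages are handled by pairwise-complete correlations.
#'
#' @param g a [genotype_matrix()] (QC is assumed to have been applied).
#' @param r2_max maximum tolerated squared correlation (default 0.1).
#' @param window window size in variants (default 50).
#' @param step window advance in variants (default 5); must not exceed
#'   `window`.
#' @return The pruned `genotype_matrix`.
#' @export
ld_prune <- function(g, r2_max = 0.1, window = 50, step = 5) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (window < step) stop("window must be >= step", call. = FALSE)
  M <- ncol(g$dosage)
  keep <- rep(TRUE, M)
  start <- 1L
  repeat {
    idx <- seq.int(start, min(start + window - 1L, M))
    live <- idx[keep[idx]]
    if (length(live) > 1) {
      r2 <- suppressWarnings(
        stats::cor(g$dosage[, live, drop = FALSE],
                   use = "pairwise.complete.obs")^2
      )
      for (i in seq_along(live)[-length(live)]) {
        if (!keep[live[i]]) next
        for (j in seq.int(i + 1L, length(live))) {
          if (keep[live[j]] && isTRUE(r2[i, j] > r2_max)) keep[live[j]] <- FALSE
        }
      }
    }
    if (start + window - 1L >= M) break
    start <- start + step
  }
  subset_genotypes(g, variants = which(keep))
}
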