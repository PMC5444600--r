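#' Reference panel of per-population allele frequencies
#'
#' @param freqs K x M matrix of alternate-allele frequencies, strictly inside
#'   (0, 1); rows named by population.
#' @param n_samples named integer vector of reference sample counts per
#'   population.
#' @param variants variant table matching the columns of `freqs`.
#' @return An object of class `reference_panel`.
#' @export
reference_panel <- function(freqs, n_samples, variants = NULL) {
  freqs <- as.matrix(freqs)
  if (any(freqs <= 0) || any(freqs >= 1)) {
    stop("reference frequencies must be strictly inside (0, 1)", call. = FALSE)
  }
  if (is.null(rownames(freqs))) rownames(freqs) <- paste0("pop", seq_len(nrow(freqs)))
  structure(
    list(populations = rownames(freqs), freqs = freqs,
         n_samples = n_samples, variants = variants),
    class = "reference_panel"
  )
}

#' @exportS3Method print reference_panel
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d populations x %d variants: %s\n",
              nrow(x$freqs), ncol(x$freqs),
              paste(x$populations, collapse = ", ")))
  invisible(x)
}

#' Estimate reference allele frequencies from labelled genotypes
#'
#' Per population and variant, `freq = (alt count + pseudocount) /
#' (2 n_called + 2 pseudocount)`. The pseudocount keeps frequencies strictly
#' inside (0, 1), which the supervised likelihood requires (frequencies of
#' exactly 0 or 1 would put probability zero on observable genotypes).
#'
#' @param genotypes either a named list of `genotype_matrix` objects (one per
#'   population) or a single `genotype_matrix` together with `labels`.
#' @param labels character vector assigning each sample of a single
#'   `genotype_matrix` to a population; ignored for the list form.
#' @param pseudocount added to both allele counts (default 0.5).
#' @return A [reference_panel()].
#' @export
estimate_reference_freqs <- function(genotypes, labels = NULL, pseudocount = 0.5) {
  if (inherits(genotypes, "genotype_matrix")) {
    if (is.null(labels)) stop("labels required for a single genotype matrix", call. = FALSE)
    genotypes <- lapply(split(seq_along(labels), labels), function(i) {
      subset_genotypes(genotypes, samples = i)
    })
  }
  pops <- names(genotypes)
  if (is.null(pops)) stop("population list must be named", call. = FALSE)
  variants <- genotypes[[1]]$variants
  M <- nrow(variants)
  freqs <- matrix(NA_real_, length(pops), M, dimnames = list(pops, variants$id))
  n_samples <- integer(length(pops)); names(n_samples) <- pops
  warned <- 0L
  for (k in seq_along(pops)) {
    g <- genotypes[[k]]
    if (length(g$samples) < 1) stop("population with no genotyped sample", call. = FALSE)
    alt <- colSums(g$dosage, na.rm = TRUE)
    called <- colSums(!is.na(g$dosage))
    warned <- warned + sum(called == 0)
    freqs[k, ] <- (alt + pseudocount) / (2 * called + 2 * pseudocount)
    n_samples[k] <- length(g$samples)
  }
  if (warned > 0) {
    warning(sprintf("%d population-variant cells had zero called genotypes; pseudocount-only frequency used", warned))
  }
  if (pseudocount == 0) {
    # exact frequencies requested; clamp fixation just inside the open interval
    freqs <- pmin(pmax(freqs, 1e-9), 1 - 1e-9)
  }
  reference_panel(freqs, n_samples, variants)
}
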