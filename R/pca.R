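#' Genetic principal component analysis
#'
#' Eigenstrat-style PCA of a dosage matrix: each variant is mean-centered and
#' scaled by `sqrt(p(1-p))` with `p` the observed alternate-allele frequency;
#' missing entries are mean-imputed before scaling. Scores are the left
#' singular vectors scaled by the singular values, so the squared singular
#' values give the variance explained by each component.
#'
#' @param g a [genotype_matrix()].
#' @param n_components number of components to return; must be smaller than
#'   `min(n_samples, n_variants)`.
#' @return A list with `scores` (samples x components), `explained`
#'   (fractions of total variance, non-increasing) and `n_variants_used`
#'   (monomorphic variants are excluded with a warning).
#' @export
pca_genotypes <- function(g, n_components = 10) {
  stopifnot(inherits(g, "genotype_matrix"))
  X <- g$dosage
  all_missing <- colSums(!is.na(X)) == 0
  if (any(all_missing)) stop("variant with no called genotypes", call. = FALSE)
  p <- colMeans(X, na.rm = TRUE) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warning(sprintf("excluding %d monomorphic variant(s) with zero scale", sum(mono)))
    X <- X[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  n_components <- min(n_components, nrow(X) - 1L, ncol(X))
  mu <- 2 * p
  sc <- sqrt(p * (1 - p))
  X <- sweep(X, 2, mu)
  X[is.na(X)] <- 0                       # mean imputation after centering
  X <- sweep(X, 2, sc, "/")
  sv <- svd(X, nu = n_components, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- g$samples
  colnames(scores) <- paste0("PC", seq_len(n_components))
  explained <- sv$d^2 / sum(sv$d^2)
  list(
    scores = scores,
    explained = explained[seq_len(n_components)],
    n_variants_used = ncol(X)
  )
}
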