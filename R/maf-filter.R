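#' Binomial confidence interval for a minor allele frequency
#'
#' Wilson score interval (default) or Wald interval for a folded allele
#' frequency estimated from `x` minor alleles among `n` allele draws.
#'
#' @param x count of minor alleles.
#' @param n number of observed allele copies (2 x called samples).
#' @param level confidence level (default 0.80).
#' @param method `"wilson"` (default) or `"wald"`.
#' @return Numeric vector `c(lower, upper)`; vectorized over `x`, `n` (matrix
#'   with two columns when inputs have length > 1).
#' @export
maf_confint <- function(x, n, level = 0.80, method = c("wilson", "wald")) {
  method <- match.arg(method)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  if (method == "wilson") {
    den <- 1 + z^2 / n
    center <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  } else {
    center <- p
    half <- z * sqrt(p * (1 - p) / n)
  }
  lo <- pmax(center - half, 0)
  hi <- pmin(center + half, 1)
  if (length(lo) == 1) c(lo, hi) else cbind(lower = lo, upper = hi)
}

group_maf_ci <- function(g, level, method) {
  called <- colSums(!is.na(g$dosage))
  alt <- colSums(g$dosage, na.rm = TRUE)
  n <- 2 * called
  x <- pmin(alt, n - alt)               # fold to the minor allele per group
  ci <- maf_confint(x, n, level = level, method = method)
  if (is.null(dim(ci))) ci <- matrix(ci, 1, 2, dimnames = list(NULL, c("lower", "upper")))
  list(ci = ci, called = called)
}

#' Ancestry-informative-marker filter by MAF confidence-interval overlap
#'
#' Per variant, a binomial confidence interval of the minor allele frequency
#' is computed independently within the European-like group, the pooled
#' Native-like group and the Mapuche-like group. A variant is EXCLUDED when
#' the European interval overlaps the pooled-Native interval AND the European
#' interval overlaps the Mapuche interval; it is retained otherwise. Variants
#' where any group has zero called samples are skipped with a warning. The
#' conjunction can be switched to a disjunction via `rule = "or"`.
#'
#' @param panel_eur,panel_pooled_native,panel_mapuche_like `genotype_matrix`
#'   objects over a common variant list (same column order).
#' @param level confidence level for the intervals (default 0.80).
#' @param method interval method, `"wilson"` (default) or `"wald"`.
#' @param rule `"and"` (default: excluded when both overlaps hold) or `"or"`.
#' @return List with `retained` (variant ids), `excluded` (variant ids),
#'   `detail` (per-variant intervals and overlap flags).
#' @export
maf_ci_filter <- function(panel_eur, panel_pooled_native, panel_mapuche_like,
                          level = 0.80, method = c("wilson", "wald"),
                          rule = c("and", "or")) {
  method <- match.arg(method)
  rule <- match.arg(rule)
  M <- ncol(panel_eur$dosage)
  if (ncol(panel_pooled_native$dosage) != M || ncol(panel_mapuche_like$dosage) != M) {
    stop("the three genotype sets must share one variant list", call. = FALSE)
  }
  eur <- group_maf_ci(panel_eur, level, method)
  poo <- group_maf_ci(panel_pooled_native, level, method)
  map <- group_maf_ci(panel_mapuche_like, level, method)

  skipped <- eur$called == 0 | poo$called == 0 | map$called == 0
  if (any(skipped)) {
    warning(sprintf("%d variant(s) skipped: a group has zero called samples", sum(skipped)))
  }
  overlaps <- function(a, b) a[, "lower"] <= b[, "upper"] & b[, "lower"] <= a[, "upper"]
  ov_pool <- overlaps(eur$ci, poo$ci)
  ov_map <- overlaps(eur$ci, map$ci)
  excluded <- if (rule == "and") ov_pool & ov_map else ov_pool | ov_map
  excluded[skipped] <- NA
  ids <- panel_eur$variants$id
  list(
    retained = ids[!skipped & !excluded],
    excluded = ids[!skipped & excluded],
    detail = data.frame(
      id = ids,
      eur_lower = eur$ci[, "lower"], eur_upper = eur$ci[, "upper"],
      pooled_lower = poo$ci[, "lower"], pooled_upper = poo$ci[, "upper"],
      mapuche_lower = map$ci[, "lower"], mapuche_upper = map$ci[, "upper"],
      overlap_pooled = ov_pool, overlap_mapuche = ov_map,
      excluded = excluded, skipped = skipped
    )
  )
}
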