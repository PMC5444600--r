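#' Leave-one-out influence on regional ancestry estimates
#'
#' For every individual, recomputes their region's mean ancestry proportion
#' without them and flags influential individuals whose removal shifts the
#' regional mean by more than `2 / n` (with `n` the region size). Only
#' individuals from the same region affect a region's estimate.
#'
#' @param ancestry numeric vector of individual ancestry proportions.
#' @param region character or factor vector of region labels, aligned with
#'   `ancestry`.
#' @param ids optional individual identifiers.
#' @return Data frame with one row per individual in a region of size >= 2:
#'   `id`, `region`, `n`, `beta` (regional mean with everyone), `beta_loo`
#'   (without the individual), `shift`, `flagged`. Regions of size 1 are
#'   skipped with a warning.
#' @export
loo_influence <- function(ancestry, region, ids = NULL) {
  stopifnot(length(ancestry) == length(region))
  if (is.null(ids)) ids <- paste0("i", seq_along(ancestry))
  region <- as.character(region)
  out <- vector("list", 0)
  for (r in unique(region)) {
    sel <- region == r
    n <- sum(sel)
    if (n < 2) {
      warning(sprintf("region '%s' has a single individual; skipped", r))
      next
    }
    x <- ancestry[sel]
    beta <- mean(x)
    beta_loo <- (sum(x) - x) / (n - 1)
    shift <- beta_loo - beta
    out[[length(out) + 1]] <- data.frame(
      id = ids[sel], region = r, n = n, beta = beta, beta_loo = beta_loo,
      shift = shift, flagged = abs(shift) > 2 / n,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Resampling-based uncertainty propagation into the SMR
#'
#' Draws regional ancestry vectors from independent normal distributions
#' centered at the stage-1 expected regional proportions with standard
#' deviation `scale * SE`, refits the stage-2 model per draw, and summarizes
#' the per-draw SMR by the median and the 2.5th/97.5th percentiles. Draws for
#' which the stage-2 refit fails are dropped and counted.
#'
#' @param stage1 a `stage1_model` (supplies regional expectations and
#'   standard errors, on the proportion scale).
#' @param std_rates stage-2 response table restricted to one category (see
#'   [fit_stage2()]).
#' @param S number of draws (default 50000).
#' @param scale multiplier applied to the stage-1 standard errors (default 1;
#'   `scale = 0` degenerates to the plug-in estimate).
#' @param seed integer seed.
#' @param ... passed to [fit_stage2()].
#' @return A `resample_summary`: list with `draws` (per-draw SMR, failed
#'   draws `NA`), `median`, `q2.5`, `q97.5`, `n_failed`, `plugin_smr`.
#' @export
resample_smr <- function(stage1, std_rates, S = 50000, scale = 1, seed = 1, ...) {
  stopifnot(inherits(stage1, "stage1_model"))
  exp_r <- stage1$expectations
  set.seed(seed)
  plugin <- fit_stage2(std_rates,
                       stats::setNames(100 * exp_r$expected, exp_r$region), ...)
  draws <- rep(NA_real_, S)
  for (s in seq_len(S)) {
    x <- stats::rnorm(nrow(exp_r), exp_r$expected, scale * exp_r$se)
    fit <- fit_stage2(std_rates, stats::setNames(100 * x, exp_r$region), ...)
    if (isTRUE(fit$converged)) draws[s] <- fit$smr
  }
  ok <- !is.na(draws)
  qs <- stats::quantile(draws[ok], c(0.025, 0.5, 0.975), names = FALSE)
  structure(
    list(draws = draws, median = qs[2], q2.5 = qs[1], q97.5 = qs[3],
         n_failed = sum(!ok), S = S, scale = scale,
         plugin_smr = plugin$smr),
    class = "resample_summary"
  )
}

#' @exportS3Method print resample_summary
print.resample_summary <- function(x, ...) {
  cat(sprintf(
    "<resample_summary> S=%d (failed %d): median SMR %.4f [%.4f, %.4f], plug-in %.4f\n",
    x$S, x$n_failed, x$median, x$q2.5, x$q97.5, x$plugin_smr))
  invisible(x)
}

#' Stage-2 adjustment for an additional regional covariate
#'
#' Refits the stage-2 model with an extra region-level explanatory column
#' (for example, a standardized hospitalization rate as a surrogate of access
#' to the health system) and reports the adjusted and unadjusted SMR side by
#' side.
#'
#' @param std_rates stage-2 response table (one category).
#' @param ancestry_pct expected regional ancestry in percentage points (named
#'   vector).
#' @param covariate named numeric vector of the extra regional covariate
#'   (must cover every region).
#' @param covariate_name column label for the covariate.
#' @param ... passed to [fit_stage2()].
#' @return List with `unadjusted` and `adjusted` `stage2_model` objects and
#'   `smr` (named vector of the two point estimates).
#' @export
adjust_regional_covariate <- function(std_rates, ancestry_pct, covariate,
                                      covariate_name = "extra", ...) {
  regions <- unique(std_rates$region)
  if (!all(regions %in% names(covariate))) {
    stop("covariate must be defined for every region", call. = FALSE)
  }
  unadj <- fit_stage2(std_rates, ancestry_pct, ...)
  rc <- data.frame(region = names(covariate), stringsAsFactors = FALSE)
  rc[[covariate_name]] <- as.numeric(covariate)
  if (stats::var(as.numeric(covariate)) == 0) {
    warning("extra covariate is constant across regions; aliased with the intercept")
  }
  adj <- fit_stage2(std_rates, ancestry_pct, region_covariates = rc, ...)
  list(
    unadjusted = unadj, adjusted = adj,
    smr = c(unadjusted = unadj$smr, adjusted = adj$smr)
  )
}
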