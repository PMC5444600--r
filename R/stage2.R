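#' Stage 2: Poisson model for SMR per 1\% ancestry
#'
#' Log-linear model of the yearly disease-specific age-standardized mortality
#' burden on expected regional ancestry: standardized rates are converted to
#' standardized expected death counts `std_rate * person_years / 1e5` and fit
#' with a Poisson log link and `log(person_years)` offset, so `exp(beta)` is
#' the standardized mortality ratio per 1 percentage point of ancestry.
#' Repeated region-year observations share a region-level covariance, handled
#' by cluster-robust (by region) standard errors with a G-1 degrees-of-freedom
#' t reference. A region random-intercept variant is available via
#' `random_intercept = TRUE` (penalized quasi-likelihood, `MASS::glmmPQL`),
#' which reports model-based Wald errors instead of cluster-robust ones.
#'
#' @param std_rates data frame from [standardized_rates()] restricted to one
#'   category: columns `region`, `year`, `std_rate`, `person_years`.
#' @param ancestry_pct expected regional ancestry in percentage points:
#'   either a named numeric vector (one component) or a region x component
#'   matrix with named rows for joint fits.
#' @param region_covariates optional data frame of additional region-level
#'   columns (first column `region`).
#' @param response `"expected_deaths"` (default: Poisson on standardized
#'   expected deaths with offset) or `"rate"` (quasi-Poisson directly on the
#'   standardized rate, no offset); both give `exp(beta)` the same per-1\%
#'   interpretation.
#' @param random_intercept when `TRUE`, fit a region random intercept by
#'   penalized quasi-likelihood instead of the fixed-effect + cluster-robust
#'   route.
#' @param level confidence level for the Wald interval (default 0.95).
#' @return A `stage2_model`: list with `fit`, `terms` (data frame with one
#'   row per ancestry component: `beta`, `se`, `smr`, `ci_lower`, `ci_upper`,
#'   `p`), `smr` (first component's SMR), `converged`, `n_clusters`.
#' @export
fit_stage2 <- function(std_rates, ancestry_pct, region_covariates = NULL,
                       response = c("expected_deaths", "rate"),
                       random_intercept = FALSE,
                       level = 0.95) {
  response <- match.arg(response)
  stopifnot(all(c("region", "year", "std_rate", "person_years") %in% names(std_rates)))
  if (length(unique(std_rates$region)) < 2) {
    stop("need at least 2 regions", call. = FALSE)
  }
  if (is.null(dim(ancestry_pct)) || length(dim(ancestry_pct)) < 2) {
    ancestry_pct <- matrix(as.numeric(ancestry_pct), ncol = 1,
                           dimnames = list(names(ancestry_pct), "ancestry"))
  }
  if (is.null(rownames(ancestry_pct))) {
    stop("ancestry_pct must be named by region", call. = FALSE)
  }
  missing_r <- setdiff(unique(std_rates$region), rownames(ancestry_pct))
  if (length(missing_r)) {
    stop("ancestry_pct missing regions: ", paste(missing_r, collapse = ", "),
         call. = FALSE)
  }
  comp_names <- colnames(ancestry_pct)
  d <- std_rates
  for (k in comp_names) d[[k]] <- ancestry_pct[d$region, k]
  if (!is.null(region_covariates)) {
    extra <- setdiff(names(region_covariates), "region")
    d <- merge(d, region_covariates, by = "region", sort = FALSE)
  } else {
    extra <- character(0)
  }
  rhs <- paste(c(make.names(comp_names), make.names(extra)), collapse = " + ")
  names(d) <- make.names(names(d))
  if (response == "expected_deaths") {
    d$.y <- d$std_rate * d$person_years / 1e5
    d$.off <- log(d$person_years)
    form <- stats::as.formula(paste(".y ~", rhs, "+ offset(.off)"))
  } else {
    d$.y <- d$std_rate
    form <- stats::as.formula(paste(".y ~", rhs))
  }
  if (random_intercept) {
    rform <- stats::as.formula(paste(
      ".y ~", rhs, if (response == "expected_deaths") "+ offset(.off)" else ""))
    fit <- tryCatch(
      suppressMessages(MASS::glmmPQL(rform, random = ~ 1 | region,
                                     family = stats::quasipoisson(), data = d,
                                     verbose = FALSE)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      return(structure(list(fit = fit, terms = NULL, smr = NA_real_,
                            converged = FALSE,
                            diagnostics = conditionMessage(fit)),
                       class = "stage2_model"))
    }
    sm <- summary(fit)$tTable
    comp_terms <- make.names(comp_names)
    beta <- sm[comp_terms, "Value"]
    se <- sm[comp_terms, "Std.Error"]
    G <- length(unique(d$region))
    tq <- stats::qt(1 - (1 - level) / 2, df = G - 1)
    terms <- data.frame(
      component = comp_names, beta = as.numeric(beta), se = as.numeric(se),
      smr = exp(as.numeric(beta)),
      ci_lower = exp(as.numeric(beta - tq * se)),
      ci_upper = exp(as.numeric(beta + tq * se)),
      p = as.numeric(sm[comp_terms, "p-value"]),
      stringsAsFactors = FALSE
    )
    return(structure(
      list(fit = fit, terms = terms, smr = terms$smr[1], converged = TRUE,
           n_clusters = G, level = level),
      class = "stage2_model"
    ))
  }
  fit <- tryCatch(
    stats::glm(form, family = stats::quasipoisson(), data = d),
    error = function(e) e
  )
  if (inherits(fit, "error") || !fit$converged) {
    return(structure(
      list(fit = fit, terms = NULL, smr = NA_real_, converged = FALSE,
           diagnostics = if (inherits(fit, "error")) conditionMessage(fit)
                         else "glm did not converge"),
      class = "stage2_model"
    ))
  }
  aliased <- is.na(stats::coef(fit))
  if (any(aliased)) warning("aliased column(s) in stage-2 design: ",
                            paste(names(aliased)[aliased], collapse = ", "))
  G <- length(unique(d$region))
  V <- sandwich::vcovCL(fit, cluster = d$region, type = "HC1")
  beta <- stats::coef(fit)[make.names(comp_names)]
  se <- sqrt(diag(V)[make.names(comp_names)])
  tq <- stats::qt(1 - (1 - level) / 2, df = G - 1)
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df = G - 1, lower.tail = FALSE)
  terms <- data.frame(
    component = comp_names,
    beta = as.numeric(beta),
    se = as.numeric(se),
    smr = exp(as.numeric(beta)),
    ci_lower = exp(as.numeric(beta - tq * se)),
    ci_upper = exp(as.numeric(beta + tq * se)),
    p = as.numeric(p),
    stringsAsFactors = FALSE
  )
  structure(
    list(fit = fit, terms = terms, smr = terms$smr[1], converged = TRUE,
         n_clusters = G, level = level),
    class = "stage2_model"
  )
}

#' @exportS3Method print stage2_model
print.stage2_model <- function(x, ...) {
  if (!x$converged) {
    cat("<stage2_model> NOT converged:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat("<stage2_model> SMR per 1% ancestry (cluster-robust,",
      x$n_clusters, "regions)\n")
  print(x$terms, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Linear excess-mortality projection
#'
#' The back-of-envelope reading of a per-1\% SMR: a difference of
#' `delta_points` percentage points in an ancestry component projects to a
#' `delta_points * 100 * (smr - 1)` percent difference in mortality (linear
#' in the excess, not compounded).
#'
#' @param smr standardized mortality ratio per 1 percentage point.
#' @param delta_points difference in the ancestry component, percentage
#'   points.
#' @return Projected percent excess mortality.
#' @export
excess_projection <- function(smr, delta_points) {
  delta_points * 100 * (smr - 1)
}

#' Association report with Bonferroni-style highlighting
#'
#' Assembles per-category, per-component SMR results and flags associations
#' whose p-value is strictly under `0.05 / n_categories`.
#'
#' @param results list of per-category results; each element a list with
#'   `icd`, `description`, `deaths`, and a data frame `terms` as returned in
#'   a `stage2_model` (one row per ancestry component).
#' @param n_categories number of tested disease categories used for the
#'   threshold (defaults to `length(results)`).
#' @return Data frame with one row per category x component, sorted by ICD
#'   code, with a logical `highlight` column; the threshold is stored in
#'   `attr(, "threshold")`.
#' @export
smr_report <- function(results, n_categories = length(results)) {
  threshold <- 0.05 / n_categories
  rows <- lapply(results, function(r) {
    if (is.null(r$terms)) return(NULL)
    data.frame(
      icd = r$icd,
      description = if (!is.null(r$description)) r$description else NA_character_,
      deaths = if (!is.null(r$deaths)) r$deaths else NA_real_,
      r$terms,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(icd = character(0), description = character(0),
                      deaths = numeric(0), component = character(0),
                      beta = numeric(0), se = numeric(0), smr = numeric(0),
                      ci_lower = numeric(0), ci_upper = numeric(0),
                      p = numeric(0), highlight = logical(0))
    attr(out, "threshold") <- threshold
    return(out)
  }
  out$highlight <- out$p < threshold     # "under" is strict
  out <- out[order(out$icd, out$component), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}
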