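#' Stage 1: individual-level linear model for expected regional ancestry
#'
#' Ordinary least squares of one ancestry proportion on individual-level
#' categorical covariates, `E[X | Z] = Z' d`. The per-region expected
#' proportion is the model prediction for each region with the remaining
#' covariates held at their reference levels (default, matching a
#' presentation of an intercept plus region offsets) or averaged over the
#' observed covariate distribution (`evaluate = "population"`). Standard
#' errors come from the coefficient covariance matrix.
#'
#' @param covariates data frame of individual-level covariates including a
#'   `region` column; character columns are converted to factors (first level
#'   = reference unless already a factor).
#' @param ancestry numeric vector of individual ancestry proportions in
#'   [0, 1], aligned with `covariates` rows.
#' @param factors character vector of covariate columns to include besides
#'   `region` (default: all columns except `sample_id` and `region`).
#' @param evaluate `"reference"` (default) or `"population"`.
#' @return A `stage1_model`: list with `fit` (the `lm`), `expectations`
#'   (data frame `region`, `expected`, `se`), `component_name`, `factors`.
#' @export
fit_stage1 <- function(covariates, ancestry, factors = NULL,
                       evaluate = c("reference", "population")) {
  evaluate <- match.arg(evaluate)
  stopifnot("region" %in% names(covariates),
            length(ancestry) == nrow(covariates))
  if (is.null(factors)) {
    factors <- setdiff(names(covariates), c("sample_id", "region"))
  }
  d <- covariates
  for (nm in c("region", factors)) {
    if (!is.factor(d[[nm]])) d[[nm]] <- factor(d[[nm]])
  }
  d$.y <- ancestry
  # single-level factors carry no contrast; drop them from the design
  terms_rhs <- c("region", factors)
  terms_rhs <- terms_rhs[vapply(terms_rhs, function(nm) {
    !is.factor(d[[nm]]) || nlevels(droplevels(d[[nm]])) > 1
  }, logical(1))]
  rhs <- if (length(terms_rhs)) paste(terms_rhs, collapse = " + ") else "1"
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d)
  if (anyNA(stats::coef(fit))) {
    warning("rank-deficient design: aliased columns dropped")
  }
  regions <- levels(d$region)
  if (evaluate == "reference") {
    nd <- data.frame(region = factor(regions, levels = regions))
    for (nm in factors) {
      nd[[nm]] <- factor(levels(d[[nm]])[1], levels = levels(d[[nm]]))
    }
    pr <- stats::predict(fit, newdata = nd, se.fit = TRUE)
    expected <- as.numeric(pr$fit)
    se <- as.numeric(pr$se.fit)
  } else {
    # population-average: set every individual's region to r, average fits
    X <- stats::model.matrix(fit)
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    expected <- se <- numeric(length(regions))
    for (i in seq_along(regions)) {
      dr <- d; dr$region <- factor(regions[i], levels = regions)
      Xi <- stats::model.matrix(stats::delete.response(stats::terms(fit)), dr)
      xbar <- colMeans(Xi)
      expected[i] <- sum(xbar * beta)
      se[i] <- sqrt(drop(t(xbar) %*% V %*% xbar))
    }
  }
  if (any(expected < 0 | expected > 1)) {
    warning("expected proportions outside [0, 1]; clipping")
    expected <- pmin(pmax(expected, 0), 1)
  }
  structure(
    list(
      fit = fit,
      expectations = data.frame(region = regions, expected = expected, se = se,
                                stringsAsFactors = FALSE),
      factors = factors,
      evaluate = evaluate
    ),
    class = "stage1_model"
  )
}

#' @exportS3Method print stage1_model
print.stage1_model <- function(x, ...) {
  cat("<stage1_model> covariates:", paste(c("region", x$factors), collapse = ", "), "\n")
  print(x$expectations, row.names = FALSE)
  invisible(x)
}

#' Stepwise forward covariate selection with partial F tests
#'
#' Iteratively adds the candidate factor with the smallest partial-F p-value
#' below `alpha_enter`; after each addition, factors whose partial-F p-value
#' (given the others) exceeds `alpha_stay` are removed, worst first.
#' Terminates when no factor enters or leaves. Deterministic given the data.
#'
#' @param covariates data frame holding the candidate columns.
#' @param ancestry numeric response vector (an ancestry proportion).
#' @param candidates character vector of candidate factor columns.
#' @param alpha_enter,alpha_stay significance levels for entering and staying
#'   (defaults 0.1 and 0.1).
#' @param include factors kept in the model unconditionally (never tested for
#'   removal).
#' @return Character vector of selected factors (possibly empty; `include`
#'   terms are not repeated in the return value).
#' @export
stepwise_forward <- function(covariates, ancestry, candidates,
                             alpha_enter = 0.1, alpha_stay = 0.1,
                             include = character(0)) {
  cols <- union(candidates, include)
  d <- covariates[, cols, drop = FALSE]
  for (nm in cols) if (!is.factor(d[[nm]]) && !is.numeric(d[[nm]])) {
    d[[nm]] <- factor(d[[nm]])
  }
  d$.y <- ancestry
  partial_p <- function(small, big_terms) {
    small <- union(include, small)
    big_terms <- union(include, big_terms)
    f_small <- stats::as.formula(
      paste(".y ~", if (length(small)) paste(small, collapse = "+") else "1"))
    f_big <- stats::as.formula(paste(".y ~", paste(big_terms, collapse = "+")))
    a <- stats::anova(stats::lm(f_small, data = d), stats::lm(f_big, data = d))
    a$`Pr(>F)`[2]
  }
  selected <- character(0)
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 4 * length(candidates) + 4) break  # cycle guard
    changed <- FALSE
    remaining <- setdiff(candidates, selected)
    if (length(remaining) && alpha_enter > 0) {
      pvals <- vapply(remaining, function(f) {
        partial_p(selected, c(selected, f))
      }, numeric(1))
      if (min(pvals) < alpha_enter) {
        selected <- c(selected, remaining[which.min(pvals)])
        changed <- TRUE
      }
    }
    repeat {
      if (length(selected) < 1) break
      pdrop <- vapply(selected, function(f) {
        partial_p(setdiff(selected, f), selected)
      }, numeric(1))
      if (max(pdrop) > alpha_stay) {
        selected <- setdiff(selected, selected[which.max(pdrop)])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  selected
}
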