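#' Direct age standardization
#'
#' Weights age-band-specific rates by a fixed standard population's age
#' distribution: `sum_a w_a (deaths_a / person_years_a) * 1e5`.
#'
#' @param deaths,person_years numeric vectors by age band (same order, named
#'   by age band when `std_weights` is named).
#' @param std_weights standard-population weights; renormalized with a
#'   warning when they do not sum to 1. When named, bands are matched by
#'   name and must agree with the data's bands.
#' @return The standardized rate per 10^5 person-years.
#' @export
direct_standardize <- function(deaths, person_years, std_weights) {
  if (!is.null(names(std_weights)) && !is.null(names(deaths))) {
    if (!setequal(names(std_weights), names(deaths))) {
      stop("age bands of the data and the standard do not match", call. = FALSE)
    }
    ord <- match(names(std_weights), names(deaths))
    deaths <- deaths[ord]; person_years <- person_years[ord]
  } else if (length(std_weights) != length(deaths)) {
    stop("age bands of the data and the standard do not match", call. = FALSE)
  }
  if (any(person_years == 0 & deaths > 0)) {
    stop("zero person-years in an age band with nonzero deaths", call. = FALSE)
  }
  if (abs(sum(std_weights) - 1) > 1e-8) {
    warning("standard weights do not sum to 1; renormalizing")
    std_weights <- std_weights / sum(std_weights)
  }
  rate <- ifelse(person_years == 0, 0, deaths / person_years)
  sum(std_weights * rate) * 1e5
}

#' Standardized rates per region-year-category
#'
#' Applies [direct_standardize()] to every (region, year, icd) cell of a long
#' mortality table.
#'
#' @param mortality long data frame with columns `region`, `year`, `icd`,
#'   `age_band`, `deaths`, `person_years`.
#' @param std_weights named standard-population age weights.
#' @return Data frame with `region`, `year`, `icd`, `std_rate` (per 10^5
#'   person-years) and `person_years` (total over bands).
#' @export
standardized_rates <- function(mortality, std_weights) {
  needed <- c("region", "year", "icd", "age_band", "deaths", "person_years")
  stopifnot(all(needed %in% names(mortality)))
  key <- interaction(mortality$region, mortality$year, mortality$icd, drop = TRUE)
  pieces <- split(mortality, key)
  out <- lapply(pieces, function(d) {
    data.frame(
      region = d$region[1], year = d$year[1], icd = d$icd[1],
      std_rate = direct_standardize(
        stats::setNames(d$deaths, d$age_band),
        stats::setNames(d$person_years, d$age_band),
        std_weights
      ),
      person_years = sum(d$person_years),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$icd, res$region, res$year), ]
}

#' Filter disease categories by national death count
#'
#' Keeps categories with at least `min_deaths` deaths summed over all regions
#' and years ("at least" is inclusive).
#'
#' @param mortality long mortality table (as in [standardized_rates()]).
#' @param min_deaths inclusive national minimum (default 100).
#' @return List with `retained` (category ids), `dropped`, and `totals`
#'   (named national death totals).
#' @export
filter_categories <- function(mortality, min_deaths = 100) {
  totals <- tapply(mortality$deaths, mortality$icd, sum)
  retained <- names(totals)[totals >= min_deaths]
  list(
    retained = retained,
    dropped = setdiff(names(totals), retained),
    totals = totals
  )
}
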