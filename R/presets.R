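# Default study conditions for the synthetic generator.
#
# The regional structure mirrors the published admixture geography of Chile:
# 15 first-level administrative regions, a north-south gradient with the
# Aymara-like component concentrated in the north and the Mapuche-like
# component in the south, a constant small African component, and region
# sample sizes matching the aggregate-data cohort (n = 1805 in total).

chile_region_table <- function() {
  data.frame(
    region = c("Arica y Parinacota", "Tarapaca", "Antofagasta", "Atacama",
               "Coquimbo", "Valparaiso", "Santiago", "OHiggins", "Maule",
               "Biobio", "Araucania", "Los Rios", "Los Lagos", "Aysen",
               "Magallanes"),
    n = c(794L, 69L, 85L, 25L, 25L, 97L, 312L, 35L, 67L, 158L, 71L, 24L,
          30L, 8L, 5L),
    Mapuche = c(0.30, 0.30, 0.33, 0.35, 0.40, 0.38, 0.40, 0.39, 0.41, 0.44,
                0.51, 0.54, 0.51, 0.52, 0.46),
    Aymara  = c(0.29, 0.28, 0.22, 0.17, 0.15, 0.10, 0.08, 0.08, 0.07, 0.07,
                0.08, 0.06, 0.07, 0.07, 0.10),
    African = rep(0.03, 15),
    # population at risk (person-years per calendar year), census-scale
    person_years = c(190e3, 240e3, 490e3, 250e3, 600e3, 1530e3, 6060e3,
                     780e3, 910e3, 1860e3, 870e3, 360e3, 720e3, 90e3, 150e3),
    stringsAsFactors = FALSE
  )
}

#' Default regional mean ancestry matrix
#'
#' Mean admixture proportions per region for the default four-component
#' preset (African, European, Mapuche-like and Aymara-like components on a
#' 15-region north-south gradient).
#'
#' @return Matrix with regions in rows and components in columns; rows sum
#'   to 1.
#' @export
chile_region_means <- function() {
  tb <- chile_region_table()
  m <- cbind(
    African = tb$African,
    European = 1 - tb$African - tb$Mapuche - tb$Aymara,
    Mapuche = tb$Mapuche,
    Aymara = tb$Aymara
  )
  rownames(m) <- tb$region
  m
}

#' Default ancestral divergence model
#'
#' Four ancestral populations under the Balding-Nichols model. Drift
#' parameters are calibrated so the African component is the most diverged,
#' the European component intermediate, and the two Native-like components
#' the closest pair, with expected pairwise Fst between them of 0.038.
#'
#' @param M number of SNPs.
#' @return An [ancestral_model()].
#' @export
chile_ancestral_model <- function(M = 3000) {
  ancestral_model(
    M = M,
    divergence = c(African = 0.25, European = 0.12,
                   Mapuche = 0.038, Aymara = 0.038),
    pairwise_targets = matrix(
      c(NA, NA, NA, NA,
        NA, NA, NA, NA,
        NA, NA, NA, 0.038,
        NA, NA, 0.038, NA), 4, 4,
      dimnames = list(c("African", "European", "Mapuche", "Aymara"),
                      c("African", "European", "Mapuche", "Aymara"))
    )
  )
}

#' Default covariate model
#'
#' Categorical covariates (age class, gender, education, socioeconomic
#' status, salary) whose log-odds are linear in the individual admixture
#' vector. Couplings reproduce the qualitative pattern of the study
#' population: higher Mapuche-like ancestry goes with lower socioeconomic
#' status and lower educational level, men carry slightly more Mapuche-like
#' and less Aymara-like ancestry. Component order: African, European,
#' Mapuche, Aymara.
#'
#' @return Named list of covariate specifications for [cohort_config()].
#' @export
chile_covariate_model <- function() {
  cf <- function(nlev, ...) {
    m <- matrix(0, nlev, 4,
                dimnames = list(NULL, c("African", "European", "Mapuche", "Aymara")))
    dots <- list(...)
    for (d in dots) m[d[[1]], d[[2]]] <- d[[3]]
    m
  }
  list(
    age_class = list(
      levels = c("<24", "24-26", "27-32", ">32"),
      base = c(0, 0.13, 0.20, 0.16),
      coef = cf(4)
    ),
    gender = list(
      levels = c("Female", "Male"),
      base = c(0, 0.44),
      coef = cf(2, list(2, "Mapuche", 1.7), list(2, "Aymara", -1.7))
    ),
    education = list(
      levels = c("Primary/secondary", "Technical", "University"),
      base = c(0, -3.1, -1.0),
      coef = cf(3, list(3, "Mapuche", -1.7))
    ),
    ses = list(
      levels = c("E/D", "C3", "C2", "ABC1", "Missing"),
      base = c(0, 0.01, -1.2, -2.4, 0.24),
      coef = cf(5, list(3, "Mapuche", -1.5), list(4, "Mapuche", -4.5))
    ),
    salary = list(
      levels = c("<350k", "350-450k", "450k+", "Missing"),
      base = c(-0.96, -0.79, 0, 0.51),
      coef = cf(4, list(1, "Mapuche", 0.8), list(4, "Mapuche", -0.8))
    )
  )
}

#' Default cohort configuration
#'
#' The 15-region study cohort: region sample sizes (1805 individuals in
#' total), region-specific Dirichlet concentrations equal to the regional
#' mean ancestry times a common precision, and the default covariate model.
#'
#' @param seed integer seed.
#' @param precision Dirichlet precision (sum of concentrations); 25 gives a
#'   within-region standard deviation of roughly 9 percentage points for a
#'   component with mean 40\%.
#' @return A [cohort_config()].
#' @export
chile_cohort_config <- function(seed = 1, precision = 25) {
  tb <- chile_region_table()
  mm <- chile_region_means()
  regions <- data.frame(region = tb$region, n = tb$n, stringsAsFactors = FALSE)
  for (k in colnames(mm)) regions[[k]] <- mm[, k] * precision
  cohort_config(regions, covariate_model = chile_covariate_model(), seed = seed)
}

# Solve the baseline log-rate so that the expected national death count over
# all years equals `target`, given regional ancestry and person-years.
calibrate_baseline <- function(target_deaths, effects, regional_means,
                               region_py, years, age_bands) {
  w <- age_bands$std_weight
  mult <- age_bands$log_mult - log(sum(w * exp(age_bands$log_mult)))
  eta_r <- as.numeric(100 * regional_means[region_py$region, names(effects), drop = FALSE] %*% effects)
  # region age shares equal to the standard here; the share term sums to ~1
  per_year <- sum(region_py$person_years * exp(eta_r) *
                    sum(w * exp(mult))) / 1e5
  log(target_deaths / (length(years) * per_year))
}

#' Default mortality model
#'
#' Six ICD10-like categories at census-scale person-years over 2005-2011.
#' Baseline log-rates are calibrated so expected national death totals match
#' registry-scale counts (about 9641 deaths for the focal gallbladder-cancer
#' category). The focal category's generative excess is carried entirely by
#' the Mapuche-like component (3.7\% per percentage point) so that the
#' per-component fit of the association stage targets exactly the generative
#' value; opposite-signed Native subcomponent effects are present in the
#' asthma and lung-cancer categories.
#'
#' @param regional_means matrix of per-region mean ancestry used to calibrate
#'   baseline rates (defaults to [chile_region_means()]).
#' @param focal_smr generative SMR per 1\% Mapuche-like ancestry for the
#'   focal category (default 1.037).
#' @return A [mortality_model()].
#' @export
chile_mortality_model <- function(regional_means = chile_region_means(),
                                  focal_smr = 1.037) {
  tb <- chile_region_table()
  years <- 2005:2011
  age_bands <- data.frame(
    age_band = c("0-24", "25-44", "45-64", "65+"),
    std_weight = c(0.42, 0.31, 0.19, 0.08),
    log_mult = c(-4, -1.5, 1.2, 2.8),
    stringsAsFactors = FALSE
  )
  region_py <- data.frame(region = tb$region, person_years = tb$person_years,
                          stringsAsFactors = FALSE)
  # mild deterministic regional age-structure tilt so that direct
  # standardization is exercised (older south, younger north)
  tilt <- seq(-0.15, 0.15, length.out = nrow(tb))
  for (a in seq_along(age_bands$age_band)) {
    region_py[[paste0("share_", age_bands$age_band[a])]] <-
      age_bands$std_weight[a] * exp(tilt * (a - 2.5) * 0.4)
  }
  cats <- data.frame(
    icd = c("C23", "J45", "C34", "E14", "I63", "R99"),
    description = c("Malignant neoplasm of gallbladder", "Asthma",
                    "Malignant neoplasm of bronchus and lung",
                    "Unspecified diabetes mellitus", "Cerebral infarction",
                    "Ill-defined causes (rare)"),
    target_deaths = c(9641, 1383, 17633, 12490, 4316, 60),
    effect_Mapuche = c(log(focal_smr), log(1.047), log(0.965), log(0.987), 0, 0),
    effect_Aymara = c(0, log(0.950), log(1.032), log(1.007), 0, 0),
    stringsAsFactors = FALSE
  )
  cats$effect_African <- 0
  cats$effect_European <- 0
  cats$baseline_log_rate <- vapply(seq_len(nrow(cats)), function(i) {
    eff <- c(Mapuche = cats$effect_Mapuche[i], Aymara = cats$effect_Aymara[i])
    calibrate_baseline(cats$target_deaths[i], eff, regional_means,
                       region_py, years, age_bands)
  }, numeric(1))
  mortality_model(cats, years, age_bands, region_py)
}

#' Regional means for the effect-masking preset
#'
#' Fifteen synthetic regions in which the two Native-like subcomponents are
#' positively correlated across regions (a shared gradient) but retain an
#' independent contrast that identifies their separate effects.
#'
#' @return Matrix of per-region mean ancestry (rows sum to 1).
#' @export
masking_region_means <- function() {
  a <- seq(-1, 1, length.out = 15)
  b <- rep(c(-1, 0, 1), 5)
  map <- 0.22 + 0.12 * a + 0.05 * b
  aym <- 0.22 + 0.12 * a - 0.05 * b
  m <- cbind(
    African = rep(0.03, 15),
    European = 1 - 0.03 - map - aym,
    Mapuche = map,
    Aymara = aym
  )
  rownames(m) <- sprintf("MR%02d", 1:15)
  m
}

#' Mortality model for the effect-masking preset
#'
#' A single focal category with exactly opposite log-linear effects for the
#' two Native-like subcomponents (+/- log(1.03) per percentage point), so the
#' pooled Native sum carries no net effect while each subcomponent does.
#'
#' @param effect log-rate change per 1 percentage point (default `log(1.03)`).
#' @param target_deaths expected national death count over all years.
#' @return A [mortality_model()].
#' @export
masking_mortality_model <- function(effect = log(1.03), target_deaths = 10000) {
  years <- 2005:2011
  age_bands <- data.frame(
    age_band = c("0-44", "45+"), std_weight = c(0.7, 0.3),
    log_mult = c(-1.5, 1.5), stringsAsFactors = FALSE
  )
  mm <- masking_region_means()
  region_py <- data.frame(region = rownames(mm), person_years = 1e6,
                          stringsAsFactors = FALSE)
  cats <- data.frame(
    icd = "X01", description = "Masking focal category",
    effect_Mapuche = effect, effect_Aymara = -effect,
    effect_African = 0, effect_European = 0,
    stringsAsFactors = FALSE
  )
  cats$baseline_log_rate <- calibrate_baseline(
    target_deaths, c(Mapuche = effect, Aymara = -effect), mm,
    region_py, years, age_bands
  )
  mortality_model(cats, years, age_bands, region_py)
}
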