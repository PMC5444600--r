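#' Ancestral divergence model
#'
#' Describes K ancestral populations under the Balding-Nichols model: every
#' locus has a shared ancestral allele frequency p drawn uniformly from
#' `ancestral_maf_range`, and population k's frequency is drawn from
#' `Beta(p (1 - F_k) / F_k, (1 - p)(1 - F_k) / F_k)`, so that `F_k` is the
#' drift of population k away from the ancestral pool. The expected pairwise
#' Fst between populations a and b is approximately `(F_a + F_b) / 2`.
#'
#' @param K number of ancestral populations (>= 2).
#' @param M number of SNPs.
#' @param divergence numeric vector of length K with per-population drift
#'   parameters `F_k`, each strictly inside (0, 1). Named entries name the
#'   populations.
#' @param ancestral_maf_range interval for the shared ancestral allele
#'   frequency, a sub-interval of (0, 1).
#' @param pairwise_targets optional matrix of target pairwise Fst values used
#'   only by calibration checks.
#' @return An object of class `ancestral_model`.
#' @export
ancestral_model <- function(K = length(divergence), M = 5000,
                            divergence,
                            ancestral_maf_range = c(0.05, 0.95),
                            pairwise_targets = NULL) {
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  if (length(divergence) != K) stop("divergence must have length K", call. = FALSE)
  if (any(divergence <= 0) || any(divergence >= 1)) {
    stop("all drift parameters F_k must lie strictly in (0, 1)", call. = FALSE)
  }
  if (ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] >= 1 ||
      ancestral_maf_range[1] >= ancestral_maf_range[2]) {
    stop("ancestral_maf_range must be an interval inside (0, 1)", call. = FALSE)
  }
  if (is.null(names(divergence))) names(divergence) <- paste0("pop", seq_len(K))
  structure(
    list(K = K, M = M, divergence = divergence,
         ancestral_maf_range = ancestral_maf_range,
         pairwise_targets = pairwise_targets),
    class = "ancestral_model"
  )
}

#' Simulate reference panels under the Balding-Nichols model
#'
#' Draws per-population allele frequencies around shared ancestral frequencies
#' and samples reference genotypes `Binomial(2, f_km)` for `n_per_pop`
#' individuals in each population. The returned panel records the true
#' per-population frequencies alongside the sampled genotypes, so downstream
#' estimators can be tested against ground truth.
#'
#' @param model an [ancestral_model()].
#' @param n_per_pop number of reference individuals per population (>= 2).
#' @param seed integer seed; the generator is bit-reproducible given the seed.
#' @param contamination optional list describing two-way admixed reference
#'   individuals for one population, with elements `pop` (population name),
#'   `with` (admixing population name) and `min_fraction` (minimum proportion
#'   of the labelled population's own ancestry, e.g. 0.74). Each contaminated
#'   reference individual gets own-ancestry fraction drawn uniformly from
#'   `[min_fraction, 1]`.
#' @return A list with `true_freqs` (K x M matrix of generative frequencies),
#'   `genotypes` (named list of `genotype_matrix`, one per population),
#'   `ancestral_freq` (length-M vector) and, when contamination is requested,
#'   `contamination_fractions`.
#' @export
simulate_reference_panels <- function(model, n_per_pop = 50, seed = 1,
                                      contamination = NULL) {
  stopifnot(inherits(model, "ancestral_model"))
  if (n_per_pop < 2) stop("n_per_pop must be >= 2", call. = FALSE)
  set.seed(seed)
  K <- model$K; M <- model$M
  pops <- names(model$divergence)
  p0 <- stats::runif(M, model$ancestral_maf_range[1], model$ancestral_maf_range[2])
  freqs <- matrix(NA_real_, K, M, dimnames = list(pops, NULL))
  for (k in seq_len(K)) {
    Fk <- model$divergence[k]
    shape <- (1 - Fk) / Fk
    freqs[k, ] <- stats::rbeta(M, p0 * shape, (1 - p0) * shape)
  }
  # keep generative frequencies away from exact fixation (Beta can underflow)
  freqs <- pmin(pmax(freqs, 1e-9), 1 - 1e-9)

  variants <- data.frame(
    chrom = rep("1", M), pos = seq_len(M) * 1000L,
    id = sprintf("snp%05d", seq_len(M)),
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  genotypes <- vector("list", K); names(genotypes) <- pops
  contamination_fractions <- NULL
  for (k in seq_len(K)) {
    if (!is.null(contamination) && pops[k] == contamination$pop) {
      j <- match(contamination$with, pops)
      if (is.na(j)) stop("contamination 'with' population not in model", call. = FALSE)
      frac <- stats::runif(n_per_pop, contamination$min_fraction, 1)
      contamination_fractions <- frac
      pmat <- outer(frac, freqs[k, ]) + outer(1 - frac, freqs[j, ])
      g <- matrix(stats::rbinom(n_per_pop * M, 2L, pmat), n_per_pop, M)
    } else {
      g <- matrix(
        stats::rbinom(n_per_pop * M, 2L, rep(freqs[k, ], each = n_per_pop)),
        n_per_pop, M
      )
    }
    genotypes[[k]] <- genotype_matrix(
      g, samples = sprintf("%s_%03d", pops[k], seq_len(n_per_pop)),
      variants = variants
    )
  }
  list(true_freqs = freqs, genotypes = genotypes, ancestral_freq = p0,
       variants = variants, contamination_fractions = contamination_fractions)
}

#' Cohort configuration for the admixed-cohort generator
#'
#' @param regions data frame with one row per region: a `region` label column,
#'   an `n` column of individuals to draw, and one numeric column per
#'   ancestral population giving the Dirichlet concentration for that
#'   component (all strictly positive).
#' @param covariate_model optional named list of categorical covariate
#'   specifications; each element is a list with `levels` (character),
#'   `base` (baseline log-odds per level) and `coef` (levels x K matrix of
#'   log-odds coefficients multiplying the individual admixture vector q).
#' @param seed integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(regions, covariate_model = NULL, seed = 1) {
  stopifnot(is.data.frame(regions), "region" %in% names(regions), "n" %in% names(regions))
  if (anyDuplicated(regions$region)) stop("region labels must be unique", call. = FALSE)
  conc <- as.matrix(regions[, setdiff(names(regions), c("region", "n")), drop = FALSE])
  if (any(conc <= 0)) stop("Dirichlet concentrations must be strictly positive", call. = FALSE)
  structure(list(regions = regions, covariate_model = covariate_model, seed = seed),
            class = "cohort_config")
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              n, length(alpha))
  x / rowSums(x)
}

sample_categorical <- function(Q, spec) {
  # log-odds per level: base + coef %*% q
  eta <- matrix(spec$base, nrow(Q), length(spec$levels), byrow = TRUE)
  if (!is.null(spec$coef)) eta <- eta + Q %*% t(spec$coef)
  pr <- exp(eta - apply(eta, 1, max))
  pr <- pr / rowSums(pr)
  idx <- apply(pr, 1, function(p) sample.int(length(p), 1, prob = p))
  factor(spec$levels[idx], levels = spec$levels)
}

#' Simulate an admixed cohort with covariates
#'
#' Each individual's admixture vector `q` is drawn from the Dirichlet
#' distribution of their region; genotype dosages follow
#' `Binomial(2, sum_k q_k f_km)` with `f` the panel's true frequencies;
#' categorical covariates are drawn from multinomial-logit models whose
#' log-odds are linear in `q`. The true Q matrix is returned for recovery
#' tests.
#'
#' @param panels result of [simulate_reference_panels()] (the true frequencies
#'   are used as the generative frequencies).
#' @param cfg a [cohort_config()].
#' @return A list with `genotypes` (a `genotype_matrix`), `covariates`
#'   (data frame with `sample_id`, `region` and one column per configured
#'   covariate) and `Q` (n x K matrix of true admixture proportions).
#' @export
simulate_admixed_cohort <- function(panels, cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!nrow(panels$variants)) stop("panel SNP set is empty", call. = FALSE)
  set.seed(cfg$seed)
  freqs <- panels$true_freqs
  pops <- rownames(freqs)
  conc_cols <- setdiff(names(cfg$regions), c("region", "n"))
  if (!setequal(conc_cols, pops)) {
    stop("region concentration columns must match the panel populations", call. = FALSE)
  }
  M <- ncol(freqs)
  n_total <- sum(cfg$regions$n)
  Q <- matrix(NA_real_, n_total, length(pops), dimnames = list(NULL, pops))
  region <- character(n_total)
  at <- 0L
  for (r in seq_len(nrow(cfg$regions))) {
    nr <- cfg$regions$n[r]
    if (nr == 0) next
    alpha <- as.numeric(cfg$regions[r, pops])
    Q[at + seq_len(nr), ] <- rdirichlet(nr, alpha)
    region[at + seq_len(nr)] <- cfg$regions$region[r]
    at <- at + nr
  }
  pmat <- Q %*% freqs                       # n x M expected allele frequency
  g <- matrix(stats::rbinom(n_total * M, 2L, pmat), n_total, M)
  ids <- sprintf("IND_%04d", seq_len(n_total))
  rownames(Q) <- ids
  covars <- data.frame(sample_id = ids, region = region, stringsAsFactors = FALSE)
  for (nm in names(cfg$covariate_model)) {
    covars[[nm]] <- sample_categorical(Q, cfg$covariate_model[[nm]])
  }
  list(
    genotypes = genotype_matrix(g, samples = ids, variants = panels$variants),
    covariates = covars,
    Q = Q
  )
}

#' Mortality model for the regional registry generator
#'
#' Death counts are Poisson with log-rate linear in the regional mean ancestry
#' components (expressed in percentage points) plus an age-band multiplier.
#' Age-band log multipliers are normalized so that the directly standardized
#' rate has expectation `exp(baseline_log_rate + sum_k effect_k * 100 q_k)`
#' per 10^5 person-years, i.e. the ground-truth SMR per 1\% of component k is
#' exactly `exp(effect_k)`.
#'
#' @param categories data frame with columns `icd`, `description`,
#'   `baseline_log_rate` (log deaths per 10^5 person-years per year at zero
#'   ancestry) and one `effect_<pop>` column per ancestry component (log-rate
#'   change per 1 percentage point).
#' @param years integer vector of calendar years.
#' @param age_bands data frame with columns `age_band` and `std_weight`
#'   (standard-population weights, summing to 1) and `log_mult` (raw age-band
#'   log rate multipliers; normalized internally).
#' @param region_py data frame with columns `region` and `person_years`
#'   (per calendar year), plus optionally one share column per age band named
#'   `share_<age_band>`; equal-to-standard shares are used when absent.
#' @return An object of class `mortality_model`.
#' @export
mortality_model <- function(categories, years, age_bands, region_py) {
  stopifnot(all(c("icd", "baseline_log_rate") %in% names(categories)))
  if (any(region_py$person_years <= 0)) stop("person-years must be > 0", call. = FALSE)
  w <- age_bands$std_weight
  if (abs(sum(w) - 1) > 1e-8) {
    warning("standard weights do not sum to 1; renormalizing")
    age_bands$std_weight <- w / sum(w)
  }
  # normalize so that sum_a w_a exp(mult_a) = 1
  age_bands$log_mult <- age_bands$log_mult -
    log(sum(age_bands$std_weight * exp(age_bands$log_mult)))
  structure(
    list(categories = categories, years = years, age_bands = age_bands,
         region_py = region_py),
    class = "mortality_model"
  )
}

#' Simulate a regional mortality table
#'
#' @param model a [mortality_model()].
#' @param regional_ancestry matrix of per-region mean ancestry proportions
#'   (regions in rows, named; components in columns matching the
#'   `effect_<pop>` columns of the model); rows must sum to 1.
#' @param seed integer seed.
#' @return A list with `table` (long data frame: region, year, icd, age_band,
#'   deaths, person_years), `true_smr` (per-category named vectors of
#'   ground-truth SMR per 1\%) and `std_weights` (age standard weights).
#' @export
simulate_mortality <- function(model, regional_ancestry, seed = 1) {
  stopifnot(inherits(model, "mortality_model"))
  if (any(abs(rowSums(regional_ancestry) - 1) > 1e-6)) {
    stop("regional_ancestry rows must sum to 1", call. = FALSE)
  }
  set.seed(seed)
  regions <- model$region_py$region
  if (!all(regions %in% rownames(regional_ancestry))) {
    stop("regional_ancestry missing rows for some regions", call. = FALSE)
  }
  ab <- model$age_bands
  eff_cols <- grep("^effect_", names(model$categories), value = TRUE)
  comps <- sub("^effect_", "", eff_cols)
  if (!all(comps %in% colnames(regional_ancestry))) {
    stop("effect columns do not match ancestry components", call. = FALSE)
  }
  X <- 100 * regional_ancestry[regions, comps, drop = FALSE]  # percentage points

  grid <- expand.grid(
    age_band = ab$age_band, year = model$years, region = regions,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  shares <- matrix(rep(ab$std_weight, length(regions)),
                   nrow = length(regions), byrow = TRUE,
                   dimnames = list(regions, ab$age_band))
  share_cols <- paste0("share_", ab$age_band)
  if (all(share_cols %in% names(model$region_py))) {
    shares <- as.matrix(model$region_py[, share_cols])
    dimnames(shares) <- list(regions, ab$age_band)
    shares <- shares / rowSums(shares)
  }
  py <- model$region_py$person_years[match(grid$region, regions)] *
    shares[cbind(grid$region, grid$age_band)]

  out <- vector("list", nrow(model$categories))
  true_smr <- list()
  for (i in seq_len(nrow(model$categories))) {
    cat_i <- model$categories[i, ]
    eta_r <- as.numeric(as.matrix(X) %*% t(as.matrix(cat_i[, eff_cols])))
    names(eta_r) <- regions
    lograte <- cat_i$baseline_log_rate + eta_r[grid$region] +
      ab$log_mult[match(grid$age_band, ab$age_band)] - log(1e5)
    mu <- py * exp(lograte)
    out[[i]] <- data.frame(
      region = grid$region, year = grid$year, icd = cat_i$icd,
      age_band = grid$age_band,
      deaths = stats::rpois(nrow(grid), mu),
      person_years = py,
      stringsAsFactors = FALSE
    )
    s <- exp(as.numeric(cat_i[, eff_cols])); names(s) <- comps
    true_smr[[cat_i$icd]] <- s
  }
  list(
    table = do.call(rbind, out),
    true_smr = true_smr,
    std_weights = stats::setNames(ab$std_weight, ab$age_band)
  )
}

#' Simulate an individual-level survival cohort
#'
#' Generates disease-free survival times (age at diagnosis) with a constant
#' baseline hazard multiplied by `exp(log(hr_per_point) * ancestry_pct)`,
#' censored at a uniformly drawn interview age. Used to exercise the
#' proportional-hazards validation stage with known ground truth.
#'
#' @param n cohort size.
#' @param hr_per_point true hazard ratio per 1 percentage point of ancestry.
#' @param baseline_hazard baseline hazard per year at 0\% ancestry.
#' @param censor_range interview-age interval for uniform censoring.
#' @param ancestry_mean,ancestry_sd mean and standard deviation of the
#'   individual ancestry percentage (normal, truncated to [0, 100]).
#' @param seed integer seed.
#' @return Data frame with `id`, `time`, `event`, `ancestry_pct`, `gender`.
#' @export
simulate_survival_cohort <- function(n = 5000, hr_per_point = 1.02,
                                     baseline_hazard = 2e-3,
                                     censor_range = c(40, 90),
                                     ancestry_mean = 40, ancestry_sd = 12,
                                     seed = 1) {
  set.seed(seed)
  x <- pmin(pmax(stats::rnorm(n, ancestry_mean, ancestry_sd), 0), 100)
  rate <- baseline_hazard * hr_per_point^x
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, censor_range[1], censor_range[2])
  data.frame(
    id = sprintf("V%04d", seq_len(n)),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    ancestry_pct = x,
    gender = factor(sample(c("Female", "Male"), n, replace = TRUE,
                           prob = c(0.6, 0.4)))
  )
}
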