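# Direct standardization ------------------------------------------------------

test_that("standardization reduces to the crude rate when age structures agree", {
  w <- c(a = 0.3, b = 0.5, c = 0.2)
  py <- 1e5 * w                          # region age structure == standard
  deaths <- c(a = 12, b = 40, c = 9)
  crude <- sum(deaths) / sum(py) * 1e5
  expect_equal(direct_standardize(deaths, py, w), crude)
})

test_that("weighted band rates follow the stated arithmetic", {
  # bands at 10 and 30 per 1e5
  d <- c(10, 30); py <- c(1e5, 1e5)
  expect_equal(direct_standardize(d, py, c(0.5, 0.5)), 20)
  expect_equal(direct_standardize(d, py, c(0.2, 0.8)), 26)
})

test_that("non-normalized weights are renormalized with a warning", {
  expect_warning(
    r <- direct_standardize(c(10, 30), c(1e5, 1e5), c(1, 1)),
    "renormalizing"
  )
  expect_equal(r, 20)
})

test_that("zero person-years with deaths is a data error; band mismatch too", {
  expect_error(direct_standardize(c(5, 1), c(0, 1e5), c(0.5, 0.5)),
               "zero person-years")
  expect_error(
    direct_standardize(c(a = 1, b = 2), c(a = 1e5, b = 1e5),
                       c(a = 0.5, z = 0.5)),
    "do not match"
  )
})

test_that("category filter is inclusive at the minimum and reports drops", {
  tab <- data.frame(
    region = "r", year = 2005, age_band = "a", person_years = 1e5,
    icd = rep(c("A", "B", "C"), c(3, 2, 1)),
    deaths = c(33, 33, 33, 50, 50, 5000)
  )
  out <- filter_categories(tab, min_deaths = 100)
  expect_setequal(out$retained, c("B", "C"))   # A totals 99, B exactly 100
  expect_equal(out$dropped, "A")
  expect_equal(as.numeric(out$totals[c("A", "B", "C")]), c(99, 100, 5000))
})

# Stage 1 ----------------------------------------------------------------------

test_that("intercept-only stage 1 returns the sample mean", {
  d <- data.frame(region = rep("R1", 50))
  x <- stats::runif(50, 0.2, 0.6)
  m <- fit_stage1(d, x, factors = character(0))
  expect_equal(m$expectations$expected, mean(x))
  expect_equal(m$expectations$se, stats::sd(x) / sqrt(50), tolerance = 1e-10)
})

test_that("stratum prediction is the intercept plus the stratum offset", {
  # intercept 0.40 (reference stratum), offset -0.06 for the high-SES
  # stratum: predicted proportion 0.34
  d <- data.frame(
    region = "R1",
    ses = factor(rep(c("D/E", "ABC1"), c(30, 10)), levels = c("D/E", "ABC1"))
  )
  x <- c(rep(0.40, 30), rep(0.34, 10))
  m <- fit_stage1(d, x, factors = "ses")
  cf <- stats::coef(m$fit)
  expect_equal(unname(cf["(Intercept)"]), 0.40)
  expect_equal(unname(cf["sesABC1"]), -0.06)
  pred <- stats::predict(m$fit, data.frame(region = "R1", ses = "ABC1"))
  expect_equal(unname(pred), 0.34)
})

test_that("regional expectations recover known region offsets", {
  set.seed(101)
  regions <- sprintf("R%02d", 1:6)
  true_means <- seq(0.25, 0.50, length.out = 6)
  n_per <- 250
  d <- data.frame(region = rep(regions, each = n_per))
  x <- stats::rnorm(6 * n_per, rep(true_means, each = n_per), 0.08)
  m <- fit_stage1(d, x, factors = character(0))
  expect_equal(m$expectations$expected, true_means, tolerance = 0.02)
  expect_equal(m$expectations$se, rep(0.08 / sqrt(n_per), 6), tolerance = 0.01)
})

test_that("population-average evaluation preserves between-region contrasts", {
  set.seed(102)
  n <- 400
  region <- rep(c("A", "B"), each = n / 2)
  ses <- factor(ifelse(stats::runif(n) < ifelse(region == "A", 0.7, 0.3),
                       "low", "high"))
  x <- 0.3 + 0.1 * (region == "B") + 0.05 * (ses == "low") +
    stats::rnorm(n, 0, 0.02)
  d <- data.frame(region = region, ses = ses)
  pop <- fit_stage1(d, x, factors = "ses", evaluate = "population")
  raw <- tapply(x, region, mean)
  contrast_pop <- diff(pop$expectations$expected)
  # population evaluation keeps the model's region coefficient as contrast
  expect_equal(contrast_pop, unname(stats::coef(pop$fit)["regionB"]))
  ref <- fit_stage1(d, x, factors = "ses", evaluate = "reference")
  expect_equal(diff(ref$expectations$expected), contrast_pop)
})

# Stepwise selection -----------------------------------------------------------

test_that("alpha_enter = 0 selects nothing", {
  set.seed(110)
  d <- data.frame(f1 = factor(sample(letters[1:3], 100, TRUE)))
  x <- stats::rnorm(100)
  expect_length(stepwise_forward(d, x, "f1", alpha_enter = 0), 0)
})

test_that("forward selection respects its entry size under the null", {
  set.seed(111)
  empty <- 0L
  for (r in 1:50) {
    d <- data.frame(noise = factor(sample(letters[1:4], 300, TRUE)))
    x <- stats::rnorm(300)
    sel <- stepwise_forward(d, x, "noise")
    if (!length(sel)) empty <- empty + 1L
  }
  # selection probability under the null is the per-candidate size 0.1;
  # 0.82 is ~2.4 binomial SD below the nominal 0.9
  expect_gte(empty / 50, 0.82)
})

test_that("a factor with a strong true effect is selected among noise", {
  set.seed(112)
  hits <- 0L
  for (r in 1:20) {
    f_true <- factor(sample(c("lo", "hi"), 400, TRUE))
    d <- data.frame(
      signal = f_true,
      n1 = factor(sample(letters[1:3], 400, TRUE)),
      n2 = factor(sample(letters[1:3], 400, TRUE))
    )
    x <- 0.3 + 0.1 * (f_true == "hi") + stats::rnorm(400, 0, 0.08)
    sel <- stepwise_forward(d, x, c("signal", "n1", "n2"))
    if ("signal" %in% sel) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.95)
})

# Stage 2 ----------------------------------------------------------------------

test_that("two-region saturated fit gives the closed-form SMR", {
  # deterministic rates with ratio 2 over a 24-point contrast
  r <- toy_std_rates(c("lo", "hi"), rates = c(10, 20), years = 4)
  fit <- fit_stage2(r, c(lo = 10, hi = 34))
  expect_equal(fit$terms$smr, 2^(1 / 24), tolerance = 1e-6)
  expect_equal(2^(1 / 24), 1.0293, tolerance = 1e-4)
  expect_true(fit$terms$ci_lower <= fit$terms$smr &
                fit$terms$smr <= fit$terms$ci_upper)
})

test_that("rate-response variant agrees with the offset variant on point estimates", {
  r <- toy_std_rates(c("a", "b", "c"), rates = c(8, 12, 20), years = 2)
  x <- c(a = 10, b = 20, c = 30)
  f1 <- fit_stage2(r, x, response = "expected_deaths")
  f2 <- fit_stage2(r, x, response = "rate")
  expect_equal(f1$terms$beta, f2$terms$beta, tolerance = 1e-6)
})

test_that("null-effect confidence intervals cover 1 at near-nominal rate", {
  mm <- masking_mortality_model(effect = 0, target_deaths = 8000)
  means <- masking_region_means()
  x <- stats::setNames(100 * means[, "Mapuche"], rownames(means))
  covered <- 0L
  for (r in 1:40) {
    m <- simulate_mortality(mm, means, seed = 7000 + r)
    rates <- standardized_rates(m$table, m$std_weights)
    fit <- fit_stage2(rates, x)
    if (fit$terms$ci_lower <= 1 && fit$terms$ci_upper >= 1) covered <- covered + 1L
  }
  expect_gte(covered / 40, 0.85)        # nominal 0.95, 40 replicates
})

test_that("fewer than two regions is an error", {
  r <- toy_std_rates("only", rates = 10)
  expect_error(fit_stage2(r, c(only = 10)), "at least 2 regions")
})

test_that("random-intercept variant returns comparable point estimates", {
  mm <- masking_mortality_model(effect = log(1.02), target_deaths = 20000)
  means <- masking_region_means()
  m <- simulate_mortality(mm, means, seed = 55)
  rates <- standardized_rates(m$table, m$std_weights)
  x <- 100 * means[, c("Mapuche", "Aymara")]
  f_fix <- fit_stage2(rates, x)
  f_ran <- fit_stage2(rates, x, random_intercept = TRUE)
  expect_true(f_ran$converged)
  expect_equal(f_ran$terms$beta, f_fix$terms$beta, tolerance = 0.02)
})

# Report -----------------------------------------------------------------------

test_that("highlight threshold scales exactly as 0.05/n and is strict", {
  res <- list(
    list(icd = "A00", description = "a", deaths = 500,
         terms = data.frame(component = "M", beta = 0.01, se = 0.001,
                            smr = 1.01, ci_lower = 1.008, ci_upper = 1.012,
                            p = 0.0001)),
    list(icd = "B00", description = "b", deaths = 300,
         terms = data.frame(component = "M", beta = 0, se = 0.001,
                            smr = 1, ci_lower = 0.99, ci_upper = 1.01,
                            p = 0.00009))
  )
  rep500 <- smr_report(res, n_categories = 500)
  expect_equal(attr(rep500, "threshold"), 0.0001)
  # p exactly at the threshold is NOT highlighted; strictly below is
  expect_false(rep500$highlight[rep500$icd == "A00"])
  expect_true(rep500$highlight[rep500$icd == "B00"])
  rep1 <- smr_report(res[1], n_categories = 1)
  expect_equal(attr(rep1, "threshold"), 0.05)
  empty <- smr_report(list(), n_categories = 500)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "threshold"), 0.0001)
})
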