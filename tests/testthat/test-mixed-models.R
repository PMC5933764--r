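# Crossed-random-effects growth models, AIC comparison and the
# Walford -> von Bertalanffy transform.

test_that("mixed fit with both random effects off reduces to the OLS fit", {
  cfg <- truth_config(n_fish = 60L, seed = 21L)
  pop <- generate_population(cfg)
  pairs <- build_growth_pairs(pop$increments)
  ols <- fit_walford_temp(pairs, pop$temps)
  red <- fit_mixed_growth(pairs, pop$temps, random_year = FALSE,
                          random_fish = FALSE)
  expect_s3_class(red, "growth_fit")
  expect_false(inherits(red, "mixed_growth_fit"))
  expect_identical(coef(red), coef(ols))
})

test_that("zero random-effect variance: mixed fit approaches the OLS limit", {
  # a wide crossed design with truly zero random-effect variance: ML
  # variance estimates shrink toward the boundary and the GLS weighting
  # collapses to OLS
  set.seed(8)
  temps <- annual_temperature(1981:2020, rnorm(40, 20.5, 0.5))
  pairs <- sim_pairs(1200, 0.7033, -0.0631, 2.120, 0.08, temps)
  pairs$fish_id <- rep(sprintf("F%03d", 1:300), each = 4)
  ols <- fit_walford_temp(pairs, temps)
  mix <- fit_mixed_growth(pairs, temps)
  expect_equal(coef(mix), coef(ols), tolerance = 2e-3)
  expect_lt(mix$sd_year, 0.02)
  expect_lt(mix$sd_fish, 0.02)

  # data that are exactly degenerate in a grouping factor sit at the
  # boundary and are flagged, not rejected
  cfg <- truth_config(n_fish = 80L, sd_year = 0, sd_fish = 0,
                      sigma_growth = 1e-4, seed = 8L)
  pop <- generate_population(cfg)
  p2 <- build_growth_pairs(pop$increments)
  m2 <- fit_mixed_growth(p2, pop$temps, random_year = FALSE,
                         random_fish = TRUE)
  expect_true(is.finite(m2$aic))
  expect_true(m2$sd_fish >= 0)
})

test_that("variance components are recovered across seeded replicates", {
  truth <- c(year = 0.05, fish = 0.04, resid = 0.06)
  err <- matrix(NA_real_, 20, 3)
  for (r in 1:20) {
    cfg <- truth_config(n_fish = 300L, sigma_growth = 0.06,
                        sd_year = 0.05, sd_fish = 0.04, seed = 300 + r)
    pop <- suppressWarnings(generate_population(cfg))
    pairs <- build_growth_pairs(pop$increments)
    m <- fit_mixed_growth(pairs, pop$temps)
    err[r, ] <- abs(c(m$sd_year, m$sd_fish, m$sigma) - truth) / truth
  }
  expect_lt(mean(err[, 1]), 0.5)  # year SD
  expect_lt(mean(err[, 2]), 0.5)  # fish SD
  expect_lt(mean(err[, 3]), 0.5)  # residual SD
})

test_that("marginal R-squared is a proper fraction and grows with an informative covariate", {
  cfg <- truth_config(n_fish = 150L, sigma_growth = 0.005,
                      sd_year = 0.002, sd_fish = 0.002, seed = 31L)
  pop <- generate_population(cfg)
  pairs <- build_growth_pairs(pop$increments)
  m_no_t <- fit_mixed_growth(pairs)
  m_t <- fit_mixed_growth(pairs, pop$temps)
  expect_true(m_no_t$marginal_r2 >= 0 && m_no_t$marginal_r2 <= 1)
  expect_true(m_t$marginal_r2 >= 0 && m_t$marginal_r2 <= 1)
  expect_gte(m_t$marginal_r2, m_no_t$marginal_r2)
})

test_that("model comparison: delta-AIC anchoring, comparability, penalization", {
  cfg <- truth_config(n_fish = 120L, seed = 13L)
  pop <- generate_population(cfg)
  pairs <- build_growth_pairs(pop$increments)
  f1 <- fit_walford(pairs)
  f2 <- fit_walford_temp(pairs, pop$temps)

  one <- compare_models(list(lm1 = f1))
  expect_equal(one$delta_aic, 0)
  both <- compare_models(list(a = f1, b = f1))
  expect_equal(both$delta_aic, c(0, 0))
  cmp <- compare_models(list(lm1 = f1, lm2 = f2))
  expect_equal(min(cmp$delta_aic), 0)
  expect_true(all(cmp$delta_aic >= 0))
  expect_equal(cmp$aic, sort(cmp$aic))

  short <- fit_walford(pairs[1:50, ])
  expect_error(compare_models(list(f1, short)), "not AIC-comparable")

  # adding a covariate whose true coefficient is zero costs AIC on average
  set.seed(77)
  temps <- annual_temperature(2001:2012, rnorm(12, 20.5, 0.5))
  d <- replicate(40, {
    p <- sim_pairs(120, 0.7, 0, 0.8, 0.08, temps)
    fit_walford_temp(p, temps)$aic - fit_walford(p)$aic
  })
  expect_gt(mean(d), 0)
})

test_that("temperature model wins the AIC comparison when the effect is real", {
  wins <- 0L
  for (r in 1:100) {
    cfg <- truth_config(n_fish = 320L, seed = 600 + r)
    pop <- suppressWarnings(generate_population(cfg))
    pairs <- build_growth_pairs(pop$increments)
    if (fit_walford_temp(pairs, pop$temps)$aic < fit_walford(pairs)$aic) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 90L)
})

test_that("Walford fixed-point algebra is exact and unit conventions hold", {
  w <- growth_fit("walford", intercept = 1.0, slope_Z = 0.5,
                  sigma = 0.1)
  a <- growth_fit("allometry", intercept = 0, slope_Z = 100,
                  sigma = 10)
  vb <- vb_transform(w, a)
  expect_equal(vb$Z_inf, 2.0)
  expect_equal(vb$K, log(2))
  # identities: Z_inf (1 - slope) = intercept; the Walford map fixes Z_inf
  slope <- coef(w)[["slope_Z"]]
  expect_equal(vb$Z_inf * (1 - slope), coef(w)[["intercept"]])
  expect_equal(slope * vb$Z_inf + coef(w)[["intercept"]], vb$Z_inf)
  # phi-prime uses L_inf in cm: adding a round-trip unit conversion is a
  # no-op
  expect_equal(vb$phi_prime, log(vb$K) + 2 * log(10 * vb$L_inf / 100))

  bad <- growth_fit("walford", intercept = 1, slope_Z = 1.1,
                    sigma = 0.1)
  expect_error(vb_transform(bad, a), "outside \\(0, 1\\)")
  neg <- growth_fit("walford", intercept = 1, slope_Z = -0.2,
                    sigma = 0.1)
  expect_error(vb_transform(neg, a), "outside \\(0, 1\\)")
})
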