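# The discretized cohort projection against its exact affine-Gaussian
# counterpart, plus mesh/normalization behaviour.

test_that("one projection step matches closed-form Gaussian propagation", {
  mesh <- cipm_mesh(-2, 6, 500)
  mu0 <- 1.5; s0 <- 0.2
  d0 <- list(mesh = mesh, density = dnorm(mesh$nodes, mu0, s0),
             age = 1L, variable = "otolith_radius")
  class(d0) <- "size_distribution"
  gf <- growth_fit("walford", intercept = 0.83, slope_Z = 0.7,
                   sigma = 0.08)
  k <- growth_kernel(gf, temperature = NA)
  d1 <- project_step(d0, k)
  m <- dist_moments(d1)
  exp_mean <- 0.7 * mu0 + 0.83
  exp_sd <- sqrt(0.7^2 * s0^2 + 0.08^2)
  expect_lt(abs(m[["mean"]] - exp_mean) / exp_mean, 1e-6)
  expect_lt(abs(m[["sd"]] - exp_sd) / exp_sd, 1e-6)
  expect_equal(d1$age, 2L)
  expect_equal(dist_integral(d1), 1, tolerance = 1e-9)
})

test_that("a near-identity kernel leaves the distribution unchanged", {
  # kernel SD small relative to the distribution but still resolved by
  # the mesh (a few cells wide)
  mesh <- cipm_mesh(0, 4, 1000)
  d0 <- list(mesh = mesh, density = dnorm(mesh$nodes, 2, 0.25),
             age = 1L, variable = "otolith_radius")
  class(d0) <- "size_distribution"
  gf <- growth_fit("walford", intercept = 0, slope_Z = 1, sigma = 0.01)
  d1 <- project_step(d0, growth_kernel(gf, NA))
  expect_equal(dist_moments(d1)[["mean"]], 2, tolerance = 1e-5)
  expect_equal(dist_moments(d1)[["sd"]], 0.25, tolerance = 1e-3)
  expect_lt(max(abs(d1$density - d0$density)), 0.01 * max(d0$density))
})

test_that("initial distribution: analytic mean, normalization, truncation warning", {
  fits <- injected_fits()
  d <- make_initial_distribution(fits$lm3, 20.48)
  expect_equal(mean(d), 2.937 - 0.0718 * 20.48, tolerance = 1e-3)
  expect_equal(dist_integral(d), 1, tolerance = 1e-9)
  expect_equal(d$age, 1L)

  narrow <- cipm_mesh(1.45, 1.48, 50)  # cuts both Gaussian tails
  expect_warning(make_initial_distribution(fits$lm3, 20.48, narrow),
                 "truncates")

  # SD comparable to the cell width concentrates mass at one node
  tight <- growth_fit("initial_size", 2.937, slope_T = -0.0718,
                      sigma = 1e-4)
  wide <- cipm_mesh(0, 3, 300)
  d2 <- suppressWarnings(make_initial_distribution(tight, 20.48, wide))
  expect_gt(max(d2$density) * d2$mesh$dz, 0.99)
})

test_that("cohort projection: monotone means converging to the Walford fixed point", {
  fits <- injected_fits()
  proj <- project_cohort(fits$lm3, fits$lm2, 20.48, max_age = 16)
  mom <- summary(proj)
  expect_true(all(diff(mom$mean) > 0))
  zfix <- (2.120 - 0.0631 * 20.48) / (1 - 0.7033)
  expect_lt(abs(mom$mean[16] - zfix), 0.01)
  gaps <- abs(mom$mean - zfix)
  expect_true(all(diff(gaps) < 0))

  one <- project_cohort(fits$lm3, fits$lm2, 20.48, max_age = 1)
  expect_length(one$distributions, 1L)
  expect_equal(one$distributions[[1]]$age, 1L)
})

test_that("numerical projection matches the closed-form oracle at every age", {
  fits <- injected_fits()
  mom <- closed_form_moments(fits$lm3, fits$lm2, fits$lm4, 20.48,
                             max_age = 7)
  proj <- project_cohort(fits$lm3, fits$lm2, 20.48, max_age = 7)
  num <- summary(proj)
  expect_true(all(abs(num$mean - mom$z_mean) / mom$z_mean < 1e-6))
  expect_true(all(abs(num$sd - mom$z_sd) / mom$z_sd < 1e-6))
  for (a in 1:7) {
    ld <- map_to_length(proj$distributions[[a]], fits$lm4)
    m <- dist_moments(ld)
    expect_lt(abs(m[["mean"]] - mom$l_mean[a]) / mom$l_mean[a], 1e-6)
    expect_lt(abs(m[["sd"]] - mom$l_sd[a]) / mom$l_sd[a], 1e-6)
  }
})

test_that("length mapping is the allometry in expectation for any input density", {
  fits <- injected_fits()
  mesh <- cipm_mesh(0.5, 4, 800)
  # deliberately non-Gaussian input: bimodal mixture
  dens <- 0.65 * dnorm(mesh$nodes, 1.5, 0.12) +
    0.35 * dnorm(mesh$nodes, 2.4, 0.2)
  d <- list(mesh = mesh, density = dens / (sum(dens) * mesh$dz),
            age = 3L, variable = "otolith_radius")
  class(d) <- "size_distribution"
  ld <- map_to_length(d, fits$lm4)
  expect_equal(dist_moments(ld)[["mean"]],
               176.38 * dist_moments(d)[["mean"]] - 74.62,
               tolerance = 1e-6)
  expect_equal(ld$variable, "total_length")
  expect_equal(ld$age, 3L)

  # identity allometry with small (mesh-resolved) SD reproduces the
  # input density
  id <- growth_fit("allometry", 0, slope_Z = 1, sigma = 0.01)
  ld2 <- map_to_length(d, id, mesh = mesh)
  expect_equal(dist_moments(ld2)[["mean"]], dist_moments(d)[["mean"]],
               tolerance = 1e-4)
  expect_lt(max(abs(ld2$density - d$density)), 0.02 * max(d$density))
})

test_that("every projected density conserves mass", {
  fits <- injected_fits()
  for (T in c(19.48, 20.48, 21.48)) {
    proj <- project_cohort(fits$lm3, fits$lm2, T, max_age = 7)
    ints <- vapply(proj$distributions, dist_integral, numeric(1))
    expect_true(all(abs(ints - 1) < 1e-6))
    ld <- map_to_length(proj$distributions[[7]], fits$lm4)
    expect_lt(abs(dist_integral(ld) - 1), 1e-6)
  }
})

test_that("mean length at age declines monotonically in temperature", {
  fits <- injected_fits()
  temps <- c(18.5, 19.5, 20.5, 21.5, 22.5)
  means <- sapply(temps, function(T) {
    proj <- project_cohort(fits$lm3, fits$lm2, T, max_age = 5)
    vapply(proj$distributions, function(d) {
      dist_moments(map_to_length(d, fits$lm4))[["mean"]]
    }, numeric(1))
  })
  # each row (age) strictly decreasing across temperature columns
  expect_true(all(apply(means, 1, function(r) all(diff(r) < 0))))
})

test_that("projected means are mesh-converged", {
  fits <- injected_fits()
  m1 <- summary(project_cohort(fits$lm3, fits$lm2, 20.48, max_age = 5,
                               n_nodes = 1000))$mean
  m2 <- summary(project_cohort(fits$lm3, fits$lm2, 20.48, max_age = 5,
                               n_nodes = 2000))$mean
  expect_true(all(abs(m1 - m2) < 1e-8))
})

test_that("closed-form recursion agrees with direct hand iteration", {
  fits <- injected_fits()
  mom <- closed_form_moments(fits$lm3, fits$lm2, fits$lm4, 20.48,
                             max_age = 3)
  mu1 <- 2.937 - 0.0718 * 20.48
  mu2 <- 0.7033 * mu1 - 0.0631 * 20.48 + 2.120
  mu3 <- 0.7033 * mu2 - 0.0631 * 20.48 + 2.120
  expect_equal(mom$z_mean, c(mu1, mu2, mu3), tolerance = 1e-12)
  expect_equal(mom$l_mean, 176.38 * c(mu1, mu2, mu3) - 74.62,
               tolerance = 1e-12)
  s2 <- c(0.2^2, 0.7033^2 * 0.2^2 + 0.08^2)
  s2 <- c(s2, 0.7033^2 * s2[2] + 0.08^2)
  expect_equal(mom$z_sd, sqrt(s2), tolerance = 1e-12)

  # zero kernel SDs propagate zero spread
  det <- closed_form_moments(
    growth_fit("initial_size", 2.937, slope_T = -0.0718, sigma = 0),
    growth_fit("walford_temp", 2.120, slope_Z = 0.7033,
               slope_T = -0.0631, sigma = 0),
    growth_fit("allometry", -74.62, slope_Z = 176.38, sigma = 0),
    20.48, max_age = 4)
  expect_equal(det$z_sd, rep(0, 4))
  expect_equal(det$l_sd, rep(0, 4))
})
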