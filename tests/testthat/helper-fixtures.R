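# Fixture builders shared across test files. All data is generated in
# code; nothing is read from disk except files the tests write themselves.

# Three fish with 4, 3 and 2 complete annuli (9 increments total), with
# hand-set radii.
fixture_increments <- function() {
  mk <- function(id, spawn, radii) {
    idx <- seq_along(radii) - 1L
    data.frame(fish_id = id, spawn_year = spawn, increment_index = idx,
               formation_year = spawn + idx,
               width = c(radii[1L], diff(radii)),
               cumulative_radius = radii, stringsAsFactors = FALSE)
  }
  rbind(mk("A", 2004L, c(1.0, 1.8, 2.3, 2.6)),
        mk("B", 2006L, c(1.2, 1.9, 2.4)),
        mk("C", 2008L, c(1.5, 2.1)))
}

fixture_fish <- function() {
  data.frame(fish_id = c("A", "B", "C"),
             capture_date = c("2008-06-15", "2009-07-01", "2010-05-20"),
             capture_location = c("lagoon", "gulf", "lagoon"),
             total_length = c(340, 310, 280), weight = c(520, 410, 300),
             age_at_capture = c(4L, 3L, 2L),
             Z1 = c(2.1, 1.9, 1.7), Z2 = c(2.3, 2.1, 1.9),
             Z3 = c(2.4, 2.2, 2.0), Z4 = c(2.6, 2.4, 2.1),
             stringsAsFactors = FALSE)
}

# Flat temperature table over a span of years.
fixture_temps <- function(years = 2000:2020, temp = 20.48,
                          source = "mediterranean") {
  annual_temperature(years, rep(temp, length(years)), source)
}

# The published bootstrap-mean coefficient set used for point
# projections (residual SDs are free choices; the projected means do not
# depend on them).
injected_fits <- function(sigma_growth = 0.08, sigma_init = 0.2,
                          sigma_length = 20) {
  list(lm2 = growth_fit("walford_temp", 2.120, slope_Z = 0.7033,
                        slope_T = -0.0631, sigma = sigma_growth),
       lm3 = growth_fit("initial_size", 2.937, slope_T = -0.0718,
                        sigma = sigma_init),
       lm4 = growth_fit("allometry", -74.62, slope_Z = 176.38,
                        sigma = sigma_length))
}

# Simulates pair tables directly (not through the population generator)
# so each regression can be tested in isolation.
sim_pairs <- function(n, beta1, beta2 = 0, alpha0, sigma, temps,
                      z_range = c(1.4, 2.8)) {
  years <- temps$year
  year <- years[1L + (seq_len(n) - 1L) %% length(years)]
  T <- temps$temperature[match(year, temps$year)]
  Z <- runif(n, z_range[1], z_range[2])
  data.frame(fish_id = sprintf("S%04d", seq_len(n)), year = year,
             Z = Z,
             Zprime = beta1 * Z + beta2 * T + alpha0 +
               rnorm(n, 0, sigma))
}

# Small noiseless world: deterministic recursion, temperature the only
# source of variation.
noiseless_config <- function(n_fish = 120L, seed = 42L) {
  truth_config(sigma_growth = 0, sigma_init = 0, sigma_length = 0,
               sd_year = 0, sd_fish = 0, n_fish = n_fish, seed = seed)
}
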