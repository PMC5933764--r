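## Synthetic-data generator: simulates otolith increment panels, fish
## metadata and temperature series with exactly the statistical
## structure the analysis assumes -- the temperature-dependent Walford
## recursion with crossed year/fish random intercepts, an initial-size
## model, and a linear otolith-length allometry -- so every stage of the
## pipeline can be exercised and validated without field data.

#' Configuration of the synthetic world
#'
#' Parameter set defining the data-generating process. Defaults are the
#' published bootstrap-mean coefficients of the growth, initial-size and
#' allometry regressions for Gulf of Lions gilthead seabream; the
#' residual and random-effect SDs, which the source analysis does not
#' print, default to values calibrated to give realistic scatter
#' (growth 0.08 mm, initial size 0.20 mm, length 20 mm; year 0.05 mm,
#' fish 0.04 mm).
#'
#' @param beta1 Walford slope on Z (mm/mm), in (0, 1).
#' @param beta2 temperature slope of annual growth (mm per degree C).
#' @param alpha0 growth-model intercept (mm).
#' @param sigma_growth residual SD of annual growth (mm).
#' @param init_intercept,init_slope initial-size model: radius at first
#'   birthday = `init_intercept + init_slope * T` (mm, mm/degree C).
#' @param sigma_init residual SD of initial size (mm).
#' @param allo_slope,allo_intercept otolith-length allometry (mm/mm, mm).
#' @param sigma_length residual SD of total length (mm).
#' @param sd_year SD of the random year intercept (mm), shared across
#'   fish within a calendar year (crossed design).
#' @param sd_fish SD of the random fish intercept (mm).
#' @param n_fish number of fish (>= 0).
#' @param spawn_years calendar years fish can be spawned in.
#' @param max_age maximum age at capture (years).
#' @param age_weights sampling weights for age at capture 1..max_age;
#'   the default favours ages 1-3, mimicking a catch dominated by young
#'   fish.
#' @param temp_mean,temp_sd mean and SD of annual summer temperature
#'   (degrees C).
#' @param seed master seed; all randomness flows from it, with per-fish
#'   substreams derived deterministically.
#' @return object of class `truth_config` (a validated list).
#' @export
truth_config <- function(beta1 = 0.7033, beta2 = -0.0631,
                         alpha0 = 2.120, sigma_growth = 0.08,
                         init_intercept = 2.937, init_slope = -0.0718,
                         sigma_init = 0.20, allo_slope = 176.38,
                         allo_intercept = -74.62, sigma_length = 20,
                         sd_year = 0.05, sd_fish = 0.04,
                         n_fish = 400L, spawn_years = 2002:2012,
                         max_age = 7L,
                         age_weights = c(25, 30, 25, 10, 5, 3, 2),
                         temp_mean = 20.48, temp_sd = 0.5,
                         seed = 1L) {
  cfg <- list(beta1 = beta1, beta2 = beta2, alpha0 = alpha0,
              sigma_growth = sigma_growth,
              init_intercept = init_intercept, init_slope = init_slope,
              sigma_init = sigma_init, allo_slope = allo_slope,
              allo_intercept = allo_intercept,
              sigma_length = sigma_length, sd_year = sd_year,
              sd_fish = sd_fish, n_fish = as.integer(n_fish),
              spawn_years = as.integer(spawn_years),
              max_age = as.integer(max_age),
              age_weights = age_weights, temp_mean = temp_mean,
              temp_sd = temp_sd, seed = as.integer(seed))
  if (!(cfg$beta1 > 0 && cfg$beta1 < 1)) {
    stop("beta1 must lie in (0, 1)", call. = FALSE)
  }
  sds <- c(cfg$sigma_growth, cfg$sigma_init, cfg$sigma_length,
           cfg$sd_year, cfg$sd_fish, cfg$temp_sd)
  if (any(sds < 0)) stop("SDs must be >= 0", call. = FALSE)
  if (cfg$n_fish < 0) stop("n_fish must be >= 0", call. = FALSE)
  if (length(cfg$spawn_years) < 1L) stop("spawn_years must be non-empty",
                                         call. = FALSE)
  if (length(cfg$age_weights) != cfg$max_age) {
    stop("age_weights must have max_age entries", call. = FALSE)
  }
  class(cfg) <- "truth_config"
  cfg
}

## Years the simulation needs temperatures for: increments can form up
## to max_age - 1 years after the latest spawn year.
.sim_years <- function(config) {
  seq(min(config$spawn_years),
      max(config$spawn_years) + config$max_age - 1L)
}

#' Generate annual (and optionally daily) summer temperatures
#'
#' Annual summer means are drawn i.i.d. Normal(`temp_mean`,
#' `temp_sd`^2) for every year the simulated fish can grow in. With
#' `daily = TRUE` a daily series is also returned: a seasonal sinusoid
#' plus small noise, constructed so its June-August mean reproduces the
#' annual value (for exercising [summer_mean()]).
#'
#' @param config a `truth_config`.
#' @param daily also return a daily series?
#' @param source region label of the output.
#' @return an `annual_temperature` table, or (with `daily = TRUE`) a
#'   list with elements `annual` and `daily`.
#' @export
generate_temperatures <- function(config, daily = FALSE,
                                  source = "mediterranean") {
  years <- .sim_years(config)
  set.seed(config$seed)
  ann <- annual_temperature(
    years, rnorm(length(years), config$temp_mean, config$temp_sd),
    source)
  if (!daily) return(ann)
  amp <- 5
  rows <- lapply(seq_along(years), function(i) {
    y <- years[i]
    dates <- seq(as.Date(sprintf("%d-01-01", y)),
                 as.Date(sprintf("%d-12-31", y)), by = "day")
    doy <- as.integer(format(dates, "%j"))
    shape <- -cos(2 * pi * (doy - 15) / 365)  # peak near early August
    mo <- as.integer(format(dates, "%m"))
    summer_shape_mean <- mean(shape[mo %in% 6:8])
    value <- ann$temperature[i] + amp * (shape - summer_shape_mean) +
      rnorm(length(dates), 0, 0.1)
    data.frame(date = as.character(dates), value = value,
               stringsAsFactors = FALSE)
  })
  list(annual = ann, daily = do.call(rbind, rows))
}

#' Generate a synthetic otolith-increment population
#'
#' Simulates `n_fish` fish by inverting the fitted model structure:
#' spawn year uniform over `spawn_years`; age at capture drawn with
#' `age_weights` (right-truncated lifespans); a shared random year
#' intercept per calendar year and a random fish intercept; radius at
#' the first annulus from the initial-size model at the spawn-year
#' temperature; subsequent radii from the temperature-dependent Walford
#' recursion with residual noise, redrawing any draw that would shrink
#' the otolith (otoliths never shrink; the truncation bias is negligible
#' at the default SDs); total length from the allometry applied to the
#' final radius (the dorsal axis `Z4`). The other radius axes `Z1`-`Z3`
#' are noisier rescalings of `Z4`, so the dorsal axis is the best length
#' predictor by construction.
#'
#' Fish `i`'s trajectory uses a substream seeded deterministically from
#' the master seed, so it is invariant to `n_fish`.
#'
#' @param config a `truth_config`.
#' @param temps optional `annual_temperature` table covering all
#'   formation years (default: regenerated from `config`).
#' @return list with elements `increments` (validated increment table),
#'   `fish` (fish metadata table) and `temps`.
#' @export
generate_population <- function(config, temps = NULL) {
  if (is.null(temps)) temps <- generate_temperatures(config)
  years <- .sim_years(config)
  ti <- match(years, temps$year)
  if (anyNA(ti)) stop("temps do not cover all simulation years",
                      call. = FALSE)
  temp_of <- setNames(temps$temperature[ti], years)
  set.seed(config$seed + 1L)
  year_eff <- setNames(rnorm(length(years), 0, config$sd_year), years)
  fish_seeds <- sample.int(.Machine$integer.max - 1L,
                           max(config$n_fish, 1L))
  inc_rows <- vector("list", config$n_fish)
  fish_rows <- vector("list", config$n_fish)
  draw_positive <- function(mu, sd, lower) {
    # truncated Gaussian by rejection: redraw until above `lower`
    for (i in 1:10000) {
      x <- mu + rnorm(1, 0, sd)
      if (x > lower) return(x)
    }
    stop("rejection sampling failed: growth mean far below current size",
         call. = FALSE)
  }
  for (i in seq_len(config$n_fish)) {
    set.seed(fish_seeds[i])
    spawn <- if (length(config$spawn_years) == 1L) config$spawn_years else
      sample(config$spawn_years, 1L)
    age <- sample.int(config$max_age, 1L, prob = config$age_weights)
    f_eff <- rnorm(1, 0, config$sd_fish)
    radii <- numeric(age)
    mu0 <- config$init_intercept +
      config$init_slope * temp_of[[as.character(spawn)]]
    radii[1L] <- draw_positive(mu0, config$sigma_init, 0)
    if (age > 1L) {
      for (j in 2:age) {
        yr <- spawn + (j - 1L)
        mu <- config$beta1 * radii[j - 1L] +
          config$beta2 * temp_of[[as.character(yr)]] + config$alpha0 +
          year_eff[[as.character(yr)]] + f_eff
        radii[j] <- draw_positive(mu, config$sigma_growth, radii[j - 1L])
      }
    }
    idx <- seq_len(age) - 1L
    inc_rows[[i]] <- data.frame(
      fish_id = sprintf("F%04d", i), spawn_year = spawn,
      increment_index = idx, formation_year = spawn + idx,
      width = c(radii[1L], diff(radii)), cumulative_radius = radii,
      stringsAsFactors = FALSE)
    z4 <- radii[age]
    L <- max(config$allo_slope * z4 + config$allo_intercept +
               rnorm(1, 0, config$sigma_length), 1)
    fish_rows[[i]] <- data.frame(
      fish_id = sprintf("F%04d", i),
      capture_date = sprintf("%d-06-15", spawn + age),
      capture_location = sample(c("lagoon", "gulf"), 1L),
      total_length = L, weight = 1e-5 * L^3 * exp(rnorm(1, 0, 0.1)),
      age_at_capture = age,
      Z1 = 0.80 * z4 + rnorm(1, 0, 0.15),
      Z2 = 0.90 * z4 + rnorm(1, 0, 0.15),
      Z3 = 0.95 * z4 + rnorm(1, 0, 0.15),
      Z4 = z4, stringsAsFactors = FALSE)
  }
  empty_inc <- data.frame(fish_id = character(), spawn_year = integer(),
                          increment_index = integer(),
                          formation_year = integer(), width = numeric(),
                          cumulative_radius = numeric())
  empty_fish <- data.frame(fish_id = character(),
                           capture_date = character(),
                           capture_location = character(),
                           total_length = numeric(), weight = numeric(),
                           age_at_capture = integer(), Z1 = numeric(),
                           Z2 = numeric(), Z3 = numeric(),
                           Z4 = numeric())
  increments <- if (config$n_fish) do.call(rbind, inc_rows) else empty_inc
  fish <- if (config$n_fish) do.call(rbind, fish_rows) else empty_fish
  if (config$n_fish) validate_increments(increments)
  list(increments = increments, fish = fish, temps = temps)
}

#' Expected downstream quantities implied by a truth configuration
#'
#' Computes, in closed form, the von Bertalanffy quantities and per-age
#' moments that the analysis should recover from data generated under
#' `config`: K = -log(beta1), the otolith and length asymptotes at a
#' given temperature, phi-prime, and the exact affine-Gaussian per-age
#' means/SDs ([closed_form_moments()] evaluated at the truth). Used as
#' test and validation expectations.
#'
#' @param config a `truth_config`.
#' @param temperature temperature at which asymptotes and moments are
#'   evaluated (default `config$temp_mean`).
#' @return list with `K`, `Z_inf`, `L_inf`, `phi_prime`, and `moments`
#'   (data frame from [closed_form_moments()]).
#' @export
truth_report <- function(config, temperature = config$temp_mean) {
  gf <- growth_fit("walford_temp", config$alpha0,
                   slope_Z = config$beta1, slope_T = config$beta2,
                   sigma = config$sigma_growth)
  inf <- growth_fit("initial_size", config$init_intercept,
                    slope_T = config$init_slope,
                    sigma = max(config$sigma_init, 1e-12))
  af <- growth_fit("allometry", config$allo_intercept,
                   slope_Z = config$allo_slope,
                   sigma = max(config$sigma_length, 1e-12))
  K <- -log(config$beta1)
  Z_inf <- (config$alpha0 + config$beta2 * temperature) /
    (1 - config$beta1)
  L_inf <- config$allo_slope * Z_inf + config$allo_intercept
  list(K = K, Z_inf = Z_inf, L_inf = L_inf,
       phi_prime = log(K) + 2 * log(L_inf / 10),
       moments = closed_form_moments(inf, gf, af, temperature,
                                     config$max_age))
}
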