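## The cohort integral projection model: a Gaussian growth kernel
## g(Z'|Z; T) advances the otolith-size density one age class,
##   n(Z', t+1) = int g(Z'|Z) n(Z, t) dZ,
## discretized by the midpoint rule on a uniform mesh (the canonical IPM
## discretization). A second Gaussian kernel s(L|Z), the otolith-length
## allometry, maps an otolith-size density to a body-length density.
## The model carries no mortality: every density integrates to 1, and
## distributions are conditional on survival to each age.

#' Construct a uniform midpoint mesh
#'
#' @param z_min,z_max mesh bounds (mm).
#' @param n_nodes number of midpoint nodes (default 500).
#' @return object of class `cipm_mesh`: list with `nodes` (cell
#'   midpoints), `dz` (cell width), `z_min`, `z_max`, `n_nodes`.
#' @export
cipm_mesh <- function(z_min, z_max, n_nodes = 500L) {
  if (!(z_max > z_min)) stop("z_max must exceed z_min", call. = FALSE)
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 2L) stop("need at least 2 mesh nodes", call. = FALSE)
  dz <- (z_max - z_min) / n_nodes
  structure(list(nodes = z_min + (seq_len(n_nodes) - 0.5) * dz,
                 dz = dz, z_min = z_min, z_max = z_max,
                 n_nodes = n_nodes),
            class = "cipm_mesh")
}

.new_size_distribution <- function(mesh, density, age,
                                   variable = "otolith_radius") {
  structure(list(mesh = mesh, density = density, age = age,
                 variable = variable), class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  m <- dist_moments(x)
  cat(sprintf(
    "size distribution (%s) at age %d: mean %.4f, SD %.4f [%d nodes]\n",
    x$variable, x$age, m[["mean"]], m[["sd"]], x$mesh$n_nodes))
  invisible(x)
}

#' Midpoint-rule integral of a size distribution
#' @param dist a `size_distribution`.
#' @return the integral of the density over the mesh (1 for a
#'   normalized distribution).
#' @export
dist_integral <- function(dist) sum(dist$density) * dist$mesh$dz

#' Mean and SD of a size distribution
#' @param dist a `size_distribution`.
#' @return named numeric `c(mean, sd)` computed by midpoint quadrature.
#' @export
dist_moments <- function(dist) {
  w <- dist$density * dist$mesh$dz
  w <- w / sum(w)
  m <- sum(w * dist$mesh$nodes)
  v <- sum(w * (dist$mesh$nodes - m)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' @export
mean.size_distribution <- function(x, ...) dist_moments(x)[["mean"]]

#' @export
plot.size_distribution <- function(x, ...) {
  plot(x$mesh$nodes, x$density, type = "l",
       xlab = if (x$variable == "total_length") "total length (mm)" else
         "otolith radius (mm)",
       ylab = "density (1/mm)", ...)
  invisible(x)
}

## Normalize a density on a mesh; warn when the mesh truncates more than
## `tol` of the mass (a too-narrow mesh silently biases moments).
.normalize_density <- function(density, mesh, tol = 1e-3, what = "density") {
  if (any(!is.finite(density))) {
    stop("non-finite values in projected density", call. = FALSE)
  }
  mass <- sum(density) * mesh$dz
  if (mass <= 0) stop("zero mass on mesh: mesh does not cover the ",
                      what, call. = FALSE)
  if (abs(1 - mass) > tol) {
    warning(sprintf(
      "mesh truncates ~%.3g of the %s mass; widen the mesh",
      abs(1 - mass), what), call. = FALSE)
  }
  density / mass
}

#' Initial (age-1) otolith size distribution
#'
#' Evaluates the Gaussian density implied by the initial-size model --
#' mean b1 T + a0 at the given temperature, SD equal to the fit's
#' residual SD -- on a mesh, and renormalizes. The result is the otolith
#' size distribution at the first birthday (age 1).
#'
#' @param init_fit a `growth_fit` of model `"initial_size"` with
#'   residual SD > 0.
#' @param temperature mean summer temperature, degrees C.
#' @param mesh a `cipm_mesh`, or `NULL` to auto-build one spanning
#'   the mean +/- 8 SD.
#' @param n_nodes nodes for the auto-built mesh.
#' @return a `size_distribution` at age 1.
#' @export
make_initial_distribution <- function(init_fit, temperature, mesh = NULL,
                                      n_nodes = 500L) {
  if (init_fit$model != "initial_size") {
    stop("init_fit must be an initial_size model", call. = FALSE)
  }
  if (!is.finite(init_fit$sigma) || init_fit$sigma <= 0) {
    stop("initial-size fit needs residual SD > 0", call. = FALSE)
  }
  m <- predict(init_fit, data.frame(T = temperature))
  s <- init_fit$sigma
  if (is.null(mesh)) mesh <- cipm_mesh(m - 8 * s, m + 8 * s, n_nodes)
  dens <- dnorm(mesh$nodes, m, s)
  .new_size_distribution(mesh, .normalize_density(dens, mesh,
                                                  what = "initial"), 1L)
}

#' Gaussian growth kernel at a given temperature
#'
#' The transition density g(Z'|Z) = Normal(b1 Z + b2 T + a0, sd^2)
#' evaluated at a fixed temperature. The kernel SD defaults to the
#' residual SD of the growth fit (homoscedastic Gaussian errors).
#'
#' @param growth_fit a `growth_fit` of model `"walford"` or
#'   `"walford_temp"`.
#' @param temperature mean summer temperature, degrees C (ignored for a
#'   temperature-free model).
#' @param sd kernel SD override (mm); default the fit's residual SD.
#' @return object of class `growth_kernel`: list with `slope`,
#'   `intercept` (temperature-collapsed), `sd`, `temperature`.
#' @export
growth_kernel <- function(growth_fit, temperature, sd = NULL) {
  cf <- growth_fit$coefficients
  if (!"slope_Z" %in% names(cf)) {
    stop("growth fit has no slope on Z", call. = FALSE)
  }
  intercept <- cf[["intercept"]] +
    if ("slope_T" %in% names(cf)) cf[["slope_T"]] * temperature else 0
  if (is.null(sd)) sd <- growth_fit$sigma
  if (!is.finite(sd) || sd <= 0) stop("kernel SD must be > 0",
                                      call. = FALSE)
  structure(list(slope = cf[["slope_Z"]], intercept = intercept,
                 sd = sd, temperature = temperature),
            class = "growth_kernel")
}

## K[j, i] = g(nodes_to[j] | nodes_from[i]) * dz_from: one application of
## the midpoint-discretized integral operator is K %*% density.
.kernel_matrix <- function(nodes_to, mu_from, sd_from, dz_from) {
  n_to <- length(nodes_to)
  n_from <- length(mu_from)
  K <- dnorm(matrix(nodes_to, n_to, n_from),
             mean = matrix(mu_from, n_to, n_from, byrow = TRUE),
             sd = matrix(sd_from, n_to, n_from, byrow = TRUE))
  K * dz_from
}

#' Advance a size distribution one age class
#'
#' One application of the midpoint-discretized projection operator:
#' n_{t+1}(z'_j) = sum_i g(z'_j | z_i) n_t(z_i) dz, renormalized, with
#' the age incremented.
#'
#' @param dist a normalized `size_distribution` of otolith radii.
#' @param kernel a `growth_kernel` sharing the distribution's units.
#' @return a `size_distribution` one age older.
#' @export
project_step <- function(dist, kernel) {
  mesh <- dist$mesh
  K <- .kernel_matrix(mesh$nodes,
                      kernel$slope * mesh$nodes + kernel$intercept,
                      kernel$sd, mesh$dz)
  dens <- as.vector(K %*% dist$density)
  .new_size_distribution(mesh, .normalize_density(dens, mesh,
                                                  what = "projected"),
                         dist$age + 1L, dist$variable)
}

## Auto mesh for a cohort projection: cover the initial mean and the
## Walford fixed point, extended by 8 x the larger of the initial SD and
## the stationary kernel SD sd/sqrt(1 - slope^2).
.auto_mesh <- function(init_fit, kernel, temperature, n_nodes) {
  m1 <- predict(init_fit, data.frame(T = temperature))
  s1 <- init_fit$sigma
  s_stat <- if (abs(kernel$slope) < 1) {
    kernel$sd / sqrt(1 - kernel$slope^2)
  } else kernel$sd
  zfix <- if (kernel$slope != 1) {
    kernel$intercept / (1 - kernel$slope)
  } else m1
  pad <- 8 * max(s1, s_stat)
  cipm_mesh(min(m1, zfix) - pad, max(m1, zfix) + pad, n_nodes)
}

#' Project a cohort's otolith size distributions across ages
#'
#' Builds the age-1 distribution from the initial-size model and applies
#' the growth kernel repeatedly: the distribution at age a+1 is the
#' projected distribution at age a. All densities are renormalized (the
#' model has no mortality).
#'
#' @inheritParams make_initial_distribution
#' @param growth_fit a `growth_fit` of model `"walford"` or
#'   `"walford_temp"` with residual SD > 0.
#' @param max_age oldest age class to project to (default 7).
#' @param kernel_sd optional growth-kernel SD override (mm).
#' @return object of class `cipm_projection`: list with `distributions`
#'   (one `size_distribution` per age 1..max_age), `temperature`,
#'   `mesh`, `kernel`.
#' @export
project_cohort <- function(init_fit, growth_fit, temperature,
                           max_age = 7L, mesh = NULL, n_nodes = 500L,
                           kernel_sd = NULL) {
  max_age <- as.integer(max_age)
  if (max_age < 1L) stop("max_age must be >= 1", call. = FALSE)
  kern <- growth_kernel(growth_fit, temperature, sd = kernel_sd)
  if (is.null(mesh)) mesh <- .auto_mesh(init_fit, kern, temperature,
                                        n_nodes)
  dists <- vector("list", max_age)
  dists[[1L]] <- make_initial_distribution(init_fit, temperature, mesh)
  if (max_age > 1L) {
    K <- .kernel_matrix(mesh$nodes,
                        kern$slope * mesh$nodes + kern$intercept,
                        kern$sd, mesh$dz)
    for (a in 2:max_age) {
      dens <- as.vector(K %*% dists[[a - 1L]]$density)
      dists[[a]] <- .new_size_distribution(
        mesh, .normalize_density(dens, mesh, what = "projected"), a)
    }
  }
  structure(list(distributions = dists, temperature = temperature,
                 mesh = mesh, kernel = kern),
            class = "cipm_projection")
}

#' @export
print.cipm_projection <- function(x, ...) {
  cat(sprintf("cIPM projection at T = %.2f C, ages 1-%d (%d nodes)\n",
              x$temperature, length(x$distributions), x$mesh$n_nodes))
  print(summary(x))
  invisible(x)
}

#' @export
summary.cipm_projection <- function(object, ...) {
  mom <- t(vapply(object$distributions, dist_moments, numeric(2)))
  data.frame(age = seq_len(nrow(mom)), mean = mom[, "mean"],
             sd = mom[, "sd"])
}

#' @export
plot.cipm_projection <- function(x, ...) {
  dens <- vapply(x$distributions, function(d) d$density,
                 numeric(x$mesh$n_nodes))
  matplot(x$mesh$nodes, dens, type = "l", lty = 1,
          xlab = "otolith radius (mm)", ylab = "density (1/mm)", ...)
  legend("topleft", legend = paste("age", seq_along(x$distributions)),
         col = seq_along(x$distributions), lty = 1, bty = "n")
  invisible(x)
}

#' Map an otolith-size distribution to a body-length distribution
#'
#' Applies the otolith-length size kernel s(L|Z) -- Gaussian with mean
#' b1 Z + a0 and, by default, constant SD equal to the allometry fit's
#' residual SD -- to an otolith-radius density by midpoint quadrature on
#' a length mesh. With `heteroscedastic = TRUE` and an allometry fitted
#' with the exponential variance function, the kernel SD grows as
#' sigma * exp(gamma/2 * (b1 Z + a0)).
#'
#' @param dist a `size_distribution` of otolith radii.
#' @param allometry a `growth_fit` of model `"allometry"` with residual
#'   SD > 0.
#' @param mesh length mesh (`cipm_mesh`), or `NULL` to auto-build.
#' @param n_nodes nodes for the auto-built length mesh.
#' @param heteroscedastic use the exponential variance function carried
#'   by the allometry fit?
#' @return a `size_distribution` with `variable = "total_length"`, same
#'   age.
#' @export
map_to_length <- function(dist, allometry, mesh = NULL, n_nodes = 500L,
                          heteroscedastic = FALSE) {
  if (dist$variable != "otolith_radius") {
    stop("dist must be an otolith-radius density", call. = FALSE)
  }
  if (allometry$model != "allometry") {
    stop("allometry must be an allometry model", call. = FALSE)
  }
  if (!is.finite(allometry$sigma) || allometry$sigma <= 0) {
    stop("allometry fit needs residual SD > 0", call. = FALSE)
  }
  mu <- predict(allometry, data.frame(Z = dist$mesh$nodes))
  s <- if (heteroscedastic) {
    if (is.null(allometry$variance_model$gamma)) {
      stop("allometry fit carries no variance-function gamma",
           call. = FALSE)
    }
    allometry$sigma * exp(0.5 * allometry$variance_model$gamma * mu)
  } else rep(allometry$sigma, length(mu))
  if (is.null(mesh)) {
    pad <- 8 * max(s)
    mesh <- cipm_mesh(min(mu) - pad, max(mu) + pad, n_nodes)
  }
  K <- .kernel_matrix(mesh$nodes, mu, s, dist$mesh$dz)
  dens <- as.vector(K %*% dist$density)
  .new_size_distribution(mesh, .normalize_density(dens, mesh,
                                                  what = "length"),
                         dist$age, "total_length")
}

#' Closed-form affine-Gaussian moments of the cohort projection
#'
#' With Gaussian kernels of constant SD and affine means, the projected
#' distributions stay Gaussian and their moments obey the exact
#' recursion mu_{a+1} = b1 mu_a + b2 T + a0 and
#' s^2_{a+1} = b1^2 s^2_a + sigma^2; length moments follow by the affine
#' allometry. This is the analytic oracle against which the numerical
#' midpoint-rule projection is checked.
#'
#' @inheritParams project_cohort
#' @param allometry a `growth_fit` of model `"allometry"`.
#' @return data frame with columns `age`, `z_mean`, `z_sd`, `l_mean`,
#'   `l_sd`.
#' @export
closed_form_moments <- function(init_fit, growth_fit, allometry,
                                temperature, max_age = 7L,
                                kernel_sd = NULL) {
  max_age <- as.integer(max_age)
  cf <- growth_fit$coefficients
  slope <- cf[["slope_Z"]]
  intercept <- cf[["intercept"]] +
    if ("slope_T" %in% names(cf)) cf[["slope_T"]] * temperature else 0
  ksd <- if (is.null(kernel_sd)) growth_fit$sigma else kernel_sd
  mu <- numeric(max_age)
  s2 <- numeric(max_age)
  mu[1L] <- predict(init_fit, data.frame(T = temperature))
  s2[1L] <- init_fit$sigma^2
  if (max_age > 1L) {
    for (a in 2:max_age) {
      mu[a] <- slope * mu[a - 1L] + intercept
      s2[a] <- slope^2 * s2[a - 1L] + ksd^2
    }
  }
  a1 <- allometry$coefficients[["slope_Z"]]
  a0 <- allometry$coefficients[["intercept"]]
  data.frame(age = seq_len(max_age), z_mean = mu, z_sd = sqrt(s2),
             l_mean = a1 * mu + a0,
             l_sd = sqrt(a1^2 * s2 + allometry$sigma^2))
}
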