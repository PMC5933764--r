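## The growth_fit S3 class: a light, serializable summary of a fitted
## linear (or mixed) growth model, carrying exactly what the projection
## machinery needs -- named coefficients (intercept, slope_Z, slope_T),
## residual SD, sample size, R^2, coefficient covariance and the variance
## model. Mixed fits subclass it with variance components and marginal R^2.

.new_growth_fit <- function(model, coefficients, sigma, n,
                            r_squared = NA_real_, vcov = NULL,
                            variance_model = list(type = "constant",
                                                  gamma = NULL),
                            logLik = NULL, aic = NA_real_,
                            fitted = NULL, residuals = NULL,
                            response = "Zprime", call = NULL,
                            extra = list()) {
  obj <- c(list(model = model, coefficients = coefficients, sigma = sigma,
                n = n, r_squared = r_squared, vcov = vcov,
                variance_model = variance_model, logLik = logLik,
                aic = aic, fitted = fitted, residuals = residuals,
                response = response, call = call), extra)
  class(obj) <- "growth_fit"
  obj
}

#' Construct a growth model fit from known coefficients
#'
#' Builds a `growth_fit` object directly from coefficient values, without
#' fitting to data. This "coefficient injection" constructor lets
#' published point estimates (e.g. bootstrap-mean regression coefficients)
#' drive the projection machinery when the raw data behind them are not
#' available.
#'
#' @param model one of `"walford"` (Z' on Z), `"walford_temp"` (Z' on Z
#'   and T), `"initial_size"` (Z on T), `"allometry"` (L on Z).
#' @param intercept intercept, response units (mm).
#' @param slope_Z slope on otolith radius Z (mm/mm), if the model has one.
#' @param slope_T slope on summer temperature (mm per degree C), if the
#'   model has one.
#' @param sigma residual standard deviation, response units; must be > 0
#'   for use as a projection kernel SD.
#' @param n nominal sample size (optional).
#' @return object of class `growth_fit`.
#' @examples
#' lm2 <- growth_fit("walford_temp", intercept = 2.120,
#'                   slope_Z = 0.7033, slope_T = -0.0631, sigma = 0.08)
#' coef(lm2)
#' @export
growth_fit <- function(model = c("walford", "walford_temp", "initial_size",
                                 "allometry"),
                       intercept, slope_Z = NULL, slope_T = NULL,
                       sigma, n = NA_integer_) {
  model <- match.arg(model)
  need <- switch(model,
                 walford = c(Z = TRUE, T = FALSE),
                 walford_temp = c(Z = TRUE, T = TRUE),
                 initial_size = c(Z = FALSE, T = TRUE),
                 allometry = c(Z = TRUE, T = FALSE))
  cf <- c(intercept = as.numeric(intercept))
  if (need[["Z"]]) {
    if (is.null(slope_Z)) stop("model '", model, "' needs slope_Z",
                               call. = FALSE)
    cf <- c(cf, slope_Z = as.numeric(slope_Z))
  }
  if (need[["T"]]) {
    if (is.null(slope_T)) stop("model '", model, "' needs slope_T",
                               call. = FALSE)
    cf <- c(cf, slope_T = as.numeric(slope_T))
  }
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0",
                                           call. = FALSE)
  resp <- if (model == "allometry") "L" else
    if (model == "initial_size") "Z" else "Zprime"
  .new_growth_fit(model, cf, as.numeric(sigma), as.integer(n),
                  response = resp, call = match.call())
}

## Wrap a stats::lm into a growth_fit, renaming coefficients onto the
## domain vocabulary. `map` is c(lm_name = domain_name).
.from_lm <- function(fit, model, map, response, call) {
  cf <- coef(fit)
  names(cf) <- map[names(cf)]
  vc <- vcov(fit)
  dimnames(vc) <- list(map[rownames(vc)], map[colnames(vc)])
  sm <- summary(fit)
  .new_growth_fit(model, cf[c("intercept",
                              intersect(c("slope_Z", "slope_T"), names(cf)))],
                  sigma = sm$sigma, n = nobs(fit),
                  r_squared = sm$r.squared, vcov = vc,
                  logLik = logLik(fit), aic = AIC(fit),
                  fitted = unname(fitted(fit)),
                  residuals = unname(residuals(fit)),
                  response = response, call = call)
}

.check_nondegenerate <- function(x, what) {
  if (length(unique(x)) < 2L) {
    stop(sprintf("singular fit: %s has no variation", what), call. = FALSE)
  }
}

#' Fit the baseline Walford growth model (Z' ~ Z)
#'
#' Ordinary least-squares regression of otolith radius at year t (`Zprime`)
#' on radius at year t-1 (`Z`): the size-size (Walford) growth model
#' Z' = b1 Z + a0 + e. Its slope and intercept map to von Bertalanffy
#' parameters via [vb_transform()].
#'
#' @param pairs a `growth_pairs` table (see [build_growth_pairs()]) with
#'   at least 3 rows.
#' @return object of class `growth_fit` (model `"walford"`).
#' @seealso [fit_walford_temp()], [vb_transform()]
#' @export
fit_walford <- function(pairs) {
  if (nrow(pairs) < 3L) stop("need at least 3 growth pairs", call. = FALSE)
  .check_nondegenerate(pairs$Z, "Z")
  fit <- lm(Zprime ~ Z, data = pairs)
  .from_lm(fit, "walford",
           c("(Intercept)" = "intercept", Z = "slope_Z"),
           "Zprime", match.call())
}

#' Fit the temperature-dependent Walford growth model (Z' ~ Z + T)
#'
#' As [fit_walford()] with the mean summer temperature of the year of
#' increment formation as an additional covariate:
#' Z' = b1 Z + b2 T + a0 + e. This is the growth kernel model of the
#' cohort projection. Temperatures are joined onto pairs by formation
#' year; a pair year with no temperature value is an error listing the
#' offending years.
#'
#' @inheritParams fit_walford
#' @param temps an `annual_temperature` table.
#' @param source temperature source to join (default `"mediterranean"`).
#' @return object of class `growth_fit` (model `"walford_temp"`).
#' @export
fit_walford_temp <- function(pairs, temps, source = "mediterranean") {
  if (nrow(pairs) < 3L) stop("need at least 3 growth pairs", call. = FALSE)
  df <- .join_temperature(as.data.frame(pairs), temps, source)
  .check_nondegenerate(df$Z, "Z")
  .check_nondegenerate(df$T, "temperature")
  fit <- lm(Zprime ~ Z + T, data = df)
  out <- .from_lm(fit, "walford_temp",
                  c("(Intercept)" = "intercept", Z = "slope_Z",
                    T = "slope_T"), "Zprime", match.call())
  out$temperature_source <- source
  out
}

#' Fit the initial otolith size model (Z ~ T)
#'
#' Regression of otolith radius at the first annulus (age-0 growth, i.e.
#' size at the first birthday) on the summer temperature of the formation
#' year: Z = b1 T + a0 + e. Together with its residual SD this defines the
#' initial (age-1) size distribution of the cohort projection.
#'
#' @param first data frame with columns `year` and `Z`
#'   (see [first_increments()]).
#' @inheritParams fit_walford_temp
#' @return object of class `growth_fit` (model `"initial_size"`).
#' @export
fit_initial_size <- function(first, temps, source = "mediterranean") {
  if (nrow(first) < 3L) stop("need at least 3 first increments",
                             call. = FALSE)
  df <- .join_temperature(first, temps, source)
  .check_nondegenerate(df$T, "temperature")
  fit <- lm(Z ~ T, data = df)
  out <- .from_lm(fit, "initial_size",
                  c("(Intercept)" = "intercept", T = "slope_T"),
                  "Z", match.call())
  out$temperature_source <- source
  out
}

#' Fit the otolith-radius to body-size allometry (L ~ Z)
#'
#' Linear allometry between the otolith radius at capture and total fish
#' length (mm) or weight (g): L = b1 Z + a0 + e. The default is ordinary
#' least squares; `variance_model = "exp_in_covariate"` fits a generalized
#' least-squares model with residual variance proportional to
#' exp(gamma * fitted value) (the exponential variance function), with
#' gamma estimated.
#'
#' @param fish fish metadata table (see [read_fish()]).
#' @param response `"length"` (total length) or `"weight"`.
#' @param radius which radius column to use as predictor (default `"Z4"`,
#'   the dorsal growth axis).
#' @param variance_model `"constant"` or `"exp_in_covariate"`.
#' @return object of class `growth_fit` (model `"allometry"`); the
#'   `variance_model` field carries the estimated `gamma` when the
#'   exponential variance function is used.
#' @export
fit_allometry <- function(fish, response = c("length", "weight"),
                          radius = "Z4",
                          variance_model = c("constant",
                                             "exp_in_covariate")) {
  response <- match.arg(response)
  variance_model <- match.arg(variance_model)
  ycol <- if (response == "length") "total_length" else "weight"
  df <- data.frame(y = fish[[ycol]], Z = fish[[radius]])
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 3L) stop("need at least 3 complete (Z, response) pairs",
                          call. = FALSE)
  .check_nondegenerate(df$Z, radius)
  if (variance_model == "constant") {
    fit <- lm(y ~ Z, data = df)
    out <- .from_lm(fit, "allometry",
                    c("(Intercept)" = "intercept", Z = "slope_Z"),
                    "L", match.call())
  } else {
    fit <- tryCatch(
      nlme::gls(y ~ Z, data = df,
                weights = nlme::varExp(form = ~ fitted(.)),
                control = nlme::glsControl(maxIter = 200L,
                                           msMaxIter = 200L)),
      error = function(e) stop(
        "exponential-variance fit did not converge: ",
        conditionMessage(e), call. = FALSE))
    cf <- coef(fit)
    names(cf) <- c("intercept", "slope_Z")
    vc <- vcov(fit)
    dimnames(vc) <- list(names(cf), names(cf))
    delta <- unname(coef(fit$modelStruct$varStruct))
    ss <- 1 - sum(residuals(fit)^2) / sum((df$y - mean(df$y))^2)
    out <- .new_growth_fit(
      "allometry", cf, sigma = fit$sigma, n = nrow(df),
      r_squared = ss, vcov = vc,
      variance_model = list(type = "exp_in_covariate", gamma = 2 * delta),
      logLik = logLik(fit), aic = AIC(fit),
      fitted = unname(fitted(fit)), residuals = unname(residuals(fit)),
      response = "L", call = match.call())
  }
  out$response_label <- response
  out$radius <- radius
  out
}

#' Select the otolith radius axis that best predicts body length
#'
#' Regresses total fish length on each of the four radius measures
#' (`Z1`-`Z4`, the natural growth axes of the sagittal otolith) separately
#' and returns the axis with the greatest R-squared. Ties are broken in
#' favour of the lowest axis index, deterministically. An axis that is
#' entirely missing is excluded with a warning.
#'
#' @param fish fish metadata table with columns `total_length` and
#'   `Z1`..`Z4`.
#' @param axes candidate radius columns, in tie-break order.
#' @return object of class `radius_selection`: list with `axis` (the
#'   winning column name) and `r_squared` (named vector over axes).
#' @export
select_best_radius <- function(fish, axes = c("Z1", "Z2", "Z3", "Z4")) {
  r2 <- setNames(rep(NA_real_, length(axes)), axes)
  for (ax in axes) {
    if (!ax %in% names(fish) || all(is.na(fish[[ax]]))) {
      warning(sprintf("axis %s entirely missing; excluded", ax),
              call. = FALSE)
      next
    }
    df <- data.frame(L = fish$total_length, Z = fish[[ax]])
    df <- df[complete.cases(df), , drop = FALSE]
    if (nrow(df) < 3L) {
      warning(sprintf("axis %s has < 3 complete pairs; excluded", ax),
              call. = FALSE)
      next
    }
    r2[ax] <- summary(lm(L ~ Z, data = df))$r.squared
  }
  if (all(is.na(r2))) stop("no usable radius axis", call. = FALSE)
  best <- axes[which.max(r2)]   # which.max: first maximum -> lowest index
  structure(list(axis = best, r_squared = r2), class = "radius_selection")
}

#' @export
print.radius_selection <- function(x, ...) {
  cat("Radius selection (L ~ Z per axis)\n")
  print(round(x$r_squared, 4))
  cat("selected axis:", x$axis, "\n")
  invisible(x)
}

## ------------------------------------------------------------------
## growth_fit methods

#' @export
print.growth_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Growth model fit ('%s'), n = %s\n", x$model,
              ifelse(is.na(x$n), "?", x$n)))
  print(round(x$coefficients, digits))
  cat(sprintf("residual SD: %s", format(x$sigma, digits = digits)))
  if (!is.null(x$variance_model$gamma)) {
    cat(sprintf("  (Var ~ exp(%s * fitted))",
                format(x$variance_model$gamma, digits = digits)))
  }
  cat("\n")
  if (is.finite(x$r_squared)) {
    cat(sprintf("R-squared: %s\n", format(x$r_squared, digits = digits)))
  }
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$coefficients

#' @export
vcov.growth_fit <- function(object, ...) object$vcov

#' @export
nobs.growth_fit <- function(object, ...) object$n

#' @export
logLik.growth_fit <- function(object, ...) {
  if (is.null(object$logLik)) {
    stop("no log-likelihood stored (coefficient-injected fit)",
         call. = FALSE)
  }
  object$logLik
}

#' @export
residuals.growth_fit <- function(object, ...) object$residuals

#' @export
fitted.growth_fit <- function(object, ...) object$fitted

## Linear predictor on new data; columns are looked up by role: Z for
## radius-type predictors, T for temperature.
#' @export
predict.growth_fit <- function(object, newdata, ...) {
  cf <- object$coefficients
  mu <- rep(cf[["intercept"]], nrow(newdata))
  if ("slope_Z" %in% names(cf)) {
    if (!"Z" %in% names(newdata)) stop("newdata needs a Z column",
                                       call. = FALSE)
    mu <- mu + cf[["slope_Z"]] * newdata$Z
  }
  if ("slope_T" %in% names(cf)) {
    if (!"T" %in% names(newdata)) stop("newdata needs a T column",
                                       call. = FALSE)
    mu <- mu + cf[["slope_T"]] * newdata$T
  }
  mu
}

#' Simulate responses from a fitted growth model
#'
#' Draws Gaussian responses at the linear predictor for new data, using
#' the fitted residual SD (and the exponential variance function when the
#' fit carries one).
#'
#' @param object a `growth_fit`.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param newdata data frame with the covariate columns the model needs
#'   (`Z` and/or `T`).
#' @param ... unused.
#' @return data frame with `nsim` columns of simulated responses.
#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL,
                                newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, newdata)
  s <- if (identical(object$variance_model$type, "exp_in_covariate")) {
    object$sigma * exp(0.5 * object$variance_model$gamma * mu)
  } else rep(object$sigma, length(mu))
  draws <- matrix(rnorm(length(mu) * nsim, mu, s), nrow = length(mu))
  out <- as.data.frame(draws)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
summary.growth_fit <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov)) else
    rep(NA_real_, length(object$coefficients))
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = se[names(object$coefficients)])
  structure(list(model = object$model, coefficients = tab,
                 sigma = object$sigma, n = object$n,
                 r_squared = object$r_squared,
                 variance_model = object$variance_model,
                 aic = object$aic),
            class = "summary.growth_fit")
}

#' @export
print.summary.growth_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Growth model '%s' (n = %s)\n", x$model,
              ifelse(is.na(x$n), "?", x$n)))
  print(round(x$coefficients, digits))
  cat(sprintf("residual SD %s", format(x$sigma, digits = digits)))
  if (is.finite(x$r_squared)) {
    cat(sprintf(", R-squared %s", format(x$r_squared, digits = digits)))
  }
  if (is.finite(x$aic)) cat(sprintf(", AIC %s", format(x$aic, digits = 6)))
  cat("\n")
  invisible(x)
}
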