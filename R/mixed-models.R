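## Linear mixed-effects growth models with crossed year and fish random
## intercepts, fitted by maximum likelihood so AIC is comparable across
## fixed-effects structures (REML likelihoods are not).

#' Fit a mixed-effects Walford growth model
#'
#' Fits Z' = b1 Z (+ b2 T) + a0 with optional crossed random intercepts
#' for formation year and for individual fish, by maximum likelihood
#' (`REML = FALSE`) via \pkg{lme4}. With both random effects off the
#' model degenerates to the corresponding fixed-effects fit
#' ([fit_walford()] or [fit_walford_temp()]) and that `growth_fit` is
#' returned. A variance component estimated at the boundary (zero) is
#' returned with `boundary = TRUE`, not treated as an error.
#'
#' The marginal R-squared reported is the Nakagawa-Schielzeth ratio of
#' fixed-effects variance to total variance (fixed + year + fish +
#' residual).
#'
#' @inheritParams fit_walford_temp
#' @param temps optional `annual_temperature` table; when supplied,
#'   summer temperature of the formation year enters as a fixed effect.
#' @param random_year include a random intercept per formation year?
#' @param random_fish include a random intercept per fish?
#' @return object of class `mixed_growth_fit` (inherits `growth_fit`)
#'   with fields `sd_year`, `sd_fish`, `marginal_r2`, `boundary`; or a
#'   plain `growth_fit` when both random effects are off.
#' @export
fit_mixed_growth <- function(pairs, temps = NULL,
                             source = "mediterranean",
                             random_year = TRUE, random_fish = TRUE) {
  if (!random_year && !random_fish) {
    return(if (is.null(temps)) fit_walford(pairs) else
             fit_walford_temp(pairs, temps, source))
  }
  df <- as.data.frame(pairs)
  if (!is.null(temps)) df <- .join_temperature(df, temps, source)
  if (random_year && length(unique(df$year)) < 2L) {
    stop("random year effect needs >= 2 years", call. = FALSE)
  }
  if (random_fish && length(unique(df$fish_id)) < 2L) {
    stop("random fish effect needs >= 2 fish", call. = FALSE)
  }
  fx <- if (is.null(temps)) "Zprime ~ Z" else "Zprime ~ Z + T"
  re <- c(if (random_year) "(1 | year)", if (random_fish) "(1 | fish_id)")
  form <- stats::as.formula(paste(fx, "+", paste(re, collapse = " + ")))
  fit <- lme4::lmer(form, data = df, REML = FALSE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore"))
  fe <- lme4::fixef(fit)
  map <- c("(Intercept)" = "intercept", Z = "slope_Z", T = "slope_T")
  names(fe) <- map[names(fe)]
  vc <- as.matrix(vcov(fit))
  dimnames(vc) <- list(names(fe), names(fe))
  vcs <- as.data.frame(lme4::VarCorr(fit))
  getsd <- function(g) {
    i <- which(vcs$grp == g)
    if (length(i)) vcs$sdcor[i] else 0
  }
  sd_year <- if (random_year) getsd("year") else 0
  sd_fish <- if (random_fish) getsd("fish_id") else 0
  sigma <- vcs$sdcor[vcs$grp == "Residual"]
  mu <- as.vector(model.matrix(fit) %*% lme4::fixef(fit))
  var_fixed <- sum((mu - mean(mu))^2) / length(mu)
  mr2 <- var_fixed / (var_fixed + sd_year^2 + sd_fish^2 + sigma^2)
  out <- .new_growth_fit(
    if (is.null(temps)) "walford" else "walford_temp",
    fe, sigma = sigma, n = nrow(df),
    vcov = vc, logLik = logLik(fit), aic = AIC(fit),
    fitted = unname(fitted(fit)), residuals = unname(residuals(fit)),
    response = "Zprime", call = match.call(),
    extra = list(sd_year = sd_year, sd_fish = sd_fish,
                 marginal_r2 = mr2,
                 boundary = lme4::isSingular(fit, tol = 1e-5),
                 random_year = random_year, random_fish = random_fish,
                 temperature_source = if (is.null(temps)) NULL else source))
  class(out) <- c("mixed_growth_fit", "growth_fit")
  out
}

#' @export
print.mixed_growth_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Mixed-effects growth model ('%s', ML), n = %d\n",
              x$model, x$n))
  cat("fixed effects:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("random intercept SDs: year %s, fish %s; residual SD %s%s\n",
              format(x$sd_year, digits = digits),
              format(x$sd_fish, digits = digits),
              format(x$sigma, digits = digits),
              if (isTRUE(x$boundary)) " [boundary]" else ""))
  cat(sprintf("marginal R-squared %s, AIC %s\n",
              format(x$marginal_r2, digits = digits),
              format(x$aic, digits = 6)))
  invisible(x)
}

#' Compare growth models by AIC
#'
#' Tabulates AIC, delta-AIC (difference from the minimum-AIC model) and
#' R-squared (marginal R-squared for mixed fits) for a set of models
#' fitted to the same response rows. Models fitted to different numbers
#' of rows are not AIC-comparable and raise an error.
#'
#' @param fits named list of `growth_fit` / `mixed_growth_fit` objects.
#' @return data frame of class `model_comparison` with columns `model`,
#'   `aic`, `delta_aic`, `r2`, sorted by AIC.
#' @export
compare_models <- function(fits) {
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  ns <- vapply(fits, function(f) as.integer(f$n), integer(1))
  if (length(unique(ns)) > 1L) {
    stop("models fitted to different n are not AIC-comparable: ",
         paste(sprintf("%s (n=%d)", names(fits), ns), collapse = ", "),
         call. = FALSE)
  }
  aic <- vapply(fits, function(f) as.numeric(f$aic), numeric(1))
  if (any(!is.finite(aic))) stop("all fits need a finite AIC",
                                 call. = FALSE)
  r2 <- vapply(fits, function(f) {
    if (!is.null(f$marginal_r2)) f$marginal_r2 else f$r_squared
  }, numeric(1))
  out <- data.frame(model = names(fits), aic = aic,
                    delta_aic = aic - min(aic), r2 = r2,
                    stringsAsFactors = FALSE)
  out <- out[order(out$aic), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, digits = 4, ...) {
  cat("Model comparison (ML fits, same data)\n")
  y <- as.data.frame(x)
  y$aic <- round(y$aic, 2)
  y$delta_aic <- round(y$delta_aic, 2)
  y$r2 <- round(y$r2, digits)
  print(y)
  invisible(x)
}

#' Derive von Bertalanffy growth parameters from a Walford fit
#'
#' Maps the Walford regression Z' = b1 Z + a0 to the von Bertalanffy
#' parameterization: growth coefficient K = -log(b1) (per year), the
#' asymptotic otolith radius Z_inf = a0 / (1 - b1) (the fixed point where
#' Z' = Z), the asymptotic body length L_inf obtained by applying the
#' otolith-length allometry at Z_inf, and the growth-performance index
#' phi' = ln K + 2 ln L_inf with L_inf expressed in centimetres (the
#' convention under which published phi' values for sparids are
#' comparable).
#'
#' @param walford a `growth_fit` of model `"walford"` or
#'   `"walford_temp"` (for the latter the temperature term is not used;
#'   supply the intercept at a chosen temperature via
#'   [growth_fit()] if a temperature-specific asymptote is wanted).
#' @param allometry a `growth_fit` of model `"allometry"` on length.
#' @return object of class `vb_params`: list with `K` (1/yr), `Z_inf`
#'   (mm), `L_inf` (mm), `phi_prime`.
#' @examples
#' w <- growth_fit("walford", intercept = 0.8154, slope_Z = 0.7097,
#'                 sigma = 0.08)
#' a <- growth_fit("allometry", intercept = -74.1, slope_Z = 176.1,
#'                 sigma = 20)
#' vb_transform(w, a)
#' @export
vb_transform <- function(walford, allometry) {
  slope <- walford$coefficients[["slope_Z"]]
  if (!is.finite(slope) || slope <= 0 || slope >= 1) {
    stop(sprintf(
      "Walford slope %.4f outside (0, 1): no finite asymptote", slope),
      call. = FALSE)
  }
  K <- -log(slope)
  Z_inf <- walford$coefficients[["intercept"]] / (1 - slope)
  L_inf <- allometry$coefficients[["slope_Z"]] * Z_inf +
    allometry$coefficients[["intercept"]]
  if (L_inf <= 0) stop("allometry gives non-positive L_inf", call. = FALSE)
  phi_prime <- log(K) + 2 * log(L_inf / 10)  # L_inf in cm
  structure(list(K = K, Z_inf = Z_inf, L_inf = L_inf,
                 phi_prime = phi_prime), class = "vb_params")
}

#' @export
print.vb_params <- function(x, digits = 4, ...) {
  cat("von Bertalanffy parameters (from Walford fit)\n")
  cat(sprintf("  K         = %s / yr\n", format(x$K, digits = digits)))
  cat(sprintf("  Z_inf     = %s mm\n", format(x$Z_inf, digits = digits)))
  cat(sprintf("  L_inf     = %s mm\n", format(x$L_inf, digits = digits)))
  cat(sprintf("  phi-prime = %s (L_inf in cm)\n",
              format(x$phi_prime, digits = digits)))
  invisible(x)
}
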