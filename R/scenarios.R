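## Temperature-scenario projection and bootstrap uncertainty. A
## scenario_result holds, per scenario and age, the mean and SD of the
## projected total-length distribution plus (for bootstrapped runs) a
## percentile 95% CI of the mean across replicates and a 95% prediction
## interval from the pooled mixture of per-replicate Gaussian predictive
## distributions.

.default_scenarios <- function(reference_T = 20.48,
                               offsets = c(minus1 = -1, reference = 0,
                                           plus1 = 1)) {
  setNames(reference_T + offsets, names(offsets))
}

.scenario_result <- function(summary, temperatures, B, B_used, seed,
                             discarded) {
  ref <- summary[summary$scenario == "reference", c("age", "mean")]
  pc <- summary[, c("scenario", "age", "mean")]
  pc$percent_change <- 100 *
    (ref$mean[match(pc$age, ref$age)] - pc$mean) /
    ref$mean[match(pc$age, ref$age)]
  pc$mean <- NULL
  structure(list(summary = summary, percent_change = pc,
                 temperatures = temperatures, B = B, B_used = B_used,
                 seed = seed, discarded = discarded),
            class = "scenario_result")
}

#' Point-estimate scenario projection
#'
#' Runs the cohort projection and length mapping once per temperature
#' scenario with the supplied (typically coefficient-injected) fits and
#' summarizes the total-length distribution per age. With fixed
#' coefficients there is no parameter uncertainty: the confidence
#' interval degenerates to the point estimate and the prediction
#' interval is the Gaussian 95% band of the length distribution.
#'
#' @param init_fit initial-size model (`growth_fit`, `"initial_size"`).
#' @param growth_fit growth model (`growth_fit`, `"walford"` or
#'   `"walford_temp"`).
#' @param allometry otolith-length allometry (`growth_fit`,
#'   `"allometry"`).
#' @param temperatures named vector of scenario temperatures (degrees C);
#'   the scenario named `"reference"` anchors percent changes. Default
#'   reference 20.48 with +/- 1 degree scenarios.
#' @param max_age oldest age class (default 7).
#' @param mesh optional otolith-radius `cipm_mesh`.
#' @param n_nodes mesh resolution (default 500).
#' @param heteroscedastic heteroscedastic length kernel? (see
#'   [map_to_length()]).
#' @return object of class `scenario_result`.
#' @examples
#' lm2 <- growth_fit("walford_temp", 2.120, slope_Z = 0.7033,
#'                   slope_T = -0.0631, sigma = 0.08)
#' lm3 <- growth_fit("initial_size", 2.937, slope_T = -0.0718,
#'                   sigma = 0.2)
#' lm4 <- growth_fit("allometry", -74.62, slope_Z = 176.38, sigma = 20)
#' res <- project_scenarios(lm3, lm2, lm4, max_age = 3)
#' compare_scenarios(res, ages = 2:3)
#' @export
project_scenarios <- function(init_fit, growth_fit, allometry,
                              temperatures = .default_scenarios(),
                              max_age = 7L, mesh = NULL, n_nodes = 500L,
                              heteroscedastic = FALSE) {
  if (is.null(names(temperatures)) ||
      !"reference" %in% names(temperatures)) {
    stop("temperatures must be named and include 'reference'",
         call. = FALSE)
  }
  rows <- list()
  for (sc in names(temperatures)) {
    proj <- project_cohort(init_fit, growth_fit, temperatures[[sc]],
                           max_age = max_age, mesh = mesh,
                           n_nodes = n_nodes)
    for (a in seq_len(max_age)) {
      ld <- map_to_length(proj$distributions[[a]], allometry,
                          n_nodes = n_nodes,
                          heteroscedastic = heteroscedastic)
      m <- dist_moments(ld)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, temperature = temperatures[[sc]], age = a,
        mean = m[["mean"]], sd = m[["sd"]],
        ci_lo = m[["mean"]], ci_hi = m[["mean"]],
        pi_lo = m[["mean"]] - qnorm(0.975) * m[["sd"]],
        pi_hi = m[["mean"]] + qnorm(0.975) * m[["sd"]],
        stringsAsFactors = FALSE)
    }
  }
  .scenario_result(do.call(rbind, rows), temperatures, B = 1L,
                   B_used = 1L, seed = NA_integer_, discarded = 0L)
}

## Quantile of a Gaussian mixture with equal weights, by root-finding on
## the mixture CDF.
.mixture_quantile <- function(p, means, sds) {
  lo <- min(means - 10 * max(sds))
  hi <- max(means + 10 * max(sds))
  uniroot(function(x) mean(pnorm(x, means, sds)) - p, c(lo, hi),
          tol = 1e-8)$root
}

#' Bootstrap scenario projection
#'
#' Propagates parameter uncertainty through the cohort projection by
#' nonparametric case resampling: each replicate resamples the
#' growth-pair table, the first-increment table and the fish table
#' independently, refits the temperature-dependent growth model, the
#' initial-size model and the allometry, and reruns the projection and
#' length mapping for every temperature scenario. Per scenario and age,
#' the summary reports the mean of replicate means, the mean of
#' replicate SDs, the percentile 95% CI of the mean across replicates,
#' and a 95% prediction interval from the pooled mixture of the
#' per-replicate Gaussian predictive distributions (parameter plus
#' residual uncertainty).
#'
#' Growth pairs are not independent rows: pairs sharing a formation
#' year share that year's growth anomaly, and pairs within a fish share
#' its individual effect. The pair table is therefore resampled in
#' whole clusters, by default calendar years (`resample_pairs =
#' "year"`), which restores near-nominal CI coverage when year-to-year
#' growth variation is present; `"fish"` clusters on individuals and
#' `"row"` gives the plain iid-row bootstrap (anti-conservative under
#' shared year effects). The first-increment and fish tables are
#' resampled by row (their model errors are independent across rows).
#'
#' Replicates with a singular fit are discarded and counted; more than
#' 5% discards is an error. Each replicate runs on a deterministic
#' substream derived from `seed`, so identical seeds and inputs give
#' identical results.
#'
#' @param pairs `growth_pairs` table.
#' @param first first-increment table (see [first_increments()]).
#' @param fish fish metadata table.
#' @param temps `annual_temperature` table.
#' @param temperatures named scenario temperatures including
#'   `"reference"`.
#' @param B number of bootstrap replicates (>= 1; the full analysis uses
#'   10000, scale down for exploration).
#' @param seed integer seed for the resampling.
#' @param source temperature source joined to pairs.
#' @param radius radius column used for the allometry (default `"Z4"`).
#' @param max_age,n_nodes projection settings (see
#'   [project_scenarios()]).
#' @param resample_pairs resampling unit for the growth-pair table:
#'   `"year"` (cluster on formation year, default), `"fish"` (cluster
#'   on individual) or `"row"`.
#' @return object of class `scenario_result`; `summary` is a tidy data
#'   frame (scenario, temperature, age, mean, sd, ci_lo, ci_hi, pi_lo,
#'   pi_hi), `percent_change` the per-age reduction relative to the
#'   reference scenario.
#' @export
bootstrap_projection <- function(pairs, first, fish, temps,
                                 temperatures = .default_scenarios(),
                                 B = 1000L, seed = 1L,
                                 source = "mediterranean",
                                 radius = "Z4", max_age = 7L,
                                 n_nodes = 500L,
                                 resample_pairs = c("year", "fish",
                                                    "row")) {
  resample_pairs <- match.arg(resample_pairs)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  if (is.null(names(temperatures)) ||
      !"reference" %in% names(temperatures)) {
    stop("temperatures must be named and include 'reference'",
         call. = FALSE)
  }
  max_age <- as.integer(max_age)
  n_sc <- length(temperatures)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, B)
  means <- array(NA_real_, c(B, n_sc, max_age),
                 dimnames = list(NULL, names(temperatures), NULL))
  sds <- means
  discarded <- 0L
  pairs <- as.data.frame(pairs)
  cluster_idx <- switch(resample_pairs,
                        year = split(seq_len(nrow(pairs)), pairs$year),
                        fish = split(seq_len(nrow(pairs)),
                                     pairs$fish_id),
                        row = NULL)
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    pb <- if (is.null(cluster_idx)) {
      pairs[sample.int(nrow(pairs), replace = TRUE), , drop = FALSE]
    } else {
      picked <- sample.int(length(cluster_idx),
                           length(cluster_idx), replace = TRUE)
      pairs[unlist(cluster_idx[picked], use.names = FALSE), ,
            drop = FALSE]
    }
    fb <- first[sample.int(nrow(first), replace = TRUE), , drop = FALSE]
    hb <- fish[sample.int(nrow(fish), replace = TRUE), , drop = FALSE]
    fits <- tryCatch(list(
      lm2 = fit_walford_temp(pb, temps, source),
      lm3 = fit_initial_size(fb, temps, source),
      lm4 = fit_allometry(hb, "length", radius, "constant")),
      error = function(e) NULL)
    if (is.null(fits) ||
        any(!is.finite(unlist(lapply(fits, coef)))) ||
        fits$lm2$sigma <= 0 || fits$lm3$sigma <= 0 ||
        fits$lm4$sigma <= 0) {
      discarded <- discarded + 1L
      next
    }
    for (s in seq_len(n_sc)) {
      proj <- project_cohort(fits$lm3, fits$lm2, temperatures[[s]],
                             max_age = max_age, n_nodes = n_nodes)
      for (a in seq_len(max_age)) {
        ld <- map_to_length(proj$distributions[[a]], fits$lm4,
                            n_nodes = n_nodes)
        m <- dist_moments(ld)
        means[b, s, a] <- m[["mean"]]
        sds[b, s, a] <- m[["sd"]]
      }
    }
  }
  if (discarded > 0.05 * B) {
    stop(sprintf("%d of %d bootstrap replicates had singular fits",
                 discarded, B), call. = FALSE)
  }
  keep <- !is.na(means[, 1L, 1L])
  rows <- list()
  for (s in seq_len(n_sc)) {
    for (a in seq_len(max_age)) {
      mm <- means[keep, s, a]
      ss <- sds[keep, s, a]
      ci <- if (length(mm) > 1L) {
        unname(quantile(mm, c(0.025, 0.975), type = 7))
      } else c(mm, mm)
      pi <- c(.mixture_quantile(0.025, mm, ss),
              .mixture_quantile(0.975, mm, ss))
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = names(temperatures)[s],
        temperature = temperatures[[s]], age = a,
        mean = mean(mm), sd = mean(ss),
        ci_lo = ci[1L], ci_hi = ci[2L],
        pi_lo = pi[1L], pi_hi = pi[2L], stringsAsFactors = FALSE)
    }
  }
  .scenario_result(do.call(rbind, rows), temperatures, B = B,
                   B_used = sum(keep), seed = as.integer(seed),
                   discarded = discarded)
}

#' Percent change in mean length relative to the reference scenario
#'
#' @param result a `scenario_result`.
#' @param ages ages to report (default all projected ages).
#' @return data frame with columns `scenario`, `age`, `percent_change`
#'   (100 x (reference mean - scenario mean) / reference mean; positive
#'   means smaller fish than under the reference temperature).
#' @export
compare_scenarios <- function(result, ages = NULL) {
  pc <- result$percent_change
  if (is.null(ages)) return(pc)
  bad <- setdiff(ages, unique(pc$age))
  if (length(bad)) {
    stop("age(s) beyond projected range: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- pc[pc$age %in% ages, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.scenario_result <- function(x, digits = 1, ...) {
  cat(sprintf(
    "Scenario projection: %d scenario(s), ages 1-%d, B = %d (%d used)\n",
    length(x$temperatures), max(x$summary$age), x$B, x$B_used))
  y <- x$summary
  for (cn in c("mean", "sd", "ci_lo", "ci_hi", "pi_lo", "pi_hi")) {
    y[[cn]] <- round(y[[cn]], digits)
  }
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
summary.scenario_result <- function(object, ...) object$summary

#' @export
plot.scenario_result <- function(x, ...) {
  s <- x$summary
  scen <- unique(s$scenario)
  cols <- setNames(seq_along(scen), scen)
  plot(range(s$age), range(c(s$ci_lo, s$ci_hi, s$mean)), type = "n",
       xlab = "age (yr)", ylab = "total length (mm)", ...)
  for (sc in scen) {
    sub <- s[s$scenario == sc, ]
    lines(sub$age, sub$mean, col = cols[sc], lwd = 2)
    lines(sub$age, sub$ci_lo, col = cols[sc], lty = 2)
    lines(sub$age, sub$ci_hi, col = cols[sc], lty = 2)
  }
  legend("bottomright", legend = scen, col = cols, lwd = 2, bty = "n")
  invisible(x)
}
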