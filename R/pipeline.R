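## End-to-end orchestration: simulate -> fit -> project -> report, with a
## single config object (YAML/JSON-serializable), fixed output filenames
## under a run directory, and seed + config-hash provenance in every
## artifact.

#' Build a pipeline configuration
#'
#' Exactly one of `paths` (CSV inputs) or `synthetic` (a
#' [truth_config()]) drives the data stage. `inject` optionally supplies
#' published coefficients directly (a list with elements `lm2`, `lm3`,
#' `lm4`, each a list of the arguments of [growth_fit()] minus `model`),
#' bypassing fitting in the projection stage so printed point estimates
#' can be reproduced exactly without the raw data.
#'
#' @param synthetic a `truth_config`, or `NULL` when `paths` is given.
#' @param paths named list with `increments`, `fish`, `temperatures`
#'   CSV paths, or `NULL`.
#' @param source temperature source used in fitting/projection.
#' @param reference_T reference summer temperature, degrees C (default
#'   20.48, the study-period mean).
#' @param offsets named scenario offsets from `reference_T`, degrees C;
#'   must include `reference = 0`.
#' @param B bootstrap replicates (default 10000, the full analysis;
#'   scale down for quick runs).
#' @param max_age oldest projected age class.
#' @param n_nodes cIPM mesh resolution.
#' @param seed integer seed.
#' @param inject optional coefficient-injection list (see above).
#' @return object of class `pipeline_config` (a list).
#' @export
pipeline_config <- function(synthetic = truth_config(), paths = NULL,
                            source = "mediterranean",
                            reference_T = 20.48,
                            offsets = c(minus1 = -1, reference = 0,
                                        plus1 = 1),
                            B = 10000L, max_age = 7L, n_nodes = 500L,
                            seed = 1L, inject = NULL) {
  if (is.null(synthetic) == is.null(paths)) {
    stop("exactly one of 'synthetic' and 'paths' must be supplied",
         call. = FALSE)
  }
  if (!"reference" %in% names(offsets) ||
      offsets[["reference"]] != 0) {
    stop("offsets must include reference = 0", call. = FALSE)
  }
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  structure(list(synthetic = synthetic, paths = paths, source = source,
                 reference_T = reference_T, offsets = offsets,
                 B = as.integer(B), max_age = as.integer(max_age),
                 n_nodes = as.integer(n_nodes), seed = as.integer(seed),
                 inject = inject),
            class = "pipeline_config")
}

.strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), .strip_classes) else x
}

## Write the config as JSON and return its md5, giving every artifact a
## provenance stamp tied to the exact configuration.
.write_config <- function(config, outdir) {
  path <- file.path(outdir, "config.json")
  jsonlite::write_json(.strip_classes(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(path))
}

.provenance <- function(config, outdir) {
  list(config_hash = .write_config(config, outdir), seed = config$seed)
}

.read_tables <- function(config, datadir) {
  if (!is.null(config$paths)) {
    list(increments = read_increments(config$paths$increments),
         fish = read_fish(config$paths$fish),
         temps = read_temperatures(config$paths$temperatures))
  } else {
    list(increments = read_increments(file.path(datadir,
                                                "increments.csv")),
         fish = read_fish(file.path(datadir, "fish.csv")),
         temps = read_temperatures(file.path(datadir,
                                             "temperatures.csv")))
  }
}

#' Simulate a dataset and write it to a run directory
#'
#' Writes `increments.csv`, `fish.csv`, `temperatures.csv`,
#' `truth.json` (the closed-form expectations of the synthetic world)
#' and `config.json` under `outdir`. Identical configs (including seed)
#' give byte-identical outputs.
#'
#' @param config a `pipeline_config` with a `synthetic` component.
#' @param outdir output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
run_simulate <- function(config, outdir) {
  if (is.null(config$synthetic)) {
    stop("run_simulate needs a synthetic config", call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pop <- generate_population(config$synthetic)
  write_increments(pop$increments, file.path(outdir, "increments.csv"))
  write_fish(pop$fish, file.path(outdir, "fish.csv"))
  write_temperatures(pop$temps, file.path(outdir, "temperatures.csv"))
  tr <- truth_report(config$synthetic)
  jsonlite::write_json(
    c(list(K = tr$K, Z_inf = tr$Z_inf, L_inf = tr$L_inf,
           phi_prime = tr$phi_prime, moments = tr$moments),
      .provenance(config, outdir)),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(outdir)
}

#' Fit the growth-model suite and write model artifacts
#'
#' Reads the run-directory (or configured) CSVs, builds the growth-pair
#' and first-increment tables, fits the fixed-effects suite (Walford,
#' Walford + temperature, initial size, allometry) and the mixed models
#' (year; year + fish; year + fish + temperature), compares the growth
#' models by AIC, derives von Bertalanffy parameters, and writes
#' `models.json`, `model_comparison.csv`, `vb.json`.
#'
#' @param config a `pipeline_config`.
#' @param outdir run directory for outputs.
#' @param datadir directory with the input CSVs (default `outdir`).
#' @return list of fitted objects, invisibly.
#' @export
run_fit <- function(config, outdir, datadir = outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tabs <- .read_tables(config, datadir)
  pairs <- build_growth_pairs(tabs$increments)
  first <- first_increments(tabs$increments)
  if (!config$source %in% tabs$temps$source) {
    stop(sprintf("fit stage: temperature source '%s' not in inputs",
                 config$source), call. = FALSE)
  }
  fits <- list(
    lm1 = fit_walford(pairs),
    lm2 = fit_walford_temp(pairs, tabs$temps, config$source),
    lm3 = fit_initial_size(first, tabs$temps, config$source),
    lm4 = fit_allometry(tabs$fish, "length", "Z4", "constant"),
    mod1 = fit_mixed_growth(pairs, random_year = TRUE,
                            random_fish = FALSE),
    mod2 = fit_mixed_growth(pairs, random_year = TRUE,
                            random_fish = TRUE),
    mod3 = fit_mixed_growth(pairs, tabs$temps, config$source,
                            random_year = TRUE, random_fish = TRUE))
  comp <- compare_models(fits[c("lm1", "lm2", "mod1", "mod2", "mod3")])
  vb <- vb_transform(fits$lm1, fits$lm4)
  write.csv(as.data.frame(comp),
            file.path(outdir, "model_comparison.csv"),
            row.names = FALSE)
  ser <- lapply(fits, function(f) {
    list(model = f$model, coefficients = as.list(f$coefficients),
         sigma = f$sigma, n = f$n, r_squared = f$r_squared,
         aic = f$aic, sd_year = f$sd_year, sd_fish = f$sd_fish,
         marginal_r2 = f$marginal_r2,
         vcov = if (!is.null(f$vcov)) unclass(as.data.frame(f$vcov)))
  })
  jsonlite::write_json(c(ser, .provenance(config, outdir)),
                       file.path(outdir, "models.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(c(unclass(vb), .provenance(config, outdir)),
                       file.path(outdir, "vb.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(fits, list(comparison = comp, vb = vb)))
}

.injected_fits <- function(inject) {
  stopifnot(all(c("lm2", "lm3", "lm4") %in% names(inject)))
  list(lm2 = do.call(growth_fit, c(list(model = "walford_temp"),
                                   inject$lm2)),
       lm3 = do.call(growth_fit, c(list(model = "initial_size"),
                                   inject$lm3)),
       lm4 = do.call(growth_fit, c(list(model = "allometry"),
                                   inject$lm4)))
}

#' Project size-at-age under the configured temperature scenarios
#'
#' With `config$inject` set, runs the point-estimate projection from the
#' injected coefficients; otherwise runs [bootstrap_projection()] on the
#' run-directory data with `config$B` replicates. Writes the tidy
#' scenario table to `scenarios.csv` and `scenarios.json`.
#'
#' @inheritParams run_fit
#' @return the `scenario_result`, invisibly.
#' @export
run_project <- function(config, outdir, datadir = outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  temperatures <- setNames(config$reference_T + config$offsets,
                           names(config$offsets))
  res <- if (!is.null(config$inject)) {
    fits <- .injected_fits(config$inject)
    project_scenarios(fits$lm3, fits$lm2, fits$lm4, temperatures,
                      max_age = config$max_age,
                      n_nodes = config$n_nodes)
  } else {
    tabs <- .read_tables(config, datadir)
    bootstrap_projection(build_growth_pairs(tabs$increments),
                         first_increments(tabs$increments), tabs$fish,
                         tabs$temps, temperatures, B = config$B,
                         seed = config$seed, source = config$source,
                         max_age = config$max_age,
                         n_nodes = config$n_nodes)
  }
  tidy <- merge(res$summary, res$percent_change,
                by = c("scenario", "age"), sort = FALSE)
  write.csv(tidy, file.path(outdir, "scenarios.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(list(summary = res$summary, percent_change = res$percent_change,
           B = res$B, B_used = res$B_used, discarded = res$discarded),
      .provenance(config, outdir)),
    file.path(outdir, "scenarios.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(res)
}

#' Assemble a human-readable run report
#'
#' Collects the von Bertalanffy parameters and the scenario table from
#' the artifacts written by [run_fit()] and [run_project()] into
#' `report.json` and a plain-text `report.txt`. Regeneration is
#' idempotent and the report values equal the serialized artifacts'.
#'
#' @param outdir run directory containing `vb.json` and
#'   `scenarios.json`.
#' @return the report list, invisibly.
#' @export
run_report <- function(outdir) {
  vb_path <- file.path(outdir, "vb.json")
  sc_path <- file.path(outdir, "scenarios.json")
  if (!file.exists(sc_path)) {
    stop("report stage: missing scenarios.json (run run_project first)",
         call. = FALSE)
  }
  vb <- if (file.exists(vb_path)) jsonlite::read_json(vb_path,
                                                      simplifyVector = TRUE)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  report <- list(vb = vb, scenarios = sc$summary,
                 percent_change = sc$percent_change,
                 B = sc$B, seed = sc$seed, config_hash = sc$config_hash)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  txt <- c("otolithIPM run report",
           sprintf("config %s, seed %s", sc$config_hash, sc$seed))
  if (!is.null(vb)) {
    txt <- c(txt, sprintf(
      "K = %.4f /yr, Z_inf = %.4f mm, L_inf = %.1f mm, phi' = %.3f",
      vb$K, vb$Z_inf, vb$L_inf, vb$phi_prime))
  }
  s <- as.data.frame(sc$summary)
  txt <- c(txt, "", "mean total length (mm) by scenario and age:",
           capture.output(print(
             s[, c("scenario", "age", "mean", "ci_lo", "ci_hi")],
             row.names = FALSE)))
  writeLines(txt, file.path(outdir, "report.txt"))
  invisible(report)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("otolithIPM pipeline config\n")
  cat(sprintf("  data: %s\n",
              if (!is.null(x$synthetic)) "synthetic" else "CSV paths"))
  cat(sprintf("  reference T %.2f C, offsets %s\n", x$reference_T,
              paste(sprintf("%s=%+g", names(x$offsets), x$offsets),
                    collapse = ", ")))
  cat(sprintf("  B = %d, max_age = %d, n_nodes = %d, seed = %d\n",
              x$B, x$max_age, x$n_nodes, x$seed))
  if (!is.null(x$inject)) cat("  coefficient injection active\n")
  invisible(x)
}

#' Read/write a pipeline config as YAML
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()] returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- if (!is.null(y$synthetic)) do.call(truth_config, y$synthetic)
  pipeline_config(
    synthetic = syn, paths = y$paths,
    source = y$source %||% "mediterranean",
    reference_T = y$reference_T %||% 20.48,
    offsets = if (!is.null(y$offsets)) unlist(y$offsets) else
      c(minus1 = -1, reference = 0, plus1 = 1),
    B = y$B %||% 10000L, max_age = y$max_age %||% 7L,
    n_nodes = y$n_nodes %||% 500L, seed = y$seed %||% 1L,
    inject = y$inject)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- lapply(unclass(config), function(x) {
    if (inherits(x, "truth_config")) unclass(x) else x
  })
  out$offsets <- as.list(config$offsets)  # keep names through YAML
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
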