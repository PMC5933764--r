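## CSV readers/writers and construction of modelling tables from raw
## increment records. All tables are plain data frames with declared
## column schemas; extra columns pass through untouched.

.increment_cols <- c("fish_id", "spawn_year", "increment_index",
                     "formation_year", "width", "cumulative_radius")
.fish_cols <- c("fish_id", "capture_date", "capture_location",
                "total_length", "weight", "age_at_capture",
                "Z1", "Z2", "Z3", "Z4")
.temperature_sources <- c("mediterranean", "all_lagoons",
                          "shallow_lagoons", "deep_lagoons")

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Validate a table of otolith increment records
#'
#' Checks the type invariants of an increment table: positive widths,
#' cumulative radii strictly increasing with increment index within each
#' fish, and formation year equal to spawn year plus increment index.
#' Violations are reported with row numbers (widths, consistency) or
#' fish ids (radius ordering).
#'
#' @param increments data frame with columns `fish_id`, `spawn_year`,
#'   `increment_index`, `formation_year`, `width`, `cumulative_radius`.
#' @return the validated data frame, invisibly.
#' @export
validate_increments <- function(increments) {
  .check_columns(increments, .increment_cols, "increment table")
  bad_w <- which(!is.finite(increments$width) | increments$width <= 0)
  if (length(bad_w)) {
    stop(sprintf("non-positive increment width at row(s): %s",
                 paste(head(bad_w, 10L), collapse = ", ")), call. = FALSE)
  }
  bad_y <- which(increments$formation_year !=
                   increments$spawn_year + increments$increment_index)
  if (length(bad_y)) {
    stop(sprintf(
      "formation_year != spawn_year + increment_index at row(s): %s",
      paste(head(bad_y, 10L), collapse = ", ")), call. = FALSE)
  }
  for (id in unique(increments$fish_id)) {
    sub <- increments[increments$fish_id == id, ]
    sub <- sub[order(sub$increment_index), ]
    if (any(diff(sub$cumulative_radius) <= 0)) {
      stop(sprintf(
        "cumulative_radius not strictly increasing for fish '%s'", id),
        call. = FALSE)
    }
    if (any(!is.finite(sub$cumulative_radius) | sub$cumulative_radius <= 0)) {
      stop(sprintf("non-positive cumulative_radius for fish '%s'", id),
           call. = FALSE)
    }
  }
  invisible(increments)
}

#' Read otolith increment records from CSV
#'
#' One row per fish x annual increment, with the schema columns
#' `fish_id`, `spawn_year`, `increment_index` (0 = core to first annulus),
#' `formation_year`, `width` (mm), `cumulative_radius` (mm). Extra columns
#' are retained. Records are validated on read ([validate_increments()]).
#'
#' @param path path to a CSV file with a header row.
#' @return data frame of increment records.
#' @export
read_increments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_increments(df)
  df
}

#' Read per-fish capture metadata from CSV
#'
#' Schema columns: `fish_id`, `capture_date` (ISO-8601), `capture_location`,
#' `total_length` (mm), `weight` (g), `age_at_capture` (years, count of
#' complete annuli) and the four otolith radii `Z1`..`Z4` (mm, ventral,
#' lateroventral, laterodorsal and dorsal growth axes).
#'
#' @param path path to a CSV file with a header row.
#' @return data frame of fish records.
#' @export
read_fish <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, .fish_cols, "fish table")
  bad_l <- which(!is.na(df$total_length) & df$total_length <= 0)
  if (length(bad_l)) {
    stop(sprintf("non-positive total_length at row(s): %s",
                 paste(head(bad_l, 10L), collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read an annual summer-temperature table from CSV
#'
#' Expects columns `source`, `year`, `temperature` (degrees C); values must
#' be finite with one row per (source, year).
#'
#' @param path path to a CSV file with a header row.
#' @return an `annual_temperature` data frame.
#' @export
read_temperatures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("source", "year", "temperature"), "temperature table")
  annual_temperature(df$year, df$temperature, df$source)
}

#' Construct an annual temperature table
#'
#' @param year calendar years.
#' @param temperature mean summer temperatures, degrees C (finite).
#' @param source region label, e.g. `"mediterranean"`, `"all_lagoons"`,
#'   `"shallow_lagoons"`, `"deep_lagoons"`; recycled.
#' @return data frame of class `annual_temperature` with columns
#'   `source`, `year`, `temperature`.
#' @export
annual_temperature <- function(year, temperature, source = "mediterranean") {
  df <- data.frame(source = as.character(source), year = as.integer(year),
                   temperature = as.numeric(temperature),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$temperature))) {
    stop("temperature values must be finite", call. = FALSE)
  }
  if (anyDuplicated(df[c("source", "year")])) {
    stop("duplicate (source, year) in temperature table", call. = FALSE)
  }
  class(df) <- c("annual_temperature", "data.frame")
  df
}

#' @export
#' @rdname read_increments
#' @param increments validated increment data frame.
#' @param path output CSV path.
write_increments <- function(increments, path) {
  validate_increments(increments)
  write.csv(increments, path, row.names = FALSE)
  invisible(path)
}

#' @export
#' @rdname read_fish
#' @param fish fish data frame.
#' @param path output CSV path.
write_fish <- function(fish, path) {
  .check_columns(fish, .fish_cols, "fish table")
  write.csv(fish, path, row.names = FALSE)
  invisible(path)
}

#' @export
#' @rdname read_temperatures
#' @param temps an `annual_temperature` data frame.
#' @param path output CSV path.
write_temperatures <- function(temps, path) {
  write.csv(as.data.frame(temps), path, row.names = FALSE)
  invisible(path)
}

#' Build the Walford growth-pair table from increment records
#'
#' Forms one row per consecutive pair of complete annuli within a fish:
#' `Z` is the cumulative otolith radius at year t-1 and `Zprime` the radius
#' at year t. The year label of a pair is the formation year of the later
#' annulus (the calendar year in which the increment grew), which is the
#' year temperature covariates are joined on. Fish with fewer than two
#' complete annuli contribute no rows; growth beyond the last annulus is
#' not represented in the increment table and therefore never enters.
#' Pairs with non-increasing radius (measurement inversions) are dropped
#' with a warning rather than raising, since the growth model presumes
#' `Zprime > Z`.
#'
#' @param increments validated increment data frame
#'   (see [read_increments()]).
#' @return data frame of class `growth_pairs` with columns `fish_id`,
#'   `year`, `Z`, `Zprime`; attributes `n_fish_skipped` (fish with < 2
#'   annuli) and `n_dropped` (inverted pairs removed).
#' @export
build_growth_pairs <- function(increments) {
  # schema check only: tables from read_increments() are already strictly
  # validated, but tables assembled elsewhere may carry measurement
  # inversions, which are handled below by drop-and-warn
  .check_columns(increments, .increment_cols, "increment table")
  out <- list()
  skipped <- 0L
  ids <- unique(increments$fish_id)
  for (id in ids) {
    sub <- increments[increments$fish_id == id, ]
    sub <- sub[order(sub$increment_index), ]
    n <- nrow(sub)
    if (n < 2L) { skipped <- skipped + 1L; next }
    out[[length(out) + 1L]] <- data.frame(
      fish_id = id,
      year = sub$formation_year[-1L],
      Z = sub$cumulative_radius[-n],
      Zprime = sub$cumulative_radius[-1L],
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(fish_id = character(), year = integer(),
               Z = numeric(), Zprime = numeric())
  bad <- pairs$Zprime <= pairs$Z
  n_dropped <- sum(bad)
  if (n_dropped) {
    warning(sprintf("dropped %d growth pair(s) with non-increasing radius",
                    n_dropped), call. = FALSE)
    pairs <- pairs[!bad, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  attr(pairs, "n_fish_skipped") <- skipped
  attr(pairs, "n_dropped") <- n_dropped
  class(pairs) <- c("growth_pairs", "data.frame")
  pairs
}

#' Extract first-annulus (age-0 growth) sizes
#'
#' Returns the cumulative otolith radius at the first annulus for every
#' fish, labelled with the formation year of that annulus. This is the
#' fitting table for the initial-size model (otolith size at the first
#' birthday as a function of summer temperature).
#'
#' @param increments validated increment data frame.
#' @return data frame with columns `fish_id`, `year`, `Z`.
#' @export
first_increments <- function(increments) {
  validate_increments(increments)
  sub <- increments[increments$increment_index == 0L, ]
  data.frame(fish_id = sub$fish_id, year = sub$formation_year,
             Z = sub$cumulative_radius, stringsAsFactors = FALSE)
}

#' Aggregate a daily temperature series into annual summer means
#'
#' Computes the arithmetic mean of all observations falling in the summer
#' window (June-August by default, the period of maximal growth for
#' lagoon-dwelling sparids) for each requested year. Years with no
#' in-window observations are flagged missing (dropped from the output,
#' listed in the `missing_years` attribute, warned about) rather than
#' silently reported as zero.
#'
#' @param daily data frame with columns `date` (ISO-8601 or `Date`) and
#'   `value` (degrees C).
#' @param years integer years to aggregate; default all years present.
#' @param months integer months defining the window (default `6:8`).
#' @param source region label for the output table.
#' @return an `annual_temperature` data frame; attribute `missing_years`
#'   lists requested years with no in-window data.
#' @export
summer_mean <- function(daily, years = NULL, months = 6:8,
                        source = "mediterranean") {
  .check_columns(daily, c("date", "value"), "daily series")
  d <- as.Date(daily$date)
  if (anyNA(d)) stop("unparseable dates in daily series", call. = FALSE)
  yr <- as.integer(format(d, "%Y"))
  mo <- as.integer(format(d, "%m"))
  if (is.null(years)) years <- sort(unique(yr))
  means <- vapply(years, function(y) {
    v <- daily$value[yr == y & mo %in% months]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  missing_years <- years[is.na(means)]
  if (length(missing_years)) {
    warning(sprintf("no summer observations for year(s): %s",
                    paste(missing_years, collapse = ", ")), call. = FALSE)
  }
  out <- annual_temperature(years[!is.na(means)], means[!is.na(means)],
                            source)
  attr(out, "missing_years") <- missing_years
  out
}

## Join temperatures onto a table by year for one source; error names the
## years without a value, as silent NA would corrupt downstream fits.
.join_temperature <- function(df, temps, source = "mediterranean") {
  t_sub <- temps[temps$source == source, , drop = FALSE]
  if (nrow(t_sub) == 0L) {
    stop(sprintf("no temperatures for source '%s'", source), call. = FALSE)
  }
  idx <- match(df$year, t_sub$year)
  if (anyNA(idx)) {
    stop(sprintf("no temperature for year(s): %s (source '%s')",
                 paste(sort(unique(df$year[is.na(idx)])), collapse = ", "),
                 source), call. = FALSE)
  }
  df$T <- t_sub$temperature[idx]
  df
}
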