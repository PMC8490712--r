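#' Assemble a county-year panel bundle
#'
#' Collects the aligned tables that the yield model consumes: geography
#' (county, crop reporting district, state, centroid), observed yields and
#' planted areas, weekly weather, static soil, plant density, and cumulative
#' planting/harvesting progress. All tables are coerced to tibbles and checked
#' for required columns; deeper consistency checks live in
#' [validate_bundle()].
#'
#' @param geography tibble with columns `county_id`, `district_id`,
#'   `state_id`, `lat`, `lon`.
#' @param yields tibble with columns `county_id`, `year`, `yield` (bu/ac),
#'   `area` (acres planted).
#' @param weather long tibble with columns `county_id`, `year`, `week`
#'   (1..52), `var`, `value`.
#' @param soil long tibble with columns `county_id`, `var`, `value`.
#' @param density tibble with columns `county_id`, `year`, `density`
#'   (plants/acre).
#' @param progress tibble with columns `county_id`, `year`, `week`,
#'   `planting`, `harvesting` — cumulative fractions in `[0, 1]`.
#' @param weather_vars,soil_vars optional character vectors fixing the
#'   variable order; defaults to order of first appearance.
#' @return an object of class `gem_bundle`: a named list of the six tables
#'   with attributes `weather_vars`, `soil_vars`, `normalized`, `scalers`.
#' @export
gem_bundle <- function(geography, yields, weather, soil, density, progress,
                       weather_vars = NULL, soil_vars = NULL) {
  need <- function(df, cols, name) {
    df <- tibble::as_tibble(df)
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      abort(sprintf("table '%s' is missing column(s): %s",
                    name, paste(missing, collapse = ", ")))
    }
    df
  }
  geography <- need(geography, c("county_id", "district_id", "state_id", "lat", "lon"), "geography")
  yields <- need(yields, c("county_id", "year", "yield", "area"), "yields")
  weather <- need(weather, c("county_id", "year", "week", "var", "value"), "weather")
  soil <- need(soil, c("county_id", "var", "value"), "soil")
  density <- need(density, c("county_id", "year", "density"), "density")
  progress <- need(progress, c("county_id", "year", "week", "planting", "harvesting"), "progress")

  weather_vars <- weather_vars %||% unique(weather$var)
  soil_vars <- soil_vars %||% unique(soil$var)

  out <- list(geography = geography, yields = yields, weather = weather,
              soil = soil, density = density, progress = progress)
  structure(out,
            class = "gem_bundle",
            weather_vars = as.character(weather_vars),
            soil_vars = as.character(soil_vars),
            normalized = FALSE,
            scalers = NULL)
}

#' @export
print.gem_bundle <- function(x, ...) {
  ct <- nrow(x$yields)
  cat(sprintf(
    "<gem_bundle> %d county-year yield records | %d counties, %d districts, %d states | years %s-%s\n",
    ct, dplyr::n_distinct(x$geography$county_id),
    dplyr::n_distinct(x$geography$district_id),
    dplyr::n_distinct(x$geography$state_id),
    min(x$yields$year), max(x$yields$year)))
  cat(sprintf("  weather vars: %s\n  soil vars:    %s\n  normalized:   %s\n",
              paste(attr(x, "weather_vars"), collapse = ", "),
              paste(attr(x, "soil_vars"), collapse = ", "),
              attr(x, "normalized")))
  invisible(x)
}

is_normalized <- function(bundle) isTRUE(attr(bundle, "normalized"))

#' Subset a panel bundle by year and/or county
#'
#' Filters every table consistently. Used to build training folds for
#' cross-validation (e.g. drop one year or one county entirely).
#'
#' @param bundle a [gem_bundle()].
#' @param years,counties values to keep (or to drop when `drop = TRUE`).
#'   `NULL` keeps everything.
#' @param drop if `TRUE`, the given years/counties are removed instead of
#'   kept.
#' @return a `gem_bundle` with the same attributes.
#' @export
filter_bundle <- function(bundle, years = NULL, counties = NULL, drop = FALSE) {
  keep <- function(values, wanted) {
    if (is.null(wanted)) rep(TRUE, length(values))
    else if (drop) !(values %in% wanted)
    else values %in% wanted
  }
  out <- bundle
  for (nm in names(out)) {
    tb <- out[[nm]]
    sel <- rep(TRUE, nrow(tb))
    if ("year" %in% names(tb)) sel <- sel & keep(tb$year, years)
    if ("county_id" %in% names(tb)) sel <- sel & keep(tb$county_id, counties)
    out[[nm]] <- tb[sel, , drop = FALSE]
  }
  out
}

#' Derive the vegetative/reproductive stage calendar
#'
#' The season of each (county, year) is split into a vegetative and a
#' reproductive phase at the division week, defined as the first week in
#' which the cumulative planting fraction reaches 1. Weeks strictly before
#' the division week are vegetative; the division week and all later weeks
#' are reproductive, so the two sets always partition weeks 1..52.
#'
#' @param x a `gem_bundle` or a progress tibble
#'   (`county_id`, `year`, `week`, `planting`, `harvesting`).
#' @return tibble with columns `county_id`, `year`, `division_week`.
#' @export
stage_calendar <- function(x) {
  progress <- if (inherits(x, "gem_bundle")) x$progress else tibble::as_tibble(x)
  out <- progress |>
    dplyr::group_by(.data$county_id, .data$year) |>
    dplyr::summarise(
      division_week = if (any(.data$planting >= 1)) min(.data$week[.data$planting >= 1]) else NA_integer_,
      .groups = "drop")
  bad <- dplyr::filter(out, is.na(.data$division_week))
  if (nrow(bad)) {
    abort(sprintf(
      "planting progress never reaches 1 for %d (county, year) pair(s), e.g. %s",
      nrow(bad),
      paste(utils::head(paste0("(", bad$county_id, ", ", bad$year, ")"), 3), collapse = ", ")))
  }
  out
}

#' Aggregate daily weather to the fixed weekly grid
#'
#' Weeks are fixed seven-day blocks counted from January 1 (days 1-7 are
#' week 1, and so on); days 365/366 fold into week 52, so week 52 averages
#' 8-9 days.
#'
#' @param daily tibble with columns `county_id`, `year`, `day` (1-based day
#'   of year), `var`, `value`.
#' @return long weekly weather tibble (`county_id`, `year`, `week`, `var`,
#'   `value`).
#' @export
aggregate_daily_weather <- function(daily) {
  daily |>
    dplyr::mutate(week = pmin(ceiling(.data$day / 7), 52L)) |>
    dplyr::group_by(.data$county_id, .data$year, .data$week, .data$var) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}
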