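# Evaluation protocols: leave-one-year-out (temporal transfer),
# leave-one-county-out (spatial transfer), nearest-neighbor baselines, and
# in-season prediction by splicing observed with historical weather.

new_gem_cv <- function(mode, folds, predictions) {
  pooled <- tibble::tibble(
    rmse = weighted_rmse(predictions),
    r2 = weighted_r2(predictions),
    n = nrow(predictions))
  structure(list(mode = mode, folds = folds, predictions = predictions,
                 pooled = pooled), class = "gem_cv")
}

#' @export
print.gem_cv <- function(x, ...) {
  cat(sprintf("<gem_cv> %s: %d folds, %d pooled records\n",
              x$mode, nrow(x$folds), x$pooled$n))
  cat(sprintf("  pooled weighted RMSE %.3f bu/ac, weighted R2 %.3f\n",
              x$pooled$rmse, x$pooled$r2))
  invisible(x)
}

fold_metrics <- function(predictions, fold_col = "fold") {
  predictions |>
    dplyr::group_by(fold = .data[[fold_col]]) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(rmse = weighted_rmse(df),
                     r2 = tryCatch(weighted_r2(df), error = function(e) NA_real_),
                     n = nrow(df))
    }) |>
    dplyr::ungroup()
}

#' Leave-one-year-out cross-validation
#'
#' For each year in the bundle, the model is calibrated on all other years
#' (min-max scalers refit on that training scope only) and used to predict
#' the held-out year from its observed weather, soil and management
#' variables. Per-fold and pooled area-weighted metrics are reported.
#'
#' @param bundle an un-normalized [gem_bundle()] (each fold fits its own
#'   scalers).
#' @param control a [gem_control()]; when it carries an `rng_seed`, each
#'   fold derives its own sub-seed so the whole procedure is reproducible.
#' @return object of class `gem_cv` with elements `folds` (per-fold tibble:
#'   `fold`, `rmse`, `r2`, `n`), `predictions` (pooled per-record tibble),
#'   `pooled`.
#' @export
cv_leave_year_out <- function(bundle, control = gem_control()) {
  if (is_normalized(bundle)) abort("pass an un-normalized bundle; folds refit their scalers")
  years <- sort(unique(bundle$yields$year))
  if (length(years) < 2) abort("need at least two years for leave-one-year-out")
  preds <- vector("list", length(years))
  for (k in seq_along(years)) {
    yr <- years[k]
    ctl <- control
    if (!is.null(ctl$rng_seed)) ctl$rng_seed <- (control$rng_seed + 7919L * k) %% .Machine$integer.max
    train <- filter_bundle(bundle, years = yr, drop = TRUE)
    fit <- fit_gem(train, ctl)
    test <- filter_bundle(bundle, years = yr)
    yhat <- predict(fit, test)
    preds[[k]] <- join_predictions(yhat, test$yields) |>
      dplyr::mutate(fold = as.character(yr))
  }
  predictions <- dplyr::bind_rows(preds)
  new_gem_cv("leave-one-year-out", fold_metrics(predictions), predictions)
}

# State-level mean of fitted district coefficient vectors; the fallback for
# districts absent from a training fold (leave-one-county-out with a
# single-county district).
state_mean_alpha <- function(params, geography, districts_needed) {
  map <- geography |> dplyr::distinct(.data$district_id, .data$state_id)
  have <- rownames(params$alpha)
  out <- matrix(NA_real_, length(districts_needed), ncol(params$alpha),
                dimnames = list(districts_needed, colnames(params$alpha)))
  for (d in districts_needed) {
    st <- map$state_id[map$district_id == d][1]
    sibs <- intersect(map$district_id[map$state_id == st], have)
    rows <- if (length(sibs)) params$alpha[sibs, , drop = FALSE] else params$alpha
    out[d, ] <- colMeans(rows)
  }
  out
}

#' Leave-one-county-out cross-validation
#'
#' For each county, the model is calibrated on every other county and used
#' to predict the held-out county from its own weather, soil and management
#' variables, with the genetic coefficients of its crop reporting district
#' learned from the district's remaining counties. If the held-out county
#' was its district's only member, the fold falls back to the state-level
#' mean of the fitted district coefficients (flagged in the predictions).
#'
#' @inheritParams cv_leave_year_out
#' @return a `gem_cv`; `predictions` carries a logical `alpha_fallback`
#'   column.
#' @export
cv_leave_county_out <- function(bundle, control = gem_control()) {
  if (is_normalized(bundle)) abort("pass an un-normalized bundle; folds refit their scalers")
  counties <- sort(unique(bundle$yields$county_id))
  if (length(counties) < 2) abort("need at least two counties for leave-one-county-out")
  geo <- bundle$geography
  preds <- vector("list", length(counties))
  for (k in seq_along(counties)) {
    cid <- counties[k]
    ctl <- control
    if (!is.null(ctl$rng_seed)) ctl$rng_seed <- (control$rng_seed + 104729L * k) %% .Machine$integer.max
    train <- filter_bundle(bundle, counties = cid, drop = TRUE)
    fit <- fit_gem(train, ctl)
    test <- filter_bundle(bundle, counties = cid)
    test_norm <- normalize_bundle(test, fit$scalers)
    prep <- prep_panel(test_norm)
    d_needed <- setdiff(unique(prep$ct$district_id), rownames(fit$params$alpha))
    fallback <- NULL
    if (length(d_needed)) fallback <- state_mean_alpha(fit$params, geo, d_needed)
    yhat <- tibble::tibble(county_id = prep$ct$county_id, year = prep$ct$year,
                           yhat = predict_from_prep(fit$params, prep, fallback))
    preds[[k]] <- join_predictions(yhat, test$yields) |>
      dplyr::mutate(fold = cid, alpha_fallback = length(d_needed) > 0)
  }
  predictions <- dplyr::bind_rows(preds)
  new_gem_cv("leave-one-county-out", fold_metrics(predictions), predictions)
}

#' Nearest-year baseline
#'
#' Predicts each target (county, year) with the county's observed yield
#' from the closest other year with data (before or after); ties go to the
#' earlier year. Records with no other year for that county get `NA`.
#'
#' @param yields yield table (`county_id`, `year`, `yield`, `area`).
#' @param targets tibble of (`county_id`, `year`) to predict; defaults to
#'   every record in `yields` (each predicted from the others).
#' @return `targets` with a `yhat` column.
#' @export
nearest_year_baseline <- function(yields, targets = NULL) {
  targets <- targets %||% dplyr::select(yields, "county_id", "year")
  by_county <- split(yields[c("year", "yield")], yields$county_id)
  yhat <- purrr::map2_dbl(targets$county_id, targets$year, function(cid, yr) {
    cand <- by_county[[cid]]
    if (is.null(cand)) return(NA_real_)
    cand <- cand[cand$year != yr, , drop = FALSE]
    if (nrow(cand) == 0) return(NA_real_)
    dist <- abs(cand$year - yr)
    best <- which(dist == min(dist))
    if (length(best) > 1) best <- best[which.min(cand$year[best])]
    cand$yield[best]
  })
  dplyr::mutate(targets, yhat = yhat)
}

#' Nearest-county baseline
#'
#' Predicts each target (county, year) with the same-year observed yield of
#' the geographically nearest other county (great-circle distance between
#' county centroids); ties go to the lexicographically smallest county id.
#' Years in which no other county has data get `NA`.
#'
#' @param yields yield table.
#' @param geography geography table with centroids.
#' @param targets as in [nearest_year_baseline()].
#' @return `targets` with a `yhat` column.
#' @export
nearest_county_baseline <- function(yields, geography, targets = NULL) {
  targets <- targets %||% dplyr::select(yields, "county_id", "year")
  geo <- dplyr::arrange(geography, .data$county_id)
  dmat <- geosphere::distm(cbind(geo$lon, geo$lat))
  dimnames(dmat) <- list(geo$county_id, geo$county_id)
  by_year <- split(yields[c("county_id", "yield")], yields$year)
  yhat <- purrr::map2_dbl(targets$county_id, targets$year, function(cid, yr) {
    cand <- by_year[[as.character(yr)]]
    if (is.null(cand)) return(NA_real_)
    cand <- cand[cand$county_id != cid, , drop = FALSE]
    if (nrow(cand) == 0 || !(cid %in% rownames(dmat))) return(NA_real_)
    d <- dmat[cid, cand$county_id]
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[order(cand$county_id[best])[1]]
    cand$yield[best]
  })
  dplyr::mutate(targets, yhat = yhat)
}

#' In-season yield forecast with historical weather scenarios
#'
#' Forecasts a target year mid-season from a model trained without that
#' year: for each requested day-of-year `d` and each historical scenario
#' year, observed daily weather for days `1..d` is spliced with the
#' scenario year's weather for the remaining days, aggregated to the weekly
#' grid, and run through the model. The per-county predictions are averaged
#' with planted-area weights from the most recent training year (target-year
#' areas are unknown mid-season). With `d = 365` no days are imputed, so
#' all scenarios collapse to the same forecast.
#'
#' @param object a `gem_fit` trained *without* the target year.
#' @param bundle bundle providing the target year's soil, density and
#'   progress tables (and yields of training years for the area weights).
#' @param daily_weather daily weather tibble (`county_id`, `year`, `day`,
#'   `var`, `value`) covering the target year and the scenario years.
#' @param target_year year being forecast.
#' @param days integer vector of days-of-year at which to forecast.
#' @param scenario_years historical years to use as weather scenarios;
#'   defaults to all training years present in `daily_weather`. Requested
#'   years missing from `daily_weather` are skipped with a warning.
#' @return object of class `gem_forecast`: tibble `day`, `scenario_year`,
#'   `yhat` (area-weighted average bu/ac), with the per-county table in
#'   `attr(x, "by_county")`.
#' @export
in_season_forecast <- function(object, bundle, daily_weather, target_year,
                               days = c(1L, seq(30L, 360L, by = 30L), 365L),
                               scenario_years = NULL) {
  if (target_year %in% object$years) {
    abort("the model was trained with the target year; in-season forecasting requires a held-out year")
  }
  scenario_years <- scenario_years %||% object$years
  have <- sort(unique(daily_weather$year))
  miss <- setdiff(scenario_years, have)
  if (length(miss)) {
    warn(sprintf("no daily weather for scenario year(s) %s; skipped",
                 paste(miss, collapse = ", ")))
    scenario_years <- setdiff(scenario_years, miss)
  }
  if (!length(scenario_years)) abort("no usable scenario years")
  if (!(target_year %in% have)) abort("no daily weather for the target year")

  counties <- sort(intersect(unique(bundle$soil$county_id),
                             unique(daily_weather$county_id[daily_weather$year == target_year])))
  wv <- attr(bundle, "weather_vars")

  # day x var x county arrays for the target year and each scenario year
  to_array <- function(yr) {
    dd <- daily_weather |>
      dplyr::filter(.data$year == yr, .data$county_id %in% counties,
                    .data$day <= 365)
    arr <- array(NA_real_, c(365, length(wv), length(counties)),
                 dimnames = list(NULL, wv, counties))
    arr[cbind(dd$day, match(dd$var, wv), match(dd$county_id, counties))] <- dd$value
    if (anyNA(arr)) abort(sprintf("incomplete daily weather for year %s", yr))
    arr
  }
  obs <- to_array(target_year)
  scn <- lapply(setNames(scenario_years, scenario_years), to_array)

  week_of <- pmin(ceiling(seq_len(365) / 7), 52L)
  weekly_from <- function(arr) apply(arr, 2:3, function(v) rowsum(v, week_of) / as.vector(table(week_of)))

  # static pieces of the target-year prediction bundle
  target_tables <- filter_bundle(bundle, years = target_year)
  area_year <- max(object$years[object$years %in% bundle$yields$year])
  weights <- bundle$yields |>
    dplyr::filter(.data$year == area_year, .data$county_id %in% counties) |>
    dplyr::select("county_id", "area")

  by_county <- list()
  for (d in days) {
    for (s in scenario_years) {
      spliced <- scn[[as.character(s)]]
      if (d > 0) spliced[seq_len(min(d, 365)), , ] <- obs[seq_len(min(d, 365)), , ]
      wk <- weekly_from(spliced)  # 52 x var x county
      weather_tb <- tidyr::expand_grid(county_id = counties, var = wv, week = 1:52) |>
        dplyr::mutate(year = target_year,
                      value = wk[cbind(.data$week, match(.data$var, wv),
                                       match(.data$county_id, counties))]) |>
        dplyr::select("county_id", "year", "week", "var", "value")
      pb <- target_tables
      pb$weather <- weather_tb
      pb$yields <- tibble::tibble(county_id = counties, year = target_year,
                                  yield = NA_real_, area = NA_real_)
      attr(pb, "normalized") <- FALSE
      attr(pb, "scalers") <- NULL
      pred <- predict(object, pb)
      by_county[[length(by_county) + 1L]] <- dplyr::mutate(pred, day = d, scenario_year = s)
    }
  }
  by_county <- dplyr::bind_rows(by_county)
  agg <- by_county |>
    dplyr::inner_join(weights, by = "county_id") |>
    dplyr::group_by(.data$day, .data$scenario_year) |>
    dplyr::summarise(yhat = sum(.data$area * .data$yhat) / sum(.data$area),
                     .groups = "drop")
  structure(agg, class = c("gem_forecast", class(agg)), by_county = by_county,
            target_year = target_year)
}
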