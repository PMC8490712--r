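# Synthetic county-year panels with the structure the model assumes:
# nested geography (counties in districts in states), seasonal weekly
# weather with county gradients and interannual anomalies, static soil
# fields on a spatial gradient, an upward plant-density trend, logistic
# planting/harvest progress curves shifted by latitude, district-level
# slowly increasing genetic trends, and yields generated by the forward
# model plus truncated Gaussian noise. Ground-truth parameters are returned
# so recovery can be tested end to end.

# per-variable seasonal profiles (natural units): weekly mean =
# base + amplitude * cos(2*pi*(week - peak_week)/52) + lat_slope * (lat - mean lat)
weather_profiles <- list(
  tmax = list(base = 12, amplitude = 16, peak_week = 29, lat_slope = -0.8, noise_sd = 2.5, anomaly_sd = 1.0),
  tmin = list(base = 2, amplitude = 14, peak_week = 29, lat_slope = -0.8, noise_sd = 2.5, anomaly_sd = 1.0),
  prcp = list(base = 20, amplitude = 10, peak_week = 23, lat_slope = 0.5, noise_sd = 8, anomaly_sd = 4),
  srad = list(base = 300, amplitude = 150, peak_week = 26, lat_slope = -5, noise_sd = 30, anomaly_sd = 12),
  dayl = list(base = 43200, amplitude = 10800, peak_week = 25, lat_slope = 300, noise_sd = 600, anomaly_sd = 200),
  swe = list(base = 8, amplitude = 8, peak_week = 3, lat_slope = 1.2, noise_sd = 3, anomaly_sd = 1.5),
  vp = list(base = 1200, amplitude = 900, peak_week = 28, lat_slope = -40, noise_sd = 120, anomaly_sd = 60)
)

soil_profiles <- list(
  aws = list(base = 160, lon_slope = 8, noise_sd = 15),
  soc = list(base = 6000, lon_slope = 400, noise_sd = 600),
  tka = list(base = 150, lon_slope = 5, noise_sd = 12),
  tks = list(base = 140, lon_slope = 5, noise_sd = 12),
  nccpi3corn = list(base = 0.55, lon_slope = 0.03, noise_sd = 0.05),
  pctearthmc = list(base = 90, lon_slope = 1, noise_sd = 3),
  rootznemc = list(base = 1200, lon_slope = 50, noise_sd = 100),
  rootznaws = list(base = 220, lon_slope = 10, noise_sd = 20),
  droughty = list(base = 0.3, lon_slope = -0.04, noise_sd = 0.08),
  pwsl1pomu = list(base = 25, lon_slope = 2, noise_sd = 5)
)

#' Synthetic panel configuration
#'
#' Defaults define a compact panel: 3 states x 2 districts x 2 counties
#' over 15 years with 3 weather and 2 soil variables, genetic trends of
#' polynomial order 3, yield noise of 10 bu/ac, and 26% of county-year
#' records missing (mirroring the roughly three-quarters coverage of the
#' kind of national yield survey panel the model targets).
#'
#' @param n_states,districts_per_state,counties_per_district geography
#'   nesting counts.
#' @param years integer vector of simulated years.
#' @param weather_vars,soil_vars variable names to simulate (up to the 7
#'   weather / 10 soil variables with built-in seasonal/spatial profiles).
#' @param K_true polynomial order of the true genetic trends.
#' @param yield_noise_sd additive yield noise, bu/ac (truncated at 0).
#' @param missing_fraction fraction of county-year yield records dropped at
#'   random.
#' @param target_potential calibration target for the area-weighted mean
#'   seasonal growth potential (component E), bu/ac.
#' @param density_start,density_slope plant density trend (plants/acre and
#'   per-year increment).
#' @param plant_mid_week,harvest_mid_week mean logistic midpoints of the
#'   planting and harvesting progress curves.
#' @param seed RNG seed; everything the generator draws derives from it.
#' @return a list of class `gem_sim_config`.
#' @export
sim_config <- function(n_states = 3L,
                       districts_per_state = 2L,
                       counties_per_district = 2L,
                       years = 2001:2015,
                       weather_vars = c("tmax", "prcp", "srad"),
                       soil_vars = c("aws", "soc"),
                       K_true = 3L,
                       yield_noise_sd = 10,
                       missing_fraction = 0.26,
                       target_potential = 500,
                       density_start = 24000,
                       density_slope = 300,
                       plant_mid_week = 16,
                       harvest_mid_week = 42,
                       seed = 1L) {
  stopifnot(n_states >= 1, districts_per_state >= 1, counties_per_district >= 1,
            length(years) >= 2,
            missing_fraction >= 0, missing_fraction < 0.9,
            all(weather_vars %in% names(weather_profiles)),
            all(soil_vars %in% names(soil_profiles)))
  structure(as.list(environment()), class = "gem_sim_config")
}

sim_geography <- function(cfg) {
  n_c <- cfg$n_states * cfg$districts_per_state * cfg$counties_per_district
  idx <- expand.grid(county = seq_len(cfg$counties_per_district),
                     district = seq_len(cfg$districts_per_state),
                     state = seq_len(cfg$n_states))
  tibble::tibble(
    county_id = sprintf("C%03d", seq_len(n_c)),
    district_id = sprintf("S%d-D%d", idx$state, idx$district),
    state_id = sprintf("S%d", idx$state),
    lat = 37 + 2.2 * (idx$state - 1) + 0.4 * (idx$district - 1) + 0.15 * (idx$county - 1),
    lon = -97 + 2.5 * (idx$district - 1) + 0.8 * (idx$county - 1) + 0.3 * (idx$state - 1)
  )
}

logistic_progress <- function(mid, steep) {
  w <- 1:52
  L <- plogis((w - mid) / steep)
  full <- which(L >= 0.999)
  wcap <- if (length(full)) full[1] else 52L
  P <- (L - L[1]) / (L[wcap] - L[1])
  P[w >= wcap] <- 1
  P <- cummax(pmin(pmax(P, 0), 1))
  P
}

# Deterministic given cfg$seed: geography, weather, soil, density, progress
# and planted areas.
sim_covariates <- function(cfg) {
  withr::with_seed(cfg$seed, {
    geo <- sim_geography(cfg)
    n_c <- nrow(geo)
    lat0 <- mean(geo$lat)
    years <- cfg$years
    weeks <- 1:52

    weather <- purrr::map_dfr(cfg$weather_vars, function(v) {
      pf <- weather_profiles[[v]]
      anomaly <- setNames(rnorm(length(years), 0, pf$anomaly_sd), years)
      grid <- tidyr::expand_grid(county_id = geo$county_id, year = years, week = weeks)
      lat <- geo$lat[match(grid$county_id, geo$county_id)]
      mu <- pf$base + pf$amplitude * cos(2 * pi * (grid$week - pf$peak_week) / 52) +
        pf$lat_slope * (lat - lat0) + anomaly[as.character(grid$year)]
      dplyr::mutate(grid, var = v,
                    value = unname(mu) + rnorm(nrow(grid), 0, pf$noise_sd))
    })

    soil <- purrr::map_dfr(cfg$soil_vars, function(v) {
      pf <- soil_profiles[[v]]
      tibble::tibble(county_id = geo$county_id, var = v,
                     value = pf$base + pf$lon_slope * (geo$lon - mean(geo$lon)) +
                       rnorm(n_c, 0, pf$noise_sd))
    })

    density <- tidyr::expand_grid(county_id = geo$county_id, year = years) |>
      dplyr::mutate(density = cfg$density_start +
                      cfg$density_slope * (.data$year - min(years)) +
                      rnorm(dplyr::n(), 0, 250))

    progress <- tidyr::expand_grid(county_id = geo$county_id, year = years) |>
      dplyr::rowwise() |>
      dplyr::mutate(curves = {
        lat <- geo$lat[geo$county_id == .data$county_id]
        pmid <- cfg$plant_mid_week + 0.35 * (lat - lat0) + rnorm(1, 0, 0.5)
        hmid <- cfg$harvest_mid_week + 0.25 * (lat - lat0) + rnorm(1, 0, 0.5)
        P <- logistic_progress(pmid, 1.2)
        H <- pmin(logistic_progress(hmid, 1.6), P)
        list(tibble::tibble(week = 1:52, planting = P, harvesting = H))
      }) |>
      dplyr::ungroup() |>
      tidyr::unnest("curves")

    areas <- tibble::tibble(county_id = geo$county_id,
                            area = exp(rnorm(n_c, log(60000), 0.5)))

    list(geography = geo, weather = weather, soil = soil,
         density = density, progress = progress, areas = areas)
  })
}

# District genetic trends: scaled cumulative-logistic curves projected onto
# the degree-K_true polynomial basis, then verified against the level and
# change bounds.
sim_alpha <- function(cfg, districts) {
  t_norm <- (cfg$years - min(cfg$years)) / (max(cfg$years) - min(cfg$years))
  withr::with_seed(cfg$seed + 1L, {
    alpha <- matrix(0, length(districts), cfg$K_true + 1L,
                    dimnames = list(districts, paste0("k", 0:cfg$K_true)))
    for (d in seq_along(districts)) {
      lo <- runif(1, 0.60, 0.68)
      # annual gain of 1.5-2% keeps the steepest part of the logistic well
      # inside the +5% change bound whatever the panel length
      hi <- min(lo + runif(1, 0.015, 0.02) * (length(cfg$years) - 1L), 0.93)
      target <- lo + (hi - lo) * plogis((t_norm - 0.5) / 0.22)
      fit <- lm(target ~ poly(t_norm, cfg$K_true, raw = TRUE))
      alpha[d, ] <- coef(fit)
    }
    alpha
  })
}

check_alpha_bounds <- function(alpha, t_norm, level = c(0, 1), change = c(-0.025, 0.05)) {
  V <- outer(t_norm, seq_len(ncol(alpha)) - 1L, `^`)
  G <- V %*% t(alpha)
  dG <- apply(G, 2, diff)
  ok_level <- all(G >= level[1] - 1e-9) && all(G <= level[2] + 1e-9)
  ok_change <- all(dG >= change[1] - 1e-9) && all(dG <= change[2] + 1e-9)
  list(ok = ok_level && ok_change, level = range(G), change = range(dG))
}

# Sparse stage coefficients in normalized-variable units, before the global
# rescaling that sets the seasonal potential level. The pattern gives a
# seasonal sign structure: negative off-season potential, positive in-season.
sim_gamma_pattern <- function(cfg) {
  wv <- cfg$weather_vars
  sv <- cfg$soil_vars
  base <- function(stage) {
    g <- c("(Intercept)" = if (stage == "v") -0.35 else -0.30)
    g[wv[1]] <- if (stage == "v") 1.6 else 1.5
    g[paste0(wv[1], "*", wv[1])] <- if (stage == "v") -0.7 else -0.6
    if (length(wv) >= 2) {
      g[wv[2]] <- 0.5
      g[paste0(wv[2], "*", wv[2])] <- -0.35
    }
    if (length(wv) >= 3) g[wv[3]] <- 0.25
    g[sv[1]] <- if (stage == "v") 0.30 else 0.35
    g[paste0(wv[1], "*", sv[1])] <- 0.30
    if (length(sv) >= 2) g[sv[2]] <- 0.15
    g
  }
  list(v = base("v"), r = base("r"))
}

#' Ground-truth parameters for a synthetic configuration
#'
#' Builds the true model: per-district monotone increasing genetic
#' polynomials kept inside the level and year-over-year change bounds, and
#' sparse stage coefficients scaled so the area-weighted mean seasonal
#' growth potential matches `target_potential` and no noiseless yield
#' exceeds the 300 bu/ac prediction cap. Deterministic given the
#' configuration's seed.
#'
#' @param config a [sim_config()].
#' @return a [gem_params()] object.
#' @export
sim_true_parameters <- function(config) {
  sim_panel(config)$truth$params
}

#' Generate a synthetic panel with known truth
#'
#' @param config a [sim_config()].
#' @return a list of class `gem_sim`:
#'   * `bundle` — the observed [gem_bundle()] (un-normalized, with
#'     `missing_fraction` of the yield records dropped),
#'   * `truth` — list with `params`, `scalers` (the full-scope scalers used
#'     to generate), `noiseless` (county-year tibble with `g`, `e`, `m`,
#'     `yhat`), and the `config`,
#'   * `daily_weather` — daily expansion of the weekly weather (piecewise
#'     constant within weeks) for in-season forecasting.
#' @export
sim_panel <- function(config = sim_config()) {
  cfg <- config
  cov <- sim_covariates(cfg)
  grid <- tidyr::expand_grid(county_id = cov$geography$county_id, year = cfg$years)
  yields0 <- grid |>
    dplyr::left_join(cov$areas, by = "county_id") |>
    dplyr::mutate(yield = 0)
  bundle0 <- gem_bundle(cov$geography, yields0, cov$weather, cov$soil,
                        cov$density, cov$progress,
                        weather_vars = cfg$weather_vars, soil_vars = cfg$soil_vars)
  nb <- normalize_bundle(bundle0)
  scalers <- attr(nb, "scalers")

  alpha_true <- sim_alpha(cfg, sort(unique(cov$geography$district_id)))
  t_norm <- (cfg$years - min(cfg$years)) / (max(cfg$years) - min(cfg$years))
  chk <- check_alpha_bounds(alpha_true, t_norm)
  if (!chk$ok) {
    abort(sprintf("simulated genetic trends violate the bounds (level %.3f..%.3f, change %.4f..%.4f)",
                  chk$level[1], chk$level[2], chk$change[1], chk$change[2]))
  }

  pat <- sim_gamma_pattern(cfg)
  params <- gem_params(alpha_true, gamma_v = pat$v, gamma_r = pat$r,
                       weather_vars = cfg$weather_vars, soil_vars = cfg$soil_vars,
                       K = cfg$K_true)
  prep <- prep_panel(nb)
  dec0 <- decompose_from_prep(params, prep)
  area_by <- setNames(yields0$area, paste(yields0$county_id, yields0$year))
  w <- area_by[paste(dec0$county_id, dec0$year)]
  kappa <- cfg$target_potential / (sum(w * dec0$e) / sum(w))
  params$gamma_v <- params$gamma_v * kappa
  params$gamma_r <- params$gamma_r * kappa
  dec <- decompose_from_prep(params, prep)
  cap_max <- max(dec$yhat)
  if (cap_max > 285) {
    shrink <- 285 / cap_max
    params$gamma_v <- params$gamma_v * shrink
    params$gamma_r <- params$gamma_r * shrink
    dec <- decompose_from_prep(params, prep)
  }

  obs <- withr::with_seed(cfg$seed + 2L, {
    y <- pmax(0, dec$yhat + rnorm(nrow(dec), 0, cfg$yield_noise_sd))
    keep <- rep(TRUE, nrow(dec))
    if (cfg$missing_fraction > 0) {
      n_drop <- floor(cfg$missing_fraction * nrow(dec))
      for (attempt in 1:25) {
        drop <- sample.int(nrow(dec), n_drop)
        k <- rep(TRUE, nrow(dec)); k[drop] <- FALSE
        ok <- all(table(dec$year[k]) > 0) &&
          length(unique(dec$county_id[k])) == length(unique(dec$county_id)) &&
          length(unique(dec$year[k])) == length(unique(dec$year))
        if (ok) { keep <- k; break }
      }
    }
    tibble::tibble(county_id = dec$county_id, year = dec$year, yield = y)[keep, ]
  })
  yields <- obs |>
    dplyr::left_join(cov$areas, by = "county_id") |>
    dplyr::select("county_id", "year", "yield", "area")

  bundle <- gem_bundle(cov$geography, yields, cov$weather, cov$soil,
                       cov$density, cov$progress,
                       weather_vars = cfg$weather_vars, soil_vars = cfg$soil_vars)

  daily <- cov$weather |>
    dplyr::rename(wk_value = "value") |>
    dplyr::inner_join(tibble::tibble(day = 1:365, week = pmin(ceiling(1:365 / 7), 52L)),
                      by = "week", relationship = "many-to-many") |>
    dplyr::select(county_id = "county_id", year = "year", day = "day",
                  var = "var", value = "wk_value")

  structure(list(
    bundle = bundle,
    truth = list(params = params, scalers = scalers,
                 noiseless = dec, config = cfg),
    daily_weather = daily
  ), class = "gem_sim")
}

#' @export
print.gem_sim <- function(x, ...) {
  cat("<gem_sim> synthetic panel\n")
  print(x$bundle)
  invisible(x)
}

#' Remove yield records at random
#'
#' Drops an additional fraction of the observed yield records uniformly at
#' random (without replacement); covariate tables are untouched. Warns if
#' the removal empties an entire year or county, which would break
#' leave-one-out folds.
#'
#' @param bundle a [gem_bundle()].
#' @param fraction fraction of yield records to remove, in `[0, 1)`.
#' @param seed RNG seed for the removal draw.
#' @return the thinned `gem_bundle`.
#' @export
sim_drop_records <- function(bundle, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(bundle)
  n <- nrow(bundle$yields)
  n_drop <- floor(fraction * n)
  keep <- withr::with_seed(seed, {
    k <- rep(TRUE, n)
    k[sample.int(n, n_drop)] <- FALSE
    k
  })
  out <- bundle
  out$yields <- bundle$yields[keep, , drop = FALSE]
  if (length(unique(out$yields$year)) < length(unique(bundle$yields$year)) ||
      length(unique(out$yields$county_id)) < length(unique(bundle$yields$county_id))) {
    warn("removal emptied an entire year or county; leave-one-out folds may fail")
  }
  out
}
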