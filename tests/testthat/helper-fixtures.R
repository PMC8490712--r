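# Shared fixtures, all built in code.

# Identity scalers: normalization with these leaves weather/soil/density
# values untouched, so hand-constructed "already normalized" values can be
# fed straight through the model.
identity_scalers <- function(weather_vars, soil_vars, year_range) {
  structure(list(
    weather = tibble::tibble(var = weather_vars, min = 0, max = 1),
    soil = tibble::tibble(var = soil_vars, min = 0, max = 1),
    density = c(min = 0, max = 1),
    year = c(min = year_range[1], max = year_range[2])
  ), class = "gem_scalers")
}

# Minimal hand-checkable bundle: n_county counties, years given, one weather
# variable ("w1") and one soil variable ("s1"). Weekly weather, soil,
# density, progress and yields are supplied per county via functions or
# defaults.
tiny_bundle <- function(n_county = 2, years = 2000:2001,
                        weather_fn = function(cid, yr) rep(0.5, 52),
                        soil_val = 0.2,
                        density_val = 1,
                        planting = c(rep(0, 18), rep(1, 34)),
                        harvesting = rep(0, 52) + c(rep(0, 44), rep(1, 8)),
                        yield_val = 100, area_val = 1000) {
  cids <- sprintf("C%02d", seq_len(n_county))
  geography <- tibble::tibble(
    county_id = cids,
    district_id = rep(sprintf("D%02d", ceiling(seq_len(n_county) / 2)), length.out = n_county),
    state_id = "S1", lat = 40 + seq_len(n_county) * 0.5, lon = -95 + seq_len(n_county) * 0.5)
  yields <- tidyr::expand_grid(county_id = cids, year = years) |>
    dplyr::mutate(yield = yield_val, area = area_val)
  weather <- tidyr::expand_grid(county_id = cids, year = years) |>
    dplyr::rowwise() |>
    dplyr::mutate(w = list(tibble::tibble(week = 1:52, var = "w1",
                                          value = weather_fn(county_id, year)))) |>
    dplyr::ungroup() |>
    tidyr::unnest("w")
  soil <- tibble::tibble(county_id = cids, var = "s1", value = soil_val)
  density <- tidyr::expand_grid(county_id = cids, year = years) |>
    dplyr::mutate(density = density_val)
  progress <- tidyr::expand_grid(county_id = cids, year = years) |>
    dplyr::rowwise() |>
    dplyr::mutate(p = list(tibble::tibble(week = 1:52, planting = planting,
                                          harvesting = harvesting))) |>
    dplyr::ungroup() |>
    tidyr::unnest("p")
  gem_bundle(geography, yields, weather, soil, density, progress)
}

normalize_identity <- function(bundle, year_range = range(bundle$yields$year)) {
  normalize_bundle(bundle, identity_scalers(attr(bundle, "weather_vars"),
                                            attr(bundle, "soil_vars"), year_range))
}

# Cached default synthetic panels so several test files can share them.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_sim <- function() cached("default_sim", sim_panel(sim_config()))
noise_free_sim <- function() cached("noise_free_sim", sim_panel(sim_config(yield_noise_sd = 0)))

# Compact panel for solver tests: fewer records so the QPs run in
# milliseconds.
small_sim <- function() {
  cached("small_sim", sim_panel(sim_config(
    n_states = 1, districts_per_state = 2, counties_per_district = 2,
    years = 2001:2010, weather_vars = "tmax", soil_vars = "aws",
    yield_noise_sd = 0, missing_fraction = 0)))
}
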