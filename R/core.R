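# Forward model. The predicted yield for a county-year is
#   yhat = g(t) * sum_w D * (P_w - H_w) * G_w
# where g(t) is the district's genetic polynomial in the normalized year,
# D the normalized plant density, P/H the cumulative planting/harvesting
# fractions, and G_w the weekly growth potential: a quadratic form in the
# normalized weather and soil variables with stage-specific coefficients
# (vegetative before the division week, reproductive from it on). Because
# G_w is linear in the stage coefficients, each county-year collapses to a
# single feature row z so that yhat = g(t) * z %*% gamma; both calibration
# QPs are built on that reduction.

# ---- panel preparation --------------------------------------------------

locf_fill <- function(x, init) {
  for (i in seq_along(x)) {
    if (is.na(x[i])) x[i] <- if (i == 1L) init else x[i - 1L]
  }
  x
}

# Precompute everything fitting/prediction needs from a normalized bundle:
# the county-year table (district, normalized year, density, division week),
# per-record weekly weather blocks and management weights, the soil matrix,
# and the aggregated feature matrix Z (n x 2p; vegetative block then
# reproductive block).
prep_panel <- function(bundle) {
  if (!is_normalized(bundle)) abort("bundle must be normalized (see normalize_bundle())")
  wv <- attr(bundle, "weather_vars")
  sv <- attr(bundle, "soil_vars")
  scalers <- attr(bundle, "scalers")
  terms <- gamma_term_names(wv, sv)
  p <- length(terms)

  stage <- stage_calendar(bundle)
  geo <- dplyr::select(bundle$geography, "county_id", "district_id", "state_id")
  ct <- bundle$yields |>
    dplyr::inner_join(geo, by = "county_id") |>
    dplyr::left_join(bundle$density, by = c("county_id", "year")) |>
    dplyr::left_join(stage, by = c("county_id", "year")) |>
    dplyr::arrange(.data$county_id, .data$year) |>
    dplyr::mutate(t_norm = normalize_year(.data$year, scalers))
  if (nrow(ct) < nrow(bundle$yields)) {
    missing <- setdiff(bundle$yields$county_id, geo$county_id)
    abort(sprintf("counties missing from geography: %s", paste(missing, collapse = ", ")))
  }
  if (anyNA(ct$density)) abort("missing plant density for some county-year records")
  if (anyNA(ct$division_week)) abort("missing stage calendar for some county-year records")

  soil_wide <- bundle$soil |>
    tidyr::pivot_wider(names_from = "var", values_from = "value")
  miss_s <- setdiff(sv, names(soil_wide))
  if (length(miss_s)) abort(sprintf("missing soil variable(s): %s", paste(miss_s, collapse = ", ")))
  S <- as.matrix(soil_wide[sv])
  rownames(S) <- soil_wide$county_id

  ww <- bundle$weather |>
    tidyr::pivot_wider(names_from = "var", values_from = "value") |>
    dplyr::arrange(.data$county_id, .data$year, .data$week)
  miss_w <- setdiff(wv, names(ww))
  if (length(miss_w)) abort(sprintf("missing weather variable(s): %s", paste(miss_w, collapse = ", ")))
  wkey <- paste(ww$county_id, ww$year)
  widx <- split(seq_len(nrow(ww)), wkey)
  WMall <- as.matrix(ww[wv])

  pr <- bundle$progress |> dplyr::arrange(.data$county_id, .data$year, .data$week)
  pkey <- paste(pr$county_id, pr$year)
  pidx <- split(seq_len(nrow(pr)), pkey)

  n <- nrow(ct)
  blocks <- vector("list", n)
  Z <- matrix(0, n, 2L * p)
  for (i in seq_len(n)) {
    key <- paste(ct$county_id[i], ct$year[i])
    wi <- widx[[key]]
    if (is.null(wi) || length(wi) < 52L) {
      abort(sprintf("incomplete weekly weather for (%s, %s)", ct$county_id[i], ct$year[i]))
    }
    wk <- ww$week[wi]
    WM <- WMall[wi[order(wk)], , drop = FALSE][1:52, , drop = FALSE]
    if (anyNA(WM)) abort(sprintf("missing weather cell for (%s, %s)", ct$county_id[i], ct$year[i]))

    pi_ <- pidx[[key]]
    if (is.null(pi_)) abort(sprintf("missing progress curve for (%s, %s)", ct$county_id[i], ct$year[i]))
    P <- H <- rep(NA_real_, 52)
    P[pr$week[pi_]] <- pr$planting[pi_]
    H[pr$week[pi_]] <- pr$harvesting[pi_]
    P <- locf_fill(P, 0)
    H <- locf_fill(H, 0)

    svec <- S[ct$county_id[i], ]
    if (anyNA(svec)) abort(sprintf("missing soil value for county %s", ct$county_id[i]))
    ph <- ct$density[i] * (P - H)
    w_star <- ct$division_week[i]
    phi <- quad_feature_matrix(WM, svec)
    veg <- seq_len(52L) < w_star
    zv <- crossprod(phi[veg, , drop = FALSE], ph[veg])
    zr <- crossprod(phi[!veg, , drop = FALSE], ph[!veg])
    Z[i, ] <- c(zv, zr)
    blocks[[i]] <- list(WM = WM, ph = ph, w_star = w_star)
  }

  list(ct = ct, Z = Z, blocks = blocks, S = S,
       weather_vars = wv, soil_vars = sv, terms = terms, p = p,
       scalers = scalers)
}

# Genetic multiplier per county-year record; errors when a district has no
# coefficients unless a fallback matrix is supplied (used by
# leave-one-county-out evaluation). The polynomial is only constrained on
# the training window, so the normalized year is clamped to [0, 1]:
# predictions outside the window carry the nearest training year's genetic
# level instead of extrapolating a high-order polynomial.
genetic_multiplier <- function(params, ct, fallback_alpha = NULL) {
  K <- attr(params, "K")
  alpha <- params$alpha
  idx <- match(ct$district_id, rownames(alpha))
  if (anyNA(idx)) {
    missing <- unique(ct$district_id[is.na(idx)])
    if (is.null(fallback_alpha)) {
      abort(sprintf("no genetic coefficients for district(s): %s",
                    paste(missing, collapse = ", ")))
    }
    alpha <- rbind(alpha, fallback_alpha[missing, , drop = FALSE])
    idx <- match(ct$district_id, rownames(alpha))
  }
  tp <- outer(pmin(pmax(ct$t_norm, 0), 1), 0:K, `^`)
  unname(rowSums(tp * alpha[idx, , drop = FALSE]))
}

predict_from_prep <- function(params, prep, fallback_alpha = NULL) {
  gam <- c(params$gamma_v, params$gamma_r)
  if (length(gam) != ncol(prep$Z)) {
    abort(sprintf("parameter term set (%d per stage) does not match bundle variables (%d per stage)",
                  length(params$gamma_v), prep$p))
  }
  m <- as.numeric(prep$Z %*% gam)
  gvec <- genetic_multiplier(params, prep$ct, fallback_alpha)
  gvec * m
}

# ---- exported model operations ------------------------------------------

#' Weekly growth potential for one observation
#'
#' Evaluates the stage-specific quadratic form: intercept + linear terms +
#' all pairwise products (weather-weather including squares, soil-soil,
#' weather-soil) at one week's normalized weather vector and a county's
#' normalized soil vector.
#'
#' @param params a [gem_params()] object.
#' @param weather numeric vector, one value per weather variable.
#' @param soil numeric vector, one value per soil variable.
#' @param stage `"vegetative"` or `"reproductive"`.
#' @return a single numeric growth potential.
#' @export
growth_potential_week <- function(params, weather, soil,
                                  stage = c("vegetative", "reproductive")) {
  stage <- match.arg(stage)
  wv <- attr(params, "weather_vars")
  sv <- attr(params, "soil_vars")
  if (length(weather) != length(wv)) {
    abort(sprintf("expected %d weather values, got %d", length(wv), length(weather)))
  }
  if (length(soil) != length(sv)) {
    abort(sprintf("expected %d soil values, got %d", length(sv), length(soil)))
  }
  phi <- quad_feature_matrix(matrix(as.numeric(weather), 1), as.numeric(soil))
  gam <- if (stage == "vegetative") params$gamma_v else params$gamma_r
  as.numeric(phi %*% gam)
}

#' Weekly growth potential panel
#'
#' Computes the growth potential for every (county, year, week) covered by
#' the bundle's yield records, using the vegetative coefficients before each
#' record's division week and the reproductive coefficients from it on.
#'
#' @param params a [gem_params()].
#' @param bundle a normalized [gem_bundle()].
#' @return tibble with columns `county_id`, `year`, `week`, `stage`,
#'   `potential`.
#' @export
growth_matrix <- function(params, bundle) {
  prep <- prep_panel(bundle)
  weekly_growth(params, prep)
}

weekly_growth <- function(params, prep) {
  n <- nrow(prep$ct)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    b <- prep$blocks[[i]]
    phi <- quad_feature_matrix(b$WM, prep$S[prep$ct$county_id[i], ])
    veg <- seq_len(52L) < b$w_star
    G <- numeric(52)
    G[veg] <- phi[veg, , drop = FALSE] %*% params$gamma_v
    G[!veg] <- phi[!veg, , drop = FALSE] %*% params$gamma_r
    out[[i]] <- tibble::tibble(
      county_id = prep$ct$county_id[i], year = prep$ct$year[i],
      week = 1:52,
      stage = ifelse(veg, "vegetative", "reproductive"),
      potential = G)
  }
  dplyr::bind_rows(out)
}

#' Predict county-year yield
#'
#' @param params a [gem_params()].
#' @param bundle a normalized [gem_bundle()].
#' @return tibble `county_id`, `year`, `yhat` (bu/ac).
#' @export
predict_yield <- function(params, bundle) {
  prep <- prep_panel(bundle)
  tibble::tibble(county_id = prep$ct$county_id, year = prep$ct$year,
                 yhat = predict_from_prep(params, prep))
}

#' Decompose predicted yield into G, E and M components
#'
#' The environment component `e` is the season sum of positive weekly growth
#' potentials (the maximally achievable yield under the observed weather and
#' soil); the genetics component `g` is the district polynomial value in
#' `[0, 1]`; the management component `m` is the fraction of `e` captured by
#' density and planting/harvesting timing. Whenever `e > 0`, the product
#' `g * e * m` equals the predicted yield exactly; when `e = 0` the record
#' is flagged and `m` is set to 0 while `yhat` still comes from the forward
#' model directly.
#'
#' @param params a [gem_params()].
#' @param bundle a normalized [gem_bundle()].
#' @return tibble `county_id`, `year`, `g`, `e`, `m`, `yhat`,
#'   `degenerate_e`.
#' @export
decompose_yield <- function(params, bundle) {
  prep <- prep_panel(bundle)
  decompose_from_prep(params, prep)
}

decompose_from_prep <- function(params, prep, fallback_alpha = NULL) {
  gw <- weekly_growth(params, prep)
  e <- gw |>
    dplyr::group_by(.data$county_id, .data$year) |>
    dplyr::summarise(e = sum(pmax(.data$potential, 0)), .groups = "drop")
  gvec <- genetic_multiplier(params, prep$ct, fallback_alpha)
  gam <- c(params$gamma_v, params$gamma_r)
  raw <- as.numeric(prep$Z %*% gam)  # sum_w D (P - H) G_w
  out <- tibble::tibble(county_id = prep$ct$county_id, year = prep$ct$year,
                        g = gvec, raw = raw) |>
    dplyr::left_join(e, by = c("county_id", "year")) |>
    dplyr::mutate(
      degenerate_e = .data$e <= 0,
      m = dplyr::if_else(.data$degenerate_e, 0, .data$raw / .data$e),
      yhat = .data$g * .data$raw) |>
    dplyr::select("county_id", "year", "g", "e", "m", "yhat", "degenerate_e")
  out
}
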