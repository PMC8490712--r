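# Min-max normalization of explanatory variables. Yield and planted area are
# left in natural units (bu/ac, acres): the error metric and the prediction
# cap both operate on the bu/ac scale. Planting/harvesting progress is
# already a fraction.

#' Fit min-max scalers on a bundle
#'
#' One `(min, max)` pair per weather variable (over all county-week-year
#' cells), per soil variable (over counties), for plant density (over
#' county-years) and for the year index (over the yield table's years). For
#' out-of-sample evaluation the scalers are fit on the training scope only
#' and re-applied to held-out data.
#'
#' @param bundle an un-normalized [gem_bundle()].
#' @return object of class `gem_scalers`.
#' @export
gem_scalers <- function(bundle) {
  rng <- function(x) c(min = min(x), max = max(x))
  weather <- bundle$weather |>
    dplyr::group_by(.data$var) |>
    dplyr::summarise(min = min(.data$value), max = max(.data$value), .groups = "drop")
  soil <- bundle$soil |>
    dplyr::group_by(.data$var) |>
    dplyr::summarise(min = min(.data$value), max = max(.data$value), .groups = "drop")
  structure(list(
    weather = weather,
    soil = soil,
    density = rng(bundle$density$density),
    year = rng(bundle$yields$year)
  ), class = "gem_scalers")
}

#' @export
print.gem_scalers <- function(x, ...) {
  cat(sprintf("<gem_scalers> %d weather vars, %d soil vars; years [%s, %s]\n",
              nrow(x$weather), nrow(x$soil), x$year[["min"]], x$year[["max"]]))
  invisible(x)
}

scale_minmax <- function(x, lo, hi) {
  if (hi <= lo) {
    warn(sprintf("variable is constant over the scaling scope (min = max = %g); mapped to 0", lo))
    return(rep(0, length(x)))
  }
  (x - lo) / (hi - lo)
}

unscale_minmax <- function(x, lo, hi) {
  lo <- rep_len(lo, length(x))
  hi <- rep_len(hi, length(x))
  ifelse(hi <= lo, lo, x * (hi - lo) + lo)
}

#' Normalize a bundle to the unit interval
#'
#' Applies min-max scaling to every weather variable, every soil variable,
#' and plant density. The year scaler is stored for use by the genetic trend
#' polynomial but the year column itself keeps its natural values. Yield,
#' area and the progress fractions are untouched. Supplying `scalers`
#' re-applies a previously fit scaling (the training scope's), which is how
#' held-out data must be normalized; values may then fall slightly outside
#' `[0, 1]`.
#'
#' @param bundle an un-normalized [gem_bundle()].
#' @param scalers optional [gem_scalers()] to apply; fit from `bundle` when
#'   `NULL`.
#' @return a normalized `gem_bundle` carrying its scalers in
#'   `attr(x, "scalers")`.
#' @export
normalize_bundle <- function(bundle, scalers = NULL) {
  if (is_normalized(bundle)) abort("bundle is already normalized")
  refit <- is.null(scalers)
  if (refit) scalers <- gem_scalers(bundle)

  apply_table <- function(tb, sc) {
    lut <- setNames(split(c(sc$min, sc$max), rep(seq_len(nrow(sc)), 2)), sc$var)
    miss <- setdiff(unique(tb$var), sc$var)
    if (length(miss)) {
      abort(sprintf("no scaler for variable(s): %s", paste(miss, collapse = ", ")))
    }
    tb |>
      dplyr::group_by(.data$var) |>
      dplyr::mutate(value = scale_minmax(.data$value,
                                         lut[[.data$var[1]]][1],
                                         lut[[.data$var[1]]][2])) |>
      dplyr::ungroup()
  }
  out <- bundle
  out$weather <- apply_table(bundle$weather, scalers$weather)
  out$soil <- apply_table(bundle$soil, scalers$soil)
  out$density <- dplyr::mutate(bundle$density,
                               density = scale_minmax(.data$density,
                                                      scalers$density[["min"]],
                                                      scalers$density[["max"]]))
  attr(out, "normalized") <- TRUE
  attr(out, "scalers") <- scalers
  out
}

#' Invert the normalization of a bundle
#'
#' @param bundle a normalized [gem_bundle()].
#' @return the bundle on its original scales.
#' @export
denormalize_bundle <- function(bundle) {
  if (!is_normalized(bundle)) abort("bundle is not normalized")
  scalers <- attr(bundle, "scalers")
  invert_table <- function(tb, sc) {
    tb |>
      dplyr::left_join(sc, by = "var") |>
      dplyr::mutate(value = unscale_minmax(.data$value, .data$min, .data$max)) |>
      dplyr::select(-"min", -"max")
  }
  out <- bundle
  out$weather <- invert_table(bundle$weather, scalers$weather)
  out$soil <- invert_table(bundle$soil, scalers$soil)
  out$density <- dplyr::mutate(bundle$density,
                               density = unscale_minmax(.data$density,
                                                        scalers$density[["min"]],
                                                        scalers$density[["max"]]))
  attr(out, "normalized") <- FALSE
  attr(out, "scalers") <- NULL
  out
}

# Year index on the normalized scale used by the genetic polynomial.
normalize_year <- function(year, scalers) {
  lo <- scalers$year[["min"]]
  hi <- scalers$year[["max"]]
  if (hi <= lo) return(rep(0, length(year)))
  (year - lo) / (hi - lo)
}
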