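#' Area-weighted prediction metrics
#'
#' Root mean square error and coefficient of determination with squared
#' planted area as the record weight:
#' `rmse = sqrt(sum(A^2 (y - yhat)^2) / sum(A^2))` and
#' `R2 = 1 - sum(A^2 (y - yhat)^2) / sum(A^2 (y - ybar)^2)` where `ybar` is
#' the `A^2`-weighted mean of the observations. Large-acreage counties
#' therefore dominate both metrics, and uniform rescaling of all areas
#' leaves them unchanged.
#'
#' @param data data frame holding observations and predictions.
#' @param obs,pred,weight columns (tidy-eval) with the observed yield, the
#'   predicted yield, and the planted area; defaults `yield`, `yhat`,
#'   `area`.
#' @return a single numeric value.
#' @export
weighted_rmse <- function(data, obs = yield, pred = yhat, weight = area) {
  y <- dplyr::pull(data, {{ obs }})
  p <- dplyr::pull(data, {{ pred }})
  a <- dplyr::pull(data, {{ weight }})
  ok <- is.finite(y) & is.finite(p) & is.finite(a)
  if (!any(ok)) abort("no records to score")
  w <- a[ok]^2
  sqrt(sum(w * (y[ok] - p[ok])^2) / sum(w))
}

#' @rdname weighted_rmse
#' @export
weighted_r2 <- function(data, obs = yield, pred = yhat, weight = area) {
  y <- dplyr::pull(data, {{ obs }})
  p <- dplyr::pull(data, {{ pred }})
  a <- dplyr::pull(data, {{ weight }})
  ok <- is.finite(y) & is.finite(p) & is.finite(a)
  if (sum(ok) < 2) abort("need at least two records for R^2")
  y <- y[ok]; p <- p[ok]; w <- a[ok]^2
  ybar <- sum(w * y) / sum(w)
  sst <- sum(w * (y - ybar)^2)
  if (sst <= 0) abort("zero weighted variance in observations; R^2 undefined")
  1 - sum(w * (y - p)^2) / sst
}

# Join a prediction table onto observed yields; keeps area for weighting.
join_predictions <- function(pred, yields) {
  dplyr::inner_join(yields, pred, by = c("county_id", "year"))
}
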