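# Quadratic feature expansion shared by the forward model and both QPs.
#
# The weekly growth potential is linear in the stage coefficients once the
# weather/soil observations are expanded into: an intercept, linear terms for
# every weather and soil variable, all weather-weather products (i1 <= i2,
# including squares), all soil-soil products, and all weather-soil cross
# products. The fixed term ordering below is the internal storage order for a
# stage coefficient vector; serialized files always use the term names so the
# order never leaks into the interchange format.

pair_index <- function(n) {
  if (n == 0L) return(matrix(integer(0), ncol = 2L))
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, i:n)))
}

#' Term names for one stage's coefficient vector
#'
#' @param weather_vars character vector of weather variable names (order fixed).
#' @param soil_vars character vector of soil variable names (order fixed).
#' @return character vector: `"(Intercept)"`, linear terms, then pairwise
#'   products named `"a*b"`.
#' @keywords internal
gamma_term_names <- function(weather_vars, soil_vars) {
  nw <- length(weather_vars)
  ns <- length(soil_vars)
  wp <- pair_index(nw)
  sp <- pair_index(ns)
  c(
    "(Intercept)",
    weather_vars,
    soil_vars,
    if (nrow(wp)) paste0(weather_vars[wp[, 1]], "*", weather_vars[wp[, 2]]),
    if (nrow(sp)) paste0(soil_vars[sp[, 1]], "*", soil_vars[sp[, 2]]),
    as.vector(t(outer(weather_vars, soil_vars, paste, sep = "*")))
  )
}

n_gamma_terms <- function(nw, ns) {
  1L + nw + ns + nw * (nw + 1L) %/% 2L + ns * (ns + 1L) %/% 2L + nw * ns
}

# Expand a weeks-by-weather matrix plus a static soil vector into the
# weeks-by-terms feature matrix. Soil-only terms repeat across weeks;
# weather-soil cross terms use the week-specific weather value.
quad_feature_matrix <- function(WM, S) {
  WM <- as.matrix(WM)
  nwk <- nrow(WM)
  nw <- ncol(WM)
  ns <- length(S)
  wp <- pair_index(nw)
  sp <- pair_index(ns)
  cols <- vector("list", 6L)
  cols[[1]] <- matrix(1, nwk, 1L)
  cols[[2]] <- WM
  cols[[3]] <- matrix(S, nwk, ns, byrow = TRUE)
  if (nrow(wp)) cols[[4]] <- WM[, wp[, 1], drop = FALSE] * WM[, wp[, 2], drop = FALSE]
  if (nrow(sp)) {
    cols[[5]] <- matrix(S[sp[, 1]] * S[sp[, 2]], nwk, nrow(sp), byrow = TRUE)
  }
  if (nw > 0 && ns > 0) {
    cross <- matrix(0, nwk, nw * ns)
    k <- 0L
    for (i in seq_len(nw)) {
      for (j in seq_len(ns)) {
        k <- k + 1L
        cross[, k] <- WM[, i] * S[j]
      }
    }
    cols[[6]] <- cross
  }
  do.call(cbind, cols[!vapply(cols, is.null, logical(1))])
}
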