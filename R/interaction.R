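#' Pairwise interaction map of the stage coefficients
#'
#' Summarizes how pairs of weather/soil variables jointly shape the weekly
#' growth potential. For each unordered pair of distinct variables `i, j`
#' the cell value is
#' `gamma[i,j] + (gamma[i,0] + gamma[i,i] + gamma[0,j] + gamma[j,j]) / (v - 1)`
#' where `v` is the number of variables: the bilinear term plus each
#' variable's linear and quadratic effect spread evenly over its `v - 1`
#' partners (1/16 with the full 7 weather + 10 soil set). Summing a stage's
#' cells over all pairs therefore recovers that stage's total non-intercept
#' contribution at the given observation scale. With 17 variables each stage
#' has 136 cells, 272 in total.
#'
#' @param params a [gem_params()].
#' @return tibble with columns `stage`, `var1`, `var2`, `effect`; one row
#'   per unordered pair per stage, `var1` earlier in the variable order.
#' @export
interaction_map <- function(params) {
  vars <- c(attr(params, "weather_vars"), attr(params, "soil_vars"))
  v <- length(vars)
  if (v < 2) abort("need at least two variables for an interaction map")
  pairs <- t(utils::combn(v, 2))
  one_stage <- function(gam, stage) {
    g <- function(term) unname(gam[term])
    pair_term <- function(i, j) {
      # bilinear term name in canonical order (as generated by the expansion)
      t1 <- paste0(vars[i], "*", vars[j])
      if (t1 %in% names(gam)) g(t1) else g(paste0(vars[j], "*", vars[i]))
    }
    eff <- vapply(seq_len(nrow(pairs)), function(r) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      marg <- g(vars[i]) + g(paste0(vars[i], "*", vars[i])) +
        g(vars[j]) + g(paste0(vars[j], "*", vars[j]))
      pair_term(i, j) + marg / (v - 1)
    }, numeric(1))
    tibble::tibble(stage = stage, var1 = vars[pairs[, 1]], var2 = vars[pairs[, 2]],
                   effect = eff)
  }
  dplyr::bind_rows(one_stage(params$gamma_v, "vegetative"),
                   one_stage(params$gamma_r, "reproductive"))
}

#' Interaction map as a single square matrix
#'
#' Vegetative cells fill the upper triangle, reproductive cells the lower
#' triangle; the diagonal is `NA`.
#'
#' @param params a [gem_params()].
#' @return square numeric matrix with variable names as dimnames.
#' @export
interaction_matrix <- function(params) {
  vars <- c(attr(params, "weather_vars"), attr(params, "soil_vars"))
  mp <- interaction_map(params)
  M <- matrix(NA_real_, length(vars), length(vars), dimnames = list(vars, vars))
  veg <- dplyr::filter(mp, .data$stage == "vegetative")
  rep_ <- dplyr::filter(mp, .data$stage == "reproductive")
  M[cbind(match(veg$var1, vars), match(veg$var2, vars))] <- veg$effect
  M[cbind(match(rep_$var2, vars), match(rep_$var1, vars))] <- rep_$effect
  M
}
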