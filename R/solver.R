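# Calibration heuristic: alternate two convex QPs, each fit on a random
# ~80% subsample, blend the candidate 0.2/0.8 with the incumbent, and accept
# only when the blend improves the area-weighted RMSE on the *full* record
# set; stop after two consecutive iterations without any accepted update.

#' Solver settings
#'
#' @param K polynomial order of the genetic trend (default 10).
#' @param subsample_fraction fraction of records drawn (without replacement)
#'   for each QP (default 0.8).
#' @param blend_weight_incumbent,blend_weight_candidate convex blend applied
#'   to every candidate before the acceptance check (defaults 0.2 / 0.8).
#' @param yield_cap upper bound on predicted yield in the gamma QP, bu/ac
#'   (default 300; the lower bound is 0).
#' @param genetic_level_bounds bounds on the genetic multiplier at every
#'   training (district, year) (default `c(0, 1)`).
#' @param genetic_change_bounds bounds on its change between consecutive
#'   calendar years (default `c(-0.025, 0.05)`).
#' @param stagnation_limit consecutive iterations without an accepted update
#'   before stopping (default 2).
#' @param max_iterations hard iteration cap (default 50).
#' @param rng_seed seed for the subsample draws; `NULL` uses the current RNG
#'   state.
#' @param qp_tolerance feasibility tolerance the fitted parameters are
#'   checked against (default 1e-8).
#' @return a list of class `gem_control`.
#' @export
gem_control <- function(K = 10L,
                        subsample_fraction = 0.8,
                        blend_weight_incumbent = 0.2,
                        blend_weight_candidate = 0.8,
                        yield_cap = 300,
                        genetic_level_bounds = c(0, 1),
                        genetic_change_bounds = c(-0.025, 0.05),
                        stagnation_limit = 2L,
                        max_iterations = 50L,
                        rng_seed = NULL,
                        qp_tolerance = 1e-8) {
  stopifnot(subsample_fraction > 0, subsample_fraction <= 1,
            abs(blend_weight_incumbent + blend_weight_candidate - 1) < 1e-12,
            genetic_level_bounds[1] < genetic_level_bounds[2],
            genetic_change_bounds[1] < genetic_change_bounds[2])
  structure(list(K = as.integer(K),
                 subsample_fraction = subsample_fraction,
                 blend_weight_incumbent = blend_weight_incumbent,
                 blend_weight_candidate = blend_weight_candidate,
                 yield_cap = yield_cap,
                 genetic_level_bounds = genetic_level_bounds,
                 genetic_change_bounds = genetic_change_bounds,
                 stagnation_limit = as.integer(stagnation_limit),
                 max_iterations = as.integer(max_iterations),
                 rng_seed = rng_seed,
                 qp_tolerance = qp_tolerance),
            class = "gem_control")
}

resolve_subset <- function(prep, subset) {
  if (is.null(subset)) return(seq_len(nrow(prep$ct)))
  if (is.numeric(subset)) return(as.integer(subset))
  key <- paste(prep$ct$county_id, prep$ct$year)
  idx <- which(key %in% paste(subset$county_id, subset$year))
  if (!length(idx)) abort("subset matches no county-year records")
  idx
}

# ---- stage-coefficient QP -----------------------------------------------

gamma_qp_core <- function(prep, params, idx, control) {
  gvec <- genetic_multiplier(params, prep$ct)
  X <- prep$Z * gvec
  Xs <- X[idx, , drop = FALSE]
  ys <- prep$ct$yield[idx]
  ws <- prep$ct$area[idx]^2
  # cap constraints 0 <= yhat <= yield_cap on the subsampled records
  nzrow <- apply(abs(Xs), 1, max) > 1e-14
  Acon <- rbind(Xs[nzrow, , drop = FALSE], -Xs[nzrow, , drop = FALSE])
  bcon <- c(rep(0, sum(nzrow)), rep(-control$yield_cap, sum(nzrow)))
  sol <- solve_qp_wls(Xs, ys, ws, Amat = t(Acon), bvec = bcon,
                      tol = control$qp_tolerance)
  p <- prep$p
  list(gamma_v = setNames(sol$solution[seq_len(p)], prep$terms),
       gamma_r = setNames(sol$solution[p + seq_len(p)], prep$terms))
}

#' Stage-coefficient quadratic program
#'
#' With the genetic coefficients held fixed, the growth-potential
#' coefficients of both stages minimize the area-squared-weighted squared
#' error over the given subset, subject to every subset record's predicted
#' yield lying in `[0, yield_cap]`. The problem is a convex QP (the
#' objective is a weighted least-squares form, the constraints linear).
#'
#' @param bundle a normalized [gem_bundle()].
#' @param params incumbent [gem_params()] supplying the fixed genetic
#'   coefficients.
#' @param subset tibble of (`county_id`, `year`) records to fit on, or
#'   `NULL` for all.
#' @param control a [gem_control()].
#' @return list with named vectors `gamma_v`, `gamma_r`.
#' @export
solve_gamma_qp <- function(bundle, params, subset = NULL, control = gem_control()) {
  prep <- prep_panel(bundle)
  gamma_qp_core(prep, params, resolve_subset(prep, subset), control)
}

# ---- genetic-coefficient QP ---------------------------------------------

alpha_qp_core <- function(prep, params, idx, control) {
  K <- control$K
  gam <- c(params$gamma_v, params$gamma_r)
  m <- as.numeric(prep$Z %*% gam)
  ct <- prep$ct
  ds <- sort(unique(ct$district_id[idx]))
  nd <- length(ds)
  nb <- K + 1L
  sub_d <- match(ct$district_id[idx], ds)
  tp <- outer(ct$t_norm[idx], 0:K, `^`)
  n_sub <- length(idx)
  X <- matrix(0, n_sub, nd * nb)
  for (r in seq_len(n_sub)) {
    X[r, (sub_d[r] - 1L) * nb + seq_len(nb)] <- m[idx[r]] * tp[r, ]
  }
  # bounds on the genetic multiplier at every training (district, year) and
  # on its change across consecutive calendar years
  years <- sort(unique(ct$year))
  tn <- normalize_year(years, prep$scalers)
  V <- outer(tn, 0:K, `^`)
  consec <- which(diff(years) == 1L)
  DV <- V[consec + 1L, , drop = FALSE] - V[consec, , drop = FALSE]
  lv <- control$genetic_level_bounds
  cb <- control$genetic_change_bounds
  one_block <- rbind(V, -V, DV, -DV)
  one_b <- c(rep(lv[1], nrow(V)), rep(-lv[2], nrow(V)),
             rep(cb[1], nrow(DV)), rep(-cb[2], nrow(DV)))
  Acon <- matrix(0, nd * nrow(one_block), nd * nb)
  bcon <- rep(one_b, nd)
  for (d in seq_len(nd)) {
    rows <- (d - 1L) * nrow(one_block) + seq_len(nrow(one_block))
    Acon[rows, (d - 1L) * nb + seq_len(nb)] <- one_block
  }
  sol <- solve_qp_wls(X, ct$yield[idx], ct$area[idx]^2,
                      Amat = t(Acon), bvec = bcon, tol = control$qp_tolerance)
  alpha <- params$alpha
  for (d in seq_len(nd)) {
    alpha[ds[d], ] <- sol$solution[(d - 1L) * nb + seq_len(nb)]
  }
  alpha
}

#' Genetic-coefficient quadratic program
#'
#' With the growth panel from the incumbent stage coefficients held fixed,
#' the district-level genetic polynomial coefficients minimize the weighted
#' squared error over the subset, subject to (a) counties in a district
#' sharing coefficients (built into the parameterization), (b) the genetic
#' multiplier lying in `[0, 1]` at every training (district, year), and
#' (c) its change between consecutive calendar years lying in
#' `[-2.5%, +5%]`. Districts with no record in the subset keep the
#' incumbent coefficients.
#'
#' @inheritParams solve_gamma_qp
#' @return alpha matrix (districts x K+1).
#' @export
solve_alpha_qp <- function(bundle, params, subset = NULL, control = gem_control()) {
  prep <- prep_panel(bundle)
  alpha_qp_core(prep, params, resolve_subset(prep, subset), control)
}

# ---- alternating heuristic ----------------------------------------------

rmse_of <- function(params, prep, control) {
  yhat <- predict_from_prep(params, prep)
  sqrt(sum(prep$ct$area^2 * (prep$ct$yield - yhat)^2) / sum(prep$ct$area^2))
}

blend_core <- function(prep, params, candidate, control, rmse_incumbent = NULL) {
  wi <- control$blend_weight_incumbent
  wc <- control$blend_weight_candidate
  try_params <- params
  if (is.matrix(candidate)) {
    try_params$alpha <- wi * params$alpha + wc * candidate
  } else {
    try_params$gamma_v <- wi * params$gamma_v + wc * candidate$gamma_v
    try_params$gamma_r <- wi * params$gamma_r + wc * candidate$gamma_r
  }
  if (is.null(rmse_incumbent)) rmse_incumbent <- rmse_of(params, prep, control)
  rmse_candidate <- rmse_of(try_params, prep, control)
  accepted <- rmse_candidate < rmse_incumbent
  list(params = if (accepted) try_params else params,
       accepted = accepted,
       rmse_candidate = rmse_candidate,
       rmse = if (accepted) rmse_candidate else rmse_incumbent)
}

#' Blend a QP candidate into the incumbent and test acceptance
#'
#' Forms the convex combination `0.2 * incumbent + 0.8 * candidate` of the
#' relevant coefficient block and accepts it only if the blend strictly
#' improves the area-weighted RMSE over *all* records of the bundle (not
#' just the subsample the candidate was fit on). The incumbent is returned
#' unchanged on rejection.
#'
#' @param bundle a normalized [gem_bundle()].
#' @param params incumbent [gem_params()].
#' @param candidate either the list returned by [solve_gamma_qp()] or the
#'   alpha matrix returned by [solve_alpha_qp()].
#' @param control a [gem_control()].
#' @return list with `params` (new incumbent), `accepted` (logical),
#'   `rmse_candidate` and `rmse` (full-data weighted RMSE of the returned
#'   incumbent).
#' @export
blend_and_accept <- function(bundle, params, candidate, control = gem_control()) {
  prep <- prep_panel(bundle)
  blend_core(prep, params, candidate, control)
}

#' Calibrate the model by alternating quadratic programs
#'
#' Starts from a constant genetic multiplier of 1 and all-zero stage
#' coefficients, then repeats: (1) solve the stage-coefficient QP on a fresh
#' random subsample of about `subsample_fraction` of the records, blend the
#' solution `0.2 * incumbent + 0.8 * candidate`, and accept it only if it
#' strictly improves the full-data weighted RMSE; (2) the same for the
#' genetic-coefficient QP. Stops once `stagnation_limit` consecutive
#' iterations pass without an accepted update (or at `max_iterations`).
#' The subsample-then-validate-on-everything acceptance rule is what keeps
#' the greedy alternation from overfitting individual draws.
#'
#' @param bundle a [gem_bundle()]; normalized as-is, or normalized
#'   internally (fitting scalers on the bundle) when not.
#' @param control a [gem_control()].
#' @return object of class `gem_fit`: `params`, `scalers`, `trace` (one row
#'   per QP step: iteration, step, candidate and incumbent full-data RMSE,
#'   acceptance flag, subset size), `final_rmse`, plus bookkeeping
#'   (`years`, `counties`, `districts`, `n_records`, `control`).
#' @export
fit_gem <- function(bundle, control = gem_control()) {
  if (!is_normalized(bundle)) bundle <- normalize_bundle(bundle)
  prep <- prep_panel(bundle)
  if (!all(is.finite(prep$ct$yield)) || !all(is.finite(prep$Z))) {
    abort("non-finite values in the prepared panel")
  }
  if (!is.null(control$rng_seed)) withr::local_seed(control$rng_seed)

  districts <- sort(unique(prep$ct$district_id))
  alpha0 <- matrix(0, length(districts), control$K + 1L,
                   dimnames = list(districts, paste0("k", 0:control$K)))
  alpha0[, 1] <- 1
  params <- gem_params(alpha0, weather_vars = prep$weather_vars,
                       soil_vars = prep$soil_vars, K = control$K)
  rmse_inc <- rmse_of(params, prep, control)

  n <- nrow(prep$ct)
  n_sub <- max(1L, floor(control$subsample_fraction * n))
  trace <- list()
  stagnant <- 0L
  for (it in seq_len(control$max_iterations)) {
    accepted_any <- FALSE

    idx1 <- sort(sample.int(n, n_sub))
    cand_g <- gamma_qp_core(prep, params, idx1, control)
    res <- blend_core(prep, params, cand_g, control, rmse_inc)
    params <- res$params
    rmse_inc <- res$rmse
    accepted_any <- accepted_any || res$accepted
    trace[[length(trace) + 1L]] <- tibble::tibble(
      iteration = it, step = "gamma", rmse_candidate = res$rmse_candidate,
      rmse_incumbent = rmse_inc, accepted = res$accepted, n_subset = n_sub)

    idx2 <- sort(sample.int(n, n_sub))
    cand_a <- alpha_qp_core(prep, params, idx2, control)
    res <- blend_core(prep, params, cand_a, control, rmse_inc)
    params <- res$params
    rmse_inc <- res$rmse
    accepted_any <- accepted_any || res$accepted
    trace[[length(trace) + 1L]] <- tibble::tibble(
      iteration = it, step = "alpha", rmse_candidate = res$rmse_candidate,
      rmse_incumbent = rmse_inc, accepted = res$accepted, n_subset = n_sub)

    stagnant <- if (accepted_any) 0L else stagnant + 1L
    if (stagnant >= control$stagnation_limit) break
  }

  structure(list(
    params = params,
    scalers = attr(bundle, "scalers"),
    trace = dplyr::bind_rows(trace),
    final_rmse = rmse_inc,
    control = control,
    years = sort(unique(prep$ct$year)),
    counties = sort(unique(prep$ct$county_id)),
    districts = districts,
    n_records = n
  ), class = "gem_fit")
}

#' @export
print.gem_fit <- function(x, ...) {
  cat(sprintf(
    "<gem_fit> %d records, %d districts, years %s-%s | %d iterations, %d accepted updates\n",
    x$n_records, length(x$districts), min(x$years), max(x$years),
    max(x$trace$iteration), sum(x$trace$accepted)))
  cat(sprintf("  full-data weighted RMSE: %.3f bu/ac\n", x$final_rmse))
  invisible(x)
}

#' Predict from a calibrated model
#'
#' @param object a `gem_fit`.
#' @param bundle a [gem_bundle()] with the covariates to predict for; if not
#'   yet normalized, the fit's stored scalers are applied (never refit), so
#'   held-out data is scaled exactly as the training data was.
#' @param ... unused.
#' @return tibble `county_id`, `year`, `yhat`.
#' @export
predict.gem_fit <- function(object, bundle, ...) {
  if (!is_normalized(bundle)) bundle <- normalize_bundle(bundle, object$scalers)
  predict_yield(object$params, bundle)
}

#' @describeIn fit_gem coefficient table of the fitted parameters.
#' @param x a `gem_fit`.
#' @param ... unused.
#' @export
tidy.gem_fit <- function(x, ...) tidy(x$params)

#' @describeIn fit_gem one-row model summary.
#' @export
glance.gem_fit <- function(x, ...) {
  tibble::tibble(
    final_rmse = x$final_rmse,
    n_iterations = max(x$trace$iteration),
    n_accepted = sum(x$trace$accepted),
    n_records = x$n_records,
    n_districts = length(x$districts),
    K = x$control$K)
}
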