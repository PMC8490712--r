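test_that("stage-coefficient QP recovers a feasible truth and matches the WLS oracle", {
  sim <- small_sim()
  nb <- normalize_bundle(sim$bundle)
  truth <- sim$truth$params
  ctl <- gem_control(K = attr(truth, "K"))

  # noise-free data with the genetic block fixed at truth: the true gamma is
  # feasible and attains (near-)zero weighted squared error
  cand <- solve_gamma_qp(nb, truth, subset = NULL, control = ctl)
  fitted <- truth
  fitted$gamma_v <- cand$gamma_v
  fitted$gamma_r <- cand$gamma_r
  obs <- dplyr::inner_join(predict_yield(fitted, nb), sim$bundle$yields,
                           by = c("county_id", "year"))
  sse <- sum(obs$area^2 * (obs$yield - obs$yhat)^2)
  expect_lt(sse, 1e-6 * sum(obs$area^2 * obs$yield^2))

  # with the cap slack, the constrained QP equals the closed-form weighted
  # least squares solution (normal equations oracle)
  prep <- gemyield:::prep_panel(nb)
  gvec <- gemyield:::genetic_multiplier(truth, prep$ct)
  X <- prep$Z * gvec
  keep <- which(colSums(abs(X)) > 1e-10)  # identified columns
  w <- prep$ct$area^2 / mean(prep$ct$area^2)
  beta_ols <- solve(crossprod(X[, keep], X[, keep] * w),
                    crossprod(X[, keep], w * prep$ct$yield))
  yhat_ols <- X[, keep] %*% beta_ols
  expect_true(all(yhat_ols > -1e-8 & yhat_ols < ctl$yield_cap))  # cap slack
  qp_beta <- c(cand$gamma_v, cand$gamma_r)[keep]
  expect_equal(unname(qp_beta), as.numeric(beta_ols), tolerance = 1e-6)
})

test_that("the prediction cap binds when the unconstrained fit exceeds it", {
  sim <- small_sim()
  nb <- normalize_bundle(sim$bundle)
  truth <- sim$truth$params
  # lower the cap below observed yields so the unconstrained optimum violates it
  cap <- 0.6 * max(sim$bundle$yields$yield)
  ctl <- gem_control(K = attr(truth, "K"), yield_cap = cap)
  cand <- solve_gamma_qp(nb, truth, subset = NULL, control = ctl)
  fitted <- truth
  fitted$gamma_v <- cand$gamma_v
  fitted$gamma_r <- cand$gamma_r
  yhat <- predict_yield(fitted, nb)$yhat
  expect_true(all(yhat <= cap + 1e-6))
  expect_true(all(yhat >= -1e-6))
  expect_gt(max(yhat), cap - 1e-3)  # the bound is active, not vacuous
})

test_that("genetic QP satisfies sharing, level, and change constraints", {
  sim <- small_sim()
  nb <- normalize_bundle(sim$bundle)
  truth <- sim$truth$params
  K <- attr(truth, "K")
  ctl <- gem_control(K = K)

  alpha <- solve_alpha_qp(nb, truth, subset = NULL, control = ctl)
  # district sharing: one coefficient row per district, used by every county
  expect_setequal(rownames(alpha), unique(sim$bundle$geography$district_id))

  years <- sort(unique(sim$bundle$yields$year))
  tn <- (years - min(years)) / (max(years) - min(years))
  V <- outer(tn, 0:K, `^`)
  G <- V %*% t(alpha)
  expect_true(all(G >= -1e-6 & G <= 1 + 1e-6))
  dG <- apply(G, 2, diff)
  expect_true(all(dG >= -0.025 - 1e-6 & dG <= 0.05 + 1e-6))

  # noise-free with gamma at truth: recovered genetic curves match the true
  # curves at every training year
  G_true <- V %*% t(truth$alpha)
  expect_equal(unname(G[, rownames(truth$alpha)]), unname(G_true), tolerance = 1e-4)
})

test_that("a forced jump in yields is clipped to the change bounds", {
  sim <- small_sim()
  b <- sim$bundle
  # double the yields from one year onward: the unconstrained per-district
  # polynomial fit wants a year-over-year genetic jump far above 5%
  jump_year <- 2006
  b$yields$yield <- b$yields$yield * ifelse(b$yields$year >= jump_year, 2, 1)
  nb <- normalize_bundle(b)
  truth <- sim$truth$params
  K <- attr(truth, "K")
  ctl <- gem_control(K = K)

  years <- sort(unique(b$yields$year))
  tn <- (years - min(years)) / (max(years) - min(years))
  V <- outer(tn, 0:K, `^`)

  # oracle: unconstrained weighted fit of the genetic block shows the jump
  prep <- gemyield:::prep_panel(nb)
  m <- as.numeric(prep$Z %*% c(truth$gamma_v, truth$gamma_r))
  d1 <- rownames(truth$alpha)[1]
  rows <- prep$ct$district_id == d1
  Xd <- outer(prep$ct$t_norm[rows], 0:K, `^`) * m[rows]
  bu <- solve(crossprod(Xd), crossprod(Xd, prep$ct$yield[rows]))
  expect_gt(max(diff(as.numeric(V %*% bu))), 0.05)

  # the constrained QP keeps every district inside the bounds
  alpha <- solve_alpha_qp(nb, truth, subset = NULL, control = ctl)
  dG <- apply(V %*% t(alpha), 2, diff)
  expect_true(all(dG <= 0.05 + 1e-6 & dG >= -0.025 - 1e-6))
})

test_that("blending follows the 0.2/0.8 rule and rejects non-improving candidates", {
  sim <- small_sim()
  nb <- normalize_bundle(sim$bundle)
  truth <- sim$truth$params
  ctl <- gem_control(K = attr(truth, "K"))

  # candidate identical to the incumbent: nothing changes, nothing accepted
  same <- list(gamma_v = truth$gamma_v, gamma_r = truth$gamma_r)
  res <- blend_and_accept(nb, truth, same, ctl)
  expect_false(res$accepted)
  expect_identical(res$params$gamma_v, truth$gamma_v)

  # a worse candidate is rejected and the incumbent is bit-identical
  worse <- list(gamma_v = truth$gamma_v * 5, gamma_r = truth$gamma_r * 5)
  res_w <- blend_and_accept(nb, truth, worse, ctl)
  expect_false(res_w$accepted)
  expect_identical(res_w$params, truth)

  # an improving candidate is accepted as the exact convex combination
  start <- truth
  start$gamma_v <- truth$gamma_v * 0.2
  start$gamma_r <- truth$gamma_r * 0.2
  better <- list(gamma_v = truth$gamma_v, gamma_r = truth$gamma_r)
  res_b <- blend_and_accept(nb, start, better, ctl)
  expect_true(res_b$accepted)
  expect_equal(res_b$params$gamma_v,
               0.2 * start$gamma_v + 0.8 * better$gamma_v, tolerance = 1e-12)
  rmse_start <- weighted_rmse(dplyr::inner_join(
    predict_yield(start, nb), sim$bundle$yields, by = c("county_id", "year")))
  expect_lt(res_b$rmse, rmse_start)
})

test_that("the alternating heuristic improves monotonically, stops on stagnation, and is seed-reproducible", {
  sim <- small_sim()
  ctl <- gem_control(K = 3, rng_seed = 99)
  fit1 <- fit_gem(sim$bundle, ctl)
  fit2 <- fit_gem(sim$bundle, ctl)
  expect_identical(fit1$trace, fit2$trace)
  expect_identical(fit1$params$alpha, fit2$params$alpha)
  expect_identical(fit1$params$gamma_v, fit2$params$gamma_v)

  # incumbent RMSE never increases
  expect_true(all(diff(fit1$trace$rmse_incumbent) <= 1e-12))
  # accepted steps strictly improve
  acc <- fit1$trace$accepted
  expect_true(all(fit1$trace$rmse_candidate[acc] <=
                    c(Inf, fit1$trace$rmse_incumbent)[which(acc)]))

  # termination: the last two iterations contain no accepted update
  iters <- split(fit1$trace$accepted, fit1$trace$iteration)
  n_it <- length(iters)
  if (n_it < ctl$max_iterations) {
    expect_false(any(iters[[n_it]]))
    expect_false(any(iters[[n_it - 1]]))
  }
  # and no earlier pair of consecutive stagnant iterations exists
  stagnant <- !vapply(iters, any, logical(1))
  runs <- rle(stagnant)
  early <- runs$lengths[runs$values]
  if (length(early) > 1) expect_true(all(head(early, -1) < 2))

  # a different seed draws different subsets (trace differs)
  fit3 <- fit_gem(sim$bundle, gem_control(K = 3, rng_seed = 100))
  expect_false(identical(fit1$trace, fit3$trace))
})

test_that("noise-free calibration recovers the generating model's predictions", {
  sim <- noise_free_sim()
  fit <- cached("nf_fit", fit_gem(sim$bundle, gem_control(rng_seed = 42)))
  mean_yield <- mean(sim$bundle$yields$yield)
  expect_lt(fit$final_rmse, 0.02 * mean_yield)
  # fitted parameters respect the constraint system at tolerance
  years <- fit$years
  tn <- (years - min(years)) / (max(years) - min(years))
  V <- outer(tn, 0:fit$control$K, `^`)
  G <- V %*% t(fit$params$alpha)
  expect_true(all(G >= -1e-6 & G <= 1 + 1e-6))
  dG <- apply(G, 2, diff)
  expect_true(all(dG >= -0.025 - 1e-6 & dG <= 0.05 + 1e-6))
})
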