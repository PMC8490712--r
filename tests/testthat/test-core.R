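test_that("yield prediction matches hand-evaluated cases", {
  # constant growth potential c = 0.3 via intercept-only coefficients in both
  # stages; D = 1, P - H = 1 all year, genetic multiplier 1  ->  yhat = 52 c
  b <- tiny_bundle(planting = rep(1, 52), harvesting = rep(0, 52))
  nb <- normalize_identity(b)
  p <- gem_params(matrix(c(1, 0), 1, 2, dimnames = list("D01", c("k0", "k1"))),
                  gamma_v = c("(Intercept)" = 0.3), gamma_r = c("(Intercept)" = 0.3),
                  weather_vars = "w1", soil_vars = "s1", K = 1)
  pred <- predict_yield(p, nb)
  expect_equal(pred$yhat, rep(52 * 0.3, 4), tolerance = 1e-12)

  # harvest tracking planting exactly -> nothing in the ground -> 0
  b0 <- tiny_bundle(planting = rep(1, 52), harvesting = rep(1, 52))
  pred0 <- predict_yield(p, normalize_identity(b0))
  expect_equal(pred0$yhat, rep(0, 4))

  # two live weeks with G = (100, 50), D = 0.8, genetic multiplier 0.5:
  # yhat = 0.5 * 0.8 * 150 = 60
  wfun <- function(cid, yr) c(100, 50, rep(0, 50))
  b2 <- tiny_bundle(weather_fn = wfun, soil_val = 0,
                    density_val = 0.8,
                    planting = rep(1, 52),
                    harvesting = c(0, 0, rep(1, 50)))
  nb2 <- normalize_identity(b2)
  p2 <- gem_params(matrix(c(0.5, 0), 1, 2, dimnames = list("D01", c("k0", "k1"))),
                   gamma_r = c("w1" = 1),
                   weather_vars = "w1", soil_vars = "s1", K = 1)
  pred2 <- predict_yield(p2, nb2)
  expect_equal(pred2$yhat, rep(60, 4), tolerance = 1e-12)
})

test_that("growth panel switches coefficient sets exactly at the division week", {
  b <- tiny_bundle()  # division week 19
  nb <- normalize_identity(b)
  p <- gem_params(matrix(1, 1, 1, dimnames = list("D01", "k0")),
                  gamma_v = c("(Intercept)" = 1), gamma_r = c("(Intercept)" = 2),
                  weather_vars = "w1", soil_vars = "s1", K = 0)
  gm <- growth_matrix(p, nb)
  one <- dplyr::filter(gm, county_id == "C01", year == 2000)
  expect_equal(one$potential, c(rep(1, 18), rep(2, 34)))
  expect_equal(one$stage, c(rep("vegetative", 18), rep("reproductive", 34)))

  # equal stage coefficients behave as a single-stage model
  p_same <- gem_params(matrix(1, 1, 1, dimnames = list("D01", "k0")),
                       gamma_v = c("w1" = 2, "s1" = 1), gamma_r = c("w1" = 2, "s1" = 1),
                       weather_vars = "w1", soil_vars = "s1", K = 0)
  gm2 <- growth_matrix(p_same, nb)
  manual <- growth_potential_week(p_same, 0.5, 0.2, "vegetative")
  expect_true(all(abs(gm2$potential - manual) < 1e-12))

  # growth panel equals brute-force weekly evaluation
  sim <- small_sim()
  nbs <- normalize_bundle(sim$bundle)
  gms <- growth_matrix(sim$truth$params, nbs)
  wlong <- nbs$weather
  slong <- nbs$soil
  cal <- stage_calendar(nbs)
  set.seed(3)
  pick <- gms[sample.int(nrow(gms), 25), ]
  for (i in seq_len(nrow(pick))) {
    r <- pick[i, ]
    wval <- wlong$value[wlong$county_id == r$county_id & wlong$year == r$year &
                          wlong$week == r$week]
    sval <- slong$value[slong$county_id == r$county_id]
    stg <- if (r$week < cal$division_week[cal$county_id == r$county_id &
                                            cal$year == r$year]) "vegetative" else "reproductive"
    expect_equal(r$potential,
                 growth_potential_week(sim$truth$params, wval, sval, stg),
                 tolerance = 1e-10)
  }
})

test_that("decomposition components follow their definitions and multiply back", {
  # weekly G = (10, -5, 20) on three live weeks, weights D(P-H) = (1, 1, 0.5),
  # genetic multiplier 0.9: e = 30, raw = 15, m = 0.5, yhat = 13.5
  wfun <- function(cid, yr) c(10, -5, 20, rep(0, 49))
  b <- tiny_bundle(weather_fn = wfun, soil_val = 0, density_val = 1,
                   planting = rep(1, 52),
                   harvesting = c(0, 0, 0.5, rep(1, 49)))
  nb <- normalize_identity(b)
  p <- gem_params(matrix(c(0.9, 0), 1, 2, dimnames = list("D01", c("k0", "k1"))),
                  gamma_r = c("w1" = 1),
                  weather_vars = "w1", soil_vars = "s1", K = 1)
  dec <- decompose_yield(p, nb)
  expect_equal(dec$g, rep(0.9, 4))
  expect_equal(dec$e, rep(30, 4))
  expect_equal(dec$m, rep(0.5, 4))
  expect_equal(dec$yhat, rep(13.5, 4))
  expect_false(any(dec$degenerate_e))
  expect_equal(dec$g * dec$e * dec$m, dec$yhat, tolerance = 1e-12)

  # all-negative weekly potential: e = 0, m = 0, yhat still from the model
  wneg <- function(cid, yr) rep(-2, 52)
  bneg <- tiny_bundle(weather_fn = wneg, soil_val = 0, density_val = 1,
                      planting = rep(1, 52), harvesting = rep(0, 52))
  decn <- decompose_yield(p, normalize_identity(bneg))
  expect_true(all(decn$degenerate_e))
  expect_equal(decn$e, rep(0, 4))
  expect_equal(decn$m, rep(0, 4))
  expect_equal(decn$yhat, rep(0.9 * 52 * -2, 4))

  # identity holds across a full synthetic panel
  sim <- default_sim()
  nbs <- normalize_bundle(sim$bundle, sim$truth$scalers)
  decs <- decompose_yield(sim$truth$params, nbs)
  pos <- decs[!decs$degenerate_e, ]
  expect_gt(nrow(pos), 0)
  expect_equal(pos$g * pos$e * pos$m, pos$yhat, tolerance = 1e-9)
})

test_that("prediction is linear in each coefficient block (superposition)", {
  sim <- small_sim()
  nb <- normalize_bundle(sim$bundle)
  p1 <- sim$truth$params
  p2 <- p1
  set.seed(11)
  p2$gamma_v <- setNames(rnorm(length(p1$gamma_v)), names(p1$gamma_v))
  p2$gamma_r <- setNames(rnorm(length(p1$gamma_r)), names(p1$gamma_r))
  mix <- p1
  mix$gamma_v <- 0.3 * p1$gamma_v + 0.7 * p2$gamma_v
  mix$gamma_r <- 0.3 * p1$gamma_r + 0.7 * p2$gamma_r
  y1 <- predict_yield(p1, nb)$yhat
  y2 <- predict_yield(p2, nb)$yhat
  ymix <- predict_yield(mix, nb)$yhat
  expect_equal(ymix, 0.3 * y1 + 0.7 * y2, tolerance = 1e-9)

  # and in alpha for fixed gamma (alphas kept inside the level bounds so no
  # clamping path is exercised)
  a2 <- p1$alpha * 0.5
  pa <- p1; pa$alpha <- a2
  pmixa <- p1; pmixa$alpha <- 0.6 * p1$alpha + 0.4 * a2
  ya1 <- predict_yield(p1, nb)$yhat
  ya2 <- predict_yield(pa, nb)$yhat
  yamix <- predict_yield(pmixa, nb)$yhat
  expect_equal(yamix, 0.6 * ya1 + 0.4 * ya2, tolerance = 1e-9)
})

test_that("weighted metrics follow their formulas", {
  d <- tibble::tibble(yield = c(10, 20), yhat = c(10, 20), area = c(1, 2))
  expect_equal(weighted_rmse(d), 0)
  d1 <- tibble::tibble(yield = 17, yhat = 12, area = 3)
  expect_equal(weighted_rmse(d1), 5)
  # A = (1, 2), errors (3, 3): sqrt((9 + 36) / 5) = 3
  d2 <- tibble::tibble(yield = c(3, 3), yhat = c(0, 0), area = c(1, 2))
  expect_equal(weighted_rmse(d2), 3)
  # uniform area rescaling cancels out of the A^2 weights
  d3 <- dplyr::mutate(d2, area = area * 137)
  expect_equal(weighted_rmse(d3), weighted_rmse(d2))

  expect_equal(weighted_r2(d), 1)
  # predicting the weighted mean gives R2 = 0
  y <- c(100, 120, 140); a <- c(1, 2, 3)
  ybar <- sum(a^2 * y) / sum(a^2)
  d4 <- tibble::tibble(yield = y, yhat = ybar, area = a)
  expect_equal(weighted_r2(d4), 0)
  # three-record hand computation
  d5 <- tibble::tibble(yield = y, yhat = c(105, 115, 150), area = a)
  w <- a^2
  expect_equal(weighted_r2(d5),
               1 - sum(w * (y - d5$yhat)^2) / sum(w * (y - sum(w * y) / sum(w))^2))
  expect_equal(weighted_r2(d5), 0.5279605, tolerance = 1e-6)
  expect_error(weighted_r2(tibble::tibble(yield = c(5, 5), yhat = c(1, 2), area = c(1, 1))),
               "zero weighted variance")
  expect_error(weighted_rmse(tibble::tibble(yield = numeric(), yhat = numeric(),
                                            area = numeric())),
               "no records")
})
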