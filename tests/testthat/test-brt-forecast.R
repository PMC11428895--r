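test_that("model specs A-D carry the stated manifests", {
  a <- spread_model_spec("A")
  b <- spread_model_spec("B")
  c <- spread_model_spec("C")
  d <- spread_model_spec("D")
  expect_true("prev_occ" %in% a$covariates)
  expect_false("prev_occ" %in% b$covariates)
  expect_equal(setdiff(a$covariates, b$covariates), "prev_occ")
  expect_equal(a$response_scale, "prop")
  expect_equal(c$response_scale, "km2")
  expect_true(c$include_prev_status)
  expect_false(d$include_prev_status)
})

test_that("identical strata data give identical stratum ensembles", {
  # counties i and i+10 are exact copies placed in different strata
  L <- chain_landscape(20)
  L$adjacency <- data.frame(county_id = c(1:20, 1:20),
                            neighbor_id = c(2:20, 1, 20, 1:19))
  years <- 2008:2013
  set.seed(7)
  base <- matrix(runif(10 * 6, 0.1, 0.6), 10, 6)
  m <- rbind(base, base)
  h <- occ_df(m, years)
  cv <- zero_covariates(L, years)
  cv$county$habitat_suitability <- rep(runif(10), 2)
  cv$county$pct_tree <- rep(runif(10, 0, 80), 2)
  strata <- list(persistent = 1:10, transient = 11:20, never = integer())
  sm <- fit_spread_models(L, h, cv, spread_model_spec("A"), strata,
                          window = 2009:2013,
                          control = boost_control(n_rounds = 20))
  feats <- data.frame(prev_occ = 0.3, adj_mean_prop = 0.2,
                      removals_focal = 0, adj_mean_removals_log = 0,
                      prop_active_removal = 0, adj_mean_prop_active = 0,
                      habitat_suitability = 0.5, density_rescaled = 0,
                      pct_hydrology = 0, pct_tree = 40, pct_crops = 0,
                      pct_pasture = 0, pct_deciduous = 0)
  expect_equal(predict(sm$persistent, feats), predict(sm$transient, feats))
})

test_that("habitat-driven response ranks habitat first in importance", {
  L <- chain_landscape(40)
  years <- 2008:2013
  set.seed(11)
  hab <- runif(40)
  # occupancy grows each year by ~0.08 * habitat suitability
  m <- outer(0.08 * hab, 0:5) + 0.05
  h <- occ_df(m, years)
  cv <- zero_covariates(L, years)
  cv$county$habitat_suitability <- hab
  cv$county$pct_tree <- runif(40, 0, 80)       # decoys
  cv$county$pct_crops <- runif(40, 0, 70)
  strata <- list(persistent = 1:20, transient = 21:40, never = integer())
  sm <- fit_spread_models(L, h, cv, spread_model_spec("B"), strata,
                          window = 2009:2013,
                          control = boost_control(n_rounds = 50))
  expect_equal(names(lsboost_importance(sm$transient))[1],
               "habitat_suitability")

  # a stratum below the row minimum is rejected
  strata_bad <- list(persistent = 1:2, transient = 3:40, never = integer())
  expect_error(fit_spread_models(L, h, cv, spread_model_spec("B"),
                                 strata_bad, window = 2009:2013),
               "stratum")
})

test_that("zero-delta stub keeps the state constant with no transitions", {
  L <- chain_landscape(4)
  cv <- zero_covariates(L, 2013)
  s0 <- data.frame(county_id = 1:4, prop = c(0.5, 0, 0.9, 0.2))
  fc <- step_ahead(stub_models(function(f) rep(0, nrow(f))), L, s0, cv,
                   horizon = 8)
  for (y in unique(fc$occupancy$year)) {
    expect_equal(fc$occupancy$prop[fc$occupancy$year == y], s0$prop)
  }
  tr <- forecast_transition_rates(fc)
  expect_true(all(tr$n_newly_occupied == 0))
  expect_true(all(tr$n_newly_unoccupied == 0))
  expect_error(step_ahead(stub_models(function(f) 0), L, s0, cv,
                          horizon = 0), "horizon")
})

test_that("predictions are clipped to [0,1] and [0, area]", {
  L <- chain_landscape(2, areas = c(100, 100))
  cv <- zero_covariates(L, 2013)
  s0 <- data.frame(county_id = 1:2, prop = c(0.95, 0.05))
  fc <- step_ahead(stub_models(function(f) rep(0.20, nrow(f))), L, s0, cv,
                   horizon = 1)
  expect_equal(fc$occupancy$prop, c(1.0, 0.25))

  spec_c <- spread_model_spec("C")
  fc2 <- step_ahead(stub_models(function(f) rep(200, nrow(f)), spec_c),
                    L, s0, cv, horizon = 3)
  expect_true(all(fc2$occupancy$km2 <= 100 + 1e-9))
  expect_equal(fc2$occupancy$prop[fc2$occupancy$year == 2014], c(1, 1))
})

test_that("adjacent-mean update follows the hand-computed two-step trace", {
  # chain 1-2-3, stub delta = 0.1 x mean occupancy of adjacent counties,
  # start (1, 0, 0):
  #  year 1: deltas 0.1*(0, (1+0)/2, 0) -> (1.0, 0.05, 0)
  #  year 2: deltas 0.1*(0.05, (1+0)/2, 0.05) -> (1.0, 0.10, 0.005)
  L <- chain_landscape(3)
  cv <- zero_covariates(L, 2013)
  s0 <- data.frame(county_id = 1:3, prop = c(1, 0, 0))
  fc <- step_ahead(stub_models(function(f) 0.1 * f$adj_mean_prop), L, s0, cv,
                   horizon = 2)
  y1 <- fc$occupancy$prop[fc$occupancy$year == 2014]
  y2 <- fc$occupancy$prop[fc$occupancy$year == 2015]
  expect_equal(y1, c(1.0, 0.05, 0))
  expect_equal(y2, c(1.0, 0.10, 0.005))
  expect_equal(fc$newly_occupied[["2014"]], 2L)
  expect_equal(fc$newly_occupied[["2015"]], 3L)
})

test_that("step_ahead matches an independently coded simulator", {
  # brute-force oracle: explicit per-county loops, no shared code paths
  set.seed(21)
  L <- chain_landscape(5, areas = runif(5, 500, 2000))
  cv <- zero_covariates(L, 2013)
  cv$county$habitat_suitability <- runif(5)
  s0 <- data.frame(county_id = 1:5, prop = runif(5))
  stub <- function(f) 0.08 * f$adj_mean_prop + 0.05 * f$habitat_suitability -
    0.02
  fc <- step_ahead(stub_models(stub), L, s0, cv, horizon = 6)

  p <- s0$prop
  hab <- cv$county$habitat_suitability
  oracle <- matrix(NA_real_, 5, 6)
  for (t in 1:6) {
    newp <- numeric(5)
    for (i in 1:5) {
      nbs <- c(i - 1, i + 1)
      nbs <- nbs[nbs >= 1 & nbs <= 5]
      adjm <- mean(p[nbs])
      d <- 0.08 * adjm + 0.05 * hab[i] - 0.02
      newp[i] <- min(max(p[i] + d, 0), 1)
    }
    p <- newp
    oracle[, t] <- p
  }
  for (t in 1:6) {
    expect_equal(fc$occupancy$prop[fc$occupancy$year == 2013 + t],
                 oracle[, t])
  }
})

test_that("forecasts stay in bounds for random stub predictors", {
  set.seed(31)
  L <- chain_landscape(6, areas = runif(6, 100, 3000))
  cv <- zero_covariates(L, 2013)
  for (k in 1:5) {
    coefs <- rnorm(2, sd = 0.5)
    stub <- function(f) coefs[1] * f$adj_mean_prop + coefs[2]
    s0 <- data.frame(county_id = 1:6, prop = runif(6))
    fc <- step_ahead(stub_models(stub), L, s0, cv, horizon = 5)
    expect_true(all(fc$occupancy$prop >= 0 & fc$occupancy$prop <= 1))
    expect_true(all(fc$occupancy$km2 >= 0 &
                      fc$occupancy$km2 <= L$counties$area_km2 + 1e-9))
    # per-year occupied/unoccupied sets are disjoint
    for (y in names(fc$newly_occupied)) {
      expect_length(intersect(fc$newly_occupied[[y]],
                              fc$newly_unoccupied[[y]]), 0)
    }
  }
})

test_that("forecast determinism and opt-in noise", {
  w <- tiny_world()
  st <- stratify(w$history, 2009:2013)
  sm <- fit_spread_models(w$landscape, w$history, w$covariates,
                          spread_model_spec("A"), st, 2009:2013,
                          boost_control(n_rounds = 20))
  s0 <- w$history$occupancy[w$history$occupancy$year == 2013, ]
  f1 <- step_ahead(sm, w$landscape, s0, w$covariates, horizon = 3)
  f2 <- step_ahead(sm, w$landscape, s0, w$covariates, horizon = 3)
  expect_identical(f1$occupancy, f2$occupancy)

  n1 <- step_ahead(sm, w$landscape, s0, w$covariates, horizon = 3,
                   noise = TRUE, seed = 9)
  n2 <- step_ahead(sm, w$landscape, s0, w$covariates, horizon = 3,
                   noise = TRUE, seed = 9)
  expect_identical(n1$occupancy, n2$occupancy)
  expect_false(identical(n1$occupancy$prop, f1$occupancy$prop))
})

test_that("transition counts equal a recount from the yearly maps", {
  w <- tiny_world()
  L <- w$landscape
  cv <- w$covariates
  s0 <- w$history$occupancy[w$history$occupancy$year == 2013, ]
  set.seed(5)
  stub <- function(f) 0.2 * f$adj_mean_prop - 0.05
  fc <- step_ahead(stub_models(stub), L, s0, cv, horizon = 5)
  tr <- forecast_transition_rates(fc)
  prev <- s0$prop[order(s0$county_id)]
  occ <- fc$occupancy
  for (i in seq_len(nrow(tr))) {
    cur <- occ$prop[occ$year == tr$year[i]]
    expect_equal(tr$n_newly_occupied[i], sum(cur > 0 & prev <= 0))
    expect_equal(tr$n_newly_unoccupied[i], sum(cur <= 0 & prev > 0))
    prev <- cur
  }
  expect_equal(tr$cum_occupied, cumsum(tr$n_newly_occupied))
})

test_that("removal updates propagate predictions into next-year covariates", {
  # single county: the removal covariate at t+1 equals the model's
  # prediction at t (here constant 0.07 removals/km2)
  L <- chain_landscape(1, areas = 500)
  cv <- zero_covariates(L, 2013)
  cv$removals$removals <- 100   # baseline: 0.2 per km2
  s0 <- data.frame(county_id = 1, prop = 0.2)
  stub <- function(f) f$removals_focal   # delta = removals per km2
  fc <- step_ahead(stub_models(stub), L, s0, cv, horizon = 2,
                   removal_model = function(f) rep(0.07, nrow(f)))
  p <- fc$occupancy$prop
  expect_equal(p[1] - 0.2, 100 / 500)   # year 1 uses observed removals
  expect_equal(p[2] - p[1], 0.07)       # year 2 uses the model prediction
})

test_that("zero-removal worlds are unchanged by a zero removal model", {
  L <- chain_landscape(3)
  cv <- zero_covariates(L, 2013)
  s0 <- data.frame(county_id = 1:3, prop = c(0.4, 0.1, 0))
  stub <- function(f) 0.05 - 0.1 * f$removals_focal
  base <- step_ahead(stub_models(stub), L, s0, cv, horizon = 4)
  upd <- step_ahead(stub_models(stub), L, s0, cv, horizon = 4,
                    removal_model = function(f) rep(0, nrow(f)))
  expect_equal(base$occupancy, upd$occupancy)
})

test_that("removal updates give weakly higher invasion in a control scenario", {
  # baseline removals suppress spread; the removal model predicts lower
  # effort, so updated forecasts invade at least as many counties
  L <- chain_landscape(5)
  cv <- zero_covariates(L, 2013)
  cv$removals$removals <- 300
  s0 <- data.frame(county_id = 1:5, prop = c(0.6, 0, 0, 0, 0))
  stub <- function(f) 0.1 * f$adj_mean_prop + 0.02 - 0.2 * f$removals_focal
  base <- step_ahead(stub_models(stub), L, s0, cv, horizon = 6)
  upd <- step_ahead(stub_models(stub), L, s0, cv, horizon = 6,
                    removal_model = function(f) rep(0, nrow(f)))
  expect_false(identical(base$occupancy, upd$occupancy))
  expect_gte(sum(lengths(upd$newly_occupied)),
             sum(lengths(base$newly_occupied)))
})

test_that("fit_removal_model learns the removal-covariate relationship", {
  w <- tiny_world()
  rm_fit <- fit_removal_model(w$landscape, w$history, w$covariates,
                              years = 2009:2013,
                              control = boost_control(n_rounds = 30))
  expect_s3_class(rm_fit, "lsboost")
  expect_true(all(diff(rm_fit$train_mse) <= 1e-12))
})
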