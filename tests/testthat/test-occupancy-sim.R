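test_that("beta moment fit matches the closed form", {
  b <- fit_beta_rates(c(0.1, 0.2, 0.3), "invasion")
  expect_equal(b$shape1, 3)
  expect_equal(b$shape2, 12)
  expect_equal(b$shape1 / (b$shape1 + b$shape2), 0.2)  # mean identity

  set.seed(1)
  r <- runif(50, 0.05, 0.6)
  f <- fit_beta_rates(r)
  expect_equal(f$shape1 / (f$shape1 + f$shape2), mean(r))

  expect_error(fit_beta_rates(c(0.2, 0.2, 0.2)), "zero variance")
  expect_error(fit_beta_rates(0.2), ">= 2")
  # variance at the bernoulli limit: no valid beta
  expect_error(fit_beta_rates(c(0, 1, 0, 1), shrink_extremes = FALSE),
               "no valid beta")
  # extreme values are shrunk into the open interval by default
  ok <- fit_beta_rates(c(0, 0.2, 0.5, 1))
  expect_gt(ok$shape1, 0)
  expect_gt(ok$shape2, 0)
})

test_that("intercept-only structure recovers logit of the mean rate", {
  # all covariates zero: the penalized fit reduces to the intercept MLE
  n <- 40
  resp <- data.frame(k = rep(c(1, 0), n / 2), n = 2,
                     ruggedness = 0, lewis_density = 0, temp_range = 0,
                     precip = 0, prev_rate = 0, dist_nearest = 0)
  m <- suppressWarnings(fit_invasion_model(resp, "fixed"))
  intercept <- m$coefficients$estimate[m$coefficients$term == "(Intercept)"]
  expect_equal(stats::plogis(intercept), 0.25, tolerance = 0.01)
})

test_that("invasion model variants expose the right structure", {
  w <- tiny_world()
  status <- w$history$huc12_status
  inv <- prepare_invasion_data(w$landscape,
                               status[status$year <= 2013, ],
                               w$covariates$huc8)
  m_f <- fit_invasion_model(inv, "fixed")
  expect_setequal(m_f$coefficients$term,
                  c("(Intercept)", "ruggedness", "lewis_density",
                    "temp_range", "precip", "prev_rate", "dist_nearest"))
  m_red <- fit_invasion_model(inv, "fixed_reduced")
  expect_false(any(c("temp_range", "precip") %in% m_red$coefficients$term))

  m_ri <- suppressWarnings(fit_invasion_model(inv, "ri"))
  expect_s4_class(m_ri$fit, "glmerMod")

  # degenerate responses rejected
  inv0 <- inv
  inv0$k <- 0
  expect_error(fit_invasion_model(inv0), "all-uninvaded")
  inv1 <- inv
  inv1$k <- inv1$n
  expect_error(fit_invasion_model(inv1), "all-invaded")
})

test_that("plain-ML fit errors on complete separation", {
  resp <- data.frame(k = c(rep(0, 10), rep(5, 10)), n = 5,
                     ruggedness = c(rep(-1, 10), rep(1, 10)),
                     lewis_density = 0, temp_range = 0, precip = 0,
                     prev_rate = 0, dist_nearest = 0)
  expect_error(fit_invasion_model(resp, "fixed", penalty_sd = NULL),
               "separation")
  # the penalized default handles the same data
  m <- fit_invasion_model(resp, "fixed")
  expect_true(all(is.finite(m$coefficients$estimate)))
})

test_that("predict_invasion_prob is monotone and matches hand arithmetic", {
  resp <- data.frame(k = c(2, 5, 8, 1, 6, 3), n = 10,
                     ruggedness = rnorm(6), lewis_density = rnorm(6),
                     temp_range = 0, precip = 0,
                     prev_rate = runif(6), dist_nearest = runif(6, 0, 5))
  m <- fit_invasion_model(resp, "fixed")
  beta <- m$coefficients$estimate
  names(beta) <- m$coefficients$term
  nd <- data.frame(ruggedness = c(0.5, -1, 2), lewis_density = 0.3,
                   temp_range = 0, precip = 0, prev_rate = 0.2,
                   dist_nearest = c(1, 2, 3))
  p <- predict_invasion_prob(m, nd)
  eta <- beta["(Intercept)"] + beta["ruggedness"] * nd$ruggedness +
    beta["lewis_density"] * 0.3 + beta["prev_rate"] * 0.2 +
    beta["dist_nearest"] * nd$dist_nearest
  expect_equal(p, unname(stats::plogis(eta)))
  expect_true(all(p > 0 & p < 1))
  expect_error(predict_invasion_prob(m, nd[, -1]), "ruggedness")

  # negative distance coefficient: probability decreases with distance
  if (beta["dist_nearest"] < 0) {
    nd2 <- nd[c(1, 1, 1), ]
    nd2$dist_nearest <- c(0, 2, 10)
    expect_true(all(diff(predict_invasion_prob(m, nd2)) < 0))
  }
})

test_that("coefficients and beta parameters recover truth", {
  L <- make_landscape(100, 50, 20, seed = 11)
  truth <- c(ruggedness = 0.5, lewis_density = 0.8, temp_range = -0.4,
             precip = 0.3, prev_rate = 1.5, dist_nearest = -0.15)
  ts <- make_truth_scenario(L, truth, intercept = -1,
                            years = 1974:2013, seed = 4)
  expect_gte(nrow(ts$response), 2000)
  m <- fit_invasion_model(ts$response, "fixed")
  full <- c("(Intercept)" = -1, truth)
  z <- (m$coefficients$estimate - full[m$coefficients$term]) /
    m$coefficients$se
  expect_true(all(abs(z) < 3))

  bi <- fit_beta_rates(ts$rate_series$invasion, "invasion")
  expect_lt(abs(bi$shape1 - 3) / 3, 0.2)
  expect_lt(abs(bi$shape2 - 12) / 12, 0.2)
  be <- fit_beta_rates(ts$rate_series$extinction, "extinction")
  expect_lt(abs(be$shape1 - 2) / 2, 0.2)
  expect_lt(abs(be$shape2 - 18) / 18, 0.2)
})

test_that("forced-zero rate hooks freeze the simulation", {
  w <- tiny_world()
  init <- w$history$huc12_status[w$history$huc12_status$year == 2013,
                                 c("huc12_id", "invaded")]
  tr <- simulate_occupancy(function(nd) rep(0.5, nrow(nd)), w$landscape,
                           init, w$covariates$huc8,
                           function() 0, function() 0,
                           horizon = 3, reps = 5, seed = 1)
  init_prop <- watershed_response(
    cbind(init, year = 2013), w$landscape)
  for (r in 1:5) {
    for (t in 1:3) {
      expect_equal(unname(tr$prop[r, t, ]),
                   init_prop$rate[match(tr$huc8_ids, init_prop$huc8_id)])
    }
  }
})

test_that("invaded counts are conserved each replicate-year", {
  w <- tiny_world()
  init <- w$history$huc12_status[w$history$huc12_status$year == 2013,
                                 c("huc12_id", "invaded")]
  status <- w$history$huc12_status
  inv <- prepare_invasion_data(w$landscape, status[status$year <= 2013, ],
                               w$covariates$huc8)
  m <- fit_invasion_model(inv, "fixed")
  rates <- suppressWarnings(observed_rates(status, 2004:2012))
  ib <- fit_beta_rates(rates$invasion$rate, "invasion")
  eb <- fit_beta_rates(rates$extinction$rate, "extinction")
  tr <- simulate_occupancy(m, w$landscape, init, w$covariates$huc8, ib, eb,
                           horizon = 8, reps = 50, seed = 3)
  led <- tr$ledger
  expect_true(all(led$n_after ==
                    led$n_before + led$invasions - led$extinctions))
  expect_true(all(tr$prop >= 0 & tr$prop <= 1))
})

test_that("weighted selection frequencies match the 0.9/0.1 example", {
  # two uninvaded units with invasion weights 0.9 and 0.1; one invasion per
  # year; binomial check at 10,000 replicates with 3-sigma tolerance
  L <- unit_landscape(2)
  init <- data.frame(huc12_id = L$huc12$huc12_id, invaded = 0L)
  cv8 <- data.frame(huc8_id = L$huc8$huc8_id, ruggedness = 0,
                    lewis_density = 0, temp_range = 0, precip = 0)
  stub <- function(nd) c(0.9, 0.1)
  tr <- simulate_occupancy(stub, L, init, cv8,
                           function() 0.5, function() 0,
                           horizon = 1, reps = 10000, seed = 17)
  expect_true(all(tr$n_invaded == 1L))
  freq <- mean(tr$prop[, 1, 1])  # share of reps where unit 1 was chosen
  sigma <- sqrt(0.9 * 0.1 / 10000)
  expect_lt(abs(freq - 0.9), 3 * sigma)
})

test_that("full 1000-replicate 8-year runs are seed-reproducible", {
  L <- make_landscape(16, 4, 10, seed = 5)
  h <- make_history(L, 2008:2013, seed = 6)
  cv <- make_covariates(L, 2008:2013, seed = 7)
  init <- h$huc12_status[h$huc12_status$year == 2013,
                         c("huc12_id", "invaded")]
  stub <- function(nd) stats::plogis(-1 + nd$prev_rate)
  ib <- fit_beta_rates(c(0.05, 0.1, 0.2, 0.15, 0.08), "invasion")
  eb <- fit_beta_rates(c(0.02, 0.05, 0.1, 0.04, 0.06), "extinction")
  a <- simulate_occupancy(stub, L, init, cv$huc8, ib, eb,
                          horizon = 8, reps = 1000, seed = 23)
  b <- simulate_occupancy(stub, L, init, cv$huc8, ib, eb,
                          horizon = 8, reps = 1000, seed = 23)
  expect_identical(a$prop, b$prop)
  expect_identical(a$ledger, b$ledger)
  expect_equal(dim(a$prop), c(1000L, 8L, 4L))
  c <- simulate_occupancy(stub, L, init, cv$huc8, ib, eb,
                          horizon = 2, reps = 50, seed = 24)
  expect_false(identical(a$prop[1:50, 1:2, ], c$prop))
})

test_that("expected growth matches the invasion beta mean", {
  # with invasion mean m and no extinction, invaded count grows by
  # ~ m x uninvaded each year
  L <- make_landscape(16, 4, 25, seed = 9)   # 100 fine units
  init <- data.frame(huc12_id = L$huc12$huc12_id, invaded = 0L)
  cv8 <- data.frame(huc8_id = L$huc8$huc8_id, ruggedness = 0,
                    lewis_density = 0, temp_range = 0, precip = 0)
  stub <- function(nd) rep(0.5, nrow(nd))
  m <- 0.1
  ib <- list(shape1 = 3, shape2 = 27)  # mean 0.1
  class(ib) <- "beta_rate"
  tr <- simulate_occupancy(stub, L, init, cv8, ib, function() 0,
                           horizon = 3, reps = 2000, seed = 31)
  # E[n1] = 100m, E[n2] = n1 + m(100 - n1)
  e1 <- 100 * m
  e2 <- e1 + m * (100 - e1)
  expect_equal(mean(tr$n_invaded[, 1]), e1, tolerance = 0.05)
  expect_equal(mean(tr$n_invaded[, 2]), e2, tolerance = 0.05)
})

test_that("distance updates equal brute-force nearest neighbours", {
  set.seed(13)
  L <- make_landscape(16, 4, 10, seed = 2)   # 40 fine units
  h12 <- L$huc12
  invaded <- runif(nrow(h12)) < 0.3
  pts <- cbind(h12$cx[invaded], h12$cy[invaded])
  d <- pigspread:::nearest_dist(cbind(L$huc8$cx, L$huc8$cy), pts)
  for (i in seq_len(nrow(L$huc8))) {
    dd <- sqrt((h12$cx[invaded] - L$huc8$cx[i])^2 +
                 (h12$cy[invaded] - L$huc8$cy[i])^2)
    expect_equal(d[i], min(dd))
  }
})

test_that("summaries are elementwise order statistics", {
  tr <- structure(list(
    prop = array(c(0.2, 0.4, 0.9), dim = c(3, 1, 1),
                 dimnames = list(NULL, NULL, "H8_001")),
    years = 1L, huc8_ids = "H8_001"), class = "sim_trajectories")
  s <- summarize_trajectories(tr)
  expect_equal(s$median, 0.4)
  expect_true(s$lo <= s$median && s$median <= s$hi)

  # single replicate: median equals the trajectory
  tr1 <- structure(list(
    prop = array(c(0.3, 0.7), dim = c(1, 2, 1),
                 dimnames = list(NULL, NULL, "H8_001")),
    years = 1:2, huc8_ids = "H8_001"), class = "sim_trajectories")
  s1 <- summarize_trajectories(tr1)
  expect_equal(s1$median, c(0.3, 0.7))
  expect_equal(s1$lo, s1$median)
})

test_that("to_county computes overlap-weighted means", {
  ov <- data.frame(county_id = c(1, 2, 2), huc8_id = c("a", "a", "b"),
                   weight = c(1, 0.5, 0.5))
  hp <- data.frame(huc8_id = c("a", "b"), median = c(0.2, 0.6))
  cp <- to_county(hp, ov)
  expect_equal(cp$median, c(0.2, 0.4))

  hp0 <- data.frame(huc8_id = c("a", "b"), median = 0)
  expect_equal(to_county(hp0, ov)$median, c(0, 0))

  ov_bad <- ov
  ov_bad$weight[1] <- 0.7
  expect_error(to_county(hp, ov_bad), "sum to 1")
})
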