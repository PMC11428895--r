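# Dynamic occupancy framework: binomial-logit invasion model at the coarse
# watershed scale, beta-distributed annual invasion/extinction counts, and a
# probability-weighted stochastic step-ahead simulation.

INVASION_COVS <- c("ruggedness", "lewis_density", "temp_range", "precip",
                   "prev_rate", "dist_nearest")

#' Assemble the coarse-watershed invasion modelling table
#'
#' Builds one row per coarse watershed and year (from the second year on):
#' the binomial response (k invaded of n fine units), the four static
#' covariates, the previous year's invaded rate, and the distance from the
#' watershed centroid to the nearest fine unit invaded in the previous year
#' (the landscape diagonal when nothing is invaded).
#'
#' @param landscape a `pig_landscape`.
#' @param huc12_status data frame (huc12_id, year, invaded).
#' @param covariates_huc8 static covariate table (huc8_id, ruggedness,
#'   lewis_density, temp_range, precip).
#' @return data frame ready for [fit_invasion_model()].
#' @export
prepare_invasion_data <- function(landscape, huc12_status, covariates_huc8) {
  resp <- watershed_response(huc12_status, landscape)
  h8 <- landscape$huc8
  h12 <- landscape$huc12
  years <- sort(unique(resp$year))
  assert_that(length(years) >= 2, "need >= 2 years of status data")
  extent <- sqrt(diff(range(h12$cx))^2 + diff(range(h12$cy))^2)
  out <- list()
  for (ti in 2:length(years)) {
    cur <- resp[resp$year == years[ti], ]
    prev <- resp[resp$year == years[ti - 1L], ]
    prev_rate <- prev$rate[match(cur$huc8_id, prev$huc8_id)]
    prev_inv <- huc12_status[huc12_status$year == years[ti - 1L] &
                               huc12_status$invaded > 0, "huc12_id"]
    pts <- cbind(h12$cx[h12$huc12_id %in% prev_inv],
                 h12$cy[h12$huc12_id %in% prev_inv])
    d <- nearest_dist(cbind(h8$cx, h8$cy), pts)
    d[!is.finite(d)] <- extent
    cur$prev_rate <- prev_rate
    cur$dist_nearest <- d[match(cur$huc8_id, h8$huc8_id)]
    out[[ti - 1L]] <- cur
  }
  out <- do.call(rbind, out)
  cc <- covariates_huc8[match(out$huc8_id, covariates_huc8$huc8_id), ]
  out$ruggedness <- cc$ruggedness
  out$lewis_density <- cc$lewis_density
  out$temp_range <- cc$temp_range
  out$precip <- cc$precip
  out$region <- h8$region[match(out$huc8_id, h8$huc8_id)]
  rownames(out) <- NULL
  out
}

#' Fit the six-predictor invasion-probability model
#'
#' A binomial-logit model of the occupancy rate within coarse watersheds,
#' with fine watersheds as spatial replicates. Predictors: terrain
#' ruggedness, Lewis predicted density, annual temperature range, annual mean
#' precipitation, rate of invaded fine watersheds in the previous year, and
#' distance to the nearest invaded watershed. Variants add regional structure
#' over the four regions (west, plains, Great Lakes, east): uncorrelated
#' random intercepts (`ri`) or correlated random intercepts and prev-rate
#' slopes (`rs`). `fixed_reduced` refits the fixed-effects model on the
#' covariate subset without the two climate predictors (the fourth
#' parameterization). Estimation is penalized maximum likelihood; downstream
#' forecasting consumes only the fitted probability function.
#'
#' @param response output of [prepare_invasion_data()] (or
#'   [make_truth_scenario()]'s `response`).
#' @param variant one of "fixed", "ri", "rs", "fixed_reduced".
#' @param penalty_sd Gaussian prior standard deviation on standardized
#'   coefficients for the fixed-effects variants (posterior-mode / ridge
#'   estimation; default 2.5). `NULL` requests plain maximum likelihood,
#'   which errors on complete separation.
#' @return object of class `invasion_model`: `fit`, `variant`,
#'   `coefficients` (data frame term/estimate/se), `covariates`.
#' @export
fit_invasion_model <- function(response,
                               variant = c("fixed", "ri", "rs",
                                           "fixed_reduced"),
                               penalty_sd = 2.5) {
  variant <- match.arg(variant)
  missing_cols <- setdiff(c("k", "n", INVASION_COVS), names(response))
  assert_that(length(missing_cols) == 0,
              paste("response lacks columns:",
                    paste(missing_cols, collapse = ", ")))
  assert_that(!all(response$k == 0),
              "response is all-uninvaded; cannot fit")
  assert_that(!all(response$k == response$n),
              "response is all-invaded; cannot fit")
  covs <- if (variant == "fixed_reduced") {
    setdiff(INVASION_COVS, c("temp_range", "precip"))
  } else INVASION_COVS
  rhs <- paste(covs, collapse = " + ")
  sep_err <- function(w) {
    if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
      stop("complete separation detected; regularize or reduce covariates",
           call. = FALSE)
    }
    invokeRestart("muffleWarning")
  }
  if (variant %in% c("fixed", "fixed_reduced")) {
    if (is.null(penalty_sd)) {
      f <- stats::as.formula(paste("cbind(k, n - k) ~", rhs))
      fit <- withCallingHandlers(
        stats::glm(f, family = stats::binomial(), data = response),
        warning = sep_err)
      mu <- stats::fitted(fit)
      if (!fit$converged || any(mu < 1e-8 | mu > 1 - 1e-8)) {
        stop("complete separation detected; regularize or reduce covariates",
             call. = FALSE)
      }
      sm <- summary(fit)$coefficients
      coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                          se = sm[, 2], row.names = NULL)
    } else {
      fit <- penalized_logistic(response, covs, penalty_sd)
      coefs <- data.frame(term = names(fit$coef), estimate = fit$coef,
                          se = fit$se, row.names = NULL)
    }
  } else {
    assert_that("region" %in% names(response),
                "regional variants need a region column")
    ranef_term <- if (variant == "ri") "(1 | region)"
      else "(1 + prev_rate | region)"
    f <- stats::as.formula(paste("cbind(k, n - k) ~", rhs, "+", ranef_term))
    fit <- lme4::glmer(f, family = stats::binomial(), data = response,
                       control = lme4::glmerControl(calc.derivs = FALSE))
    sm <- stats::coef(summary(fit))
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                        row.names = NULL)
  }
  structure(list(fit = fit, variant = variant, coefficients = coefs,
                 covariates = covs),
            class = "invasion_model")
}

# Ridge-penalized binomial-logit IRLS (posterior mode under independent
# Gaussian priors on standardized coefficients; intercept prior sd 10).
# Robust to (quasi-)separation, which sparse occupancy tables produce often.
penalized_logistic <- function(data, covs, penalty_sd, max_iter = 100,
                               tol = 1e-9) {
  X <- as.matrix(data[, covs, drop = FALSE])
  k <- data$k
  n <- data$n
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[s == 0] <- 1
  Z <- cbind(1, sweep(sweep(X, 2, m), 2, s, "/"))
  p <- ncol(Z)
  P <- diag(c(1 / 100, rep(1 / penalty_sd^2, p - 1L)))
  b <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% b)
    mu <- stats::plogis(eta)
    w <- pmax(n * mu * (1 - mu), 1e-12)
    zw <- eta + (k - n * mu) / w
    H <- crossprod(Z, Z * w) + P
    bn <- drop(solve(H, crossprod(Z, w * zw)))
    if (max(abs(bn - b)) < tol) {
      b <- bn
      break
    }
    b <- bn
  }
  V <- solve(crossprod(Z, Z * pmax(n * stats::plogis(drop(Z %*% b)) *
                                     (1 - stats::plogis(drop(Z %*% b))),
                                   1e-12)) + P)
  # back-transform to the raw covariate scale
  Tm <- diag(c(1, 1 / s))
  Tm[1, -1] <- -m / s
  coef_raw <- drop(Tm %*% b)
  V_raw <- Tm %*% V %*% t(Tm)
  names(coef_raw) <- c("(Intercept)", covs)
  structure(list(coef = coef_raw, se = sqrt(diag(V_raw)), vcov = V_raw,
                 covariates = covs, penalty_sd = penalty_sd),
            class = "pen_logit")
}

#' @export
print.invasion_model <- function(x, ...) {
  cat(sprintf("<invasion_model> variant %s\n", x$variant))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Predict invasion probability
#'
#' Inverse-logit of the fitted linear predictor (including regional offsets
#' for the random-effect variants) for each row of `newdata`.
#'
#' @param model an `invasion_model`.
#' @param newdata data frame carrying the model's covariate columns (plus
#'   `region` for regional variants).
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_invasion_prob <- function(model, newdata) {
  missing_cols <- setdiff(model$covariates, names(newdata))
  assert_that(length(missing_cols) == 0,
              paste("newdata lacks covariate(s):",
                    paste(missing_cols, collapse = ", ")))
  if (model$variant %in% c("ri", "rs")) {
    assert_that("region" %in% names(newdata),
                "newdata lacks covariate(s): region")
    stats::predict(model$fit, newdata = newdata, type = "response",
                   allow.new.levels = TRUE)
  } else if (inherits(model$fit, "pen_logit")) {
    X <- cbind(1, as.matrix(newdata[, model$covariates, drop = FALSE]))
    stats::plogis(drop(X %*% model$fit$coef))
  } else {
    stats::predict(model$fit, newdata = newdata, type = "response")
  }
}

#' Fit a beta distribution to an observed rate series by moments
#'
#' Method of moments: with sample mean m and unbiased variance v,
#' alpha = m(m(1-m)/v - 1) and beta = (1-m)(m(1-m)/v - 1). Exact zeros or
#' ones in the series are first shrunk by (r(n-1) + 0.5)/n so the moments
#' stay inside the valid region (disable with `shrink_extremes = FALSE`).
#'
#' @param rates numeric vector of rates in \[0, 1\] (>= 2 values).
#' @param kind "invasion" or "extinction" (metadata).
#' @param shrink_extremes shrink exact 0/1 values before fitting.
#' @return object of class `beta_rate`: shape1, shape2, kind, n, mean.
#' @export
fit_beta_rates <- function(rates, kind = c("invasion", "extinction"),
                           shrink_extremes = TRUE) {
  kind <- match.arg(kind)
  rates <- rates[is.finite(rates)]
  n <- length(rates)
  assert_that(n >= 2, "need >= 2 rates")
  assert_that(all(rates >= 0 & rates <= 1), "rates must lie in [0, 1]")
  if (shrink_extremes && any(rates <= 0 | rates >= 1)) {
    rates <- (rates * (n - 1) + 0.5) / n
  }
  m <- mean(rates)
  v <- stats::var(rates)
  assert_that(v > 0, "zero variance; beta fit undefined")
  assert_that(v < m * (1 - m),
              "variance >= m(1-m); no valid beta distribution")
  common <- m * (1 - m) / v - 1
  structure(list(shape1 = m * common, shape2 = (1 - m) * common,
                 kind = kind, n = n, mean = m),
            class = "beta_rate")
}

#' @export
print.beta_rate <- function(x, ...) {
  cat(sprintf("<beta_rate> %s: Beta(%.3g, %.3g), mean %.3g (n = %d)\n",
              x$kind, x$shape1, x$shape2, x$mean, x$n))
  invisible(x)
}

draw_rate <- function(b) {
  if (is.function(b)) b() else stats::rbeta(1, b$shape1, b$shape2)
}

#' Stochastic invasion/extinction simulation
#'
#' Step-ahead simulation over fine watersheds. Each replicate year: (1) the
#' invasion model predicts an invasion probability for every uninvaded fine
#' unit (by default the coarse-watershed prediction shared by member units;
#' `level = "fine"` uses each unit's own distance covariate); (2) an annual
#' invasion rate is drawn from `inv_beta` and converted to a count,
#' round(rate x number of uninvaded units); (3) that many uninvaded units are
#' invaded by probability-weighted sampling without replacement; (4) an
#' extinction rate drawn from `ext_beta` is converted to round(rate x number
#' of invaded units) and that many invaded units are set extinct uniformly at
#' random; (5) coarse proportions and distances are updated. Counts exceeding
#' the available units are capped (and counted in the output). Each replicate
#' runs on its own child seed, so the full set of trajectories is reproducible
#' bit-for-bit from `seed`.
#'
#' @param model an `invasion_model`, or a `function(newdata)` returning a
#'   probability per row (stub hook for tests).
#' @param landscape a `pig_landscape`.
#' @param init_status data frame (huc12_id, invaded) for the launch year.
#' @param covariates_huc8 static covariate table.
#' @param inv_beta,ext_beta `beta_rate` objects, or zero-argument functions
#'   returning a rate draw (test hook; e.g. `function() 0`).
#' @param horizon forecast years (default 8).
#' @param reps replicates (default 1000).
#' @param seed master seed.
#' @param level "coarse" (default) or "fine" prediction granularity.
#' @param denominator "at_risk" converts rates against currently
#'   uninvaded/invaded counts (default); "total" against all fine units.
#' @return object of class `sim_trajectories`: `prop` array
#'   \[rep, year, huc8\], `n_invaded` matrix \[rep, year\], `ledger` data
#'   frame per replicate-year (n_before, invasions, extinctions, n_after),
#'   `years` (1..horizon indices), `huc8_ids`, `n_capped`.
#' @export
simulate_occupancy <- function(model, landscape, init_status, covariates_huc8,
                               inv_beta, ext_beta, horizon = 8, reps = 1000,
                               seed = 1L, level = c("coarse", "fine"),
                               denominator = c("at_risk", "total")) {
  level <- match.arg(level)
  denominator <- match.arg(denominator)
  assert_that(horizon >= 1 && reps >= 1, "horizon and reps must be >= 1")
  h8 <- landscape$huc8
  h12 <- landscape$huc12
  n12 <- nrow(h12)
  memb <- split(seq_len(n12), h12$huc8_id)[h8$huc8_id]
  h8_of <- match(h12$huc8_id, h8$huc8_id)
  extent <- sqrt(diff(range(h12$cx))^2 + diff(range(h12$cy))^2)
  init <- init_status$invaded[match(h12$huc12_id, init_status$huc12_id)] > 0
  assert_that(!anyNA(init), "init_status must cover every fine watershed")
  cc <- covariates_huc8[match(h8$huc8_id, covariates_huc8$huc8_id), ]
  static8 <- data.frame(ruggedness = cc$ruggedness,
                        lewis_density = cc$lewis_density,
                        temp_range = cc$temp_range, precip = cc$precip,
                        region = h8$region)

  seeds <- child_seeds(seed, reps)
  prop <- array(NA_real_, dim = c(reps, horizon, nrow(h8)),
                dimnames = list(NULL, NULL, h8$huc8_id))
  n_invaded <- matrix(NA_integer_, reps, horizon)
  ledger <- vector("list", reps)
  n_capped <- 0L

  for (r in seq_len(reps)) {
    rows <- matrix(NA_real_, horizon, 4)
    with_seed(seeds[r], {
      invaded <- init
      for (t in seq_len(horizon)) {
        n_before <- sum(invaded)
        uninv <- which(!invaded)
        # dynamic covariates from the current map
        prev_rate8 <- vapply(memb, function(ix) mean(invaded[ix]), 0)
        pts <- cbind(h12$cx[invaded], h12$cy[invaded])
        if (level == "coarse") {
          d8 <- nearest_dist(cbind(h8$cx, h8$cy), pts)
          d8[!is.finite(d8)] <- extent
          nd <- cbind(static8, prev_rate = prev_rate8, dist_nearest = d8)
          p8 <- if (is.function(model)) model(nd)
            else predict_invasion_prob(model, nd)
          p_unit <- p8[h8_of]
        } else {
          du <- nearest_dist(cbind(h12$cx[uninv], h12$cy[uninv]), pts)
          du[!is.finite(du)] <- extent
          nd <- cbind(static8[h8_of[uninv], ],
                      prev_rate = prev_rate8[h8_of[uninv]],
                      dist_nearest = du)
          p_unit <- rep(NA_real_, n12)
          p_unit[uninv] <- if (is.function(model)) model(nd)
            else predict_invasion_prob(model, nd)
        }
        denom_inv <- if (denominator == "at_risk") length(uninv) else n12
        k_inv <- round(draw_rate(inv_beta) * denom_inv)
        if (k_inv > length(uninv)) {
          n_capped <- n_capped + 1L
          k_inv <- length(uninv)
        }
        chosen <- sample_safe(uninv, k_inv, prob = p_unit[uninv])
        invaded[chosen] <- TRUE

        inv_ids <- which(invaded)
        denom_ext <- if (denominator == "at_risk") length(inv_ids) else n12
        k_ext <- round(draw_rate(ext_beta) * denom_ext)
        if (k_ext > length(inv_ids)) {
          n_capped <- n_capped + 1L
          k_ext <- length(inv_ids)
        }
        gone <- sample_safe(inv_ids, k_ext)
        invaded[gone] <- FALSE

        prop[r, t, ] <- vapply(memb, function(ix) mean(invaded[ix]), 0)
        n_invaded[r, t] <- sum(invaded)
        rows[t, ] <- c(n_before, length(chosen), length(gone), sum(invaded))
      }
    })
    ledger[[r]] <- data.frame(rep = r, year = seq_len(horizon),
                              n_before = rows[, 1], invasions = rows[, 2],
                              extinctions = rows[, 3], n_after = rows[, 4])
  }
  structure(list(prop = prop, n_invaded = n_invaded,
                 ledger = do.call(rbind, ledger),
                 years = seq_len(horizon), huc8_ids = h8$huc8_id,
                 n_capped = n_capped),
            class = "sim_trajectories")
}

#' @export
print.sim_trajectories <- function(x, ...) {
  cat(sprintf("<sim_trajectories> %d replicates x %d years x %d watersheds\n",
              dim(x$prop)[1], dim(x$prop)[2], dim(x$prop)[3]))
  invisible(x)
}

#' Median (and 95-percentile) invaded proportion per watershed-year
#'
#' Elementwise median and 2.5/97.5 percentiles across replicates.
#'
#' @param traj a `sim_trajectories`.
#' @return data frame (huc8_id, year, median, lo, hi).
#' @export
summarize_trajectories <- function(traj) {
  nh <- dim(traj$prop)[3]
  nt <- dim(traj$prop)[2]
  out <- expand.grid(huc8_id = traj$huc8_ids, year = traj$years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$median <- NA_real_
  out$lo <- NA_real_
  out$hi <- NA_real_
  for (w in seq_len(nh)) {
    for (t in seq_len(nt)) {
      v <- traj$prop[, t, w]
      i <- which(out$huc8_id == traj$huc8_ids[w] & out$year == traj$years[t])
      out$median[i] <- stats::median(v)
      q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
      out$lo[i] <- q[1]
      out$hi[i] <- q[2]
    }
  }
  out
}

#' Map watershed proportions to county proportions
#'
#' County proportion invaded = sum over coarse watersheds of the county's
#' overlap weight times the watershed proportion. Weights must sum to one per
#' county.
#'
#' @param huc8_props data frame with `huc8_id`, optionally `year`, and one or
#'   more numeric value columns (e.g. `median`, `lo`, `hi`).
#' @param overlap overlap-weight table (county_id, huc8_id, weight).
#' @return data frame (county_id \[, year\], value columns).
#' @export
to_county <- function(huc8_props, overlap) {
  sums <- tapply(overlap$weight, overlap$county_id, sum)
  assert_that(all(abs(sums - 1) < 1e-6),
              "overlap weights must sum to 1 per county")
  val_cols <- setdiff(names(huc8_props), c("huc8_id", "year"))
  has_year <- "year" %in% names(huc8_props)
  merged <- merge(overlap, huc8_props, by = "huc8_id")
  by_cols <- if (has_year) list(county_id = merged$county_id,
                                year = merged$year)
    else list(county_id = merged$county_id)
  out <- NULL
  for (vc in val_cols) {
    agg <- stats::aggregate(merged$weight * merged[[vc]], by = by_cols, sum)
    names(agg)[ncol(agg)] <- vc
    out <- if (is.null(out)) agg else merge(out, agg, by = names(by_cols))
  }
  ord <- if (has_year) order(out$county_id, out$year) else order(out$county_id)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}
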