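# Boosted-regression-tree spread models (A-D) and deterministic step-ahead
# forecasting with bounding and adjacent-occupancy updates.

#' Specification of one of the four county spread models
#'
#' Models A and B predict the annual change in proportion occupied, C and D
#' the change in km2 occupied. A and C include the focal county's occupancy in
#' the previous year as a covariate; B and D exclude it (it is a very strong
#' predictor, so both variants bracket the extent of path dependency).
#'
#' @param model one of "A", "B", "C", "D".
#' @return list of class `spread_model_spec` with `model`, `response_scale`
#'   ("prop" or "km2"), `include_prev_status`, and `covariates` (the feature
#'   manifest).
#' @export
spread_model_spec <- function(model = c("A", "B", "C", "D")) {
  model <- match.arg(model)
  scale <- if (model %in% c("A", "B")) "prop" else "km2"
  include_prev <- model %in% c("A", "C")
  covs <- c(
    if (include_prev) "prev_occ",
    "adj_mean_prop", "removals_focal", "adj_mean_removals_log",
    "prop_active_removal", "adj_mean_prop_active",
    "habitat_suitability", "density_rescaled", "pct_hydrology",
    "pct_tree", "pct_crops", "pct_pasture", "pct_deciduous")
  structure(list(model = model, response_scale = scale,
                 include_prev_status = include_prev, covariates = covs),
            class = "spread_model_spec")
}

#' Boosting hyperparameters
#'
#' @param n_rounds boosting rounds M.
#' @param shrinkage learning rate nu.
#' @param max_depth maximum tree depth.
#' @param min_leaf minimum leaf size.
#' @param min_rows minimum stratum size required to fit.
#' @return list of class `boost_control`.
#' @export
boost_control <- function(n_rounds = 500, shrinkage = 0.05, max_depth = 3,
                          min_leaf = 5, min_rows = 10) {
  structure(list(n_rounds = n_rounds, shrinkage = shrinkage,
                 max_depth = max_depth, min_leaf = min_leaf,
                 min_rows = min_rows), class = "boost_control")
}

neighbor_index <- function(landscape) {
  ids <- landscape$counties$county_id
  adj <- landscape$adjacency
  lapply(ids, function(i) match(adj$neighbor_id[adj$county_id == i], ids))
}

adj_mean <- function(values, nb) {
  vapply(nb, function(ix) if (length(ix)) mean(values[ix]) else 0, 0)
}

# Per-county feature rows for predicting the change from the current year to
# the next. `prop` is the current proportion-occupied vector (county order of
# landscape$counties); `removals`/`prop_active` are current-year vectors.
build_features <- function(landscape, prop, removals, prop_active,
                           covariates, spec, nb = NULL) {
  cn <- landscape$counties
  if (is.null(nb)) nb <- neighbor_index(landscape)
  cc <- covariates$county[match(cn$county_id, covariates$county$county_id), ]
  feats <- data.frame(
    adj_mean_prop = adj_mean(prop, nb),
    removals_focal = if (spec$response_scale == "prop")
      removals / cn$area_km2 else removals,
    adj_mean_removals_log = log1p(adj_mean(removals, nb)),
    prop_active_removal = prop_active,
    adj_mean_prop_active = adj_mean(prop_active, nb),
    habitat_suitability = cc$habitat_suitability,
    density_rescaled = cc$density_rescaled,
    pct_hydrology = cc$pct_hydrology,
    pct_tree = cc$pct_tree,
    pct_crops = cc$pct_crops,
    pct_pasture = cc$pct_pasture,
    pct_deciduous = cc$pct_deciduous
  )
  if (spec$include_prev_status) {
    feats$prev_occ <- if (spec$response_scale == "prop") prop
      else prop * cn$area_km2
  }
  feats[, spec$covariates, drop = FALSE]
}

year_vector <- function(df, year, col, ids) {
  sub <- df[df$year == year, ]
  out <- sub[[col]][match(ids, sub$county_id)]
  out[is.na(out)] <- 0
  out
}

#' Fit persistent and transient spread models for one specification
#'
#' The response is the per-county mean pre-program spread rate on the spec's
#' scale; features are the county's state and removal covariates in the year
#' before the window plus static habitat/land-cover covariates. The two
#' strata are fit independently because spread rates and covariate effects
#' differ between long-established and newly invaded counties.
#'
#' @param landscape a `pig_landscape`.
#' @param history a `pig_history` covering the window and its preceding year.
#' @param covariates output of [make_covariates()].
#' @param spec a `spread_model_spec`.
#' @param strata output of [stratify()].
#' @param window pre-program years (default 2009-2013).
#' @param control a `boost_control`.
#' @param seed RNG seed.
#' @return list of class `spread_models`: `persistent` and `transient`
#'   (each `lsboost`), plus `spec`, `strata`, `control`.
#' @export
fit_spread_models <- function(landscape, history, covariates, spec,
                              strata = NULL, window = 2009:2013,
                              control = boost_control(), seed = 1L) {
  if (is.null(strata)) strata <- stratify(history, window)
  ids <- landscape$counties$county_id
  response <- preprogram_mean(annual_deltas(history, landscape), window)
  ycol <- if (spec$response_scale == "prop") "mean_dprop" else "mean_dkm2"
  base_year <- min(window) - 1L
  occ <- if (inherits(history, "pig_history")) history$occupancy else history
  prop0 <- year_vector(occ, base_year, "prop", ids)
  rem0 <- year_vector(covariates$removals, base_year, "removals", ids)
  act0 <- year_vector(covariates$removals, base_year,
                      "prop_active_removal", ids)
  feats <- build_features(landscape, prop0, rem0, act0, covariates, spec)
  y <- response[[ycol]][match(ids, response$county_id)]

  fit_stratum <- function(sids) {
    ix <- match(sids, ids)
    assert_that(length(ix) >= control$min_rows,
                sprintf("stratum has %d rows; need >= %d",
                        length(ix), control$min_rows))
    fit_lsboost(feats[ix, , drop = FALSE], y[ix],
                n_rounds = control$n_rounds, shrinkage = control$shrinkage,
                max_depth = control$max_depth, min_leaf = control$min_leaf,
                seed = seed)
  }
  structure(list(persistent = fit_stratum(strata$persistent),
                 transient = fit_stratum(strata$transient),
                 spec = spec, strata = strata, control = control),
            class = "spread_models")
}

# dispatch: a model may be an lsboost fit or a plain function(features)
predict_delta <- function(model, feats) {
  if (is.function(model)) model(feats) else stats::predict(model, feats)
}

model_response_sd <- function(model) {
  if (is.function(model)) 0 else model$response_sd
}

#' Deterministic step-ahead occupancy forecast
#'
#' Starting from the last observed occupancy map, each forecast year predicts
#' the rate of change for every county with its stratum's model (persistent
#' counties use the persistent model; transient and never-occupied counties
#' use the transient model), adds the change to the current value, and bounds
#' the result: proportions are clipped to \[0,1\], areas to \[0, county
#' area\]. The updated map feeds the next year's adjacent-mean-occupancy
#' covariate, and tau-crossings are recorded as newly occupied/unoccupied
#' counties. All other covariates are held at their last observed values
#' unless a removal model is supplied, in which case focal and adjacent
#' removal covariates are refreshed from its predictions each year.
#'
#' @param models a `spread_models` fit, or a list with elements `persistent`,
#'   `transient` (each an `lsboost` or a `function(features) -> delta`),
#'   `spec` and `strata`.
#' @param landscape a `pig_landscape`.
#' @param state0 data frame (county_id, prop): occupancy in the launch year.
#' @param covariates output of [make_covariates()].
#' @param horizon number of forecast years (default 8: 2014-2021).
#' @param start_year first forecast year.
#' @param tau occupancy threshold for transition bookkeeping.
#' @param removal_model optional removal-update model from
#'   [fit_removal_model()]; off by default.
#' @param noise if TRUE, adds N(0, sd) noise to each predicted change, with
#'   sd the empirical standard deviation of the stratum's training response
#'   (opt-in; the headline forecasts are deterministic).
#' @param seed RNG seed (used only when `noise = TRUE`).
#' @return object of class `forecast_result`: `occupancy` (county_id, year,
#'   prop, km2), `newly_occupied`/`newly_unoccupied` (lists of county ids per
#'   year), `spec`, `start_year`, `horizon`.
#' @export
step_ahead <- function(models, landscape, state0, covariates, horizon = 8,
                       start_year = 2014, tau = 0, removal_model = NULL,
                       noise = FALSE, seed = 1L) {
  assert_that(horizon >= 1, "horizon must be >= 1")
  spec <- models$spec
  strata <- models$strata
  cn <- landscape$counties
  ids <- cn$county_id
  nb <- neighbor_index(landscape)
  prop <- state0$prop[match(ids, state0$county_id)]
  assert_that(!anyNA(prop), "state0 must cover every county")

  last_year <- max(covariates$removals$year)
  removals <- year_vector(covariates$removals, last_year, "removals", ids)
  prop_active <- year_vector(covariates$removals, last_year,
                             "prop_active_removal", ids)

  use_transient <- !(ids %in% strata$persistent)
  years <- start_year + seq_len(horizon) - 1L
  occ_rows <- vector("list", horizon)
  new_occ <- new_unocc <- stats::setNames(vector("list", horizon),
                                          years)
  with_seed(seed, {
    for (h in seq_len(horizon)) {
      feats <- build_features(landscape, prop, removals, prop_active,
                              covariates, spec, nb)
      delta <- numeric(length(ids))
      delta[!use_transient] <- predict_delta(models$persistent,
                                             feats[!use_transient, ,
                                                   drop = FALSE])
      delta[use_transient] <- predict_delta(models$transient,
                                            feats[use_transient, ,
                                                  drop = FALSE])
      if (noise) {
        sds <- ifelse(use_transient, model_response_sd(models$transient),
                      model_response_sd(models$persistent))
        delta <- delta + stats::rnorm(length(ids), 0, sds)
      }
      if (spec$response_scale == "prop") {
        newp <- clamp(prop + delta, 0, 1)
      } else {
        newp <- clamp(prop * cn$area_km2 + delta, 0, cn$area_km2) /
          cn$area_km2
      }
      new_occ[[h]] <- ids[newp > tau & prop <= tau]
      new_unocc[[h]] <- ids[newp <= tau & prop > tau]
      prop <- newp
      occ_rows[[h]] <- data.frame(county_id = ids, year = years[h],
                                  prop = prop, km2 = prop * cn$area_km2)
      if (!is.null(removal_model)) {
        rem_feats <- build_removal_features(landscape, prop, removals,
                                            covariates, nb)
        per_km2 <- pmax(0, update_removals(removal_model, rem_feats))
        removals <- per_km2 * cn$area_km2
      }
    }
  })
  structure(list(occupancy = do.call(rbind, occ_rows),
                 newly_occupied = new_occ, newly_unoccupied = new_unocc,
                 spec = spec, start_year = start_year, horizon = horizon),
            class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("<forecast_result> model %s, years %d-%d, %d counties\n",
              x$spec$model, x$start_year, x$start_year + x$horizon - 1L,
              length(unique(x$occupancy$county_id))))
  invisible(x)
}

build_removal_features <- function(landscape, prop, removals, covariates,
                                   nb = NULL) {
  cn <- landscape$counties
  if (is.null(nb)) nb <- neighbor_index(landscape)
  cc <- covariates$county[match(cn$county_id, covariates$county$county_id), ]
  data.frame(
    km2_occupied = prop * cn$area_km2,
    removals_prev_per_km2 = removals / cn$area_km2,
    adj_mean_removals_log = log1p(adj_mean(removals, nb)),
    habitat_suitability = cc$habitat_suitability,
    density_rescaled = cc$density_rescaled,
    pct_hydrology = cc$pct_hydrology,
    pct_tree = cc$pct_tree,
    pct_crops = cc$pct_crops,
    pct_pasture = cc$pct_pasture,
    pct_deciduous = cc$pct_deciduous
  )
}

#' Fit the optional removal-update model
#'
#' Models the relationship between current removal intensity (removals per
#' km2) and covariates (current occupied area, previous-year removal
#' covariates, habitat and land cover) pooled across all counties, so that
#' forecasts can hold removal effort at pre-program levels as the invasion
#' front advances. The data are not stratified: the removal-covariate
#' relationship shows no dependence on historical presence.
#'
#' @param landscape a `pig_landscape`.
#' @param history a `pig_history`.
#' @param covariates output of [make_covariates()].
#' @param years fit years (each needs its predecessor in the removal series).
#' @param control a `boost_control`.
#' @param seed RNG seed.
#' @return an `lsboost` fit (response: removals per km2).
#' @export
fit_removal_model <- function(landscape, history, covariates,
                              years = 2009:2013, control = boost_control(),
                              seed = 1L) {
  ids <- landscape$counties$county_id
  occ <- if (inherits(history, "pig_history")) history$occupancy else history
  nb <- neighbor_index(landscape)
  rows <- list()
  resp <- list()
  for (y in years) {
    prop <- year_vector(occ, y, "prop", ids)
    rem_prev <- year_vector(covariates$removals, y - 1L, "removals", ids)
    rows[[length(rows) + 1L]] <-
      build_removal_features(landscape, prop, rem_prev, covariates, nb)
    resp[[length(resp) + 1L]] <-
      year_vector(covariates$removals, y, "removals", ids) /
      landscape$counties$area_km2
  }
  fit_lsboost(do.call(rbind, rows), unlist(resp),
              n_rounds = control$n_rounds, shrinkage = control$shrinkage,
              max_depth = control$max_depth, min_leaf = control$min_leaf,
              seed = seed)
}

#' Refresh removal covariates from the removal model
#'
#' @param model removal model (an `lsboost` or `function(features)`).
#' @param features output of the internal removal feature builder.
#' @return predicted removals per km2 per county.
#' @export
update_removals <- function(model, features) {
  predict_delta(model, features)
}

#' Newly occupied / unoccupied counts per forecast year
#'
#' @param result a `forecast_result`.
#' @return data frame (year, n_newly_occupied, n_newly_unoccupied,
#'   cum_occupied, cum_unoccupied).
#' @export
forecast_transition_rates <- function(result) {
  years <- result$start_year + seq_len(result$horizon) - 1L
  occ <- vapply(result$newly_occupied, length, 0L)
  unocc <- vapply(result$newly_unoccupied, length, 0L)
  data.frame(year = years, n_newly_occupied = occ,
             n_newly_unoccupied = unocc,
             cum_occupied = cumsum(occ), cum_unoccupied = cumsum(unocc))
}
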