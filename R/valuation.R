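# Safeguarded-resource accounting: forecast occupancy x acreage/head,
# valued at constant 2017 prices, yields, and cash rents.

#' Acre / square-kilometre conversion
#'
#' Uses the fixed constant 1 acre = 0.0040468564 km2; the round trip is exact
#' to machine precision.
#'
#' @param acres,km2 finite nonnegative quantities.
#' @return converted quantity.
#' @export
acres_to_km2 <- function(acres) {
  assert_that(all(is.finite(acres)) && all(acres >= 0),
              "acres must be finite and nonnegative")
  acres * ACRE_KM2
}

#' @rdname acres_to_km2
#' @export
km2_to_acres <- function(km2) {
  assert_that(all(is.finite(km2)) && all(km2 >= 0),
              "km2 must be finite and nonnegative")
  km2 / ACRE_KM2
}

#' Additional (safeguarded) occupancy per county-year
#'
#' The proportion of each county that the counterfactual forecast occupies
#' beyond what was actually observed: max(0, forecast - observed). Counties
#' observed occupied at full extent contribute zero regardless of the
#' forecast, so resources in always-fully-occupied counties are never
#' counted as safeguarded.
#'
#' @param forecast data frame (county_id, year, prop) of forecast occupancy.
#' @param observed data frame (county_id, year, prop) of observed occupancy
#'   over the same counties and years.
#' @return data frame (county_id, year, prop_safeguarded).
#' @export
incremental_occupancy <- function(forecast, observed) {
  assert_that(setequal(forecast$county_id, observed$county_id),
              "forecast and observed county universes differ")
  m <- merge(forecast[, c("county_id", "year", "prop")],
             observed[, c("county_id", "year", "prop")],
             by = c("county_id", "year"), suffixes = c("_f", "_o"))
  assert_that(nrow(m) == nrow(forecast),
              "forecast and observed years differ")
  data.frame(county_id = m$county_id, year = m$year,
             prop_safeguarded = pmax(0, m$prop_f - m$prop_o))
}

#' Resource amounts threatened by forecast occupancy
#'
#' Interacts each county-year safeguarded proportion with the county's total
#' acreage (or head count) of each resource. The resource ledger is held
#' constant across all years (census-year data are assumed constant over the
#' forecast window).
#'
#' @param safeguarded output of [incremental_occupancy()].
#' @param resources resource table (county_id, state_id, category, resource,
#'   amount, unit); counties absent from the table contribute zero.
#' @return data frame (county_id, state_id, year, category, resource, amount,
#'   unit).
#' @export
threatened_amount <- function(safeguarded, resources) {
  assert_that(all(safeguarded$prop_safeguarded >= 0),
              "negative safeguarded proportion")
  m <- merge(safeguarded, resources, by = "county_id")
  data.frame(county_id = m$county_id, state_id = m$state_id, year = m$year,
             category = m$category, resource = m$resource,
             amount = m$prop_safeguarded * m$amount, unit = m$unit)
}

#' State-level dollar value per acre
#'
#' Crops: national price times state yield. Pasture: the state's cash rent,
#' or the national cash rent where the state has none. Wetlands and livestock
#' carry no per-acre value and are excluded (reported in physical units
#' only).
#'
#' @param resources a `pig_resources` bundle (or any list with elements
#'   `prices`, `yields`, `cash_rents`, `national_rent`).
#' @return data frame (state_id, resource, value_per_acre).
#' @export
per_acre_value <- function(resources) {
  yields <- resources$yields
  prices <- resources$prices
  no_price <- setdiff(unique(yields$resource), prices$resource)
  assert_that(length(no_price) == 0,
              paste("crop(s) with yield but no price:",
                    paste(no_price, collapse = ", ")))
  m <- merge(yields, prices, by = "resource")
  crops <- data.frame(state_id = m$state_id, resource = m$resource,
                      value_per_acre = m$price * m$yield)
  states <- sort(unique(yields$state_id))
  rent <- resources$cash_rents$rent[match(states,
                                          resources$cash_rents$state_id)]
  rent[is.na(rent)] <- resources$national_rent
  pasture <- data.frame(state_id = states, resource = "pasture",
                        value_per_acre = rent)
  out <- rbind(crops, pasture)
  out[order(out$state_id, out$resource), ]
}

#' Aggregate safeguarded amounts and dollar values
#'
#' Sums amounts over counties and years per category, and values the valued
#' resources: dollars = sum over (county, year, resource) of amount x
#' $/acre joined on (state, resource). Resources without a per-acre value
#' (wetlands, livestock) report amounts only (`value` is NA).
#'
#' @param amounts output of [threatened_amount()].
#' @param values output of [per_acre_value()].
#' @param model optional model label attached to the summary.
#' @return data frame of class `safeguard_summary` (model, category, amount,
#'   unit, value).
#' @export
value_safeguarded <- function(amounts, values, model = NA_character_) {
  m <- merge(amounts, values, by = c("state_id", "resource"), all.x = TRUE)
  m$dollars <- m$amount * m$value_per_acre
  cats <- sort(unique(amounts$category))
  if (length(cats) == 0) {
    out <- data.frame(model = character(), category = character(),
                      amount = numeric(), unit = character(),
                      value = numeric())
    class(out) <- c("safeguard_summary", "data.frame")
    return(out)
  }
  out <- data.frame(model = model, category = cats,
                    amount = NA_real_, unit = NA_character_,
                    value = NA_real_)
  for (i in seq_along(cats)) {
    sub <- m[m$category == cats[i], ]
    out$amount[i] <- sum(sub$amount)
    out$unit[i] <- sub$unit[1]
    out$value[i] <- if (all(is.na(sub$value_per_acre))) NA_real_
      else sum(sub$dollars, na.rm = TRUE)
  }
  class(out) <- c("safeguard_summary", "data.frame")
  out
}

#' Ensemble statistics across model summaries
#'
#' Unweighted mean, minimum, and maximum across models of each category's
#' safeguarded amount and (where valued) dollar value.
#'
#' @param summaries list of `safeguard_summary` data frames (>= 1).
#' @return data frame (category, unit, metric in amount/value, mean, min,
#'   max, n_models).
#' @export
ensemble_stats <- function(summaries) {
  assert_that(length(summaries) >= 1, "need >= 1 model summary")
  all <- do.call(rbind, lapply(summaries, as.data.frame))
  out <- list()
  for (cat in sort(unique(all$category))) {
    sub <- all[all$category == cat, ]
    out[[length(out) + 1L]] <- data.frame(
      category = cat, unit = sub$unit[1], metric = "amount",
      mean = mean(sub$amount), min = min(sub$amount), max = max(sub$amount),
      n_models = nrow(sub))
    if (!all(is.na(sub$value))) {
      out[[length(out) + 1L]] <- data.frame(
        category = cat, unit = "usd", metric = "value",
        mean = mean(sub$value), min = min(sub$value), max = max(sub$value),
        n_models = nrow(sub))
    }
  }
  do.call(rbind, out)
}
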