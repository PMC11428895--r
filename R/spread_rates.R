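#' Annual occupancy deltas on both scales
#'
#' For every county and consecutive year pair, computes the change in
#' proportion occupied, dP = p_t - p_(t-1) (in \[-1, 1\]), and the change in
#' area occupied, dKm2 = dP * A_c, where A_c is the county area. The delta is
#' indexed at the later year t.
#'
#' @param history a `pig_history`, or a data frame with columns county_id,
#'   year, prop.
#' @param landscape a `pig_landscape` supplying county areas.
#' @return data frame (county_id, year, dprop, dkm2), one row per county per
#'   year pair.
#' @export
annual_deltas <- function(history, landscape) {
  occ <- if (inherits(history, "pig_history")) history$occupancy else history
  years <- sort(unique(occ$year))
  assert_that(length(years) >= 2, "need at least 2 consecutive years")
  counties <- landscape$counties
  wide <- occupancy_matrix(occ, counties$county_id, years)
  out <- list()
  for (ti in 2:length(years)) {
    dp <- wide[, ti] - wide[, ti - 1L]
    out[[ti - 1L]] <- data.frame(
      county_id = counties$county_id, year = years[ti],
      dprop = dp, dkm2 = dp * counties$area_km2
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# occupancy long -> matrix [county x year]; errors on any missing cell
occupancy_matrix <- function(occ, county_ids, years) {
  m <- matrix(NA_real_, nrow = length(county_ids), ncol = length(years),
              dimnames = list(county_ids, years))
  ci <- match(occ$county_id, county_ids)
  yi <- match(occ$year, years)
  keep <- !is.na(ci) & !is.na(yi)
  m[cbind(ci[keep], yi[keep])] <- occ$prop[keep]
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing occupancy for county %s in year %s",
                 county_ids[miss[1]], years[miss[2]]), call. = FALSE)
  }
  m
}

#' Pre-program mean spread rates per county
#'
#' Arithmetic mean of the annual deltas inside a window of years, per county
#' and on both scales — the average pre-program spread rate used as the
#' boosted-tree response.
#'
#' @param deltas output of [annual_deltas()].
#' @param window years (delta index years) to average over; default the
#'   five pre-program years 2009-2013.
#' @return data frame (county_id, mean_dprop, mean_dkm2).
#' @export
preprogram_mean <- function(deltas, window = 2009:2013) {
  assert_that(length(window) >= 1, "empty window rejected")
  sub <- deltas[deltas$year %in% window, ]
  assert_that(all(window %in% deltas$year),
              "window contains years absent from the delta table")
  agg <- stats::aggregate(cbind(dprop, dkm2) ~ county_id, data = sub, FUN = mean)
  names(agg) <- c("county_id", "mean_dprop", "mean_dkm2")
  agg[order(agg$county_id), ]
}

#' Stratify counties into persistent / transient / never sets
#'
#' A county is persistent if its proportion occupied exceeds `tau` in every
#' year of the window, transient if it exceeds `tau` in at least one but not
#' all years, and never otherwise. The three sets partition the counties.
#'
#' @param history a `pig_history` or occupancy data frame.
#' @param window years defining the labels (default the pre-program window).
#' @param tau occupancy threshold; the default 0 counts any strictly positive
#'   mapped proportion as presence.
#' @return list with integer vectors `persistent`, `transient`, `never`.
#' @export
stratify <- function(history, window = 2009:2013, tau = 0) {
  occ <- if (inherits(history, "pig_history")) history$occupancy else history
  assert_that(all(window %in% occ$year), "window outside available years")
  sub <- occ[occ$year %in% window, ]
  ids <- sort(unique(occ$county_id))
  occ_flag <- occupancy_matrix(sub, ids, sort(window)) > tau
  n_occ <- rowSums(occ_flag)
  list(persistent = ids[n_occ == length(window)],
       transient = ids[n_occ > 0 & n_occ < length(window)],
       never = ids[n_occ == 0])
}

#' Coarse-watershed binomial response from fine presence flags
#'
#' Counts, per coarse watershed and year, the number of invaded fine units k
#' out of the n member units.
#'
#' @param huc12_status data frame (huc12_id, year, invaded in 0/1).
#' @param landscape a `pig_landscape` giving the fine-to-coarse mapping.
#' @return data frame (huc8_id, year, k, n, rate).
#' @export
watershed_response <- function(huc12_status, landscape) {
  map <- landscape$huc12
  orphan <- setdiff(unique(huc12_status$huc12_id), map$huc12_id)
  assert_that(length(orphan) == 0,
              paste("fine watersheds without a coarse parent:",
                    paste(utils::head(orphan, 3), collapse = ", ")))
  parent <- map$huc8_id[match(huc12_status$huc12_id, map$huc12_id)]
  agg <- stats::aggregate(
    huc12_status$invaded,
    by = list(huc8_id = parent, year = huc12_status$year),
    FUN = function(z) c(k = sum(z), n = length(z)))
  out <- data.frame(huc8_id = agg$huc8_id, year = agg$year,
                    k = agg$x[, "k"], n = agg$x[, "n"])
  out$rate <- out$k / out$n
  out[order(out$huc8_id, out$year), ]
}

#' Observed annual invasion and extinction rate series
#'
#' For each consecutive year pair in the window: invasion rate = newly invaded
#' fine units / previously uninvaded units; extinction rate = newly extinct
#' units / previously invaded units. Years whose denominator is zero are
#' excluded with a warning. With `denominator = "total"` both rates are
#' instead divided by the total number of fine units (an alternative reading
#' kept as a switch; the at-risk denominator is the default).
#'
#' @param huc12_status data frame (huc12_id, year, invaded).
#' @param window years to use (>= 2); defaults to all years present.
#' @param denominator `"at_risk"` (default) or `"total"`.
#' @return list of data frames `invasion` and `extinction`, each
#'   (year, rate), the rate of the transition into that year.
#' @export
observed_rates <- function(huc12_status, window = NULL,
                           denominator = c("at_risk", "total")) {
  denominator <- match.arg(denominator)
  years <- sort(unique(huc12_status$year))
  if (!is.null(window)) years <- years[years %in% window]
  assert_that(length(years) >= 2, "need >= 2 years in window")
  huc12_status <- huc12_status[huc12_status$year %in% years, ]
  ids <- sort(unique(huc12_status$huc12_id))
  m <- matrix(NA_integer_, length(ids), length(years),
              dimnames = list(ids, years))
  m[cbind(match(huc12_status$huc12_id, ids),
          match(huc12_status$year, years))] <- huc12_status$invaded
  inv <- ext <- data.frame(year = integer(), rate = numeric())
  for (ti in 2:length(years)) {
    prev <- m[, ti - 1L] > 0
    cur <- m[, ti] > 0
    n_uninv <- sum(!prev)
    n_inv <- sum(prev)
    total <- length(ids)
    if ((if (denominator == "at_risk") n_uninv else total) > 0) {
      den <- if (denominator == "at_risk") n_uninv else total
      inv <- rbind(inv, data.frame(year = years[ti],
                                   rate = sum(cur & !prev) / den))
    } else {
      warning(sprintf("invasion rate undefined in %d (no units at risk)",
                      years[ti]))
    }
    if ((if (denominator == "at_risk") n_inv else total) > 0) {
      den <- if (denominator == "at_risk") n_inv else total
      ext <- rbind(ext, data.frame(year = years[ti],
                                   rate = sum(!cur & prev) / den))
    } else {
      warning(sprintf("extinction rate undefined in %d (no invaded units)",
                      years[ti]))
    }
  }
  list(invasion = inv, extinction = ext)
}

#' Transition-rate summary of an occupancy history
#'
#' Counts counties newly occupied (crossing `tau` upward) and newly
#' unoccupied (crossing downward) over the year pairs ending in the window,
#' the per-year rates (count / number of year pairs), and the mean occupied
#' area (km2) and proportion in the establishment year with a normal
#' approximation 95% CI (mean +/- 1.96 SE).
#'
#' @param history a `pig_history` or occupancy data frame.
#' @param landscape a `pig_landscape` for county areas.
#' @param window years t whose transition (t-1 -> t) is counted; year t-1 for
#'   the first window year must be present in the history.
#' @param tau occupancy threshold.
#' @return list: `newly_occupied`, `newly_unoccupied` (counts),
#'   `rate_occupied`, `rate_unoccupied` (counts/year), `n_years`,
#'   `establish_km2`, `establish_prop` (each mean, lo, hi, n) and
#'   `unoccupy_km2` (area lost at local extinction, mean, lo, hi, n).
#' @export
rate_summary <- function(history, landscape, window, tau = 0) {
  occ <- if (inherits(history, "pig_history")) history$occupancy else history
  years <- sort(unique(occ$year))
  window <- sort(window)
  assert_that(all(window %in% years), "window outside available years")
  assert_that(all((window - 1L) %in% years),
              "each window year needs its predecessor in the history")
  ids <- sort(unique(occ$county_id))
  m <- occupancy_matrix(occ, ids, years)
  areas <- landscape$counties$area_km2[match(ids, landscape$counties$county_id)]

  est_km2 <- est_prop <- lost_km2 <- numeric()
  n_occ <- n_unocc <- 0L
  for (y in window) {
    yi <- match(y, years)
    up <- m[, yi] > tau & m[, yi - 1L] <= tau
    dn <- m[, yi] <= tau & m[, yi - 1L] > tau
    n_occ <- n_occ + sum(up)
    n_unocc <- n_unocc + sum(dn)
    est_km2 <- c(est_km2, (m[, yi] * areas)[up])
    est_prop <- c(est_prop, m[, yi][up])
    lost_km2 <- c(lost_km2, (m[, yi - 1L] * areas)[dn])
  }
  ci <- function(x) {
    if (length(x) == 0) return(list(mean = NA_real_, lo = NA_real_,
                                    hi = NA_real_, n = 0L))
    se <- stats::sd(x) / sqrt(length(x))
    list(mean = mean(x), lo = mean(x) - 1.96 * se,
         hi = mean(x) + 1.96 * se, n = length(x))
  }
  ny <- length(window)
  list(newly_occupied = n_occ, newly_unoccupied = n_unocc,
       rate_occupied = n_occ / ny, rate_unoccupied = n_unocc / ny,
       n_years = ny,
       establish_km2 = ci(est_km2), establish_prop = ci(est_prop),
       unoccupy_km2 = ci(lost_km2))
}
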