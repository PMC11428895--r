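#' Generate a synthetic county/watershed landscape
#'
#' Builds a rectangular grid of counties with queen adjacency as a stand-in
#' for the national county map, plus a two-level watershed hierarchy: coarse
#' (8-digit analogue) watersheds each containing `fine_per_coarse` fine
#' (12-digit analogue) units that act as spatial replicates. County-to-coarse
#' overlap weights are computed from centroid proximity with a softmax, so
#' each county's weights are nonnegative and sum to one. Coarse watersheds are
#' labelled with one of four regions (west, plains, great_lakes, east) by
#' longitudinal band.
#'
#' The real methods depend only on adjacency, areas, centroids, and overlap
#' weights — not on actual shapes — so a grid landscape exercises every code
#' path the national data would.
#'
#' @param n_counties number of counties (>= 4); laid out on a near-square grid.
#' @param n_coarse number of coarse watersheds.
#' @param fine_per_coarse fine watershed units per coarse watershed.
#' @param n_states number of states (vertical bands of grid columns).
#' @param mean_area_km2 mean county area; areas are log-normal around this.
#' @param area_sdlog log-sd of county areas.
#' @param softmax_temp temperature of the centroid-distance softmax used for
#'   county-to-watershed overlap weights (smaller = sharper assignment).
#' @param seed integer RNG seed; output is deterministic given the seed.
#' @return an object of class `pig_landscape`: a list with data frames
#'   `counties` (county_id, state_id, area_km2, cx, cy, row, col),
#'   `adjacency` (county_id, neighbor_id; symmetric, irreflexive),
#'   `huc8` (huc8_id, cx, cy, region), `huc12` (huc12_id, huc8_id, cx, cy)
#'   and `overlap` (county_id, huc8_id, weight).
#' @export
make_landscape <- function(n_counties, n_coarse = 4L, fine_per_coarse = 10L,
                           n_states = 4L, mean_area_km2 = 1500,
                           area_sdlog = 0.5, softmax_temp = 1.0, seed = 1L) {
  assert_that(n_counties >= 4, "n_counties must be >= 4")
  assert_that(n_coarse >= 1 && fine_per_coarse >= 1,
              "watershed counts must be positive")
  nr <- floor(sqrt(n_counties))
  nc <- ceiling(n_counties / nr)
  with_seed(seed, {
    idx <- seq_len(n_counties)
    row <- ((idx - 1L) %/% nc) + 1L
    col <- ((idx - 1L) %% nc) + 1L
    state_band <- pmin(ceiling(col / (nc / n_states)), n_states)
    counties <- data.frame(
      county_id = idx,
      state_id = sprintf("S%02d", state_band),
      area_km2 = stats::rlnorm(n_counties,
                               meanlog = log(mean_area_km2) - area_sdlog^2 / 2,
                               sdlog = area_sdlog),
      cx = as.numeric(col), cy = as.numeric(row),
      row = row, col = col
    )

    # queen adjacency on the (possibly ragged) grid
    pairs <- expand.grid(a = idx, b = idx)
    pairs <- pairs[pairs$a != pairs$b, ]
    keep <- abs(row[pairs$a] - row[pairs$b]) <= 1L &
      abs(col[pairs$a] - col[pairs$b]) <= 1L
    adjacency <- data.frame(county_id = pairs$a[keep],
                            neighbor_id = pairs$b[keep])
    adjacency <- adjacency[order(adjacency$county_id, adjacency$neighbor_id), ]
    rownames(adjacency) <- NULL

    huc8 <- data.frame(
      huc8_id = sprintf("H8_%03d", seq_len(n_coarse)),
      cx = stats::runif(n_coarse, 0.5, nc + 0.5),
      cy = stats::runif(n_coarse, 0.5, nr + 0.5)
    )
    regions <- c("west", "plains", "great_lakes", "east")
    band <- ceiling(rank(huc8$cx, ties.method = "first") /
                      (n_coarse / min(4L, n_coarse)))
    huc8$region <- regions[pmin(band, 4L)]

    n_fine <- n_coarse * fine_per_coarse
    huc12 <- data.frame(
      huc12_id = sprintf("H12_%04d", seq_len(n_fine)),
      huc8_id = rep(huc8$huc8_id, each = fine_per_coarse),
      cx = rep(huc8$cx, each = fine_per_coarse) +
        stats::rnorm(n_fine, sd = 0.6),
      cy = rep(huc8$cy, each = fine_per_coarse) +
        stats::rnorm(n_fine, sd = 0.6)
    )

    # overlap weights: softmax of negative centroid distance
    d <- outer(counties$cx, huc8$cx, "-")^2 + outer(counties$cy, huc8$cy, "-")^2
    w <- exp(-sqrt(d) / softmax_temp)
    w <- w / rowSums(w)
    overlap <- data.frame(
      county_id = rep(counties$county_id, times = n_coarse),
      huc8_id = rep(huc8$huc8_id, each = n_counties),
      weight = as.vector(w)
    )
    overlap <- overlap[order(overlap$county_id, overlap$huc8_id), ]
    rownames(overlap) <- NULL

    structure(list(counties = counties, adjacency = adjacency,
                   huc8 = huc8, huc12 = huc12, overlap = overlap),
              class = "pig_landscape")
  })
}

#' @export
print.pig_landscape <- function(x, ...) {
  cat(sprintf("<pig_landscape> %d counties, %d coarse x %d fine watersheds\n",
              nrow(x$counties), nrow(x$huc8), nrow(x$huc12)))
  invisible(x)
}

# Draw annual occupancy-change increments: a spike at zero plus a
# right-skewed gamma tail and a shorter negative gamma tail, matching the
# qualitative shape of observed county spread-rate distributions (high
# density near 0, short negative tail, long positive tail).
draw_delta <- function(k, kp) {
  nonzero <- stats::runif(k) > kp$spike
  pos <- stats::runif(k) < kp$p_pos
  mag_pos <- stats::rgamma(k, shape = kp$shape, scale = kp$scale_pos)
  mag_neg <- stats::rgamma(k, shape = kp$shape, scale = kp$scale_neg)
  ifelse(nonzero, ifelse(pos, mag_pos, -mag_neg), 0)
}

default_kernel_params <- function() {
  list(spike = 0.5, p_pos = 0.85, shape = 1.5,
       scale_pos = 0.06, scale_neg = 0.02)
}

#' Generate a synthetic annual occupancy history
#'
#' Produces per-county annual proportions occupied and per-fine-watershed
#' presence flags with the structure the downstream analysis assumes: a
#' persistent core of counties occupied in every year of the labelling window,
#' a transient fringe that toggles occupancy at least once inside the window,
#' and a never-occupied remainder. Annual occupancy increments follow a
#' zero-spike plus gamma-tail mixture so the km2-scaled changes are
#' right-skewed. Persistent and transient counties are chosen by proximity to
#' a randomly placed invasion origin, giving a spatial core-plus-fringe
#' pattern.
#'
#' Fine-watershed presence is derived from the nearest county: each fine unit
#' carries a fixed threshold u ~ U(0.01, 0.5) and is invaded in a year iff the
#' nearest county's proportion occupied exceeds u.
#'
#' @param landscape a `pig_landscape`.
#' @param years integer vector of consecutive years (non-empty). The first
#'   year is a baseline (so that annual deltas exist for every labelling
#'   year); the label window starts at the second year.
#' @param persistent_frac,transient_frac fractions of all counties assigned to
#'   the persistent core and transient fringe; must lie in \[0,1\] and sum to
#'   at most 1. Defaults mirror the national split (376 persistent and 926
#'   transient of roughly 3100 counties).
#' @param kernel_params list with elements `spike`, `p_pos`, `shape`,
#'   `scale_pos`, `scale_neg` controlling the increment mixture.
#' @param establish_mean mean proportion occupied in the year a county first
#'   becomes occupied (beta-distributed around this mean).
#' @param flicker_prob probability that an invaded fine watershed drops out
#'   in a given year (transient fine-scale population turnover); flicker only
#'   removes presence, so fine flags stay consistent with county proportions.
#' @param label_window years that define the persistent/transient labels;
#'   default the `label_window_len` years starting at the second history
#'   year. Transient toggles are scheduled inside this window.
#' @param label_window_len length of the default label window (5, the
#'   pre-program window length).
#' @param seed integer RNG seed.
#' @return a list of class `pig_history`: `occupancy` (county_id, year, prop),
#'   `huc12_status` (huc12_id, year, invaded), `labels` (county_id, status),
#'   `events` (county_id, year, type) recording every 0-crossing the generator
#'   scheduled, and `label_window`.
#' @export
make_history <- function(landscape, years = 2008:2021,
                         persistent_frac = 0.12, transient_frac = 0.30,
                         kernel_params = default_kernel_params(),
                         establish_mean = 0.17, flicker_prob = 0.05,
                         label_window = NULL,
                         label_window_len = 5L, seed = 1L) {
  assert_that(length(years) >= 1, "empty year range rejected")
  assert_that(persistent_frac >= 0 && transient_frac >= 0 &&
                persistent_frac + transient_frac <= 1,
              "fractions must be in [0,1] and sum to <= 1")
  cn <- landscape$counties
  n <- nrow(cn)
  ny <- length(years)
  if (is.null(label_window)) {
    # default: label_window_len years starting at the second history year
    # (the first year is the delta baseline)
    wlen <- min(label_window_len, max(ny - 1L, 1L))
    w_first <- min(2L, ny)
    w_last <- w_first + wlen - 1L
  } else {
    assert_that(all(label_window %in% years),
                "label_window must be a subset of years")
    w_first <- match(min(label_window), years)
    w_last <- match(max(label_window), years)
    wlen <- w_last - w_first + 1L
  }
  kp <- utils::modifyList(default_kernel_params(), kernel_params)

  with_seed(seed, {
    n_pers <- round(persistent_frac * n)
    n_trans <- round(transient_frac * n)
    # invasion origin: a random corner of the grid; core = nearest counties
    ox <- sample(c(min(cn$cx), max(cn$cx)), 1)
    oy <- sample(c(min(cn$cy), max(cn$cy)), 1)
    d0 <- sqrt((cn$cx - ox)^2 + (cn$cy - oy)^2) + stats::runif(n, 0, 0.25)
    ord <- order(d0)
    pers_ids <- cn$county_id[ord[seq_len(n_pers)]]
    trans_ids <- cn$county_id[ord[n_pers + seq_len(n_trans)]]

    prop <- matrix(0, nrow = n, ncol = ny,
                   dimnames = list(cn$county_id, years))
    events <- list()

    # establishment proportion: beta with the stated mean
    r_establish <- function(k) {
      m <- establish_mean
      stats::rbeta(k, shape1 = 2, shape2 = 2 * (1 - m) / m)
    }
    evolve <- function(p0, steps) {
      out <- numeric(steps + 1L)
      out[1] <- p0
      if (steps > 0) {
        d <- draw_delta(steps, kp)
        for (s in seq_len(steps)) out[s + 1L] <- clamp(out[s] + d[s], 0.01, 1)
      }
      out
    }

    for (cid in pers_ids) {
      i <- match(cid, cn$county_id)
      prop[i, ] <- evolve(stats::runif(1, 0.2, 0.9), ny - 1L)
    }
    pick <- function(v) v[sample.int(length(v), 1L)]
    for (cid in trans_ids) {
      i <- match(cid, cn$county_id)
      if (w_last <= w_first) { # cannot toggle inside a 1-year window
        prop[i, ] <- evolve(r_establish(1), ny - 1L)
        next
      }
      if (stats::runif(1) < 0.7) {
        # invader: unoccupied, then establishes inside the label window
        j <- pick((w_first + 1L):w_last)
        p_est <- r_establish(1)
        traj <- evolve(p_est, ny - j)
        prop[i, j:ny] <- traj
        events[[length(events) + 1L]] <-
          data.frame(county_id = cid, year = years[j], type = "invade")
        if (ny > j && stats::runif(1) < 0.3) {  # later local extinction
          j2 <- pick((j + 1L):ny)
          prop[i, j2:ny] <- 0
          events[[length(events) + 1L]] <-
            data.frame(county_id = cid, year = years[j2], type = "extinct")
        }
      } else {
        # leaver: occupied at start, goes locally extinct inside the window
        j <- pick((w_first + 1L):w_last)
        traj <- evolve(stats::runif(1, 0.05, 0.4), j - 2L)
        prop[i, seq_len(j - 1L)] <- traj
        events[[length(events) + 1L]] <-
          data.frame(county_id = cid, year = years[j], type = "extinct")
        if (ny > j && stats::runif(1) < 0.2) {  # reinvasion after the window
          j2 <- pick((j + 1L):ny)
          prop[i, j2:ny] <- evolve(r_establish(1), ny - j2)
          events[[length(events) + 1L]] <-
            data.frame(county_id = cid, year = years[j2], type = "invade")
        }
      }
    }

    # populations decline before local extinction: taper the three years
    # ahead of each extinction event so the negative delta tail stays short
    # (the positive establishment/growth tail is the long one)
    ev <- if (length(events)) do.call(rbind, events) else NULL
    if (!is.null(ev)) {
      fac <- c(0.04, 0.12, 0.35)
      for (e in which(ev$type == "extinct")) {
        i <- match(ev$county_id[e], cn$county_id)
        j <- match(ev$year[e], years)
        for (o in 1:3) {
          if (j - o >= 1L && prop[i, j - o] > 0) {
            prop[i, j - o] <- prop[i, j - o] * fac[o]
          }
        }
      }
    }

    occupancy <- data.frame(
      county_id = rep(cn$county_id, times = ny),
      year = rep(years, each = n),
      prop = as.vector(prop)
    )

    # fine-watershed presence from the nearest county's proportion
    h12 <- landscape$huc12
    nf <- nrow(h12)
    nearest_county <- integer(nf)
    for (f in seq_len(nf)) {
      nearest_county[f] <-
        which.min((cn$cx - h12$cx[f])^2 + (cn$cy - h12$cy[f])^2)
    }
    u <- stats::runif(nf, 0.01, 0.5)
    flags <- prop[nearest_county, , drop = FALSE] > u
    # downward flicker: invaded units drop out with small probability,
    # producing fine-scale extinction/reinvasion churn; never adds presence
    flags <- flags & (matrix(stats::runif(nf * ny), nf, ny) > flicker_prob)
    huc12_status <- data.frame(
      huc12_id = rep(h12$huc12_id, times = ny),
      year = rep(years, each = nf),
      invaded = as.integer(as.vector(flags))
    )

    status <- rep("never", n)
    status[cn$county_id %in% pers_ids] <- "persistent"
    status[cn$county_id %in% trans_ids] <- "transient"
    structure(list(
      occupancy = occupancy,
      huc12_status = huc12_status,
      labels = data.frame(county_id = cn$county_id, status = status),
      events = if (!is.null(ev)) ev else
        data.frame(county_id = integer(), year = integer(),
                   type = character()),
      label_window = years[w_first:w_last]
    ), class = "pig_history")
  })
}

# spatially autocorrelated surface over points (x, y): linear gradient plus
# white noise, rescaled to [lo, hi]
smooth_surface <- function(x, y, lo, hi, noise = 0.3) {
  a <- stats::rnorm(2)
  sx <- (x - mean(x)) / max(stats::sd(x), 1e-9)
  sy <- (y - mean(y)) / max(stats::sd(y), 1e-9)
  v <- a[1] * sx + a[2] * sy + stats::rnorm(length(x), sd = noise)
  lo + (hi - lo) * (v - min(v)) / max(max(v) - min(v), 1e-12)
}

#' Generate synthetic covariate tables
#'
#' County-level static covariates (habitat suitability, rescaled median
#' density, land-cover percentages), annual removal effort series, and
#' coarse-watershed static covariates (terrain ruggedness, Lewis predicted
#' density, annual temperature range, annual mean precipitation). All surfaces
#' are spatially autocorrelated (gradient plus noise over centroids), so
#' adjacent units are more similar than distant ones.
#'
#' @param landscape a `pig_landscape`.
#' @param years years for the time-varying removal series.
#' @param seed integer RNG seed.
#' @return list with data frames `county` (static, one row per county),
#'   `removals` (county_id, year, removals, prop_active_removal) and `huc8`
#'   (static, one row per coarse watershed).
#' @export
make_covariates <- function(landscape, years = 2009:2021, seed = 1L) {
  cn <- landscape$counties
  h8 <- landscape$huc8
  n <- nrow(cn)
  ny <- length(years)
  with_seed(seed, {
    county <- data.frame(
      county_id = cn$county_id,
      habitat_suitability = smooth_surface(cn$cx, cn$cy, 0, 1),
      density_rescaled = smooth_surface(cn$cx, cn$cy, 0, 1),
      pct_hydrology = smooth_surface(cn$cx, cn$cy, 0, 30),
      pct_tree = smooth_surface(cn$cx, cn$cy, 0, 80),
      pct_crops = smooth_surface(cn$cx, cn$cy, 0, 70),
      pct_pasture = smooth_surface(cn$cx, cn$cy, 0, 60),
      pct_deciduous = smooth_surface(cn$cx, cn$cy, 0, 50)
    )
    base_rem <- stats::rgamma(n, shape = 1.2, scale = 30)
    removals <- data.frame(
      county_id = rep(cn$county_id, times = ny),
      year = rep(years, each = n),
      removals = stats::rpois(n * ny, lambda = rep(base_rem, times = ny)),
      prop_active_removal = clamp(
        rep(smooth_surface(cn$cx, cn$cy, 0, 0.8), times = ny) +
          stats::rnorm(n * ny, sd = 0.05), 0, 1)
    )
    huc8 <- data.frame(
      huc8_id = h8$huc8_id,
      ruggedness = smooth_surface(h8$cx, h8$cy, -1.5, 1.5),
      lewis_density = smooth_surface(h8$cx, h8$cy, 0, 1),
      temp_range = smooth_surface(h8$cx, h8$cy, -1.5, 1.5),
      precip = smooth_surface(h8$cx, h8$cy, -1.5, 1.5)
    )
    list(county = county, removals = removals, huc8 = huc8)
  })
}

default_resource_catalog <- function() {
  data.frame(
    category = c("field_crops", "field_crops", "field_crops",
                 "grasses_hay", "pasture", "wetlands",
                 "livestock", "livestock"),
    resource = c("corn", "soybeans", "wheat",
                 "hay", "pasture", "wetlands",
                 "cattle", "hogs"),
    unit = c(rep("acres", 6), rep("head", 2)),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic resource, price, yield and cash-rent tables
#'
#' Emulates 2017-census-style inputs: per-county acreage by resource (with
#' total land acreage never exceeding the county's area in acres, via a
#' Dirichlet split that reserves a slack share for unenumerated land), head
#' counts for livestock, national crop prices, state crop yields, and state
#' pasture cash rents with at least one state always missing so the national
#' fallback is exercised.
#'
#' @param landscape a `pig_landscape`.
#' @param catalog data frame with columns category, resource, unit; the
#'   default covers field crops, grasses/hay, pasture, wetlands, livestock.
#' @param seed integer RNG seed.
#' @return list of class `pig_resources`: `resources` (county_id, state_id,
#'   category, resource, amount, unit), `prices` (resource, price),
#'   `yields` (state_id, resource, yield), `cash_rents` (state_id, rent),
#'   `national_rent` (scalar $/acre).
#' @export
make_resources <- function(landscape, catalog = default_resource_catalog(),
                           seed = 1L) {
  assert_that(is.data.frame(catalog) && nrow(catalog) > 0,
              "catalog must be a nonempty data frame")
  assert_that(all(c("category", "resource", "unit") %in% names(catalog)),
              "catalog needs columns category, resource, unit")
  cn <- landscape$counties
  n <- nrow(cn)
  land <- catalog[catalog$unit == "acres", ]
  stock <- catalog[catalog$unit == "head", ]
  states <- sort(unique(cn$state_id))
  with_seed(seed, {
    rows <- list()
    if (nrow(land) > 0) {
      # Dirichlet split of county acres across land resources + slack
      shapes <- c(stats::runif(nrow(land), 0.3, 1.5), 4)  # last = slack
      g <- matrix(stats::rgamma(n * length(shapes),
                                shape = rep(shapes, each = n)),
                  nrow = n)
      share <- g / rowSums(g)
      county_acres <- cn$area_km2 / ACRE_KM2
      for (j in seq_len(nrow(land))) {
        rows[[length(rows) + 1L]] <- data.frame(
          county_id = cn$county_id, state_id = cn$state_id,
          category = land$category[j], resource = land$resource[j],
          amount = share[, j] * county_acres, unit = "acres"
        )
      }
    }
    if (nrow(stock) > 0) {
      for (j in seq_len(nrow(stock))) {
        rows[[length(rows) + 1L]] <- data.frame(
          county_id = cn$county_id, state_id = cn$state_id,
          category = stock$category[j], resource = stock$resource[j],
          amount = stats::rpois(n, lambda = 8000), unit = "head"
        )
      }
    }
    resources <- do.call(rbind, rows)

    crop_res <- unique(land$resource[!land$resource %in%
                                       c("pasture", "wetlands")])
    prices <- data.frame(resource = crop_res,
                         price = stats::runif(length(crop_res), 2.5, 12))
    yields <- data.frame(
      state_id = rep(states, each = length(crop_res)),
      resource = rep(crop_res, times = length(states)),
      yield = stats::runif(length(states) * length(crop_res), 30, 180)
    )
    # drop the last state so the national cash-rent fallback is exercised
    rent_states <- states[-length(states)]
    cash_rents <- data.frame(
      state_id = rent_states,
      rent = stats::runif(length(rent_states), 10, 40)
    )
    structure(list(resources = resources, prices = prices, yields = yields,
                   cash_rents = cash_rents,
                   national_rent = stats::runif(1, 12, 30)),
              class = "pig_resources")
  })
}

#' Generate a known-truth invasion scenario for parameter recovery
#'
#' Simulates coarse-watershed occupancy counts from the exact binomial-logit
#' model the fitting routine estimates: for watershed w in year t, the number
#' of invaded fine units is k ~ Binomial(n_w, logit^-1(b0 + X b)), where X
#' holds the four static covariates plus the previous year's invaded rate and
#' the distance from the watershed centroid to the nearest invaded fine unit.
#' Which member units are invaded is uniform given k. Annual invasion and
#' extinction rate series are drawn directly from the stated beta
#' distributions so moment-based recovery can be checked against truth.
#'
#' @param landscape a `pig_landscape`.
#' @param coefficients named numeric of length 6 in the order
#'   ruggedness, lewis_density, temp_range, precip, prev_rate, dist_nearest.
#' @param intercept scalar intercept on the logit scale.
#' @param beta_params list with `invasion = c(shape1, shape2)` and
#'   `extinction = c(shape1, shape2)`.
#' @param years simulation years.
#' @param init_frac initial invaded fraction of fine units.
#' @param n_rate_draws length of the generated annual rate series.
#' @param seed integer RNG seed.
#' @return list: `response` (huc8_id, year, k, n, covariates, prev_rate,
#'   dist_nearest, region, truth_prob), `huc12_status` (long presence flags),
#'   `covariates_huc8`, `rate_series` (list invasion/extinction), and `truth`
#'   (list recording coefficients, intercept, beta_params, seed).
#' @export
make_truth_scenario <- function(landscape, coefficients, intercept = 0,
                                beta_params = list(invasion = c(3, 12),
                                                   extinction = c(2, 18)),
                                years = 2004:2013, init_frac = 0.2,
                                n_rate_draws = 500, seed = 1L) {
  cov_names <- c("ruggedness", "lewis_density", "temp_range", "precip",
                 "prev_rate", "dist_nearest")
  assert_that(length(coefficients) == 6,
              "coefficients must have length 6 (the six-predictor model)")
  if (is.null(names(coefficients)) || !all(nzchar(names(coefficients)))) {
    names(coefficients) <- cov_names
  }
  assert_that(setequal(names(coefficients), cov_names),
              paste("coefficient names must be:",
                    paste(cov_names, collapse = ", ")))
  coefficients <- coefficients[cov_names]

  seeds <- child_seeds(seed, 3)
  covs <- make_covariates(landscape, years, seed = seeds[1])$huc8
  h12 <- landscape$huc12
  h8 <- landscape$huc8
  n8 <- nrow(h8)
  memb <- split(seq_len(nrow(h12)), h12$huc8_id)[h8$huc8_id]
  n_w <- lengths(memb)
  extent <- sqrt(diff(range(h12$cx))^2 + diff(range(h12$cy))^2)

  with_seed(seeds[2], {
    invaded <- stats::runif(nrow(h12)) < init_frac
    resp <- vector("list", length(years))
    status_rows <- vector("list", length(years))
    for (ti in seq_along(years)) {
      prev_rate <- vapply(memb, function(ix) mean(invaded[ix]), 0)
      pts <- cbind(h12$cx[invaded], h12$cy[invaded])
      dist <- nearest_dist(cbind(h8$cx, h8$cy), pts)
      dist[!is.finite(dist)] <- extent
      X <- cbind(covs$ruggedness, covs$lewis_density, covs$temp_range,
                 covs$precip, prev_rate, dist)
      p <- stats::plogis(intercept + drop(X %*% coefficients))
      k <- stats::rbinom(n8, size = n_w, prob = p)
      new_inv <- logical(nrow(h12))
      for (w in seq_len(n8)) {
        new_inv[sample_safe(memb[[w]], k[w])] <- TRUE
      }
      resp[[ti]] <- data.frame(
        huc8_id = h8$huc8_id, year = years[ti], k = k, n = n_w,
        ruggedness = covs$ruggedness, lewis_density = covs$lewis_density,
        temp_range = covs$temp_range, precip = covs$precip,
        prev_rate = prev_rate, dist_nearest = dist,
        region = h8$region, truth_prob = p
      )
      status_rows[[ti]] <- data.frame(huc12_id = h12$huc12_id,
                                      year = years[ti],
                                      invaded = as.integer(new_inv))
      invaded <- new_inv
    }
    response <- do.call(rbind, resp)
    huc12_status <- do.call(rbind, status_rows)

    rate_series <- with_seed(seeds[3], list(
      invasion = stats::rbeta(n_rate_draws, beta_params$invasion[1],
                              beta_params$invasion[2]),
      extinction = stats::rbeta(n_rate_draws, beta_params$extinction[1],
                                beta_params$extinction[2])
    ))
    list(response = response, huc12_status = huc12_status,
         covariates_huc8 = covs, rate_series = rate_series,
         truth = list(coefficients = coefficients, intercept = intercept,
                      beta_params = beta_params, seed = seed))
  })
}

#' Write all synthetic tables of a scenario to CSV
#'
#' @param landscape a `pig_landscape`.
#' @param history a `pig_history` (optional).
#' @param covariates output of [make_covariates()] (optional).
#' @param resources a `pig_resources` (optional).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_landscape_csv <- function(landscape, history = NULL, covariates = NULL,
                                resources = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(landscape$counties, "counties.csv")
  wr(landscape$adjacency, "adjacency.csv")
  wr(landscape$huc8, "watersheds.csv")
  wr(landscape$huc12, "watersheds_fine.csv")
  wr(landscape$overlap, "overlap.csv")
  if (!is.null(history)) {
    wr(history$occupancy, "occupancy.csv")
    wr(history$huc12_status, "huc12_status.csv")
  }
  if (!is.null(covariates)) {
    wr(covariates$county, "covariates_county.csv")
    wr(covariates$removals, "removals.csv")
    wr(covariates$huc8, "covariates_huc8.csv")
  }
  if (!is.null(resources)) {
    wr(resources$resources, "resources.csv")
    wr(resources$prices, "prices.csv")
    wr(resources$yields, "yields.csv")
    wr(resources$cash_rents, "cash_rents.csv")
  }
  invisible(paths)
}
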