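# Fixtures built in code: hand-made landscapes with fully controlled
# geometry, and stub predictors for forecasting tests.

# A 1 x n chain of counties (adjacency i ~ i+1), one coarse watershed with
# `n_fine` fine units, all overlap weight on that watershed.
chain_landscape <- function(n, areas = rep(1000, n), n_fine = 4L) {
  counties <- data.frame(
    county_id = seq_len(n), state_id = "S01", area_km2 = areas,
    cx = as.numeric(seq_len(n)), cy = 1, row = 1L, col = seq_len(n))
  adj <- NULL
  if (n > 1) {
    a <- seq_len(n - 1L)
    adj <- data.frame(county_id = c(a, a + 1L), neighbor_id = c(a + 1L, a))
    adj <- adj[order(adj$county_id, adj$neighbor_id), ]
  } else {
    adj <- data.frame(county_id = integer(), neighbor_id = integer())
  }
  huc8 <- data.frame(huc8_id = "H8_001", cx = (n + 1) / 2, cy = 1,
                     region = "west")
  huc12 <- data.frame(huc12_id = sprintf("H12_%04d", seq_len(n_fine)),
                      huc8_id = "H8_001",
                      cx = seq(1, n, length.out = n_fine), cy = 1)
  overlap <- data.frame(county_id = seq_len(n), huc8_id = "H8_001",
                        weight = 1)
  structure(list(counties = counties, adjacency = adj, huc8 = huc8,
                 huc12 = huc12, overlap = overlap),
            class = "pig_landscape")
}

# landscape with one fine unit per coarse watershed at given x positions,
# so per-unit invasion weights can be scripted through a coarse-level stub
unit_landscape <- function(n_units, xs = seq_len(n_units)) {
  counties <- data.frame(county_id = 1L, state_id = "S01", area_km2 = 100,
                         cx = mean(xs), cy = 1, row = 1L, col = 1L)
  huc8 <- data.frame(huc8_id = sprintf("H8_%03d", seq_len(n_units)),
                     cx = xs, cy = 1, region = "west")
  huc12 <- data.frame(huc12_id = sprintf("H12_%04d", seq_len(n_units)),
                      huc8_id = huc8$huc8_id, cx = xs, cy = 1)
  overlap <- data.frame(county_id = 1L, huc8_id = huc8$huc8_id,
                        weight = 1 / n_units)
  structure(list(counties = counties,
                 adjacency = data.frame(county_id = integer(),
                                        neighbor_id = integer()),
                 huc8 = huc8, huc12 = huc12, overlap = overlap),
            class = "pig_landscape")
}

# long-format occupancy table from a county x year matrix
occ_df <- function(m, years) {
  data.frame(county_id = rep(seq_len(nrow(m)), times = ncol(m)),
             year = rep(years, each = nrow(m)),
             prop = as.vector(m))
}

# zero covariates for chain landscapes (static county covariates + removals)
zero_covariates <- function(landscape, years) {
  cn <- landscape$counties
  county <- data.frame(county_id = cn$county_id, habitat_suitability = 0,
                       density_rescaled = 0, pct_hydrology = 0, pct_tree = 0,
                       pct_crops = 0, pct_pasture = 0, pct_deciduous = 0)
  removals <- data.frame(
    county_id = rep(cn$county_id, times = length(years)),
    year = rep(years, each = nrow(cn)),
    removals = 0, prop_active_removal = 0)
  huc8 <- data.frame(huc8_id = landscape$huc8$huc8_id, ruggedness = 0,
                     lewis_density = 0, temp_range = 0, precip = 0)
  list(county = county, removals = removals, huc8 = huc8)
}

# stub spread-model bundle: both strata share one delta function
stub_models <- function(fun, spec = spread_model_spec("B"),
                        persistent_ids = integer()) {
  list(persistent = fun, transient = fun, spec = spec,
       strata = list(persistent = persistent_ids, transient = integer(),
                     never = integer()))
}

# default small synthetic world, shared across tests (built once per run)
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      L <- make_landscape(100, 8, 15, seed = 7)
      h <- make_history(L, 2008:2021, seed = 2)
      cv <- make_covariates(L, 2008:2021, seed = 3)
      cache <<- list(landscape = L, history = h, covariates = cv)
    }
    cache
  }
})
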