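# End-to-end orchestration: generate -> prepare -> fit -> forecast (4 BRT
# models + 4 occupancy variants) -> value -> summarize.

#' Pipeline run configuration
#'
#' @param seed master seed; every stochastic stage derives child seeds from
#'   it, so a full run is reproducible end to end.
#' @param n_counties,n_coarse,fine_per_coarse synthetic landscape size.
#' @param years observed history years (watershed records reach back before
#'   the county fit window, and the program period is included so incremental
#'   occupancy can be computed).
#' @param window pre-program years used for fitting the county models.
#' @param rates_window years of the observed fine-watershed invasion and
#'   extinction rate series that the beta distributions are fit to.
#' @param forecast_start first forecast year.
#' @param horizon forecast years.
#' @param reps stochastic simulation replicates.
#' @param tau occupancy threshold.
#' @param brt_models subset of c("A","B","C","D").
#' @param occ_variants subset of c("fixed","ri","rs","fixed_reduced").
#' @param boost a [boost_control()].
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_counties = 100L, n_coarse = 8L,
                       fine_per_coarse = 15L, years = 2004:2021,
                       window = 2009:2013, rates_window = 2004:2012,
                       forecast_start = 2014L,
                       horizon = 8L, reps = 1000L, tau = 0,
                       brt_models = c("A", "B", "C", "D"),
                       occ_variants = c("fixed", "ri", "rs", "fixed_reduced"),
                       boost = boost_control(), out_dir = tempfile("pigrun")) {
  assert_that(horizon >= 1, "horizon must be >= 1")
  assert_that(reps >= 1, "reps must be >= 1")
  assert_that(!anyDuplicated(brt_models) && !anyDuplicated(occ_variants),
              "model ids must be unique")
  structure(list(seed = as.integer(seed), n_counties = n_counties,
                 n_coarse = n_coarse, fine_per_coarse = fine_per_coarse,
                 years = years, window = window, rates_window = rates_window,
                 forecast_start = forecast_start, horizon = horizon,
                 reps = reps, tau = tau, brt_models = brt_models,
                 occ_variants = occ_variants, boost = boost,
                 out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the [run_config()] defaults.
#'
#' @param path YAML file.
#' @param ... overrides applied after the file.
#' @return a `run_config`.
#' @export
load_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  assert_that(length(bad) == 0,
              paste("unknown config keys:", paste(bad, collapse = ", ")))
  if (!is.null(raw$boost)) raw$boost <- do.call(boost_control, raw$boost)
  if (!is.null(raw$years) && length(raw$years) == 2) {
    raw$years <- seq(raw$years[1], raw$years[2])
  }
  if (!is.null(raw$window) && length(raw$window) == 2) {
    raw$window <- seq(raw$window[1], raw$window[2])
  }
  if (!is.null(raw$rates_window) && length(raw$rates_window) == 2) {
    raw$rates_window <- seq(raw$rates_window[1], raw$rates_window[2])
  }
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(run_config, raw)
}

stage_log <- function(cfg, msg) {
  line <- sprintf("[%s] seed=%d %s", format(Sys.time(), "%H:%M:%S"),
                  cfg$seed, msg)
  message(line)
  cat(line, "\n", file = file.path(cfg$out_dir, "log.txt"), append = TRUE)
}

#' Run the full pipeline
#'
#' Executes every stage: synthetic generation, response preparation, the four
#' boosted-tree spread models with step-ahead forecasts, the four dynamic
#' occupancy variants with stochastic simulation, valuation of safeguarded
#' resources for all eight forecasts, and the ensemble summary. All outputs
#' are written as CSV under `config$out_dir` and listed, with MD5 checksums,
#' in `manifest.csv`.
#'
#' @param config a `run_config`.
#' @return invisibly, a list with the in-memory stage results and `manifest`.
#' @export
run_all <- function(config = run_config()) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- child_seeds(cfg$seed, 10)
  t0 <- Sys.time()

  ## stage 1: synthetic world
  landscape <- make_landscape(cfg$n_counties, cfg$n_coarse,
                              cfg$fine_per_coarse, seed = seeds[1])
  history <- make_history(landscape, cfg$years, label_window = cfg$window,
                          seed = seeds[2])
  covariates <- make_covariates(landscape, cfg$years, seed = seeds[3])
  resources <- make_resources(landscape, seed = seeds[4])
  write_landscape_csv(landscape, history, covariates, resources,
                      dir = cfg$out_dir)
  stage_log(cfg, sprintf("synth: %d counties, %d fine watersheds (%.1fs)",
                         nrow(landscape$counties), nrow(landscape$huc12),
                         as.numeric(Sys.time() - t0, units = "secs")))

  ## stage 2: responses
  deltas <- annual_deltas(history, landscape)
  strata <- stratify(history, cfg$window, cfg$tau)
  resp8 <- watershed_response(history$huc12_status, landscape)
  rates <- suppressWarnings(
    observed_rates(history$huc12_status, cfg$rates_window))
  utils::write.csv(deltas, file.path(cfg$out_dir, "spread_rates.csv"),
                   row.names = FALSE)
  utils::write.csv(resp8, file.path(cfg$out_dir, "huc8_response.csv"),
                   row.names = FALSE)
  stage_log(cfg, "prep: responses written")

  observed <- history$occupancy[history$occupancy$year >= cfg$forecast_start, ]
  state0 <- history$occupancy[history$occupancy$year ==
                                cfg$forecast_start - 1L, ]
  pav <- per_acre_value(resources)
  forecasts <- list()
  summaries <- list()
  transitions <- list()

  ## stage 3: BRT forecasts
  for (m in cfg$brt_models) {
    spec <- spread_model_spec(m)
    models <- fit_spread_models(landscape, history, covariates, spec, strata,
                                cfg$window, cfg$boost, seed = seeds[5])
    fc <- step_ahead(models, landscape, state0, covariates,
                     horizon = cfg$horizon, start_year = cfg$forecast_start,
                     tau = cfg$tau, seed = seeds[6])
    forecasts[[m]] <- fc
    transitions[[m]] <- forecast_transition_rates(fc)
    utils::write.csv(fc$occupancy,
                     file.path(cfg$out_dir, sprintf("forecast_%s.csv", m)),
                     row.names = FALSE)
    utils::write.csv(transitions[[m]],
                     file.path(cfg$out_dir, sprintf("transitions_%s.csv", m)),
                     row.names = FALSE)
    imp <- lsboost_importance(models$transient)
    utils::write.csv(data.frame(feature = names(imp), importance = imp),
                     file.path(cfg$out_dir, sprintf("importance_%s.csv", m)),
                     row.names = FALSE)
    sg <- incremental_occupancy(fc$occupancy, observed)
    summaries[[m]] <- value_safeguarded(
      threatened_amount(sg, resources$resources), pav, model = m)
    stage_log(cfg, sprintf("brt %s: done", m))
  }

  ## stage 4: occupancy simulations
  inv_data <- prepare_invasion_data(
    landscape,
    history$huc12_status[history$huc12_status$year < cfg$forecast_start, ],
    covariates$huc8)
  inv_beta <- fit_beta_rates(rates$invasion$rate, "invasion")
  ext_beta <- fit_beta_rates(rates$extinction$rate, "extinction")
  init <- history$huc12_status[history$huc12_status$year ==
                                 cfg$forecast_start - 1L,
                               c("huc12_id", "invaded")]
  for (v in cfg$occ_variants) {
    model <- suppressWarnings(fit_invasion_model(inv_data, v))
    traj <- simulate_occupancy(model, landscape, init, covariates$huc8,
                               inv_beta, ext_beta, horizon = cfg$horizon,
                               reps = cfg$reps, seed = seeds[7])
    med <- summarize_trajectories(traj)
    utils::write.csv(med, file.path(cfg$out_dir,
                                    sprintf("huc8_median_%s.csv", v)),
                     row.names = FALSE)
    cp <- to_county(med[, c("huc8_id", "year", "median")],
                    landscape$overlap)
    cp$year <- cfg$forecast_start + cp$year - 1L
    names(cp)[names(cp) == "median"] <- "prop"
    utils::write.csv(cp, file.path(cfg$out_dir,
                                   sprintf("county_prop_%s.csv", v)),
                     row.names = FALSE)
    forecasts[[v]] <- cp
    # county transition counts from the median map
    prev <- stats::setNames(state0$prop, state0$county_id)
    tr <- data.frame(year = integer(), n_newly_occupied = integer(),
                     n_newly_unoccupied = integer())
    for (y in sort(unique(cp$year))) {
      cur <- cp[cp$year == y, ]
      curv <- stats::setNames(cur$prop, cur$county_id)[names(prev)]
      tr <- rbind(tr, data.frame(
        year = y,
        n_newly_occupied = sum(curv > cfg$tau & prev <= cfg$tau),
        n_newly_unoccupied = sum(curv <= cfg$tau & prev > cfg$tau)))
      prev <- curv
    }
    tr$cum_occupied <- cumsum(tr$n_newly_occupied)
    tr$cum_unoccupied <- cumsum(tr$n_newly_unoccupied)
    transitions[[v]] <- tr
    sg <- incremental_occupancy(cp, observed)
    summaries[[v]] <- value_safeguarded(
      threatened_amount(sg, resources$resources), pav, model = v)
    stage_log(cfg, sprintf("occsim %s: done (%d reps)", v, cfg$reps))
  }

  ## stage 5: valuation summaries
  for (m in names(summaries)) {
    utils::write.csv(summaries[[m]],
                     file.path(cfg$out_dir,
                               sprintf("safeguard_values_%s.csv", m)),
                     row.names = FALSE)
  }
  ens <- ensemble_stats(summaries)
  utils::write.csv(ens, file.path(cfg$out_dir, "ensemble_summary.csv"),
                   row.names = FALSE)
  stage_log(cfg, "value: ensemble summary written")

  ## report tables + manifest
  rep_tables <- report_tables(transitions, summaries)
  for (nm in names(rep_tables)) {
    utils::write.csv(rep_tables[[nm]],
                     file.path(cfg$out_dir, paste0("report_", nm, ".csv")),
                     row.names = FALSE)
  }
  files <- setdiff(list.files(cfg$out_dir), c("manifest.csv", "log.txt"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(cfg$out_dir, files))))
  utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE)
  stage_log(cfg, sprintf("run complete (%.1fs)",
                         as.numeric(Sys.time() - t0, units = "secs")))
  invisible(list(config = cfg, landscape = landscape, history = history,
                 covariates = covariates, resources = resources,
                 strata = strata, forecasts = forecasts,
                 transitions = transitions, summaries = summaries,
                 ensemble = ens, manifest = manifest))
}

#' Long-format report tables
#'
#' Builds the newly-occupied-per-year table, the per-category amount table,
#' and the per-category value table, each with per-model rows plus ensemble
#' mean rows (model = "ensemble_mean").
#'
#' @param transitions named list of per-model transition data frames.
#' @param summaries named list of `safeguard_summary` data frames.
#' @return list of data frames `newly_occupied`, `amounts`, `values`.
#' @export
report_tables <- function(transitions, summaries) {
  rows <- list()
  for (m in names(transitions)) {
    tr <- transitions[[m]]
    rows[[m]] <- data.frame(model = m, metric = "newly_occupied",
                            year = tr$year, value = tr$n_newly_occupied)
  }
  newly <- do.call(rbind, rows)
  ens <- stats::aggregate(value ~ year, data = newly, FUN = mean)
  newly <- rbind(newly, data.frame(model = "ensemble_mean",
                                   metric = "newly_occupied",
                                   year = ens$year, value = ens$value))
  all_s <- do.call(rbind, lapply(summaries, as.data.frame))
  amounts <- data.frame(model = all_s$model, metric = "amount",
                        category = all_s$category, value = all_s$amount)
  am_ens <- stats::aggregate(value ~ category, data = amounts, FUN = mean)
  amounts <- rbind(amounts,
                   data.frame(model = "ensemble_mean", metric = "amount",
                              category = am_ens$category,
                              value = am_ens$value))
  vals <- all_s[!is.na(all_s$value), ]
  values <- data.frame(model = vals$model, metric = "value",
                       category = vals$category, value = vals$value)
  if (nrow(values) > 0) {
    v_ens <- stats::aggregate(value ~ category, data = values, FUN = mean)
    values <- rbind(values,
                    data.frame(model = "ensemble_mean", metric = "value",
                               category = v_ens$category,
                               value = v_ens$value))
  }
  rownames(newly) <- rownames(amounts) <- rownames(values) <- NULL
  list(newly_occupied = newly, amounts = amounts, values = values)
}

#' Command-line entry point
#'
#' Subcommands: `synth` (write the synthetic tables only) and `run-all` (full
#' pipeline). Flags: `--config FILE` (YAML), `--seed N`, `--out DIR`,
#' `--reps N`, `--horizon N`. Stages re-derive their inputs from the seeded
#' generators, so a stage rerun with the same config is bit-identical.
#'
#' @param args character vector of command-line arguments.
#' @return invisibly, the stage result.
#' @export
pigspread_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: pigspread {synth|run-all} [--config FILE] [--seed N] [--out DIR] [--reps N] [--horizon N]"
  assert_that(length(args) >= 1, usage)
  cmd <- args[1]
  opts <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    assert_that(i + 1 <= length(args), paste("missing value for", args[i]))
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfg <- if (!is.null(opts$config)) load_config(opts$config) else run_config()
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$out)) cfg$out_dir <- opts$out
  if (!is.null(opts$reps)) cfg$reps <- as.integer(opts$reps)
  if (!is.null(opts$horizon)) cfg$horizon <- as.integer(opts$horizon)
  switch(cmd,
    "synth" = {
      seeds <- child_seeds(cfg$seed, 10)
      landscape <- make_landscape(cfg$n_counties, cfg$n_coarse,
                                  cfg$fine_per_coarse, seed = seeds[1])
      history <- make_history(landscape, cfg$years, seed = seeds[2])
      covariates <- make_covariates(landscape, cfg$years, seed = seeds[3])
      resources <- make_resources(landscape, seed = seeds[4])
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      invisible(write_landscape_csv(landscape, history, covariates,
                                    resources, dir = cfg$out_dir))
    },
    "run-all" = run_all(cfg),
    stop(usage, call. = FALSE)
  )
}
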