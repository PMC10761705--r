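# End-to-end orchestration: assemble the synthetic-world pipeline context,
# run original vs constrained projections, and wire the sensitivity
# experiment variants.

#' Assemble a pipeline context from a world and an ESM ensemble
#'
#' Runs the observational chain once: samples site records, fits the
#' boosted-tree upscalers, predicts turnover-time and fraction maps across
#' the covariate source combinations, and calibrates the refined model
#' against the observed (SOC x fraction-map) pool stocks and apparent
#' turnover times. The result carries everything the projection engine and
#' the sensitivity variants need.
#'
#' @param world a \code{soil_world}.
#' @param ensemble an \code{esm_ensemble} generated on the same grid.
#' @param n_sites,site_noise site sampling controls (see \code{\link{gen_sites}}).
#' @param cv_config boosted-tree grid, see \code{\link{default_cv_config}}.
#' @param seed integer RNG seed for every stochastic stage.
#' @param emulator_params \code{"generating"} to drive reduced-model
#'   variants with each synthetic ESM's stored generating parameters, or
#'   \code{"calibrate"} to diagnose (r_f, r_s, b) per cell from the ESM
#'   output first.
#' @return list of class \code{"soil_pipeline"} with the world, ensemble,
#'   records, upscalers, maps, refined calibration and options.
#' @export
build_pipeline <- function(world, ensemble, n_sites = 300, site_noise = 0.1,
                           cv_config = default_cv_config(), seed = 1,
                           emulator_params = c("generating", "calibrate")) {
  emulator_params <- match.arg(emulator_params)
  records <- gen_sites(world, n_sites, site_noise, seed)
  upscalers <- fit_upscalers(records, cv_config, seed)
  maps <- predict_maps(upscalers, covariate_combinations(world))
  clim <- list(tas = rowMeans(world$climate$tas),
               pr = rowMeans(world$climate$pr),
               npp = rowMeans(world$climate$npp))
  obs_stocks <- world$soc_stock * maps$fractions
  calib <- calibrate_refined(obs_stocks, world$tau_a, clim,
                             maps$tau_mean, world$covariates$clay,
                             world$truth$P_max, mask = world$mask,
                             seed = seed)
  emu <- lapply(ensemble$models, function(mod) {
    if (emulator_params == "generating") {
      list(r_f = mod$params$r_f, r_s = mod$params$r_s, b = mod$params$b)
    } else {
      sc <- ensemble$scenarios[1]
      st2014 <- mod$hist_pools$stocks[, , dim(mod$hist_pools$stocks)[3]]
      fit <- calibrate_emulator(mod$future_pools[[sc]],
                                window_forcing(mod$forcing[[sc]], 2015, 2100),
                                st2014, mod$params, seed = seed)
      list(r_f = fit$params[, 1], r_s = fit$params[, 2], b = fit$params[, 3])
    }
  })
  structure(list(world = world, ensemble = ensemble, records = records,
                 upscalers = upscalers, maps = maps, calib = calib,
                 clim = clim, emulator_params = emu,
                 cv_config = cv_config, seed = seed),
            class = "soil_pipeline")
}

#' @export
print.soil_pipeline <- function(x, ...) {
  cat("Constrained-projection pipeline context\n")
  print(x$world); print(x$ensemble); print(x$calib)
  invisible(x)
}

#' Sensitivity-experiment presets
#'
#' Named option sets for the projection engine. \code{default} is the
#' refined model with data-driven turnover maps, calibrated Q10 and
#' bias-corrected forcing. \code{SE1} re-normalizes site turnover times
#' with an Arrhenius function before upscaling; \code{SE2} prescribes the
#' passive-pool turnover time from the ESM ensemble mean; \code{SE3}-
#' \code{SE6} use the climate-only reduced model driven directly by ESM
#' forcing, crossing data vs ESM turnover times and calibrated vs ESM Q10;
#' \code{SE6} is \code{SE4} with the ESM passive-pool turnover time.
#'
#' @param variant one of \code{"default"}, \code{"SE1"}..\code{"SE6"}, or a
#'   list of options to merge over the default.
#' @return list of engine options.
#' @export
sensitivity_preset <- function(variant = "default") {
  base <- list(model = "refined", tau = "data", tau_passive = "default",
               q10 = "calibrated", forcing = "corrected",
               normalization = "q10")
  presets <- list(
    default = base,
    SE1 = utils::modifyList(base, list(normalization = "arrhenius")),
    SE2 = utils::modifyList(base, list(tau_passive = "esm")),
    SE3 = utils::modifyList(base, list(model = "reduced", forcing = "esm")),
    SE4 = utils::modifyList(base, list(model = "reduced", forcing = "esm",
                                       q10 = "esm")),
    SE5 = utils::modifyList(base, list(model = "reduced", forcing = "esm",
                                       tau = "esm")),
    SE6 = utils::modifyList(base, list(model = "reduced", forcing = "esm",
                                       q10 = "esm", tau_passive = "esm")))
  if (is.list(variant)) return(utils::modifyList(base, variant))
  if (!variant %in% names(presets)) stop("unknown variant: ", variant)
  presets[[variant]]
}

# turnover maps under the requested normalization / source options
variant_tau_maps <- function(ctx, opts) {
  maps <- ctx$maps
  if (opts$normalization == "arrhenius") {
    rec <- ctx$records
    for (p in c("fast", "slow", "passive")) {
      inc <- rec[[paste0("tau_", p, "_inc")]]
      if (is.null(inc)) stop("records lack tau at incubation temperature")
      rec[[paste0("tau_", p)]] <-
        normalize_arrhenius(inc, rec$incubation_T)
    }
    ups <- fit_upscalers(rec, ctx$cv_config, ctx$seed)
    maps <- predict_maps(ups, covariate_combinations(ctx$world))
  }
  tau <- maps$tau_mean
  if (opts$tau == "esm")
    tau <- matrix(ctx$ensemble$tau_i, nrow(tau), 3, byrow = TRUE)
  if (opts$tau_passive == "esm") tau[, 3] <- ctx$ensemble$tau_i[3]
  list(tau = tau, fractions = maps$fractions)
}

# run one model x scenario constrained projection; returns the 2000-2100
# trajectory of the variant model
variant_run_one <- function(ctx, opts, mod, scenario, tau) {
  world <- ctx$world
  refined <- opts$model == "refined"
  q10 <- if (opts$q10 == "calibrated") ctx$calib$Q10 else mod$params$Q10
  t_ref <- if (opts$q10 == "calibrated") 15 else mod$params$T_ref
  if (refined) {
    b <- ctx$calib$b; r_f <- ctx$calib$r_f; r_s <- ctx$calib$r_s
    p_max <- world$truth$P_max
  } else {
    ep <- ctx$emulator_params[[mod$name]]
    b <- ep$b; r_f <- ep$r_f; r_s <- ep$r_s
    p_max <- mod$params$P_max
  }
  vparams <- list(tau = tau, Q10 = q10, T_ref = t_ref, b = b,
                  P_max = p_max, clay = world$covariates$clay,
                  r_f = r_f, r_s = r_s,
                  root_frac = if (is.null(ctx$calib$root_frac)) 0.07
                              else ctx$calib$root_frac,
                  use_M = refined, use_RP = refined)
  if (opts$forcing == "corrected") {
    base_forcing <- world$climate
    mod_hist <- window_forcing(mod$forcing[[scenario]], 2000, 2014)
    mod_base <- list(tas = rowMeans(mod_hist$tas),
                     pr = rowMeans(mod_hist$pr),
                     npp = rowMeans(mod_hist$npp))
    fut <- correct_forcing(window_forcing(mod$forcing[[scenario]], 2015, 2100),
                           ctx$clim, mod_base)
  } else {
    base_forcing <- window_forcing(mod$forcing[[scenario]], 2000, 2014)
    fut <- window_forcing(mod$forcing[[scenario]], 2015, 2100)
  }
  sp <- spin_up(vparams, base_forcing)
  proj <- project(vparams, sp$state, fut)
  list(traj = combine_trajectories(sp$last_cycle, proj), spinup = sp)
}

#' Run original vs constrained soil-carbon projections
#'
#' The projection engine behind both the default constrained analysis and
#' the sensitivity experiments. For every ensemble member and scenario it
#' computes the original ESM change in soil carbon stock between the
#' current period (2005-2014) and the end of the century (2080-2099), the
#' corresponding constrained change from the variant model, the fraction of
#' land cells in which the constraint lowers the projected change, the
#' global warming relative to the 1850-1900 surrogate baseline, and
#' 2020-baselined stock changes for the carbon-budget analysis.
#'
#' @param ctx a \code{soil_pipeline} from \code{\link{build_pipeline}}.
#' @param variant preset name or option list, see
#'   \code{\link{sensitivity_preset}}.
#' @param scenarios subset of the ensemble's scenarios (default all).
#' @return object of class \code{"constrained_projection"}: \code{results}
#'   data.frame (one row per model x scenario), per-run delta-stock
#'   \code{fields}, the spin-up diagnostics and the options used.
#' @export
constrain_projections <- function(ctx, variant = "default",
                                  scenarios = ctx$ensemble$scenarios) {
  opts <- sensitivity_preset(variant)
  world <- ctx$world
  tm <- variant_tau_maps(ctx, opts)
  areas <- world$areas; mask <- world$mask
  rows <- list(); fields <- list(); spin_cycles <- integer(0)
  glob_w <- areas / sum(areas)
  for (mod in ctx$ensemble$models) {
    for (sc in scenarios) {
      run <- variant_run_one(ctx, opts, mod, sc, tm$tau)
      traj_c <- run$traj
      traj_o <- combine_trajectories(mod$hist_pools, mod$future_pools[[sc]])
      d_c <- delta_stock(traj_c, areas = areas, mask = mask)
      d_o <- delta_stock(traj_o, areas = areas, mask = mask)
      frac_lower <- mean(d_c$field[mask] < d_o$field[mask])
      # warming vs the pre-industrial surrogate baseline
      fut_tas <- window_forcing(mod$forcing[[sc]], 2080, 2099)$tas
      dT <- sum(rowMeans(fut_tas) * glob_w) - mod$t_preindustrial
      # 2020-baselined global stock changes (PgC) for the budget analysis
      stock_series <- function(traj) {
        tot <- apply(traj$stocks, 3, function(s) global_total(rowSums(s),
                                                              areas, mask))
        stats::setNames(tot, traj$years)
      }
      ts_c <- stock_series(traj_c); ts_o <- stock_series(traj_o)
      eoc <- function(ts) mean(ts[as.character(2080:2099)])
      rows[[length(rows) + 1L]] <- data.frame(
        model = mod$name, scenario = sc,
        dsoc_constrained = d_c$total_pgc, dsoc_original = d_o$total_pgc,
        frac_cells_lower = frac_lower, dT = dT,
        dsoc2020_constrained = eoc(ts_c) - ts_c["2020"],
        dsoc2020_original = eoc(ts_o) - ts_o["2020"],
        stock2020_constrained = ts_c["2020"],
        stringsAsFactors = FALSE)
      fields[[paste(mod$name, sc, sep = "_")]] <-
        list(constrained = d_c$field, original = d_o$field)
      spin_cycles <- c(spin_cycles, run$spinup$cycles)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, fields = fields, opts = opts,
                 spin_cycles = spin_cycles, tau_used = tm$tau),
            class = "constrained_projection")
}

#' @export
print.constrained_projection <- function(x, ...) {
  cat("Original vs constrained soil-carbon projections\n")
  agg <- stats::aggregate(cbind(dsoc_original, dsoc_constrained,
                                frac_cells_lower) ~ scenario,
                          data = x$results, FUN = mean)
  print(agg, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run a sensitivity experiment
#'
#' Executes one of the sensitivity variants (or the default wiring) through
#' the projection engine and summarizes the constrained global soil-carbon
#' change per scenario.
#'
#' @param variant \code{"default"} or \code{"SE1"}..\code{"SE6"}, or an
#'   explicit option list.
#' @param ctx a \code{soil_pipeline}.
#' @param scenarios subset of scenarios.
#' @return list with the full \code{projection} object and a
#'   \code{summary} data.frame (per-scenario mean constrained and original
#'   change, PgC), plus \code{mean_dsoc} across scenarios.
#' @export
run_sensitivity <- function(variant, ctx, scenarios = ctx$ensemble$scenarios) {
  proj <- constrain_projections(ctx, variant, scenarios)
  summ <- stats::aggregate(cbind(dsoc_constrained, dsoc_original) ~ scenario,
                           data = proj$results, FUN = mean)
  list(projection = proj, summary = summ,
       mean_dsoc = mean(proj$results$dsoc_constrained))
}

#' Budget points from a constrained projection
#'
#' Extracts the (warming, soil-carbon change) points used by
#' \code{\link{budget_reduction}}: warming above the 1850-1900 surrogate
#' baseline and 2020-baselined global stock changes of the original and
#' constrained ensembles.
#'
#' @param proj a \code{constrained_projection}.
#' @return data.frame with \code{dT}, \code{dsoc_constrained},
#'   \code{dsoc_original}.
#' @export
budget_points <- function(proj) {
  data.frame(dT = proj$results$dT,
             dsoc_constrained = proj$results$dsoc2020_constrained,
             dsoc_original = proj$results$dsoc2020_original)
}
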