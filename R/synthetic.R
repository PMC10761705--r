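# Synthetic inputs with known ground truth: an idealized world grid whose
# soil carbon obeys the refined three-pool model exactly, site-level
# incubation series generated from the kinetic forward model, and an
# ESM-like ensemble generated by the reduced-complexity emulator itself.

# separable Gaussian smoothing of an n_lat x n_lon matrix (reflecting edges),
# used to give random fields realistic spatial autocorrelation
gauss_smooth <- function(mat, sigma = 2) {
  r <- ceiling(3 * sigma)
  kern <- stats::dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(min(r, n))]), v, rev(v[seq.int(n, by = -1,
                                                         length.out = min(r, n))]))
    stats::filter(vp, kern, sides = 2)[(r + 1):(r + n)]
  }
  sm <- apply(mat, 2, pad_conv)
  t(apply(sm, 1, pad_conv))
}

# smooth standard-normal random field flattened to cell order
grf <- function(n_lat, n_lon, sigma = 2) {
  z <- gauss_smooth(matrix(stats::rnorm(n_lat * n_lon), n_lat, n_lon), sigma)
  z <- (z - mean(z)) / stats::sd(z)
  as.vector(z)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Default configuration of the synthetic world
#'
#' Ground-truth parameters of the refined model used to construct the world
#' (carbon-quality-ordered Q10, precipitation exponent, transfer
#' coefficients, root-respiration fraction of NPP) and the
#' covariate-to-turnover mapping coefficients (log10 tau linear in MAT with
#' small NDVI/clay terms, plus a weak smooth spatial residual).
#'
#' @return named list of configuration values.
#' @export
default_world_config <- function() {
  list(Q10 = c(1.6, 2.2, 2.8), b = 0.8, r_f = 0.3, r_s = 0.02,
       root_frac = 0.07,
       tau_ref = c(0.3, 6.68, 398),           # global-scale central values, yr at 15 C
       mat_slope = c(0.010, 0.013, 0.012),    # decades of log10(tau) per degree C
       ndvi_slope = c(0.08, 0.06, 0),
       clay_slope = c(0, 0, 0.30),
       residual_sd = 0.02,                    # log10 spatial residual
       lat_range = c(-55, 75),
       land_fraction = 0.30)
}

#' Generate a synthetic world grid with known ground truth
#'
#' Builds a regular lat/lon grid with smooth covariate fields (Gaussian
#' random fields plus latitudinal gradients), a known monotone
#' covariate-to-turnover mapping (log10 tau increasing with mean annual
#' temperature), per-cell true pool fractions, NPP, a 2000-2014 yearly
#' climate series, and a soil organic carbon stock that is exactly the
#' refined model's closed-form steady state under the climatological
#' forcing. Two alternative climate and soil covariate "sources" (small
#' smooth perturbations) are included so map uncertainty across dataset
#' combinations can be exercised.
#'
#' @param n_lat,n_lon grid dimensions (each >= 2).
#' @param seed integer RNG seed; same seed gives a bit-identical world.
#' @param config list as \code{\link{default_world_config}}; entries may be
#'   overridden individually.
#' @return object of class \code{"soil_world"}.
#' @export
gen_world <- function(n_lat = 20, n_lon = 20, seed = 1,
                      config = default_world_config()) {
  if (n_lat < 2 || n_lon < 2) stop("grid must be at least 2 x 2")
  cfg <- utils::modifyList(default_world_config(), config)
  set.seed(as.integer(seed))
  lat_c <- seq(cfg$lat_range[1], cfg$lat_range[2], length.out = n_lat)
  lon_c <- seq(-180, 180 - 360 / n_lon, length.out = n_lon)
  n <- n_lat * n_lon
  lat <- rep(lat_c, times = n_lon)
  lon <- rep(lon_c, each = n_lat)
  areas <- cell_areas(lat_c, n_lon)

  # --- covariates -----------------------------------------------------
  MAT <- 27 - 0.45 * abs(lat) + 2.5 * grf(n_lat, n_lon, 2.5)
  MAP <- clip(250 + 1500 * exp(-(abs(lat) / 28)^2) +
                250 * grf(n_lat, n_lon, 2.5), 60, 4000)
  NDVI <- clip(0.15 + 0.65 * stats::plogis((MAT - 4) / 8) +
                 0.06 * grf(n_lat, n_lon, 2), 0.05, 0.95)
  sand <- clip(0.45 + 0.14 * grf(n_lat, n_lon, 2.5), 0.10, 0.80)
  clay <- clip(0.20 + 0.08 * grf(n_lat, n_lon, 2.5), 0.03, 0.55)
  over <- sand + clay > 0.95
  clay[over] <- 0.95 - sand[over]
  silt <- 0.9 * (1 - sand - clay)
  BD <- clip(1.30 + 0.10 * grf(n_lat, n_lon, 2.5), 0.8, 1.8)
  pH <- clip(6.8 - MAP / 2500 + 0.35 * grf(n_lat, n_lon, 2.5), 4, 9)
  SOC_pct <- clip(1.5 + 6 * stats::plogis((8 - MAT) / 6) +
                    0.8 * grf(n_lat, n_lon, 2.5), 0.2, 20)
  CN <- clip(12 + 2.5 * grf(n_lat, n_lon, 2.5), 6, 30)
  TN <- SOC_pct / CN
  covariates <- data.frame(MAT = MAT, MAP = MAP, NDVI = NDVI, BD = BD,
                           pH = pH, SOC_pct = SOC_pct, TN = TN, CN = CN,
                           sand = sand, silt = silt, clay = clay)

  # --- true intrinsic turnover times (yr at 15 C) ---------------------
  tau <- matrix(NA_real_, n, 3,
                dimnames = list(NULL, c("tau_fast", "tau_slow", "tau_passive")))
  for (p in 1:3) {
    l10 <- log10(cfg$tau_ref[p]) + cfg$mat_slope[p] * (MAT - 15) +
      cfg$ndvi_slope[p] * (NDVI - 0.5) + cfg$clay_slope[p] * (clay - 0.2) +
      cfg$residual_sd * grf(n_lat, n_lon, 2)
    tau[, p] <- 10^l10
  }

  # --- productivity, mask, yearly climate -----------------------------
  NPP <- clip((120 + 1200 * NDVI) *
                (0.35 + 0.65 * stats::plogis((MAP - 400) / 300)), 30, 2000)
  mask <- grf(n_lat, n_lon, 3) > stats::qnorm(1 - cfg$land_fraction)
  years <- 2000:2014
  tas <- MAT + outer(rep(1, n), stats::rnorm(length(years), 0, 0.35)) +
    matrix(stats::rnorm(n * length(years), 0, 0.15), n)
  pr <- pmax(MAP * (1 + matrix(stats::rnorm(n * length(years), 0, 0.03), n)),
             20)
  npp <- NPP * (1 + matrix(stats::rnorm(n * length(years), 0, 0.02), n))
  climate <- list(years = years, tas = tas, pr = pr, npp = npp)
  P_max <- max(pr)

  # --- steady-state stocks from the refined model ---------------------
  truth <- list(tau = tau, Q10 = cfg$Q10, b = cfg$b, P_max = P_max,
                clay = clay, r_f = cfg$r_f, r_s = cfg$r_s,
                root_frac = cfg$root_frac, T_ref = 15)
  k <- refined_rates_climatology(truth, MAT, MAP, NPP)
  stocks <- steady_state(NPP, k[, 1], k[, 2], k[, 3], cfg$r_f, cfg$r_s)
  soc <- rowSums(stocks)
  fractions <- stocks / soc
  colnames(fractions) <- c("f_fast", "f_slow", "f_passive")
  tau_a <- apparent_turnover(stocks, k)

  # --- alternative covariate sources (dataset-combination uncertainty) -
  clim_bias <- 0.25 * grf(n_lat, n_lon, 3)
  alt_climate <- data.frame(MAT = MAT + 0.3 + clim_bias,
                            MAP = MAP * (1 + 0.03 * grf(n_lat, n_lon, 3)))
  soil_pert <- function(x, rel) x * (1 + rel * grf(n_lat, n_lon, 3))
  alt_soil <- data.frame(BD = soil_pert(BD, 0.02), pH = soil_pert(pH, 0.01),
                         SOC_pct = soil_pert(SOC_pct, 0.05),
                         TN = soil_pert(TN, 0.05), CN = soil_pert(CN, 0.03),
                         sand = clip(soil_pert(sand, 0.03), 0.05, 0.85),
                         silt = clip(soil_pert(silt, 0.03), 0.01, 0.85),
                         clay = clip(soil_pert(clay, 0.03), 0.02, 0.6))

  structure(list(n_lat = n_lat, n_lon = n_lon, lat = lat, lon = lon,
                 lat_centers = lat_c, lon_centers = lon_c, areas = areas,
                 mask = mask, covariates = covariates, tau = tau,
                 fractions = fractions, NPP = NPP, stocks = stocks,
                 soc_stock = soc, tau_a = tau_a, climate = climate,
                 truth = truth, alt_climate = alt_climate,
                 alt_soil = alt_soil, config = cfg, seed = seed),
            class = "soil_world")
}

#' @export
print.soil_world <- function(x, ...) {
  cat(sprintf("Synthetic soil world: %d x %d grid (%d cells, %.0f%% land)\n",
              x$n_lat, x$n_lon, length(x$lat), 100 * mean(x$mask)))
  cat(sprintf("  true tau at 15 C (land medians, yr): fast %.2f, slow %.1f, passive %.0f\n",
              stats::median(x$tau[x$mask, 1]), stats::median(x$tau[x$mask, 2]),
              stats::median(x$tau[x$mask, 3])))
  cat(sprintf("  SOC stock: %.0f PgC over land (steady state by construction)\n",
              global_total(x$soc_stock, x$areas, x$mask)))
  invisible(x)
}

#' Covariate grids for each dataset-source combination
#'
#' Crosses the two climate sources with the two soil sources of a synthetic
#' world (mirroring the 2 climate x 2 soil combinations used for map
#' uncertainty), returning one full predictor data.frame per combination.
#'
#' @param world a \code{soil_world}.
#' @return named list of 4 data.frames with the full predictor set.
#' @export
covariate_combinations <- function(world) {
  cov1 <- world$covariates
  clim <- list(c1 = cov1[c("MAT", "MAP")], c2 = world$alt_climate)
  soil_cols <- c("BD", "pH", "SOC_pct", "TN", "CN", "sand", "silt", "clay")
  soil <- list(s1 = cov1[soil_cols], s2 = world$alt_soil[soil_cols])
  out <- list()
  for (ci in names(clim)) for (si in names(soil)) {
    out[[paste(ci, si, sep = "_")]] <-
      cbind(clim[[ci]], NDVI = cov1$NDVI, soil[[si]])
  }
  out
}

#' Generate a synthetic incubation CO2-flux series
#'
#' Evaluates the three-pool forward model at regular sampling times and adds
#' i.i.d. zero-mean Gaussian measurement noise (negative noisy fluxes are
#' truncated at zero, as measured effluxes are non-negative). With
#' \code{noise_sd = 0} the series equals the forward model exactly.
#'
#' @param params a \code{\link{pool_params}}.
#' @param C_tot initial carbon (mgC g^-1 dw), positive.
#' @param temperature incubation temperature (degrees C).
#' @param duration incubation length (days), positive.
#' @param sampling_interval days between observations.
#' @param noise_sd measurement noise standard deviation (flux units), >= 0.
#' @param seed integer RNG seed.
#' @param site_id identifier for the series.
#' @param metadata extra metadata list (merged over sensible defaults).
#' @return an \code{\link{incubation_series}}.
#' @export
gen_incubation_series <- function(params, C_tot, temperature = 15,
                                  duration = 730, sampling_interval = 7,
                                  noise_sd = 0, seed = 1,
                                  site_id = "synthetic",
                                  metadata = list()) {
  if (duration <= 0) stop("duration must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (C_tot <= 0) stop("C_tot must be positive")
  times <- seq(0, duration, by = sampling_interval)
  set.seed(as.integer(seed))
  fl <- forward_flux(params, C_tot, times)
  if (noise_sd > 0) fl <- pmax(fl + stats::rnorm(length(fl), 0, noise_sd), 0)
  md <- utils::modifyList(list(aerobic = TRUE, substrate_added = FALSE),
                          metadata)
  incubation_series(site_id, times, fl, C_tot, temperature, md)
}

#' Sample site records from a synthetic world
#'
#' Draws land cells and attaches the true turnover times perturbed by
#' multiplicative lognormal noise (sd of log10 tau = log10(1 + noise)), the
#' true fractions with small Dirichlet-like jitter (renormalized), and the
#' cell's predictor covariates.
#'
#' Each site also carries a simulated incubation temperature (uniform on
#' 4-35 C) and the turnover times expressed at that temperature (obtained
#' by inverting the reference-temperature normalization), so alternative
#' normalization schemes can be exercised downstream.
#'
#' @param world a \code{soil_world}.
#' @param n number of sites.
#' @param noise relative multiplicative noise on tau (default 0.1 = 10%).
#' @param seed integer RNG seed.
#' @return data.frame of site records (tau at 15 C, tau at incubation
#'   temperature, fractions, predictors).
#' @export
gen_sites <- function(world, n = 300, noise = 0.1, seed = 1) {
  set.seed(as.integer(seed))
  land <- which(world$mask)
  idx <- sample(land, n, replace = n > length(land))
  sd10 <- log10(1 + noise)
  tau <- world$tau[idx, , drop = FALSE] *
    10^matrix(stats::rnorm(3 * n, 0, sd10), n, 3)
  fr <- world$fractions[idx, , drop = FALSE] *
    exp(matrix(stats::rnorm(3 * n, 0, 0.05), n, 3))
  fr <- fr / rowSums(fr)
  inc_T <- stats::runif(n, 4, 35)
  # tau at the incubation temperature: invert the Q10 normalization so the
  # default scheme recovers the 15 C values exactly
  tau_inc <- tau / default_q10(inc_T)^((inc_T - 15) / 10)
  colnames(tau_inc) <- paste0(colnames(tau), "_inc")
  cbind(data.frame(site_id = paste0("site", seq_len(n)), cell = idx,
                   incubation_T = inc_T),
        as.data.frame(tau), as.data.frame(tau_inc), as.data.frame(fr),
        world$covariates[idx, , drop = FALSE])
}

# scenario shorthand: additional warming (K) and NPP fertilization
# (fractional increase) from 2015 to 2100, CMIP6-like magnitudes
scenario_profiles <- function() {
  list(ssp126 = list(warm = 1.5, fert = 0.10, pr_trend = 0.02),
       ssp245 = list(warm = 2.8, fert = 0.20, pr_trend = 0.04),
       ssp585 = list(warm = 5.5, fert = 0.35, pr_trend = 0.07))
}

#' Generate a synthetic ESM-like ensemble
#'
#' Each synthetic "ESM" is the reduced-complexity emulator itself, run with
#' known parameters: spatially uniform pool turnover times equal to the
#' world's carbon-weighted global mean per pool multiplied by
#' \code{tau_bias_factor} (1.3 emulates the ~30% overestimate found in
#' CMIP6 models), a model-specific Q10, transfer coefficients and
#' precipitation exponent. Forcing covers 2000-2100: historical climate
#' follows the world's fields with smooth model biases, futures add
#' scenario-specific warming ramps, precipitation trends and NPP
#' fertilization. Historical pools (2000-2014) and future pool trajectories
#' per scenario are produced by the emulator, so a calibration run on this
#' output can recover the generating parameters exactly up to optimizer
#' tolerance.
#'
#' @param world a \code{soil_world}.
#' @param n_models number of ensemble members (default 3).
#' @param scenarios character vector of scenario names among
#'   \code{"ssp126"}, \code{"ssp245"}, \code{"ssp585"}; non-empty.
#' @param tau_bias_factor multiplicative bias of ensemble turnover times
#'   relative to the world's (must be > 0; default 1.3).
#' @param seed integer RNG seed.
#' @return object of class \code{"esm_ensemble"}: list of \code{models},
#'   each with \code{params} (the generating truth), \code{forcing} per
#'   scenario (2000-2100), \code{hist_pools} (2000-2014 trajectory),
#'   \code{future_pools} per scenario (2015-2100 trajectory), and
#'   \code{t_preindustrial} (global-mean 1850-1900 surrogate temperature).
#' @export
gen_esm_ensemble <- function(world, n_models = 3,
                             scenarios = c("ssp126", "ssp245", "ssp585"),
                             tau_bias_factor = 1.3, seed = 1) {
  if (length(scenarios) == 0) stop("scenarios list must be non-empty")
  if (tau_bias_factor <= 0) stop("tau_bias_factor must be positive")
  profs <- scenario_profiles()
  if (!all(scenarios %in% names(profs)))
    stop("unknown scenario; available: ", paste(names(profs), collapse = ", "))
  set.seed(as.integer(seed))
  n <- length(world$lat)
  land <- world$mask
  # carbon-weighted global mean tau per pool (weights: pool stock x area)
  w <- world$areas[land]
  tau_w <- vapply(1:3, function(p) {
    cw <- world$stocks[land, p] * w
    sum(world$tau[land, p] * cw) / sum(cw)
  }, numeric(1))
  tau_esm <- tau_w * tau_bias_factor

  years_all <- 2000:2100
  fut <- years_all > 2014
  ramp <- pmax(years_all - 2014, 0) / (2100 - 2014)

  models <- list()
  for (m in seq_len(n_models)) {
    t_bias <- 0.6 * grf(world$n_lat, world$n_lon, 3) + 0.2 * (m - 2)
    p_bias <- 1 + 0.05 * grf(world$n_lat, world$n_lon, 3)
    n_bias <- 1 + 0.06 * grf(world$n_lat, world$n_lon, 3)
    params <- list(tau_i = tau_esm, Q10 = 1.4 + 0.1 * (m - 1), T_ref = 15,
                   r_f = 0.30 + 0.05 * (m - 1), r_s = 0.03 + 0.02 * (m - 1),
                   b = 0.4 + 0.15 * (m - 1))
    forcing <- list()
    for (sc in scenarios) {
      pf <- profs[[sc]]
      ny_all <- length(years_all)
      warm <- 0.01 * pmin(years_all - 2000, 14) + pf$warm * ramp^1.15
      tas <- world$covariates$MAT + t_bias +
        outer(rep(1, n), warm + stats::rnorm(ny_all, 0, 0.1)) +
        matrix(stats::rnorm(n * ny_all, 0, 0.1), n)
      pr <- pmax(world$covariates$MAP * p_bias *
                   outer(rep(1, n), 1 + pf$pr_trend * ramp) *
                   (1 + matrix(stats::rnorm(n * ny_all, 0, 0.03), n)), 10)
      npp <- world$NPP * n_bias *
        outer(rep(1, n), 1 + pf$fert * ramp) *
        (1 + matrix(stats::rnorm(n * ny_all, 0, 0.015), n))
      forcing[[sc]] <- list(years = years_all, tas = tas, pr = pr, npp = npp)
    }
    params$P_max <- max(vapply(forcing, function(f) max(f$pr), numeric(1)))

    # historical pools from the emulator's own steady state
    f_hist <- window_forcing(forcing[[1]], 2000, 2014)
    k0 <- actual_decay_rate(matrix(params$tau_i, n, 3, byrow = TRUE),
                            rowMeans(f_hist$tas), rowMeans(f_hist$pr), params)
    st0 <- steady_state(rowMeans(f_hist$npp), k0[, 1], k0[, 2], k0[, 3],
                        params$r_f, params$r_s)
    hist_pools <- run_emulator(params, f_hist, st0)
    st2014 <- hist_pools$stocks[, , dim(hist_pools$stocks)[3]]
    future_pools <- lapply(forcing, function(f) {
      run_emulator(params, window_forcing(f, 2015, 2100), st2014)
    })
    t_pi <- sum(rowMeans(f_hist$tas) * world$areas) / sum(world$areas) - 0.9
    models[[paste0("esm", m)]] <- list(
      name = paste0("esm", m), params = params, forcing = forcing,
      hist_pools = hist_pools, future_pools = future_pools,
      t_preindustrial = t_pi)
  }
  structure(list(models = models, scenarios = scenarios,
                 tau_i = tau_esm, tau_bias_factor = tau_bias_factor,
                 n_cells = n, seed = seed),
            class = "esm_ensemble")
}

#' @export
print.esm_ensemble <- function(x, ...) {
  cat(sprintf("Synthetic ESM ensemble: %d models x %d scenarios (%d cells)\n",
              length(x$models), length(x$scenarios), x$n_cells))
  cat(sprintf("  uniform tau_i (yr): fast %.2f, slow %.1f, passive %.0f (bias factor %.2f)\n",
              x$tau_i[1], x$tau_i[2], x$tau_i[3], x$tau_bias_factor))
  invisible(x)
}
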