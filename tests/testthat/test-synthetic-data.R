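test_that("generated incubation series match the forward model exactly when noiseless", {
  p <- ref_params()
  s <- gen_incubation_series(p, 20, 15, duration = 365, sampling_interval = 7,
                             noise_sd = 0, seed = 3)
  expect_equal(s$fluxes, forward_flux(p, 20, s$times), tolerance = 1e-14)
  # fitting residual of the true parameters is exactly zero
  expect_equal(max(abs(s$fluxes - forward_flux(p, s$C_tot, s$times))), 0)
  # single pool trivial value at t = 0
  s1 <- gen_incubation_series(list(k = c(0.01, 1e-4, 1e-6), f = c(1, 0, 0)),
                              10, 15, 100, 10, 0, seed = 1)
  expect_equal(s1$fluxes[1], 0.1)
  expect_error(gen_incubation_series(p, -5, 15, 100, 7, 0), "positive")
  expect_error(gen_incubation_series(p, 10, 15, -10, 7, 0), "positive")
  expect_error(gen_incubation_series(p, 10, 15, 100, 7, -0.1), "non-negative")
})

test_that("incubation noise is reproducible and zero-mean", {
  p <- ref_params()
  a <- gen_incubation_series(p, 20, 15, 730, 7, 0.002, seed = 11)
  b <- gen_incubation_series(p, 20, 15, 730, 7, 0.002, seed = 11)
  expect_identical(a$fluxes, b$fluxes)
  cc <- gen_incubation_series(p, 20, 15, 730, 7, 0.002, seed = 12)
  expect_false(identical(a$fluxes, cc$fluxes))
  resid <- a$fluxes - forward_flux(p, 20, a$times)
  expect_lt(abs(mean(resid)), 3 * 0.002 / sqrt(length(resid)))
})

test_that("the synthetic world satisfies its structural invariants", {
  w <- small_world()
  n <- w$n_lat * w$n_lon
  expect_length(w$lat, n)
  expect_equal(max(abs(rowSums(w$fractions) - 1)), 0, tolerance = 1e-9)
  expect_true(all(w$tau[, 1] < w$tau[, 2] & w$tau[, 2] < w$tau[, 3]))
  tex <- w$covariates$clay + w$covariates$silt + w$covariates$sand
  expect_true(all(tex <= 1 + 1e-12))
  expect_true(all(w$stocks >= 0) && all(is.finite(w$stocks)))
  # turnover times lengthen toward warm climates by construction
  expect_gt(cor(w$tau[, 1], w$covariates$MAT, method = "spearman"), 0.5)
  expect_error(gen_world(1, 5), "2 x 2")
})

test_that("worlds are bit-identical under a fixed seed", {
  a <- gen_world(8, 8, seed = 21)
  b <- gen_world(8, 8, seed = 21)
  expect_identical(a, b)
  cc <- gen_world(8, 8, seed = 22)
  expect_false(identical(a$covariates$MAT, cc$covariates$MAT))
})

test_that("world stocks are at the refined model's steady state", {
  w <- small_world()
  # closed-form construction check
  k <- refined_rates_climatology(w$truth, w$covariates$MAT, w$covariates$MAP,
                                 w$NPP)
  ss <- steady_state(w$NPP, k[, 1], k[, 2], k[, 3], w$truth$r_f, w$truth$r_s)
  expect_equal(unname(w$stocks), unname(ss), tolerance = 1e-12)
  # forward run under the yearly climate drifts < 0.1% over 15 years
  tr <- run_refined(w$truth, w$climate, w$stocks)
  drift <- abs(sum(tr$stocks[, , 15]) - sum(w$stocks)) / sum(w$stocks)
  expect_lt(drift, 0.001)
})

test_that("site records carry noisy but unbiased turnover times", {
  w <- small_world()
  rec <- gen_sites(w, n = 150, noise = 0.1, seed = 5)
  expect_equal(nrow(rec), 150)
  expect_true(all(abs(rowSums(rec[, c("f_fast", "f_slow", "f_passive")]) - 1)
                  < 1e-9))
  # log-scale noise is centred: median ratio to truth near 1
  ratio <- rec$tau_slow / w$tau[rec$cell, 2]
  expect_lt(abs(median(log10(ratio))), 0.02)
  # normalizing tau at incubation T with the default Q10 recovers the 15 C value
  back <- normalize_to_reference(rec$tau_fast_inc, rec$incubation_T)
  expect_equal(back, rec$tau_fast, tolerance = 1e-12)
})

test_that("the synthetic ESM ensemble matches its stated construction", {
  w <- small_world()
  e <- small_ensemble()
  expect_length(e$models, 2)
  # unbiased ensemble turnover equals the world's carbon-weighted mean
  e1 <- gen_esm_ensemble(w, 1, scenarios = "ssp126", tau_bias_factor = 1,
                         seed = 3)
  land <- w$mask
  for (p in 1:3) {
    cw <- w$stocks[land, p] * w$areas[land]
    expect_equal(e1$tau_i[p], sum(w$tau[land, p] * cw) / sum(cw),
                 tolerance = 1e-12)
  }
  expect_equal(e$tau_i / e1$tau_i, rep(1.3, 3), tolerance = 1e-12)
  # forcing sets: n_models x scenarios, years 2000-2100
  for (m in e$models) {
    expect_named(m$forcing, e$scenarios)
    for (f in m$forcing) expect_equal(f$years, 2000:2100)
    expect_true(all(is.finite(m$hist_pools$stocks)))
    expect_true(all(m$hist_pools$stocks >= 0))
    for (fp in m$future_pools) expect_true(all(fp$stocks >= 0))
  }
  expect_error(gen_esm_ensemble(w, 2, scenarios = character(0)), "non-empty")
  expect_error(gen_esm_ensemble(w, 2, tau_bias_factor = 0), "positive")
})

test_that("incubation series survive a CSV round trip", {
  p <- ref_params()
  recs <- list(
    gen_incubation_series(p, 20, 25, 365, 7, 0.001, seed = 1, site_id = "a",
                          metadata = list(lat = 45.5, lon = -93.2, MAT = 6,
                                          MAP = 700, depth_cm = 10,
                                          biome = "temperate forest")),
    gen_incubation_series(p, 15, 15, 200, 10, 0, seed = 2, site_id = "b"))
  path <- tempfile(fileext = ".csv")
  write_incubation_csv(recs, path)
  back <- read_incubation_csv(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$fluxes, recs[[1]]$fluxes, tolerance = 1e-9)
  expect_equal(back[[1]]$C_tot, 20)
  expect_equal(back[[1]]$metadata$biome, "temperate forest")
  expect_equal(back[[2]]$times, recs[[2]]$times)
})
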