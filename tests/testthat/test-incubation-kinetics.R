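test_that("forward flux matches closed-form single-pool values", {
  p1 <- list(k = c(0.01, 1e-4, 1e-6), f = c(1, 0, 0))
  expect_equal(forward_flux(p1, 10, 0), 0.1)
  expect_equal(forward_flux(p1, 10, 100), 0.1 * exp(-1), tolerance = 1e-12)
  expect_error(forward_flux(p1, -1, 0), "positive")
  expect_error(forward_flux(p1, 10, -5), "negative")
})

test_that("forward flux agrees with an independent ODE integration", {
  skip_if_not_installed("deSolve")
  p <- pool_params(k = c(0.05, 0.001, 1e-5), f = c(0.1, 0.3, 0.6))
  C_tot <- 20
  # oracle: integrate the pool depletion ODEs and read the respiration rate
  deriv <- function(t, y, parms) list(-p$k * y)
  y0 <- C_tot * p$f
  times <- c(0, 5, 30, 100, 365, 730)
  sol <- deSolve::lsoda(y0, times, deriv, NULL, rtol = 1e-10, atol = 1e-12)
  oracle_flux <- as.numeric(sol[, 2:4] %*% p$k)
  expect_equal(forward_flux(p, C_tot, times), oracle_flux, tolerance = 1e-8)
})

test_that("flux integrates to the initial carbon and decays monotonically", {
  p <- ref_params()
  C_tot <- 20
  total <- stats::integrate(function(t) forward_flux(p, C_tot, t), 0, Inf,
                            rel.tol = 1e-10)$value
  expect_equal(total, C_tot, tolerance = 1e-6)
  fl <- forward_flux(p, C_tot, seq(0, 5000, by = 10))
  expect_true(all(diff(fl) < 0))
})

test_that("log-likelihood equals the brute-force Gaussian sum", {
  p <- pool_params(k = c(0.02, 1e-3, 1e-6), f = c(0.2, 0.3, 0.5))
  s <- gen_incubation_series(p, 10, 15, duration = 28, sampling_interval = 7,
                             noise_sd = 0.001, seed = 4)
  sigma <- 0.02
  oracle <- -sum((forward_flux(p, 10, s$times) - s$fluxes)^2) / (2 * sigma^2)
  expect_equal(log_likelihood(p, s, sigma), oracle, tolerance = 1e-12)
  # residual term is a quadratic form: doubling residuals scales it by 4
  s2 <- s; s2$fluxes <- forward_flux(p, 10, s$times) +
    2 * (s$fluxes - forward_flux(p, 10, s$times))
  expect_equal(log_likelihood(p, s2, sigma), 4 * log_likelihood(p, s, sigma),
               tolerance = 1e-10)
  # generating parameters on a noiseless series sit at the maximum (0)
  s0 <- gen_incubation_series(p, 10, 15, 28, 7, 0, seed = 1)
  expect_equal(log_likelihood(p, s0, sigma), 0)
  expect_error(log_likelihood(p, list(times = 1:3, fluxes = 1:2, C_tot = 1),
                              sigma), "length")
  expect_error(log_likelihood(p, s, 0), "positive")
})

test_that("screening applies the inclusion criteria in order", {
  mk <- function(duration = 400, aerobic = TRUE, substrate = FALSE,
                 C_tot = 10, decline = TRUE, id = "s") {
    t <- seq(0, duration, by = 10)
    fl <- if (decline) 0.1 * exp(-0.005 * t) + 0.01 else rep(0.05, length(t))
    list(site_id = id, times = t, fluxes = fl, C_tot = C_tot,
         duration = duration,
         metadata = list(aerobic = aerobic, substrate_added = substrate))
  }
  recs <- list(mk(id = "ok"),
               mk(duration = 150, id = "short"),
               mk(aerobic = FALSE, id = "anaerobic"),
               mk(C_tot = NA, id = "no_c"),
               mk(substrate = TRUE, id = "amended"),
               mk(decline = FALSE, id = "flat"),
               list(site_id = "broken", times = NULL, fluxes = NULL))
  out <- screen_records(recs)
  expect_length(out$kept, 1)
  expect_equal(out$kept[[1]]$site_id, "ok")
  rej <- stats::setNames(out$rejected$reason, out$rejected$site_id)
  expect_equal(rej[["short"]], "duration")
  expect_equal(rej[["anaerobic"]], "aerobic")
  expect_equal(rej[["no_c"]], "c_tot")
  expect_equal(rej[["amended"]], "substrate")
  expect_equal(rej[["flat"]], "decline")
  expect_equal(rej[["broken"]], "unparseable")
})

test_that("reference-temperature normalization follows the Q10 scaling", {
  expect_equal(normalize_to_reference(3.7, 15, function(T) 2.4), 3.7)
  expect_equal(normalize_to_reference(2, 25, function(T) 2), 4)
  expect_equal(normalize_to_reference(2, 5, function(T) 2), 1)
  expect_error(normalize_to_reference(-1, 25), "positive")
  expect_error(normalize_to_reference(2, 25, function(T) -1), "positive")
  # default Q10 declines with temperature and stays positive
  tt <- seq(-10, 45, by = 5)
  q <- default_q10(tt)
  expect_true(all(q > 0))
  expect_true(all(diff(q) <= 0))
})

test_that("Arrhenius normalization matches Q10 when the activation energy is tuned to it", {
  T_inc <- 22
  Ea <- arrhenius_ea_for_q10(2, T_inc)
  tau_q10 <- normalize_to_reference(5, T_inc, function(T) 2)
  tau_arr <- normalize_arrhenius(5, T_inc, Ea = Ea)
  expect_equal(tau_arr, tau_q10, tolerance = 0.05)
  # at the reference temperature both are the identity
  expect_equal(normalize_arrhenius(5, 15), 5)
})

test_that("pool parameter validation enforces ordering and the simplex", {
  expect_error(pool_params(c(1e-3, 0.01, 1e-6), c(0.3, 0.3, 0.4)), "ordering|k_fast")
  expect_error(pool_params(c(0.01, 1e-3, 1e-6), c(0.5, 0.5, 0.5)), "sum")
  p <- pool_params(c(0.01, 1e-3, 1e-6), c(0.3, 0.3, 0.4))
  expect_s3_class(p, "pool_params")
})

test_that("rate/turnover unit conversions are mutually inverse", {
  k <- c(0.01, 5e-4, 8e-6)
  expect_equal(k_per_day(tau_years(k)), k, tolerance = 1e-12)
  expect_equal(tau_years(1 / 365.25), 1)
})
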