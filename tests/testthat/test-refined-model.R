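test_that("mineral-protection modifier evaluates both branches of its clay response", {
  expect_equal(modifier_M(0.01), 0.242, tolerance = 1e-12)
  expect_equal(modifier_M(0.1), -2.1 * 0.01 + 6.2 * 0.1 + 0.6,
               tolerance = 1e-12)
  # the two branches nearly agree at the breakpoint
  gap <- abs(24.2 * 0.033 - (-2.1 * 0.033^2 + 6.2 * 0.033 + 0.6))
  expect_lt(gap, 0.005)
  expect_error(modifier_M(1.2), "clay")
})

test_that("priming modifier is a saturating function of root respiration", {
  expect_equal(modifier_RP(0), 1)
  expect_equal(modifier_RP(13.01), 1 / (1 + 2.47 / 2), tolerance = 1e-12)
  expect_equal(modifier_RP(1e12), 1 / 3.47, tolerance = 1e-6)
  rr <- seq(0, 500, by = 5)
  frp <- modifier_RP(rr)
  expect_true(all(frp > 1 / 3.47 & frp <= 1))
  expect_true(all(diff(frp) < 0))
  expect_error(modifier_RP(-1), "non-negative")
})

test_that("refined decay rate is the product of its factors", {
  par <- list(Q10 = c(1.6, 2.2, 2.8), b = 0.8, P_max = 2000, T_ref = 15)
  set.seed(41)
  for (i in 1:100) {
    pool <- sample(1:3, 1)
    tau <- runif(1, 0.1, 500); T_c <- runif(1, -5, 30)
    P <- runif(1, 100, 2000); clay <- runif(1, 0, 0.6)
    rr <- runif(1, 0, 100)
    oracle <- (1 / tau) * par$Q10[pool]^((T_c - 15) / 10) *
      (P / par$P_max)^par$b * modifier_M(clay) *
      (if (pool == 1) 1 else modifier_RP(rr))
    expect_equal(refined_decay_rate(pool, tau, T_c, P, clay, rr, par),
                 oracle, tolerance = 1e-12)
  }
  # priming affects only slow and passive pools, monotonically
  k_fast <- sapply(c(0, 50, 200), function(r)
    refined_decay_rate(1, 10, 15, 1000, 0.2, r, par))
  expect_equal(diff(k_fast), c(0, 0))
  k_slow <- sapply(c(0, 50, 200), function(r)
    refined_decay_rate(2, 10, 15, 1000, 0.2, r, par))
  expect_true(all(diff(k_slow) < 0))
})

test_that("apparent turnover is the flux-weighted residence time", {
  # single-pool cell
  st <- cbind(0, 0, 1000); k <- cbind(1, 0.1, 0.002)
  expect_equal(apparent_turnover(st, k), 500)
  set.seed(42)
  for (i in 1:20) {
    st <- matrix(runif(3, 1, 1000), 1)
    k <- matrix(sort(runif(3, 1e-4, 1), decreasing = TRUE), 1)
    ta <- apparent_turnover(st, k)
    oracle <- sum(st) / sum(st * k)
    expect_equal(ta, oracle, tolerance = 1e-12)
    expect_gte(ta, min(1 / k))
    expect_lte(ta, max(1 / k))
  }
})

test_that("spin-up reaches and holds the flux-balance steady state", {
  w <- small_world()
  sp <- spin_up(w$truth, w$climate)
  expect_true(all(sp$converged))
  # a converged state is invariant over further cycles
  sp2 <- spin_up(w$truth, w$climate, init = sp$state, max_cycles = 5)
  drift <- abs(sum(sp2$state) - sum(sp$state)) / sum(sp$state)
  expect_lt(drift, 1e-4)
})

test_that("pooled calibration of the refined model recovers the generating truth", {
  w <- small_world()
  clim <- list(tas = rowMeans(w$climate$tas), pr = rowMeans(w$climate$pr),
               npp = rowMeans(w$climate$npp))
  fit <- calibrate_refined(w$stocks, w$tau_a, clim, w$tau,
                           w$covariates$clay, w$truth$P_max, mask = w$mask,
                           seed = 6)
  expect_equal(fit$Q10, w$truth$Q10, tolerance = 0.1)
  expect_equal(fit$b, w$truth$b, tolerance = 0.1)
  expect_lt(abs(fit$r_f - w$truth$r_f), 0.05)
  expect_lt(abs(fit$r_s - w$truth$r_s), 0.05)
  # the generating parameters beat random prior draws
  obj_at <- function(th) {
    params <- list(tau = w$tau, Q10 = th[1:3], b = th[4], P_max = w$truth$P_max,
                   clay = w$covariates$clay, r_f = th[5], r_s = th[6],
                   root_frac = 0.07, T_ref = 15)
    k <- refined_rates_climatology(params, clim$tas, clim$pr, clim$npp)
    st <- steady_state(clim$npp, k[, 1], k[, 2], k[, 3], th[5], th[6])
    land <- w$mask
    nr <- vapply(1:3, function(p)
      sqrt(mean((st[land, p] - w$stocks[land, p])^2)) /
        mean(w$stocks[land, p]), numeric(1))
    sum(nr) + mean((log(apparent_turnover(st[land, ], k[land, ])) -
                      log(w$tau_a[land]))^2)
  }
  truth_obj <- obj_at(c(w$truth$Q10, w$truth$b, w$truth$r_f, w$truth$r_s))
  set.seed(43)
  rand_obj <- replicate(100, {
    q1 <- runif(1, 1, 4)
    obj_at(c(q1, q1 + runif(1, 0, 1.5), q1 + runif(1, 0, 3),
             runif(1, 0.01, 3), runif(1), runif(1)))
  })
  expect_true(all(truth_obj <= rand_obj + 1e-12))
})

test_that("projections respond with the right sign to idealized forcing", {
  w <- small_world()
  sp <- spin_up(w$truth, w$climate)
  n <- length(w$lat)
  mk_forcing <- function(dT) {
    yrs <- 2015:2100
    ramp <- (yrs - 2014) / length(yrs)
    list(years = yrs,
         tas = rowMeans(w$climate$tas) + outer(rep(1, n), dT * ramp),
         pr = matrix(rowMeans(w$climate$pr), n, length(yrs)),
         npp = matrix(rowMeans(w$climate$npp), n, length(yrs)))
  }
  base <- project(w$truth, sp$state, mk_forcing(0))
  warm <- project(w$truth, sp$state, mk_forcing(4))
  tot0 <- sum(sp$state)
  expect_lt(abs(sum(base$stocks[, , 86]) - tot0) / tot0, 0.002)
  tot_warm <- apply(warm$stocks, 3, sum)
  expect_true(all(diff(tot_warm) < 0))
  # deterministic: identical inputs give bit-identical trajectories
  warm2 <- project(w$truth, sp$state, mk_forcing(4))
  expect_identical(warm$stocks, warm2$stocks)
})
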