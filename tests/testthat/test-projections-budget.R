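test_that("global totals use exact spherical areas", {
  # grid whose centers tile the sphere: uniform 1 kgC m^-2 integrates to
  # 4 pi R^2 * 1000 gC = ~510 PgC
  n_lat <- 36; n_lon <- 72
  lat <- seq(-90 + 180 / n_lat / 2, 90 - 180 / n_lat / 2, length.out = n_lat)
  areas <- cell_areas(lat, n_lon)
  expect_equal(sum(areas), 4 * pi * 6.371e6^2, tolerance = 1e-12)
  field <- rep(1000, n_lat * n_lon)
  oracle <- 4 * pi * 6.371e6^2 * 1000 / 1e15
  expect_equal(global_total(field, areas), oracle, tolerance = 1e-12)
  expect_equal(global_total(field, areas), 510, tolerance = 0.01)
  expect_equal(global_total(rep(0, length(field)), areas), 0)
  expect_equal(global_total(2 * field, areas),
               2 * global_total(field, areas))
})

test_that("period deltas follow the trajectory arithmetic", {
  n <- 4; yrs <- 2000:2100
  stocks <- array(0, c(n, 3, length(yrs)))
  # constant trajectory: delta is zero
  stocks[, 1, ] <- 5; stocks[, 2, ] <- 50; stocks[, 3, ] <- 500
  traj <- structure(list(years = yrs, stocks = stocks), class = "pool_trajectory")
  expect_equal(delta_stock(traj)$field, rep(0, n))
  # linear ramp of 1 gC m^-2 yr^-1 in total: delta equals the 80-yr midpoint gap
  for (i in seq_along(yrs)) stocks[, 1, i] <- 5 + (i - 1)
  traj <- structure(list(years = yrs, stocks = stocks), class = "pool_trajectory")
  d <- delta_stock(traj)
  expect_equal(d$field, rep(80, n), tolerance = 1e-12)
  lat <- c(-10, 10); areas <- cell_areas(lat, 2)
  d2 <- delta_stock(traj, areas = areas, mask = rep(TRUE, 4))
  expect_equal(d2$total_pgc, global_total(d2$field, areas), tolerance = 1e-9)
  expect_error(delta_stock(traj, periodA = c(1900, 1910)), "cover")
})

test_that("aggregation reproduces a brute-force area-weighted group-by", {
  w <- small_world()
  set.seed(71)
  field <- rnorm(length(w$lat))
  # uniform field: every occupied band equals the value
  agg_u <- aggregate_field(rep(3.5, length(w$lat)), w$lat, w$areas, w$mask,
                           "latitude", band_width = 10)
  expect_true(all(abs(agg_u$mean - 3.5) < 1e-12))
  # a single nonzero cell contributes only to its own band
  one <- rep(0, length(w$lat)); one[which(w$mask)[1]] <- 7
  agg_o <- aggregate_field(one, w$lat, w$areas, w$mask, "latitude",
                           band_width = 10)
  expect_equal(sum(agg_o$mean != 0), 1)
  # brute-force oracle for the biome scheme
  agg_b <- aggregate_field(field, w$lat, w$areas, w$mask, "biome")
  grp <- cut(w$lat, c(-90, -50, -23, 23, 50, 90), include.lowest = TRUE,
             labels = c("southern_polar", "temperate_south", "tropical",
                        "temperate_north", "boreal"))
  for (i in seq_len(nrow(agg_b))) {
    sel <- w$mask & grp == agg_b$band[i]
    expect_equal(agg_b$mean[i],
                 sum(field[sel] * w$areas[sel]) / sum(w$areas[sel]),
                 tolerance = 1e-12)
  }
  # area weights add up to the land area
  expect_equal(sum(agg_b$area_m2), sum(w$areas[w$mask]), tolerance = 1e-9)
})

test_that("budget reduction follows the linear-fit arithmetic", {
  # exact line dSOC = -20 dT with the original ensemble at zero
  pts <- data.frame(dT = c(1, 2, 3),
                    dsoc_constrained = -20 * c(1, 2, 3),
                    dsoc_original = c(0, 0, 0))
  br <- budget_reduction(pts)
  expect_equal(unname(br$coef_constrained[2]), -20, tolerance = 1e-10)
  r15 <- br$table$reduction_fraction[br$table$target_K == 1.5]
  expect_equal(r15, 30 / 68, tolerance = 1e-10)
  expect_equal(r15, 0.441, tolerance = 1e-3)
  # zero slope and intercept: no reduction anywhere
  pts0 <- data.frame(dT = c(1, 2, 3), dsoc_constrained = c(0, 0, 0),
                     dsoc_original = c(0, 0, 0))
  expect_true(all(budget_reduction(pts0)$table$reduction_fraction == 0))
  expect_error(budget_reduction(pts0[1:2, ]), "3 points")
  # reductions grow with the fitted slope magnitude
  steeper <- budget_reduction(transform(pts, dsoc_constrained = -40 * dT))
  expect_true(all(steeper$table$reduction_fraction >
                    br$table$reduction_fraction))
})

test_that("trajectory concatenation preserves years and stocks", {
  w <- small_world()
  e <- small_ensemble()
  m <- e$models[[1]]
  tr <- combine_trajectories(m$hist_pools, m$future_pools$ssp126)
  expect_equal(tr$years, 2000:2100)
  expect_equal(tr$stocks[, , 15], m$hist_pools$stocks[, , 15])
  expect_equal(tr$stocks[, , 16], m$future_pools$ssp126$stocks[, , 1])
  expect_error(combine_trajectories(m$hist_pools, m$hist_pools), "adjacent")
})
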