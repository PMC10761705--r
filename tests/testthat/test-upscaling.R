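test_that("carbon-weighted turnover follows its defining sum", {
  expect_equal(weighted_tau(cbind(0.3, 6.68, 398), cbind(0.3, 0.3, 0.4)),
               161.294, tolerance = 1e-10)
  expect_equal(weighted_tau(cbind(2, 5, 70), cbind(1, 0, 0)), 2)
  # equal pool turnover gives that value for any fractions
  expect_equal(weighted_tau(cbind(7, 7, 7), cbind(0.2, 0.5, 0.3)), 7)
  # linear in the fractions and monotone in each turnover time
  t1 <- weighted_tau(cbind(1, 10, 100), cbind(0.5, 0.25, 0.25))
  t2 <- weighted_tau(cbind(1, 12, 100), cbind(0.5, 0.25, 0.25))
  expect_gt(t2, t1)
  expect_error(weighted_tau(cbind(1, 2, 3), cbind(0.5, 0.2, 0.2)), "sum")
})

test_that("the boosted-tree upscaler learns a single-covariate mapping and ranks it first", {
  set.seed(51)
  n <- 120
  rec <- data.frame(MAT = runif(n, -5, 25), MAP = runif(n, 200, 2000),
                    NDVI = runif(n), BD = runif(n, 1, 1.6),
                    pH = runif(n, 4, 8), SOC_pct = runif(n, 1, 10),
                    TN = runif(n, 0.1, 1), CN = runif(n, 8, 20),
                    silt = runif(n, 0.1, 0.5), sand = runif(n, 0.2, 0.6))
  rec$tau_fast <- 0.3 * 10^(0.02 * (rec$MAT - 10) + rnorm(n, 0, 0.01))
  fit <- fit_tau_model(rec, "tau_fast",
                       cv_config = list(eta = 0.1, max_depth = 2,
                                        nrounds = 200, nfold = 5), seed = 1)
  expect_gt(fit$cv_r2, 0.75)
  expect_equal(names(sort(fit$importance, decreasing = TRUE))[1], "MAT")
  expect_equal(sum(fit$importance), 100, tolerance = 1e-6)
  # deterministic under seed
  fit2 <- fit_tau_model(rec, "tau_fast",
                        cv_config = list(eta = 0.1, max_depth = 2,
                                         nrounds = 200, nfold = 5), seed = 1)
  expect_equal(predict(fit, rec), predict(fit2, rec))
})

test_that("a constant target degenerates gracefully", {
  set.seed(52)
  n <- 60
  rec <- data.frame(MAT = runif(n), MAP = runif(n), NDVI = runif(n),
                    BD = runif(n), pH = runif(n), SOC_pct = runif(n),
                    TN = runif(n), CN = runif(n), silt = runif(n),
                    sand = runif(n), tau_fast = rep(2, n))
  fit <- fit_tau_model(rec, "tau_fast",
                       cv_config = list(eta = 0.1, max_depth = 2,
                                        nrounds = 50, nfold = 5), seed = 2)
  expect_lte(fit$cv_r2, 0.05)
  expect_true(all(is.finite(predict(fit, rec))))
})

test_that("records with missing predictors are dropped, not imputed", {
  set.seed(53)
  n <- 80
  rec <- data.frame(MAT = runif(n, 0, 20), MAP = runif(n, 200, 2000),
                    NDVI = runif(n), BD = runif(n, 1, 1.6),
                    pH = runif(n, 4, 8), SOC_pct = runif(n, 1, 10),
                    TN = runif(n, 0.1, 1), CN = runif(n, 8, 20),
                    silt = runif(n, 0.1, 0.5), sand = runif(n, 0.2, 0.6))
  rec$tau_slow <- 6 * 10^(0.015 * rec$MAT + rnorm(n, 0, 0.02))
  rec$MAP[1:5] <- NA
  warns <- testthat::capture_warnings(
    fit <- fit_tau_model(rec, "tau_slow",
                         cv_config = list(eta = 0.1, max_depth = 2,
                                          nrounds = 100, nfold = 5), seed = 3))
  expect_match(warns, "dropped", all = FALSE)
  expect_equal(fit$n_records, n - 5)
  expect_error(suppressWarnings(fit_tau_model(rec[1:20, ], "tau_slow")),
               "at least 30")
})

test_that("map prediction handles source combinations correctly", {
  ctx <- small_ctx()
  w <- small_world()
  combos <- covariate_combinations(w)
  expect_length(combos, 4)
  # a single combination yields zero spread; duplicating it changes nothing
  m1 <- predict_maps(ctx$upscalers, combos[1])
  expect_true(all(m1$tau_sd == 0))
  m2 <- predict_maps(ctx$upscalers, combos[c(1, 1)])
  expect_equal(m2$tau_mean, m1$tau_mean)
  expect_true(all(m2$tau_sd == 0))
  m4 <- predict_maps(ctx$upscalers, combos)
  expect_true(all(m4$tau_mean > 0))
  expect_true(all(abs(rowSums(m4$fractions) - 1) < 1e-9))
  tw <- m4$tau_weighted
  expect_true(all(tw >= apply(m4$tau_mean, 1, min) - 1e-9 &
                    tw <= apply(m4$tau_mean, 1, max) + 1e-9))
  bad <- combos; bad[[2]] <- bad[[2]][1:10, ]
  expect_error(predict_maps(ctx$upscalers, bad), "mismatch")
})

test_that("training-site predictions are unbiased on the log scale", {
  ctx <- small_ctx()
  rec <- ctx$records
  pred <- predict(ctx$upscalers$tau[[2]], rec)
  expect_lt(abs(mean(log10(pred) - log10(rec$tau_slow))), 0.02)
})

test_that("extrapolation flags match a brute-force range check", {
  ctx <- small_ctx()
  w <- small_world()
  flags <- extrapolation_flags(ctx$records, w$covariates)
  preds <- intersect(upscaling_predictors(), names(w$covariates))
  oracle <- rep(FALSE, nrow(w$covariates))
  for (p in preds) {
    r <- range(ctx$records[[p]])
    oracle <- oracle | w$covariates[[p]] < r[1] | w$covariates[[p]] > r[2]
  }
  expect_identical(flags, oracle)
  # inside-hull points are never flagged
  expect_false(any(extrapolation_flags(ctx$records,
                                       ctx$records[5:20, preds])))
  # pushing one predictor beyond the training maximum flags the cell
  one <- w$covariates[1, , drop = FALSE]
  one$MAT <- max(ctx$records$MAT) + 10
  expect_true(extrapolation_flags(ctx$records, one))
})
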