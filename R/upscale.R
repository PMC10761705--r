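# Upscaling of site-level turnover times and pool fractions to grids with
# gradient-boosted regression trees (grid-searched 10-fold CV, log10 target).

#' Predictor set used for upscaling
#'
#' Local climate (MAT, MAP), vegetation productivity (NDVI) and edaphic
#' properties (bulk density, pH, organic carbon, total nitrogen, C:N ratio,
#' silt and sand content).
#'
#' @return character vector of predictor column names.
#' @export
upscaling_predictors <- function() {
  c("MAT", "MAP", "NDVI", "BD", "pH", "SOC_pct", "TN", "CN", "silt", "sand")
}

#' Default cross-validation grid for the boosted-tree upscaler
#'
#' @return list of hyperparameter vectors crossed during grid search.
#' @export
default_cv_config <- function() {
  list(eta = c(0.05, 0.1), max_depth = c(2, 3), nrounds = c(300, 600),
       subsample = 0.8, nfold = 10)
}

#' Fit a boosted-regression-tree model of log10 turnover time
#'
#' Learns the covariate-to-turnover mapping from site records with
#' gradient-boosted regression trees. The target is log10-transformed;
#' hyperparameters are chosen by grid search minimizing 10-fold
#' cross-validation RMSE; records with missing predictors are dropped with
#' a warning (no imputation). Relative variable importances (gain) are
#' normalized to sum to 100%.
#'
#' @param records data.frame of site records containing the target column
#'   and the predictors of \code{\link{upscaling_predictors}}; >= 30 rows.
#' @param target column name of the (positive) response, e.g.
#'   \code{"tau_fast"} or \code{"f_slow"}.
#' @param cv_config hyperparameter grid, see \code{\link{default_cv_config}}.
#' @param seed integer RNG seed (controls CV folds and subsampling).
#' @return object of class \code{"tau_model"} with the fitted booster, the
#'   selected hyperparameters, \code{cv_rmse} and \code{cv_r2} (on the log10
#'   scale), the importance table and the training predictor ranges.
#' @export
fit_tau_model <- function(records, target, cv_config = default_cv_config(),
                          seed = 1) {
  cfg <- utils::modifyList(default_cv_config(), cv_config)
  preds <- upscaling_predictors()
  missing_cols <- setdiff(c(target, preds), names(records))
  if (length(missing_cols) > 0)
    stop("records lack columns: ", paste(missing_cols, collapse = ", "))
  ok <- stats::complete.cases(records[, c(target, preds)])
  if (any(!ok))
    warning(sum(!ok), " records dropped for missing predictors (no imputation)")
  records <- records[ok, , drop = FALSE]
  if (nrow(records) < 30) stop("need at least 30 complete records")
  x <- as.matrix(records[, preds])
  y <- log10(records[[target]])
  if (any(!is.finite(y))) stop("target must be positive for the log10 transform")
  dtrain <- xgboost::xgb.DMatrix(x, label = y)

  grid <- expand.grid(eta = cfg$eta, max_depth = cfg$max_depth,
                      nrounds = cfg$nrounds, subsample = cfg$subsample)
  cv_rmse <- rep(NA_real_, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    set.seed(as.integer(seed))
    cv <- xgboost::xgb.cv(
      params = list(objective = "reg:squarederror", eta = grid$eta[g],
                    max_depth = grid$max_depth[g],
                    subsample = grid$subsample[g], nthread = 1),
      data = dtrain, nrounds = grid$nrounds[g], nfold = cfg$nfold,
      verbose = 0)
    cv_rmse[g] <- utils::tail(cv$evaluation_log$test_rmse_mean, 1)
  }
  best <- which.min(cv_rmse)
  vy <- stats::var(y)
  cv_r2 <- if (vy > 0) 1 - cv_rmse[best]^2 / vy else 0

  set.seed(as.integer(seed))
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = grid$eta[best],
                  max_depth = grid$max_depth[best],
                  subsample = grid$subsample[best], nthread = 1),
    data = dtrain, nrounds = grid$nrounds[best])

  imp <- tryCatch(as.data.frame(xgboost::xgb.importance(model = booster)),
                  error = function(e) NULL)
  importance <- stats::setNames(rep(0, length(preds)), preds)
  if (!is.null(imp) && nrow(imp) > 0)
    importance[imp$Feature] <- 100 * imp$Gain / sum(imp$Gain)

  structure(list(booster = booster, target = target, predictors = preds,
                 best = grid[best, , drop = FALSE],
                 cv_rmse = cv_rmse[best], cv_r2 = cv_r2,
                 importance = importance,
                 predictor_ranges = apply(x, 2, range),
                 n_records = nrow(records), seed = seed),
            class = "tau_model")
}

#' @export
print.tau_model <- function(x, ...) {
  cat(sprintf("Boosted-tree upscaler for %s (n = %d sites)\n",
              x$target, x$n_records))
  cat(sprintf("  CV RMSE %.4f (log10), CV R2 %.3f; eta %.2f, depth %d, %d trees\n",
              x$cv_rmse, x$cv_r2, x$best$eta, x$best$max_depth, x$best$nrounds))
  top <- sort(x$importance, decreasing = TRUE)[1:3]
  cat(sprintf("  top importances: %s\n",
              paste(sprintf("%s %.0f%%", names(top), top), collapse = ", ")))
  invisible(x)
}

#' @export
predict.tau_model <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$predictors])
  10^stats::predict(object$booster, x)
}

#' Predict gridded turnover-time and fraction maps with uncertainty
#'
#' Forces fitted upscalers with each covariate source combination, then
#' reports the per-cell mean and standard deviation across combinations.
#' Predictions are made on the log10 scale and back-transformed before
#' averaging; pool fractions are renormalized to sum to one per cell.
#'
#' @param models list with \code{tau} (list of 3 \code{tau_model}s for
#'   fast/slow/passive) and optionally \code{fractions} (list of 3 models of
#'   the pool fractions).
#' @param combos named list of covariate data.frames, one per source
#'   combination, all on the same grid.
#' @return object of class \code{"tau_maps"}: per-pool \code{tau_mean} and
#'   \code{tau_sd} (cells x 3, yr at 15 C), \code{fractions} (cells x 3,
#'   summing to 1), and \code{tau_weighted} (carbon-weighted turnover time).
#' @export
predict_maps <- function(models, combos) {
  n <- vapply(combos, nrow, integer(1))
  if (length(unique(n)) != 1)
    stop("covariate grids mismatch: ", paste(n, collapse = " vs "))
  nc <- n[1]; nk <- length(combos)
  tau_mean <- tau_sd <- matrix(NA_real_, nc, 3,
                               dimnames = list(NULL, c("tau_fast", "tau_slow",
                                                       "tau_passive")))
  for (p in 1:3) {
    pred <- vapply(combos, function(cv) predict(models$tau[[p]], cv),
                   numeric(nc))
    pred <- matrix(pred, nc, nk)
    tau_mean[, p] <- rowMeans(pred)
    tau_sd[, p] <- if (nk > 1) apply(pred, 1, stats::sd) else 0
  }
  fractions <- NULL
  if (!is.null(models$fractions)) {
    fr <- matrix(0, nc, 3, dimnames = list(NULL, c("f_fast", "f_slow",
                                                   "f_passive")))
    for (ci in seq_len(nk)) {
      f1 <- vapply(1:3, function(p) predict(models$fractions[[p]],
                                            combos[[ci]]), numeric(nc))
      fr <- fr + f1 / rowSums(f1)
    }
    fractions <- fr / nk
    fractions <- fractions / rowSums(fractions)
  }
  tw <- if (!is.null(fractions)) weighted_tau(tau_mean, fractions) else NULL
  structure(list(tau_mean = tau_mean, tau_sd = tau_sd,
                 fractions = fractions, tau_weighted = tw, n_combos = nk),
            class = "tau_maps")
}

#' @export
print.tau_maps <- function(x, ...) {
  cat(sprintf("Gridded turnover-time maps (%d cells, %d source combinations)\n",
              nrow(x$tau_mean), x$n_combos))
  med <- apply(x$tau_mean, 2, stats::median)
  cat(sprintf("  median tau (yr at 15 C): fast %.2f, slow %.1f, passive %.0f\n",
              med[1], med[2], med[3]))
  if (!is.null(x$tau_weighted))
    cat(sprintf("  median carbon-weighted tau: %.0f yr\n",
                stats::median(x$tau_weighted)))
  invisible(x)
}

#' Carbon-weighted turnover time
#'
#' \deqn{\tau_w = \sum_p \tau_p f_p} per cell; fractions must sum to one.
#'
#' @param tau_per_pool cells x 3 matrix of pool turnover times (yr).
#' @param fractions cells x 3 matrix of pool fractions summing to 1.
#' @return vector of carbon-weighted turnover times (yr).
#' @export
weighted_tau <- function(tau_per_pool, fractions) {
  tau_per_pool <- as.matrix(tau_per_pool); fractions <- as.matrix(fractions)
  if (any(abs(rowSums(fractions) - 1) > 1e-6))
    stop("fractions must sum to 1 per cell")
  rowSums(tau_per_pool * fractions)
}

#' Flag grid cells outside the training covariate hull
#'
#' A cell is flagged when any predictor lies outside the [min, max] range of
#' the training sites (a rectangular extrapolation check).
#'
#' @param records training site records.
#' @param covariate_grid data.frame of per-cell predictors.
#' @param predictors predictor names; default \code{\link{upscaling_predictors}}.
#' @return logical vector, TRUE where extrapolating.
#' @export
extrapolation_flags <- function(records, covariate_grid,
                                predictors = upscaling_predictors()) {
  predictors <- intersect(predictors, intersect(names(records),
                                                names(covariate_grid)))
  flag <- rep(FALSE, nrow(covariate_grid))
  for (p in predictors) {
    r <- range(records[[p]], na.rm = TRUE)
    flag <- flag | covariate_grid[[p]] < r[1] | covariate_grid[[p]] > r[2]
  }
  flag
}

#' Fit the full set of upscalers (turnover times and fractions)
#'
#' Convenience wrapper fitting one boosted-tree model per pool for log10
#' turnover time and one per pool for the fractions, reusing the same
#' cross-validated configuration.
#'
#' @param records site records (see \code{\link{gen_sites}}).
#' @param cv_config hyperparameter grid.
#' @param seed integer RNG seed.
#' @return list with \code{tau} and \code{fractions} model lists, suitable
#'   for \code{\link{predict_maps}}.
#' @export
fit_upscalers <- function(records, cv_config = default_cv_config(), seed = 1) {
  tau_targets <- c("tau_fast", "tau_slow", "tau_passive")
  f_targets <- c("f_fast", "f_slow", "f_passive")
  list(tau = lapply(tau_targets, function(tg)
         fit_tau_model(records, tg, cv_config, seed)),
       fractions = lapply(f_targets, function(tg)
         fit_tau_model(records, tg, cv_config, seed)))
}
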