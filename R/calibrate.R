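# Parameter diagnosis by seeded global search: iteratively shrinking
# uniform sampling around the incumbent optimum, vectorized over grid
# cells so one candidate evaluation runs the forward model for every cell
# at once.

# obj_fn takes an n_units x d parameter matrix and returns a length-n_units
# objective vector; returns list(par = n_units x d, value, evals).
# component_wise = TRUE perturbs one random coordinate per candidate, which
# escapes the anisotropic traps joint perturbations can fall into.
shrink_search <- function(obj_fn, lower, upper, n_units, rounds = 12,
                          pop = 40, shrink = 0.6, seed = 1,
                          component_wise = FALSE) {
  d <- length(lower)
  lo <- matrix(lower, n_units, d, byrow = TRUE)
  hi <- matrix(upper, n_units, d, byrow = TRUE)
  center <- (lo + hi) / 2
  best_val <- obj_fn(center)
  width <- (hi - lo) / 2
  set.seed(as.integer(seed))
  for (r in seq_len(rounds)) {
    for (j in seq_len(pop)) {
      pert <- (matrix(stats::runif(n_units * d), n_units, d) - 0.5) * 2 * width
      if (component_wise) {
        keep <- matrix(0, n_units, d)
        keep[cbind(seq_len(n_units), sample.int(d, n_units, replace = TRUE))] <- 1
        pert <- pert * keep
      }
      cand <- pmin(pmax(center + pert, lo), hi)
      val <- obj_fn(cand)
      better <- val < best_val
      if (any(better)) {
        center[better, ] <- cand[better, , drop = FALSE]
        best_val[better] <- val[better]
      }
    }
    width <- width * shrink
  }
  list(par = center, value = best_val, evals = rounds * pop + 1L)
}

#' Diagnose emulator transfer and moisture parameters per grid cell
#'
#' Calibrates (r_f, r_s, b) of the reduced-complexity model against an
#' ESM's pool trajectories, cell by cell. The emulator is initialized with
#' the ESM's historical pool state (end of 2000-2014) and run over the
#' scenario years; the objective is the sum over pools of the trajectory
#' RMSE normalized by the time-mean target stock of that pool (so all three
#' pools constrain the fit regardless of their very different sizes). The
#' optimizer is a seeded global search (shrinking uniform sampling around
#' the incumbent), vectorized across cells and deterministic under the
#' seed. Cells whose objective stays above \code{warn_tol} are flagged.
#'
#' @param esm_traj \code{pool_trajectory} of the target ESM pools over the
#'   scenario years (e.g. 2015-2100).
#' @param forcing scenario forcing over the same years.
#' @param state0 n x 3 initial pools (historical 2014 state).
#' @param fixed list of fixed parameters: \code{tau_i} (length 3),
#'   \code{Q10}, \code{T_ref}, \code{P_max}.
#' @param priors list of length-2 ranges for \code{r_f}, \code{r_s} (within
#'   [0,1]) and \code{b} (> 0); defaults r in [0,1], b in (0, 3].
#' @param seed integer RNG seed.
#' @param rounds,pop search-intensity controls.
#' @param warn_tol normalized-RMSE threshold above which a cell is flagged
#'   as not converged (default 0.05).
#' @return object of class \code{"emulator_fit"}: \code{params} (n x 3
#'   matrix of r_f, r_s, b), \code{objective} per cell, \code{flagged}
#'   logical, and the fixed parameters.
#' @export
calibrate_emulator <- function(esm_traj, forcing, state0, fixed,
                               priors = list(r_f = c(0, 1), r_s = c(0, 1),
                                             b = c(1e-3, 3)),
                               seed = 1, rounds = 12, pop = 40,
                               warn_tol = 0.05) {
  n <- nrow(state0)
  ny <- length(forcing$years)
  target <- esm_traj$stocks
  norm <- vapply(1:3, function(p) rowMeans(target[, p, ]), numeric(n))
  norm <- pmax(norm, .Machine$double.eps)
  inv_tau <- 1 / fixed$tau_i
  # precompute yearly climate factors independent of theta
  ftemp <- modifier_T(forcing$tas, fixed$Q10, fixed$T_ref)  # n x ny
  prn <- forcing$pr / fixed$P_max

  obj_for <- function(cells) {
    tg <- target[cells, , , drop = FALSE]
    nm <- norm[cells, , drop = FALSE]
    ft <- ftemp[cells, , drop = FALSE]
    pn <- prn[cells, , drop = FALSE]
    np <- forcing$npp[cells, , drop = FALSE]
    st <- state0[cells, , drop = FALSE]
    nc <- length(cells)
    function(theta) {
      r_f <- theta[, 1]; r_s <- theta[, 2]; b <- theta[, 3]
      cf <- st[, 1]; cs <- st[, 2]; cp <- st[, 3]
      sse <- matrix(0, nc, 3)
      for (y in seq_len(ny)) {
        env <- ft[, y] * pn[, y]^b
        k1 <- inv_tau[1] * env; k2 <- inv_tau[2] * env
        k3 <- inv_tau[3] * env
        n_sub <- max(1L, ceiling(max(k1) / 0.5))
        h <- 1 / n_sub
        npp <- np[, y]
        for (s in seq_len(n_sub)) {
          o1 <- k1 * cf; o2 <- k2 * cs; o3 <- k3 * cp
          cf <- cf + (npp - o1) * h
          cs <- cs + (o1 * r_f - o2) * h
          cp <- cp + (o2 * r_s - o3) * h
        }
        sse[, 1] <- sse[, 1] + (cf - tg[, 1, y])^2
        sse[, 2] <- sse[, 2] + (cs - tg[, 2, y])^2
        sse[, 3] <- sse[, 3] + (cp - tg[, 3, y])^2
      }
      rowSums(sqrt(sse / ny) / nm)
    }
  }
  obj <- obj_for(seq_len(n))

  lower <- c(priors$r_f[1], priors$r_s[1], priors$b[1])
  upper <- c(priors$r_f[2], priors$r_s[2], priors$b[2])
  fit <- shrink_search(obj, lower, upper, n, rounds = rounds, pop = pop,
                       seed = seed)
  params <- fit$par
  value <- fit$value
  # the greedy contraction occasionally strands individual cells at a poor
  # incumbent; re-search those cells from scratch with a fresh sample
  for (retry in 1:3) {
    bad <- which(value > warn_tol)
    if (length(bad) == 0) break
    refit <- shrink_search(obj_for(bad), lower, upper, length(bad),
                           rounds = 2 * rounds, pop = pop, shrink = 0.85,
                           seed = seed + retry, component_wise = TRUE)
    better <- refit$value < value[bad]
    params[bad[better], ] <- refit$par[better, , drop = FALSE]
    value[bad[better]] <- refit$value[better]
  }
  colnames(params) <- c("r_f", "r_s", "b")
  flagged <- value > warn_tol
  if (any(flagged))
    warning(sum(flagged), " cells above the convergence tolerance; ",
            "best-found parameters returned")
  structure(list(params = params, objective = fit$value, flagged = flagged,
                 fixed = fixed, evals = fit$evals, seed = seed),
            class = "emulator_fit")
}

#' @export
print.emulator_fit <- function(x, ...) {
  cat(sprintf("Emulator calibration: %d cells, %d objective evaluations/cell\n",
              nrow(x$params), x$evals))
  cat(sprintf("  median (r_f, r_s, b) = (%.3f, %.3f, %.3f); median objective %.2g\n",
              stats::median(x$params[, 1]), stats::median(x$params[, 2]),
              stats::median(x$params[, 3]), stats::median(x$objective)))
  if (any(x$flagged)) cat(sprintf("  %d cells flagged unconverged\n",
                                  sum(x$flagged)))
  invisible(x)
}

#' @export
coef.emulator_fit <- function(object, ...) object$params

#' Calibrate the refined model against observed stocks and turnover
#'
#' Optimizes the pool-specific temperature sensitivities (subject to the
#' carbon-quality ordering Q10_fast <= Q10_slow <= Q10_passive), the
#' precipitation exponent b and the transfer coefficients (r_f, r_s) so that
#' the refined model's closed-form steady state under the baseline
#' climatology matches the observed per-pool carbon stocks and the apparent
#' turnover time surrogate. The parameters are pooled across grid cells
#' (one set per data-source combination): a per-cell calibration of six
#' parameters against four per-cell constraints (three stocks and one
#' turnover time) is underdetermined, whereas pooling makes the problem
#' strongly overdetermined while spatial heterogeneity of the rates still
#' enters through the per-cell turnover-time maps, clay and climate.
#'
#' The objective is the equally weighted sum of the three per-pool
#' normalized RMSEs of the stocks and the mean squared error of log
#' apparent turnover time, over land cells with non-zero carbon.
#'
#' @param obs_stocks n x 3 observed pool stocks (gC m^-2): gridded SOC times
#'   per-pool fraction maps.
#' @param obs_tau_a observed apparent turnover time per cell (yr), e.g. a
#'   radiocarbon-derived surrogate.
#' @param clim list of per-cell climatological \code{tas}, \code{pr},
#'   \code{npp}.
#' @param tau n x 3 intrinsic turnover-time maps (yr at 15 C).
#' @param clay per-cell clay fraction.
#' @param P_max precipitation normalization constant (mm yr^-1).
#' @param mask logical land mask; cells with zero SOC are dropped.
#' @param priors list of length-2 ranges: \code{Q10} (first-pool value),
#'   \code{dQ10} (increments to slow and passive), \code{b}, \code{r_f},
#'   \code{r_s}.
#' @param root_frac root respiration as a fraction of NPP (default 0.07).
#' @param seed integer RNG seed.
#' @param rounds,pop global-search intensity.
#' @return object of class \code{"refined_fit"} with \code{Q10} (length 3),
#'   \code{b}, \code{r_f}, \code{r_s}, the achieved \code{objective} and
#'   search metadata.
#' @export
calibrate_refined <- function(obs_stocks, obs_tau_a, clim, tau, clay, P_max,
                              mask = rep(TRUE, nrow(obs_stocks)),
                              priors = list(Q10 = c(1, 4), dQ10 = c(0, 1.5),
                                            b = c(1e-3, 3), r_f = c(0, 1),
                                            r_s = c(0, 1)),
                              root_frac = 0.07, seed = 1,
                              rounds = 14, pop = 60) {
  keep <- mask & rowSums(obs_stocks) > 0 & is.finite(obs_tau_a)
  os <- obs_stocks[keep, , drop = FALSE]
  ot <- log(obs_tau_a[keep])
  tk <- tau[keep, , drop = FALSE]
  ck <- clay[keep]
  tas <- clim$tas[keep]; pr <- clim$pr[keep]; npp <- clim$npp[keep]
  pool_norm <- colMeans(os)

  eval_theta <- function(th) {
    q10 <- c(th[1], th[1] + th[2], th[1] + th[2] + th[3])
    params <- list(tau = tk, Q10 = q10, b = th[4], P_max = P_max,
                   clay = ck, r_f = th[5], r_s = th[6],
                   root_frac = root_frac, T_ref = 15)
    k <- refined_rates_climatology(params, tas, pr, npp)
    st <- steady_state(npp, k[, 1], k[, 2], k[, 3], th[5], th[6])
    nrmse <- vapply(1:3, function(p)
      sqrt(mean((st[, p] - os[, p])^2)) / pool_norm[p], numeric(1))
    ta <- apparent_turnover(st, k)
    sum(nrmse) + mean((log(ta) - ot)^2)
  }
  obj <- function(theta_mat) {
    apply(theta_mat, 1, eval_theta)
  }

  lower <- c(priors$Q10[1], priors$dQ10[1], priors$dQ10[1], priors$b[1],
             priors$r_f[1], priors$r_s[1])
  upper <- c(priors$Q10[2], priors$dQ10[2], priors$dQ10[2], priors$b[2],
             priors$r_f[2], priors$r_s[2])
  fit <- shrink_search(obj, lower, upper, 1, rounds = rounds, pop = pop,
                       shrink = 0.7, seed = seed)
  # a second, component-wise pass escapes curved-valley traps, then a local
  # polish refines whichever incumbent is better
  fit2 <- shrink_search(obj, lower, upper, 1, rounds = 2 * rounds, pop = pop,
                        shrink = 0.85, seed = seed + 1L,
                        component_wise = TRUE)
  th <- if (fit2$value[1] < fit$value[1]) fit2$par[1, ] else fit$par[1, ]
  val <- min(fit$value[1], fit2$value[1])
  for (start in list(th, (lower + upper) / 2)) {
    pol <- stats::optim(start, eval_theta, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 500))
    if (pol$value < val) { th <- pol$par; val <- pol$value }
  }
  structure(list(Q10 = c(th[1], th[1] + th[2], th[1] + th[2] + th[3]),
                 b = th[4], r_f = th[5], r_s = th[6],
                 objective = val, n_cells = sum(keep),
                 root_frac = root_frac, P_max = P_max, seed = seed),
            class = "refined_fit")
}

#' @export
print.refined_fit <- function(x, ...) {
  cat("Refined-model calibration (pooled over cells)\n")
  cat(sprintf("  Q10 (fast, slow, passive) = (%.2f, %.2f, %.2f); b = %.2f\n",
              x$Q10[1], x$Q10[2], x$Q10[3], x$b))
  cat(sprintf("  r_f = %.3f, r_s = %.3f; objective %.4g on %d cells\n",
              x$r_f, x$r_s, x$objective, x$n_cells))
  invisible(x)
}

#' @export
coef.refined_fit <- function(object, ...) {
  c(Q10_fast = object$Q10[1], Q10_slow = object$Q10[2],
    Q10_passive = object$Q10[3], b = object$b, r_f = object$r_f,
    r_s = object$r_s)
}
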