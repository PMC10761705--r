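#' Environmental rate modifiers
#'
#' Dimensionless multipliers applied to intrinsic decay rates.
#'
#' \code{modifier_T} is the Q10 temperature response
#' \eqn{F(T) = Q_{10}^{(T - T_{ref})/10}}; \code{modifier_P} the
#' precipitation response \eqn{F(P) = (P/P_{max})^b} with annual
#' precipitation normalized to the domain maximum; \code{modifier_M} the
#' mineral-protection scalar, a piecewise function of soil clay fraction
#' (linear below clay = 0.033, quadratic above); \code{modifier_RP} the
#' rhizosphere-priming scalar, a saturating (Michaelis–Menten) function of
#' root respiration that accelerates decomposition of older carbon
#' (values in (1/3.47, 1], applied to the slow and passive pools only).
#'
#' @param T_c temperature (degrees C).
#' @param Q10 temperature sensitivity (>= 1 typically).
#' @param T_ref reference temperature (degrees C).
#' @name modifiers
#' @return numeric modifier value(s), dimensionless and positive.
NULL

#' @rdname modifiers
#' @export
modifier_T <- function(T_c, Q10, T_ref) Q10^((T_c - T_ref) / 10)

#' @rdname modifiers
#' @param P annual precipitation (mm yr^-1).
#' @param P_max maximal annual precipitation for normalization (mm yr^-1).
#' @param b precipitation exponent (> 0).
#' @export
modifier_P <- function(P, P_max, b) {
  if (any(P_max <= 0)) stop("P_max must be positive")
  (P / P_max)^b
}

#' @rdname modifiers
#' @param clay clay fraction in [0, 1].
#' @export
modifier_M <- function(clay) {
  if (any(clay < 0 | clay > 1)) stop("clay fraction must lie in [0,1]")
  ifelse(clay < 0.033, 24.2 * clay, -2.1 * clay^2 + 6.2 * clay + 0.6)
}

#' @rdname modifiers
#' @param R_root root respiration (gC m^-2 yr^-1), >= 0.
#' @export
modifier_RP <- function(R_root) {
  if (any(R_root < 0)) stop("R_root must be non-negative")
  1 / (1 + 2.47 * R_root / (13.01 + R_root))
}

#' Actual decay rate in the reduced-complexity (ESM emulator) model
#'
#' \deqn{k = \frac{1}{\tau_i} Q_{10}^{(T-T_{ref})/10} (P/P_{max})^b}
#'
#' @param tau_i intrinsic turnover time (yr).
#' @param T_c temperature (degrees C).
#' @param P annual precipitation (mm yr^-1).
#' @param params list with \code{Q10}, \code{T_ref}, \code{b}, \code{P_max}.
#' @return actual decay rate (yr^-1), same shape as the broadcast inputs.
#' @export
actual_decay_rate <- function(tau_i, T_c, P, params) {
  (1 / tau_i) * modifier_T(T_c, params$Q10, params$T_ref) *
    modifier_P(P, params$P_max, params$b)
}

#' Actual decay rate in the refined (observationally constrained) model
#'
#' Adds mineral protection and rhizosphere priming to the climate modifiers:
#' \deqn{k = \frac{1}{\tau_i} F(T) F(P) F(M) F(RP)}
#' with pool-specific Q10 (reference temperature 15 C) and F(RP) applied
#' only to the slow and passive pools (priming acts on older carbon).
#'
#' @param pool 1 (fast), 2 (slow) or 3 (passive).
#' @param tau_i intrinsic turnover time at 15 C (yr).
#' @param T_c temperature (degrees C).
#' @param P annual precipitation (mm yr^-1).
#' @param clay clay fraction in [0,1].
#' @param R_root root respiration (gC m^-2 yr^-1).
#' @param params list with per-pool \code{Q10} (length 3), \code{b},
#'   \code{P_max}, and optionally \code{T_ref} (default 15).
#' @return decay rate (yr^-1).
#' @export
refined_decay_rate <- function(pool, tau_i, T_c, P, clay, R_root, params) {
  stopifnot(pool %in% 1:3)
  T_ref <- if (is.null(params$T_ref)) 15 else params$T_ref
  q10 <- if (length(params$Q10) >= 3) params$Q10[[pool]] else params$Q10
  frp <- if (pool == 1) 1 else modifier_RP(R_root)
  (1 / tau_i) * modifier_T(T_c, q10, T_ref) *
    modifier_P(P, params$P_max, params$b) * modifier_M(clay) * frp
}

#' Closed-form steady state of the three-pool cascade
#'
#' Setting the pool balance equations to zero under constant input and
#' rates gives \eqn{C_f^* = NPP/k_f}, \eqn{C_s^* = r_f NPP / k_s},
#' \eqn{C_p^* = r_f r_s NPP / k_p}.
#'
#' @param NPP carbon input (gC m^-2 yr^-1); vectorized over cells.
#' @param k_f,k_s,k_p decay rates (yr^-1).
#' @param r_f,r_s transfer coefficients in [0,1].
#' @return matrix with columns \code{C_f}, \code{C_s}, \code{C_p}.
#' @export
steady_state <- function(NPP, k_f, k_s, k_p, r_f, r_s) {
  cf <- NPP / k_f
  cs <- r_f * NPP / k_s
  cp <- r_f * r_s * NPP / k_p
  m <- cbind(C_f = cf, C_s = cs, C_p = cp)
  m
}

#' Advance the three-pool cascade by one forcing interval
#'
#' Explicit Euler update of the cascade
#' \deqn{\dot C_f = NPP - k_f C_f;\quad \dot C_s = r_f k_f C_f - k_s C_s;
#'   \quad \dot C_p = r_s k_s C_s - k_p C_p}
#' with automatic sub-stepping whenever \eqn{k \cdot dt \ge 0.5} for any
#' pool and cell, preserving non-negativity. All arguments are vectorized
#' over grid cells (rows).
#'
#' @param state n x 3 matrix (C_f, C_s, C_p), gC m^-2.
#' @param npp carbon input over the interval (gC m^-2 yr^-1), length n.
#' @param k n x 3 matrix of decay rates (yr^-1), constant over the interval.
#' @param r_f,r_s transfer coefficients.
#' @param dt interval length (yr), default 1.
#' @return updated n x 3 state matrix; attribute \code{"respired"} holds the
#'   heterotrophic respiration integrated over the interval (gC m^-2).
#' @export
step_pools <- function(state, npp, k, r_f, r_s, dt = 1) {
  if (anyNA(npp) || anyNA(k)) {
    bad <- which(is.na(npp) | rowSums(is.na(k)) > 0)[1]
    stop("NaN forcing at cell ", bad)
  }
  n_sub <- max(1L, ceiling(max(k) * dt / 0.5))
  h <- dt / n_sub
  resp <- numeric(nrow(state))
  cf <- state[, 1]; cs <- state[, 2]; cp <- state[, 3]
  kf <- k[, 1]; ks <- k[, 2]; kp <- k[, 3]
  for (s in seq_len(n_sub)) {
    out_f <- kf * cf; out_s <- ks * cs; out_p <- kp * cp
    resp <- resp + (out_f * (1 - r_f) + out_s * (1 - r_s) + out_p) * h
    cf <- cf + (npp - out_f) * h
    cs <- cs + (out_f * r_f - out_s) * h
    cp <- cp + (out_s * r_s - out_p) * h
  }
  new <- cbind(C_f = cf, C_s = cs, C_p = cp)
  attr(new, "respired") <- resp
  new
}

#' Run the three-pool cascade over a yearly forcing series
#'
#' @param state0 n x 3 initial state (gC m^-2).
#' @param forcing list with \code{years} and n x n_years matrices
#'   \code{npp}, \code{tas}, \code{pr}.
#' @param rates_fn function(year_index) returning the n x 3 rate matrix
#'   (yr^-1) for that year.
#' @param r_f,r_s transfer coefficients.
#' @return object of class \code{"pool_trajectory"}: list with \code{years},
#'   \code{stocks} (n x 3 x n_years array of end-of-year states),
#'   \code{respired} (n x n_years), and \code{state0}.
#' @export
run_pools <- function(state0, forcing, rates_fn, r_f, r_s) {
  ny <- length(forcing$years)
  n <- nrow(state0)
  stocks <- array(NA_real_, c(n, 3, ny))
  respired <- matrix(NA_real_, n, ny)
  st <- state0
  for (y in seq_len(ny)) {
    k <- rates_fn(y)
    st <- step_pools(st, forcing$npp[, y], k, r_f, r_s)
    respired[, y] <- attr(st, "respired")
    attr(st, "respired") <- NULL
    stocks[, , y] <- st
  }
  structure(list(years = forcing$years, stocks = stocks,
                 respired = respired, state0 = state0),
            class = "pool_trajectory")
}

#' @export
print.pool_trajectory <- function(x, ...) {
  ny <- length(x$years)
  cat(sprintf("Three-pool trajectory: %d cells, years %d-%d\n",
              dim(x$stocks)[1], x$years[1], x$years[ny]))
  tot <- colSums(x$stocks[, , ny, drop = FALSE][, , 1])
  cat(sprintf("  final mean stocks (gC m-2): fast %.4g, slow %.4g, passive %.4g\n",
              mean(x$stocks[, 1, ny]), mean(x$stocks[, 2, ny]),
              mean(x$stocks[, 3, ny])))
  invisible(x)
}

# per-year rate matrices for the emulator parameterization
emulator_rates_fn <- function(params, forcing) {
  inv_tau <- 1 / params$tau_i
  function(y) {
    ft <- modifier_T(forcing$tas[, y], params$Q10, params$T_ref)
    fp <- modifier_P(forcing$pr[, y], params$P_max, params$b)
    env <- ft * fp
    cbind(inv_tau[1] * env, inv_tau[2] * env, inv_tau[3] * env)
  }
}

# per-year rate matrices for the refined parameterization
# params: tau (n x 3 matrix, or length 3 of uniform values), Q10 (scalar,
# length 3, or n x 3), b, P_max, clay (n), root_frac (default 0.07),
# T_ref (default 15). use_M / use_RP toggle the mineral-protection and
# priming modifiers (both TRUE for the refined model, FALSE reduces to the
# climate-only model with possibly pool-specific Q10).
refined_rates_fn <- function(params, forcing) {
  T_ref <- if (is.null(params$T_ref)) 15 else params$T_ref
  root_frac <- if (is.null(params$root_frac)) 0.07 else params$root_frac
  use_M <- if (is.null(params$use_M)) TRUE else isTRUE(params$use_M)
  use_RP <- if (is.null(params$use_RP)) TRUE else isTRUE(params$use_RP)
  n <- length(forcing$tas[, 1])
  tau <- params$tau
  taumat <- if (is.matrix(tau)) tau else matrix(tau, n, 3, byrow = TRUE)
  fm <- if (use_M) modifier_M(params$clay) else 1
  q10 <- params$Q10
  qmat <- if (is.matrix(q10)) q10 else
    matrix(q10, n, if (length(q10) == 1) 3 else length(q10), byrow = TRUE)
  function(y) {
    fp <- modifier_P(forcing$pr[, y], params$P_max, params$b)
    frp <- if (use_RP) modifier_RP(root_frac * forcing$npp[, y]) else 1
    dT <- (forcing$tas[, y] - T_ref) / 10
    k <- matrix(NA_real_, n, 3)
    for (p in 1:3) {
      k[, p] <- (1 / taumat[, p]) * qmat[, p]^dT * fp * fm *
        (if (p == 1) 1 else frp)
    }
    k
  }
}

#' Simulate the reduced-complexity emulator over a forcing series
#'
#' @param params emulator parameters: \code{tau_i} (length 3, yr),
#'   \code{Q10}, \code{T_ref}, \code{b}, \code{P_max}, \code{r_f}, \code{r_s}.
#' @param forcing yearly forcing list (\code{years}, \code{npp}, \code{tas},
#'   \code{pr} as cells x years matrices).
#' @param state0 n x 3 initial pools.
#' @return a \code{pool_trajectory}.
#' @export
run_emulator <- function(params, forcing, state0) {
  run_pools(state0, forcing, emulator_rates_fn(params, forcing),
            params$r_f, params$r_s)
}

#' Simulate the refined constrained model over a forcing series
#'
#' @param params refined parameters: \code{tau} (n x 3 map of intrinsic
#'   turnover times at 15 C), \code{Q10} (length 3, carbon-quality ordered),
#'   \code{b}, \code{P_max}, \code{clay} (n), \code{r_f}, \code{r_s},
#'   optional \code{root_frac} (default 0.07) and \code{T_ref} (default 15).
#' @param forcing yearly forcing list.
#' @param state0 n x 3 initial pools.
#' @return a \code{pool_trajectory}.
#' @export
run_refined <- function(params, forcing, state0) {
  run_pools(state0, forcing, refined_rates_fn(params, forcing),
            params$r_f, params$r_s)
}

#' Refined-model decay rates under climatological forcing
#'
#' @param params refined parameter list (see \code{\link{run_refined}}).
#' @param tas,pr,npp climatological per-cell forcing vectors.
#' @return n x 3 matrix of decay rates (yr^-1).
#' @export
refined_rates_climatology <- function(params, tas, pr, npp) {
  f <- refined_rates_fn(params, list(tas = cbind(tas), pr = cbind(pr),
                                     npp = cbind(npp)))
  f(1)
}

#' Apparent (realized) turnover time of a pool ensemble
#'
#' Flux-weighted whole-soil turnover time
#' \deqn{\tau_a = \frac{C_f + C_s + C_p}{k_f C_f + k_s C_s + k_p C_p}}
#' the quantity surrogated by radiocarbon-derived carbon age.
#'
#' @param state n x 3 pool stocks.
#' @param k n x 3 decay rates (yr^-1).
#' @return numeric vector of apparent turnover times (yr).
#' @export
apparent_turnover <- function(state, k) {
  rowSums(state) / rowSums(state * k)
}

#' Spin the refined model up to steady state
#'
#' Repeatedly cycles the model through the supplied baseline yearly forcing
#' (canonically 2000-2014) until the 15-year mean imbalance between carbon
#' input and simulated decomposition is below tolerance in every land cell:
#' |mean(NPP - decomposition)| < tol * mean(NPP). Because
#' d(total)/dt = NPP - decomposition holds exactly for the integrator, the
#' cycle-mean imbalance equals the net stock drift per year over the cycle.
#' Unless an initial state is given, pools start from the closed-form steady
#' state under the cycle-mean climatology, which typically converges within
#' a few cycles.
#'
#' @param params refined parameter list (see \code{\link{run_refined}}).
#' @param forcing baseline yearly forcing (cells x years).
#' @param tol relative tolerance on the NPP-decomposition balance, default
#'   0.001 (0.1% of mean NPP).
#' @param max_cycles maximum number of forcing cycles (>= 30 recommended;
#'   default 60).
#' @param init optional n x 3 initial state.
#' @return list with \code{state} (n x 3), \code{cycles} used,
#'   \code{converged} (logical per cell), \code{last_cycle} (the
#'   \code{pool_trajectory} of the final cycle).
#' @export
spin_up <- function(params, forcing, tol = 0.001, max_cycles = 60,
                    init = NULL) {
  if (max_cycles < 1) stop("max_cycles must be positive")
  npp_bar <- rowMeans(forcing$npp)
  if (is.null(init)) {
    k0 <- refined_rates_climatology(params, rowMeans(forcing$tas),
                                    rowMeans(forcing$pr), npp_bar)
    init <- steady_state(npp_bar, k0[, 1], k0[, 2], k0[, 3],
                         params$r_f, params$r_s)
  }
  ny <- length(forcing$years)
  st <- init
  cycles <- 0L; traj <- NULL
  repeat {
    cycles <- cycles + 1L
    total0 <- rowSums(st)
    traj <- run_pools(st, forcing, refined_rates_fn(params, forcing),
                      params$r_f, params$r_s)
    st <- traj$stocks[, , ny]
    imbalance <- (rowSums(st) - total0) / ny   # = mean(NPP - decomposition)
    converged <- abs(imbalance) < tol * pmax(npp_bar, .Machine$double.eps)
    if (all(converged) || cycles >= max_cycles) break
  }
  list(state = st, cycles = cycles, converged = converged, last_cycle = traj)
}

#' Project the refined model forward under scenario forcing
#'
#' Runs the calibrated refined model from an initial (spun-up) state over
#' bias-corrected scenario forcing (canonically 2015-2100).
#'
#' @param params refined parameter list.
#' @param state0 n x 3 initial pools.
#' @param forcing corrected scenario forcing (cells x years).
#' @return a \code{pool_trajectory}.
#' @export
project <- function(params, state0, forcing) {
  run_refined(params, forcing, state0)
}
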