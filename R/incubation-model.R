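#' Three-pool decomposition parameters
#'
#' Constructor and validator for the parameter set of the three-pool soil
#' carbon decomposition model: pool-specific first-order decay rates
#' \code{k = (k_fast, k_slow, k_passive)} in d^-1 and partition coefficients
#' \code{f = (f_fast, f_slow, f_passive)} that allocate the initial carbon
#' \code{C_tot} among the pools.
#'
#' Validity requires \code{k_fast > k_slow > k_passive > 0}, each fraction in
#' \code{[0, 1]} and the fractions summing to one (tolerance 1e-9).
#'
#' @param k numeric length-3 vector of decay rates (d^-1), fast/slow/passive.
#' @param f numeric length-3 vector of pool fractions, summing to 1.
#' @return An object of class \code{"pool_params"}: a list with elements
#'   \code{k} and \code{f}.
#' @examples
#' pool_params(k = c(0.01, 5e-4, 8e-6), f = c(0.02, 0.15, 0.83))
#' @export
pool_params <- function(k, f) {
  stopifnot(length(k) == 3, length(f) == 3)
  if (!all(is.finite(k)) || !all(is.finite(f)))
    stop("pool parameters must be finite")
  if (!(k[1] > k[2] && k[2] > k[3] && k[3] > 0))
    stop("decay rates must satisfy k_fast > k_slow > k_passive > 0")
  if (any(f < 0) || any(f > 1) || abs(sum(f) - 1) > 1e-9)
    stop("fractions must lie in [0,1] and sum to 1")
  structure(list(k = as.numeric(k), f = as.numeric(f)), class = "pool_params")
}

#' Forward model: total CO2 flux of a decaying three-pool soil
#'
#' Total soil respiration from independent first-order depletion of each
#' pool: \deqn{R(t) = \sum_p k_p C_{tot} f_p e^{-k_p t}} so that
#' \eqn{R(0) = \sum_p k_p C_{tot} f_p} and the integral of the flux over
#' \eqn{[0, \infty)} equals \code{C_tot} (mass exhaustion).
#'
#' @param params a \code{\link{pool_params}} object (or a list with \code{k},
#'   \code{f}).
#' @param C_tot initial total carbon (mgC g^-1 dry weight); must be positive.
#' @param times numeric vector of times (days); must be non-negative.
#' @return numeric vector of fluxes (mgC g^-1 d^-1) at \code{times}.
#' @export
forward_flux <- function(params, C_tot, times) {
  if (!is.numeric(C_tot) || C_tot <= 0) stop("C_tot must be positive")
  if (any(times < 0)) stop("negative time not allowed")
  k <- params$k; f <- params$f
  # outer(times, k): n x 3 matrix of k_p * t
  drop(exp(-outer(times, k)) %*% (k * f)) * C_tot
}

#' Gaussian log-likelihood of an incubation flux series
#'
#' Log of the likelihood of observed fluxes given three-pool parameters,
#' assuming i.i.d. zero-mean Gaussian measurement errors with standard
#' deviation \code{sigma}: \eqn{-\frac{1}{2\sigma^2}\sum_t (S(t)-O(t))^2}
#' up to an additive constant independent of the parameters.
#'
#' @param params \code{\link{pool_params}}.
#' @param series an \code{\link{incubation_series}} (list with \code{times},
#'   \code{fluxes}, \code{C_tot}).
#' @param sigma positive error standard deviation (flux units).
#' @return scalar log-likelihood (unnormalized).
#' @export
log_likelihood <- function(params, series, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  if (length(series$times) != length(series$fluxes))
    stop("times and fluxes differ in length")
  s <- forward_flux(params, series$C_tot, series$times)
  -sum((s - series$fluxes)^2) / (2 * sigma^2)
}

#' Incubation CO2-flux time series
#'
#' Container for one site's incubation record: flux observations plus the
#' metadata needed for screening and temperature normalization.
#'
#' @param site_id site identifier.
#' @param times observation times in days since incubation start, strictly
#'   increasing.
#' @param fluxes CO2 fluxes (mgC g^-1 dw d^-1), non-negative.
#' @param C_tot initial total soil carbon (mgC g^-1 dw), positive.
#' @param incubation_T incubation temperature (degrees C).
#' @param metadata named list; recognized entries include \code{lat},
#'   \code{lon}, \code{MAT}, \code{MAP}, \code{depth_cm}, \code{biome},
#'   \code{substrate_added} (logical) and \code{aerobic} (logical).
#' @return object of class \code{"incubation_series"}.
#' @export
incubation_series <- function(site_id, times, fluxes, C_tot, incubation_T,
                              metadata = list()) {
  if (length(times) != length(fluxes)) stop("times/fluxes length mismatch")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(fluxes < 0)) stop("fluxes must be non-negative")
  if (!is.numeric(C_tot) || length(C_tot) != 1 || is.na(C_tot) || C_tot <= 0)
    stop("C_tot must be a positive scalar")
  structure(list(site_id = site_id, times = as.numeric(times),
                 fluxes = as.numeric(fluxes), C_tot = C_tot,
                 incubation_T = incubation_T,
                 duration = max(times), metadata = metadata),
            class = "incubation_series")
}

#' Screen incubation records against the inclusion criteria
#'
#' A record is kept only if (in this order of checking): it is parseable
#' (times and fluxes present, equal length, non-empty); the incubation lasted
#' at least 180 days (six months); it was aerobic; the initial carbon
#' concentration is available; no substrate was added; and respiration in the
#' initial phase exceeds that at the end (mean flux over the first 10% of
#' observation times greater than the mean over the last 10%). Each rejected
#' record is labelled with the first failing criterion.
#'
#' @param records list of \code{\link{incubation_series}} objects (possibly
#'   malformed lists, which are rejected as \code{"unparseable"}).
#' @return list with \code{kept} (list of records) and \code{rejected}
#'   (data.frame with \code{site_id}, \code{reason}).
#' @export
screen_records <- function(records) {
  kept <- list(); rej_id <- character(0); rej_reason <- character(0)
  for (rec in records) {
    id <- if (!is.null(rec$site_id)) as.character(rec$site_id) else NA_character_
    reason <- screen_one(rec)
    if (is.na(reason)) kept[[length(kept) + 1L]] <- rec
    else { rej_id <- c(rej_id, id); rej_reason <- c(rej_reason, reason) }
  }
  list(kept = kept,
       rejected = data.frame(site_id = rej_id, reason = rej_reason,
                             stringsAsFactors = FALSE))
}

screen_one <- function(rec) {
  t <- rec$times; fl <- rec$fluxes
  if (is.null(t) || is.null(fl) || length(t) == 0 ||
      length(t) != length(fl) || anyNA(t) || anyNA(fl)) return("unparseable")
  dur <- if (!is.null(rec$duration)) rec$duration else max(t)
  if (dur < 180) return("duration")
  aerobic <- isTRUE(rec$metadata$aerobic)
  if (!aerobic) return("aerobic")
  if (is.null(rec$C_tot) || is.na(rec$C_tot) || rec$C_tot <= 0) return("c_tot")
  if (isTRUE(rec$metadata$substrate_added)) return("substrate")
  span <- diff(range(t))
  early <- fl[t <= min(t) + 0.1 * span]
  late <- fl[t >= max(t) - 0.1 * span]
  if (!(mean(early) > mean(late))) return("decline")
  NA_character_
}

#' Default temperature-dependent Q10 function
#'
#' Decomposition Q10 declines with temperature in laboratory syntheses; this
#' default is a piecewise-linear curve from 3.0 at 0 degrees C to 1.8 at
#' 35 degrees C, held constant outside that range. Replace it with any
#' function of temperature returning a positive scalar when an empirical
#' curve is available.
#'
#' @param T_c temperature in degrees C (vectorized).
#' @return Q10 value(s).
#' @export
default_q10 <- function(T_c) {
  tt <- pmin(pmax(T_c, 0), 35)
  3.0 + (1.8 - 3.0) * tt / 35
}

#' Normalize a turnover time to a reference temperature
#'
#' Converts a turnover time inverted at the incubation temperature to the
#' 15 degree C reference:
#' \deqn{\tau_{15} = \tau_T \cdot Q_{10}^{(T - T_{ref})/10}}
#' with a (possibly temperature-dependent) Q10 evaluated at the incubation
#' temperature.
#'
#' @param tau turnover time (yr), positive.
#' @param T_inc incubation temperature (degrees C).
#' @param q10_fn function of temperature returning Q10 (> 0); default
#'   \code{\link{default_q10}}.
#' @param T_ref reference temperature, default 15.
#' @return turnover time (yr) at \code{T_ref}.
#' @export
normalize_to_reference <- function(tau, T_inc, q10_fn = default_q10,
                                   T_ref = 15) {
  if (any(tau <= 0)) stop("tau must be positive")
  q10 <- q10_fn(T_inc)
  if (any(!is.finite(q10)) || any(q10 <= 0))
    stop("q10_fn must return positive values")
  tau * q10^((T_inc - T_ref) / 10)
}

#' Arrhenius-based normalization to a reference temperature
#'
#' Alternative temperature scaling used in sensitivity analysis: rates follow
#' \eqn{k \propto e^{-E_a/(R T_K)}}, and since \eqn{\tau \propto 1/k},
#' \deqn{\tau_{ref} = \tau_T \cdot k(T_{inc})/k(T_{ref})
#'   = \tau_T \exp\{ E_a/R (1/T_{K,ref} - 1/T_{K,inc}) \}.}
#' The default activation energy reproduces Q10 = 2 at 15 degrees C.
#'
#' @param tau turnover time (yr) at \code{T_inc}.
#' @param T_inc incubation temperature (degrees C).
#' @param Ea activation energy (J mol^-1). The default solves
#'   \eqn{Q_{10} = \exp\{E_a/R (1/T_K - 1/(T_K+10))\} = 2} at 15 C.
#' @param T_ref reference temperature (degrees C), default 15.
#' @return turnover time (yr) at \code{T_ref}.
#' @export
normalize_arrhenius <- function(tau, T_inc, Ea = arrhenius_ea_for_q10(2, 15),
                                T_ref = 15) {
  if (any(tau <= 0)) stop("tau must be positive")
  R <- 8.314462618
  Tk_i <- T_inc + 273.15; Tk_r <- T_ref + 273.15
  # k(T) ~ exp(-Ea/(R T)); tau_ref = tau_T * k(T_inc)/k(T_ref)
  tau * exp(Ea / R * (1 / Tk_r - 1 / Tk_i))
}

#' Activation energy matching a given Q10 at a given temperature
#'
#' @param q10 target Q10.
#' @param T_c temperature (degrees C) at which the Arrhenius rate ratio over
#'   a 10-degree step equals \code{q10}.
#' @return activation energy (J mol^-1).
#' @export
arrhenius_ea_for_q10 <- function(q10, T_c = 15) {
  R <- 8.314462618
  Tk <- T_c + 273.15
  log(q10) * R / (1 / Tk - 1 / (Tk + 10))
}

# days per year used for rate <-> turnover-time conversions
DAYS_PER_YEAR <- 365.25

#' Convert pool decay rates (d^-1) to turnover times (yr) and back
#'
#' @param k decay rate(s) in d^-1.
#' @return \code{tau_years}: turnover time in years (1/k converted).
#' @export
tau_years <- function(k) 1 / (k * DAYS_PER_YEAR)

#' @rdname tau_years
#' @param tau turnover time(s) in years.
#' @return \code{k_per_day}: decay rate in d^-1.
#' @export
k_per_day <- function(tau) 1 / (tau * DAYS_PER_YEAR)
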