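#' Climatological mean of a yearly series
#'
#' Arithmetic mean of each cell's series over a year window (canonically the
#' 2000-2014 baseline), mask-aware.
#'
#' @param series cells x years matrix.
#' @param years year labels for the columns.
#' @param window length-2 inclusive year range; default \code{c(2000, 2014)}.
#' @param mask logical per-cell mask; masked cells return NA.
#' @return per-cell climatological mean vector.
#' @export
climatology <- function(series, years, window = c(2000, 2014),
                        mask = rep(TRUE, nrow(series))) {
  sel <- which(years >= window[1] & years <= window[2])
  if (length(sel) == 0) stop("no years inside the window")
  out <- rowMeans(series[, sel, drop = FALSE])
  out[!mask] <- NA_real_
  out
}

#' Delta (change) bias correction of future model forcing
#'
#' Corrects a modeled future series against an observed baseline using the
#' delta method: temperature and NPP additively,
#' \eqn{X_{cor} = X_{bas,obs} + (X_{fut,mod} - X_{bas,mod})};
#' precipitation multiplicatively,
#' \eqn{P_{cor} = P_{bas,obs} \times P_{fut,mod} / P_{bas,mod}}.
#' Cells with a zero modeled precipitation baseline are masked (NA) with a
#' warning. Negative corrected NPP is clipped to zero; the number of clipped
#' values is reported in the \code{"n_clipped"} attribute.
#'
#' @param kind one of \code{"T"}, \code{"P"}, \code{"NPP"}.
#' @param future_mod modeled future series, cells x years matrix (or vector).
#' @param baseline list with per-cell \code{obs} and \code{mod} baseline
#'   means (same variable, same grid).
#' @return corrected future series, same shape as \code{future_mod}.
#' @export
delta_correct <- function(kind = c("T", "P", "NPP"), future_mod, baseline) {
  kind <- match.arg(kind)
  fm <- as.matrix(future_mod)
  obs <- baseline$obs; mod <- baseline$mod
  if (length(obs) != nrow(fm) || length(mod) != nrow(fm))
    stop("baseline and future grids are not co-registered: ",
         length(obs), " / ", length(mod), " vs ", nrow(fm), " cells")
  n_clipped <- 0L
  if (kind == "P") {
    bad <- !is.na(mod) & mod == 0
    if (any(bad)) {
      warning(sum(bad), " cells masked: zero modeled precipitation baseline")
      mod[bad] <- NA_real_
    }
    out <- obs * fm / mod
  } else {
    out <- obs + (fm - mod)
    if (kind == "NPP") {
      neg <- !is.na(out) & out < 0
      n_clipped <- sum(neg)
      out[neg] <- 0
    }
  }
  if (!is.matrix(future_mod)) out <- drop(out)
  if (kind == "NPP") attr(out, "n_clipped") <- n_clipped
  out
}

#' Bias-correct a full scenario forcing set
#'
#' Applies \code{\link{delta_correct}} to the tas, pr and npp components of
#' a scenario forcing, using observed and modeled baselines computed over a
#' common window.
#'
#' @param forcing modeled scenario forcing (list with \code{years},
#'   \code{tas}, \code{pr}, \code{npp} matrices) covering the future period.
#' @param obs_baseline list of per-cell observed baseline means
#'   (\code{tas}, \code{pr}, \code{npp}).
#' @param mod_baseline list of per-cell modeled baseline means, same names.
#' @return forcing list with corrected components.
#' @export
correct_forcing <- function(forcing, obs_baseline, mod_baseline) {
  out <- forcing
  out$tas <- delta_correct("T", forcing$tas,
                           list(obs = obs_baseline$tas, mod = mod_baseline$tas))
  out$pr <- delta_correct("P", forcing$pr,
                          list(obs = obs_baseline$pr, mod = mod_baseline$pr))
  out$npp <- delta_correct("NPP", forcing$npp,
                           list(obs = obs_baseline$npp, mod = mod_baseline$npp))
  out
}

#' Restrict a forcing list to a year range
#'
#' @param forcing forcing list (\code{years} plus cells x years matrices).
#' @param from,to inclusive year range.
#' @return forcing list covering the requested years.
#' @export
window_forcing <- function(forcing, from, to) {
  sel <- which(forcing$years >= from & forcing$years <= to)
  if (length(sel) == 0) stop("no years in range")
  list(years = forcing$years[sel],
       tas = forcing$tas[, sel, drop = FALSE],
       pr = forcing$pr[, sel, drop = FALSE],
       npp = forcing$npp[, sel, drop = FALSE])
}
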