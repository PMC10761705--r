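# Fields on a regular lat/lon grid are stored as plain vectors in
# column-major cell order: cell = (i_lat, j_lon) -> index i + (j-1)*n_lat.
# Helpers here do the spherical-area accounting.

EARTH_RADIUS_M <- 6.371e6

#' Spherical areas of regular lat/lon grid cells
#'
#' Cell edges are placed midway between neighbouring latitude centers (outer
#' edges extended by half a spacing and clamped to +/-90), so a grid whose
#' centers tile the sphere has areas summing to exactly 4 pi R^2. Area of a
#' cell is R^2 * dlon * (sin(lat_top) - sin(lat_bottom)).
#'
#' @param lat vector of latitude cell centers (degrees), increasing.
#' @param n_lon number of longitude cells (assumed equally spaced around the
#'   globe, or supply \code{dlon_deg}).
#' @param dlon_deg longitude cell width in degrees; default \code{360/n_lon}.
#' @return vector of cell areas (m^2) in column-major cell order
#'   (latitude varying fastest), length \code{length(lat) * n_lon}.
#' @export
cell_areas <- function(lat, n_lon, dlon_deg = 360 / n_lon) {
  nl <- length(lat)
  if (nl > 1 && any(diff(lat) <= 0)) stop("lat centers must be increasing")
  half <- if (nl > 1) diff(lat) / 2 else 45
  lo <- c(lat[1] - half[1], lat[-nl] + half)
  hi <- c(lat[-nl] + half, lat[nl] + half[length(half)])
  lo <- pmax(lo, -90); hi <- pmin(hi, 90)
  band <- EARTH_RADIUS_M^2 * (dlon_deg * pi / 180) *
    (sin(hi * pi / 180) - sin(lo * pi / 180))
  rep(band, times = n_lon)
}

#' Global total of an areal-density field, in PgC
#'
#' Multiplies a per-cell density (gC m^-2) by spherical cell areas over the
#' land mask and converts to petagrams (1 PgC = 1e15 gC).
#'
#' @param field per-cell values (gC m^-2), vector in cell order.
#' @param areas per-cell areas (m^2), as from \code{\link{cell_areas}}.
#' @param mask logical land mask (default all TRUE).
#' @return scalar total in PgC.
#' @export
global_total <- function(field, areas, mask = rep(TRUE, length(field))) {
  stopifnot(length(field) == length(areas), length(mask) == length(field))
  sum(field[mask] * areas[mask]) / 1e15
}

#' Change in stock between two period means of a trajectory
#'
#' Per-cell difference of total (three-pool) stock averaged over two year
#' windows; positive values are a sink, negative a source.
#'
#' @param traj a \code{pool_trajectory} whose years cover both periods.
#' @param periodA,periodB length-2 year ranges (inclusive); defaults are the
#'   current period 2005-2014 and the end of century 2080-2099.
#' @param areas,mask optional; when given, the area-weighted global total
#'   (PgC) is included.
#' @return list with \code{field} (per-cell Delta stock, gC m^-2) and, when
#'   areas are supplied, \code{total_pgc}.
#' @export
delta_stock <- function(traj, periodA = c(2005, 2014),
                        periodB = c(2080, 2099),
                        areas = NULL, mask = NULL) {
  yrs <- traj$years
  ia <- which(yrs >= periodA[1] & yrs <= periodA[2])
  ib <- which(yrs >= periodB[1] & yrs <= periodB[2])
  if (length(ia) == 0 || length(ib) == 0)
    stop("trajectory does not cover the requested periods")
  tot <- apply(traj$stocks, c(1, 3), sum)      # cells x years
  field <- rowMeans(tot[, ib, drop = FALSE]) - rowMeans(tot[, ia, drop = FALSE])
  out <- list(field = field)
  if (!is.null(areas)) {
    if (is.null(mask)) mask <- rep(TRUE, length(field))
    out$total_pgc <- global_total(field, areas, mask)
  }
  out
}

#' Concatenate two trajectories in time
#'
#' @param t1,t2 \code{pool_trajectory} objects over adjacent year ranges.
#' @return combined \code{pool_trajectory}.
#' @export
combine_trajectories <- function(t1, t2) {
  if (t2$years[1] != t1$years[length(t1$years)] + 1)
    stop("trajectories are not adjacent in time")
  structure(list(years = c(t1$years, t2$years),
                 stocks = array(c(t1$stocks, t2$stocks),
                                c(dim(t1$stocks)[1], 3,
                                  length(t1$years) + length(t2$years))),
                 respired = cbind(t1$respired, t2$respired),
                 state0 = t1$state0),
            class = "pool_trajectory")
}

#' Aggregate a field into latitude bands or biome classes
#'
#' Area-weighted means of a per-cell field, either over latitude bands of a
#' given width or over latitudinally defined biome classes (tropical
#' 23S-23N, temperate 23-50 degrees in both hemispheres, boreal north of
#' 50N, southern polar south of 50S).
#'
#' @param field per-cell values.
#' @param lat per-cell latitudes (degrees).
#' @param areas per-cell areas (m^2).
#' @param mask logical land mask.
#' @param scheme \code{"latitude"} or \code{"biome"}.
#' @param band_width latitude band width in degrees (default 0.5).
#' @return data.frame with the band/biome label, its area-weighted mean and
#'   the summed area.
#' @export
aggregate_field <- function(field, lat, areas, mask = rep(TRUE, length(field)),
                            scheme = c("latitude", "biome"),
                            band_width = 0.5) {
  scheme <- match.arg(scheme)
  keep <- mask & is.finite(field)
  grp <- if (scheme == "latitude") {
    edges <- seq(-90, 90, by = band_width)
    cut(lat, edges, include.lowest = TRUE)
  } else {
    cut(lat, c(-90, -50, -23, 23, 50, 90), include.lowest = TRUE,
        labels = c("southern_polar", "temperate_south", "tropical",
                   "temperate_north", "boreal"))
  }
  w <- areas * keep
  num <- tapply(field * w, grp, sum, na.rm = TRUE)
  den <- tapply(w, grp, sum)
  ok <- !is.na(den) & den > 0
  data.frame(band = names(num)[ok],
             mean = as.numeric(num[ok] / den[ok]),
             area_m2 = as.numeric(den[ok]),
             stringsAsFactors = FALSE)
}

#' Remaining-carbon-budget implications of constrained soil carbon changes
#'
#' Fits ordinary least squares lines of constrained and original global soil
#' carbon change (PgC) against global warming (K above the 1850-1900
#' baseline) across models and scenarios, evaluates both lines at each
#' warming target, and expresses the sequestration shortfall
#' (original minus constrained) as a fraction of the remaining carbon
#' budget for that target.
#'
#' @param points data.frame with columns \code{dT} (warming, K),
#'   \code{dsoc_constrained} and \code{dsoc_original} (PgC, relative to the
#'   chosen baselines); at least 3 rows.
#' @param budgets named numeric of remaining budgets (PgC) keyed by target
#'   warming; default \code{c("1.5" = 68, "2" = 327)}.
#' @return object of class \code{"budget_result"}: data.frame per target
#'   with the fitted soil change of both ensembles, the difference, the
#'   budget and the reduction fraction, plus the fitted coefficients.
#' @export
budget_reduction <- function(points, budgets = c("1.5" = 68, "2" = 327)) {
  if (nrow(points) < 3) stop("need at least 3 points to fit")
  fit_c <- stats::lm(dsoc_constrained ~ dT, data = points)
  fit_o <- stats::lm(dsoc_original ~ dT, data = points)
  tw <- as.numeric(names(budgets))
  nd <- data.frame(dT = tw)
  soc_c <- stats::predict(fit_c, nd)
  soc_o <- stats::predict(fit_o, nd)
  diff <- soc_o - soc_c
  tab <- data.frame(target_K = tw,
                    soil_change_constrained_pgc = as.numeric(soc_c),
                    soil_change_original_pgc = as.numeric(soc_o),
                    shortfall_pgc = as.numeric(diff),
                    budget_pgc = as.numeric(budgets),
                    reduction_fraction = as.numeric(diff) / as.numeric(budgets))
  structure(list(table = tab,
                 coef_constrained = stats::coef(fit_c),
                 coef_original = stats::coef(fit_o),
                 n_points = nrow(points)),
            class = "budget_result")
}

#' @export
print.budget_result <- function(x, ...) {
  cat("Remaining-carbon-budget impact of constrained soil carbon change\n")
  cat(sprintf("  fit on %d model x scenario points; constrained slope %.2f PgC/K\n",
              x$n_points, x$coef_constrained[2]))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
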