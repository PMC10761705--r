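# Plain-text interchange: long-format CSV for flux series and grids.

#' Write and read incubation series as CSV
#'
#' The flux table is long-format (\code{site_id}, \code{time_d},
#' \code{flux_mgC_g_d}); per-site metadata (initial carbon, incubation
#' temperature, screening flags, location and climate) go to a sidecar
#' table.
#'
#' @param records list of \code{\link{incubation_series}}.
#' @param path flux CSV path.
#' @param meta_path metadata CSV path (default: \code{path} with
#'   \code{_meta} inserted before the extension).
#' @return \code{path}, invisibly.
#' @export
write_incubation_csv <- function(records, path,
                                 meta_path = sub("(\\.[^.]+)$", "_meta\\1",
                                                 path)) {
  flux <- do.call(rbind, lapply(records, function(r)
    data.frame(site_id = r$site_id, time_d = r$times,
               flux_mgC_g_d = r$fluxes, stringsAsFactors = FALSE)))
  md_field <- function(r, f, default = NA)
    if (!is.null(r$metadata[[f]])) r$metadata[[f]] else default
  meta <- do.call(rbind, lapply(records, function(r)
    data.frame(site_id = r$site_id, C_tot = r$C_tot,
               incubation_T = r$incubation_T, duration = r$duration,
               lat = md_field(r, "lat"), lon = md_field(r, "lon"),
               MAT = md_field(r, "MAT"), MAP = md_field(r, "MAP"),
               depth_cm = md_field(r, "depth_cm"),
               biome = md_field(r, "biome", NA_character_),
               substrate_added = md_field(r, "substrate_added", FALSE),
               aerobic = md_field(r, "aerobic", TRUE),
               stringsAsFactors = FALSE)))
  utils::write.csv(flux, path, row.names = FALSE)
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_incubation_csv
#' @export
read_incubation_csv <- function(path,
                                meta_path = sub("(\\.[^.]+)$", "_meta\\1",
                                                path)) {
  flux <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    fl <- flux[flux$site_id == m$site_id, ]
    incubation_series(m$site_id, fl$time_d, fl$flux_mgC_g_d, m$C_tot,
                      m$incubation_T,
                      metadata = list(lat = m$lat, lon = m$lon, MAT = m$MAT,
                                      MAP = m$MAP, depth_cm = m$depth_cm,
                                      biome = m$biome,
                                      substrate_added = isTRUE(m$substrate_added),
                                      aerobic = isTRUE(m$aerobic)))
  })
}

#' Write gridded fields as long-format CSV
#'
#' One row per cell with latitude, longitude, land-mask flag and the named
#' field columns.
#'
#' @param fields named list (or data.frame) of per-cell vectors.
#' @param lat,lon per-cell coordinates (degrees).
#' @param path output CSV path.
#' @param mask optional logical land mask column.
#' @return \code{path}, invisibly.
#' @export
write_grid_csv <- function(fields, lat, lon, path, mask = NULL) {
  df <- data.frame(lat = lat, lon = lon)
  if (!is.null(mask)) df$land <- mask
  for (nm in names(fields)) df[[nm]] <- fields[[nm]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
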