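#' Simulate mean yields over a location grid
#'
#' Runs the factorial years-by-accessions campaign at every grid location
#' (each with its own weather series and soil water capacity) and returns
#' per-location mean yields per accession plus the accession mean.
#'
#' @param grid_weather named list of `weather_series` (one per location), as
#'   from [generate_grid()].
#' @param spec the matching grid specification (supplies lat/lon and pawc).
#' @param years integer vector of season years.
#' @param accessions accession labels.
#' @param config,cardinals passed to [run_season()].
#' @return a data frame of class `yield_field`: loc_id, lat, lon, one
#'   `yield_<accession>` column each, and `yield_mean` (kg/ha).
#' @export
simulate_grid <- function(grid_weather, spec, years,
                          accessions = proso_genotypes()$accession,
                          config = sim_config(),
                          cardinals = cardinal_temps()) {
  rows <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    soil <- soil_profile(pawc = max(spec$pawc[i], 1e-6))
    cam <- run_campaign(grid_weather[[spec$loc_id[i]]], years, accessions,
                        soil = soil, config = config, cardinals = cardinals)
    m <- tapply(cam$yield, cam$accession, mean)[accessions]
    row <- data.frame(loc_id = spec$loc_id[i], lat = spec$lat[i],
                      lon = spec$lon[i], stringsAsFactors = FALSE)
    for (a in accessions) row[[paste0("yield_", a)]] <- m[[a]]
    row$yield_mean <- mean(m)
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("yield_field", "data.frame")
  out
}

#' Inverse-distance-weighted interpolation on geographic coordinates
#'
#' Weights are `distance^-p` with great-circle (haversine) distances; a query
#' point coinciding with a source point returns that point's value exactly.
#' The result is a convex combination of the source values.
#'
#' @param src data frame with columns lat, lon and the value column.
#' @param query data frame with columns lat, lon.
#' @param value name of the value column in `src`.
#' @param p IDW power (> 0).
#' @return numeric vector of interpolated values, one per query row.
#' @export
idw_interpolate <- function(src, query, value = "yield_mean", p = 2) {
  if (nrow(src) == 0L) stop("no source points")
  if (p <= 0) stop("power must be positive")
  y <- src[[value]]
  vapply(seq_len(nrow(query)), function(i) {
    d <- geosphere::distHaversine(cbind(query$lon[i], query$lat[i]),
                                  cbind(src$lon, src$lat))
    hit <- which(d < 1e-6)
    if (length(hit)) return(y[hit[1]])
    w <- d^(-p)
    sum(w * y) / sum(w)
  }, numeric(1))
}

#' Percent yield difference relative to a reference location
#'
#' @param field a `yield_field` from [simulate_grid()].
#' @param reference `loc_id` of the reference location (e.g. the current
#'   growing area).
#' @param value value column to compare (default `"yield_mean"`).
#' @return the field with an added `pct_diff` column, plus attributes
#'   `share_above` (fraction of non-reference locations strictly above the
#'   reference) and `share_within_5` (fraction within +/- 5 percent).
#' @export
percent_difference_map <- function(field, reference, value = "yield_mean") {
  i <- match(reference, field$loc_id)
  if (is.na(i)) stop("reference location not in field: ", reference)
  ref <- field[[value]][i]
  if (ref == 0) stop("reference yield is zero")
  field$pct_diff <- percent_change(field[[value]], ref)
  others <- field$pct_diff[-i]
  attr(field, "reference") <- reference
  attr(field, "share_above") <- mean(others > 0)
  attr(field, "share_within_5") <- mean(abs(field$pct_diff) <= 5)
  field
}

#' Re-simulate the grid under a uniform climate scenario
#'
#' Applies one idealised anomaly (see [uniform_scenarios()]) to every
#' location's weather, re-simulates, and differences against the unperturbed
#' field.
#'
#' @param grid_weather,spec,years as in [simulate_grid()].
#' @param dT,dP the uniform anomaly (deg C additive / percent multiplicative).
#' @param base_field the unperturbed field; computed if `NULL`.
#' @param accessions accession labels (a single accession gives the
#'   single-cultivar maps).
#' @param ... passed to [simulate_grid()].
#' @return the perturbed `yield_field` with columns `yield_change` (kg/ha)
#'   and `pct_change` vs the unperturbed field, plus attribute
#'   `frac_increased` (share of locations with strictly higher yield).
#' @export
scenario_map <- function(grid_weather, spec, years, dT = 0, dP = 0,
                         base_field = NULL,
                         accessions = proso_genotypes()$accession, ...) {
  if (is.null(base_field))
    base_field <- simulate_grid(grid_weather, spec, years, accessions, ...)
  pert <- lapply(grid_weather, apply_anomaly, dT = dT, dP = dP)
  field <- simulate_grid(pert, spec, years, accessions, ...)
  stopifnot(identical(field$loc_id, base_field$loc_id))
  field$yield_change <- field$yield_mean - base_field$yield_mean
  field$pct_change <- ifelse(base_field$yield_mean > 0,
                             100 * field$yield_change / base_field$yield_mean,
                             NA_real_)
  attr(field, "frac_increased") <- mean(field$yield_change > 0)
  attr(field, "scenario") <- c(dT = dT, dP = dP)
  field
}
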