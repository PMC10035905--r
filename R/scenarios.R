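#' Build the 99-member Latin-hypercube climate sensitivity design
#'
#' Samples 99 temperature/rainfall anomaly pairs by Latin-hypercube sampling:
#' each dimension is partitioned into 99 equal-width strata, one point is
#' drawn uniformly within each stratum, and strata are paired by a seeded
#' permutation (via [lhs::randomLHS()]).  The canonical protocol ranges are
#' -1 to +8 deg C for temperature and -50 to +50 percent for rainfall; the
#' CO2 dimension of the original protocol is omitted because the crop model
#' has no CO2 response.
#'
#' @param dT_range,dP_range lower/upper bounds of the two anomaly dimensions.
#' @param seed integer seed; recorded in the result.
#' @param n number of members (99 in the canonical design).
#' @return a data frame of class `c3mp_design` with columns member, dT
#'   (deg C, additive) and dP (percent, multiplicative), plus `ranges` and
#'   `seed` attributes.
#' @export
make_c3mp_design <- function(dT_range = c(-1, 8), dP_range = c(-50, 50),
                             seed = 1L, n = 99L) {
  if (dT_range[1] >= dT_range[2] || dP_range[1] >= dP_range[2])
    stop("ranges must be ordered (lower < upper)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(n, 2L)
  d <- data.frame(member = seq_len(n),
                  dT = dT_range[1] + u[, 1] * diff(dT_range),
                  dP = dP_range[1] + u[, 2] * diff(dP_range))
  structure(d, class = c("c3mp_design", "data.frame"),
            ranges = list(dT = dT_range, dP = dP_range), seed = as.integer(seed))
}

#' Apply a uniform temperature/rainfall anomaly to daily weather
#'
#' The standard sensitivity-test perturbation: `dT` is added to every day's
#' tmin and tmax; rain is multiplied by `1 + dP/100` on every day, so the
#' number of rain days is unchanged; radiation is untouched.
#'
#' @param series a valid `weather_series`.
#' @param dT temperature anomaly (deg C, additive).
#' @param dP rainfall anomaly (percent, multiplicative); must be > -100.
#' @return the perturbed `weather_series`.
#' @export
apply_anomaly <- function(series, dT = 0, dP = 0) {
  if (dP <= -100) stop("dP must be > -100 percent")
  out <- as.data.frame(series)
  out$tmin <- out$tmin + dT
  out$tmax <- out$tmax + dT
  out$rain <- out$rain * (1 + dP / 100)
  loc <- attr(series, "location")
  weather_series(out, lat = loc$lat, lon = loc$lon, elev = loc$elev,
                 label = loc$label, provenance = attr(series, "provenance"))
}

#' Construct a GCM delta set
#'
#' A monthly change signal from one general circulation model under one
#' emission scenario: additive deltas for tmax/tmin and multiplicative
#' ratios for rainfall, applied per calendar month by [apply_delta()].
#'
#' @param model model name.
#' @param scenario `"RCP4.5"` or `"RCP8.5"`.
#' @param d_tmax,d_tmin monthly additive temperature deltas (deg C, length 12
#'   or 1, recycled).
#' @param rain_ratio monthly multiplicative rain ratios (>= 0, length 12 or 1).
#' @return an object of class `gcm_delta`.
#' @export
gcm_delta <- function(model, scenario = c("RCP4.5", "RCP8.5"),
                      d_tmax = 0, d_tmin = 0, rain_ratio = 1) {
  scenario <- match.arg(scenario)
  d_tmax <- rep_len(d_tmax, 12L)
  d_tmin <- rep_len(d_tmin, 12L)
  rain_ratio <- rep_len(rain_ratio, 12L)
  if (any(rain_ratio < 0)) stop("rain ratios must be >= 0")
  structure(list(model = model, scenario = scenario, d_tmax = d_tmax,
                 d_tmin = d_tmin, rain_ratio = rain_ratio),
            class = "gcm_delta")
}

#' Apply a GCM delta set to daily weather (delta-method downscaling)
#'
#' Per calendar month m: `tmax' = tmax + d_tmax(m)`,
#' `tmin' = tmin + d_tmin(m)`, `rain' = rain * rain_ratio(m)`; radiation is
#' unchanged.  The delta method assumes the day-to-day structure of the
#' baseline climate is preserved into the future.
#'
#' @param series a valid `weather_series`.
#' @param delta a [gcm_delta()].
#' @return the perturbed `weather_series`; errors (naming the date) if any
#'   perturbed day would have tmax < tmin.
#' @export
apply_delta <- function(series, delta) {
  mon <- as.integer(format(series$date, "%m"))
  out <- as.data.frame(series)
  out$tmax <- out$tmax + delta$d_tmax[mon]
  out$tmin <- out$tmin + delta$d_tmin[mon]
  out$rain <- out$rain * delta$rain_ratio[mon]
  bad <- which(out$tmax < out$tmin)
  if (length(bad))
    stop("delta produces tmax < tmin on ", out$date[bad[1]])
  loc <- attr(series, "location")
  weather_series(out, lat = loc$lat, lon = loc$lon, elev = loc$elev,
                 label = loc$label, provenance = attr(series, "provenance"))
}

#' Uniform delta set reproducing a pair of climate normals
#'
#' Bridges scenario climate summaries to daily deltas when only normals are
#' published: constant monthly temperature deltas equal to the difference of
#' means, and a constant monthly rain ratio equal to the ratio of annual
#' totals.  Applying the result to a series with the baseline normals and
#' re-summarising recovers the future tmax/tmin/annual-rain normals.
#'
#' @param baseline,future [climate_normals()] objects.
#' @param model,scenario passed to [gcm_delta()].
#' @return a [gcm_delta()] with constant monthly entries.
#' @export
delta_from_normals <- function(baseline, future, model = "uniform",
                               scenario = "RCP4.5") {
  if (baseline$annual_rain == 0) stop("baseline annual rain is zero")
  gcm_delta(model, scenario,
            d_tmax = future$mean_tmax - baseline$mean_tmax,
            d_tmin = future$mean_tmin - baseline$mean_tmin,
            rain_ratio = future$annual_rain / baseline$annual_rain)
}

#' The five uniform mapping scenarios
#'
#' The idealised single-variable perturbations used for gridded sensitivity
#' mapping: +1, +1.5 and +2 deg C warming, and +25 / -25 percent rainfall.
#'
#' @return a data frame with columns label, dT, dP.
#' @export
uniform_scenarios <- function() {
  data.frame(label = c("+1C", "+1.5C", "+2C", "+25P", "-25P"),
             dT = c(1, 1.5, 2, 0, 0),
             dP = c(0, 0, 0, 25, -25),
             stringsAsFactors = FALSE)
}

#' Load the CMIP5 ensemble climate-normals fixture
#'
#' The shipped per-model mid-century (2040-2069) climate normals of the study
#' site for 20 CMIP5 general circulation models (labelled A-T) under RCP4.5
#' and RCP8.5, downscaled by the delta method, together with the observed
#' 1980-2009 baseline row.
#'
#' @return a data frame of class `gcm_ensemble` with columns model, label,
#'   scenario, mean_tmax, mean_tmin, annual_rain, seasonal_rain.  The
#'   baseline row has scenario `"baseline"`.
#' @export
load_gcm_ensemble <- function() {
  path <- system.file("extdata", "gcm_climate_normals.csv",
                      package = "prosoclim", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("gcm_ensemble", "data.frame")
  df
}

#' Turn one ensemble row into a GCM delta
#'
#' Without a baseline series, returns the uniform bridge of
#' [delta_from_normals()] (constant monthly ratios from the annual totals).
#' With `baseline_weather`, returns a seasonal-aware delta: the
#' growing-season months (March-June) get the rain ratio of the row's
#' *seasonal* change signal (row seasonal / baseline seasonal), and the
#' remaining months get the complementary ratio that makes the series'
#' annual total change by the row's *annual* signal — so both printed
#' relative rainfall changes are reproduced on the series at once.
#' Temperature deltas are the row-minus-baseline differences in both cases.
#'
#' @param ensemble a `gcm_ensemble` as from [load_gcm_ensemble()].
#' @param model model name (or single-letter label).
#' @param scenario `"RCP4.5"` or `"RCP8.5"`.
#' @param baseline_weather optional `weather_series` the delta will be
#'   applied to; enables the seasonal-aware rain ratios.
#' @param window growing-season window (seasonal-aware mode).
#' @return a [gcm_delta()].
#' @export
ensemble_delta <- function(ensemble, model, scenario, baseline_weather = NULL,
                           window = season_window()) {
  b <- ensemble[ensemble$scenario == "baseline", ][1, ]
  r <- ensemble[(ensemble$model == model | ensemble$label == model) &
                  ensemble$scenario == scenario, ]
  if (nrow(r) != 1L) stop("no unique ensemble row for ", model, " ", scenario)
  if (is.null(baseline_weather))
    return(delta_from_normals(
      climate_normals(b$mean_tmax, b$mean_tmin, b$annual_rain, b$seasonal_rain),
      climate_normals(r$mean_tmax, r$mean_tmin, r$annual_rain, r$seasonal_rain),
      model = r$model, scenario = scenario))
  s <- summarize_weather(baseline_weather, window)
  if (s$seasonal_rain <= 0) stop("baseline series has no growing-season rain")
  # per-year rain falling in the growing-season months (whole months)
  yr <- as.integer(format(baseline_weather$date, "%Y"))
  mon <- as.integer(format(baseline_weather$date, "%m"))
  keep <- yr %in% s$period
  season_months <- 3:6
  in_m <- keep & mon %in% season_months
  m_rain <- sum(baseline_weather$rain[in_m]) / length(s$period)
  a_rain <- s$annual_rain
  r_season <- r$seasonal_rain / b$seasonal_rain
  r_other <- (a_rain * r$annual_rain / b$annual_rain - r_season * m_rain) /
    (a_rain - m_rain)
  r_other <- max(0, r_other)
  ratio <- rep(r_other, 12L)
  ratio[season_months] <- r_season
  gcm_delta(r$model, scenario,
            d_tmax = r$mean_tmax - b$mean_tmax,
            d_tmin = r$mean_tmin - b$mean_tmin,
            rain_ratio = ratio)
}
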