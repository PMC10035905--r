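#' Weather generator configuration
#'
#' Monthly parameters of a standard single-site stochastic weather generator:
#' first-order two-state Markov rainfall occurrence, gamma-distributed wet-day
#' amounts, monthly temperature means with AR(1) daily anomalies, and a
#' deterministic clear-sky radiation curve reduced on wet days.
#'
#' @param p_wet stationary probability that a day is wet, by month (12).
#' @param p_ww probability a wet day follows a wet day, by month (12).
#' @param shape gamma shape of wet-day rainfall amounts, by month (12).
#' @param mean_wet mean wet-day rainfall amount (mm), by month (12).
#' @param tmax_mean,tmin_mean monthly mean daily max/min temperature (deg C).
#' @param temp_sd standard deviation of the AR(1) daily temperature anomaly
#'   (deg C).
#' @param temp_rho lag-1 autocorrelation of the daily temperature anomaly.
#' @param srad_mean annual-mean clear-sky radiation (MJ/m2/day).
#' @param srad_amp amplitude of the seasonal radiation harmonic (MJ/m2/day).
#' @param wet_srad_factor multiplicative radiation reduction on wet days.
#' @param seed integer seed; every realisation is deterministic given it.
#' @return an object of class `weather_gen_config`.
#' @export
weather_gen_config <- function(p_wet, p_ww, shape, mean_wet,
                               tmax_mean, tmin_mean,
                               temp_sd = 1.0, temp_rho = 0.6,
                               srad_mean = 20, srad_amp = 2,
                               wet_srad_factor = 0.75, seed = 1L) {
  for (v in list(p_wet, p_ww, shape, mean_wet, tmax_mean, tmin_mean))
    if (length(v) != 12L) stop("monthly parameters must have length 12")
  if (any(p_wet < 0 | p_wet > 1 | p_ww < 0 | p_ww > 1))
    stop("probabilities must lie in [0, 1]")
  if (any(shape < 0) || any(mean_wet < 0) || temp_sd < 0)
    stop("shape, mean_wet and temp_sd must be non-negative")
  if (abs(temp_rho) >= 1) stop("temp_rho must lie in (-1, 1)")
  # wet-after-dry probability implied by the stationary wet fraction:
  # pi = p_wd / (1 + p_wd - p_ww)  =>  p_wd = pi (1 - p_ww) / (1 - pi)
  p_wd <- ifelse(p_wet >= 1, 1, p_wet * (1 - p_ww) / (1 - p_wet))
  if (any(p_wd > 1))
    stop("p_wet/p_ww combination implies wet-after-dry probability > 1")
  structure(list(p_wet = p_wet, p_ww = p_ww, p_wd = p_wd, shape = shape,
                 mean_wet = mean_wet, tmax_mean = tmax_mean,
                 tmin_mean = tmin_mean, temp_sd = temp_sd,
                 temp_rho = temp_rho, srad_mean = srad_mean,
                 srad_amp = srad_amp, wet_srad_factor = wet_srad_factor,
                 seed = as.integer(seed)),
            class = "weather_gen_config")
}

# month lengths used for closed-form expectations (Feb counts leap years
# at the 1-in-4 Gregorian-approximate rate used only for expectations;
# simulation itself is exact-calendar)
.MDAYS <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

# days of each month falling inside the default 15 Mar - 15 Jun window
.season_month_days <- function(window = season_window()) {
  d <- seq(as.Date(paste0("2001-", window$start)),
           as.Date(paste0("2001-", window$end)), by = "day")
  tab <- tabulate(as.integer(format(d, "%m")), nbins = 12L)
  tab
}

#' Closed-form expected climate normals of a generator configuration
#'
#' Uses the stationary wet-day probability of the occurrence chain and the
#' gamma mean: expected rain in month m is `ndays(m) * p_wet(m) * mean_wet(m)`;
#' expected temperatures are day-weighted monthly means.
#'
#' @param config a [weather_gen_config()].
#' @param window growing-season window for the seasonal component.
#' @return a [climate_normals()] object.
#' @export
expected_normals <- function(config, window = season_window()) {
  m_rain <- .MDAYS * config$p_wet * config$mean_wet
  sdays <- .season_month_days(window)
  seas <- sum(sdays * config$p_wet * config$mean_wet)
  climate_normals(
    mean_tmax = sum(.MDAYS * config$tmax_mean) / sum(.MDAYS),
    mean_tmin = sum(.MDAYS * config$tmin_mean) / sum(.MDAYS),
    annual_rain = sum(m_rain), seasonal_rain = seas, window = window)
}

#' Calibrate a generator configuration to target climate normals
#'
#' Rescales the monthly mean wet-day amounts (one factor for the months
#' touching the growing-season window, another for the remaining months, so
#' both the seasonal and the annual totals are matched in expectation) and
#' shifts the monthly temperature means by constants.  The template's monthly
#' seasonality pattern is preserved; occurrence probabilities are untouched.
#'
#' @param target a [climate_normals()] to match in expectation.
#' @param template a [weather_gen_config()] supplying the seasonal shape.
#' @param window growing-season window.
#' @return a calibrated `weather_gen_config`.
#' @export
calibrate_gen_config <- function(target, template = NULL,
                                 window = season_window()) {
  if (is.null(template)) template <- .template_gen_config()
  if (target$seasonal_rain > target$annual_rain)
    stop("target seasonal_rain exceeds annual_rain")
  sdays <- .season_month_days(window)
  in_season <- sdays > 0
  e_m <- .MDAYS * template$p_wet * template$mean_wet
  e_seas <- sum(sdays * template$p_wet * template$mean_wet)
  e_in <- sum(e_m[in_season])
  e_out <- sum(e_m[!in_season])
  alpha <- target$seasonal_rain / e_seas
  beta <- (target$annual_rain - alpha * e_in) / e_out
  if (beta < 0)
    stop("target annual rain too small for the template's off-season share")
  cfg <- template
  cfg$mean_wet[in_season] <- cfg$mean_wet[in_season] * alpha
  cfg$mean_wet[!in_season] <- cfg$mean_wet[!in_season] * beta
  en <- expected_normals(template, window)
  cfg$tmax_mean <- cfg$tmax_mean + (target$mean_tmax - en$mean_tmax)
  cfg$tmin_mean <- cfg$tmin_mean + (target$mean_tmin - en$mean_tmin)
  weather_gen_config(cfg$p_wet, cfg$p_ww, cfg$shape, cfg$mean_wet,
                     cfg$tmax_mean, cfg$tmin_mean, cfg$temp_sd, cfg$temp_rho,
                     cfg$srad_mean, cfg$srad_amp, cfg$wet_srad_factor,
                     cfg$seed)
}

# uncalibrated bimodal-monsoon shape template: minor rains Mar-Jun (the
# millet season), major rains Oct-Dec (northeast monsoon), warm dry-zone
# temperatures peaking around April-May
.template_gen_config <- function(seed = 1L) {
  weather_gen_config(
    p_wet     = c(0.30, 0.20, 0.25, 0.40, 0.35, 0.20,
                  0.15, 0.15, 0.25, 0.45, 0.55, 0.45),
    p_ww      = rep(0.55, 12),
    shape     = rep(0.8, 12),
    mean_wet  = c(8, 6, 8, 12, 10, 6, 4, 4, 8, 14, 15, 12),
    tmax_mean = c(31.0, 32.5, 33.5, 34.0, 33.5, 33.0,
                  32.5, 32.5, 32.0, 31.5, 30.5, 30.5),
    tmin_mean = c(22.5, 22.7, 23.3, 24.0, 24.2, 24.0,
                  23.7, 23.6, 23.4, 23.3, 23.0, 22.6),
    seed = seed)
}

#' Default generator configuration for the study site
#'
#' The bimodal-monsoon template calibrated so its expected normals equal the
#' site's observed baseline normals: mean Tmax 32.1 deg C, mean Tmin
#' 23.3 deg C, annual rainfall 1121 mm, growing-season (15 Mar - 15 Jun)
#' rainfall 289 mm.
#'
#' @param seed integer seed stored in the configuration.
#' @return a calibrated [weather_gen_config()].
#' @export
default_gen_config <- function(seed = 1L) {
  calibrate_gen_config(baseline_normals(), .template_gen_config(seed))
}

#' Observed baseline climate normals of the study site
#'
#' The 1980-2009 normals of the Proso millet growing area used throughout
#' as the reference climate: mean Tmax 32.1, mean Tmin 23.3 (deg C), annual
#' rainfall 1121 mm, growing-season rainfall 289 mm.
#'
#' @return a [climate_normals()] object.
#' @export
baseline_normals <- function() {
  climate_normals(32.1, 23.3, 1121, 289)
}

# deterministic substream seed for (seed, stream k); kept under 2^31
.substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}

#' Generate a stochastic daily weather series
#'
#' Rain occurrence follows a first-order two-state Markov chain with monthly
#' transition probabilities; wet-day amounts are gamma; daily temperatures are
#' monthly means plus AR(1) anomalies (tmax > tmin enforced); radiation is a
#' seasonal harmonic reduced by a fixed factor on wet days.  Output values are
#' rounded to 0.01 so file round-trips are exact.  Deterministic given
#' `config$seed`; separate substreams are used per variable.
#'
#' @param config a [weather_gen_config()].
#' @param years number of calendar years to simulate.
#' @param start_year first calendar year.
#' @param lat,lon,label site metadata attached to the series.
#' @return a `weather_series` with provenance "synthetic".
#' @export
generate_weather <- function(config, years, start_year = 1980,
                             lat = 6.428, lon = 81.090, label = "synthetic") {
  stopifnot(years >= 1)
  dates <- seq(as.Date(paste0(start_year, "-01-01")),
               as.Date(paste0(start_year + years - 1L, "-12-31")), by = "day")
  n <- length(dates)
  mon <- as.integer(format(dates, "%m"))
  doy <- as.integer(format(dates, "%j"))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))

  # occurrence chain
  set.seed(.substream(config$seed, 1L))
  u <- stats::runif(n)
  wet <- logical(n)
  wet[1] <- u[1] < config$p_wet[mon[1]]
  p_ww <- config$p_ww; p_wd <- config$p_wd
  for (i in 2:n)
    wet[i] <- u[i] < if (wet[i - 1L]) p_ww[mon[i]] else p_wd[mon[i]]

  # amounts
  set.seed(.substream(config$seed, 2L))
  rain <- numeric(n)
  k <- config$shape[mon]; mu <- config$mean_wet[mon]
  nw <- sum(wet)
  if (nw > 0)
    rain[wet] <- stats::rgamma(nw, shape = k[wet], scale = (mu / k)[wet])

  # temperatures: AR(1) anomalies, one stream per variable
  ar1 <- function(eps, rho) {
    z <- numeric(length(eps))
    z[1] <- eps[1]
    for (i in 2:length(eps)) z[i] <- rho * z[i - 1L] + sqrt(1 - rho^2) * eps[i]
    z
  }
  set.seed(.substream(config$seed, 3L))
  zx <- ar1(stats::rnorm(n), config$temp_rho)
  set.seed(.substream(config$seed, 4L))
  zn <- ar1(stats::rnorm(n), config$temp_rho)
  tmax <- config$tmax_mean[mon] + config$temp_sd * zx
  tmin <- config$tmin_mean[mon] + 0.8 * config$temp_sd * zn
  tmax <- pmax(tmax, tmin + 0.5)   # physical floor; ~never binds at default sds

  srad <- (config$srad_mean +
             config$srad_amp * cos(2 * pi * (doy - 105) / 365.25)) *
    ifelse(wet, config$wet_srad_factor, 1)

  df <- data.frame(date = dates,
                   tmin = round(tmin, 2), tmax = round(tmax, 2),
                   rain = round(rain, 2), srad = round(srad, 2))
  prov <- data.frame(tmin = "synthetic", tmax = "synthetic",
                     rain = "synthetic", srad = "synthetic",
                     stringsAsFactors = FALSE)[rep(1L, n), , drop = FALSE]
  weather_series(df, lat = lat, lon = lon, label = label, provenance = prov)
}

#' Synthetic island-gradient grid specification
#'
#' An abstract 0.25-degree grid of `n` locations with the two climatic
#' features that shape yield on a tropical monsoon island: a smooth
#' southwest-wet to northeast-dry rainfall gradient (the minor-season rains
#' weaken towards the corner dominated by the opposite monsoon) and a cool
#' central-highland temperature anomaly (a Gaussian bump of elevation-driven
#' cooling, up to ~7 deg C, in the grid interior).  Per-location soil
#' plant-available water capacity follows the rainfall gradient.
#'
#' @param n number of grid locations (default 95).
#' @param lat0,lon0 grid origin (south-west corner), decimal degrees.
#' @param highland_cooling peak temperature reduction of the central
#'   highlands (deg C).
#' @return a data frame of class `grid_spec` with columns loc_id, lat, lon,
#'   mean_tmax, mean_tmin, annual_rain, seasonal_rain, pawc.
#' @export
island_grid_spec <- function(n = 95, lat0 = 6.0, lon0 = 79.75,
                             highland_cooling = 9) {
  ncol_g <- ceiling(sqrt(n * 2 / 3))
  nrow_g <- ceiling(n / ncol_g)
  g <- expand.grid(col = seq_len(ncol_g) - 1L, row = seq_len(nrow_g) - 1L)
  g <- g[seq_len(n), ]
  lat <- lat0 + g$row * 0.25
  lon <- lon0 + g$col * 0.25
  # wetness: 1 at SW corner, 0 at NE corner
  w <- 1 - (g$row / max(1, max(g$row)) + g$col / max(1, max(g$col))) / 2
  # highland cooling: Gaussian bump centred in the grid interior
  rc <- max(g$row) * 0.45; cc <- max(g$col) * 0.45
  sp <- (max(1, max(g$row)) / 3.5)^2
  h <- exp(-((g$row - rc)^2 + (g$col - cc)^2) / (2 * sp))
  spec <- data.frame(
    loc_id = sprintf("g%02d", seq_len(n)),
    lat = lat, lon = lon,
    mean_tmax = round(33.5 - 2.5 * w - highland_cooling * h, 2),
    mean_tmin = round(24.5 - 2.0 * w - 0.9 * highland_cooling * h, 2),
    annual_rain = round(700 + 1600 * w),
    seasonal_rain = round(150 + 350 * w),
    pawc = round(90 + 60 * w),
    stringsAsFactors = FALSE)
  class(spec) <- c("grid_spec", "data.frame")
  spec
}

#' Generate weather for every location of a grid specification
#'
#' Each location gets its own calibrated generator (the shared template
#' rescaled to the location's target normals) and an independent seed derived
#' from `(seed, location index)`, so adding locations never perturbs existing
#' ones.
#'
#' @param spec a grid specification as from [island_grid_spec()].
#' @param years simulated years per location.
#' @param seed master integer seed.
#' @param start_year first calendar year.
#' @return a named list of `weather_series`, one per `loc_id`.
#' @export
generate_grid <- function(spec, years, seed = 1L, start_year = 1980) {
  template <- .template_gen_config()
  out <- vector("list", nrow(spec))
  names(out) <- spec$loc_id
  for (i in seq_len(nrow(spec))) {
    target <- climate_normals(spec$mean_tmax[i], spec$mean_tmin[i],
                              spec$annual_rain[i], spec$seasonal_rain[i])
    cfg <- calibrate_gen_config(target, template)
    cfg$seed <- .substream(seed, 100L + i)
    out[[i]] <- generate_weather(cfg, years, start_year = start_year,
                                 lat = spec$lat[i], lon = spec$lon[i],
                                 label = spec$loc_id[i])
  }
  out
}
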