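#' Cardinal temperatures for millet development
#'
#' Base, optimum and maximum temperatures of the triangular thermal-time
#' response used for all phases: 10, 30 and 45 deg C.
#'
#' @param t_base,t_opt,t_max cardinal temperatures (deg C), strictly ordered.
#' @return an object of class `cardinal_temps`.
#' @export
cardinal_temps <- function(t_base = 10, t_opt = 30, t_max = 45) {
  if (!(t_base < t_opt && t_opt < t_max))
    stop("require t_base < t_opt < t_max")
  structure(list(t_base = t_base, t_opt = t_opt, t_max = t_max),
            class = "cardinal_temps")
}

# CERES-style eight-point diurnal interpolation fractions of the
# tmin..tmax range (period i of 8)
.DIURNAL_FRAC <- local({
  i <- 1:8
  0.92105 + 0.1140 * i - 0.0703 * i^2 + 0.0053 * i^3
})

#' Daily thermal time from a triangular temperature response
#'
#' The response rises linearly from 0 at `t_base` to `t_opt - t_base` deg-days
#' at `t_opt`, then falls linearly to 0 at `t_max`.  `"daily-mean"` evaluates
#' it at `(tmin + tmax)/2`; `"diurnal-8pt"` averages it over eight standard
#' within-day interpolation temperatures, which matters when afternoon
#' temperatures exceed the optimum.
#'
#' @param tmin,tmax daily extremes (deg C), vectorised.
#' @param cardinals a [cardinal_temps()].
#' @param mode `"daily-mean"` or `"diurnal-8pt"`.
#' @return thermal time in deg C days, in `[0, t_opt - t_base]`.
#' @export
thermal_time <- function(tmin, tmax, cardinals = cardinal_temps(),
                         mode = c("daily-mean", "diurnal-8pt")) {
  mode <- match.arg(mode)
  f <- function(T) {
    tt <- numeric(length(T))
    up <- T > cardinals$t_base & T <= cardinals$t_opt
    dn <- T > cardinals$t_opt & T < cardinals$t_max
    tt[up] <- T[up] - cardinals$t_base
    tt[dn] <- (cardinals$t_opt - cardinals$t_base) *
      (cardinals$t_max - T[dn]) / (cardinals$t_max - cardinals$t_opt)
    tt
  }
  if (mode == "daily-mean") return(f((tmin + tmax) / 2))
  acc <- 0
  for (fr in .DIURNAL_FRAC) acc <- acc + f(tmin + fr * (tmax - tmin))
  acc / 8
}

#' Accession genotype coefficients
#'
#' The shipped table of calibrated coefficients for the five Proso millet
#' accessions (L_1, L_11, L_12, L_14, L_25): potential grains per head,
#' potential grain growth rate (mg/grain/day), and the phase thermal-time
#' targets (deg C days) plus the photoperiod sensitivity slope (deg C days
#' per hour).
#'
#' @param accession optional accession label; if given, the single row is
#'   returned as a list.
#' @return a data frame (all accessions) or a list (one accession).
#' @export
proso_genotypes <- function(accession = NULL) {
  path <- system.file("extdata", "proso_genotypes.csv",
                      package = "prosoclim", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(accession)) return(df)
  r <- df[df$accession == accession, ]
  if (nrow(r) != 1L) stop("unknown accession: ", accession)
  as.list(r)
}

#' Default soil profile (single-bucket water balance)
#'
#' None of these values come from a published soil survey of the study site;
#' they are a generic shallow dry-zone profile and are all configurable.
#'
#' @param pawc plant-available water capacity of the root zone (mm).
#' @param initial_fraction_full fraction of `pawc` present at sowing.
#' @param runoff_fraction fraction of daily rain above `intake_cap` lost to
#'   runoff.
#' @param intake_cap daily infiltration cap (mm/day).
#' @param soil_evap_coeff stage-1 bare-soil evaporation rate (mm/day).
#' @param kl maximum fraction of the available water extractable per day.
#' @param germination_threshold fraction of `pawc` required for germination.
#' @return an object of class `soil_profile`.
#' @export
soil_profile <- function(pawc = 120, initial_fraction_full = 0.6,
                         runoff_fraction = 1, intake_cap = 50,
                         soil_evap_coeff = 2, kl = 0.08,
                         germination_threshold = 0.15) {
  if (pawc <= 0) stop("pawc must be positive")
  fr <- c(initial_fraction_full, runoff_fraction, germination_threshold)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  structure(list(pawc = pawc, initial_fraction_full = initial_fraction_full,
                 runoff_fraction = runoff_fraction, intake_cap = intake_cap,
                 soil_evap_coeff = soil_evap_coeff, kl = kl,
                 germination_threshold = germination_threshold),
            class = "soil_profile")
}

#' Simulator configuration
#'
#' Crop- and canopy-level parameters that close the gaps the genotype table
#' leaves open.  None are site-measured values; all are generic millet-scale
#' defaults and configurable.
#'
#' @param rue radiation-use efficiency (g biomass per MJ intercepted).
#' @param te_coeff transpiration-efficiency coefficient (kPa): biomass per mm
#'   of water transpired is `1000 * te_coeff / vpd` g/m2/mm.
#' @param plant_density plants per m2.
#' @param heads_per_plant heads per plant.
#' @param tt_germ_to_emerg thermal-time target germination to emergence
#'   (deg C days).
#' @param tt_floralinit_to_flagleaf thermal-time target floral initiation to
#'   flag leaf (deg C days).
#' @param base_photoperiod photoperiod (h) below which the short-day floral
#'   induction delay vanishes.
#' @param twilight_angle solar angle (degrees, negative below horizon) that
#'   defines day length.
#' @param chill_opt daily mean temperature (deg C) below which C4
#'   photosynthetic efficiency declines linearly towards zero at the base
#'   temperature; full efficiency at or above it.
#' @param max_harvest_index upper bound on grain/biomass ratio.
#' @param cover_tt50 cumulative thermal time at which canopy cover reaches
#'   one half (deg C days).
#' @param cover_rate steepness of the canopy-cover logistic (per deg C day).
#' @param retrans_fraction fraction of biomass at the start of grain fill
#'   available for retranslocation to grain.
#' @param tt_mode thermal-time mode, see [thermal_time()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(rue = 2.2, te_coeff = 0.009, plant_density = 10,
                       heads_per_plant = 1.0, tt_germ_to_emerg = 40,
                       tt_floralinit_to_flagleaf = 180,
                       base_photoperiod = 11.5, twilight_angle = -2.2,
                       chill_opt = 24, max_harvest_index = 0.45,
                       cover_tt50 = 350, cover_rate = 0.012,
                       retrans_fraction = 0.1, tt_mode = "daily-mean") {
  if (max_harvest_index <= 0 || max_harvest_index > 1)
    stop("max_harvest_index must lie in (0, 1]")
  structure(list(rue = rue, te_coeff = te_coeff,
                 plant_density = plant_density,
                 heads_per_plant = heads_per_plant,
                 tt_germ_to_emerg = tt_germ_to_emerg,
                 tt_floralinit_to_flagleaf = tt_floralinit_to_flagleaf,
                 base_photoperiod = base_photoperiod,
                 twilight_angle = twilight_angle,
                 chill_opt = chill_opt,
                 max_harvest_index = max_harvest_index,
                 cover_tt50 = cover_tt50, cover_rate = cover_rate,
                 retrans_fraction = retrans_fraction, tt_mode = tt_mode),
            class = "sim_config")
}

#' The eleven crop stages, in order
#' @return character vector of stage names.
#' @export
crop_stages <- function() {
  c("sowing", "germination", "emergence", "end_juvenile",
    "floral_initiation", "flag_leaf", "flowering", "start_grain_fill",
    "end_grain_fill", "maturity", "harvest_ripe")
}

#' Day length from solar geometry
#'
#' Standard solar-declination day length at a latitude, with a configurable
#' twilight angle.
#'
#' @param lat latitude (decimal degrees).
#' @param doy day of year (1-366), vectorised.
#' @param twilight_angle solar elevation angle defining day/night (degrees).
#' @return day length in hours.
#' @export
day_length <- function(lat, doy, twilight_angle = -2.2) {
  decl <- 23.45 * sin(2 * pi * (284 + doy) / 365) * pi / 180
  latr <- lat * pi / 180
  a <- twilight_angle * pi / 180
  cosH <- (sin(a) - sin(latr) * sin(decl)) / (cos(latr) * cos(decl))
  cosH <- pmin(1, pmax(-1, cosH))
  2 * acos(cosH) * 180 / pi / 15
}

#' Thermal-time target to exit a phase
#'
#' Returns the deg C day target that ends the phase beginning at `stage`.
#' Emergence, flag-leaf, flowering and maturity phases come from the genotype
#' table; the floral-induction phase is the short-day response
#' `photoperiod_sensitivity * max(0, daylength - base_photoperiod)`; grain
#' fill is allocated the flowering-to-maturity total minus the
#' flowering-to-start-grain-fill lag, with end-grain-fill and maturity
#' coincident (target 0).  The sowing phase has no thermal target (it is
#' soil-moisture-controlled).
#'
#' @param stage stage name opening the phase (see [crop_stages()]).
#' @param genotype a genotype row, see [proso_genotypes()].
#' @param config a [sim_config()].
#' @param daylength day length (h), used only for the floral-induction phase.
#' @return thermal-time target (deg C days).
#' @export
phase_target <- function(stage, genotype, config, daylength = 12) {
  switch(stage,
    germination = config$tt_germ_to_emerg,
    emergence = genotype$tt_emerg_to_endjuv,
    end_juvenile = genotype$photoperiod_sensitivity *
      max(0, daylength - config$base_photoperiod),
    floral_initiation = config$tt_floralinit_to_flagleaf,
    flag_leaf = genotype$tt_flagleaf_to_flower,
    flowering = genotype$tt_flower_to_startgrainfill,
    start_grain_fill = genotype$tt_flower_to_maturity -
      genotype$tt_flower_to_startgrainfill,
    end_grain_fill = 0,
    maturity = genotype$tt_maturity_to_ripe,
    stop("no thermal-time-controlled exit from stage '", stage, "'"))
}

#' Initial crop state at sowing
#'
#' @param soil a [soil_profile()].
#' @return a `crop_state` list; see [step_day()] for the fields.
#' @export
new_crop_state <- function(soil = soil_profile()) {
  list(stage = 1L, cum_tt = 0, cum_tt_cover = 0, cover = 0, biomass = 0,
       grain_number = 0, grain_weight = 0,
       soil_water = soil$initial_fraction_full * soil$pawc,
       stress_photo = 1, stress_pheno = 1,
       pre_stress_sum = 0, pre_stress_n = 0L,
       gf_stress_sum = 0, gf_stress_n = 0L,
       retrans_pool = 0, runoff = 0, soil_evap = 0, transp = 0,
       day = 0L, transitions = rep(NA_integer_, 11L))
}

# saturation vapour pressure (kPa), Tetens
.svp <- function(T) 0.6108 * exp(17.27 * T / (T + 237.3))

#' Advance the crop state by one day
#'
#' The daily order of operations: (1) water balance (infiltration with a
#' runoff cap, stage-1 soil evaporation); (2) potential growth
#' `rue * srad * cover`, cover a logistic in cumulative thermal time from
#' emergence; (3) transpiration demand `potential * vpd / (1000 te_coeff)`
#' with vpd from `0.75 tmax + 0.25 tmin` against tmin, floored at 0.1 kPa;
#' (4) supply `kl * soil_water`; (5) the water-stress factor
#' `min(1, supply/demand)` scales growth, transpiration is
#' `min(demand, supply)`; (6) the same factor multiplies daily thermal time
#' between emergence and flag leaf (stress delays phenology there);
#' (7) thermal-time accumulation and stage transitions (germination requires
#' soil water above the germination threshold); (8) grain number is fixed at
#' flowering, scaled by mean pre-flowering stress; (9) during grain fill,
#' grain growth is sink-limited (`grain_number * rate * stress`), capped by
#' the day's assimilate plus a retranslocation pool, and by the maximum
#' harvest index.
#'
#' @param state a `crop_state` from [new_crop_state()].
#' @param wx one daily record: a list/row with tmin, tmax, rain, srad and
#'   `doy` (day of year).
#' @param soil a [soil_profile()].
#' @param genotype a genotype row ([proso_genotypes()]).
#' @param config a [sim_config()].
#' @param cardinals a [cardinal_temps()].
#' @param lat latitude for day length (floral induction).
#' @return the updated `crop_state`.
#' @export
step_day <- function(state, wx, soil, genotype, config,
                     cardinals = cardinal_temps(), lat = 6.428) {
  st <- state
  st$day <- st$day + 1L
  stage <- st$stage

  # (1) water balance
  rain <- wx$rain
  runoff <- soil$runoff_fraction * max(0, rain - soil$intake_cap)
  sw <- st$soil_water + rain - runoff
  if (sw > soil$pawc) {              # saturation excess joins runoff
    runoff <- runoff + (sw - soil$pawc)
    sw <- soil$pawc
  }
  pot_evap <- soil$soil_evap_coeff * (1 - st$cover) *
    (if (rain >= 0.2) 1 else 0.3)
  evap <- min(pot_evap, sw)
  sw <- sw - evap

  # (2) potential growth
  emerged <- stage >= 3L
  active <- emerged && stage < 10L   # growth stops at maturity
  cover <- if (emerged)
    1 / (1 + exp(-config$cover_rate * (st$cum_tt_cover - config$cover_tt50)))
  else 0
  # C4 chilling limitation: photosynthetic efficiency declines linearly
  # below chill_opt, reaching zero at the base development temperature
  tmean <- (wx$tmin + wx$tmax) / 2
  f_chill <- min(1, max(0, (tmean - 10) / (config$chill_opt - 10)))
  pot_growth <- if (active) config$rue * wx$srad * cover * f_chill else 0

  # (3)-(5) water-limited growth
  vpd <- max(0.1, .svp(0.75 * wx$tmax + 0.25 * wx$tmin) - .svp(wx$tmin))
  demand <- pot_growth * vpd / (1000 * config$te_coeff)
  supply <- soil$kl * sw
  stress <- if (demand > 0) min(1, supply / demand) else 1
  growth <- pot_growth * stress
  transp <- if (active) min(demand, supply) else 0
  sw <- sw - transp
  st$biomass <- st$biomass + growth
  st$stress_photo <- stress
  if (emerged && stage < 7L) {       # pre-flowering stress record
    st$pre_stress_sum <- st$pre_stress_sum + stress
    st$pre_stress_n <- st$pre_stress_n + 1L
  }

  # (6)-(7) phenology (tt/daylength may be precomputed by run_season)
  tt <- if (is.null(wx$tt))
    thermal_time(wx$tmin, wx$tmax, cardinals, config$tt_mode) else wx$tt
  delayed <- stage >= 3L && stage < 6L   # emergence..flag-leaf phases
  st$stress_pheno <- if (delayed) stress else 1
  tt_eff <- tt * st$stress_pheno
  stages <- crop_stages()
  if (stage == 1L) {
    if (sw >= soil$germination_threshold * soil$pawc) {
      stage <- 2L
      st$transitions[2L] <- st$day
      st$cum_tt <- 0
    }
  } else if (stage < 11L) {
    st$cum_tt <- st$cum_tt + tt_eff
    if (emerged) st$cum_tt_cover <- st$cum_tt_cover + tt_eff
    repeat {
      if (stage >= 11L) break
      dl <- if (is.null(wx$daylength))
        day_length(lat, wx$doy, config$twilight_angle) else wx$daylength
      target <- phase_target(stages[stage], genotype, config, dl)
      if (st$cum_tt < target) break
      st$cum_tt <- st$cum_tt - target
      stage <- stage + 1L
      st$transitions[stage] <- st$day
      if (stage == 7L) {             # (8) flowering: fix grain number
        pre <- if (st$pre_stress_n > 0) st$pre_stress_sum / st$pre_stress_n else 1
        st$grain_number <- genotype$potential_grains_per_head *
          config$heads_per_plant * config$plant_density * pre
      }
      if (stage == 8L)               # start grain fill: retranslocation pool
        st$retrans_pool <- config$retrans_fraction * st$biomass
    }
  }

  # (9) grain fill: sink advances per degree-day, so the potential grain
  # mass depends on the fill phase's thermal target, not its calendar span
  if (stage == 8L && st$grain_number > 0) {
    dev_rate <- tt / (cardinals$t_opt - cardinals$t_base)
    sink <- st$grain_number * genotype$potential_grain_growth_rate *
      dev_rate * stress / 1000
    inc <- min(sink, growth + st$retrans_pool)
    inc <- min(inc, config$max_harvest_index * st$biomass - st$grain_weight)
    inc <- max(0, inc)
    st$retrans_pool <- st$retrans_pool - max(0, inc - growth)
    st$grain_weight <- st$grain_weight + inc
    st$gf_stress_sum <- st$gf_stress_sum + stress
    st$gf_stress_n <- st$gf_stress_n + 1L
  }

  st$stage <- stage
  st$cover <- cover
  st$soil_water <- sw
  st$runoff <- st$runoff + runoff
  st$soil_evap <- st$soil_evap + evap
  st$transp <- st$transp + transp
  st
}

#' Simulate one growing season
#'
#' Runs [step_day()] from the sowing date until harvest-ripe or a hard stop
#' 30 days after the season window closes, whichever comes first.  Yield in
#' kg/ha is grain weight (g/m2) times 10.
#'
#' @param weather a valid `weather_series` covering the season.
#' @param year calendar year of the season.
#' @param genotype an accession label or a genotype row list.
#' @param soil a [soil_profile()].
#' @param config a [sim_config()].
#' @param cardinals a [cardinal_temps()].
#' @param sowing sowing month-day, `"MM-DD"`.
#' @param window the [season_window()] (its end sets the hard stop).
#' @return a one-row data frame: year, accession, yield and biomass (kg/ha),
#'   season_rain (mm), mean stresses, failure flag/reason, and one date
#'   column per stage transition reached.
#' @export
run_season <- function(weather, year, genotype, soil = soil_profile(),
                       config = sim_config(), cardinals = cardinal_temps(),
                       sowing = "03-15", window = season_window()) {
  if (is.character(genotype)) genotype <- proso_genotypes(genotype)
  sow_date <- as.Date(sprintf("%d-%s", year, sowing))
  stop_date <- .window_dates(window, year)[2] + 30
  keep <- weather$date >= sow_date & weather$date <= stop_date
  if (weather$date[1] > sow_date || weather$date[nrow(weather)] < stop_date)
    stop("weather does not cover ", sow_date, " to ", stop_date)
  wxd <- as.data.frame(weather)[keep, ]
  doy <- as.integer(format(wxd$date, "%j"))
  lat <- attr(weather, "location")$lat
  if (is.na(lat)) lat <- 6.428

  tmin <- wxd$tmin; tmax <- wxd$tmax; rain <- wxd$rain; srad <- wxd$srad
  tt <- thermal_time(tmin, tmax, cardinals, config$tt_mode)
  dl <- day_length(lat, doy, config$twilight_angle)
  st <- new_crop_state(soil)
  water0 <- st$soil_water
  for (i in seq_len(nrow(wxd))) {
    st <- step_day(st,
                   list(tmin = tmin[i], tmax = tmax[i], rain = rain[i],
                        srad = srad[i], doy = doy[i], tt = tt[i],
                        daylength = dl[i]),
                   soil, genotype, config, cardinals, lat)
    if (st$stage >= 11L) break
  }

  failed <- FALSE; reason <- ""
  if (st$stage == 1L) { failed <- TRUE; reason <- "no germination" }
  else if (st$stage < 10L) { failed <- TRUE; reason <- "season ended before maturity" }

  tr <- st$transitions
  dates <- as.Date(ifelse(is.na(tr), NA, as.numeric(sow_date) + tr - 1),
                   origin = "1970-01-01")
  names(dates) <- paste0("date_", crop_stages())
  slim <- .window_dates(window, year)
  season_rain <- sum(weather$rain[weather$date >= slim[1] &
                                    weather$date <= slim[2]])
  out <- data.frame(
    year = year, accession = genotype$accession,
    yield = st$grain_weight * 10, biomass = st$biomass * 10,
    season_rain = season_rain,
    stress_preflower = if (st$pre_stress_n > 0)
      st$pre_stress_sum / st$pre_stress_n else NA_real_,
    stress_grainfill = if (st$gf_stress_n > 0)
      st$gf_stress_sum / st$gf_stress_n else NA_real_,
    failed = failed, failure_reason = reason,
    water_balance_error = water0 + sum(wxd$rain[seq_len(st$day)]) -
      (st$soil_water + st$runoff + st$soil_evap + st$transp),
    stringsAsFactors = FALSE)
  out[names(dates)] <- as.list(dates)
  out
}

#' Run a factorial years-by-accessions simulation campaign
#'
#' @param weather a valid `weather_series` covering all requested seasons.
#' @param years integer vector of season years.
#' @param accessions character vector of accession labels (default all five).
#' @param ... passed to [run_season()] (soil, config, cardinals, ...).
#' @return a data frame with one row per (year, accession), in stable
#'   year-major order.
#' @export
run_campaign <- function(weather, years, accessions = proso_genotypes()$accession,
                         ...) {
  gen <- lapply(accessions, proso_genotypes)
  names(gen) <- accessions
  rows <- vector("list", length(years) * length(accessions))
  k <- 0L
  for (y in years) for (a in accessions) {
    k <- k + 1L
    rows[[k]] <- run_season(weather, y, gen[[a]], ...)
  }
  do.call(rbind, rows)
}
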