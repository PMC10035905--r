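test_that("triangular thermal time matches hand-evaluated values", {
  card <- cardinal_temps()
  expect_equal(thermal_time(10, 10, card), 0)            # at base
  expect_equal(thermal_time(30, 30, card), 20)           # at optimum
  expect_equal(thermal_time(23.3, 32.1, card), 17.7)     # f((23.3+32.1)/2)
  expect_equal(thermal_time(45, 45, card), 0)            # at maximum
  expect_equal(thermal_time(35, 45, card), 20 * (45 - 40) / 15)
  # supra-optimal afternoons: the 8-point mode is below the daily-mean mode
  expect_lt(thermal_time(25, 44, card, "diurnal-8pt"),
            thermal_time(25, 44, card, "daily-mean"))
  expect_error(cardinal_temps(30, 10, 45), "t_base < t_opt")
})

test_that("phase targets come from the genotype table and the short-day response", {
  cfg <- sim_config()
  g1 <- proso_genotypes("L_1")
  expect_equal(phase_target("emergence", g1, cfg), 348.5)
  g25 <- proso_genotypes("L_25")
  expect_equal(phase_target("start_grain_fill", g25, cfg), 457 - 95)
  # at the base photoperiod the floral-induction delay vanishes
  expect_equal(phase_target("end_juvenile", g1, cfg,
                            daylength = cfg$base_photoperiod), 0)
  expect_equal(phase_target("end_juvenile", g1, cfg,
                            daylength = cfg$base_photoperiod + 1), 112.4)
  expect_equal(phase_target("end_grain_fill", g1, cfg), 0)
  expect_equal(phase_target("maturity", g1, cfg), 1)
  expect_error(phase_target("sowing", g1, cfg), "sowing")
})

test_that("a day without energy adds no biomass and loses only evaporation", {
  soil <- soil_profile()
  st <- new_crop_state(soil)
  st$stage <- 3L; st$cum_tt_cover <- 350   # emerged, half cover
  g <- proso_genotypes("L_1")
  sw0 <- st$soil_water
  out <- step_day(st, list(tmin = 23.3, tmax = 32.1, rain = 0, srad = 0,
                           doy = 100), soil, g, sim_config())
  expect_equal(out$biomass, 0)
  expect_equal(out$transp, 0)
  expect_equal(out$soil_water, sw0 - out$soil_evap)
})

test_that("water-limited growth follows the supply/demand arithmetic", {
  # saturated bucket, full cover, srad 20, rue 2.2:
  # potential = 44 g/m2; vpd(23.3, 32.1) = svp(29.9) - svp(23.3) = 1.358 kPa;
  # demand = 44 * 1.358 / 9 = 6.64 mm < supply = 0.08 * 120 = 9.6 mm
  soil <- soil_profile(initial_fraction_full = 1, soil_evap_coeff = 0)
  st <- new_crop_state(soil)
  st$stage <- 3L; st$cum_tt_cover <- 1e6   # cover ~ 1
  cfg <- sim_config()
  out <- step_day(st, list(tmin = 23.3, tmax = 32.1, rain = 0, srad = 20,
                           doy = 100), soil, proso_genotypes("L_1"), cfg)
  svp <- function(T) 0.6108 * exp(17.27 * T / (T + 237.3))
  vpd <- svp(0.75 * 32.1 + 0.25 * 23.3) - svp(23.3)
  demand <- 44 * vpd / (1000 * cfg$te_coeff)
  expect_equal(out$stress_photo, 1)
  expect_equal(out$biomass, 44, tolerance = 1e-6)
  expect_equal(out$transp, demand, tolerance = 1e-6)

  # drain the bucket: growth is scaled by supply/demand
  soil2 <- soil_profile(initial_fraction_full = 0.1, soil_evap_coeff = 0)
  st2 <- new_crop_state(soil2)
  st2$stage <- 3L; st2$cum_tt_cover <- 1e6
  out2 <- step_day(st2, list(tmin = 23.3, tmax = 32.1, rain = 0, srad = 20,
                             doy = 100), soil2, proso_genotypes("L_1"), cfg)
  supply <- soil2$kl * 12
  expect_equal(out2$stress_photo, supply / demand, tolerance = 1e-9)
  expect_equal(out2$biomass, 44 * supply / demand, tolerance = 1e-6)
})

test_that("a dry sowing never germinates and the failure is flagged", {
  wx <- const_series(2001, rain = 0)
  soil <- soil_profile(initial_fraction_full = 0)
  r <- run_season(wx, 2001, "L_1", soil = soil)
  expect_true(r$failed)
  expect_identical(r$failure_reason, "no germination")
  expect_equal(r$yield, 0)
})

test_that("seasonal water balance closes and yield respects the harvest-index cap", {
  wx <- baseline_wx()
  cam <- run_campaign(wx, 1980:2009, c("L_1", "L_25"))
  expect_true(all(abs(cam$water_balance_error) < 1e-6))
  expect_true(all(cam$yield >= 0))
  expect_true(all(cam$yield <= sim_config()$max_harvest_index * cam$biomass + 1e-9))
})

test_that("stage transitions are ordered and stress never accelerates phenology", {
  wx <- baseline_wx()
  r <- run_season(wx, 1983, "L_12")
  dates <- unlist(r[paste0("date_", crop_stages()[2:8])])
  dates <- dates[!is.na(dates)]
  expect_true(all(diff(dates) > 0))          # strict through start-grain-fill
  all10 <- unlist(r[paste0("date_", crop_stages()[2:11])])
  expect_true(all(diff(all10[!is.na(all10)]) >= 0))

  # removing water stress can only advance (or keep) every transition
  r0 <- run_season(wx, 1983, "L_12", soil = unstressed_soil())
  for (s in crop_stages()[3:10]) {
    d_str <- r[[paste0("date_", s)]]
    d_uns <- r0[[paste0("date_", s)]]
    if (!is.na(d_str) && !is.na(d_uns)) expect_lte(d_uns, d_str)
  }
})

test_that("the grain sink orders accessions and ripening time does not change yield", {
  wx <- baseline_wx()
  soil <- unstressed_soil()
  y25 <- mean(run_campaign(wx, 1981:1985, "L_25", soil = soil)$yield)
  y14 <- mean(run_campaign(wx, 1981:1985, "L_14", soil = soil)$yield)
  expect_gte(y25, y14)   # 3210 vs 2795 grains/head, longer grain fill

  g <- proso_genotypes("L_1")
  g2 <- g; g2$tt_maturity_to_ripe <- 50
  a <- run_season(wx, 1982, g)
  b <- run_season(wx, 1982, g2)
  expect_equal(a$yield, b$yield)
})

test_that("30-season mean yield sits in the plausible band with inter-annual spread", {
  cam <- run_campaign(baseline_wx(), 1980:2009)
  m <- mean(cam$yield)
  expect_gt(m, 500)
  expect_lt(m, 4000)
  expect_gt(stats::var(cam$yield), 0)
  expect_identical(nrow(cam), 150L)
})

test_that("warming reduces yield monotonically and drying reduces it monotonically", {
  wx <- baseline_wx()
  yrs <- 1980:2009
  mean_y <- function(dT, dP)
    mean(run_campaign(apply_anomaly(wx, dT, dP), yrs)$yield)
  base <- mean_y(0, 0)
  y1 <- mean_y(1, 0); y2 <- mean_y(2, 0); y3 <- mean_y(3, 0)
  expect_gt(y1, y2); expect_gt(y2, y3)
  expect_gt(base, y1)
  # slight cooling must not cost more than 2% of yield
  expect_gt(mean_y(-1, 0), 0.98 * base)
  d25 <- mean_y(0, -25); d50 <- mean_y(0, -50)
  expect_gt(base, d25); expect_gt(d25, d50)
})

test_that("run_campaign is the factorial of run_season", {
  wx <- baseline_wx()
  one <- run_campaign(wx, 1985, "L_11")
  direct <- run_season(wx, 1985, "L_11")
  expect_equal(one, direct)
  two <- run_campaign(wx, 1985:1986, c("L_1", "L_11"))
  expect_identical(nrow(two), 4L)
  expect_identical(two$accession, rep(c("L_1", "L_11"), 2))
})
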