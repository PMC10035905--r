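test_that("the sensitivity design has 99 members, exact marginal stratification, seeded pairing", {
  d <- make_c3mp_design(seed = 42L)
  expect_identical(nrow(d), 99L)
  expect_true(all(d$dT >= -1 & d$dT <= 8))
  expect_true(all(d$dP >= -50 & d$dP <= 50))

  # enumeration oracle: exactly one point per equal-width stratum, per margin
  count_strata <- function(x, lo, hi, n = 99L) {
    tabulate(findInterval(x, seq(lo, hi, length.out = n + 1L),
                          rightmost.closed = TRUE), nbins = n)
  }
  expect_identical(count_strata(d$dT, -1, 8), rep(1L, 99L))
  expect_identical(count_strata(d$dP, -50, 50), rep(1L, 99L))

  # different seeds: different pairings, same flat marginal occupancy
  d2 <- make_c3mp_design(seed = 43L)
  expect_false(identical(d$dT, d2$dT))
  expect_identical(count_strata(d2$dT, -1, 8), rep(1L, 99L))
  expect_identical(count_strata(d2$dP, -50, 50), rep(1L, 99L))
  # same seed reproduces the design
  expect_identical(make_c3mp_design(seed = 42L), d)
  expect_error(make_c3mp_design(dT_range = c(8, -1)), "ordered")
})

test_that("anomaly application shifts temperatures, scales rain, keeps wet days", {
  wx <- baseline_wx()
  expect_equal(as.data.frame(apply_anomaly(wx, 0, 0)), as.data.frame(wx))

  s0 <- season_slice(wx, 1984)
  half <- season_slice(apply_anomaly(wx, 0, -50), 1984)
  expect_equal(sum(half$rain), sum(s0$rain) / 2)

  hot <- apply_anomaly(wx, 8, 50)
  expect_equal(hot$tmax, wx$tmax + 8)
  expect_equal(hot$tmin, wx$tmin + 8)
  expect_identical(hot$rain > 0, wx$rain > 0)     # wet-day mask unchanged
  expect_identical(hot$date, wx$date)
  expect_identical(hot$srad, wx$srad)
  expect_error(apply_anomaly(wx, 0, -100), "-100")
})

test_that("temperature anomalies compose additively, rain multiplicatively", {
  wx <- season_slice(baseline_wx(), 1990)
  ab <- apply_anomaly(apply_anomaly(wx, 1.5, 0), 2.5, 0)
  expect_equal(as.data.frame(ab), as.data.frame(apply_anomaly(wx, 4, 0)))
  pq <- apply_anomaly(apply_anomaly(wx, 0, 20), 0, 25)
  expect_equal(as.data.frame(pq), as.data.frame(apply_anomaly(wx, 0, 50)))
})

test_that("delta application is monthly, validates, and zero delta is the identity", {
  wx <- baseline_wx()
  id <- gcm_delta("null", "RCP4.5", 0, 0, 1)
  expect_equal(as.data.frame(apply_delta(wx, id)), as.data.frame(wx))

  d <- gcm_delta("m", "RCP4.5", d_tmax = 1:12 / 10, d_tmin = 0, rain_ratio = 1)
  out <- apply_delta(wx, d)
  mon <- as.integer(format(wx$date, "%m"))
  expect_equal(out$tmax, wx$tmax + (1:12 / 10)[mon])
  expect_identical(out$srad, wx$srad)

  # a tmin delta large enough to cross tmax errors with the date
  bad <- gcm_delta("m", "RCP4.5", d_tmax = 0, d_tmin = 20, rain_ratio = 1)
  expect_error(apply_delta(wx, bad), "tmax < tmin on")
})

test_that("uniform deltas reproduce a future row's normals on the baseline series", {
  wx <- baseline_wx()
  b <- summarize_weather(wx)
  # warmest-model row: +2.1 C on tmax, and a wet-model annual ratio
  fut <- climate_normals(b$mean_tmax + 2.1, b$mean_tmin + 2.0,
                         b$annual_rain * 1628 / 1121, b$seasonal_rain)
  d <- delta_from_normals(b, fut)
  n <- summarize_weather(apply_delta(wx, d))
  expect_equal(n$mean_tmax, fut$mean_tmax, tolerance = 1e-10)
  expect_equal(n$mean_tmin, fut$mean_tmin, tolerance = 1e-10)
  expect_equal(n$annual_rain, fut$annual_rain, tolerance = 1e-10)
  expect_error(delta_from_normals(climate_normals(32, 23, 0, 0), fut),
               "zero")
})

test_that("seasonal-aware ensemble deltas reproduce both printed rainfall change signals", {
  wx <- baseline_wx()
  s <- summarize_weather(wx)
  ens <- load_gcm_ensemble()
  b <- ens[ens$scenario == "baseline", ][1, ]
  # rows where annual and seasonal changes pull in opposite directions,
  # plus the extreme seasonal outlier
  cases <- list(c("CSIRO-Mk3-6-0", "RCP4.5"), c("GFDL-ESM2G", "RCP4.5"),
                c("GFDL_CM3", "RCP8.5"))
  for (cs in cases) {
    row <- ens[ens$model == cs[1] & ens$scenario == cs[2], ]
    d <- ensemble_delta(ens, cs[1], cs[2], baseline_weather = wx)
    n <- summarize_weather(apply_delta(wx, d))
    expect_equal(n$annual_rain / s$annual_rain,
                 row$annual_rain / b$annual_rain, tolerance = 1e-9)
    expect_equal(n$seasonal_rain / s$seasonal_rain,
                 row$seasonal_rain / b$seasonal_rain, tolerance = 1e-9)
  }
  # without a baseline series the bridge stays uniform
  du <- ensemble_delta(ens, "CSIRO-Mk3-6-0", "RCP4.5")
  expect_equal(du$rain_ratio, rep(1628 / 1121, 12), tolerance = 1e-10)
})

test_that("round trip recovers every ensemble row's temperature and annual rain", {
  wx <- baseline_wx()
  b <- summarize_weather(wx)
  ens <- load_gcm_ensemble()
  rows <- ens[ens$scenario != "baseline", ]
  expect_identical(nrow(rows), 40L)
  for (i in seq_len(nrow(rows))) {
    fut <- climate_normals(rows$mean_tmax[i], rows$mean_tmin[i],
                           rows$annual_rain[i], rows$seasonal_rain[i])
    n <- summarize_weather(apply_delta(wx, delta_from_normals(b, fut)))
    expect_lt(abs(n$annual_rain - fut$annual_rain) / fut$annual_rain, 0.005)
    expect_lt(abs(n$mean_tmax - fut$mean_tmax), 0.005 * fut$mean_tmax)
    expect_lt(abs(n$mean_tmin - fut$mean_tmin), 0.005 * fut$mean_tmin)
  }
})
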