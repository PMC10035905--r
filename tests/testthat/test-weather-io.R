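test_that("csv and met dialects round-trip a validated series exactly", {
  wx <- generate_weather(default_gen_config(7L), 2L)
  for (dialect in c("csv", "met")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_weather(wx, f, dialect)
    back <- read_weather(f, dialect)
    expect_equal(wx_data(back), wx_data(wx))
    # writer output is bit-stable under a read/write cycle
    f2 <- withr::local_tempfile(fileext = ".txt")
    write_weather(back, f2, dialect)
    expect_identical(readLines(f), readLines(f2))
  }
})

test_that("reader rejects invariant violations, naming the offender", {
  df <- data.frame(date = as.Date("2001-01-01") + 0:3,
                   tmin = 20, tmax = 30, rain = c(0, 1, -1, 0), srad = 18)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_weather(f, "csv"), "negative rain.*2001-01-03")
  df$rain <- 0
  df$tmax[2] <- 15
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_weather(f, "csv"), "tmax < tmin.*2001-01-02")
  expect_error(read_weather(withr::local_tempfile(), "csv"), "no such file")
})

test_that("met year/day-of-year columns convert correctly for every day of a leap year", {
  # brute-force calendar oracle: enumerate all 366 dates of 2000 directly
  dates <- seq(as.Date("2000-01-01"), as.Date("2000-12-31"), by = "day")
  f <- withr::local_tempfile(fileext = ".met")
  writeLines(c("year day radn maxt mint rain",
               "() () (MJ/m2) (oC) (oC) (mm)",
               paste(2000, 1:366, 20, 32, 23, 0)), f)
  wx <- read_weather(f, "met")
  expect_identical(wx$date, dates)
  expect_identical(wx$date[60], as.Date("2000-02-29"))
})

test_that("gap_fill completes a gappy primary from the fallback and flags sources", {
  fb <- const_series(2001, rain = 1)
  # primary missing 10 whole days
  drop <- 41:50
  pr <- weather_series(as.data.frame(fb)[-drop, ], validate = FALSE)
  filled <- gap_fill(pr, fb)
  expect_identical(nrow(filled), nrow(fb))
  prov <- attr(filled, "provenance")
  expect_identical(sum(prov$rain == "fallback"), 10L)
  expect_equal(wx_data(filled), wx_data(fb))

  # complete primary: identity, zero fallback flags
  filled2 <- gap_fill(fb, fb)
  expect_equal(wx_data(filled2), wx_data(fb))
  expect_true(all(attr(filled2, "provenance")$tmin == "primary"))

  # primary with rain only: other variables all flagged fallback
  pr3 <- as.data.frame(fb)
  pr3$tmin <- NA; pr3$tmax <- NA; pr3$srad <- NA
  pr3 <- weather_series(pr3, validate = FALSE)
  filled3 <- gap_fill(pr3, fb)
  prov3 <- attr(filled3, "provenance")
  expect_true(all(prov3$tmin == "fallback"))
  expect_true(all(prov3$tmax == "fallback"))
  expect_true(all(prov3$srad == "fallback"))
  expect_true(all(prov3$rain == "primary"))

  # a value missing from both sources is a gap error naming the date
  fb_bad <- as.data.frame(fb); fb_bad$tmin[5] <- NA
  expect_error(gap_fill(pr3, weather_series(fb_bad, validate = FALSE)),
               "2001-01-05")
})

test_that("gap_fill is idempotent", {
  fb <- const_series(2001)
  pr <- weather_series(as.data.frame(fb)[-(100:120), ], validate = FALSE)
  once <- gap_fill(pr, fb)
  twice <- gap_fill(once, fb)
  expect_equal(as.data.frame(twice), as.data.frame(once))
  expect_identical(attr(twice, "provenance"), attr(once, "provenance"))
})

test_that("season_slice returns the inclusive 93-day window and its totals", {
  wx <- const_series(2001, rain = 2)
  s <- season_slice(wx, 2001)
  expect_identical(nrow(s), 93L)
  expect_identical(range(s$date), as.Date(c("2001-03-15", "2001-06-15")))
  expect_equal(sum(s$rain), 186)
  expect_identical(nrow(season_slice(const_series(2000), 2000)), 93L) # leap year too
  expect_error(season_slice(s, 2002), "does not cover")
})

test_that("summarize_weather computes day-means and per-year totals on complete years", {
  wx <- const_series(2001:2002, tmin = 23.3, tmax = 32.1, rain = 0)
  n <- summarize_weather(wx)
  expect_equal(n$mean_tmax, 32.1)
  expect_equal(n$mean_tmin, 23.3)
  expect_equal(n$annual_rain, 0)

  # all the year's rain on 1 Jan: annual total is caught, seasonal is zero
  df <- as.data.frame(const_series(2001, rain = 0))
  df$rain[1] <- 1121
  n2 <- summarize_weather(weather_series(df))
  expect_equal(n2$annual_rain, 1121)
  expect_equal(n2$seasonal_rain, 0)

  # concatenating identical years leaves the normals unchanged
  one <- const_series(2001, rain = 3)
  three <- const_series(2001:2003, rain = 3)
  expect_equal(summarize_weather(three)$annual_rain,
               summarize_weather(one)$annual_rain)
  expect_equal(summarize_weather(three)$seasonal_rain,
               summarize_weather(one)$seasonal_rain)

  # partial years are excluded from the normals
  wx3 <- weather_series(rbind(as.data.frame(one),
                              utils::head(as.data.frame(const_series(2002, rain = 50)), 40)))
  expect_equal(summarize_weather(wx3)$annual_rain, 3 * 365)
})

test_that("configuration objects round-trip through structured text files", {
  for (obj in list(default_gen_config(3L), sim_config(), soil_profile(),
                   cardinal_temps())) {
    f <- withr::local_tempfile(fileext = ".yml")
    write_config(obj, f)
    back <- read_config(f)
    expect_equal(back, obj)
  }
  expect_error(write_config(list(a = 1), tempfile()), "not a serialisable")

  spec <- island_grid_spec(12)
  f <- withr::local_tempfile(fileext = ".csv")
  write_grid_spec(spec, f)
  back <- read_grid_spec(f)
  expect_equal(as.data.frame(back), as.data.frame(spec))
  bad <- spec; bad$seasonal_rain <- bad$annual_rain + 1
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_grid_spec(bad, f2)
  expect_error(read_grid_spec(f2), "annual_rain")
})
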