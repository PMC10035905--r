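# small in-code fixtures shared across test files

# constant-valued daily series spanning whole calendar years
const_series <- function(years = 2000, tmin = 23.3, tmax = 32.1,
                         rain = 2, srad = 20, lat = 6.428, lon = 81.09) {
  dates <- seq(as.Date(paste0(min(years), "-01-01")),
               as.Date(paste0(max(years), "-12-31")), by = "day")
  weather_series(data.frame(date = dates, tmin = tmin, tmax = tmax,
                            rain = rain, srad = srad),
                 lat = lat, lon = lon, label = "const")
}

# cached synthetic baseline weather (31 calendar years, seasons 1980-2009)
baseline_wx <- local({
  wx <- NULL
  function() {
    if (is.null(wx)) wx <<- generate_weather(default_gen_config(1L), 31L)
    wx
  }
})

# soil so deep and full that water stress never develops
unstressed_soil <- function() {
  soil_profile(pawc = 5000, initial_fraction_full = 1, kl = 0.5,
               germination_threshold = 0)
}

# bare data columns of a weather series (drops site/provenance metadata,
# which a file reader cannot be expected to reconstruct)
wx_data <- function(w) {
  data.frame(date = w$date, tmin = w$tmin, tmax = w$tmax,
             rain = w$rain, srad = w$srad)
}

# exact two-sided permutation test on the difference of means
# (strict exceedance: permutations tying the observed arrangement are not
# counted, the convention under which the n=3 comparison with Welch is
# meaningful for well-separated samples)
perm_test_p <- function(a, b) {
  pool <- c(a, b)
  idx <- utils::combn(length(pool), length(a))
  obs <- abs(mean(a) - mean(b))
  ds <- apply(idx, 2, function(k) abs(mean(pool[k]) - mean(pool[-k])))
  mean(ds > obs + 1e-12)
}
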