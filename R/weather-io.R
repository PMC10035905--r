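#' Construct a daily weather series
#'
#' A weather series is a data frame of contiguous daily records with columns
#' `date` (class `Date`), `tmin`, `tmax` (deg C), `rain` (mm/day) and `srad`
#' (MJ/m2/day), carrying the site location as attributes.  Missing values are
#' encoded as `NA` (the single sentinel used throughout the package); a series
#' is only *valid* once it is gap-free.
#'
#' @param records data frame with columns date, tmin, tmax, rain, srad.
#' @param lat,lon site coordinates in decimal degrees (north / east positive).
#' @param elev site elevation in m (optional).
#' @param label free-text site label.
#' @param provenance optional data frame (same rows) with character columns
#'   tmin, tmax, rain, srad, each one of "primary", "fallback", "synthetic";
#'   defaults to "primary" everywhere.
#' @param validate check the series invariants (set `FALSE` for series that
#'   still contain gaps, e.g. before [gap_fill()]).
#' @return an object of class `weather_series`.
#' @export
weather_series <- function(records, lat = NA_real_, lon = NA_real_,
                           elev = NA_real_, label = "",
                           provenance = NULL, validate = TRUE) {
  need <- c("date", "tmin", "tmax", "rain", "srad")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("weather records lack column(s): ", paste(miss, collapse = ", "))
  records <- as.data.frame(records)[need]
  records$date <- as.Date(records$date)
  ord <- order(records$date)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  if (!is.null(provenance)) {
    provenance <- as.data.frame(provenance)[ord, , drop = FALSE]
    rownames(provenance) <- NULL
  }
  if (is.null(provenance)) {
    provenance <- data.frame(tmin = "primary", tmax = "primary",
                             rain = "primary", srad = "primary",
                             stringsAsFactors = FALSE)[rep(1L, nrow(records)), ,
                                                       drop = FALSE]
    rownames(provenance) <- NULL
  }
  structure(records,
            class = c("weather_series", "data.frame"),
            location = list(lat = lat, lon = lon, elev = elev, label = label),
            provenance = provenance) -> ws
  if (validate) validate_weather(ws)
  ws
}

#' Validate weather series invariants
#'
#' Checks: unique contiguous dates, `tmax >= tmin`, `rain >= 0`, `srad >= 0`,
#' no missing values.  Errors name the offending date.
#'
#' @param series a `weather_series`.
#' @return the series, invisibly, if valid.
#' @export
validate_weather <- function(series) {
  d <- series$date
  if (nrow(series) == 0L) stop("empty weather series")
  if (anyDuplicated(d)) stop("duplicate date: ", d[duplicated(d)][1])
  if (nrow(series) > 1L && any(diff(d) != 1))
    stop("gap in weather series after ", d[which(diff(d) != 1)[1]])
  for (v in c("tmin", "tmax", "rain", "srad"))
    if (anyNA(series[[v]]))
      stop("missing ", v, " on ", d[which(is.na(series[[v]]))[1]])
  bad <- which(series$tmax < series$tmin)
  if (length(bad)) stop("tmax < tmin on ", d[bad[1]])
  bad <- which(series$rain < 0)
  if (length(bad)) stop("negative rain on ", d[bad[1]])
  bad <- which(series$srad < 0)
  if (length(bad)) stop("negative srad on ", d[bad[1]])
  invisible(series)
}

#' @export
print.weather_series <- function(x, ...) {
  loc <- attr(x, "location")
  cat(sprintf("<weather_series> %d days  %s to %s\n", nrow(x),
              format(min(x$date)), format(max(x$date))))
  cat(sprintf("  site: %s (%.3f N, %.3f E)\n",
              if (nzchar(loc$label)) loc$label else "unnamed",
              loc$lat, loc$lon))
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("  ...\n")
  invisible(x)
}

# numeric formatter shared by the writers: full double precision, no
# scientific notation, so read(write(x)) is the identity for data recorded
# at any ordinary decimal precision
.fmt_num <- function(x) {
  vapply(x, function(v) format(v, digits = 15, trim = TRUE,
                               scientific = FALSE), character(1))
}

#' Read a daily weather series
#'
#' Two dialects are supported: `"csv"` with columns
#' `date` (ISO-8601), `tmin`, `tmax`, `rain`, `srad`; and `"met"`, an
#' APSIM-met-like whitespace-separated text format with a two-line header
#' (column names, then units) and columns `year day radn maxt mint rain`
#' (`day` is the day of year).
#'
#' @param path file path.
#' @param dialect `"csv"` or `"met"`.
#' @param lat,lon,elev,label site metadata (the met dialect stores lat/lon in
#'   its header; explicit arguments override).
#' @param validate validate the result (default `TRUE`; use `FALSE` to read a
#'   gappy primary source destined for [gap_fill()]).
#' @return a `weather_series`.
#' @export
read_weather <- function(path, dialect = c("csv", "met"),
                         lat = NA_real_, lon = NA_real_, elev = NA_real_,
                         label = "", validate = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("date", "tmin", "tmax", "rain", "srad")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("malformed weather csv ", path, ": missing column(s) ",
           paste(miss, collapse = ", "))
    d <- as.Date(df$date, format = "%Y-%m-%d")
    if (anyNA(d))
      stop("malformed date at line ", which(is.na(d))[1] + 1L, " of ", path)
    df$date <- d
  } else {
    lines <- readLines(path)
    meta <- grep("^!", lines, value = TRUE)
    body <- grep("^!", lines, invert = TRUE, value = TRUE)
    if (length(body) < 3L) stop("malformed met file ", path)
    hdr <- strsplit(trimws(body[1]), "\\s+")[[1]]
    dat <- utils::read.table(text = paste(body[-(1:2)], collapse = "\n"),
                             col.names = hdr)
    need <- c("year", "day", "radn", "maxt", "mint", "rain")
    miss <- setdiff(need, names(dat))
    if (length(miss))
      stop("malformed met file ", path, ": missing column(s) ",
           paste(miss, collapse = ", "))
    for (m in meta) {
      kv <- regmatches(m, regexec("^!\\s*(\\w+)\\s*=\\s*(-?[0-9.]+)", m))[[1]]
      if (length(kv) == 3L) {
        if (kv[2] == "latitude" && is.na(lat)) lat <- as.numeric(kv[3])
        if (kv[2] == "longitude" && is.na(lon)) lon <- as.numeric(kv[3])
      }
    }
    df <- data.frame(
      date = as.Date(dat$day - 1L, origin = as.Date(paste0(dat$year, "-01-01"))),
      tmin = dat$mint, tmax = dat$maxt, rain = dat$rain, srad = dat$radn)
  }
  weather_series(df, lat = lat, lon = lon, elev = elev, label = label,
                 validate = validate)
}

#' Write a daily weather series
#'
#' Inverse of [read_weather()]; both dialects round-trip bit-identically
#' (write, read, write reproduces the same file).
#'
#' @param series a `weather_series`.
#' @param path output file path.
#' @param dialect `"csv"` or `"met"`.
#' @return `path`, invisibly.
#' @export
write_weather <- function(series, path, dialect = c("csv", "met")) {
  dialect <- match.arg(dialect)
  loc <- attr(series, "location")
  if (dialect == "csv") {
    df <- data.frame(date = format(series$date, "%Y-%m-%d"),
                     tmin = .fmt_num(series$tmin),
                     tmax = .fmt_num(series$tmax),
                     rain = .fmt_num(series$rain),
                     srad = .fmt_num(series$srad))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.na(loc$lat)) writeLines(sprintf("! latitude = %s", .fmt_num(loc$lat)), con)
    if (!is.na(loc$lon)) writeLines(sprintf("! longitude = %s", .fmt_num(loc$lon)), con)
    writeLines("year day radn maxt mint rain", con)
    writeLines("() () (MJ/m2) (oC) (oC) (mm)", con)
    yr <- as.integer(format(series$date, "%Y"))
    doy <- as.integer(format(series$date, "%j"))
    writeLines(paste(yr, doy, .fmt_num(series$srad), .fmt_num(series$tmax),
                     .fmt_num(series$tmin), .fmt_num(series$rain)), con)
  }
  invisible(path)
}

#' Fill gaps in a primary weather series from a fallback source
#'
#' Every day in the fallback's date range is present in the result; each value
#' is taken from the primary when available, otherwise from the fallback, and
#' the per-value provenance ("primary"/"fallback") is recorded in the
#' `provenance` attribute.  Typical use: merge station observations with a
#' reanalysis product.  The operation is idempotent.
#'
#' @param primary a `weather_series`, possibly with missing days or values
#'   (read with `validate = FALSE`).
#' @param fallback a complete, valid `weather_series` covering the full range.
#' @return a complete `weather_series` with provenance flags.
#' @export
gap_fill <- function(primary, fallback) {
  validate_weather(fallback)
  dates <- fallback$date
  idx <- match(dates, primary$date)
  prov_p <- attr(primary, "provenance")
  out <- as.data.frame(fallback)[c("date", "tmin", "tmax", "rain", "srad")]
  prov <- attr(fallback, "provenance")
  prov[] <- "fallback"
  for (v in c("tmin", "tmax", "rain", "srad")) {
    pv <- primary[[v]][idx]                 # NA where day absent from primary
    use <- !is.na(pv)
    out[[v]][use] <- pv[use]
    src <- rep("fallback", length(dates))
    src[use] <- prov_p[[v]][idx[use]]
    prov[[v]] <- src
  }
  if (anyNA(out[-1]))
    stop("day missing from both sources: ",
         dates[which(rowSums(is.na(out[-1])) > 0)[1]])
  loc <- attr(primary, "location")
  weather_series(out, lat = loc$lat, lon = loc$lon, elev = loc$elev,
                 label = loc$label, provenance = prov)
}

#' Growing-season window
#'
#' The crop's growing season, fixed to calendar dates and inclusive on both
#' ends.  The default, 15 March to 15 June (93 days in every year), is the
#' Proso millet season in the study region's secondary rainy season.
#'
#' @param start,end month-day strings `"MM-DD"`.
#' @return a `season_window` (list with start/end).
#' @export
season_window <- function(start = "03-15", end = "06-15") {
  structure(list(start = start, end = end), class = "season_window")
}

.window_dates <- function(window, year) {
  c(as.Date(sprintf("%d-%s", year, window$start)),
    as.Date(sprintf("%d-%s", year, window$end)))
}

#' Extract one growing season from a weather series
#'
#' @param series a valid `weather_series`.
#' @param year calendar year of the season.
#' @param window a [season_window()]; both endpoints included.
#' @return a `weather_series` covering exactly the window (93 days for the
#'   default window).
#' @export
season_slice <- function(series, year, window = season_window()) {
  lim <- .window_dates(window, year)
  keep <- series$date >= lim[1] & series$date <= lim[2]
  if (series$date[1] > lim[1] || series$date[nrow(series)] < lim[2])
    stop("series does not cover ", lim[1], " to ", lim[2])
  loc <- attr(series, "location")
  prov <- attr(series, "provenance")[keep, , drop = FALSE]
  weather_series(as.data.frame(series)[keep, , drop = FALSE],
                 lat = loc$lat, lon = loc$lon, elev = loc$elev,
                 label = loc$label, provenance = prov)
}

#' Climate normals container
#'
#' @param mean_tmax,mean_tmin mean daily maximum / minimum temperature (deg C)
#'   over all days of the period.
#' @param annual_rain mean annual rainfall total (mm/yr).
#' @param seasonal_rain mean growing-season rainfall total (mm/season).
#' @param period integer vector of the calendar years summarised.
#' @param window the [season_window()] used for `seasonal_rain`.
#' @return an object of class `climate_normals`.
#' @export
climate_normals <- function(mean_tmax, mean_tmin, annual_rain, seasonal_rain,
                            period = integer(), window = season_window()) {
  if (annual_rain < seasonal_rain || seasonal_rain < 0)
    stop("require annual_rain >= seasonal_rain >= 0")
  structure(list(mean_tmax = mean_tmax, mean_tmin = mean_tmin,
                 annual_rain = annual_rain, seasonal_rain = seasonal_rain,
                 period = period, window = window),
            class = "climate_normals")
}

#' @export
print.climate_normals <- function(x, ...) {
  cat(sprintf(paste0("<climate_normals> Tmax %.1f C  Tmin %.1f C  ",
                     "annual rain %.0f mm  seasonal rain %.0f mm\n"),
              x$mean_tmax, x$mean_tmin, x$annual_rain, x$seasonal_rain))
  if (length(x$period))
    cat(sprintf("  period %d-%d, season %s to %s\n", min(x$period),
                max(x$period), x$window$start, x$window$end))
  invisible(x)
}

#' Summarise a weather series into climate normals
#'
#' Temperature normals are means of daily values over all complete calendar
#' years; `annual_rain` is the mean of per-year totals and `seasonal_rain`
#' the mean of per-season totals.  Partial first/last years are excluded.
#'
#' @param series a valid `weather_series` covering at least one complete
#'   calendar year.
#' @param window the growing-season window.
#' @return a [climate_normals()] object.
#' @export
summarize_weather <- function(series, window = season_window()) {
  validate_weather(series)
  yr <- as.integer(format(series$date, "%Y"))
  counts <- table(yr)
  ylen <- ifelse(as.integer(names(counts)) %% 4L == 0L &
                   (as.integer(names(counts)) %% 100L != 0L |
                      as.integer(names(counts)) %% 400L == 0L), 366L, 365L)
  complete <- as.integer(names(counts))[as.integer(counts) == ylen]
  if (!length(complete)) stop("no complete calendar year in series")
  keep <- yr %in% complete
  seas <- vapply(complete, function(y) {
    lim <- .window_dates(window, y)
    sum(series$rain[series$date >= lim[1] & series$date <= lim[2]])
  }, numeric(1))
  climate_normals(
    mean_tmax = mean(series$tmax[keep]),
    mean_tmin = mean(series$tmin[keep]),
    annual_rain = mean(tapply(series$rain[keep], yr[keep], sum)),
    seasonal_rain = mean(seas),
    period = complete, window = window)
}
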