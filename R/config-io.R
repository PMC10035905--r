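#' Write a configuration object to a structured text file
#'
#' Serialises a [weather_gen_config()], [sim_config()], [soil_profile()] or
#' [cardinal_temps()] as YAML, with a `type` key recording the class, so
#' campaign settings can live beside the data they produced.
#'
#' @param x the configuration object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(x, path) {
  type <- class(x)[1]
  if (!type %in% c("weather_gen_config", "sim_config", "soil_profile",
                   "cardinal_temps"))
    stop("not a serialisable configuration object: ", type)
  fields <- unclass(x)
  fields$p_wd <- NULL    # derived, recomputed by the constructor
  writeLines(yaml::as.yaml(c(list(type = type), fields)), path)
  invisible(path)
}

#' Read a configuration object written by [write_config()]
#'
#' @param path file path.
#' @return the restored, re-validated configuration object.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  type <- y$type
  y$type <- NULL
  switch(type,
    weather_gen_config = do.call(weather_gen_config, y),
    sim_config = do.call(sim_config, y),
    soil_profile = do.call(soil_profile, y),
    cardinal_temps = do.call(cardinal_temps, y),
    stop("unknown configuration type in ", path, ": ", type))
}

#' Write / read a grid specification as CSV
#'
#' @param spec a `grid_spec` as from [island_grid_spec()].
#' @param path file path.
#' @return `write_grid_spec`: `path`, invisibly; `read_grid_spec`: the
#'   validated `grid_spec`.
#' @export
write_grid_spec <- function(spec, path) {
  utils::write.csv(as.data.frame(spec), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_spec
#' @export
read_grid_spec <- function(path) {
  spec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("loc_id", "lat", "lon", "mean_tmax", "mean_tmin",
            "annual_rain", "seasonal_rain", "pawc")
  miss <- setdiff(need, names(spec))
  if (length(miss))
    stop("grid spec lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(spec$loc_id)) stop("duplicate loc_id in grid spec")
  if (any(spec$annual_rain < spec$seasonal_rain))
    stop("annual_rain must be >= seasonal_rain at every location")
  class(spec) <- c("grid_spec", "data.frame")
  spec
}
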