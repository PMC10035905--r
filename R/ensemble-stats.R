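#' Percent change relative to a baseline value
#'
#' @param value,baseline_value numeric (vectorised over `value`).
#' @return `100 * (value - baseline_value) / baseline_value`.
#' @export
percent_change <- function(value, baseline_value) {
  if (any(baseline_value == 0)) stop("zero baseline value")
  100 * (value - baseline_value) / baseline_value
}

# internal: pull one scenario's values of one variable, with baseline
.ens_values <- function(ensemble, variable, scenario) {
  if (!variable %in% names(ensemble)) stop("unknown variable: ", variable)
  b <- ensemble[ensemble$scenario == "baseline", variable][1]
  r <- ensemble[ensemble$scenario == scenario &
                  !ensemble$model %in% "Multi-model mean", ]
  r <- r[order(r$label), ]
  list(baseline = b, models = r$model, labels = r$label,
       values = r[[variable]])
}

#' Count ensemble members beyond a threshold
#'
#' Strict inequality against either the baseline value of the variable or an
#' absolute threshold; also reports the share of the ensemble.
#'
#' @param ensemble a `gcm_ensemble` ([load_gcm_ensemble()]).
#' @param variable one of mean_tmax, mean_tmin, annual_rain, seasonal_rain.
#' @param scenario `"RCP4.5"` or `"RCP8.5"`.
#' @param direction `"above"` or `"below"`.
#' @param threshold `"baseline"` or a number.
#' @return list with `count`, `n`, `percent`, `models`.
#' @export
count_exceeding <- function(ensemble, variable, scenario,
                            direction = c("above", "below"),
                            threshold = "baseline") {
  direction <- match.arg(direction)
  v <- .ens_values(ensemble, variable, scenario)
  thr <- if (identical(threshold, "baseline")) v$baseline else threshold
  hit <- if (direction == "above") v$values > thr else v$values < thr
  list(count = sum(hit), n = length(hit),
       percent = 100 * sum(hit) / length(hit), models = v$models[hit])
}

#' Coefficient of variation
#'
#' Sample (n-1 denominator) standard deviation divided by the mean.
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return dimensionless CV.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least two values")
  m <- mean(values)
  if (m == 0) stop("zero mean")
  stats::sd(values) / m
}

#' Multi-model ensemble mean with optional exclusions
#'
#' @param ensemble a `gcm_ensemble`.
#' @param variable,scenario see [count_exceeding()].
#' @param exclude character vector of model names (or labels) to drop.
#' @return arithmetic mean over the included models (unrounded).
#' @export
multimodel_mean <- function(ensemble, variable, scenario, exclude = character()) {
  v <- .ens_values(ensemble, variable, scenario)
  bad <- setdiff(exclude, c(v$models, v$labels))
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
  keep <- !(v$models %in% exclude | v$labels %in% exclude)
  if (!any(keep)) stop("all models excluded")
  mean(v$values[keep])
}

#' Extreme percent changes across the ensemble
#'
#' Identifies the models attaining the minimum and maximum percent change of
#' a variable relative to the baseline (ties broken by model-label order).
#'
#' @param ensemble a `gcm_ensemble`.
#' @param variable,scenario see [count_exceeding()].
#' @return list with `min` and `max`, each `list(model, label, percent)`.
#' @export
change_range <- function(ensemble, variable, scenario) {
  v <- .ens_values(ensemble, variable, scenario)
  pc <- percent_change(v$values, v$baseline)
  i <- which.min(pc); j <- which.max(pc)
  list(min = list(model = v$models[i], label = v$labels[i], percent = pc[i]),
       max = list(model = v$models[j], label = v$labels[j], percent = pc[j]))
}
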