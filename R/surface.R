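#' Run the climate sensitivity experiment over a Latin-hypercube design
#'
#' For every design member, the baseline daily weather is perturbed with
#' [apply_anomaly()] and the factorial years-by-accessions campaign is run;
#' per-member mean yields (over years, per accession and accession-mean) are
#' expressed as percent change against an unperturbed reference run, and a
#' quadratic response-surface emulator is fitted to the accession-mean
#' changes.
#'
#' @param weather baseline `weather_series` covering all season years.
#' @param design a [make_c3mp_design()] data frame (columns dT, dP).
#' @param years integer vector of season years.
#' @param accessions accession labels.
#' @param ... passed to [run_season()] (soil, config, ...).
#' @return an object of class `yield_surface`: list with `members` (one row
#'   per design member with mean yields and relative changes), `reference`
#'   (per-accession reference mean yields), `emulator` (see
#'   [fit_surface_emulator()]), `design`.
#' @export
run_c3mp <- function(weather, design, years,
                     accessions = proso_genotypes()$accession, ...) {
  ref <- run_campaign(weather, years, accessions, ...)
  ref_mean <- tapply(ref$yield, ref$accession, mean)[accessions]
  ref_all <- mean(ref_mean)
  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    wx <- apply_anomaly(weather, design$dT[i], design$dP[i])
    cam <- run_campaign(wx, years, accessions, ...)
    m <- tapply(cam$yield, cam$accession, mean)[accessions]
    row <- data.frame(member = design$member[i], dT = design$dT[i],
                      dP = design$dP[i], yield_mean = mean(m),
                      rel_change = percent_change(mean(m), ref_all))
    for (a in accessions) {
      row[[paste0("yield_", a)]] <- m[[a]]
      row[[paste0("rel_", a)]] <- percent_change(m[[a]], ref_mean[[a]])
    }
    rows[[i]] <- row
  }
  members <- do.call(rbind, rows)
  structure(list(members = members, reference = ref_mean,
                 reference_mean = ref_all,
                 emulator = fit_surface_emulator(members), design = design),
            class = "yield_surface")
}

#' Fit the quadratic impact-response-surface emulator
#'
#' Ordinary least squares of relative yield change (percent) on
#' `dT, dP, dT^2, dP^2, dT*dP` with intercept, the conventional smooth
#' emulator for temperature-by-rainfall impact response surfaces.
#'
#' @param members data frame with columns dT, dP and `response`.
#' @param response name of the response column (default `"rel_change"`).
#' @return list with `coef` (c0..c5 named intercept, dT, dP, dT2, dP2, dTdP),
#'   `rms_residual`, and the fitted `lm` object.
#' @export
fit_surface_emulator <- function(members, response = "rel_change") {
  d <- data.frame(y = members[[response]], dT = members$dT, dP = members$dP)
  fit <- stats::lm(y ~ dT + dP + I(dT^2) + I(dP^2) + I(dT * dP), data = d)
  co <- stats::coef(fit)
  names(co) <- c("intercept", "dT", "dP", "dT2", "dP2", "dTdP")
  list(coef = co, rms_residual = sqrt(mean(stats::residuals(fit)^2)),
       fit = fit)
}

#' Evaluate a fitted response-surface emulator
#'
#' @param emulator as returned by [fit_surface_emulator()].
#' @param dT,dP anomaly coordinates (vectorised).
#' @return predicted relative yield change (percent).
#' @export
predict_surface <- function(emulator, dT, dP) {
  co <- emulator$coef
  co[["intercept"]] + co[["dT"]] * dT + co[["dP"]] * dP +
    co[["dT2"]] * dT^2 + co[["dP2"]] * dP^2 + co[["dTdP"]] * dT * dP
}

#' Evaluate the emulator on a regular anomaly grid (for contouring)
#'
#' @param emulator a fitted emulator.
#' @param dT_range,dP_range axis ranges.
#' @param n grid points per axis.
#' @return data frame dT, dP, rel_change.
#' @export
surface_grid <- function(emulator, dT_range = c(-1, 8),
                         dP_range = c(-50, 50), n = 41) {
  g <- expand.grid(dT = seq(dT_range[1], dT_range[2], length.out = n),
                   dP = seq(dP_range[1], dP_range[2], length.out = n))
  g$rel_change <- predict_surface(emulator, g$dT, g$dP)
  g
}

#' Bin relative yield changes into 10-percent classes
#'
#' Left-closed bins throughout (`[-10, 0)`, `[0, 10)`, ...), so a change of
#' exactly zero falls in the first increase bin.
#'
#' @param changes relative yield changes (percent), one per ensemble member.
#' @param width bin width (percent).
#' @return data frame with bin label, lower/upper edge, count and percent of
#'   members; percentages sum to 100.
#' @export
bin_changes <- function(changes, width = 10) {
  lo <- floor(min(c(changes, 0)) / width) * width
  hi <- ceiling(max(c(changes, max(changes) + 1e-9)) / width) * width
  breaks <- seq(lo, hi + width, by = width)
  idx <- findInterval(changes, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  lab <- function(a, b) {
    if (b <= 0) sprintf("%g-%g%% decrease", -b, -a)
    else sprintf("%g-%g%% increase", a, b)
  }
  data.frame(
    bin = mapply(lab, breaks[-length(breaks)], breaks[-1]),
    lower = breaks[-length(breaks)], upper = breaks[-1],
    count = counts, percent = 100 * counts / length(changes),
    stringsAsFactors = FALSE)
}

#' Compare future against baseline yields (Welch two-sample t-test)
#'
#' @param future,baseline yield samples (kg/ha), n >= 2 each.
#' @return list with t, df, p_value, mean relative change (percent).
#' @export
compare_to_baseline <- function(future, baseline) {
  if (stats::sd(future) == 0 && stats::sd(baseline) == 0) {
    if (mean(future) == mean(baseline))
      return(list(t = 0, df = NA_real_, p_value = 1,
                  rel_change = percent_change(mean(future), mean(baseline))))
    stop("zero variance in both samples")
  }
  tt <- stats::t.test(future, baseline, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       rel_change = percent_change(mean(future), mean(baseline)))
}

#' Linear yield trend over years
#'
#' Ordinary least-squares slope of yield on calendar year with a two-sided
#' t-test on the slope.
#'
#' @param years calendar years (>= 3).
#' @param yields yields (kg/ha), same length.
#' @return list with slope (kg/ha/yr), p_value, significant (at 95 percent).
#' @export
linear_trend <- function(years, yields) {
  if (length(years) < 3L) stop("need at least three years")
  fit <- stats::lm(yields ~ years)
  slope <- unname(stats::coef(fit)[2])
  sm <- suppressWarnings(summary(fit))$coefficients
  p <- sm[2, 4]
  # a noiseless series gives a zero residual standard error: the slope is
  # then known exactly (p = 0 unless it is itself zero)
  if (is.nan(p)) p <- if (slope == 0) 1 else 0
  list(slope = slope, p_value = p, significant = p < 0.05)
}
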