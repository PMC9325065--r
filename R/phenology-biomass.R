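#' Maximum quantum efficiency of photosystem II
#'
#' Computes Fv/Fm = (Fm - F0) / Fm from a dark-adapted fluorescence pair:
#' `F0` is the minimum fluorescence under weak measuring light, `Fm` the
#' maximum under a saturating flash. Values near 0.8 indicate a fully
#' active photosystem; low values indicate winter downregulation.
#'
#' @param F0 Minimum fluorescence (relative units, >= 0).
#' @param Fm Maximum fluorescence (> 0, and >= F0).
#' @return Fv/Fm in \[0, 1\].
#' @examples
#' fv_fm(0.2, 1.0)  # 0.8, a typical summer value
#' @export
fv_fm <- function(F0, Fm) {
  if (any(Fm <= 0)) stop("Fm must be positive")
  if (any(F0 < 0)) stop("F0 must be non-negative")
  if (any(F0 > Fm))
    stop("F0 exceeds Fm: the saturating flash must exceed minimum fluorescence")
  (Fm - F0) / Fm
}

#' Cumulative growing degree days
#'
#' Accumulates daily mean temperature excess above a base temperature
#' (default 5 C), the thermal-time axis on which conifer shoot elongation is
#' modelled.
#'
#' @param daily_mean_temps Daily mean temperatures, C.
#' @param base Base temperature, C.
#' @param dates Optional vector of dates (same length); when given the
#'   result is a data.frame of class `gdd_series`.
#' @return Numeric cumulative degree days (C day), or a data.frame with
#'   columns `date`, `gdd` when `dates` is supplied. Empty input gives an
#'   empty series.
#' @examples
#' gdd_accumulate(c(3, 7, 10))  # 0 2 7
#' @export
gdd_accumulate <- function(daily_mean_temps, base = 5, dates = NULL) {
  g <- cumsum(pmax(0, daily_mean_temps - base))
  if (is.null(dates)) return(g)
  if (length(dates) != length(g)) stop("dates must match temperatures in length")
  out <- data.frame(date = as.Date(dates), gdd = g)
  class(out) <- c("gdd_series", "data.frame")
  out
}

logistic_gdd <- function(g, g50, s) 1 / (1 + exp(-s * (g - g50)))

#' Relative shoot elongation growth as a function of thermal time
#'
#' Models the relative elongation of current-year (Y0) shoots as a logistic
#' function of cumulative growing degree days, `L(g) = 1 / (1 + exp(-s (g -
#' g50)))`. By default the curve is min-max rescaled over the campaign so
#' growth is 0 at the first date and exactly 1 at the campaign end, matching
#' the convention that relative growth = length on day / final length.
#'
#' @param gdd A [gdd_accumulate()] `gdd_series` (or numeric GDD vector).
#' @param g50 Thermal midpoint of elongation, C day.
#' @param steepness Logistic steepness per C day (> 0).
#' @param rescale Rescale to \[0, 1\] over the input span (default TRUE).
#' @return data.frame with `date` (when available), `gdd`, `fraction`;
#'   monotone non-decreasing in `gdd`.
#' @export
relative_growth <- function(gdd, g50 = 150, steepness = 0.03, rescale = TRUE) {
  if (steepness <= 0) stop("steepness must be positive")
  g <- if (is.data.frame(gdd)) gdd$gdd else as.numeric(gdd)
  L <- logistic_gdd(g, g50, steepness)
  if (rescale) {
    span <- max(L) - min(L)
    if (span < 1e-9)
      stop("no growth signal: cumulative degree days do not move the growth curve")
    frac <- (L - min(L)) / span
  } else {
    frac <- L
  }
  out <- data.frame(gdd = g, fraction = frac)
  if (is.data.frame(gdd) && "date" %in% names(gdd)) {
    out <- cbind(date = gdd$date, out)
  }
  out
}

#' Fit the logistic growth model to measured shoot elongation
#'
#' Estimates `(g50, steepness)` by nonlinear least squares from measured
#' relative elongation (length on day / final length) against cumulative
#' growing degree days.
#'
#' @param gdd GDD at the observation dates, C day.
#' @param rel_obs Observed relative elongation in \[0, 1\].
#' @param g50_init,s_init Starting values.
#' @return List with `g50`, `steepness`, `fitted`, `converged`.
#' @export
fit_growth_model <- function(gdd, rel_obs, g50_init = stats::median(gdd),
                             s_init = 0.02) {
  stopifnot(length(gdd) == length(rel_obs))
  g <- as.numeric(gdd)
  dat <- data.frame(g = g, y = rel_obs)
  model <- function(g, g50, s) {
    L <- logistic_gdd(g, g50, s)
    (L - logistic_gdd(min(g), g50, s)) /
      (logistic_gdd(max(g), g50, s) - logistic_gdd(min(g), g50, s))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ model(g, g50, s),
                      data = dat,
                      start = list(g50 = g50_init, s = s_init),
                      lower = c(g50 = 0, s = 1e-5),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(g50 = NA_real_, steepness = NA_real_, fitted = NULL,
                converged = FALSE))
  cf <- stats::coef(fit)
  list(g50 = cf[["g50"]], steepness = cf[["s"]],
       fitted = stats::fitted(fit), converged = TRUE)
}

#' Shoot biomass record
#'
#' @param shoot_id Shoot identifier.
#' @param species Species label.
#' @param m_y1 Dry mass of 1-yr-old needles, g.
#' @param m_y0_final Dry mass of current-year needles at campaign end, g.
#' @param elongation Optional data.frame `date`, `length_mm` of measured
#'   shoot elongation.
#' @return Object of class `shoot_biomass`.
#' @export
shoot_biomass <- function(shoot_id, species, m_y1, m_y0_final,
                          elongation = NULL) {
  if (m_y1 < 0 || m_y0_final < 0) stop("needle masses must be >= 0")
  structure(list(shoot_id = shoot_id, species = species, m_y1 = m_y1,
                 m_y0_final = m_y0_final, elongation = elongation),
            class = "shoot_biomass")
}

#' Needle dry mass in the chamber on a given date
#'
#' Needle biomass is assumed to grow proportionally with Y0 shoot
#' elongation: `m(date) = m_y1 + rel(date) * m_y0_final`. When the shoot has
#' measured elongation observations, the relative growth is interpolated
#' linearly between them (relative to the final length); otherwise the
#' thermal-time model supplied via `rel` is used. Dates before the campaign
#' return `m_y1` (no current-year mass yet).
#'
#' @param date Date of the measurement.
#' @param biomass A [shoot_biomass()].
#' @param rel A [relative_growth()] table (date, fraction), used when no
#'   elongation observations exist.
#' @return Needle dry mass, g.
#' @export
needle_mass_at <- function(date, biomass, rel = NULL) {
  stopifnot(inherits(biomass, "shoot_biomass"))
  date <- as.Date(date)
  frac <- if (!is.null(biomass$elongation) && nrow(biomass$elongation) >= 2) {
    el <- biomass$elongation[order(biomass$elongation$date), ]
    relmeas <- el$length_mm / el$length_mm[nrow(el)]
    stats::approx(as.numeric(el$date), relmeas, xout = as.numeric(date),
                  rule = 2)$y
  } else if (!is.null(rel)) {
    if (!"date" %in% names(rel)) stop("rel table needs a date column")
    if (date < min(rel$date)) 0
    else stats::approx(as.numeric(rel$date), rel$fraction,
                       xout = as.numeric(date), rule = 2)$y
  } else {
    stop("no elongation observations and no growth model supplied")
  }
  biomass$m_y1 + frac * biomass$m_y0_final
}

#' Compare measured and modelled relative growth
#'
#' @param measured data.frame `date`, `fraction` of measured relative growth.
#' @param modelled data.frame `date`, `fraction` from [relative_growth()].
#' @return List with `rmse`, `max_abs_dev`, `n_shared` over shared dates
#'   (>= 4 required).
#' @export
validate_growth_model <- function(measured, modelled) {
  shared <- merge(measured, modelled, by = "date",
                  suffixes = c("_meas", "_model"))
  if (nrow(shared) == 0) stop("no overlapping dates between measurement and model")
  if (nrow(shared) < 4) stop("need at least 4 shared dates to validate")
  dev <- shared$fraction_meas - shared$fraction_model
  list(rmse = sqrt(mean(dev^2)), max_abs_dev = max(abs(dev)),
       n_shared = nrow(shared))
}
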