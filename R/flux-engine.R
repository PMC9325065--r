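#' Linear fit of concentration change over the trimmed window
#'
#' Ordinary least squares of concentration on time over the half-open trim
#' window; the slope is reported in mol fraction per second (ppm input is
#' scaled by 1e-6) so that the flux conversion is dimensionally closed.
#'
#' @param series A QC-passing, trimmed [closure_series()].
#' @param channel `"ch4"` (uses `ch4_dry_corr` when present, else raw) or
#'   `"co2"`.
#' @param require_qc Refuse closures not labelled `pass` (default TRUE).
#' @return Object of class `linear_fit` with `slope` (mol fraction s^-1),
#'   `slope_se`, `intercept_ppm`, `r2`, `n_points`.
#' @export
fit_linear_slope <- function(series, channel = c("ch4", "co2"),
                             require_qc = TRUE) {
  channel <- match.arg(channel)
  stopifnot(inherits(series, "closure_series"))
  if (require_qc && !identical(series$qc_status, "pass"))
    stop("closure has not passed QC (qc_status = ", series$qc_status, ")")
  r <- trimmed_records(series)
  if (nrow(r) < 20) stop("need at least 20 records inside the trim window")
  y <- switch(channel,
    ch4 = if (!is.null(r$ch4_dry_corr)) r$ch4_dry_corr else r$ch4_dry_raw,
    co2 = r$co2)
  tt <- r$t
  n <- length(tt)
  tc <- tt - mean(tt)
  sxx <- sum(tc^2)
  slope_ppm <- sum(tc * (y - mean(y))) / sxx
  intercept <- mean(y) - slope_ppm * mean(tt)
  res <- y - (intercept + slope_ppm * tt)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  se_ppm <- sqrt(rss / (n - 2) / sxx)
  structure(list(
    slope = slope_ppm * 1e-6,
    slope_se = se_ppm * 1e-6,
    intercept_ppm = intercept,
    r2 = if (tss > 0) 1 - rss / tss else NA_real_,
    n_points = n,
    channel = channel
  ), class = "linear_fit")
}

#' Exponential fit of a saturating concentration trajectory
#'
#' Fits `C(t) = Clim + (C0 - Clim) * exp(-k * t)` by nonlinear least squares
#' (Levenberg-Marquardt), the model used for CO2 drawdown toward an
#' asymptote in a closed chamber. The flux-relevant quantity is the initial
#' slope `dC/dt(0) = -k * (C0 - Clim)`. Initialization takes `C0` from the
#' first value, `Clim` from the last, and `k` from the log-linearized
#' decrement; when the trajectory is indistinguishable from a straight line
#' (k -> 0 ridge) the fit falls back to the linear slope with
#' `converged = FALSE`.
#'
#' @param series A QC-passing, trimmed [closure_series()] with a CO2 channel.
#' @param require_qc Refuse closures not labelled `pass`.
#' @return Object of class `exponential_fit` with `C0`, `Clim`, `k` (s^-1),
#'   `initial_slope` (ppm s^-1), `initial_slope_molfrac` (mol fraction s^-1)
#'   and `converged`.
#' @export
fit_exponential <- function(series, require_qc = TRUE) {
  stopifnot(inherits(series, "closure_series"))
  if (require_qc && !identical(series$qc_status, "pass"))
    stop("closure has not passed QC (qc_status = ", series$qc_status, ")")
  r <- trimmed_records(series)
  if (nrow(r) < 20) stop("need at least 20 records inside the trim window")
  tt <- r$t - r$t[1]
  y <- r$co2
  lin <- fit_linear_slope(series, "co2", require_qc = require_qc)
  lin_slope_ppm <- lin$slope * 1e6

  c0_init <- y[1]
  clim_init <- y[length(y)]
  # log-linearized decrement for k when the span allows it
  span <- diff(range(y))
  k_init <- if (abs(c0_init - clim_init) > 1e-9) {
    max(1e-5, abs(lin_slope_ppm / (c0_init - clim_init)))
  } else 1e-4

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ Clim + (C0 - Clim) * exp(-k * tt),
      start = list(C0 = c0_init, Clim = clim_init, k = k_init),
      lower = c(C0 = -Inf, Clim = -Inf, k = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL)

  if (is.null(fit) || span < 1e-12) {
    return(structure(list(
      C0 = y[1], Clim = NA_real_, k = NA_real_,
      initial_slope = lin_slope_ppm,
      initial_slope_molfrac = lin$slope,
      converged = FALSE
    ), class = "exponential_fit"))
  }
  cf <- stats::coef(fit)
  k <- cf[["k"]]
  init_slope <- -k * (cf[["C0"]] - cf[["Clim"]])
  # degenerate near-linear ridge: k at its floor, or wildly extrapolated Clim
  degenerate <- k <= 2e-8 || !is.finite(init_slope)
  if (degenerate) {
    return(structure(list(
      C0 = cf[["C0"]], Clim = NA_real_, k = NA_real_,
      initial_slope = lin_slope_ppm,
      initial_slope_molfrac = lin$slope,
      converged = FALSE
    ), class = "exponential_fit"))
  }
  structure(list(
    C0 = cf[["C0"]], Clim = cf[["Clim"]], k = k,
    initial_slope = init_slope,
    initial_slope_molfrac = init_slope * 1e-6,
    converged = TRUE
  ), class = "exponential_fit")
}

#' Convert a fitted concentration slope to a chamber and dry-weight flux
#'
#' The chamber-level flux is
#'
#'   F_chamber = dC/dt * (p V / (R T)) * M * 3600
#'
#' with `dC/dt` in mol fraction s^-1, giving ng h^-1 for CH4
#' (M = 1.604e10 ng mol^-1) and mg h^-1 for CO2 (M = 4.401e4 mg mol^-1).
#' The dry-weight flux divides by the needle mass:
#' `F_dw = F_chamber / m_needles`. The sample temperature is the mean over
#' the trim window, as the air enters the analyser.
#'
#' @param fit A [fit_linear_slope()] or [fit_exponential()] result, or a bare
#'   numeric slope in mol fraction s^-1.
#' @param chamber A [chamber_spec()].
#' @param gas `"ch4"` or `"co2"`.
#' @param needle_mass Needle dry mass, g; `NULL` for empty chambers
#'   (chamber-level flux only).
#' @param sample_temp Mean sample temperature over the trim window, K
#'   (must lie in \[250, 330\]).
#' @return Object of class `flux_estimate` with `gas`, `chamber_flux`
#'   (ng h^-1 or mg h^-1), `dw_flux` (per g DW, or NA), `needle_mass_used`,
#'   `sample_temp_used`, `slope`, `slope_se`, `background_corrected`,
#'   `below_mdl` flags.
#' @examples
#' f <- slope_to_flux(1e-9 / 60, chamber_spec(), "ch4",
#'                    needle_mass = 23.6, sample_temp = 293.15)
#' f$chamber_flux   # ~208 ng CH4 per hour
#' @export
slope_to_flux <- function(fit, chamber, gas = c("ch4", "co2"),
                          needle_mass = NULL, sample_temp = 293.15) {
  gas <- match.arg(gas)
  stopifnot(inherits(chamber, "chamber_spec"))
  if (!is.numeric(sample_temp) || sample_temp < 250 || sample_temp > 330)
    stop("sample_temp must be in [250, 330] K")
  slope <- if (inherits(fit, "linear_fit")) fit$slope
    else if (inherits(fit, "exponential_fit")) fit$initial_slope_molfrac
    else if (is.numeric(fit) && length(fit) == 1L) fit
    else stop("fit must be a linear_fit, exponential_fit or numeric slope")
  slope_se <- if (inherits(fit, "linear_fit")) fit$slope_se else NA_real_

  M <- if (gas == "ch4") chamber$M_ch4 else chamber$M_co2
  n_air <- chamber$pressure_pa * chamber$volume_m3 / (chamber$R * sample_temp)
  conv <- n_air * M * 3600
  chamber_flux <- slope * conv
  dw_flux <- NA_real_
  if (!is.null(needle_mass)) {
    if (!is.numeric(needle_mass) || length(needle_mass) != 1L || needle_mass <= 0)
      stop("needle_mass must be a single positive mass (g) when dw flux is requested")
    dw_flux <- chamber_flux / needle_mass
  }
  structure(list(
    gas = gas,
    chamber_flux = chamber_flux,
    chamber_flux_se = slope_se * conv,
    dw_flux = dw_flux,
    needle_mass_used = if (is.null(needle_mass)) NA_real_ else needle_mass,
    sample_temp_used = sample_temp,
    slope = slope,
    slope_se = slope_se,
    background_corrected = FALSE,
    below_mdl = NA
  ), class = "flux_estimate")
}

#' @export
print.flux_estimate <- function(x, ...) {
  unit <- if (x$gas == "ch4") "ng" else "mg"
  cat(sprintf("<flux_estimate> %s: chamber %.3g %s h^-1, dw %.3g %s gDW^-1 h^-1%s\n",
              toupper(x$gas), x$chamber_flux, unit, x$dw_flux, unit,
              if (isTRUE(x$background_corrected)) " (background-corrected)" else ""))
  invisible(x)
}
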