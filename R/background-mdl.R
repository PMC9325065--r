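#' Fit the empty-chamber background flux model
#'
#' Chamber materials themselves emit a small apparent CH4 flux. Before
#' subtraction, the empty-chamber fluxes are tested for sensitivity to the
#' environment by regressing them on global radiation (and, diagnostically,
#' on air temperature and on time). If the radiation slope is significant at
#' `alpha` the background is modelled as a linear function of global
#' radiation and predicted per closure; otherwise the campaign mean is used.
#'
#' @param empty_fluxes Numeric vector of empty-chamber CH4 fluxes, ng h^-1
#'   (chamber scale, H2O-corrected, not background-subtracted).
#' @param global_radiation Mean global radiation per empty closure, W m^-2.
#' @param air_temp Optional mean air temperature per closure, C (diagnostic).
#' @param time Optional closure times (diagnostic trend test).
#' @param alpha Significance level for the radiation slope (two-sided t).
#' @return Object of class `background_model` with fields `mode`
#'   (`"constant_mean"` or `"radiation_regression"`), `mean_flux`, `mean_se`,
#'   `slope`, `intercept`, `sd_resid`, `n_empty`, and a `diagnostics` table
#'   of the sensitivity regressions.
#' @export
fit_background <- function(empty_fluxes, global_radiation = NULL,
                           air_temp = NULL, time = NULL, alpha = 0.05) {
  y <- as.numeric(empty_fluxes)
  n <- length(y)
  if (n < 3) stop("need at least 3 empty-chamber closures to model the background")

  slope_test <- function(x, label) {
    if (is.null(x)) return(NULL)
    fit <- stats::lm(y ~ x)
    cf <- summary(fit)$coefficients
    data.frame(predictor = label,
               slope = cf[2, 1], se = cf[2, 2], p = cf[2, 4])
  }
  diag <- do.call(rbind, Filter(Negate(is.null), list(
    slope_test(global_radiation, "global_radiation"),
    slope_test(air_temp, "air_temp"),
    slope_test(if (is.null(time)) NULL else as.numeric(time), "time")
  )))

  use_rad <- FALSE
  slope <- intercept <- sd_resid <- NA_real_
  if (!is.null(global_radiation)) {
    fit <- stats::lm(y ~ global_radiation)
    p_rad <- summary(fit)$coefficients[2, 4]
    if (stats::var(y) > 0 && is.finite(p_rad) && p_rad < alpha) {
      use_rad <- TRUE
      slope <- stats::coef(fit)[[2]]
      intercept <- stats::coef(fit)[[1]]
      sd_resid <- stats::sd(stats::resid(fit))
    }
  }
  if (!use_rad) sd_resid <- stats::sd(y)
  structure(list(
    mode = if (use_rad) "radiation_regression" else "constant_mean",
    mean_flux = mean(y),
    mean_se = stats::sd(y) / sqrt(n),
    slope = slope,
    intercept = intercept,
    sd_resid = sd_resid,
    n_empty = n,
    alpha = alpha,
    diagnostics = diag
  ), class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  if (x$mode == "constant_mean") {
    cat(sprintf("<background_model> constant mean %.2f +/- %.2f ng h^-1 (n = %d)\n",
                x$mean_flux, x$mean_se, x$n_empty))
  } else {
    cat(sprintf("<background_model> radiation regression: %.3g + %.3g * Rg ng h^-1 (n = %d)\n",
                x$intercept, x$slope, x$n_empty))
  }
  invisible(x)
}

#' Predict the background flux for a closure
#'
#' @param object A [fit_background()] model.
#' @param global_radiation Mean global radiation of the closure, W m^-2
#'   (required in radiation mode).
#' @param ... Unused.
#' @return Predicted background flux, ng h^-1.
#' @export
predict.background_model <- function(object, global_radiation = NULL, ...) {
  if (object$mode == "radiation_regression") {
    if (is.null(global_radiation) || any(is.na(global_radiation)))
      stop("radiation-regression background needs the closure's mean global radiation")
    object$intercept + object$slope * global_radiation
  } else {
    rep(object$mean_flux, max(1L, length(global_radiation)))
  }
}

#' Subtract the chamber background from a shoot-chamber flux
#'
#' Subtraction happens on the chamber scale (ng h^-1), before any
#' normalization to needle dry weight.
#'
#' @param chamber_flux Shoot-chamber CH4 flux(es), ng h^-1.
#' @param model A [fit_background()] model.
#' @param global_radiation Mean global radiation per closure, W m^-2
#'   (required in radiation mode).
#' @return Background-corrected chamber flux(es), ng h^-1.
#' @examples
#' m <- fit_background(c(11, 12, 12.3))
#' subtract_background(50, m)
#' @export
subtract_background <- function(chamber_flux, model, global_radiation = NULL) {
  stopifnot(inherits(model, "background_model"))
  chamber_flux - predict(model, global_radiation = global_radiation)
}

#' Method detection limits from empty-chamber fluxes
#'
#' The method detection limit (MDL) of a single closure is three times the
#' SD of the apparent CH4 flux measured in the empty chambers (chamber
#' scale, ng h^-1). Scaling by the average shoot dry weight of each species
#' gives the per-measurement limit (ng gDW^-1 h^-1); dividing by the square
#' root of the number of replicate measurements in an averaging period gives
#' the per-period limit. Full precision is carried internally; rounding
#' happens only in [format_mdl_report()].
#'
#' @param empty_fluxes Empty-chamber CH4 fluxes, ng h^-1 (ignored when
#'   `per_chamber` is given directly).
#' @param avg_dw Named numeric vector: average shoot dry weight per species, g.
#' @param n_per_period Named integer vector: replicate measurements per
#'   averaging period, per species (same names as `avg_dw`).
#' @param per_chamber Optional precomputed per-chamber limit, ng h^-1
#'   (e.g. a published value), bypassing the 3*SD computation.
#' @return Object of class `detection_limits` with `per_chamber`,
#'   `per_measurement`, `per_period` (named by species) and `n_used`.
#' @examples
#' compute_mdl(per_chamber = 120.9, avg_dw = c(pine = 23.6),
#'             n_per_period = c(pine = 49))
#' @export
compute_mdl <- function(empty_fluxes = NULL, avg_dw, n_per_period,
                        per_chamber = NULL) {
  if (is.null(per_chamber)) {
    if (is.null(empty_fluxes) || length(empty_fluxes) < 3)
      stop("need at least 3 empty-chamber fluxes (or a per_chamber value)")
    per_chamber <- 3 * stats::sd(empty_fluxes)
  }
  if (is.null(names(avg_dw)) || is.null(names(n_per_period)))
    stop("avg_dw and n_per_period must be named by species")
  if (any(avg_dw <= 0)) stop("average dry weights must be positive")
  sp <- names(avg_dw)
  if (!setequal(sp, names(n_per_period)))
    stop("avg_dw and n_per_period must cover the same species")
  n_per_period <- n_per_period[sp]
  if (any(n_per_period < 1)) stop("n per period must be >= 1 for every species")
  per_measurement <- per_chamber / avg_dw
  per_period <- per_measurement / sqrt(n_per_period)
  structure(list(
    per_chamber = per_chamber,
    per_measurement = per_measurement,
    per_period = per_period,
    n_used = n_per_period,
    avg_dw = avg_dw
  ), class = "detection_limits")
}

#' @export
print.detection_limits <- function(x, ...) {
  cat(sprintf("<detection_limits> per chamber %.3g ng h^-1\n", x$per_chamber))
  for (sp in names(x$per_measurement))
    cat(sprintf("  %s: %.3g ng gDW^-1 h^-1 per measurement, %.3g per period (n = %d)\n",
                sp, x$per_measurement[[sp]], x$per_period[[sp]], x$n_used[[sp]]))
  invisible(x)
}

#' Report-style rounding of a detection-limit ladder
#'
#' Reported limits carry 3 significant figures, capped at 2 decimal places
#' (so 5.1229 prints as 5.12, 0.7318 as 0.73 and 27.158 as 27.2); internal
#' values stay at full precision.
#'
#' @param limits A [compute_mdl()] result.
#' @return data.frame with one row per species and rounded columns.
#' @export
format_mdl_report <- function(limits) {
  stopifnot(inherits(limits, "detection_limits"))
  rnd <- function(x) round(signif(x, 3), 2)
  data.frame(
    species = names(limits$per_measurement),
    per_chamber_ng_h = round(limits$per_chamber, 1),
    per_measurement_ng_gdw_h = as.numeric(rnd(limits$per_measurement)),
    n_per_period = as.integer(limits$n_used),
    per_period_ng_gdw_h = as.numeric(rnd(limits$per_period)),
    row.names = NULL
  )
}

#' Flag dry-weight fluxes below the per-measurement detection limit
#'
#' Never deletes data: fluxes whose absolute dry-weight value falls below
#' the species' per-measurement limit are labelled, not removed.
#'
#' @param flux A [slope_to_flux()] `flux_estimate`, or a data.frame with a
#'   dry-weight flux column and a `species` column.
#' @param limits A [compute_mdl()] result.
#' @param species Species of the flux (required for a bare `flux_estimate`).
#' @param column Name of the dry-weight flux column for data.frame input.
#' @return The input with `below_mdl` set.
#' @export
flag_below_mdl <- function(flux, limits, species = NULL, column = "dw_flux") {
  stopifnot(inherits(limits, "detection_limits"))
  lim_for <- function(sp) {
    if (!sp %in% names(limits$per_measurement))
      stop("no detection limit available for species: ", sp)
    limits$per_measurement[[sp]]
  }
  if (inherits(flux, "flux_estimate")) {
    if (is.null(species)) stop("species is required to look up the detection limit")
    flux$below_mdl <- abs(flux$dw_flux) < lim_for(species)
    return(flux)
  }
  if (is.data.frame(flux)) {
    if (!all(c(column, "species") %in% names(flux)))
      stop("data.frame input needs '", column, "' and species columns")
    flux$below_mdl <- mapply(function(v, sp) {
      if (is.na(v)) NA else abs(v) < lim_for(sp)
    }, flux[[column]], flux$species)
    return(flux)
  }
  stop("flux must be a flux_estimate or a data.frame")
}
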