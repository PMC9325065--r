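#' Default parameters for the synthetic meteorology generator
#'
#' The generator emulates a boreal spring: photosynthetically active
#' radiation (PAR) follows a clipped diel sinusoid whose clear-sky peak ramps
#' up over the season, modulated by a lognormal day-level cloudiness factor;
#' air temperature is a seasonal ramp plus a phase-shifted diel cycle plus
#' noise, optionally coupled to the PAR cloudiness anomaly (sunny days run
#' warmer); global shortwave radiation is PAR divided by a fixed quantum
#' conversion, with small proportional noise so the two are collinear but
#' not identical.
#'
#' @param par_peak_start,par_peak_end Clear-sky midday PAR at campaign start
#'   and end, umol m^-2 s^-1.
#' @param cloud_lsd Lognormal SD of the day-level cloudiness multiplier.
#' @param temp_mean_start,temp_mean_end Seasonal daily-mean temperature ramp, C.
#' @param temp_diel_amp Half-amplitude of the diel temperature cycle, C.
#' @param temp_noise_sd SD of day-level temperature noise, C.
#' @param par_temp_cov Day-level coupling, C of warming per unit of relative
#'   PAR cloudiness anomaly times 10 (0 decouples daily PAR and temperature).
#' @param c_conv PAR to shortwave conversion, umol J^-1 (PAR/global radiation).
#' @param rad_noise_rel Relative noise on global radiation around PAR/c_conv.
#' @param rain_prob Daily probability of a wet day.
#' @param rain_mean Mean daily precipitation on wet days, mm.
#' @return Named list of generator parameters.
#' @export
meteo_params <- function(par_peak_start = 700, par_peak_end = 1500,
                         cloud_lsd = 0.45,
                         temp_mean_start = 0, temp_mean_end = 14,
                         temp_diel_amp = 4, temp_noise_sd = 1.5,
                         par_temp_cov = 3, c_conv = 2.1,
                         rad_noise_rel = 0.04,
                         rain_prob = 0.3, rain_mean = 2) {
  as.list(environment())
}

#' Generate a synthetic meteorological series
#'
#' @param days Number of days (>= 1).
#' @param params Parameter list from [meteo_params()].
#' @param seed Integer seed; fixed seed gives identical output.
#' @param start_date Date of the first day.
#' @param step_s Averaging window of the records, seconds (300 = 5 min).
#' @return data.frame of class `meteo_series` with columns `timestamp`
#'   (POSIXct, UTC), `par` (umol m^-2 s^-1), `global_radiation` (W m^-2),
#'   `air_temp` (C), `precipitation` (mm per step) and attribute
#'   `averaging_window` (s).
#' @examples
#' m <- gen_meteo(3, seed = 1)
#' summary(m$par)
#' @export
gen_meteo <- function(days, params = meteo_params(), seed = 1,
                      start_date = as.Date("2019-04-01"), step_s = 300) {
  if (!is.numeric(days) || length(days) != 1L || days < 1)
    stop("days must be a positive number of days (>= 1)")
  days <- as.integer(days)
  p <- params
  rng <- local_rng(seed)

  per_day <- as.integer(86400 / step_s)
  n <- days * per_day
  day_idx <- rep(seq_len(days), each = per_day)
  sec_of_day <- rep(seq(0, 86400 - step_s, by = step_s), times = days)
  hour <- sec_of_day / 3600
  frac <- (day_idx - 1) / max(1, days - 1)

  # day-level stochastic components
  cloud <- rng(stats::rlnorm(days, meanlog = -p$cloud_lsd^2 / 2, sdlog = p$cloud_lsd))
  cloud <- pmin(cloud, 1.6)  # cannot be much brighter than clear sky
  t_noise <- rng(stats::rnorm(days, 0, p$temp_noise_sd))
  wet <- rng(stats::runif(days)) < p$rain_prob
  rain_amt <- rng(stats::rexp(days, rate = 1 / max(p$rain_mean, 1e-9))) * wet
  # rainy days are cloudy days
  cloud[wet] <- cloud[wet] * 0.6

  # PAR: clipped diel sinusoid (daylight 06-18 h at equinox, widening ignored)
  peak <- p$par_peak_start + (p$par_peak_end - p$par_peak_start) * frac
  diel_par <- pmax(0, sin(pi * (hour - 6) / 12))
  par <- peak * diel_par * cloud[day_idx]

  # air temperature: seasonal + diel (peak ~15:00) + day noise + PAR coupling
  t_season <- p$temp_mean_start + (p$temp_mean_end - p$temp_mean_start) * frac
  diel_t <- p$temp_diel_amp * sin(pi * (hour - 9) / 12)
  cloud_anom <- (cloud - mean(cloud)) / 10
  air_temp <- t_season + diel_t + t_noise[day_idx] +
    p$par_temp_cov * cloud_anom[day_idx] * 10 * diel_par

  grad <- par / p$c_conv *
    (1 + rng(stats::rnorm(n, 0, p$rad_noise_rel)))
  grad <- pmax(0, grad)

  precip <- numeric(n)
  # spread the day's rain uniformly over its steps
  precip <- rain_amt[day_idx] / per_day

  ts <- as.POSIXct(start_date, tz = "UTC") + (day_idx - 1) * 86400 + sec_of_day
  out <- data.frame(
    timestamp = ts,
    par = par,
    global_radiation = grad,
    air_temp = air_temp,
    precipitation = precip
  )
  attr(out, "averaging_window") <- step_s
  class(out) <- c("meteo_series", "data.frame")
  out
}

#' Daily mean air temperature from a meteorological series
#'
#' @param meteo A `meteo_series` (or data.frame with `timestamp`, `air_temp`).
#' @return data.frame with columns `date` and `tmean` (C).
#' @export
daily_mean_temp <- function(meteo) {
  d <- as.Date(meteo$timestamp, tz = "UTC")
  agg <- tapply(meteo$air_temp, d, mean)
  data.frame(date = as.Date(names(agg)), tmean = as.numeric(agg),
             row.names = NULL)
}

#' Mean meteorology over a time window
#'
#' Averages the meteorological records whose timestamp falls inside
#' `[from, to)`; falls back to the record nearest to the window midpoint when
#' none overlap (short closures between coarse averaging steps).
#'
#' @param meteo A `meteo_series`.
#' @param from,to POSIXct window bounds.
#' @return Named list `par`, `global_radiation`, `air_temp`.
#' @export
meteo_window_mean <- function(meteo, from, to) {
  sel <- meteo$timestamp >= from & meteo$timestamp < to
  if (!any(sel)) {
    mid <- as.numeric(from) + (as.numeric(to) - as.numeric(from)) / 2
    sel <- which.min(abs(as.numeric(meteo$timestamp) - mid))
  }
  list(
    par = mean(meteo$par[sel]),
    global_radiation = mean(meteo$global_radiation[sel]),
    air_temp = mean(meteo$air_temp[sel])
  )
}

# Run expressions under a private RNG stream so generators are deterministic
# and do not disturb the caller's RNG state. Returns an evaluator.
local_rng <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("seed must be a single integer")
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    expr
  }
}
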