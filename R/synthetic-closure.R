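#' Ground-truth parameters for synthetic campaigns
#'
#' Defines the emission model and instrument behaviour that the synthetic
#' generator embeds in each closure, so every downstream estimate can be
#' checked against a known truth. The true dry-weight-normalized emission of
#' a shoot is
#'
#'   F_true = base_emission + (par_slope_intercept +
#'            par_slope_temp_gain * T_air) * PAR + tree intercept
#'
#' in ng CH4 gDW^-1 h^-1, i.e. light-driven emission whose PAR slope grows
#' with air temperature. Empty chambers emit a background flux (constant or
#' proportional to global radiation) with closure-to-closure variability.
#' The analyser reports dry CH4 with a residual water-vapour spectral
#' cross-talk: reported = true + interference_f_true * H2O(t).
#'
#' @param base_emission Light-independent emission, ng gDW^-1 h^-1.
#' @param par_slope_intercept PAR slope at 0 C, ng gDW^-1 h^-1 per umol m^-2 s^-1.
#' @param par_slope_temp_gain Increase of the PAR slope per degree C.
#' @param background_mode `"constant"` or `"radiation"`.
#' @param background_mean Mean empty-chamber flux, ng h^-1 (constant mode, and
#'   the intercept in radiation mode).
#' @param background_rad_slope Background sensitivity to global radiation,
#'   ng h^-1 per W m^-2 (radiation mode).
#' @param background_sd Closure-to-closure SD of the true background flux,
#'   ng h^-1.
#' @param interference_f_true Spectral cross-talk, ppm CH4 per ppm H2O.
#' @param leak_rate First-order chamber leak, fraction of headspace exchanged
#'   per second, in `[0, 0.01]`.
#' @param noise_sd_ch4,noise_sd_co2 Analyser noise SD, ppm.
#' @param random_intercept_sd SD of per-tree emission offsets, ng gDW^-1 h^-1.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return Object of class `truth_params`.
#' @export
truth_params <- function(base_emission = 1.1,
                         par_slope_intercept = 0.002,
                         par_slope_temp_gain = 0.0002,
                         background_mode = c("constant", "radiation"),
                         background_mean = 27.4,
                         background_rad_slope = 0,
                         background_sd = 40,
                         interference_f_true = -9.122e-7,
                         leak_rate = 0,
                         noise_sd_ch4 = 0.0015,
                         noise_sd_co2 = 0.5,
                         random_intercept_sd = 0.5,
                         seed = 1L) {
  background_mode <- match.arg(background_mode)
  if (noise_sd_ch4 < 0 || noise_sd_co2 < 0 || background_sd < 0 ||
      random_intercept_sd < 0)
    stop("noise and variability SDs must be >= 0")
  if (leak_rate < 0 || leak_rate > 0.01)
    stop("leak_rate must lie in [0, 0.01]")
  structure(as.list(environment()), class = "truth_params")
}

#' True shoot emission implied by the truth parameters
#'
#' @param truth A [truth_params()] object.
#' @param par PAR, umol m^-2 s^-1.
#' @param air_temp Air temperature, C.
#' @param tree_intercept Per-tree offset, ng gDW^-1 h^-1.
#' @return True emission, ng CH4 gDW^-1 h^-1.
#' @export
true_emission <- function(truth, par, air_temp, tree_intercept = 0) {
  truth$base_emission +
    (truth$par_slope_intercept + truth$par_slope_temp_gain * air_temp) * par +
    tree_intercept
}

#' True background (empty-chamber) flux implied by the truth parameters
#'
#' @param truth A [truth_params()] object.
#' @param global_radiation Global radiation, W m^-2.
#' @return Expected background flux, ng h^-1 (without the closure-level draw).
#' @export
true_background <- function(truth, global_radiation = 0) {
  if (truth$background_mode == "radiation")
    truth$background_mean + truth$background_rad_slope * global_radiation
  else truth$background_mean
}

# saturation vapour pressure over water (Magnus), T in C -> Pa
svp_pa <- function(temp_c) 611.2 * exp(17.62 * temp_c / (243.12 + temp_c))

#' Generate one synthetic chamber closure
#'
#' Builds the analyser record of a single closure by inverting the flux
#' equations: the configured true flux sets the linear dry-CH4 accumulation
#' rate (with optional first-order leakage back toward ambient), CO2 follows
#' a saturating exponential drawdown, H2O rises toward a dew-point-dependent
#' ceiling, the reported dry CH4 adds the spectral cross-talk
#' `f_true * H2O(t)`, and Gaussian analyser noise is added last. The realized
#' ground truth is stored in `attr(x, "truth")`.
#'
#' @param truth [truth_params()] object.
#' @param chamber [chamber_spec()] object.
#' @param shoot `NULL` for an empty chamber, else a list with `shoot_id`,
#'   `species`, `needle_mass` (g DW) and optional `tree_intercept`
#'   (ng gDW^-1 h^-1).
#' @param meteo_at Named list `par`, `global_radiation`, `air_temp` at closure.
#' @param duration_s Closure length, seconds (7-10 min by default).
#' @param seed Integer seed for this closure.
#' @param dt_s Sampling interval, s.
#' @param chamber_id Chamber identifier.
#' @param start_time Optional POSIXct start.
#' @param ambient_ch4 Ambient dry CH4, ppm.
#' @param co2_start Headspace CO2 at closure start, ppm.
#' @param h2o_start Headspace H2O at closure start, ppm.
#' @param noise_mult Multiplier on the analyser noise SDs (used to inject
#'   deliberately unstable closures).
#' @return A [closure_series()] whose `"truth"` attribute records
#'   `flux_chamber` (ng h^-1), `flux_dw` (ng gDW^-1 h^-1 or NA), `slope_ppm_s`,
#'   `co2_initial_slope_ppm_s`, `background` flag and `needle_mass`.
#' @examples
#' tp <- truth_params(noise_sd_ch4 = 0, noise_sd_co2 = 0)
#' cl <- gen_closure(tp, chamber_spec(),
#'                   shoot = list(shoot_id = "p1", species = "pine",
#'                                needle_mass = 20),
#'                   meteo_at = list(par = 800, global_radiation = 380,
#'                                   air_temp = 10))
#' attr(cl, "truth")$flux_dw
#' @export
gen_closure <- function(truth, chamber, shoot = NULL,
                        meteo_at = list(par = 0, global_radiation = 0,
                                        air_temp = 10),
                        duration_s = 480, seed = 1L, dt_s = 1,
                        chamber_id = "ch1", start_time = NULL,
                        ambient_ch4 = 2.0, co2_start = 420,
                        h2o_start = 8000, noise_mult = 1) {
  stopifnot(inherits(truth, "truth_params"))
  if (!inherits(chamber, "chamber_spec")) stop("chamber must be a chamber_spec")
  if (duration_s < 60) stop("closure duration too short")
  rng <- local_rng(seed)

  t <- seq(0, duration_s, by = dt_s)
  n <- length(t)
  temp_k <- meteo_at$air_temp + 273.15
  n_air <- chamber$pressure_pa * chamber$volume_m3 / (chamber$R * temp_k)

  empty <- is.null(shoot)
  # chamber materials emit in every closure, with closure-to-closure spread
  background_realized <- true_background(truth, meteo_at$global_radiation) +
    if (truth$background_sd > 0) rng(stats::rnorm(1, 0, truth$background_sd)) else 0
  if (empty) {
    flux_chamber <- background_realized
    flux_dw <- NA_real_
    needle_mass <- NA_real_
  } else {
    ti <- if (is.null(shoot$tree_intercept)) 0 else shoot$tree_intercept
    flux_dw <- true_emission(truth, meteo_at$par, meteo_at$air_temp, ti)
    needle_mass <- shoot$needle_mass
    if (!is.numeric(needle_mass) || needle_mass <= 0)
      stop("shoot needle_mass must be positive")
    flux_chamber <- flux_dw * needle_mass + background_realized
  }

  # invert the flux equation: ng h^-1 -> mol-fraction s^-1 -> ppm s^-1
  slope_molfrac <- flux_chamber / (3600 * n_air * chamber$M_ch4)
  slope_ppm <- slope_molfrac * 1e6

  # CH4 accumulation with optional first-order leakage toward ambient:
  # dC/dt = s - lambda * (C - ambient)  =>  C = ambient + s/lambda (1 - e^-lt)
  lam <- truth$leak_rate
  ch4_true <- if (lam > 0) {
    ambient_ch4 + slope_ppm / lam * (1 - exp(-lam * t))
  } else {
    ambient_ch4 + slope_ppm * t
  }

  # CO2: photosynthetic drawdown under light, slight respiration rise dark
  if (empty) {
    co2_true <- rep(co2_start, n)
    co2_slope0 <- 0
  } else {
    k <- 0.004
    drawdown <- 60 * meteo_at$par / (meteo_at$par + 400)  # ppm, saturating in light
    clim <- co2_start - drawdown + 5   # +5: respiration offsets a little
    if (meteo_at$par < 1) clim <- co2_start + 15  # dark: respiration only
    co2_true <- clim + (co2_start - clim) * exp(-k * t)
    co2_slope0 <- -k * (co2_start - clim)
  }

  # H2O rises (transpiration/evaporation) toward a dew-point ceiling
  h2o_ceiling <- svp_pa(meteo_at$air_temp) / chamber$pressure_pa * 1e6
  h2o_ceiling <- max(h2o_ceiling, h2o_start * 1.05)
  r_h2o <- 0.004
  h2o <- h2o_ceiling + (h2o_start - h2o_ceiling) * exp(-r_h2o * t)

  # reported dry CH4 carries the spectral cross-talk; noise added last
  ch4_raw <- ch4_true + truth$interference_f_true * h2o
  if (truth$noise_sd_ch4 > 0 && noise_mult > 0)
    ch4_raw <- ch4_raw +
      rng(stats::rnorm(n, 0, truth$noise_sd_ch4 * noise_mult))
  co2 <- co2_true
  if (truth$noise_sd_co2 > 0 && noise_mult > 0)
    co2 <- co2 + rng(stats::rnorm(n, 0, truth$noise_sd_co2 * noise_mult))
  ch4_raw <- pmax(ch4_raw, 0)
  co2 <- pmax(co2, 0)

  rec <- data.frame(
    t = t,
    ch4_dry_raw = ch4_raw,
    co2 = co2,
    h2o = h2o,
    sample_temp = rep(temp_k, n)  # held at ambient during closure
  )
  out <- closure_series(
    rec, chamber_id = chamber_id,
    shoot_id = if (empty) NA_character_ else shoot$shoot_id,
    species = if (empty) NA_character_ else shoot$species,
    start_time = start_time
  )
  attr(out, "truth") <- list(
    flux_chamber = flux_chamber,
    flux_dw = flux_dw,
    background_realized = background_realized,
    slope_ppm_s = slope_ppm,
    co2_initial_slope_ppm_s = co2_slope0,
    background = empty,
    needle_mass = needle_mass,
    meteo = meteo_at
  )
  out
}

#' Generate a synthetic water-injection calibration run
#'
#' Emulates the laboratory determination of the H2O interference factor: a
#' small dry chamber in a closed loop receives a water injection, H2O rises
#' rapidly toward saturation while the actual dry CH4 stays constant, and the
#' analyser's reported dry CH4 drifts by `f_true` ppm per ppm H2O.
#'
#' @param f_true Interference slope, ppm CH4 per ppm H2O.
#' @param seed Integer seed.
#' @param duration_s Run length, s.
#' @param noise_sd_ch4 Analyser CH4 noise SD, ppm.
#' @param run_effect_sd Between-replicate SD of the realized slope (ppm CH4
#'   per ppm H2O): replicate injections differ slightly (mixing, residual
#'   droplets), which dominates the calibration's confidence interval. Set 0
#'   for idealized replicates.
#' @param h2o_start,h2o_end H2O span of the run, ppm.
#' @param ch4_level Actual dry CH4, ppm.
#' @return A [closure_series()] with attributes `f_true` and `f_run`
#'   (this replicate's realized slope).
#' @export
gen_injection_run <- function(f_true = -9.122e-7, seed = 1L, duration_s = 300,
                              noise_sd_ch4 = 0.0015, run_effect_sd = 4.3e-8,
                              h2o_start = 500,
                              h2o_end = 25000, ch4_level = 2.0) {
  rng <- local_rng(seed)
  t <- seq(0, duration_s, by = 1)
  # rapid saturation after the injection
  h2o <- h2o_end + (h2o_start - h2o_end) * exp(-0.02 * t)
  f_run <- f_true +
    if (run_effect_sd > 0) rng(stats::rnorm(1, 0, run_effect_sd)) else 0
  ch4 <- ch4_level + f_run * h2o
  if (noise_sd_ch4 > 0)
    ch4 <- ch4 + rng(stats::rnorm(length(t), 0, noise_sd_ch4))
  rec <- data.frame(
    t = t, ch4_dry_raw = pmax(ch4, 0), co2 = rep(420, length(t)),
    h2o = h2o, sample_temp = rep(295, length(t))
  )
  out <- closure_series(rec, chamber_id = "cal")
  attr(out, "f_true") <- f_true
  attr(out, "f_run") <- f_run
  out
}
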