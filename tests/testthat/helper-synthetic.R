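# shared fixtures: small deterministic synthetic objects built in code

quiet_truth <- function(...) {
  truth_params(noise_sd_ch4 = 0, noise_sd_co2 = 0, background_sd = 0,
               random_intercept_sd = 0, ...)
}

# a clean linear closure: known slope (ppm/s), no interference, no noise
linear_closure <- function(slope_ppm_s = 1e-4, duration_s = 480, dt = 1,
                           c0 = 2.0, h2o = 8000) {
  t <- seq(0, duration_s, by = dt)
  closure_series(data.frame(
    t = t,
    ch4_dry_raw = c0 + slope_ppm_s * t,
    co2 = 420 - 0.02 * t,
    h2o = rep(h2o, length(t)),
    sample_temp = rep(293.15, length(t))
  ), shoot_id = "s1", species = "pine")
}

# exhaustive two-segment changepoint oracle: best breakpoint by total RSS
changepoint_oracle <- function(t, y, min_seg = 20) {
  n <- length(t)
  rss <- function(idx) {
    if (length(idx) < 2) return(0)
    f <- stats::lm.fit(cbind(1, t[idx]), y[idx])
    sum(f$residuals^2)
  }
  cps <- seq(min_seg, n - min_seg)
  tot <- vapply(cps, function(k) rss(1:k) + rss((k + 1):n), numeric(1))
  t[cps[which.min(tot)]]
}

# tidy driver table simulated directly at the processed-flux level
sim_driver_table <- function(n = 200, n_trees = 4, seed = 1,
                             par_fun = function(n) runif(n, 0, 1500),
                             temp_fun = function(n) runif(n, 0, 20),
                             flux_fun = function(par, temp, tree_eff) {
                               tree_eff + rnorm(length(par))
                             },
                             tree_sd = 0.5) {
  set.seed(seed)
  tree <- sample(paste0("tr", seq_len(n_trees)), n, replace = TRUE)
  eff <- stats::setNames(rnorm(n_trees, 0, tree_sd), paste0("tr", seq_len(n_trees)))
  par <- par_fun(n)
  temp <- temp_fun(n)
  data.frame(
    tree_id = tree,
    par = par,
    air_temp = temp,
    dw_flux_ch4 = flux_fun(par, temp, eff[tree])
  )
}
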