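test_that("radiation-insensitive empties select the constant-mean model", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    rad <- runif(40, 0, 600)
    y <- rnorm(40, 25, 12)  # no radiation dependence
    m <- fit_background(y, global_radiation = rad)
    if (m$mode == "constant_mean" &&
        abs(m$mean_flux - 25) < 2 * 12 / sqrt(40)) hits <- hits + 1L
  }
  # constant mode chosen ~95% (5% false radiation hits), mean within 2 SE ~95%
  expect_gt(hits / 100, 0.8)
})

test_that("a real radiation slope is detected with high power at n = 55", {
  slope <- 3 * 10 / 100  # 3x residual SE per 100 W m^-2, sd_resid = 10
  hits <- 0L
  for (s in 1:200) {
    set.seed(2000 + s)
    rad <- runif(55, 0, 600)
    y <- 15 + slope * rad + rnorm(55, 0, 10)
    m <- fit_background(y, global_radiation = rad)
    if (m$mode == "radiation_regression") hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("identical empty fluxes give a zero-spread constant model", {
  m <- fit_background(rep(20, 10), global_radiation = runif(10, 0, 500))
  expect_equal(m$mode, "constant_mean")
  expect_equal(m$sd_resid, 0)
  expect_equal(m$mean_flux, 20)
  expect_error(fit_background(c(1, 2)), "at least 3")
})

test_that("background subtraction is plain arithmetic on the chamber scale", {
  m <- fit_background(c(11.76, 11.76, 11.76))
  expect_equal(subtract_background(50, m), 38.24)
  expect_equal(subtract_background(m$mean_flux, m), 0)
  # differences between shoots under equal radiation are preserved
  m2 <- structure(list(mode = "radiation_regression", mean_flux = 20,
                       mean_se = 1, slope = 0.05, intercept = 5,
                       sd_resid = 3, n_empty = 10, alpha = 0.05,
                       diagnostics = NULL), class = "background_model")
  a <- subtract_background(80, m2, global_radiation = 300)
  b <- subtract_background(55, m2, global_radiation = 300)
  expect_equal(a - b, 25)
  expect_error(subtract_background(50, m2), "global radiation")
})

test_that("regression-mode subtraction beats the constant mean on radiation-driven background", {
  rmse_reg <- numeric(30); rmse_const <- numeric(30)
  for (s in 1:30) {
    set.seed(3000 + s)
    rad_e <- runif(55, 0, 600)
    bg_slope <- 0.3; bg_int <- 10
    empt <- bg_int + bg_slope * rad_e + rnorm(55, 0, 10)
    m <- fit_background(empt, global_radiation = rad_e)
    mc <- fit_background(empt, global_radiation = NULL)
    rad_s <- runif(60, 0, 600)
    true_shoot <- 120
    raw <- true_shoot + bg_int + bg_slope * rad_s + rnorm(60, 0, 10)
    corr_reg <- subtract_background(raw, m, global_radiation = rad_s)
    corr_const <- subtract_background(raw, mc)
    rmse_reg[s] <- sqrt(mean((corr_reg - true_shoot)^2))
    rmse_const[s] <- sqrt(mean((corr_const - true_shoot)^2))
  }
  expect_lt(mean(rmse_reg), 0.5 * mean(rmse_const) + 2)
  expect_true(mean(rmse_reg) < mean(rmse_const))
})

test_that("the MDL ladder identities hold exactly", {
  set.seed(4)
  empt <- rnorm(30, 25, 13)
  lim <- compute_mdl(empt, avg_dw = c(pine = 23.6, spruce = 5.53),
                     n_per_period = c(pine = 49, spruce = 17))
  expect_equal(lim$per_chamber, 3 * sd(empt))
  expect_equal(lim$per_measurement * lim$avg_dw,
               rep(lim$per_chamber, 2), ignore_attr = TRUE)
  expect_equal(lim$per_period * sqrt(lim$n_used), lim$per_measurement,
               ignore_attr = TRUE)
  # monotone in n and in dry weight
  lim2 <- compute_mdl(empt, avg_dw = c(pine = 30), n_per_period = c(pine = 64))
  expect_lt(lim2$per_measurement[["pine"]], lim$per_measurement[["pine"]])
  expect_lt(lim2$per_period[["pine"]],
            lim$per_chamber / 30 / sqrt(49))
})

test_that("zero empty-chamber spread gives zero detection limits", {
  lim <- compute_mdl(rep(12, 5), avg_dw = c(pine = 10),
                     n_per_period = c(pine = 9))
  expect_equal(lim$per_chamber, 0)
  expect_equal(lim$per_measurement[["pine"]], 0)
  expect_equal(lim$per_period[["pine"]], 0)
})

test_that("MDL input validation rejects bad species maps", {
  expect_error(compute_mdl(rnorm(5), avg_dw = c(pine = -1),
                           n_per_period = c(pine = 3)), "positive")
  expect_error(compute_mdl(rnorm(5), avg_dw = c(pine = 5),
                           n_per_period = c(pine = 0)), ">= 1")
  expect_error(compute_mdl(rnorm(5), avg_dw = c(pine = 5),
                           n_per_period = c(spruce = 3)), "same species")
})

test_that("below-MDL flagging matches a brute-force comparison", {
  lim <- compute_mdl(per_chamber = 120.9,
                     avg_dw = c(pine = 23.6, spruce = 5.53),
                     n_per_period = c(pine = 49, spruce = 17))
  fx <- slope_to_flux(1e-12, chamber_spec(), "ch4", needle_mass = 23.6,
                      sample_temp = 293.15)
  expect_true(flag_below_mdl(fx, lim, species = "pine")$below_mdl)
  expect_error(flag_below_mdl(fx, lim, species = "birch"), "no detection limit")

  set.seed(9)
  tab <- data.frame(
    dw_flux = runif(200, -10, 30),
    species = sample(c("pine", "spruce"), 200, replace = TRUE)
  )
  flagged <- flag_below_mdl(tab, lim)
  brute <- mapply(function(v, sp) abs(v) < lim$per_measurement[[sp]],
                  tab$dw_flux, tab$species)
  expect_identical(unname(flagged$below_mdl), unname(brute))
  expect_equal(nrow(flagged), 200)  # flagging never deletes rows
})

test_that("report rounding lands the conventional display values", {
  lim <- compute_mdl(per_chamber = 120.9,
                     avg_dw = c(pine = 23.6, spruce = 5.53),
                     n_per_period = c(pine = 49, spruce = 17))
  rep <- format_mdl_report(lim)
  expect_equal(rep$per_measurement_ng_gdw_h[rep$species == "pine"], 5.12)
  expect_equal(rep$per_period_ng_gdw_h[rep$species == "pine"], 0.73)
  expect_equal(rep$per_period_ng_gdw_h[rep$species == "spruce"], 5.30)
})
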