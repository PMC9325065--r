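test_that("noiseless meteorology is an exact clipped sinusoid", {
  p <- meteo_params(cloud_lsd = 1e-12, temp_noise_sd = 0, par_temp_cov = 0,
                    rad_noise_rel = 0, rain_prob = 0)
  m <- gen_meteo(2, params = p, seed = 4)
  # midnight PAR is zero, midday equals the configured peak (day 1)
  hours <- as.numeric(format(m$timestamp, "%H"))
  expect_equal(m$par[hours == 0], rep(0, sum(hours == 0)))
  midday <- m$par[hours == 12 & as.Date(m$timestamp) == min(as.Date(m$timestamp))]
  expect_equal(max(midday), p$par_peak_start, tolerance = 1e-6)
})

test_that("global radiation and PAR are collinear by construction", {
  m <- gen_meteo(90, seed = 1)
  r2 <- summary(lm(global_radiation ~ par, data = m))$r.squared
  expect_gt(r2, 0.97)
})

test_that("zero PAR-temperature coupling leaves daily values uncorrelated", {
  p <- meteo_params(par_temp_cov = 0, temp_mean_start = 5, temp_mean_end = 5,
                    par_peak_start = 1000, par_peak_end = 1000)
  m <- gen_meteo(90, params = p, seed = 2)
  d <- as.Date(m$timestamp)
  daily_par <- tapply(m$par, d, mean)
  daily_t <- tapply(m$air_temp, d, mean)
  expect_lt(abs(cor(daily_par, daily_t)), 0.1)
})

test_that("meteo generation rejects non-positive durations", {
  expect_error(gen_meteo(0), "positive")
  expect_error(gen_meteo(-3), "positive")
})

test_that("a closure with zero flux, background and interference is constant", {
  tp <- quiet_truth(base_emission = 0, par_slope_intercept = 0,
                    par_slope_temp_gain = 0, background_mean = 0,
                    interference_f_true = 0)
  cl <- gen_closure(tp, chamber_spec(),
                    shoot = list(shoot_id = "s", species = "pine",
                                 needle_mass = 10),
                    meteo_at = list(par = 500, global_radiation = 240,
                                    air_temp = 10))
  expect_equal(diff(range(cl$records$ch4_dry_raw)), 0)
})

test_that("the spectral cross-talk shifts reported CH4 by f times the H2O rise", {
  f <- -9.122e-7
  tp <- quiet_truth(interference_f_true = f, background_mean = 0)
  cl <- gen_closure(tp, chamber_spec(),
                    shoot = list(shoot_id = "s", species = "pine",
                                 needle_mass = 10),
                    meteo_at = list(par = 800, global_radiation = 380,
                                    air_temp = 20),
                    duration_s = 480)
  tr <- attr(cl, "truth")
  n <- nrow(cl$records)
  dur <- cl$records$t[n] - cl$records$t[1]
  d_h2o <- cl$records$h2o[n] - cl$records$h2o[1]
  d_raw <- cl$records$ch4_dry_raw[n] - cl$records$ch4_dry_raw[1]
  d_true <- tr$slope_ppm_s * dur
  # apparent change minus true change equals f * (H2O rise); for a 10000 ppm
  # rise that is -9.122e-3 ppm over the closure
  expect_equal(d_raw - d_true, f * d_h2o, tolerance = 1e-10)
  expect_gt(d_h2o, 10000)  # humid 20 C closure wets by > 1e4 ppm
  expect_lt(d_raw - d_true, 0)
})

test_that("the full pipeline recovers a known flux within three slope SEs", {
  tp <- truth_params(base_emission = 10, par_slope_intercept = 0,
                     par_slope_temp_gain = 0, background_mean = 0,
                     background_sd = 0, random_intercept_sd = 0)
  ch <- chamber_spec()
  ok <- 0L
  for (s in 1:5) {
    cl <- gen_closure(tp, ch,
                      shoot = list(shoot_id = "s", species = "pine",
                                   needle_mass = 20),
                      meteo_at = list(par = 0, global_radiation = 0,
                                      air_temp = 12), seed = s)
    cl <- qc_closure(trim_closure(cl))
    cl <- correct_h2o(cl, tp$interference_f_true)
    fit <- fit_linear_slope(cl, "ch4")
    fx <- slope_to_flux(fit, ch, "ch4", needle_mass = 20,
                        sample_temp = mean(trimmed_records(cl)$sample_temp))
    se_dw <- fx$chamber_flux_se / 20
    if (abs(fx$dw_flux - 10) <= 3 * se_dw) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("campaign scheduling reproduces the 2019-style closure counts", {
  camp <- gen_campaign(campaign_config(weeks = 6), seed = 42)
  n_pine <- sum(camp$meta$species == "pine")
  n_spruce <- sum(camp$meta$species == "spruce")
  n_empty <- sum(camp$meta$shoot_id == "EMPTY")
  expect_gt(n_pine, 181 * 0.9); expect_lt(n_pine, 181 * 1.1)
  expect_gt(n_spruce, 53 * 0.9); expect_lt(n_spruce, 53 * 1.1)
  expect_gt(n_empty, 55 * 0.9); expect_lt(n_empty, 55 * 1.1)
  # an empty-chamber control leads every measurement round
  first_of_round <- camp$meta$shoot_id[!duplicated(format(camp$meta$start_time, "%Y-%m-%d %H"))]
  expect_true(all(first_of_round == "EMPTY"))
})

test_that("a campaign with no trees contains only empty-chamber closures", {
  camp <- gen_campaign(campaign_config(n_pine = 0, n_spruce = 0, weeks = 1),
                       seed = 1)
  expect_true(all(camp$meta$shoot_id == "EMPTY"))
  expect_gt(nrow(camp$meta), 0)
})

test_that("the same seed reproduces a campaign byte for byte", {
  cfg <- campaign_config(weeks = 1)
  d1 <- file.path(tempdir(), "campA"); d2 <- file.path(tempdir(), "campB")
  write_campaign(gen_campaign(cfg, seed = 9), d1)
  write_campaign(gen_campaign(cfg, seed = 9), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("empty-chamber apparent fluxes match the configured background", {
  tp <- truth_params(background_mean = 27.4, background_sd = 40)
  ch <- chamber_spec()
  est <- vapply(1:50, function(s) {
    cl <- gen_closure(tp, ch, shoot = NULL,
                      meteo_at = list(par = 600, global_radiation = 280,
                                      air_temp = 10), seed = 100 + s)
    cl <- qc_closure(trim_closure(cl))
    cl <- correct_h2o(cl, tp$interference_f_true)
    fx <- slope_to_flux(fit_linear_slope(cl, "ch4"), ch, "ch4",
                        sample_temp = mean(trimmed_records(cl)$sample_temp))
    fx$chamber_flux
  }, numeric(1))
  # mean within MC error of the configured mean; SD compatible with the
  # configured closure SD plus the analyser-noise contribution
  expect_lt(abs(mean(est) - 27.4), 3 * 40 / sqrt(50))
  expect_gt(sd(est), 40 * 0.7)
  expect_lt(sd(est), 40 * 1.4)
})

test_that("truth parameter validation rejects out-of-range settings", {
  expect_error(truth_params(noise_sd_ch4 = -1), ">= 0")
  expect_error(truth_params(leak_rate = 0.5), "leak_rate")
})
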