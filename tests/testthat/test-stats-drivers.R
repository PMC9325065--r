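test_that("period labels follow half-open 14-day bins from the first date", {
  d0 <- as.Date("2020-03-06")
  expect_equal(assign_periods(d0), 1L)
  expect_equal(assign_periods(c(d0, d0 + 13, d0 + 14, d0 + 27, d0 + 28)),
               c(1L, 1L, 2L, 2L, 3L))
  set.seed(17)
  dates <- d0 + sample(0:99, 100, replace = TRUE)
  oracle <- vapply(dates, function(d) {
    k <- 0L
    while (d >= d0 + (k + 1L) * 14) k <- k + 1L
    k + 1L
  }, integer(1))
  expect_equal(assign_periods(dates), oracle)
})

test_that("the mixed model collapses to OLS without tree-level variance", {
  tab <- sim_driver_table(
    n = 200, seed = 21, tree_sd = 0,
    flux_fun = function(par, temp, eff) 1 + 0.004 * par + rnorm(length(par)))
  fit <- fit_lmm(tab, "dw_flux_ch4", "par")
  ols <- coef(lm(dw_flux_ch4 ~ par, tab))[["par"]]
  est <- fit$coefficients$estimate[fit$coefficients$term == "par"]
  expect_lt(abs(est - ols), 1e-6)
  # single grouping level: exact OLS, flagged
  tab$tree_id <- "only"
  fit1 <- fit_lmm(tab, "dw_flux_ch4", "par")
  expect_true(fit1$singular)
  expect_equal(fit1$coefficients$estimate[fit1$coefficients$term == "par"],
               ols, tolerance = 1e-12)
})

test_that("the mixed model covers a true PAR slope across repeats", {
  beta <- 0.004
  hit <- 0L
  for (s in 1:60) {
    tab <- sim_driver_table(
      n = 200, seed = 400 + s, tree_sd = 0.5,
      flux_fun = function(par, temp, eff) 1 + beta * par + eff + rnorm(length(par)))
    fit <- fit_lmm(tab, "dw_flux_ch4", "par")
    row <- fit$coefficients[fit$coefficients$term == "par", ]
    if (abs(row$estimate - beta) <= 2 * row$se) hit <- hit + 1L
  }
  expect_gte(hit / 60, 0.85)  # ~95% nominal, 60 Monte-Carlo repeats
})

test_that("a constant response yields a zero slope and zero residual spread", {
  tab <- sim_driver_table(n = 50, seed = 3, tree_sd = 0,
                          flux_fun = function(par, temp, eff) rep(5, length(par)))
  fit <- fit_lmm(tab, "dw_flux_ch4", "par")
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "par"], 0,
               tolerance = 1e-10)
  expect_lt(fit$resid_sd, 1e-8)
})

test_that("period comparison letters separate a strongly shifted period", {
  set.seed(31)
  tab <- sim_driver_table(n = 120, seed = 31,
                          flux_fun = function(par, temp, eff) eff + rnorm(length(par)))
  tab$period <- rep(1:3, length.out = 120)
  tab$dw_flux_ch4[tab$period == 3] <- tab$dw_flux_ch4[tab$period == 3] + 10
  res <- compare_period_means(tab, "dw_flux_ch4")
  expect_false(res$letters[["3"]] %in% res$letters[c("1", "2")])
  # a single period gets the single letter "a"
  one <- tab[tab$period == 1, ]
  expect_equal(unname(compare_period_means(one, "dw_flux_ch4")$letters), "a")
})

test_that("sparse periods are excluded with a warning", {
  tab <- sim_driver_table(n = 60, seed = 5,
                          flux_fun = function(par, temp, eff) rnorm(length(par)))
  tab$period <- c(rep(1, 30), rep(2, 29), 3)
  expect_warning(res <- compare_period_means(tab, "dw_flux_ch4"),
                 "excluding period")
  expect_false("3" %in% names(res$letters))
})

test_that("Welch tests against the empty chamber behave at the extremes", {
  empt <- rep(10, 30)
  same <- data.frame(shoot_id = "a", chamber_flux = rep(10, 30))
  res <- ttest_vs_empty(same, empt)
  expect_equal(res$p, 1)
  expect_equal(res$t, 0)
  set.seed(41)
  empt2 <- rnorm(30, 10, 4)
  shifted <- data.frame(shoot_id = "b",
                        chamber_flux = rnorm(30, 10 + 10 * 4, 4))
  res2 <- ttest_vs_empty(shifted, empt2)
  expect_lt(res2$p, 0.001)
  few <- data.frame(shoot_id = "c", chamber_flux = c(1, 2))
  res3 <- ttest_vs_empty(few, empt2)
  expect_true(res3$insufficient_n)
  expect_true(is.na(res3$p))
})

test_that("Welch decisions agree with a permutation oracle", {
  set.seed(43)
  agree <- 0L; B <- 100
  for (i in 1:B) {
    shift <- sample(c(0, 1.2), 1)
    empt <- rnorm(25, 10, 3)
    shoot <- rnorm(25, 10 + shift, 3)
    p_welch <- t.test(shoot, empt)$p.value
    obs <- mean(shoot) - mean(empt)
    pool <- c(shoot, empt)
    perm <- replicate(199, {
      k <- sample(50, 25)
      mean(pool[k]) - mean(pool[-k])
    })
    p_perm <- (1 + sum(abs(perm) >= abs(obs))) / 200
    if ((p_welch < 0.05) == (p_perm < 0.05)) agree <- agree + 1L
  }
  expect_gte(agree / B, 0.9)
})

test_that("the PAR split isolates a high-light-only temperature effect", {
  tab <- sim_driver_table(
    n = 300, seed = 51,
    flux_fun = function(par, temp, eff)
      ifelse(par >= 500, 0.3 * temp, 0) + eff + rnorm(length(par)))
  res <- par_split_regression(tab)
  expect_lt(res$high$p, 0.05)
  expect_equal(res$high$slope, 0.3, tolerance = 0.15)
  # threshold above every PAR value: empty stratum flagged
  res2 <- par_split_regression(tab, threshold = 5000)
  expect_null(res2$high)
  expect_true("high_stratum_insufficient" %in% res2$flags)
  # rows at exactly the threshold belong to both strata
  tab$par[1] <- 500
  res3 <- par_split_regression(tab)
  expect_equal(res3$low$n + res3$high$n, nrow(tab) + 1)
})

test_that("Helmert coding compares each level against the preceding mean", {
  H <- helmert_contrasts(4)
  expect_equal(colSums(H), rep(0, 3), ignore_attr = TRUE)
  expect_equal(max(abs(crossprod(H) - diag(diag(crossprod(H))))), 0)
  expect_equal(H[, 1], c(-1, 1, 0, 0), ignore_attr = TRUE)
  expect_equal(H[, 3], c(-1, -1, -1, 3), ignore_attr = TRUE)
})

test_that("temperature-bin interaction recovers per-bin PAR slopes", {
  a0 <- 0.002; a1 <- 0.0004
  tab <- sim_driver_table(
    n = 400, seed = 61,
    flux_fun = function(par, temp, eff)
      (a0 + a1 * temp) * par + eff + rnorm(length(par)))
  res <- temp_bin_interaction(tab)
  expect_equal(nrow(res$bin_slopes), 4)
  expect_true(all(diff(res$bin_slopes$slope) > 0))
  mids <- c(2.5, 7.5, 12.5, 17.5)
  expect_equal(res$bin_slopes$slope, a0 + a1 * mids, tolerance = 0.3)
  # sparse bins merge downward with a warning
  tab2 <- tab[tab$air_temp < 15 | seq_len(nrow(tab)) %in% 1:3, ]
  expect_warning(temp_bin_interaction(tab2), "merging")
})

test_that("residual regressions point to the true driver under covariance", {
  set.seed(71)
  n <- 300
  par <- runif(n, 0, 1500)
  temp <- 5 + 0.008 * par + rnorm(n, 0, 2)  # PAR and temperature covary
  tab <- data.frame(tree_id = "t1", par = par, air_temp = temp,
                    dw_flux_ch4 = 0.004 * par + rnorm(n, 0, 0.8))
  res <- residual_disentangle(tab)
  expect_lt(res$resid_temp_on_par$p, 0.05)
  expect_gt(res$resid_par_on_temp$p, 0.05)
  # flux driven by both, drivers independent: both residual slopes show
  tab2 <- data.frame(tree_id = "t1", par = runif(n, 0, 1500),
                     air_temp = runif(n, 0, 20))
  tab2$dw_flux_ch4 <- 0.004 * tab2$par + 0.3 * tab2$air_temp + rnorm(n, 0, 0.8)
  res2 <- residual_disentangle(tab2)
  expect_lt(res2$resid_temp_on_par$p, 0.05)
  expect_lt(res2$resid_par_on_temp$p, 0.05)
})

test_that("driver results are invariant to row order and PAR rescaling", {
  tab <- sim_driver_table(
    n = 150, seed = 81,
    flux_fun = function(par, temp, eff) 1 + 0.004 * par + eff + rnorm(length(par)))
  fit <- fit_lmm(tab, "dw_flux_ch4", "par")
  shuf <- tab[sample(nrow(tab)), ]
  fit2 <- fit_lmm(shuf, "dw_flux_ch4", "par")
  expect_equal(fit$coefficients$estimate, fit2$coefficients$estimate,
               tolerance = 1e-8)
  # PAR in mmol: slope scales by 1000, inference unchanged
  scaled <- tab; scaled$par <- scaled$par / 1000
  fit3 <- fit_lmm(scaled, "dw_flux_ch4", "par")
  i <- which(fit$coefficients$term == "par")
  expect_equal(fit3$coefficients$estimate[i],
               fit$coefficients$estimate[i] * 1000, tolerance = 1e-6)
  expect_equal(fit3$coefficients$p[i], fit$coefficients$p[i], tolerance = 1e-8)
})
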