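# lmer with lme4's predictor-scaling advisory muffled (PAR in umol m^-2 s^-1
# against unit-scale covariates triggers it; rescaling is the caller's choice)
quiet_lmer <- function(formula, data) {
  withCallingHandlers(
    suppressMessages(lme4::lmer(formula, data = data, REML = TRUE)),
    warning = function(w) {
      if (grepl("different scales|rescaling", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Assign chronological 2-week period labels
#'
#' Splits a campaign into consecutive half-open bins of `width_days` days
#' anchored at the first measurement date; the first date gets period 1 and
#' a date exactly `width_days` later starts period 2.
#'
#' @param dates Vector of dates.
#' @param width_days Bin width, days (default 14).
#' @param origin Anchor date (defaults to the earliest date).
#' @return Integer period labels.
#' @examples
#' d <- as.Date("2020-03-06") + c(0, 13, 14, 30)
#' assign_periods(d)  # 1 1 2 3
#' @export
assign_periods <- function(dates, width_days = 14, origin = min(dates)) {
  dates <- as.Date(dates)
  as.integer(floor(as.numeric(dates - as.Date(origin)) / width_days)) + 1L
}

#' Random-intercept linear mixed model for repeated shoot measurements
#'
#' Fits `response ~ fixed + (1 | group)` by REML, the standard treatment of
#' non-independent repeated measurements on the same trees. Fixed effects
#' are tested with Wald z statistics. When the grouping factor has a single
#' level (or the intercept variance collapses to zero) the fit reduces to
#' ordinary least squares and is flagged.
#'
#' @param table data.frame of per-closure rows.
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect terms (RHS), e.g.
#'   `c("par", "air_temp")` or `"factor(period)"`.
#' @param group Grouping column for the random intercept (default
#'   `"tree_id"`).
#' @return Object of class `lmm_result` with `coefficients` (estimate, se,
#'   z, p), `ranef_sd`, `resid_sd`, `n_obs`, `n_groups`, `singular`,
#'   `converged` and the underlying `model`.
#' @export
fit_lmm <- function(table, response, fixed, group = "tree_id") {
  stopifnot(is.data.frame(table))
  if (!response %in% names(table)) stop("response column not found: ", response)
  if (!group %in% names(table)) stop("grouping column not found: ", group)
  tab <- table[stats::complete.cases(table[, c(response, group)]), , drop = FALSE]
  if (nrow(tab) < 10) stop("need at least 10 rows to fit the mixed model")
  n_groups <- length(unique(tab[[group]]))
  rhs <- paste(fixed, collapse = " + ")

  if (n_groups < 2 || stats::var(tab[[response]]) < 1e-20) {
    fit <- stats::lm(stats::reformulate(fixed, response), data = tab)
    cf <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                        z = cf[, 1] / cf[, 2],
                        p = 2 * stats::pnorm(-abs(cf[, 1] / cf[, 2])),
                        row.names = NULL)
    return(structure(list(coefficients = coefs, ranef_sd = 0,
                          resid_sd = summary(fit)$sigma, n_obs = nrow(tab),
                          n_groups = n_groups, singular = TRUE,
                          converged = TRUE, model = fit),
                     class = "lmm_result"))
  }
  form <- stats::as.formula(paste(response, "~", rhs, "+ (1 |", group, ")"))
  fit <- quiet_lmer(form, tab)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ranef_sd <- vc$sdcor[vc$grp == group][1]
  resid_sd <- vc$sdcor[vc$grp == "Residual"][1]
  cf <- summary(fit)$coefficients  # estimate, se, t
  z <- cf[, 1] / cf[, 2]
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                      z = z, p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  structure(list(coefficients = coefs, ranef_sd = ranef_sd,
                 resid_sd = resid_sd, n_obs = nrow(tab),
                 n_groups = n_groups,
                 singular = lme4::isSingular(fit),
                 converged = TRUE, model = fit),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("<lmm_result> n = %d obs, %d groups; random-intercept SD %.3g, residual SD %.3g%s\n",
              x$n_obs, x$n_groups, x$ranef_sd, x$resid_sd,
              if (x$singular) " [singular]" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Marginal R2 of a mixed model (fixed effects only)
#'
#' Variance explained by the fixed effects relative to the total of fixed,
#' random-intercept and residual variance.
#'
#' @param x An [fit_lmm()] result.
#' @return Marginal R2 in \[0, 1\].
#' @export
marginal_r2 <- function(x) {
  stopifnot(inherits(x, "lmm_result"))
  if (inherits(x$model, "lm")) return(summary(x$model)$r.squared)
  fe <- as.numeric(lme4::getME(x$model, "X") %*% lme4::fixef(x$model))
  vf <- stats::var(fe)
  vf / (vf + x$ranef_sd^2 + x$resid_sd^2)
}

#' Pairwise comparison of period means with a compact letter display
#'
#' Fits a random-intercept model with the 2-week period as a factor, runs
#' Tukey-style simultaneous pairwise tests on the period means, and encodes
#' the outcome as a compact letter display: periods sharing a letter do not
#' differ at `alpha`.
#'
#' @param table data.frame with the response, a `period` column and the
#'   grouping column.
#' @param response Response column name.
#' @param group Random-intercept grouping column.
#' @param alpha Family-wise significance level.
#' @return List with `letters` (named by period), `pairwise` (data.frame of
#'   estimates and adjusted p-values), `excluded` periods (< 2 observations).
#' @export
compare_period_means <- function(table, response, group = "tree_id",
                                 alpha = 0.05) {
  stopifnot("period" %in% names(table))
  tab <- table[!is.na(table[[response]]), , drop = FALSE]
  cnt <- table(tab$period)
  excluded <- names(cnt)[cnt < 2]
  if (length(excluded)) {
    warning("excluding period(s) with < 2 observations: ",
            paste(excluded, collapse = ", "))
    tab <- tab[!tab$period %in% as.integer(excluded), , drop = FALSE]
  }
  periods <- sort(unique(tab$period))
  if (length(periods) < 1) stop("no period with enough observations")
  if (length(periods) == 1) {
    lt <- stats::setNames("a", periods)
    return(list(letters = lt, pairwise = NULL, excluded = excluded))
  }
  tab$period_f <- factor(tab$period)
  n_groups <- length(unique(tab[[group]]))
  if (n_groups >= 2) {
    form <- stats::as.formula(paste(response, "~ period_f + (1 |", group, ")"))
    fit <- quiet_lmer(form, tab)
  } else {
    fit <- stats::lm(stats::as.formula(paste(response, "~ period_f")), data = tab)
  }
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(period_f = "Tukey"))
  sm <- summary(glht)
  cld <- multcomp::cld(glht, level = alpha)
  letters <- cld$mcletters$Letters
  pw <- data.frame(
    comparison = names(sm$test$coefficients),
    estimate = as.numeric(sm$test$coefficients),
    se = as.numeric(sm$test$sigma),
    p_adj = as.numeric(sm$test$pvalues),
    row.names = NULL
  )
  list(letters = letters, pairwise = pw, excluded = excluded)
}

#' Welch t-tests of each shoot chamber against the empty chamber
#'
#' Tests, shoot by shoot, whether the chamber-scale CH4 flux (ng h^-1,
#' uncorrected for the background) differs from the empty-chamber fluxes,
#' using Welch's unequal-variance two-sample t-test.
#'
#' @param shoot_fluxes data.frame with `shoot_id` and `chamber_flux`
#'   (ng h^-1, background-uncorrected).
#' @param empty_fluxes Numeric vector of empty-chamber fluxes, ng h^-1.
#' @param min_n Minimum closures per shoot and minimum empties (default 3).
#' @return data.frame per shoot: `n`, `mean_diff`, `t`, `p` (NA and flagged
#'   when n is insufficient).
#' @export
ttest_vs_empty <- function(shoot_fluxes, empty_fluxes, min_n = 3) {
  stopifnot(all(c("shoot_id", "chamber_flux") %in% names(shoot_fluxes)))
  enough_empty <- length(empty_fluxes) >= min_n
  ids <- unique(shoot_fluxes$shoot_id)
  out <- lapply(ids, function(id) {
    x <- shoot_fluxes$chamber_flux[shoot_fluxes$shoot_id == id]
    x <- x[!is.na(x)]
    if (length(x) < min_n || !enough_empty) {
      return(data.frame(shoot_id = id, n = length(x), mean_diff = NA_real_,
                        t = NA_real_, p = NA_real_, insufficient_n = TRUE))
    }
    if (stats::sd(x) == 0 && stats::sd(empty_fluxes) == 0 &&
        mean(x) == mean(empty_fluxes)) {
      # degenerate identical samples: no evidence of a difference
      return(data.frame(shoot_id = id, n = length(x), mean_diff = 0,
                        t = 0, p = 1, insufficient_n = FALSE))
    }
    tt <- stats::t.test(x, empty_fluxes, var.equal = FALSE)
    data.frame(shoot_id = id, n = length(x),
               mean_diff = mean(x) - mean(empty_fluxes),
               t = unname(tt$statistic), p = tt$p.value,
               insufficient_n = FALSE)
  })
  do.call(rbind, out)
}

#' Temperature response of CH4 flux in low- and high-PAR strata
#'
#' Splits the table at a PAR threshold (rows at exactly the threshold fall
#' in both strata, matching the overlapping "<= 500 and >= 500" convention)
#' and fits, within each stratum, a random-intercept model of the CH4 flux
#' on air temperature.
#'
#' @param table data.frame with `dw_flux_ch4`, `par`, `air_temp` and the
#'   grouping column.
#' @param threshold PAR threshold, umol m^-2 s^-1.
#' @param response Response column (default `"dw_flux_ch4"`).
#' @param group Grouping column.
#' @return List with elements `low` and `high`, each either `NULL` (empty
#'   stratum, flagged in `$flags`) or a list `slope`, `se`, `p`,
#'   `r2_marginal`, `n`; plus `flags`.
#' @export
par_split_regression <- function(table, threshold = 500,
                                 response = "dw_flux_ch4",
                                 group = "tree_id") {
  stopifnot(all(c("par", "air_temp") %in% names(table)))
  strata <- list(low = table[table$par <= threshold, , drop = FALSE],
                 high = table[table$par >= threshold, , drop = FALSE])
  flags <- character(0)
  out <- lapply(names(strata), function(nm) {
    d <- strata[[nm]]
    if (nrow(d) < 10) {
      flags <<- c(flags, paste0(nm, "_stratum_insufficient"))
      return(NULL)
    }
    fit <- fit_lmm(d, response, "air_temp", group = group)
    row <- fit$coefficients[fit$coefficients$term == "air_temp", ]
    list(slope = row$estimate, se = row$se, p = row$p,
         r2_marginal = marginal_r2(fit), n = fit$n_obs)
  })
  names(out) <- names(strata)
  c(out, list(flags = flags, threshold = threshold))
}

#' Helmert contrast matrix for ordered factor levels
#'
#' Coding in which each level is compared with the mean of all preceding
#' levels; columns are orthogonal and sum to zero.
#'
#' @param n Number of levels.
#' @return n x (n-1) contrast matrix.
#' @export
helmert_contrasts <- function(n) stats::contr.helmert(n)

#' PAR-slope by temperature-bin interaction with Helmert contrasts
#'
#' Bins the data by air temperature (default every 5 C from 0 to 20 C),
#' fits a random-intercept model `flux ~ PAR * bin` with Helmert-coded bin
#' contrasts, and reports (i) the fitted PAR slope with SE inside each bin
#' and (ii) Wald tests of the PAR-by-Helmert-contrast interactions, i.e.
#' whether the PAR slope in each bin exceeds the mean slope of the colder
#' bins.
#'
#' @param table data.frame with the response, `par`, `air_temp`, grouping.
#' @param bins Bin edges, C; rows outside the range are dropped.
#' @param response Response column (default `"dw_flux_ch4"`).
#' @param group Grouping column.
#' @param min_bin_n Bins with fewer rows are merged into the neighbouring
#'   colder bin (with a warning).
#' @return List with `bin_slopes` (data.frame bin, slope, se, n),
#'   `contrasts` (data.frame term, estimate, se, z, p), `model`.
#' @export
temp_bin_interaction <- function(table, bins = c(0, 5, 10, 15, 20),
                                 response = "dw_flux_ch4",
                                 group = "tree_id", min_bin_n = 5) {
  stopifnot(all(c("par", "air_temp") %in% names(table)))
  tab <- table[!is.na(table[[response]]) & !is.na(table$air_temp) &
                 table$air_temp >= min(bins) & table$air_temp <= max(bins), ,
               drop = FALSE]
  tab$bin <- cut(tab$air_temp, breaks = bins, include.lowest = TRUE,
                 right = FALSE)
  # merge sparse bins into the neighbouring colder (previous) level
  repeat {
    cnt <- table(tab$bin)
    small <- names(cnt)[cnt > 0 & cnt < min_bin_n]
    if (!length(small)) break
    lv <- levels(tab$bin)
    i <- match(small[1], lv)
    target <- if (i > 1) lv[i - 1] else lv[i + 1]
    warning("merging sparse temperature bin ", small[1], " into ", target)
    lv[lv == small[1]] <- target
    levels(tab$bin) <- lv
  }
  tab$bin <- droplevels(tab$bin)
  nlev <- nlevels(tab$bin)
  if (nlev < 2) stop("need at least 2 populated temperature bins")
  stats::contrasts(tab$bin) <- stats::contr.helmert(nlev)

  n_groups <- length(unique(tab[[group]]))
  if (n_groups >= 2) {
    form <- stats::as.formula(paste(response, "~ par * bin + (1 |", group, ")"))
    fit <- quiet_lmer(form, tab)
    cf <- summary(fit)$coefficients
    V <- as.matrix(stats::vcov(fit))
    beta <- lme4::fixef(fit)
  } else {
    fit <- stats::lm(stats::as.formula(paste(response, "~ par * bin")), data = tab)
    cf <- summary(fit)$coefficients[, 1:3]
    V <- stats::vcov(fit)
    beta <- stats::coef(fit)
  }

  # per-bin PAR slope: beta_par + H[j, ] %*% beta_interactions
  H <- stats::contr.helmert(nlev)
  int_terms <- grep("^par:bin", names(beta), value = TRUE)
  slope_rows <- lapply(seq_len(nlev), function(j) {
    w <- stats::setNames(numeric(length(beta)), names(beta))
    w["par"] <- 1
    w[int_terms] <- H[j, ]
    est <- sum(w * beta)
    se <- sqrt(drop(t(w) %*% V %*% w))
    data.frame(bin = levels(tab$bin)[j], slope = est, se = se,
               n = sum(tab$bin == levels(tab$bin)[j]))
  })
  bin_slopes <- do.call(rbind, slope_rows)

  zi <- cf[int_terms, 1] / cf[int_terms, 2]
  contrasts <- data.frame(term = int_terms,
                          estimate = cf[int_terms, 1],
                          se = cf[int_terms, 2],
                          z = zi, p = 2 * stats::pnorm(-abs(zi)),
                          row.names = NULL)
  list(bin_slopes = bin_slopes, contrasts = contrasts, model = fit)
}

#' Disentangle PAR and temperature as flux drivers via residual regressions
#'
#' When light and temperature co-vary, either may masquerade as the driver.
#' This runs the two residual regressions: (i) residuals of flux ~
#' temperature regressed on PAR, and (ii) residuals of flux ~ PAR regressed
#' on temperature. A true PAR driver leaves (i) significant and (ii) not.
#'
#' @param table data.frame with the response, `par`, `air_temp`.
#' @param response Response column (default `"dw_flux_ch4"`).
#' @return List with `resid_temp_on_par` and `resid_par_on_temp`, each
#'   holding `slope`, `se`, `p`.
#' @export
residual_disentangle <- function(table, response = "dw_flux_ch4") {
  stopifnot(all(c("par", "air_temp") %in% names(table)))
  tab <- table[stats::complete.cases(table[, c(response, "par", "air_temp")]), ]
  y <- tab[[response]]
  one <- function(first, second) {
    r <- stats::resid(stats::lm(y ~ tab[[first]]))
    fit <- stats::lm(r ~ tab[[second]])
    cf <- summary(fit)$coefficients
    list(slope = cf[2, 1], se = cf[2, 2], p = cf[2, 4])
  }
  list(resid_temp_on_par = one("air_temp", "par"),
       resid_par_on_temp = one("par", "air_temp"))
}
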