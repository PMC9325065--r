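#' Automatically trim the unstable parts of a closure
#'
#' Field practice inspects each closure graphically and moves the start/end
#' of the flux-calculation window past segments disturbed by headspace
#' mixing, chamber leakage or mis-recorded closure times. This function
#' automates that judgement: a fixed initial deadband is removed, then the
#' window is shrunk from both ends while the rolling median of the residuals
#' from a provisional linear CH4 fit exceeds `mad_k` times the robust
#' residual scale (MAD). The procedure is iterated to convergence, never
#' widens the window, and is idempotent.
#'
#' @param series A [closure_series()] with at least 60 s of records.
#' @param deadband_s Initial seconds always excluded (headspace mixing).
#' @param mad_k Threshold in MAD units for excluding edge segments.
#' @param min_span_s Minimum post-trim span; shorter closures are marked
#'   `discard` with reason `"too short after trim"`.
#' @param roll_width Width (records) of the rolling median of residuals.
#' @param max_iter Maximum shrink iterations.
#' @return The series with `trim` set (half-open `[t_start, t_end)` seconds),
#'   and `qc_status`/`qc_reason` updated when the trimmed span is too short.
#' @export
trim_closure <- function(series, deadband_s = 30, mad_k = 4,
                         min_span_s = 120, roll_width = 11, max_iter = 10) {
  stopifnot(inherits(series, "closure_series"))
  r <- series$records
  if (max(r$t) - min(r$t) < 60) stop("need at least 60 s of records to trim")

  lo <- max(r$t[1] + deadband_s, if (!is.null(series$trim)) series$trim[1] else -Inf)
  hi <- if (!is.null(series$trim)) series$trim[2] else max(r$t) + 1
  hi <- min(hi, max(r$t) + 1)

  ych <- if (!is.null(r$ch4_dry_corr)) r$ch4_dry_corr else r$ch4_dry_raw
  sel <- function(lo, hi) which(r$t >= lo & r$t < hi)
  idx <- sel(lo, hi)
  for (it in seq_len(max_iter)) {
    if (length(idx) < 20) break
    tt <- r$t[idx]; y <- ych[idx]
    fit <- repeated_median_line(tt, y)
    res <- y - (fit$intercept + fit$slope * tt)
    # noise scale from differenced residuals so that structural deviations
    # (the thing we want to cut) do not inflate the threshold
    scale <- stats::mad(diff(res)) / sqrt(2)
    if (!is.finite(scale) || scale < 1e-12) break  # noiseless / flat: nothing to cut
    roll <- roll_median(res, roll_width)
    bad_hi <- abs(roll) > mad_k * scale
    bad_lo <- abs(roll) > scale
    if (!any(bad_hi)) break
    # hysteresis: a run must contain a strong excursion (> mad_k sigma) but is
    # cut back to where it first left the 1-sigma band, so the unstable
    # segment is removed from its onset
    keep <- rep(TRUE, length(idx))
    lead_lo <- cumprod(bad_lo) > 0
    if (any(lead_lo & bad_hi)) keep[lead_lo] <- FALSE
    trail_lo <- rev(cumprod(rev(bad_lo)) > 0)
    if (any(trail_lo & bad_hi)) keep[trail_lo] <- FALSE
    if (!any(keep) || all(keep)) break
    lo <- max(lo, tt[which(keep)[1]])
    hi <- min(hi, tt[rev(which(keep))[1]] + min(diff(tt)))
    idx2 <- sel(lo, hi)
    if (length(idx2) == length(idx)) break
    idx <- idx2
  }

  series$trim <- c(lo, hi)
  span <- hi - lo
  if (span < min_span_s || length(idx) < 20) {
    series$qc_status <- "discard"
    series$qc_reason <- "too short after trim"
  }
  series
}

# deterministic robust line: repeated-median slope (50% breakdown), so the
# provisional fit tracks the majority segment rather than a compromise
repeated_median_line <- function(t, y) {
  n <- length(t)
  if (n > 200) {  # thin for the O(n^2) pairwise slopes; fit is provisional
    pick <- unique(round(seq(1, n, length.out = 200)))
    ts <- t[pick]; ys <- y[pick]
  } else {
    ts <- t; ys <- y
  }
  m <- length(ts)
  dt <- outer(ts, ts, "-")
  dy <- outer(ys, ys, "-")
  sl <- dy / dt
  diag(sl) <- NA
  slope <- stats::median(apply(sl, 1, stats::median, na.rm = TRUE))
  intercept <- stats::median(y - slope * t)
  list(slope = slope, intercept = intercept)
}

# rolling median with shrinking windows at the edges
roll_median <- function(x, width) {
  n <- length(x)
  half <- width %/% 2
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Quality-control labelling of a trimmed closure
#'
#' Applies configurable discard rules to a trimmed closure; QC never raises,
#' it labels. A closure is discarded when (i) its post-trim span is shorter
#' than `min_span_s`, (ii) the robust spread (MAD) of the residuals from the
#' linear CH4 fit exceeds `spread_max_ppm` (unstable loop), or (iii) the
#' residuals show systematic curvature larger than `drift_k` times their MAD
#' (drift, e.g. a developing leak the trimming did not isolate).
#'
#' @param series A trimmed [closure_series()].
#' @param min_span_s Minimum trimmed span, s.
#' @param spread_max_ppm Maximum allowed MAD of CH4 fit residuals, ppm.
#' @param drift_k Maximum allowed quadratic-deviation to MAD ratio.
#' @return The series with `qc_status` set to `"pass"` or `"discard"` and
#'   `qc_reason` recorded.
#' @export
qc_closure <- function(series, min_span_s = 120, spread_max_ppm = 0.01,
                       drift_k = 8) {
  stopifnot(inherits(series, "closure_series"))
  if (is.null(series$trim)) stop("closure must be trimmed before QC")
  if (identical(series$qc_status, "discard")) return(series)

  r <- trimmed_records(series)
  span <- series$trim[2] - series$trim[1]
  if (span < min_span_s || nrow(r) < 20) {
    series$qc_status <- "discard"
    series$qc_reason <- "too short after trim"
    return(series)
  }
  tt <- r$t
  y <- if (!is.null(r$ch4_dry_corr)) r$ch4_dry_corr else r$ch4_dry_raw
  fit <- stats::lm.fit(cbind(1, tt), y)
  res <- fit$residuals
  scale <- stats::mad(res)
  if (is.finite(scale) && scale > spread_max_ppm) {
    series$qc_status <- "discard"
    series$qc_reason <- "unstable"
    return(series)
  }
  # curvature: quadratic component's peak deviation relative to noise
  tc <- tt - mean(tt)
  qfit <- stats::lm.fit(cbind(1, tc, tc^2), y)
  qdev <- abs(qfit$coefficients[3]) * (span / 2)^2
  if (is.finite(scale) && scale > 1e-12 && qdev > drift_k * scale) {
    series$qc_status <- "discard"
    series$qc_reason <- "drift"
    return(series)
  }
  series$qc_status <- "pass"
  series$qc_reason <- NA_character_
  series
}

#' H2O spectral-interference calibration
#'
#' @param f Interference slope, ppm CH4 per ppm H2O.
#' @param ci95_halfwidth Half-width of the 95% confidence interval, same units.
#' @param n_replicates Number of injection replicates behind the estimate.
#' @param method `"mean_of_slopes"` or `"pooled"` (how `f` was estimated).
#' @return Object of class `interference_calibration`.
#' @export
interference_calibration <- function(f, ci95_halfwidth = 0,
                                     n_replicates = NA_integer_,
                                     method = "mean_of_slopes") {
  if (ci95_halfwidth < 0) stop("ci95_halfwidth must be >= 0")
  structure(list(f = f, ci95_halfwidth = ci95_halfwidth,
                 n_replicates = n_replicates, method = method),
            class = "interference_calibration")
}

#' @export
print.interference_calibration <- function(x, ...) {
  cat(sprintf("<interference_calibration> f = %.4g ppm CH4 / ppm H2O (95%% CI +/- %.3g, n = %s, %s)\n",
              x$f, x$ci95_halfwidth,
              ifelse(is.na(x$n_replicates), "?", x$n_replicates), x$method))
  invisible(x)
}

#' Correct reported dry CH4 for the water-vapour spectral interference
#'
#' The analyser's internal water correction leaves a residual cross-talk:
#' rising H2O produces an apparent change in the reported dry CH4. The
#' corrected mixing ratio is, pointwise,
#'
#'   ch4_dry_corr(t) = ch4_dry_raw(t) - h2o(t) * f
#'
#' @param series A [closure_series()] with an `h2o` channel.
#' @param cal An [interference_calibration()], or a bare numeric `f`.
#' @return The series with a `ch4_dry_corr` column added to its records.
#' @export
correct_h2o <- function(series, cal) {
  stopifnot(inherits(series, "closure_series"))
  f <- if (inherits(cal, "interference_calibration")) cal$f else cal
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f))
    stop("calibration must supply a single finite f")
  h2o <- series$records$h2o
  if (is.null(h2o) || all(is.na(h2o)))
    stop("closure has no h2o channel; interference calibration cannot apply")
  series$records$ch4_dry_corr <- series$records$ch4_dry_raw - h2o * f
  series
}

#' Estimate the H2O interference factor from water-injection runs
#'
#' Each replicate run holds the actual dry CH4 constant while H2O sweeps a
#' wide range; the reported dry CH4 then drifts linearly in H2O with slope
#' `f`. Per replicate, `f` is the OLS slope of reported dry CH4 on H2O; the
#' calibration value is the mean of the replicate slopes with a
#' t-distribution 95% confidence interval of the mean (a pooled single
#' regression across all runs is available as an option).
#'
#' @param runs List of [closure_series()] injection runs (>= 2).
#' @param method `"mean_of_slopes"` (default) or `"pooled"`.
#' @param min_h2o_range_ppm Minimum H2O span a run must cover, ppm.
#' @return An [interference_calibration()].
#' @export
estimate_f <- function(runs, method = c("mean_of_slopes", "pooled"),
                       min_h2o_range_ppm = 5000) {
  method <- match.arg(method)
  if (!is.list(runs) || length(runs) < 2)
    stop("need at least 2 injection replicates to estimate f")
  for (r in runs) {
    if (!inherits(r, "closure_series")) stop("runs must be closure_series objects")
    rng <- diff(range(r$records$h2o))
    if (rng < min_h2o_range_ppm)
      stop(sprintf("H2O range %.0f ppm too small to identify the slope (need >= %.0f)",
                   rng, min_h2o_range_ppm))
  }
  if (method == "mean_of_slopes") {
    slopes <- vapply(runs, function(r) {
      stats::coef(stats::lm(ch4_dry_raw ~ h2o, data = r$records))[["h2o"]]
    }, numeric(1))
    n <- length(slopes)
    f <- mean(slopes)
    se <- stats::sd(slopes) / sqrt(n)
    ci <- stats::qt(0.975, df = n - 1) * se
  } else {
    dat <- do.call(rbind, lapply(runs, function(r)
      r$records[, c("ch4_dry_raw", "h2o")]))
    fit <- stats::lm(ch4_dry_raw ~ h2o, data = dat)
    f <- stats::coef(fit)[["h2o"]]
    se <- summary(fit)$coefficients["h2o", "Std. Error"]
    ci <- stats::qt(0.975, df = fit$df.residual) * se
    n <- length(runs)
  }
  interference_calibration(f, ci95_halfwidth = ci, n_replicates = n,
                           method = method)
}
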