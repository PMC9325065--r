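#' Pipeline configuration
#'
#' Collects every tunable of the processing pipeline in one validated list.
#' Unknown keys are rejected so a typo cannot silently fall back to a
#' default.
#'
#' @param f H2O interference factor, ppm CH4 per ppm H2O (applied as
#'   `ch4_corr = ch4_raw - h2o * f`).
#' @param deadband_s,mad_k,min_span_s Trimming parameters, see
#'   [trim_closure()].
#' @param spread_max_ppm,drift_k QC thresholds, see [qc_closure()].
#' @param background_alpha Significance level for the radiation sensitivity
#'   test of the empty-chamber background.
#' @param gdd_base Base temperature for growing degree days, C.
#' @param growth_g50,growth_steepness Logistic growth-model parameters.
#' @param chamber_volume_m3,chamber_pressure_pa Chamber geometry.
#' @param par_threshold PAR split threshold, umol m^-2 s^-1.
#' @param temp_bins Temperature bin edges, C.
#' @param period_width_days Width of the chronological subgroups, days.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(f = -9.122e-7,
                            deadband_s = 30, mad_k = 4, min_span_s = 120,
                            spread_max_ppm = 0.01, drift_k = 8,
                            background_alpha = 0.05,
                            gdd_base = 5, growth_g50 = 150,
                            growth_steepness = 0.03,
                            chamber_volume_m3 = 5.2e-3,
                            chamber_pressure_pa = 101325,
                            par_threshold = 500,
                            temp_bins = c(0, 5, 10, 15, 20),
                            period_width_days = 14) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments;
#'   unknown keys are an error.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Read a campaign raw-file directory
#'
#' Reads the delimited-text dialect written by [write_campaign()]:
#' `analyzer.csv`, `closures.csv`, `meteo.csv`, `biomass.csv`. A column
#' mapping can adapt externally produced files (e.g. an archived deposit
#' with different headers) to the expected names.
#'
#' @param dir Directory of raw files.
#' @param column_map Optional named character vector mapping expected
#'   analyzer column names to the names found in the file, e.g.
#'   `c(ch4_dry_ppm = "CH4_dry")`.
#' @return List with `analyzer`, `meta`, `meteo`, `biomass` data.frames.
#' @export
read_campaign <- function(dir, column_map = NULL) {
  need <- function(fn) {
    p <- file.path(dir, fn)
    if (!file.exists(p)) stop("missing input file: ", p)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  ana <- need("analyzer.csv")
  if (!is.null(column_map)) {
    for (want in names(column_map)) {
      have <- column_map[[want]]
      if (!have %in% names(ana))
        stop("column mapping refers to missing column '", have, "' in analyzer.csv")
      names(ana)[names(ana) == have] <- want
    }
  }
  req <- c("timestamp", "ch4_dry_ppm", "co2_ppm", "h2o_ppm", "sample_temp_K")
  miss <- setdiff(req, names(ana))
  if (length(miss))
    stop("analyzer.csv lacks column(s): ", paste(miss, collapse = ", "))
  ana$timestamp <- as.POSIXct(ana$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                              tz = "UTC")
  meta <- need("closures.csv")
  meta$start_time <- as.POSIXct(meta$start_time, format = "%Y-%m-%dT%H:%M:%S",
                                tz = "UTC")
  meta$end_time <- as.POSIXct(meta$end_time, format = "%Y-%m-%dT%H:%M:%S",
                              tz = "UTC")
  met <- need("meteo.csv")
  met$timestamp <- as.POSIXct(met$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                              tz = "UTC")
  class(met) <- c("meteo_series", "data.frame")
  bio <- need("biomass.csv")
  list(analyzer = ana, meta = meta, meteo = met, biomass = bio)
}

slice_closure <- function(analyzer, meta_row) {
  sel <- analyzer$timestamp >= meta_row$start_time &
    analyzer$timestamp <= meta_row$end_time
  rec <- analyzer[sel, , drop = FALSE]
  if (nrow(rec) < 2) return(NULL)
  empty <- identical(meta_row$shoot_id, "EMPTY")
  closure_series(
    data.frame(
      t = as.numeric(rec$timestamp) - as.numeric(meta_row$start_time),
      ch4_dry_raw = rec$ch4_dry_ppm,
      co2 = rec$co2_ppm,
      h2o = rec$h2o_ppm,
      sample_temp = rec$sample_temp_K
    ),
    chamber_id = meta_row$chamber_id,
    shoot_id = if (empty) NA_character_ else meta_row$shoot_id,
    species = if (empty) NA_character_ else meta_row$species,
    start_time = meta_row$start_time
  )
}

#' Process a raw campaign into a tidy flux table
#'
#' Runs the full chain on every closure of a campaign: trim, QC, H2O
#' interference correction, linear CH4 and exponential CO2 fits, flux
#' conversion with the mean sample temperature over the trim window,
#' needle-mass reconstruction from the growing-degree-day growth model,
#' empty-chamber background modelling and subtraction (chamber scale), and
#' the detection-limit ladder. Every closure ends up in exactly one of the
#' flux table or the discard log.
#'
#' @param campaign Either a [gen_campaign()] object or the list returned by
#'   [read_campaign()].
#' @param config A [pipeline_config()].
#' @return List of class `process_result` with `fluxes` (tidy per-closure
#'   table), `discards` (closure id + reason), `background`
#'   ([fit_background()] model), `mdl` ([compute_mdl()] ladder or NULL),
#'   `empties` (per-empty-closure fluxes), `config`.
#' @export
run_process <- function(campaign, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  chamber <- chamber_spec(config$chamber_volume_m3, config$chamber_pressure_pa)
  cal <- interference_calibration(config$f)

  if (inherits(campaign, "campaign")) {
    closures <- campaign$closures
    meta <- campaign$meta
    meteo <- campaign$meteo
    biomass <- campaign$biomass
    names(biomass)[names(biomass) == "m_y1"] <- "m_y1_g"
    names(biomass)[names(biomass) == "m_y0_final"] <- "m_y0_final_g"
  } else {
    closures <- lapply(seq_len(nrow(campaign$meta)), function(i)
      slice_closure(campaign$analyzer, campaign$meta[i, ]))
    names(closures) <- campaign$meta$closure_id
    meta <- campaign$meta
    meteo <- campaign$meteo
    biomass <- campaign$biomass
  }
  if (!"closure_id" %in% names(meta))
    meta$closure_id <- sprintf("c%04d", seq_len(nrow(meta)))

  # growth model shared by all shoots without measured elongation
  dm <- daily_mean_temp(meteo)
  gdd <- gdd_accumulate(dm$tmean, base = config$gdd_base, dates = dm$date)
  rel <- tryCatch(
    relative_growth(gdd, g50 = config$growth_g50,
                    steepness = config$growth_steepness),
    error = function(e) NULL)

  bio_for <- function(id) {
    row <- biomass[biomass$shoot_id == id, , drop = FALSE]
    if (nrow(row) != 1) stop("biomass record missing for shoot ", id)
    shoot_biomass(id, row$species, row$m_y1_g, row$m_y0_final_g)
  }

  rows <- list(); discards <- list(); empty_rows <- list()
  for (i in seq_len(nrow(meta))) {
    cid <- meta$closure_id[i]
    cl <- closures[[i]]
    if (is.null(cl)) {
      discards[[length(discards) + 1L]] <-
        data.frame(closure_id = cid, reason = "no analyzer records")
      next
    }
    # correct before trimming so trim/QC judge the physical CH4 signal, not
    # the smooth H2O cross-talk component
    cl <- correct_h2o(cl, cal)
    cl <- trim_closure(cl, deadband_s = config$deadband_s,
                       mad_k = config$mad_k, min_span_s = config$min_span_s)
    cl <- qc_closure(cl, min_span_s = config$min_span_s,
                     spread_max_ppm = config$spread_max_ppm,
                     drift_k = config$drift_k)
    if (!identical(cl$qc_status, "pass")) {
      discards[[length(discards) + 1L]] <-
        data.frame(closure_id = cid, reason = cl$qc_reason)
      next
    }
    tr <- trimmed_records(cl)
    temp_k <- mean(tr$sample_temp)
    mwin <- meteo_window_mean(meteo,
                              cl$start_time + cl$trim[1],
                              cl$start_time + cl$trim[2])
    lin <- fit_linear_slope(cl, "ch4")
    fx_ch4 <- slope_to_flux(lin, chamber, "ch4", sample_temp = temp_k)

    empty <- is_empty_closure(cl)
    if (empty) {
      empty_rows[[length(empty_rows) + 1L]] <- data.frame(
        closure_id = cid,
        chamber_flux_ch4 = fx_ch4$chamber_flux,
        par = mwin$par, global_radiation = mwin$global_radiation,
        air_temp = mwin$air_temp,
        start_time = cl$start_time
      )
      next
    }
    exp_fit <- fit_exponential(cl)
    fx_co2 <- slope_to_flux(exp_fit, chamber, "co2", sample_temp = temp_k)
    mass <- needle_mass_at(as.Date(cl$start_time, tz = "UTC"),
                           bio_for(cl$shoot_id), rel = rel)
    rows[[length(rows) + 1L]] <- data.frame(
      closure_id = cid,
      date = as.Date(cl$start_time, tz = "UTC"),
      shoot_id = cl$shoot_id,
      tree_id = cl$shoot_id,
      species = cl$species,
      chamber_flux_ch4_raw = fx_ch4$chamber_flux,
      slope_se_ch4 = fx_ch4$slope_se,
      r2_ch4 = lin$r2,
      chamber_flux_co2 = fx_co2$chamber_flux,
      co2_fit_converged = exp_fit$converged,
      needle_mass = mass,
      sample_temp = temp_k,
      par = mwin$par,
      global_radiation = mwin$global_radiation,
      air_temp = mwin$air_temp,
      stringsAsFactors = FALSE
    )
  }

  fluxes <- if (length(rows)) do.call(rbind, rows) else NULL
  empties <- if (length(empty_rows)) do.call(rbind, empty_rows) else NULL
  discards <- if (length(discards)) do.call(rbind, discards) else
    data.frame(closure_id = character(0), reason = character(0))

  background <- NULL; mdl <- NULL
  if (!is.null(empties) && nrow(empties) >= 3) {
    background <- fit_background(empties$chamber_flux_ch4,
                                 global_radiation = empties$global_radiation,
                                 air_temp = empties$air_temp,
                                 time = empties$start_time,
                                 alpha = config$background_alpha)
  }
  if (!is.null(fluxes)) {
    if (!is.null(background)) {
      fluxes$chamber_flux_ch4 <- subtract_background(
        fluxes$chamber_flux_ch4_raw, background,
        global_radiation = fluxes$global_radiation)
    } else {
      fluxes$chamber_flux_ch4 <- fluxes$chamber_flux_ch4_raw
    }
    fluxes$dw_flux_ch4 <- fluxes$chamber_flux_ch4 / fluxes$needle_mass
    fluxes$dw_flux_co2 <- fluxes$chamber_flux_co2 / fluxes$needle_mass
    fluxes$period <- assign_periods(fluxes$date,
                                    width_days = config$period_width_days)
    if (!is.null(empties) && nrow(empties) >= 3) {
      avg_dw <- tapply(fluxes$needle_mass, fluxes$species, mean)
      npp <- tapply(fluxes$period, fluxes$species, function(p)
        max(1L, as.integer(stats::median(table(p)))))
      mdl <- compute_mdl(empty_fluxes = empties$chamber_flux_ch4,
                         avg_dw = stats::setNames(as.numeric(avg_dw), names(avg_dw)),
                         n_per_period = stats::setNames(as.integer(npp), names(npp)))
      fluxes <- flag_below_mdl(fluxes, mdl, column = "dw_flux_ch4")
    }
  }

  structure(list(fluxes = fluxes, discards = discards, empties = empties,
                 background = background, mdl = mdl, config = config),
            class = "process_result")
}

#' @export
print.process_result <- function(x, ...) {
  cat(sprintf("<process_result> %d shoot fluxes, %d empties, %d discards; background %s\n",
              if (is.null(x$fluxes)) 0L else nrow(x$fluxes),
              if (is.null(x$empties)) 0L else nrow(x$empties),
              nrow(x$discards),
              if (is.null(x$background)) "not fitted" else x$background$mode))
  invisible(x)
}

#' Driver analysis of a processed flux table
#'
#' Runs the statistical battery on the tidy flux table: 2-week period
#' comparisons with a compact letter display, per-shoot Welch t-tests
#' against the empty chamber (chamber scale, background-uncorrected),
#' mixed-model regressions of the CH4 flux on PAR/radiation/temperature/CO2,
#' the PAR-split temperature analysis, temperature-bin Helmert interaction
#' contrasts and the PAR-versus-temperature residual disentangling. Species
#' sections are produced only for species present in the table.
#'
#' @param processed A [run_process()] result (or a compatible flux table
#'   plus `empties`).
#' @param config A [pipeline_config()].
#' @return List of class `analysis_report`, one element per species plus
#'   metadata; row order of the input does not affect the result.
#' @export
run_analyze <- function(processed, config = pipeline_config()) {
  fluxes <- if (inherits(processed, "process_result")) processed$fluxes
    else processed$fluxes
  if (is.null(fluxes) || nrow(fluxes) == 0) stop("empty flux table")
  empties <- processed$empties
  fluxes <- fluxes[order(fluxes$date, fluxes$closure_id), ]

  per_species <- lapply(split(fluxes, fluxes$species), function(d) {
    out <- list(n = nrow(d))
    out$periods <- tryCatch(
      compare_period_means(d, "dw_flux_ch4"), error = function(e) conditionMessage(e))
    out$drivers <- tryCatch({
      fit <- fit_lmm(d, "dw_flux_ch4", c("par", "air_temp"))
      fit$coefficients
    }, error = function(e) conditionMessage(e))
    out$par_regression <- tryCatch({
      fit <- fit_lmm(d, "dw_flux_ch4", "par")
      list(coefficients = fit$coefficients, r2_marginal = marginal_r2(fit))
    }, error = function(e) conditionMessage(e))
    out$co2_regression <- tryCatch({
      fit <- fit_lmm(d, "dw_flux_ch4", "dw_flux_co2")
      list(coefficients = fit$coefficients, r2_marginal = marginal_r2(fit))
    }, error = function(e) conditionMessage(e))
    out$par_split <- tryCatch(
      par_split_regression(d, threshold = config$par_threshold),
      error = function(e) conditionMessage(e))
    out$temp_bins <- tryCatch(
      temp_bin_interaction(d, bins = config$temp_bins),
      error = function(e) conditionMessage(e))
    out$residuals <- tryCatch(
      residual_disentangle(d), error = function(e) conditionMessage(e))
    if (!is.null(empties)) {
      out$vs_empty <- tryCatch(
        ttest_vs_empty(
          data.frame(shoot_id = d$shoot_id,
                     chamber_flux = d$chamber_flux_ch4_raw),
          empties$chamber_flux_ch4),
        error = function(e) conditionMessage(e))
    }
    out
  })

  structure(list(
    species = per_species,
    n_fluxes = nrow(fluxes),
    n_empties = if (is.null(empties)) 0L else nrow(empties),
    notes = c("empty-chamber comparison uses background-uncorrected chamber-scale fluxes"),
    config = unclass(config)
  ), class = "analysis_report")
}

#' Simulate, write and return a synthetic campaign (one-call front end)
#'
#' @param out_dir Directory for the raw file set (`NULL` to skip writing).
#' @param config [campaign_config()].
#' @param truth [truth_params()].
#' @param seed Integer seed.
#' @return The [gen_campaign()] object, invisibly when written.
#' @export
run_simulate <- function(out_dir = NULL, config = campaign_config(),
                         truth = truth_params(), seed = 1L) {
  camp <- gen_campaign(config, truth = truth, seed = seed)
  if (!is.null(out_dir)) {
    write_campaign(camp, out_dir)
    return(invisible(camp))
  }
  camp
}
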