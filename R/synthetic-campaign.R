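#' Configuration of a synthetic measurement campaign
#'
#' Describes the measurement schedule of a spring shoot-chamber campaign:
#' several measurement days per week, several rounds per day, an
#' empty-chamber control closure leading every round, all pine chambers
#' measured in (almost) every round and the spruce chambers rotating so one
#' is measured per round. The defaults emulate a six-week campaign with four
#' pines and three spruces measured nine times a week.
#'
#' @param n_pine,n_spruce Number of shoot chambers (trees) per species.
#' @param weeks Campaign length, weeks (>= 1).
#' @param days_per_week Measurement days per week.
#' @param rounds_per_day Measurement rounds per day.
#' @param pine_skip_prob Probability that a given pine chamber is skipped in
#'   a round (field interruptions); spruce follows the rotation instead.
#' @param round_start_hour Local hour of the first round; subsequent rounds
#'   follow every `round_spacing_h` hours.
#' @param round_spacing_h Hours between rounds within a day.
#' @param closure_duration_s Closure length, s (7-10 min window).
#' @param closure_gap_s Gap between consecutive closures on a round, s.
#' @param noisy_fraction Fraction of closures generated with 10x analyser
#'   noise (emulating unstable loop mixing); 0 disables.
#' @param start_date First campaign day.
#' @param pine_m_y1,pine_m_y0 Mean 1-yr-old and final current-year needle dry
#'   mass per pine shoot, g.
#' @param spruce_m_y1,spruce_m_y0 Same for spruce.
#' @param biomass_cv Between-tree coefficient of variation of needle masses.
#' @return List of class `campaign_config`.
#' @export
campaign_config <- function(n_pine = 4, n_spruce = 3, weeks = 6,
                            days_per_week = 3, rounds_per_day = 3,
                            pine_skip_prob = 0.18,
                            round_start_hour = 9, round_spacing_h = 3,
                            closure_duration_s = 480, closure_gap_s = 120,
                            noisy_fraction = 0,
                            start_date = as.Date("2019-04-01"),
                            pine_m_y1 = 20, pine_m_y0 = 5,
                            spruce_m_y1 = 5, spruce_m_y0 = 0.8,
                            biomass_cv = 0.15) {
  if (weeks < 1) stop("campaign must span at least one week")
  if (n_pine < 0 || n_spruce < 0) stop("tree counts must be non-negative")
  structure(as.list(environment()), class = "campaign_config")
}

#' Generate a complete synthetic campaign
#'
#' Generates meteorology, per-tree biomass, per-tree random emission
#' intercepts, and all chamber closures of a campaign following the schedule
#' in `config`. Every measurement round starts with an empty-chamber control
#' closure; shoot closures follow back-to-back (never overlapping on a
#' chamber). Needle mass on a given day follows the growing-degree-day
#' relative-growth model, so the embedded per-closure truth uses the mass a
#' correct pipeline should reconstruct.
#'
#' @param config [campaign_config()].
#' @param truth [truth_params()].
#' @param chamber [chamber_spec()].
#' @param seed Integer master seed; the same seed reproduces the campaign
#'   byte-for-byte.
#' @param meteo_params Parameters for [gen_meteo()].
#' @return List of class `campaign` with elements `closures` (list of
#'   [closure_series()] with truth attributes), `meta` (per-closure
#'   data.frame), `meteo`, `biomass` (per shoot), `trees` (random
#'   intercepts), `truth`, `config`.
#' @examples
#' camp <- gen_campaign(campaign_config(weeks = 1), seed = 7)
#' nrow(camp$meta)
#' @export
gen_campaign <- function(config = campaign_config(), truth = truth_params(),
                         chamber = chamber_spec(), seed = 1L,
                         meteo_params = shootflux::meteo_params()) {
  stopifnot(inherits(config, "campaign_config"))
  rng <- local_rng(seed + 1000003)

  n_days <- as.integer(ceiling(config$weeks * 7))
  meteo <- gen_meteo(n_days, params = meteo_params, seed = seed + 11,
                     start_date = config$start_date)

  # trees, biomass, random intercepts (drawn once per campaign)
  ids <- c(if (config$n_pine > 0) paste0("pine_", seq_len(config$n_pine)),
           if (config$n_spruce > 0) paste0("spruce_", seq_len(config$n_spruce)))
  trees <- data.frame(
    shoot_id = if (is.null(ids)) character(0) else ids,
    species = c(rep("pine", config$n_pine), rep("spruce", config$n_spruce)),
    stringsAsFactors = FALSE
  )
  n_tree <- nrow(trees)
  if (n_tree > 0) {
    trees$tree_intercept <- rng(stats::rnorm(n_tree, 0, truth$random_intercept_sd))
    m1 <- ifelse(trees$species == "pine", config$pine_m_y1, config$spruce_m_y1)
    m0 <- ifelse(trees$species == "pine", config$pine_m_y0, config$spruce_m_y0)
    trees$m_y1 <- pmax(0.1, m1 * (1 + rng(stats::rnorm(n_tree, 0, config$biomass_cv))))
    trees$m_y0_final <- pmax(0.01, m0 * (1 + rng(stats::rnorm(n_tree, 0, config$biomass_cv))))
  } else {
    trees$tree_intercept <- numeric(0)
    trees$m_y1 <- numeric(0)
    trees$m_y0_final <- numeric(0)
  }

  # relative growth over the campaign from cumulative degree days
  dm <- daily_mean_temp(meteo)
  gdd <- gdd_accumulate(dm$tmean, dates = dm$date)
  rel <- tryCatch(relative_growth(gdd), error = function(e) NULL)
  rel_at <- function(date) {
    if (is.null(rel)) return(1)  # no growth signal: mass fixed at final
    rel$fraction[match(as.Date(date), rel$date)]
  }

  # measurement schedule
  meas_days <- as.Date(unlist(lapply(seq_len(config$weeks) - 1L, function(w) {
    as.character(config$start_date + w * 7 +
                   round(seq(0, 6, length.out = config$days_per_week + 2))[
                     2:(config$days_per_week + 1)])
  })))
  meas_days <- meas_days[meas_days <= config$start_date + n_days - 1]

  closures <- list()
  meta <- list()
  ci <- 0L
  spruce_ptr <- 0L
  spruce_ids <- trees$shoot_id[trees$species == "spruce"]
  for (d in seq_along(meas_days)) {
    for (r in seq_len(config$rounds_per_day)) {
      round_start <- as.POSIXct(meas_days[d], tz = "UTC") +
        (config$round_start_hour + (r - 1) * config$round_spacing_h) * 3600
      # who is measured this round: empty first, pines (with skips), 1 spruce
      ids <- character(0)
      if (config$n_pine > 0) {
        pines <- trees$shoot_id[trees$species == "pine"]
        keep <- rng(stats::runif(length(pines))) >= config$pine_skip_prob
        ids <- c(ids, pines[keep])
      }
      if (length(spruce_ids) > 0) {
        spruce_ptr <- spruce_ptr %% length(spruce_ids) + 1L
        ids <- c(ids, spruce_ids[spruce_ptr])
      }
      slots <- c("EMPTY", ids)
      t0 <- round_start
      for (s in slots) {
        ci <- ci + 1L
        dur <- config$closure_duration_s
        mwin <- meteo_window_mean(meteo, t0, t0 + dur)
        noisy <- config$noisy_fraction > 0 &&
          rng(stats::runif(1)) < config$noisy_fraction
        if (identical(s, "EMPTY")) {
          shoot <- NULL
          chamber_id <- "empty"
        } else {
          tr <- trees[trees$shoot_id == s, ]
          mass <- tr$m_y1 + rel_at(meas_days[d]) * tr$m_y0_final
          shoot <- list(shoot_id = s, species = tr$species,
                        needle_mass = mass,
                        tree_intercept = tr$tree_intercept)
          chamber_id <- s
        }
        cl <- gen_closure(truth, chamber, shoot = shoot, meteo_at = mwin,
                          duration_s = dur, seed = seed + 37L * ci,
                          chamber_id = chamber_id, start_time = t0,
                          noise_mult = if (noisy) 10 else 1)
        closures[[ci]] <- cl
        meta[[ci]] <- data.frame(
          closure_id = sprintf("c%04d", ci),
          chamber_id = chamber_id,
          shoot_id = if (identical(s, "EMPTY")) "EMPTY" else s,
          species = if (identical(s, "EMPTY")) "EMPTY" else shoot$species,
          start_time = t0,
          end_time = t0 + dur,
          stringsAsFactors = FALSE
        )
        t0 <- t0 + dur + config$closure_gap_s
      }
    }
  }
  meta <- if (length(meta)) do.call(rbind, meta) else
    data.frame(closure_id = character(0), chamber_id = character(0),
               shoot_id = character(0), species = character(0),
               start_time = as.POSIXct(character(0)),
               end_time = as.POSIXct(character(0)))
  if (ci > 0) names(closures) <- meta$closure_id

  structure(list(closures = closures, meta = meta, meteo = meteo,
                 biomass = trees[, c("shoot_id", "species", "m_y1", "m_y0_final")],
                 trees = trees, truth = truth, chamber = chamber,
                 config = config),
            class = "campaign")
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf("<campaign> %d closures (%d empty), %d trees, %d meteo records\n",
              nrow(x$meta), sum(x$meta$shoot_id == "EMPTY"),
              nrow(x$trees), nrow(x$meteo)))
  invisible(x)
}

#' Write a synthetic campaign to a directory of delimited text files
#'
#' Emits the raw-file dialect the processing pipeline reads: `analyzer.csv`
#' (timestamp, ch4_dry_ppm, co2_ppm, h2o_ppm, sample_temp_K), `closures.csv`
#' (closure metadata with nominal start/end times), `meteo.csv`,
#' `biomass.csv`, and `truth.json` holding the per-closure ground truth.
#'
#' @param campaign A [gen_campaign()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  stopifnot(inherits(campaign, "campaign"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

  ana <- do.call(rbind, lapply(seq_along(campaign$closures), function(i) {
    cl <- campaign$closures[[i]]
    data.frame(
      timestamp = fmt_time(cl$start_time + cl$records$t),
      ch4_dry_ppm = cl$records$ch4_dry_raw,
      co2_ppm = cl$records$co2,
      h2o_ppm = cl$records$h2o,
      sample_temp_K = cl$records$sample_temp
    )
  }))
  if (is.null(ana)) ana <- data.frame(timestamp = character(0),
                                      ch4_dry_ppm = numeric(0),
                                      co2_ppm = numeric(0),
                                      h2o_ppm = numeric(0),
                                      sample_temp_K = numeric(0))
  utils::write.csv(ana, file.path(dir, "analyzer.csv"), row.names = FALSE)

  meta <- campaign$meta
  meta$start_time <- fmt_time(meta$start_time)
  meta$end_time <- fmt_time(meta$end_time)
  utils::write.csv(meta, file.path(dir, "closures.csv"), row.names = FALSE)

  met <- campaign$meteo
  met$timestamp <- fmt_time(met$timestamp)
  utils::write.csv(met, file.path(dir, "meteo.csv"), row.names = FALSE)

  bio <- campaign$biomass
  names(bio) <- c("shoot_id", "species", "m_y1_g", "m_y0_final_g")
  utils::write.csv(bio, file.path(dir, "biomass.csv"), row.names = FALSE)

  truths <- lapply(campaign$closures, function(cl) {
    tr <- attr(cl, "truth")
    tr$meteo <- NULL
    tr
  })
  jsonlite::write_json(
    list(format_version = "1.0", truth_params = unclass(campaign$truth),
         closures = truths),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
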