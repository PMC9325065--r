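#' Construct a chamber-closure concentration time series
#'
#' A closure is the interval during which a chamber is sealed and its
#' headspace recirculates through the analyser; fluxes are inferred from the
#' concentration change during this interval. The container carries the raw
#' records, the trim window used for fitting, and the quality-control state.
#'
#' @param records data.frame with columns `t` (seconds since closure start,
#'   strictly increasing), `ch4_dry_raw` (ppm), `co2` (ppm), `h2o` (ppm),
#'   `sample_temp` (K). A `ch4_dry_corr` column may be added later by
#'   [correct_h2o()].
#' @param chamber_id Chamber identifier.
#' @param shoot_id Shoot identifier, or `NA` for an empty (control) chamber.
#' @param species Species label (e.g. `"pine"`, `"spruce"`), `NA` for empty.
#' @param start_time Optional POSIXct closure start (used to join meteorology).
#' @param trim Optional numeric length-2 half-open window `[t_start, t_end)`
#'   in seconds; `NULL` until set by [trim_closure()].
#' @param qc_status `"pending"`, `"pass"` or `"discard"`.
#' @param qc_reason Reason string when discarded.
#' @return An object of class `closure_series`.
#' @seealso [trim_closure()], [qc_closure()], [correct_h2o()]
#' @export
closure_series <- function(records, chamber_id = "ch1", shoot_id = NA_character_,
                           species = NA_character_, start_time = NULL,
                           trim = NULL, qc_status = "pending",
                           qc_reason = NA_character_) {
  req <- c("t", "ch4_dry_raw", "co2", "h2o", "sample_temp")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("closure records lack column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) >= 2L && any(diff(records$t) <= 0))
    stop("record times must be strictly increasing within a closure")
  conc <- c("ch4_dry_raw", "co2", "h2o")
  if (any(unlist(records[conc]) < 0, na.rm = TRUE))
    stop("mixing ratios must be non-negative")
  if (!is.null(trim)) trim <- check_trim(trim, records$t)
  structure(
    list(
      chamber_id = chamber_id,
      shoot_id = shoot_id,
      species = species,
      start_time = start_time,
      records = records,
      trim = trim,
      qc_status = qc_status,
      qc_reason = qc_reason
    ),
    class = "closure_series"
  )
}

check_trim <- function(trim, t) {
  if (!is.numeric(trim) || length(trim) != 2L || trim[1] >= trim[2])
    stop("trim must be numeric [t_start, t_end) with t_start < t_end")
  if (trim[1] < t[1] || trim[2] > t[length(t)] + 1e-9)
    # allow end = last time + one instant: window is half-open
    if (trim[2] > t[length(t)] + 1.0)
      stop("trim window must lie within the recorded span")
  trim
}

#' @export
print.closure_series <- function(x, ...) {
  who <- if (is_empty_closure(x)) "EMPTY" else
    sprintf("%s shoot %s", x$species, x$shoot_id)
  tr <- if (is.null(x$trim)) "untrimmed" else
    sprintf("trim [%g, %g) s", x$trim[1], x$trim[2])
  cat(sprintf("<closure_series> chamber %s (%s), %d records over %.0f s, %s, qc=%s\n",
              x$chamber_id, who, nrow(x$records),
              max(x$records$t) - min(x$records$t), tr, x$qc_status))
  invisible(x)
}

#' Is this closure an empty-chamber (control) measurement?
#' @param x A `closure_series`.
#' @return Logical.
#' @export
is_empty_closure <- function(x) {
  is.na(x$shoot_id) || identical(toupper(as.character(x$shoot_id)), "EMPTY")
}

#' Records inside the trim window
#'
#' Returns the record rows whose time falls in the half-open trim window
#' `[t_start, t_end)`; the full record table if no trim is set.
#'
#' @param x A `closure_series`.
#' @return data.frame of records.
#' @export
trimmed_records <- function(x) {
  r <- x$records
  if (is.null(x$trim)) return(r)
  r[r$t >= x$trim[1] & r$t < x$trim[2], , drop = FALSE]
}
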