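#' Physical specification of the shoot chamber and analyser loop
#'
#' Holds the geometry and physical constants needed to convert a fitted
#' concentration change (mol fraction per second) into a chamber-level flux.
#' Defaults describe a 5.2 l transparent shoot chamber whose volume includes
#' the closed analyser loop, at an assumed ambient pressure of 101325 Pa.
#'
#' @param volume_m3 Chamber volume including the circulation loop, m^3.
#' @param pressure_pa Air pressure inside the loop, Pa.
#' @return An object of class `chamber_spec` with fields `volume_m3`,
#'   `pressure_pa` and the constants `R` (J mol^-1 K^-1), `M_ch4`
#'   (ng mol^-1) and `M_co2` (mg mol^-1).
#' @examples
#' ch <- chamber_spec()
#' ch$volume_m3
#' @export
chamber_spec <- function(volume_m3 = 5.2e-3, pressure_pa = 101325) {
  if (!is.numeric(volume_m3) || length(volume_m3) != 1L || volume_m3 <= 0)
    stop("chamber volume must be a single positive number (m^3)")
  if (!is.numeric(pressure_pa) || length(pressure_pa) != 1L || pressure_pa <= 0)
    stop("chamber pressure must be a single positive number (Pa)")
  structure(
    list(
      volume_m3 = volume_m3,
      pressure_pa = pressure_pa,
      R = 8.31446,        # J mol^-1 K^-1
      M_ch4 = 1.604e10,   # ng mol^-1
      M_co2 = 4.401e4     # mg mol^-1
    ),
    class = "chamber_spec"
  )
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat(sprintf("<chamber_spec> V = %.4g m^3, p = %.0f Pa\n",
              x$volume_m3, x$pressure_pa))
  invisible(x)
}
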