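## Physical constants (CODATA). RT/F is always derived from temperature,
## never hard-coded, so simulated and inverted reversal potentials agree
## at any declared recording temperature.

.FARADAY <- 96485.33212     # C / mol
.GAS_R   <- 8.314462618     # J / (mol K)

#' Thermal voltage RT/F
#'
#' @param temperature absolute temperature, K (default 295 K, room
#'   temperature)
#' @return RT/F in mV
#' @examples
#' thermalVoltage(295)  # ~25.4 mV
#' @export
thermalVoltage <- function(temperature = 295) {
  stopifnot(is.finite(temperature), temperature > 0)
  1000 * .GAS_R * temperature / .FARADAY
}

## Debye-Hueckel "A" coefficient for the Davies equation, with the
## temperature dependence of the dielectric constant of water
## (Malmberg & Maryott polynomial). At 25 C this evaluates to ~0.509.
.daviesA <- function(temperature) {
  tc <- temperature - 273.15
  eps <- 87.74 - 0.40008 * tc + 9.398e-4 * tc^2 - 1.41e-6 * tc^3
  1.82483e6 * (eps * temperature)^-1.5
}
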