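#' Physical constants for gating and partitioning calculations
#'
#' Bundles the constants entering the Boltzmann gating and mole-fraction
#' partitioning equations. The thermal voltage \eqn{RT/F} is computed from
#' the temperature, never hard-coded; at the default room temperature
#' (295.15 K, ~22 degrees C) it is about 25.43 mV.
#'
#' @param temperature Absolute temperature in kelvin. Default 295.15 K.
#' @param water_molarity Molar concentration of water, in mol/L, used in the
#'   mole-fraction partition function. Default 55.3 M.
#'
#' @return A list of class `channel_constants` with elements `faraday`
#'   (C/mol), `gas_constant` (J/mol/K), `temperature` (K), `water_molarity`
#'   (M) and `thermal_voltage` (mV).
#' @examples
#' cc <- channel_constants()
#' cc$thermal_voltage # ~25.43 mV
#' @export
channel_constants <- function(temperature = 295.15, water_molarity = 55.3) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0,
            is.numeric(water_molarity), water_molarity > 0)
  faraday <- 96485.33212      # C mol^-1
  gas_constant <- 8.314462618 # J mol^-1 K^-1
  structure(
    list(
      faraday = faraday,
      gas_constant = gas_constant,
      temperature = temperature,
      water_molarity = water_molarity,
      # in mV: (J/C) * 1000
      thermal_voltage = 1000 * gas_constant * temperature / faraday
    ),
    class = "channel_constants"
  )
}

#' @export
print.channel_constants <- function(x, ...) {
  cat("<channel_constants>\n")
  cat(sprintf("  T = %.2f K, RT/F = %.4f mV, [W] = %.1f M\n",
              x$temperature, x$thermal_voltage, x$water_molarity))
  invisible(x)
}
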