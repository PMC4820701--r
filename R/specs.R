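#' Voltage-step protocol for an activation family
#'
#' Describes the stimulus used to elicit a family of currents: a holding
#' voltage, a series of strictly increasing test steps, and a fixed
#' repolarization ("tail") voltage after each step. Defaults follow common
#' two-electrode voltage-clamp practice for delayed-rectifier-like channels:
#' holding -100 mV, 500 ms test pulses, tail at -60 mV, 10 kHz sampling.
#'
#' @param holding Holding voltage, mV.
#' @param test_voltages Strictly increasing test-step voltages, mV.
#' @param step_duration Test step duration, ms.
#' @param tail_voltage Repolarization voltage after the step, mV.
#' @param tail_duration Tail duration, ms.
#' @param sample_interval Sampling interval, ms.
#'
#' @return A list of class `voltage_protocol`.
#' @export
voltage_protocol <- function(holding = -100,
                             test_voltages = seq(-80, 80, by = 10),
                             step_duration = 500,
                             tail_voltage = -60,
                             tail_duration = 100,
                             sample_interval = 0.1) {
  stopifnot(is.numeric(holding), length(holding) == 1L, is.finite(holding))
  if (length(test_voltages) < 1L || any(!is.finite(test_voltages)) ||
      is.unsorted(test_voltages, strictly = TRUE)) {
    rlang::abort("`test_voltages` must be strictly increasing and finite.",
                 class = "paddletox_bad_input")
  }
  if (any(c(step_duration, tail_duration, sample_interval) <= 0)) {
    rlang::abort("Durations and sample interval must be > 0.",
                 class = "paddletox_bad_input")
  }
  structure(
    list(holding = holding, test_voltages = as.numeric(test_voltages),
         step_duration = step_duration, tail_voltage = tail_voltage,
         tail_duration = tail_duration, sample_interval = sample_interval),
    class = "voltage_protocol"
  )
}

#' Channel gating specification for the simulator
#'
#' Equilibrium gating (Boltzmann `v_half`, `z`), a simple voltage-dependent
#' time constant, and the ohmic current scale. The kinetic law is a single
#' first-order gate relaxing toward its Boltzmann steady state with
#' \deqn{\tau(V) = \tau_{V_{1/2}}\,\mathrm{sech}\!\left(\frac{V - V_{1/2}}{w}\right),}
#' a smooth unimodal profile peaking at `v_half` (single-exponential
#' relaxations are what the analysis stage fits at each voltage).
#'
#' @param v_half Half-activation voltage, mV.
#' @param z Effective gating valence, elementary charges.
#' @param v_rev Reversal voltage, mV. Defaults to -90 (K+ mode) or +40
#'   (Ba2+ mode) when missing.
#' @param g_max Maximum conductance, uS (current comes out in nA).
#' @param tau_at_vhalf Gating time constant at `v_half`, ms.
#' @param tau_voltage_width Voltage width `w` of the tau profile, mV.
#' @param mode `"kv"` for tail-conducting K+ currents, `"cav"` for Ba2+
#'   currents whose peak within the step is measured.
#'
#' @return A list of class `channel_spec`.
#' @export
channel_spec <- function(v_half, z, v_rev = NULL, g_max = 0.02,
                         tau_at_vhalf = 10, tau_voltage_width = 30,
                         mode = c("kv", "cav")) {
  mode <- match.arg(mode)
  check_gating_params(v_half, z)
  if (is.null(v_rev)) v_rev <- if (mode == "kv") -90 else 40
  stopifnot(is.finite(v_rev), g_max > 0, tau_at_vhalf > 0,
            tau_voltage_width > 0)
  structure(
    list(v_half = v_half, z = z, v_rev = v_rev, g_max = g_max,
         tau_at_vhalf = tau_at_vhalf, tau_voltage_width = tau_voltage_width,
         mode = mode),
    class = "channel_spec"
  )
}

#' Toxin binding and gating-modification specification
#'
#' Occupancy truth for the independent-sites binding model plus the gating
#' phenotype of toxin-bound channels: their activation curve is shifted to
#' more positive voltages by `bound_vhalf_shift` and their kinetics slowed
#' by `bound_tau_factor`. The default +100 mV shift keeps bound channels
#' effectively closed over the weak-depolarization range where the fraction
#' unbound is read off, which is the regime the occupancy method assumes.
#'
#' @param kd Per-site dissociation constant, uM.
#' @param n_sites Number of equal and independent sites per channel.
#' @param concentration Applied toxin concentration, uM (>= 0).
#' @param bound_vhalf_shift Positive shift of the bound-channel activation
#'   midpoint, mV (>= 0). Default 100.
#' @param bound_tau_factor Slowing factor (>= 1) applied to the bound-channel
#'   gating time constant. Default 3.
#'
#' @return A list of class `toxin_spec`.
#' @export
toxin_spec <- function(kd, n_sites, concentration,
                       bound_vhalf_shift = 100, bound_tau_factor = 3) {
  check_occupancy_params(kd, n_sites)
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      !is.finite(concentration) || concentration < 0) {
    rlang::abort("`concentration` must be a single finite value >= 0.",
                 class = "paddletox_bad_input")
  }
  stopifnot(bound_vhalf_shift >= 0, bound_tau_factor >= 1)
  structure(
    list(kd = kd, n_sites = n_sites, concentration = concentration,
         bound_vhalf_shift = bound_vhalf_shift,
         bound_tau_factor = bound_tau_factor),
    class = "toxin_spec"
  )
}
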