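# Shared fixtures: published gating/binding parameter sets and a shortened
# protocol for fast unit tests (steady state still reached: step >= 20 tau).

kv21 <- list(v_half = -5.8, z = 2.6)
chim_dii <- list(v_half = 25.5, z = 2.9)
chim_diii <- list(v_half = -1.3, z = 2.6)
chim_div <- list(v_half = -87.1, z = 3.4)
diii_protx <- list(kd = 1.2, n = 4, conc = 1.33)
wt_cav_dose <- list(kd = 1.30, n = 2.11)
mut_cav_dose <- list(kd = 1.44, n = 1.45)
protx_part <- list(kx = 1.0e7, f_max = 1.65)
gsaf2_part <- list(kx = 9.8e5, f_max = 1.53)

fast_protocol <- function(test_voltages = seq(-80, 80, by = 10), ...) {
  voltage_protocol(test_voltages = test_voltages, step_duration = 120,
                   tail_duration = 40, sample_interval = 0.2, ...)
}

fast_channel <- function(v_half, z, ...) {
  channel_spec(v_half = v_half, z = z, tau_at_vhalf = 5, ...)
}

# closed-form activation curve on a voltage grid (kv form)
boltz_curve <- function(v, v_half, z) {
  tibble::tibble(voltage = v,
                 response = boltzmann_open_fraction(v, v_half, z))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
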