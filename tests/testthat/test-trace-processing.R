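test_that("linear leak is recovered and removed; purely ohmic input zeroes out", {
  # channel far from the subthreshold fit range, so only leak is seen there
  ch <- fast_channel(40, 2.6)
  pr <- fast_protocol()
  fam <- simulate_activation_family(ch, pr, leak_conductance = 0.002,
                                    noise_sd = 0)
  sub <- subtract_leak(fam, fit_voltages = c(-80, -70, -60))
  expect_equal(attr(sub, "leak_fit")$conductance, 0.002, tolerance = 1e-3)
  expect_false(attr(sub, "leak_warning"))
  # residual at fit voltages ~ 0
  resid <- sub$current[sub$voltage == -70 & sub$phase == "step"]
  expect_lt(max(abs(resid)), 1e-4)

  # an effectively channel-free family (gmax ~ 0) is pure leak everywhere
  ohmic <- simulate_activation_family(
    channel_spec(v_half = 40, z = 2.6, g_max = 1e-12),
    pr, leak_conductance = 0.003, noise_sd = 0)
  zeroed <- subtract_leak(ohmic, fit_voltages = c(-80, -70, -60))
  expect_lt(max(abs(zeroed$current)), 1e-9)
})

test_that("zero-leak input passes through unchanged and subtraction is idempotent", {
  ch <- fast_channel(40, 2.6) # closed over the subthreshold fit range
  fam <- simulate_activation_family(ch, fast_protocol(), leak_conductance = 0,
                                    noise_sd = 0)
  sub1 <- subtract_leak(fam, fit_voltages = c(-80, -70))
  expect_lt(max(abs(sub1$current - fam$current)), 5e-4)
  # idempotence with a real leak (channel closed over the fit range)
  fam2 <- simulate_activation_family(fast_channel(40, 2.6), fast_protocol(),
                                     leak_conductance = 0.002, noise_sd = 0)
  once <- subtract_leak(fam2, fit_voltages = c(-80, -70))
  twice <- subtract_leak(once, fit_voltages = c(-80, -70))
  expect_equal(twice$current, once$current, tolerance = 1e-6)
  expect_lt(abs(attr(twice, "leak_fit")$conductance), 1e-8)
})

test_that("fit voltages overlapping the activation range raise the warning flag", {
  ch <- fast_channel(-40, 2.6) # activates within the fit range
  fam <- simulate_activation_family(ch, fast_protocol(),
                                    leak_conductance = 0.001, noise_sd = 0)
  expect_warning(
    sub <- subtract_leak(fam, fit_voltages = c(-80, -60, -40, -20)),
    "activation range")
  expect_true(attr(sub, "leak_warning"))
})

test_that("noiseless Kv family yields the Boltzmann activation curve", {
  # tail voltage far below activation so the steady tail current is ~0 and
  # the relaxing amplitude is proportional to the open probability
  ch <- fast_channel(chim_dii$v_half, chim_dii$z)
  fam <- simulate_activation_family(ch, fast_protocol(), noise_sd = 0)
  curve <- extract_activation_curve(fam)
  expected <- boltzmann_open_fraction(curve$voltage, chim_dii$v_half,
                                      chim_dii$z)
  expected <- expected / max(expected)
  expect_lt(max(abs(curve$response - expected)), 1e-3)
})

test_that("noiseless Ba2+ family yields the normalized ohmic-Boltzmann I-V", {
  ch <- channel_spec(v_half = -41, z = 2, v_rev = 40, g_max = 0.02,
                     tau_at_vhalf = 5, mode = "cav")
  pr <- fast_protocol(test_voltages = seq(-70, 30, by = 10))
  fam <- simulate_activation_family(ch, pr, noise_sd = 0)
  curve <- extract_activation_curve(fam)
  expected <- ohmic_boltzmann_current(curve$voltage, -41, 2, 40, 0.02)
  expected <- expected / max(abs(expected))
  expect_lt(max(abs(curve$response - expected)), 1e-3)
})

test_that("activation-curve extraction is invariant to current scaling", {
  ch <- fast_channel(kv21$v_half, kv21$z)
  fam <- simulate_activation_family(ch, fast_protocol(), noise_sd = 0.01,
                                    seed = 2)
  scaled <- fam
  scaled$current <- scaled$current * 7.5
  c1 <- extract_activation_curve(fam)
  c2 <- extract_activation_curve(scaled)
  expect_equal(c2$response, c1$response, tolerance = 1e-6)
  expect_equal(c2$amplitude, 7.5 * c1$amplitude, tolerance = 1e-6)
})

test_that("single-voltage family normalizes to +/-1", {
  ch <- fast_channel(kv21$v_half, kv21$z)
  fam <- simulate_activation_family(ch, fast_protocol(test_voltages = 20),
                                    noise_sd = 0)
  curve <- extract_activation_curve(fam)
  expect_equal(nrow(curve), 1L)
  expect_equal(abs(curve$response), 1)
})

test_that("mono-exponential fit recovers tau exactly and flags degenerate input", {
  t <- seq(0, 100, by = 0.5)
  seg <- tibble::tibble(time = t, current = 3 * exp(-t / 10) + 0.2)
  fit <- fit_time_constant(seg)
  expect_equal(fit$tau, 10, tolerance = 1e-6)
  expect_equal(fit$amplitude, 3, tolerance = 1e-6)
  expect_equal(fit$baseline, 0.2, tolerance = 1e-6)
  expect_error(fit_time_constant(tibble::tibble(time = t, current = 0 * t)),
               class = "paddletox_degenerate")
  expect_error(fit_time_constant(seg[1:3, ]), class = "paddletox_bad_input")
})

test_that("activation time constants match the simulator's tau(V)", {
  ch <- fast_channel(kv21$v_half, kv21$z)
  pr <- fast_protocol(test_voltages = seq(-20, 40, by = 20))
  fam <- simulate_activation_family(ch, pr, noise_sd = 0)
  tt <- time_constant_table(fam, phase = "activation")
  tau_true <- ch$tau_at_vhalf /
    cosh((tt$voltage - ch$v_half) / ch$tau_voltage_width)
  expect_true(all(abs(tt$tau - tau_true) / tau_true < 0.05))
  expect_true(all(tt$phase == "activation"))
})
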