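make_ratio <- function(voltage, ratio) {
  structure(tibble::tibble(voltage = voltage, ratio = ratio,
                           dropped = FALSE),
            class = c("ratio_curve", class(tibble::tibble())))
}

test_that("ratio_curve divides raw amplitudes and polices the grid", {
  v <- seq(-60, 40, 10)
  ctrl <- tibble::tibble(voltage = v, amplitude = seq(0.5, 5.5, 0.5))
  same <- ratio_curve(ctrl, ctrl)
  expect_equal(same$ratio[!same$dropped], rep(1, sum(!same$dropped)))
  tox <- ctrl
  tox$amplitude <- 0.3 * ctrl$amplitude
  rc <- ratio_curve(tox, ctrl)
  expect_equal(rc$ratio[!rc$dropped], rep(0.3, sum(!rc$dropped)))
  # near-zero control amplitudes are flagged and excluded
  ctrl2 <- ctrl
  ctrl2$amplitude[1] <- 1e-6
  rc2 <- ratio_curve(tox, ctrl2)
  expect_true(rc2$dropped[1])
  expect_true(is.na(rc2$ratio[1]))
  # mismatched grids are an error
  expect_error(ratio_curve(tox[-1, ], ctrl), class = "paddletox_bad_input")
})

test_that("simulated DIII ratio plateau equals the closed-form Fu", {
  ch <- fast_channel(chim_diii$v_half, chim_diii$z)
  pr <- fast_protocol()
  tx <- toxin_spec(diii_protx$kd, diii_protx$n, diii_protx$conc)
  ctrl <- extract_activation_curve(simulate_activation_family(ch, pr, noise_sd = 0))
  tox <- extract_activation_curve(
    simulate_activation_family(ch, pr, toxin = tx, noise_sd = 0))
  rc <- ratio_curve(tox, ctrl, concentration = tx$concentration)
  fu_true <- unbound_probability(tx$kd, tx$n_sites, tx$concentration)
  kept <- rc[!rc$dropped & rc$voltage <= 0, ]
  expect_lt(max(abs(kept$ratio - fu_true)), 2e-3)
  occ <- estimate_fu(rc)
  expect_equal(occ$fu, fu_true, tolerance = 0.05)
  expect_equal(occ$mode, "plateau")
  # Kd recovered within 5% noiseless
  full <- kd_for_construct(occ, n_sites = 4, concentration = 1.33)
  expect_rel_equal(full$kd, diii_protx$kd, 0.05)
})

test_that("plateau detection: flat curves, windows and failure modes", {
  v <- seq(-60, 40, 10)
  flat <- make_ratio(v, rep(0.3, length(v)))
  occ <- estimate_fu(flat)
  expect_equal(occ$fu, 0.3)
  expect_equal(c(occ$window_lo, occ$window_hi), range(v))
  # plateau followed by a rising limb: only the flat run is averaged
  rising <- make_ratio(v, c(rep(0.226, 6), 0.3, 0.45, 0.7, 0.9, 1))
  occ2 <- estimate_fu(rising)
  expect_equal(occ2$fu, 0.226, tolerance = 1e-9)
  expect_lte(occ2$window_hi, -10)
  # strictly rising curve has no plateau
  steep <- make_ratio(v, seq(0.1, 1, length.out = length(v)))
  expect_error(estimate_fu(steep), class = "paddletox_no_plateau")
  # single-voltage mode reads one point
  occ3 <- estimate_fu(rising, mode = "voltage", at_voltage = -40)
  expect_equal(occ3$fu, 0.226)
  expect_equal(occ3$n_points, 1L)
})

test_that("estimate_fu is invariant to a common current scale", {
  ch <- fast_channel(chim_diii$v_half, chim_diii$z)
  pr <- fast_protocol()
  tx <- toxin_spec(2, 4, 1.33)
  fam_c <- simulate_activation_family(ch, pr, noise_sd = 0.002, seed = 4)
  fam_t <- simulate_activation_family(ch, pr, toxin = tx, noise_sd = 0.002,
                                      seed = 5)
  scale_fam <- function(f, k) { f$current <- f$current * k; f }
  fu1 <- estimate_fu(ratio_curve(extract_activation_curve(fam_t),
                                 extract_activation_curve(fam_c)))$fu
  fu2 <- estimate_fu(ratio_curve(extract_activation_curve(scale_fam(fam_t, 3)),
                                 extract_activation_curve(scale_fam(fam_c, 3))))$fu
  expect_equal(fu2, fu1, tolerance = 1e-6)
})

test_that("kd_for_construct completes and censors occupancy results", {
  r <- kd_for_construct(0.0506, n_sites = 4, concentration = 1.33)
  expect_equal(r$kd, 1.2, tolerance = 2e-3)
  expect_false(r$censored)
  r2 <- kd_for_construct(0.98, n_sites = 4, concentration = 1.33)
  expect_true(r2$censored)
  r3 <- kd_for_construct(1, n_sites = 4, concentration = 1.33)
  expect_true(r3$censored)
})

test_that("free stoichiometry fits recover published dose-response truths", {
  conc <- 10^seq(log10(0.1), log10(30), length.out = 8)
  for (truth in list(wt_cav_dose, mut_cav_dose)) {
    dt <- simulate_dose_response(truth$kd, truth$n, conc, noise_sd = 0)
    fit <- fit_stoichiometry(dt)
    g <- glance(fit)
    expect_rel_equal(g$kd, truth$kd, 0.01)
    expect_rel_equal(g$n_sites, truth$n, 0.01)
  }
})

test_that("constrained fits are nested in the free fit", {
  conc <- 10^seq(log10(0.1), log10(30), length.out = 8)
  # data generated with n = 2: n = 1 constraint leaves systematic residual
  dt <- simulate_dose_response(1.5, 2, conc, noise_sd = 0)
  fit <- fit_stoichiometry(dt)
  r1 <- fit$constrained$rss[fit$constrained$n == 1]
  expect_gt(r1, fit$rss_free)
  expect_true(all(fit$rss_free <= fit$constrained$rss + 1e-12))
  # also under noise
  dtn <- simulate_dose_response(1.5, 2, conc, noise_sd = 0.05, seed = 8)
  fitn <- fit_stoichiometry(dtn)
  expect_true(all(fitn$rss_free <= fitn$constrained$rss + 1e-12))
  expect_error(fit_stoichiometry(dt[1:2, ]), class = "paddletox_bad_input")
})

test_that("alanine-scan ratios match the closed-form occupancy oracle", {
  expect_equal(alanine_scan_ratio(0.4, 0.4), 1)
  # mutant vs parent chimaera at matched toxin dose, from the published Kd
  # pair (9.1 vs 1.2 uM, n = 4, 1.33 uM): oracle via unbound_probability
  fu_mut <- unbound_probability(9.1, 4, 1.33)
  fu_ctl <- unbound_probability(1.2, 4, 1.33)
  oracle <- ((9.1 / 10.43) / (1.2 / 2.53))^4
  expect_equal(alanine_scan_ratio(fu_mut, fu_ctl), oracle, tolerance = 1e-12)
  expect_equal(oracle, 11.449, tolerance = 1e-4)
  expect_gt(oracle, 1) # mutation weakens inhibition
  # a mutation that increases inhibition gives a ratio < 1
  fu_mut2 <- unbound_probability(6.4, 4, 1.33)
  fu_ctl2 <- unbound_probability(20, 4, 1.33)
  expect_lt(alanine_scan_ratio(fu_mut2, fu_ctl2), 1)
  expect_error(alanine_scan_ratio(0, 0.5), class = "paddletox_bad_input")
  expect_error(alanine_scan_ratio(0.5, 1.2), class = "paddletox_bad_input")
})

test_that("end-to-end Kd recovery is unbiased over noisy replicates", {
  ch <- fast_channel(chim_diii$v_half, chim_diii$z)
  pr <- fast_protocol()
  tx <- toxin_spec(diii_protx$kd, diii_protx$n, diii_protx$conc)
  kds <- withr::with_seed(31, vapply(1:20, function(i) {
    fam_c <- simulate_activation_family(ch, pr, leak_conductance = 0.001,
                                        noise_sd = NULL,
                                        seed = sample.int(1e6, 1))
    fam_t <- simulate_activation_family(ch, pr, toxin = tx,
                                        leak_conductance = 0.001,
                                        noise_sd = NULL,
                                        seed = sample.int(1e6, 1))
    cc <- extract_activation_curve(subtract_leak(fam_c))
    ct <- extract_activation_curve(subtract_leak(fam_t))
    occ <- estimate_fu(ratio_curve(ct, cc, concentration = tx$concentration))
    kd_for_construct(occ, n_sites = 4, concentration = tx$concentration)$kd
  }, numeric(1)))
  expect_lt(abs(mean(kds) - diii_protx$kd), 2 * stats::sd(kds) + 0.05 * diii_protx$kd)
})
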