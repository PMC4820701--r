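test_that("simulated families are reproducible given a seed", {
  ch <- fast_channel(kv21$v_half, kv21$z)
  pr <- fast_protocol()
  a <- simulate_activation_family(ch, pr, noise_sd = 0.05, seed = 123)
  b <- simulate_activation_family(ch, pr, noise_sd = 0.05, seed = 123)
  expect_identical(a$current, b$current)
  c <- simulate_activation_family(ch, pr, noise_sd = 0.05, seed = 124)
  expect_false(identical(a$current, c$current))
})

test_that("zero toxin concentration reproduces the control family exactly", {
  ch <- fast_channel(chim_diii$v_half, chim_diii$z)
  pr <- fast_protocol()
  ctrl <- simulate_activation_family(ch, pr, noise_sd = 0, seed = 1)
  tox0 <- simulate_activation_family(
    ch, pr, toxin = toxin_spec(kd = 1.2, n_sites = 4, concentration = 0),
    noise_sd = 0, seed = 1)
  expect_equal(tox0$current, ctrl$current, tolerance = 1e-12)
})

test_that("half occupancy at kd = concentration, n = 1 splits populations", {
  tx <- toxin_spec(kd = 2, n_sites = 1, concentration = 2)
  expect_equal(unbound_probability(tx$kd, tx$n_sites, tx$concentration), 0.5)
  # current at a saturating voltage for both populations is unchanged
  ch <- fast_channel(-10, 2.6)
  pr <- fast_protocol(test_voltages = c(-60, 200))
  ctrl <- simulate_activation_family(ch, pr, noise_sd = 0)
  tox <- simulate_activation_family(ch, pr, toxin = tx, noise_sd = 0)
  i_ctrl <- ctrl$current[ctrl$voltage == 200 & ctrl$phase == "step"]
  i_tox <- tox$current[tox$voltage == 200 & tox$phase == "step"]
  n <- length(i_ctrl)
  expect_equal(i_tox[n], i_ctrl[n], tolerance = 1e-4)
})

test_that("toxin/control tail ratio at weak depolarizations equals Fu", {
  # noiseless DIII-like condition: bound channels stay closed there, so the
  # ratio reduces to the closed-form unbound probability
  ch <- fast_channel(chim_diii$v_half, chim_diii$z)
  pr <- fast_protocol()
  tx <- toxin_spec(kd = diii_protx$kd, n_sites = diii_protx$n,
                   concentration = diii_protx$conc)
  ctrl <- simulate_activation_family(ch, pr, noise_sd = 0)
  tox <- simulate_activation_family(ch, pr, toxin = tx, noise_sd = 0)
  tail_amp <- function(fam, v) {
    seg <- fam[fam$voltage == v & fam$phase == "tail", ]
    head(seg$current, 1)
  }
  fu <- unbound_probability(tx$kd, tx$n_sites, tx$concentration)
  for (v in c(-30, -20, -10)) {
    expect_equal(tail_amp(tox, v) / tail_amp(ctrl, v), fu, tolerance = 1e-3)
  }
  expect_equal(fu, 0.0506, tolerance = 1e-3)
})

test_that("negative toxin concentration is rejected", {
  expect_error(toxin_spec(kd = 1, n_sites = 4, concentration = -1),
               class = "paddletox_bad_input")
})

test_that("dose-response generator matches the closed form and clips noise", {
  conc <- 10^seq(-1, 1.5, length.out = 8)
  exact <- simulate_dose_response(wt_cav_dose$kd, wt_cav_dose$n, conc,
                                  noise_sd = 0)
  expect_equal(exact$fu,
               unbound_probability(wt_cav_dose$kd, wt_cav_dose$n, conc),
               tolerance = 1e-12)
  # worked value at the screening concentration
  expect_equal(
    simulate_dose_response(1.30, 2.11, 1.33, noise_sd = 0)$fu,
    0.226107, tolerance = 1e-5)
  # very high concentration drives fu toward 0
  expect_lt(simulate_dose_response(1.30, 2.11, 1e5, noise_sd = 0)$fu, 1e-6)
  # noisy draws stay in (0, 1] and are seed-reproducible
  noisy1 <- simulate_dose_response(1.3, 2.11, conc, noise_sd = 0.3, seed = 5)
  noisy2 <- simulate_dose_response(1.3, 2.11, conc, noise_sd = 0.3, seed = 5)
  expect_identical(noisy1$fu, noisy2$fu)
  expect_true(all(noisy1$fu > 0 & noisy1$fu <= 1))
  # noise averages out: mean of many replicates approaches the model
  withr::with_seed(9, {
    reps <- replicate(400, simulate_dose_response(1.3, 2.11, 1.33,
                                                  noise_sd = 0.05)$fu)
  })
  expect_equal(mean(reps), 0.226107, tolerance = 0.01)
})

test_that("emission spectra obey the partition function at 320 nm", {
  totals <- c(0, 10^seq(-7, -4, length.out = 8))
  sp <- simulate_emission_spectra(protx_part$kx, protx_part$f_max, totals)
  at320 <- sp[sp$wavelength == 320, ]
  f0 <- at320$intensity[at320$lipid_total == 0]
  cc <- channel_constants()
  for (i in seq_along(totals)) {
    ft <- at320$intensity[at320$lipid_total == totals[i]]
    expect_equal(ft / f0,
                 partition_f_ratio(0.6 * totals[i], protx_part$kx,
                                   protx_part$f_max, cc),
                 tolerance = 1e-9)
  }
  # midpoint worked example: available lipid [W]/Kx -> halfway to f_max
  mid_total <- (cc$water_molarity / protx_part$kx) / 0.6
  spm <- simulate_emission_spectra(protx_part$kx, protx_part$f_max,
                                   c(0, mid_total))
  a <- spm[spm$wavelength == 320, ]
  expect_equal(a$intensity[a$lipid_total > 0] / a$intensity[a$lipid_total == 0],
               1.325, tolerance = 1e-9)
})

test_that("spectral peaks sit at 355 nm free and 347 nm lipid-saturated", {
  sp <- simulate_emission_spectra(1e7, 1.65, c(0, 1.5e-3))
  free <- sp[sp$lipid_total == 0, ]
  sat <- sp[sp$lipid_total == 1.5e-3, ]
  expect_equal(free$wavelength[which.max(free$intensity)], 355)
  expect_equal(sat$wavelength[which.max(sat$intensity)], 347)
  expect_true(all(sp$intensity >= 0))
  expect_error(simulate_emission_spectra(1e7, 1.65, c(1e-5)),
               class = "paddletox_bad_input")
})

test_that("trace and spectrum sets survive a CSV round trip", {
  dir <- withr::local_tempdir()
  ch <- fast_channel(kv21$v_half, kv21$z)
  fam <- simulate_activation_family(ch, fast_protocol(c(-40, 0, 40)),
                                    toxin = toxin_spec(1.2, 4, 1.33),
                                    noise_sd = 0.02, seed = 3)
  p <- file.path(dir, "fam.csv")
  write_trace_set(fam, p)
  back <- read_trace_set(p)
  expect_equal(back$current, fam$current, tolerance = 1e-12)
  expect_equal(attr(back, "channel")$v_half, ch$v_half)
  expect_equal(attr(back, "toxin")$kd, 1.2)

  sp <- simulate_emission_spectra(1e6, 1.4, c(0, 1e-5))
  ps <- file.path(dir, "sp.csv")
  write_spectrum_set(sp, ps)
  back_sp <- read_spectrum_set(ps)
  expect_equal(back_sp$intensity, sp$intensity, tolerance = 1e-12)
  expect_equal(attr(back_sp, "kx"), 1e6)
})
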