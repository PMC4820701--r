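#' Boltzmann open fraction of a voltage-gated channel
#'
#' Two-state Boltzmann voltage dependence of activation,
#' \deqn{I/I_{max} = \left[1 + e^{-zF(V - V_{1/2})/RT}\right]^{-1},}
#' the form used to fit normalized tail-current activation curves of
#' K+-conducting channels. Strictly increasing in `v` and exactly 0.5 at
#' `v = v_half`.
#'
#' @param v Membrane voltage(s), mV. Must be finite.
#' @param v_half Half-activation voltage, mV.
#' @param z Effective gating valence, elementary charges (> 0).
#' @param constants A [channel_constants()] list.
#'
#' @return Open fraction(s) in (0, 1), same length as `v`.
#' @examples
#' boltzmann_open_fraction(-5.8, v_half = -5.8, z = 2.6) # 0.5
#' @family gating models
#' @export
boltzmann_open_fraction <- function(v, v_half, z, constants = channel_constants()) {
  check_gating_params(v_half, z)
  if (!all(is.finite(v))) {
    rlang::abort("`v` must be finite.", class = "paddletox_bad_input")
  }
  stats::plogis(z * (v - v_half) / constants$thermal_voltage)
}

#' Ohmic-driving-force Boltzmann current
#'
#' Current-voltage relationship for channels whose peak current is measured
#' directly (Ba2+ currents through Cav channels),
#' \deqn{I/I_{max} = \frac{(V - V_{rev})\,G_{max}}{1 + e^{-zF(V - V_{1/2})/RT}}.}
#' Zero at the reversal voltage, with sign following the driving force.
#'
#' @inheritParams boltzmann_open_fraction
#' @param v_rev Reversal voltage, mV.
#' @param g_max Maximum conductance, normalized-current units per mV (> 0).
#'
#' @return Normalized current(s), same length as `v`.
#' @examples
#' ohmic_boltzmann_current(-41, v_half = -41, z = 2, v_rev = 40, g_max = 0.02)
#' @family gating models
#' @export
ohmic_boltzmann_current <- function(v, v_half, z, v_rev, g_max,
                                    constants = channel_constants()) {
  stopifnot(is.numeric(v_rev), is.finite(v_rev), is.numeric(g_max), g_max > 0)
  (v - v_rev) * g_max * boltzmann_open_fraction(v, v_half, z, constants)
}

#' Probability that a channel carries no bound toxin
#'
#' Under `n_sites` equal and independent toxin-binding sites per channel,
#' each with per-site dissociation constant `kd`, the fraction of channels
#' with zero bound toxins is
#' \deqn{F_u = \left(\frac{K_d}{K_d + [T]}\right)^n.}
#' Equals 1 at zero toxin and decreases strictly with concentration.
#' [kd_from_fu()] is its exact algebraic inverse.
#'
#' @param kd Per-site dissociation constant, uM (> 0).
#' @param n_sites Number of equal and independent sites per channel;
#'   a positive real (non-integer values arise from free fits).
#' @param concentration Toxin concentration(s), uM (>= 0).
#'
#' @return Unbound fraction(s) in (0, 1].
#' @examples
#' unbound_probability(1.2, 4, 1.33) # ~0.0506
#' @family occupancy models
#' @export
unbound_probability <- function(kd, n_sites, concentration) {
  check_occupancy_params(kd, n_sites)
  if (!all(is.finite(concentration) & concentration >= 0)) {
    rlang::abort("`concentration` must be finite and >= 0.",
                 class = "paddletox_bad_input")
  }
  (kd / (kd + concentration))^n_sites
}

#' Apparent per-site Kd from an unbound fraction
#'
#' Inverts the independent-sites occupancy model:
#' \deqn{K_d = \left(\frac{1}{1 - F_u^{1/n}} - 1\right)[T].}
#' A fraction unbound at (or within tolerance of) 1 means no detectable
#' binding and yields a censored result; values above `censor_limit` are
#' likewise censored, mirroring summary tables that print ">50".
#'
#' @param fu Fraction(s) of unbound channels, in (0, 1].
#' @param n_sites Number of equal and independent sites per channel (> 0).
#' @param concentration Toxin concentration, uM (> 0).
#' @param censor_limit Kd reporting limit in uM; estimates above it are
#'   flagged as censored. Default 50.
#' @param tol `fu >= 1 - tol` is treated as "no binding" (Kd infinite).
#'
#' @return A tibble with columns `fu`, `n_sites`, `concentration`, `kd`
#'   (uM; `Inf` when no binding is detectable) and `censored` (logical).
#' @examples
#' kd_from_fu(0.25, n_sites = 1, concentration = 1) # kd = 1/3 uM
#' @family occupancy models
#' @export
kd_from_fu <- function(fu, n_sites, concentration, censor_limit = 50,
                       tol = 1e-9) {
  check_occupancy_params(1, n_sites)
  if (!all(is.finite(concentration) & concentration > 0)) {
    rlang::abort("`concentration` must be finite and > 0.",
                 class = "paddletox_bad_input")
  }
  if (!all(is.finite(fu)) || any(fu <= 0) || any(fu > 1 + tol)) {
    rlang::abort("`fu` must lie in (0, 1].", class = "paddletox_bad_input")
  }
  saturated <- fu >= 1 - tol
  kd <- ifelse(saturated, Inf,
               (1 / (1 - pmin(fu, 1)^(1 / n_sites)) - 1) * concentration)
  tibble::tibble(
    fu = fu,
    n_sites = n_sites,
    concentration = concentration,
    kd = kd,
    censored = !is.finite(kd) | kd > censor_limit,
    censor_limit = censor_limit
  )
}

#' Mole-fraction partition function for fluorescence titrations
#'
#' Relative tryptophan fluorescence at the read wavelength as a function of
#' available lipid concentration,
#' \deqn{F/F_0([L]) = 1 + (F/F_0^{max} - 1)\frac{K_x [L]}{[W] + K_x [L]},}
#' where `[W]` is the molar concentration of water. Equals 1 at zero lipid,
#' rises monotonically to `f_max`, and reaches the half-effect at
#' `lipid_avail = [W] / kx`.
#'
#' @param lipid_avail Available lipid concentration(s), mol/L (>= 0).
#' @param kx Dimensionless mole-fraction partition coefficient (> 0).
#' @param f_max Fluorescence ratio at saturating lipid (>= 1).
#' @inheritParams boltzmann_open_fraction
#'
#' @return F/F0 ratio(s) in `[1, f_max]`.
#' @examples
#' partition_f_ratio(5.53e-6, kx = 1e7, f_max = 1.65) # midpoint: 1.325
#' @family partitioning models
#' @export
partition_f_ratio <- function(lipid_avail, kx, f_max,
                              constants = channel_constants()) {
  check_partition_params(kx, f_max)
  if (!all(is.finite(lipid_avail) & lipid_avail >= 0)) {
    rlang::abort("`lipid_avail` must be finite and >= 0.",
                 class = "paddletox_bad_input")
  }
  w <- constants$water_molarity
  1 + (f_max - 1) * kx * lipid_avail / (w + kx * lipid_avail)
}

# -- shared validators ------------------------------------------------------

check_gating_params <- function(v_half, z) {
  if (!is.numeric(v_half) || !all(is.finite(v_half))) {
    rlang::abort("`v_half` must be finite.", class = "paddletox_bad_input")
  }
  if (!is.numeric(z) || !all(is.finite(z) & z > 0)) {
    rlang::abort("`z` must be finite and > 0.", class = "paddletox_bad_input")
  }
  invisible(TRUE)
}

check_occupancy_params <- function(kd, n_sites) {
  if (!is.numeric(kd) || !all(is.finite(kd) & kd > 0)) {
    rlang::abort("`kd` must be finite and > 0.", class = "paddletox_bad_input")
  }
  if (!is.numeric(n_sites) || !all(is.finite(n_sites) & n_sites > 0)) {
    rlang::abort("`n_sites` must be finite and > 0.",
                 class = "paddletox_bad_input")
  }
  invisible(TRUE)
}

check_partition_params <- function(kx, f_max) {
  if (!is.numeric(kx) || !all(is.finite(kx) & kx > 0)) {
    rlang::abort("`kx` must be finite and > 0.", class = "paddletox_bad_input")
  }
  if (!is.numeric(f_max) || !all(is.finite(f_max) & f_max >= 1)) {
    rlang::abort("`f_max` must be finite and >= 1.",
                 class = "paddletox_bad_input")
  }
  invisible(TRUE)
}
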