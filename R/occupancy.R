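#' Ratio of currents recorded with and without toxin
#'
#' Pointwise `I / I0` between matching activation curves recorded in the
#' presence (`I`) and absence (`I0`) of toxin, computed on raw
#' (un-normalized) amplitudes. Voltages where the control amplitude is
#' essentially zero (below `drop_tol` of the largest control amplitude) are
#' kept in the table but flagged `dropped` with `ratio = NA`, since the
#' quotient there is dominated by noise.
#'
#' @param toxin_curve,control_curve Activation-curve tibbles with `voltage`
#'   and `amplitude` columns on identical voltage grids.
#' @param concentration Toxin concentration, uM (recorded as an attribute
#'   and used downstream for Kd).
#' @param drop_tol Relative control-amplitude threshold below which a point
#'   is dropped. Default 0.02.
#'
#' @return A tibble of class `ratio_curve` with `voltage`, `ratio`,
#'   `dropped`; the concentration is attached as an attribute.
#' @export
ratio_curve <- function(toxin_curve, control_curve, concentration = NULL,
                        drop_tol = 0.02) {
  tc <- dplyr::arrange(tibble::as_tibble(toxin_curve), .data$voltage)
  cc <- dplyr::arrange(tibble::as_tibble(control_curve), .data$voltage)
  if (nrow(tc) != nrow(cc) || !all(tc$voltage == cc$voltage)) {
    rlang::abort("Toxin and control curves must share an identical voltage grid.",
                 class = "paddletox_bad_input")
  }
  dropped <- abs(cc$amplitude) < drop_tol * max(abs(cc$amplitude))
  out <- tibble::tibble(
    voltage = tc$voltage,
    ratio = ifelse(dropped, NA_real_, tc$amplitude / cc$amplitude),
    dropped = dropped
  )
  structure(out, class = c("ratio_curve", class(tibble::tibble())),
            concentration = concentration)
}

#' Fraction of unbound channels from the plateau of a ratio curve
#'
#' At depolarizations too weak to open toxin-bound channels the current
#' ratio `I / I0` is voltage-independent and equals the fraction of
#' channels with no bound toxin. The plateau is located as the longest
#' contiguous run (at least `min_run` points) of consecutive retained
#' points whose local slope `|d(ratio)/dV|` stays below `slope_tol`; ties
#' go to the run at the more negative voltages (the weak-depolarization
#' side). `fu` is the mean ratio over the run. A curve with no qualifying
#' run errors ("no plateau") -- in the source experiments the voltage
#' protocol is adjusted until a well-defined plateau exists.
#'
#' A single-voltage alternative (`mode = "voltage"`) reads `fu` at one
#' stated voltage instead of averaging a plateau.
#'
#' @param rc A [ratio_curve()] tibble.
#' @param slope_tol Maximum |slope| within the plateau, per mV. Default 0.002.
#' @param min_run Minimum number of points in the plateau. Default 3.
#' @param mode `"plateau"` (default) or `"voltage"`.
#' @param at_voltage Voltage (mV) at which to read `fu` in `"voltage"` mode.
#' @param v_max Optional upper voltage bound restricting the plateau search
#'   to weak depolarizations.
#'
#' @return A one-row tibble with `fu`, `window_lo`, `window_hi` (mV),
#'   `n_points` and `mode`.
#' @export
estimate_fu <- function(rc, slope_tol = 0.002, min_run = 3,
                        mode = c("plateau", "voltage"), at_voltage = NULL,
                        v_max = NULL) {
  mode <- match.arg(mode)
  df <- tibble::as_tibble(rc)
  df <- df[!df$dropped & is.finite(df$ratio), ]
  if (!is.null(v_max)) df <- df[df$voltage <= v_max, ]
  if (mode == "voltage") {
    if (is.null(at_voltage)) {
      rlang::abort("`at_voltage` is required in voltage mode.",
                   class = "paddletox_bad_input")
    }
    i <- which.min(abs(df$voltage - at_voltage))
    return(tibble::tibble(fu = df$ratio[i], window_lo = df$voltage[i],
                          window_hi = df$voltage[i], n_points = 1L,
                          mode = "voltage"))
  }
  if (nrow(df) < min_run + 1L) {
    rlang::abort("Too few usable points for plateau detection.",
                 class = "paddletox_bad_input")
  }
  slopes <- abs(diff(df$ratio) / diff(df$voltage))
  ok <- slopes < slope_tol
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values & runs$lengths >= (min_run - 1L))
  if (length(cand) == 0) {
    rlang::abort("No plateau: no flat run in the I/I0-voltage relationship.",
                 class = "paddletox_no_plateau")
  }
  best <- cand[which.max(runs$lengths[cand])] # ties: which.max takes first,
  # i.e. the lowest-voltage run
  idx <- starts[best]:(ends[best] + 1L)       # k flat gaps span k+1 points
  tibble::tibble(
    fu = mean(df$ratio[idx]),
    window_lo = min(df$voltage[idx]),
    window_hi = max(df$voltage[idx]),
    n_points = length(idx),
    mode = "plateau"
  )
}

#' Complete an occupancy estimate with the apparent Kd
#'
#' Applies [kd_from_fu()] to a plateau (or single-voltage) `fu` estimate,
#' using a fixed site count (`n = 4` for homotetrameric K+-conducting
#' constructs) and censoring estimates beyond the reporting limit.
#'
#' @param occ A one-row tibble from [estimate_fu()], or a bare `fu` value.
#' @param n_sites Site count used in the inversion.
#' @param concentration Toxin concentration, uM.
#' @param censor_limit Censoring limit, uM. Default 50.
#'
#' @return The input row augmented with `n_sites`, `concentration`, `kd`
#'   and `censored`.
#' @export
kd_for_construct <- function(occ, n_sites, concentration, censor_limit = 50) {
  if (is.numeric(occ)) occ <- tibble::tibble(fu = occ)
  kd <- kd_from_fu(occ$fu, n_sites, concentration,
                   censor_limit = censor_limit)
  dplyr::bind_cols(occ,
                   kd[, c("n_sites", "concentration", "kd", "censored")])
}

#' Alanine-scan sensitivity ratio
#'
#' Ratio of the uninhibited fraction of a mutant to its parent construct at
#' matched toxin concentration. Values above 1 indicate weaker inhibition
#' of the mutant (toxin-binding residue); below 1, stronger inhibition.
#'
#' @param fu_mut,fu_control Unbound fractions in (0, 1].
#' @return `fu_mut / fu_control`, vectorized.
#' @export
alanine_scan_ratio <- function(fu_mut, fu_control) {
  if (!all(is.finite(fu_mut) & fu_mut > 0 & fu_mut <= 1) ||
      !all(is.finite(fu_control) & fu_control > 0 & fu_control <= 1)) {
    rlang::abort("Unbound fractions must lie in (0, 1].",
                 class = "paddletox_bad_input")
  }
  fu_mut / fu_control
}
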