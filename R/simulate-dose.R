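#' Simulate a dose-response table of unbound fractions
#'
#' Generates observed fractions of uninhibited current at a series of toxin
#' concentrations from the independent-sites occupancy model, with optional
#' multiplicative Gaussian noise (fractional, emulating cell-to-cell scatter
#' in plateau estimates). Observations are clipped to (0, 1].
#'
#' @param kd True per-site dissociation constant, uM.
#' @param n_sites True number of equal and independent sites per channel.
#' @param concentrations Toxin concentrations, uM (> 0).
#' @param noise_sd Fractional noise standard deviation (e.g. `0.01` for 1%).
#'   `0` gives the exact model curve.
#' @param seed Integer seed for reproducible noise.
#'
#' @return A tibble with columns `concentration` (uM) and `fu`.
#' @examples
#' simulate_dose_response(1.30, 2.11, c(0.3, 1, 3, 10), noise_sd = 0)
#' @export
simulate_dose_response <- function(kd, n_sites, concentrations,
                                   noise_sd = 0.01, seed = NULL) {
  if (!all(is.finite(concentrations) & concentrations > 0)) {
    rlang::abort("`concentrations` must be finite and > 0.",
                 class = "paddletox_bad_input")
  }
  fu <- unbound_probability(kd, n_sites, concentrations)
  if (noise_sd > 0) {
    jitter <- function() fu * (1 + stats::rnorm(length(fu), sd = noise_sd))
    fu <- if (is.null(seed)) jitter() else withr::with_seed(seed, jitter())
    fu <- pmin(1, pmax(.Machine$double.eps, fu))
  }
  tibble::tibble(concentration = as.numeric(concentrations), fu = fu)
}
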