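#' Simulate tryptophan emission spectra over a lipid titration
#'
#' Each spectrum is a weighted sum of two log-normal emission bands: a free
#' (aqueous) band peaking at `free_peak` (~355 nm) and a membrane-inserted
#' band blue-shifted by `bound_peak_shift` (~8 nm). The weight of the bound
#' band is the partitioned fraction
#' `f_b = kx * [L] / ([W] + kx * [L])` with available lipid
#' `[L] = avail_fraction * total`, and the bound-band amplitude is chosen so
#' that the intensity ratio at 320 nm reproduces [partition_f_ratio()]
#' exactly at every lipid concentration. At saturating lipid the spectral
#' argmax sits at `free_peak - bound_peak_shift`.
#'
#' Optionally, toxin-free vesicle blanks (a smooth scattering background
#' proportional to total lipid) are emitted alongside, and the same
#' background is added to the toxin spectra, so a blank-subtraction stage
#' can be exercised.
#'
#' @param kx True mole-fraction partition coefficient.
#' @param f_max True F/F0 ratio at saturating lipid.
#' @param lipid_totals Total lipid concentrations, mol/L; must include 0
#'   (the aqueous reference).
#' @param wavelengths Emission wavelength grid, nm; must cover 320 nm and
#'   both band peaks. Default 300-400 nm in 1 nm steps.
#' @param noise_sd Fractional noise sd relative to `base_intensity`;
#'   `0` (default) gives noiseless spectra.
#' @param seed Integer seed for reproducible noise.
#' @param free_peak Aqueous band peak, nm. Default 355.
#' @param bound_peak_shift Blue shift of the inserted band, nm. Default 8.
#' @param band_fwhm Full width at half maximum of each band, nm. Default 60.
#' @param base_intensity Amplitude scale, arbitrary units. Default 1000.
#' @param avail_fraction Fraction of total lipid available to the toxin
#'   (outer leaflet plus accessible surface). Default 0.6.
#' @param include_blanks Emit matching toxin-free blank spectra and add the
#'   same scattering background to the toxin spectra. Default `FALSE`.
#' @param scatter_coef Blank scattering amplitude per mM total lipid,
#'   relative to `base_intensity`. Default 0.03.
#' @param constants A [channel_constants()] list (supplies `[W]`).
#'
#' @return A tibble of class `spectrum_set` with columns `lipid_total` (M),
#'   `wavelength` (nm), `intensity` (a.u.) and `is_blank`. Generator truth
#'   is attached as attributes.
#' @examples
#' sp <- simulate_emission_spectra(1e7, 1.65, c(0, 1.5e-3))
#' @export
simulate_emission_spectra <- function(kx, f_max, lipid_totals,
                                      wavelengths = seq(300, 400, by = 1),
                                      noise_sd = 0, seed = NULL,
                                      free_peak = 355, bound_peak_shift = 8,
                                      band_fwhm = 60, base_intensity = 1000,
                                      avail_fraction = 0.6,
                                      include_blanks = FALSE,
                                      scatter_coef = 0.03,
                                      constants = channel_constants()) {
  check_partition_params(kx, f_max)
  if (!all(is.finite(lipid_totals) & lipid_totals >= 0)) {
    rlang::abort("`lipid_totals` must be finite and >= 0.",
                 class = "paddletox_bad_input")
  }
  if (!any(lipid_totals == 0)) {
    rlang::abort("`lipid_totals` must include 0 (aqueous reference).",
                 class = "paddletox_bad_input")
  }
  bound_peak <- free_peak - bound_peak_shift
  if (min(wavelengths) > min(320, bound_peak) ||
      max(wavelengths) < max(320, free_peak)) {
    rlang::abort("`wavelengths` must cover 320 nm and both band peaks.",
                 class = "paddletox_bad_input")
  }

  band <- function(lambda, peak) {
    # log-normal in wavelength; sigma set so the FWHM equals band_fwhm
    a <- asinh(band_fwhm / (2 * peak))
    sigma <- a / sqrt(2 * log(2))
    exp(-log(lambda / peak)^2 / (2 * sigma^2))
  }
  # bound-band amplitude making F(320, L)/F(320, 0) = partition_f_ratio([L])
  c_bound <- f_max * band(320, free_peak) / band(320, bound_peak)

  w <- constants$water_molarity
  one_level <- function(total) {
    l_avail <- avail_fraction * total
    f_b <- kx * l_avail / (w + kx * l_avail)
    signal <- base_intensity *
      ((1 - f_b) * band(wavelengths, free_peak) +
         f_b * c_bound * band(wavelengths, bound_peak))
    scatter <- if (include_blanks) {
      base_intensity * scatter_coef * (total / 1e-3) * (320 / wavelengths)^4
    } else {
      rep(0, length(wavelengths))
    }
    out <- tibble::tibble(
      lipid_total = total, wavelength = as.numeric(wavelengths),
      intensity = signal + scatter, is_blank = FALSE
    )
    if (include_blanks) {
      out <- dplyr::bind_rows(
        out,
        tibble::tibble(lipid_total = total,
                       wavelength = as.numeric(wavelengths),
                       intensity = scatter, is_blank = TRUE)
      )
    }
    out
  }

  spectra <- purrr::map(sort(unique(lipid_totals)), one_level) |>
    purrr::list_rbind()

  if (noise_sd > 0) {
    jitter <- function() {
      spectra$intensity +
        stats::rnorm(nrow(spectra), sd = noise_sd * base_intensity)
    }
    spectra$intensity <- if (is.null(seed)) jitter() else {
      withr::with_seed(seed, jitter())
    }
    spectra$intensity <- pmax(spectra$intensity, 0)
  }

  structure(
    spectra,
    class = c("spectrum_set", class(tibble::tibble())),
    kx = kx, f_max = f_max, free_peak = free_peak,
    bound_peak_shift = bound_peak_shift, band_fwhm = band_fwhm,
    avail_fraction = avail_fraction, noise_sd = noise_sd, seed = seed,
    water_molarity = w
  )
}
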