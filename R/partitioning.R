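#' Blue shift between aqueous and lipid-exposed emission spectra
#'
#' Locates the emission peak of each spectrum by argmax after moving-average
#' smoothing and reports `peak_free - peak_lipid` (positive = blue shift,
#' the signature of tryptophans moving into a lipid environment). A peak
#' found at a grid boundary is flagged.
#'
#' @param free_spectrum,lipid_spectrum Data frames with `wavelength` (nm)
#'   and `intensity` columns.
#' @param smoothing_window Moving-average window, nm. Default 3.
#'
#' @return A one-row tibble with `peak_free`, `peak_lipid`, `shift` (nm)
#'   and `flagged`.
#' @export
spectral_shift <- function(free_spectrum, lipid_spectrum,
                           smoothing_window = 3) {
  locate <- function(sp) {
    sp <- dplyr::arrange(tibble::as_tibble(sp), .data$wavelength)
    step <- stats::median(diff(sp$wavelength))
    k <- max(1L, round(smoothing_window / step))
    if (k %% 2L == 0L) k <- k + 1L
    sm <- as.numeric(stats::filter(sp$intensity, rep(1 / k, k)))
    usable <- which(!is.na(sm))
    i <- usable[which.max(sm[usable])]
    list(peak = sp$wavelength[i],
         at_edge = i <= min(usable) || i >= max(usable))
  }
  f <- locate(free_spectrum)
  l <- locate(lipid_spectrum)
  tibble::tibble(peak_free = f$peak, peak_lipid = l$peak,
                 shift = f$peak - l$peak,
                 flagged = f$at_edge || l$at_edge)
}

#' Build an F/F0 titration curve from an emission spectrum set
#'
#' Reads the fluorescence intensity at `read_wavelength` for each lipid
#' concentration, normalizes to the zero-lipid intensity (`F0`), and maps
#' total lipid to available lipid (`avail_fraction` of total: only the
#' accessible leaflets count). If the set contains vesicle blanks
#' (`is_blank` column), each blank spectrum is subtracted from its matching
#' toxin spectrum first (scattering correction).
#'
#' @param spectra A data frame with `lipid_total` (M), `wavelength` (nm),
#'   `intensity` and optionally `is_blank`, e.g. from
#'   [simulate_emission_spectra()].
#' @param read_wavelength Read wavelength, nm. Default 320.
#' @param avail_fraction Available fraction of total lipid. Default 0.6.
#'
#' @return A tibble of class `partition_curve` with `lipid_total`,
#'   `lipid_avail` (M) and `f_ratio`.
#' @export
build_partition_curve <- function(spectra, read_wavelength = 320,
                                  avail_fraction = 0.6) {
  df <- tibble::as_tibble(spectra)
  if ("is_blank" %in% names(df) && any(df$is_blank)) {
    blanks <- df[df$is_blank, c("lipid_total", "wavelength", "intensity")]
    names(blanks)[3] <- "blank_intensity"
    df <- df[!df$is_blank, ] |>
      dplyr::left_join(blanks, by = c("lipid_total", "wavelength")) |>
      dplyr::mutate(intensity = .data$intensity -
                      dplyr::coalesce(.data$blank_intensity, 0)) |>
      dplyr::select(-"blank_intensity")
  }
  wl <- sort(unique(df$wavelength))
  step <- if (length(wl) > 1) stats::median(diff(wl)) else Inf
  i <- which.min(abs(wl - read_wavelength))
  if (abs(wl[i] - read_wavelength) > step / 2 + 1e-9) {
    rlang::abort("`read_wavelength` is not covered by the wavelength grid.",
                 class = "paddletox_bad_input")
  }
  at_read <- df[df$wavelength == wl[i], ] |>
    dplyr::group_by(.data$lipid_total) |>
    dplyr::summarise(f = mean(.data$intensity), .groups = "drop") |>
    dplyr::arrange(.data$lipid_total)
  if (!any(at_read$lipid_total == 0)) {
    rlang::abort("Zero-lipid reference spectrum is missing.",
                 class = "paddletox_bad_input")
  }
  f0 <- at_read$f[at_read$lipid_total == 0]
  out <- tibble::tibble(
    lipid_total = at_read$lipid_total,
    lipid_avail = avail_fraction * at_read$lipid_total,
    f_ratio = at_read$f / f0
  )
  structure(out, class = c("partition_curve", class(tibble::tibble())),
            read_wavelength = wl[i], avail_fraction = avail_fraction)
}

#' Fit the mole-fraction partition coefficient to an F/F0 curve
#'
#' Least-squares fit of [partition_f_ratio()] to an `(lipid_avail, f_ratio)`
#' titration, estimating `kx` and `f_max`. Because `kx` spans several
#' decades across toxins, it is fitted on a log10 scale internally and
#' reported on the linear scale (standard error by the delta method). The
#' half-saturation of the fitted curve sits at `lipid_avail = [W] / kx`.
#' Flat data (no detectable titration) is rejected.
#'
#' @param curve A [build_partition_curve()] tibble (columns `lipid_avail`,
#'   `f_ratio`).
#' @param constants A [channel_constants()] list (supplies `[W]`).
#' @param flat_tol Minimum F/F0 span regarded as detectable partitioning.
#'
#' @return An object of class `partition_fit`: estimates `kx`, `f_max` with
#'   standard errors ([tidy()]), residual summary ([glance()]), data and
#'   fitted values.
#' @export
fit_partition <- function(curve, constants = channel_constants(),
                          flat_tol = 0.02) {
  df <- tibble::as_tibble(curve)[, c("lipid_avail", "f_ratio")]
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 3L) {
    rlang::abort("Need at least 3 titration points.",
                 class = "paddletox_bad_input")
  }
  if (diff(range(df$f_ratio)) < flat_tol) {
    rlang::abort("No partitioning detectable (flat F/F0 curve).",
                 class = "paddletox_degenerate")
  }
  w <- constants$water_molarity
  l <- df$lipid_avail
  f <- df$f_ratio

  f_max0 <- max(f)
  half <- 1 + (f_max0 - 1) / 2
  pos <- df[df$lipid_avail > 0, ]
  l_half0 <- tryCatch(
    stats::approx(pos$f_ratio, pos$lipid_avail, xout = half,
                  ties = mean)$y,
    error = function(e) NA_real_
  )
  if (!is.finite(l_half0) || l_half0 <= 0) l_half0 <- stats::median(pos$lipid_avail)
  lk0 <- log10(w / l_half0)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ 1 + (f_max - 1) * (10^lk) * l / (w + (10^lk) * l),
      start = list(lk = lk0, f_max = f_max0),
      lower = c(-10, 1), upper = c(20, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    rlang::abort("Partition fit failed to converge.",
                 class = "paddletox_degenerate")
  }
  co <- summary(fit)$coefficients
  kx <- 10^unname(co["lk", "Estimate"])
  kx_se <- log(10) * kx * unname(co["lk", "Std. Error"])
  structure(
    list(
      params = tibble::tibble(
        term = c("kx", "f_max"),
        estimate = c(kx, unname(co["f_max", "Estimate"])),
        std.error = c(kx_se, unname(co["f_max", "Std. Error"]))
      ),
      data = df,
      fitted = as.numeric(stats::fitted(fit)),
      rss = sum(stats::residuals(fit)^2),
      sigma = summary(fit)$sigma,
      n = nrow(df),
      water_molarity = w,
      half_saturation = w / kx
    ),
    class = "partition_fit"
  )
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf("<partition_fit> %d points, half-saturation at %.3g M\n",
              x$n, x$half_saturation))
  print(x$params)
  invisible(x)
}

#' @method tidy partition_fit
#' @export
tidy.partition_fit <- function(x, ...) x$params

#' @method glance partition_fit
#' @export
glance.partition_fit <- function(x, ...) {
  tibble::tibble(
    kx = x$params$estimate[x$params$term == "kx"],
    f_max = x$params$estimate[x$params$term == "f_max"],
    half_saturation = x$half_saturation,
    rss = x$rss, sigma = x$sigma, n = x$n
  )
}
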