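#' Write and read trace families and spectra as CSV with a JSON sidecar
#'
#' Long-format CSV holds the data; a JSON sidecar (same path with extension
#' `.json`) records the protocol and generator truth so a round trip
#' restores the object's attributes.
#'
#' @param x A `trace_set` or `spectrum_set` tibble.
#' @param path CSV file path; the sidecar goes to `sub("\\\\.csv$", ".json", path)`.
#' @return `write_trace_set()`/`write_spectrum_set()` invisibly return
#'   `path`; the readers return the restored object.
#' @name paddletox-io
NULL

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

spec_to_list <- function(x) {
  if (is.null(x)) NULL else unclass(x)
}

#' @rdname paddletox-io
#' @export
write_trace_set <- function(x, path) {
  stopifnot(inherits(x, "trace_set"))
  readr::write_csv(tibble::as_tibble(x), path)
  meta <- list(
    type = "trace_set",
    protocol = spec_to_list(attr(x, "protocol")),
    channel = spec_to_list(attr(x, "channel")),
    toxin = spec_to_list(attr(x, "toxin")),
    leak_conductance = attr(x, "leak_conductance"),
    noise_sd = attr(x, "noise_sd"),
    seed = attr(x, "seed")
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname paddletox-io
#' @export
read_trace_set <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  protocol <- do.call(voltage_protocol, meta$protocol)
  channel <- do.call(channel_spec, meta$channel)
  toxin <- if (is.null(meta$toxin)) NULL else do.call(toxin_spec, meta$toxin)
  new_trace_set(df, protocol = protocol, channel = channel, toxin = toxin,
                leak_conductance = meta$leak_conductance,
                noise_sd = meta$noise_sd, seed = meta$seed)
}

#' @rdname paddletox-io
#' @export
write_spectrum_set <- function(x, path) {
  stopifnot(inherits(x, "spectrum_set"))
  readr::write_csv(tibble::as_tibble(x), path)
  meta <- list(
    type = "spectrum_set",
    kx = attr(x, "kx"), f_max = attr(x, "f_max"),
    free_peak = attr(x, "free_peak"),
    bound_peak_shift = attr(x, "bound_peak_shift"),
    band_fwhm = attr(x, "band_fwhm"),
    avail_fraction = attr(x, "avail_fraction"),
    noise_sd = attr(x, "noise_sd"), seed = attr(x, "seed"),
    water_molarity = attr(x, "water_molarity")
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname paddletox-io
#' @export
read_spectrum_set <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  structure(
    tibble::as_tibble(df),
    class = c("spectrum_set", class(tibble::tibble())),
    kx = meta$kx, f_max = meta$f_max, free_peak = meta$free_peak,
    bound_peak_shift = meta$bound_peak_shift, band_fwhm = meta$band_fwhm,
    avail_fraction = meta$avail_fraction, noise_sd = meta$noise_sd,
    seed = meta$seed, water_molarity = meta$water_molarity
  )
}

#' Write an activation curve as a two-column CSV
#'
#' @param curve An activation-curve tibble (see [extract_activation_curve()]).
#' @param path Output CSV path.
#' @export
write_activation_curve <- function(curve, path) {
  readr::write_csv(dplyr::select(tibble::as_tibble(curve),
                                 dplyr::any_of(c("voltage", "response"))),
                   path)
  invisible(path)
}
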