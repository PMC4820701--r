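#' Subtract the linear leak estimated at subthreshold voltages
#'
#' Estimates the ohmic leak by linear regression of the steady-state step
#' current against voltage over the supplied subthreshold test voltages,
#' then subtracts the extrapolated leak (`slope * command + intercept`) from
#' every sample of every sweep. After subtraction the steady current at the
#' fit voltages is ~0. The operation is idempotent: reapplying it estimates
#' a near-zero residual conductance.
#'
#' If the regression shows systematic curvature (root-mean-square residual
#' above `warn_tol` of the fitted current span), the fit voltages likely
#' overlap the activation range and the result is flagged via the
#' `leak_warning` attribute.
#'
#' @param traces A `trace_set` tibble.
#' @param fit_voltages Two or more test voltages assumed below the
#'   activation threshold. Default: the three most negative test voltages.
#' @param steady_fraction Fraction of the step end used to measure the
#'   steady-state current. Default 0.1.
#' @param warn_tol Relative residual threshold for the overlap warning.
#'
#' @return The leak-subtracted `trace_set`; the estimated leak is attached
#'   as attribute `leak_fit` (tibble with `conductance` in uS, `intercept`
#'   in nA, `rmse`) and `leak_warning` (logical).
#' @export
subtract_leak <- function(traces, fit_voltages = NULL,
                          steady_fraction = 0.1, warn_tol = 0.05) {
  stopifnot(inherits(traces, "trace_set"))
  volts <- sort(unique(traces$voltage))
  if (is.null(fit_voltages)) fit_voltages <- utils::head(volts, 3L)
  if (length(fit_voltages) < 2L) {
    rlang::abort("Need at least two `fit_voltages`.",
                 class = "paddletox_bad_input")
  }
  if (!all(fit_voltages %in% volts)) {
    rlang::abort("`fit_voltages` must be test voltages of the family.",
                 class = "paddletox_bad_input")
  }

  ss <- traces |>
    dplyr::filter(.data$phase == "step", .data$voltage %in% fit_voltages) |>
    dplyr::group_by(.data$voltage) |>
    dplyr::filter(.data$time >= stats::quantile(.data$time,
                                                1 - steady_fraction)) |>
    dplyr::summarise(i_ss = mean(.data$current), .groups = "drop")

  fit <- stats::lm(i_ss ~ voltage, data = ss)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  span <- max(abs(diff(range(stats::fitted(fit)))), .Machine$double.eps)
  warn <- nrow(ss) >= 3L && rmse > warn_tol * span
  if (warn) {
    rlang::warn("Leak fit shows curvature; `fit_voltages` may overlap the activation range.")
  }

  out <- traces
  out$current <- out$current - (slope * out$command + intercept)
  attr(out, "leak_fit") <- tibble::tibble(conductance = slope,
                                          intercept = intercept, rmse = rmse)
  attr(out, "leak_warning") <- warn
  out
}

#' Extract an activation curve from a current family
#'
#' Converts a (leak-subtracted) trace family into per-voltage activation
#' amplitudes. In `"kv"` mode the amplitude is the relaxing (deactivating)
#' tail-current component extrapolated to the moment of repolarization: a
#' mono-exponential `A * exp(-t/tau) + C` is fitted to the tail segment
#' (after blanking the first `blank_ms`, which in real recordings contains
#' the capacitive transient) and `A` is reported. Constant tail offsets --
#' residual leak, steady-state current at the tail voltage -- land in `C`
#' and are excluded by construction, which keeps toxin/control amplitude
#' ratios unbiased. In `"cav"` mode the amplitude is the signed extremum of
#' the current within the test step. Responses are the amplitudes
#' normalized to the largest absolute amplitude.
#'
#' @param traces A `trace_set` tibble.
#' @param mode `"kv"` or `"cav"`; defaults to the simulating channel's mode
#'   when available.
#' @param blank_ms Initial blanking window after each voltage transition, ms.
#' @param tail_fit_ms Length of tail segment used in the exponential fit,
#'   ms; `NULL` uses the whole tail.
#' @param normalize Add a `response` column normalized to max |amplitude|.
#'
#' @return A tibble of class `activation_curve` with columns `voltage`,
#'   `amplitude` (nA, raw), `response` (normalized), `tau` (tail time
#'   constant, ms; `NA` in cav mode) and `flag` (`NA` or a quality note).
#' @export
extract_activation_curve <- function(traces, mode = NULL, blank_ms = 2,
                                     tail_fit_ms = NULL, normalize = TRUE) {
  stopifnot(inherits(traces, "trace_set"))
  if (is.null(mode)) {
    ch <- attr(traces, "channel")
    mode <- if (!is.null(ch)) ch$mode else "kv"
  }
  mode <- match.arg(mode, c("kv", "cav"))

  one_voltage <- function(df) {
    if (mode == "cav") {
      seg <- df[df$phase == "step" & df$time >= blank_ms, ]
      amp <- seg$current[which.max(abs(seg$current))]
      return(tibble::tibble(voltage = df$voltage[1], amplitude = amp,
                            tau = NA_real_, flag = NA_character_))
    }
    seg <- df[df$phase == "tail", ]
    t0 <- min(seg$time)
    seg$t_rel <- seg$time - t0
    fit_seg <- seg[seg$t_rel >= blank_ms, ]
    if (!is.null(tail_fit_ms)) {
      fit_seg <- fit_seg[fit_seg$t_rel <= blank_ms + tail_fit_ms, ]
    }
    res <- tryCatch(
      fit_time_constant(fit_seg, time = "t_rel", current = "current"),
      error = function(e) NULL
    )
    if (is.null(res) || !res$converged) {
      # degenerate or failed tail fit: early-minus-late difference as a
      # crude relaxation amplitude, flagged
      early <- seg$current[seg$t_rel >= blank_ms &
                             seg$t_rel <= blank_ms + 5]
      late <- seg$current[seg$t_rel >= max(seg$t_rel) * 0.8]
      return(tibble::tibble(voltage = df$voltage[1],
                            amplitude = mean(early) - mean(late),
                            tau = NA_real_,
                            flag = "degenerate_tail"))
    }
    tibble::tibble(voltage = df$voltage[1],
                   amplitude = res$amplitude,
                   tau = res$tau, flag = NA_character_)
  }

  curve <- traces |>
    tibble::as_tibble() |>
    dplyr::group_split(.data$voltage) |>
    purrr::map(one_voltage) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$voltage)

  if (normalize) {
    # kv: divide by the signed largest-magnitude amplitude, so the curve
    # saturates at +1 even when the tail driving force is inward (tail
    # voltage below the reversal); cav: preserve the sign of the I-V
    ref <- if (mode == "kv") {
      curve$amplitude[which.max(abs(curve$amplitude))]
    } else {
      max(abs(curve$amplitude))
    }
    curve$response <- curve$amplitude / ref
  }
  structure(curve, class = c("activation_curve", class(tibble::tibble())),
            mode = mode)
}

#' Fit a mono-exponential time constant to a trace segment
#'
#' Least-squares fit of `I(t) = A * exp(-t / tau) + C` (Levenberg-Marquardt,
#' data-driven starting values), the single-exponential description of
#' activation or deactivation at a fixed voltage. A segment with essentially
#' no relaxation (amplitude ~ 0, e.g. a constant trace) is rejected rather
#' than silently returned.
#'
#' @param segment Data frame with time and current columns.
#' @param time,current Column names. Time is re-zeroed to the segment start.
#' @param min_points Minimum number of samples. Default 5.
#'
#' @return A list of class `exp_fit`: `tau` (ms), `amplitude` (`A`, value of
#'   the decaying component at segment start), `baseline` (`C`), `se_tau`,
#'   `sigma` (residual sd), `converged`, `n`.
#' @export
fit_time_constant <- function(segment, time = "time", current = "current",
                              min_points = 5) {
  t <- segment[[time]]
  y <- segment[[current]]
  if (length(t) < min_points) {
    rlang::abort(sprintf("Need at least %d samples.", min_points),
                 class = "paddletox_bad_input")
  }
  t <- t - min(t)
  span <- diff(range(y))
  scale <- max(abs(y), .Machine$double.xmin)
  if (span <= 1e-10 * max(scale, 1e-12) || span == 0) {
    rlang::abort("Segment has no measurable relaxation (amplitude ~ 0).",
                 class = "paddletox_degenerate")
  }
  n_head <- max(3L, ceiling(length(y) * 0.02))
  n_tail <- max(3L, ceiling(length(y) * 0.2))
  c0 <- mean(utils::tail(y, n_tail))
  a0 <- mean(utils::head(y, n_head)) - c0
  if (abs(a0) <= 1e-10 * max(scale, 1e-12)) {
    rlang::abort("Segment has no measurable relaxation (amplitude ~ 0).",
                 class = "paddletox_degenerate")
  }
  # first crossing of 1/e decay as the tau start
  target <- c0 + a0 / exp(1)
  crossed <- if (a0 > 0) y <= target else y >= target
  tau0 <- if (any(crossed)) max(t[which(crossed)[1]], t[2]) else max(t) / 3

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-t / tau) + C,
      start = list(A = a0, tau = tau0, C = c0),
      lower = c(-Inf, 1e-9, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(tau = NA_real_, amplitude = NA_real_,
                          baseline = NA_real_, se_tau = NA_real_,
                          sigma = NA_real_, converged = FALSE,
                          n = length(y)),
                     class = "exp_fit"))
  }
  co <- summary(fit)$coefficients
  structure(
    list(tau = unname(co["tau", "Estimate"]),
         amplitude = unname(co["A", "Estimate"]),
         baseline = unname(co["C", "Estimate"]),
         se_tau = unname(co["tau", "Std. Error"]),
         sigma = summary(fit)$sigma,
         converged = TRUE,
         n = length(y)),
    class = "exp_fit"
  )
}

#' Time constants of activation or deactivation across a family
#'
#' Applies [fit_time_constant()] to the chosen phase of every sweep,
#' yielding a tau-voltage table (the single-exponential kinetic summary of
#' an activation family).
#'
#' @param traces A `trace_set` tibble.
#' @param phase `"activation"` (test step, tau vs step voltage) or
#'   `"deactivation"` (tail, tau vs step voltage at the fixed tail voltage).
#' @param blank_ms Blanking window after the voltage transition, ms.
#'
#' @return A tibble with `voltage`, `tau` (ms), `se_tau`, `phase` and
#'   `converged`.
#' @export
time_constant_table <- function(traces, phase = c("activation", "deactivation"),
                                blank_ms = 2) {
  stopifnot(inherits(traces, "trace_set"))
  phase <- match.arg(phase)
  target <- if (phase == "activation") "step" else "tail"
  traces |>
    tibble::as_tibble() |>
    dplyr::filter(.data$phase == target) |>
    dplyr::group_split(.data$voltage) |>
    purrr::map(function(df) {
      df$t_rel <- df$time - min(df$time)
      res <- tryCatch(
        fit_time_constant(df[df$t_rel >= blank_ms, ],
                          time = "t_rel", current = "current"),
        error = function(e) NULL
      )
      tibble::tibble(
        voltage = df$voltage[1],
        tau = if (is.null(res)) NA_real_ else res$tau,
        se_tau = if (is.null(res)) NA_real_ else res$se_tau,
        phase = phase,
        converged = !is.null(res) && isTRUE(res$converged)
      )
    }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$voltage)
}
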