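#' Fit a Boltzmann activation model to an activation curve
#'
#' `"kv"` mode fits the two-parameter Boltzmann
#' `r = 1 / (1 + exp(-z (V - V1/2) / (RT/F)))` to normalized tail-current
#' responses. `"cav"` mode fits the ohmic-driving-force form
#' `r = (V - Vrev) Gmax / (1 + exp(-z (V - V1/2) / (RT/F)))` to normalized
#' peak-current I-V data. Estimation is nonlinear least squares
#' (Levenberg-Marquardt) with deterministic, data-driven starting values:
#' `V1/2` from the half-maximum crossing by linear interpolation, `z` from
#' the 10-90% voltage width (`z0 = ln(81) * (RT/F) / width`), and, for cav,
#' `Vrev`/`Gmax` from the linear top of the I-V. `z` is bounded to
#' `z_bounds` to prevent runaway; a fit that lands on a bound or fails to
#' converge is flagged (and a warning raised), never silently returned.
#'
#' @param curve A data frame with columns `voltage` (mV) and `response`
#'   (normalized amplitude), e.g. from [extract_activation_curve()].
#' @param mode `"kv"` or `"cav"`; defaults to the curve's own mode
#'   attribute when present.
#' @param init Optional named list of starting values overriding the
#'   data-driven ones (`v_half`, `z`, and for cav `v_rev`, `g_max`).
#' @param constants A [channel_constants()] list.
#' @param z_bounds Allowed range for the gating valence. Default (0.1, 10].
#'
#' @return An object of class `boltzmann_fit`: parameter estimates with
#'   asymptotic standard errors (see [tidy()]), residual summary (see
#'   [glance()]), the data, fitted values, `converged` and `flags`.
#' @examples
#' v <- seq(-80, 80, 5)
#' curve <- tibble::tibble(voltage = v,
#'                         response = boltzmann_open_fraction(v, -5.8, 2.6))
#' fit_boltzmann(curve, mode = "kv")
#' @export
fit_boltzmann <- function(curve, mode = NULL, init = NULL,
                          constants = channel_constants(),
                          z_bounds = c(0.1, 10)) {
  if (is.null(mode)) mode <- attr(curve, "mode") %||% "kv"
  mode <- match.arg(mode, c("kv", "cav"))
  df <- tibble::as_tibble(curve)[, c("voltage", "response")]
  df <- df[stats::complete.cases(df), ]
  n_min <- if (mode == "kv") 4L else 6L
  if (nrow(df) < n_min) {
    rlang::abort(sprintf("Need at least %d points for a %s fit.", n_min, mode),
                 class = "paddletox_bad_input")
  }
  if (diff(range(df$response)) < 1e-3) {
    rlang::abort("No voltage-dependent transition in the data.",
                 class = "paddletox_degenerate")
  }
  vt <- constants$thermal_voltage
  v <- df$voltage
  r <- df$response

  interp_cross <- function(x, y, target) {
    # first crossing of `target` by linear interpolation
    s <- sign(y - target)
    idx <- which(s[-1] * s[-length(s)] <= 0)
    if (length(idx) == 0) return(stats::median(x))
    i <- idx[1]
    x[i] + (target - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
  }

  start_gate <- function(g) {
    lo <- min(g); hi <- max(g)
    v50 <- interp_cross(v, g, lo + 0.5 * (hi - lo))
    v10 <- interp_cross(v, g, lo + 0.1 * (hi - lo))
    v90 <- interp_cross(v, g, lo + 0.9 * (hi - lo))
    width <- max(abs(v90 - v10), 1e-3)
    z0 <- min(max(log(81) * vt / width, z_bounds[1] * 1.01),
              z_bounds[2] * 0.99)
    list(v_half = v50, z = z0)
  }

  flags <- character()
  if (mode == "kv") {
    s0 <- start_gate(r)
    if (!is.null(init)) s0[names(init)] <- init
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ 1 / (1 + exp(-z * (v - v_half) / vt)),
        start = s0[c("v_half", "z")],
        lower = c(-Inf, z_bounds[1]), upper = c(Inf, z_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  } else {
    # top of the I-V is ~linear in V: slope = Gmax, root = Vrev
    n_top <- min(4L, max(2L, nrow(df) - 4L))
    top <- utils::tail(dplyr::arrange(df, .data$voltage), n_top)
    lf <- stats::lm(response ~ voltage, data = top)
    g0 <- unname(stats::coef(lf)[2])
    vrev0 <- if (abs(g0) > 1e-12) -unname(stats::coef(lf)[1]) / g0 else {
      max(v) + 20
    }
    if (!is.finite(vrev0) || vrev0 <= max(v)) vrev0 <- max(v) + 20
    if (!is.finite(g0) || abs(g0) < 1e-12) g0 <- max(abs(r)) / abs(diff(range(v)))
    gate <- r / (v - vrev0)
    gate <- gate / max(abs(gate))
    s_g <- start_gate(gate)
    s0 <- list(v_half = s_g$v_half, z = s_g$z, v_rev = vrev0, g_max = abs(g0))
    if (!is.null(init)) s0[names(init)] <- init
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ (v - v_rev) * g_max / (1 + exp(-z * (v - v_half) / vt)),
        start = s0[c("v_half", "z", "v_rev", "g_max")],
        lower = c(-Inf, z_bounds[1], -Inf, 1e-12),
        upper = c(Inf, z_bounds[2], Inf, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }

  if (is.null(fit)) {
    rlang::warn("Boltzmann fit did not converge; result flagged.")
    return(structure(
      list(params = tibble::tibble(term = character(), estimate = double(),
                                   std.error = double()),
           mode = mode, data = df, fitted = rep(NA_real_, nrow(df)),
           n_points = nrow(df), rss = NA_real_, sigma = NA_real_,
           converged = FALSE, flags = "not_converged", constants = constants),
      class = "boltzmann_fit"
    ))
  }

  co <- summary(fit)$coefficients
  params <- tibble::tibble(term = rownames(co),
                           estimate = unname(co[, "Estimate"]),
                           std.error = unname(co[, "Std. Error"]))
  z_hat <- params$estimate[params$term == "z"]
  if (z_hat <= z_bounds[1] * 1.001 || z_hat >= z_bounds[2] * 0.999) {
    rlang::warn("Gating valence landed on its bound; result flagged.")
    flags <- c(flags, "z_at_bound")
  }
  structure(
    list(params = params, mode = mode, data = df,
         fitted = as.numeric(stats::fitted(fit)),
         n_points = nrow(df),
         rss = sum(stats::residuals(fit)^2),
         sigma = summary(fit)$sigma,
         converged = TRUE, flags = flags, constants = constants),
    class = "boltzmann_fit"
  )
}

boltz_param <- function(fit, term) {
  i <- match(term, fit$params$term)
  c(estimate = fit$params$estimate[i], se = fit$params$std.error[i])
}

#' Half-activation voltage shift between two Boltzmann fits
#'
#' Difference `V1/2(a) - V1/2(b)` with the standard error propagated in
#' quadrature. Flags from either fit propagate.
#'
#' @param fit_a,fit_b Objects from [fit_boltzmann()].
#' @return A one-row tibble with `delta_v_half` (mV), `se` and `flagged`.
#' @export
delta_v12 <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "boltzmann_fit"), inherits(fit_b, "boltzmann_fit"))
  if (!fit_a$converged || !fit_b$converged) {
    rlang::abort("Both fits must have converged.",
                 class = "paddletox_degenerate")
  }
  a <- boltz_param(fit_a, "v_half")
  b <- boltz_param(fit_b, "v_half")
  tibble::tibble(
    delta_v_half = unname(a["estimate"] - b["estimate"]),
    se = unname(sqrt(a["se"]^2 + b["se"]^2)),
    flagged = length(fit_a$flags) > 0 || length(fit_b$flags) > 0
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> mode %s, %d points%s\n", x$mode, x$n_points,
              if (x$converged) "" else " (NOT CONVERGED)"))
  if (nrow(x$params)) print(x$params)
  invisible(x)
}

#' @method tidy boltzmann_fit
#' @export
tidy.boltzmann_fit <- function(x, ...) x$params

#' @method glance boltzmann_fit
#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble::tibble(mode = x$mode, n = x$n_points, rss = x$rss, sigma = x$sigma,
                 converged = x$converged,
                 flagged = length(x$flags) > 0)
}
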