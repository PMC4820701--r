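#' Fit binding stoichiometry and affinity to a dose-response table
#'
#' Least-squares fit of the independent-sites occupancy model
#' `F_u = (K_d / (K_d + c))^n` to (concentration, `fu`) data, with both
#' `K_d` and `n` free, plus companion fits with `n` constrained to each
#' value in `constrained_n` (and `K_d` free) for model comparison. Because
#' the constrained models are nested in the free one, the free-fit residual
#' sum of squares never exceeds any constrained fit's; if the optimizer
#' lands worse, the free fit is re-polished from the best constrained
#' solution.
#'
#' @param dose_table Data frame with columns `concentration` (uM, > 0) and
#'   `fu`, e.g. from [simulate_dose_response()].
#' @param constrained_n Integer site counts for the constrained companion
#'   fits. Default `c(1, 2, 3)`.
#'
#' @return An object of class `dose_response_fit`: free-fit estimates with
#'   asymptotic standard errors ([tidy()]), constrained fits (`$constrained`:
#'   `n`, `kd`, `kd_se`, `rss`), `rss_free`, the data and fitted values.
#' @examples
#' dt <- simulate_dose_response(1.30, 2.11,
#'                              10^seq(log10(0.1), log10(30), length.out = 8),
#'                              noise_sd = 0)
#' fit_stoichiometry(dt)
#' @export
fit_stoichiometry <- function(dose_table, constrained_n = c(1, 2, 3)) {
  df <- tibble::as_tibble(dose_table)[, c("concentration", "fu")]
  df <- df[stats::complete.cases(df), ]
  if (!all(df$concentration > 0)) {
    rlang::abort("Concentrations must be > 0.", class = "paddletox_bad_input")
  }
  n_conc <- length(unique(df$concentration))
  if (n_conc < 3L) {
    rlang::abort("Need at least 3 distinct concentrations for a free fit.",
                 class = "paddletox_bad_input")
  }
  conc <- df$concentration
  fu <- df$fu

  kd_start <- function(n0) {
    # concentration giving fu = 0.5 under site count n0
    target <- 0.5^(1 / n0)
    i <- which.min(abs(fu - 0.5))
    c0 <- conc[i]
    max(c0 * target / max(1 - target, 1e-6), min(conc) / 10)
  }

  fit_constrained <- function(n_fix) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fu ~ (kd / (kd + conc))^n_fix,
        start = list(kd = kd_start(n_fix)),
        lower = 1e-9,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(tibble::tibble(n = n_fix, kd = NA_real_, kd_se = NA_real_,
                            rss = Inf))
    }
    co <- summary(fit)$coefficients
    tibble::tibble(n = n_fix, kd = unname(co["kd", "Estimate"]),
                   kd_se = unname(co["kd", "Std. Error"]),
                   rss = sum(stats::residuals(fit)^2))
  }
  constrained <- purrr::map(constrained_n, fit_constrained) |>
    purrr::list_rbind()

  fit_free <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        fu ~ (kd / (kd + conc))^n,
        start = start,
        lower = c(1e-9, 1e-3), upper = c(Inf, 100),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
  }
  free <- fit_free(list(kd = kd_start(1.5), n = 1.5))
  rss_of <- function(f) if (is.null(f)) Inf else sum(stats::residuals(f)^2)
  # nesting safeguard: restart from the best constrained solution if needed
  best_c <- which.min(constrained$rss)
  if (is.finite(constrained$rss[best_c]) &&
      rss_of(free) > constrained$rss[best_c]) {
    free2 <- fit_free(list(kd = constrained$kd[best_c],
                           n = constrained$n[best_c]))
    if (rss_of(free2) < rss_of(free)) free <- free2
  }
  if (is.null(free)) {
    rlang::abort("Free (Kd, n) fit failed to converge.",
                 class = "paddletox_degenerate")
  }
  co <- summary(free)$coefficients
  structure(
    list(
      params = tibble::tibble(term = rownames(co),
                              estimate = unname(co[, "Estimate"]),
                              std.error = unname(co[, "Std. Error"])),
      constrained = constrained,
      rss_free = sum(stats::residuals(free)^2),
      sigma = summary(free)$sigma,
      data = df,
      fitted = as.numeric(stats::fitted(free)),
      n_obs = nrow(df)
    ),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> %d observations\n", x$n_obs))
  print(x$params)
  cat("constrained-n companions:\n")
  print(x$constrained)
  invisible(x)
}

#' @method tidy dose_response_fit
#' @export
tidy.dose_response_fit <- function(x, ...) x$params

#' @method glance dose_response_fit
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble::tibble(
    kd = x$params$estimate[x$params$term == "kd"],
    n_sites = x$params$estimate[x$params$term == "n"],
    rss_free = x$rss_free,
    rss_best_constrained = min(x$constrained$rss),
    sigma = x$sigma,
    n_obs = x$n_obs
  )
}
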