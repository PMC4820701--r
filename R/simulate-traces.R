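#' Simulate a voltage-clamp current family
#'
#' Forward model of an activation-family experiment. Channels are split into
#' an unbound subpopulation (probability `p0`, from [unbound_probability()])
#' gating with the channel's own Boltzmann parameters, and a toxin-bound
#' subpopulation (`1 - p0`) whose activation midpoint is shifted positive and
#' whose kinetics are slowed (see [toxin_spec()]). Each subpopulation relaxes
#' first-order toward its Boltzmann steady state with the channel's
#' voltage-dependent time constant. The ensemble current is
#' `g_max * (V - v_rev) * (p0 * p_unbound + (1 - p0) * p_bound)`, plus an
#' ohmic leak through 0 mV and optional Gaussian recording noise.
#'
#' @param channel A [channel_spec()].
#' @param protocol A [voltage_protocol()].
#' @param toxin A [toxin_spec()], or `NULL` for a control family.
#' @param leak_conductance Ohmic leak conductance, uS (leak current
#'   `g_leak * V` is added before any subtraction stage).
#' @param noise_sd Standard deviation of additive Gaussian noise on each
#'   current sample, nA. `0` gives a noiseless family; `NULL` (default) uses
#'   1% of the maximum absolute current in the measurement phase (tail phase
#'   for `"kv"` mode, test step for `"cav"` mode).
#' @param seed Integer seed making the noise reproducible; ignored for
#'   noiseless families.
#' @param constants A [channel_constants()] list.
#'
#' @return A tibble of class `trace_set` with columns `voltage` (test-step
#'   label, mV), `time` (ms from step onset), `phase` (`"step"`/`"tail"`),
#'   `command` (instantaneous command voltage, mV) and `current` (nA).
#'   The protocol, channel, toxin, leak, noise level and seed are attached
#'   as attributes.
#' @examples
#' fam <- simulate_activation_family(
#'   channel_spec(v_half = -5.8, z = 2.6),
#'   voltage_protocol(test_voltages = seq(-40, 40, 20), step_duration = 50,
#'                    tail_duration = 20, sample_interval = 0.5),
#'   noise_sd = 0)
#' @export
simulate_activation_family <- function(channel,
                                       protocol = voltage_protocol(),
                                       toxin = NULL,
                                       leak_conductance = 0,
                                       noise_sd = NULL,
                                       seed = NULL,
                                       constants = channel_constants()) {
  stopifnot(inherits(channel, "channel_spec"),
            inherits(protocol, "voltage_protocol"))
  if (!is.null(toxin)) {
    stopifnot(inherits(toxin, "toxin_spec"))
    if (toxin$concentration < 0) {
      rlang::abort("Toxin concentration must be >= 0.",
                   class = "paddletox_bad_input")
    }
  }
  p0 <- if (is.null(toxin)) 1 else {
    unbound_probability(toxin$kd, toxin$n_sites, toxin$concentration)
  }

  dt <- protocol$sample_interval
  t_step <- seq(0, protocol$step_duration, by = dt)
  t_tail <- seq(dt, protocol$tail_duration, by = dt)
  n_s <- length(t_step)
  n_t <- length(t_tail)

  pops <- list(list(weight = p0, v_half = channel$v_half, tau_scale = 1))
  if (!is.null(toxin) && p0 < 1) {
    pops <- c(pops, list(list(weight = 1 - p0,
                              v_half = channel$v_half + toxin$bound_vhalf_shift,
                              tau_scale = toxin$bound_tau_factor)))
  }

  tau_of <- function(v, v_half, scale) {
    x <- (v - v_half) / channel$tau_voltage_width
    scale * channel$tau_at_vhalf / cosh(x)
  }

  sweep_one <- function(v_test) {
    open_total <- numeric(n_s + n_t)
    for (pop in pops) {
      p_hold <- boltzmann_open_fraction(protocol$holding, pop$v_half,
                                        channel$z, constants)
      p_inf_s <- boltzmann_open_fraction(v_test, pop$v_half, channel$z,
                                         constants)
      tau_s <- tau_of(v_test, pop$v_half, pop$tau_scale)
      p_step <- p_inf_s + (p_hold - p_inf_s) * exp(-t_step / tau_s)
      p_end <- p_step[n_s]
      p_inf_t <- boltzmann_open_fraction(protocol$tail_voltage, pop$v_half,
                                         channel$z, constants)
      tau_t <- tau_of(protocol$tail_voltage, pop$v_half, pop$tau_scale)
      p_tail <- p_inf_t + (p_end - p_inf_t) * exp(-t_tail / tau_t)
      open_total <- open_total + pop$weight * c(p_step, p_tail)
    }
    command <- c(rep(v_test, n_s), rep(protocol$tail_voltage, n_t))
    current <- channel$g_max * (command - channel$v_rev) * open_total +
      leak_conductance * command
    tibble::tibble(
      voltage = v_test,
      time = c(t_step, protocol$step_duration + t_tail),
      phase = c(rep("step", n_s), rep("tail", n_t)),
      command = command,
      current = current
    )
  }

  traces <- purrr::map(protocol$test_voltages, sweep_one) |> purrr::list_rbind()

  if (is.null(noise_sd)) {
    measured <- if (channel$mode == "kv") "tail" else "step"
    noise_sd <- 0.01 * max(abs(traces$current[traces$phase == measured]))
  }
  if (noise_sd > 0) {
    add_noise <- function() {
      traces$current + stats::rnorm(nrow(traces), sd = noise_sd)
    }
    traces$current <- if (is.null(seed)) add_noise() else {
      withr::with_seed(seed, add_noise())
    }
  }

  new_trace_set(traces, protocol = protocol, channel = channel, toxin = toxin,
                leak_conductance = leak_conductance, noise_sd = noise_sd,
                seed = seed)
}

new_trace_set <- function(df, protocol, channel, toxin, leak_conductance,
                          noise_sd, seed) {
  structure(
    df,
    class = c("trace_set", class(tibble::tibble())),
    protocol = protocol, channel = channel, toxin = toxin,
    leak_conductance = leak_conductance, noise_sd = noise_sd, seed = seed
  )
}

#' @export
print.trace_set <- function(x, ...) {
  ch <- attr(x, "channel")
  cat(sprintf("<trace_set> %d sweeps, %s mode, noise sd %.4g nA\n",
              length(unique(x$voltage)),
              if (is.null(ch)) "?" else ch$mode,
              attr(x, "noise_sd") %||% 0))
  NextMethod()
}
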