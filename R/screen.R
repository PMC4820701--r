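#' Assemble a construct x toxin screening configuration
#'
#' Bundles the gating truth of each construct, the per-(construct, toxin)
#' binding truths, the stimulus protocol, and run settings into one object
#' consumed by [run_screen()].
#'
#' @param constructs Tibble with one row per construct. Required columns:
#'   `construct`, `v_half`, `z`. Optional: `v_rev`, `g_max`, `mode`,
#'   `tau_at_vhalf`, `tau_voltage_width`, `holding`, `tail_voltage`,
#'   `test_lo`, `test_hi` (per-construct protocol overrides).
#' @param conditions Tibble with one row per (construct, toxin) cell.
#'   Required: `construct`, `toxin`, `kd` (true per-site Kd, uM). Optional
#'   per-row `n_sites`, `concentration` overriding the defaults.
#' @param protocol Base [voltage_protocol()].
#' @param n_sites Default site count (4 for homotetrameric K+-conducting
#'   constructs).
#' @param concentration Default toxin concentration, uM.
#' @param noise_sd Recording noise per cell, nA; `0` for noiseless runs,
#'   `NULL` for the simulator default (1% of the measurement-phase maximum).
#' @param n_cells Number of simulated cells averaged per condition
#'   (mirroring mean +/- SEM over oocytes). Default 6.
#' @param leak_conductance Simulated leak conductance, uS.
#' @param censor_limit Kd censoring limit, uM.
#' @param seed Base integer seed; each simulated family derives its own
#'   sub-seed from it.
#'
#' @return A list of class `study_config`.
#' @export
study_config <- function(constructs, conditions = NULL,
                         protocol = voltage_protocol(),
                         n_sites = 4, concentration = 1.33,
                         noise_sd = 0, n_cells = 6,
                         leak_conductance = 0.001,
                         censor_limit = 50, seed = NULL) {
  constructs <- tibble::as_tibble(constructs)
  req <- c("construct", "v_half", "z")
  if (!all(req %in% names(constructs))) {
    rlang::abort("`constructs` needs columns construct, v_half, z.",
                 class = "paddletox_bad_input")
  }
  if (anyDuplicated(constructs$construct)) {
    rlang::abort("Construct names must be unique.",
                 class = "paddletox_bad_input")
  }
  if (is.null(conditions)) {
    conditions <- tibble::tibble(construct = character(), toxin = character(),
                                 kd = double())
  }
  conditions <- tibble::as_tibble(conditions)
  if (nrow(conditions) &&
      !all(conditions$construct %in% constructs$construct)) {
    rlang::abort("Every condition must reference a known construct.",
                 class = "paddletox_bad_input")
  }
  structure(
    list(constructs = constructs, conditions = conditions,
         protocol = protocol, n_sites = n_sites,
         concentration = concentration, noise_sd = noise_sd,
         n_cells = n_cells, leak_conductance = leak_conductance,
         censor_limit = censor_limit, seed = seed),
    class = "study_config"
  )
}

#' Read a screening configuration from YAML
#'
#' Expected layout:
#' ```yaml
#' protocol: {holding: -100, test_lo: -80, test_hi: 80, test_step: 10}
#' concentration: 1.33
#' n_sites: 4
#' constructs:
#'   - {name: DIII, v_half: -1.3, z: 2.6}
#' toxins:
#'   - name: ProTx-II
#'     kd: {DIII: 1.2}
#' ```
#'
#' @param path Path to a YAML file.
#' @param ... Further arguments passed to [study_config()].
#' @return A `study_config`.
#' @export
read_study_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  constructs <- purrr::map(y$constructs, function(cs) {
    tibble::as_tibble(c(list(construct = cs$name),
                        cs[setdiff(names(cs), "name")]))
  }) |> purrr::list_rbind()
  conditions <- purrr::map(y$toxins %||% list(), function(tx) {
    purrr::imap(tx$kd, function(kd, construct) {
      tibble::tibble(construct = construct, toxin = tx$name, kd = kd)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  proto_args <- y$protocol %||% list()
  if (!is.null(proto_args$test_lo)) {
    proto_args$test_voltages <- seq(proto_args$test_lo, proto_args$test_hi,
                                    by = proto_args$test_step %||% 10)
    proto_args$test_lo <- proto_args$test_hi <- proto_args$test_step <- NULL
  }
  protocol <- do.call(voltage_protocol, proto_args)
  extra <- y[setdiff(names(y), c("constructs", "toxins", "protocol"))]
  do.call(study_config,
          c(list(constructs = constructs, conditions = conditions,
                 protocol = protocol), extra, list(...)))
}

row_field <- function(row, field, default = NULL) {
  if (!field %in% names(row)) return(default)
  val <- row[[field]]
  if (is.null(val) || (length(val) == 1L && is.na(val))) default else val
}

construct_protocol <- function(base, row) {
  args <- unclass(base)
  holding <- row_field(row, "holding")
  tail_v <- row_field(row, "tail_voltage")
  lo <- row_field(row, "test_lo")
  hi <- row_field(row, "test_hi")
  if (!is.null(holding)) args$holding <- holding
  if (!is.null(tail_v)) args$tail_voltage <- tail_v
  if (!is.null(lo) && !is.null(hi)) {
    step <- stats::median(diff(args$test_voltages))
    args$test_voltages <- seq(lo, hi, by = step)
  }
  do.call(voltage_protocol, args)
}

construct_channel <- function(row) {
  channel_spec(
    v_half = row$v_half, z = row$z,
    v_rev = row_field(row, "v_rev"),
    g_max = row_field(row, "g_max", 0.02),
    tau_at_vhalf = row_field(row, "tau_at_vhalf", 10),
    tau_voltage_width = row_field(row, "tau_voltage_width", 30),
    mode = as.character(row_field(row, "mode", "kv"))
  )
}

simulate_mean_family <- function(channel, protocol, toxin, leak, noise_sd,
                                 n_cells, seed) {
  fams <- purrr::map(seq_len(n_cells), function(i) {
    cell_seed <- if (is.null(seed)) NULL else seed + i
    simulate_activation_family(channel, protocol, toxin = toxin,
                               leak_conductance = leak, noise_sd = noise_sd,
                               seed = cell_seed)
  })
  avg <- fams[[1]]
  if (n_cells > 1) {
    avg$current <- purrr::reduce(purrr::map(fams, "current"), `+`) / n_cells
  }
  avg
}

#' Run the full construct x toxin occupancy screen
#'
#' For each construct: simulate a control current family (averaging
#' `n_cells` cells), subtract the linear leak, extract the activation
#' curve, and fit the Boltzmann model. For each (construct, toxin) cell:
#' simulate the paired toxin family, form the current ratio, locate the
#' plateau, and convert the fraction unbound into an apparent Kd. Any
#' per-cell failure is caught and recorded in the `note` column; the screen
#' continues (failed cells report `NA`/censored values, like "ND" entries
#' in a summary table). Two runs with the same config and seed produce
#' identical tables.
#'
#' @param config A [study_config()].
#' @param seed Overrides `config$seed` when given.
#' @param out_dir Optional directory; when set, every intermediate
#'   (families, curves, ratio curves, summary) is written there as
#'   CSV/JSON, so each summary number is traceable to an artifact file.
#'
#' @return A tibble of class `construct_summary`, one row per construct
#'   without conditions and one per (construct, toxin) cell: `construct`,
#'   `v_half`, `v_half_se`, `z`, `z_se`, `toxin`, `concentration`, `fu`,
#'   `kd`, `censored`, `note`.
#' @export
run_screen <- function(config, seed = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  seed <- seed %||% config$seed
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(obj, name, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, name))
    invisible(obj)
  }

  rows <- list()
  for (ci in seq_len(nrow(config$constructs))) {
    row <- config$constructs[ci, ]
    nm <- row$construct
    base_seed <- if (is.null(seed)) NULL else seed + 1000L * ci
    res <- tryCatch({
      channel <- construct_channel(row)
      protocol <- construct_protocol(config$protocol, row)
      ctrl <- simulate_mean_family(channel, protocol, toxin = NULL,
                                   leak = config$leak_conductance,
                                   noise_sd = config$noise_sd,
                                   n_cells = config$n_cells,
                                   seed = base_seed)
      emit(ctrl, sprintf("%s_control.csv", nm), write_trace_set)
      ctrl_sub <- subtract_leak(ctrl)
      ctrl_curve <- extract_activation_curve(ctrl_sub)
      emit(ctrl_curve, sprintf("%s_control_curve.csv", nm),
           write_activation_curve)
      bfit <- fit_boltzmann(ctrl_curve, mode = channel$mode)
      vh <- boltz_param(bfit, "v_half")
      zz <- boltz_param(bfit, "z")
      list(channel = channel, protocol = protocol, curve = ctrl_curve,
           v_half = vh[["estimate"]], v_half_se = vh[["se"]],
           z = zz[["estimate"]], z_se = zz[["se"]], note = NA_character_)
    }, error = function(e) {
      list(channel = NULL, protocol = NULL, curve = NULL,
           v_half = NA_real_, v_half_se = NA_real_,
           z = NA_real_, z_se = NA_real_, note = conditionMessage(e))
    })

    conds <- config$conditions[config$conditions$construct == nm, ]
    if (nrow(conds) == 0) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        construct = nm, v_half = res$v_half, v_half_se = res$v_half_se,
        z = res$z, z_se = res$z_se, toxin = NA_character_,
        concentration = NA_real_, fu = NA_real_, kd = NA_real_,
        censored = NA, note = res$note
      )
      next
    }
    for (ti in seq_len(nrow(conds))) {
      cond <- conds[ti, ]
      n_sites <- row_field(cond, "n_sites", config$n_sites)
      conc <- row_field(cond, "concentration", config$concentration)
      cell <- tryCatch({
        if (!is.null(res$note) && !is.na(res$note)) stop(res$note)
        toxin <- toxin_spec(kd = cond$kd, n_sites = n_sites,
                            concentration = conc)
        tox_seed <- if (is.null(base_seed)) NULL else base_seed + 500L * ti
        fam <- simulate_mean_family(res$channel, res$protocol, toxin = toxin,
                                    leak = config$leak_conductance,
                                    noise_sd = config$noise_sd,
                                    n_cells = config$n_cells,
                                    seed = tox_seed)
        emit(fam, sprintf("%s_%s.csv", nm, cond$toxin), write_trace_set)
        fam_sub <- subtract_leak(fam)
        tox_curve <- extract_activation_curve(fam_sub)
        rc <- ratio_curve(tox_curve, res$curve, concentration = conc)
        emit(rc, sprintf("%s_%s_ratio.csv", nm, cond$toxin),
             function(x, p) readr::write_csv(tibble::as_tibble(x), p))
        occ <- estimate_fu(rc)
        if (conc == 0) {
          occ$fu <- 1
        }
        kd_for_construct(occ, n_sites = n_sites, concentration = max(conc, 1e-12),
                         censor_limit = config$censor_limit)
      }, error = function(e) {
        tibble::tibble(fu = NA_real_, kd = NA_real_, censored = NA,
                       note = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- tibble::tibble(
        construct = nm, v_half = res$v_half, v_half_se = res$v_half_se,
        z = res$z, z_se = res$z_se, toxin = cond$toxin,
        concentration = conc, fu = cell$fu %||% NA_real_,
        kd = cell$kd %||% NA_real_, censored = cell$censored %||% NA,
        note = if ("note" %in% names(cell)) cell$note else res$note
      )
    }
  }
  summary <- purrr::list_rbind(rows)
  if (!is.null(out_dir)) {
    readr::write_csv(summary, file.path(out_dir, "construct_summary.csv"))
  }
  structure(summary, class = c("construct_summary", class(tibble::tibble())))
}

#' Correlate channel inhibition with membrane-partitioning strength
#'
#' Spearman rank correlation between per-toxin inhibition (1 - Fu at a
#' fixed concentration) and the log10 mole-fraction partition coefficient.
#' With only a handful of toxins the statistic is a sign/rank summary, not
#' an inference; the p-value is reported for completeness.
#'
#' @param df Data frame with columns `toxin`, `inhibition` and `kx`.
#' @return A one-row tibble with `rho`, `p_value` and `n_toxins`; the
#'   kx-sorted paired table is attached as attribute `paired_table`.
#' @export
correlate_inhibition_partitioning <- function(df) {
  df <- tibble::as_tibble(df)[, c("toxin", "inhibition", "kx")]
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 3L) {
    rlang::abort("Need at least 3 paired toxins.",
                 class = "paddletox_bad_input")
  }
  if (length(unique(df$inhibition)) == 1L || length(unique(df$kx)) == 1L) {
    rlang::abort("Rank correlation undefined: all values tied on one axis.",
                 class = "paddletox_degenerate")
  }
  ct <- suppressWarnings(
    stats::cor.test(log10(df$kx), df$inhibition, method = "spearman")
  )
  out <- tibble::tibble(rho = unname(ct$estimate),
                        p_value = ct$p.value,
                        n_toxins = nrow(df))
  attr(out, "paired_table") <- dplyr::arrange(df, .data$kx)
  out
}
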