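#' Run a predefined scenario
#'
#' Three study designs are provided. `single_day` integrates one forcing to
#' (approximate) periodic state and reports the diel diagnostics.
#' `ablation` runs the identical configuration twice — with the default
#' initial heterotroph fraction and with heterotrophs removed — and
#' contrasts organic-acid load, pH and final composition; it probes the
#' heterotrophs' waste-scavenging, pH-stabilizing role. `seasons` runs the
#' four seasonal presets and reports the ordering of daily growth and water
#' activity across them.
#'
#' @param config an [sab_config()] object.
#' @param scenario one of `"single_day"`, `"ablation"`, `"seasons"`.
#' @param compute_rates forward to [sab_simulate()].
#' @return an object of class `sab_scenario`: list with the scenario name,
#'   per-variant trajectories, and a `metrics` data frame.
#' @export
run_scenario <- function(config = sab_config(),
                         scenario = c("single_day", "ablation", "seasons"),
                         compute_rates = TRUE) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(config, "sab_config"))
  run1 <- function(forcing, f_H) {
    ini <- config$initial
    y0 <- sab_initial_state(config$kin, M0 = ini$M0, f_H = f_H,
                            Q_SOC = ini$Q_SOC, Q_N = ini$Q_N,
                            Q_ATP = ini$Q_ATP, Q_NADPH = ini$Q_NADPH,
                            S_HCO3 = ini$S_HCO3, S_TOA = ini$S_TOA,
                            S_OA = ini$S_OA)
    sab_simulate(forcing, days = config$run$days, y0 = y0,
                 kin = config$kin, micro = config$micro, chem = config$chem,
                 grid = config$run$grid_h, compute_rates = compute_rates)
  }
  final_day_metrics <- function(traj, label) {
    ds <- daily_summary(traj)
    last <- ds[nrow(ds), ]
    per <- detect_periodic_state(traj)
    data.frame(variant = label,
               mean_S_TOA = last$mean_S_TOA, min_pH = last$min_pH,
               median_pH = stats::median(final_day(traj)$pH),
               mean_aw = last$mean_aw,
               growth_per_day = per$growth_rate_per_day,
               periodic = per$periodic, extinct = traj$extinct,
               frac_cyano = last$frac_cyano, frac_hetero = last$frac_hetero,
               frac_pol = last$frac_pol, frac_cdb = last$frac_cdb)
  }
  if (scenario == "single_day") {
    traj <- run1(config$forcing, config$initial$f_H)
    metrics <- final_day_metrics(traj, "default")
    trajs <- list(default = traj)
  } else if (scenario == "ablation") {
    with_h <- run1(config$forcing, config$initial$f_H)
    without_h <- run1(config$forcing, 0)
    metrics <- rbind(final_day_metrics(with_h, "with_heterotrophs"),
                     final_day_metrics(without_h, "without_heterotrophs"))
    trajs <- list(with_heterotrophs = with_h, without_heterotrophs = without_h)
  } else {
    seasons <- c("summer", "spring", "autumn", "winter")
    trajs <- lapply(seasons, function(s) {
      run1(make_diel_forcing(season_preset(s),
                             config$environment$resolution_h),
           config$initial$f_H)
    })
    names(trajs) <- seasons
    metrics <- do.call(rbind, Map(final_day_metrics, trajs, seasons))
    rownames(metrics) <- NULL
  }
  structure(list(scenario = scenario, trajectories = trajs,
                 metrics = metrics, config = config),
            class = "sab_scenario")
}

#' @export
print.sab_scenario <- function(x, ...) {
  cat(sprintf("<sab_scenario '%s'> %d variant(s)\n", x$scenario,
              length(x$trajectories)))
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Extract the final simulated day of a trajectory
#'
#' @param traj an [sab_simulate()] trajectory.
#' @return the `derived` data frame restricted to the last full day, with
#'   an added `hour` column in \[0, 24\].
#' @export
final_day <- function(traj) {
  stopifnot(inherits(traj, "sab_trajectory"))
  per_day <- round(24 / traj$grid)
  n_days <- floor((length(traj$times) - 1) / per_day)
  idx <- ((n_days - 1) * per_day + 1):(n_days * per_day + 1)
  d <- traj$derived[idx, , drop = FALSE]
  d$hour <- d$t - (n_days - 1) * 24
  if (!is.null(traj$rates)) {
    d <- cbind(d, as.data.frame(traj$rates[idx, , drop = FALSE]))
  }
  d
}

#' Write trajectory outputs to a directory
#'
#' Writes `states.csv` (grid times, extensive states and derived intensive
#' diagnostics), `rates.csv` (process rates plus the name of the limiting
#' factor per process) and `summary.json` (periodicity report, growth per
#' day, daily pH / water-activity statistics, final composition fractions).
#' Output is deterministic: two runs of the same configuration give
#' byte-identical files.
#'
#' @param traj an [sab_simulate()] trajectory.
#' @param outdir output directory (created if needed).
#' @param config optional [sab_config()] echoed as `config.yaml`.
#' @return the directory path, invisibly.
#' @export
write_outputs <- function(traj, outdir, config = NULL) {
  stopifnot(inherits(traj, "sab_trajectory"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  states <- cbind(data.frame(time_h = traj$times), as.data.frame(traj$states),
                  traj$derived[setdiff(names(traj$derived), "t")])
  utils::write.csv(states, file.path(outdir, "states.csv"), row.names = FALSE)
  if (!is.null(traj$rates)) {
    lim <- traj$limiting
    colnames(lim) <- paste0("limiting_", colnames(lim))
    rates <- cbind(data.frame(time_h = traj$times), as.data.frame(traj$rates),
                   as.data.frame(lim))
    utils::write.csv(rates, file.path(outdir, "rates.csv"), row.names = FALSE)
  }
  per <- detect_periodic_state(traj)
  ds <- daily_summary(traj)
  summary <- list(
    periodic = per$periodic, day_reached = per$day_reached,
    growth_rate_per_day = per$growth_rate_per_day, extinct = traj$extinct,
    final_day = as.list(ds[nrow(ds), ]),
    n_days = nrow(ds)
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(config)) write_config(config, file.path(outdir, "config.yaml"))
  invisible(outdir)
}
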