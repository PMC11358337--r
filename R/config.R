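#' Assemble a full model configuration
#'
#' A configuration bundles every parameter block with run settings into one
#' validated object. Each block accepts a plain named list of overrides on
#' top of the package defaults; unknown keys are an error. Blocks:
#' `environment` (preset name or forcing CSV path and generator resolution),
#' `microclimate`, `chemistry` (pKa values accepted on the molar scale),
#' `kinetics`, `initial` (reference mass, heterotroph fraction, starting
#' quotas and concentrations) and `run` (days, output grid).
#'
#' @param environment,microclimate,chemistry,kinetics,initial,run named
#'   lists of overrides (may be empty).
#' @return an object of class `sab_config` with resolved parameter objects.
#' @export
#' @examples
#' cfg <- sab_config(environment = list(preset = "winter"),
#'                   run = list(days = 10))
sab_config <- function(environment = list(), microclimate = list(),
                       chemistry = list(), kinetics = list(),
                       initial = list(), run = list()) {
  env_defaults <- list(preset = "summer", forcing_csv = NULL,
                       resolution_h = 0.25)
  env <- merge_block(env_defaults, environment, "environment")
  init_defaults <- list(M0 = 1, f_H = 0.008, Q_SOC = 0.5, Q_N = 0.1,
                        Q_ATP = 0.01, Q_NADPH = 0.01, S_HCO3 = 2.4e-3,
                        S_TOA = 0, S_OA = 0)
  init <- merge_block(init_defaults, initial, "initial")
  run_defaults <- list(days = 40, grid_h = 0.1)
  run <- merge_block(run_defaults, run, "run")
  micro <- do.call(microclimate_params, normalize_micro(microclimate))
  chem <- do.call(chemistry_params, check_keys(chemistry,
                                               names(formals(chemistry_params)),
                                               "chemistry"))
  kin <- do.call(kinetic_params, check_keys(kinetics,
                                            names(formals(kinetic_params)),
                                            "kinetics"))
  forcing <- if (!is.null(env$forcing_csv)) {
    read_forcing_table(env$forcing_csv)
  } else {
    make_diel_forcing(season_preset(env$preset), env$resolution_h)
  }
  structure(list(environment = env, initial = init, run = run,
                 micro = micro, chem = chem, kin = kin, forcing = forcing),
            class = "sab_config")
}

check_keys <- function(x, allowed, block) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0)
    stop("unknown keys in [", block, "]: ", paste(unknown, collapse = ", "))
  x
}

merge_block <- function(defaults, overrides, block) {
  overrides <- check_keys(overrides, names(defaults), block)
  utils::modifyList(defaults, overrides, keep.null = TRUE)
}

# config-facing microclimate units: lambda in um, delta in mm
normalize_micro <- function(x) {
  x <- check_keys(x, c("b", "c", "lambda_um", "delta_mm", "k_a", "k_b"),
                  "microclimate")
  out <- x[intersect(names(x), c("b", "c", "k_a", "k_b"))]
  if (!is.null(x$lambda_um)) out$lambda <- x$lambda_um * 1e-6
  if (!is.null(x$delta_mm)) out$delta <- x$delta_mm * 1e-3
  out
}

#' Load a configuration from a YAML file
#'
#' Reads the file (empty files give the full default configuration), merges
#' each block over the defaults and validates every field. The resolved
#' configuration can be echoed back with [write_config()] and reloaded to
#' the identical object.
#'
#' @param path path to a YAML config file.
#' @return an [sab_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  blocks <- c("environment", "microclimate", "chemistry", "kinetics",
              "initial", "run")
  unknown <- setdiff(names(raw), blocks)
  if (length(unknown) > 0)
    stop("unknown config blocks: ", paste(unknown, collapse = ", "))
  args <- lapply(blocks, function(b) if (is.null(raw[[b]])) list() else raw[[b]])
  names(args) <- blocks
  do.call(sab_config, args)
}

#' Write the resolved configuration to YAML
#'
#' @param config an [sab_config()] object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sab_config"))
  micro <- config$micro
  out <- list(
    environment = config$environment[!vapply(config$environment, is.null,
                                             logical(1))],
    microclimate = list(b = micro$b, c = micro$c,
                        lambda_um = micro$lambda * 1e6,
                        delta_mm = micro$delta * 1e3,
                        k_a = micro$k_a, k_b = micro$k_b),
    chemistry = unclass(config$chem)[setdiff(names(config$chem),
                                             c("Ka_CO2", "Ka_OA"))],
    kinetics = unclass(config$kin),
    initial = config$initial,
    run = config$run
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
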