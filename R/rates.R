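#' Names of the metabolic processes, in stoichiometric-column order
#'
#' @return character vector of the 19 process names: 11 cyanobacterial
#'   (electron transport, fixation, growth, secretion, respiration, uptake,
#'   maintenance, decay) and 8 heterotrophic (scavenging, uptake,
#'   respiration, growth, maintenance, decay).
#' @export
process_names <- function() {
  c("r_nc", "r_cy", "r_fix", "r_photo", "r_Nfix", "r_C_growth", "r_POLprod",
    "r_C_resp", "r_C_uptake", "r_C_main", "r_C_d",
    "r_POL_scav", "r_CDB_scav", "r_NDB_scav", "r_H_uptake",
    "r_H_resp", "r_H_growth", "r_H_main", "r_H_d")
}

#' Cyanobacterial process rates and limitation diagnostics
#'
#' Evaluates every cyanobacterial rate `r_i = k_i M_C min(phi)` at one
#' instant. The non-cyclic chain carries the photoinhibited (Haldane) light
#' response, a water-activity ramp and carrier-capacity factors; the cyclic
#' chain adds a stress increment shaped by the water-activity tent; carbon
#' fixation and photorespiration share one limitation evaluation and split by
#' the branching function; respiration and organic-acid uptake carry a
#' darkness factor; maintenance and decay follow the ATP sufficiency rule.
#' All photosynthetic and growth rates are zero in darkness, and every rate
#' except decay is zero at or below the minimum viable water activity.
#'
#' @param M_C functional biomass \[mol C\].
#' @param Q_SOC,Q_N,Q_ATP,Q_NADPH cyanobacterial quotas.
#' @param S_TOA total organic-acid concentration \[mol C m-3\].
#' @param chem instantaneous chemistry from [derived_chemistry()].
#' @param I light intensity \[uE m-2 s-1\].
#' @param a_w water activity.
#' @param p an [kinetic_params()] object.
#' @return list with `rates` (named vector, 11 entries), `f` (combined
#'   limitation per process), `limiting` (argmin factor names), `g_fix`,
#'   `omega` (specific ATP production) and `sufficiency`.
#' @export
cyano_rates <- function(M_C, Q_SOC, Q_N, Q_ATP, Q_NADPH, S_TOA, chem, I, a_w,
                        p = kinetic_params()) {
  M_C <- unname(M_C); Q_SOC <- unname(Q_SOC); Q_N <- unname(Q_N)
  Q_ATP <- unname(Q_ATP); Q_NADPH <- unname(Q_NADPH); S_TOA <- unname(S_TOA)
  I <- unname(I); a_w <- unname(a_w)
  if (M_C < 0 || Q_SOC < 0 || Q_N < 0 || Q_ATP < 0 || Q_NADPH < 0 || S_TOA < 0)
    stop("cyanobacterial state must be non-negative")
  ramp <- aw_ramp(a_w, p$a_w_min)
  tent <- aw_tent(a_w, p$a_w_min, p$a_w_peak)
  L_haldane <- light_response(I, p$K_I, p$K_I_inh)
  L_monod <- light_response(I, p$K_I)
  dark <- darkness_response(I, p$K_I_dark)
  room_ATP <- quota_room(Q_ATP, p$Q_ATP_max)
  room_NADPH <- quota_room(Q_NADPH, p$Q_NADPH_max)
  room_SOC <- quota_room(Q_SOC, p$Q_SOC_max)
  room_N <- quota_room(Q_N, p$Q_N_max)
  mono_ATP <- monod(Q_ATP, p$K_ATP)
  mono_NADPH <- monod(Q_NADPH, p$K_NADPH)
  dro_SOC <- droop(Q_SOC, p$Q_SOC_min)
  dro_N <- droop(Q_N, p$Q_N_min)
  phi_pH <- ph_window(chem$pH, p$pH_L, p$pH_U)

  phis <- list(
    r_nc = c(a_w = ramp, light = L_haldane, ATP_room = room_ATP,
             NADPH_room = room_NADPH),
    r_cy = c(a_w = ramp, light = L_monod, ATP_room = room_ATP),
    r_fix = c(a_w = ramp, light = L_monod, DIC = monod(chem$S_DIC, p$K_DIC),
              ATP = mono_ATP, NADPH = mono_NADPH, SOC_room = room_SOC,
              pH = phi_pH),
    r_Nfix = c(a_w = ramp, ATP = mono_ATP, NADPH = mono_NADPH,
               N_room = room_N),
    r_C_growth = c(SOC = dro_SOC, N = dro_N, ATP = mono_ATP,
                   NADPH = mono_NADPH, light = L_monod, a_w = ramp),
    r_POLprod = c(a_w_tent = tent, SOC = dro_SOC),
    r_C_resp = c(a_w = ramp, darkness = dark, SOC = dro_SOC,
                 ATP_room = room_ATP),
    r_C_uptake = c(a_w = ramp, darkness = dark,
                   TOA = monod(S_TOA, p$K_TOA), SOC_room = room_SOC)
  )
  mins <- lapply(phis, function(v) {
    i <- which.min(v)
    list(f = v[[i]], limiting = names(v)[i])
  })
  f <- vapply(mins, `[[`, numeric(1), "f")
  limiting <- vapply(mins, `[[`, character(1), "limiting")

  g_fix <- branching_fraction(chem$S_O2, chem$S_DIC, p$gamma_spec)
  cy2 <- min(tent, L_monod, room_ATP)

  r <- c(
    r_nc = p$k_nc * M_C * f[["r_nc"]],
    r_cy = p$k_cy * M_C * f[["r_cy"]] + p$dk_cy * M_C * cy2,
    r_fix = g_fix * p$k_fix * M_C * f[["r_fix"]],
    r_photo = (1 - g_fix) * p$k_fix * M_C * f[["r_fix"]],
    r_Nfix = p$k_Nfix * M_C * f[["r_Nfix"]],
    r_C_growth = p$k_growth_C * M_C * f[["r_C_growth"]],
    r_POLprod = p$k_pol * M_C * f[["r_POLprod"]],
    r_C_resp = p$k_resp * M_C * f[["r_C_resp"]],
    r_C_uptake = p$k_uptake * M_C * f[["r_C_uptake"]]
  )

  omega <- if (M_C > 0) {
    (p$y_ATP_nc * r[["r_nc"]] + r[["r_cy"]] + p$y_ATP_resp * r[["r_C_resp"]]) / M_C
  } else 0
  f_star <- maintenance_requirement(a_w, p$m0, p$m1)
  md <- maintenance_and_decay(omega, f_star, Q_ATP, p$k_d, p$K_ATP)
  f_d <- if (p$strict_decay_gamma) p$k_d * min(1, md$sufficiency) else md$f_d
  r <- c(r, r_C_main = M_C * md$f_main, r_C_d = M_C * f_d)

  list(rates = r,
       f = c(f, r_photo = mins$r_fix$f, r_C_main = md$f_main, r_C_d = f_d),
       limiting = c(limiting, r_photo = mins$r_fix$limiting,
                    r_C_main = "ATP_budget", r_C_d = "ATP_budget"),
       g_fix = g_fix, omega = omega, sufficiency = md$sufficiency)
}

#' Heterotroph process rates and limitation diagnostics
#'
#' Scavenging of polysaccharides and decayed biomass saturates in the
#' biofilm-volume substrate concentration and carries the water-activity
#' ramp; organic-acid uptake saturates in `S_TOA`; respiration and growth are
#' limited by quotas as for cyanobacteria but with no light dependence
#' (heterotrophs work day and night); maintenance and decay follow the same
#' ATP sufficiency rule with `omega_H` from respiration alone.
#'
#' @param M_H functional biomass \[mol C\].
#' @param Q_SOC,Q_N,Q_ATP heterotroph quotas.
#' @param S_POL,S_CDB,S_NDB scavenging-substrate concentrations (masses over
#'   biofilm volume) \[mol m-3\].
#' @param S_TOA total organic-acid concentration \[mol C m-3\].
#' @param a_w water activity.
#' @param p an [kinetic_params()] object.
#' @return list with `rates` (named vector, 8 entries), `f`, `limiting`,
#'   `omega` and `sufficiency`, as for [cyano_rates()].
#' @export
hetero_rates <- function(M_H, Q_SOC, Q_N, Q_ATP, S_POL, S_CDB, S_NDB, S_TOA,
                         a_w, p = kinetic_params()) {
  M_H <- unname(M_H); Q_SOC <- unname(Q_SOC); Q_N <- unname(Q_N)
  Q_ATP <- unname(Q_ATP); S_POL <- unname(S_POL); S_CDB <- unname(S_CDB)
  S_NDB <- unname(S_NDB); S_TOA <- unname(S_TOA); a_w <- unname(a_w)
  if (M_H < 0 || Q_SOC < 0 || Q_N < 0 || Q_ATP < 0 ||
      S_POL < 0 || S_CDB < 0 || S_NDB < 0 || S_TOA < 0)
    stop("heterotroph state must be non-negative")
  ramp <- aw_ramp(a_w, p$a_w_min)
  room_SOC <- quota_room(Q_SOC, p$Q_SOC_max)
  room_N <- quota_room(Q_N, p$Q_N_max)
  room_ATP <- quota_room(Q_ATP, p$Q_ATP_max)
  mono_ATP <- monod(Q_ATP, p$K_ATP)
  dro_SOC <- droop(Q_SOC, p$Q_SOC_min)
  dro_N <- droop(Q_N, p$Q_N_min)

  phis <- list(
    r_POL_scav = c(a_w = ramp, POL = monod(S_POL, p$K_POL),
                   SOC_room = room_SOC),
    r_CDB_scav = c(a_w = ramp, CDB = monod(S_CDB, p$K_CDB),
                   SOC_room = room_SOC),
    r_NDB_scav = c(a_w = ramp, NDB = monod(S_NDB, p$K_NDB),
                   N_room = room_N),
    r_H_uptake = c(a_w = ramp, TOA = monod(S_TOA, p$K_TOA),
                   SOC_room = room_SOC),
    r_H_resp = c(a_w = ramp, SOC = dro_SOC, ATP_room = room_ATP),
    r_H_growth = c(SOC = dro_SOC, N = dro_N, ATP = mono_ATP, a_w = ramp)
  )
  mins <- lapply(phis, function(v) {
    i <- which.min(v)
    list(f = v[[i]], limiting = names(v)[i])
  })
  f <- vapply(mins, `[[`, numeric(1), "f")
  limiting <- vapply(mins, `[[`, character(1), "limiting")

  r <- c(
    r_POL_scav = p$k_scav * M_H * f[["r_POL_scav"]],
    r_CDB_scav = p$k_scav * M_H * f[["r_CDB_scav"]],
    r_NDB_scav = p$k_scav * M_H * f[["r_NDB_scav"]],
    r_H_uptake = p$k_uptake * M_H * f[["r_H_uptake"]],
    r_H_resp = p$k_resp * M_H * f[["r_H_resp"]],
    r_H_growth = p$k_growth_H * M_H * f[["r_H_growth"]]
  )
  omega <- if (M_H > 0) p$y_ATP_resp * r[["r_H_resp"]] / M_H else 0
  f_star <- maintenance_requirement(a_w, p$m0, p$m1)
  md <- maintenance_and_decay(omega, f_star, Q_ATP, p$k_d, p$K_ATP)
  f_d <- if (p$strict_decay_gamma) p$k_d * min(1, md$sufficiency) else md$f_d
  r <- c(r, r_H_main = M_H * md$f_main, r_H_d = M_H * f_d)

  list(rates = r,
       f = c(f, r_H_main = md$f_main, r_H_d = f_d),
       limiting = c(limiting, r_H_main = "ATP_budget", r_H_d = "ATP_budget"),
       omega = omega, sufficiency = md$sufficiency)
}

#' Largest water activity at which all water-limited metabolism is suppressed
#'
#' Scans water activity on a regular grid with every other limitation factor
#' (quotas, substrates, light, pH) held replete, and reports the largest
#' water activity at which every water-activity-limited process rate (both
#' guilds, ramp- and tent-shaped alike) is exactly zero. With the default
#' parameterization this is the minimum viable water activity.
#'
#' @param p an [kinetic_params()] object.
#' @param step grid step on \[0, 1\] (default 0.001).
#' @return list with `threshold` (water activity), `n_grid`, and the matrix
#'   of scanned specific rates.
#' @export
#' @examples
#' aw_suppression_threshold()$threshold
aw_suppression_threshold <- function(p = kinetic_params(), step = 0.001) {
  aw_grid <- seq(0, 1, by = step)
  ramp <- aw_ramp(aw_grid, p$a_w_min)
  tent <- aw_tent(aw_grid, p$a_w_min, p$a_w_peak)
  # every water-limited process at replete non-water factors
  rates <- cbind(
    r_nc = p$k_nc * ramp,
    r_cy = p$k_cy * ramp + p$dk_cy * tent,
    r_fix = p$k_fix * ramp,
    r_photo = p$k_fix * ramp,
    r_Nfix = p$k_Nfix * ramp,
    r_C_growth = p$k_growth_C * ramp,
    r_POLprod = p$k_pol * tent,
    r_C_resp = p$k_resp * ramp,
    r_C_uptake = p$k_uptake * ramp,
    r_POL_scav = p$k_scav * ramp,
    r_CDB_scav = p$k_scav * ramp,
    r_NDB_scav = p$k_scav * ramp,
    r_H_uptake = p$k_uptake * ramp,
    r_H_resp = p$k_resp * ramp,
    r_H_growth = p$k_growth_H * ramp
  )
  all_zero <- apply(rates == 0, 1, all)
  threshold <- max(aw_grid[all_zero])
  list(threshold = threshold, n_grid = length(aw_grid), rates = rates)
}
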