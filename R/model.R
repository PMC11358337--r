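#' Default initial extensive state
#'
#' Functional biomass is split 0.9 : 0.008 between cyanobacteria and
#' heterotrophs (relative to the reference mass `M0`), with a small equal
#' remainder assigned to polysaccharides and carbon decayed biomass;
#' quotas start mid-range and the dissolved pools near carbonate
#' equilibrium with the atmosphere. Cumulative gas-exchange trackers
#' (`G_CO2`, `G_O2`, `G_N2`) start at zero; they are bookkeeping states used
#' by the conservation audit, not part of the biofilm state proper.
#'
#' @param p an [kinetic_params()] object (supplies `rho` for the volume).
#' @param M0 reference total biomass \[mol C\].
#' @param f_H initial heterotroph fraction of `M0` (set 0 for the ablation
#'   variant).
#' @param Q_SOC,Q_N,Q_ATP,Q_NADPH initial quotas (both guilds).
#' @param S_HCO3,S_TOA,S_OA initial dissolved concentrations \[mol m-3\].
#' @return named numeric vector over [state_names()] plus the three `G_*`
#'   trackers.
#' @export
sab_initial_state <- function(p = kinetic_params(), M0 = 1, f_H = 0.008,
                              Q_SOC = 0.5, Q_N = 0.1, Q_ATP = 0.01,
                              Q_NADPH = 0.01,
                              S_HCO3 = 2.4e-3, S_TOA = 0, S_OA = 0) {
  stopifnot(M0 > 0, f_H >= 0, f_H < 1)
  M_C <- 0.9 * M0
  M_H <- f_H * M0
  rem <- max(M0 - M_C - M_H, 0)
  M_POL <- rem / 2
  M_CDB <- rem / 2
  M <- M_C * (1 + Q_SOC) + M_H * (1 + Q_SOC) + M_POL + M_CDB
  V <- M / p$rho
  y <- c(M_C = M_C, E_SOC_C = M_C * Q_SOC, E_N_C = M_C * Q_N,
         E_ATP_C = M_C * Q_ATP, E_NADPH_C = M_C * Q_NADPH,
         M_H = M_H, E_SOC_H = M_H * Q_SOC, E_N_H = M_H * Q_N,
         E_ATP_H = M_H * Q_ATP,
         M_POL = M_POL, M_CDB = M_CDB, M_NDB = 0.005 * M0,
         A_TOA = V * S_TOA, A_OA = V * S_OA, A_HCO3 = V * S_HCO3,
         G_CO2 = 0, G_O2 = 0, G_N2 = 0)
  y
}

#' Bundle model components for the right-hand side
#'
#' @param forcing an [sab_forcing()] object.
#' @param kin an [kinetic_params()] object.
#' @param micro an [microclimate_params()] object.
#' @param chem an [chemistry_params()] object.
#' @return a parameter environment for [sab_rhs()].
#' @export
sab_parms <- function(forcing, kin = kinetic_params(),
                      micro = microclimate_params(),
                      chem = chemistry_params()) {
  stopifnot(inherits(forcing, "sab_forcing"))
  K0 <- build_stoichiometry(kin)
  s <- forcing$samples
  ftab <- list(tt = c(s$time_h, s$time_h[1] + 24),
               vv = rbind(as.matrix(s[c("T_air_C", "T_stone_C", "RH_air",
                                        "light_uE")]),
                          as.numeric(s[1, c("T_air_C", "T_stone_C", "RH_air",
                                            "light_uE")])))
  Kn <- unclass(K0)
  # integer positions of the state-dependent entries (row + (col-1)*nrow)
  pos <- function(row, col) {
    match(row, rownames(Kn)) + (match(col, colnames(Kn)) - 1) * nrow(Kn)
  }
  idx <- list(
    hco3_fix = pos("A_HCO3", "r_fix"), co2_fix = pos("CO2_gas", "r_fix"),
    hco3_photo = pos("A_HCO3", "r_photo"), co2_photo = pos("CO2_gas", "r_photo"),
    oa_up_C = pos("A_OA", "r_C_uptake"), oa_up_H = pos("A_OA", "r_H_uptake"),
    d_soc_C = pos("E_SOC_C", "r_C_d"), d_n_C = pos("E_N_C", "r_C_d"),
    d_atp_C = pos("E_ATP_C", "r_C_d"), d_nadph_C = pos("E_NADPH_C", "r_C_d"),
    d_cdb_C = pos("M_CDB", "r_C_d"), d_ndb_C = pos("M_NDB", "r_C_d"),
    d_soc_H = pos("E_SOC_H", "r_H_d"), d_n_H = pos("E_N_H", "r_H_d"),
    d_atp_H = pos("E_ATP_H", "r_H_d"), d_cdb_H = pos("M_CDB", "r_H_d"),
    d_ndb_H = pos("M_NDB", "r_H_d")
  )
  Kbare <- Kn
  dimnames(Kbare) <- NULL
  list(forc = forcing_functions(forcing), kin = kin, micro = micro,
       chem = chem, K0 = Kn, Kbare = Kbare, kidx = idx, ftab = ftab,
       wa = micro$lambda * micro$k_a, wb = micro$delta * micro$k_b,
       comp = attr(K0, "composition"))
}

# linear periodic interpolation of all four forcing channels at scalar t
interp_forcing <- function(ftab, t) {
  tt <- ftab$tt
  tm <- (t - tt[1]) %% 24 + tt[1]
  i <- findInterval(tm, tt, rightmost.closed = TRUE)
  if (i >= length(tt)) i <- length(tt) - 1
  w <- (tm - tt[i]) / (tt[i + 1] - tt[i])
  ftab$vv[i, ] + w * (ftab$vv[i + 1, ] - ftab$vv[i, ])
}

#' Right-hand side of the biofilm ODE system
#'
#' Evaluates the environment, the algebraic chemistry (Henry saturations and
#' charge-balance pH), all 19 process rates, the state-dependent
#' stoichiometric columns and the acid-base kinetics, and returns
#' `dy/dt = K r` for the 15 extensive states plus the three cumulative
#' gas-exchange trackers. Small solver undershoots below zero are clipped
#' for rate evaluation. Suitable for direct use with deSolve integrators.
#'
#' This is a hand-inlined scalar evaluation of the same factor compositions
#' exposed by [cyano_rates()] and [hetero_rates()] (the two paths are held
#' equal by tests); the inlining keeps a multi-day stiff integration fast.
#'
#' @param t time \[h\].
#' @param y named state vector as from [sab_initial_state()].
#' @param parms from [sab_parms()].
#' @return list whose first element is the derivative vector.
#' @export
sab_rhs <- function(t, y, parms) {
  p <- parms$kin
  ch <- parms$chem
  mi <- parms$micro
  y <- pmax(y, 0)
  M_C <- y[1]; M_H <- y[6]
  M <- M_C + y[2] + M_H + y[7] + y[10] + y[11]
  V <- M / p$rho
  if (V <= 0) return(list(numeric(18)))

  env <- interp_forcing(parms$ftab, t)
  T_a <- env[1]; T_s <- env[2]
  RH_a <- min(max(env[3], 0), 1)
  I <- max(env[4], 0)
  T_star <- (T_a * parms$wa + T_s * parms$wb) / (parms$wa + parms$wb)
  a_w <- RH_a * exp(mi$b * T_a / (mi$c + T_a) - mi$b * T_star / (mi$c + T_star))
  a_w <- min(max(a_w, 0), 1)

  if (M_C > 1e-12) {
    Q_SOC_C <- y[2] / M_C; Q_N_C <- y[3] / M_C
    Q_ATP_C <- y[4] / M_C; Q_NADPH_C <- y[5] / M_C
  } else Q_SOC_C <- Q_N_C <- Q_ATP_C <- Q_NADPH_C <- 0
  if (M_H > 1e-12) {
    Q_SOC_H <- y[7] / M_H; Q_N_H <- y[8] / M_H; Q_ATP_H <- y[9] / M_H
  } else Q_SOC_H <- Q_N_H <- Q_ATP_H <- 0

  S_TOA <- y[13] / V
  S_OA <- min(y[14] / V, S_TOA)
  S_HCO3 <- y[15] / V
  T_K <- T_star + 273.15
  S_CO2 <- p_henry(ch$KH_CO2_ref, ch$vantHoff_CO2, T_K, ch$T_ref, ch$pCO2)
  S_O2 <- p_henry(ch$KH_O2_ref, ch$vantHoff_O2, T_K, ch$T_ref, ch$pO2)
  S_DIC <- S_CO2 + S_HCO3
  B <- S_HCO3 + S_OA + ch$S_An - ch$S_Cat
  S_H <- (B + sqrt(B * B + 4 * ch$Kw)) / 2
  pH <- -log10(S_H / 1000)

  # limitation primitives (inline scalar forms of the exported factors)
  ramp <- min(max((a_w - p$a_w_min) / (1 - p$a_w_min), 0), 1)
  tent <- min(max(min((a_w - p$a_w_min) / (p$a_w_peak - p$a_w_min),
                      (1 - a_w) / (1 - p$a_w_peak)), 0), 1)
  L_mono <- I / (p$K_I + I)
  I_opt <- sqrt(p$K_I * p$K_I_inh)
  L_hald <- min((I / (p$K_I + I + I * I / p$K_I_inh)) /
                  (I_opt / (p$K_I + I_opt + I_opt * I_opt / p$K_I_inh)), 1)
  dark <- p$K_I_dark / (p$K_I_dark + I)
  half <- (p$pH_U - p$pH_L) / 2
  phi_pH <- min(max((pH - p$pH_L) * (p$pH_U - pH) / (half * half), 0), 1)
  room_ATP <- min(max(1 - Q_ATP_C / p$Q_ATP_max, 0), 1)
  room_NADPH <- min(max(1 - Q_NADPH_C / p$Q_NADPH_max, 0), 1)
  room_SOC <- min(max(1 - Q_SOC_C / p$Q_SOC_max, 0), 1)
  room_N <- min(max(1 - Q_N_C / p$Q_N_max, 0), 1)
  mono_ATP <- Q_ATP_C / (p$K_ATP + Q_ATP_C)
  mono_NADPH <- Q_NADPH_C / (p$K_NADPH + Q_NADPH_C)
  dro_SOC <- if (Q_SOC_C <= 0) 0 else min(max(1 - p$Q_SOC_min / Q_SOC_C, 0), 1)
  dro_N <- if (Q_N_C <= 0) 0 else min(max(1 - p$Q_N_min / Q_N_C, 0), 1)

  g_fix <- if (S_DIC <= 0) 0 else 1 / (1 + p$gamma_spec * S_O2 / S_DIC)
  f_fix <- min(ramp, L_mono, S_DIC / (p$K_DIC + S_DIC), mono_ATP, mono_NADPH,
               room_SOC, phi_pH)

  r <- numeric(19)
  r[1] <- p$k_nc * M_C * min(ramp, L_hald, room_ATP, room_NADPH)
  r[2] <- p$k_cy * M_C * min(ramp, L_mono, room_ATP) +
    p$dk_cy * M_C * min(tent, L_mono, room_ATP)
  r[3] <- g_fix * p$k_fix * M_C * f_fix
  r[4] <- (1 - g_fix) * p$k_fix * M_C * f_fix
  r[5] <- p$k_Nfix * M_C * min(ramp, mono_ATP, mono_NADPH, room_N)
  r[6] <- p$k_growth_C * M_C *
    min(dro_SOC, dro_N, mono_ATP, mono_NADPH, L_mono, ramp)
  r[7] <- p$k_pol * M_C * min(tent, dro_SOC)
  r[8] <- p$k_resp * M_C * min(ramp, dark, dro_SOC, room_ATP)
  r[9] <- p$k_uptake * M_C *
    min(ramp, dark, S_TOA / (p$K_TOA + S_TOA), room_SOC)

  f_star <- p$m0 + p$m1 * (1 - a_w)
  omega_C <- if (M_C > 0) (p$y_ATP_nc * r[1] + r[2] + p$y_ATP_resp * r[8]) / M_C else 0
  sigma_C <- Q_ATP_C / (p$K_ATP + Q_ATP_C)
  s_C <- if (f_star > 0) min(1, (omega_C / f_star) * sigma_C) else 1
  r[10] <- M_C * (if (s_C >= 1) f_star else omega_C * sigma_C)
  f_d_C <- if (p$strict_decay_gamma) p$k_d * min(1, s_C) else p$k_d * (1 - s_C)
  r[11] <- M_C * f_d_C

  room_SOC_H <- min(max(1 - Q_SOC_H / p$Q_SOC_max, 0), 1)
  room_N_H <- min(max(1 - Q_N_H / p$Q_N_max, 0), 1)
  room_ATP_H <- min(max(1 - Q_ATP_H / p$Q_ATP_max, 0), 1)
  mono_ATP_H <- Q_ATP_H / (p$K_ATP + Q_ATP_H)
  dro_SOC_H <- if (Q_SOC_H <= 0) 0 else min(max(1 - p$Q_SOC_min / Q_SOC_H, 0), 1)
  dro_N_H <- if (Q_N_H <= 0) 0 else min(max(1 - p$Q_N_min / Q_N_H, 0), 1)
  S_POL <- y[10] / V; S_CDB <- y[11] / V; S_NDB <- y[12] / V

  r[12] <- p$k_scav * M_H * min(ramp, S_POL / (p$K_POL + S_POL), room_SOC_H)
  r[13] <- p$k_scav * M_H * min(ramp, S_CDB / (p$K_CDB + S_CDB), room_SOC_H)
  r[14] <- p$k_scav * M_H * min(ramp, S_NDB / (p$K_NDB + S_NDB), room_N_H)
  r[15] <- p$k_uptake * M_H *
    min(ramp, S_TOA / (p$K_TOA + S_TOA), room_SOC_H)
  r[16] <- p$k_resp * M_H * min(ramp, dro_SOC_H, room_ATP_H)
  r[17] <- p$k_growth_H * M_H * min(dro_SOC_H, dro_N_H, mono_ATP_H, ramp)
  omega_H <- if (M_H > 0) p$y_ATP_resp * r[16] / M_H else 0
  sigma_H <- Q_ATP_H / (p$K_ATP + Q_ATP_H)
  s_H <- if (f_star > 0) min(1, (omega_H / f_star) * sigma_H) else 1
  r[18] <- M_H * (if (s_H >= 1) f_star else omega_H * sigma_H)
  f_d_H <- if (p$strict_decay_gamma) p$k_d * min(1, s_H) else p$k_d * (1 - s_H)
  r[19] <- (if (p$strict_hetero_decay_mass) M_C else M_H) * f_d_H

  beta <- if (S_DIC > 0) S_HCO3 / S_DIC else 0
  alpha <- if (S_TOA > 0) S_OA / S_TOA else 0
  K <- parms$Kbare
  i <- parms$kidx
  K[i$hco3_fix] <- -beta;   K[i$co2_fix] <- -(1 - beta)
  K[i$hco3_photo] <- -beta; K[i$co2_photo] <- -(1 - beta)
  K[i$oa_up_C] <- -alpha;   K[i$oa_up_H] <- -alpha
  K[i$d_soc_C] <- -Q_SOC_C; K[i$d_n_C] <- -Q_N_C
  K[i$d_atp_C] <- -Q_ATP_C; K[i$d_nadph_C] <- -Q_NADPH_C
  K[i$d_cdb_C] <- 1 + Q_SOC_C; K[i$d_ndb_C] <- Q_N_C + p$q_N_bio
  K[i$d_soc_H] <- -Q_SOC_H; K[i$d_n_H] <- -Q_N_H
  K[i$d_atp_H] <- -Q_ATP_H
  K[i$d_cdb_H] <- 1 + Q_SOC_H; K[i$d_ndb_H] <- Q_N_H + p$q_N_bio

  dy <- drop(K %*% r)

  r_hyd <- ch$k_AB_CO2 * (S_CO2 - S_H * S_HCO3 / ch$Ka_CO2)
  r_oa <- ch$k_AB_OA * (S_OA * (ch$Ka_OA + S_H) - ch$Ka_OA * S_TOA)
  dy[15] <- dy[15] + V * r_hyd # A_HCO3
  dy[14] <- dy[14] - V * r_oa  # A_OA
  dy[16] <- dy[16] - V * r_hyd # CO2_gas tracker

  if (any(!is.finite(dy)))
    stop("non-finite derivative at t = ", t, "; state: ",
         paste(sprintf("%.3g", y), collapse = ", "))
  list(dy)
}

# Henry's law with van 't Hoff temperature correction (scalar hot path)
p_henry <- function(KH_ref, vH, T_K, T_ref, pgas) {
  KH_ref * exp(vH * (1 / T_K - 1 / T_ref)) * pgas
}

# flat parameter vector for the compiled right-hand side; the order must
# match the #define block in src/sabrhs.c
flat_parms <- function(kin, chem, micro, extinct_mass) {
  p <- kin
  ch <- chem
  c(p$k_nc, p$k_cy, p$dk_cy, p$k_fix, p$k_Nfix, p$k_growth_C, p$k_growth_H,
    p$k_pol, p$k_resp, p$k_uptake, p$k_scav, p$gamma_spec, p$K_I, p$K_I_inh,
    p$K_I_dark, p$K_DIC, p$K_TOA, p$K_POL, p$K_CDB, p$K_NDB,
    p$Q_SOC_min, p$Q_SOC_max, p$Q_N_min, p$Q_N_max, p$Q_ATP_max,
    p$Q_NADPH_max, p$K_ATP, p$K_NADPH, p$a_w_min, p$a_w_peak, p$pH_L, p$pH_U,
    p$m0, p$m1, p$k_d, p$rho, p$q_N_bio,
    p$y_ATP_nc, p$y_ATP_fix, p$y_NADPH_fix, p$y_ATP_Nfix, p$y_NADPH_Nfix,
    p$y_ATP_growth, p$y_NADPH_growth, p$y_ATP_pol, p$y_ATP_resp, p$y_ATP_scav,
    as.numeric(p$strict_hetero_decay_mass), as.numeric(p$strict_decay_gamma),
    ch$KH_CO2_ref, ch$vantHoff_CO2, ch$KH_O2_ref, ch$vantHoff_O2, ch$T_ref,
    ch$pCO2, ch$pO2, ch$Ka_CO2, ch$k_AB_CO2, ch$Ka_OA, ch$k_AB_OA, ch$Kw,
    ch$S_An, ch$S_Cat,
    micro$b, micro$c, micro$lambda * micro$k_a, micro$delta * micro$k_b,
    extinct_mass)
}

# periodic forcing unrolled over the simulation span for the compiled model
unroll_forcings <- function(forcing, days) {
  s <- forcing$samples
  tt <- s$time_h
  t_all <- as.numeric(outer(tt, 24 * (0:(days - 1)), "+"))
  t_all <- c(t_all, days * 24)
  chans <- c("T_air_C", "T_stone_C", "RH_air", "light_uE")
  lapply(chans, function(ch) {
    v <- rep(s[[ch]], days)
    cbind(t_all, c(v, s[[ch]][1]))
  })
}

#' Simulate the biofilm over repeated forcing days
#'
#' Adaptive stiff integration (deSolve `lsodar`) of the extensive state over
#' `days` repetitions of the 24 h forcing, with output on a fixed grid.
#' Integration terminates early with an extinction flag if the living
#' biomass (functional plus stored carbon, both guilds) falls below `1e-6`
#' of the initial total mass. Quotas,
#' concentrations, pH, water activity, process rates and per-process
#' limiting-factor names are recomputed on the output grid.
#'
#' @param forcing an [sab_forcing()] object.
#' @param days number of simulated days.
#' @param y0 initial state; defaults to [sab_initial_state()].
#' @param kin,micro,chem parameter objects.
#' @param grid output time step \[h\] (default 0.1; must divide 24).
#' @param rtol,atol solver tolerances.
#' @param compute_rates recompute diagnostic rates on the output grid
#'   (default `TRUE`).
#' @param engine `"compiled"` (default) integrates the C right-hand side;
#'   `"R"` integrates the reference [sab_rhs()] (slower, same model — the
#'   two are held equal by tests).
#' @return an object of class `sab_trajectory`: list with `times`, `states`
#'   (matrix), `derived` (data frame of intensive diagnostics), `rates`
#'   (matrix), `limiting` (character matrix), `extinct` flag, and the
#'   parameter objects.
#' @export
sab_simulate <- function(forcing, days = 40, y0 = NULL,
                         kin = kinetic_params(),
                         micro = microclimate_params(),
                         chem = chemistry_params(),
                         grid = 0.1, rtol = 1e-6, atol = NULL,
                         compute_rates = TRUE,
                         engine = c("compiled", "R")) {
  engine <- match.arg(engine)
  stopifnot(days >= 1, grid > 0)
  if (abs(24 / grid - round(24 / grid)) > 1e-9)
    stop("grid must divide 24 h evenly")
  parms <- sab_parms(forcing, kin, micro, chem)
  if (is.null(y0)) y0 <- sab_initial_state(kin)
  M0 <- y0[["M_C"]] + y0[["E_SOC_C"]] + y0[["M_H"]] + y0[["E_SOC_H"]] +
    y0[["M_POL"]] + y0[["M_CDB"]]
  if (is.null(atol)) {
    atol <- c(rep(1e-10 * max(M0, 1e-6), 12), rep(1e-16, 3), rep(1e-10, 3))
  }
  times <- seq(0, days * 24, by = grid)
  if (engine == "compiled") {
    sol <- deSolve::lsodar(y = y0, times = times, func = "sab_derivs",
                           parms = flat_parms(kin, chem, micro, 1e-6 * M0),
                           dllname = "sabsim", initfunc = "sab_init",
                           initforc = "sab_forc",
                           forcings = unroll_forcings(forcing, days),
                           rootfunc = "sab_root", nroot = 1,
                           rtol = rtol, atol = atol, maxsteps = 50000)
  } else {
    rootfun <- function(t, y, parms_) {
      # living biomass only: decayed pools are inert and cannot sustain a film
      y[["M_C"]] + y[["E_SOC_C"]] + y[["M_H"]] + y[["E_SOC_H"]] - 1e-6 * M0
    }
    sol <- deSolve::lsodar(y = y0, times = times, func = sab_rhs,
                           parms = parms, rtol = rtol, atol = atol,
                           rootfunc = rootfun, maxsteps = 50000)
  }
  extinct <- !is.null(attr(sol, "troot")) && length(attr(sol, "troot")) > 0
  times_out <- sol[, "time"]
  states <- sol[, names(y0), drop = FALSE]

  traj <- structure(list(times = times_out, states = states,
                         extinct = extinct, grid = grid,
                         forcing = forcing, kin = kin, micro = micro,
                         chem = chem),
                    class = "sab_trajectory")
  traj$derived <- trajectory_derived(traj, parms)
  if (compute_rates) {
    rl <- trajectory_rates(traj, parms)
    traj$rates <- rl$rates
    traj$limiting <- rl$limiting
  }
  traj
}

# intensive diagnostics on the output grid (vectorized)
trajectory_derived <- function(traj, parms) {
  y <- traj$states
  p <- traj$kin
  t <- traj$times
  M_C <- pmax(y[, "M_C"], 0); M_H <- pmax(y[, "M_H"], 0)
  M <- M_C + pmax(y[, "E_SOC_C"], 0) + M_H + pmax(y[, "E_SOC_H"], 0) +
    pmax(y[, "M_POL"], 0) + pmax(y[, "M_CDB"], 0)
  V <- M / p$rho
  safe_q <- function(E, Mb) ifelse(Mb > 1e-12, pmax(E, 0) / Mb, 0)
  T_a <- parms$forc$T_a(t); T_s <- parms$forc$T_s(t)
  RH_a <- pmin(pmax(parms$forc$RH_a(t), 0), 1)
  I <- pmax(parms$forc$I(t), 0)
  T_star <- interface_temperature(T_a, T_s, traj$micro)
  a_w <- water_activity(RH_a, T_a, T_star, traj$micro)
  S_TOA <- ifelse(V > 0, pmax(y[, "A_TOA"], 0) / V, 0)
  S_OA <- pmin(ifelse(V > 0, pmax(y[, "A_OA"], 0) / V, 0), S_TOA)
  S_HCO3 <- ifelse(V > 0, pmax(y[, "A_HCO3"], 0) / V, 0)
  ch <- derived_chemistry(S_HCO3, S_OA, T_star, a_w, traj$chem)
  data.frame(
    t = t, T_a = T_a, T_s = T_s, RH_a = RH_a, I = I, T_star = T_star,
    a_w = a_w, M = M, V = V,
    Q_SOC_C = safe_q(y[, "E_SOC_C"], M_C), Q_N_C = safe_q(y[, "E_N_C"], M_C),
    Q_ATP_C = safe_q(y[, "E_ATP_C"], M_C),
    Q_NADPH_C = safe_q(y[, "E_NADPH_C"], M_C),
    Q_SOC_H = safe_q(y[, "E_SOC_H"], M_H), Q_N_H = safe_q(y[, "E_N_H"], M_H),
    Q_ATP_H = safe_q(y[, "E_ATP_H"], M_H),
    S_TOA = S_TOA, S_OA = S_OA, S_HCO3 = S_HCO3,
    S_CO2 = ch$S_CO2, S_O2 = ch$S_O2, S_DIC = ch$S_DIC, pH = ch$pH
  )
}

# per-grid-point process rates + limiting factors (loop; diagnostics only)
trajectory_rates <- function(traj, parms) {
  n <- length(traj$times)
  pn <- process_names()
  rates <- matrix(0, n, length(pn), dimnames = list(NULL, pn))
  limiting <- matrix(NA_character_, n, length(pn), dimnames = list(NULL, pn))
  p <- traj$kin
  d <- traj$derived
  y <- traj$states
  for (i in seq_len(n)) {
    if (d$V[i] <= 0) next
    chem_i <- list(S_CO2 = d$S_CO2[i], S_O2 = d$S_O2[i], S_DIC = d$S_DIC[i],
                   pH = d$pH[i])
    cyr <- cyano_rates(max(y[i, "M_C"], 0), d$Q_SOC_C[i], d$Q_N_C[i],
                       d$Q_ATP_C[i], d$Q_NADPH_C[i], d$S_TOA[i], chem_i,
                       d$I[i], d$a_w[i], p)
    her <- hetero_rates(max(y[i, "M_H"], 0), d$Q_SOC_H[i], d$Q_N_H[i],
                        d$Q_ATP_H[i],
                        max(y[i, "M_POL"], 0) / d$V[i],
                        max(y[i, "M_CDB"], 0) / d$V[i],
                        max(y[i, "M_NDB"], 0) / d$V[i],
                        d$S_TOA[i], d$a_w[i], p)
    r <- c(cyr$rates, her$rates)
    if (p$strict_hetero_decay_mass)
      r[["r_H_d"]] <- max(y[i, "M_C"], 0) * her$f[["r_H_d"]]
    rates[i, ] <- r[pn]
    lim <- c(cyr$limiting, her$limiting)
    limiting[i, ] <- lim[pn]
  }
  list(rates = rates, limiting = limiting)
}

#' @export
print.sab_trajectory <- function(x, ...) {
  days <- max(x$times) / 24
  cat(sprintf("<sab_trajectory> %.1f days on a %.2g h grid%s\n", days, x$grid,
              if (x$extinct) " (terminated: extinction)" else ""))
  per <- detect_periodic_state(x)
  cat(sprintf("  periodic: %s (day %s), daily growth factor %.4f\n",
              per$periodic, ifelse(is.na(per$day_reached), "-", per$day_reached),
              per$growth_rate_per_day))
  invisible(x)
}

#' Detect the diel periodic state of a trajectory
#'
#' Compares consecutive daily profiles of all intensive variables (quotas,
#' dissolved concentrations, pH) in relative supremum norm; biomasses are
#' excluded, since at the periodic state they change by a constant daily
#' factor, which is reported separately. A day counts as periodic when its
#' profile is within `tol` of the previous day's for every variable.
#'
#' @param traj an [sab_simulate()] trajectory of at least 2 days.
#' @param tol relative tolerance (default 1e-3).
#' @return list with `periodic` (logical), `day_reached` (first day from
#'   which all subsequent days are within tolerance; `NA` if none),
#'   `growth_rate_per_day` (total solid-phase mass ratio over the final
#'   day) and `distance` (per-day profile distances).
#' @export
detect_periodic_state <- function(traj, tol = 1e-3) {
  stopifnot(inherits(traj, "sab_trajectory"))
  d <- traj$derived
  per_day <- round(24 / traj$grid)
  n_days <- floor((length(traj$times) - 1) / per_day)
  if (n_days < 2 || traj$extinct) {
    gr <- NA_real_
    if (n_days >= 1) {
      M <- d$M
      gr <- M[1 + n_days * per_day] / M[1 + (n_days - 1) * per_day]
    }
    return(list(periodic = FALSE, day_reached = NA_integer_,
                growth_rate_per_day = gr,
                distance = numeric(0), extinct = traj$extinct))
  }
  vars <- c("Q_SOC_C", "Q_N_C", "Q_ATP_C", "Q_NADPH_C",
            "Q_SOC_H", "Q_N_H", "Q_ATP_H",
            "S_TOA", "S_OA", "S_HCO3", "pH")
  X <- as.matrix(d[vars])
  scale <- pmax(apply(abs(X), 2, max), 1e-9)
  dist <- numeric(n_days - 1)
  for (day in 2:n_days) {
    i1 <- ((day - 2) * per_day + 1):((day - 1) * per_day)
    i2 <- ((day - 1) * per_day + 1):(day * per_day)
    dist[day - 1] <- max(abs(t(X[i2, , drop = FALSE] - X[i1, , drop = FALSE])) / scale)
  }
  ok <- dist < tol
  day_reached <- if (any(rev(cumprod(rev(ok))) == 1)) {
    1 + min(which(rev(cumprod(rev(ok))) == 1))
  } else NA_integer_
  M <- d$M
  gr <- M[1 + n_days * per_day] / M[1 + (n_days - 1) * per_day]
  list(periodic = isTRUE(ok[length(ok)]), day_reached = day_reached,
       growth_rate_per_day = gr, distance = dist, extinct = traj$extinct)
}

#' Per-day summary of a trajectory
#'
#' @param traj an [sab_simulate()] trajectory.
#' @return data frame with one row per simulated day: mean/min/max of pH and
#'   water activity, daily growth factor of total solid-phase mass, and
#'   end-of-day composition fractions (cyanobacteria and heterotrophs with
#'   their stored carbon, polysaccharides, decayed biomass).
#' @export
daily_summary <- function(traj) {
  stopifnot(inherits(traj, "sab_trajectory"))
  d <- traj$derived
  y <- traj$states
  per_day <- round(24 / traj$grid)
  n_days <- floor((length(traj$times) - 1) / per_day)
  out <- vector("list", n_days)
  for (day in seq_len(n_days)) {
    idx <- ((day - 1) * per_day + 1):(day * per_day + 1)
    last <- idx[length(idx)]
    M <- d$M[last]
    out[[day]] <- data.frame(
      day = day,
      mean_pH = mean(d$pH[idx]), min_pH = min(d$pH[idx]),
      max_pH = max(d$pH[idx]),
      mean_aw = mean(d$a_w[idx]), min_aw = min(d$a_w[idx]),
      max_aw = max(d$a_w[idx]),
      mean_S_TOA = mean(d$S_TOA[idx]),
      growth_factor = d$M[last] / d$M[idx[1]],
      frac_cyano = (y[last, "M_C"] + y[last, "E_SOC_C"]) / M,
      frac_hetero = (y[last, "M_H"] + y[last, "E_SOC_H"]) / M,
      frac_pol = y[last, "M_POL"] / M,
      frac_cdb = y[last, "M_CDB"] / M
    )
  }
  do.call(rbind, out)
}
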