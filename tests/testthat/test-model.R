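test_that("compiled and reference right-hand sides agree at random states", {
  f <- summer_forcing()
  parms <- sab_parms(f)
  y0 <- sab_initial_state()
  pvec <- sabsim:::flat_parms(kinetic_params(), chemistry_params(),
                              microclimate_params(), 1e-6)
  fc <- sabsim:::unroll_forcings(f, 3)
  set.seed(42)
  for (k in 1:100) {
    y <- y0 * exp(runif(18, -1.5, 1.5))
    y[16:18] <- 0
    tt <- runif(1, 0, 72)
    dyR <- sab_rhs(tt, y, parms)[[1]]
    dyC <- deSolve::DLLfunc(y = y, times = tt, func = "sab_derivs",
                            parms = pvec, dllname = "sabsim",
                            initfunc = "sab_init", initforc = "sab_forc",
                            forcings = fc)$dy
    expect_equal(unname(dyC), unname(dyR), tolerance = 1e-9)
  }
})

test_that("the reference derivative matches the rich diagnostic path", {
  # sab_rhs inlines the factor compositions; rebuild the same derivative from
  # the exported cyano_rates / hetero_rates / build_stoichiometry surface
  f <- summer_forcing()
  parms <- sab_parms(f)
  y0 <- sab_initial_state()
  p <- kinetic_params(); chp <- chemistry_params(); mic <- microclimate_params()
  set.seed(43)
  for (k in 1:30) {
    y <- y0 * exp(runif(18, -1, 1)); y[16:18] <- 0
    tt <- runif(1, 0, 48)
    yc <- pmax(unname(y), 0)
    M_C <- yc[1]; M_H <- yc[6]
    M <- M_C + yc[2] + M_H + yc[7] + yc[10] + yc[11]
    V <- M / p$rho
    es <- sample_forcing(f, tt)
    Ts <- interface_temperature(es$T_a, es$T_s, mic)
    aw <- water_activity(es$RH_a, es$T_a, Ts, mic)
    S_TOA <- yc[13] / V; S_OA <- min(yc[14] / V, S_TOA); S_HCO3 <- yc[15] / V
    ch <- derived_chemistry(S_HCO3, S_OA, Ts, aw, chp)
    qC <- list(Q_SOC = yc[2] / M_C, Q_N = yc[3] / M_C, Q_ATP = yc[4] / M_C,
               Q_NADPH = yc[5] / M_C)
    qH <- list(Q_SOC = yc[7] / M_H, Q_N = yc[8] / M_H, Q_ATP = yc[9] / M_H)
    cyr <- cyano_rates(M_C, qC$Q_SOC, qC$Q_N, qC$Q_ATP, qC$Q_NADPH, S_TOA,
                       ch, es$I, aw, p)
    her <- hetero_rates(M_H, qH$Q_SOC, qH$Q_N, qH$Q_ATP, yc[10] / V,
                        yc[11] / V, yc[12] / V, S_TOA, aw, p)
    K <- build_stoichiometry(p, qC, qH,
                             beta_HCO3 = S_HCO3 / ch$S_DIC,
                             alpha_OA = if (S_TOA > 0) S_OA / S_TOA else 0)
    dy_ref <- drop(unclass(K) %*% c(cyr$rates, her$rates))
    r_hyd <- co2_hydration_rate(ch$S_CO2, ch$S_H, S_HCO3, chp)
    r_oa <- oa_dissociation_rate(S_TOA, S_OA, ch$S_H, chp)
    dy_ref[15] <- dy_ref[15] + V * r_hyd
    dy_ref[14] <- dy_ref[14] - V * r_oa
    dy_ref[16] <- dy_ref[16] - V * r_hyd
    dy <- sab_rhs(tt, y, parms)[[1]]
    expect_equal(unname(dy), unname(dy_ref), tolerance = 1e-8)
  }
})

test_that("an abiotic system only relaxes bicarbonate toward equilibrium", {
  f <- constant_forcing(T_a = 20, T_s = 20, RH = 0.8)
  parms <- sab_parms(f)
  y <- sab_initial_state() * 0
  y[["M_POL"]] <- 1e-3 # tiny inert solid so the volume is defined
  dy <- sab_rhs(1, y, parms)[[1]]
  nz <- which(abs(dy) > 0)
  expect_true(all(names(sab_initial_state())[nz] %in% c("A_HCO3", "G_CO2")))
  expect_gt(dy[15], 0) # hydration fills the empty bicarbonate pool
})

test_that("a permanently dry film can only lose biomass", {
  f <- constant_forcing(T_a = 20, T_s = 20, RH = 0, I = 500)
  parms <- sab_parms(f)
  y0 <- sab_initial_state()
  dy <- sab_rhs(1, y0, parms)[[1]]
  expect_lt(dy[1], 0) # M_C decays
  expect_lt(dy[6], 0) # M_H decays
  expect_gt(dy[11], 0) # decayed biomass accumulates
})

test_that("carbon and nitrogen are conserved against the virtual gas ledger", {
  traj <- sab_simulate(summer_forcing(), days = 3, compute_rates = FALSE)
  y <- traj$states
  p <- kinetic_params()
  Ctot <- y[, "M_C"] + y[, "E_SOC_C"] + y[, "M_H"] + y[, "E_SOC_H"] +
    y[, "M_POL"] + y[, "M_CDB"] + y[, "A_TOA"] + y[, "A_HCO3"]
  consC <- Ctot + y[, "G_CO2"]
  expect_lt(max(abs(consC - consC[1])) / consC[1], 1e-5) # 10x solver rtol
  Ntot <- y[, "E_N_C"] + y[, "E_N_H"] + y[, "M_NDB"] +
    p$q_N_bio * (y[, "M_C"] + y[, "M_H"])
  consN <- Ntot + y[, "G_N2"]
  expect_lt(max(abs(consN - consN[1])) / consN[1], 1e-5)
})

test_that("states stay non-negative and quotas within bounds along a run", {
  traj <- sab_simulate(summer_forcing(), days = 4, compute_rates = FALSE)
  expect_true(all(traj$states[, 1:15] > -1e-9))
  d <- traj$derived
  p <- kinetic_params()
  expect_true(all(d$Q_SOC_C <= p$Q_SOC_max + 1e-6))
  expect_true(all(d$Q_ATP_C <= p$Q_ATP_max + 1e-6))
  expect_true(all(d$a_w >= 0 & d$a_w <= 1))
})

test_that("removing the heterotroph seed keeps the guild at exactly zero", {
  y0 <- sab_initial_state(f_H = 0)
  traj <- sab_simulate(summer_forcing(), days = 3, y0 = y0,
                       compute_rates = FALSE)
  h_states <- traj$states[, c("M_H", "E_SOC_H", "E_N_H", "E_ATP_H")]
  expect_true(all(h_states == 0))
})

test_that("bicarbonate tracks quasi-equilibrium when acid-base kinetics are fast", {
  ch <- chemistry_params(k_AB_CO2 = 1e6, k_AB_OA = 1e6)
  traj <- sab_simulate(summer_forcing(), days = 2, chem = ch,
                       compute_rates = FALSE)
  d <- traj$derived
  idx <- d$t > 12 # past the initial relaxation
  S_eq <- d$S_CO2[idx] * ch$Ka_CO2 / (10^(-d$pH[idx]) * 1000)
  expect_lt(max(abs(d$S_HCO3[idx] - S_eq) / S_eq), 0.01)
})

test_that("volume scales inversely with biofilm density", {
  y0 <- sab_initial_state()
  t1 <- sab_simulate(summer_forcing(), days = 1, y0 = y0,
                     compute_rates = FALSE)
  t2 <- sab_simulate(summer_forcing(), days = 1, y0 = y0,
                     kin = kinetic_params(rho = 10000),
                     compute_rates = FALSE)
  expect_equal(t2$derived$V[1], t1$derived$V[1] / 2)
  expect_equal(t2$derived$S_HCO3[1], 2 * t1$derived$S_HCO3[1])
})

test_that("permanent desiccation drives the film to the extinction flag", {
  f <- constant_forcing(T_a = 20, T_s = 20, RH = 0.55, I = 0)
  kin <- kinetic_params(k_d = 0.05)
  y0 <- sab_initial_state(kin, Q_SOC = 0.021, Q_ATP = 1e-4, Q_NADPH = 1e-4)
  traj <- sab_simulate(f, days = 15, y0 = y0, kin = kin,
                       compute_rates = FALSE)
  expect_true(traj$extinct)
  per <- detect_periodic_state(traj)
  expect_false(per$periodic)
})

test_that("periodic-state detection distinguishes transient from settled runs", {
  short <- sab_simulate(summer_forcing(), days = 3, compute_rates = FALSE)
  expect_false(detect_periodic_state(short, tol = 1e-4)$periodic)

  long <- sab_simulate(summer_forcing(), days = 60, compute_rates = FALSE)
  per <- detect_periodic_state(long, tol = 1e-2)
  expect_true(per$periodic)
  expect_true(is.finite(per$growth_rate_per_day))
  expect_lt(abs(per$growth_rate_per_day - 1), 0.1)
})

test_that("daily summaries are recomputable from the trajectory", {
  traj <- sab_simulate(summer_forcing(), days = 3, compute_rates = FALSE)
  ds <- daily_summary(traj)
  expect_equal(nrow(ds), 3)
  d <- traj$derived
  per_day <- round(24 / traj$grid)
  idx <- 1:(per_day + 1)
  expect_equal(ds$mean_aw[1], mean(d$a_w[idx]))
  expect_equal(ds$min_pH[1], min(d$pH[idx]))
  expect_equal(ds$growth_factor[1], d$M[per_day + 1] / d$M[1])
})
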