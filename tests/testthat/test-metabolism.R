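test_that("limitation primitives match their stated forms", {
  expect_equal(combine_limitations(c(a = 1, b = 1, c = 1))$f, 1)
  lim <- combine_limitations(c(x = 0.3, y = 0.7))
  expect_equal(lim$f, 0.3)
  expect_equal(lim$limiting, "x")
  expect_equal(combine_limitations(c(0.5, 0, 0.9))$f, 0)
  expect_error(combine_limitations(c(0.5, 1.4)), "\\[0, 1\\]")

  expect_equal(aw_ramp(1, 0.6), 1)
  expect_equal(aw_ramp(0.6, 0.6), 0)
  expect_equal(aw_ramp(0.8, 0.6), 0.5)

  expect_equal(aw_tent(1, 0.6, 0.8), 0)
  expect_equal(aw_tent(0.8, 0.6, 0.8), 1)
  expect_equal(aw_tent(0.6, 0.6, 0.8), 0)

  expect_equal(light_response(0, 150), 0)
  expect_equal(light_response(150, 150), 0.5)

  expect_equal(ph_window(7, 4.5, 9.5), 1)
  expect_equal(ph_window(4.5, 4.5, 9.5), 0)
  expect_equal(ph_window(11, 4.5, 9.5), 0)
  expect_error(ph_window(7, 8, 6), "below")
})

test_that("Haldane light response peaks at the geometric-mean intensity", {
  K_I <- 150; K_I_inh <- 1000
  I_grid <- seq(0, 5000, by = 1)
  phi <- light_response(I_grid, K_I, K_I_inh)
  expect_equal(I_grid[which.max(phi)], round(sqrt(K_I * K_I_inh)))
  expect_equal(max(phi), 1, tolerance = 1e-6)
  # non-monotone: decreasing past the optimum
  expect_lt(phi[length(phi)], 0.9)
})

test_that("photorespiration branching function has the stated limits", {
  expect_equal(branching_fraction(0, 1, 10), 1)
  expect_equal(branching_fraction(0.1, 1, 10), 0.5)
  expect_equal(branching_fraction(0.2, 1, 10), 1 / 3)
  expect_equal(branching_fraction(0.5, 0, 10), 0) # no substrate convention
})

test_that("maintenance requirement and the decay trigger follow the ATP budget", {
  expect_equal(maintenance_requirement(1, 0.002, 0.03), 0.002)
  expect_equal(maintenance_requirement(0, 0.002, 0.03), 0.032)
  aw <- seq(0, 1, by = 0.1)
  expect_true(all(diff(maintenance_requirement(aw, 0.002, 0.03)) < 0))

  # ample production and stores: full maintenance, no decay
  md <- maintenance_and_decay(omega = 1, f_star_main = 0.01, Q_ATP = 1,
                              k_d = 0.01, K_ATP = 0.002)
  expect_equal(md$f_main, 0.01)
  expect_equal(md$f_d, 0)

  # no production, no stores: zero maintenance, full decay
  md0 <- maintenance_and_decay(0, 0.01, 0, 0.01, 0.002)
  expect_equal(md0$f_main, 0)
  expect_equal(md0$f_d, 0.01)

  # half production with saturated stores: half decay
  md5 <- maintenance_and_decay(0.005, 0.01, 1e6, 0.01, 0.002)
  expect_equal(md5$f_d, 0.005, tolerance = 1e-5)

  # no requirement at all: trivially sufficient
  expect_equal(maintenance_and_decay(0, 0, 0, 0.01, 0.002)$f_d, 0)
})

test_that("darkness and water-activity switches shut the cyanobacterial rates", {
  p <- kinetic_params()
  ch <- replete_chem()
  dark <- cyano_rates(1, 0.5, 0.1, 0.01, 0.01, 0, ch, I = 0, a_w = 0.9, p)
  for (nm in c("r_nc", "r_cy", "r_fix", "r_photo", "r_C_growth"))
    expect_equal(unname(dark$rates[nm]), 0, label = nm)

  dry <- cyano_rates(1, 0.5, 0.1, 0.01, 0.01, 0.5, ch, I = 800, a_w = 0.55, p)
  active <- setdiff(names(dry$rates), c("r_C_d", "r_C_main"))
  expect_true(all(dry$rates[active] == 0))
  expect_equal(unname(dry$rates["r_C_d"]), p$k_d) # M_C = 1, full decay
})

test_that("replete conditions saturate the non-cyclic chain and branch conservation holds", {
  p <- kinetic_params()
  # oxygen-free chemistry so g_fix = 1; optimal light; empty carrier pools
  ch <- replete_chem()
  ch$S_O2 <- 0
  I_opt <- sqrt(p$K_I * p$K_I_inh)
  r <- cyano_rates(2, Q_SOC = 0.5, Q_N = 0.1, Q_ATP = 0, Q_NADPH = 0,
                   S_TOA = 0, chem = ch, I = I_opt, a_w = 1, p = p)
  expect_equal(unname(r$rates["r_nc"]), p$k_nc * 2)
  expect_equal(r$g_fix, 1)
  expect_equal(unname(r$rates["r_photo"]), 0)

  # branch conservation r_fix + r_photo = k_fix * M * f on random states
  set.seed(31)
  for (i in 1:50) {
    ch2 <- replete_chem(T_star = runif(1, 5, 35))
    M <- runif(1, 0.1, 2)
    rr <- cyano_rates(M, runif(1, 0.02, 1.4), runif(1, 0.02, 0.2),
                      runif(1, 0, 0.02), runif(1, 0, 0.02), runif(1, 0, 0.5),
                      ch2, I = runif(1, 0, 2000), a_w = runif(1), p)
    expect_equal(unname(rr$rates["r_fix"] + rr$rates["r_photo"]),
                 p$k_fix * M * rr$f[["r_fix"]], tolerance = 1e-12)
  }
})

test_that("every rate respects its k_i * M bound and factors stay in [0,1]", {
  p <- kinetic_params()
  caps <- c(r_nc = p$k_nc, r_cy = p$k_cy + p$dk_cy, r_fix = p$k_fix,
            r_photo = p$k_fix, r_Nfix = p$k_Nfix, r_C_growth = p$k_growth_C,
            r_POLprod = p$k_pol, r_C_resp = p$k_resp, r_C_uptake = p$k_uptake,
            r_C_d = p$k_d)
  set.seed(32)
  for (i in 1:100) {
    M <- runif(1, 0, 3)
    ch <- replete_chem(T_star = runif(1, 0, 40))
    r <- cyano_rates(M, runif(1, 0, 2), runif(1, 0, 0.3), runif(1, 0, 0.03),
                     runif(1, 0, 0.03), runif(1, 0, 1), ch,
                     I = runif(1, 0, 2500), a_w = runif(1), p)
    expect_true(all(r$rates >= 0))
    for (nm in names(caps))
      expect_lte(r$rates[[nm]], caps[[nm]] * M + 1e-12)
    expect_true(all(r$f >= 0 & r$f <= 1 + 1e-12))
  }
})

test_that("heterotroph rates vanish without substrate, water or reserves", {
  p <- kinetic_params()
  none <- hetero_rates(1, 0.5, 0.1, 0.01, S_POL = 0, S_CDB = 0, S_NDB = 0,
                       S_TOA = 0, a_w = 0.9, p = p)
  for (nm in c("r_POL_scav", "r_CDB_scav", "r_NDB_scav", "r_H_uptake"))
    expect_equal(unname(none$rates[nm]), 0, label = nm)

  dry <- hetero_rates(1, 0.5, 0.1, 0.01, 500, 500, 50, 1, a_w = 0.5, p = p)
  active <- setdiff(names(dry$rates), c("r_H_d", "r_H_main"))
  expect_true(all(dry$rates[active] == 0))
  expect_gt(unname(dry$rates["r_H_d"]), 0)

  # stored carbon at the subsistence quota: nothing to burn or build with
  starved <- hetero_rates(1, p$Q_SOC_min, 0.1, 0.01, 500, 500, 50, 1,
                          a_w = 0.9, p = p)
  expect_equal(unname(starved$rates["r_H_resp"]), 0)
  expect_equal(unname(starved$rates["r_H_growth"]), 0)
})

test_that("rates are monotone in their own substrate and in water activity", {
  p <- kinetic_params()
  ch <- replete_chem()
  aw_grid <- seq(p$a_w_min, 1, by = 0.02)
  resp <- vapply(aw_grid, function(a)
    hetero_rates(1, 0.5, 0.1, 0.01, 500, 500, 50, 1, a, p)$rates[["r_H_resp"]],
    numeric(1))
  expect_true(all(diff(resp) >= -1e-12))

  toa_grid <- seq(0, 1, by = 0.05)
  up <- vapply(toa_grid, function(s)
    hetero_rates(1, 0.5, 0.1, 0.01, 0, 0, 0, s, 0.95, p)$rates[["r_H_uptake"]],
    numeric(1))
  expect_true(all(diff(up) >= -1e-12))
})

test_that("guild ablation zeroes all of that guild's rates", {
  p <- kinetic_params()
  ch <- replete_chem()
  r0 <- cyano_rates(0, 0, 0, 0, 0, 0.2, ch, I = 500, a_w = 0.9, p)
  expect_true(all(r0$rates == 0))
  h0 <- hetero_rates(0, 0, 0, 0, 100, 100, 10, 0.2, a_w = 0.9, p = p)
  expect_true(all(h0$rates == 0))
})

test_that("the water-activity suppression scan finds the viability threshold", {
  scan <- aw_suppression_threshold()
  expect_equal(scan$threshold, 0.6)
  # above the threshold at least one water-limited rate is active
  above <- aw_ramp(scan$threshold + 0.001, 0.6)
  expect_gt(above, 0)
  # a shifted parameterization moves the threshold with it
  scan2 <- aw_suppression_threshold(kinetic_params(a_w_min = 0.5,
                                                   a_w_peak = 0.7))
  expect_equal(scan2$threshold, 0.5)
})
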