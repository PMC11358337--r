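test_that("Henry saturation has the right reference value and temperature trend", {
  p <- chemistry_params()
  expect_equal(henry_saturation(25, "CO2", p), p$KH_CO2_ref * p$pCO2)
  expect_equal(henry_saturation(25, "O2", p), p$KH_O2_ref * p$pO2)

  p0 <- chemistry_params(vantHoff_CO2 = 0)
  expect_equal(henry_saturation(5, "CO2", p0), henry_saturation(35, "CO2", p0))

  # CO2 is less soluble at higher temperature
  expect_gt(henry_saturation(10, "CO2", p), henry_saturation(30, "CO2", p))
})

test_that("charge-balance hydrogen solve reproduces closed-form pH values", {
  p <- chemistry_params()
  expect_equal(solve_hydrogen(0, 0, p)$pH, 7) # pure water, Kw = 1e-8

  # bicarbonate excess: Kw negligible, S_H ~ B -> pH ~ 4.0
  expect_equal(solve_hydrogen(0.1, 0, p)$pH, 4.0, tolerance = 1e-4)

  # cation excess: S_H ~ Kw/|B| -> pH ~ 10.0
  p_cat <- chemistry_params(S_Cat = 0.1)
  expect_equal(solve_hydrogen(0, 0, p_cat)$pH, 10.0, tolerance = 1e-4)
})

test_that("electroneutrality holds to near machine precision on random inputs", {
  p <- chemistry_params(S_An = 0.01, S_Cat = 0.03)
  set.seed(5)
  for (i in 1:200) {
    S_HCO3 <- 10^runif(1, -6, 1)
    S_OA <- 10^runif(1, -6, 1)
    h <- solve_hydrogen(S_HCO3, S_OA, p)
    resid <- h$S_H + p$S_Cat - (p$Kw / h$S_H + S_HCO3 + S_OA + p$S_An)
    expect_lt(abs(resid), 1e-12 * max(1, h$S_H))
  }
  # pH strictly decreasing in the net anion excess
  pH_seq <- solve_hydrogen(seq(0, 1, by = 0.01), 0, p)$pH
  expect_true(all(diff(pH_seq) < 0))
})

test_that("CO2 hydration rate has the stated structure", {
  p <- chemistry_params()
  co2 <- henry_saturation(25, "CO2", p)
  expect_equal(co2_hydration_rate(co2, 1e-3, 0, p), p$k_AB_CO2 * co2)
  # equilibrium: S_H * S_HCO3 = Ka * CO2_sat
  S_H <- 2e-3
  S_eq <- p$Ka_CO2 * co2 / S_H
  expect_equal(co2_hydration_rate(co2, S_H, S_eq, p), 0, tolerance = 1e-12)
  # linear in the rate constant
  p2 <- chemistry_params(k_AB_CO2 = 2 * p$k_AB_CO2)
  expect_equal(co2_hydration_rate(co2, 1e-3, 1e-3, p2),
               2 * co2_hydration_rate(co2, 1e-3, 1e-3, p))
})

test_that("organic-acid interconversion rate has the right roots and signs", {
  p <- chemistry_params()
  expect_equal(oa_dissociation_rate(0, 0, 1e-3, p), 0)
  # fully undissociated acid: net dissociation (negative sign convention)
  expect_equal(oa_dissociation_rate(0.5, 0, 1e-3, p), -p$k_AB_OA * p$Ka_OA * 0.5)
  # analytic equilibrium fraction Ka/(Ka + S_H)
  S_H <- 3e-3; S_TOA <- 0.2
  S_OA_eq <- S_TOA * p$Ka_OA / (p$Ka_OA + S_H)
  expect_equal(oa_dissociation_rate(S_TOA, S_OA_eq, S_H, p), 0,
               tolerance = 1e-12)
  expect_error(oa_dissociation_rate(0.1, 0.2, 1e-3, p), "exceeds")
})

test_that("derived chemistry is internally consistent", {
  p <- chemistry_params()
  ch <- derived_chemistry(2.4e-3, 1e-4, 22, a_w = 0.8, p = p)
  expect_equal(ch$S_DIC, ch$S_CO2 + 2.4e-3)
  expect_equal(ch$pH, solve_hydrogen(2.4e-3, 1e-4, p)$pH)
  expect_equal(ch$a_w, 0.8)
})
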