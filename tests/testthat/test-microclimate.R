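test_that("interface temperature has the right limits and bracketing", {
  p <- microclimate_params()
  expect_equal(interface_temperature(20, 20, p), 20)

  # vanishing film thickness pins the interface to the stone
  p_thin <- microclimate_params(lambda = 1e-12)
  expect_equal(interface_temperature(30, 35, p_thin), 35, tolerance = 1e-6)

  # equal transport weights give the arithmetic mean
  p_eq <- microclimate_params(lambda = 1e-3, delta = 1e-3, k_a = 0.5, k_b = 0.5)
  expect_equal(interface_temperature(30, 35, p_eq), 32.5)

  # always a convex combination of the two temperatures
  set.seed(11)
  for (i in 1:50) {
    T_a <- runif(1, -10, 40); T_s <- runif(1, -10, 40)
    pp <- microclimate_params(lambda = runif(1, 1e-6, 1e-4),
                              delta = runif(1, 1e-4, 1e-2),
                              k_a = runif(1, 0.01, 1), k_b = runif(1, 0.01, 1))
    Ts <- interface_temperature(T_a, T_s, pp)
    expect_gte(Ts, min(T_a, T_s) - 1e-12)
    expect_lte(Ts, max(T_a, T_s) + 1e-12)
  }
})

test_that("water activity matches the Magnus vapor-pressure oracle", {
  p <- microclimate_params()
  # independent oracle: a_w = RH * e_sat(T_a) / e_sat(T*)
  e_sat <- function(T) 6.1094 * exp(17.62 * T / (243.12 + T))
  aw <- water_activity(0.7, 25, 30, p)
  expect_equal(aw, 0.7 * e_sat(25) / e_sat(30), tolerance = 1e-12)
  expect_equal(round(aw, 2), 0.52)

  expect_equal(water_activity(0.7, 25, 25, p), 0.7) # T* = T_a cancels
  expect_equal(water_activity(0, 25, 35, p), 0)
  expect_error(water_activity(0.5, -250, 20, p), "Magnus")
})

test_that("water activity is bounded and monotone in its drivers", {
  p <- microclimate_params()
  set.seed(21)
  for (i in 1:100) {
    RH <- runif(1); T_a <- runif(1, -5, 40); T_star <- runif(1, -5, 45)
    aw <- water_activity(RH, T_a, T_star, p)
    expect_gte(aw, 0); expect_lte(aw, 1)
  }
  # non-increasing in T*, non-decreasing in RH
  T_grid <- seq(10, 40, by = 0.5)
  aw_T <- water_activity(0.7, 25, T_grid, p)
  expect_true(all(diff(aw_T) <= 1e-12))
  RH_grid <- seq(0, 1, by = 0.01)
  aw_RH <- water_activity(RH_grid, 25, 30, p)
  expect_true(all(diff(aw_RH) >= -1e-12))
})

test_that("diel water-activity profiles behave as the microclimate predicts", {
  # constant, equilibrated forcing: a_w equals ambient humidity everywhere
  prof <- aw_profile(constant_forcing(T_a = 20, T_s = 20, RH = 0.8))
  expect_equal(prof$a_w, rep(0.8, nrow(prof)), tolerance = 1e-12)

  # summer day: driest point falls inside the daylight window
  prof2 <- aw_profile(summer_forcing())
  t_min <- prof2$t[which.min(prof2$a_w)]
  expect_gt(t_min, 5.5)
  expect_lt(t_min, 19.5)
  expect_gt(min(prof2$I[prof2$t == t_min]), 0)

  # 24 h periodicity of the composed profile
  expect_equal(prof2$a_w[prof2$t == 0], prof2$a_w[prof2$t == 24])
})
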