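test_that("degenerate presets produce the expected limiting profiles", {
  dark <- season_preset("custom", T_a_min = 10, T_a_max = 20, dewpoint = 5,
                        I_max = 0, sunrise = 6, sunset = 18,
                        stone_day_offset = 3, stone_night_offset = 2)
  f <- make_diel_forcing(dark)
  expect_true(all(f$samples$light_uE == 0))

  saturated <- season_preset("custom", T_a_min = 15, T_a_max = 15,
                             dewpoint = 15, I_max = 500, sunrise = 6,
                             sunset = 18, stone_day_offset = 3,
                             stone_night_offset = 2)
  f2 <- make_diel_forcing(saturated)
  expect_equal(f2$samples$RH_air, rep(1, nrow(f2$samples)))
})

test_that("minimum relative humidity coincides with maximum air temperature", {
  f <- summer_forcing(resolution = 1 / 60) # 1-minute grid brute-force scan
  s <- f$samples
  expect_equal(which.min(s$RH_air), which.max(s$T_air_C))
})

test_that("generated profiles satisfy the physical invariants on a fine grid", {
  for (name in c("summer", "spring", "autumn", "winter")) {
    f <- make_diel_forcing(season_preset(name), resolution = 1 / 60)
    s <- f$samples
    expect_true(all(s$RH_air >= 0 & s$RH_air <= 1), label = name)
    expect_true(all(s$light_uE >= 0), label = name)
    # stone warmer than air only under light, cooler at night
    night <- s$light_uE == 0
    expect_true(all(s$T_stone_C[night] < s$T_air_C[night]), label = name)
    expect_gt(max(s$T_stone_C - s$T_air_C), 0)
  }
})

test_that("invalid presets are rejected", {
  expect_error(season_preset("summer", I_max = -5), "I_max")
  expect_error(season_preset("summer", T_a_min = 40), "T_a_min")
  expect_error(season_preset("summer", sunrise = 20, sunset = 19), "sunrise")
})

test_that("sampling is exactly 24 h periodic and piecewise linear", {
  f <- summer_forcing()
  t <- seq(0, 23.9, by = 0.37)
  a <- sample_forcing(f, t)
  b <- sample_forcing(f, t + 24)
  expect_equal(a[c("T_a", "T_s", "RH_a", "I")], b[c("T_a", "T_s", "RH_a", "I")])

  expect_equal(sample_forcing(f, 25)$T_a, sample_forcing(f, 1)$T_a)

  # at a sample node the stored value is returned
  s <- f$samples
  at_node <- sample_forcing(f, s$time_h[10])
  expect_equal(at_node$T_a, s$T_air_C[10])
  expect_equal(at_node$I, s$light_uE[10])

  # midway between two nodes: arithmetic mean
  mid_t <- (s$time_h[5] + s$time_h[6]) / 2
  mid <- sample_forcing(f, mid_t)
  expect_equal(mid$T_s, (s$T_stone_C[5] + s$T_stone_C[6]) / 2)
})

test_that("forcing CSV round trip preserves sampled values and units normalize", {
  f <- summer_forcing()
  path <- withr::local_tempfile(fileext = ".csv")
  write_forcing_table(f, path)
  f2 <- read_forcing_table(path)
  t <- f$samples$time_h
  expect_equal(sample_forcing(f2, t), sample_forcing(f, t), tolerance = 1e-12)

  # percent-scale humidity is auto-detected
  tab <- f$samples
  tab$RH_air <- tab$RH_air * 100
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path2, row.names = FALSE)
  f3 <- read_forcing_table(path2)
  expect_equal(f3$samples$RH_air, f$samples$RH_air, tolerance = 1e-12)
})

test_that("malformed forcing tables are rejected", {
  f <- summer_forcing()
  tab <- f$samples
  tab$time_h[2] <- tab$time_h[1] # duplicate time
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  expect_error(read_forcing_table(path), "increasing")

  tab2 <- f$samples[, -3] # missing column
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab2, path2, row.names = FALSE)
  expect_error(read_forcing_table(path2), "missing columns")

  tab3 <- f$samples
  tab3$RH_air[1] <- 130
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab3, path3, row.names = FALSE)
  expect_error(read_forcing_table(path3), "RH_air")
})
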