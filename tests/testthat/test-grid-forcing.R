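test_that("build_grid produces the expected discretizations", {
  g <- build_grid(1500, 0.5)
  expect_equal(g$n, 3000L)
  expect_equal(length(g$edges), 3001L)
  expect_equal(g$centers[1], 0.25)
  expect_equal(g$centers, (g$edges[-1] + g$edges[-3001]) / 2)
  expect_true(all(diff(g$centers) > 0))

  g2 <- build_grid(100, 50)
  expect_equal(g2$n, 2L)
  expect_equal(g2$centers, c(25, 75))

  expect_error(build_grid(1500, 7), "integer multiple")
  expect_error(build_grid(-10, 1), "positive")
})

test_that("solar events match an independently coded NOAA oracle", {
  spec <- season_spec("JAS")
  # frozen from a separate implementation of the NOAA spreadsheet equations
  e <- solar_events(as.Date("2019-07-15"), spec)
  expect_lt(abs(e$sunrise - 4.329181) * 60, 2) # minutes
  expect_lt(abs(e$sunset - 19.330242) * 60, 2)

  # equinox: day length within 10 minutes of 12 h
  eq <- solar_events(as.Date("2019-03-20"), spec)
  expect_lt(abs((eq$sunset - eq$sunrise) - 12) * 60, 10)

  # solstice ordering
  s1 <- solar_events(as.Date("2019-06-21"), spec)
  s2 <- solar_events(as.Date("2019-12-21"), spec)
  expect_gt(s1$sunset - s1$sunrise, s2$sunset - s2$sunrise)

  expect_error(season_spec("JAS", latitude = 70), "polar")
})

test_that("day length at the equator is close to 12 h on every date", {
  spec <- season_spec("JAS", latitude = 0)
  days <- seq(as.Date("2019-01-01"), as.Date("2019-12-31"), by = "15 days")
  for (d in as.list(days)) {
    e <- solar_events(d, spec)
    expect_lt(abs((e$sunset - e$sunrise) - 12) * 60, 10)
  }
})

test_that("seasonal migration times are the mean of daily solar events", {
  spec <- season_spec("JFM")
  m <- seasonal_migration_times(spec)
  # frozen from the independent day-by-day oracle (Jan 1 - Mar 31, 2019)
  expect_lt(abs(m$mean_sunrise - 6.593183) * 60, 2)

  # brute-force day loop over solar_events
  days <- seq(as.Date("2019-01-01"), as.Date("2019-03-31"), by = "day")
  sr <- vapply(as.list(days), function(d) solar_events(d, spec)$sunrise,
               numeric(1))
  expect_equal(m$mean_sunrise, mean(sr), tolerance = 1e-12)

  # seasonal ordering of sunset
  jas <- seasonal_migration_times(season_spec("JAS"))
  ond <- seasonal_migration_times(season_spec("OND"))
  expect_gt(jas$mean_sunset, ond$mean_sunset)
})

test_that("synthetic diffusivity has a mixed layer and background tail", {
  g <- build_grid(1500, 2)
  k <- synth_diffusivity(g, kappa_ml = 1e-3, kappa_bg = 1e-5, mld = 20)
  at <- function(z) k[which.min(abs(g$edges - z))]
  expect_equal(at(10), 1e-3)
  expect_lt(abs(at(500) - 1e-5) / 1e-5, 0.01)
  expect_true(all(k >= 0))
  expect_error(synth_diffusivity(g, 1e-5, 1e-3, 20), "kappa_ml >= kappa_bg")
})

test_that("synthetic temperature is a monotone exponential thermocline", {
  g <- build_grid(1500, 2)
  temp <- synth_temperature(g, t_surf = 24, t_deep = 4, thermocline_scale = 150)
  expect_lt(abs(temp[1] - 24), 0.15) # cell-centered surface value
  expect_lt(abs(temp[g$n] - 4), 0.01)
  expect_true(all(diff(temp) <= 0))
  expect_equal(synth_temperature(g, 4, 4), rep(4, g$n))

  # summer volume-mean temperature-dependent decay over the binned column
  f <- forcing_profiles(season_spec("JAS"), g)
  in_col <- g$centers < 550
  k_avg <- mean(f$decay_rate[in_col]) * 3600
  expect_gt(k_avg, 0.055)
  expect_lt(k_avg, 0.065)
})

test_that("advection profile is the prescribed triangular shape", {
  g <- build_grid(1500, 0.5)
  w <- advection_profile(g, "up", 1e-4)
  at <- function(z) w[which.min(abs(g$edges - z))]
  expect_equal(at(200), 1e-4)
  expect_equal(at(300), 0.5e-4)
  expect_equal(at(0), 0)
  expect_true(all(w[g$edges >= 400] == 0))
  expect_equal(advection_profile(g, "down", 1e-4), -w)
  expect_equal(advection_profile(g, "none", 1e-4), rep(0, g$n + 1))
})

test_that("decay profiles follow the configured model", {
  expect_equal(decay_profile(20, decay_model()) * 3600, 0.078)
  expect_equal(decay_profile(0, decay_model()) * 3600, 0.05)
  expect_equal(decay_profile(c(0, 10, 25), decay_model("constant", k_const = 0.1)) * 3600,
               rep(0.1, 3))
  expect_error(decay_profile(-100, decay_model()), "negative")

  # monotone non-increasing with depth whenever temperature is
  g <- build_grid(1000, 5)
  temp <- synth_temperature(g, 20, 4, 100)
  expect_true(all(diff(decay_profile(temp, decay_model())) <= 0))
})

test_that("forcing CSV overrides interpolate onto the grid", {
  g <- build_grid(100, 10)
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(depth_m = c(0, 50, 100), value = c(1, 2, 1)), f,
            row.names = FALSE)
  v <- read_forcing_csv(f, g, "centers")
  expect_equal(length(v), g$n)
  expect_equal(v[g$centers == 25], 1.5)
  # edge-value hold beyond the sampled range
  g2 <- build_grid(200, 10)
  v2 <- read_forcing_csv(f, g2, "centers")
  expect_equal(v2[g2$centers > 100], rep(1, sum(g2$centers > 100)))
  unlink(f)
})
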