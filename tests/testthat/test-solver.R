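test_that("decay-only step matches the exponential closed form", {
  g <- build_grid(600, 2)
  f <- bare_forcing(g, k_h = 0.1)
  st <- list(c_lp = rep(100, g$n), c_sp = rep(100, g$n))
  cfg <- solver_config(dt = 60, duration_days = 1, dz = 2, depth_extent = 600)
  out <- edna_step(st, f, params = edna_params(0, 0), config = cfg,
                   nsteps = 24 * 60)
  expect_equal(out$c_lp, rep(100 * exp(-2.4), g$n), tolerance = 1e-9)
  expect_equal(out$c_sp, rep(100 * exp(-2.4), g$n), tolerance = 1e-9)
  b <- attr(out, "budget")
  expect_lt(abs(b$decayed - (b$shed + 2 * 100 * 600 - b$resident)) /
              (2 * 100 * 600), 1e-9)
})

test_that("settling translates a pulse by w_s * t within one cell", {
  g <- build_grid(600, 2)
  f <- bare_forcing(g)
  st <- pulse_state(g, 300)
  cfg <- solver_config(dt = 60, duration_days = 1, dz = 2, depth_extent = 600)
  out <- edna_step(st, f, params = edna_params(0, settling_rate = 25),
                   config = cfg, nsteps = 24 * 60)
  shift <- centre_of_mass(out$c_lp, g) - centre_of_mass(st$c_lp, g)
  expect_lt(abs(shift - 25), g$dz)
  expect_equal(column_mass(out, g), 1, tolerance = 1e-9) # far from bottom
})

test_that("breakdown conserves the LP + SP sum", {
  g <- build_grid(600, 2)
  f <- bare_forcing(g)
  st <- pulse_state(g, 200)
  cfg <- solver_config(dt = 60, duration_days = 1, dz = 2, depth_extent = 600)
  out <- edna_step(st, f, params = edna_params(breakdown_rate = 0.19,
                                               settling_rate = 0),
                   config = cfg, nsteps = 500)
  expect_equal(out$c_lp + out$c_sp, st$c_lp + st$c_sp, tolerance = 1e-12)
  expect_gt(sum(out$c_sp), 0)
  # transfer follows the exact exponential
  expect_equal(sum(out$c_lp) / sum(st$c_lp), exp(-0.19 / 3600 * 60 * 500),
               tolerance = 1e-9)
})

test_that("implicit diffusion conserves mass and grows variance as 2*kappa*t", {
  g <- build_grid(600, 2)
  kappa <- 5e-4
  f <- bare_forcing(g, kappa = kappa)
  st <- pulse_state(g, 300, sd = 10)
  cfg <- solver_config(dt = 60, duration_days = 1, dz = 2, depth_extent = 600)
  nsteps <- 12 * 60 # 12 h, pulse stays far from boundaries
  out <- edna_step(st, f, params = edna_params(0, 0), config = cfg,
                   nsteps = nsteps)
  expect_equal(column_mass(out, g), column_mass(st, g), tolerance = 1e-9)
  var0 <- sum(st$c_lp * (g$centers - centre_of_mass(st$c_lp, g))^2) / sum(st$c_lp)
  var1 <- sum(out$c_lp * (g$centers - centre_of_mass(out$c_lp, g))^2) / sum(out$c_lp)
  expected <- 2 * kappa * nsteps * 60
  expect_lt(abs((var1 - var0) - expected) / expected, 0.05)
})

test_that("constant point source with decay approaches S/k steady state", {
  g <- build_grid(100, 2)
  k_h <- 0.5
  f <- bare_forcing(g, k_h = k_h)
  src <- list(S_LP = numeric(g$n), S_SP = numeric(g$n))
  icell <- 25
  src$S_SP[icell] <- 10 # mass / m / h
  cfg <- solver_config(dt = 60, duration_days = 1, dz = 2, depth_extent = 100)
  st <- list(c_lp = numeric(g$n), c_sp = numeric(g$n))
  hours <- 24
  out <- edna_step(st, f, source = src, params = edna_params(0, 0),
                   config = cfg, nsteps = hours * 60)
  # analytic: C(t) = (S/k)(1 - exp(-k t)); k t = 12 so effectively S/k
  expect_equal(out$c_sp[icell], 10 / k_h * (1 - exp(-k_h * hours)),
               tolerance = 1e-2)
  expect_true(all(out$c_sp[-icell] == 0))
})

test_that("the operator is linear: doubling shedding doubles concentrations", {
  cfg <- solver_config(dt = 120, duration_days = 2, dz = 5)
  s1 <- run_simulation(season_spec("JAS"), pm = 0.5,
                       shedding = shedding_config(rate = 360), config = cfg)
  s2 <- run_simulation(season_spec("JAS"), pm = 0.5,
                       shedding = shedding_config(rate = 720), config = cfg)
  expect_equal(2 * s1$c_lp, s2$c_lp, tolerance = 1e-12)
  expect_equal(2 * s1$c_sp, s2$c_sp, tolerance = 1e-12)
  expect_equal(2 * s1$bin_series$surface, s2$bin_series$surface,
               tolerance = 1e-12)
})

test_that("mass budget closes with and without export", {
  # no sinks: resident equals shed exactly
  cfg <- solver_config(dt = 120, duration_days = 1, dz = 5)
  grid <- build_grid(1500, 5)
  f0 <- forcing_profiles(season_spec("JAS"), grid,
                         kappa = rep(0, grid$n + 1),
                         temperature = rep(10, grid$n),
                         w = rep(0, grid$n + 1),
                         decay = decay_model("constant", k_const = 0))
  sim0 <- run_simulation(season_spec("JAS"), pm = 0.5, forcing = f0,
                         params = edna_params(0, 0), config = cfg)
  b0 <- mass_budget(sim0)
  expect_lt(abs(b0$resident - b0$shed) / b0$shed, 1e-9)

  # decay only: decayed + resident = shed
  f1 <- forcing_profiles(season_spec("JAS"), grid,
                         kappa = rep(0, grid$n + 1),
                         temperature = rep(10, grid$n),
                         w = rep(0, grid$n + 1),
                         decay = decay_model("constant", k_const = 0.1))
  sim1 <- run_simulation(season_spec("JAS"), pm = 0.5, forcing = f1,
                         params = edna_params(0, 0), config = cfg)
  b1 <- mass_budget(sim1)
  expect_lt(abs(b1$decayed + b1$resident - b1$shed) / b1$shed, 1e-9)

  # strong settling, no decay: bottom export is positive and closure holds
  small <- build_grid(600, 2)
  f2 <- forcing_profiles(season_spec("JAS"), small,
                         kappa = rep(0, small$n + 1),
                         temperature = rep(10, small$n),
                         w = rep(0, small$n + 1),
                         decay = decay_model("constant", k_const = 0))
  cfg2 <- solver_config(dt = 60, duration_days = 5, dz = 2, depth_extent = 600)
  sim2 <- run_simulation(season_spec("JAS"), pm = 0, forcing = f2,
                         params = edna_params(0, settling_rate = 50),
                         config = cfg2)
  b2 <- mass_budget(sim2)
  expect_gt(b2$exported, 0)
  expect_lt(abs(b2$closure), 1e-9)
})

test_that("advective residual is logged, not hidden", {
  cfg <- solver_config(dt = 120, duration_days = 2, dz = 5)
  grid <- build_grid(1500, 5)
  f <- forcing_profiles(season_spec("JAS"), grid, advection_mode = "up",
                        decay = decay_model("constant", k_const = 0.05))
  sim <- run_simulation(season_spec("JAS"), pm = 1, forcing = f, config = cfg)
  b <- mass_budget(sim)
  expect_true(is.finite(b$adv_residual))
  expect_lt(abs(b$closure), 1e-3) # closure after accounting for the residual
})

test_that("CFL violations raise a stability error naming the term", {
  grid <- build_grid(1500, 0.5)
  f <- forcing_profiles(season_spec("JAS"), grid)
  expect_error(
    run_simulation(season_spec("JAS"),
                   params = edna_params(settling_rate = 5000),
                   forcing = f, config = solver_config(dt = 60, dz = 0.5)),
    "settling CFL")
})

test_that("halving dt changes 30-day bin proportions by well under half a point", {
  base <- solver_config(dt = 120, duration_days = 10, dz = 4)
  half <- solver_config(dt = 60, duration_days = 10, dz = 4)
  p1 <- colMeans(ednadvm:::bin_proportion_series(
    run_simulation(season_spec("JAS"), pm = 0.5, config = base)))
  p2 <- colMeans(ednadvm:::bin_proportion_series(
    run_simulation(season_spec("JAS"), pm = 0.5, config = half)))
  expect_lt(max(abs(p1 - p2)), 0.5)
})
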