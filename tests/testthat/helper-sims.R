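# Shared fixtures. Desk-preset runs are deterministic, so they are cached
# and reused across test files.

.sim_cache <- new.env(parent = emptyenv())

desk_sim <- function(season = "JAS", pm = 0.5, ...) {
  key <- paste(season, pm, ..., sep = "|")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- run_simulation(
      season_spec(season), pm = pm, config = solver_config("desk"), ...)
  }
  .sim_cache[[key]]
}

# Forcing with every transport/decay term individually controllable; used to
# isolate single process terms in solver tests.
bare_forcing <- function(grid, kappa = 0, k_h = 0, w = 0) {
  forcing_profiles(
    season_spec("JAS"), grid,
    kappa = rep(kappa, grid$n + 1L),
    temperature = rep(10, grid$n),
    w = rep(w, grid$n + 1L),
    decay = decay_model("constant", k_const = k_h))
}

# Gaussian pulse of unit mass centered at `z0`
pulse_state <- function(grid, z0, sd = 10) {
  c0 <- exp(-(grid$centers - z0)^2 / (2 * sd^2))
  c0 <- c0 / (sum(c0) * grid$dz)
  list(c_lp = c0, c_sp = numeric(grid$n))
}

column_mass <- function(state, grid) {
  sum(state$c_lp + state$c_sp) * grid$dz
}

centre_of_mass <- function(conc, grid) {
  sum(conc * grid$centers) / sum(conc)
}
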