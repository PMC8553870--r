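#' Decay-rate model
#'
#' First-order eDNA decay, either a constant rate or a linear function of
#' water temperature, k(T) = a + b * T (rates in 1/h).
#'
#' @param kind `"linear_in_T"` (default) or `"constant"`.
#' @param k_const Constant rate in 1/h (required when `kind = "constant"`;
#'   the sensitivity sweep uses 0.01 and 0.1).
#' @param a Intercept in 1/h (default 0.05).
#' @param b Slope in 1/h per degree C (default 0.0014).
#' @return An object of class `decay_model`.
#' @examples
#' decay_model() # temperature-dependent default
#' decay_model("constant", k_const = 0.1)
#' @export
decay_model <- function(kind = c("linear_in_T", "constant"), k_const = NULL,
                        a = 0.05, b = 0.0014) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    if (is.null(k_const) || !is.numeric(k_const) || k_const < 0)
      stop("constant decay model needs a non-negative `k_const` (1/h)", call. = FALSE)
  }
  structure(list(kind = kind, k_const = k_const, a = a, b = b),
            class = "decay_model")
}

#' @export
print.decay_model <- function(x, ...) {
  if (x$kind == "constant")
    cat(sprintf("<decay_model> constant k = %g 1/h\n", x$k_const))
  else
    cat(sprintf("<decay_model> k(T) = %g + %g * T 1/h\n", x$a, x$b))
  invisible(x)
}

#' Decay-rate profile from a temperature profile
#'
#' Evaluates the decay model on a per-cell temperature profile and converts
#' the result to 1/s for the solver.
#'
#' @param temperature Per-cell temperatures in degrees C.
#' @param model A [decay_model()].
#' @return Per-cell decay rates in 1/s.
#' @export
decay_profile <- function(temperature, model = decay_model()) {
  stopifnot(inherits(model, "decay_model"))
  k_h <- if (model$kind == "constant") rep(model$k_const, length(temperature))
         else model$a + model$b * temperature
  if (any(k_h < 0))
    stop("decay model yields a negative rate over this temperature range", call. = FALSE)
  k_h / 3600
}

# Default seasonal mixed-layer depth (m) and surface temperature (C) for the
# built-in synthetic profiles. Calibrated so the summer 0-550 m volume-mean
# temperature-dependent decay rate is about 0.06 1/h.
season_defaults <- function(season) {
  switch(season,
    JFM = list(mld = 150, t_surf = 13),
    AMJ = list(mld = 30,  t_surf = 16),
    JAS = list(mld = 15,  t_surf = 24),
    OND = list(mld = 80,  t_surf = 18),
    stop("unknown season", call. = FALSE))
}

#' Synthetic vertical diffusivity profile
#'
#' Mixed-layer step with an exponential tail: kappa equals `kappa_ml` from
#' the surface down to the mixed-layer depth, then relaxes to the background
#' `kappa_bg` with a 10 m e-folding scale. Evaluated on cell edges (where
#' diffusive fluxes live).
#'
#' @param grid An [build_grid()] grid.
#' @param kappa_ml Mixed-layer diffusivity, m^2/s (default 1e-3).
#' @param kappa_bg Background (deep) diffusivity, m^2/s (default 1e-5).
#' @param mld Mixed-layer depth, m.
#' @return Diffusivity on cell edges, m^2/s (length `grid$n + 1`).
#' @export
synth_diffusivity <- function(grid, kappa_ml = 1e-3, kappa_bg = 1e-5, mld = 15) {
  stopifnot_grid(grid)
  if (!(kappa_ml >= kappa_bg && kappa_bg > 0))
    stop("need kappa_ml >= kappa_bg > 0", call. = FALSE)
  if (!(mld > 0 && mld < grid$depth_extent))
    stop("mixed-layer depth must lie inside the column", call. = FALSE)
  z <- grid$edges
  ifelse(z <= mld, kappa_ml,
         kappa_bg + (kappa_ml - kappa_bg) * exp(-(z - mld) / 10))
}

#' Synthetic temperature profile
#'
#' Exponential thermocline: T(z) = t_deep + (t_surf - t_deep) * exp(-z /
#' thermocline_scale). Monotone non-increasing with depth. Evaluated on cell
#' centers. This is an analytic stand-in for climatological seasonal
#' profiles; it is static within a run.
#'
#' @param grid An [build_grid()] grid.
#' @param t_surf Surface temperature, degrees C.
#' @param t_deep Deep asymptote, degrees C (default 4).
#' @param thermocline_scale e-folding depth of the thermocline, m (default 150).
#' @return Per-cell temperatures, degrees C.
#' @export
synth_temperature <- function(grid, t_surf = 24, t_deep = 4,
                              thermocline_scale = 150) {
  stopifnot_grid(grid)
  if (t_surf < t_deep) stop("need t_surf >= t_deep", call. = FALSE)
  t_deep + (t_surf - t_deep) * exp(-grid$centers / thermocline_scale)
}

#' Prescribed vertical-velocity profile
#'
#' Piecewise-linear vertical velocity representing sub-mesoscale upwelling or
#' downwelling: zero at the surface, maximum magnitude at 200 m, back to zero
#' at 400 m and below. Positive values point upward. Evaluated on cell edges.
#'
#' @param grid An [build_grid()] grid.
#' @param mode `"none"` (all zero), `"up"` (positive, upwelling) or `"down"`.
#' @param w_max Peak speed at 200 m, m/s (default 1e-4).
#' @return Vertical velocity on cell edges, m/s, positive upward.
#' @export
advection_profile <- function(grid, mode = c("none", "up", "down"),
                              w_max = 1e-4) {
  stopifnot_grid(grid)
  mode <- match.arg(mode)
  if (w_max < 0) stop("`w_max` must be >= 0", call. = FALSE)
  z <- grid$edges
  w <- ifelse(z <= 200, z / 200,
              ifelse(z <= 400, (400 - z) / 200, 0)) * w_max
  switch(mode, none = w * 0, up = w, down = -w)
}

#' Assemble seasonal forcing profiles
#'
#' Bundles the prescribed diffusivity, temperature, vertical velocity and
#' derived decay-rate profiles for a season onto a grid. Any profile can be
#' overridden with a user-supplied two-column CSV via [read_forcing_csv()].
#'
#' @param spec A [season_spec()].
#' @param grid An [build_grid()] grid.
#' @param kappa_ml,kappa_bg,mld Diffusivity parameters; `mld` and `t_surf`
#'   default to the season's built-in values.
#' @param t_surf,t_deep,thermocline_scale Temperature parameters.
#' @param advection_mode,w_max Vertical-velocity parameters.
#' @param decay A [decay_model()].
#' @param kappa,temperature,w Optional explicit profiles (edges, centers,
#'   edges respectively) overriding the synthetic generators.
#' @return An object of class `edna_forcing` with fields `kappa` (edges,
#'   m^2/s), `temperature` (centers, C), `w` (edges, m/s, positive upward),
#'   `decay_rate` (centers, 1/s), `mld`, `spec`, `grid`.
#' @examples
#' f <- forcing_profiles(season_spec("JAS"), build_grid(1500, 2))
#' @export
forcing_profiles <- function(spec, grid,
                             kappa_ml = 1e-3, kappa_bg = 1e-5, mld = NULL,
                             t_surf = NULL, t_deep = 4, thermocline_scale = 150,
                             advection_mode = "none", w_max = 1e-4,
                             decay = decay_model(),
                             kappa = NULL, temperature = NULL, w = NULL) {
  stopifnot(inherits(spec, "season_spec"))
  stopifnot_grid(grid)
  sd <- season_defaults(spec$season)
  if (is.null(mld)) mld <- sd$mld
  if (is.null(t_surf)) t_surf <- sd$t_surf
  if (is.null(kappa))
    kappa <- synth_diffusivity(grid, kappa_ml, kappa_bg, mld)
  if (is.null(temperature))
    temperature <- synth_temperature(grid, t_surf, t_deep, thermocline_scale)
  if (is.null(w))
    w <- advection_profile(grid, advection_mode, w_max)
  if (length(kappa) != grid$n + 1L || length(w) != grid$n + 1L)
    stop("kappa and w must be on cell edges (length n + 1)", call. = FALSE)
  if (length(temperature) != grid$n)
    stop("temperature must be on cell centers (length n)", call. = FALSE)
  if (any(kappa < 0)) stop("kappa must be non-negative", call. = FALSE)
  structure(
    list(kappa = kappa, temperature = temperature, w = w,
         decay_rate = decay_profile(temperature, decay),
         decay = decay, mld = mld, spec = spec, grid = grid),
    class = "edna_forcing"
  )
}

#' @export
print.edna_forcing <- function(x, ...) {
  cat(sprintf(
    "<edna_forcing> %s: mld %g m, T %g..%g C, max|w| %g m/s, k %g..%g 1/h\n",
    x$spec$season, x$mld, max(x$temperature), min(x$temperature),
    max(abs(x$w)), min(x$decay_rate) * 3600, max(x$decay_rate) * 3600))
  invisible(x)
}

#' Read a forcing-profile override from CSV
#'
#' Reads a headered two-column CSV (`depth_m`, `value`) and linearly
#' interpolates it onto grid cell centers or edges; beyond the sampled depth
#' range the nearest value is held.
#'
#' @param file Path to the CSV.
#' @param grid An [build_grid()] grid.
#' @param at `"centers"` or `"edges"`.
#' @return Interpolated values on the requested locations.
#' @export
read_forcing_csv <- function(file, grid, at = c("centers", "edges")) {
  stopifnot_grid(grid)
  at <- match.arg(at)
  d <- utils::read.csv(file)
  if (ncol(d) < 2L) stop("expected two columns: depth_m, value", call. = FALSE)
  z <- d[[1L]]; v <- d[[2L]]
  if (anyNA(z) || anyNA(v)) stop("forcing CSV contains missing values", call. = FALSE)
  stats::approx(z, v, xout = if (at == "centers") grid$centers else grid$edges,
                rule = 2, ties = "ordered")$y
}
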