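#' Diel vertical migration schedule
#'
#' Describes the daily trajectory of the organism cohort: a constant day
#' depth, a constant night depth, and two 3-hour constant-speed migration
#' ramps anchored to the season's mean sunset (upward: 2 h before to 1 h
#' after sunset) and mean sunrise (downward: 1 h before to 2 h after
#' sunrise). A fraction `pm` of individuals migrates; the rest reside at the
#' day depth at all times.
#'
#' @param spec A [season_spec()] used to compute the seasonal mean sunrise
#'   and sunset, or `NULL` if `sunrise`/`sunset` are given directly.
#' @param day_depth Daytime residence depth, m (default 500).
#' @param night_depth Nighttime residence depth, m (default 50).
#' @param layer_thickness Vertical extent of the shedding layer, m
#'   (default 20).
#' @param pm Fraction of individuals that migrate, in `[0, 1]` (default 1).
#' @param sunrise,sunset Optional clock times (decimal hours) overriding the
#'   seasonal means.
#' @param up_start_offset_h,up_end_offset_h Window offsets in hours relative
#'   to sunset (defaults -2 and +1).
#' @param down_start_offset_h,down_end_offset_h Offsets relative to sunrise
#'   (defaults -1 and +2).
#'
#' @return An object of class `migration_schedule` with the resolved window
#'   clock times `up_start`, `up_end`, `down_start`, `down_end`.
#' @examples
#' migration_schedule(season_spec("JAS"), pm = 0.5)
#' @export
migration_schedule <- function(spec = season_spec("JAS"),
                               day_depth = 500, night_depth = 50,
                               layer_thickness = 20, pm = 1,
                               sunrise = NULL, sunset = NULL,
                               up_start_offset_h = -2, up_end_offset_h = 1,
                               down_start_offset_h = -1, down_end_offset_h = 2) {
  if (is.null(sunrise) || is.null(sunset)) {
    mt <- seasonal_migration_times(spec)
    if (is.null(sunrise)) sunrise <- mt$mean_sunrise
    if (is.null(sunset)) sunset <- mt$mean_sunset
  }
  if (!(pm >= 0 && pm <= 1)) stop("`pm` must be in [0, 1]", call. = FALSE)
  if (!(day_depth > night_depth))
    stop("`day_depth` must exceed `night_depth`", call. = FALSE)
  if (night_depth < layer_thickness / 2)
    warning("shedding layer extends above the surface at night; ",
            "deposits will be clipped and renormalized")
  ds <- sunrise + down_start_offset_h; de <- sunrise + down_end_offset_h
  us <- sunset + up_start_offset_h;  ue <- sunset + up_end_offset_h
  if (!(ds >= 0 && ue <= 24 && ds < de && de <= us && us < ue))
    stop("migration windows must be ordered within one day: ",
         "down window (around sunrise) before up window (around sunset)",
         call. = FALSE)
  structure(
    list(day_depth = day_depth, night_depth = night_depth,
         layer_thickness = layer_thickness, pm = pm,
         sunrise = sunrise, sunset = sunset,
         down_start = ds, down_end = de, up_start = us, up_end = ue),
    class = "migration_schedule"
  )
}

#' @export
print.migration_schedule <- function(x, ...) {
  cat(sprintf(
    "<migration_schedule> day %g m / night %g m, pm = %.0f%%\n  down %05.2f-%05.2f h, up %05.2f-%05.2f h (local)\n",
    x$day_depth, x$night_depth, 100 * x$pm,
    x$down_start, x$down_end, x$up_start, x$up_end))
  invisible(x)
}

#' Organism depth at a time of day
#'
#' Piecewise-linear daily trajectory of the migrating cohort: night depth
#' between the end of the upward window and the start of the downward
#' window, day depth between the windows, and constant-speed linear ramps
#' inside each window.
#'
#' @param time_of_day Decimal hours in `[0, 24)`; vectorized.
#' @param schedule A [migration_schedule()].
#' @return Depth in meters (positive down).
#' @examples
#' sch <- migration_schedule(season_spec("JAS"))
#' organism_depth(12, sch) # 500
#' organism_depth(0, sch)  # 50
#' @export
organism_depth <- function(time_of_day, schedule) {
  stopifnot(inherits(schedule, "migration_schedule"))
  t <- time_of_day %% 24
  s <- schedule
  night <- s$night_depth; day <- s$day_depth
  vapply(t, function(ti) {
    if (ti < s$down_start) night
    else if (ti < s$down_end)
      night + (day - night) * (ti - s$down_start) / (s$down_end - s$down_start)
    else if (ti < s$up_start) day
    else if (ti < s$up_end)
      day + (night - day) * (ti - s$up_start) / (s$up_end - s$up_start)
    else night
  }, numeric(1))
}

#' eDNA shedding configuration
#'
#' Total cohort shedding rate and its split between the two particle size
#' classes. The rate is per unit time so that model output is invariant to
#' the solver time step; the default 360 units/h equals one mass unit per
#' 10-second step.
#'
#' @param rate Total shedding rate, eDNA mass units per hour (default 360).
#' @param f_lp Fraction of shed mass released as large particles, in
#'   `[0, 1]` (default 0.5, i.e. a 1:1 large-to-small ratio).
#' @return An object of class `shedding_config`.
#' @export
shedding_config <- function(rate = 360, f_lp = 0.5) {
  if (!(rate > 0)) stop("`rate` must be positive", call. = FALSE)
  if (!(f_lp >= 0 && f_lp <= 1)) stop("`f_lp` must be in [0, 1]", call. = FALSE)
  structure(list(rate = rate, f_lp = f_lp), class = "shedding_config")
}

#' Large-to-small particle ratio presets
#'
#' Named presets for the large-particle fraction `f_lp`. `"ratios"` maps the
#' shed-mass ratios LP:SP of 1:1, 1:2 and 2:1 to `f_lp` of 1/2, 1/3 and 2/3;
#' `"extremes"` uses all-small, half/half and all-large (0, 1/2, 1).
#'
#' @param which `"ratios"` (default) or `"extremes"`.
#' @return A numeric vector of three `f_lp` levels.
#' @export
f_lp_levels <- function(which = c("ratios", "extremes")) {
  switch(match.arg(which),
         ratios = c(1 / 2, 1 / 3, 2 / 3),
         extremes = c(0, 1 / 2, 1))
}

# Per-cell density weights (1/m) of a uniform deposit of unit mass over
# [center - h/2, center + h/2], clipped to the column; integral over depth
# is exactly 1 (renormalized if clipped).
deposit_weights <- function(center, h, grid) {
  lo <- max(0, center - h / 2)
  hi <- min(grid$depth_extent, center + h / 2)
  if (hi <= lo) stop("deposit layer lies entirely outside the column", call. = FALSE)
  e <- grid$edges
  ov <- pmin(e[-1L], hi) - pmax(e[-(grid$n + 1L)], lo)
  ov[ov < 0] <- 0
  ov / (sum(ov) * grid$dz) * (sum(ov) > 0)
}

#' Depth-resolved shedding source fields
#'
#' Converts the cohort state at a clock time into per-cell shedding rate
#' densities for the two particle classes. The migrating fraction `pm`
#' deposits in a `layer_thickness`-thick uniform layer centered on
#' [organism_depth()]; the non-migrating fraction deposits at the day depth.
#' The depth integral of `S_LP + S_SP` equals the configured total rate at
#' every instant.
#'
#' @param time_of_day Decimal hours.
#' @param schedule A [migration_schedule()].
#' @param shedding A [shedding_config()].
#' @param grid An [build_grid()] grid.
#' @return A list with `S_LP` and `S_SP`, per-cell rate densities in mass
#'   units per meter per hour.
#' @export
source_fields <- function(time_of_day, schedule, shedding, grid) {
  stopifnot(inherits(shedding, "shedding_config"))
  stopifnot_grid(grid)
  w_mig <- deposit_weights(organism_depth(time_of_day, schedule),
                           schedule$layer_thickness, grid)
  w_res <- deposit_weights(schedule$day_depth, schedule$layer_thickness, grid)
  s_tot <- shedding$rate * (schedule$pm * w_mig + (1 - schedule$pm) * w_res)
  list(S_LP = shedding$f_lp * s_tot, S_SP = (1 - shedding$f_lp) * s_tot)
}
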