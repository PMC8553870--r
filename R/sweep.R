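#' Sensitivity-sweep specification
#'
#' Factor levels for the full factorial sensitivity experiment. The default
#' levels reproduce the study design: 4 seasonal forcing profiles, 3
#' vertical advection modes, 3 settling rates, 3 decay-rate scenarios (low
#' constant 0.01 1/h, high constant 0.1 1/h, temperature-dependent), 3
#' migrating percentages and 3 large-to-small shed ratios, for 972 runs.
#'
#' @param seasons Character vector of season codes.
#' @param advection Advection modes (subset of `none`, `up`, `down`).
#' @param settling Settling rates, m/day.
#' @param decay Decay scenario labels (subset of `low`, `high`,
#'   `linear_in_T`).
#' @param pm Migrating fractions in `[0, 1]`.
#' @param f_lp Large-particle shed fractions (see [f_lp_levels()]).
#' @return An object of class `sweep_spec`.
#' @examples
#' nrow(enumerate_sensitivity_grid(sweep_spec())) # 972
#' @export
sweep_spec <- function(seasons = c("JFM", "AMJ", "JAS", "OND"),
                       advection = c("none", "up", "down"),
                       settling = c(0, 25, 50),
                       decay = c("low", "high", "linear_in_T"),
                       pm = c(0, 0.5, 1),
                       f_lp = f_lp_levels("ratios")) {
  lv <- list(season = seasons, advection = advection, settling = settling,
             decay = decay, pm = pm, f_lp = f_lp)
  if (any(lengths(lv) == 0))
    stop("every factor needs at least one level", call. = FALSE)
  if (!all(decay %in% c("low", "high", "linear_in_T")))
    stop("decay levels must be among low, high, linear_in_T", call. = FALSE)
  structure(lv, class = "sweep_spec")
}

decay_from_label <- function(label) {
  switch(label,
         low = decay_model("constant", k_const = 0.01),
         high = decay_model("constant", k_const = 0.1),
         linear_in_T = decay_model("linear_in_T"),
         stop("unknown decay label: ", label, call. = FALSE))
}

#' Enumerate the sensitivity grid
#'
#' Expands a [sweep_spec()] into one complete run configuration per row, in
#' deterministic lexicographic order (last factor varying fastest). The
#' default spec yields exactly 972 rows.
#'
#' @param spec A [sweep_spec()].
#' @return A data frame with columns `season`, `advection`, `settling`,
#'   `decay`, `pm`, `f_lp` and a `run` index.
#' @export
enumerate_sensitivity_grid <- function(spec = sweep_spec()) {
  stopifnot(inherits(spec, "sweep_spec"))
  g <- expand.grid(f_lp = spec$f_lp, pm = spec$pm, decay = spec$decay,
                   settling = spec$settling, advection = spec$advection,
                   season = spec$season,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("season", "advection", "settling", "decay", "pm", "f_lp")]
  g$run <- seq_len(nrow(g))
  g
}

#' Enumerate the percent-migrating study
#'
#' One run per season and migrating percentage 0 to 100% in 10-point steps:
#' 44 configurations with all other parameters at their defaults.
#'
#' @param seasons Character vector of season codes.
#' @param pm Migrating fractions (default `seq(0, 1, 0.1)`).
#' @return A data frame with `season`, `pm` and a `run` index.
#' @export
enumerate_pm_study <- function(seasons = c("JAS", "OND", "JFM", "AMJ"),
                               pm = seq(0, 1, by = 0.1)) {
  g <- expand.grid(pm = pm, season = seasons,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("season", "pm")]
  g$run <- seq_len(nrow(g))
  g
}

run_one_config <- function(season, advection = "none", settling = 25,
                           decay = "linear_in_T", pm = 1, f_lp = 0.5,
                           config = solver_config("desk"),
                           bins = depth_bins()) {
  spec <- season_spec(season)
  grid <- build_grid(config$depth_extent, config$dz)
  forcing <- forcing_profiles(spec, grid, advection_mode = advection,
                              decay = decay_from_label(decay))
  run_simulation(spec, shedding = shedding_config(f_lp = f_lp),
                 params = edna_params(settling_rate = settling),
                 forcing = forcing, config = config, bins = bins, pm = pm)
}

sim_metrics_row <- function(sim) {
  sb <- summarize_bins(sim)
  row <- data.frame(
    season = sim$spec$season, pm = sim$schedule$pm,
    settling = sim$params$settling_rate,
    decay = if (sim$forcing$decay$kind == "constant")
      sprintf("const_%g", sim$forcing$decay$k_const) else "linear_in_T",
    f_lp = sim$shedding$f_lp)
  for (i in 1:3) {
    b <- sb$bin[i]
    row[[paste0(b, "_min")]] <- sb$min[i]
    row[[paste0(b, "_mean")]] <- sb$mean[i]
    row[[paste0(b, "_max")]] <- sb$max[i]
    row[[paste0(b, "_sd")]] <- sb$sd[i]
  }
  row$ratio_mean <- tryCatch(surface_deep_ratio(sim, "mean"),
                             error = function(e) NA_real_)
  row$ratio_max <- tryCatch(surface_deep_ratio(sim, "max"),
                            error = function(e) NA_real_)
  eq <- equilibration_time(sim)
  row$equilibration_day <- as.numeric(eq)
  row$error <- NA_character_
  row
}

#' Execute a sweep and collect metrics
#'
#' Runs every configuration of an enumerated grid and returns one metrics
#' row per run (bin statistics, surface-to-deep ratios, equilibration day).
#' Runs are independent and deterministic, so the output is identical for a
#' given spec regardless of execution order. Per-run failures are recorded
#' in the `error` column rather than aborting the sweep.
#'
#' @param grid_df A data frame from [enumerate_sensitivity_grid()] or
#'   [enumerate_pm_study()] (missing factor columns fall back to defaults).
#' @param config A [solver_config()]; the `"desk"` preset is the default
#'   working scale.
#' @param bins A [depth_bins()] definition.
#' @param verbose Print progress lines.
#' @return A data frame with one row per configuration.
#' @export
run_sweep <- function(grid_df, config = solver_config("desk"),
                      bins = depth_bins(), verbose = FALSE) {
  stopifnot(is.data.frame(grid_df), nrow(grid_df) > 0)
  get_col <- function(nm, default) {
    if (nm %in% names(grid_df)) grid_df[[nm]] else rep(default, nrow(grid_df))
  }
  adv <- get_col("advection", "none")
  settl <- get_col("settling", 25)
  dec <- get_col("decay", "linear_in_T")
  pm <- get_col("pm", 1)
  flp <- get_col("f_lp", 0.5)
  rows <- vector("list", nrow(grid_df))
  for (i in seq_len(nrow(grid_df))) {
    if (verbose)
      message(sprintf("run %d/%d: %s pm=%g", i, nrow(grid_df),
                      grid_df$season[i], pm[i]))
    rows[[i]] <- tryCatch({
      sim <- run_one_config(grid_df$season[i], adv[i], settl[i], dec[i],
                            pm[i], flp[i], config, bins)
      sim_metrics_row(sim)
    }, error = function(e) {
      data.frame(season = grid_df$season[i], pm = pm[i], settling = settl[i],
                 decay = dec[i], f_lp = flp[i], error = conditionMessage(e))
    })
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    template <- rows[[which(vapply(rows, ncol, 0L) == max(vapply(rows, ncol, 0L)))[1]]]
    miss <- setdiff(names(template), names(r))
    for (m in miss) r[[m]] <- NA
    r[names(template)]
  }))
  out$run <- grid_df$run %||% seq_len(nrow(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a Pm calibration curve for a season
#'
#' Runs the model at migrating percentages 0 to 100% in 10-point steps and
#' stores the surface-to-deep concentration ratio at each knot together
#' with a monotone piecewise-linear interpolant. A non-monotone curve
#' signals a broken configuration and raises an error.
#'
#' @param season Season code.
#' @param config A [solver_config()].
#' @param mode Ratio mode, `"mean"` (default) or `"max"`.
#' @param ... Further arguments passed to [run_one_config()] (e.g.
#'   `settling`, `advection`).
#' @return An object of class `pm_calibration` with `pm` (%), `ratio`,
#'   `season`, `mode`.
#' @export
build_pm_calibration <- function(season, config = solver_config("desk"),
                                 mode = c("mean", "max"), ...) {
  mode <- match.arg(mode)
  pm <- seq(0, 1, by = 0.1)
  ratio <- vapply(pm, function(p) {
    sim <- run_one_config(season, pm = p, config = config, ...)
    surface_deep_ratio(sim, mode)
  }, numeric(1))
  if (any(diff(ratio) <= 0))
    stop("calibration curve is not strictly increasing in pm; ",
         "check the configuration", call. = FALSE)
  structure(list(pm = 100 * pm, ratio = ratio, season = season, mode = mode),
            class = "pm_calibration")
}

#' @export
print.pm_calibration <- function(x, ...) {
  cat(sprintf("<pm_calibration> %s (%s ratio): Cs/Cd %0.3g..%0.3g over pm 0..100%%\n",
              x$season, x$mode, min(x$ratio), max(x$ratio)))
  invisible(x)
}

#' Invert the migrating percentage from a measured ratio
#'
#' Monotone piecewise-linear inversion of a [build_pm_calibration()] curve.
#' Ratios above the pm = 100% knot clamp to 100% with attribute
#' `out_of_range = TRUE`.
#'
#' @param ratio Measured surface-to-deep concentration ratio (>= 0).
#' @param calibration A `pm_calibration`.
#' @return Estimated migrating percentage in `[0, 100]`.
#' @export
invert_pm <- function(ratio, calibration) {
  stopifnot(inherits(calibration, "pm_calibration"))
  if (any(ratio < 0)) stop("`ratio` must be non-negative", call. = FALSE)
  out_hi <- ratio > max(calibration$ratio)
  est <- stats::approx(calibration$ratio, calibration$pm, xout = ratio,
                       rule = 2, ties = "ordered")$y
  structure(est, out_of_range = any(out_hi))
}

#' Read a measured eDNA concentration profile
#'
#' Reads a two-column CSV (`depth_m`, `concentration`) of discrete-depth
#' eDNA measurements and computes bin-average concentrations by trapezoidal
#' integration over each bin's sampled depths (a single sample in a bin is
#' used directly). The surface and deep bins must each contain at least one
#' sample.
#'
#' @param file Path to the CSV.
#' @param bins A [depth_bins()] definition.
#' @return A list with per-bin average concentrations `surface`, `mid`,
#'   `deep` (possibly `NA` for an unsampled mid bin) and `ratio` = Cs/Cd.
#' @export
read_measured_profile <- function(file, bins = depth_bins()) {
  d <- utils::read.csv(file)
  if (ncol(d) < 2L)
    stop("expected two columns: depth_m, concentration", call. = FALSE)
  z <- d[[1L]]; v <- d[[2L]]
  o <- order(z); z <- z[o]; v <- v[o]
  bin_avg <- function(rng, name, required) {
    in_bin <- z >= rng[1] & z < rng[2]
    if (!any(in_bin)) {
      if (required)
        stop(sprintf("no samples in the %s bin (%g-%g m)", name, rng[1], rng[2]),
             call. = FALSE)
      return(NA_real_)
    }
    zi <- z[in_bin]; vi <- v[in_bin]
    if (length(zi) == 1L) return(vi)
    # trapezoid over the sampled span
    sum(diff(zi) * (utils::head(vi, -1) + utils::tail(vi, -1)) / 2) /
      (max(zi) - min(zi))
  }
  cs <- bin_avg(bins$surface, "surface", TRUE)
  cm <- bin_avg(bins$mid, "mid", FALSE)
  cd <- bin_avg(bins$deep, "deep", TRUE)
  if (cd <= 0) stop("deep-bin concentration is zero: ratio undefined", call. = FALSE)
  list(surface = cs, mid = cm, deep = cd, ratio = cs / cd)
}
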