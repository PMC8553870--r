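#' Write simulation output to plain-text files
#'
#' Writes the per-step depth-bin series (`<stem>_bins.csv`), the saved
#' concentration profiles in long form (`<stem>_profiles.csv`, columns
#' `time_days`, `depth_m`, `c_lp`, `c_sp`), and a JSON echo of the run
#' configuration (`<stem>_config.json`).
#'
#' @param sim An [run_simulation()] result.
#' @param stem Output path stem (directories must exist).
#' @return Invisibly, the paths written.
#' @export
write_simulation_csv <- function(sim, stem) {
  stopifnot(inherits(sim, "edna_sim"))
  paths <- c(bins = paste0(stem, "_bins.csv"),
             profiles = paste0(stem, "_profiles.csv"),
             config = paste0(stem, "_config.json"))
  utils::write.csv(sim$bin_series, paths[["bins"]], row.names = FALSE)
  if (length(sim$profile_times) > 0) {
    long <- data.frame(
      time_days = rep(sim$profile_times, each = sim$grid$n),
      depth_m = rep(sim$grid$centers, times = length(sim$profile_times)),
      c_lp = as.vector(sim$profiles_lp),
      c_sp = as.vector(sim$profiles_sp))
    utils::write.csv(long, paths[["profiles"]], row.names = FALSE)
  }
  cfg <- list(
    season = sim$spec$season, year = sim$spec$year,
    latitude = sim$spec$latitude, longitude = sim$spec$longitude,
    utc_offset = sim$spec$utc_offset,
    day_depth = sim$schedule$day_depth, night_depth = sim$schedule$night_depth,
    layer_thickness = sim$schedule$layer_thickness, pm = sim$schedule$pm,
    shedding_rate_per_h = sim$shedding$rate, f_lp = sim$shedding$f_lp,
    breakdown_rate_per_h = sim$params$breakdown_rate,
    settling_rate_m_per_day = sim$params$settling_rate,
    decay = unclass(sim$forcing$decay)[!vapply(unclass(sim$forcing$decay), is.null, TRUE)],
    dt_s = sim$config$dt, duration_days = sim$config$duration_days,
    dz_m = sim$grid$dz, depth_extent_m = sim$grid$depth_extent,
    budget = mass_budget(sim))
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Save or load a Pm calibration curve
#'
#' Calibration curves are stored as JSON with the season, ratio mode and the
#' eleven (pm, ratio) knots.
#'
#' @param calibration A [build_pm_calibration()] object.
#' @param file Path to a JSON file.
#' @return `write_calibration_json` returns `file` invisibly;
#'   `read_calibration_json` returns a `pm_calibration`.
#' @export
write_calibration_json <- function(calibration, file) {
  stopifnot(inherits(calibration, "pm_calibration"))
  jsonlite::write_json(unclass(calibration), file, auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!all(c("pm", "ratio", "season", "mode") %in% names(x)))
    stop("not a calibration file: ", file, call. = FALSE)
  structure(x[c("pm", "ratio", "season", "mode")], class = "pm_calibration")
}
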