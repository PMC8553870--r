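#' Season specification
#'
#' Describes one of the four three-month seasons used by the model and the
#' location/time conventions used to compute sunrise and sunset. All clock
#' times in the package are local standard time (fixed UTC offset, no
#' daylight saving), expressed as decimal hours since local midnight.
#'
#' @param season One of `"JFM"`, `"AMJ"`, `"JAS"`, `"OND"` (winter, spring,
#'   summer, fall in the northern hemisphere).
#' @param year Calendar year used for the solar calculation (default 2019).
#' @param latitude Degrees north (default 42.35).
#' @param longitude Degrees east (default -71.05, i.e. 71.05 W).
#' @param utc_offset Hours relative to UTC for local standard time
#'   (default -5).
#'
#' @return An object of class `season_spec`.
#' @examples
#' season_spec("JAS")
#' @export
season_spec <- function(season = c("JAS", "OND", "JFM", "AMJ"),
                        year = 2019, latitude = 42.35, longitude = -71.05,
                        utc_offset = -5) {
  season <- match.arg(season)
  months <- switch(season,
    JFM = 1:3, AMJ = 4:6, JAS = 7:9, OND = 10:12)
  if (abs(latitude) >= 66.5)
    stop("latitudes poleward of the polar circles are not supported", call. = FALSE)
  structure(
    list(season = season, months = months, year = year,
         latitude = latitude, longitude = longitude, utc_offset = utc_offset),
    class = "season_spec"
  )
}

#' @export
print.season_spec <- function(x, ...) {
  cat(sprintf("<season_spec> %s %d at (%.2f N, %.2f E), UTC%+d\n",
              x$season, x$year, x$latitude, x$longitude, x$utc_offset))
  invisible(x)
}

# NOAA solar-position equations (fractional year, equation of time, solar
# declination, hour angle at zenith 90.833 deg). One fixed-point refinement
# of the fractional year at the event time, matching the NOAA spreadsheet's
# use of the event's own time of day.
noaa_event <- function(doy, rise, latitude, longitude, utc_offset) {
  latr <- latitude * pi / 180
  t <- if (rise) 6 else 18 # initial guess, local hours
  for (it in 1:3) {
    g <- 2 * pi / 365 * (doy - 1 + (t - utc_offset - 12) / 24)
    eqt <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                       0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
    decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
      0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
      0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
    cosha <- cos(90.833 * pi / 180) / (cos(latr) * cos(decl)) -
      tan(latr) * tan(decl)
    if (cosha > 1 || cosha < -1)
      stop("sun does not rise/set on this date at this latitude", call. = FALSE)
    ha <- acos(cosha) * 180 / pi
    if (!rise) ha <- -ha
    t <- (720 - 4 * (longitude + ha) - eqt + utc_offset * 60) / 60
  }
  t
}

#' Sunrise and sunset times
#'
#' Computes sunrise and sunset in local standard time for a given date using
#' the standard NOAA solar-position equations (fractional year, equation of
#' time, solar declination, hour angle at zenith 90.833 degrees).
#'
#' @param date A `Date` (or string coercible to one).
#' @param spec A [season_spec()] supplying latitude, longitude and UTC offset.
#'
#' @return A list with `sunrise` and `sunset` in decimal hours (local
#'   standard time).
#' @examples
#' solar_events(as.Date("2019-07-15"), season_spec("JAS"))
#' @export
solar_events <- function(date, spec = season_spec("JAS")) {
  date <- as.Date(date)
  if (abs(spec$latitude) >= 66.5)
    stop("latitudes poleward of the polar circles are not supported", call. = FALSE)
  doy <- as.integer(strftime(date, "%j"))
  sr <- noaa_event(doy, TRUE, spec$latitude, spec$longitude, spec$utc_offset)
  ss <- noaa_event(doy, FALSE, spec$latitude, spec$longitude, spec$utc_offset)
  list(sunrise = sr, sunset = ss)
}

#' Seasonal mean migration clock times
#'
#' The model holds migration timing fixed within a season: the daily sunrise
#' and sunset times are averaged over every day of the season's three months
#' and those means anchor the migration windows for the whole run.
#'
#' @param spec A [season_spec()].
#' @return A list with `mean_sunrise` and `mean_sunset` in decimal hours.
#' @examples
#' seasonal_migration_times(season_spec("JAS"))
#' @export
seasonal_migration_times <- function(spec) {
  stopifnot(inherits(spec, "season_spec"))
  start <- as.Date(sprintf("%d-01-01", spec$year))
  days <- seq(start, as.Date(sprintf("%d-12-31", spec$year)), by = "day")
  days <- days[as.integer(strftime(days, "%m")) %in% spec$months]
  ev <- vapply(as.list(days), function(d) {
    e <- solar_events(d, spec)
    c(e$sunrise, e$sunset)
  }, numeric(2))
  list(mean_sunrise = mean(ev[1, ]), mean_sunset = mean(ev[2, ]))
}
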