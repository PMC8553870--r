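#' Depth-bin definition
#'
#' The three analysis layers bracketing the two residence depths: surface
#' (0-100 m), mid-depth (100-450 m) and deep (450-550 m). Proportions are
#' normalized over these three bins; mass below the deep bin (settled
#' material) is tracked separately.
#'
#' @param surface,mid,deep Two-element `c(top, bottom)` depth ranges in m.
#' @return An object of class `depth_bins`.
#' @export
depth_bins <- function(surface = c(0, 100), mid = c(100, 450),
                       deep = c(450, 550)) {
  b <- list(surface = surface, mid = mid, deep = deep)
  e <- unlist(b)
  if (any(diff(e) < 0) || any(e < 0))
    stop("bins must be disjoint, ordered and non-negative", call. = FALSE)
  structure(b, class = "depth_bins")
}

bin_widths <- function(bins) {
  vapply(unclass(bins), diff, numeric(1))
}

#' Depth-bin proportions of a concentration profile
#'
#' Integrates total eDNA (`C_LP + C_SP`) over each bin and normalizes by the
#' sum over the three bins, returning percentages that sum to 100.
#'
#' @param c_lp,c_sp Per-cell concentrations (mass/m); `c_sp` may be omitted
#'   if `c_lp` already holds the total.
#' @param grid An [build_grid()] grid.
#' @param bins A [depth_bins()] definition.
#' @return Named percentages `c(surface, mid, deep)`.
#' @examples
#' g <- build_grid(1500, 2)
#' conc <- as.numeric(g$centers < 550) # uniform over 0-550 m
#' bin_proportions(conc, grid = g)
#' @export
bin_proportions <- function(c_lp, c_sp = NULL, grid, bins = depth_bins()) {
  stopifnot_grid(grid)
  tot <- if (is.null(c_sp)) c_lp else c_lp + c_sp
  id <- bin_ids(grid, bins)
  m <- vapply(1:3, function(b) sum(tot[id == b]) * grid$dz, numeric(1))
  if (sum(m) <= 0)
    stop("no eDNA mass within the bins: proportions undefined", call. = FALSE)
  stats::setNames(100 * m / sum(m), c("surface", "mid", "deep"))
}

# Per-step bin proportions (%) over the three named bins, from a run's bin
# series (or a plain data frame with surface/mid/deep columns).
bin_proportion_series <- function(x) {
  bs <- if (inherits(x, "edna_sim")) x$bin_series else x
  m <- as.matrix(bs[, c("surface", "mid", "deep")])
  tot <- rowSums(m)
  keep <- tot > 0
  p <- 100 * m[keep, , drop = FALSE] / tot[keep]
  attr(p, "time_days") <- bs$time_days[keep]
  p
}

#' Summary statistics of the depth-bin proportion series
#'
#' Minimum, mean, maximum and (population) standard deviation of the
#' percentage of eDNA in each depth bin over the whole run, including
#' spin-up unless `exclude_days` is set.
#'
#' @param x An [run_simulation()] result or its `bin_series` data frame.
#' @param exclude_days Initial days to drop before computing statistics
#'   (default 0).
#' @return A data frame with one row per bin and columns `bin`, `min`,
#'   `mean`, `max`, `sd`.
#' @export
summarize_bins <- function(x, exclude_days = 0) {
  p <- bin_proportion_series(x)
  td <- attr(p, "time_days")
  if (exclude_days > 0) p <- p[td > exclude_days, , drop = FALSE]
  if (nrow(p) == 0) stop("empty bin series", call. = FALSE)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  data.frame(
    bin = c("surface", "mid", "deep"),
    min = apply(p, 2, min), mean = colMeans(p), max = apply(p, 2, max),
    sd = apply(p, 2, pop_sd), row.names = NULL)
}

#' Surface-to-deep concentration ratio
#'
#' Ratio of the surface-bin to deep-bin eDNA concentration, the observable
#' used to infer the migrating percentage. For `mode = "mean"` each bin is
#' summarized by its bin-average concentration (bin mass divided by bin
#' thickness); for `mode = "max"` by its per-step maximum concentration.
#' Both series are averaged over the run before taking the ratio.
#'
#' @param x An [run_simulation()] result or its `bin_series` data frame.
#' @param mode `"mean"` (default) or `"max"`.
#' @param bins The [depth_bins()] used for the run (for bin thicknesses).
#' @return The dimensionless ratio Cs/Cd.
#' @export
surface_deep_ratio <- function(x, mode = c("mean", "max"),
                               bins = depth_bins()) {
  mode <- match.arg(mode)
  bs <- if (inherits(x, "edna_sim")) x$bin_series else x
  if (inherits(x, "edna_sim")) bins <- x$bins
  w <- bin_widths(bins)
  if (mode == "mean") {
    cs <- mean(bs$surface) / w[["surface"]]
    cd <- mean(bs$deep) / w[["deep"]]
  } else {
    cs <- mean(bs$max_surface)
    cd <- mean(bs$max_deep)
  }
  if (cd <= 0) stop("deep-bin concentration is zero: ratio undefined", call. = FALSE)
  cs / cd
}

#' Equilibration time of the bin proportions
#'
#' First day after which every daily-mean bin proportion changes by less
#' than `tolerance` percentage points per day for the remainder of the run.
#'
#' @param x An [run_simulation()] result or bin-series data frame.
#' @param tolerance Points per day (default 1).
#' @return Days (integer-valued). If the series never stabilizes, the run
#'   length is returned with attribute `stabilized = FALSE`.
#' @export
equilibration_time <- function(x, tolerance = 1) {
  p <- bin_proportion_series(x)
  td <- attr(p, "time_days")
  day <- ceiling(td - 1e-9)
  days <- sort(unique(day))
  dm <- t(vapply(days, function(d) colMeans(p[day == d, , drop = FALSE]),
                 numeric(3)))
  if (nrow(dm) < 2) return(structure(0, stabilized = TRUE))
  chg <- apply(abs(diff(dm)), 1, max) # change from day i to day i+1
  ok <- rev(cumprod(rev(chg < tolerance))) == 1
  if (!any(ok)) return(structure(days[length(days)], stabilized = FALSE))
  # chg[i] is the change across the boundary after day i; a series whose
  # very first daily comparison is already stable counts as day 0
  structure(max(days[which(ok)[1]] - 1, 0), stabilized = TRUE)
}

# Time (h per 24 h) the trajectory spends in each depth bin, by exact
# piecewise integration of the daily trajectory.
trajectory_occupancy <- function(schedule, bins) {
  s <- schedule
  segs <- list( # t0, t1, d0, d1
    c(0, s$down_start, s$night_depth, s$night_depth),
    c(s$down_start, s$down_end, s$night_depth, s$day_depth),
    c(s$down_end, s$up_start, s$day_depth, s$day_depth),
    c(s$up_start, s$up_end, s$day_depth, s$night_depth),
    c(s$up_end, 24, s$night_depth, s$night_depth))
  occ <- c(surface = 0, mid = 0, deep = 0)
  rng <- rbind(bins$surface, bins$mid, bins$deep)
  for (sg in segs) {
    t0 <- sg[1]; t1 <- sg[2]; d0 <- sg[3]; d1 <- sg[4]
    if (t1 <= t0) next
    lo <- min(d0, d1); hi <- max(d0, d1)
    for (b in 1:3) {
      if (hi == lo) { # stationary segment
        if (lo >= rng[b, 1] && lo < rng[b, 2]) occ[b] <- occ[b] + (t1 - t0)
      } else {        # constant-speed ramp: time in bin ~ path length in bin
        ov <- max(0, min(hi, rng[b, 2]) - max(lo, rng[b, 1]))
        occ[b] <- occ[b] + (t1 - t0) * ov / (hi - lo)
      }
    }
  }
  occ
}

#' Semi-analytic box-model prediction of bin proportions
#'
#' Independent first-order check on the full solver: at equilibrium each
#' bin's eDNA standing stock is proportional to the rate at which the source
#' occupies the bin divided by the bin's decay rate. The migrating cohort's
#' occupancy comes from exact integration of the daily trajectory (ramp time
#' allocated by path length through each bin); the resident cohort sits in
#' the bin containing the day depth. Transport between bins is neglected.
#'
#' @param schedule A [migration_schedule()] (its `pm` is used).
#' @param k_per_bin Decay rates for (surface, mid, deep), 1/h.
#' @param bins A [depth_bins()] definition.
#' @return Named percentages `c(surface, mid, deep)` summing to 100.
#' @export
occupancy_box_model <- function(schedule, k_per_bin, bins = depth_bins()) {
  stopifnot(length(k_per_bin) == 3, all(k_per_bin > 0))
  occ_mig <- trajectory_occupancy(schedule, bins)
  occ_res <- c(surface = 0, mid = 0, deep = 0)
  rng <- rbind(bins$surface, bins$mid, bins$deep)
  for (b in 1:3)
    if (schedule$day_depth >= rng[b, 1] && schedule$day_depth < rng[b, 2])
      occ_res[b] <- 24
  occ <- schedule$pm * occ_mig + (1 - schedule$pm) * occ_res
  stock <- occ / k_per_bin
  stats::setNames(100 * stock / sum(stock), c("surface", "mid", "deep"))
}

#' Bin-mean decay rates from a forcing profile
#'
#' Convenience for driving [occupancy_box_model()]: the mean decay rate
#' (1/h) over the cells of each depth bin.
#'
#' @param forcing An [forcing_profiles()] object.
#' @param bins A [depth_bins()] definition.
#' @return Rates `c(surface, mid, deep)` in 1/h.
#' @export
bin_mean_decay <- function(forcing, bins = depth_bins()) {
  id <- bin_ids(forcing$grid, bins)
  vapply(1:3, function(b) mean(forcing$decay_rate[id == b]) * 3600,
         numeric(1)) |>
    stats::setNames(c("surface", "mid", "deep"))
}
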