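#' Build the vertical model grid
#'
#' Discretizes the water column from the sea surface (z = 0) down to
#' `depth_extent` into cells of uniform thickness `dz`. Depth is positive
#' downward throughout the package.
#'
#' @param depth_extent Total column depth in meters (default 1500).
#' @param dz Cell thickness in meters (default 0.5). Must divide
#'   `depth_extent` exactly.
#'
#' @return An object of class `edna_grid`: a list with `depth_extent`, `dz`,
#'   `n` (cell count), `centers` (cell-center depths, surface to bottom) and
#'   `edges` (cell-edge depths, length `n + 1`).
#' @examples
#' g <- build_grid(1500, 0.5)
#' g$n # 3000
#' @export
build_grid <- function(depth_extent = 1500, dz = 0.5) {
  if (!is.numeric(depth_extent) || length(depth_extent) != 1L || depth_extent <= 0)
    stop("`depth_extent` must be a single positive number", call. = FALSE)
  if (!is.numeric(dz) || length(dz) != 1L || dz <= 0)
    stop("`dz` must be a single positive number", call. = FALSE)
  n_real <- depth_extent / dz
  n <- round(n_real)
  if (abs(n_real - n) > 1e-8 || n < 1)
    stop(sprintf("depth_extent (%g m) is not an integer multiple of dz (%g m)",
                 depth_extent, dz), call. = FALSE)
  edges <- (0:n) * dz
  structure(
    list(depth_extent = depth_extent, dz = dz, n = as.integer(n),
         centers = (edges[-1L] + edges[-(n + 1L)]) / 2, edges = edges),
    class = "edna_grid"
  )
}

#' @export
print.edna_grid <- function(x, ...) {
  cat(sprintf("<edna_grid> 0-%g m, dz = %g m, %d cells\n",
              x$depth_extent, x$dz, x$n))
  invisible(x)
}

is_grid <- function(x) inherits(x, "edna_grid")

stopifnot_grid <- function(x) {
  if (!is_grid(x)) stop("expected an `edna_grid` (see build_grid())", call. = FALSE)
  invisible(x)
}
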