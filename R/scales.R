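#' Decay timescale T90
#'
#' Time for 90% of released eDNA to decay under first-order kinetics with a
#' column/time-averaged rate constant: T90 = -ln(0.1) / k_avg.
#'
#' @param k_avg Average decay-rate constant, 1/h. Must be positive.
#' @return T90 in hours.
#' @examples
#' t90(0.06) # about 38.4 h
#' @export
t90 <- function(k_avg) {
  if (any(k_avg <= 0)) stop("`k_avg` must be positive", call. = FALSE)
  -log(0.1) / k_avg
}

#' Transport length scales over the decay timescale
#'
#' The vertical distances mixing, advection and settling can move eDNA
#' before 90% of it has decayed: L_mix = sqrt(kappa_v * T90), L_advect =
#' w_vm * T90, L_settle = w_s * T90, with T90 from [t90()]. With the
#' representative summer inputs (k_avg 0.06 1/h, kappa_v 1e-3 m^2/s, w_vm
#' 1e-4 m/s, w_s 10 m/day) these evaluate to about 11.8 m, 13.8 m and
#' 16.0 m. Note that w_vm * T90 at these inputs is 13.8 m, slightly above
#' the commonly quoted 13 m, which corresponds to rounding T90 down to 38 h
#' first; the exact value is returned.
#'
#' @param k_avg Average decay rate, 1/h.
#' @param kappa_v Maximum vertical diffusivity, m^2/s.
#' @param w_vm Maximum vertical velocity, m/s.
#' @param w_s Settling rate, m/day.
#' @return A list with `T90` (hours) and `L_mix`, `L_advect`, `L_settle`
#'   (meters).
#' @examples
#' length_scales(0.06, 1e-3, 1e-4, 10)
#' @export
length_scales <- function(k_avg, kappa_v = 1e-3, w_vm = 1e-4, w_s = 10) {
  if (any(c(kappa_v, w_vm, w_s) < 0))
    stop("transport parameters must be non-negative", call. = FALSE)
  T90_h <- t90(k_avg)
  T90_s <- T90_h * 3600
  list(T90 = T90_h,
       L_mix = sqrt(kappa_v * T90_s),
       L_advect = w_vm * T90_s,
       L_settle = w_s * T90_h / 24)
}
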