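#' Microclimate parameters
#'
#' Parameters of the biofilm-air interface model: the Magnus saturation vapor
#' pressure coefficients, the biofilm thickness, the thermal boundary-layer
#' thickness, and the effective thermal transport coefficients of air and
#' biofilm. Only the ratio `k_a / k_b` (together with the two thicknesses)
#' enters the interface temperature, so the two coefficients act as effective
#' weights of air versus stone temperature.
#'
#' @param b,c Magnus coefficients (dimensionless; degC). Defaults 17.62 and
#'   243.12 degC, the standard Magnus parameterization over liquid water.
#' @param lambda biofilm thickness \[m\]; default 15e-6 (15 um, the thin-film
#'   regime in which the homogeneous, fully penetrated assumption holds).
#' @param delta thermal boundary-layer thickness \[m\]; default 1e-3.
#' @param k_a,k_b thermal transport coefficients of air and biofilm
#'   \[W m-1 K-1\]; defaults 0.026 (air) and 0.6 (water-like film).
#' @return an object of class `sab_microclimate`.
#' @export
microclimate_params <- function(b = 17.62, c = 243.12, lambda = 15e-6,
                                delta = 1e-3, k_a = 0.026, k_b = 0.6) {
  stopifnot(c > 0, lambda > 0, delta > 0, k_a > 0, k_b > 0)
  structure(list(b = b, c = c, lambda = lambda, delta = delta,
                 k_a = k_a, k_b = k_b),
            class = "sab_microclimate")
}

# Magnus saturation vapor pressure [hPa]; shared by the forcing generator
# (dewpoint -> RH) and the water-activity formula so the two are consistent.
magnus_e_sat <- function(T_C, b = 17.62, c = 243.12) {
  if (any(T_C <= -c)) stop("temperature at or below the Magnus singularity -c")
  6.1094 * exp(b * T_C / (c + T_C))
}

#' Biofilm-air interface temperature
#'
#' Steady-state 1-D diffusive heat transport across the boundary layer and the
#' biofilm gives the interface temperature as a flux-matching weighted mean of
#' air and stone temperatures:
#' `T* = (T_a k_a lambda + T_s delta k_b) / (lambda k_a + delta k_b)`.
#' It always lies between `T_a` and `T_s`; with the default thin film it is
#' dominated by the stone temperature.
#'
#' @param T_a air temperature \[degC\] (vectorized).
#' @param T_s stone temperature \[degC\] (vectorized).
#' @param p an [microclimate_params()] object.
#' @return interface temperature \[degC\].
#' @export
interface_temperature <- function(T_a, T_s, p = microclimate_params()) {
  (T_a * p$k_a * p$lambda + T_s * p$delta * p$k_b) /
    (p$lambda * p$k_a + p$delta * p$k_b)
}

#' Biofilm water activity from air humidity and interface temperature
#'
#' `a_w = RH_a * exp(b T_a / (c + T_a)) * exp(-b T* / (c + T*))`, clipped to
#' \[0, 1\]. Equivalently `RH_a * e_sat(T_a) / e_sat(T*)`: the film equilibrates
#' with the ambient vapor pressure but at its own (interface) temperature, so
#' a stone surface warmer than the air dries the film (`a_w < RH_a`) and a
#' cooler one wets it, up to condensation at `a_w = 1`.
#'
#' @param RH_a ambient relative humidity, fraction in \[0, 1\] (vectorized).
#' @param T_a air temperature \[degC\].
#' @param T_star interface temperature \[degC\], from
#'   [interface_temperature()].
#' @param p an [microclimate_params()] object.
#' @return water activity in \[0, 1\].
#' @export
water_activity <- function(RH_a, T_a, T_star, p = microclimate_params()) {
  if (any(RH_a < 0 | RH_a > 1)) stop("RH_a must lie in [0, 1]")
  if (any(T_a <= -p$c) || any(T_star <= -p$c))
    stop("temperature at or below the Magnus singularity -c")
  aw <- RH_a * exp(p$b * T_a / (p$c + T_a)) * exp(-p$b * T_star / (p$c + T_star))
  pmin(pmax(aw, 0), 1)
}

#' Diel water-activity profile for a forcing
#'
#' Samples the forcing on a regular grid and composes
#' [interface_temperature()] and [water_activity()] pointwise (the
#' quasi-static, steady-state evaporation assumption).
#'
#' @param forcing an [sab_forcing()] object.
#' @param p an [microclimate_params()] object.
#' @param grid time step \[h\] (default 0.1).
#' @return data frame with columns `t`, `T_a`, `T_s`, `RH_a`, `I`, `T_star`,
#'   `a_w` over one 24 h period.
#' @export
#' @examples
#' prof <- aw_profile(make_diel_forcing(season_preset("summer")))
#' range(prof$a_w)
aw_profile <- function(forcing, p = microclimate_params(), grid = 0.1) {
  env <- sample_forcing(forcing, seq(0, 24, by = grid))
  env$T_star <- interface_temperature(env$T_a, env$T_s, p)
  env$a_w <- water_activity(env$RH_a, env$T_a, env$T_star, p)
  env
}
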