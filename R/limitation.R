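#' Combine limitation factors by the law of the minimum
#'
#' Each metabolic process rate is `k_i * M_i * min(phi_1, ..., phi_k)`: a
#' single limiting factor applies at any instant, avoiding the rate
#' underestimation of multiplicative composition.
#'
#' @param phis named numeric vector of limitation factors, each in \[0, 1\].
#' @return list with `f` (the minimum) and `limiting` (name of the argmin;
#'   first on ties).
#' @export
#' @examples
#' combine_limitations(c(light = 1, water = 0.3, ATP = 0.7))
combine_limitations <- function(phis) {
  if (length(phis) == 0) stop("need at least one limitation factor")
  if (any(!is.finite(phis)) || any(phis < -1e-12) || any(phis > 1 + 1e-12))
    stop("limitation factors must lie in [0, 1]")
  i <- which.min(phis)
  nm <- names(phis)
  list(f = max(0, min(1, phis[[i]])),
       limiting = if (is.null(nm)) as.character(i) else nm[i])
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Monod saturation, zero at zero substrate.
monod <- function(x, K) {
  x <- pmax(x, 0)
  x / (K + x)
}

# Droop subsistence-quota factor: zero at or below Q_min.
droop <- function(Q, Q_min) {
  ifelse(Q <= 0, 0, clip01(1 - Q_min / pmax(Q, 1e-300)))
}

# Carrier-capacity (product-inhibition) factor: zero when the pool is full.
quota_room <- function(Q, Q_max) clip01(1 - Q / Q_max)

#' Water-activity ramp limitation
#'
#' Linear increase from 0 at the minimum viable water activity `a_w_min` to 1
#' at pure water; every rate carrying this factor is fully suppressed at or
#' below `a_w_min` (default 0.6, the experimentally supported metabolic
#' shutdown level).
#'
#' @param a_w water activity in \[0, 1\] (vectorized).
#' @param a_w_min minimum viable water activity.
#' @return limitation factor in \[0, 1\].
#' @export
aw_ramp <- function(a_w, a_w_min = 0.6) {
  if (any(a_w < 0 | a_w > 1)) stop("a_w must lie in [0, 1]")
  clip01((a_w - a_w_min) / (1 - a_w_min))
}

#' Water-activity tent (osmotic-stress response) limitation
#'
#' Piecewise-linear tent: 0 at or below `a_w_min`, rising to 1 at `a_w_peak`,
#' falling back to 0 at pure water. Shapes processes that intensify under
#' moderate osmotic stress (the extra cyclic electron transport and
#' polysaccharide secretion) but cease both in desiccation and in pure water.
#'
#' @param a_w water activity in \[0, 1\] (vectorized).
#' @param a_w_min minimum viable water activity.
#' @param a_w_peak water activity of maximal response, in
#'   `(a_w_min, 1)`.
#' @return limitation factor in \[0, 1\].
#' @export
aw_tent <- function(a_w, a_w_min = 0.6, a_w_peak = 0.8) {
  if (any(a_w < 0 | a_w > 1)) stop("a_w must lie in [0, 1]")
  stopifnot(a_w_min < a_w_peak, a_w_peak < 1)
  up <- (a_w - a_w_min) / (a_w_peak - a_w_min)
  down <- (1 - a_w) / (1 - a_w_peak)
  clip01(pmin(up, down))
}

#' Light limitation, with optional photoinhibition
#'
#' Without inhibition a Monod response `I / (K_I + I)` (supremum 1). With
#' `K_I_inh` a Haldane response `I / (K_I + I + I^2 / K_I_inh)` normalized so
#' its interior maximum (at `I = sqrt(K_I * K_I_inh)`) equals 1; it describes
#' photodamage to PSII at high intensity, so only the non-cyclic pathway
#' carries it.
#'
#' @param I light intensity \[uE m-2 s-1\], non-negative (vectorized).
#' @param K_I half-saturation intensity \[uE m-2 s-1\].
#' @param K_I_inh photoinhibition constant \[uE m-2 s-1\], or `NULL` for the
#'   Monod form.
#' @return limitation factor in \[0, 1\].
#' @export
light_response <- function(I, K_I, K_I_inh = NULL) {
  if (any(I < 0)) stop("I must be non-negative")
  if (is.null(K_I_inh)) {
    I / (K_I + I)
  } else {
    I_opt <- sqrt(K_I * K_I_inh)
    peak <- I_opt / (K_I + I_opt + I_opt^2 / K_I_inh)
    clip01((I / (K_I + I + I^2 / K_I_inh)) / peak)
  }
}

# Darkness factor for night-time processes (respiration, acid reuptake).
darkness_response <- function(I, K_I) K_I / (K_I + pmax(I, 0))

#' Viable-pH window limitation
#'
#' Cardinal parabolic bump, zero outside `[pH_L, pH_U]`, maximal (1) at the
#' midpoint: `(pH - pH_L)(pH_U - pH) / ((pH_U - pH_L)/2)^2` clipped at 0.
#'
#' @param pH pH value (vectorized).
#' @param pH_L,pH_U window bounds, `pH_L < pH_U`.
#' @return limitation factor in \[0, 1\].
#' @export
ph_window <- function(pH, pH_L = 4.5, pH_U = 9.5) {
  if (pH_L >= pH_U) stop("pH_L must be below pH_U")
  half <- (pH_U - pH_L) / 2
  clip01((pH - pH_L) * (pH_U - pH) / half^2)
}

#' Photorespiration branching function
#'
#' Fraction of the light-independent carbon flux going to fixation rather
#' than photorespiration: `g_fix = 1 / (1 + gamma * S_O2 / S_DIC)`, with
#' `gamma` the inverse specificity factor of the carboxylation site. Oxygen
#' competing with inorganic carbon diverts the complementary fraction
#' `1 - g_fix` to released organic acids.
#'
#' @param S_O2 dissolved oxygen \[mol m-3\] (vectorized).
#' @param S_DIC dissolved inorganic carbon \[mol m-3\]; `g_fix = 0` by
#'   convention when `S_DIC = 0` (no substrate).
#' @param gamma_spec inverse specificity factor (dimensionless).
#' @return branching fraction in \[0, 1\].
#' @export
branching_fraction <- function(S_O2, S_DIC, gamma_spec) {
  if (any(S_O2 < 0) || any(S_DIC < 0)) stop("concentrations must be non-negative")
  ifelse(S_DIC <= 0, 0, 1 / (1 + gamma_spec * S_O2 / pmax(S_DIC, 1e-300)))
}

#' Total maintenance-energy requirement
#'
#' `f*_main = m0 + m1 * (1 - a_w)` \[mol ATP (mol C)-1 h-1\]: the osmotic
#' homeostasis cost grows linearly as water activity falls.
#'
#' @param a_w water activity in \[0, 1\] (vectorized).
#' @param m0 baseline maintenance rate \[mol ATP (mol C)-1 h-1\].
#' @param m1 osmotic-stress slope \[mol ATP (mol C)-1 h-1\].
#' @return required specific ATP expenditure.
#' @export
maintenance_requirement <- function(a_w, m0, m1) {
  if (any(a_w < 0 | a_w > 1)) stop("a_w must lie in [0, 1]")
  m0 + m1 * (1 - a_w)
}

#' Realized maintenance and energy-deficit decay
#'
#' When ATP production `omega` (gated by the stored-ATP Monod factor
#' `sigma = Q_ATP / (K_ATP + Q_ATP)`) covers the requirement `f*_main`, the
#' cell pays full maintenance and no decay occurs. Otherwise all available
#' ATP flux goes to maintenance and decay proceeds in proportion to the unmet
#' fraction: `f_d = k_d * (1 - s)` with sufficiency
#' `s = min(1, (omega / f*_main) * sigma)`.
#'
#' @param omega specific ATP production rate \[mol ATP (mol C)-1 h-1\].
#' @param f_star_main total maintenance requirement, from
#'   [maintenance_requirement()].
#' @param Q_ATP ATP quota \[mol ATP / mol C\].
#' @param k_d maximum decay rate \[h-1\].
#' @param K_ATP ATP-quota half-saturation.
#' @return list with `f_main` (realized maintenance), `f_d` (decay factor)
#'   and `sufficiency` `s`.
#' @export
maintenance_and_decay <- function(omega, f_star_main, Q_ATP, k_d, K_ATP) {
  stopifnot(omega >= 0, f_star_main >= 0, Q_ATP >= 0, k_d >= 0, K_ATP > 0)
  sigma <- Q_ATP / (K_ATP + Q_ATP)
  if (f_star_main == 0) {
    return(list(f_main = 0, f_d = 0, sufficiency = 1))
  }
  s <- min(1, (omega / f_star_main) * sigma)
  f_main <- if (s >= 1) f_star_main else omega * sigma
  list(f_main = f_main, f_d = k_d * (1 - s), sufficiency = s)
}
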