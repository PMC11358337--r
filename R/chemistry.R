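#' Carbonate and organic-acid chemistry parameters
#'
#' Dissolved CO2 and O2 are held at Henry's-law saturation with the atmosphere
#' (van 't Hoff temperature dependence); bicarbonate and the organic-acid
#' anion relax toward acid-base equilibrium with finite-rate kinetics; the
#' hydrogen-ion concentration is algebraic, recomputed from electroneutrality
#' at every evaluation. Concentrations are in mol m-3 throughout; pH is
#' reported on the conventional mol L-1 scale. Dissociation of bicarbonate to
#' carbonate is neglected (only relevant near pH 10.3, well above the regime
#' simulated here).
#'
#' @param KH_CO2_ref,KH_O2_ref Henry solubilities at `T_ref`
#'   \[mol m-3 atm-1\].
#' @param vantHoff_CO2,vantHoff_O2 van 't Hoff temperature coefficients \[K\].
#' @param T_ref reference temperature \[K\].
#' @param pCO2,pO2 atmospheric partial pressures \[atm\].
#' @param pKa_CO2 CO2/HCO3- dissociation pKa on the molar scale (default
#'   6.36); stored internally as `Ka_CO2 = 1000 * 10^-pKa` \[mol m-3\].
#' @param k_AB_CO2 CO2 hydration rate constant \[h-1\]; default fast relative
#'   to biology so bicarbonate tracks its quasi-equilibrium.
#' @param pKa_OA organic-acid pKa on the molar scale (default 3.83, glycolic
#'   acid, the dominant photorespiration byproduct).
#' @param k_AB_OA organic-acid interconversion rate constant
#'   \[m3 mol-1 h-1\].
#' @param Kw ion product of water \[(mol m-3)^2\]; default 1e-8 (= 1e-14 M^2).
#' @param S_An,S_Cat inert anion/cation concentrations \[mol m-3\]; default 0.
#' @return an object of class `sab_chemistry`.
#' @export
chemistry_params <- function(KH_CO2_ref = 34, vantHoff_CO2 = 2400,
                             KH_O2_ref = 1.3, vantHoff_O2 = 1700,
                             T_ref = 298.15, pCO2 = 4.15e-4, pO2 = 0.209,
                             pKa_CO2 = 6.36, k_AB_CO2 = 1000,
                             pKa_OA = 3.83, k_AB_OA = 1000,
                             Kw = 1e-8, S_An = 0, S_Cat = 0) {
  stopifnot(KH_CO2_ref > 0, KH_O2_ref > 0, T_ref > 0, pCO2 > 0, pO2 > 0,
            k_AB_CO2 > 0, k_AB_OA > 0, Kw > 0, S_An >= 0, S_Cat >= 0)
  structure(list(KH_CO2_ref = KH_CO2_ref, vantHoff_CO2 = vantHoff_CO2,
                 KH_O2_ref = KH_O2_ref, vantHoff_O2 = vantHoff_O2,
                 T_ref = T_ref, pCO2 = pCO2, pO2 = pO2,
                 pKa_CO2 = pKa_CO2, Ka_CO2 = 1000 * 10^(-pKa_CO2),
                 k_AB_CO2 = k_AB_CO2,
                 pKa_OA = pKa_OA, Ka_OA = 1000 * 10^(-pKa_OA),
                 k_AB_OA = k_AB_OA, Kw = Kw, S_An = S_An, S_Cat = S_Cat),
            class = "sab_chemistry")
}

#' Henry's-law saturation concentration of a dissolved gas
#'
#' `KH(T) = KH_ref * exp(vantHoff * (1/T_K - 1/T_ref))`, multiplied by the
#' atmospheric partial pressure. Solubility decreases with temperature
#' (positive van 't Hoff coefficient), so warm midday stone carries less
#' dissolved CO2 than the cool morning film.
#'
#' @param T_C temperature \[degC\] (vectorized).
#' @param gas `"CO2"` or `"O2"`.
#' @param p an [chemistry_params()] object.
#' @return saturation concentration \[mol m-3\].
#' @export
henry_saturation <- function(T_C, gas = c("CO2", "O2"), p = chemistry_params()) {
  gas <- match.arg(gas)
  if (any(T_C <= -273.15)) stop("temperature below absolute zero")
  T_K <- T_C + 273.15
  if (gas == "CO2") {
    p$KH_CO2_ref * exp(p$vantHoff_CO2 * (1 / T_K - 1 / p$T_ref)) * p$pCO2
  } else {
    p$KH_O2_ref * exp(p$vantHoff_O2 * (1 / T_K - 1 / p$T_ref)) * p$pO2
  }
}

#' Solve the charge balance for the hydrogen-ion concentration
#'
#' Electroneutrality `S_H + S_Cat = Kw/S_H + S_HCO3 + S_OA- + S_An` reduces to
#' a quadratic in `S_H` with the closed-form positive root
#' `S_H = (B + sqrt(B^2 + 4 Kw)) / 2`, `B = S_HCO3 + S_OA- + S_An - S_Cat`.
#' pH is `-log10(S_H / 1000)` (mol L-1 scale).
#'
#' @param S_HCO3 bicarbonate concentration \[mol m-3\] (vectorized).
#' @param S_OAminus organic-acid anion concentration \[mol m-3\].
#' @param p an [chemistry_params()] object.
#' @return list with components `S_H` \[mol m-3\] and `pH`.
#' @export
#' @examples
#' solve_hydrogen(0, 0)$pH # pure water: 7
solve_hydrogen <- function(S_HCO3, S_OAminus, p = chemistry_params()) {
  if (any(S_HCO3 < 0) || any(S_OAminus < 0)) stop("ionic inputs must be non-negative")
  B <- S_HCO3 + S_OAminus + p$S_An - p$S_Cat
  S_H <- (B + sqrt(B^2 + 4 * p$Kw)) / 2
  list(S_H = S_H, pH = -log10(S_H / 1000))
}

#' CO2 hydration rate toward bicarbonate equilibrium
#'
#' `r = k_AB_CO2 * (CO2_sat - S_H * S_HCO3 / Ka_CO2)` \[mol m-3 h-1\];
#' positive values produce bicarbonate (net hydration), negative values
#' outgas it back to CO2.
#'
#' @param CO2_sat dissolved CO2 concentration at Henry saturation
#'   \[mol m-3\].
#' @param S_H hydrogen-ion concentration \[mol m-3\].
#' @param S_HCO3 bicarbonate concentration \[mol m-3\].
#' @param p an [chemistry_params()] object.
#' @return rate \[mol m-3 h-1\].
#' @export
co2_hydration_rate <- function(CO2_sat, S_H, S_HCO3, p = chemistry_params()) {
  if (any(CO2_sat < 0) || any(S_H < 0) || any(S_HCO3 < 0))
    stop("inputs must be non-negative")
  p$k_AB_CO2 * (CO2_sat - S_H * S_HCO3 / p$Ka_CO2)
}

#' Organic-acid interconversion rate
#'
#' `r = k_AB_OA * (S_OA- * (Ka_OA + S_H) - Ka_OA * S_TOA)` \[mol m-3 h-1\].
#' Sign convention: positive `r` consumes the anion (association); the anion
#' balance applies it with negative stoichiometry. The rate vanishes at the
#' dissociation equilibrium `S_OA-/S_TOA = Ka_OA / (Ka_OA + S_H)`.
#'
#' @param S_TOA total organic-acid concentration \[mol C m-3\].
#' @param S_OAminus anion concentration \[mol C m-3\], `<= S_TOA`.
#' @param S_H hydrogen-ion concentration \[mol m-3\].
#' @param p an [chemistry_params()] object.
#' @return rate \[mol m-3 h-1\].
#' @export
oa_dissociation_rate <- function(S_TOA, S_OAminus, S_H, p = chemistry_params()) {
  if (any(S_TOA < 0) || any(S_OAminus < 0) || any(S_H < 0))
    stop("inputs must be non-negative")
  if (any(S_OAminus > S_TOA * (1 + 1e-9) + 1e-15))
    stop("S_OAminus exceeds S_TOA (undissociated acid would be negative)")
  p$k_AB_OA * (S_OAminus * (p$Ka_OA + S_H) - p$Ka_OA * S_TOA)
}

#' Instantaneous derived chemistry of the biofilm liquid phase
#'
#' Bundles the algebraic chemistry evaluated at one instant: Henry-saturated
#' CO2 and O2 at the interface temperature, total dissolved inorganic carbon
#' `S_DIC = S_CO2 + S_HCO3`, and the charge-balance hydrogen ion / pH.
#'
#' @param S_HCO3,S_OAminus dissolved ionic concentrations \[mol m-3\]
#'   (vectorized).
#' @param T_star interface temperature \[degC\].
#' @param a_w water activity (carried through for diagnostics).
#' @param p an [chemistry_params()] object.
#' @return list with `S_CO2`, `S_O2`, `S_DIC`, `S_H`, `pH`, `a_w`, `T_star`.
#' @export
derived_chemistry <- function(S_HCO3, S_OAminus, T_star, a_w = NA_real_,
                              p = chemistry_params()) {
  S_CO2 <- henry_saturation(T_star, "CO2", p)
  S_O2 <- henry_saturation(T_star, "O2", p)
  h <- solve_hydrogen(S_HCO3, S_OAminus, p)
  list(S_CO2 = S_CO2, S_O2 = S_O2, S_DIC = S_CO2 + S_HCO3,
       S_H = h$S_H, pH = h$pH, a_w = a_w, T_star = T_star)
}
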