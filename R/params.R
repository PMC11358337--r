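#' Kinetic and stoichiometric parameters of the metabolic network
#'
#' Maximum specific rates, half-saturations, quota bounds, energetic yields
#' and the water-activity / pH response parameters of both guilds. Rate
#' constants are per hour in the currency of each process (mol NADPH, mol
#' ATP, mol C or mol N per mol functional-biomass C per hour). Defaults are
#' order-of-magnitude choices producing day-scale dynamics; all are exposed
#' in the `[kinetics]` config block.
#'
#' @param k_nc maximum non-cyclic photophosphorylation rate
#'   \[mol NADPH (mol C)-1 h-1\].
#' @param k_cy basal cyclic photophosphorylation rate
#'   \[mol ATP (mol C)-1 h-1\].
#' @param dk_cy maximum stress increment of the cyclic rate.
#' @param k_fix maximum carbon fixation rate \[mol C (mol C)-1 h-1\] (shared
#'   between fixation and photorespiration via the branching function).
#' @param k_Nfix maximum nitrogen fixation rate \[mol N (mol C)-1 h-1\].
#' @param k_growth_C,k_growth_H maximum growth rates \[h-1\].
#' @param k_pol maximum polysaccharide secretion rate
#'   \[mol C (mol C)-1 h-1\].
#' @param k_resp maximum respiration rate \[mol C (mol C)-1 h-1\] (both
#'   guilds).
#' @param k_uptake maximum organic-acid uptake rate
#'   \[mol C (mol C)-1 h-1\] (both guilds).
#' @param k_scav maximum scavenging rate \[per substrate currency, h-1\].
#' @param gamma_spec inverse specificity factor of the carboxylation site.
#' @param K_I light half-saturation \[uE m-2 s-1\]; also sets the darkness
#'   factor `K_I / (K_I + I)` of night-time processes.
#' @param K_I_inh photoinhibition constant \[uE m-2 s-1\] (Haldane form of
#'   the non-cyclic pathway).
#' @param K_I_dark darkness half-saturation \[uE m-2 s-1\] of the night-time
#'   gate `K_I_dark / (K_I_dark + I)` on respiration and organic-acid
#'   reuptake; small so these switch on only near darkness.
#' @param K_DIC,K_TOA half-saturations for dissolved inorganic carbon and
#'   total organic acid \[mol m-3\].
#' @param K_POL,K_CDB,K_NDB half-saturations for scavenging substrates,
#'   expressed as biofilm-volume concentrations \[mol m-3\].
#' @param Q_SOC_min,Q_SOC_max stored-organic-carbon quota bounds
#'   \[mol C / mol C\] (Droop subsistence and storage capacity).
#' @param Q_N_min,Q_N_max bound-nitrogen quota bounds \[mol N / mol C\].
#' @param Q_ATP_max,Q_NADPH_max carrier pool capacities \[mol / mol C\].
#' @param K_ATP,K_NADPH carrier-quota half-saturations \[mol / mol C\].
#' @param a_w_min minimum viable water activity (all metabolism suppressed at
#'   or below it; default 0.6).
#' @param a_w_peak water activity of maximal osmotic-stress response.
#' @param pH_L,pH_U viable pH window for carbon fixation.
#' @param m0,m1 maintenance baseline and osmotic slope
#'   \[mol ATP (mol C)-1 h-1\].
#' @param k_d maximum decay rate \[h-1\].
#' @param rho biofilm molar density \[mol C m-3\]; the liquid volume is
#'   `V = M / rho`.
#' @param q_N_bio structural nitrogen content of functional biomass
#'   \[mol N / mol C\].
#' @param y_ATP_nc ATP produced per NADPH in the non-cyclic chain.
#' @param y_ATP_fix,y_NADPH_fix ATP and NADPH consumed per mol C in fixation
#'   (and, by assumption, photorespiration).
#' @param y_ATP_Nfix,y_NADPH_Nfix ATP and NADPH consumed per mol N fixed.
#' @param y_ATP_growth,y_NADPH_growth ATP and NADPH consumed per mol C of new
#'   biomass (heterotroph growth uses only the ATP term).
#' @param y_ATP_pol ATP consumed per mol C of polysaccharide secreted.
#' @param y_ATP_resp ATP produced per mol C respired.
#' @param y_ATP_scav ATP consumed per unit substrate scavenged.
#' @param strict_hetero_decay_mass if `TRUE`, scale heterotroph decay by the
#'   cyanobacterial biomass (an alternative convention retained for
#'   comparison); default `FALSE` scales it by heterotroph biomass.
#' @param strict_decay_gamma if `TRUE`, make decay proportional to the
#'   fulfilled-maintenance fraction instead of the unmet fraction; default
#'   `FALSE`.
#' @return an object of class `sab_kinetics`.
#' @export
kinetic_params <- function(k_nc = 0.35, k_cy = 0.04, dk_cy = 0.1,
                           k_fix = 0.2, k_Nfix = 0.015,
                           k_growth_C = 0.08, k_growth_H = 0.03,
                           k_pol = 0.03, k_resp = 0.06, k_uptake = 0.6,
                           k_scav = 0.08,
                           gamma_spec = 0.015,
                           K_I = 150, K_I_inh = 1000, K_I_dark = 1,
                           K_DIC = 0.005, K_TOA = 0.02,
                           K_POL = 250, K_CDB = 250, K_NDB = 25,
                           Q_SOC_min = 0.02, Q_SOC_max = 1.5,
                           Q_N_min = 0.02, Q_N_max = 0.25,
                           Q_ATP_max = 0.02, Q_NADPH_max = 0.02,
                           K_ATP = 0.002, K_NADPH = 0.002,
                           a_w_min = 0.6, a_w_peak = 0.8,
                           pH_L = 4.5, pH_U = 9.5,
                           m0 = 0.002, m1 = 0.02, k_d = 0.003,
                           rho = 5000, q_N_bio = 0.15,
                           y_ATP_nc = 0.5, y_ATP_fix = 2.5, y_NADPH_fix = 2,
                           y_ATP_Nfix = 8, y_NADPH_Nfix = 2,
                           y_ATP_growth = 2.5, y_NADPH_growth = 0.5,
                           y_ATP_pol = 0.5, y_ATP_resp = 5,
                           y_ATP_scav = 0.1,
                           strict_hetero_decay_mass = FALSE,
                           strict_decay_gamma = FALSE) {
  p <- as.list(environment())
  num <- p[!names(p) %in% c("strict_hetero_decay_mass", "strict_decay_gamma")]
  if (any(!vapply(num, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1))))
    stop("all kinetic parameters must be finite scalars")
  if (any(unlist(num) < 0)) stop("kinetic parameters must be non-negative")
  stopifnot(p$a_w_min < p$a_w_peak, p$a_w_peak < 1,
            p$pH_L < p$pH_U,
            p$Q_SOC_min < p$Q_SOC_max, p$Q_N_min < p$Q_N_max,
            p$rho > 0, p$K_ATP > 0, p$K_NADPH > 0)
  structure(p, class = "sab_kinetics")
}

#' @export
print.sab_kinetics <- function(x, ...) {
  cat(sprintf("<sab_kinetics> k_growth_C %g h-1, k_fix %g h-1, a_w_min %g, pH window [%g, %g], rho %g mol C m-3\n",
              x$k_growth_C, x$k_fix, x$a_w_min, x$pH_L, x$pH_U, x$rho))
  invisible(x)
}
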