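#' Names of the extensive state variables
#'
#' The integrated state is extensive throughout: functional biomasses
#' `M_C`, `M_H` \[mol C\], carrier/reserve pools `E_* = M * Q` \[mol\],
#' extracellular masses `M_POL`, `M_CDB` \[mol C\], `M_NDB` \[mol N\], and
#' dissolved amounts `A_* = V * S_*` \[mol\]. Quotas and concentrations are
#' derived outputs; integrating products keeps elemental audits exact and
#' absorbs volume change without an explicit dilution term.
#'
#' @return character vector of the 15 state names.
#' @export
state_names <- function() {
  c("M_C", "E_SOC_C", "E_N_C", "E_ATP_C", "E_NADPH_C",
    "M_H", "E_SOC_H", "E_N_H", "E_ATP_H",
    "M_POL", "M_CDB", "M_NDB", "A_TOA", "A_OA", "A_HCO3")
}

virtual_gas_names <- function() c("CO2_gas", "O2_gas", "N2_gas")

# Carbon and nitrogen content per unit of each state (and virtual gas row).
# A_OA is a speciation sub-pool of A_TOA and carries no extra carbon.
elemental_composition <- function(q_N_bio) {
  nm <- c(state_names(), virtual_gas_names())
  cC <- stats::setNames(numeric(length(nm)), nm)
  cN <- cC
  cC[c("M_C", "E_SOC_C", "M_H", "E_SOC_H", "M_POL", "M_CDB",
       "A_TOA", "A_HCO3", "CO2_gas")] <- 1
  cN[c("E_N_C", "E_N_H", "M_NDB", "N2_gas")] <- 1
  cN[c("M_C", "M_H")] <- q_N_bio
  list(C = cC, N = cN)
}

#' Build the stoichiometric matrix of the metabolic network
#'
#' One column per process (see [process_names()]), one row per extensive
#' state plus three virtual gas rows (CO2, O2, N2) that are not integrated
#' but close the carbon and nitrogen balances of every column. The biological
#' entries are written down; the virtual CO2 and N2 entries are then solved
#' from the elemental content of the biological entries, so closure holds by
#' construction for any parameter values.
#'
#' Three groups of entries are state-dependent and must be supplied: the
#' decay columns route the decaying cell's current quotas to the
#' decayed-biomass pools; inorganic-carbon assimilation draws bicarbonate and
#' gaseous CO2 in proportion `beta_HCO3 : (1 - beta_HCO3)` to their
#' instantaneous availability; and organic-acid uptake removes the anion in
#' the current dissociated fraction `alpha_OA` (a pure speciation entry with
#' no elemental weight).
#'
#' @param p an [kinetic_params()] object.
#' @param Q_C named list/vector of cyanobacterial quotas `Q_SOC`, `Q_N`,
#'   `Q_ATP`, `Q_NADPH` used in the decay column.
#' @param Q_H heterotroph quotas `Q_SOC`, `Q_N`, `Q_ATP`.
#' @param beta_HCO3 fraction of assimilated inorganic carbon drawn from
#'   bicarbonate (default 1).
#' @param alpha_OA dissociated fraction of the organic-acid pool
#'   (default 1).
#' @return an 18 x 19 matrix of class `sab_stoichiometry` with attribute
#'   `composition` (the elemental weight vectors).
#' @export
build_stoichiometry <- function(p = kinetic_params(),
                                Q_C = list(Q_SOC = 0.5, Q_N = 0.1,
                                           Q_ATP = 0.01, Q_NADPH = 0.01),
                                Q_H = list(Q_SOC = 0.5, Q_N = 0.1,
                                           Q_ATP = 0.01),
                                beta_HCO3 = 1, alpha_OA = 1) {
  stopifnot(beta_HCO3 >= 0, beta_HCO3 <= 1, alpha_OA >= 0, alpha_OA <= 1)
  rows <- c(state_names(), virtual_gas_names())
  cols <- process_names()
  K <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))

  # light-dependent electron transport [currency: mol NADPH; mol ATP]
  K["E_ATP_C", "r_nc"] <- p$y_ATP_nc
  K["E_NADPH_C", "r_nc"] <- 1
  K["O2_gas", "r_nc"] <- 0.5 # water splitting
  K["E_ATP_C", "r_cy"] <- 1

  # carbon fixation / photorespiration [mol C]
  K["E_SOC_C", "r_fix"] <- 1
  K["A_HCO3", "r_fix"] <- -beta_HCO3
  K["E_ATP_C", "r_fix"] <- -p$y_ATP_fix
  K["E_NADPH_C", "r_fix"] <- -p$y_NADPH_fix
  K["A_TOA", "r_photo"] <- 1
  K["A_HCO3", "r_photo"] <- -beta_HCO3
  K["E_ATP_C", "r_photo"] <- -p$y_ATP_fix
  K["E_NADPH_C", "r_photo"] <- -p$y_NADPH_fix
  K["O2_gas", "r_photo"] <- -1

  # nitrogen fixation [mol N]
  K["E_N_C", "r_Nfix"] <- 1
  K["E_ATP_C", "r_Nfix"] <- -p$y_ATP_Nfix
  K["E_NADPH_C", "r_Nfix"] <- -p$y_NADPH_Nfix

  # growth [mol C of new functional biomass]
  K["M_C", "r_C_growth"] <- 1
  K["E_SOC_C", "r_C_growth"] <- -1
  K["E_N_C", "r_C_growth"] <- -p$q_N_bio
  K["E_ATP_C", "r_C_growth"] <- -p$y_ATP_growth
  K["E_NADPH_C", "r_C_growth"] <- -p$y_NADPH_growth

  # polysaccharide secretion [mol C]
  K["M_POL", "r_POLprod"] <- 1
  K["E_SOC_C", "r_POLprod"] <- -1
  K["E_ATP_C", "r_POLprod"] <- -p$y_ATP_pol

  # respiration [mol C]; cyanobacteria release the carbon as bicarbonate,
  # balancing the charge of night-time anion reuptake
  K["E_SOC_C", "r_C_resp"] <- -1
  K["A_HCO3", "r_C_resp"] <- 1
  K["E_ATP_C", "r_C_resp"] <- p$y_ATP_resp
  K["O2_gas", "r_C_resp"] <- -1

  # organic-acid uptake [mol C]; anion removed in its speciation fraction
  K["A_TOA", "r_C_uptake"] <- -1
  K["A_OA", "r_C_uptake"] <- -alpha_OA
  K["E_SOC_C", "r_C_uptake"] <- 1

  # maintenance [mol ATP]
  K["E_ATP_C", "r_C_main"] <- -1

  # decay [mol C of functional biomass], routing current quotas
  K["M_C", "r_C_d"] <- -1
  K["E_SOC_C", "r_C_d"] <- -Q_C$Q_SOC
  K["E_N_C", "r_C_d"] <- -Q_C$Q_N
  K["E_ATP_C", "r_C_d"] <- -Q_C$Q_ATP
  K["E_NADPH_C", "r_C_d"] <- -Q_C$Q_NADPH
  K["M_CDB", "r_C_d"] <- 1 + Q_C$Q_SOC
  K["M_NDB", "r_C_d"] <- Q_C$Q_N + p$q_N_bio

  # heterotroph scavenging [mol C; mol C; mol N]
  K["M_POL", "r_POL_scav"] <- -1
  K["E_SOC_H", "r_POL_scav"] <- 1
  K["E_ATP_H", "r_POL_scav"] <- -p$y_ATP_scav
  K["M_CDB", "r_CDB_scav"] <- -1
  K["E_SOC_H", "r_CDB_scav"] <- 1
  K["E_ATP_H", "r_CDB_scav"] <- -p$y_ATP_scav
  K["M_NDB", "r_NDB_scav"] <- -1
  K["E_N_H", "r_NDB_scav"] <- 1
  K["E_ATP_H", "r_NDB_scav"] <- -p$y_ATP_scav

  # heterotroph organic-acid uptake [mol C]
  K["A_TOA", "r_H_uptake"] <- -1
  K["A_OA", "r_H_uptake"] <- -alpha_OA
  K["E_SOC_H", "r_H_uptake"] <- 1

  # heterotroph respiration [mol C], released as gaseous CO2
  K["E_SOC_H", "r_H_resp"] <- -1
  K["E_ATP_H", "r_H_resp"] <- p$y_ATP_resp
  K["O2_gas", "r_H_resp"] <- -1

  # heterotroph growth [mol C]
  K["M_H", "r_H_growth"] <- 1
  K["E_SOC_H", "r_H_growth"] <- -1
  K["E_N_H", "r_H_growth"] <- -p$q_N_bio
  K["E_ATP_H", "r_H_growth"] <- -p$y_ATP_growth

  # heterotroph maintenance [mol ATP] and decay [mol C]
  K["E_ATP_H", "r_H_main"] <- -1
  K["M_H", "r_H_d"] <- -1
  K["E_SOC_H", "r_H_d"] <- -Q_H$Q_SOC
  K["E_N_H", "r_H_d"] <- -Q_H$Q_N
  K["E_ATP_H", "r_H_d"] <- -Q_H$Q_ATP
  K["M_CDB", "r_H_d"] <- 1 + Q_H$Q_SOC
  K["M_NDB", "r_H_d"] <- Q_H$Q_N + p$q_N_bio

  # close the virtual gas rows from the elemental content of each column
  comp <- elemental_composition(p$q_N_bio)
  bio <- state_names()
  K["CO2_gas", ] <- -as.numeric(comp$C[bio] %*% K[bio, ])
  K["N2_gas", ] <- -as.numeric(comp$N[bio] %*% K[bio, ])

  structure(K, class = c("sab_stoichiometry", "matrix", "array"),
            composition = comp)
}

#' Audit elemental closure of a stoichiometric matrix
#'
#' Weighs each column by the carbon and nitrogen content of every state
#' (virtual gas rows included) and reports the per-column residuals; a closed
#' network has residuals at machine precision.
#'
#' @param K a matrix from [build_stoichiometry()].
#' @return data frame with columns `process`, `C_residual`, `N_residual`.
#' @export
elemental_audit <- function(K) {
  comp <- attr(K, "composition")
  if (is.null(comp)) comp <- elemental_composition(kinetic_params()$q_N_bio)
  rows <- rownames(K)
  data.frame(process = colnames(K),
             C_residual = as.numeric(comp$C[rows] %*% K),
             N_residual = as.numeric(comp$N[rows] %*% K),
             row.names = NULL)
}
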