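# shared fixtures: small forcings and a constant-environment helper

summer_forcing <- function(resolution = 0.25) {
  make_diel_forcing(season_preset("summer"), resolution)
}

# flat forcing (no diel cycle) for analytic checks
constant_forcing <- function(T_a = 20, T_s = 20, RH = 0.8, I = 0) {
  sab_forcing(data.frame(time_h = c(0, 6, 12, 18), T_air_C = T_a,
                         T_stone_C = T_s, RH_air = RH, light_uE = I))
}

# replete chemistry snapshot for rate-function tests
replete_chem <- function(T_star = 25, p = chemistry_params()) {
  derived_chemistry(S_HCO3 = 2.4e-3, S_OAminus = 0, T_star = T_star, a_w = 1,
                    p = p)
}
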