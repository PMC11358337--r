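Package: sabsim
Title: Diel Metabolic Dynamics of Phototrophic Subaerial Biofilms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a thin subaerial biofilm (SAB) of cyanobacteria and
    heterotrophic bacteria coupled through a simplified metabolic network and
    driven by 24 h-periodic temperature, humidity and light forcing. Water
    activity at the stone-air interface gates every metabolic process;
    carbonate chemistry and a charge-balance pH close the abiotic loop. The
    package provides a synthetic diel forcing generator with seasonal presets,
    a stiff ODE model of quota (Droop-type) physiology with elemental
    conservation audits, periodic-state detection, and scenario runners for
    single-day, guild-ablation and cross-season studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
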