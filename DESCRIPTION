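Package: dfbalink
Title: Dynamic Flux Balance Analysis Coupling of Whole-Body PBPK Models
    and Stoichiometric Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples compartmental whole-body physiologically-based
    pharmacokinetic (PBPK) models with constraint-based metabolic networks
    through dynamic flux balance analysis (dFBA). Drug concentrations in
    liver tissue constrain enzyme fluxes through competitive-inhibition
    rate laws (indirect coupling), and flux-balance exchange rates replace
    PBPK clearance and production terms each minute (direct coupling).
    Ships a fixed-step PBPK ODE engine, a deterministic two-stage
    (parsimonious) flux balance solver, hand-verifiable hepatocyte fixture
    networks, three configured case studies (xanthine-oxidase inhibition by
    allopurinol, urea-cycle-disorder hyperammonemia, paracetamol-overdose
    liver robustness), virtual-population biomarker statistics, and an
    objective-panel robustness scanner with flux-change classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
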