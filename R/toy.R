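# Hand-verifiable fixture networks and whole-body parameter sets.
#
# All whole-body rates (production, clearance, network exchange fluxes)
# live on a shared reference-volume basis (micromol/L/min, the model's
# volume_basis), which is how the hepatocyte-network fluxes and the
# macroscopic clearance rates can be compared on one scale. Organ volumes
# only shape distribution; the reference basis carries the kinetics.

#' Toy hepatic ammonia-detoxification network
#'
#' A minimal hepatocyte network around the urea cycle: ammonia enters via
#' an uptake exchange and leaves as urea (the lumped urea-cycle reaction
#' contains ornithine transcarbamylase, OTC), glutamine (glutamate
#' dehydrogenase + glutamine synthetase, two ammonia-derived nitrogens
#' per glutamine) and alanine (transamination, one nitrogen). Glutamine
#' and alanine secretion are fixed physiological demands (bounds pinned
#' at the cap), reflecting the observed partitioning of hepatic ammonia
#' nitrogen of roughly 95% urea, 5% glutamine, 1% alanine; nitrogen
#' balance gives `uptake = 2 urea + 2 gln + ala`.
#'
#' @param glutamine_cap,alanine_cap secretion demands, micromol/L/min
#'   (defaults 0.008 and 0.002, ~5% and ~1% of baseline uptake in molar
#'   terms).
#' @param uptake_ub ammonia uptake upper bound, micromol/L/min (default
#'   0.163, the macroscopic hepatic clearance rate).
#' @return a [metabolic_network()]. The lumped urea-cycle reaction is
#'   tagged `"OTC"` in `notes`.
#' @examples
#' net <- make_ammonia_network()
#' sol <- fba(net, "EX_nh3")
#' flux_of(sol, c("EX_nh3", "EX_urea", "EX_gln", "EX_ala"))
#' @export
make_ammonia_network <- function(glutamine_cap = 0.008,
                                 alanine_cap = 0.002,
                                 uptake_ub = 0.163) {
  stopifnot(glutamine_cap >= 0, alanine_cap >= 0, uptake_ub >= 0)
  metabolic_network(tibble::tibble(
    reaction_id = c("EX_nh3", "GDH", "GS", "ALT", "urea_cycle",
                    "EX_urea", "EX_gln", "EX_ala",
                    "S_akg", "S_pyr", "S_co2"),
    equation = c(
      "-> nh3[c]",
      "akg[c] + nh3[c] -> glu[c]",
      "glu[c] + nh3[c] -> gln[c]",
      "glu[c] + pyr[c] -> ala[c] + akg[c]",
      "2 nh3[c] + co2[c] -> urea[c]",
      "urea[c] ->",
      "gln[c] ->",
      "ala[c] ->",
      "-> akg[c]", "-> pyr[c]", "-> co2[c]"),
    lb = c(0, 0, 0, 0, 0, 0, glutamine_cap, alanine_cap, 0, 0, 0),
    ub = c(uptake_ub, Inf, Inf, Inf, Inf, Inf,
           glutamine_cap, alanine_cap, Inf, Inf, Inf),
    notes = c("ammonia uptake", "", "", "", "OTC", "", "", "",
              "", "", "")))
}

#' Toy purine-degradation network (xanthine oxidase chain)
#'
#' Hypoxanthine is oxidised to xanthine and further to uric acid; both
#' oxidation steps are catalysed by xanthine oxidase and tagged `"XO"` so
#' that one inhibitable activity spans the chain (allopurinol and
#' oxypurinol inhibit both steps).
#'
#' @param supply_ub hypoxanthine supply upper bound, micromol/L/min.
#' @return a [metabolic_network()].
#' @export
make_purine_network <- function(supply_ub = Inf) {
  metabolic_network(tibble::tibble(
    reaction_id = c("S_hx", "XO1", "XO2", "EX_ua"),
    equation = c("-> hx[c]", "hx[c] -> xan[c]", "xan[c] -> ua[c]",
                 "ua[c] ->"),
    lb = 0, ub = c(supply_ub, Inf, Inf, Inf),
    notes = c("", "XO", "XO", "uric acid export")))
}

#' Reactions carrying an activity tag
#'
#' @param network a [metabolic_network()].
#' @param tag tag string matched against the `notes` column.
#' @return character vector of reaction ids.
#' @export
reactions_by_tag <- function(network, tag) {
  network$reactions$id[grepl(tag, network$reactions$notes, fixed = TRUE)]
}

#' Toy branched network and objective panel for robustness scans
#'
#' A small liver-task panel: amino-acid, carbohydrate, nucleotide and
#' conjugation arms share four inhibitable activities -- THFDH
#' (tetrahydrofolate supply), GDH (glutamate supply), ATPS (ATP supply)
#' and two glutathione-producing reactions (tagged GSH). Each panel
#' objective maximises one export; the constructed ground-truth
#' dependency of every objective on the inhibitable activities is
#' returned, so scans can be checked exactly.
#'
#' @param n_objectives number of panel objectives (up to 12, default 12);
#'   the first `n_objectives` of the constructed panel are returned.
#' @return list with `network` (a [metabolic_network()]), `panel` (tibble
#'   `name`, `objective`), and `depends` (named list: objective ->
#'   character vector of activity tags it requires).
#' @export
make_gsh_panel <- function(n_objectives = 12) {
  stopifnot(n_objectives >= 1, n_objectives <= 12)
  net <- metabolic_network(tibble::tibble(
    reaction_id = c(
      "S_pre", "S_cys", "S_gly", "S_akg", "S_nh3", "S_glc", "S_o2",
      "ATPS", "GDH", "THFDH", "GSH1", "GSH2",
      "R_lac", "R_pyr", "R_ket", "R_ox",
      "R_ala", "R_gln", "R_pur", "R_thy", "R_cre", "R_prot", "R_merc",
      "EX_lac", "EX_pyr", "EX_ket", "EX_ox", "EX_ala", "EX_gln",
      "EX_pur", "EX_thy", "EX_cre", "EX_prot", "EX_gsh", "EX_merc"),
    equation = c(
      "-> pre[c]", "-> cys[c]", "-> gly[c]", "-> akg[c]", "-> nh3[c]",
      "-> glc[c]", "-> o2[c]",
      "pre[c] -> atp[c]",
      "akg[c] + nh3[c] -> glu[c]",
      "pre[c] -> thf[c]",
      "glu[c] + cys[c] + gly[c] -> gsh[c]",
      "pre[c] + cys[c] -> gsh[c]",
      "glc[c] -> 2 lac[c]",
      "glc[c] -> 2 pyr[c]",
      "pre[c] -> ket[c]",
      "glc[c] + o2[c] -> ox[c]",
      "glu[c] + pre[c] -> ala[c] + akg[c]",
      "glu[c] + nh3[c] -> gln[c]",
      "thf[c] + pre[c] -> pur[c]",
      "thf[c] + gly[c] -> thy[c]",
      "atp[c] + pre[c] -> cre[c]",
      "atp[c] + thf[c] + pre[c] -> prot[c]",
      "gsh[c] + pre[c] -> merc[c]",
      "lac[c] ->", "pyr[c] ->", "ket[c] ->", "ox[c] ->", "ala[c] ->",
      "gln[c] ->", "pur[c] ->", "thy[c] ->", "cre[c] ->", "prot[c] ->",
      "gsh[c] ->", "merc[c] ->"),
    lb = 0,
    ub = c(10, 1, 1, 1, 1, 1, 1, rep(Inf, 28)),
    notes = c(rep("", 7), "ATPS", "GDH", "THFDH", "GSH", "GSH",
              rep("", 23))))
  depends <- list(
    EX_lac = character(0), EX_pyr = character(0), EX_ket = character(0),
    EX_ox = character(0),
    EX_ala = "GDH", EX_gln = "GDH",
    EX_pur = "THFDH", EX_thy = "THFDH",
    EX_cre = "ATPS", EX_prot = c("ATPS", "THFDH"),
    EX_gsh = "GSH", EX_merc = "GSH")
  keep <- names(depends)[seq_len(n_objectives)]
  list(network = net,
       panel = tibble::tibble(name = keep, objective = keep),
       depends = depends[keep])
}

# ---- whole-body PBPK fixtures ----------------------------------------------

.body_compartments <- function() {
  tibble::tibble(
    name = c("venous_blood", "arterial_blood", "liver", "kidney",
             "gut_lumen", "gut", "rest"),
    volume = c(3.6, 1.8, 1.8, 1.0, 1.0, 1.1, 31.7),
    sub_space = c("vascular", "vascular", "lumped", "lumped", "lumen",
                  "lumped", "lumped"))
}

.body_flows <- function() {
  # plasma-equivalent circulation, L/min; portal vein drains the gut
  tibble::tibble(
    source = c("arterial_blood", "arterial_blood", "gut", "liver",
               "arterial_blood", "kidney", "arterial_blood", "rest",
               "venous_blood"),
    target = c("liver", "gut", "liver", "venous_blood", "kidney",
               "venous_blood", "rest", "venous_blood", "arterial_blood"),
    rate = c(0.3, 1.0, 1.0, 1.3, 1.2, 1.2, 2.5, 2.5, 5.0))
}

#' Whole-body ammonia fixture
#'
#' A lumped one-box-per-organ model of systemic ammonia turnover:
#' zero-order whole-body production (in the rest-of-body compartment),
#' first-order hepatic metabolisation (the process that couples to the
#' liver network) and first-order renal excretion. Default clearance
#' constants are the analytic guesses for the printed macroscopic rates;
#' [calibrate_ammonia_model()] refines them against the healthy venous
#' target.
#'
#' @param production whole-body ammonia production on the reference
#'   volume basis, micromol/L/min (default 0.694; equivalently ~17 g/day
#'   split ~13 g renal, ~4 g hepatic).
#' @param liver_k,kidney_k first-order clearance constants, 1/min.
#' @param target_venous healthy venous concentration used for the
#'   analytic default constants, uM.
#' @return a [pbpk_model()] with species `nh3` and processes
#'   `liver_clearance`, `kidney_clearance`, `production`.
#' @export
ammonia_pbpk_model <- function(production = 0.694, liver_k = NULL,
                               kidney_k = NULL, target_venous = 29) {
  comp <- .body_compartments()
  basis <- sum(comp$volume)
  v_liv <- comp$volume[comp$name == "liver"]
  v_kid <- comp$volume[comp$name == "kidney"]
  v_rest <- comp$volume[comp$name == "rest"]
  liver_flux <- production * 4 / 17        # hepatic share of elimination
  kidney_flux <- production * 13 / 17
  liver_k <- liver_k %||num% (liver_flux * basis / (target_venous * v_liv))
  kidney_k <- kidney_k %||num% (kidney_flux * basis /
                                  (target_venous * v_kid))
  pbpk_model(
    compartments = comp, flows = .body_flows(),
    species = tibble::tibble(name = "nh3", mw = 17.03),
    processes = list(
      process_zero_order("production", "rest", "nh3",
                         rate = production * basis / v_rest),
      process_first_order("liver_clearance", "liver", "nh3", k = liver_k),
      process_first_order("kidney_clearance", "kidney", "nh3",
                          k = kidney_k)),
    volume_basis = basis)
}

#' Calibrate the ammonia fixture to the healthy venous steady state
#'
#' Fits the hepatic and renal first-order constants so that (i) the
#' venous steady-state concentration hits the healthy target and (ii)
#' the renal-to-hepatic elimination flux ratio equals the physiological
#' 13:4 mass split. Production is fixed by the whole-body mass balance.
#' Reports the calibrated macroscopic rates on the reference-volume
#' basis, which reproduce the production/liver/kidney rate triple.
#'
#' @param model an [ammonia_pbpk_model()].
#' @param target_venous healthy venous concentration, uM (default 29).
#' @param ss_tol,ss_max_time steady-state settings passed through.
#' @return a `pbpk_calibration` whose `$rates` element holds the
#'   basis-normalised steady-state rates (production, liver, kidney in
#'   micromol/L/min).
#' @export
calibrate_ammonia_model <- function(model, target_venous = 29,
                                    ss_tol = 1e-7, ss_max_time = 10080) {
  basis <- model$volume_basis
  memo <- new.env(parent = emptyenv())
  ss_fluxes <- function(m) {
    key <- paste(m$processes$liver_clearance$params$k,
                 m$processes$kidney_clearance$params$k, sep = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    ss <- steady_state(m, tol = ss_tol, max_time = ss_max_time)
    out <- list(
      venous = ss$concentrations$concentration_uM[
        ss$concentrations$compartment == "venous_blood"],
      liver = process_rate(m, "liver_clearance", ss$state) / basis,
      kidney = process_rate(m, "kidney_clearance", ss$state) / basis)
    memo[[key]] <- out
    out
  }
  cal <- calibrate(
    model,
    free_params = c("process/liver_clearance/k",
                    "process/kidney_clearance/k"),
    targets = list(
      list(name = "venous_ss",
           observable = function(m) ss_fluxes(m)$venous,
           value = target_venous),
      list(name = "renal_hepatic_ratio",
           observable = function(m) {
             f <- ss_fluxes(m); f$kidney / f$liver
           },
           value = 13 / 4)))
  f <- ss_fluxes(cal$model)
  cal$rates <- tibble::tibble(
    rate = c("production", "liver", "kidney"),
    flux_umol_L_min = c(f$liver + f$kidney, f$liver, f$kidney))
  cal
}

#' Coupled ammonia multiscale model
#'
#' Direct-couples the hepatic clearance of the whole-body ammonia model
#' to the ammonia uptake exchange of the toy liver network, with hepatic
#' ammonia uptake as the FBA objective.
#'
#' @param pbpk an (ideally calibrated) [ammonia_pbpk_model()].
#' @param network a [make_ammonia_network()].
#' @param dt coupling step, minutes.
#' @return a [multiscale_model()].
#' @export
ammonia_multiscale_model <- function(pbpk = ammonia_pbpk_model(),
                                     network = make_ammonia_network(),
                                     dt = 1) {
  multiscale_model(
    pbpk, network, objective = "EX_nh3",
    direct_links = list(direct_link("liver_clearance", "EX_nh3",
                                    "uptake")),
    dt = dt)
}

#' Whole-body fixtures for the xanthine-oxidase case study
#'
#' `allopurinol_pbpk_model()` builds the coupled parent + metabolite
#' model: oral allopurinol (molar mass 136.11 g/mol) absorbed
#' first-order from the gut lumen, oxidised by hepatic xanthine oxidase
#' to oxypurinol (yield 1, via [link_metabolite()]) with a minor direct
#' renal route (whole-body half-life ~1.5 h); oxypurinol is cleared
#' renally with a whole-body half-life of ~21 h, which is why it
#' accumulates under once-daily dosing while the parent does not. The
#' organ-level first-order constants are chosen to reproduce those
#' half-lives; the oxypurinol value corresponds to ~23 mL/min renal
#' clearance, which puts the mean plasma level under once-daily 200 mg
#' dosing near the observed ~45 uM.
#' Both purine analogs carry a liver partition coefficient of
#' 0.75 (polar compounds distribute below unity into tissue).
#' `uric_acid_pbpk_model()` is the downstream endogenous model: constant
#' hepatic uric-acid production (the network-coupled process) and
#' first-order renal excretion, with gout modelled purely as reduced
#' renal clearance.
#'
#' @param ka absorption constant, 1/min.
#' @param k_xo hepatic oxidation constant of allopurinol, 1/min.
#' @param k_renal_allo renal clearance constant of allopurinol, 1/min.
#' @param k_renal_oxy renal clearance constant of oxypurinol, 1/min.
#' @param production uric-acid production on the reference basis,
#'   micromol/L/min.
#' @param k_renal renal uric-acid clearance constant, 1/min.
#' @return a [pbpk_model()].
#' @name purine_fixtures
NULL

#' @rdname purine_fixtures
#' @export
allopurinol_pbpk_model <- function(ka = 0.04, k_xo = 0.25,
                                   k_renal_allo = 0.03,
                                   k_renal_oxy = 0.0227) {
  comp <- .body_compartments()
  parent <- pbpk_model(
    compartments = comp, flows = .body_flows(),
    species = tibble::tibble(name = "allopurinol", mw = 136.11),
    processes = list(
      process_oral_absorption("allo_abs", "gut_lumen", "allopurinol",
                              ka = ka, to = "gut"),
      process_first_order("allo_xo", "liver", "allopurinol", k = k_xo),
      process_first_order("allo_renal", "kidney", "allopurinol",
                          k = k_renal_allo)),
    partition = tibble::tibble(species = "allopurinol",
                               compartment = "liver", k = 0.75))
  metab <- pbpk_model(
    compartments = comp, flows = .body_flows(),
    species = tibble::tibble(name = "oxypurinol", mw = 152.11),
    processes = list(
      process_first_order("oxy_renal", "kidney", "oxypurinol",
                          k = k_renal_oxy)),
    partition = tibble::tibble(species = "oxypurinol",
                               compartment = "liver", k = 0.75))
  link_metabolite(parent, metab, "allo_xo", stoichiometric_yield = 1)
}

#' @rdname purine_fixtures
#' @export
uric_acid_pbpk_model <- function(production = 0.35, k_renal = NULL) {
  comp <- .body_compartments()
  basis <- sum(comp$volume)
  v_liv <- comp$volume[comp$name == "liver"]
  v_kid <- comp$volume[comp$name == "kidney"]
  # analytic guess: venous ~302 uM healthy
  k_renal <- k_renal %||num% (production * basis / (302 * v_kid))
  pbpk_model(
    compartments = comp, flows = .body_flows(),
    species = tibble::tibble(name = "uric_acid", mw = 168.11),
    processes = list(
      process_zero_order("ua_production", "liver", "uric_acid",
                         rate = production * basis / v_liv),
      process_first_order("ua_renal", "kidney", "uric_acid",
                          k = k_renal)),
    volume_basis = basis)
}

#' Whole-body paracetamol fixture with three clearance pathways
#'
#' Oral paracetamol (151.16 g/mol) cleared by saturable hepatic
#' glucuronidation and sulfation (Michaelis-Menten; sulfation saturates
#' first, which is what shifts overdose metabolism toward the toxic
#' route) and by first-order CYP2E1 N-hydroxylation to NAPQI. Each
#' pathway forms its metabolite (PG, PS, NAPQI) at yield 1; metabolites
#' are cleared first-order (NAPQI fast, by glutathione conjugation).
#'
#' @param ka absorption constant, 1/min.
#' @param vmax_gluc,km_gluc glucuronidation kinetics (micromol/L liver
#'   /min, uM).
#' @param vmax_sulf,km_sulf sulfation kinetics.
#' @param k_cyp CYP2E1 N-hydroxylation constant, 1/min.
#' @param k_napqi NAPQI (glutathione-conjugation) elimination, 1/min.
#' @param k_pg,k_ps renal clearance of the conjugates, 1/min.
#' @return a [pbpk_model()] with species `paracetamol`, `PG`, `PS`,
#'   `NAPQI`.
#' @export
paracetamol_pbpk_model <- function(ka = 0.02, vmax_gluc = 55,
                                   km_gluc = 5000, vmax_sulf = 18,
                                   km_sulf = 300, k_cyp = 0.004,
                                   k_napqi = 0.05, k_pg = 0.01,
                                   k_ps = 0.01) {
  comp <- .body_compartments()
  pbpk_model(
    compartments = comp, flows = .body_flows(),
    species = tibble::tibble(
      name = c("paracetamol", "PG", "PS", "NAPQI"),
      mw = c(151.16, 327.29, 231.23, 149.15)),
    processes = list(
      process_oral_absorption("apap_abs", "gut_lumen", "paracetamol",
                              ka = ka, to = "gut"),
      process_michaelis_menten("apap_gluc", "liver", "paracetamol",
                               vmax = vmax_gluc, km = km_gluc,
                               yields = c(PG = 1)),
      process_michaelis_menten("apap_sulf", "liver", "paracetamol",
                               vmax = vmax_sulf, km = km_sulf,
                               yields = c(PS = 1)),
      process_first_order("apap_cyp", "liver", "paracetamol", k = k_cyp,
                          yields = c(NAPQI = 1)),
      process_first_order("pg_renal", "kidney", "PG", k = k_pg),
      process_first_order("ps_renal", "kidney", "PS", k = k_ps),
      process_first_order("napqi_gsh", "liver", "NAPQI", k = k_napqi)))
}
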