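# The three case studies, scripted over the coupling machinery.

#' Merge two PBPK models sharing the same body
#'
#' Combines the species, partition coefficients, processes and doses of
#' two models with identical compartments and flows into one model (so
#' that one coupled simulation can carry drug and endogenous compound
#' simultaneously).
#'
#' @param a,b [pbpk_model()]s with identical compartments/flows and
#'   disjoint species.
#' @return the merged `pbpk_model`.
#' @export
merge_pbpk <- function(a, b) {
  stopifnot(inherits(a, "pbpk_model"), inherits(b, "pbpk_model"))
  if (!identical(a$compartments, b$compartments)) {
    stop("models must share identical compartments")
  }
  clash_sp <- intersect(a$species$name, b$species$name)
  if (length(clash_sp) > 0) {
    stop("species present in both models: ",
         paste(clash_sp, collapse = ", "))
  }
  clash_pr <- intersect(names(a$processes), names(b$processes))
  if (length(clash_pr) > 0) {
    stop("process ids present in both models: ",
         paste(clash_pr, collapse = ", "))
  }
  m <- a
  m$species <- dplyr::bind_rows(a$species, b$species)
  m$partition <- dplyr::bind_rows(a$partition, b$partition)
  m$processes <- c(a$processes, b$processes)
  m$doses <- dplyr::bind_rows(a$doses, b$doses)
  m
}

.new_scenario_result <- function(scenario, summary, ...) {
  structure(c(list(scenario = scenario, summary = summary), list(...)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> ", x$scenario, "\n", sep = "")
  print(x$summary, n = 20)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.scenario_result <- function(x, ...) x$summary

#' Urea-cycle-disorder protocol
#'
#' Disease schedule for [run_ammonia_ucd()]: ornithine transcarbamylase
#' (OTC) activity falls linearly from 1 to 0 over `ramp_duration`
#' starting at `onset`; the glutamine/alanine secretion demands rise
#' `upregulation_factor`-fold `upregulation_delay` after onset
#' (transcription/translation delay).
#'
#' @param onset minutes until disease onset (default 24 h).
#' @param ramp_duration duration of the linear OTC activity loss
#'   (default 4 days, placing the new steady state around day 6.5).
#' @param upregulation_delay delay of the secretion upregulation after
#'   onset (default 6 h).
#' @param upregulation_factor factor on the secretion demands
#'   (default 4).
#' @param total_duration simulated time (default 21 days).
#' @return a `ucd_protocol` list.
#' @export
ucd_protocol <- function(onset = 1440, ramp_duration = 5760,
                         upregulation_delay = 360,
                         upregulation_factor = 4,
                         total_duration = 30240) {
  stopifnot(onset > 0, ramp_duration > 0, upregulation_delay > 0,
            upregulation_factor > 0, total_duration > 0,
            onset + ramp_duration <= total_duration)
  structure(list(onset = onset, ramp_duration = ramp_duration,
                 upregulation_delay = upregulation_delay,
                 upregulation_factor = upregulation_factor,
                 total_duration = total_duration),
            class = "ucd_protocol")
}

#' Simulate urea-cycle-disorder pathogenesis
#'
#' Calibrates (or accepts) the whole-body ammonia model, establishes the
#' healthy baseline steady state, then simulates the disease protocol
#' with the coupled liver network: the OTC-containing urea-cycle
#' reaction is ramped down while glutamine/alanine secretion is
#' upregulated, and the venous ammonia concentration rises to its new
#' steady state.
#'
#' @param protocol a [ucd_protocol()].
#' @param patient named vector `production`, `liver_k`, `kidney_k`, or
#'   `NULL` to calibrate the mean patient to the healthy venous target.
#' @param target_venous healthy venous calibration target, uM.
#' @param dt coupling step (minutes).
#' @param record_every record every this many steps.
#' @return a `scenario_result` with `summary` (baseline/final venous
#'   concentrations, relative increase, final exchange fluxes),
#'   `trajectory` (a `coupled_trajectory`), `baseline` (steady-state
#'   info) and `calibration` (if performed).
#' @export
run_ammonia_ucd <- function(protocol = ucd_protocol(), patient = NULL,
                            target_venous = 29, dt = 1,
                            record_every = 60) {
  cal <- NULL
  if (is.null(patient)) {
    cal <- calibrate_ammonia_model(ammonia_pbpk_model(),
                                   target_venous = target_venous)
    model <- cal$model
  } else {
    model <- ammonia_pbpk_model(production = patient[["production"]],
                                liver_k = patient[["liver_k"]],
                                kidney_k = patient[["kidney_k"]])
  }
  base <- steady_state(model, tol = 1e-7)
  if (!base$converged) {
    stop("baseline steady state did not converge within ", base$time,
         " min; cannot start the disease protocol")
  }
  vi <- match("venous_blood", model$compartments$name)
  vv <- model$compartments$volume[vi]
  baseline_venous <- base$state[vi, "nh3"] / vv

  net <- make_ammonia_network()
  ms <- ammonia_multiscale_model(model, network = net, dt = dt)
  onset <- protocol$onset; ramp <- protocol$ramp_duration
  act <- list(urea_cycle = function(t) {
    max(0, min(1, 1 - (t - onset) / ramp))
  })
  fac <- protocol$upregulation_factor
  ev <- tibble::tibble(
    time = onset + protocol$upregulation_delay,
    reaction = c("EX_gln", "EX_ala"),
    lb = c(fac * 0.008, fac * 0.002),
    ub = c(fac * 0.008, fac * 0.002))
  traj <- simulate_coupled(ms, duration = protocol$total_duration,
                           init = base$state, events = ev, activity = act,
                           record_every = record_every)
  cv <- concentration(traj, "venous_blood", "nh3")
  final_venous <- cv[length(cv)]
  fl <- traj$fluxes[traj$fluxes$time_min == max(traj$fluxes$time_min), ]
  fx <- stats::setNames(fl$flux, fl$reaction)
  summary <- tibble::tibble(
    metric = c("baseline_venous_uM", "final_venous_uM",
               "relative_increase_pct", "final_uptake_umol_L_min",
               "final_glutamine_umol_L_min", "final_alanine_umol_L_min",
               "final_urea_umol_L_min"),
    value = c(baseline_venous, final_venous,
              100 * (final_venous - baseline_venous) / baseline_venous,
              fx[["EX_nh3"]], fx[["EX_gln"]], fx[["EX_ala"]],
              fx[["EX_urea"]]))
  .new_scenario_result("ammonia_ucd", summary, trajectory = traj,
                       baseline = base, calibration = cal,
                       protocol = protocol, model = model)
}

#' Simulate allopurinol therapy of hyperuricemia
#'
#' Builds the full multiscale chain: oral allopurinol and its metabolite
#' oxypurinol distribute at the whole-body scale, their intrahepatic
#' concentrations inhibit the xanthine-oxidase activity of the purine
#' network (indirect coupling, combined same-site competitive
#' inhibition with IC50s 13.4 and 15.6 uM), and the network's uric-acid
#' export drives the downstream uric-acid whole-body model (direct
#' coupling). The gouty patient is calibrated as reduced renal uric-acid
#' clearance at unchanged production.
#'
#' @param dose_mg oral allopurinol dose (default 200 mg).
#' @param n_doses number of once-daily doses (default 35).
#' @param dose_interval minutes between doses (default 1440).
#' @param follow_up additional simulated minutes after the last
#'   interval (default 0); use with `n_doses = 1` to watch the
#'   uric-acid rebound after therapy interruption.
#' @param gouty_target,healthy_target venous uric-acid calibration
#'   targets, uM.
#' @param production uric-acid production on the reference basis,
#'   micromol/L/min.
#' @param dt coupling step (minutes).
#' @param record_every record every this many steps.
#' @return a `scenario_result`: `summary` (pre/post steady states,
#'   percent reduction, drug exposure metrics), `trajectory`, `relE`
#'   (time course of xanthine-oxidase activity), and the calibrated
#'   models.
#' @export
run_allopurinol <- function(dose_mg = 200, n_doses = 35,
                            dose_interval = 1440, follow_up = 0,
                            gouty_target = 476, healthy_target = 302,
                            production = 0.35, dt = 1,
                            record_every = 30) {
  drug <- allopurinol_pbpk_model()
  ua <- uric_acid_pbpk_model(production = production)
  cal_gouty <- calibrate(
    ua, "process/ua_renal/k",
    targets = list(list(
      name = "gouty_venous",
      observable = function(m) {
        ss <- steady_state(m, tol = 1e-7)
        ss$concentrations$concentration_uM[
          ss$concentrations$compartment == "venous_blood"]
      },
      value = gouty_target)))
  ua_gouty <- cal_gouty$model
  ss_gouty <- steady_state(ua_gouty, tol = 1e-7)
  pre_venous <- ss_gouty$concentrations$concentration_uM[
    ss_gouty$concentrations$compartment == "venous_blood"]

  dose_umol <- dose_mg / 136.11 * 1000
  doses <- tibble::tibble(
    species = "allopurinol", amount = dose_umol, route = "oral",
    time = seq(0, by = dose_interval, length.out = n_doses))
  combined <- merge_pbpk(drug, ua_gouty)
  combined$doses <- doses

  net <- make_purine_network()
  allo_par <- inhibition_params(ic50 = 13.4)
  oxy_par <- inhibition_params(ic50 = 15.6)
  ms <- multiscale_model(
    combined, net, objective = "EX_ua",
    indirect_links = list(
      indirect_link("allopurinol", "liver", "XO1", allo_par),
      indirect_link("oxypurinol", "liver", "XO1", oxy_par),
      indirect_link("allopurinol", "liver", "XO2", allo_par),
      indirect_link("oxypurinol", "liver", "XO2", oxy_par)),
    direct_links = list(direct_link("ua_production", "EX_ua",
                                    "secretion")),
    dt = dt)

  init <- .initial_state(combined, NULL)
  init[, "uric_acid"] <- ss_gouty$state[, "uric_acid"]
  duration <- n_doses * dose_interval + follow_up
  traj <- simulate_coupled(ms, duration = duration, init = init,
                           record_every = record_every)

  cv_ua <- concentration(traj, "venous_blood", "uric_acid")
  cv_allo <- concentration(traj, "venous_blood", "allopurinol")
  cv_oxy <- concentration(traj, "venous_blood", "oxypurinol")
  last <- traj$times > duration - dose_interval
  post_venous <- mean(cv_ua[last])
  relE_tbl <- .relE_series(traj)
  summary <- tibble::tibble(
    metric = c("pre_treatment_uric_uM", "post_treatment_uric_uM",
               "reduction_pct", "healthy_reference_uM",
               "oxypurinol_mean_uM_last_interval",
               "allopurinol_peak_uM", "allopurinol_trough_uM",
               "mean_relE_last_interval"),
    value = c(pre_venous, post_venous,
              100 * (pre_venous - post_venous) / pre_venous,
              healthy_target,
              mean(cv_oxy[last]), max(cv_allo),
              min(cv_allo[traj$times > duration - 0.1 * dose_interval]),
              mean(relE_tbl$relE[relE_tbl$reaction == "XO1" &
                                   relE_tbl$time_min > duration -
                                     dose_interval])))
  .new_scenario_result("allopurinol", summary, trajectory = traj,
                       relE = relE_tbl, uric_model_gouty = ua_gouty,
                       calibration = cal_gouty, pre_venous = pre_venous,
                       post_venous = post_venous)
}

.relE_series <- function(traj) {
  rows <- purrr::imap(traj$relE, function(r, i) {
    if (is.null(r) || length(r) == 0) return(NULL)
    tibble::tibble(time_min = traj$times[i], reaction = names(r),
                   relE = unname(r))
  })
  dplyr::bind_rows(rows)
}

#' Simulate paracetamol dosing and its impact on liver function
#'
#' Simulates the PK of paracetamol and its metabolites (PG, PS, NAPQI;
#' paracetamol cysteine is assumed concentration-equivalent to NAPQI),
#' derives the time-resolved relative activities of the four inhibited
#' targets (THFDH, GDH, ATPS and the glutathione-producing reactions)
#' from the intrahepatic NAPQI concentration, and scans the objective
#' panel at the paracetamol peak, the NAPQI peak and 24 h.
#'
#' Inhibition constants are calibrated so that the NAPQI peak after a
#' lethal 15 g dose produces the maximal inhibitions (default reading:
#' activity *lost* at peak is 25%, 25%, 60%, 80%; set
#' `inhibition_reading = "remaining"` for the alternative reading where
#' activity is reduced *to* those levels).
#'
#' @param dose_g oral dose in grams (0 allowed: no inhibition).
#' @param duration simulated minutes (default 24 h).
#' @param panel a [make_gsh_panel()] result (network + panel +
#'   ground-truth dependencies).
#' @param inhibition_reading `"lost"` (default) or `"remaining"`.
#' @param dt PBPK step (minutes).
#' @return a `scenario_result`: `summary`, `pk` (trajectory), `relE`
#'   (tibble time x target), `panel_report` (stacked over time points),
#'   `classification` (flux-change classification of the
#'   mercapturate-conjugation objective at the NAPQI peak), `ki`
#'   (calibrated constants).
#' @export
run_paracetamol <- function(dose_g = 1, duration = 1440,
                            panel = make_gsh_panel(),
                            inhibition_reading = c("lost", "remaining"),
                            dt = 1) {
  inhibition_reading <- match.arg(inhibition_reading)
  stopifnot(dose_g >= 0)
  model <- paracetamol_pbpk_model()
  dose_of <- function(g) g * 1e6 / 151.16
  with_dose <- function(g) {
    m <- model
    if (g > 0) {
      m$doses <- tibble::tibble(species = "paracetamol",
                                amount = dose_of(g), route = "oral",
                                time = 0)
    }
    m
  }
  liv <- function(traj) concentration(traj, "liver", "NAPQI")

  # Ki calibration anchored at the 15 g NAPQI peak
  ref15 <- simulate_pbpk(with_dose(15), duration = max(duration, 1440),
                         dt = dt)
  cmax15 <- max(liv(ref15))
  lost <- c(THFDH = 0.25, GDH = 0.25, ATPS = 0.60, GSH = 0.80)
  if (inhibition_reading == "remaining") lost <- 1 - lost
  ki <- purrr::map(lost, \(f) calibrate_ki_to_max_inhibition(cmax15, f))

  traj <- simulate_pbpk(with_dose(dose_g), duration = duration, dt = dt)
  napqi <- liv(traj)
  relE_mat <- purrr::map(ki, \(p) 1 / (1 + napqi / p$ic50))
  relE_tbl <- tibble::tibble(time_min = traj$times) |>
    dplyr::bind_cols(tibble::as_tibble(relE_mat))

  cv_para <- concentration(traj, "venous_blood", "paracetamol")
  t_max_para <- traj$times[which.max(cv_para)]
  t_max_napqi <- traj$times[which.max(napqi)]
  tps <- c(t_max_paracetamol = t_max_para, t_max_napqi = t_max_napqi,
           t_24h = min(1440, max(traj$times)))
  inh_at <- function(tp) {
    i <- which.min(abs(traj$times - tp))
    out <- numeric(0)
    for (tag in names(ki)) {
      rids <- reactions_by_tag(panel$network, tag)
      out[rids] <- relE_mat[[tag]][i]
    }
    out
  }
  reports <- purrr::imap(tps, function(tp, nm) {
    rep <- evaluate_panel(panel$network, panel$panel, inh_at(tp))
    rep$time_point <- nm
    rep$time_min <- tp
    rep
  })
  panel_report <- dplyr::bind_rows(reports)

  # flux rerouting example: the glutathione-conjugation task at the
  # NAPQI peak (two GSH-producing routes; capping both reroutes and
  # shrinks the optimum)
  ref_fd <- fba(panel$network, "EX_merc")
  v0 <- flux_of(ref_fd)
  inh <- inh_at(t_max_napqi)
  ov <- purrr::imap(inh, \(r, rid) constrain_flux(panel$network, rid, r,
                                                  v0[[rid]]))
  per_fd <- fba(panel$network, "EX_merc",
                overrides = dplyr::bind_rows(ov))
  classification <- if (per_fd$status == "optimal") {
    classify_flux_changes(ref_fd, per_fd)
  }

  n_aff <- panel_report |>
    dplyr::group_by(.data$time_point) |>
    dplyr::summarise(n = sum(.data$affected), .groups = "drop")
  summary <- tibble::tibble(
    metric = c("dose_g", "napqi_cmax_liver_uM",
               "napqi_cmax15_liver_uM",
               paste0("n_affected_", n_aff$time_point)),
    value = c(dose_g, max(napqi), cmax15, n_aff$n))
  .new_scenario_result("paracetamol", summary, pk = traj,
                       relE = relE_tbl, panel_report = panel_report,
                       classification = classification, ki = ki,
                       depends = panel$depends, time_points = tps)
}
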