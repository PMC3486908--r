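# Coupling layer: indirect (enzyme inhibition) and direct (exchange-rate
# feedback) coupling between a whole-body PBPK model and a stoichiometric
# network, iterated as dynamic FBA on a fixed time grid (default
# 1 step/min). Within an interval the flux distribution is held constant;
# intracellular steady state is assumed at every step because metabolic
# adaptation is fast relative to whole-body distribution.

#' Enzyme inhibition parameters
#'
#' At least one of `ki`/`ic50` must be given. Under the substrate-at-Km
#' convention used throughout (`km_assumption`), competitive inhibition
#' gives `IC50 = 2 Ki` (Cheng-Prusoff), so either parameter determines
#' the other.
#'
#' @param ki inhibition constant, uM.
#' @param ic50 half-inhibitory concentration, uM.
#' @param km_assumption logical; substrate concentration assumed equal to
#'   Km (the convention under which `relE(IC50) = 0.5`).
#' @param max_inhibition optional fraction of activity lost at the
#'   calibration concentration (see [calibrate_ki_to_max_inhibition()]).
#' @param model `"competitive"` (default) or `"noncompetitive"`. With the
#'   substrate-at-Km convention both reduce to `relE = 1/(1 + I/IC50)`;
#'   the switch is kept for documentation and future rate laws.
#' @return an `inhibition_params` object.
#' @export
inhibition_params <- function(ki = NULL, ic50 = NULL, km_assumption = TRUE,
                              max_inhibition = NULL,
                              model = c("competitive", "noncompetitive")) {
  model <- match.arg(model)
  if (is.null(ki) && is.null(ic50)) {
    stop("at least one of ki/ic50 must be given")
  }
  if (!is.null(ki) && ki <= 0) stop("ki must be > 0")
  if (!is.null(ic50) && ic50 <= 0) stop("ic50 must be > 0")
  if (is.null(ic50)) ic50 <- if (model == "competitive") 2 * ki else ki
  if (is.null(ki)) ki <- if (model == "competitive") ic50 / 2 else ic50
  structure(list(ki = ki, ic50 = ic50, km_assumption = km_assumption,
                 max_inhibition = max_inhibition, model = model),
            class = "inhibition_params")
}

#' Relative enzyme activity under inhibition
#'
#' The time-resolved ratio `relE = v(I)/v(0)` of inhibited to uninhibited
#' reaction rate. With competitive inhibition and substrate at Km this is
#' `1/(1 + I/IC50)` (equivalently `1/(1 + I/(2 Ki))`), so `relE(0) = 1`
#' and `relE(IC50) = 0.5`. Several same-site inhibitors combine as
#' `1/(1 + sum_i I_i/IC50_i)`; pass vectors of equal length.
#'
#' @param I inhibitor concentration(s), uM; one value per inhibitor.
#' @param params an [inhibition_params()], or a list of them (one per
#'   inhibitor).
#' @return relative activity in `[0, 1]`.
#' @examples
#' relative_activity(45, inhibition_params(ic50 = 15.6))  # ~0.257
#' relative_activity(c(10, 45),
#'   list(inhibition_params(ic50 = 13.4), inhibition_params(ic50 = 15.6)))
#' @export
relative_activity <- function(I, params) {
  if (inherits(params, "inhibition_params")) params <- list(params)
  if (any(I < 0)) stop("inhibitor concentration must be >= 0")
  if (length(I) != length(params)) {
    stop("need one concentration per inhibitor parameter set")
  }
  ic50 <- purrr::map_dbl(params, "ic50")
  1 / (1 + sum(I / ic50))
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' For competitive inhibition, `Ki = IC50 / (1 + S/Km)`; with the
#' substrate-at-Km assumption this is `IC50 / 2`.
#'
#' @param ic50 half-inhibitory concentration, uM.
#' @param S substrate concentration, uM.
#' @param Km Michaelis constant, uM.
#' @return Ki in uM.
#' @examples
#' ki_from_ic50(13.4, S = 10, Km = 10)  # 6.7
#' @export
ki_from_ic50 <- function(ic50, S, Km) {
  stopifnot(ic50 > 0, S >= 0, Km > 0)
  ic50 / (1 + S / Km)
}

#' Calibrate an inhibition constant from a maximal-inhibition assumption
#'
#' Finds the Ki (and effective IC50) such that the relative activity at a
#' reference peak concentration `c_max` equals `1 - max_inhibition`, i.e.
#' the peak induces the stated maximal enzyme inhibition. Used when no
#' in-vitro constant is available but the extent of inhibition at a known
#' exposure is (e.g. enzyme activities after a lethal overdose).
#'
#' @param c_max peak inhibitor concentration, uM.
#' @param max_inhibition fraction of activity lost at `c_max`, in (0, 1).
#' @return an [inhibition_params()] with the calibrated constants.
#' @examples
#' p <- calibrate_ki_to_max_inhibition(100, 0.5)
#' p$ic50                      # 100
#' relative_activity(100, p)   # 0.5
#' @export
calibrate_ki_to_max_inhibition <- function(c_max, max_inhibition) {
  stopifnot(c_max > 0)
  if (max_inhibition <= 0 || max_inhibition >= 1) {
    stop("max_inhibition must be strictly between 0 and 1")
  }
  ic50 <- c_max * (1 - max_inhibition) / max_inhibition
  inhibition_params(ic50 = ic50, max_inhibition = max_inhibition)
}

#' Flux constraint from a relative enzyme activity
#'
#' Builds the bound override capping the magnitude of the flux through a
#' reaction at `relE * |v0|`, preserving the sign of the unperturbed
#' reference flux `v0`. Applied as a cap (not an equality) so that
#' objectives not routed through the enzyme stay feasible.
#'
#' @param network a [metabolic_network()].
#' @param reaction reaction id.
#' @param relE relative enzyme activity in `[0, 1]`.
#' @param v0 flux through the reaction in the unperturbed reference FBA
#'   solution (micromol/L/min).
#' @return one-row tibble `reaction`, `lb`, `ub` (NA = keep network
#'   bound), suitable for the `overrides` argument of [fba()].
#' @export
constrain_flux <- function(network, reaction, relE, v0) {
  if (!reaction %in% network$reactions$id) {
    stop("unknown reaction: ", reaction)
  }
  stopifnot(relE >= 0, relE <= 1)
  cap <- relE * abs(v0)
  if (v0 > 0) {
    tibble::tibble(reaction = reaction, lb = NA_real_, ub = cap)
  } else if (v0 < 0) {
    tibble::tibble(reaction = reaction, lb = -cap, ub = NA_real_)
  } else {
    tibble::tibble(reaction = reaction, lb = 0, ub = 0)
  }
}

#' Coupling link constructors
#'
#' `indirect_link()` declares a feed-forward regulatory link: the
#' concentration of a PBPK species in a tissue compartment inhibits a
#' network reaction via an inhibitory rate law (no mass feedback).
#' `direct_link()` declares a feed-back mass link: a PBPK clearance or
#' production process is replaced, step by step, by the corresponding FBA
#' exchange flux (unit-converted through the model's reference volume).
#'
#' @param species PBPK species whose tissue concentration acts as
#'   inhibitor.
#' @param compartment PBPK compartment supplying the inhibitor
#'   concentration (typically the liver).
#' @param reaction network reaction id (for `direct_link` an exchange
#'   reaction).
#' @param params an [inhibition_params()].
#' @param process PBPK process id whose rate is exchanged with the
#'   network.
#' @param direction `"uptake"` (a clearance feeding the cell) or
#'   `"secretion"` (a production drawn from the cell).
#' @return a link object.
#' @name coupling_links
NULL

#' @rdname coupling_links
#' @export
indirect_link <- function(species, compartment, reaction, params) {
  stopifnot(inherits(params, "inhibition_params"))
  structure(list(species = species, compartment = compartment,
                 reaction = reaction, params = params),
            class = "indirect_link")
}

#' @rdname coupling_links
#' @export
direct_link <- function(process, reaction,
                        direction = c("uptake", "secretion")) {
  direction <- match.arg(direction)
  structure(list(process = process, reaction = reaction,
                 direction = direction), class = "direct_link")
}

#' Assemble a multiscale (PBPK + network) model
#'
#' @param pbpk a [pbpk_model()].
#' @param network a [metabolic_network()].
#' @param objective FBA objective (see [fba()]): a functional liver
#'   task, e.g. maximise hepatic ammonia uptake.
#' @param indirect_links list of [indirect_link()]s.
#' @param direct_links list of [direct_link()]s.
#' @param dt coupling step, minutes (default 1).
#' @param volume_basis liters converting network fluxes (micromol/L/min)
#'   to whole-body rates (micromol/min); defaults to the PBPK model's
#'   reference volume.
#' @return a `multiscale_model`.
#' @export
multiscale_model <- function(pbpk, network, objective,
                             indirect_links = list(),
                             direct_links = list(), dt = 1,
                             volume_basis = NULL) {
  stopifnot(inherits(pbpk, "pbpk_model"),
            inherits(network, "metabolic_network"), dt > 0)
  for (l in indirect_links) {
    stopifnot(inherits(l, "indirect_link"))
    if (!l$reaction %in% network$reactions$id) {
      stop("indirect link references unknown reaction: ", l$reaction)
    }
    if (!l$species %in% pbpk$species$name) {
      stop("indirect link references unknown species: ", l$species)
    }
    if (!l$compartment %in% pbpk$compartments$name) {
      stop("indirect link references unknown compartment: ", l$compartment)
    }
  }
  for (l in direct_links) {
    stopifnot(inherits(l, "direct_link"))
    if (is.null(pbpk$processes[[l$process]])) {
      stop("direct link references unknown process: ", l$process)
    }
    i <- match(l$reaction, network$reactions$id)
    if (is.na(i)) {
      stop("direct link references unknown reaction: ", l$reaction)
    }
    if (!network$reactions$is_exchange[i]) {
      stop("direct link reaction must be an exchange: ", l$reaction)
    }
  }
  structure(list(pbpk = pbpk, network = network, objective = objective,
                 indirect_links = indirect_links,
                 direct_links = direct_links, dt = dt,
                 volume_basis = volume_basis %||num% pbpk$volume_basis),
            class = "multiscale_model")
}

#' @export
print.multiscale_model <- function(x, ...) {
  cat("<multiscale_model> dt = ", x$dt, " min, ",
      length(x$indirect_links), " indirect + ",
      length(x$direct_links), " direct links, volume basis ",
      x$volume_basis, " L\n", sep = "")
  invisible(x)
}

# ---- the dFBA loop ---------------------------------------------------------

# Warm-reuse rule for consecutive LP solves: the cached optimum stays
# optimal when every new bound still contains the cached flux vector and
# no bound that was binding has moved outward (loosening a binding
# constraint can improve the optimum; anything else cannot).
.lp_cache_reusable <- function(cache, lb, ub, eps = 1e-12) {
  if (is.null(cache$v)) return(FALSE)
  v <- cache$v
  if (any(v < lb - eps) || any(v > ub + eps)) return(FALSE)
  bind_ub <- cache$v >= cache$ub - 1e-9
  bind_lb <- cache$v <= cache$lb + 1e-9
  if (any(bind_ub & (ub > cache$ub + eps))) return(FALSE)
  if (any(bind_lb & (lb < cache$lb - eps))) return(FALSE)
  TRUE
}

.solve_fba_cached <- function(prep, lb, ub, cache) {
  if (.lp_cache_reusable(cache, lb, ub)) {
    return(list(v = cache$v, objective = cache$objective,
                status = "optimal", cache = cache))
  }
  sol <- .fba_core(prep$S, prep$rx_ids, prep$f, lb, ub, pfba = TRUE,
                   tol = 1e-9)
  if (sol$status != "optimal") {
    return(list(v = NULL, objective = NA_real_, status = sol$status,
                cache = list(v = NULL)))
  }
  v <- stats::setNames(sol$fluxes$flux, sol$fluxes$reaction)
  list(v = v, objective = sol$objective_value, status = "optimal",
       cache = list(v = v, lb = lb, ub = ub,
                    objective = sol$objective_value))
}

# static per-simulation context for the stepping core: compiled PBPK,
# LP structure and integer-indexed link metadata (no per-step tibbles)
.prep_coupling <- function(ms) {
  cp <- .compile_pbpk(ms$pbpk,
                      dynamic = purrr::map_chr(ms$direct_links, "process"))
  rx <- ms$network$reactions
  cn <- ms$pbpk$compartments$name
  sn <- ms$pbpk$species$name
  vols <- ms$pbpk$compartments$volume
  dl_proc <- purrr::map_chr(ms$direct_links, "process")
  dl <- list(
    proc = dl_proc,
    ridx = match(purrr::map_chr(ms$direct_links, "reaction"), rx$id),
    expl = purrr::map(dl_proc, \(p) cp$expl[[p]]))
  il <- list()
  if (length(ms$indirect_links) > 0) {
    by_rxn <- split(ms$indirect_links,
                    purrr::map_chr(ms$indirect_links, "reaction"))
    il <- purrr::imap(by_rxn, function(links, rid) {
      list(ridx = match(rid, rx$id),
           ci = purrr::map_int(links, \(l) match(l$compartment, cn)),
           si = purrr::map_int(links, \(l) match(l$species, sn)),
           vol = vols[purrr::map_int(links, \(l) match(l$compartment,
                                                       cn))],
           ic50 = purrr::map_dbl(links, \(l) l$params$ic50))
    })
  }
  list(cp = cp, nsub = .auto_substeps(cp, ms$dt), S = ms$network$S,
       rx_ids = rx$id, f = .objective_vector(ms$network, ms$objective),
       dl = dl, il = il, basis = ms$volume_basis, dt = ms$dt,
       pbpk = ms$pbpk)
}

#' Reference flux solution of a multiscale model
#'
#' Solves the unperturbed FBA problem (all enzyme activities at 1) with
#' the direct-link exchange bounds taken from the PBPK kinetic rates at a
#' given state, returning the reference fluxes `v0` used by the
#' inhibition constraints.
#'
#' @param ms a [multiscale_model()].
#' @param state amounts matrix; defaults to zero amounts, under which
#'   only concentration-independent (zero-order) offered rates are
#'   nonzero.
#' @return a `flux_distribution`.
#' @export
reference_fluxes <- function(ms, state = NULL) {
  if (is.null(state)) state <- .initial_state(ms$pbpk, NULL)
  b <- .offered_bounds(ms, state)
  rx <- ms$network$reactions
  f <- .objective_vector(ms$network, ms$objective)
  .fba_core(ms$network$S, rx$id, f, b$lb, b$ub, pfba = TRUE, tol = 1e-9)
}

# exchange bounds offered by the PBPK kinetic rates at the current state
.offered_bounds <- function(ms, A) {
  rx <- ms$network$reactions
  lb <- rx$lb; ub <- rx$ub
  offered <- stats::setNames(numeric(length(ms$direct_links)),
                             purrr::map_chr(ms$direct_links, "process"))
  for (l in ms$direct_links) {
    r <- process_rate(ms$pbpk, l$process, A) / ms$volume_basis
    offered[[l$process]] <- r
    i <- match(l$reaction, rx$id)
    ub[i] <- min(ub[i], r)
    lb[i] <- max(lb[i], 0)
  }
  list(lb = lb, ub = ub, offered = offered)
}

.safe_reference_v0 <- function(ms, A) {
  ref <- reference_fluxes(ms, A)
  if (ref$status == "optimal") flux_of(ref) else NULL
}

#' One dFBA step
#'
#' Implements the five-step direct-coupling loop: (1) evaluate the PBPK
#' kinetic rates at the current concentrations; (2) offer them as
#' exchange bounds and apply all inhibition (indirect-link) constraints
#' from current tissue concentrations; (3) solve FBA; (4) replace the
#' linked PBPK process rates by the FBA exchange fluxes; (5) integrate
#' the PBPK model one step.
#'
#' @param ms a [multiscale_model()].
#' @param state amounts matrix (compartment x species).
#' @param v0 named reference fluxes for the inhibition caps (from
#'   [reference_fluxes()]); required if there are indirect links or an
#'   `activity` schedule.
#' @param activity optional named vector of additional relative
#'   activities (disease schedules) multiplying the drug-derived relE per
#'   reaction.
#' @param time current time in minutes (used only for dose events).
#' @return list with `state` (new amounts), `fluxes` (named vector),
#'   `objective`, `status`, `relE` (named vector of applied activities).
#' @export
dfba_step <- function(ms, state, v0 = NULL, activity = NULL, time = 0) {
  if (is.null(v0)) v0 <- .safe_reference_v0(ms, state)
  prep <- .prep_coupling(ms)
  b <- .base_bounds(ms)
  v0v <- .v0_vector(prep, v0)
  st <- .dfba_step_core(prep, state, b$lb, b$ub, v0v, activity,
                        cache = list(v = NULL), time = time)
  list(state = st$A, fluxes = st$v, objective = st$objective,
       status = st$status, relE = st$relE)
}

.base_bounds <- function(ms) {
  list(lb = ms$network$reactions$lb, ub = ms$network$reactions$ub)
}

.v0_vector <- function(prep, v0) {
  out <- stats::setNames(rep(NA_real_, length(prep$rx_ids)), prep$rx_ids)
  if (!is.null(v0)) out[names(v0)] <- v0
  out
}

# activity: named numeric vector (scheduled relE per reaction), or NULL
.dfba_step_core <- function(prep, A, base_lb, base_ub, v0v, activity,
                            cache, time) {
  lb <- base_lb; ub <- base_ub

  # (1)+(2) offer the PBPK kinetic rates as exchange bounds
  nl <- length(prep$dl$proc)
  offered <- numeric(nl)
  if (nl > 0) {
    for (j in seq_len(nl)) {
      r <- .expl_rate(prep$dl$expl[[j]], A) / prep$basis
      offered[j] <- r
      i <- prep$dl$ridx[j]
      if (r < ub[i]) ub[i] <- r
      if (lb[i] < 0) lb[i] <- 0
    }
  }

  # (2) inhibition constraints from current tissue concentrations
  relE_named <- NULL
  caps <- NULL
  n_caps <- length(prep$il) + length(activity)
  if (n_caps > 0) {
    relE <- stats::setNames(rep(1, length(prep$il)), names(prep$il))
    for (rid in names(prep$il)) {
      g <- prep$il[[rid]]
      I <- A[cbind(g$ci, g$si)] / g$vol
      relE[rid] <- 1 / (1 + sum(I / g$ic50))
    }
    if (!is.null(activity)) {
      extra <- setdiff(names(activity), names(relE))
      if (length(extra) > 0) {
        relE[extra] <- 1
      }
      relE[names(activity)] <- relE[names(activity)] * activity
    }
    capped <- relE < 1
    if (any(capped)) {
      if (all(is.na(v0v))) {
        stop("inhibition constraints need reference fluxes v0")
      }
      for (rid in names(relE)[capped]) {
        v0r <- v0v[[rid]]
        if (is.na(v0r)) {
          stop("no reference flux v0 for inhibited reaction ", rid)
        }
        cap <- relE[[rid]] * abs(v0r)
        i <- match(rid, prep$rx_ids)
        if (v0r > 0) {
          if (cap < ub[i]) ub[i] <- cap
        } else if (v0r < 0) {
          if (-cap > lb[i]) lb[i] <- -cap
        } else {
          if (lb[i] < 0) lb[i] <- 0
          if (ub[i] > 0) ub[i] <- 0
        }
      }
    }
    relE_named <- relE[relE < 1]
  }

  # (3) solve FBA (warm-reused when the cached optimum must still hold)
  sol <- .solve_fba_cached(prep, lb, ub, cache)

  # (4) replace linked PBPK rates by the FBA exchange fluxes; where the
  # network accepts the full offered rate it does not limit the process,
  # so the kinetic law is kept and the coupled model is exactly the
  # PBPK model alone in the unperturbed reference state
  overrides <- NULL
  if (nl > 0) {
    if (sol$status == "optimal") {
      ov <- sol$v[prep$dl$ridx]
      limiting <- ov < offered * (1 - 1e-9) - 1e-12
      if (any(limiting)) {
        overrides <- stats::setNames((ov * prep$basis)[limiting],
                                     prep$dl$proc[limiting])
      }
    } else {
      # infeasible network: zero linked rates for this step
      overrides <- stats::setNames(rep(0, nl), prep$dl$proc)
    }
  }

  # (5) integrate the whole-body model one coupling step
  A <- .apply_doses(prep$pbpk, A, time, time + prep$dt)
  A <- .rk4_step(prep$cp, A, prep$dt, prep$nsub, overrides)
  A[A < 0] <- 0
  list(A = A, v = sol$v, objective = sol$objective, status = sol$status,
       relE = relE_named, cache = sol$cache)
}

#' Simulate a coupled multiscale model
#'
#' Iterates [dfba_step()] over `duration` minutes. Timed events may
#' modify network bounds (e.g. fourfold raised secretion demands) and an
#' `activity` schedule imposes time-varying relative enzyme activities
#' (e.g. a linear loss of urea-cycle activity); both snap to the
#' coupling grid.
#'
#' @param ms a [multiscale_model()].
#' @param duration minutes.
#' @param init initial amounts matrix (compartment x species), or `NULL`.
#' @param events data frame with columns `time`, `reaction`, `lb`, `ub`
#'   (NA = keep): permanent bound changes applied from their time on.
#' @param activity named list of functions `time -> [0,1]` giving the
#'   scheduled relative activity of a reaction.
#' @param v0 named reference fluxes (default: computed once from the
#'   initial state with all activities at 1).
#' @param record_every record state/fluxes every this many steps.
#' @return a `coupled_trajectory`: `times`, `amounts` (array),
#'   `fluxes` (tibble `time_min`, `reaction`, `flux`), `objective`
#'   series, `relE` series, count of infeasible steps, and the model.
#' @export
simulate_coupled <- function(ms, duration, init = NULL, events = NULL,
                             activity = NULL, v0 = NULL,
                             record_every = 1L) {
  stopifnot(inherits(ms, "multiscale_model"), duration >= ms$dt)
  A <- .initial_state(ms$pbpk, init)
  if (is.null(v0)) v0 <- .safe_reference_v0(ms, A)
  if (!is.null(events)) {
    events <- tibble::as_tibble(events)
    events <- events[order(events$time), ]
    bad <- setdiff(events$reaction, ms$network$reactions$id)
    if (length(bad) > 0) {
      stop("event references unknown reaction: ", paste(bad, collapse = ", "))
    }
  }
  prep <- .prep_coupling(ms)
  b <- .base_bounds(ms)
  base_lb <- b$lb; base_ub <- b$ub
  v0v <- .v0_vector(prep, v0)
  cp <- prep$cp
  nstep <- ceiling(duration / ms$dt)
  rec_steps <- unique(c(seq(record_every, nstep, by = record_every), nstep))
  nrec <- length(rec_steps) + 1L          # + initial state
  times_rec <- c(0, rec_steps * ms$dt)
  amounts <- array(NA_real_, c(nrec, cp$nc, cp$ns),
                   dimnames = list(NULL, cp$cn, cp$sn))
  flux_rec <- matrix(NA_real_, nrec, nrow(ms$network$reactions),
                     dimnames = list(NULL, ms$network$reactions$id))
  obj_rec <- rep(NA_real_, nrec)
  relE_rec <- list()
  amounts[1, , ] <- A
  cache <- list(v = NULL)
  n_infeasible <- 0L
  ri <- 1L
  act_ids <- names(activity)
  for (k in seq_len(nstep)) {
    t0 <- (k - 1) * ms$dt
    if (!is.null(events)) {
      due <- events$time <= t0 + 1e-9 & !is.na(events$time)
      if (any(due)) {
        for (i in which(due)) {
          j <- match(events$reaction[i], prep$rx_ids)
          if (!is.na(events$lb[i])) base_lb[j] <- events$lb[i]
          if (!is.na(events$ub[i])) base_ub[j] <- events$ub[i]
        }
        events <- events[!due, , drop = FALSE]
        cache <- list(v = NULL)
      }
    }
    act <- if (is.null(activity)) NULL else
      vapply(activity, function(f) f(t0), numeric(1))
    st <- .dfba_step_core(prep, A, base_lb, base_ub, v0v, act, cache,
                          time = t0)
    A <- st$A
    cache <- st$cache
    if (st$status != "optimal") n_infeasible <- n_infeasible + 1L
    if (ri < nrec && k == rec_steps[ri]) {
      ri <- ri + 1L
      amounts[ri, , ] <- A
      if (!is.null(st$v)) flux_rec[ri, ] <- st$v
      obj_rec[ri] <- st$objective
      relE_rec[[ri]] <- st$relE
    }
  }
  fluxes <- tibble::as_tibble(flux_rec)
  fluxes$time_min <- times_rec
  fluxes <- tidyr::pivot_longer(fluxes, -"time_min",
                                names_to = "reaction", values_to = "flux")
  structure(list(
    times = times_rec, amounts = amounts, model = ms$pbpk, dt = ms$dt,
    fluxes = fluxes, objective = obj_rec, relE = relE_rec,
    n_infeasible = n_infeasible, multiscale = ms, v0 = v0),
    class = c("coupled_trajectory", "pbpk_trajectory"))
}

#' @export
print.coupled_trajectory <- function(x, ...) {
  cat("<coupled_trajectory> ", length(x$times), " recorded states, t = 0..",
      max(x$times), " min", sep = "")
  if (x$n_infeasible > 0) cat(" (", x$n_infeasible, " infeasible steps)")
  cat("\n")
  invisible(x)
}

#' Coupled steady state by dFBA iteration
#'
#' Iterates the coupled model until the largest relative change of any
#' amount over a 60-min window falls below `tol` (same convention as
#' [steady_state()], but with the liver network in the loop).
#'
#' @param ms a [multiscale_model()].
#' @param init initial amounts matrix.
#' @param activity named vector of constant relative activities (e.g.
#'   `c(urea_cycle = 0)` for a fully developed enzyme deficiency).
#' @param v0 named reference fluxes; computed from `init` if missing.
#' @param tol relative change per hour declaring stationarity.
#' @param max_time give up after this many simulated minutes.
#' @return list with `state`, `fluxes` (named vector of the stationary
#'   flux distribution), `time`, `converged`.
#' @export
coupled_steady_state <- function(ms, init = NULL, activity = NULL,
                                 v0 = NULL, tol = 1e-6, max_time = 10080) {
  A <- .initial_state(ms$pbpk, init)
  if (is.null(v0)) v0 <- .safe_reference_v0(ms, A)
  prep <- .prep_coupling(ms)
  b <- .base_bounds(ms)
  v0v <- .v0_vector(prep, v0)
  cache <- list(v = NULL)
  t <- 0
  steps <- ceiling(60 / ms$dt)
  repeat {
    A_prev <- A
    for (k in seq_len(steps)) {
      st <- .dfba_step_core(prep, A, b$lb, b$ub, v0v, activity, cache,
                            time = t)
      A <- st$A
      cache <- st$cache
      t <- t + ms$dt
    }
    rel <- max(abs(A - A_prev) / pmax(abs(A), 1e-12))
    if (rel < tol || t >= max_time) {
      return(list(state = A, fluxes = st$v, time = t,
                  converged = rel < tol))
    }
  }
}
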