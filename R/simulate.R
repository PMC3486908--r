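# PBPK integration engine.
#
# The state is a compartments x species matrix of amounts (micromol).
# Linear transport (flows, first-order clearance without product yields,
# absorption) is pre-assembled into one matrix per species; saturable and
# product-forming processes are evaluated explicitly. Integration is
# fixed-step classic RK4 with automatic sub-stepping inside each
# reporting/coupling interval, so that dFBA can hold exchange bounds
# piecewise-constant per interval.

.compile_pbpk <- function(model, dynamic = character()) {
  nc <- nrow(model$compartments); ns <- nrow(model$species)
  cn <- model$compartments$name; sn <- model$species$name
  V <- model$compartments$volume
  K <- matrix(1, nc, ns, dimnames = list(cn, sn))
  K[cbind(model$partition$compartment, model$partition$species)] <-
    model$partition$k

  # flow operator per species: dA = W %*% A
  W <- array(0, c(nc, nc, ns))
  for (i in seq_len(nrow(model$flows))) {
    s <- match(model$flows$source[i], cn)
    t <- match(model$flows$target[i], cn)
    q <- model$flows$rate[i]
    for (j in seq_len(ns)) {
      eff <- q / (V[s] * K[s, j])      # effluent conc per unit amount
      W[s, s, j] <- W[s, s, j] - eff
      W[t, s, j] <- W[t, s, j] + eff
    }
  }

  b <- matrix(0, nc, ns, dimnames = list(cn, sn))  # constant productions
  expl <- list()                                   # explicitly evaluated
  for (p in model$processes) {
    ci <- match(p$compartment, cn); si <- match(p$species, sn)
    is_dyn <- p$id %in% dynamic
    if (p$kind == "zero_order_production" && !is_dyn) {
      b[ci, si] <- b[ci, si] + p$params$rate * V[ci]
    } else if (p$kind == "first_order" && !is_dyn &&
               length(p$yields) == 0) {
      W[ci, ci, si] <- W[ci, ci, si] - p$params$k
    } else if (p$kind == "oral_absorption" && !is_dyn) {
      ti <- match(p$params$to, cn)
      W[ci, ci, si] <- W[ci, ci, si] - p$params$ka
      W[ti, ci, si] <- W[ti, ci, si] + p$params$ka
    } else {
      expl[[p$id]] <- list(
        p = p, ci = ci, si = si,
        ti = if (p$kind == "oral_absorption") match(p$params$to, cn)
             else NA_integer_,
        yi = match(names(p$yields), sn), yv = unname(p$yields),
        vol = V[ci])
    }
  }
  list(nc = nc, ns = ns, cn = cn, sn = sn, V = V, K = K, W = W, b = b,
       expl = expl)
}

# instantaneous magnitude (micromol/min) of one compiled explicit process
.expl_rate <- function(e, A) {
  p <- e$p
  switch(p$kind,
    first_order = p$params$k * A[e$ci, e$si],
    michaelis_menten = {
      C <- A[e$ci, e$si] / e$vol
      p$params$vmax * e$vol * C / (p$params$km + C)
    },
    zero_order_production = p$params$rate * e$vol,
    oral_absorption = p$params$ka * A[e$ci, e$si])
}

# full right-hand side; overrides: named flux magnitudes (micromol/min)
# replacing the kinetic law of the named process for this interval
.pbpk_rhs <- function(cp, A, overrides = NULL) {
  dA <- cp$b
  for (j in seq_len(cp$ns)) {
    dA[, j] <- dA[, j] + cp$W[, , j] %*% A[, j]
  }
  for (id in names(cp$expl)) {
    e <- cp$expl[[id]]
    r <- if (!is.null(overrides) && id %in% names(overrides)) {
      overrides[[id]]
    } else {
      .expl_rate(e, A)
    }
    kind <- e$p$kind
    if (kind == "zero_order_production") {
      dA[e$ci, e$si] <- dA[e$ci, e$si] + r
    } else if (kind == "oral_absorption") {
      dA[e$ci, e$si] <- dA[e$ci, e$si] - r
      dA[e$ti, e$si] <- dA[e$ti, e$si] + r
    } else {                              # clearances
      dA[e$ci, e$si] <- dA[e$ci, e$si] - r
      if (length(e$yi) > 0) {
        dA[e$ci, e$yi] <- dA[e$ci, e$yi] + e$yv * r
      }
    }
  }
  dA
}

# one RK4 macro step of length dt with nsub sub-steps
.rk4_step <- function(cp, A, dt, nsub, overrides = NULL) {
  h <- dt / nsub
  for (i in seq_len(nsub)) {
    k1 <- .pbpk_rhs(cp, A, overrides)
    k2 <- .pbpk_rhs(cp, A + h / 2 * k1, overrides)
    k3 <- .pbpk_rhs(cp, A + h / 2 * k2, overrides)
    k4 <- .pbpk_rhs(cp, A + h * k3, overrides)
    A <- A + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  A
}

# conservative estimate of the fastest linear rate (1/min), for sub-step
# selection: RK4 needs |lambda| h < ~2.8; we target <= 1.
.stiffness_scale <- function(cp) {
  lam <- 0
  for (j in seq_len(cp$ns)) {
    d <- abs(diag(cp$W[, , j]))
    if (length(d) > 0) lam <- max(lam, d)
  }
  for (e in cp$expl) {
    if (e$p$kind == "first_order") lam <- max(lam, e$p$params$k)
    if (e$p$kind == "oral_absorption") lam <- max(lam, e$p$params$ka)
    if (e$p$kind == "michaelis_menten") {
      lam <- max(lam, e$p$params$vmax / e$p$params$km)
    }
  }
  lam
}

.auto_substeps <- function(cp, dt) {
  # target |lambda| h <= 0.6: comfortably inside RK4 stability with
  # fourth-order accuracy left over for the transients
  max(1L, ceiling(dt * .stiffness_scale(cp) / 0.6))
}

.initial_state <- function(model, init) {
  A <- matrix(0, nrow(model$compartments), nrow(model$species),
              dimnames = list(model$compartments$name, model$species$name))
  if (!is.null(init)) {
    stopifnot(is.matrix(init))
    A[rownames(init), colnames(init)] <- init
  }
  A
}

.apply_doses <- function(model, A, t_from, t_to) {
  hit <- model$doses$time >= t_from & model$doses$time < t_to
  if (any(hit)) {
    for (i in which(hit)) {
      comp <- model$dose_targets[[model$doses$route[i]]]
      A[comp, model$doses$species[i]] <-
        A[comp, model$doses$species[i]] + model$doses$amount[i]
    }
  }
  A
}

#' Simulate a PBPK model
#'
#' Integrates the whole-body mass balances with a fixed macro step `dt`
#' (the dFBA coupling grid) and automatic RK4 sub-stepping inside each
#' step. Dose events fire at the beginning of the step containing their
#' time. Negative amounts produced by discretised clearance near zero are
#' clipped to zero and counted.
#'
#' @param model a [pbpk_model()].
#' @param duration simulated time, minutes.
#' @param dt macro step, minutes (default 1).
#' @param init optional initial amounts: matrix with compartment rownames
#'   and species colnames (micromol); zero elsewhere.
#' @param substeps RK4 sub-steps per macro step, or `NULL` for automatic
#'   selection from the fastest linear rate in the model.
#' @return a `pbpk_trajectory`: times, an amounts array
#'   (time x compartment x species) and the model; convert with
#'   [trajectory_tbl()] or query with [concentration()].
#' @examples
#' m <- pbpk_model(
#'   compartments = tibble::tibble(name = "body", volume = 10),
#'   flows = tibble::tibble(source = character(), target = character(),
#'                          rate = numeric()),
#'   species = tibble::tibble(name = "drug"),
#'   processes = list(process_first_order("cl", "body", "drug", k = 0.01)))
#' tr <- simulate_pbpk(m, duration = 100,
#'                     init = matrix(100, 1, 1, dimnames = list("body", "drug")))
#' concentration(tr, "body", "drug")[c(1, 101)] * 10  # amounts 100 -> ~36.8
#' @export
simulate_pbpk <- function(model, duration, dt = 1, init = NULL,
                          substeps = NULL) {
  stopifnot(inherits(model, "pbpk_model"), dt > 0, duration >= dt)
  cp <- .compile_pbpk(model)
  nsub <- substeps %||num% .auto_substeps(cp, dt)
  nstep <- ceiling(duration / dt)
  A <- .initial_state(model, init)
  out <- array(NA_real_, c(nstep + 1, cp$nc, cp$ns),
               dimnames = list(NULL, cp$cn, cp$sn))
  out[1, , ] <- A
  clipped <- 0L
  for (k in seq_len(nstep)) {
    t0 <- (k - 1) * dt
    A <- .apply_doses(model, A, t0, t0 + dt)
    A <- .rk4_step(cp, A, dt, nsub)
    if (any(A < 0)) {
      neg <- A < -1e-9
      clipped <- clipped + sum(neg)
      A[A < 0] <- 0
    }
    if (anyNA(A) || any(!is.finite(A))) {
      stop("integration failure at t = ", t0 + dt,
           " min: non-finite amounts (species: ",
           paste(cp$sn[colSums(!is.finite(A)) > 0], collapse = ", "),
           "); consider more substeps")
    }
    out[k + 1, , ] <- A
  }
  if (clipped > 0) {
    warning("clipped ", clipped, " negative amounts to zero")
  }
  structure(list(times = seq(0, by = dt, length.out = nstep + 1),
                 amounts = out, model = model, dt = dt, clipped = clipped),
            class = "pbpk_trajectory")
}

#' @export
print.pbpk_trajectory <- function(x, ...) {
  cat("<pbpk_trajectory> ", length(x$times), " states, t = 0..",
      max(x$times), " min, dt = ", x$dt, " min\n", sep = "")
  invisible(x)
}

#' Tidy a trajectory into a long tibble
#'
#' @param traj a `pbpk_trajectory`.
#' @param every keep every `every`-th time point (thinning for long runs).
#' @return tibble with `time_min`, `compartment`, `species`, `amount_umol`,
#'   `concentration_uM`.
#' @export
trajectory_tbl <- function(traj, every = 1L) {
  idx <- seq(1, length(traj$times), by = every)
  arr <- traj$amounts[idx, , , drop = FALSE]
  dn <- dimnames(arr)
  # as.vector(arr) runs time fastest, then compartment, then species;
  # expand_grid varies its last column fastest
  out <- tidyr::expand_grid(species = dn[[3]], compartment = dn[[2]],
                            time_min = traj$times[idx])
  out$amount_umol <- as.vector(arr)
  V <- traj$model$compartments$volume
  out$concentration_uM <- out$amount_umol /
    V[match(out$compartment, traj$model$compartments$name)]
  dplyr::select(out, "time_min", "compartment", "species",
                "amount_umol", "concentration_uM")
}

#' Extract a concentration time course
#'
#' @param traj a `pbpk_trajectory`.
#' @param compartment,species names to extract.
#' @return numeric vector of concentrations (uM), aligned with
#'   `traj$times`.
#' @export
concentration <- function(traj, compartment, species) {
  V <- traj$model$compartments$volume[
    match(compartment, traj$model$compartments$name)]
  traj$amounts[, compartment, species] / V
}

#' Find the steady state of a PBPK model
#'
#' Simulates forward and declares steady state when the largest relative
#' concentration change across all compartments and species over a 60-min
#' window drops below `tol`. Dose events disqualify the model (steady
#' state is only meaningful for autonomous production/clearance systems).
#'
#' @param model a [pbpk_model()] without dose events.
#' @param tol relative change per hour below which the state is declared
#'   stationary.
#' @param max_time give up after this many simulated minutes.
#' @param dt,init,substeps as in [simulate_pbpk()].
#' @return list with `state` (amounts matrix), `concentrations` (tibble),
#'   `time` (minutes simulated), `converged` (logical).
#' @export
steady_state <- function(model, tol = 1e-6, max_time = 20160, dt = 1,
                         init = NULL, substeps = NULL) {
  stopifnot(inherits(model, "pbpk_model"))
  if (nrow(model$doses) > 0) {
    stop("steady_state requires a model without dose events")
  }
  cp <- .compile_pbpk(model)
  nsub <- substeps %||num% .auto_substeps(cp, dt)
  A <- .initial_state(model, init)
  t <- 0
  window <- 60
  repeat {
    A_prev <- A
    steps <- ceiling(window / dt)
    for (k in seq_len(steps)) A <- .rk4_step(cp, A, dt, nsub)
    A[A < 0] <- 0
    t <- t + steps * dt
    denom <- pmax(abs(A), 1e-12)
    rel <- max(abs(A - A_prev) / denom)
    if (rel < tol) {
      return(.ss_result(model, A, t, TRUE))
    }
    if (t >= max_time) {
      return(.ss_result(model, A, t, FALSE))
    }
  }
}

.ss_result <- function(model, A, t, converged) {
  conc <- tibble::tibble(
    compartment = rep(model$compartments$name, nrow(model$species)),
    species = rep(model$species$name, each = nrow(model$compartments)),
    concentration_uM = as.vector(A) / model$compartments$volume)
  list(state = A, concentrations = conc, time = t, converged = converged)
}

#' Evaluate the instantaneous rate of a kinetic process
#'
#' Returns the flux magnitude (micromol/min) of a process at a given
#' state; used by the direct-coupling loop to offer PBPK kinetic rates as
#' FBA exchange bounds.
#'
#' @param model a [pbpk_model()].
#' @param process_id process identifier.
#' @param state amounts matrix (compartment x species).
#' @return flux in micromol/min.
#' @export
process_rate <- function(model, process_id, state) {
  p <- model$processes[[process_id]]
  if (is.null(p)) stop("unknown process: ", process_id)
  cn <- model$compartments$name
  V <- model$compartments$volume[match(p$compartment, cn)]
  e <- list(p = p, ci = match(p$compartment, cn),
            si = match(p$species, model$species$name), vol = V)
  .expl_rate(e, state)
}
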