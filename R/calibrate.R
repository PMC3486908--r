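#' Calibrate PBPK model parameters to observed targets
#'
#' Deterministic local least-squares: minimises the sum of squared
#' relative residuals over the listed targets, starting from the model's
#' current parameter values (the documented starting point), using
#' box-constrained quasi-Newton optimisation ([stats::nlminb()]). No
#' randomness is involved.
#'
#' @param model a [pbpk_model()].
#' @param free_params character vector (at most 10) of parameter paths,
#'   see [get_parameter()].
#' @param targets list of targets, each a list with `observable` (a
#'   function `model -> numeric`), `value` (the observed value), and
#'   optionally `name` and `weight`.
#' @param lower,upper parameter bounds (recycled; defaults `1e-12` and
#'   `Inf`).
#' @return a `pbpk_calibration` object: fitted parameters, residual
#'   table, objective value, convergence flag, and the updated model
#'   (`$model`). Supports [generics::tidy()] and [generics::glance()].
#' @export
calibrate <- function(model, free_params, targets, lower = 1e-12,
                      upper = Inf) {
  stopifnot(inherits(model, "pbpk_model"))
  if (length(free_params) > 10) {
    stop("at most 10 free parameters are supported")
  }
  start <- purrr::map_dbl(free_params, \(p) get_parameter(model, p))
  names(start) <- free_params
  lower <- rep_len(lower, length(start))
  upper <- rep_len(upper, length(start))
  tvals <- purrr::map_dbl(targets, "value")
  tw <- purrr::map_dbl(targets, \(t) t$weight %||num% 1)
  tnames <- purrr::imap_chr(targets, \(t, i) t$name %||num% paste0("target", i))

  apply_par <- function(par) {
    m <- model
    for (i in seq_along(free_params)) {
      m <- set_parameter(m, free_params[i], unname(par[[i]]))
    }
    m
  }
  resid_fun <- function(par) {
    m <- apply_par(par)
    obs <- purrr::map_dbl(targets, \(t) t$observable(m))
    (obs - tvals) / ifelse(tvals == 0, 1, abs(tvals))
  }
  obj <- function(par) sum(tw * resid_fun(par)^2)

  fit <- stats::nlminb(start, obj, lower = lower, upper = upper,
                       control = list(rel.tol = 1e-12, x.tol = 1e-10))
  par <- fit$par
  names(par) <- free_params

  # flat-objective (unidentifiability) diagnostic
  f0 <- fit$objective
  curv <- purrr::map_dbl(seq_along(par), function(i) {
    p <- par; p[i] <- p[i] * 1.05 + 1e-12
    abs(obj(p) - f0)
  })
  if (any(curv < 1e-14)) {
    warning("flat objective along: ",
            paste(free_params[curv < 1e-14], collapse = ", "),
            " (residual landscape locally insensitive; parameter not ",
            "identifiable from these targets)")
  }

  m_fit <- apply_par(par)
  obs <- purrr::map_dbl(targets, \(t) t$observable(m_fit))
  structure(list(
    par = par, start = start,
    residuals = tibble::tibble(
      target = tnames, observed = obs, value = tvals,
      rel_residual = (obs - tvals) / ifelse(tvals == 0, 1, abs(tvals))),
    objective = fit$objective,
    convergence = fit$convergence == 0,
    model = m_fit), class = "pbpk_calibration")
}

#' @export
print.pbpk_calibration <- function(x, ...) {
  cat("<pbpk_calibration> objective ", format(x$objective, digits = 4),
      if (x$convergence) " (converged)" else " (NOT converged)", "\n",
      sep = "")
  print(generics::tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.pbpk_calibration <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par),
                 start = unname(x$start))
}

#' @exportS3Method generics::glance
glance.pbpk_calibration <- function(x, ...) {
  tibble::tibble(objective = x$objective, converged = x$convergence,
                 n_params = length(x$par), n_targets = nrow(x$residuals))
}

#' Local sensitivity coefficient of an observable to a parameter
#'
#' Central finite difference of the normalised response:
#' `(dY/Y) / (dp/p)` evaluated at the model's current parameter value.
#'
#' @param model a [pbpk_model()].
#' @param param parameter path (see [get_parameter()]).
#' @param observable function `model -> numeric`.
#' @param delta relative perturbation in `(0, 0.5]` (default 0.01).
#' @return the dimensionless sensitivity coefficient; `NA` with a warning
#'   if the observable is zero at the nominal point.
#' @export
local_sensitivity <- function(model, param, observable, delta = 0.01) {
  stopifnot(delta > 0, delta <= 0.5)
  p0 <- get_parameter(model, param)
  y0 <- observable(model)
  if (y0 == 0) {
    warning("observable is zero at the nominal point; sensitivity undefined")
    return(NA_real_)
  }
  yp <- observable(set_parameter(model, param, p0 * (1 + delta)))
  ym <- observable(set_parameter(model, param, p0 * (1 - delta)))
  ((yp - ym) / y0) / (2 * delta)
}

#' Chain a metabolite PBPK model onto its parent's clearance
#'
#' Merges two whole-body models sharing the same body structure so that
#' the metabolite's formation rate equals `yield` times the parent's
#' clearance flux through `via_process`, in the compartment where that
#' clearance lives (e.g. oxypurinol formed in the liver at the rate
#' allopurinol is oxidised there).
#'
#' @param parent a [pbpk_model()] containing `via_process`.
#' @param metabolite a [pbpk_model()] with identical compartments and
#'   flows and exactly one species not present in the parent.
#' @param via_process id of a clearance process (`first_order` or
#'   `michaelis_menten`) of the parent.
#' @param stoichiometric_yield mol metabolite formed per mol parent
#'   cleared.
#' @return the merged `pbpk_model`.
#' @export
link_metabolite <- function(parent, metabolite, via_process,
                            stoichiometric_yield = 1) {
  stopifnot(inherits(parent, "pbpk_model"),
            inherits(metabolite, "pbpk_model"),
            stoichiometric_yield >= 0)
  p <- parent$processes[[via_process]]
  if (is.null(p)) stop("unknown parent process: ", via_process)
  if (!p$kind %in% c("first_order", "michaelis_menten")) {
    stop("via_process must be a clearance (first_order or michaelis_menten)")
  }
  same_comp <- identical(parent$compartments[order(parent$compartments$name), ],
                         metabolite$compartments[
                           order(metabolite$compartments$name), ])
  if (!same_comp) {
    stop("parent and metabolite models must share identical compartments")
  }
  new_sp <- setdiff(metabolite$species$name, parent$species$name)
  if (length(new_sp) != 1) {
    stop("metabolite model must add exactly one new species; found: ",
         paste(new_sp, collapse = ", "))
  }

  merged <- parent
  merged$species <- dplyr::bind_rows(
    parent$species, metabolite$species[metabolite$species$name == new_sp, ])
  merged$partition <- dplyr::bind_rows(
    parent$partition,
    metabolite$partition[metabolite$partition$species == new_sp, ])
  met_proc <- metabolite$processes[
    purrr::map_chr(metabolite$processes, "species") == new_sp]
  clash <- intersect(names(met_proc), names(parent$processes))
  if (length(clash) > 0) {
    stop("process id clash between parent and metabolite models: ",
         paste(clash, collapse = ", "))
  }
  merged$processes <- c(parent$processes, met_proc)
  y <- merged$processes[[via_process]]$yields %||num% numeric(0)
  y[new_sp] <- stoichiometric_yield
  merged$processes[[via_process]]$yields <- y
  merged$doses <- dplyr::bind_rows(
    parent$doses, metabolite$doses[metabolite$doses$species == new_sp, ])
  merged
}
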