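#' Flux balance analysis with reproducible optimum selection
#'
#' Solves the linear program `max f'v` subject to `S v = 0` and
#' `lb <= v <= ub`. Because the optimal flux vector of an FBA problem is
#' generally degenerate, a second stage fixes the objective at its
#' optimum and minimises the total absolute flux (parsimonious FBA via
#' positive/negative flux splitting), yielding a unique, reproducible
#' flux vector that downstream flux-change classification can rely on.
#'
#' @param network a [metabolic_network()].
#' @param objective reaction id to maximise, or a named numeric vector of
#'   reaction weights.
#' @param overrides optional bound overrides: a data frame with columns
#'   `reaction`, `lb`, `ub` (`NA` = keep the network bound). Fixed-flux
#'   constraints are expressed as `lb == ub`. See [constrain_flux()].
#' @param pfba run the second (total-flux-minimising) stage
#'   (default `TRUE`).
#' @param tol LP feasibility tolerance.
#' @return a `flux_distribution`: list with `fluxes` (tibble `reaction`,
#'   `flux`), `objective_value`, `status` (`"optimal"`, `"infeasible"`
#'   or `"unbounded"`), and `tol`. Reported fluxes are rounded to 1e-10
#'   to suppress solver noise.
#' @examples
#' net <- metabolic_network(tibble::tibble(
#'   reaction_id = c("in", "out"),
#'   equation = c("-> a[c]", "a[c] ->"),
#'   lb = c(0, 0), ub = c(5, Inf)))
#' fba(net, "out")
#' @export
fba <- function(network, objective, overrides = NULL, pfba = TRUE,
                tol = 1e-9) {
  stopifnot(inherits(network, "metabolic_network"))
  rx <- network$reactions
  f <- .objective_vector(network, objective)
  bounds <- .apply_overrides(rx, overrides)
  .fba_core(network$S, rx$id, f, bounds$lb, bounds$ub, pfba, tol)
}

.objective_vector <- function(network, objective) {
  rx <- network$reactions
  if (is.character(objective)) {
    if (!all(objective %in% rx$id)) {
      stop("objective references unknown reaction: ",
           paste(setdiff(objective, rx$id), collapse = ", "))
    }
    f <- stats::setNames(numeric(nrow(rx)), rx$id)
    f[objective] <- 1
  } else {
    if (is.null(names(objective)) || !all(names(objective) %in% rx$id)) {
      stop("objective weights must be named by existing reaction ids")
    }
    f <- stats::setNames(numeric(nrow(rx)), rx$id)
    f[names(objective)] <- objective
  }
  if (all(f == 0)) stop("objective has no nonzero weight")
  f
}

.apply_overrides <- function(rx, overrides) {
  lb <- rx$lb; ub <- rx$ub
  if (!is.null(overrides) && nrow(tibble::as_tibble(overrides)) > 0) {
    ov <- tibble::as_tibble(overrides)
    bad <- setdiff(ov$reaction, rx$id)
    if (length(bad) > 0) {
      stop("override references unknown reaction: ",
           paste(bad, collapse = ", "))
    }
    i <- match(ov$reaction, rx$id)
    if ("lb" %in% names(ov)) lb[i] <- ifelse(is.na(ov$lb), lb[i], ov$lb)
    if ("ub" %in% names(ov)) ub[i] <- ifelse(is.na(ov$ub), ub[i], ov$ub)
  }
  list(lb = lb, ub = ub)
}

.fba_core <- function(S, ids, f, lb, ub, pfba, tol) {
  m <- nrow(S); n <- ncol(S)
  s1 <- lp_solve(f, S, rep(0, m), lb, ub, maximize = TRUE, tol = tol)
  if (s1$status != "optimal") {
    return(structure(list(fluxes = NULL, objective_value = NA_real_,
                          status = s1$status, tol = tol),
                     class = "flux_distribution"))
  }
  v <- s1$x
  if (pfba) {
    # stage 2: split v = p - q, p,q >= 0; min sum(p + q) subject to
    # S(p - q) = 0, f'(p - q) = z*, and the original box bounds
    zstar <- s1$objective
    A2 <- cbind(rbind(S, f), -rbind(S, f))
    rhs2 <- c(rep(0, m), zstar)
    lb2 <- c(pmax(lb, 0), pmax(-ub, 0))
    ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
    obj2 <- rep(-1, 2 * n)             # maximise -(sum) = minimise sum
    s2 <- lp_solve(obj2, A2, rhs2, lb2, ub2, maximize = TRUE, tol = tol)
    if (s2$status == "optimal") {
      v <- s2$x[seq_len(n)] - s2$x[n + seq_len(n)]
    }
  }
  v <- round(v, 10)
  structure(list(
    fluxes = tibble::tibble(reaction = ids, flux = v),
    objective_value = sum(f * v),
    status = "optimal", tol = tol), class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> status: ", x$status, sep = "")
  if (x$status == "optimal") {
    cat(", objective ", format(x$objective_value, digits = 6), sep = "")
  }
  cat("\n")
  if (!is.null(x$fluxes)) print(x$fluxes, n = 12)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.flux_distribution <- function(x, ...) {
  if (is.null(x$fluxes)) {
    return(tibble::tibble(reaction = character(), flux = numeric()))
  }
  x$fluxes
}

#' @exportS3Method generics::glance
glance.flux_distribution <- function(x, ...) {
  tibble::tibble(status = x$status, objective_value = x$objective_value,
                 n_active = if (is.null(x$fluxes)) NA_integer_
                            else sum(x$fluxes$flux != 0))
}

#' Named flux accessor
#'
#' @param flux a `flux_distribution`.
#' @param reaction reaction id(s); default all.
#' @return named numeric vector of fluxes.
#' @export
flux_of <- function(flux, reaction = NULL) {
  stopifnot(inherits(flux, "flux_distribution"))
  if (is.null(flux$fluxes)) stop("no flux vector (status ", flux$status, ")")
  v <- stats::setNames(flux$fluxes$flux, flux$fluxes$reaction)
  if (is.null(reaction)) v else v[reaction]
}

#' Mass-balance residual of a flux vector
#'
#' Computes `max |S v|`, the worst metabolite imbalance of a flux
#' distribution, and compares it against a pass threshold.
#'
#' @param network a [metabolic_network()].
#' @param flux a `flux_distribution` or named flux vector covering all
#'   reactions.
#' @param threshold pass/fail cutoff (default 1e-8 micromol/L/min).
#' @return tibble with `residual` and `pass`.
#' @export
check_balance <- function(network, flux, threshold = 1e-8) {
  v <- if (inherits(flux, "flux_distribution")) flux_of(flux) else flux
  if (!setequal(names(v), network$reactions$id)) {
    stop("flux vector must cover exactly the network's reactions")
  }
  r <- max(abs(network$S %*% v[colnames(network$S)]))
  tibble::tibble(residual = r, pass = r < threshold)
}
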