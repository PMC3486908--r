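# Shared fixtures and independent oracles.

# exhaustive vertex enumeration for  max c'x  s.t.  A x = b, lb<=x<=ub
# (finite bounds required); the independent optimum oracle for small LPs
enum_lp_max <- function(cc, A, b, lb, ub, tol = 1e-8) {
  n <- length(cc); m <- nrow(A)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  best <- -Inf
  fix_n <- n - m
  if (fix_n <= 0) {
    x <- tryCatch(qr.solve(A, b), error = function(e) NULL)
    if (!is.null(x) && all(x >= lb - tol & x <= ub + tol)) {
      best <- sum(cc * x)
    }
    return(best)
  }
  for (k in seq_len(ncol(idx <- utils::combn(n, fix_n)))) {
    fixv <- idx[, k]
    freev <- setdiff(seq_len(n), fixv)
    grid <- expand.grid(rep(list(c(1, 2)), fix_n))
    for (g in seq_len(nrow(grid))) {
      xf <- ifelse(grid[g, ] == 1, lb[fixv], ub[fixv])
      xf <- as.numeric(xf)
      Af <- A[, freev, drop = FALSE]
      rhs <- b - A[, fixv, drop = FALSE] %*% xf
      sol <- tryCatch(qr.solve(Af, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(Af %*% sol - rhs)) > tol) next
      x <- numeric(n); x[fixv] <- xf; x[freev] <- sol
      if (all(x >= lb - tol & x <= ub + tol)) {
        best <- max(best, sum(cc * x))
      }
    }
  }
  best
}

# enumeration oracle on a metabolic network (finite caps substituted for
# infinite bounds; callers must ensure the cap never binds the optimum)
enum_fba_max <- function(network, objective, overrides = NULL, cap = 100) {
  rx <- network$reactions
  lb <- rx$lb; ub <- rx$ub
  if (!is.null(overrides)) {
    i <- match(overrides$reaction, rx$id)
    if ("lb" %in% names(overrides)) {
      lb[i] <- ifelse(is.na(overrides$lb), lb[i], overrides$lb)
    }
    if ("ub" %in% names(overrides)) {
      ub[i] <- ifelse(is.na(overrides$ub), ub[i], overrides$ub)
    }
  }
  lb[!is.finite(lb)] <- -cap
  ub[!is.finite(ub)] <- cap
  cc <- stats::setNames(numeric(nrow(rx)), rx$id)
  cc[objective] <- 1
  enum_lp_max(cc, network$S, rep(0, nrow(network$S)), lb, ub)
}

one_compartment_model <- function(k = 0.01, volume = 10,
                                  production = 0) {
  procs <- list()
  if (k > 0) procs <- c(procs, list(
    process_first_order("cl", "body", "drug", k = k)))
  if (production > 0) procs <- c(procs, list(
    process_zero_order("prod", "body", "drug", rate = production)))
  pbpk_model(
    compartments = tibble::tibble(name = "body", volume = volume),
    flows = tibble::tibble(source = character(), target = character(),
                           rate = numeric()),
    species = tibble::tibble(name = "drug"),
    processes = procs)
}

init_one <- function(amount, model) {
  matrix(amount, 1, 1, dimnames = list("body", "drug"))
}

# calibrated mean-patient ammonia model, computed once per test run
.fixture_env <- new.env(parent = emptyenv())
cached_ammonia_calibration <- function() {
  if (is.null(.fixture_env$cal)) {
    .fixture_env$cal <- calibrate_ammonia_model(ammonia_pbpk_model())
  }
  .fixture_env$cal
}
cached_ammonia_base_ss <- function() {
  if (is.null(.fixture_env$ss)) {
    .fixture_env$ss <- steady_state(cached_ammonia_calibration()$model,
                                    tol = 1e-7)
  }
  .fixture_env$ss
}
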