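#' Solve a small dense linear program
#'
#' Maximises (or minimises) `obj %*% x` subject to `mat %*% x = rhs` and
#' `lb <= x <= ub`, by a dense two-phase tableau simplex with Bland's rule.
#' Intended for the small flux-balance programs this package generates
#' (tens of variables); it is deterministic, which the downstream
#' flux-change classification relies on.
#'
#' Variables with a finite lower bound are shifted to the origin; free
#' variables (`lb = -Inf`) are split into positive and negative parts, so
#' unboundedness is detected exactly rather than masked by big-M bounds.
#'
#' @param obj numeric objective coefficients, length n.
#' @param mat equality-constraint matrix (m x n).
#' @param rhs equality right-hand side, length m.
#' @param lb,ub variable bounds, length n; may be infinite.
#' @param maximize logical; maximise (default) or minimise.
#' @param tol feasibility/pivot tolerance.
#' @return list with `x`, `objective`, `status` ("optimal", "infeasible",
#'   "unbounded").
#' @keywords internal
lp_solve <- function(obj, mat, rhs, lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(ncol(mat) == n, length(rhs) == nrow(mat),
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(x = NULL, objective = NA_real_, status = "infeasible"))
  }
  sense <- if (maximize) 1 else -1
  c0 <- sense * obj

  # --- convert to standard form: all variables >= 0 ---------------------
  # columns of the standard-form problem map back to original variables
  free <- !is.finite(lb)
  shift <- ifelse(free, 0, lb)
  # x = y_pos - y_neg (free) or x = y + lb (bounded below)
  ncols <- n + sum(free)
  map_pos <- integer(n)   # standard column of the positive part
  map_neg <- integer(n)   # standard column of the negative part (free only)
  k <- 0L
  for (j in seq_len(n)) {
    k <- k + 1L
    map_pos[j] <- k
    if (free[j]) {
      k <- k + 1L
      map_neg[j] <- k
    }
  }
  A <- matrix(0, nrow(mat), ncols)
  A[, map_pos] <- mat
  if (any(free)) A[, map_neg[free]] <- -mat[, free, drop = FALSE]
  b <- rhs - as.vector(mat %*% shift)
  cc <- numeric(ncols)
  cc[map_pos] <- c0
  if (any(free)) cc[map_neg[free]] <- -c0[free]

  # finite upper bounds become inequality rows y <= ub - lb
  ub_shift <- ub - shift
  has_ub <- is.finite(ub_shift)
  # free variables with finite ub: x <= ub -> y_pos - y_neg <= ub
  ub_rows <- which(has_ub)
  p <- length(ub_rows)
  if (p > 0) {
    Aub <- matrix(0, p, ncols)
    for (i in seq_len(p)) {
      j <- ub_rows[i]
      Aub[i, map_pos[j]] <- 1
      if (free[j]) Aub[i, map_neg[j]] <- -1
    }
    bub <- ub_shift[ub_rows]
  } else {
    Aub <- matrix(0, 0, ncols); bub <- numeric(0)
  }

  res <- .simplex_two_phase(A, b, Aub, bub, cc, tol)
  if (res$status != "optimal") {
    return(list(x = NULL, objective = NA_real_, status = res$status))
  }
  y <- res$x
  x <- y[map_pos]
  if (any(free)) x[free] <- x[free] - y[map_neg[free]]
  x <- x + shift
  list(x = x, objective = sum(obj * x), status = "optimal")
}

# Two-phase tableau simplex for
#   max c'y  s.t.  A y = b, Aub y <= bub, y >= 0
# Equality rows may have negative b (sign-flipped here); bub >= 0 by
# construction in lp_solve. Bland's rule throughout (anti-cycling).
.simplex_two_phase <- function(A, b, Aub, bub, cc, tol) {
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  m1 <- nrow(A); m2 <- nrow(Aub); m <- m1 + m2
  n <- ncol(A)
  # columns: [y (n)] [slack (m2)] [artificial (m1)]
  ntot <- n + m2 + m1
  T <- matrix(0, m, ntot + 1)
  if (m1 > 0) {
    T[seq_len(m1), seq_len(n)] <- A
    T[seq_len(m1), n + m2 + seq_len(m1)] <- diag(1, m1)
    T[seq_len(m1), ntot + 1] <- b
  }
  if (m2 > 0) {
    T[m1 + seq_len(m2), seq_len(n)] <- Aub
    T[m1 + seq_len(m2), n + seq_len(m2)] <- diag(1, m2)
    T[m1 + seq_len(m2), ntot + 1] <- bub
  }
  basis <- integer(m)
  if (m1 > 0) basis[seq_len(m1)] <- n + m2 + seq_len(m1)
  if (m2 > 0) basis[m1 + seq_len(m2)] <- n + seq_len(m2)

  if (m1 > 0) {
    # phase 1: minimise sum of artificials
    c1 <- numeric(ntot)
    c1[n + m2 + seq_len(m1)] <- -1   # maximise -(sum art)
    out <- .simplex_iterate(T, basis, c1, allowed = ntot, tol)
    T <- out$T; basis <- out$basis
    art_val <- -out$objective
    if (out$status != "optimal" || art_val > 1e-7) {
      return(list(status = "infeasible"))
    }
    # drive artificials out of the basis where possible
    for (i in which(basis > n + m2)) {
      piv <- which(abs(T[i, seq_len(n + m2)]) > tol)
      if (length(piv) > 0) {
        T <- .pivot(T, i, piv[1])
        basis[i] <- piv[1]
      }
    }
    keep <- basis <= n + m2
    T <- T[keep, , drop = FALSE]
    basis <- basis[keep]
  }
  c2 <- c(cc, numeric(m2), numeric(m1))
  out <- .simplex_iterate(T, basis, c2, allowed = n + m2, tol)
  if (out$status != "optimal") return(list(status = out$status))
  y <- numeric(n)
  rhs_col <- ncol(out$T)
  in_y <- out$basis <= n
  y[out$basis[in_y]] <- out$T[in_y, rhs_col]
  list(status = "optimal", x = pmax(y, 0), objective = out$objective)
}

.pivot <- function(T, row, col) {
  T[row, ] <- T[row, ] / T[row, col]
  other <- setdiff(seq_len(nrow(T)), row)
  if (length(other) > 0) {
    fac <- T[other, col]
    nz <- fac != 0
    if (any(nz)) {
      rows <- other[nz]
      T[rows, ] <- T[rows, , drop = FALSE] - outer(fac[nz], T[row, ])
    }
  }
  T
}

# maximise c'y over the current tableau; columns > `allowed` may not enter
.simplex_iterate <- function(T, basis, cvec, allowed, tol, max_iter = 10000L) {
  m <- nrow(T); rhs_col <- ncol(T)
  for (iter in seq_len(max_iter)) {
    # reduced costs
    cb <- cvec[basis]
    z <- crossprod(T[, seq_len(rhs_col - 1), drop = FALSE], cb)
    red <- cvec - as.vector(z)
    cand <- which(red > tol & seq_along(red) <= allowed)
    if (length(cand) == 0) {
      obj <- sum(cb * T[, rhs_col])
      return(list(T = T, basis = basis, objective = obj, status = "optimal"))
    }
    enter <- min(cand)                       # Bland's rule
    col <- T[, enter]
    pos <- which(col > tol)
    if (length(pos) == 0) {
      return(list(T = T, basis = basis, objective = NA_real_,
                  status = "unbounded"))
    }
    ratio <- T[pos, rhs_col] / col[pos]
    best <- min(ratio)
    ties <- pos[ratio <= best + tol]
    leave <- ties[which.min(basis[ties])]    # Bland's rule on ties
    T <- .pivot(T, leave, enter)
    basis[leave] <- enter
  }
  stop("simplex did not converge within ", max_iter, " iterations")
}
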