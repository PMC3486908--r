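# Objective-panel robustness scan and flux-change classification.

#' Evaluate an objective panel under enzyme inhibition
#'
#' For every objective in the panel the reference optimum is computed
#' first (no inhibition); then each inhibited reaction is capped at
#' `relE * |v0|`, where `v0` is that reaction's flux in the reference
#' solution of the same objective, and the perturbed optimum is
#' computed. The decrease is `1 - perturbed/reference` (0 where the
#' reference optimum is 0); an objective counts as affected when its
#' decrease exceeds `tol`. Infeasible perturbed problems are recorded
#' with optimum 0 and flagged.
#'
#' @param network a [metabolic_network()].
#' @param panel tibble with columns `name` and `objective` (reaction id
#'   to maximise), e.g. from [make_gsh_panel()].
#' @param inhibition_state named numeric vector: reaction id -> relative
#'   enzyme activity in `[0, 1]`.
#' @param tol relative decrease above which an objective counts as
#'   affected (default 1e-6; reported as part of the result).
#' @return a `panel_report`: tibble with `objective`, `reference`,
#'   `perturbed`, `decrease`, `affected`, `status`; attributes `tol` and
#'   `inhibition_state`.
#' @export
evaluate_panel <- function(network, panel, inhibition_state,
                           tol = 1e-6) {
  stopifnot(all(c("name", "objective") %in% names(panel)))
  if (length(inhibition_state) > 0) {
    stopifnot(!is.null(names(inhibition_state)),
              all(inhibition_state >= 0), all(inhibition_state <= 1))
    bad <- setdiff(names(inhibition_state), network$reactions$id)
    if (length(bad) > 0) {
      stop("inhibition_state references unknown reaction: ",
           paste(bad, collapse = ", "))
    }
  }
  rows <- purrr::map2(panel$name, panel$objective, function(nm, obj) {
    ref <- fba(network, obj)
    if (ref$status != "optimal") {
      return(tibble::tibble(objective = nm, reference = NA_real_,
                            perturbed = NA_real_, decrease = NA_real_,
                            affected = NA, status = ref$status))
    }
    v0 <- flux_of(ref)
    ov <- purrr::imap(inhibition_state, function(relE, rid) {
      constrain_flux(network, rid, relE, v0[[rid]])
    })
    per <- fba(network, obj, overrides = dplyr::bind_rows(ov))
    pval <- if (per$status == "optimal") per$objective_value else 0
    dec <- if (ref$objective_value == 0) 0 else
      1 - pval / ref$objective_value
    tibble::tibble(objective = nm, reference = ref$objective_value,
                   perturbed = pval, decrease = dec,
                   affected = dec > tol,
                   status = per$status)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "tol") <- tol
  attr(out, "inhibition_state") <- inhibition_state
  class(out) <- c("panel_report", class(out))
  out
}

#' @exportS3Method generics::glance
glance.panel_report <- function(x, ...) {
  tibble::tibble(n_objectives = nrow(x),
                 n_affected = sum(x$affected, na.rm = TRUE),
                 mean_decrease = mean(x$decrease, na.rm = TRUE),
                 tol = attr(x, "tol"))
}

#' Classify flux changes between two flux distributions
#'
#' Compares the minimum-total-flux optima of the same objective before
#' and after a perturbation, restricted to reactions that are nonzero in
#' at least one of the two solutions. Each compared reaction is
#' classified as `equal` (`|v_p - v_r| <= tol * max(|v_r|, |v_p|)`),
#' `smaller` / `larger` (magnitude decreased / increased from a nonzero
#' reference), or `new` (zero in the reference, nonzero perturbed) --
#' newly active fluxes indicate rerouting through alternative pathways.
#'
#' @param reference,perturbed `flux_distribution`s over the same
#'   reaction set (each the parsimonious optimum).
#' @param tol relative tolerance for "equal" (default 1e-6).
#' @return a `flux_classification`: list with `counts` (tibble `class`,
#'   `n`), `fraction_unchanged`, `n_compared`, `detail` (per-reaction
#'   tibble), `tol`.
#' @export
classify_flux_changes <- function(reference, perturbed, tol = 1e-6) {
  vr <- flux_of(reference); vp <- flux_of(perturbed)
  if (!setequal(names(vr), names(vp))) {
    stop("flux distributions cover different reaction sets")
  }
  vp <- vp[names(vr)]
  keep <- vr != 0 | vp != 0
  vr <- vr[keep]; vp <- vp[keep]
  cls <- dplyr::case_when(
    abs(vp - vr) <= tol * pmax(abs(vr), abs(vp)) ~ "equal",
    vr == 0 & vp != 0 ~ "new",
    abs(vp) < abs(vr) ~ "smaller",
    TRUE ~ "larger")
  detail <- tibble::tibble(reaction = names(vr), reference = unname(vr),
                           perturbed = unname(vp), class = cls)
  counts <- dplyr::count(detail, class = factor(
    class, levels = c("equal", "smaller", "larger", "new")),
    .drop = FALSE, name = "n")
  structure(list(
    counts = counts,
    fraction_unchanged = if (length(cls) == 0) NA_real_
                         else mean(cls == "equal"),
    n_compared = length(cls), detail = detail, tol = tol),
    class = "flux_classification")
}

#' @export
print.flux_classification <- function(x, ...) {
  cat("<flux_classification> ", x$n_compared, " fluxes compared, ",
      round(100 * x$fraction_unchanged, 1), "% unchanged\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.flux_classification <- function(x, ...) x$detail
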