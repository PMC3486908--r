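#' Construct a whole-body PBPK model
#'
#' A compartmental physiologically-based pharmacokinetic model: organs as
#' well-stirred compartments connected by blood flows, with kinetic
#' processes (clearance, production, absorption) and dose events.
#' Distribution is perfusion-limited: the effluent concentration of a
#' compartment for species `s` is `C / K`, where `K` is the
#' tissue-to-blood partition coefficient, so a flow `i -> j` of `Q` L/min
#' carries `Q * C_i / K_i` micromol/min.
#'
#' @param compartments data frame with columns `name`, `volume` (liters)
#'   and optionally `sub_space` (one of `"vascular"`, `"interstitial"`,
#'   `"intracellular"`, `"lumen"`, `"lumped"`; default `"lumped"`).
#' @param flows data frame with columns `source`, `target`, `rate`
#'   (L/min); rates must be non-negative and `source != target`.
#' @param species data frame with columns `name` and optionally `mw`
#'   (g/mol, used only for dose conversion helpers).
#' @param processes list of kinetic processes built with
#'   [process_first_order()], [process_michaelis_menten()],
#'   [process_zero_order()] or [process_oral_absorption()].
#' @param doses data frame with columns `species`, `amount` (micromol),
#'   `route` (`"oral"` or `"intravenous"`) and `time` (minutes); or
#'   `NULL`.
#' @param partition data frame with columns `species`, `compartment`, `k`
#'   overriding the default partition coefficient of 1.
#' @param dose_targets named character vector mapping routes to
#'   compartment names, e.g.
#'   `c(oral = "gut_lumen", intravenous = "venous_blood")`.
#' @param volume_basis reference volume (liters) used to normalise
#'   whole-body rates to volumetric fluxes (micromol/L/min); defaults to
#'   the total compartment volume. All printed fluxes and the network
#'   coupling use this basis.
#' @return an object of class `pbpk_model`.
#' @export
pbpk_model <- function(compartments, flows, species, processes = list(),
                       doses = NULL, partition = NULL,
                       dose_targets = NULL, volume_basis = NULL) {
  compartments <- tibble::as_tibble(compartments)
  if (!"sub_space" %in% names(compartments)) compartments$sub_space <- "lumped"
  stopifnot(all(c("name", "volume") %in% names(compartments)))
  if (anyDuplicated(compartments$name)) stop("duplicate compartment names")
  if (any(compartments$volume <= 0)) stop("compartment volumes must be > 0")
  ok_space <- c("vascular", "interstitial", "intracellular", "lumen", "lumped")
  if (!all(compartments$sub_space %in% ok_space)) {
    stop("sub_space must be one of: ", paste(ok_space, collapse = ", "))
  }

  flows <- tibble::as_tibble(flows)
  stopifnot(all(c("source", "target", "rate") %in% names(flows)))
  if (any(flows$rate < 0)) stop("flow rates must be >= 0")
  if (any(flows$source == flows$target)) stop("flow with source == target")
  unknown <- setdiff(c(flows$source, flows$target), compartments$name)
  if (length(unknown) > 0) {
    stop("flow references unknown compartment: ",
         paste(unique(unknown), collapse = ", "))
  }
  # connectivity of the flow graph (undirected reachability); absorption
  # processes count as edges, and lumen compartments without any edge are
  # tolerated (they hold dosed material awaiting absorption)
  nc <- nrow(compartments)
  if (nc > 1) {
    adj <- matrix(FALSE, nc, nc,
                  dimnames = list(compartments$name, compartments$name))
    adj[cbind(flows$source, flows$target)] <- TRUE
    for (p in processes) {
      if (identical(p$kind, "oral_absorption") &&
          p$compartment %in% compartments$name &&
          p$params$to %in% compartments$name) {
        adj[p$compartment, p$params$to] <- TRUE
      }
    }
    adj <- adj | t(adj)
    seen <- c(TRUE, rep(FALSE, nc - 1))
    repeat {
      new <- seen | apply(adj[seen, , drop = FALSE], 2, any)
      if (all(new == seen)) break
      seen <- new
    }
    isolated <- !seen & compartments$sub_space == "lumen"
    if (!all(seen | isolated)) {
      stop("flow graph is not connected; unreachable: ",
           paste(compartments$name[!(seen | isolated)], collapse = ", "))
    }
  }

  species <- tibble::as_tibble(species)
  stopifnot("name" %in% names(species))
  if (!"mw" %in% names(species)) species$mw <- NA_real_
  if (anyDuplicated(species$name)) stop("duplicate species names")

  part <- tidyr::expand_grid(species = species$name,
                             compartment = compartments$name)
  part$k <- 1
  if (!is.null(partition)) {
    partition <- tibble::as_tibble(partition)
    if (any(partition$k <= 0)) stop("partition coefficients must be > 0")
    bad_sp <- setdiff(partition$species, species$name)
    bad_cp <- setdiff(partition$compartment, compartments$name)
    if (length(c(bad_sp, bad_cp)) > 0) {
      stop("partition table references unknown species/compartment: ",
           paste(c(bad_sp, bad_cp), collapse = ", "))
    }
    key <- paste(part$species, part$compartment)
    pkey <- paste(partition$species, partition$compartment)
    part$k[match(pkey, key)] <- partition$k
  }

  if (!is.null(processes) && length(processes) > 0) {
    ids <- purrr::map_chr(processes, "id")
    if (anyDuplicated(ids)) stop("duplicate process ids")
    names(processes) <- ids
    for (p in processes) {
      if (!p$compartment %in% compartments$name) {
        stop("process ", p$id, " references unknown compartment ",
             p$compartment)
      }
      if (!p$species %in% species$name) {
        stop("process ", p$id, " references unknown species ", p$species)
      }
      if (p$kind == "oral_absorption" &&
          !p$params$to %in% compartments$name) {
        stop("absorption process ", p$id, " targets unknown compartment ",
             p$params$to)
      }
      bad_yield <- setdiff(names(p$yields), species$name)
      if (length(bad_yield) > 0) {
        stop("process ", p$id, " yields unknown species: ",
             paste(bad_yield, collapse = ", "))
      }
    }
  } else {
    processes <- list()
  }

  if (!is.null(doses)) {
    doses <- tibble::as_tibble(doses)
    stopifnot(all(c("species", "amount", "route", "time") %in% names(doses)))
    if (any(doses$amount <= 0)) stop("dose amounts must be > 0")
    if (any(doses$time < 0)) stop("dose times must be >= 0")
    if (!all(doses$route %in% c("oral", "intravenous"))) {
      stop("dose route must be oral or intravenous")
    }
    if (!all(doses$species %in% species$name)) {
      stop("dose references unknown species")
    }
    dup <- doses |>
      dplyr::count(.data$species, .data$route, .data$time) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) stop("dose times must be strictly increasing per ",
                            "species/route (duplicated times found)")
  } else {
    doses <- tibble::tibble(species = character(), amount = numeric(),
                            route = character(), time = numeric())
  }

  if (is.null(dose_targets)) {
    dose_targets <- c(
      oral = if ("gut_lumen" %in% compartments$name) "gut_lumen"
             else compartments$name[1],
      intravenous = if ("venous_blood" %in% compartments$name) "venous_blood"
                    else compartments$name[1])
  }
  used_routes <- unique(doses$route)
  if (!all(used_routes %in% names(dose_targets))) {
    stop("no dose target compartment for route: ",
         paste(setdiff(used_routes, names(dose_targets)), collapse = ", "))
  }

  structure(list(
    compartments = compartments, flows = flows, species = species,
    partition = part, processes = processes, doses = doses,
    dose_targets = dose_targets,
    volume_basis = volume_basis %||num% sum(compartments$volume)),
    class = "pbpk_model")
}

`%||num%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pbpk_model <- function(x, ...) {
  cat("<pbpk_model> ", nrow(x$compartments), " compartments, ",
      nrow(x$species), " species, ", length(x$processes), " processes, ",
      nrow(x$doses), " dose events\n", sep = "")
  invisible(x)
}

# ---- kinetic process constructors ------------------------------------------

new_process <- function(id, kind, compartment, species, params,
                        yields = NULL) {
  stopifnot(is.character(id), length(id) == 1)
  structure(list(id = id, kind = kind, compartment = compartment,
                 species = species, params = params,
                 yields = yields %||num% numeric(0)),
            class = "pbpk_process")
}

#' Kinetic process constructors
#'
#' Processes attach ADME kinetics to a compartment and species.
#' `process_first_order()` is a linear clearance (rate `k * A`, `k` in
#' 1/min, `A` the compartment amount); `process_michaelis_menten()` a
#' saturable clearance (`Vmax` in micromol/L/min on the compartment
#' volume, `Km` in uM); `process_zero_order()` a constant production
#' (`rate` in micromol/L/min on the compartment volume); and
#' `process_oral_absorption()` a first-order transfer (`ka` in 1/min)
#' from a lumen compartment into the absorbing tissue `to`.
#'
#' Clearance processes may carry `yields`, a named vector mapping product
#' species to their molar yield: the cleared flux times the yield is
#' formed as product in the same compartment (see [link_metabolite()]).
#'
#' @param id unique process identifier.
#' @param compartment compartment name the process lives in.
#' @param species species acted on.
#' @param k,vmax,km,rate,ka kinetic parameters (see above).
#' @param to absorption target compartment.
#' @param yields named numeric vector of product species yields (mol/mol).
#' @return a `pbpk_process` object.
#' @name processes
NULL

#' @rdname processes
#' @export
process_first_order <- function(id, compartment, species, k, yields = NULL) {
  stopifnot(k >= 0)
  new_process(id, "first_order", compartment, species, list(k = k), yields)
}

#' @rdname processes
#' @export
process_michaelis_menten <- function(id, compartment, species, vmax, km,
                                     yields = NULL) {
  stopifnot(vmax >= 0, km > 0)
  new_process(id, "michaelis_menten", compartment, species,
              list(vmax = vmax, km = km), yields)
}

#' @rdname processes
#' @export
process_zero_order <- function(id, compartment, species, rate) {
  stopifnot(rate >= 0)
  new_process(id, "zero_order_production", compartment, species,
              list(rate = rate))
}

#' @rdname processes
#' @export
process_oral_absorption <- function(id, compartment, species, ka, to) {
  stopifnot(ka >= 0)
  new_process(id, "oral_absorption", compartment, species,
              list(ka = ka, to = to))
}

# ---- parameter paths (used by calibrate and local_sensitivity) -------------

#' Get or set a scalar model parameter by path
#'
#' Paths address kinetic parameters as `"process/<id>/<param>"` (e.g.
#' `"process/liver_cl/k"`), flows as `"flow/<source>/<target>"` and
#' volumes as `"volume/<compartment>"`.
#'
#' @param model a [pbpk_model()].
#' @param path parameter path string.
#' @param value replacement value (for `set_parameter`).
#' @return `get_parameter`: the numeric value. `set_parameter`: the
#'   modified model.
#' @export
get_parameter <- function(model, path) {
  p <- strsplit(path, "/", fixed = TRUE)[[1]]
  switch(p[1],
    process = {
      pr <- model$processes[[p[2]]]
      if (is.null(pr)) stop("unknown process: ", p[2])
      val <- pr$params[[p[3]]]
      if (is.null(val)) stop("process ", p[2], " has no parameter ", p[3])
      val
    },
    flow = {
      i <- which(model$flows$source == p[2] & model$flows$target == p[3])
      if (length(i) != 1) stop("unknown flow: ", p[2], " -> ", p[3])
      model$flows$rate[i]
    },
    volume = {
      i <- match(p[2], model$compartments$name)
      if (is.na(i)) stop("unknown compartment: ", p[2])
      model$compartments$volume[i]
    },
    stop("unknown parameter path: ", path))
}

#' @rdname get_parameter
#' @export
set_parameter <- function(model, path, value) {
  p <- strsplit(path, "/", fixed = TRUE)[[1]]
  switch(p[1],
    process = {
      if (is.null(model$processes[[p[2]]])) stop("unknown process: ", p[2])
      model$processes[[p[2]]]$params[[p[3]]] <- value
    },
    flow = {
      i <- which(model$flows$source == p[2] & model$flows$target == p[3])
      if (length(i) != 1) stop("unknown flow: ", p[2], " -> ", p[3])
      model$flows$rate[i] <- value
    },
    volume = {
      i <- match(p[2], model$compartments$name)
      if (is.na(i)) stop("unknown compartment: ", p[2])
      model$compartments$volume[i] <- value
    },
    stop("unknown parameter path: ", path))
  model
}
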