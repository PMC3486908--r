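# Structured-config interfaces: PBPK model YAML/JSON, coupling-spec YAML,
# CSV trajectory/flux output, and run manifests.

.read_config_file <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Load a PBPK model from a YAML/JSON configuration
#'
#' The schema mirrors [pbpk_model()]: top-level keys `compartments`
#' (list of `name`/`volume`/`sub_space`), `flows`
#' (`source`/`target`/`rate`), `species` (`name`/`mw`), `partition`
#' (`species`/`compartment`/`k`), `processes` (each with `id`, `kind`,
#' `compartment`, `species` and its kinetic `parameters`, plus optional
#' `yields`), `doses` (`species`/`amount`/`route`/`time` or `times`),
#' `dose_targets`, `volume_basis`. Units are fixed (L, L/min, uM,
#' micromol, micromol/L/min, 1/min) and validated on load.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON (`.json`) file.
#' @return a [pbpk_model()].
#' @export
read_pbpk_config <- function(path) {
  cfg <- .read_config_file(path)
  need <- c("compartments", "flows", "species")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0) {
    stop("config ", path, " lacks keys: ", paste(miss, collapse = ", "))
  }
  as_tbl <- function(x, proto = NULL) {
    if (length(x) == 0) {
      return(proto %||num% tibble::tibble())
    }
    dplyr::bind_rows(purrr::map(x, tibble::as_tibble))
  }
  empty_flows <- tibble::tibble(source = character(),
                                target = character(), rate = numeric())
  procs <- purrr::map(cfg$processes %||num% list(), function(p) {
    par <- p$parameters %||num% list()
    yields <- if (!is.null(p$yields)) unlist(p$yields)
    switch(p$kind %||num% stop("process without kind"),
      first_order = process_first_order(p$id, p$compartment, p$species,
                                        k = par$k, yields = yields),
      michaelis_menten = process_michaelis_menten(
        p$id, p$compartment, p$species, vmax = par$vmax, km = par$km,
        yields = yields),
      zero_order_production = process_zero_order(
        p$id, p$compartment, p$species, rate = par$rate),
      oral_absorption = process_oral_absorption(
        p$id, p$compartment, p$species, ka = par$ka, to = par$to),
      stop("unknown process kind: ", p$kind))
  })
  doses <- NULL
  if (!is.null(cfg$doses)) {
    doses <- dplyr::bind_rows(purrr::map(cfg$doses, function(d) {
      tibble::tibble(species = d$species, amount = d$amount,
                     route = d$route,
                     time = unlist(d$times %||num% d$time))
    }))
  }
  pbpk_model(
    compartments = as_tbl(cfg$compartments),
    flows = as_tbl(cfg$flows, proto = empty_flows),
    species = as_tbl(cfg$species),
    processes = procs,
    doses = doses,
    partition = if (!is.null(cfg$partition)) as_tbl(cfg$partition),
    dose_targets = if (!is.null(cfg$dose_targets))
      unlist(cfg$dose_targets),
    volume_basis = cfg$volume_basis)
}

#' Load a coupling specification and assemble the multiscale model
#'
#' YAML schema: `dt`, `objective`, `indirect_links` (each `species`,
#' `compartment`, `reaction`, and `ic50` or `ki`, optional `model`),
#' `direct_links` (each `process`, `reaction`, `direction`). Every id is
#' validated against the supplied PBPK model and network.
#'
#' @param path YAML file.
#' @param pbpk a [pbpk_model()].
#' @param network a [metabolic_network()].
#' @return a [multiscale_model()].
#' @export
read_coupling_spec <- function(path, pbpk, network) {
  cfg <- .read_config_file(path)
  if (is.null(cfg$objective)) stop("coupling spec needs an objective")
  il <- purrr::map(cfg$indirect_links %||num% list(), function(l) {
    indirect_link(l$species, l$compartment, l$reaction,
                  inhibition_params(ki = l$ki, ic50 = l$ic50,
                                    model = l$model %||num% "competitive"))
  })
  dl <- purrr::map(cfg$direct_links %||num% list(), function(l) {
    direct_link(l$process, l$reaction,
                direction = l$direction %||num% "uptake")
  })
  multiscale_model(pbpk, network, objective = cfg$objective,
                   indirect_links = il, direct_links = dl,
                   dt = cfg$dt %||num% 1)
}

#' Write a trajectory as CSV
#'
#' Columns `time_min`, `compartment`, `species`, `concentration_uM`.
#'
#' @param traj a `pbpk_trajectory` (or `coupled_trajectory`).
#' @param path output file.
#' @param every thinning (keep every n-th time point).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, every = 1L) {
  tb <- trajectory_tbl(traj, every = every)
  utils::write.csv(
    tb[, c("time_min", "compartment", "species", "concentration_uM")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a coupled model's flux series as CSV
#'
#' Columns `time_min`, `reaction_id`, `flux`.
#'
#' @param traj a `coupled_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_flux_csv <- function(traj, path) {
  fl <- traj$fluxes
  names(fl)[names(fl) == "reaction"] <- "reaction_id"
  utils::write.csv(fl[!is.na(fl$flux), ], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a reproducible run manifest
#'
#' Every CLI run records its configuration hash, seed, package and R
#' versions, timestamp and output paths.
#'
#' @param out_dir directory the manifest (`manifest.json`) is written to.
#' @param config list of configuration values the run used.
#' @param seed the run seed (or `NA`).
#' @param outputs character vector of produced files.
#' @return path of the manifest, invisibly.
#' @export
write_manifest <- function(out_dir, config = list(), seed = NA,
                           outputs = character()) {
  man <- list(
    config_hash = rlang::hash(config),
    seed = seed,
    package = tryCatch(as.character(utils::packageVersion("dfbalink")),
                       error = function(e) "unversioned"),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
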