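#' Construct a stoichiometric metabolic network
#'
#' Builds the network object used by [fba()] and the dFBA coupling layer
#' from a reaction table. Each reaction is given as a chemical equation
#' string, e.g. `"2 nh3[c] + co2[c] -> urea[c]"`. Exchange reactions are
#' written with an empty side (`"nh3[e] ->"` exports, `"-> akg[c]"`
#' supplies) and are auto-flagged: any reaction whose stoichiometry
#' touches a single metabolite is an exchange.
#'
#' @param reactions a data frame with columns `reaction_id`, `equation`,
#'   and optionally `lb`, `ub` (flux bounds, default `[0, Inf)` for
#'   irreversible `->` and `(-Inf, Inf)` for reversible `<->`) and
#'   `notes` (free text; used for activity tags such as `"XO"`).
#' @return an object of class `metabolic_network`: a list with
#'   `metabolites` (tibble: `id`, `compartment`), `reactions` (tibble:
#'   `id`, `lb`, `ub`, `is_exchange`, `notes`) and the dense
#'   stoichiometric matrix `S` (metabolites x reactions, negative =
#'   consumed).
#' @examples
#' net <- metabolic_network(tibble::tibble(
#'   reaction_id = c("upt", "conv", "exp"),
#'   equation = c("-> a[c]", "a[c] -> b[c]", "b[c] ->")))
#' net
#' @export
metabolic_network <- function(reactions) {
  reactions <- tibble::as_tibble(reactions)
  req <- c("reaction_id", "equation")
  if (!all(req %in% names(reactions))) {
    stop("reaction table needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(reactions) == 0) stop("empty reaction list")
  if (anyDuplicated(reactions$reaction_id)) {
    dup <- unique(reactions$reaction_id[duplicated(reactions$reaction_id)])
    stop("duplicate reaction ids: ", paste(dup, collapse = ", "))
  }
  if (!"notes" %in% names(reactions)) reactions$notes <- ""
  reactions$notes[is.na(reactions$notes)] <- ""

  parsed <- purrr::map(reactions$equation, parse_reaction_equation)
  rev_flag <- purrr::map_lgl(parsed, "reversible")
  if (!"lb" %in% names(reactions)) reactions$lb <- NA_real_
  if (!"ub" %in% names(reactions)) reactions$ub <- NA_real_
  reactions$lb <- ifelse(is.na(reactions$lb), ifelse(rev_flag, -Inf, 0),
                         reactions$lb)
  reactions$ub <- ifelse(is.na(reactions$ub), Inf, reactions$ub)
  if (any(reactions$lb > reactions$ub)) {
    stop("lower bound exceeds upper bound for: ",
         paste(reactions$reaction_id[reactions$lb > reactions$ub],
               collapse = ", "))
  }

  stoich <- purrr::map(parsed, "stoichiometry")
  empty <- purrr::map_int(stoich, length) == 0
  if (any(empty)) {
    stop("reaction with empty stoichiometry: ",
         paste(reactions$reaction_id[empty], collapse = ", "))
  }
  met_ids <- sort(unique(unlist(purrr::map(stoich, names))))
  S <- matrix(0, length(met_ids), nrow(reactions),
              dimnames = list(met_ids, reactions$reaction_id))
  for (j in seq_along(stoich)) S[names(stoich[[j]]), j] <- stoich[[j]]

  structure(list(
    metabolites = tibble::tibble(
      id = met_ids,
      compartment = sub("^.*\\[(.*)\\]$", "\\1", met_ids)),
    reactions = tibble::tibble(
      id = reactions$reaction_id,
      lb = reactions$lb, ub = reactions$ub,
      is_exchange = colSums(S != 0) == 1,
      notes = reactions$notes),
    S = S), class = "metabolic_network")
}

#' Parse a reaction equation string
#'
#' Grammar: `[coef] met[compartment] (+ ...) -> / <-> (+ ...)`, with either
#' side possibly empty (exchange reactions).
#'
#' @param eq equation string.
#' @return list with `stoichiometry` (named numeric, negative = consumed)
#'   and `reversible` flag.
#' @keywords internal
parse_reaction_equation <- function(eq) {
  arrow <- if (grepl("<->", eq, fixed = TRUE)) "<->" else
    if (grepl("->", eq, fixed = TRUE)) "->" else
      stop("malformed equation (no arrow): ", eq)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  sides <- c(sides, rep("", 2 - length(sides)))[1:2]
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (side == "") return(numeric(0))
    if (grepl("^\\+", side) || grepl("\\+$", side) ||
        grepl("\\+\\s*\\+", side)) {
      stop("malformed equation (dangling +): ", eq)
    }
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      if (tm == "") stop("malformed equation (dangling +): ", eq)
      m <- regmatches(tm, regexec(
        "^([0-9]*\\.?[0-9]+)?\\s*([A-Za-z0-9_:-]+\\[[A-Za-z0-9_]+\\])$", tm))[[1]]
      if (length(m) == 0) stop("malformed species term '", tm, "' in: ", eq)
      coef <- if (m[2] == "") 1 else as.numeric(m[2])
      out[m[3]] <- .coef(out, m[3]) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (nm in names(rhs)) st[nm] <- .coef(st, nm) + rhs[nm]
  st <- st[st != 0]
  list(stoichiometry = st, reversible = arrow == "<->")
}

.coef <- function(v, nm) if (nm %in% names(v)) v[[nm]] else 0

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions (",
      sum(x$reactions$is_exchange), " exchanges)\n", sep = "")
  invisible(x)
}

#' Load a metabolic network from a reaction-table TSV or SBML file
#'
#' The reaction-table format has a required header and columns
#' `reaction_id`, `equation`, `lb`, `ub`, `notes` (UTF-8, tab-separated;
#' empty `lb`/`ub` fall back to the arrow-implied defaults). Files ending
#' in `.xml` or `.sbml` are parsed as SBML Level 3 with the FBC flux
#' bounds package (see [read_sbml()]).
#'
#' @param source path to a `.tsv` reaction table or `.xml`/`.sbml` file.
#' @return a [metabolic_network()] object.
#' @export
load_network <- function(source) {
  if (!file.exists(source)) stop("no such file: ", source)
  if (grepl("\\.(xml|sbml)$", source, ignore.case = TRUE)) {
    return(read_sbml(source))
  }
  tab <- utils::read.delim(source, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           na.strings = c("NA", ""))
  need <- c("reaction_id", "equation")
  if (!all(need %in% names(tab))) {
    stop("reaction table ", source, " must have header with columns ",
         paste(need, collapse = ", "))
  }
  tab$lb <- suppressWarnings(as.numeric(tab$lb %||na% NA))
  tab$ub <- suppressWarnings(as.numeric(tab$ub %||na% NA))
  withCallingHandlers(
    metabolic_network(tab),
    error = function(e) stop("while loading ", source, ": ",
                             conditionMessage(e), call. = FALSE))
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

#' Write a network as a reaction-table TSV
#'
#' Inverse of [load_network()]; equations are regenerated from the
#' stoichiometric matrix.
#'
#' @param network a [metabolic_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reaction_tsv <- function(network, path) {
  eqs <- purrr::map_chr(seq_len(ncol(network$S)), function(j) {
    format_equation(network$S[, j], reversible = network$reactions$lb[j] < 0)
  })
  tab <- data.frame(reaction_id = network$reactions$id, equation = eqs,
                    lb = network$reactions$lb, ub = network$reactions$ub,
                    notes = network$reactions$notes)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

format_equation <- function(col, reversible = FALSE) {
  fmt <- function(ids, coefs) {
    paste(ifelse(coefs == 1, ids, paste(format(coefs, trim = TRUE), ids)),
          collapse = " + ")
  }
  lhs <- which(col < 0); rhs <- which(col > 0)
  arrow <- if (reversible) "<->" else "->"
  paste(fmt(names(col)[lhs], -col[lhs]), arrow, fmt(names(col)[rhs], col[rhs]))
}

# ---- minimal SBML Level 3 (FBC) interchange --------------------------------
# Covers the subset needed for constraint-based models: compartments,
# species, reactions with stoichiometry, and FBC flux bounds. This is a
# purposely small reader/writer for interchange with COBRA-style tools,
# not a general SBML implementation.

#' Read a constraint-based model from SBML Level 3 (FBC)
#'
#' @param path SBML file.
#' @return a [metabolic_network()] object.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_comp <- stats::setNames(xml2::xml_attr(sp, "compartment"),
                             xml2::xml_attr(sp, "id"))
  rxns <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rxns) == 0) stop("no reactions in SBML file ", path)
  rows <- purrr::map(rxns, function(rx) {
    id <- xml2::xml_attr(rx, "id")
    get_side <- function(which) {
      refs <- xml2::xml_find_all(rx, paste0("./", which, "/speciesReference"))
      stats::setNames(as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      xml2::xml_attr(refs, "species"))
    }
    reac <- get_side("listOfReactants"); prod <- get_side("listOfProducts")
    term <- function(ids, coefs) {
      if (length(ids) == 0) return("")
      lab <- paste0(ids, "[", sp_comp[ids] %|chr|% "c", "]")
      paste(ifelse(coefs == 1, lab, paste(coefs, lab)), collapse = " + ")
    }
    lb_id <- xml2::xml_attr(rx, "lowerFluxBound")
    ub_id <- xml2::xml_attr(rx, "upperFluxBound")
    lb <- if (!is.na(lb_id) && lb_id %in% names(pval)) pval[[lb_id]] else NA
    ub <- if (!is.na(ub_id) && ub_id %in% names(pval)) pval[[ub_id]] else NA
    rev <- identical(xml2::xml_attr(rx, "reversible"), "true")
    tibble::tibble(
      reaction_id = id,
      equation = paste(term(names(reac), reac),
                       if (rev) "<->" else "->",
                       term(names(prod), prod)),
      lb = lb, ub = ub, notes = "")
  })
  metabolic_network(dplyr::bind_rows(rows))
}

`%|chr|%` <- function(a, b) { a[is.na(a)] <- b; a }

#' Write a network as SBML Level 3 (FBC)
#'
#' @param network a [metabolic_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(network, path) {
  sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  # species id = name part; compartment carried separately, so the
  # reader reconstructs the same "name[comp]" labels (round-trip safe)
  met_sid <- stats::setNames(sid(sub("\\[[^]]*\\]$", "",
                                     network$metabolites$id)),
                             network$metabolites$id)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '<model id="model" fbc:strict="true">',
    '<listOfCompartments>',
    paste0('<compartment id="', unique(network$metabolites$compartment),
           '" constant="true"/>'),
    '</listOfCompartments>',
    '<listOfSpecies>',
    paste0('<species id="', met_sid, '" compartment="',
           network$metabolites$compartment,
           '" hasOnlySubstanceUnits="false" boundaryCondition="false" ',
           'constant="false"/>'),
    '</listOfSpecies>',
    '<listOfParameters>')
  bnd <- character(0)
  for (j in seq_len(nrow(network$reactions))) {
    rid <- sid(network$reactions$id[j])
    bnd <- c(bnd,
      paste0('<parameter id="', rid, '_lb" value="',
             network$reactions$lb[j], '" constant="true"/>'),
      paste0('<parameter id="', rid, '_ub" value="',
             network$reactions$ub[j], '" constant="true"/>'))
  }
  lines <- c(lines, bnd, '</listOfParameters>', '<listOfReactions>')
  for (j in seq_len(nrow(network$reactions))) {
    col <- network$S[, j]
    rid <- sid(network$reactions$id[j])
    side <- function(ids, coefs, tag) {
      if (length(ids) == 0) return(character(0))
      c(paste0('<', tag, '>'),
        paste0('<speciesReference species="', met_sid[ids],
               '" stoichiometry="', coefs, '" constant="true"/>'),
        paste0('</', tag, '>'))
    }
    reac <- which(col < 0); prod <- which(col > 0)
    lines <- c(lines,
      paste0('<reaction id="', rid, '" reversible="',
             tolower(network$reactions$lb[j] < 0),
             '" fast="false" fbc:lowerFluxBound="', rid,
             '_lb" fbc:upperFluxBound="', rid, '_ub">'),
      side(names(col)[reac], -col[reac], "listOfReactants"),
      side(names(col)[prod], col[prod], "listOfProducts"),
      '</reaction>')
  }
  lines <- c(lines, '</listOfReactions>', '</model>', '</sbml>')
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
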