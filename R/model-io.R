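## Model construction and readers/writers (native JSON schema + SBML core).

#' Construct a StoichiometricModel
#'
#' @param speciesId species identifier.
#' @param metabolites data.frame with columns `id`, `compartment` and
#'   optionally `name`, `formula`.
#' @param reactions data.frame with columns `id` and optionally `lb`, `ub`,
#'   `isExchange`, `isBiomass`, `reversible`. Missing bounds default to
#'   `[-1000, 1000]` for reversible and `[0, 1000]` for irreversible
#'   reactions (reactions are reversible by default).
#' @param stoichiometry either a metabolites x reactions numeric matrix, or
#'   a named list mapping reaction id to a named coefficient vector.
#' @return a validated [StoichiometricModel-class].
#' @examples
#' m <- stoichiometricModel("toy",
#'   metabolites = data.frame(id = c("glc_e", "c"),
#'                            compartment = c("extracellular", "intracellular")),
#'   reactions = data.frame(id = c("EX_glc", "CAT_glc", "BIOMASS"),
#'                          lb = c(-10, 0, 0), ub = c(1000, 1000, 1000),
#'                          isExchange = c(TRUE, FALSE, FALSE),
#'                          isBiomass = c(FALSE, FALSE, TRUE)),
#'   stoichiometry = list(EX_glc = c(glc_e = -1),
#'                        CAT_glc = c(glc_e = -1, c = 0.1),
#'                        BIOMASS = c(c = -1)))
#' growthRate(fba(m))
#' @export
stoichiometricModel <- function(speciesId, metabolites, reactions,
                                stoichiometry) {
  metabolites <- as.data.frame(metabolites)
  reactions <- as.data.frame(reactions)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  rev <- if (is.null(reactions$reversible)) rep(TRUE, nrow(reactions)) else
    reactions$reversible
  if (is.null(reactions$lb)) reactions$lb <- ifelse(rev, -1000, 0)
  if (is.null(reactions$ub)) reactions$ub <- 1000
  reactions$lb[is.na(reactions$lb)] <- ifelse(rev[is.na(reactions$lb)], -1000, 0)
  reactions$ub[is.na(reactions$ub)] <- 1000
  if (is.null(reactions$isExchange)) reactions$isExchange <- FALSE
  if (is.null(reactions$isBiomass)) reactions$isBiomass <- FALSE
  reactions$reversible <- NULL
  metabolites <- metabolites[, c("id", "name", "compartment", "formula")]
  reactions <- reactions[, c("id", "lb", "ub", "isExchange", "isBiomass")]

  if (is.list(stoichiometry) && !is.matrix(stoichiometry)) {
    S <- matrix(0, nrow(metabolites), nrow(reactions),
                dimnames = list(metabolites$id, reactions$id))
    for (rid in names(stoichiometry)) {
      coefs <- stoichiometry[[rid]]
      if (!rid %in% reactions$id) {
        stop("stoichiometry refers to undeclared reaction '", rid, "'")
      }
      bad <- setdiff(names(coefs), metabolites$id)
      if (length(bad)) {
        stop("reaction '", rid, "' references undeclared metabolite(s): ",
             paste(bad, collapse = ", "))
      }
      S[names(coefs), rid] <- coefs
    }
  } else {
    S <- as.matrix(stoichiometry)
    if (is.null(dimnames(S))) {
      dimnames(S) <- list(metabolites$id, reactions$id)
    }
  }
  obj <- new("StoichiometricModel", speciesId = as.character(speciesId),
             metabolites = metabolites, reactions = reactions,
             stoichiometry = S)
  validObject(obj)
  obj
}

#' Read a stoichiometric model from file
#'
#' Supports the package's native JSON schema and SBML Level 3 core with the
#' fbc extension (bounds and objective); SBML annotations are ignored.
#' Compartments whose id or name contains "extracellular" (or whose id is
#' "e" / ends in "_e") map to the extracellular compartment; everything else
#' is treated as intracellular.
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; guessed from the file extension when
#'   missing.
#' @return a validated [StoichiometricModel-class].
#' @seealso [writeModel()]
#' @export
readModel <- function(path, format = c("json", "sbml")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (length(format) > 1) {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
              else "json"
  }
  format <- match.arg(format)
  if (format == "json") .read_model_json(path) else .read_model_sbml(path)
}

.read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in '", path, "': ",
                             conditionMessage(e)))
  for (field in c("species_id", "metabolites", "reactions")) {
    if (is.null(doc[[field]])) {
      stop("malformed model file: missing element '", field, "'")
    }
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id) || is.null(m$compartment)) {
      stop("malformed metabolite entry: 'id' and 'compartment' are required")
    }
    data.frame(id = m$id, name = if (is.null(m$name)) m$id else m$name,
               compartment = m$compartment,
               formula = if (is.null(m$formula)) NA_character_ else m$formula)
  }))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    if (is.null(r$id) || is.null(r$stoich)) {
      stop("malformed reaction entry: 'id' and 'stoich' are required")
    }
    rev <- if (is.null(r$reversible)) TRUE else isTRUE(r$reversible)
    data.frame(id = r$id,
               lb = if (is.null(r$lb)) ifelse(rev, -1000, 0) else r$lb,
               ub = if (is.null(r$ub)) 1000 else r$ub,
               isExchange = isTRUE(r$is_exchange),
               isBiomass = isTRUE(r$is_biomass),
               reversible = rev)
  }))
  stoich <- lapply(doc$reactions, function(r) unlist(r$stoich))
  names(stoich) <- vapply(doc$reactions, function(r) r$id, character(1))
  stoichiometricModel(doc$species_id, mets, rxns, stoich)
}

#' Write a stoichiometric model to the native JSON schema
#'
#' The writer is canonical: fields appear in a fixed order and numbers keep
#' full precision, so `writeModel(readModel(f))` is byte-identical to a file
#' previously produced by `writeModel`.
#'
#' @param model a [StoichiometricModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "StoichiometricModel"))
  met <- model@metabolites
  rxn <- model@reactions
  S <- model@stoichiometry
  mets <- lapply(seq_len(nrow(met)), function(i) {
    out <- list(id = jsonlite::unbox(met$id[i]),
                name = jsonlite::unbox(met$name[i]),
                compartment = jsonlite::unbox(met$compartment[i]))
    if (!is.na(met$formula[i])) out$formula <- jsonlite::unbox(met$formula[i])
    out
  })
  rxns <- lapply(seq_len(nrow(rxn)), function(j) {
    nz <- which(S[, j] != 0)
    st <- as.list(S[nz, j])
    names(st) <- rownames(S)[nz]
    list(id = jsonlite::unbox(rxn$id[j]),
         stoich = lapply(st, jsonlite::unbox),
         lb = jsonlite::unbox(rxn$lb[j]),
         ub = jsonlite::unbox(rxn$ub[j]),
         is_exchange = jsonlite::unbox(rxn$isExchange[j]),
         is_biomass = jsonlite::unbox(rxn$isBiomass[j]))
  })
  doc <- list(species_id = jsonlite::unbox(model@speciesId),
              metabolites = mets, reactions = rxns)
  json <- jsonlite::toJSON(doc, digits = NA, pretty = 2)
  writeLines(json, path)
  invisible(path)
}

## --- SBML (Level 3 core + fbc bounds/objective) ----------------------------

.sbml_compartment_type <- function(id, name) {
  id <- tolower(id %||% "")
  name <- tolower(name %||% "")
  if (grepl("extracellular", id) || grepl("extracellular", name) ||
      id == "e" || grepl("_e$", id) || id == "e0") {
    "extracellular"
  } else {
    "intracellular"
  }
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

.read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in '", path, "': ",
                                           conditionMessage(e)))
  ns <- c(s = xml2::xml_ns(doc)[[1]])
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(model_node)) stop("malformed SBML: no <model> element")
  model_id <- xml2::xml_attr(model_node, "id") %||% "sbml_model"

  comp_nodes <- xml2::xml_find_all(doc, ".//s:listOfCompartments/s:compartment", ns)
  comp_type <- vapply(comp_nodes, function(n) {
    .sbml_compartment_type(xml2::xml_attr(n, "id"), xml2::xml_attr(n, "name"))
  }, character(1))
  names(comp_type) <- xml2::xml_attr(comp_nodes, "id")

  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (length(sp_nodes) == 0) stop("malformed SBML: no species declared")
  mets <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
                  xml2::xml_attr(sp_nodes, "id"),
                  xml2::xml_attr(sp_nodes, "name")),
    compartment = vapply(xml2::xml_attr(sp_nodes, "compartment"),
                         function(cid) comp_type[cid] %||% "intracellular",
                         character(1), USE.NAMES = FALSE),
    formula = NA_character_
  )

  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  par_val <- as.numeric(xml2::xml_attr(par_nodes, "value"))
  names(par_val) <- xml2::xml_attr(par_nodes, "id")

  obj_refs <- xml2::xml_find_all(
    doc, ".//*[local-name() = 'fluxObjective']")
  objective_rxns <- vapply(obj_refs, function(n) {
    xml2::xml_attr(n, "reaction")
  }, character(1))

  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rxn_nodes) == 0) stop("malformed SBML: no reactions declared")
  rxn_rows <- list()
  stoich <- list()
  for (n in rxn_nodes) {
    rid <- xml2::xml_attr(n, "id")
    rev <- !identical(xml2::xml_attr(n, "reversible"), "false")
    lb_ref <- xml2::xml_attr(n, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(n, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(par_val)) par_val[[lb_ref]]
          else if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(par_val)) par_val[[ub_ref]]
          else 1000
    coefs <- numeric(0)
    for (ref in xml2::xml_find_all(n, "./s:listOfReactants/s:speciesReference", ns)) {
      sid <- xml2::xml_attr(ref, "species")
      k <- as.numeric(xml2::xml_attr(ref, "stoichiometry") %||% "1")
      coefs[sid] <- (coefs[sid] %||% 0) - k
    }
    for (ref in xml2::xml_find_all(n, "./s:listOfProducts/s:speciesReference", ns)) {
      sid <- xml2::xml_attr(ref, "species")
      k <- as.numeric(xml2::xml_attr(ref, "stoichiometry") %||% "1")
      coefs[sid] <- (coefs[sid] %||% 0) + k
    }
    is_ex <- length(coefs) == 1L && coefs[[1]] == -1 &&
      mets$compartment[match(names(coefs), mets$id)] == "extracellular"
    rxn_rows[[rid]] <- data.frame(id = rid, lb = lb, ub = ub,
                                  isExchange = is_ex,
                                  isBiomass = rid %in% objective_rxns)
    stoich[[rid]] <- coefs
  }
  rxns <- do.call(rbind, rxn_rows)
  if (sum(rxns$isBiomass) == 0) {
    # fall back: a reaction named like a biomass function
    guess <- grepl("biomass", rxns$id, ignore.case = TRUE)
    if (sum(guess) == 1) rxns$isBiomass <- guess
  }
  stoichiometricModel(model_id, mets, rxns, stoich)
}
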