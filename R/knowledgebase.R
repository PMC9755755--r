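#' Load a pathway knowledgebase from JSON
#'
#' Reads a knowledgebase document describing physical entities (proteins,
#' chemicals, complexes, entity sets), biochemical reactions over those
#' entities, and a pathway hierarchy grouping the reactions. The schema is
#' documented in \code{docs/kb_schema.md} at the repository root.
#'
#' All cross-references are validated on load: every id referenced by a
#' complex, set, reaction or pathway must exist, complex/set composition must
#' be acyclic, and the pathway hierarchy must be a forest.
#'
#' @param path Path to a knowledgebase JSON file.
#' @return An object of class \code{knowledgebase}: a list with named lists
#'   \code{entities}, \code{reactions} and \code{pathways}, each keyed by id.
#' @export
load_kb <- function(path) {
  if (!file.exists(path)) {
    stop("knowledgebase file not found: ", path)
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  kb_from_lists(
    entities = doc$entities %||% list(),
    reactions = doc$reactions %||% list(),
    pathways = doc$pathways %||% list()
  )
}

#' Build a knowledgebase from in-memory record lists
#'
#' Same validation as [load_kb()], but takes the three record lists directly.
#' Used by the synthetic-data generator and by tests.
#'
#' @param entities,reactions,pathways Lists of records (see
#'   \code{docs/kb_schema.md}).
#' @return A validated \code{knowledgebase} object.
#' @export
kb_from_lists <- function(entities = list(), reactions = list(),
                          pathways = list()) {
  ent <- lapply(entities, function(e) {
    list(
      id = as.character(e$id),
      kind = as.character(e$kind),
      accession = as.character(e$accession %||% ""),
      name = as.character(e$name %||% e$id),
      components = as.character(unlist(e$components %||% character()))
    )
  })
  names(ent) <- vapply(ent, `[[`, "", "id")
  rxn <- lapply(reactions, function(r) {
    list(
      id = as.character(r$id),
      name = as.character(r$name %||% r$id),
      inputs = as.character(unlist(r$inputs %||% character())),
      outputs = as.character(unlist(r$outputs %||% character())),
      catalysts = as.character(unlist(r$catalysts %||% character())),
      regulators = as.character(unlist(r$regulators %||% character()))
    )
  })
  names(rxn) <- vapply(rxn, `[[`, "", "id")
  pwy <- lapply(pathways, function(p) {
    list(
      id = as.character(p$id),
      name = as.character(p$name %||% p$id),
      reaction_ids = as.character(unlist(p$reaction_ids %||% character())),
      child_pathway_ids = as.character(unlist(p$child_pathway_ids %||%
        character())),
      parent_pathway_id = as.character(p$parent_pathway_id %||% "")
    )
  })
  names(pwy) <- vapply(pwy, `[[`, "", "id")
  kb <- structure(list(entities = ent, reactions = rxn, pathways = pwy),
    class = "knowledgebase"
  )
  kb_validate(kb)
  kb
}

`%||%` <- function(a, b) if (is.null(a)) b else a

kb_validate <- function(kb) {
  ent_ids <- names(kb$entities)
  if (anyDuplicated(ent_ids)) {
    stop("duplicate entity id: ", ent_ids[duplicated(ent_ids)][1])
  }
  kinds <- vapply(kb$entities, `[[`, "", "kind")
  bad <- kinds[!kinds %in% c("protein", "chemical", "complex", "entity_set")]
  if (length(bad)) stop("unknown entity kind: ", bad[1])
  for (e in kb$entities) {
    if (e$kind %in% c("protein", "chemical") && length(e$components)) {
      stop("entity ", e$id, " of kind ", e$kind, " must have no components")
    }
    if (e$kind %in% c("complex", "entity_set") && !length(e$components)) {
      stop("entity ", e$id, " of kind ", e$kind, " must have components")
    }
    miss <- setdiff(e$components, ent_ids)
    if (length(miss)) {
      stop("entity ", e$id, " references missing id ", miss[1])
    }
  }
  kb_check_acyclic_entities(kb)
  rxn_ids <- names(kb$reactions)
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction id: ", rxn_ids[duplicated(rxn_ids)][1])
  }
  for (r in kb$reactions) {
    refs <- c(r$inputs, r$outputs, r$catalysts, r$regulators)
    miss <- setdiff(refs, ent_ids)
    if (length(miss)) {
      stop("reaction ", r$id, " references missing id ", miss[1])
    }
  }
  pwy_ids <- names(kb$pathways)
  if (anyDuplicated(pwy_ids)) {
    stop("duplicate pathway id: ", pwy_ids[duplicated(pwy_ids)][1])
  }
  for (p in kb$pathways) {
    miss <- setdiff(p$reaction_ids, rxn_ids)
    if (length(miss)) {
      stop("pathway ", p$id, " references missing reaction ", miss[1])
    }
    miss <- setdiff(p$child_pathway_ids, pwy_ids)
    if (length(miss)) {
      stop("pathway ", p$id, " references missing pathway ", miss[1])
    }
    if (nzchar(p$parent_pathway_id) &&
      !p$parent_pathway_id %in% pwy_ids) {
      stop(
        "pathway ", p$id, " references missing pathway ",
        p$parent_pathway_id
      )
    }
    if (nzchar(p$parent_pathway_id) &&
      !p$id %in% kb$pathways[[p$parent_pathway_id]]$child_pathway_ids) {
      stop(
        "pathway ", p$id, " names parent ", p$parent_pathway_id,
        " which does not list it as a child"
      )
    }
  }
  kb_check_forest(kb)
  invisible(kb)
}

# Depth-first cycle check over complex / entity-set composition.
kb_check_acyclic_entities <- function(kb) {
  state <- new.env(parent = emptyenv()) # 1 = on stack, 2 = done
  visit <- function(id) {
    s <- state[[id]] %||% 0L
    if (s == 1L) stop("cyclic entity composition involving ", id)
    if (s == 2L) {
      return(invisible())
    }
    state[[id]] <- 1L
    for (cid in kb$entities[[id]]$components) visit(cid)
    state[[id]] <- 2L
    invisible()
  }
  for (id in names(kb$entities)) visit(id)
  invisible()
}

kb_check_forest <- function(kb) {
  for (start in names(kb$pathways)) {
    seen <- character()
    id <- start
    while (nzchar(id)) {
      if (id %in% seen) stop("cyclic pathway hierarchy involving ", id)
      seen <- c(seen, id)
      id <- kb$pathways[[id]]$parent_pathway_id
    }
  }
  invisible()
}

#' @export
print.knowledgebase <- function(x, ...) {
  n_top <- sum(!vapply(x$pathways, function(p) nzchar(p$parent_pathway_id),
    logical(1)
  ))
  cat(
    "<knowledgebase>", length(x$entities), "entities,",
    length(x$reactions), "reactions,",
    length(x$pathways), "pathways (", n_top, "top-level )\n"
  )
  invisible(x)
}

# Accessioned leaves (proteins/chemicals) under an entity, recursively
# flattening complexes and entity sets. Each leaf reported once.
kb_leaves <- function(kb, id, memo = NULL) {
  e <- kb$entities[[id]]
  if (e$kind %in% c("protein", "chemical")) {
    return(data.frame(
      id = e$id, kind = e$kind, accession = e$accession,
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, lapply(e$components, kb_leaves, kb = kb))
  unique(out)
}
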