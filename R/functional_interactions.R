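#' Default currency-metabolite exclusion list
#'
#' Ubiquitous small molecules excluded (by display name, case-sensitive) when
#' linking reactions into the reaction network, to avoid spurious edges
#' through shared cofactors.
#'
#' @return Character vector of chemical display names.
#' @export
currency_chemicals <- function() {
  c("ATP", "ADP", "Pi", "H2O", "GTP", "GDP", "CO2", "H+")
}

# Cross product of two leaf tables -> pair rows (unordered later).
fi_cross <- function(la, lb) {
  if (!nrow(la) || !nrow(lb)) {
    return(NULL)
  }
  i <- rep(seq_len(nrow(la)), each = nrow(lb))
  j <- rep(seq_len(nrow(lb)), times = nrow(la))
  data.frame(
    acc_a = fi_key(la)[i], kind_a = la$kind[i],
    acc_b = fi_key(lb)[j], kind_b = lb$kind[j],
    stringsAsFactors = FALSE
  )
}

fi_key <- function(leaves) {
  ifelse(nzchar(leaves$accession), leaves$accession, leaves$id)
}

# Pairs of leaves co-occurring inside one complex. Components of a complex
# are physically together, so leaves of distinct components pair with each
# other; members of an entity set are alternatives and never pair among
# themselves, but a complex nested inside a set still contributes its own
# internal pairs.
fi_pairs_within <- function(kb, id) {
  e <- kb$entities[[id]]
  if (e$kind %in% c("protein", "chemical")) {
    return(NULL)
  }
  inner <- do.call(rbind, lapply(e$components, fi_pairs_within, kb = kb))
  if (e$kind == "entity_set") {
    return(inner)
  }
  comp_leaves <- lapply(e$components, kb_leaves, kb = kb)
  cross <- NULL
  n <- length(comp_leaves)
  if (n >= 2) {
    cross <- do.call(rbind, unlist(lapply(seq_len(n - 1), function(i) {
      lapply(seq(i + 1, n), function(j) fi_cross(comp_leaves[[i]], comp_leaves[[j]]))
    }), recursive = FALSE))
  }
  rbind(inner, cross)
}

fi_leaves_of_all <- function(kb, ids) {
  if (!length(ids)) {
    return(data.frame(
      id = character(), kind = character(),
      accession = character(), stringsAsFactors = FALSE
    ))
  }
  unique(do.call(rbind, lapply(unique(ids), kb_leaves, kb = kb)))
}

#' Extract functional interactions from knowledgebase reactions
#'
#' A functional interaction (FI) is an unordered protein--protein or
#' protein--chemical pair inferred from a curated reaction. Per reaction,
#' after recursively flattening complexes and entity sets to accessioned
#' leaves, three rules fire:
#' \enumerate{
#'   \item every pair of distinct leaves co-occurring in one complex among
#'     the reaction's inputs or outputs;
#'   \item every (catalyst leaf, input leaf) pair;
#'   \item every (regulator leaf, catalyst-or-output leaf) pair.
#' }
#' Members of one entity set are alternatives and never pair among
#' themselves. Chemical--chemical pairs and self pairs are discarded. Pairs
#' are stored canonically (lexicographic) and deduplicated across reactions,
#' each FI carrying all reactions that generated it.
#'
#' @param kb A \code{knowledgebase}.
#' @return A data.frame with columns \code{fi_id}, \code{a}, \code{b},
#'   \code{fi_kind} (\code{protein_protein} or \code{protein_chemical}) and a
#'   list-column \code{source_reaction_ids}.
#' @export
extract_functional_interactions <- function(kb) {
  per_rxn <- lapply(kb$reactions, function(r) {
    p <- fi_reaction_pairs(kb, r)
    if (is.null(p) || !nrow(p)) {
      return(NULL)
    }
    p$reaction_id <- r$id
    p
  })
  all <- do.call(rbind, per_rxn)
  if (is.null(all) || !nrow(all)) {
    return(fi_empty())
  }
  # canonical order, drop self and chemical-chemical pairs
  swap <- all$acc_a > all$acc_b
  tmp_a <- all$acc_a
  tmp_ka <- all$kind_a
  all$acc_a[swap] <- all$acc_b[swap]
  all$kind_a[swap] <- all$kind_b[swap]
  all$acc_b[swap] <- tmp_a[swap]
  all$kind_b[swap] <- tmp_ka[swap]
  keep <- all$acc_a != all$acc_b &
    !(all$kind_a == "chemical" & all$kind_b == "chemical")
  all <- all[keep, , drop = FALSE]
  if (!nrow(all)) {
    return(fi_empty())
  }
  all$fi_id <- paste(all$acc_a, all$acc_b, sep = "|")
  all$fi_kind <- ifelse(all$kind_a == "chemical" | all$kind_b == "chemical",
    "protein_chemical", "protein_protein"
  )
  split_rxn <- split(all$reaction_id, all$fi_id)
  first <- all[!duplicated(all$fi_id), c("fi_id", "acc_a", "acc_b", "fi_kind")]
  names(first) <- c("fi_id", "a", "b", "fi_kind")
  first <- first[order(first$fi_id), , drop = FALSE]
  first$source_reaction_ids <- lapply(
    split_rxn[first$fi_id],
    function(x) sort(unique(x))
  )
  rownames(first) <- NULL
  first
}

fi_reaction_pairs <- function(kb, r) {
  io <- unique(c(r$inputs, r$outputs))
  within <- do.call(rbind, lapply(io, fi_pairs_within, kb = kb))
  cat_leaves <- fi_leaves_of_all(kb, r$catalysts)
  in_leaves <- fi_leaves_of_all(kb, r$inputs)
  reg_leaves <- fi_leaves_of_all(kb, r$regulators)
  cat_out_leaves <- fi_leaves_of_all(kb, c(r$catalysts, r$outputs))
  rbind(
    within,
    fi_cross(cat_leaves, in_leaves),
    fi_cross(reg_leaves, cat_out_leaves)
  )
}

fi_empty <- function() {
  data.frame(
    fi_id = character(), a = character(), b = character(),
    fi_kind = character(), stringsAsFactors = FALSE
  ) -> d
  d$source_reaction_ids <- list()
  d
}

#' Build the reaction network
#'
#' Connects reaction \code{r1} to reaction \code{r2} by a directed edge when
#' an output entity of \code{r1} is an input, catalyst or regulator of
#' \code{r2}. Entity identity is by entity id, so complexes connect as whole
#' entities. Chemicals whose display name is on the exclusion list (currency
#' metabolites such as ATP or H2O) are ignored when checking connections.
#'
#' @param kb A \code{knowledgebase}.
#' @param excluded Character vector of chemical display names to ignore;
#'   defaults to [currency_chemicals()].
#' @return A list of class \code{reaction_network} with \code{nodes}
#'   (reaction ids), \code{edges} (two-column data.frame \code{from},
#'   \code{to}) and \code{excluded_small_molecules}.
#' @export
build_reaction_network <- function(kb, excluded = currency_chemicals()) {
  excluded_ids <- names(Filter(
    function(e) e$kind == "chemical" && e$name %in% excluded,
    kb$entities
  ))
  rids <- names(kb$reactions)
  outs <- lapply(kb$reactions, function(r) setdiff(r$outputs, excluded_ids))
  needs <- lapply(kb$reactions, function(r) {
    setdiff(unique(c(r$inputs, r$catalysts, r$regulators)), excluded_ids)
  })
  from <- character()
  to <- character()
  for (r1 in rids) {
    for (r2 in rids) {
      if (r1 != r2 && length(intersect(outs[[r1]], needs[[r2]]))) {
        from <- c(from, r1)
        to <- c(to, r2)
      }
    }
  }
  structure(
    list(
      nodes = rids,
      edges = data.frame(from = from, to = to, stringsAsFactors = FALSE),
      excluded_small_molecules = excluded
    ),
    class = "reaction_network"
  )
}

#' Map reactions to containing pathways and top-level pathways
#'
#' Each reaction maps to every pathway containing it either directly or via a
#' descendant pathway (i.e. the directly containing pathway and all of its
#' ancestors), and each such pathway is paired with the root of its tree. A
#' reaction in no pathway is absent from the result.
#'
#' @param kb A \code{knowledgebase}.
#' @return A data.frame with columns \code{reaction_id}, \code{pathway_id},
#'   \code{top_level_id}.
#' @export
rollup_pathways <- function(kb) {
  rows <- list()
  ancestors <- function(pid) {
    chain <- character()
    while (nzchar(pid)) {
      chain <- c(chain, pid)
      pid <- kb$pathways[[pid]]$parent_pathway_id
    }
    chain
  }
  for (p in kb$pathways) {
    if (!length(p$reaction_ids)) next
    chain <- ancestors(p$id)
    root <- chain[length(chain)]
    for (rid in p$reaction_ids) {
      rows[[length(rows) + 1]] <- data.frame(
        reaction_id = rid, pathway_id = chain, top_level_id = root,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(
      reaction_id = character(), pathway_id = character(),
      top_level_id = character(), stringsAsFactors = FALSE
    ))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$reaction_id, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a functional-interaction table as TSV
#'
#' Three columns: the two partners and the semicolon-joined source reactions.
#'
#' @param fis Result of [extract_functional_interactions()].
#' @param path Output file.
#' @export
write_fi_tsv <- function(fis, path) {
  out <- data.frame(
    a = fis$a, b = fis$b,
    reaction_ids = vapply(fis$source_reaction_ids, paste,
      "",
      collapse = ";"
    ),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Export a reaction network as SIF
#'
#' One line per edge: \code{r1 precedes r2}.
#'
#' @param net A \code{reaction_network}.
#' @param path Output file.
#' @export
write_sif <- function(net, path) {
  lines <- if (nrow(net$edges)) {
    paste(net$edges$from, "precedes", net$edges$to, sep = "\t")
  } else {
    character()
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export a reaction network as GraphML
#'
#' Optionally annotates nodes with enrichment results (q-value and
#' significance flag).
#'
#' @param net A \code{reaction_network}.
#' @param path Output file.
#' @param enrichment Optional enrichment result data.frame with
#'   \code{unit_id}, \code{q_value}, \code{significant} for reaction units.
#' @export
write_graphml <- function(net, path, enrichment = NULL) {
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, rbind(
      match(net$edges$from, net$nodes),
      match(net$edges$to, net$nodes)
    ))
  }
  if (!is.null(enrichment) && nrow(enrichment)) {
    idx <- match(net$nodes, enrichment$unit_id)
    igraph::V(g)$q_value <- enrichment$q_value[idx]
    igraph::V(g)$significant <- as.integer(enrichment$significant[idx])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
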