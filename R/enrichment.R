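#' Shuffle a cohort's substitutions among equivalent positions
#'
#' The background model repositions each sample's substitutions within their
#' proteins: for every (sample, protein, wild-type residue class) group, the
#' multiset of alternate residues is kept and the variant positions are
#' redrawn uniformly without replacement from the positions of that protein
#' carrying the same wild-type residue. Equivalent positions are therefore
#' positions of the same protein with the same reference amino acid, the
#' weakest constraint under which "the same substitutions" remain well
#' formed. The result is again a valid cohort (reference residues match by
#' construction).
#'
#' @param cohort A mapped \code{cohort}.
#' @param seed Optional integer seed for reproducibility.
#' @return A \code{cohort} with repositioned variants.
#' @export
shuffle_cohort <- function(cohort, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- cohort$variants
  if (!nrow(v)) {
    return(cohort)
  }
  class_pos <- residue_class_positions(cohort$sequences)
  grp <- paste(v$sample_id, v$protein, v$ref_aa, sep = "\r")
  idx_by_grp <- split(seq_len(nrow(v)), grp)
  new_pos <- v$position
  for (ii in idx_by_grp) {
    first <- ii[1]
    elig <- class_pos[[paste(v$protein[first], v$ref_aa[first], sep = "\r")]]
    k <- length(ii)
    if (length(elig) < k) {
      stop(
        "fewer equivalent positions than variants for ",
        v$protein[first], " residue ", v$ref_aa[first]
      )
    }
    new_pos[ii] <- if (length(elig) == 1) elig else sample(elig, k)
  }
  v$position <- new_pos
  out <- cohort
  out$variants <- v
  out
}

# protein\rresidue -> integer positions of that residue in the sequence
residue_class_positions <- function(sequences) {
  res <- list()
  for (acc in names(sequences)) {
    letters_ <- strsplit(sequences[[acc]], "")[[1]]
    sp <- split(seq_along(letters_), letters_)
    names(sp) <- paste(acc, names(sp), sep = "\r")
    res[names(sp)] <- sp
  }
  res
}

#' Build perturbation incidence tables at all unit levels
#'
#' Converts perturbation events into binary unit-by-sample incidence at the
#' interface level and, given the FI mappings, at the reaction and pathway
#' levels. A sample scores 1 for a unit when it carries at least one
#' interface-perturbing mutation mapped to the unit, however many
#' interfaces/FIs are hit.
#'
#' @param events Output of [call_perturbations()].
#' @param samples Character vector of all cohort sample ids (defines N).
#' @param records Filtered interface records (defines the interface
#'   universe).
#' @param fi_map Output of [match_fis_to_interfaces()]; may be NULL to get
#'   only the interface level.
#' @param fis FI table (for reaction membership and gene annotation).
#' @param rollup Output of [rollup_pathways()] (for the pathway level).
#' @return Named list of \code{perturbation_table} objects (levels
#'   \code{interface}, and where mappings permit \code{reaction},
#'   \code{pathway}), each with an \code{incidence} 0/1 matrix (units x
#'   samples) and \code{unit_meta} (genes, n_interfaces).
#' @export
perturbation_tables <- function(events, samples, records, fi_map = NULL,
                                fis = NULL, rollup = NULL) {
  out <- list(interface = incidence_table(
    events$interface_id, events$sample_id, records$interface_id, samples,
    "interface",
    unit_interfaces = stats::setNames(
      as.list(records$interface_id),
      records$interface_id
    ),
    records = records
  ))
  if (is.null(fi_map) || is.null(fis)) {
    return(out)
  }
  unit_fis_rxn <- reaction_fi_map(fis)
  for (level in c("reaction", "pathway")) {
    unit_fis <- if (level == "reaction") {
      unit_fis_rxn
    } else {
      pathway_fi_map(unit_fis_rxn, rollup)
    }
    if (!nrow(unit_fis)) next
    tab <- aggregate_to_units(events, samples, fi_map, unit_fis, level,
      records = records
    )
    if (!is.null(tab)) out[[level]] <- tab
  }
  out
}

#' Aggregate perturbation events to reaction or pathway units
#'
#' \code{incidence[unit, sample] = 1} iff the sample has at least one
#' perturbation event at any interface matched to any FI of the unit; a
#' sample counts once however many interfaces or FIs it hits.
#'
#' @param events Output of [call_perturbations()].
#' @param samples All cohort sample ids.
#' @param fi_map FI-to-interface matches from [match_fis_to_interfaces()].
#' @param unit_fis Unit-to-FI membership ([reaction_fi_map()] or
#'   [pathway_fi_map()]).
#' @param level \code{"reaction"} or \code{"pathway"}.
#' @param records Interface records (gene annotation).
#' @return A \code{perturbation_table}, or NULL when no unit maps to any
#'   interface.
#' @export
aggregate_to_units <- function(events, samples, fi_map, unit_fis, level,
                               records) {
  stopifnot(level %in% c("reaction", "pathway"))
  uf <- merge(unit_fis, fi_map, by = "fi_id")
  if (!nrow(uf)) {
    return(NULL)
  }
  unit_ifaces <- lapply(
    split(uf$interface_id, uf$unit_id),
    function(x) sort(unique(x))
  )
  ev_units <- unit_events(events, unit_ifaces)
  incidence_table(
    ev_units$unit_id, ev_units$sample_id, names(unit_ifaces), samples,
    level,
    unit_interfaces = unit_ifaces, records = records
  )
}

# expand events to (unit, sample) via unit -> interface lists
unit_events <- function(events, unit_ifaces) {
  if (!nrow(events) || !length(unit_ifaces)) {
    return(data.frame(
      unit_id = character(), sample_id = character(),
      stringsAsFactors = FALSE
    ))
  }
  iface_units <- split(
    rep(names(unit_ifaces), lengths(unit_ifaces)),
    unlist(unit_ifaces, use.names = FALSE)
  )
  hits <- iface_units[events$interface_id]
  n <- lengths(hits)
  data.frame(
    unit_id = unlist(hits, use.names = FALSE),
    sample_id = rep(events$sample_id, n),
    stringsAsFactors = FALSE
  )
}

incidence_table <- function(unit_of_event, sample_of_event, units, samples,
                            level, unit_interfaces, records) {
  units <- sort(unique(units))
  inc <- matrix(0L, length(units), length(samples),
    dimnames = list(units, samples)
  )
  keep <- unit_of_event %in% units & sample_of_event %in% samples
  if (any(keep)) {
    inc[cbind(
      match(unit_of_event[keep], units),
      match(sample_of_event[keep], samples)
    )] <- 1L
  }
  genes_by_iface <- stats::setNames(records$protein, records$interface_id)
  meta <- data.frame(
    unit_id = units,
    n_interfaces = vapply(
      unit_interfaces[units],
      function(x) length(unique(x)), 0L
    ),
    member_genes = vapply(unit_interfaces[units], function(x) {
      paste(sort(unique(genes_by_iface[x])), collapse = ";")
    }, ""),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      level = level, incidence = inc, unit_meta = meta,
      unit_interfaces = unit_interfaces[units]
    ),
    class = "perturbation_table"
  )
}

#' @export
print.perturbation_table <- function(x, ...) {
  cat(
    "<perturbation_table>", x$level, ":", nrow(x$incidence), "units x",
    ncol(x$incidence), "samples,", sum(rowSums(x$incidence) > 0),
    "units with c >= 1\n"
  )
  invisible(x)
}

#' Per-unit carrier counts
#'
#' @param table A \code{perturbation_table}.
#' @return Named integer vector: number of unique perturbed samples per unit.
#' @export
unit_counts <- function(table) {
  rowSums(table$incidence)
}

#' Estimate per-unit background perturbation probabilities
#'
#' Runs the within-protein shuffle [shuffle_cohort()] \code{R} times (with
#' replicate seeds \code{seed + 1 .. seed + R}), re-calls perturbation events
#' and unit incidence per replicate, and estimates each unit's probability of
#' being perturbed in a random-background sample with add-one smoothing:
#' \eqn{p_r = (hits + 1) / (R N + 1)}, where hits counts (replicate, sample)
#' pairs with at least one perturbing event at the unit. Hits are capped so
#' that \eqn{p_r \le RN / (RN + 1)}; units never hit get the minimal
#' pseudocount probability \eqn{1 / (RN + 1)}.
#'
#' @param cohort Mapped \code{cohort}.
#' @param records Filtered interface records.
#' @param fi_map,fis,rollup As in [perturbation_tables()].
#' @param R Number of shuffle replicates (at least 1).
#' @param seed Integer seed; replicate seeds are derived as seed + replicate
#'   index.
#' @return Named list per level of data.frames \code{unit_id}, \code{hits},
#'   \code{p_r}, with attributes \code{R}, \code{N}, \code{seed}.
#' @export
estimate_background <- function(cohort, records, fi_map = NULL, fis = NULL,
                                rollup = NULL, R = 100, seed = 1) {
  if (!is.numeric(R) || R < 1) stop("R must be a positive integer")
  R <- as.integer(R)
  N <- length(cohort$samples)
  if (as.double(R) * N + 1 > .Machine$integer.max) {
    stop("R * N too large")
  }
  hits <- NULL
  for (r in seq_len(R)) {
    sh <- shuffle_cohort(cohort, seed = seed + r)
    ev <- call_perturbations(sh, records)
    tabs <- perturbation_tables(ev, cohort$samples, records, fi_map, fis,
      rollup = rollup
    )
    cnt <- lapply(tabs, unit_counts)
    if (is.null(hits)) {
      hits <- cnt
    } else {
      for (lv in names(cnt)) hits[[lv]] <- hits[[lv]] + cnt[[lv]]
    }
  }
  RN <- R * N
  lapply(hits, function(h) {
    p <- pmin((h + 1) / (RN + 1), RN / (RN + 1))
    structure(
      data.frame(
        unit_id = names(h), hits = as.integer(h), p_r = p,
        stringsAsFactors = FALSE, row.names = NULL
      ),
      R = R, N = N, seed = seed
    )
  })
}

#' Upper-tail binomial probability
#'
#' Probability of observing \code{c} or more perturbed samples out of
#' \code{N} under a per-sample background perturbation probability \code{p}:
#' \eqn{\sum_{k=c}^{N} \binom{N}{k} p^k (1-p)^{N-k}}, evaluated via the
#' binomial survival function for numerical stability. Vectorized over
#' \code{c}.
#'
#' @param c Observed count(s) of unique perturbed samples, 0 <= c <= N.
#' @param N Total number of samples.
#' @param p Background probability in (0, 1).
#' @return Upper-tail probability in (0, 1].
#' @export
binomial_tail <- function(c, N, p) {
  if (any(c < 0 | c > N)) stop("c must satisfy 0 <= c <= N")
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  stats::pbinom(c - 1, N, p, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up: sort p-values ascending, take
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j} clipped at 1, and return
#' q-values in the input order.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Vector of q-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) {
    return(numeric())
  }
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Test units for mutation enrichment against the shuffle background
#'
#' For every unit with at least one perturbed sample, computes the upper-tail
#' binomial p-value [binomial_tail()] at the unit's background probability,
#' adjusts across all tested units of the level with [bh_adjust()], and flags
#' significance at adjusted p below \code{alpha}. Units with c = 0 are not
#' tested and do not enter the adjustment family.
#'
#' @param table A \code{perturbation_table}.
#' @param background The matching level's data.frame from
#'   [estimate_background()].
#' @param alpha FDR significance cutoff (strict).
#' @param cancer_type Optional label copied into the result.
#' @return A data.frame sorted by q-value then descending c: \code{unit_id},
#'   \code{unit_level}, \code{cancer_type}, \code{member_genes},
#'   \code{n_interfaces}, \code{c}, \code{N}, \code{p_r}, \code{p_value},
#'   \code{q_value}, \code{significant}.
#' @export
test_enrichment <- function(table, background, alpha = 0.05,
                            cancer_type = "") {
  cc <- unit_counts(table)
  N <- ncol(table$incidence)
  tested <- names(cc)[cc >= 1]
  res <- data.frame(
    unit_id = tested, unit_level = table$level,
    cancer_type = cancer_type, stringsAsFactors = FALSE
  )
  if (!nrow(res)) {
    res$member_genes <- character()
    res$n_interfaces <- integer()
    res$c <- integer()
    res$N <- integer()
    res$p_r <- numeric()
    res$p_value <- numeric()
    res$q_value <- numeric()
    res$significant <- logical()
    return(res)
  }
  mi <- match(tested, table$unit_meta$unit_id)
  res$member_genes <- table$unit_meta$member_genes[mi]
  res$n_interfaces <- table$unit_meta$n_interfaces[mi]
  res$c <- as.integer(cc[tested])
  res$N <- N
  bi <- match(tested, background$unit_id)
  if (anyNA(bi)) {
    stop(
      "missing background estimate for unit ",
      tested[which(is.na(bi))[1]]
    )
  }
  res$p_r <- background$p_r[bi]
  res$p_value <- binomial_tail(res$c, N, res$p_r)
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$q_value < alpha
  res <- res[order(res$q_value, -res$c, res$unit_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# unit -> FI membership tables ------------------------------------------

#' Reaction-to-FI membership
#'
#' @param fis FI table from [extract_functional_interactions()].
#' @return data.frame \code{unit_id} (reaction), \code{fi_id}.
#' @export
reaction_fi_map <- function(fis) {
  n <- lengths(fis$source_reaction_ids)
  out <- data.frame(
    unit_id = unlist(fis$source_reaction_ids, use.names = FALSE),
    fi_id = rep(fis$fi_id, n), stringsAsFactors = FALSE
  )
  unique(out)
}

#' Pathway-to-FI membership via the reaction rollup
#'
#' Every pathway (including top-level ancestors) inherits the FIs of all
#' reactions it contains directly or via descendants.
#'
#' @param reaction_fis Output of [reaction_fi_map()].
#' @param rollup Output of [rollup_pathways()].
#' @return data.frame \code{unit_id} (pathway), \code{fi_id}.
#' @export
pathway_fi_map <- function(reaction_fis, rollup) {
  if (is.null(rollup) || !nrow(rollup) || !nrow(reaction_fis)) {
    return(data.frame(
      unit_id = character(), fi_id = character(),
      stringsAsFactors = FALSE
    ))
  }
  m <- merge(reaction_fis, rollup,
    by.x = "unit_id", by.y = "reaction_id"
  )
  unique(data.frame(
    unit_id = m$pathway_id, fi_id = m$fi_id,
    stringsAsFactors = FALSE
  ))
}
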