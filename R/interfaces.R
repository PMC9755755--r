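#' Load structure-derived interface annotations
#'
#' Reads a TSV of interface records: \code{interface_id}, \code{protein}
#' (accession), \code{partner_id}, \code{partner_kind} (\code{protein},
#' \code{chemical} or \code{nucleic_acid}), \code{positions} (comma-joined
#' 1-based residue indices on the protein), \code{template_identity_pct} and
#' \code{best_match_evalue}. Records whose best structural match has an
#' E-value above \code{max_evalue} are dropped.
#'
#' @param path TSV file.
#' @param max_evalue BLAST E-value threshold for the best template match.
#' @return A data.frame with \code{positions} as a list-column of integer
#'   vectors; the number of E-value drops is in \code{attr(x, "n_evalue_dropped")}.
#' @export
load_interfaces <- function(path, max_evalue = 1e-4) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c(
    "interface_id", "protein", "partner_id", "partner_kind",
    "positions", "template_identity_pct", "best_match_evalue"
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$interface_id)) {
    stop(
      "duplicate interface_id: ",
      df$interface_id[duplicated(df$interface_id)][1]
    )
  }
  pos <- lapply(strsplit(df$positions, ","), function(x) {
    p <- suppressWarnings(as.integer(x))
    if (!length(p) || anyNA(p) || any(p < 1)) {
      stop("malformed positions field: ", paste(x, collapse = ","))
    }
    sort(unique(p))
  })
  df$positions <- pos
  df$template_identity_pct <- as.numeric(df$template_identity_pct)
  df$best_match_evalue <- as.numeric(df$best_match_evalue)
  keep <- df$best_match_evalue <= max_evalue
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_evalue_dropped") <- sum(!keep)
  out
}

#' Filter interface records by template confidence
#'
#' Protein-partner interfaces are kept only at high confidence (template
#' sequence identity at or above \code{ppi_min_identity}); chemical and
#' nucleic-acid partners are kept down to \code{other_min_identity}. Both
#' bounds are inclusive.
#'
#' @param records Output of [load_interfaces()].
#' @param ppi_min_identity Minimum identity (percent) for protein partners.
#' @param other_min_identity Minimum identity for chemical / nucleic-acid
#'   partners.
#' @return Filtered records.
#' @export
confidence_filter <- function(records, ppi_min_identity = 70,
                              other_min_identity = 30) {
  thr <- ifelse(records$partner_kind == "protein",
    ppi_min_identity, other_min_identity
  )
  out <- records[records$template_identity_pct >= thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load chemical fingerprints
#'
#' TSV with columns \code{chemical_id} and \code{bits} (a 0/1 string); all
#' fingerprints must share one length.
#'
#' @param path TSV file.
#' @return Named list of integer 0/1 vectors.
#' @export
load_fingerprints <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  fps <- lapply(df$bits, function(b) {
    v <- as.integer(strsplit(b, "")[[1]])
    if (anyNA(v) || !all(v %in% c(0L, 1L))) stop("malformed fingerprint bits")
    v
  })
  names(fps) <- df$chemical_id
  if (length(unique(lengths(fps))) > 1) {
    stop("fingerprints have differing lengths")
  }
  fps
}

#' Tanimoto similarity of two fingerprints
#'
#' \eqn{|a \cap b| / |a \cup b|} on bit vectors; defined as 0 when both
#' vectors are all-zero.
#'
#' @param a,b Integer 0/1 vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  u <- sum(a | b)
  if (u == 0) {
    return(0)
  }
  sum(a & b) / u
}

#' Match functional interactions to interface records
#'
#' A protein--protein FI matches an interface when the unordered accession
#' pair equals \{record protein, record partner\}. A protein--chemical FI
#' matches when the protein accessions agree and the Tanimoto similarity
#' between the FI chemical's fingerprint and the record ligand's fingerprint
#' is strictly greater than \code{tanimoto_min}. Candidate chemical pairs
#' with a missing fingerprint are skipped and reported in
#' \code{attr(x, "skipped_chemicals")}.
#'
#' @param fis Output of [extract_functional_interactions()].
#' @param records Confidence-filtered interface records.
#' @param fingerprints Named list from [load_fingerprints()].
#' @param tanimoto_min Strict lower bound on chemical similarity.
#' @return A data.frame \code{fi_id}, \code{interface_id} (one row per
#'   match; FIs with no match are absent).
#' @export
match_fis_to_interfaces <- function(fis, records, fingerprints = list(),
                                    tanimoto_min = 0.5) {
  skipped <- character()
  rows <- vector("list", nrow(fis))
  for (i in seq_len(nrow(fis))) {
    a <- fis$a[i]
    b <- fis$b[i]
    if (fis$fi_kind[i] == "protein_protein") {
      hit <- (records$partner_kind == "protein") &
        ((records$protein == a & records$partner_id == b) |
          (records$protein == b & records$partner_id == a))
    } else {
      # the protein side is whichever of a/b matches the record protein;
      # the other member is the FI chemical
      cand <- records$partner_kind == "chemical" &
        (records$protein == a | records$protein == b)
      hit <- rep(FALSE, nrow(records))
      for (j in which(cand)) {
        chem_id <- if (records$protein[j] == a) b else a
        fp_fi <- fingerprints[[chem_id]]
        fp_rec <- fingerprints[[records$partner_id[j]]]
        if (is.null(fp_fi) || is.null(fp_rec)) {
          skipped <- c(skipped, chem_id, records$partner_id[j])
          next
        }
        hit[j] <- tanimoto(fp_fi, fp_rec) > tanimoto_min
      }
    }
    if (any(hit)) {
      rows[[i]] <- data.frame(
        fi_id = fis$fi_id[i],
        interface_id = records$interface_id[hit],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      fi_id = character(), interface_id = character(),
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  skipped <- sort(unique(skipped[!skipped %in% names(fingerprints)]))
  if (length(skipped)) {
    warning(
      "missing fingerprint(s), pair(s) skipped: ",
      paste(skipped, collapse = ", ")
    )
  }
  attr(out, "skipped_chemicals") <- skipped
  out
}

#' Call interface perturbation events
#'
#' One event per (variant, interface) pair where the variant's protein equals
#' the interface's protein and the variant's position is among the interface
#' contact positions. A variant hitting several (possibly overlapping)
#' interfaces yields one event per interface; downstream counting
#' deduplicates samples per unit.
#'
#' @param cohort A \code{cohort}.
#' @param records Interface records (filtered).
#' @return A data.frame \code{sample_id}, \code{interface_id},
#'   \code{protein}, \code{position}, \code{ref_aa}, \code{alt_aa}.
#' @export
call_perturbations <- function(cohort, records) {
  idx <- interface_position_index(records)
  v <- cohort$variants
  empty <- data.frame(
    sample_id = character(), interface_id = character(),
    protein = character(), position = integer(),
    ref_aa = character(), alt_aa = character(),
    stringsAsFactors = FALSE
  )
  if (!nrow(v) || !length(idx$by_key)) {
    return(empty)
  }
  key <- paste(v$protein, v$position, sep = "@")
  hits <- idx$by_key[key]
  n_per <- lengths(hits)
  if (!sum(n_per)) {
    return(empty)
  }
  take <- rep(seq_len(nrow(v)), n_per)
  out <- data.frame(
    sample_id = v$sample_id[take],
    interface_id = unlist(hits, use.names = FALSE),
    protein = v$protein[take],
    position = v$position[take],
    ref_aa = v$ref_aa[take],
    alt_aa = v$alt_aa[take],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# (protein@position) -> vector of interface ids covering that residue
interface_position_index <- function(records) {
  if (!nrow(records)) {
    return(list(by_key = list()))
  }
  n_pos <- lengths(records$positions)
  key <- paste(rep(records$protein, n_pos),
    unlist(records$positions),
    sep = "@"
  )
  list(by_key = split(rep(records$interface_id, n_pos), key))
}
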