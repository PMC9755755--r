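#' Parse a MAF-like somatic mutation table
#'
#' Reads a tab-separated subset of the TCGA MAF dialect. Lines starting with
#' \code{#} are comments. Mandatory columns: \code{gene_symbol},
#' \code{sample_id}, \code{cancer_type}, \code{variant_classification},
#' \code{transcript_length_aa}, \code{protein_accession},
#' \code{protein_change}. Only rows whose classification is in
#' \code{classes} are retained (missense substitutions by default, since
#' interface perturbation is defined positionally for substitutions).
#'
#' Rows with a malformed \code{protein_change} (expected
#' \code{"<ref><pos><alt>"}, single-letter amino acids, 1-based position) are
#' skipped with a warning; the skip count is available as
#' \code{attr(x, "n_malformed")}.
#'
#' @param path Path to the TSV file.
#' @param classes Variant classifications treated as non-synonymous
#'   substitutions.
#' @return A data.frame of records with parsed \code{ref_aa},
#'   \code{position}, \code{alt_aa} columns.
#' @export
parse_maf <- function(path, classes = "Missense_Mutation") {
  df <- utils::read.delim(path,
    comment.char = "#", stringsAsFactors = FALSE,
    colClasses = "character"
  )
  required <- c(
    "gene_symbol", "sample_id", "cancer_type",
    "variant_classification", "transcript_length_aa",
    "protein_accession", "protein_change"
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[df$variant_classification %in% classes, , drop = FALSE]
  m <- regmatches(
    df$protein_change,
    regexec("^([A-Z*])([0-9]+)([A-Z*])$", df$protein_change)
  )
  ok <- lengths(m) == 4
  n_malformed <- sum(!ok)
  if (n_malformed) {
    warning(n_malformed, " row(s) with malformed protein_change skipped")
  }
  df <- df[ok, , drop = FALSE]
  m <- m[ok]
  df$ref_aa <- vapply(m, `[`, "", 2)
  df$position <- as.integer(vapply(m, `[`, "", 3))
  df$alt_aa <- vapply(m, `[`, "", 4)
  df$transcript_length_aa <- as.integer(df$transcript_length_aa)
  rownames(df) <- NULL
  attr(df, "n_malformed") <- n_malformed
  df
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file; record names are taken up to the first whitespace
#'   and used as accessions.
#' @return Named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Map MAF records onto protein sequences
#'
#' Applies the two acceptance filters for a variant call to be trusted on a
#' canonical sequence: (i) the stated transcript peptide length must equal
#' the length of the provided sequence, and (ii) the reference amino acid
#' must match the sequence letter at the stated (1-based) position. Records
#' whose accession is absent from \code{sequences} are dropped. Duplicates of
#' the same (protein, position, ref, alt, sample) collapse to one variant.
#'
#' Drops are tallied per reason in \code{x$tallies}.
#'
#' @param records Output of [parse_maf()] (or an equivalent data.frame).
#' @param sequences Named character vector of protein sequences keyed by
#'   accession.
#' @param cancer_type Optional label; defaults to the records' single cancer
#'   type.
#' @return An object of class \code{cohort}: list with \code{variants} (one
#'   row per retained unique variant), \code{samples} (all sample ids seen in
#'   the input, the cohort size N), \code{cancer_type}, \code{sequences} and
#'   \code{tallies}.
#' @export
map_to_protein <- function(records, sequences, cancer_type = NULL) {
  if (is.null(cancer_type)) {
    ct <- unique(records$cancer_type)
    cancer_type <- if (length(ct) == 1) ct else "mixed"
  }
  samples <- sort(unique(records$sample_id))
  tallies <- c(
    missing_protein = 0L, length_mismatch = 0L,
    ref_mismatch = 0L, synonymous = 0L
  )
  present <- records$protein_accession %in% names(sequences)
  tallies["missing_protein"] <- sum(!present)
  records <- records[present, , drop = FALSE]
  seq_len_aa <- nchar(sequences)[records$protein_accession]
  len_ok <- records$transcript_length_aa == seq_len_aa
  tallies["length_mismatch"] <- sum(!len_ok)
  records <- records[len_ok, , drop = FALSE]
  at <- substr(
    sequences[records$protein_accession],
    records$position, records$position
  )
  ref_ok <- !is.na(at) & at == records$ref_aa & nzchar(at)
  tallies["ref_mismatch"] <- sum(!ref_ok)
  records <- records[ref_ok, , drop = FALSE]
  syn <- records$ref_aa == records$alt_aa
  tallies["synonymous"] <- sum(syn)
  records <- records[!syn, , drop = FALSE]
  v <- records[, c(
    "protein_accession", "position", "ref_aa", "alt_aa",
    "sample_id", "cancer_type"
  )]
  names(v)[1] <- "protein"
  v <- v[!duplicated(v[, c(
    "protein", "position", "ref_aa", "alt_aa",
    "sample_id"
  )]), , drop = FALSE]
  v <- v[order(v$sample_id, v$protein, v$position, v$alt_aa), , drop = FALSE]
  rownames(v) <- NULL
  structure(
    list(
      variants = v, samples = samples, cancer_type = cancer_type,
      sequences = sequences, tallies = tallies
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(
    "<cohort>", x$cancer_type, ":", nrow(x$variants), "variants in",
    length(x$samples), "samples over", length(x$sequences), "proteins\n"
  )
  invisible(x)
}

#' Sample-agnostic unique protein variants
#'
#' @param cohort A \code{cohort}.
#' @return A data.frame of unique (protein, position, ref_aa, alt_aa) rows.
#' @export
unique_variants <- function(cohort) {
  u <- unique(cohort$variants[, c("protein", "position", "ref_aa", "alt_aa")])
  rownames(u) <- NULL
  u
}
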