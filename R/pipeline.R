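#' Pipeline run configuration
#'
#' Bundles input paths and thresholds for one cohort (one cancer type per
#' invocation; loop over configurations for multi-cancer studies).
#'
#' @param maf,fasta,interfaces,fingerprints,kb Input file paths.
#' @param clinical Optional clinical TSV path (enables the survival screen).
#' @param cancer_type Cohort label.
#' @param evalue Maximum template E-value for interface records.
#' @param ppi_identity,chem_identity Inclusive identity thresholds (percent)
#'   for protein and chemical/nucleic-acid partners.
#' @param tanimoto Strict lower bound for chemical fingerprint matching.
#' @param fdr FDR significance cutoff.
#' @param background_R Number of shuffle replicates for the background model.
#' @param seed Integer seed for the background model.
#' @param survival_mode \code{"significant"} (screen enrichment-significant
#'   units) or \code{"all"} (every tested unit).
#' @param out_dir Output directory for the result bundle.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(maf, fasta, interfaces, fingerprints, kb,
                       clinical = NULL, cancer_type = "cohort",
                       evalue = 1e-4, ppi_identity = 70, chem_identity = 30,
                       tanimoto = 0.5, fdr = 0.05,
                       background_R = 100, seed = 1,
                       survival_mode = "significant",
                       out_dir = "edgetic_run") {
  cfg <- as.list(environment())
  stopifnot(
    evalue > 0, ppi_identity >= 0, ppi_identity <= 100,
    chem_identity >= 0, chem_identity <= 100,
    tanimoto >= 0, tanimoto <= 1, fdr > 0, fdr <= 1,
    background_R >= 1, seed == as.integer(seed),
    survival_mode %in% c("significant", "all")
  )
  structure(cfg, class = "run_config")
}

#' Run the multi-scale perturbation analysis end to end
#'
#' Loads the knowledgebase, sequences, mutation table, interface annotations
#' and fingerprints; extracts functional interactions and the reaction
#' network; maps variants to proteins and calls interface perturbation
#' events; estimates the shuffle background; tests interfaces, reactions and
#' pathways for enrichment; optionally screens units against overall
#' survival; and writes a result bundle:
#' \code{enrichment_<level>.tsv}, \code{survival_<level>.tsv},
#' \code{fi.tsv}, \code{fi_interface_map.tsv}, \code{rollup.tsv},
#' \code{reaction_network.sif}, \code{reaction_network.graphml},
#' \code{drop_tally.tsv} and \code{manifest.json}.
#'
#' Outputs are deterministic given the inputs and configuration.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all intermediate and final objects.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[edgetic] ", ...)

  log_stage("loading knowledgebase: ", cfg$kb)
  kb <- load_kb(cfg$kb)
  fis <- extract_functional_interactions(kb)
  net <- build_reaction_network(kb)
  roll <- rollup_pathways(kb)
  log_stage(
    length(kb$reactions), " reactions, ", nrow(fis), " FIs, ",
    nrow(net$edges), " reaction-network edges"
  )

  sequences <- read_protein_fasta(cfg$fasta)
  records <- parse_maf(cfg$maf)
  cohort <- map_to_protein(records, sequences, cancer_type = cfg$cancer_type)
  log_stage(
    nrow(records), " missense rows -> ", nrow(cohort$variants),
    " mapped variants in ", length(cohort$samples), " samples (drops: ",
    paste(names(cohort$tallies), cohort$tallies,
      sep = "=",
      collapse = ", "
    ), ")"
  )

  ifc <- load_interfaces(cfg$interfaces, max_evalue = cfg$evalue)
  n_evalue <- attr(ifc, "n_evalue_dropped")
  ifc <- confidence_filter(ifc,
    ppi_min_identity = cfg$ppi_identity,
    other_min_identity = cfg$chem_identity
  )
  fps <- if (!is.null(cfg$fingerprints)) {
    load_fingerprints(cfg$fingerprints)
  } else {
    list()
  }
  fi_map <- match_fis_to_interfaces(fis, ifc,
    fingerprints = fps,
    tanimoto_min = cfg$tanimoto
  )
  log_stage(
    nrow(ifc), " confident interfaces; ", nrow(fi_map),
    " FI-interface matches"
  )

  events <- call_perturbations(cohort, ifc)
  tables <- perturbation_tables(events, cohort$samples, ifc, fi_map, fis,
    rollup = roll
  )
  log_stage(
    nrow(events), " perturbation events; ",
    length(unique(events$sample_id)), " samples with >= 1 event"
  )

  bg <- estimate_background(cohort, ifc, fi_map, fis,
    rollup = roll,
    R = cfg$background_R, seed = cfg$seed
  )
  enrichment <- list()
  for (lv in names(tables)) {
    enrichment[[lv]] <- test_enrichment(tables[[lv]], bg[[lv]],
      alpha = cfg$fdr, cancer_type = cfg$cancer_type
    )
    log_stage(
      lv, " level: ", nrow(enrichment[[lv]]), " tested, ",
      sum(enrichment[[lv]]$significant), " significant (q < ", cfg$fdr, ")"
    )
  }

  surv <- NULL
  surv_results <- list()
  if (!is.null(cfg$clinical)) {
    surv <- derive_survival(read_clinical(cfg$clinical))
    for (lv in names(tables)) {
      surv_results[[lv]] <- run_survival_screen(tables[[lv]], surv,
        enrichment = enrichment[[lv]], mode = cfg$survival_mode,
        alpha = cfg$fdr, cancer_type = cfg$cancer_type
      )
    }
  }

  # ---- write the bundle ----
  paths <- character()
  wt <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    write_tsv(df, p)
    paths[name] <<- p
  }
  for (lv in names(enrichment)) {
    wt(format_numeric(enrichment[[lv]]), paste0("enrichment_", lv, ".tsv"))
  }
  for (lv in names(surv_results)) {
    wt(format_numeric(surv_results[[lv]]), paste0("survival_", lv, ".tsv"))
  }
  p <- file.path(cfg$out_dir, "fi.tsv")
  write_fi_tsv(fis, p)
  paths["fi.tsv"] <- p
  wt(fi_map, "fi_interface_map.tsv")
  wt(roll, "rollup.tsv")
  p <- file.path(cfg$out_dir, "reaction_network.sif")
  write_sif(net, p)
  paths["reaction_network.sif"] <- p
  p <- file.path(cfg$out_dir, "reaction_network.graphml")
  write_graphml(net, p, enrichment = enrichment$reaction)
  paths["reaction_network.graphml"] <- p
  drops <- data.frame(
    stage = c(rep("map_to_protein", length(cohort$tallies)), "load_interfaces"),
    reason = c(names(cohort$tallies), "evalue_above_threshold"),
    n = c(unname(cohort$tallies), n_evalue),
    stringsAsFactors = FALSE
  )
  wt(drops, "drop_tally.tsv")

  manifest <- list(
    tool = "edgetic", version = as.character(utils::packageVersion("edgetic")),
    cancer_type = cfg$cancer_type,
    config = unclass(cfg),
    input_md5 = as.list(tools::md5sum(stats::na.omit(unlist(
      cfg[c("maf", "fasta", "interfaces", "fingerprints", "kb", "clinical")]
    )))),
    counts = list(
      maf_rows = nrow(records), variants = nrow(cohort$variants),
      samples = length(cohort$samples), interfaces = nrow(ifc),
      fis = nrow(fis), fi_matches = nrow(fi_map), events = nrow(events),
      tested = lapply(enrichment, nrow),
      significant = lapply(enrichment, function(e) sum(e$significant))
    ),
    output_md5 = as.list(tools::md5sum(unname(paths)))
  )
  names(manifest$output_md5) <- names(paths)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )

  invisible(list(
    config = cfg, kb = kb, fis = fis, network = net, rollup = roll,
    cohort = cohort, interfaces = ifc, fi_map = fi_map, events = events,
    tables = tables, background = bg, enrichment = enrichment,
    survival = surv_results, bundle = cfg$out_dir
  ))
}

# round-trip-stable numeric formatting for result TSVs
format_numeric <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]]) && !is.integer(df[[col]])) {
      df[[col]] <- formatC(df[[col]], format = "g", digits = 10)
    }
  }
  df
}

#' Summarize a result bundle by top-level pathway
#'
#' Reads a bundle written by [run_pipeline()], verifies the recorded output
#' checksums, and tallies, for every top-level pathway with at least one
#' significant unit: the number of unique perturbed samples (the top-level
#' pathway's own carrier count), the number of FI interfaces involved, and
#' the number of significant reactions rolling up to it. Writes
#' \code{report_top_level_pathways.tsv} into the bundle.
#'
#' @param bundle_dir Directory written by [run_pipeline()].
#' @return The summary data.frame (may have zero rows).
#' @export
report_bundle <- function(bundle_dir) {
  manifest_path <- file.path(bundle_dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("missing manifest.json in ", bundle_dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  for (name in names(manifest$output_md5)) {
    p <- file.path(bundle_dir, name)
    if (!file.exists(p)) stop("missing bundle file: ", name)
    if (unname(tools::md5sum(p)) != manifest$output_md5[[name]]) {
      stop("bundle file changed since the run: ", name)
    }
  }
  read_bundle_tsv <- function(name) {
    utils::read.delim(file.path(bundle_dir, name), stringsAsFactors = FALSE)
  }
  pw <- read_bundle_tsv("enrichment_pathway.tsv")
  rx <- read_bundle_tsv("enrichment_reaction.tsv")
  roll <- read_bundle_tsv("rollup.tsv")
  top_ids <- unique(roll$top_level_id)
  sig_rx <- rx$unit_id[rx$significant == "TRUE" | rx$significant == TRUE]
  rows <- list()
  for (tid in sort(top_ids)) {
    own <- pw[pw$unit_id == tid, , drop = FALSE]
    rx_in <- unique(roll$reaction_id[roll$pathway_id == tid])
    n_sig_rx <- length(intersect(sig_rx, rx_in))
    own_sig <- nrow(own) && isTRUE(own$significant == "TRUE" |
      own$significant == TRUE)
    if (!n_sig_rx && !own_sig) next
    rows[[length(rows) + 1]] <- data.frame(
      top_level_id = tid,
      unique_samples = if (nrow(own)) own$c else 0L,
      n_fi_interfaces = if (nrow(own)) own$n_interfaces else 0L,
      n_significant_reactions = n_sig_rx,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      top_level_id = character(), unique_samples = integer(),
      n_fi_interfaces = integer(), n_significant_reactions = integer(),
      stringsAsFactors = FALSE
    )
  }
  write_tsv(out, file.path(bundle_dir, "report_top_level_pathways.tsv"))
  out
}
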