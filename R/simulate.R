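#' Simulation configuration
#'
#' Defines the synthetic study conditions: a compact signaling-module-scale
#' system of proteins with curated reactions and a pathway hierarchy,
#' structure-derived interfaces over the extracted functional interactions, a
#' cohort of tumor samples carrying missense mutations placed uniformly over
#' protein positions (the same law as the shuffle null), optional planted
#' interface hotspots, and clinical follow-up with exponential
#' proportional-hazards survival.
#'
#' Defaults emulate a focused subproteome: 12 proteins of 100-180 residues
#' organized into two top-level pathway trees with disjoint protein blocks
#' (pathways engage largely distinct gene sets), interface contact footprints
#' of 15-40 residues on most interacting proteins, and 2-6 somatic missense
#' substitutions per sample -- a moderately mutated exome scaled down to the
#' simulated subproteome.
#'
#' @param seed Integer master seed (all stage seeds derive from it).
#' @param n_proteins,n_chemicals,n_reactions,n_pathways,hierarchy_depth
#'   Knowledgebase dimensions.
#' @param protein_length_range Min/max protein length (residues).
#' @param interface_coverage Fraction of extracted FIs receiving an interface
#'   record.
#' @param interface_size_range Min/max interface contact positions.
#' @param ppi_identity_range,chem_identity_range Uniform ranges for the
#'   template sequence identity of protein- and chemical/nucleic-partner
#'   records (some records fall below the confidence thresholds by design so
#'   the filters are exercised).
#' @param n_samples Cohort size.
#' @param mutations_per_sample_range Min/max background missense mutations
#'   per sample.
#' @param hotspots Data.frame with columns \code{interface} (interface id or
#'   integer index into the generated interface table) and \code{prob}
#'   (per-sample hit probability), or NULL.
#' @param survival_effect List \code{list(pathway = id-or-index, hr = true
#'   hazard ratio)}, or NULL for no effect.
#' @param censoring_rate Target fraction of censored samples.
#' @param baseline_hazard Event rate per day for non-carriers.
#' @param cancer_type Cohort label.
#' @param n_bad_length,n_bad_ref Planted filter violations in the mutation
#'   table (for validator tests).
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1,
                       n_proteins = 12, n_chemicals = 4, n_reactions = 15,
                       n_pathways = 6, hierarchy_depth = 2,
                       protein_length_range = c(100, 180),
                       interface_coverage = 0.9,
                       interface_size_range = c(15, 40),
                       ppi_identity_range = c(55, 100),
                       chem_identity_range = c(25, 95),
                       n_samples = 200,
                       mutations_per_sample_range = c(2, 6),
                       hotspots = NULL,
                       survival_effect = NULL,
                       censoring_rate = 0.2,
                       baseline_hazard = 1 / 1000,
                       cancer_type = "SYNTH",
                       n_bad_length = 0, n_bad_ref = 0) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$seed == as.integer(cfg$seed), cfg$seed + 10 < 2^31,
    cfg$n_proteins >= 1, cfg$n_chemicals >= 0, cfg$n_reactions >= 0,
    cfg$n_pathways >= 1, cfg$hierarchy_depth >= 1,
    cfg$hierarchy_depth <= cfg$n_pathways,
    diff(protein_length_range) >= 0, protein_length_range[1] >= 20,
    diff(interface_size_range) >= 0, interface_size_range[1] >= 1,
    interface_coverage >= 0, interface_coverage <= 1,
    n_samples >= 1, diff(mutations_per_sample_range) >= 0,
    mutations_per_sample_range[1] >= 0,
    censoring_rate >= 0, censoring_rate <= 1, baseline_hazard > 0
  )
  if (!is.null(hotspots)) {
    stopifnot(
      is.data.frame(hotspots),
      all(c("interface", "prob") %in% names(hotspots)),
      all(hotspots$prob >= 0 & hotspots$prob <= 1)
    )
  }
  structure(cfg, class = "sim_config")
}

aa_alphabet <- function() {
  c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q",
    "R", "S", "T", "V", "W", "Y"
  )
}

#' Generate protein sequences
#'
#' @param cfg A \code{sim_config}.
#' @param seed Stage seed (defaults to \code{cfg$seed + 1}).
#' @return Named character vector of sequences keyed by accession.
#' @export
generate_sequences <- function(cfg, seed = cfg$seed + 1) {
  set.seed(seed)
  acc <- sprintf("P%05d", 10000 + seq_len(cfg$n_proteins))
  lens <- sample(
    seq(cfg$protein_length_range[1], cfg$protein_length_range[2]),
    cfg$n_proteins,
    replace = TRUE
  )
  seqs <- vapply(lens, function(L) {
    paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
  }, "")
  names(seqs) <- acc
  seqs
}

#' Generate a synthetic knowledgebase
#'
#' Builds a pathway forest of the requested depth whose roots partition the
#' proteins into disjoint blocks, then wires reactions (assigned round-robin
#' to leaf pathways) over their block's proteins using three recurring
#' templates: complex-forming binding, ATP-driven catalysis producing a
#' protein-chemical complex, and regulated catalysis. Every fourth binding
#' output embeds an entity set so set flattening is exercised; consecutive
#' reactions within a block are chained (output of one is input of the next)
#' so the reaction network is connected within blocks, and currency
#' metabolites (ATP, ADP, ...) appear as inputs/outputs so the exclusion
#' logic matters.
#'
#' @param cfg A \code{sim_config}.
#' @param accessions Protein accessions (names of [generate_sequences()]).
#' @param seed Stage seed.
#' @return A validated \code{knowledgebase}.
#' @export
generate_kb <- function(cfg, accessions, seed = cfg$seed + 2) {
  set.seed(seed)
  entities <- list()
  add_entity <- function(id, kind, accession = "", name = id,
                         components = character()) {
    entities[[length(entities) + 1]] <<- list(
      id = id, kind = kind, accession = accession, name = name,
      components = components
    )
    id
  }
  prot_ids <- vapply(seq_along(accessions), function(i) {
    add_entity(paste0("E_", accessions[i]), "protein",
      accession = accessions[i], name = paste0("GENE", i)
    )
  }, "")
  currency <- currency_chemicals()
  cur_ids <- vapply(seq_along(currency), function(i) {
    add_entity(sprintf("E_CUR%02d", i), "chemical",
      accession = sprintf("CHEBI:9%04d", i), name = currency[i]
    )
  }, "")
  names(cur_ids) <- currency
  chem_ids <- if (cfg$n_chemicals > 0) {
    vapply(seq_len(cfg$n_chemicals), function(i) {
      add_entity(sprintf("E_CHEM%02d", i), "chemical",
        accession = sprintf("CHEBI:%05d", 10000 + i),
        name = sprintf("CHEM%02d", i)
      )
    }, "")
  } else {
    character()
  }

  # pathway forest: two roots (one if n_pathways == 1), remaining pathways
  # attached breadth-first up to hierarchy_depth
  n_top <- min(2, cfg$n_pathways)
  pwy <- list()
  depth <- integer()
  for (i in seq_len(cfg$n_pathways)) {
    pid <- sprintf("PW%02d", i)
    if (i <= n_top) {
      parent <- ""
      depth[pid] <- 1L
    } else {
      open <- names(depth)[depth < cfg$hierarchy_depth]
      parent <- open[(i - n_top - 1) %% length(open) + 1]
      depth[pid] <- depth[parent] + 1L
    }
    pwy[[pid]] <- list(
      id = pid, name = paste("Pathway", i),
      reaction_ids = character(), child_pathway_ids = character(),
      parent_pathway_id = parent
    )
  }
  for (pid in names(pwy)) {
    par <- pwy[[pid]]$parent_pathway_id
    if (nzchar(par)) {
      pwy[[par]]$child_pathway_ids <- c(pwy[[par]]$child_pathway_ids, pid)
    }
  }
  roots <- names(pwy)[vapply(pwy, function(p) !nzchar(p$parent_pathway_id), TRUE)]
  leaves <- names(pwy)[vapply(pwy, function(p) {
    !length(p$child_pathway_ids)
  }, TRUE)]
  root_of <- function(pid) {
    while (nzchar(pwy[[pid]]$parent_pathway_id)) {
      pid <- pwy[[pid]]$parent_pathway_id
    }
    pid
  }
  # disjoint protein blocks per root
  block_of_root <- split(prot_ids, rep(seq_along(roots),
    length.out = length(prot_ids)
  ))
  names(block_of_root) <- roots

  reactions <- list()
  last_output_in_block <- list()
  cplx_n <- 0L
  set_n <- 0L
  for (i in seq_len(cfg$n_reactions)) {
    leaf <- leaves[(i - 1) %% length(leaves) + 1]
    root <- root_of(leaf)
    block <- block_of_root[[root]]
    rid <- sprintf("RX%03d", i)
    template <- (i - 1) %% 3
    pick <- function(n) sample(block, min(n, length(block)))
    inputs <- character()
    outputs <- character()
    catalysts <- character()
    regulators <- character()
    if (template == 0) {
      # binding: two proteins (occasionally one slot is an entity set)
      ab <- pick(2)
      slot1 <- ab[1]
      if (i %% 4 == 0 && length(block) >= 3) {
        others <- setdiff(block, ab)
        set_n <- set_n + 1L
        slot1 <- add_entity(sprintf("SET%02d", set_n), "entity_set",
          components = unique(c(ab[1], others[1]))
        )
      }
      cplx_n <- cplx_n + 1L
      cplx <- add_entity(sprintf("CPLX%02d", cplx_n), "complex",
        components = c(slot1, ab[length(ab)])
      )
      inputs <- ab
      outputs <- cplx
    } else if (template == 1) {
      # catalysis: kinase K phosphorylates S consuming ATP, emits ADP and a
      # protein-chemical complex when substrate chemicals exist
      ks <- pick(2)
      catalysts <- ks[1]
      sub <- ks[length(ks)]
      inputs <- c(sub, cur_ids[["ATP"]])
      cplx_n <- cplx_n + 1L
      comp <- c(sub, if (length(chem_ids)) sample(chem_ids, 1))
      if (length(comp) >= 2) {
        outputs <- c(
          add_entity(sprintf("CPLX%02d", cplx_n), "complex",
            components = comp
          ),
          cur_ids[["ADP"]]
        )
      } else {
        outputs <- c(sub, cur_ids[["ADP"]])
      }
    } else {
      # regulated catalysis
      prs <- pick(3)
      regulators <- prs[1]
      catalysts <- prs[min(2, length(prs))]
      inputs <- prs[length(prs)]
      outputs <- prs[length(prs)]
    }
    # chain within the block: previous output feeds this reaction
    prev <- last_output_in_block[[root]]
    if (!is.null(prev)) inputs <- unique(c(inputs, prev))
    last_output_in_block[[root]] <- outputs[1]
    reactions[[rid]] <- list(
      id = rid, name = paste("Reaction", i), inputs = inputs,
      outputs = outputs, catalysts = catalysts, regulators = regulators
    )
    pwy[[leaf]]$reaction_ids <- c(pwy[[leaf]]$reaction_ids, rid)
  }
  kb_from_lists(entities, unname(reactions), unname(pwy))
}

#' Generate interface records and fingerprints for a knowledgebase
#'
#' For each extracted functional interaction, with probability
#' \code{interface_coverage} an interface record is emitted on one partner:
#' protein-protein FIs get a protein-partner record, protein-chemical FIs a
#' ligand record whose fingerprint is a lightly perturbed copy of the
#' chemical's (Tanimoto well above 0.5). Template identities are drawn from
#' the configured ranges, so a fraction of records falls below the confidence
#' thresholds. One decoy ligand with an unrelated fingerprint and one
#' nucleic-acid interface are added to exercise non-matching paths.
#'
#' @param cfg A \code{sim_config}.
#' @param fis FI table from [extract_functional_interactions()].
#' @param sequences Named protein sequences.
#' @param seed Stage seed.
#' @return List with \code{interfaces} (data.frame, positions list-column)
#'   and \code{fingerprints} (named list of 0/1 vectors).
#' @export
generate_interfaces <- function(cfg, fis, sequences, seed = cfg$seed + 3) {
  set.seed(seed)
  nbits <- 64L
  fp_random <- function() as.integer(stats::runif(nbits) < 0.3)
  fp_perturb <- function(fp, flips = 2L) {
    i <- sample(nbits, flips)
    fp[i] <- 1L - fp[i]
    fp
  }
  # every chemical referenced by a protein-chemical FI gets a fingerprint,
  # whether or not its FI draws an interface record
  fingerprints <- list()
  chem_fis <- fis[fis$fi_kind == "protein_chemical", , drop = FALSE]
  for (chem in setdiff(
    unique(c(chem_fis$a, chem_fis$b)),
    names(sequences)
  )) {
    fingerprints[[chem]] <- fp_random()
  }
  rows <- list()
  n_if <- 0L
  for (i in seq_len(nrow(fis))) {
    if (stats::runif(1) > cfg$interface_coverage) next
    a <- fis$a[i]
    b <- fis$b[i]
    if (fis$fi_kind[i] == "protein_protein") {
      protein <- a
      partner <- b
      kind <- "protein"
      ident <- stats::runif(1, cfg$ppi_identity_range[1], cfg$ppi_identity_range[2])
    } else {
      protein <- if (a %in% names(sequences)) a else b
      chem <- setdiff(c(a, b), protein)
      partner <- paste0("LIG_", sub(":", "_", chem))
      fingerprints[[partner]] <- fp_perturb(fingerprints[[chem]])
      kind <- "chemical"
      ident <- stats::runif(1, cfg$chem_identity_range[1], cfg$chem_identity_range[2])
    }
    if (!protein %in% names(sequences)) next
    L <- nchar(sequences[[protein]])
    size <- sample(
      seq(cfg$interface_size_range[1], min(cfg$interface_size_range[2], L)), 1
    )
    n_if <- n_if + 1L
    rows[[n_if]] <- data.frame(
      interface_id = sprintf("IF%04d", n_if),
      protein = protein, partner_id = partner, partner_kind = kind,
      template_identity_pct = round(ident, 1),
      best_match_evalue = signif(10^stats::runif(1, -12, -5), 3),
      stringsAsFactors = FALSE
    )
    rows[[n_if]]$positions <- list(sort(sample(L, size)))
  }
  # one nucleic-acid interface and a decoy ligand fingerprint
  if (length(sequences)) {
    p1 <- names(sequences)[1]
    L <- nchar(sequences[[p1]])
    n_if <- n_if + 1L
    na_row <- data.frame(
      interface_id = sprintf("IF%04d", n_if), protein = p1,
      partner_id = "DNA1", partner_kind = "nucleic_acid",
      template_identity_pct = round(stats::runif(
        1, cfg$chem_identity_range[1],
        cfg$chem_identity_range[2]
      ), 1),
      best_match_evalue = 1e-8, stringsAsFactors = FALSE
    )
    na_row$positions <- list(sort(sample(
      L,
      min(cfg$interface_size_range[1], L)
    )))
    rows[[n_if]] <- na_row
  }
  fingerprints[["LIG_DECOY"]] <- fp_random()
  interfaces <- do.call(rbind, rows)
  if (is.null(interfaces)) {
    interfaces <- data.frame(
      interface_id = character(), protein = character(),
      partner_id = character(), partner_kind = character(),
      template_identity_pct = numeric(), best_match_evalue = numeric(),
      stringsAsFactors = FALSE
    )
    interfaces$positions <- list()
  }
  rownames(interfaces) <- NULL
  list(interfaces = interfaces, fingerprints = fingerprints)
}

resolve_hotspots <- function(cfg, interfaces) {
  if (is.null(cfg$hotspots) || !nrow(cfg$hotspots)) {
    return(NULL)
  }
  hs <- cfg$hotspots
  ids <- vapply(seq_len(nrow(hs)), function(i) {
    x <- hs$interface[i]
    if (is.numeric(x)) {
      if (x < 1 || x > nrow(interfaces)) stop("hotspot interface index out of range")
      interfaces$interface_id[x]
    } else {
      if (!x %in% interfaces$interface_id) {
        stop("unknown hotspot interface id: ", x)
      }
      as.character(x)
    }
  }, "")
  data.frame(interface_id = ids, prob = hs$prob, stringsAsFactors = FALSE)
}

#' Generate a synthetic mutation cohort (MAF-subset table)
#'
#' Background mutations follow the shuffle-null law: per sample, a uniform
#' number of missense substitutions in \code{mutations_per_sample_range},
#' each placed on a uniformly chosen protein at a uniformly chosen position,
#' with the reference residue read off the sequence (every emitted row passes
#' the mapping filters by construction). For each planted hotspot, each
#' sample additionally receives, with the stated probability, one mutation at
#' a uniformly chosen interface position.
#'
#' Planted violations (\code{n_bad_length}, \code{n_bad_ref}) append rows
#' that fail exactly one mapping filter each.
#'
#' @param cfg A \code{sim_config}.
#' @param sequences Named protein sequences.
#' @param interfaces Interface table (needed when hotspots are configured).
#' @param seed Stage seed.
#' @return A MAF-subset data.frame (see [parse_maf()] for columns).
#' @export
generate_cohort <- function(cfg, sequences, interfaces = NULL,
                            seed = cfg$seed + 4) {
  set.seed(seed)
  acc <- names(sequences)
  lens <- nchar(sequences)
  samples <- sprintf("S%04d", seq_len(cfg$n_samples))
  mrange <- cfg$mutations_per_sample_range
  n_mut <- sample(seq(mrange[1], mrange[2]), cfg$n_samples, replace = TRUE)
  total <- sum(n_mut)
  prot <- sample(acc, total, replace = TRUE)
  pos <- vapply(lens[prot], function(L) sample.int(L, 1), 0L)
  rows <- data.frame(
    sample_id = rep(samples, n_mut), protein = prot, position = pos,
    stringsAsFactors = FALSE
  )
  hs <- resolve_hotspots(cfg, interfaces)
  if (!is.null(hs)) {
    for (i in seq_len(nrow(hs))) {
      rec <- interfaces[interfaces$interface_id == hs$interface_id[i], ]
      hit <- stats::runif(cfg$n_samples) < hs$prob[i]
      if (!any(hit)) next
      hp <- rec$positions[[1]]
      rows <- rbind(rows, data.frame(
        sample_id = samples[hit],
        protein = rec$protein,
        position = if (length(hp) == 1) {
          rep(hp, sum(hit))
        } else {
          sample(hp, sum(hit), replace = TRUE)
        },
        stringsAsFactors = FALSE
      ))
    }
  }
  ref <- substr(sequences[rows$protein], rows$position, rows$position)
  alt <- vapply(ref, function(r) sample(setdiff(aa_alphabet(), r), 1), "")
  gene <- paste0("GENE", match(rows$protein, acc))
  maf <- data.frame(
    gene_symbol = gene,
    sample_id = rows$sample_id,
    cancer_type = cfg$cancer_type,
    variant_classification = "Missense_Mutation",
    transcript_length_aa = unname(lens[rows$protein]),
    protein_accession = rows$protein,
    protein_change = paste0(ref, rows$position, alt),
    stringsAsFactors = FALSE
  )
  maf <- plant_violations(maf, cfg, sequences)
  ord <- order(maf$sample_id, maf$protein_accession, maf$protein_change)
  maf <- maf[ord, , drop = FALSE]
  rownames(maf) <- NULL
  maf
}

plant_violations <- function(maf, cfg, sequences) {
  if (cfg$n_bad_length + cfg$n_bad_ref == 0 || !nrow(maf)) {
    return(maf)
  }
  bad <- list()
  acc1 <- names(sequences)[1]
  L1 <- nchar(sequences[[acc1]])
  for (i in seq_len(cfg$n_bad_length)) {
    r <- maf[1, ]
    r$sample_id <- sprintf("SBADL%02d", i)
    r$protein_accession <- acc1
    r$transcript_length_aa <- L1 + 7L
    ref <- substr(sequences[[acc1]], 1, 1)
    r$protein_change <- paste0(ref, 1, setdiff(aa_alphabet(), ref)[1])
    bad[[length(bad) + 1]] <- r
  }
  for (i in seq_len(cfg$n_bad_ref)) {
    r <- maf[1, ]
    r$sample_id <- sprintf("SBADR%02d", i)
    r$protein_accession <- acc1
    r$transcript_length_aa <- L1
    ref <- substr(sequences[[acc1]], 2, 2)
    wrong <- setdiff(aa_alphabet(), ref)[1]
    r$protein_change <- paste0(wrong, 2, setdiff(aa_alphabet(), c(ref, wrong))[1])
    bad[[length(bad) + 1]] <- r
  }
  rbind(maf, do.call(rbind, bad))
}

#' Generate clinical records with a proportional-hazards survival effect
#'
#' Event times are exponential: non-carriers at the baseline hazard, carriers
#' at baseline times the true hazard ratio. Censoring is by an independent
#' exponential clock whose rate is scaled to hit the requested censoring
#' fraction for non-carriers (\code{rate = baseline * c / (1 - c)});
#' \code{censoring_rate = 1} yields an all-censored cohort with follow-up
#' times drawn at the baseline rate, \code{0} an uncensored one. Age is
#' normal (mean 60, sd 10, clipped to 20-90) and gender balanced. Missing
#' values are written as \code{nan} downstream.
#'
#' @param cfg A \code{sim_config}.
#' @param samples Sample ids.
#' @param carriers Sample ids carrying the survival effect (usually the
#'   perturbed-pathway incidence row computed by the real pipeline).
#' @param hr True carrier hazard ratio (1 = no effect).
#' @param seed Stage seed.
#' @return Clinical data.frame (see [read_clinical()] for columns).
#' @export
generate_clinical <- function(cfg, samples, carriers = character(),
                              hr = 1, seed = cfg$seed + 5) {
  set.seed(seed)
  n <- length(samples)
  lam <- cfg$baseline_hazard * ifelse(samples %in% carriers, hr, 1)
  t_event <- stats::rexp(n, lam)
  if (cfg$censoring_rate >= 1) {
    time <- stats::rexp(n, cfg$baseline_hazard)
    event <- rep(FALSE, n)
  } else if (cfg$censoring_rate <= 0) {
    time <- t_event
    event <- rep(TRUE, n)
  } else {
    cr <- cfg$censoring_rate
    t_cens <- stats::rexp(n, cfg$baseline_hazard * cr / (1 - cr))
    event <- t_event <= t_cens
    time <- pmin(t_event, t_cens)
  }
  time <- pmax(1, round(time))
  age <- pmin(90, pmax(20, round(stats::rnorm(n, 60, 10))))
  gender <- sample(c("male", "female"), n, replace = TRUE)
  data.frame(
    sample_id = samples,
    vital_status = ifelse(event, "dead", "alive"),
    gender = gender,
    days_to_death = ifelse(event, time, NA_real_),
    days_to_last_follow_up = ifelse(event, NA_real_, time),
    age_at_diagnosis = age,
    stringsAsFactors = FALSE
  )
}

#' Generate and write a complete synthetic study
#'
#' Runs all generators with stage seeds derived from the master seed, derives
#' survival-effect carriers through the real pipeline mappings (FI
#' extraction, confidence filtering, FI-interface matching, perturbation
#' calling, pathway aggregation), and writes every file the pipeline
#' consumes: \code{kb.json}, \code{proteins.fasta}, \code{interfaces.tsv},
#' \code{fingerprints.tsv}, \code{mutations.maf.tsv}, \code{clinical.tsv},
#' plus \code{manifest.json} recording the configuration and seed. Output is
#' byte-identical across runs with the same configuration.
#'
#' @param cfg A \code{sim_config}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
simulate_study <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sequences <- generate_sequences(cfg)
  kb <- generate_kb(cfg, names(sequences))
  fis <- extract_functional_interactions(kb)
  gi <- generate_interfaces(cfg, fis, sequences)
  interfaces <- gi$interfaces
  # planted hotspot interfaces are emitted at high confidence so they
  # survive the downstream filters
  hs <- resolve_hotspots(cfg, interfaces)
  if (!is.null(hs)) {
    i <- match(hs$interface_id, interfaces$interface_id)
    interfaces$template_identity_pct[i] <-
      pmax(interfaces$template_identity_pct[i], 85)
    interfaces$best_match_evalue[i] <-
      pmin(interfaces$best_match_evalue[i], 1e-8)
  }
  maf <- generate_cohort(cfg, sequences, interfaces)

  carriers <- character()
  effect_pathway <- NULL
  hr <- 1
  if (!is.null(cfg$survival_effect)) {
    eff <- cfg$survival_effect
    pid <- eff$pathway
    if (is.numeric(pid)) pid <- names(kb$pathways)[pid]
    if (is.null(pid) || !pid %in% names(kb$pathways)) {
      stop("unknown survival-effect pathway: ", eff$pathway)
    }
    effect_pathway <- pid
    hr <- eff$hr
    carriers <- pathway_carriers(
      cfg, kb, fis, sequences, interfaces, maf, pid,
      fingerprints = gi$fingerprints
    )
    if (!length(carriers)) {
      warning("survival effect requested but the carrier set is empty")
    }
  }
  samples <- sprintf("S%04d", seq_len(cfg$n_samples))
  clinical <- generate_clinical(cfg, samples, carriers, hr = hr)

  paths <- list(
    kb = file.path(out_dir, "kb.json"),
    fasta = file.path(out_dir, "proteins.fasta"),
    interfaces = file.path(out_dir, "interfaces.tsv"),
    fingerprints = file.path(out_dir, "fingerprints.tsv"),
    maf = file.path(out_dir, "mutations.maf.tsv"),
    clinical = file.path(out_dir, "clinical.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_kb_json(kb, paths$kb)
  writeLines(
    paste0(">", names(sequences), "\n", unname(sequences)),
    paths$fasta
  )
  write_interfaces_tsv(interfaces, paths$interfaces)
  write_fingerprints_tsv(gi$fingerprints, paths$fingerprints)
  write_tsv(maf, paths$maf)
  clin_out <- clinical
  for (col in c("days_to_death", "days_to_last_follow_up")) {
    clin_out[[col]] <- ifelse(is.na(clin_out[[col]]), "nan",
      as.character(clin_out[[col]])
    )
  }
  write_tsv(clin_out, paths$clinical)
  manifest <- list(
    generator = "edgetic::simulate_study",
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("hotspots", "survival_effect"))],
    hotspots = if (is.null(hs)) list() else hs,
    survival_effect = if (is.null(effect_pathway)) {
      list()
    } else {
      list(pathway = effect_pathway, hr = hr, n_carriers = length(carriers))
    },
    counts = list(
      proteins = length(sequences), reactions = length(kb$reactions),
      pathways = length(kb$pathways), fis = nrow(fis),
      interfaces = nrow(interfaces), maf_rows = nrow(maf),
      samples = cfg$n_samples
    )
  )
  jsonlite::write_json(manifest, paths$manifest,
    auto_unbox = TRUE,
    pretty = TRUE, digits = NA
  )
  invisible(list(
    config = cfg, sequences = sequences, kb = kb, fis = fis,
    interfaces = interfaces, fingerprints = gi$fingerprints, maf = maf,
    clinical = clinical, carriers = carriers, paths = paths
  ))
}

# carriers of a pathway's perturbation, via the real pipeline mappings
pathway_carriers <- function(cfg, kb, fis, sequences, interfaces, maf, pid,
                             fingerprints = list()) {
  recs <- interfaces
  recs <- recs[recs$best_match_evalue <= 1e-4, , drop = FALSE]
  recs <- confidence_filter(recs)
  cohort <- map_to_protein(parsed_maf_df(maf), sequences)
  fi_map <- match_fis_to_interfaces(fis, recs,
    fingerprints = fingerprints, tanimoto_min = 0.5
  )
  events <- call_perturbations(cohort, recs)
  roll <- rollup_pathways(kb)
  pmap <- pathway_fi_map(reaction_fi_map(fis), roll)
  tab <- aggregate_to_units(events, cohort$samples, fi_map, pmap, "pathway",
    records = recs
  )
  if (is.null(tab) || !pid %in% rownames(tab$incidence)) {
    return(character())
  }
  colnames(tab$incidence)[tab$incidence[pid, ] == 1L]
}

# give an in-memory MAF data.frame the parsed columns parse_maf() would add
parsed_maf_df <- function(maf) {
  m <- regmatches(
    maf$protein_change,
    regexec("^([A-Z*])([0-9]+)([A-Z*])$", maf$protein_change)
  )
  maf$ref_aa <- vapply(m, `[`, "", 2)
  maf$position <- as.integer(vapply(m, `[`, "", 3))
  maf$alt_aa <- vapply(m, `[`, "", 4)
  maf
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_interfaces_tsv <- function(interfaces, path) {
  out <- interfaces
  out$positions <- vapply(out$positions, paste, "", collapse = ",")
  write_tsv(out, path)
}

write_fingerprints_tsv <- function(fingerprints, path) {
  ids <- sort(names(fingerprints))
  write_tsv(data.frame(
    chemical_id = ids,
    bits = vapply(fingerprints[ids], paste, "", collapse = ""),
    stringsAsFactors = FALSE
  ), path)
}

write_kb_json <- function(kb, path) {
  doc <- list(
    entities = unname(lapply(kb$entities, function(e) {
      list(
        id = e$id, kind = e$kind, accession = e$accession, name = e$name,
        components = as.list(e$components)
      )
    })),
    reactions = unname(lapply(kb$reactions, function(r) {
      list(
        id = r$id, name = r$name, inputs = as.list(r$inputs),
        outputs = as.list(r$outputs), catalysts = as.list(r$catalysts),
        regulators = as.list(r$regulators)
      )
    })),
    pathways = unname(lapply(kb$pathways, function(p) {
      list(
        id = p$id, name = p$name, reaction_ids = as.list(p$reaction_ids),
        child_pathway_ids = as.list(p$child_pathway_ids),
        parent_pathway_id = p$parent_pathway_id
      )
    }))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
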