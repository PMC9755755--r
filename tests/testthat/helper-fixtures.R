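# Fixtures are built in code, in memory or in tempdir().

protein_entity <- function(acc, name = acc) {
  list(id = paste0("E_", acc), kind = "protein", accession = acc, name = name)
}
chemical_entity <- function(id, acc, name) {
  list(id = id, kind = "chemical", accession = acc, name = name)
}
complex_entity <- function(id, components) {
  list(id = id, kind = "complex", components = components)
}
set_entity <- function(id, members) {
  list(id = id, kind = "entity_set", components = members)
}
reaction <- function(id, inputs = character(), outputs = character(),
                     catalysts = character(), regulators = character(),
                     name = id) {
  list(
    id = id, name = name, inputs = inputs, outputs = outputs,
    catalysts = catalysts, regulators = regulators
  )
}
pathway <- function(id, reaction_ids = character(), children = character(),
                    parent = "") {
  list(
    id = id, reaction_ids = reaction_ids, child_pathway_ids = children,
    parent_pathway_id = parent
  )
}

# TP53-family binding reaction: four dimeric output complexes expand to
# exactly four functional interactions.
tp53_family_kb <- function() {
  accs <- c("TP63", "TP73", "TP53", "PPP1R13B", "TP53BP2")
  ents <- lapply(accs, protein_entity)
  ents <- c(ents, list(
    complex_entity("C1", c("E_TP63", "E_PPP1R13B")),
    complex_entity("C2", c("E_TP73", "E_PPP1R13B")),
    complex_entity("C3", c("E_TP53", "E_PPP1R13B")),
    complex_entity("C4", c("E_TP53", "E_TP53BP2"))
  ))
  kb_from_lists(
    entities = ents,
    reactions = list(reaction("RX_TP53",
      inputs = paste0("E_", accs),
      outputs = c("C1", "C2", "C3", "C4"),
      name = "TP53 family members bind PPP1R13B or TP53BP2"
    )),
    pathways = list(pathway("PW_TOP", "RX_TP53"))
  )
}

# kinase K phosphorylates S consuming ATP; output is an S:phosphate complex
kinase_kb <- function() {
  kb_from_lists(
    entities = list(
      protein_entity("K"), protein_entity("S"),
      chemical_entity("E_ATP", "CHEBI:30616", "ATP"),
      chemical_entity("E_P", "CHEBI:43474", "Pi"),
      complex_entity("C_SP", c("E_S", "E_P"))
    ),
    reactions = list(reaction("RX_K",
      inputs = c("E_S", "E_ATP"),
      outputs = "C_SP", catalysts = "E_K"
    ))
  )
}

# five-reaction toy chain with a currency-only link (r2 -> r3 via ATP)
chain5_kb <- function() {
  kb_from_lists(
    entities = list(
      protein_entity("A"), protein_entity("B"),
      complex_entity("AB", c("E_A", "E_B")),
      chemical_entity("E_ATP", "CHEBI:30616", "ATP"),
      chemical_entity("E_X", "CHEBI:99999", "X")
    ),
    reactions = list(
      reaction("r1", inputs = c("E_A", "E_B"), outputs = "AB"),
      reaction("r2", inputs = "AB", outputs = c("E_A", "E_B", "E_ATP")),
      reaction("r3", inputs = "E_ATP", outputs = "E_X"),
      reaction("r4", inputs = "E_X", catalysts = "AB", outputs = "E_A"),
      reaction("r5", inputs = "E_B", regulators = "E_A", outputs = "E_X")
    )
  )
}

edge_set <- function(net) {
  sort(paste(net$edges$from, net$edges$to, sep = "->"))
}

make_cohort <- function(variants, sequences, samples = NULL,
                        cancer_type = "TEST") {
  v <- variants
  v$cancer_type <- rep_len(cancer_type, nrow(v))
  if (is.null(samples)) samples <- sort(unique(v$sample_id))
  structure(
    list(
      variants = v, samples = samples, cancer_type = cancer_type,
      sequences = sequences,
      tallies = c(
        missing_protein = 0L, length_mismatch = 0L,
        ref_mismatch = 0L, synonymous = 0L
      )
    ),
    class = "cohort"
  )
}

make_interfaces <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    d <- data.frame(
      interface_id = r$id, protein = r$protein,
      partner_id = r$partner, partner_kind = r$kind %||% "protein",
      template_identity_pct = r$identity %||% 95,
      best_match_evalue = r$evalue %||% 1e-8,
      stringsAsFactors = FALSE
    )
    d$positions <- list(as.integer(r$positions))
    d
  }))
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force O(variants x interfaces) perturbation-calling oracle
brute_force_events <- function(cohort, records) {
  rows <- list()
  for (i in seq_len(nrow(cohort$variants))) {
    v <- cohort$variants[i, ]
    for (j in seq_len(nrow(records))) {
      r <- records[j, ]
      if (v$protein == r$protein && v$position %in% r$positions[[1]]) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = v$sample_id, interface_id = r$interface_id,
          protein = v$protein, position = v$position,
          ref_aa = v$ref_aa, alt_aa = v$alt_aa, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(NULL)
  }
  do.call(rbind, rows)
}

canon_events <- function(ev) {
  if (is.null(ev) || !nrow(ev)) {
    return(character())
  }
  sort(paste(ev$sample_id, ev$interface_id, ev$protein, ev$position,
    ev$alt_aa,
    sep = "/"
  ))
}

# reference BH step-up (independent of stats::p.adjust)
reference_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exact-rational upper-tail binomial oracle (python fractions)
exact_binomial_tail <- function(cases) {
  # cases: data.frame(N, c, num, den) with p = num/den
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from fractions import Fraction",
    "from math import comb",
    "for line in sys.stdin:",
    "    N, c, num, den = map(int, line.split())",
    "    p = Fraction(num, den)",
    "    t = sum(comb(N, k) * p**k * (1 - p)**(N - k) for k in range(c, N + 1))",
    "    print(repr(float(t)))"
  ), script)
  inp <- paste(cases$N, cases$c, cases$num, cases$den)
  out <- system2("python", script, input = inp, stdout = TRUE)
  as.numeric(out)
}
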