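test_that("loading an empty document yields an empty knowledgebase", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(entities = list(), reactions = list(), pathways = list()),
    path,
    auto_unbox = TRUE
  )
  kb <- load_kb(path)
  expect_s3_class(kb, "knowledgebase")
  expect_length(kb$reactions, 0)
  expect_equal(nrow(extract_functional_interactions(kb)), 0)
})

test_that("a toy knowledgebase file round-trips with the documented counts", {
  # 3 proteins, 1 chemical, 1 complex, 2 reactions, 2-level pathway
  path <- tempfile(fileext = ".json")
  doc <- list(
    entities = list(
      protein_entity("P1"), protein_entity("P2"), protein_entity("P3"),
      chemical_entity("E_ATP", "CHEBI:30616", "ATP"),
      complex_entity("C12", c("E_P1", "E_P2"))
    ),
    reactions = list(
      reaction("R1", inputs = c("E_P1", "E_P2"), outputs = "C12"),
      reaction("R2", inputs = c("C12", "E_ATP"), outputs = "E_P3")
    ),
    pathways = list(
      pathway("TOP", children = "LEAF"),
      pathway("LEAF", reaction_ids = c("R1", "R2"), parent = "TOP")
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  kb <- load_kb(path)
  expect_length(kb$reactions, 2)
  top <- Filter(function(p) !nzchar(p$parent_pathway_id), kb$pathways)
  expect_length(top, 1)
  expect_equal(top[[1]]$id, "TOP")
})

test_that("validation errors name the offending id", {
  expect_error(
    kb_from_lists(entities = list(complex_entity("CX", c("P_X")))),
    "P_X"
  )
  expect_error(
    kb_from_lists(entities = list(
      complex_entity("CA", "CB"), complex_entity("CB", "CA")
    )),
    "cyclic entity composition"
  )
  expect_error(
    kb_from_lists(pathways = list(
      pathway("PA", children = "PB", parent = "PB"),
      pathway("PB", children = "PA", parent = "PA")
    )),
    "cyclic pathway"
  )
  expect_error(
    kb_from_lists(reactions = list(reaction("R1", inputs = "GHOST"))),
    "GHOST"
  )
  expect_error(load_kb(tempfile()), "not found")
})

test_that("the TP53-family binding reaction expands to exactly four FIs", {
  fis <- extract_functional_interactions(tp53_family_kb())
  expect_setequal(
    fis$fi_id,
    c("PPP1R13B|TP63", "PPP1R13B|TP73", "PPP1R13B|TP53", "TP53|TP53BP2")
  )
  expect_true(all(fis$fi_kind == "protein_protein"))
  expect_true(all(vapply(
    fis$source_reaction_ids,
    function(x) identical(x, "RX_TP53"), TRUE
  )))
})

test_that("a reaction over free proteins only yields no FIs", {
  kb <- kb_from_lists(
    entities = list(protein_entity("A"), protein_entity("B")),
    reactions = list(reaction("R1", inputs = "E_A", outputs = "E_B"))
  )
  expect_equal(nrow(extract_functional_interactions(kb)), 0)
})

test_that("catalysis FIs match exhaustive rule application", {
  # rule (a): S-Pi inside the output complex; rule (b): K-S and K-ATP
  fis <- extract_functional_interactions(kinase_kb())
  expect_setequal(
    fis$fi_id,
    c("CHEBI:43474|S", "K|S", "CHEBI:30616|K")
  )
  kinds <- setNames(fis$fi_kind, fis$fi_id)
  expect_equal(unname(kinds["K|S"]), "protein_protein")
  expect_equal(unname(kinds["CHEBI:30616|K"]), "protein_chemical")
})

test_that("entity-set members pair with complex partners but not each other", {
  kb <- kb_from_lists(
    entities = list(
      protein_entity("A"), protein_entity("B"), protein_entity("C"),
      set_entity("S_AB", c("E_A", "E_B")),
      complex_entity("CX", c("S_AB", "E_C"))
    ),
    reactions = list(reaction("R1", outputs = "CX"))
  )
  fis <- extract_functional_interactions(kb)
  expect_setequal(fis$fi_id, c("A|C", "B|C"))
})

test_that("regulator leaves pair with catalyst and output leaves", {
  kb <- kb_from_lists(
    entities = list(
      protein_entity("REG"), protein_entity("CAT"), protein_entity("IN"),
      protein_entity("OUT")
    ),
    reactions = list(reaction("R1",
      inputs = "E_IN", outputs = "E_OUT",
      catalysts = "E_CAT", regulators = "E_REG"
    ))
  )
  fis <- extract_functional_interactions(kb)
  expect_setequal(fis$fi_id, c("CAT|IN", "CAT|REG", "OUT|REG"))
})

test_that("FI extraction is invariant under reaction order permutation", {
  kb <- tp53_family_kb()
  kb2 <- kb_from_lists(
    entities = c(
      lapply(
        c("TP63", "TP73", "TP53", "PPP1R13B", "TP53BP2"),
        protein_entity
      ),
      list(
        complex_entity("C1", c("E_TP63", "E_PPP1R13B")),
        complex_entity("C2", c("E_TP73", "E_PPP1R13B")),
        complex_entity("C3", c("E_TP53", "E_PPP1R13B")),
        complex_entity("C4", c("E_TP53", "E_TP53BP2"))
      )
    ),
    reactions = list(
      reaction("RX_B", outputs = c("C4", "C3")),
      reaction("RX_A", outputs = c("C2", "C1"))
    )
  )
  f1 <- extract_functional_interactions(kb2)
  kb3 <- kb2
  kb3$reactions <- rev(kb3$reactions)
  f2 <- extract_functional_interactions(kb3)
  expect_equal(f1$fi_id, f2$fi_id)
  expect_equal(f1$source_reaction_ids, f2$source_reaction_ids)
})

test_that("FI source reactions agree with per-reaction rule application", {
  set.seed(11)
  sim <- simulate_study(sim_config(seed = 11, n_samples = 2),
    out_dir = tempfile()
  )
  kb <- sim$kb
  fis <- extract_functional_interactions(kb)
  for (i in seq_len(nrow(fis))) {
    for (rid in names(kb$reactions)) {
      single <- kb
      single$reactions <- kb$reactions[rid]
      sub <- extract_functional_interactions(single)
      in_single <- fis$fi_id[i] %in% sub$fi_id
      in_sources <- rid %in% fis$source_reaction_ids[[i]]
      expect_equal(in_single, in_sources)
    }
  }
})

test_that("random nested acyclic complexes flatten to unique leaves", {
  set.seed(42)
  for (rep in 1:20) {
    n_prot <- sample(3:6, 1)
    ents <- lapply(sprintf("L%02d", seq_len(n_prot)), protein_entity)
    ids <- vapply(ents, `[[`, "", "id")
    for (k in 1:4) { # containers may only reference earlier entities: acyclic
      kind <- sample(c("complex", "entity_set"), 1)
      comp <- sample(ids, sample(2:3, 1))
      id <- paste0("CONT", k)
      ents <- c(ents, list(list(id = id, kind = kind, components = comp)))
      ids <- c(ids, id)
    }
    kb <- kb_from_lists(entities = ents)
    leaves <- edgetic:::kb_leaves(kb, ids[length(ids)])
    expect_false(any(duplicated(leaves$id)))
    expect_true(all(leaves$kind == "protein"))
  }
})

test_that("reaction network edges follow the output-to-consumer rule", {
  net <- build_reaction_network(chain5_kb())
  expect_setequal(edge_set(net), c(
    "r1->r2", "r1->r4", "r2->r1", "r2->r5", "r3->r4",
    "r4->r1", "r4->r5", "r5->r4"
  ))
  # currency-only links appear once the exclusion list is emptied
  net_all <- build_reaction_network(chain5_kb(), excluded = character())
  expect_setequal(setdiff(edge_set(net_all), edge_set(net)), "r2->r3")
  # filtering property: excluded edges are a subset of unfiltered edges
  expect_true(all(edge_set(net) %in% edge_set(net_all)))
  expect_false(any(net$edges$from == net$edges$to))
})

test_that("a complex connects reactions as a whole entity", {
  kb <- kb_from_lists(
    entities = list(
      protein_entity("A"), protein_entity("B"),
      complex_entity("AB", c("E_A", "E_B"))
    ),
    reactions = list(
      reaction("r1", inputs = "E_A", outputs = "AB"),
      reaction("r2", inputs = "E_B", catalysts = "AB", outputs = "E_B")
    )
  )
  expect_setequal(edge_set(build_reaction_network(kb)), "r1->r2")
})

test_that("pathway rollup computes the transitive closure to the roots", {
  kb <- kb_from_lists(
    reactions = list(reaction("R1"), reaction("R2"), reaction("R3")),
    pathways = list(
      pathway("T", children = "M"),
      pathway("M", reaction_ids = "R2", children = "L", parent = "T"),
      pathway("L", reaction_ids = "R1", parent = "M"),
      pathway("T2", reaction_ids = character())
    )
  )
  roll <- rollup_pathways(kb)
  r1 <- roll[roll$reaction_id == "R1", ]
  expect_setequal(r1$pathway_id, c("L", "M", "T"))
  expect_true(all(r1$top_level_id == "T"))
  r2 <- roll[roll$reaction_id == "R2", ]
  expect_setequal(r2$pathway_id, c("M", "T"))
  expect_false("R3" %in% roll$reaction_id)
})

test_that("FI, SIF and GraphML exports write readable files", {
  kb <- chain5_kb()
  fis <- extract_functional_interactions(kb)
  net <- build_reaction_network(kb)
  f1 <- tempfile(fileext = ".tsv")
  write_fi_tsv(fis, f1)
  back <- read.delim(f1, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(fis))
  expect_true(all(c("a", "b", "reaction_ids") %in% names(back)))
  f2 <- tempfile(fileext = ".sif")
  write_sif(net, f2)
  expect_length(readLines(f2), nrow(net$edges))
  f3 <- tempfile(fileext = ".graphml")
  write_graphml(net, f3)
  g <- igraph::read_graph(f3, format = "graphml")
  expect_equal(igraph::gorder(g), length(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
})
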