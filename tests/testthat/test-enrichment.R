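test_that("shuffling preserves per-group substitution multisets and validity", {
  set.seed(5)
  seqs <- c(
    P1 = paste(sample(c("A", "G", "L", "S"), 60, TRUE), collapse = ""),
    P2 = paste(sample(c("A", "G", "L", "S"), 40, TRUE), collapse = "")
  )
  letters1 <- strsplit(seqs[["P1"]], "")[[1]]
  letters2 <- strsplit(seqs[["P2"]], "")[[1]]
  v <- data.frame(
    protein = c(rep("P1", 6), rep("P2", 4)),
    position = c(
      which(letters1 == "A")[1:3], which(letters1 == "G")[1:3],
      which(letters2 == "L")[1:2], which(letters2 == "S")[1:2]
    ),
    sample_id = c(rep("S1", 5), rep("S2", 5)),
    stringsAsFactors = FALSE
  )
  v$ref_aa <- substr(seqs[v$protein], v$position, v$position)
  v$alt_aa <- c("V", "W", "Y", "R", "K", "E", "F", "H", "N", "Q")
  cohort <- make_cohort(v, seqs)
  for (seed in 1:25) {
    sh <- shuffle_cohort(cohort, seed = seed)
    # validity: reference residues still match the sequence
    at <- substr(
      seqs[sh$variants$protein], sh$variants$position,
      sh$variants$position
    )
    expect_equal(unname(at), sh$variants$ref_aa)
    # conservation of (sample, protein, ref) -> alt multiset and count
    key <- function(x) paste(x$sample_id, x$protein, x$ref_aa)
    pre <- split(cohort$variants$alt_aa, key(cohort$variants))
    post <- split(sh$variants$alt_aa, key(sh$variants))
    expect_equal(names(pre), names(post))
    for (g in names(pre)) expect_setequal(pre[[g]], post[[g]])
    # no two variants of one group collapse onto one position
    expect_false(any(duplicated(
      sh$variants[, c("sample_id", "protein", "ref_aa", "position")]
    )))
  }
})

test_that("a single eligible position leaves the variant in place", {
  seqs <- c(P1 = "GAAAG") # exactly one C? no: one class with G at 1,5; A at 2:4
  seqs <- c(P1 = "WAAAA") # W occurs once
  v <- data.frame(
    protein = "P1", position = 1L, ref_aa = "W", alt_aa = "R",
    sample_id = "S1", stringsAsFactors = FALSE
  )
  cohort <- make_cohort(v, seqs)
  for (seed in 1:10) {
    expect_equal(shuffle_cohort(cohort, seed = seed)$variants$position, 1L)
  }
  empty <- make_cohort(v[0, ], seqs, samples = character())
  expect_equal(nrow(shuffle_cohort(empty, seed = 1)$variants), 0)
})

test_that("two same-class substitutions land uniformly on position pairs", {
  # "GAGAG": G at positions 1, 3, 5; two G->R variants in one sample can
  # occupy C(3,2) = 3 unordered pairs, each with probability 1/3
  seqs <- c(P1 = "GAGAG")
  v <- data.frame(
    protein = c("P1", "P1"), position = c(1L, 3L), ref_aa = "G",
    alt_aa = "R", sample_id = "S1", stringsAsFactors = FALSE
  )
  cohort <- make_cohort(v, seqs)
  pairs <- vapply(1:2000, function(seed) {
    p <- sort(shuffle_cohort(cohort, seed = seed)$variants$position)
    paste(p, collapse = "-")
  }, "")
  tab <- table(factor(pairs, levels = c("1-3", "1-5", "3-5")))
  expect_equal(sum(tab), 2000)
  chi <- suppressWarnings(chisq.test(tab))
  expect_gt(chi$p.value, 0.01)
})

test_that("binomial_tail handles the boundary cases and rejects bad input", {
  expect_equal(binomial_tail(0, 10, 0.3), 1)
  expect_equal(binomial_tail(0, 500, 0.01), 1)
  expect_equal(binomial_tail(1, 1, 0.3), 0.3)
  expect_error(binomial_tail(5, 4, 0.1), "c must")
  expect_error(binomial_tail(1, 4, 0), "p must")
  expect_error(binomial_tail(1, 4, 1), "p must")
})

test_that("binomial_tail matches exact rational summation on a spot grid", {
  cases <- expand.grid(N = c(5, 20, 37), c = NA, num = c(1, 10, 30, 50), den = 100)
  cases <- do.call(rbind, lapply(seq_len(nrow(cases)), function(i) {
    data.frame(
      N = cases$N[i], c = round(c(
        1, cases$N[i] / 2,
        cases$N[i]
      )), num = cases$num[i], den = 100
    )
  }))
  cases <- unique(cases)
  exact <- exact_binomial_tail(cases)
  got <- binomial_tail(cases$c, cases$N, cases$num / cases$den)
  expect_equal(got, exact, tolerance = 1e-12)
  # monotonicity: p-value non-increasing in c
  for (N in c(10, 30)) {
    pv <- binomial_tail(0:N, N, 0.2)
    expect_true(all(diff(pv) <= 1e-15))
  }
})

test_that("bh_adjust performs the standard step-up", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(numeric()), numeric())
  set.seed(2)
  p <- runif(50)
  expect_equal(bh_adjust(p), reference_bh(p))
  # permutation contract: q-values follow their p-values
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  expect_error(bh_adjust(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("background estimation applies add-one smoothing and the cap", {
  seqs <- c(P1 = paste(rep("A", 10), collapse = ""))
  samples <- paste0("S", 1:10)
  v <- data.frame(
    protein = "P1", position = 1L, ref_aa = "A", alt_aa = "V",
    sample_id = samples, stringsAsFactors = FALSE
  )
  cohort <- make_cohort(v, seqs, samples = samples)
  # unit never hit: interface on another protein region never touched
  seqs2 <- c(P1 = paste(rep("A", 10), collapse = ""), P2 = paste(rep("G", 10), collapse = ""))
  cohort2 <- make_cohort(v, seqs2, samples = samples)
  rec_never <- make_interfaces(
    list(id = "I_never", protein = "P2", partner = "P1", positions = 1:5)
  )
  bg <- estimate_background(cohort2, rec_never, R = 10, seed = 1)
  expect_equal(bg$interface$hits, 0L)
  expect_equal(bg$interface$p_r, 1 / (10 * 10 + 1))
  # saturated unit: the whole protein is the interface -> capped below 1
  rec_all <- make_interfaces(
    list(id = "I_all", protein = "P1", partner = "P2", positions = 1:10)
  )
  bg2 <- estimate_background(cohort, rec_all, R = 10, seed = 1)
  expect_equal(bg2$interface$hits, 100L)
  expect_equal(bg2$interface$p_r, 100 / 101)
  expect_error(estimate_background(cohort, rec_all, R = 0), "positive")
})

test_that("background probability recovers the uniform placement law", {
  # 1 interface position among 10 equivalent positions, 1 variant per sample:
  # per-sample hit probability is exactly 1/10
  seqs <- c(P1 = paste(rep("A", 10), collapse = ""))
  samples <- paste0("S", 1:5)
  v <- data.frame(
    protein = "P1", position = 3L, ref_aa = "A", alt_aa = "V",
    sample_id = samples, stringsAsFactors = FALSE
  )
  cohort <- make_cohort(v, seqs, samples = samples)
  rec <- make_interfaces(
    list(id = "I1", protein = "P1", partner = "P2", positions = 7)
  )
  R <- 2000
  bg <- estimate_background(cohort, rec, R = R, seed = 99)
  se <- sqrt(0.1 * 0.9 / (R * 5))
  expect_lt(abs(bg$interface$p_r - 0.1), 3 * se)
})

test_that("aggregation counts each sample once per unit and is hierarchical", {
  records <- make_interfaces(
    list(id = "I1", protein = "P1", partner = "P2", positions = 1:5),
    list(id = "I2", protein = "P2", partner = "P1", positions = 1:5),
    list(id = "I3", protein = "P3", partner = "P4", positions = 1:5)
  )
  fi_map <- data.frame(
    fi_id = c("P1|P2", "P1|P2", "P3|P4"),
    interface_id = c("I1", "I2", "I3"), stringsAsFactors = FALSE
  )
  unit_fis <- data.frame(
    unit_id = c("RXA", "RXA", "RXB"),
    fi_id = c("P1|P2", "P3|P4", "P3|P4"), stringsAsFactors = FALSE
  )
  samples <- paste0("S", 1:8)
  # S1 hits both interfaces of RXA's first FI -> counts once for RXA
  events <- data.frame(
    sample_id = c("S1", "S1", "S2", "S3"),
    interface_id = c("I1", "I2", "I3", "I1"),
    protein = c("P1", "P2", "P3", "P1"),
    position = c(1L, 2L, 3L, 4L), ref_aa = "A", alt_aa = "V",
    stringsAsFactors = FALSE
  )
  tab <- aggregate_to_units(events, samples, fi_map, unit_fis, "reaction",
    records = records
  )
  cc <- unit_counts(tab)
  expect_equal(unname(cc["RXA"]), 3) # S1 (once), S2, S3
  expect_equal(unname(cc["RXB"]), 1)
  expect_equal(tab$unit_meta$n_interfaces[tab$unit_meta$unit_id == "RXA"], 3L)
  # brute-force oracle over all (sample, unit, fi, interface) tuples
  for (u in names(cc)) {
    fis_u <- unit_fis$fi_id[unit_fis$unit_id == u]
    ifs_u <- fi_map$interface_id[fi_map$fi_id %in% fis_u]
    manual <- length(unique(
      events$sample_id[events$interface_id %in% ifs_u]
    ))
    expect_equal(unname(cc[u]), manual)
  }
  # pathway containing a reaction has c at least as large
  path_fis <- data.frame(
    unit_id = "PW", fi_id = c("P1|P2", "P3|P4"),
    stringsAsFactors = FALSE
  )
  ptab <- aggregate_to_units(events, samples, fi_map, path_fis, "pathway",
    records = records
  )
  expect_gte(unit_counts(ptab)[["PW"]], max(cc))
})

test_that("enrichment testing excludes untested units and sorts by q", {
  samples <- paste0("S", 1:100)
  inc <- matrix(0L, 3, 100, dimnames = list(c("U1", "U2", "U3"), samples))
  inc["U1", 1:30] <- 1L # strong signal
  inc["U2", 1:3] <- 1L # weak
  # U3 never perturbed -> not tested
  tab <- structure(
    list(
      level = "interface", incidence = inc,
      unit_meta = data.frame(
        unit_id = c("U1", "U2", "U3"),
        n_interfaces = 1L, member_genes = "G",
        stringsAsFactors = FALSE
      )
    ),
    class = "perturbation_table"
  )
  bg <- data.frame(
    unit_id = c("U1", "U2", "U3"), hits = c(9L, 9L, 0L),
    p_r = c(0.01, 0.01, 0.001), stringsAsFactors = FALSE
  )
  res <- test_enrichment(tab, bg, alpha = 0.05)
  expect_setequal(res$unit_id, c("U1", "U2"))
  expect_equal(res$unit_id[1], "U1")
  expect_lt(res$p_value[1], 1e-20)
  expect_true(res$significant[1])
  expect_equal(res$q_value, sort(res$q_value))
  # missing background for a tested unit is an error
  expect_error(
    test_enrichment(tab, bg[bg$unit_id != "U2", ]),
    "missing background"
  )
})

test_that("the enrichment screen is quiet on a null synthetic cohort", {
  sim <- simulate_study(sim_config(seed = 314, n_samples = 120),
    out_dir = tempfile()
  )
  rc <- run_config(
    maf = sim$paths$maf, fasta = sim$paths$fasta,
    interfaces = sim$paths$interfaces, fingerprints = sim$paths$fingerprints,
    kb = sim$paths$kb, cancer_type = "SYNTH", background_R = 30, seed = 2718,
    out_dir = tempfile()
  )
  res <- suppressMessages(run_pipeline(rc))
  n_sig <- sum(vapply(res$enrichment, function(e) sum(e$significant), 0L))
  expect_lte(n_sig, 1)
})
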