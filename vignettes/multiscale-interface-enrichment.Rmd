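---
title: "Multi-scale enrichment of somatic variants at protein interaction interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale enrichment of somatic variants at protein interaction interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis in one paragraph

A missense mutation can act *edgetically*: rather than destroying a protein,
it perturbs one specific interaction by changing a residue at the 3D contact
interface with a partner. `edgetic` implements a multi-scale screen for such
mutations in a tumor cohort. Somatic missense variants are mapped onto
canonical protein sequences, intersected with structure-derived interface
positions to call per-sample *interface perturbation events*, and the events
are aggregated upward through a curated reaction knowledgebase: interfaces
map to functional interactions (FIs), FIs to the biochemical reactions they
mediate, and reactions to the pathway hierarchy. At every level the same
statistic is applied: the number of unique perturbed samples is compared
against a cohort-specific background obtained by shuffling each sample's
substitutions among equivalent positions of the same protein, using a
binomial tail probability and Benjamini-Hochberg correction. Significant
units are finally screened for association with overall survival by Cox
proportional-hazards regression with age and sex as covariates.

## From reactions to functional interactions

The knowledgebase (a bespoke JSON schema, `docs/kb_schema.md`) holds
physical entities — proteins and chemicals with accessions, complexes and
entity sets with components — plus reactions (inputs, outputs, catalysts,
regulators) and a pathway forest. Functional interactions are extracted per
reaction after recursively flattening complexes and entity sets to
accessioned leaves:

1. every pair of distinct leaves co-occurring in one complex among the
   reaction's inputs or outputs;
2. every (catalyst leaf, input leaf) pair;
3. every (regulator leaf, catalyst-or-output leaf) pair.

Members of an *entity set* are biological alternatives, so pairs between
members of the same set are never emitted; a set member pairs only with the
other components of a containing complex. Chemical–chemical pairs are
discarded. Pairs are stored canonically (lexicographic), deduplicated across
reactions, and each FI remembers all reactions that generated it — the
FI-to-reaction relation is many-to-many by construction. These three rules
are a deliberately minimal, auditable rule set: they are sufficient to
reproduce the canonical worked example in which a reaction whose outputs are
the four dimers TP63:PPP1R13B, TP73:PPP1R13B, TP53:PPP1R13B and TP53:TP53BP2
expands to exactly four FIs.

```{r}
library(edgetic)
kb <- load_kb("kb.json")
fis <- extract_functional_interactions(kb)
```

The *reaction network* connects reaction `r1` to `r2` when an output entity
of `r1` is an input, catalyst or regulator of `r2`, with entity identity
taken at the whole-entity level (a complex connects as a complex). Currency
metabolites — ATP, ADP, Pi, H2O, GTP, GDP, CO2, H+ — are excluded from this
check by display name (case-sensitive, configurable) because they would
connect essentially everything to everything.

## Variant mapping

Input mutation tables are a TSV subset of the MAF dialect. Two filters gate
a variant onto a protein sequence: the annotated transcript peptide length
must equal the length of the provided canonical sequence, and the reference
amino acid of the `protein_change` string must match the sequence letter at
the stated 1-based position. Every coordinate in the package is 1-based;
there are no 0-based positions anywhere. Only missense substitutions are
analyzed by default (configurable): interface perturbation is defined
positionally for substitutions, and the treatment of truncating events at
interfaces would need a different event model. Drops are tallied per reason
and written to the run bundle, never silently discarded.

## Interfaces, confidence tiers, and chemical matching

Interface records carry the protein, the partner (protein, chemical or
nucleic acid), the set of contact positions, the template sequence identity
and the best template match E-value. Records above E-value 1e-4 are dropped
at load. Confidence tiers follow the structural-homology logic: protein
partners require template identity of at least 70% (high confidence);
chemical and nucleic-acid partners are kept down to 30%. Both identity
bounds are inclusive as printed; the chemical-similarity threshold below is
strict. Protein–protein FIs match interfaces by unordered accession
equality. Protein–chemical FIs match when the protein accessions agree and
the Tanimoto similarity |A∩B|/|A∪B| between the FI chemical's topological
fingerprint and the structure ligand's fingerprint exceeds 0.5 (strictly).
The pipeline consumes precomputed fingerprint bit vectors, keeping the core
free of a cheminformatics toolkit dependency; nucleic-acid interfaces are
carried through and reported at interface level but have no FI counterpart.

A perturbation event is a (variant, interface) pair with the variant's
position among the interface's contact positions; a variant hitting two
overlapping interfaces yields two events, and all downstream counting
deduplicates samples per unit.

## The background model and the enrichment test

The null hypothesis is that a sample's substitutions are placed at random
*within their proteins*. For each (sample, protein, wild-type residue)
group, the shuffle keeps the multiset of alternate residues and redraws the
positions uniformly without replacement from the positions of that protein
carrying the same wild-type residue. "Equivalent positions" is not further
constrained — same protein, same reference residue is the weakest definition
under which "the same substitution" remains well-formed, and it guarantees
the shuffled cohort is still valid (reference residues match). Sampling
without replacement prevents two mutations collapsing onto one site;
shuffling is per protein (no cross-protein moves) and jointly over each
sample's proteins.

The shuffle runs `R` times (default 100; replicate seeds are `seed + 1` …
`seed + R`), and events and unit incidence are recomputed per replicate
exactly as for the observed cohort. The per-unit background probability uses
add-one smoothing,

    p_r = (hits + 1) / (R * N + 1),

where `hits` counts (replicate, sample) pairs with at least one perturbing
event at the unit and `N` is the cohort size; `p_r` is additionally capped
at `RN/(RN+1)` so it always lies strictly inside (0, 1) and the binomial
tail is defined even for saturated or never-hit units.

For a unit perturbed in `c` of `N` samples the p-value is the one-sided
upper binomial tail

    P = sum_{k = c..N} C(N, k) p_r^k (1 - p_r)^(N - k),

evaluated through the binomial survival function (no naive factorial
summation). The upper tail is the enrichment direction — the question is
whether the observed count exceeds chance; depletion is not tested. P-values
are BH-adjusted *per level and per cohort* (interfaces, reactions and
pathways form separate adjustment families, matching per-level significance
reporting), and units with `c = 0` are not tested and do not enter the
family. Significance is adjusted p strictly below 0.05.

Aggregation to reactions and pathways is purely set-theoretic: a sample
scores for a reaction if it perturbs any interface matched to any of the
reaction's FIs, and for a pathway if it scores for any reaction the pathway
contains directly or via descendant pathways. Carrier counts are therefore
monotone up the hierarchy: c(pathway) ≥ c(reaction) ≥ c(interface) for
nested units, which the test suite asserts.

### A note on calibration

The binomial model uses a single background probability per unit, but the
true null law of `c` is Poisson-binomial: a sample can only perturb an
interface if it happens to carry a mutation on that protein in a residue
class overlapping the interface, so per-sample perturbation probabilities
are strongly heterogeneous (many zeros, a few large values). A
Poisson-binomial count is under-dispersed relative to a binomial with the
same mean, so the test is conservative against its own shuffle null. The
acceptance suite measures this directly: the background estimate is
unbiased (mean standardized residual of `c` against `N * p_r` near 0, sd
about 0.8), and on null synthetic cohorts the fraction of tested interfaces
with raw p < 0.05 is about 1–2% rather than the nominal 5%. False-positive
control is therefore stricter than nominal — a safe direction for a
discovery screen, at some cost in power — and FDR-significant calls on null
data are correspondingly rare (at most one significant unit in ≥ 95% of
null runs). This conservatism is intrinsic to the single-parameter binomial
approximation, not to the implementation.

## Survival screen

Clinical records contribute event = death with time = days to death, or
censoring at days to last follow-up; rows with missing status, gender, age
or the applicable time, genders outside {male, female}, or non-positive
times are dropped with tallied reasons. Each eligible unit is fitted with
`survival::coxph` on the carrier indicator plus age and sex, Efron tie
handling (the common default), and the hazard ratio is the exponentiated
carrier coefficient with a 95% Wald interval. The carrier indicator *is*
the unit's incidence row from the enrichment stage — no re-derivation, so
the two stages cannot drift apart. Units need at least 2 carriers, 2
non-carriers and 1 event; others are skipped with a logged reason. By
default only enrichment-significant units are screened (`mode =
"significant"`); `mode = "all"` screens every tested unit. Adjustment is
again BH per level per cohort.

## The synthetic-data generator

Every input the pipeline reads can be generated, fully seeded, by
`simulate_study()`: knowledgebase JSON, FASTA sequences, interface and
fingerprint TSVs, a MAF-subset mutation table and a clinical table, plus a
manifest. Background mutations follow exactly the shuffle-null law —
uniform placement over protein positions with the reference residue read
off the sequence — so with no planted signal the enrichment screen should
stay quiet, and planted deviations are meaningful.

Default study conditions (chosen once as a realistic desk-scale setting and
held fixed):

* 12 proteins of 100–180 residues, organized under two top-level pathway
  trees whose roots hold *disjoint* protein blocks — pathways engage largely
  distinct gene sets, which keeps pathway-level carrier sets distinguishable;
* 15 reactions cycling through binding, ATP-driven catalysis and regulated
  catalysis templates, chained within blocks so the reaction network is
  connected and currency metabolites genuinely appear;
* interface contact footprints of 15–40 residues (typical structural
  contact patches) on 90% of extracted FIs; template identities drawn
  across the confidence thresholds so the filters do real work;
* 200 samples with 2–6 missense substitutions each — a moderately mutated
  exome scaled to the simulated subproteome;
* exponential survival at baseline hazard 1/1000 per day, independent
  exponential censoring scaled to a 20% censoring fraction, age ~ N(60, 10)
  clipped to [20, 90], balanced gender.

Hotspots are planted per interface as an extra per-sample Bernoulli hit at
a uniformly chosen interface position; survival effects multiply the hazard
of the samples that perturb a chosen pathway, with carriers derived through
the *real* pipeline mappings rather than by fiat. Exponential event times
were chosen for closed-form checkability (medians scale as 1/HR); censoring
at rate `baseline * c/(1-c)` hits the requested censoring fraction exactly
for non-carriers.

What the generator does not emulate: trinucleotide mutational signatures,
isoform structure, correlated interface geometry, informative censoring,
or per-gene selection. Passing tests on synthetic data therefore
demonstrate the statistical machinery — calibration, recovery, hierarchy
consistency, determinism — not fidelity to any particular tumor biology.

## Numerical and design choices

* Thresholds are implemented exactly as stated: identity bounds inclusive
  (≥ 70, ≥ 30), Tanimoto strict (> 0.5), E-value ≤ 1e-4, significance at
  adjusted p < 0.05 (strict).
* `binomial_tail` is the binomial survival function; the test suite checks
  it against exact rational summation (python `fractions`) across all
  N ≤ 60, c ≤ N, p ∈ {0.01, 0.1, 0.3, 0.5} at relative error < 1e-10.
* `bh_adjust` wraps the standard step-up (`stats::p.adjust`); the suite
  compares it against an independently written five-line reference on 1000
  random vectors.
* Tanimoto of two all-zero fingerprints is defined as 0.
* Ties in result ordering break by q-value, then descending carrier count,
  then unit id, so outputs are byte-stable; reruns of one configuration are
  byte-identical (asserted), with replicate seeds derived arithmetically
  from the run seed.
* Degenerate inputs: empty cohorts shuffle to themselves; units never hit
  in the background get the pseudocount probability 1/(RN+1); saturated
  units are capped below 1; Cox fits with no carrier contrast, no events or
  failed convergence are skipped with a recorded reason.

Problem sizes in the shipped test and acceptance runs (100 null seeds at
N = 200 and R = 50; 50 hotspot seeds at N = 300; 50 survival seeds at
N = 600; full-grid oracle checks) were chosen as the package's standard
verification workload; the same quantities scale to larger cohorts by
raising `n_samples` and `background_R` in the configurations.

## Known limitations

* The FI extraction rules are a documented minimal superset of curated
  reaction semantics; a richer curation model (sub-complex stoichiometry,
  catalysis on complexes of complexes with regulatory context) would emit
  additional pairs.
* The binomial single-parameter background is conservative (see the
  calibration note); an exact permutation p-value from replicate ranks
  would be calibrated but was deliberately excluded as out of scope — the
  binomial formula is the method under test.
* One cohort per run: pan-cancer analyses loop over per-cancer
  configurations rather than pooling.
* Nonsense and indel variants are excluded from interface perturbation by
  default; whether truncations should count as perturbing all downstream
  interfaces is a modeling decision the package leaves configurable rather
  than silently taking.
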