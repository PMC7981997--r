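---
title: "Methods: network-pharmacology screening with planted ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-pharmacology screening with planted ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Network pharmacology asks how a multi-compound preparation — here a
medicinal herb screened against colorectal cancer — can act on a disease
through many weak, overlapping interactions rather than a single
high-affinity target. The workflow this package implements is the
standard funnel: physicochemical triage of the herb's compounds,
prediction-based target mapping, intersection with disease genes,
expression-based validation, interaction-network topology, dense-module
detection, and pathway over-representation. Every stage is a pure
function over tabular inputs, so the whole funnel is testable offline
against synthetic data with planted ground truth.

# Stage models and parameters

## Drug-likeness gate (`select_candidates`)

Five descriptor rule systems are evaluated per compound. The published
workflow names the systems but not their thresholds; we use the
SwissADME formulations, which also fix which logP estimate each rule
consumes:

| rule | criteria (inclusive bounds unless noted) |
|---|---|
| Lipinski | at most one of mw > 500, MLOGP > 4.15, HBD > 5, HBA > 10 |
| Ghose | 160 ≤ mw ≤ 480, −0.4 ≤ WLOGP ≤ 5.6, 40 ≤ MR ≤ 130, 20 ≤ atoms ≤ 70 |
| Veber | rotatable bonds ≤ 10, TPSA ≤ 140 Å² |
| Egan | WLOGP ≤ 5.88, TPSA ≤ 131.6 Å² |
| Muegge | 200 ≤ mw ≤ 600, −2 ≤ XLOGP3 ≤ 5, TPSA ≤ 150, rings ≤ 7, C > 4 (strict), heteroatoms > 1 (strict), rot ≤ 15, HBA ≤ 10, HBD ≤ 5 |

The oral-bioavailability class is Martin's decision tree: anions score
by TPSA (≤ 75 → 0.85; ≤ 150 → 0.56; otherwise 0.11), all other
ionization classes score by rule-of-five compliance (0.55 pass / 0.17
fail). A compound is a candidate when it passes at least
`min_rules_passed = 2` systems **and** its bioavailability score is at
least `min_bas = 0.30`; because 0.17 < 0.30, a compound that fails
Lipinski and is not an anion can never pass the gate regardless of the
other rules. An unknown ionization class falls back to "neutral" with a
warning rather than an error, since descriptor exports frequently leave
the field blank.

## Target and disease-gene selection

Predicted compound–target interactions are kept at probability ≥ 0.1
(inclusive), duplicates collapsed per compound, and compounds left with
no target are dropped — this is the step that turns the 56 gate
survivors into 53 working compounds in the default synthetic study.
Disease genes are kept at relevance score ≥ 10 (inclusive). Gene
symbols are uppercased and whitespace-stripped on ingest and never
alias-mapped: symbol dictionaries change faster than the analyses that
cite them, and the intersection arithmetic must be reproducible from
the input files alone.

## Top-decile differential expression

The expression stage ranks genes by `log2((mean tumor + 1) /
(mean normal + 1))` and takes the top and bottom `ceiling(0.10 · G)`
genes. A pseudo-count of 1 keeps the ratio defined at zero expression;
ranking by fold change of group means (rather than a t-statistic) is
deterministic, needs no variance estimate, and matches the
"over/under-expression" semantics of tumor-compendium exports. A Welch
statistic would be the natural switch if per-gene variance mattered,
but the decile selection is rank-based and both orderings agree at the
planted effect sizes, so the simpler statistic is the default.

Ties are broken lexicographically by symbol — ascending on the over
side, descending on the under side. The asymmetry is deliberate: with a
shared tie-break a fully tied (degenerate) matrix would put the same
gene in both deciles, and disjointness is the stronger invariant. The
cost is that the exact swap symmetry under label reversal holds only
when no tie straddles a decile boundary, which is almost sure for
continuous data. Fractions above 0.5 (where the two deciles would
necessarily overlap) are rejected.

## Network topology

Networks are igraph objects whose vertices carry a `class` attribute
(compound, target, pathway, protein). Degree is the incident edge
count. Betweenness is Brandes' accumulation normalized by
(n−1)(n−2)/2. Closeness is computed within each connected component as
(n_c − 1)/Σd, with isolated vertices at 0; the literal reciprocal
distance sum is available via `normalized = FALSE`. We chose the
normalized per-component form because it is what the standard network
analysis tools report and it is the only convention whose values land
in the 0.3–0.45 range that published compound-target networks of this
size show; the literal inverse-sum on a ~800-node graph would sit two
orders of magnitude lower.

One published-shape subtlety: a compound that loses all its targets has
no edges, yet published compound–target figures still draw all screened
compounds. `build_bipartite()` therefore accepts an optional fixed
compound layer; the pipeline passes the full gate-survivor list, which
is how the default synthetic run reproduces the (785 nodes, 3747 edges)
shape while still reporting 53 compounds with targets.

The PPI confidence filter is strictly greater than 0.7 — an edge at
exactly 0.7 is discarded — and vertices left without edges are dropped.
Hubs are the top 20 by degree, ties broken by betweenness then id.

## MCODE

The molecular-complex detection algorithm is implemented in its
three-stage form. Vertex weighting scores each vertex v (with degree ≥
`degree_cutoff = 2`) as k_max × density of the k_max-core of v's closed
neighborhood. Complex prediction repeatedly seeds from the
highest-weight unvisited vertex (ties by id, for determinism) and grows
breadth-first over unvisited neighbors whose weight is at least
(1 − `node_score_cutoff`) × seed weight, with the cutoff at its
standard 0.2. Post-processing replaces each complex by the 2-core of
its induced subgraph ("haircut"; taking the 2-core subsumes iterative
pendant removal and is order-independent) and discards complexes with
no 2-core; "fluff" is implemented but off by default. The complex score
is density × node count, so a clique scores exactly n; all seven
reference (n, e) worked examples reproduce their printed scores to
three decimals.

A consequence worth knowing: the growth threshold makes MCODE return
the dense *core* of an irregular module, not necessarily the module
whole. A planted (13, 58) module mixes degree-8 and degree-9 vertices
whose closed neighborhoods have different maximal core numbers, so the
low-weight members fall below 0.8 × seed weight and are trimmed. This
is the algorithm's documented behavior, not an implementation artifact;
the synthetic tests therefore assert exact recovery for clique-shaped
modules and containment-within-module for all others.

## Over-representation analysis

The enrichment statistic is the hypergeometric upper tail
P(X ≥ k) for a query of n genes hitting k of a K-gene term in an
N-gene universe, computed via `phyper`. The EASE variant (tail at
k − 1, so singleton overlaps are never significant) is selectable;
the plain hypergeometric is the default because it admits an exact
enumeration oracle at small N and the planted-recovery surface does not
depend on the choice. The universe defaults to the union of term
members, overridable. BH adjustment runs within each category (BP, CC,
MF, KEGG) separately, mirroring how GO domains and pathway libraries
are reported separately; the significance gate is FDR < 0.01. The rich
factor is k/K.

# The synthetic study

The generators plant the full funnel at the published shape: 97
compounds with 56 inside all five rule boxes (the other 41 violate
every system *and* Lipinski, so they fail both gate legs); 3 of the 56
receive only sub-threshold prediction probabilities; the remaining 53
share 3747 passing compound–gene pairs over exactly 729 genes (each
gene assigned round-robin for coverage, the rest uniform); 1893
disease genes of which 272 are drawn from the target universe; a
2000-gene expression matrix (30 tumor / 10 normal samples, mirroring
the tumor-heavy designs of public compendia at reduced scale) whose top and bottom deciles (200 genes each) are filled by
planted ±2 log2-fold-change genes, 68 + 68 of them taken from the 272
candidates so the validated set is exactly 136; a PPI table whose
planted modules are wired as a spanning cycle plus uniform extra edges
(guaranteeing the 2-core) with confidences in (0.75, 0.99), over an
Erdős–Rényi background with confidences straddling the 0.7 filter; and
100 annotation terms with one planted KEGG-category term overlapping
the validated set in 30 of its 40 members.

Observation noise of SD 0.5 on log2 expression with a planted effect of
2 gives a per-gene fold-change standard error of about 0.19 on this
design, so planted and background genes are separated by roughly seven
standard errors: decile recovery is effectively exact at the defaults,
and the ≥ 90% recovery bound is met with a wide margin.

The decoy term sizes are uniform on [20, 200]. That range was fixed
analytically before any test was run: for a 50-gene query in a
2000-gene universe the discrete null probability P(p < 0.05) averages
≈ 0.030 over these sizes (it would drop below 0.02 for uniformly small
terms, where the hypergeometric tail is too coarse to ever cross 0.05
at k achievable by chance), which keeps the null-calibration check
meaningfully inside its [0.02, 0.09] band.

A single integer seed drives one substream per generator (fixed
offsets), so adding a generator never perturbs existing tables and
regeneration is byte-identical.

## What the synthetic data does not emulate

Real database exports carry structure the generators deliberately omit:
correlated descriptors (mw and heavy-atom count co-vary in real
molecules), scale-free degree distributions in prediction tables,
shared-pathway correlation between expression of related genes,
STRING's evidence-channel structure behind the combined score, and the
GO term hierarchy (no ancestor propagation). Passing the planted-
recovery suite therefore demonstrates the *arithmetic* of every stage —
thresholds, intersections, topology, module detection, enrichment — on
inputs of realistic shape and size, not robustness to the biological
correlation structure of any particular database release. Counts tied
to database versions (e.g. a specific PPI node/edge census or GO term
tallies) are correspondingly out of the test surface.

# Numerical and design choices

* All rule-box and threshold comparisons are inclusive unless the
  published rule is strict; the PPI confidence filter is the one
  strictly-greater-than comparison.
* Probabilities and scores are validated on ingest with the offending
  row named; a missing descriptor rejects the record naming the field.
* Enrichment p-values are clipped into (0, 1] before BH; BH itself is
  `p.adjust`'s step-up with monotonicity enforcement.
* Determinism everywhere: lexicographic tie-breaks in decile selection,
  hub ranking and MCODE seeding; cluster ranking by score, size, seed.
* Problem sizes in the test suite: exhaustive graph-class enumeration
  to 7 vertices (996 connected classes, compared against a
  Floyd–Warshall/path-counting oracle), brute-force subset search to 8
  vertices, draw-enumeration oracles to N = 20, a 200-node
  planted-clique instance and 1000 null-calibration replicates — sizes
  at which the oracles are exact and the suite completes in well under
  a minute per property family.

# Workflow shape

The package exposes every stage as a function (`R/`), and the analysis
is driven by the numbered scripts under `analysis/` (simulate, screen,
map, network, cluster, enrich), each a thin narrative wrapper writing
its tables under `results/`. `run_pipeline()` composes the same stages
in-memory with a validated flat configuration and writes a JSON report
whose counts are recomputable from the stage files; there is no
separate shell tool, since the scripts and functions are the interface
an analyst would actually use.

# Known limitations

* The drug-likeness thresholds are the SwissADME formulations; other
  descriptor providers differ in logP estimators and would shift
  individual verdicts (not the gate logic).
* No SMILES-to-descriptor computation: descriptor tables are the
  canonical input.
* MCODE implements undirected, unweighted complexes with the haircut
  realized as the 2-core; overlapping-complex variants and
  edge-weighted scoring are out of scope.
* Closeness and betweenness are unweighted; edge confidences filter but
  do not weight paths.
* Enrichment does no GO-graph propagation and no term-redundancy
  reduction; within-category BH assumes categories are the reporting
  unit.
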