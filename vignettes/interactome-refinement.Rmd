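---
title: "Refining interactome representations with proteoforms and small molecules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining interactome representations with proteoforms and small molecules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoformnet)
```

## The problem

Network biology mostly works with gene-centric interactomes: one node per
gene, one edge per known interaction. That representation discards two
kinds of information that curated pathway knowledgebases hold in
abundance. First, a gene's products are not interchangeable — isoforms and
post-translationally modified forms (*proteoforms*) can participate in
different reactions, in different compartments, with different partners.
Second, reactions are full of molecules that are not genome-encoded at
all: metabolites, cofactors, water — *small molecules*, identified by
ChEBI accessions. Whether and how these are represented changes the
topology of the network, and with it every downstream analysis that leans
on topology (module detection, diffusion, guilt-by-association,
robustness).

This package makes the representation an explicit, controllable choice and
measures its consequences.

## The network model

The canonical input is a flattened *participant table*: one row per leaf
participant occurrence in one reaction, with a role (input, output,
catalyst, regulator), an entity class (accessioned entity or small
molecule), and optional proteoform annotation (isoform suffix and a
multiset of PTMs, each a PSI-MOD accession with a 1-based position or an
unknown-position sentinel). Complexes and entity sets are flattened
recursively to these leaves (`flatten_entity_tree()`); excluded classes —
drugs, polymers, other entities, genome-encoded entities without a
reference identifier, small molecules without a ChEBI accession — are
dropped at that point and never reach the table.

Given a table, `build_network()` applies three rules:

1. **Node keying.** At gene level, every record of a gene maps to its HGNC
   symbol (UniProt accession as fallback for unmapped proteins). At
   proteoform level, the key is the canonical string
   `ACCESSION[-ISOFORM];mod:pos,...` with PTMs sorted by type then
   position, unknown positions last. PTM identity is strict: an unknown
   position matches only an unknown position, and a missing isoform is
   distinct from an explicitly annotated canonical isoform — the package
   takes the annotation at face value rather than guessing equivalences.
   PTM multiplicity is preserved: two modifications of the same type at
   unknown positions count twice, which is what lets heavily repeatedly
   modified proteins (polyubiquitin, histones) fan out into many
   proteoforms.
2. **Edges.** Within each reaction, all distinct node keys are pairwise
   connected, regardless of role — catalysts and regulators are
   co-participants like everyone else. Edges are undirected, deduplicated
   across reactions, and carry the set of supporting reaction ids as
   provenance. Event sequencing (outputs of one reaction re-appearing as
   inputs of the next) is captured only through shared participants, not
   through extra edges.
3. **Self-interactions.** If two participants of a reaction map to the
   same key (two proteoform states of one gene at gene level, a homodimer
   subunit listed twice), the node is flagged self-interacting; no loop
   edge is stored. Degree therefore counts distinct non-self neighbours,
   and a node whose only interactions are with itself is *isolated* — the
   definition the isolated-node analysis depends on.

Small molecules enter in one of three modes: `none` (skipped), `global`
(one node per ChEBI id, shared by all reactions), `reaction_unique` (one
node per ChEBI id *and* reaction). The third mode is the interesting
compromise: a ubiquitous metabolite no longer stitches unrelated pathways
together, but still connects the participants of each reaction it joins —
a protein meeting ATP in *k* reactions gains *k* neighbours instead
of one. Small-molecule–small-molecule co-participation edges are created
in both modes; the class-stratified edge tallies let either counting
convention be read off.

The validation oracle for the node semantics is `quotient_to_genes()`:
collapsing the proteoform network along the proteoform-to-gene map must
reproduce the directly built gene network exactly (nodes, edges,
self-interaction flags, provenance). The test suite asserts this identity
across many random synthetic datasets and all three small-molecule modes.

## Pathway subnetworks

Pathways are hierarchical: a pathway's reaction set is the transitive
closure through its sub-pathways (`pathway_closure()`), and its subnetwork
is simply the interactome restricted to those reactions. Per-pathway
metrics are computed on each pathway's own subnetwork independently, with
no cross-pathway deduplication — nested pathways deliberately repeat their
children, because the question "how prevalent are articulation points
within a pathway" is about each pathway's own context. The filter
"pathways with at least one proteoform-annotated participant" is exposed
as a flag (`annotated_only`) and never hard-coded, since only the degree
analyses call for it.

## Topology metrics

`topology_summary()` computes the metric battery on any network: counts
and degree statistics by class, components and the largest connected
component (LCC; ties broken by lexicographically smallest member, so
reports are reproducible), isolated nodes, articulation points and
bridges. Articulation points and bridges — nodes and edges whose removal
disconnects a component — are computed with igraph's linear-time
routines; the test suite verifies them against brute-force
remove-and-recount oracles (union-find, written independently of igraph)
on hundreds of random graphs. Percentages are reported on exact integer
counts.

Two cross-variant analyses target the small-molecule question directly:
`sm_dependency()` returns the accessioned nodes that are isolated without
small molecules but connected with them (their only routes into the
interactome run through chemistry), and `family_specificity()` returns
the proteins with at least two annotated proteoforms where some proteoform
participates in a reaction that involves no other member of the family —
the cases where proteoform-level measurement carries pathway-specific
information that a gene-centric network destroys.

## Percolation

Robustness is probed by link percolation: remove a fixed quantum of edges
uniformly at random, record the LCC size, repeat until no edge remains.
Design choices worth stating explicitly:

* **Completeness is the fraction of original edges remaining.** The
  alternative reading (share of nodes remaining in the LCC) would make the
  x-axis depend on the y-axis; the edge-fraction reading is the one under
  which "iteratively removing connections until completeness is 0" is
  well-defined.
* **The quantum is `floor(step_fraction * E0)` of the *original* edge
  count** (default 10%), so the procedure terminates in
  `ceiling(1/step_fraction)` steps; removing 10% of the *remaining* edges
  would never reach zero. Both readings are implemented
  (`quantum = "original"` / `"remaining"`); the default follows the
  terminating one.
* **Normalization by the initial LCC node count**, so every curve starts
  at exactly 1.0 even when isolated nodes are present, and per-repetition
  curves are non-increasing by construction.
* **Seeding.** Each of the `repetitions` (default 20) runs uses a seed
  derived deterministically from the configuration seed; identical
  configurations give identical curves.
* **Threshold estimate.** The curve is aggregated as the median with a
  20th–80th percentile ribbon; the percolation threshold is the grid point
  on which the largest single-step drop of the median lands, i.e. the
  completeness at which the collapsed state is first observed. On an
  Erdős–Rényi graph with mean degree ⟨k⟩ the giant component
  disappears where completeness × ⟨k⟩ = 1; the acceptance suite checks
  that the estimate on a 2000-node, ⟨k⟩ = 6 graph lands at 1/6 within
  the grid resolution.

## The synthetic generator

`simulate_reactome()` emulates the event structure of a curated
knowledgebase so that every stage is testable without downloads. What it
models, and why:

* **Scale.** Defaults of ~200 pathways (nested up to depth 3) with
  1 + Poisson(9) reactions each, 1000 proteins, 150 small molecules —
  large enough for stable shares and a full pipeline run in well under a
  minute, small enough for routine testing.
* **Proteoform sparsity.** Per-protein repertoires of
  1 + Poisson(0.3) states target a mean of 1.3 distinct proteoforms per
  protein, mirroring the sparse annotation level of real knowledgebases
  (≈1.29 proteoforms per gene); extra states carry an isoform suffix
  and/or 1 + Poisson(0.7) PTMs with 10% unknown positions. The generator
  records the realized mean as ground truth and the tests require the
  pipeline to reproduce it within ±0.1 at 500+ proteins.
* **Ubiquitous small molecules.** Five ATP/H2O-like molecules each join
  35% of reactions; the remaining pool appears at Poisson(0.8) per
  reaction. The hyperconnectivity findings depend on this skew, so it is
  modelled explicitly.
* **Community structure.** Each pathway draws its proteins from its own
  contiguous block (5% of the pool) with 5% cross-talk; 10% of reactions
  are *self-role* reactions in which a single protein (drawn from a
  reserved 5% "loner" sub-pool) acts as both input and output. These two
  mechanisms produce the structural motifs the analyses measure — modular
  components joined by sparse bridges, and isolated self-interacting
  nodes that small molecules rescue. A uniformly mixed pool would produce
  a single dense component with none of these features.
* **Shared code path.** Participants are assembled as entity trees
  (complexes, entity sets, occasional homodimer duplication and excluded
  drug leaves) and flattened through the same `flatten_entity_tree()`
  used by extraction, so format drift between synthetic and real input is
  impossible.
* **Ground truth.** Node counts per variant, isolated and
  small-molecule-dependent key sets, and the family-specific accession
  set are computed by independent per-row tallies (never through the
  network-build code path), and planted motifs provide
  construction-guaranteed cases: a thiamin-metabolism-style pathway
  (isolated proteins rescued by shared small molecules; exactly one
  component per reaction under reaction-unique small molecules), disjoint
  proteoform families, and an articulation-point star.

What the generator does *not* emulate: the exact size, degree
distribution or annotation biases of any real knowledgebase release, and
the long-tailed heterogeneity of real pathway sizes. Passing tests on
synthetic data therefore demonstrate the correctness of the machinery and
the qualitative motif behaviour, not quantitative agreement with any
particular database version — reproducing version-pinned numbers requires
extracting the corresponding participant table and feeding it through the
same functions.

## Extraction

`extract_participant_table()` walks a knowledgebase store through a
deliberately narrow read-only interface: events with species labels,
containment edges, and per-reaction role slots holding entity trees. The
in-memory `reactome_store()` implements the interface for tests and
desk-scale work; a live graph-database export can be materialized into
the same structure by any client. Containment cycles are broken with a
depth-first visited-set guard (warning per dropped edge); all regulation
subtypes map to the single REGULATOR role; each reaction's rows are
emitted once, under its first containing pathway, with full membership
kept in the hierarchy — so a reaction shared by several pathways cannot
spuriously inflate self-interaction flags.

## Numerical and interface conventions

Networks, tables and exports are in deterministic sorted order
throughout; writers are byte-stable, and `run_pipeline()` stamps every
TSV with input/config hashes and the seed, so identical runs are
byte-identical. Empty networks, edgeless percolation input and malformed
tables fail fast with row-level error messages. Degrees, shares and
percentages are computed on exact integer counts; the percentile ribbon
uses the default quantile estimator. Problem sizes used by the test suite
(random graphs up to 200 nodes for oracle equivalence, 50 small synthetic
datasets for the quotient identity, a 2000-node random graph for the
percolation control) were chosen as the package's own desk-scale testing
conditions.

## Known limitations

* Identifier semantics are taken from the input table as ground truth; no
  remapping against live UniProt/ChEBI/HGNC services is attempted, and
  canonical-isoform strings are deliberately not merged with bare
  accessions (both spellings are reported).
* Edges are untyped and undirected; no hypergraph, role-typed or directed
  representation is offered.
* The topology battery stops at the metrics above — no centrality
  measures beyond articulation points, no disease-module or druggability
  analyses.
* Only link (edge) percolation is implemented; site percolation and
  targeted attack curves are out of scope.
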