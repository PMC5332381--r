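---
title: "Classifying plant gene families into orthogroups: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying plant gene families into orthogroups: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogfamily)
```

## The problem

Transferring functional knowledge from model plants to crops requires knowing
which genes are orthologs — descendants of one ancestral gene at a chosen
reference speciation event. For multigene families such as plant
transcription factors this is hard: lineages duplicate genes (tandem and
segmental events), lose them (sometimes across whole orders), and evolve at
different rates. `ogfamily` implements a desk-scale pipeline for this
classification task, built around the GRAS transcription-factor family in an
eight-species angiosperm panel (three monocots, four dicots, and
*Amborella trichopoda* as basal outgroup), with the monocot/dicot split as the
reference event: an orthogroup (OG) is the set of genes descending from one
ancestral gene present at that split.

## Orthogroup inference

Similarity comes from an exact affine-gap pairwise aligner
(Needleman–Wunsch and Smith–Waterman, Gotoh three-state recurrences,
implemented in C++). The defaults are BLOSUM62 with gap open 10 / extend 0.5,
a gap of length $L$ costing $\mathrm{open} + (L-1)\,\mathrm{extend}$; `X`
scores 0 against everything; percent identity and similarity use the full
alignment length as denominator (gap columns included), with similarity
counting columns whose substitution score is positive. Traceback ties resolve
in the fixed order match/mismatch, gap-in-first, gap-in-second, so alignments
are deterministic. Raw local score, not an E-value, ranks hits: at family
scale (a few hundred sequences) score ranking is equivalent for best-hit
decisions and keeps the engine parameter-light.

`build_orthogroups()` proceeds in four deterministic stages:

1. **Cores.** Reciprocal best hits (RBH) between valid-status genes of the
   non-basal species form a graph; connected components are the OG cores.
2. **In-paralog absorption.** An unplaced gene joins the OG of its top
   cross-species hit when that score is at least `in_paralog_ratio`
   (default 0.8) times the core's median intra-core cross-species score.
   Within-species duplicates arising after the reference split are absorbed
   this way. Pseudogene/remnant records never seed cores but are attached by
   the same rule so count matrices can flag them.
3. **Outgroup attachment.** Basal-species genes attach to the OG of their top
   non-basal hit when at least one member reciprocates (has the basal gene as
   its best basal-species hit); otherwise they stay unassigned — ancient
   basal-specific duplicates legitimately remain outside every OG.
4. **Manual overrides.** A (gene, OG) table is honoured last with
   `provenance = "manual"`, so a published curation can be reproduced
   exactly on top of the automated approximation.

`classify_query()` turns a curated reference set into a diagnostic: a query
is assigned to the OG of its top hit when (i) the margin over the best hit in
any other OG is at least 5% of the top score, (ii) reciprocity holds within
the query's species — the query ranks in the member's top *k* = 3 hits among
that species' reference genes once members of the candidate OG itself are set
aside, since in-paralogs of the candidate OG outranking the query corroborate
rather than contradict membership — and (iii) the top score clears a
composition-matched null (20 within-query shuffles re-scored against the
whole reference, z ≥ 3). The third condition exists because margins between
chance scores are relatively large: without an absolute floor, a shuffled
sequence of realistic composition can pass the margin rule.

## Count matrices and lineage losses

The OG-by-species count matrix mirrors the printed-table dialect of the
family literature: integer counts, `*` marking remnants (degraded copies
detectable in the genome but not annotated as gene models), `-`/`−` for
absence, and outgroup-specific rows that are excluded from OG counting while
their genes still count in species totals — the only reading under which a
table can simultaneously report its grand total, per-species totals, and OG
count consistently. Remnant cells count as *presence* for loss calling (a
remnant proves the gene existed) but contribute their integer count to
totals.

`call_losses()` emits, per OG, the maximal clades (taxonomy internal nodes,
registry orders/families, or single species) whose sampled species all lack
the gene. A declarative evidence table — standing in for database searches
across wider taxon sets, so the pipeline stays offline and deterministic —
can lift a call to a wider clade (absence confirmed beyond the panel) or
restrict it to a narrower one (a sister lineage inside the called clade
retains the gene).

`missing_og_count()` counts a species' empty OGs. By default every
zero/no-remnant cell counts, which makes the count equal the number of loss
calls covering the species. With a registry it excludes OGs missing across
the species' entire lineage class (all sampled monocots or dicots): such
absences belong to the wider clade, which is how per-species missing counts
are reported in the family literature.

## Conserved blocks, trees, and consistency checks

`select_blocks()` applies relaxed Gblocks-style criteria: a column is
conserved when its modal residue frequency (among non-gap residues) reaches
`min_conserved_frac` (0.5) and its gap content passes `gap_policy`
(default `half`, at most 50% gaps); candidate blocks split at runs of more
than `max_nonconserved_run` (8) non-conserved columns, are trimmed to
admissible flanks, and must reach `min_block_length` (5). These defaults
encode small final blocks, gaps within blocks, and less strict flanks; the
exact numeric mapping of any particular external Gblocks run is not
recoverable, so kept-column *counts* are never asserted — only structural
properties (monotonicity in the threshold, recovery of planted conserved
segments).

Distances are p-distances over kept, mutually ungapped columns, optionally
Poisson-corrected ($d = -\ln(1-p)$). `nj_tree()` is a from-scratch
neighbor-joining implementation — exact on additive matrices, deterministic
tie-breaks by smallest leaf-label pair, negative branch lengths clamped to
zero with the deficit moved to the sibling — cross-checked in the tests
against `ape::nj`. Branch support is the bootstrap proportion of replicate
NJ trees containing each internal split of the full-data tree; this
substitutes for likelihood-based support (aLRT) deliberately: the package's
claims are consistency and recovery properties, not likelihoods, and an
adapter accepts externally computed Newick trees wherever a support tree is
consumed. Alignments themselves are accepted from external tools (or taken
as the simulator's true alignment); no progressive aligner is implemented
because alignment heuristics are not this pipeline's subject.

`check_og_monophyly()` reports whether each OG's leaves form a clade (some
edge separates exactly that leaf set), with offending leaves identified via
the best-matching bipartition side (most members, fewest intruders).
`lba_probe()` operationalises the leave-one-out check for long-branch
attraction: rebuild the tree without the longest-branch leaf other than the
focal gene and flag the focal gene if its sister group changes.

## N-terminal motifs

GRAS-like proteins pair a conserved C-terminal domain with a hypervariable,
intrinsically disordered N-terminus that nevertheless carries short
OG-specific conserved motifs. `find_motifs()` is a ZOOPS
(zero-or-one-occurrence-per-sequence) EM motif finder: per candidate width,
EM restarts from the ten highest-scoring distinct w-mers
(pseudocount 0.01 per residue, site prior γ initialised at 0.8); the width is
chosen by a BIC-penalised log-likelihood-ratio so widths compete fairly; and
a motif is only emitted when its objective exceeds a within-sequence shuffle
null (100 shuffles, z ≥ 3). The shuffle null replaces analytic E-values — at
a dozen sequences per OG an empirical null is both simpler and honest about
the background model. The EM objective (the MAP objective including the
Dirichlet pseudocount prior) is asserted non-decreasing at every iteration.

The N-terminal boundary for motif scanning comes from `domain_start` when a
record carries one, otherwise from an anchor alignment via
`anchor_domain_start()`: the least-squares change point of the per-column
conservation profile, snapped to the first kept block column after it. A
change point is used rather than the first kept column directly because
chance-conserved columns in the hypervariable region bias block starts by
up to ~20 residues, while the change point tracks the architectural boundary
to within a few residues on simulated data.

## Subfamilies and naming

Subfamilies group OGs whose representatives (the member with the smallest
mean within-OG distance) form supported, shallow clades: support at least
`support_min` (0.9) and leaf-path diameter at most `depth_max` (default the
75th percentile of pairwise representative distances). These thresholds are
openly arbitrary rank conventions, recorded in the output provenance, not
biological claims. Naming follows the family convention: singleton
subfamilies use the bare literature name (`OG-DLT`); multi-OG subfamilies
suffix a hyphen and number (`OG-SCR-1`, `-2`, …) ordered by descending size
then smallest member id, with a pinning table available to reproduce
published numberings (e.g. keeping the classic members in `-1`). Stripping
those suffixes — Arabic *and* Roman, since historical labels like `HAM-I/II`
use Roman numerals — recovers the subfamily partition from labels alone.

## The simulator

`simulate_dataset()` generates the statistical structure the analysis
assumes, plus full ground truth (gene-to-OG map, count matrix, gene trees,
event log, domain boundaries, motif sites):

* a fixed eight-species tree with a basal outgroup and a monocot/dicot split
  (root-to-tip depth ≈ 1.2–1.5 substitutions/site at unit rate);
* 29 ancestral root genes, each evolving down the tree under a branchwise
  birth–death process (exponential waiting times; duplication 0.1 and loss
  0.15 per gene per unit branch length by default), with duplications
  labelled tandem or segmental for the event log;
* one root gene (by default the last) with a 15-fold elevated duplication
  rate, emulating the family's single strongly expanding orthogroup; this
  calibration makes that OG the largest in ≈ 92% of replicates at a size
  (~42 genes) comparable to the real expansion, and is the one place where
  the default config intentionally departs from uniform rates — recovery
  benchmarks that state uniform rates disable it (`hot_og = NA`);
* two-region proteins: an N-terminus (30–60 aa) evolving 3× faster than the
  domain (110–150 aa) under the LG replacement model, no indels in the
  domain, optional geometric indels in the N-terminus (off by default).
  These lengths are deliberately shorter than real GRAS proteins
  (360–850 aa): the properties under test — reciprocal-best-hit structure,
  block selection, boundary estimation, motif recovery — depend on the
  two-region architecture and rate contrast, not on absolute length, and the
  shorter proteins keep a 25-replicate benchmark tractable on one core;
* plantable N-terminal motifs with configurable carrier fraction and
  per-site mutation probability, non-carriers recorded as ground-truth
  exceptions;
* forced clade-wide losses applied after the stochastic events, emulating
  order-level absences.

What the simulator does **not** model — whole-genome duplications (the γ
hexaploidy analysis is out of scope), indel realism inside the domain, codon
structure, selection, annotation error — bounds what green tests mean:
passing recovery benchmarks show the pipeline inverts its own generative
assumptions at realistic rates, not that it would survive every artifact of
real proteome annotation. The real curated family (manual gene-model
correction included) is exactly the situation where the manual-overrides
path exists.

## Numerical and degenerate-input choices

* All residue indices are 1-based inclusive at interfaces.
* NJ Q-matrix ties break by smallest leaf-label pair; identical inputs give
  identical trees, partitions and motif models (seeds fixed, RNG state
  restored where internal nulls are drawn).
* Poisson correction refuses saturated pairs ($p = 1$) rather than returning
  infinity; pairs with no comparable kept columns are an error, not a guess.
* Empty FASTA files load as empty record sets with a warning; empty
  N-terminal regions are returned empty with a warning.
* Bare `*` count-matrix cells (remnant with no gene model) parse as count 0
  with the remnant flag, so presence and gene count stay distinct queries.

## Problem sizes used by the checks

The packaged test suite and `scripts/acceptance.R` run, per invocation:
25-replicate orthogroup-recovery benchmarks (~250 genes, ~190 aa each,
all-vs-all alignment in C++), 20 random additive matrices up to 10 taxa,
12-sequence motif recovery with a 100-shuffle null and 20 shuffled controls,
and exhaustive alignment-path enumeration for sequence pairs up to length 7.
These sizes were chosen as the smallest at which the statistical claims are
meaningful rather than anecdotal.

## Known limitations

* RBH cores fragment inside strongly expanded orthogroups (many in-paralogs
  per species); the published analyses resolve such cases by curation, which
  the manual-overrides path supports but does not replace.
* Loss calls are qualitative presence/absence statements against sampled
  species plus declarative evidence; no probabilistic ancestral
  reconstruction is attempted.
* Bootstrap proportions are not aLRT values; numeric support thresholds from
  likelihood-based analyses should be treated as qualitative anchors only.
* The motif finder is ZOOPS-only by design: OG-level N-terminal motifs occur
  at most once per sequence; repeated or palindromic motifs are out of scope.
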