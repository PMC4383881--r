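---
title: "Terminus annotation, protease enrichment and protease-web path finding"
author: "termikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Terminus annotation, protease enrichment and protease-web path finding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termikit)
```

## The biological problem

A mature protein chain is delimited by its N- and C-termini, and those
termini are informative: a terminus can be the genome-encoded canonical
start, the product of an alternative transcript or an alternative
translation-initiation site, or a *neo*-terminus created when a protease
cleaves the chain. Terminomics experiments (TAILS and related N-terminal
enrichment methods) deliver lists of hundreds to thousands of terminal
peptides from a tissue; interpreting them requires (i) deciding, per
terminus, which process generated it, and (ii) deciding which protease
activities dominate the sample. Because proteases cleave other proteases
and protease inhibitors, a protease can also shape the degradome
*indirectly*; explaining an observed cleavage may require a path through
this "protease web" rather than a direct enzyme–substrate pair.

`termikit` implements both analyses over a self-contained flat-file
knowledgebase, with a seeded synthetic-data generator standing in for a
curated database so that every statistical property of the pipeline can be
verified against planted ground truth.

## Coordinate conventions

All residue positions are 1-based indices into the protein sequence. A
cleavage event is identified by its P1 residue: the scissile bond lies
between P1 and P1+1, so the cleavage creates a neo-N-terminus at P1+1 and a
neo-C-terminus at P1. This makes "the position of a cleavage" a single
integer and aligns with protease nomenclature (P1/P1′).

## Terminus classification

Each query peptide is located on its protein by exact substring search
(`locate_terminus()`); zero hits or multiple hits are reported as
`not_found` / `ambiguous` rather than guessed at. A located terminus is
then classified (`classify_terminus()`) by matching knowledgebase entries
on the same protein and terminus type:

* terminus evidences of category canonical / alt_splicing /
  alt_translation / experimental assign the corresponding category;
* cleavage events matching by the P1 convention assign `cleaved`, together
  with the responsible protease(s);
* evidences inferred across isoforms contribute the category of their
  source evidence.

**The ragging window.** Processive exopeptidase trimming ("ragging")
produces clusters of termini a few residues away from the true processing
site. Matching therefore tolerates a user-definable offset of 0–10
residues (`window`, default 0). The window is applied symmetrically to
evidence positions and cleavage P1s, and matching is monotone: enlarging
the window can only add categories, never remove them (a tested
invariant). Each (terminus, protease) pair counts once toward the
enrichment statistics regardless of how many sites of that protease fall
inside the window.

## The enrichment model

Knowledgebases annotate prolific proteases (collagenases, cathepsins) with
hundreds of substrates, so raw attribution counts are biased toward
well-studied enzymes. The enrichment test corrects for this by comparing
the list attribution share against the database share on the same
proteins. For each identified protease:

| symbol | meaning |
|---|---|
| `k` | cleavage-derived list termini attributed to the protease |
| `n` | all cleavage-derived list termini (each counted once) |
| `K` | distinct KB sites (substrate, P1) of the protease on the list's proteins |
| `M` | distinct KB sites on the list's proteins by any identified protease |

A site attributed to two proteases counts once in `M` but contributes to
both proteases' `K`; likewise a terminus matched by two proteases counts
once in `n` but in both `k`s. These double-counting rules are forced by
the published table this implementation reproduces (its column sums exceed
the printed totals). The p-value is the one-sided enrichment tail of the
Fisher exact test on `[[k, n−k], [K, M−K]]`, computed as the
hypergeometric upper tail `phyper(k − 1, k + K, n + M − k − K, n,
lower.tail = FALSE)`; q-values are Benjamini–Hochberg over the identified
proteases. Fold enrichment is `(k/n)/(K/M)` and fold coverage `k/K` — the
fraction of the protease's known repertoire on these proteins that the
experiment observed.

The contingency-table construction and sidedness were validated against
the five published rows that exercise all regimes (strong enrichment,
depletion, singleton counts); the test suite asserts the full 13-row table
at printed precision and checks the tail computation against an exhaustive
fixed-margin enumeration over all tables with total ≤ 40 to 12
significant digits.

Report files round folds half-up to 2 decimals and print p/q to 3
significant figures in scientific notation, matching the published
presentation (half-up matters: 2/16 = 0.125 prints as 0.13). Full
precision is kept internally.

## Isoform and cross-sequence mapping

Isoforms share most of their sequence with their canonical parent but
differ by indels, so positions do not transfer directly. Every terminus
evidence and cleavage is mapped by its local sequence context: the 20
residues following an N-terminus, preceding a C-terminus, or flanking a
scissile bond (10 per side), truncated at protein ends. A context maps
only if it occurs **exactly once** in the target sequence; multiple
matches are ambiguous and skipped, because silent multi-mapping would
corrupt positions. Windows shorter than 8 residues (very short proteins)
are skipped as `window_too_short` — an 8-mer is the shortest window whose
chance occurrence in a proteome-scale target is negligible, and the
mapping report records every skip. Contexts spanning an isoform's indel
cannot match and are reported `unmapped`. Propagation only maps original
(non-inferred) entries and deduplicates against existing rows, so it is
idempotent.

The same exact-window logic places termini from transcript products
(`map_transcript_termini()`: first/last 20-mers, category alt_splicing)
and from translation-initiation sites (`map_tis_n_terminus()`, category
alt_translation). Nucleotide handling is reduced to accepting a
pre-translated ≤20-residue window (`translate_cds()` is provided for
supplied coding sequences); transcript databases are not fetched.

## The sequence logo

Residues at offsets −span..+span (default span 8, offset 0 = the terminal
residue) around each located terminus are tallied, excluding termini whose
only categories are translational (canonical / alternative translation),
since genome-encoded starts say nothing about protease specificity. Per
offset and residue the observed fraction is compared with a background
frequency — by default the residue composition of all knowledgebase
sequences, overridable — using a two-sided exact binomial test; cells with
p < `alpha` (default 0.05) are flagged, with the direction of departure
recorded. The exact test is slightly conservative for discrete counts; the
suite verifies that under a true null the flagged fraction stays within 3
binomial standard errors of `alpha` over > 1000 cells.

## The protease web and the path grammar

Cleavage edges (protease → substrate, carrying P1) and inhibition edges
(inhibitor → protease) form a typed directed multigraph. Which edge
sequences constitute a meaningful indirect explanation is a modelling
choice; this package admits exactly:

* chains of cleavages (each cleaved protease acts next), and
* cleave–inhibit–cleave relays: cleaving an inhibitor perturbs its
  inhibition, so an inhibition edge may be traversed only immediately
  after its inhibitor was cleaved, and must be followed by a cleavage by
  the inhibited protease.

Inhibit-first and inhibit-last paths are meaningless under this reading
and are excluded. Paths are node-simple (cyclic explanations are unbounded
and uninformative) and bounded at `max_length = 4` edges by default —
enough for every published relay example while keeping exhaustive
enumeration tractable. The final edge must be a cleavage into the target;
when an observed terminus position is supplied, the edge's P1 must lie
within the ragging window of the implied P1 (`--any-position` relaxes
this, since the original tool's behaviour on this point is not
documented). The query protease is additionally connected to every list
protein by an *inferred* (dotted, in DOT output) edge at the observed
position; a path consisting solely of that single inferred edge is
reported as *hypothesized-direct*, not as an explanation — an explanation
must contain at least one knowledgebase edge. Enumeration is exhaustive
with a hard cap of 10 000 paths per target (flagged when hit); its output
is verified edge-for-edge against an independent generate-and-filter
enumeration on 100 random webs.

Cross-species mapping replaces the query protease and each target by their
one-to-one ortholog (one-to-many clusters reduced to the highest-scoring
pair at lookup, ties by accession); targets without an ortholog are
dropped and reported, and carried-over positions are flagged approximate
because residue numbering is species-specific.

## The synthetic knowledgebase

`generate_kb()` emulates the features of curated terminus databases that
the engines depend on: random protein sequences (default 100 proteins,
length 300 ± 20%, uniform residue frequencies — overridable so logo tests
can plant biased nulls); canonical N/C terminus evidences; distinct
cleavage events with P1 at least 20 residues from either end so every
context window and neo-terminal peptide is extractable (default 300
events over 10 proteases, i.e. each protease holds ≈10% of sites); a 10%
fraction of sites shared between two proteases, mirroring the
caspase-3/-7-style substrate overlap in curated data; inhibitor→protease
events; and isoforms derived by a single internal indel of 1–15 residues
placed ≥ 25 residues from both termini, which keeps every terminal context
unambiguous and makes propagation tests deterministic.
`generate_query_list()` plants an enrichment signal: a chosen fraction
(default 0.5 of a 100-peptide list) of 10-residue neo-terminal peptides
from one protease's sites, the rest canonical starts and random internal
positions. All generation flows through a single integer seed
(Mersenne–Twister with pinned sampling kind), and the same seed yields a
byte-identical serialized knowledgebase.

What the generator does **not** emulate: real cleavage-site sequence
specificity (no PSSMs), non-uniform substrate degree distributions,
evidence-confidence structure, or homology between proteins. Passing the
planted-recovery and calibration tests therefore demonstrates the
statistics are computed correctly under controlled conditions, not that
any particular biological claim holds on real data.

## Numerical and design choices

* Fisher tail via `phyper` (log-stable); BH via `p.adjust`; both are
  cross-checked in the suite against independent enumeration /
  step-up-definition oracles.
* Exact substring matching via Biostrings, which reports overlapping
  occurrences; a naive scan oracle guards it in tests.
* Deterministic tie-breaks everywhere a display order is needed: the
  substrate×protease matrix orders rows/columns by descending marginal
  totals, ties by accession then position (a deterministic stand-in for
  hierarchical clustering, which is cosmetic here); DOT output sorts nodes
  and edges; path lists sort by length then node sequence.
* Degenerate inputs are data, not crashes: unresolvable accessions,
  unlocatable or ambiguous peptides and malformed rows become status
  values in the annotation table; an empty cleaved set yields an empty
  enrichment table with a diagnostic.
* Evidence confidence values are carried and can filter at load
  (`min_confidence`) but do not enter the statistics — evidence filtering
  is an interactive-curation concern, not part of the tests.
* Query-derived evidence is not deduplicated from the knowledgebase
  background (whether the original resource did so is undocumented), and
  enrichment is computed over whichever terminus types appear in the list.

## Validation problem sizes

The shipped suite reproduces the 13-row published enrichment table at
printed precision; checks the Fisher tail exhaustively over all 2×2 tables
with total ≤ 40; verifies path enumeration against an independent oracle
on 100 random webs (≤ 10 nodes, ≤ 25 edges, path bounds 1–5); recovers a
planted protease (50% of a 100-peptide list over a 100-protein, 10-protease
knowledgebase) with minimum q < 0.05 in ≥ 90% of 50 seeds; validates
isoform propagation on 200 canonical/isoform pairs; and calibrates logo
significance on > 1000 null cells. These sizes were chosen as the smallest
that exercise every code path with stable statistics.

## Known limitations

* Exact matching only: no fuzzy isoform alignment, no splice-graph or
  genome coordinates.
* The knowledgebase is in-memory; it is designed for organism-scale
  curated data, not for millions of rows.
* Path semantics are qualitative — no rates, abundances or quantitative
  network modelling; inhibition is treated as a traversable link, not a
  modelled equilibrium.
* The logo uses per-cell binomial tests without multiplicity correction,
  as is conventional for frequency-difference logos; flagged cells are
  descriptive, not inferential.
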