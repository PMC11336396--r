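---
title: "Molecular diagnoses for sequence-based taxonomy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular diagnoses for sequence-based taxonomy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnadiag)
```

Many fungal lineages — arbuscular mycorrhizal fungi are the motivating
case — are documented almost entirely by environmental rRNA sequences.
Describing species and higher taxa for them shifts the diagnostic burden
from morphology to nucleotides: a diagnosis becomes a short barcode, a
pair of coordinates and a mismatch allowance that any reader can check
against a reference alignment. This vignette explains the models and
rules `dnadiag` implements, the parameters that matter, and the limits
of what its synthetic tests demonstrate.

## The barcode diagnosis model

All computation happens on a fixed multiple sequence alignment whose
rows carry taxonomy labels and whose columns are partitioned into marker
regions (ITS1, 5.8S, ITS2, LSU). For a target taxon, one designated
sequence — the lectotype, by default the first target row — is the
*canonical* sequence; the barcode printed in a diagnosis is always a
concrete substring of it, never a consensus with ambiguity codes,
because a diagnosis must be a checkable literal string.

For a candidate window (a run of 20–30 alignment columns inside one
region) define

* `d_in`: the maximum Hamming distance from the canonical window to any
  target sequence over those columns, and
* `d_out`: the minimum Hamming distance to any non-target sequence,

where a gap-versus-base column counts as a difference, gap-versus-gap
does not, and ambiguity codes match leniently when their IUPAC sets
intersect. A sequence is *attributed* to the target when it matches the
barcode with at most `k` mismatches; any

\[ k \in [d_{in},\; d_{out} - 1] \]

separates every target sequence from every relative in the alignment. A
window qualifies as diagnostic when the target carries **no** ambiguity
code inside it, `d_out >= min_sep` (default 2 differences — a
single-base difference is too fragile a character), and the interval
above is non-empty. Among qualifying windows the *margin*
`d_out - d_in` measures how characteristic the barcode is, and windows
are ranked by margin (descending), then fewer gap columns in the
canonical window, then leftmost start, then shorter length. The margin
is the scientific criterion; the remaining tie-breaks are reporting
conventions chosen for determinism (prefer barcodes that read cleanly
off the lectotype, earliest in the region, as short as possible) and are
not claimed to be part of any published rule.

Both the full interval and a single *reported* allowance are emitted.
The reported value is capped at 1 by default, following the convention
of quoting "no mismatch allowed" or "one mismatch allowed": a reader
checking a diagnosis wants a small number, and allowances above 1 add
little discriminatory comfort while inviting transcription drift. The
cap never forces the reported value below `d_in`.

Positions are printed 1-based and region-relative on the *degapped*
canonical sequence ("ITS2 positions 127–146 …"), while all internal
computation is alignment-column based; `column_to_region_position()` and
`region_position_to_column()` convert explicitly, and round-trip
identically on every non-gap site.

`validate_diagnosis()` runs the reverse check — every target within the
allowance, every non-target beyond it, coordinates consistent with the
barcode length — and *flags* failures rather than correcting them. This
matters for the packaged transcription of 29 published diagnosis
fragments (`load_printed_diagnoses()`): two fragments print coordinate
spans that do not match their barcode lengths, and one 30-base barcode
string appears verbatim under two different genera. Which of positions
or string is authoritative there cannot be decided from the published
material, so the package stores both and reports the inconsistency.

## Within-species variability

Descriptions quote the maximum pairwise proportion of differences among
a species' sequences per region (e.g. ITS sequences differing by up to
a few percent). `within_group_variability()` computes exactly that: the
maximum, over all member pairs, of the p-distance on comparable columns.
Contiguous gap runs longer than `max_indel = 20` columns are excluded
from the comparison entirely — a single long deletion is one mutational
event and would otherwise swamp the per-column signal (the same
convention excludes, e.g., a 29-base deletion from a published
estimate); the excluded runs are reported alongside the estimate.
Whether columns containing ambiguity codes should also be dropped is not
settled by the published material, so it is exposed as
`ambig = c("lenient", "strict", "exclude")` rather than fixed.

`estimate_species_count()` approximates the number of potential species
in a genus by single-linkage clustering at a p-distance threshold. The
default 0.03 on ITS is this package's choice — published counts of this
kind rest on visual assessment, not a stated cutoff — and the threshold
is always reported next to the result.

## Delimiting higher taxa

Higher taxa are delimited on a support-annotated phylogeny as
*least-inclusive clades*: the smallest clade (MRCA subtree) containing a
given accession set. `propose_taxa()` partitions the unlabelled leaves
into candidate taxa that each satisfy

1. monophyly (the clade contains only unlabelled leaves),
2. bootstrap support strictly above 95,
3. phylogenetic breadth comparable to reference taxa of the same rank,
4. and minimality of the number of new taxa.

"Phylogenetic breadth" has no standard operationalisation; this package
uses the maximum within-clade patristic distance, with an acceptance
band of 0.5× the smallest to 2× the largest reference breadth. Both the
metric and the band are configurable and always reported with the
output. Nodes without a support value fail criterion 2 by default
(conservative; `absent_support = "pass"` relaxes it), and single leaves
pass support trivially but must still fit the breadth band.

Criterion 4 is implemented greedily from the root: the first qualifying
node on any root-to-leaf path is accepted and its subtree skipped.
Because the qualifying clades of a tree form a nested (laminar) family,
every qualifying node is either accepted or lies under an accepted one;
a short exchange argument then shows the greedy partition covers every
coverable leaf with the minimum possible number of clades. The test
suite still verifies this against an exhaustive search over all disjoint
covers on trees of up to 12 leaves rather than trusting the argument.

Accepted candidates receive stable alphanumeric codes ordered by their
smallest member accession — `GEN01`, `FAM02`, or `GS22`-style when an
order-level prefix is configured — for preliminary communication before
formal names exist. Trees are used exactly as given: no re-rooting, no
support recomputation.

## Primer screening

`best_site()` places a primer at the position of its template (reverse
primers: the reverse complement) minimising the number of
IUPAC-incompatible positions, where a primer code covers a template base
when the base's set is a subset of the primer's set. Mismatch positions
are indexed from the 3′ end — position 1 is the extension-critical
terminal base — and classified terminal (position 1), near-terminal
(positions 2–3 by default; no standard definition of "near-terminal"
exists, so the window is a parameter), or central. `group_summary()`
aggregates per lineage and issues a verdict: "matches well" when at
least 90 % of a group's sequences have at most one mismatch and none of
those mismatches is (near-)terminal. Per-sequence evaluation followed by
fraction thresholds stands in for reading mismatches off a group
consensus; the thresholds are stated in the output. The packaged primer
table carries the three primer sequences published with this marker
system (LF350End, LR3-End2, LR3-End2a); all other commonly screened
primers are named placeholder rows whose sequences the user must supply
from the literature — the package does not reproduce sequences it cannot
cite from its own inputs.

## The synthetic-data generator

`simulate_dataset()` emulates the data regime the pipeline targets:
a Yule species tree (optionally nested in a Yule genus tree) with small
coalescent tip clusters per species, branch lengths rescaled so that
mean pairwise distances hit the configured divergence targets through
the JC69 map \(p(t) = \tfrac{3}{4}(1 - e^{-4t/3})\). Defaults — 10
species × 5 sequences, ITS1/5.8S/ITS2/LSU lengths 120/160/250/600,
within-species divergence 1 % (real intraspecific ITS variability in
these groups spans roughly 0.5–4 %), between-species 10 % — describe a
typical congeneric reference alignment. Sequences evolve site-wise under
JC69 from a uniform root; indel runs are laid down afterwards as aligned
gap runs (mean length 6, Poisson rate 0.5 per sequence), and rare
ambiguity codes (rate 0.001) replace a base with a code containing it.
JC69 is deliberately the simplest adequate model: every statistic the
pipeline computes is distance-based, and none depends on base
composition or rate heterogeneity. The model slot is an enum with one
implemented member so richer models can be added without interface
change.

`plant_barcode()` creates ground-truth diagnostic signal: a gap-free
window is chosen, all target sequences are set to a motif derived from
the canonical window with `min_separation` positions changed (preferring
a base absent from that column in the whole alignment), and any
non-target still closer than `min_separation` differences is minimally
edited away. Every simulation emits a truth record — species map,
planted window, realized within-species divergences computed by an
independent plain-loop implementation — that the loader cross-validates
against the alignment on read.

What the simulator does *not* model: rRNA secondary structure,
among-site rate variation, microsatellite/homopolymer slippage,
chimeras, and alignment error (it emits alignments directly, so
misalignment never occurs). Passing tests therefore demonstrate the
correctness of the selection, delimitation and screening machinery under
clean alignments — not robustness to alignment artefacts, which real
ITS data — often riddled with microsatellite-like repeats and
homopolymers — will present.

## Verification strategy and problem sizes

The package's guarantees are checked end to end (`tests/testthat/` and
`scripts/acceptance.R`):

* the window selector is compared against an independent brute-force
  enumerator (all windows, plain character loops, same filters and
  ranking) on 100 random alignments of up to 20 sequences × 160 columns;
* planted 25-base motifs with separation ≥ 3 are recovered on 100 seeded
  simulations at the default 10 × 5 design. These cases use a low
  between-species divergence (2 %, within-species 0.5 %) so that
  background windows separate by at most ~1 difference — the premise
  under which the planted motif is *the* signal; under the default 10 %
  divergence, genuine natural barcodes frequently outrank a minimally
  planted one, which is correct behaviour but tests nothing;
* the simulator's per-site divergence at *t* = 0.1 is compared with the
  closed-form 0.0936 over 10,000 sites;
* all 29 packaged printed diagnosis fragments must be reproduced
  character for character from their parsed parameters;
* the greedy clade partition is compared with an exhaustive minimal
  disjoint cover on trees of up to 12 leaves;
* `within_group_variability()` must equal the simulator's independently
  computed truth records exactly (within 1e-12).

These sizes keep the default check suite to roughly a minute while
exercising every code path at the scale the properties are stated for.

## Numerical and degenerate-input conventions

* Case is folded to upper on read; `U` maps to `T`; the gap character is
  `-`. Ragged alignments and non-IUPAC characters are hard errors naming
  the offending record and column.
* Distances are undefined (an error, never silently 0) when no
  comparable columns remain.
* A taxon with a single sequence reports variability 0 with an explicit
  `single_sequence` flag; species counting with one member returns one
  cluster.
* Regions shorter than the minimum window length yield an empty window
  set with a warning; a region scan with no qualifying window returns a
  machine-readable rejection (reason and best margin achieved), not an
  error.
* All simulation randomness flows from a single mandatory integer seed;
  reruns are byte-identical, and the pipeline commands write resolved
  configuration and input checksums next to their outputs.

## Known limitations

* The comparison set for a diagnosis is whatever alignment the caller
  supplies; scoping "closely related species" is a curation decision the
  package does not automate.
* Exact minimality of the clade partition is guaranteed by the laminar
  structure of qualifying clades and verified exhaustively only at small
  scale; the breadth metric and calibration band are package choices, as
  published criteria name the concept but not the measure.
* Primer verdicts aggregate per-sequence placements; they approximate,
  but are not identical to, reading a group consensus.
* Multi-window combinatorial diagnoses, probabilistic barcode
  optimality, and unaligned sliding-window search are out of scope by
  design.
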