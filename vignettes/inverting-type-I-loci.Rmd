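---
title: "Detecting inverting Type I restriction-modification loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting inverting Type I restriction-modification loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irscan)
```

## The biology and the search problem

A Type I restriction–modification system methylates (or, unmethylated,
cleaves) DNA at a bipartite motif read by the specificity subunit HsdS.
HsdS is two-domain: a 5′ and a 3′ target recognition domain (TRD), each
recognising half the motif. In several bacterial lineages the *hsdS* locus
is a shufflon: next to the expressed gene lies at least one silent,
inverted *hsdS* copy carrying alternative TRDs, and the copies share
identical sequence blocks — inverted repeats (IRs) — positioned ahead of
the 5′-TRD and between the two TRDs. Site-specific recombination between
an IR and its inverted copy swaps the intervening TRD between the
expressed and silent gene, changing the methylation motif of the whole
system at a stroke. Because methyltransferase specificity can control the
expression of many unrelated genes (a phasevarion), finding these loci
matters for understanding phase variation and for vaccine antigen
stability.

Operationally, an inverting locus leaves a clean sequence signature: a
segment of the expressed *hsdS* whose reverse complement occurs nearby,
inside a second *hsdS*. `irscan` searches for exactly that signature:

* **all** maximal inverted repeats between a gene and its flanks,
* at **100 % identity** — recombination between the repeats requires
  perfect homology, and allowing mismatches would flood a genome-scale
  survey with spurious hits,
* of length **≥ 20 bp** — comfortably above the shortest repeat (15 bp)
  known to recombine in the SpnD39III shufflon, whose repeat set
  (15, 85, 33 bp) calibrates the defaults here,
* within **30 kb** on each side of the gene — wide enough to span one
  Type I locus with several *hsdS* copies, narrow enough not to bridge
  two independent Type I systems.

## The detector

`find_inverted_repeats()` reports every maximal exact match between the
gene and the reverse complement of a flank window. The implementation is
seed-and-extend: the gene is tiled into `min_ir_len`-bp fragments
staggered by 1 bp; tiles are located in the transformed window by exact
hashing; each seed is extended along its diagonal in both directions
until the first mismatch or a sequence end; one hit is reported per
maximal diagonal run. With a 1-bp stagger a seed whose predecessor
`(a-1, b-1)` is also a seed lies inside the same run, so only run-start
seeds are extended — this makes every kept seed left-maximal by
construction and the search linear in practice.

Staged scans over bounded fragment sizes (first 20–500 bp, then
500–1500 bp) produce the same hits as direct extension to maximality,
capped at the largest fragment; extension is both simpler and exact, so
it is the implementation here, with `max_report_len` available to
reproduce a bounded-report mode. There is no upper length cap by
default.

Correctness is anchored by an independent oracle,
`brute_force_inverted_repeats()`: a dynamic program over the full
`gene × window` match matrix that reads maximal runs off the diagonals
(`L[i,j] = (L[i-1,j-1] + 1) · [a_i = b_j]`, recording runs ≥ `min_ir_len`
whose next diagonal cell breaks). The test suite asserts exact set
equality between the two on a thousand seeded random instances (genes up
to 1 kb, windows up to 2 kb, GC 0.25–0.75, half with planted repeats),
plus maximality, role symmetry, threshold-sensitivity and monotonicity
properties.

Numerical/degenerate-input conventions:

* Coordinates are 1-based inclusive everywhere a user sees them (GFF
  convention); BED export converts to 0-based half-open.
* Ambiguity codes, including N, are masked before matching (with
  different sentinels on the two sides), so no candidate overlapping an
  ambiguous base can ever satisfy the 100 % criterion — not even N
  against N.
* Nested hits (gene interval **and** partner interval both contained in
  another hit's) are removed by `filter_redundant()`; ties and orders are
  made deterministic by sorting on `(gene_start, partner_start)`.
* Windows are clamped at contig boundaries (logged, not an error), never
  span contigs, and exclude the gene body unless `include_gene_body` is
  set. A repeat straddling the window edge is truncated at the edge.
* Empty windows, genes shorter than `min_ir_len`, and `window = 0` all
  yield empty hit sets, not errors.

## Strand handling

An inverted repeat is a genome-frame notion: a gene-region segment whose
reverse complement occurs in the flank. The scan therefore runs on the
plus-strand gene sequence whatever the annotation strand, and for
minus-strand genes the gene-side coordinates of each hit are reflected
into coding orientation afterwards. This makes the reported hit set
invariant under re-stranding the locus, which the simulator verifies
seed by seed. Annotations that lack strand (as gene-table dumps often
do) are resolved by `locate_gene()`, which finds the unique exact
occurrence of the gene sequence on either strand and errors informatively
on zero or multiple occurrences. An asymmetric historical mode
(`legacy_strand = TRUE`) skips the coding-frame reflection for
minus-strand genes; it exists for fidelity comparisons only, because the
asymmetric behaviour is not well defined by any description we rely on.

## From hits to biology

`classify_locus()` calls a gene *inverting* when at least one hit's
partner interval overlaps, by at least one base, a second annotation
whose product label contains "hsdS". One base is deliberately permissive:
no fraction threshold is defensible a priori, and the follow-up fields
(partner id, silent flag, hit lengths) carry the evidence a curator
needs. When no labelled partner overlaps, repeats are *incidental* — the
category that catches, for example, long repeats flanking unrelated
mobile elements. Missing product labels degrade the call to incidental
with a warning rather than failing. The silent-partner check is
start-codon-only (first codon ≠ ATG in annotated orientation); promoter
prediction is out of scope and reported as not assessed.

`collate_identical_genes()` groups genes by exact sequence identity so a
locus annotated identically in many strains counts once;
`summarize_survey()` reports totals and the inverting percentage. The
percentage is **truncated**, not rounded, to one decimal (875 of 22,107
prints as 3.9 %, not 4.0 %), and the raw float is always carried
alongside the formatted string. `enumerate_alleles()` uses exact sequence
identity for TRD distinctness — no similarity threshold is implied by a
shufflon's mechanics — with labels A, B, C, … assigned row-major over
(5′-TRD, 3′-TRD) pairs; `combinatorial_states(m, a) = 2^m × a` counts the
methyltransferase-activity combinations available to a population that
also carries `m` biphasic ON/OFF *mod* genes.

## What the simulator emulates — and what it does not

`simulate_genome()` plants a five-gene locus
(`hsdR–hsdM–hsdS–hsdS′–recombinase`) in an i.i.d. background of
configurable GC. The expressed gene is
`ATG · pad · leaderIR · TRD5(v1) · midIR · TRD3(v1) · TAA`; the silent
copy sits on the opposite strand with a GTG start (encoding "no ATG" in
the simplest way) and variant-2 TRDs between identical copies of both
repeats. Defaults, chosen once: 85/33-bp repeats (the two ≥ 20-bp
SpnD39III repeat lengths), 450/420-bp TRDs (typical *hsdS* half-gene
scale), 2 × 2 TRD variants (the canonical four-allele locus), 150-bp
intergenic gaps, a 45-kb contig and GC 0.5. The base flanking every
planted repeat copy is forced to mismatch its counterpart, so each
planted pair is maximal at exactly the recorded coordinates and the truth
table can demand coordinate-exact recovery; for the same reason the
generator requires at least two variants per TRD (with a single shared
variant the repeats genuinely merge into one longer repeat, which is a
different fixture). Decoys stress each rejection rule separately: a
19-bp inverted copy (below threshold), a 30-bp copy with one central
mismatch (identity), a 60-bp copy 1 kb beyond the window (distance), and
a 60-bp direct copy (orientation).

The background is i.i.d., so planted repeats are the only expected
signal; real genomes carry repeat families, mobile elements and local
compositional structure that produce genuine incidental hits. Passing the
planted-recovery suite therefore demonstrates the detector's
correctness — exactness, maximality, thresholding, windowing — not that
every hit in a real genome marks an inverting locus; the
inverting/incidental classification and manual follow-up carry that
weight on real data, as the incidental category's known examples (long
repeats near unrelated genes) illustrate. The generator also produces
static locus states only; it does not model recombination dynamics or
switching rates.

## Problem sizes and determinism

The validation suite runs 1000 oracle-equivalence instances and 100
simulated-genome recoveries in about a minute on one CPU; these sizes
give every decoy class and both strands dozens of independent trials
while keeping the suite quick. All randomness is seeded: the simulator
restores the caller's RNG state, identical seeds give byte-identical
FASTA/GFF3/truth files, and identical inputs give byte-identical scan
outputs (stable sort orders throughout).

## Known limitations

* Only exact (100 %) repeats are found, by design; a mismatch-tolerant
  mode would need a different seed/extend scoring scheme and is out of
  scope.
* Gene location requires an exact full-length occurrence of the gene
  sequence; a gene split across contigs or carrying assembly errors is
  skipped (and counted) rather than fuzzily placed.
* TRD distinctness is exact identity; near-identical TRDs count as
  distinct. A clustering option would change allele counts and is left to
  downstream analysis.
* The silent-gene call inspects the start codon only; a silent copy with
  an ATG but no promoter will be flagged expressed-like.
* Multi-contig genomes are supported, but windows never span contig
  breaks, so repeats interrupted by an assembly gap are truncated or
  missed.
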