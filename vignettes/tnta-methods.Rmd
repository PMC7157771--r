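---
title: "Methods: detecting and analysing TA-carrying Tn3-family transposition modules"
author: "tnta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and analysing TA-carrying Tn3-family transposition modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures behind each stage of the
pipeline, the tunable parameters and their defaults, the design decisions
taken where several reasonable choices existed, what the synthetic-data
generator does and does not emulate, and the package's known limitations.

## The biological objects

Tn3-family transposons carry a transposition module of a large DDE
transposase gene (*tnpA*, ~1,000 aa product), a resolvase gene of one of
three types — serine recombinase *tnpR*, tyrosine recombinase *tnpI*, or
the heteromeric *tnpS*+*tnpT* pair — and a ~100–150 bp internal
resolution site (*res*, *irs* or *rst*) at which the cointegrate formed
during replicative transposition is resolved. TnpR-type *res* sites
consist of three subsites, I, II and III, each an imperfect inverted
repeat; subsite III lies next to *tnpR* and strand exchange occurs at an
AT dinucleotide inside subsite I. A subset of family members additionally
carries a type II toxin–antitoxin (TA) gene pair, characteristically
located immediately adjacent to *res* subsite I rather than out among
ordinary passenger genes. The package detects these modules, classifies
their gene arrangements, predicts the res subsites and crossover, looks
for recombination breakpoints where TA modules were exchanged between
transposons, and counts how often TA modules were independently acquired.

## Reference library and family assignment

Role and family labels (transposase subgroup; toxin families ParE, Gp49,
PIN_3, PIN, HEPN; antitoxin families ParD, RHH_6, HTH_37, Phd/YeFM, AbrB,
Mnt) are assigned by best local-alignment hit against a small labeled
exemplar library, not by profile-HMM search: a live HMM scan would tie
results to an external database release, whereas best-hit against bundled
exemplars is self-contained and deterministic. The metadata schema
reserves an `hmm_profile` column so an HMM backend can be slotted in; it
is unused and untested here. The bundled library is **synthetic**
(deterministically generated stand-in proteins with realistic lengths:
~1,000 aa transposases, ~185 aa serine resolvases, 85–150 aa toxins and
antitoxins, two related exemplars for some families). No curated exemplar
set is redistributed. Consequences: hits against the bundled library
validate the machinery (thresholding, clustering, labeling), not the
biological sensitivity of any particular exemplar choice; for real
screens users should point `load_reference_library()` at their own
curated FASTA + metadata directory.

## ORF calling

`find_orfs()` scans all six frames for ORFs from a start codon (ATG, GTG,
TTG) to the nearest in-frame stop under genetic code 11, reporting only
the longest ORF per stop (first start after the previous stop), with a
default minimum of 80 aa — long enough to cover the shortest toxin and
antitoxin families while suppressing most spurious background ORFs. ORFs
reaching the contig end without a stop are flagged `partial`; ORFs whose
span contains an N are skipped rather than guessed. An internal caller is
used instead of an external gene finder so that the package runs without
external binaries and coordinates are bit-reproducible; the cost is that
it has no translation-initiation model, which does not matter for
planted-truth testing but slightly inflates ORF counts on real genomes.

## Homology screening

Each ORF translation is aligned to each exemplar by Smith–Waterman under
BLOSUM62 with gap open 11 / extension 1, the classic protein-search
defaults. The screen keeps every (ORF, exemplar) pair with

* identity **strictly greater than 40%**, where identity is identities
  divided by **all alignment columns including gap columns**, and
* coverage **of at least 60% of the reference** (aligned reference span ÷
  reference length).

Both conventions are stated because the numbers are meaningless without
them: coverage is measured on the reference because the screen's purpose
is detecting full-length role proteins, and counting gap columns in the
identity denominator makes the threshold harder, not easier, to pass on
gappy alignments. Both thresholds and comparison directions are
configurable but never silently changed. A cheap sound prefilter skips
pairs that cannot mathematically reach the coverage threshold (an
alignment with identity > 40% has at most `aa_len / 0.4` columns).
Sub-threshold toxin hits with coverage in [20%, 60%) are retained in a
weak tier: a toxin hit covering < 50% of its reference, whose alignment
stops short of the reference end, marks a toxin gene disrupted by an
internal stop (`truncated_toxin`), a configuration that occurs in real
family members. Because such an ORF falls below the main 80-aa floor, the
locus neighborhood is rescanned with a 20-aa floor against the toxin
exemplars only.

## Locus assembly and configuration strings

Best-hit selection keeps one hit per ORF (highest score, ties by higher
identity, then lexicographically smallest reference id — fully
deterministic under input permutation). Hits are clustered by single
linkage on their nucleotide intervals with an inclusive 2,000 bp gap
(end-to-start, not midpoints); chaining means a module can span well over
2 kb in total, which is intended. Each locus renders a configuration
string: tokens in genomic order, `NAME>` for plus-strand and `<NAME` for
minus-strand genes, gene names `T`, `A`, `X`, `tnpA`, `tnpR`, `tnpI`,
`tnpS`, `tnpT`, and an optional strandless `!res!` marker where a
predicted res site falls between genes. Unclassified ORFs render as `X`
only when they lie strictly between classified members.

TA gene order considers only the `T` and `A` tokens: opposite strands →
`undetermined`; otherwise the gene transcribed first (leftmost for a
plus-strand pair, rightmost for minus) decides — antitoxin first is
`normal`, toxin first `reversed`. The rule is purely syntactic; one
published arrangement (`<tnpR <T <A tnpA>`) is sometimes described as
reversed but classifies as normal under transcription order, and the
classifier follows the syntax rather than adjudicating. Completeness is
`full_with_TA` (transposase + resolvase-role + toxin + antitoxin),
`full_no_TA` (backbone only) or `partial` (missing roles listed).
Subgroup is the label of the best transposase hit; resolvase type is
`R`, `I` or `S/T` (tnpS and tnpT are both kept when present).

## res-site prediction

The search region is the resolvase's 5′ flank: the full gap to the
nearest gene when resolvase and transposase transcribe divergently (they
share the res region and its promoters), the region between divergent
*tnpS*/*tnpT* for heteromeric systems, and otherwise up to 400 bp
upstream clipped at the neighboring gene. Within it,
`find_inverted_repeats()` exhaustively enumerates spaced inverted repeats
with arm 8–14 bp, loop 0–14 bp and at most 3 arm mismatches, scored as
arm length minus mismatches. This geometry is inferred from the canonical
~100–150 bp three-subsite res architecture; no position-weight model is
published for these sites, so a PWM or library-guided search is out of
scope and the bounds are configurable. `assemble_res_site()` picks the
three mutually non-overlapping motifs with inter-subsite gaps of 0–60 bp
maximizing total score by dynamic programming over position-sorted
motifs; ties on total score prefer fewer total mismatches (so a perfect
planted subsite beats a mismatched extension of itself), then genomic
position, making the result invariant under permutation of the motif
list. The resolvase-proximal subsite is labeled III, the distal one I; a
two-motif fallback is reported as partial only on request. The crossover
is the AT dinucleotide closest to the center of subsite I (leftmost on
ties), `NA` with a flag when the span contains no AT.

## Pairwise comparison and breakpoints

`dotplot_matches()` lists every exact shared word (default wordsize 10)
in both orientations — the standard dot-plot primitive.
`identity_profile()` computes, on a fixed pairwise DNA alignment
(match +1, mismatch −1, gap −2, free end gaps so a shared prefix scores
cleanly against a longer partner), the fraction of identical positions in
100-bp windows every 10 bp along the first sequence.
`detect_breakpoint()` fits a two-segment least-squares change point to
the profile and reports it only when one segment mean is ≥ 0.95 and the
other ≤ 0.85 — the signature of a chimera identical to the reference on
one side of a junction and diverged on the other. Visual alignment
inspection is how such junctions are traditionally localized; the
change-point statistic is an explicit, testable replacement. The
confidence interval collects split positions whose fit cost is within 5%
of the optimum. Because the estimator has window-level resolution,
`in_res_site_I` is defined as *overlap of the confidence interval with
the subsite I span* (both on reference coordinates) rather than strict
point-in-span, which would be sharper than the statistic itself.
`ta_module_identity()` uses strict end-to-end global alignment (same
scoring) over the toxin-start-to-antitoxin-end span; free end gaps are
deliberately not used there, since they would let unrelated modules score
near-100% over a trivial overlap.

## Acquisition events

Identical toxin sequences are collapsed to one representative
(lexicographically smallest id, multiplicities recorded), p-distances
(mismatches over aligned non-gap columns) computed on global alignments,
and a neighbor-joining tree built over transposon-associated toxins plus
seed (non-transposon) family members. NJ replaces maximum-likelihood
inference with model selection and bootstrapping because event counting
needs only a topology and must run in seconds; the backend is pluggable.
The tree is rooted on the seed side: on the branch separating the seeds
when they are monophyletic, else at a single deterministic seed leaf — a
position guaranteed to lie outside every transposon-only clade; midpoint
rooting is the no-seed fallback. An **acquisition event is a maximal
clade whose leaves are all transposon-associated**, the minimum number of
seed-to-transposon transitions under the rooting. This operationalizes
what is otherwise an expert reading of a tree figure; it is an
interpretation, and it can merge two true origins if no seed lineage
separates them in the reconstructed topology.

## The synthetic-data generator

Simulators are bit-reproducible given their spec (which includes a
mandatory seed) and restore the caller's RNG state.

* `mutate_to_identity()` is substitution-only: it replaces
  `round((100 − target)/100 · n)` uniform positions with a different
  letter, so realized identity equals the target up to rounding (the
  contract is ±5 points; indel stress is out of scope because identity
  control under indels has no such guarantee). No synonymous-codon bias
  is attempted.
* `simulate_transposon()` mutates exemplar proteins to per-gene target
  identities, reverse-translates with uniform codon choice (gene GC
  therefore floats free of background GC; nothing downstream uses GC),
  lays genes out per the configuration with 60 bp intergenic gaps, plants
  the res site on the resolvase's 5′ side (or at an explicit `!res!`
  token) as three perfect inverted repeats (arm 12, loop 6, 20 bp
  inter-subsite gaps, 30 bp padding) with the crossover AT embedded at
  the center of subsite I's loop and subsite III adjacent to the
  resolvase, and caps the element with 38-bp terminal inverted repeats.
  The spacers inside the res block are drawn from the complement-disjoint
  {A, C} alphabet: two spacer bases can then never pair, which makes the
  planted subsites provably the best-scoring inverted repeats in their
  region — without this, a randomly complementary flank occasionally
  forms a higher-scoring repeat and the recorded truth would not be the
  optimum of its own sequence.
  A `truncate_toxin` flag converts the codon at 40% of the toxin gene to
  a stop.
* `simulate_genome()` embeds modules at seed-chosen positions in random
  background of stated GC with ≥ 3 kb separation, shifting truth
  coordinates; zero modules gives a pure-background null genome.
* `simulate_chimera()` joins parent A up to (and including) the A of its
  crossover AT to parent B from the T onward, recording the junction;
  `mutate_simulated()` derives a diverged second parent with identical
  truth layout (possible precisely because mutation is
  substitution-only).
* `simulate_toxin_origins()` draws k mutually unrelated ancestors; each
  origin gets a **founder** carrying shared substitutions (60% of the
  divergence budget) whose descendants add the rest — without that
  shared derived branch the generating process would be a star phylogeny
  and the origin clusters would not be recoverable clades even in
  principle. Seed taxa are placed at ~1.5× the divergence from the
  ancestors, cycling over them, so each cluster is separated from its
  neighbors by a seed lineage, emulating family members never captured
  by a transposon.

What the simulations do **not** emulate: indels and rearrangements,
codon models or rate heterogeneity, imperfect/degenerate res subsites,
promoter elements, nested insertions of other mobile elements, and
compositional biases. Passing the planted-truth suites therefore shows
the algorithms are correct under their stated models, not that the
default thresholds are optimal for any particular real dataset.

## Catalog aggregation

The packaged catalog (one row per toxin family × antitoxin × resolvase
type × subgroup × configuration, with instance counts `nb` and transposon
name lists validated against `nb`) is aggregated with `nb`-weighted
counts. Antitoxin variant labels are collapsed through an **explicit
merge map** (`ParD-noDBD → ParD`, `HTH → HTH_37`) rather than in code, so
the resulting six antitoxin families are auditable and the map can be
replaced. TA order per row comes from `classify_ta_order()` on the row's
configuration string. One catalog row transcribes a typographically
ambiguous published arrangement; the package records the reading
consistent with the accompanying text (a divergently transcribed
antitoxin and an extra unknown ORF: `<T <A <X tnpR> tnpA>`).

## Numerical choices and problem sizes

All internal coordinates are 0-based half-open, converted only at format
boundaries (GFF3/GenBank are 1-based inclusive). Deterministic tie-breaks
are stated everywhere they can bite: best-hit (score, identity, ref id),
res-chain DP (score, fewer mismatches, position), crossover (leftmost of
equidistant ATs), change-point (smallest index at equal cost),
representative choice (smallest id). The test and acceptance workloads
use 15-kb genomes for recall, ten 50-kb null genomes for precision, 100
simulated modules for subsite recovery, 100 chimeras (parents at 60% DNA
identity) for breakpoint recovery, and 50 replicates per origin count
k ∈ {1, 3, 5} — sizes chosen so the whole suite runs comfortably on a
laptop while the rates have narrow binomial error.

## Known limitations

Terminal inverted repeats of the transposon ends are planted by the
simulator but not detected; passenger genes are not annotated; there are
no E-value statistics (thresholds are on identity/coverage only); no
frameshift-tolerant translated-DNA alignment; res prediction has no
trained scoring model and no support for the accessory direct repeats of
tyrosine-resolvase *irs* sites; promoter elements within res are out of
scope; and the acquisition counter reports clade counts without
adjudicating between recombination and independent acquisition for
borderline lineages.
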