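---
title: "Methods: plastome structure, diversity scanning, and barcode mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastome structure, diversity scanning, and barcode mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidscan)
```

## Scope and assumptions

`plastidscan` analyzes sets of closely related circular plastomes: it
detects their quadripartite architecture, scans alignments for variation,
mines short diagnostic barcode regions, and tests whether those regions
discriminate predefined species or lineage groups. Two assumptions run
through everything:

* **Near-identity within the genus.** Sequences are similar enough that the
  two inverted-repeat copies are exact (or almost exact) reverse complements
  of each other, and that a trustworthy multiple alignment of the
  one-IR-removed sequences exists. The package consumes alignments; it does
  not build them (MAFFT or similar is the usual pre-step).
* **Groups are given.** Species/lineage labels come from the user (in
  practice from a phylogenomic analysis); the package asks whether a short
  region can *re-identify* those groups, not whether they are real.

## Quadripartite structure

The inverted-repeat pair is found by seed-and-extend on the doubled genome
sequence, which makes the search independent of where the arbitrary circular
origin falls: exact 21-mers of the genome are matched against 21-mers of its
reverse complement, each candidate diagonal is scanned in full, and the
longest run with at most `max_mismatch` non-matching positions wins. Runs
are capped at half the genome (a repeat pair cannot overlap itself), and
overlapping best pairs are rejected with a diagnostic rather than reported.

Defaults: `min_len = 1000` bp — plastome IRs are one to two orders of
magnitude longer, while spurious repeats are shorter — and
`max_mismatch = 0`, because in a within-genus panel the two copies are
routinely identical; both are arguments. IUPAC ambiguity codes are accepted
but never match during extension, so an exact-mode IR is guaranteed to be a
literal reverse complement. At ~170 kb and near-exact repeats this is
linear-time in practice and needs no suffix-structure machinery.

The two inter-repeat arcs are labeled LSC (longer) and SSC (shorter); ties
are broken lexicographically with a warning. Results are reported on the
canonical rotation (LSC base 1 first, order LSC–IRa–SSC–IRb). The SSC is
kept in its input orientation: flipping it is only needed when comparing
across taxa with unstable architecture, which is out of scope here. All
user-facing coordinates are 1-based inclusive (the R convention); BED export
converts to 0-based half-open.

## Variation scanning

Gaps and ambiguity codes are treated as missing data everywhere — never as
partial matches — because that is conservative and independent of sample
order. A column is *variable* if at least two distinct unambiguous states
occur among non-missing samples, *parsimony-informative* if at least two
states each occur in at least two samples, a *singleton* otherwise, and
*excluded* if fewer than two non-missing states remain. By construction
`n_variable = n_PI + n_singleton` on every interval, and the test suite
asserts it on random data.

Nucleotide diversity is the average pairwise proportion of differences,
π = Σ~i<j~ d~ij~ / C(n,2). The default *complete deletion* (only columns
with no missing state anywhere are compared) mirrors the common DnaSP-style
convention; *pairwise deletion* is available by flag, and the two coincide
on gapless alignments. Sliding windows default to 800 bp at a 200 bp step —
the standard grid for plastome diversity profiling — starting at column 1,
with the final window truncated at the alignment end and flagged.

A *diagnostic site* for a group is a column where the group's non-missing
samples all carry one state and that state is absent from every other
non-outgroup sample. `complete` records whether the group itself had any
missing data; `strict` additionally requires no missing data among the other
samples, so absence is certain rather than merely unobserved. Only strict
sites count toward barcode coverage. This is a combinatorial definition —
no multiple-testing machinery is involved or needed.

## Barcode mining

A candidate core must simultaneously be:

| constraint | default | rationale |
|---|---|---|
| core length | ≤ 800 bp (and a 400 bp short option) | single-pass Sanger amplicon |
| diagnostic coverage | ≥ 1 strict site per required group | the region must identify *every* group |
| variable sites | ≥ 3 | floor on information content |
| gap fraction | ≤ 0.05 | alignment reliability |
| window π | ≤ 0.05 | rejects hypervariable, alignment-unreliable hotspots |
| flanks | `flank_len = 25` columns invariant and gap-free on both sides | primer landing sites; typical primers are 20–24 nt |

Required groups are the non-outgroup groups with at least two samples;
singletons cannot be meaningfully "covered". Cores slide on a 50 bp grid
(`step`); ranking is fully deterministic — parsimony-informative sites
descending, then gap fraction ascending, then leftmost — so runs reproduce
without a seed, and non-overlapping candidates are selected greedily. When
nothing passes, a per-constraint rejection tally is attached so the failure
is diagnosable. An independent validator (`validate_candidates`), sharing no
code with the scanner, re-checks every emitted candidate column by column.

Candidate cores live in alignment coordinates; actual product sizes are
re-measured per genome by in-silico PCR (`in_silico_pcr`), since gap columns
make the two differ. The PCR model is deliberately minimal: the forward
primer matches the sense strand, the reverse primer's reverse complement
matches downstream within `max_product`, each footprint tolerating
`max_mismatch` mismatches; circular templates are searched across the
origin, and a product can never exceed the circle. Primer thermodynamics
(Tm, GC clamp, dimers) are out of scope — the miner guarantees conserved
flank *sequence*; primer design proper belongs to dedicated tools.

## Discrimination testing

A region discriminates a group when the group is **monophyletic with
bootstrap support strictly greater than 50%**. Trees are built with
neighbor joining on JC69 distances by default (p and K2P available);
support comes from the standard nonparametric bootstrap (column resampling,
default `B = 1000`). Singleton groups are reported as trivially
monophyletic with indeterminate success, and outgroup samples sit in the
tree but are never evaluated. Monophyly is tested as a bipartition, so no
rooting is required.

This NJ + bootstrap stage is desk-scale plumbing around the success rule: a
full study would use maximum-likelihood trees with ultrafast bootstrap here,
and the package exports region alignments in relaxed PHYLIP so that remains
easy to do externally. The success *criterion* is applied unchanged.

Numerical choices in NJ: Q-criterion agglomeration with ties broken by the
smallest index pair (deterministic); negative branch lengths clamped to zero
with the deficit moved to the sister branch, preserving their sum; JC69
distances saturate at p ≥ 0.75 and are replaced by twice the maximum finite
distance with a warning. Zero-length internal edges are treated as
unresolved polytomies when counting bootstrap bipartitions, so a
variation-free region supports nothing and every multi-sample group fails —
the behavior one wants from a barcode test.

## The synthetic generator

`generate_study_like_dataset()` emulates the design of a genus-level
plastome barcoding study: one outgroup, a two-sample species clade (`spA`),
a five-sample species clade (`spB`), a large species split into eastern
(8) and western (8) lineages plus one phylogenetically unstable singleton
(`HN`) — 25 samples in all. Sequences evolve under Jukes–Cantor along a
fixed guide tree (substitution engine: `phangorn::simSeq`); tip branches are
2×10⁻⁴ and stems 3×10⁻⁴–1.2×10⁻³ substitutions/site, placing background
diversity in the π < 0.002 regime typical of conspecific plastomes, with the
outgroup at 0.03. Genomes are assembled as LSC + IRa + SSC + revcomp(IRa)
(10,000 / 3,630 / 2,800 bp — a ~20 kb scale model; every algorithm is
length-agnostic, and a full-scale geometry is exercised separately in the
test suite) and randomly rotated.

Planted, exactly recorded features:

* **Diagnostic sites**: 12 per multi-sample group, planted deterministically
  (each group overwritten with a private state, everyone else with the
  consensus) rather than arising from stem-branch simulation, so truth is
  exact. Six sites per group sit inside the barcode core, anchored from its
  left edge (`spA`) to its right edge (`spC_W`) so that a window must cover
  essentially the whole core to cover every group; the remaining six are
  scattered at 350 bp spacing in group-specific regions far from the core
  and from each other, so they cannot assemble into a competing candidate
  window.
* **A barcode core** of 800 bp in the LSC, aligned to the scanner's grid,
  with 30-column fully conserved flank blocks.
* **A hotspot** of 600 columns inside the IR with a 20× substitution
  multiplier; per-group IR length differences (−70 bp for `spA`, −210 bp for
  `spB`) are realized as deletions inside it, which also makes it the only
  gapped part of the true alignment — indels elsewhere would make "true
  alignment" ill-defined and site-level scoring ambiguous.
* **Guard bases** at the single-copy boundaries, so the detected IR cannot
  extend past the true junction by a chance complementary base and structure
  recovery is exact, not approximate.

What the generator does **not** emulate: real indel processes outside the
hotspot, rate heterogeneity beyond the single multiplier, gene content and
annotation (beyond named spans), recombination, heteroplasmy, or assembly
error. Passing the planted-truth tests therefore demonstrates that the
*algorithms* recover what was put in under study-like signal and noise
levels — it does not certify performance on pathological alignments or
misassembled genomes.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline on the ~20 kb
preset (25 × 16,430 alignment), repeat mining/discrimination over 10–20
independent seeds with B = 200 bootstrap replicates, verify structure
detection once at full deposited-scale geometry (162,115 bp), and check the
generator against the JC closed form p = ¾(1 − e^(−4d/3)) at d = 0.1. Every
stochastic step takes an explicit seed; reports regenerate byte-identically
from the same inputs, configuration and seed.

## Known limitations

* Diagnostic-site logic is allele-presence based; it does not model
  within-group polymorphism beyond "not fixed, skip".
* The π cap that rejects hypervariable windows is a heuristic stand-in for
  alignment-quality assessment.
* NJ bootstrap supports are not comparable in absolute value to ML ultrafast
  bootstrap percentages; only the >50% decision rule is shared.
* GenBank parsing is deliberately minimal (gene/tRNA/rRNA names, outer
  spans, ORIGIN); rich annotations should be handled upstream.
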