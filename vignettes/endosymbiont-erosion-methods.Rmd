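---
title: "Models and methods: gap closure, gene erosion and rearrangement in endosymbiont genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: gap closure, gene erosion and rearrangement in endosymbiont genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoerode)
```

## The setting

Facultative endosymbionts of insects sit between free-living bacteria and
the tiny, static genomes of ancient obligate symbionts. Their genomes are
eroding in real time: mobile elements (insertion sequences, prophage genes,
group II introns, TnTIR-like transposons) have multiplied, a large share of
genes are pseudogenes, gene order is scrambled by inversions frequently
mediated by those same mobile elements, and the repeat load keeps the
assemblies stuck at N-gapped draft stage. This package implements the
computational stages such a project needs — closing assembly gaps around
repeats, scoring per-strain gene states, profiling functional decay,
quantifying rearrangement, and screening a mate-pair library for
within-population rearrangements — with every stage testable against
synthetic data whose ground truth is planted by construction.

Throughout the package, in-memory coordinates are 0-based half-open;
on-disk GFF3 and TSV coordinates are 1-based inclusive and converted at the
boundary exactly once. Soft-masking is a separate interval list, never a
destructive sequence edit.

## Gap-closure primer design

`find_gaps()` reports the maximal N-runs of a scaffold set; the N-run
length is stored as the estimated gap size (assemblers rarely record a
better estimate, and the run length is what scaffolding inserted).

`detect_repeats()` stands in for an iterative de novo repeat finder with an
exact, fully testable criterion: every position covered by a k-mer
(canonical over strands, default k = 24) occurring at least `min_copies`
(default 2) times genome-wide is masked; overlapping seed hits merge into
maximal intervals; intervals sharing a seed k-mer form a family. At k = 24
a random 100 kb background contains essentially no repeated k-mers, so
planted-truth tests demand ≥ 95% base recall of planted families at ≤ 1%
false-positive masking. `repeat_mask_iterative()` wraps detection in
detect-and-mask rounds to a fixed point (default `max_iter` 5); with the
exact-k-mer detector the fixed point arrives after one round, and the loop
simply keeps the stage robust to a future detector change.

`melting_temperature()` is the two-state nearest-neighbor model: unified
dinucleotide enthalpies/entropies, per-terminal initiation terms, the
symmetry correction for self-complementary sequences, and the entropic
monovalent-salt correction `0.368 (N-1) ln[Na+]`. The duplex concentration
term uses CT/4 (equimolar strands), with CT the primer concentration
(default 500 nM, at 50 mM Na+). Divalent-cation corrections are out of
scope. The implementation is checked against a literal hand-summed table
computation and an independent implementation of the same model to
±0.1 °C.

`score_candidate()` gates windows of 18–27 nt: GC in [0.20, 0.80], Tm in
[57, 63] °C, no homopolymer ≥ 5, no 3′-terminal self-complementary run
≥ 4, no hairpin stem ≥ 6 with loop ≥ 3. Surviving windows receive the
penalty `|Tm − 60| + 2|GC − 0.5| + 0.25·(3′ run) + 0.25·(sub-threshold
stem)` — Tm and GC centering dominate, with mild pressure against residual
secondary structure. The product-size constraint is the only externally
pinned parameter of this stage; the remaining constraints mirror common
primer-design defaults and are all overridable.

`design_gap_primers()` searches a 1 kb flank (default) on each side of a
gap, left primer on the + strand upstream, right primer on the − strand
downstream. Masking is binary: a primer overlapping a single masked or N
base is rejected. The product size is measured in scaffold coordinates
(`right.end − left.start`), i.e. the gap is counted at its estimated size —
the only coherent reading of a product window spanning a gap of unknown
true size. The minimum-penalty pair within the window wins; ties break to
the smaller product, then the leftmost left primer. Failures are typed:
`product_range_unsatisfiable` (gap too large for the window by
arithmetic), `flanks_masked` (no unmasked window of primer length in a
flank), `no_candidate_window` (gates or pairing constraints eliminated
everything). For speed, windows are pre-screened with a vectorized
rolling-sum Tm/GC scan and the top 300 per side by Tm centering go through
the full structure checks; the pre-ranking is deterministic.

## Gene-state (erosion) matrices

`local_align_score()` is the Smith–Waterman local alignment raw score
under BLOSUM62 with affine gaps (open 11, extend 1; a gap of length L
costs 11 + L), computed by `Biostrings::pairwiseAlignment` and verified in
the tests against a hand-written Gotoh dynamic program. The raw score —
not the bitscore — is used deliberately: the state rule only ever consumes
the *ratio* `relative_score(query, ref) = S(query, ref) / S(ref, ref)`,
for which the bitscore's affine rescaling cancels, and the raw score is
exactly reproducible without an external search program. `X` residues
score 0 against everything.

`assign_state()` encodes the state rule: a strain is **intact** for a
group if it has an annotated intact CDS member; **pseudo** if not, but
some fragment reaches `relative_score ≥ 0.30` against the group's intact
reference; **absent** otherwise. `build_state_matrix()` applies it across
an ortholog table, dropping any group with a mobile-class member and any
group with fewer than two non-absent strains; the reference is the first
intact CDS member in strain-input order. For pseudogene loci with only
nucleotide evidence, `translate_six_frames()` provides the six conceptual
translations and the best frame's score is used.

`assign_loss_branches()` places inactivation events on the rooted
three-strain topology `((SAp,SCt),SCc)` with the root fixed intact, under
Dollo parsimony: states only degrade along a root-to-leaf path. With
states ordered intact < pseudo < absent, the total event count for an
internal (ingroup-ancestor) state `x` is `SAp + SCt + SCc − x`, so setting
`x = min(SAp, SCt)` is the unique minimum — no search needed. Patterns in
which both ingroup leaves are non-intact are flagged `ambiguous`: the
minimal labeling shares the event on the internal branch, but two
independent terminal events (one extra event) explain the same pattern,
and parsimony cannot distinguish convergent inactivation. The flag is
reported, never silently resolved. Two-way ordering of the matrix for
display is left to standard tools (e.g. `hclust` on Hamming distances) and
is treated as descriptive output only.

## COG profiles

Hit tables are consumed precomputed (the package never runs a homology
search, which would tie results to a database version). Per CDS,
`select_nonoverlapping_hits()` removes hits with e-value > 1e-3 and keeps
the maximum-total-score set of mutually non-overlapping intervals —
weighted interval scheduling, the canonical formalization of
"non-overlapping hits" — with deterministic tie-breaks (lower e-value,
leftmost start). `category_frequencies()` divides category counts by the
number of COG-assigned CDSs; a CDS hitting m distinct categories
contributes 1/m to each, keeping every profile on the simplex.
`degradation_divergence()` subtracts the free-living strains' mean
frequency per category, on the union category set with zero-fill (the mean
is otherwise undefined where categories are missing); free-living deltas
average to zero per category by construction, which the tests assert
exactly.

## Rearrangement analysis

`shared_signed_orders()` reduces two genomes to the signed permutation of
their shared single-copy nonmobile orthologs: strain A's order is `1..n`
by construction, strain B's entry for gene i is `±position`, positive when
the gene keeps its relative strand. Multicopy groups are excluded (with a
count), as are mobile-class features before indexing.

`synteny_clusters()` partitions A's order into maximal runs whose genes
are consecutive in B either in identical order and signs or fully reversed
with flipped signs — an exact, brute-force-checkable stand-in for graph
based synteny clustering. The tests verify it against exhaustive
maximal-run search over all signed permutations up to n = 5 and large
seeded samples at n = 6, 7, a verification scale chosen to keep the suite
fast while covering every structural case class.

`breakpoint_distance()` frames the permutation with 0 and n+1 and counts
adjacencies with `b − a ≠ 1`; with `circular = TRUE` the frame wraps and
conservation becomes `(b − a) mod n = 1`, making the distance invariant
under whole-genome reversal (which the linear framing deliberately is
not). Breakpoint distance is a lower-bound-style statistic — every planted
inversion count satisfies `inversions ≥ distance/2`, asserted on all
simulations — and the optional `greedy_reversal_count()` supplies a
clearly-labeled heuristic upper bound; exact inversion distance
(Hannenhalli–Pevzner) and rearrangement medians are out of scope.
`flanking_element_tally()` counts, per mobile class, the clusters with a
feature of that class starting or ending within 3 kb (default) of either
cluster boundary; a cluster can count in several classes, and clusters
with nothing in reach count as `none`.

## Mate-pair rearrangement screen

The source data for this screen never defines its conventions, so the
package fixes them by declaration: **insert size is the outer distance**
(leftmost mapped start to rightmost mapped end), and **orientation is read
off the coordinate-leftmost mate** — RF (leftmost mate reverse) is the
canonical large-insert mate-pair orientation, FR the short-insert
paired-end "innie" contamination, FF/RR likely library errors.
Classification is invariant to swapping the mate labels, which the tests
assert.

`filter_cascade()` applies the filters in their published order:
concordant pairs (same contig, RF, insert in [2,211, 3,651] bp) are
discarded first, then pairs with a mate in an annotated mobile region,
then pairs mapping across contigs are set aside, then pairs whose mates
partly or entirely overlap each other; everything else is retained.
`orientation_summary()` reports counts and percentages per orientation
among retained pairs, with the retained total as the denominator for every
class — one denominator, stated once; percentage sets computed against
other denominators (for example after excluding a class) are not
comparable to these. FF/RR pairs are retained through the summary and left
to the caller to exclude, treating "probable library error" as a reporting
decision rather than a hard filter.

`junction_evidence()` single-links retained non-FR pairs whose left and
right mate starts both lie within 1,000 bp (default) of each other on the
same contig; clusters with ≥ 10 supporting pairs (default) are candidate
rearrangement junctions. Both defaults are this package's declarations: a
true junction concentrates many pairs on one breakpoint pair, while
scattered background at realistic discordant densities (a few percent of a
library over megabases of genome) stays below support 10. The negative
control — zero clusters on a rearrangement-free library — is part of the
acceptance suite.

## The synthetic-data module

`sim_config()` pins the study conditions: a 100 kb chromosome slice with
80 genes of 300–1,500 bp (broken-stick intergenic spacing, which gives the
long-tailed intergenic lengths real gene placement has and leaves room for
planted gaps and repeats), background G+C 0.50 as a neutral, tunable
default, 2 repeat families of 400 bp × 3 copies, 5 gaps of 100–500 bp, 3
inversions, and a mate-pair library of mean insert 2,931 bp (sd 240 bp,
read length 100) mixing ~77.7% concordant RF pairs with FR contamination,
discordant RF, and rare FF/RR errors in the proportions a real screen of
this design reports. One master seed fans out to per-stage child seeds by
a fixed multiplicative rule (`sim_child_seed()`), so stages are
reproducible independently.

Design choices worth stating: inversion breakpoints fall between genes (no
gene is cut), and IS scars annotated at breakpoints are carried through
later inversions so they end up where the final genome has its junctions.
Gaps replace intergenic sequence rather than inserting Ns, keeping all
coordinates stable. Concordant mate-pair inserts are rejection-sampled
into the concordant window itself — the window spans ±3 sd, so this
trims only the ~0.3% tail — making "a pure concordant library classifies
100% concordant" hold by construction; out-of-window RF pairs are planted
explicitly through the discordant-RF class. Planted pseudogene fragments
are resampled until their *realized* score ratio lands outside the
[0.25, 0.35] gray zone around the 0.30 cutoff, on the intended side:
intact reference copies carry ~2% substitutions, so the retained fraction
alone does not pin the ratio at short fragment lengths, and excluding the
gray zone on the measured quantity is what makes planted truth
unambiguous. Cutoff sensitivity inside the gray zone is a property of the
rule, not a defect, and is deliberately not tested against truth.

What the simulator does not emulate — and what passing tests therefore do
not show about real data: read-level sequence errors and coverage
fluctuations (mate-pair records are generated at the mapped-record
abstraction), paralogy and partial homology between repeat families,
diverged repeat copies (planted copies are exact, so detection recall
bounds say nothing about decayed repeats), composition heterogeneity and
skew, real pseudogene structures (internal deletions, frame-restoring
indels), and ortholog-inference errors (membership tables are taken as
given).

## Problem sizes and runtime choices

The test and acceptance workloads use a 100–120 kb chromosome with 60–100
genes, 300 ortholog groups across three strains, 50 scaffolds for the
primer benchmark, 10 seeds for repeat recall, and 50,000-pair libraries
over 2.5 Mb of contigs — the last because junction clustering is a density
statistic, and a realistically sized genome is what makes the
rearrangement-free negative control meaningful. These sizes exercise every
code path at full statistical strength while keeping the whole suite in a
few minutes.

## Known limitations

Repeat detection is exact-match seeding: diverged repeat copies below
k-mer identity escape masking (real iterative repeat finders cluster
diverged families). The Tm model omits divalent cations and dangling-end
terms. The erosion matrix trusts the ortholog table and annotated feature
classes; misannotated mobile elements would leak through the mobile-group
filter. Breakpoint distance undercounts rearrangement relative to true
inversion distance by up to a factor of two, and the greedy reversal count
is only an upper bound. The mate-pair screen classifies mapped records; it
neither maps reads nor assembles junctions at base resolution.
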