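---
title: "Methods: antisense pair classification and the expression screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antisense pair classification and the expression screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisnat)
```

This vignette documents the model behind `cisnat`: the pair classification
and extraction rules, the statistical procedures of the expression screen,
the design decisions taken where several readings were defensible, and what
the synthetic fixtures do and do not establish about real data.

## Gene model and coordinate conventions

All analysis is at gene level: each gene is a single interval
`[start, end]` on a chromosome with a strand, the representative structure
recorded in the annotation. Coordinates are 1-based and closed throughout
(the GTF convention; the CSV dialect uses the same convention, so no
off-by-one conversion ever occurs inside the package). The TSS of a
plus-strand gene is `start` and its TES `end`; for a minus-strand gene the
roles swap. Genes without a definite strand are rejected outright —
antisense relationships are undefined without an orientation. `gene_id` must
be unique (validation enforces it); gene symbols may repeat, which is why
every join in the package is by id and symbol duplication is reported only
as a warning.

Exon structure, isoform-specific ends, and overlap composition (whether an
overlap covers exonic sequence) are deliberately out of scope: with one
representative interval per gene there is exactly one answer per gene pair,
at the price of ignoring isoform diversity. Chromosome names are compared as
exact strings; mixing `"1"` and `"chr1"` conventions across inputs is the
caller's responsibility.

## The eight-type classification

For a sense gene `S = [s1, s2]` and an opposite-strand gene on the same
chromosome with TSS/TES anchors `a_tss`, `a_tes`, the type is decided by
anchor membership in `S` (closed on both ends):

1. both anchors in `S` → `EB` (embedded);
2. only `a_tss` in `S` → `HH` (5′ overlap);
3. only `a_tes` in `S` → `TT` (3′ overlap);
4. neither in `S` but the intervals intersect → `FO` (antisense covers the
   sense gene);
5. disjoint intervals → `nHH`/`fHH` when the antisense lies on the sense
   gene's 5′ side, `nTT`/`fTT` on the 3′ side, split at a 5,000-bp gap.

These five cases are mutually exclusive and exhaustive, so classification is
total, and the role-swap map is `EB↔FO` with every other type fixed (a
5′-overlap is head-to-head from either perspective). Two boundary rules are
worth stating explicitly. Identical-extent genes on opposite strands have
both anchors inside `S`, hence `EB` in both roles — accepted as the boundary
behaviour of the symmetry rather than a special case. Single-base contact
(`antisense end == sense start`) counts as overlap because intervals are
closed, and is classified by the membership rule like any other overlap.

The gap of a disjoint pair is the absolute difference of the facing gene
ends, so adjacent genes 1 bp apart have gap 1. With the 5-kb threshold this
makes `nHH` coincide exactly with disjoint upstream pairs whose TSS offset
lies in `[-5000, -1]`: the nearby/faraway split and the mode-2 window
semantics agree by construction. An alternative reading measures the gap
TSS-to-TSS; for disjoint head-to-head pairs the two coincide, and the
end-to-end definition extends consistently to the tail-to-tail side, which
is why it was chosen.

## Signed offsets and window extraction

`as_tss_position` is `tss(antisense) − tss(sense)` for a plus-strand sense
gene and the negation for a minus-strand one: negative always means upstream
in the sense gene's own transcription direction, 0 means coincident anchors.
`as_tes_position` is the same construction on TES coordinates.

Window extraction (modes 2 and 3) keeps pairs with offset in
`[min, max]`, both bounds inclusive. The equivalent coordinate condition for
a plus-strand sense gene and TSS anchor is the closed interval
`[tss + min, tss + max]`, mirrored to `[tss − max, tss − min]` on the minus
strand. Because `max = −1` excludes offset 0, the common upstream window
`(-500, -1)` never captures a coincident TSS; a window spanning 0 includes
coincidence once (offset 0 is a single value, counted when
`min ≤ 0 ≤ max`).

Every qualifying configuration is emitted twice, once per gene in the sense
role, by two directional sweeps (plus-sense then minus-sense) that are then
sorted by `(sense_chr, sense_start, sense_gene_id, as_gene_id)`; output is
therefore byte-reproducible and no deduplication is applied. A gene is never
paired with itself — opposite strandedness is a hard precondition.
Internally each sweep builds per-chromosome interval queries
(`IRanges::findOverlaps`), which scales to genome-sized tables; the test
suite proves exact set equality against an O(n²) enumeration on randomized
tables, so the indexing is purely an implementation detail.

## Binned profiles

Divergent (TSS-anchored) and convergent (TES-anchored) landscapes are
profiled over 20 bins of 500 bp spanning ±5 kb by default (both parameters
are configurable; the range must be a multiple of the width). Upstream bins
end at −1 — the peak bin immediately upstream of the anchor is
`[-500, -1]` — and offset 0 is assigned to the first downstream bin
`[0, 499]`. The first-downstream-bin assignment of 0 is an interpretation
(nothing in the binning forces it) and is fixed here once.

Per bin the profile counts **distinct sense genes** with at least one
antisense anchor in the bin — a gene with three antisense partners in one
bin counts once there, though it may appear in several bins — and divides by
the number of genes passing the sense-biotype filter, whether or not they
have any antisense partner. Counting pairs instead of genes would weight
antisense-dense loci more heavily; the distinct-gene reading matches
"fraction of genes possessing an antisense transcript" and is used for the
biotype-combination cross-tabulation as well. Biotype filtering commutes
with profiling (filtering the table first equals filtering extracted pairs),
which the tests check as a property.

## The expression screen

**Expressing genes.** Replicate columns (sample labels
`<timepoint>_<replicate>`) are averaged to time-point means; a gene is
expressing when some mean exceeds 1 TPM and no mean is 0. Averaging before
filtering and correlating is the default because per-replicate series mix
biological trajectory with replicate noise in the ranks; a
`use_replicate_means = FALSE` flag gives the per-sample alternative.

**Correlation.** Spearman's rho is the Pearson correlation of average ranks
(`stats::cor(method = "spearman")`). A constant series has no rank ordering,
so its correlation is reported as `NA` and excluded from grouping — never
coerced to 0, which would fabricate an "uncorrelated" result. Spreadsheet
rank functions historically use minimum ranks for ties; average ranks are
the statistically standard choice and the one used here, with at least 3
points required.

**Grouping by distance.** Two groupings are provided: consecutive groups of
100 pairs along the signed offset axis (records tied at a group's boundary
offset join that group, so groups may exceed 100), and the 400 pairs with
smallest absolute offset ("around the anchor"), again tie-inclusive at the
boundary. The smallest-|offset| reading of "pairs around the TSS/TES" is a
design choice; nothing else in the procedure pins it down.

**The null.** Random same-chromosome pairs are built by drawing a
chromosome with probability proportional to the number of opposite-strand
gene pairs it can form, then one gene per strand uniformly. Constraining the
null to opposite strands mirrors the sense/antisense structure of the test
group; an unconstrained same-chromosome null would differ only in strand
composition, not in expression, but the constrained form is the cleaner
comparison and is the default. The null is fully seeded and byte-reproducible.

**Steel–Dwass (DSCF) test.** For each unordered pair of groups the
Mann–Whitney statistic is computed on the pooled pair with average ranks and
the tie-corrected variance
`σ² = n₁n₂/12 · [(N+1) − Σ(t³−t)/(N(N−1))]`, studentized, scaled by √2 and
referred to the studentized range distribution with the total number of
groups as its dimension. Degenerate pooled samples (all values tied) get
statistic 0 and p = 1. No continuity correction is applied, matching the
standard implementations of this procedure; at very small samples the
discrete permutation distribution therefore sits slightly above the
continuous reference (by half the point mass at the observed value), which
the test suite quantifies against exact enumeration. Monte-Carlo null
calibration (4 groups of 30, 2,000 replications) puts the family-wise error
within binomial error of the nominal 0.05 and 0.01 levels.

**Candidates.** Positive and negative candidates use strict cutoffs
`rho > 0.9` and `rho < −0.7`; a pair at exactly 0.9 is excluded. The export
table carries the structural type, the signed TSS offset and both genes'
time-point mean profiles, sorted by rho — the matrix a candidate heatmap is
drawn from.

## Synthetic fixtures: what they emulate, and what they do not

`simulate_gene_table()` inverts the classifier: for each requested type it
draws gene lengths (default 0.5–4 kb) and gaps/overlaps compatible with the
type, lays the pair out in a sense-plus frame and mirror-reflects it for
minus-strand sense genes (which preserves the signed offsets), so
`classify ∘ plant` is the identity by construction — the module's core
guarantee, tested over every type and both strands. Pairs and decoys are
placed by rejection sampling with footprints padded by twice the nearby
threshold plus 2 kb, with a bounded retry budget (1,000 attempts, then an
error suggesting longer chromosomes): no accidental overlap or nearby
relation can arise between different plants, so planted labels are the
exclusive truth for overlap and nearby-window queries. Decoys alternate
strands so that an empty mode-1 result among decoys is a meaningful negative
control.

`simulate_expression()` gives each planted pair a smooth unimodal latent
trajectory (a Gaussian bump with random peak and width, rising then falling
over the course, plus a tiny continuous jitter that breaks rank ties);
positive pairs share it, negative pairs get the inverted trajectory, so
noiseless rank correlations are exactly ±1. Noise is additive Gaussian with
standard deviation expressed as a fraction of the gene's signal range.
Decoys are i.i.d. noise around a constant baseline: independent of
everything, and at zero noise constant — hence an undefined correlation and
exclusion from the screen, the correct σ→0 limit. All values stay positive
and above the expressing-gene filter.

These fixtures establish algorithmic correctness — that extraction equals
its definition, that planted structure is recovered, that the screen's
cutoffs behave — on tables whose geometry is fully controlled. They do not
emulate real genomes: no gene-density gradients, clustered promoters, GC or
CpG structure, biotype-dependent length distributions, or the heavy-tailed,
zero-inflated character of real TPM matrices. Passing these tests therefore
says the machinery is right, not that any biological distribution of pair
types or correlations is expected to look like the simulated one.

## Verification problem sizes

The test suite verifies oracle equivalence on 50 seeded random tables of
60–180 genes on two deliberately dense chromosomes (overlaps of every
flavour arise frequently at that density), classifier totality and symmetry
on 100,000 random opposite-strand pairs, screen recovery on 50 planted pairs
with 30 decoys over 8 time points, and DSCF calibration with 2,000
Monte-Carlo replications; the small-sample DSCF comparison enumerates every
achievable rank-sum value for group splits of total size ≤ 12. The
acceptance script re-runs the same computations at 10 tables of 80 genes.
These sizes were chosen to exercise every code path densely while keeping a
full verification run in minutes on one CPU; all of them scale up by
argument.

## Known limitations

* Gene-level only: no isoform-aware ends, no exon-aware overlap typing.
* Annotation-driven: unannotated antisense transcription is invisible (no
  de-novo discovery).
* Chromosome naming is taken literally; harmonising conventions across
  inputs is the caller's job.
* The Steel–Dwass p-values are asymptotic; below roughly a dozen
  observations per comparison they should be read against the discreteness
  caveat above.
* The expression screen assumes a shared time grid across genes and excludes
  genes with missing TPM values rather than imputing them.
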