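---
title: "Models and methods behind tsrnakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tsrnakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsrnakit)
```

`tsrnakit` analyses tRNA-derived small RNAs (tsRNAs) from adapter-trimmed
small-RNA reads: placement on a mature-tRNA reference, classification by
cleavage position, differential expression between two conditions, and
seed-based 3′ UTR target prediction scored by duplex minimum free energy.
This vignette is the package's own account of the underlying models, the
tunable parameters, and the design decisions taken where the underlying
biology or convention leaves the choice open.

## The coordinate frame

All classification happens in mature-tRNA coordinates: 1-based, inclusive,
on intron-free sequences that end in the universal 3′ `CCA`. References
are stored in the DNA alphabet (`U` is normalised to `T` on load) so that
reads and references compare directly. The anticodon is located either
from an annotation table (which always wins) or, as a convenience, by
`locate_anticodon()`, which picks the occurrence nearest the canonical
neighbourhood `round(L/2) - 4`, breaking ties toward the 5′ end.
Mitochondrial tRNAs are loaded like cytoplasmic ones; `origin` is carried
as metadata only, and mitochondrially derived fragments stay in the
catalog. Pre-tRNA 3′ trailers, when supplied, are searched separately and
give rise to tRF-1 calls.

## What a tsRNA is here

A tsRNA is a **distinct read sequence**, not a (parent, interval) pair.
Distinct sequences that map to several members of an isodecoder family
keep all placements but are one catalog row; the primary placement
(fewest mismatches, then 5′-most start, then lexicographically smallest
parent id) fixes the name and the type. Names follow the field's
`tRF-<AA>-<anticodon>-<serial>` convention, with serials assigned per
isoacceptor in decreasing order of total count. Counts are integer: each
read contributes to exactly one row, so no fractional multi-mapping
allocation is needed.

Placement is exact matching against tRNA space (`max_mismatch = 0` by
default, 1 allowed), implemented with `Biostrings::matchPattern` rather
than a genome-scale aligner: at the scale of a tRNA reference this is
deterministic, exhaustive, and testable against a brute-force substring
scan. Reads whose 3′ end crosses into the non-templated `CCA` are handled
by a bounded retry that trims a trailing `A`, `CA` or `CCA` (recording
`cca_trimmed`) — a standard tsRNA mapping concern. The analysis window is
14–40 nt; out-of-window reads are counted and logged, never silently
dropped.

## The classification rule table

`classify_fragment()` evaluates an ordered rule list against the parent's
anticodon loop, defined as the anticodon ± `loop_halfwidth` (default 3,
i.e. a 9-nt window):

1. trailer placement → `tRF-1`;
2. `start == 1`, end inside the loop → `tiRNA-5`;
3. `start == 1`, end before the loop → `tRF-5a` (≤ 16 nt), `tRF-5b`
   (17–24 nt), `tRF-5c` (≥ 25 nt);
4. `end == L`, start inside the loop → `tiRNA-3`;
5. `end == L`, start after the loop → `tRF-3a` (≤ 19 nt), `tRF-3b`
   (≥ 20 nt);
6. internal placement overlapping the anticodon → `tRF-2`;
7. otherwise `unclassified`.

Anchoring is strict (`start == 1`, `end == L`) because the synthetic data
used for validation is exact; the loop half-width and length bins are
arguments of `classification_rules()` for real libraries where ragged
ends are expected. The tRF-5 length bins close the literature's
approximate ~14–16 / 22–24 / 28–32 nt ranges into a partition of the
14–40 nt window; tRF-2 is defined as anticodon-overlapping because the
taxonomy names the class without fixing a boundary, and internal
fragments that miss the anticodon stay `unclassified` rather than being
forced into a class. The suite verifies by exhaustive sweep over all
(start, end) pairs of a 76-nt fixture that exactly one rule fires per
placement.

Composition summaries (`type_composition()`, `length_distribution()`) are
computed under both **abundance** weighting (summed counts — the default,
since a >90% tRF-5c share alongside a heavy-tailed catalog is an
abundance statement) and **species** weighting (distinct sequences).

## Expression analysis

Normalisation is plain CPM; the pipeline makes no attempt at
composition-robust scaling (TMM-style factors, dispersion shrinkage or
count GLMs are out of scope), so strongly asymmetric spike-ins shift CPM
of unchanged rows — the test suite constructs balanced libraries where
this matters. A tsRNA is *expressed in a group* when its summed count
across the group's samples reaches `min_group_count` (default 1); the
Venn partition and the group-specific sets follow from that rule.

Differential expression is a Welch two-sample t-test on
`log2(CPM + 1)` per tsRNA, two-sided, with Benjamini–Hochberg FDR across
all tested rows and a fold-change filter on group-mean CPM: a call
requires `fdr < 0.05` **and** `|log2FC| ≥ 1` (the boundary is inclusive
to keep the floating-point behaviour defined). The direction convention
is IUGR over normal: "up" means higher in IUGR. Rows that are zero in
every sample are excluded from testing. Degenerate rows (zero variance in
both groups) get `p = 1` when the means agree and `p = 0` otherwise, so
the statistic is total. The Welch statistic is deliberately simple and
fully specified; it is isolated in one operation so a count-model test
could be slotted in. Its main liability at `n = 3` per group is the
Satterthwaite degrees of freedom collapsing toward 2 when one group's
sample variance dominates, which can leave an otherwise large effect just
above the FDR threshold; this is visible occasionally in the recovery
simulations and is a property of the chosen statistic, not of the
implementation. `benjamini_hochberg()` is written out (step-up
minimisation) because it is a specified operation with hand-checkable
examples; the tests cross-check it against `stats::p.adjust`.

## Seeds, logos and target prediction

The seed is positions 2–8 of the fragment. Because all 5′-anchored
fragments of one parent share positions 2–8, seed groups are much fewer
than fragments — grouping is a plain partition by the 7-mer.
`position_frequency_matrix()` computes the per-position base counts and
frequencies behind a sequence logo over either the seed window or the
last *k* nt (3′ end, default 7).

Target scanning is an exact reverse-complement match of the seed in the
UTR — all overlapping occurrences are reported, and no wobble pairing is
allowed in the seed. Candidate sites are then scored by `hybrid_mfe()` on
a window of ± 15 nt of UTR context around the site (capping the DP size
and mirroring the local-hybridisation view of miRNA-style targeting).

### The duplex energy model

`hybrid_mfe()` minimises free energy over all antiparallel intermolecular
duplexes: Watson–Crick and G·U pairs, bulges and internal loops, no
intramolecular structure, no pseudoknots. The energy of a duplex is

* one initiation term (+0.5 kcal/mol by default),
* a stack term for each adjacent pair step, from an embedded 6 × 6
  nearest-neighbour table (Turner-like Watson–Crick values; all stacks
  involving a wobble pair share a uniform −1.2, double-wobble −0.5), and
* an affine penalty `loop_open + loop_per_nt × (unpaired bases)` for each
  bulge/internal loop, bounded by `max_loop` unpaired nucleotides per
  strand per loop (default 10).

The dynamic programme is over "last pair (i, j)" states; the traceback is
returned and re-scoring it reproduces the energy to 1e-9 (asserted in the
tests, which also check the DP against exhaustive enumeration on random
8-mers). The table is a reduced parameterisation, not the full Turner
2004 set: no dangling ends, no terminal-AU or symmetry corrections, and a
small nominal initiation term so that short perfect helices keep a
negative reported energy, as hybridisation tools conventionally report.
Parameters are data (`energy_parameters()`), so a richer table can be
swapped in without touching the algorithm. Reported hits require
`mfe ≤ -15` kcal/mol by default — roughly a 9–10 bp perfect helix under
this table; there is no field-standard cutoff, so the value is explicit
and configurable.

Enrichment of predicted target genes is a generic upper-tail
hypergeometric test against user-supplied GMT gene sets within an
explicit universe (BH-adjusted); no live GO/KEGG access or identifier
mapping is attempted. Phenotype association uses the sample Pearson
correlation with a two-sided p from the t transform on n − 2 degrees of
freedom.

## The synthetic-data generator

The generator exists so that every downstream stage can be validated
without any external download: it emulates the statistical structure of
tsRNA expression measured in porcine skeletal muscle, and its defaults
*are* those study conditions:

* 586 distinct fragments on 160 simulated tRNAs (70–90 nt, anticodon
  start in 33–38, distinct 40-nt 5′ prefixes and distinct positions 2–8
  so fragment→parent assignment and seed accounting are unambiguous);
* an abundance mixture of 92% tRF-5c (remainder spread over tRF-5a/b,
  tRF-3a/b and tiRNA-5/3), with 80% of abundance at 31–32 nt;
* top-2 / top-4 / top-10 expression shares of 76% / 81.42% / 89.16% in
  the normal group, with the four most expressed fragments drawn from one
  parent so they share a seed, and 221 distinct seed 7-mers overall;
* 103 normal-only and 38 IUGR-only fragments, and 19 down / 9 up spiked
  fold changes of 2³ = 8;
* 3 replicates per group at 2 × 10⁶ reads, per-replicate lognormal
  abundance jitter with σ = 0.1 (a standard overdispersion stand-in; no
  noise model is dictated by the data), and error-free reads by default
  (`error_rate` is configurable).

Construction is exact rather than sampled-and-hoped: abundances are
assigned block-wise (top ranks; 31–32 nt tRF-5c tail; other tRF-5c tail;
one block per remaining type) and each block is rescaled so the type
mixture, the 31–32 nt mass and the top-k shares hold to numerical
precision on the normal-group baseline, which is the composition a normal
sample draws from. Only tRF-5c fragments are planted at 31–32 nt, which
is what makes the joint constraint solvable in closed form. Within-block
abundances decay as rank^(−0.7); a block whose head would outrank the
smallest planted top fragment is flattened to uniform, and the
configuration is rejected as infeasible if even that cannot fit — the
planted top-10 must genuinely be the top 10. Group-specific fragments are
drawn stratified by block so their removal from one group barely moves
the type shares; IUGR-only fragments receive the median tail abundance of
their block. Spiked fragments are the most abundant shared tail
fragments, so recovery is limited by the statistic, not by counting
noise. Per-sample reads are a multinomial draw of the jittered, spiked,
group-masked baseline; with 20–30 reads expected for the rarest fragment
per group, all 586 fragments are observed in practice.

Two points the generator deliberately does **not** emulate: sequencing
error and modification-induced misincorporation (reads are exact
substrings), and any adapter or ligation bias. Passing recovery tests
therefore demonstrates the pipeline's correctness on clean data, not
robustness to real library artefacts — mismatch tolerance and anchoring
tolerances exist for the latter but are not exercised by the defaults.

For target-prediction validation, `simulate_utrs()` plants the reverse
complement of the fragment's first 16 nt (an extended complementary site
that contains exactly one reverse complement of the seed) into each
planted gene's UTR and rejection-samples background UTRs free of all
listed seeds. A 7-bp seed helix alone scores only ≈ −12 kcal/mol under
the energy table, so planting a seed-only site would contradict the
default −15 reporting cutoff; the extended site (≈ −30 to −45 kcal/mol)
reflects the extensively paired alignments that motivate such
predictions, while the seed-gate property (no hit without a seed match)
is still what excludes every background gene.

## Validation strategy and problem sizes

The test suite (testthat, 3rd edition) validates each operation against
an independent oracle: brute-force substring scanning for placement,
exhaustive enumeration for the duplex DP, `stats::t.test` /
`stats::p.adjust` for the DE path, closed-form hand computations for
Benjamini–Hochberg, Pearson and hypergeometric examples, and the
generator's planted truth for end-to-end recovery. Unit tests run at
desk scale (30 tRNAs, 60-fragment catalogs, 5 × 10⁴–2 × 10⁵ reads);
the two full-scale recovery simulations (586 fragments, 6 × 2 × 10⁶
reads) run once each in the acceptance tests and again, from scratch and
seed-parameterised, in `scripts/acceptance.R`. The full-scale runs take
roughly 45 seconds each on one CPU.

Composition recovery is measured pooled over all six samples, so the
group-specific subsets pull the measured shares a fraction of a
percentage point away from the normal-group anchors; the spiked
fold-change run omits group-specific fragments (a fragment absent from
one group is trivially differential and would otherwise be counted among
the calls), and the Venn run omits spikes, matching how the two recovery
questions are posed. Under σ = 0.1 jitter the top-ten share has an
intrinsic per-run standard deviation of about 0.4 percentage points —
dominated by the two fragments that carry three quarters of the
expression — which is the resolution limit of that statistic at this
design size.

## Known limitations

* CPM-only normalisation; no batch correction, no count-model inference.
* Exact seed matching only; no wobble or mismatch seeds, no site
  accessibility, no 3′-compensatory pairing.
* The energy table is reduced; absolute MFE values are comparable within
  this package, not to full Turner-parameter tools.
* Classification assumes mature, CCA-terminated references and
  well-anchored fragments; heavily modified or truncated real reads will
  need the configurable tolerances.
* Enrichment requires user-supplied gene sets; no identifier mapping.
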