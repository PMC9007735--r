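---
title: "Methods: cohort-scale structural-variant evidence indexing"
author: "svidx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-scale structural-variant evidence indexing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the approach

Short-read SV callers disagree, and a call set from one sample says
nothing about how common an event is. `svidx` takes the approach of
indexing *raw alignment evidence* across a cohort: each sample's
alignments are scanned once for the small discordant fraction (typically
well under 5% of templates), those records are pooled into a unified
interval index, and any candidate SV can then be interrogated for
per-sample support counts without revisiting the alignments. Counts
across many unaffected samples act as a panel of normals: a "somatic"
call with cohort support is almost certainly germline or artifact.

This vignette documents the model, the tunable parameters, the
synthetic-data generator the tests rely on, and the numerical and design
choices made where the behaviour of this family of tools is
conventionally underspecified.

# Evidence extraction

## The insert-size model

Libraries are summarized by the outer fragment span of concordant pairs:
mean `meanFragment` (bp), standard deviation `sdFragment` (bp), and the
discordant distance `discordantDistance` (bp), the span beyond which a
same-chromosome `+/-` pair is considered discordant. When estimated from
data (`estimateInsertModel`, `estimateInsertModelFromFile`) the
threshold is `round(mean + 2 * sd)`, i.e. roughly the upper 2.3% tail of
a Gaussian library. The package-wide default is 500 bp — the `μ + 2σ`
value of a typical 350 ± 75 bp human short-insert library, and
deliberately generous for the 300 ± 50 bp simulated library (whose
`μ + 2σ` is 400): a threshold below the true tail floods the index with
concordant pairs, while a slightly wide one only costs a little
sensitivity to the smallest deletions.

## Classification and record geometry

A template becomes *pairend* evidence if its mates are interchromosomal,
its genome-ordered strand configuration is not `+/-`, or its outer span
exceeds the discordant distance; it becomes *split* evidence if a read
has a supplementary segment. A template that is both discordant and
split contributes exactly one record of each class; mates are never
double-counted (the extractor works at template level after pairing
primaries by name and dropping secondary, duplicate and QC-fail
records; no mapping-quality cut is applied by default, but
`extractEvidence(minMapq = ...)` enables one).

Pairend end-intervals are breakpoint-padded: a `+` end extends
downstream to `start + discordantDistance`, a `-` end upstream to
`end - discordantDistance` (clamped at 0, and clamped so the genome
order of the two ends is preserved). The rationale: the junction a
discordant fragment spans lies somewhere in the unsequenced interior,
at most one fragment length from either read, so padding by the
discordant distance makes "record overlaps breakpoint" equivalent to
"fragment could span breakpoint" for any concordant-length fragment.
Split segments are never padded — they localize the junction exactly.

Records are written as nine tab-separated columns (two chromosome /
start / end / strand end descriptions, 0-based half-open, strands
`1`/`-1`, class `0` = pairend, `1` = split), sorted bytewise by left
chromosome then numerically by start and end — the C-collation order a
`sort -k1,1 -k2,2n -k3,3n` pipeline would produce. Extraction is a pure
function of (file, model, filters); re-runs are byte-identical.

# The cohort index

`buildCohortIndex` pools per-sample evidence files; every record is
registered under *both* of its end-intervals so interchromosomal records
are findable from either side (duplicate candidates are de-duplicated at
query time by record id). Interval overlap is evaluated under half-open
semantics (`a.start < b.end && b.start < a.end`); internally the ranges
live in a `GRanges` and search uses `findOverlaps`. Fidelity to any
particular on-disk index format of prior tools is explicitly not a goal
— only search-result equivalence, which is enforced by an independent
brute-force oracle (`bruteForceSearch`, a plain arithmetic linear scan)
that the test suite compares against on thousands of random probes.
Persistence (`saveCohortIndex`/`loadCohortIndex`) writes a JSON manifest
plus one TSV shard per left-end chromosome; the format is versioned and
self-contained.

# Query semantics

A query is an SV type plus left and right breakpoint intervals (0-based
half-open internally; the CLI accepts 1-based inclusive
`chr:start-end`). The left breakpoint is the genome-ordered smaller one;
break-end queries supplied in the reverse order are normalized with a
warning.

Both breakpoints are extended by the window `w` (default 500 bp — reuse
the extraction discordant distance) according to the SV type, the index
is searched with the left probe, and a candidate record is retained when
its left end overlaps the left probe, its right end overlaps the right
probe, and its strand configuration matches the type (table in the
README). Inversions run as two sub-queries — both probes extended
downstream for `+` evidence, upstream for `-` evidence; a record is
assigned to a sub-query by its left-end orientation, and the two
sub-query hit sets are united after per-record de-duplication (whether
the original tools sum or maximize the sub-queries is unstated; the
union is the conservative choice that counts each alignment once).
For split records the strand pair is the pair of aligned-segment
orientations in genome order. Every PED sample is reported, zeros
included; `-S`/`formatResult(summary = TRUE)` emits the one-line
aggregate (its meaning is not documented upstream; summary-only output
is this package's definition).

# Evaluation procedures

Sample-level classification against a truth catalog uses the standard
confusion quantities (P, N, TP, TN, FP, FN per SV, summed per type) and
the five derived metrics; undefined ratios (zero denominators) are `NA`,
never silently 0. SV call sets are compared by reciprocal overlap
(`min(shared/len(a), shared/len(b))`) at a 0.9 threshold with `>=`
inclusion and many-to-one matching (bedtools `-f 0.9 -r` semantics).
Germline filtering queries each tumor call against the panel index and
filters calls supported in at least `minSamples` cohort samples
(default 1; whether a single supporting sample should suffice is an
open question upstream, so the threshold is exposed). The resolution
sweep shifts both breakpoints jointly — preserving the SV length — in
50-bp steps to ±500 bp and reports the per-shift proportion of
supporting samples relative to the unshifted query, with the median
curve across SVs; zero-support queries are excluded as undefined rather
than treated as zero.

# The synthetic cohort generator

The generator is coordinate-level: no sequence is synthesized and no
aligner runs. Each sample's two haplotypes are piecewise maps of
reference segments with orientation (deletions remove a segment, tandem
duplications repeat one, inversions flip one, and a reciprocal
translocation exchanges chromosome arms). Fragments are placed uniformly
along each haplotype at the requested coverage with Gaussian lengths,
and read intervals are mapped back through the segment map, which
reproduces analytically the discordant geometry an aligner would report:
`+/-` distance-discordant pairs over deletions, `-/+` pairs over
duplication junctions, `+/+` and `-/-` pairs over inversion junctions,
interchromosomal pairs over break ends, and split reads where a read
crosses a junction.

Default study conditions (`defaultTestCohort`): 20 samples, two 2-Mb
chromosomes, 30 SVs (10 DEL and 10 DUP of 200–5,000 bp, 8 INV of
500–5,000 bp drawn log-uniformly, 2 reciprocal interchromosomal break
ends), allele frequencies uniform on 0.05–0.5 with Binomial(2, AF)
genotypes, 10× sequence coverage, 300 ± 50 bp fragments, 100-bp reads,
and a 4% rate of nonspecific uniformly-placed discordant templates
(`noiseRate`, capped below 5% in line with what real alignment files
show). SVs occupy shuffled layout slots with 20-kb chromosome margins
and ≥10-kb separation so query windows never straddle two events.

Numerical choices worth knowing:

- **Fragment-length truncation.** Lengths are truncated to
  `[2*readLength, mean + 4*sd]`. The lower bound keeps reads
  non-overlapping the gap; the upper bound (≈6e-5 of the mass) keeps
  the concordant library inside its own discordance threshold, so a
  zero-noise, all-reference sample extracts exactly zero evidence —
  without it, the Gaussian tail leaks nonspecific "discordant" pairs
  into nominally noise-free cohorts, which is exactly what `noiseRate`
  is for.
- **Split emission.** A read crossing a junction with ≥20 bp on both
  sides becomes a primary + supplementary split; with less overhang it
  is truncated to its larger piece (a soft-clip analogue) and the pair
  is kept. Pieces that map reference-contiguously on the same strand
  (e.g. across the second junction of a tandem duplication) are merged
  into one alignment, as an aligner would report them.
- **Breakpoint confidence intervals.** Truth queries
  (`svQueries`) and BED-derived germline-filter queries use 2-bp
  intervals straddling each junction (`[b-1, b+1)`). A junction falls
  *between* bases; a 1-bp interval on one side would abut — not
  overlap — split segments that end exactly at the junction under
  half-open semantics.
- **Haplotype assignment and RNG.** Heterozygous SVs ride haplotype 1;
  at most one reciprocal translocation per haplotype (co-carriage of
  the two default break ends is excluded when genotypes are drawn).
  Each sample consumes an RNG stream derived from (master seed, sample
  index), so extending a cohort never perturbs existing samples.

## What the simulator does and does not show

Passing tests demonstrate that classification, indexing, query
extension, strand matching, counting, and the evaluation procedures are
correct on data whose discordant geometry is exact. The generator does
not model base errors, mappability, GC bias, chimeric artifacts,
soft-clip base-level placement, or tumor subclonality — so the tests say
nothing about robustness to alignment noise beyond the uniform
nonspecific-discordant background, and real-data accuracy will be lower
than simulated accuracy.

One consequence of honest coverage modelling deserves emphasis: at 10×
coverage a heterozygous carrier samples its alternate haplotype at ~5×,
and the number of junction-informative templates for a single SV is a
Poisson draw with mean roughly 5–15 depending on type and size. Exact
(accuracy = 1.0) zero-noise recovery of *every* carrier in the default
cohort therefore holds for most, but not all, master seeds: occasionally
a carrier receives no junction-spanning fragment at all, which no
evidence-based method can recover. The acceptance suite runs the
canonical seed and reports the accuracy actually computed.

# Problem sizes

The shipped tests and the acceptance script run: the default 20-sample
cohort (~200,000 templates per sample, ~1.6 × 10^5 evidence records at
the 4% background rate) with and without noise; five noisy cohorts for
the stability check; 1,000 random probes and 1,000 random queries for
the oracle comparisons; and a 10-sample, 20× panel of normals carrying
50 polymorphic deletions against a 100-call tumor set (50 somatic + the
50 polymorphic) for the germline-filter evaluation — panel depth 20×
reflecting that panels of normals are typically sequenced deeper than
low-coverage cohorts, and guaranteeing each polymorphic call has
detectable cohort evidence.

# Known limitations

- CRAM input, realignment, base-level breakpoint refinement and
  insertion (INS) evidence are out of scope; deletions, duplications,
  inversions and break ends are indexed.
- The index holds all records in memory; no memory-mapped server mode.
- Per-sample normal-coverage levels are not tracked, so "no support"
  and "no coverage" are indistinguishable, exactly as in the underlying
  approach.
- Counts are raw per-sample alignment tallies; no genotype likelihoods
  or allele-frequency model is fitted on top of them.
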