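---
title: "chromprofiler: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromprofiler: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromprofiler)
library(GenomicRanges)
```

chromprofiler implements the quantitative core of a chromatin time-course
analysis: turning aligned sequencing fragments (ChIP-seq, MNase-seq,
nascent RNA-seq) into normalized coverage, peak sets, aggregate (metagene)
profiles with resampling-based inference, and per-gene RNA polymerase II
pausing statistics. This vignette describes the statistical model behind
each stage, the tunable parameters and their defaults, the design choices
made where several readings were defensible, and what the synthetic-data
generator does and does not emulate.

## Coordinates and containers

All intervals live in `GRanges` (1-based, closed), the standard
Bioconductor convention; BED and bedGraph files are converted at the I/O
boundary (`read_bed()`, `read_bedgraph()`), GTF needs no conversion. Using
the field's container rather than a bespoke 0-based one means every
overlap, sort and clip operation is the extensively-tested IRanges code
path, and a single convention rules out off-by-one drift between modules.
Chromosome matching is exact-string throughout: nothing aliases `chr1` to
`1`, so a mislabeled fixture fails loudly rather than silently dropping
signal.

## Coverage tracks and normalization

`fragments_to_coverage()` converts a fragment library into a binned track.
Single-end reads can be extended to the expected fragment length from
their 5' end (`extend_to`; 200 bp is the transcription-factor ChIP
convention, 250 bp for PolII ChIP) or re-centered (`center_at`); paired
fragments are used as-is. Fragments running past a chromosome end are
clipped, not dropped, preserving depth at the boundaries of the small
synthetic chromosomes. A bin's value is the *mean per-base coverage* in
the bin — not a count — so the track's scale is independent of the bin
size and 1x-coverage semantics survive re-binning. Tracks are generated at
1-bp resolution for profile work and 10-bp bins for enrichment summaries;
both defaults can be overridden.

RPGC ("reads per genomic content") scaling divides by the total base
coverage and multiplies by an effective genome size, so that mean coverage
over the effective genome is exactly 1x. The packaged constant
`EFFECTIVE_GENOME_SIZE_MM10` (2,150,570,000 bp) is the mouse GRCm38 value;
synthetic genomes pass `genome_size(genome)` instead, since they are fully
mappable by construction. Input subtraction operates on two RPGC tracks —
the common 1x scale *is* the depth normalization — and preserves negative
bins, which carry real information about regions where input exceeds ChIP.
Ratio normalization (e.g. a histone mark against an H3 control) adds a
pseudocount to numerator and denominator before dividing; the default of
0.1 RPGC units bounds the ratio in H3-depleted bins without flattening
genuine enrichment, and is deliberately configurable because no principled
universal value exists.

## Peak-set algebra

Four conventions needed fixing where the operations are usually described
only informally:

* **Co-bound union** (`cobound_union()`): pairs of peaks from two factors
  overlapping by at least 1 bp are merged into their joint span;
  transitively touching spans merge further; peaks with no cross-set
  partner are *excluded*. This reads "union of overlapping peaks" as
  co-bound-only, which matches the biology of a complex defined by joint
  binding (one subunit's sites are largely a subset of the other's); the
  plain union of both sets is available via `cobound = FALSE`.
* **Replicate consensus** (`consensus()`): bases covered by peaks from at
  least `min_support` (default 2) distinct replicates form cores, and each
  consensus region is the union of every replicate peak overlapping its
  core. Anchoring on the core but reporting the contributing-interval
  union avoids fragmenting peaks into slivers of pairwise intersection,
  the same behavior the widely-used differential-binding preprocessors
  implement. Within a replicate, overlapping or book-ended peaks are first
  merged — a peak set is non-overlapping by construction.
* **All-dataset intersection** (`intersect_all()`): where several
  published datasets exist for a mark, only first-set peaks overlapped by
  at least one peak in *every* other dataset survive.
* **Blacklist filtering** (`filter_blacklist()`): any 1-bp overlap with a
  blacklisted region removes the whole peak; trimming would leave
  artifact-adjacent fragments of peaks in the set.

Enhancer classification labels H3K4me1 regions: overlap with H3K4me3
reassigns the region to promoter chromatin; otherwise joint H3K27ac and
p300 support makes an active enhancer, else an inactive enhancer. Region
classification against gene models applies the precedence
`promoter > active_enhancer > inactive_enhancer > other`; promoters win
because the TSS annotation is the most specific. The promoter window
reuses the traveling-ratio definition (TSS −2000/+500 bp) — one documented
constant instead of two silent ones.

Fragment-to-region counting assigns each fragment by its midpoint, making
counts additive across adjacent windows and immune to fragment-length edge
effects; input-subtracted counts rescale the input by the library-size
ratio and floor at zero.

## Aggregate profiles and bootstrap inference

`compute_matrix()` extracts, for each reference point (TSS or feature
center), signal in 5-bp bins across ±1500 bp, with out-of-chromosome
positions contributing zero. Windows are strand-symmetric: a minus-strand
reference covers the exact mirror image of a plus-strand one (offsets
−upstream .. +downstream−1 in transcription direction), so reflecting the
genome reproduces the matrix — a property the test suite checks against a
per-base oracle.

Normalization proceeds in two steps. Each location's row is divided by its
own mean (`rowwise_normalize()`), removing between-locus scale so that
every locus contributes shape, not amplitude; rows with zero signal are
undefined under this scheme and are dropped with their count reported. The
row mean is taken over the full window, including zero bins — the
alternative (non-zero bins only) would make the normalization depend on
sparsity. The replicate-averaged profile is then divided by its mean over
the outermost 50 bp on each side (−1500..−1450 and +1450..+1500),
yielding enrichment over a local baseline that is *shared by all
replicates* — a single consistent baseline rather than one per replicate —
so replicate profiles stay on a common scale and sparse flanks do not
inject per-replicate scale noise.

Bootstrap confidence intervals (`bootstrap_ci()`, default 5000 iterations)
resample *locations* within each replicate with replacement, re-running
the normalization on every resample. Locations are the exchangeable unit
of a metagene profile: replicates are few and structured, bins are
correlated, but loci are (approximately) independent draws from the
feature class being profiled. The CI is the empirical 2.5/97.5 percentile
per bin rather than a normal approximation, because normalized enrichment
values are ratio statistics with visible skew; the reported center is the
non-resampled estimate.

The center test (`empirical_pvalue()`) compares two conditions at a single
bin — by default the central bin, the reference point itself. Both
conditions are resampled independently per iteration and the two-sided
empirical p-value of the difference distribution is computed with add-one
smoothing,

\[
p = \min\!\Big(1,\; 2\min\big(\tfrac{1+\#\{d_b\le 0\}}{B+1},\;
\tfrac{1+\#\{d_b\ge 0\}}{B+1}\big)\Big),
\]

which guarantees \(p \ge 1/(B+1)\) and never reports an exact zero. The
test suite calibrates both constructions on i.i.d. Gaussian location
matrices (200 locations, 3 replicates; 1000 bootstrap iterations over 200
simulations for CI coverage, 500 iterations over 200 simulations for
type-I error) and on the MNase generator's null.

Nascent RNA-seq profiles deliberately skip both normalization steps —
absolute nascent signal is the quantity of interest — and use a parametric
CI of ±1.96 s.e.m. across replicate profiles (`sem_profile()`), computed
per strand with a plus-strand-only reporting option.

## The traveling ratio

For each gene the promoter-proximal window is TSS −2000..+500 bp and the
gene body runs from +501 bp to the gene end (the polyA addition site),
strand-aware and clipped at chromosome boundaries (RPKM uses the clipped
length, avoiding density inflation for boundary genes). Both windows are
scored as RPKM with midpoint assignment, and the default statistic is the
promoter fraction

\[
\mathrm{TR} = \frac{d_p}{d_p + d_b},
\]

where \(d_p, d_b\) are the promoter and body densities. This definition is
fixed by its reference values: a uniformly covered (unpaused) gene gives
TR = 0.5 and a gene with three-fold promoter density gives TR = 0.75 for
*any* window lengths, whereas the grammatically-possible alternative —
promoter density over the density of the combined promoter+body region —
gives 1 for uniform coverage. The alternative remains available as
`definition = "density_ratio"`. Genes need at least 1 RPKM in both windows
to enter distribution-level analyses (`tr_table()`), which removes
unexpressed genes whose TR is sampling noise. One-base conventions are
strand-symmetric: the minus-strand windows are exact mirror images of the
plus-strand ones.

Condition comparisons use the two-sample Kolmogorov–Smirnov test on the
per-gene TR values — the canonical distance between two empirical CDFs,
which is how such shifts are plotted — with Mann–Whitney as an option;
both empirical CDFs are returned as tabulated curves.

## The synthetic-data generator

The generator exists so that every stage of the pipeline runs and is
testable end to end with no external data. It is seeded and fully
deterministic: each (library, condition, replicate) derives its own RNG
stream from the master seed by stable string hashing, so adding or
reordering libraries never perturbs the others, and identical
configurations produce byte-identical fixture files.

Default geometry is two 2-Mb chromosomes. Genes (default 100) are placed
without overlap on both strands with spans of 3–10 kb, so promoter and
body windows always fit. Library depth varies between replicates as a
negative binomial around the configured mean (dispersion 0.05; Poisson in
the limit), and *within*-library composition is multinomial with
gamma-jittered per-region weights — the gamma-Poisson construction that
gives per-region counts their overdispersed, NB-like replicate-to-replicate
behavior while keeping aggregate composition realistically stable.

* **ChIP** libraries mix a genome-wide uniform background with an excess
  component uniform within peaks, weighted so that mean midpoint density
  inside peaks is exactly `enrichment`-fold the outside density; at
  enrichment 1 the excess vanishes and the library is statistically
  indistinguishable from its matched input (which is always
  background-only).
* **MNase** libraries draw ~147-bp fragments centered on nucleosome dyads
  with 20-bp Gaussian jitter. Reads are allocated between dyads (weight ∝
  occupancy, times 1+delta in the treated condition) and a delocalized
  uniform background whose weight is fixed at the control-condition share
  of 0.5. Anchoring the background weight means an occupancy gain shifts
  read share toward the dyads — which is how increased MNase protection
  manifests in a depth-normalized library — and the 0.5 background share
  reflects that real MNase libraries have pervasive nucleosomal coverage,
  keeping profile flanks populated the way real data keeps them (a
  near-empty flank would make enrichment-over-baseline ratios unstable in
  a way real MNase-seq is not).
* **PolII** libraries place per-gene fragments (NB around 2000 per gene)
  into the promoter or body window with probability proportional to
  density × window length, uniformly within the window, so the true TR of
  a gene is exactly `d_p/(d_p+d_b)` and is recoverable to within binomial
  sampling error (±0.03 at 2000 fragments).
* **Nascent RNA** reads are stranded, with 5' positions drawn from a
  mixture of a truncated exponential from the TSS (weight 0.7, decay 750
  bp — the scale of the 5' excess the profiles are meant to detect) and a
  uniform component along the gene.

What the generator does *not* emulate: sequence content and mappability
(there is no FASTA), GC bias, copy-number structure, realistic peak-width
and occupancy distributions, chromatin-state autocorrelation along the
genome, or the mouse genome's scale. Tests passing on this generator
demonstrate that the *statistics* are implemented correctly and calibrated
under their stated assumptions — not that any biological conclusion
transfers to real libraries.

## Numerical choices and degenerate inputs

* Zero-signal rows are dropped before row normalization and excluded from
  the bootstrap pool; their count is reported.
* A zero flank mean, an all-zero track under RPGC, an empty TR table, and
  a sub-2-replicate s.e.m. request are hard errors, not NaN propagation.
* Genes whose body window is empty after clipping are flagged unusable and
  skipped, with the loss logged.
* bedGraph serialization run-length merges equal adjacent bins and prints
  six significant digits; write-then-read reproduces a track to that
  precision.
* Bootstrap and p-value seeds are explicit arguments; the global RNG state
  is saved and restored around every seeded operation.

## Problem sizes in the test suite

The suite checks exactness against brute-force per-base and all-pairs
oracles on instances up to 500 intervals and 100 fragments (200 seeded
trials per operation), calibrates the bootstrap machinery on 200-location
matrices over 200 simulations, and runs the MNase detection and null
analyses at 200 sites × 3 replicates with 100,000-fragment libraries —
sizes chosen so each property is measured with useful precision while the
whole suite stays interactive.

## Known limitations

* Peak calling itself is out of scope; the pipeline consumes called peak
  sets (or the generator's truth).
* Differential-binding statistics stop at the input-subtracted count
  table; no FDR model is fitted.
* The traveling ratio scores each gene independently; overlapping genes'
  signal is not deconvolved.
* Bootstrap inference treats locations as exchangeable; spatial
  correlation between nearby features (overlapping windows) is not
  modeled and will make intervals anti-conservative if features are
  densely packed.
* bigWig and BAM adapters are not built in; convert to bedGraph/BED
  externally (e.g. with standard tooling) where needed.
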