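---
title: "Constructing small-variant benchmark sets: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing small-variant benchmark sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benchforge)
```

# The problem and the overall model

A benchmark set asserts two things at once: the variants in its VCF are
correct, and anywhere else inside its BED is homozygous reference. The
second assertion is the dangerous one — it is what turns a query's extra
call into a scored false positive — so the whole construction is shaped
by the question *where can we afford to assert hom-ref?* The answer
built into this package: only where (i) enough independent callsets are
effectively callable, (ii) no covering callset disagrees, and (iii) the
locus is not in a region class known to defeat current technologies.

The pipeline composes five stages, each usable on its own:
interval algebra (`region_set` and friends), callable-region computation
(`hifi_callable`, `linkedread_callable`, `callable_from_depth`), the
exclusion stack (`elliptical_outliers`, `filter_segdups`,
`compose_exclusions`, ...), integration (`arbitrate`,
`build_benchmark`), and evaluation (`mendelian_report`,
`compare_benchmark`).

# Interval algebra and its dialect

Every region is a 0-based half-open interval; VCF positions are 1-based
and converted exactly once at ingestion, so there is a single place to
audit off-by-one errors. The algebra is implemented natively on sorted
endpoints, and its dialect is pinned:

* normalization merges overlapping **and book-ended** intervals, after
  every operation (whether the original tooling merged book-ended
  intervals at every step or only at output is not recoverable; merging
  every time is the self-consistent choice and is what the normalization
  invariants test);
* thresholds written "greater/less than" are strict: a tandem repeat of
  exactly 10,000 bp is *not* a ">10 kb" repeat, a segdup stack of depth
  exactly 5 is *not* excluded, and the boundary cases are tested
  explicitly;
* percentage slop extends each interval of length L by
  `round(0.25 * L)` per side, rounding half away from zero, then clips
  to chromosome bounds;
* `stack_depth_filter` deliberately does **not** normalize its input:
  the overlaps are the signal.

All set operations are property-tested against per-base boolean-array
oracles on randomized instances; the oracle marks bases in a logical
vector and never touches the interval code.

# Callable regions

Tunable parameters, with units and defaults (`callable_config()`):

| parameter | default | meaning |
|---|---|---|
| `min_depth_unsplit` | 20 reads | minimum depth, all-reads track |
| `max_depth_unsplit_factor` | 2 | x median coverage, all-reads track |
| `min_depth_hap` | 5 reads | minimum depth, per-haplotype track |
| `max_depth_hap_factor` | 1 | x median coverage, per-haplotype track |
| `median_source` | `vcf_positions` | where the median is measured |

Two decisions here were genuinely open. First, "median coverage for VCF
entries" can be read as the median depth at the callset's variant
positions or as a genome-wide median; the default is the former (it is
the literal reading and is robust to large uncovered fractions), and the
latter is offered as a config option (`genome_wide`, length-weighted).
Second, whether the unsplit linked-read track used a 2x or 1x median cap
is ambiguous in the source material; the default applies the unsplit
thresholds (min 20 / 2x) to the unsplit track and the per-haplotype
thresholds (min 5 / 1x) to split tracks, for both technologies.

The mapping-quality states of the original callable-loci tooling are not
reimplemented: the contract is pure depth-window classification on
tracks that are assumed to be restricted to high-mapping-quality reads
upstream. Haplotype tracks with zero coverage (unphased regions) are
treated as not-callable, never as errors.

The variant span used for ±50 bp masks is `[pos-1, pos-1+len(ref))`
before padding, which covers deletions correctly.

# The exclusion stack

**Elliptical coverage outliers.** The displayed form of the statistic in
its source is ambiguous about a square root (the prose enumerates
"took the square root of the sum" while the printed expression divides
by 2 without a root). The implementation is
`sqrt(((hifi/median_hifi)^2 + (ont/median_ont)^2) / 2)`, which has the
useful anchors value = 1 at (median, median) and value = 2 at (2x, 2x);
because the Tukey-fence rank threshold is *not* invariant under the
nonlinear alternative, both forms are exposed
(`form = "sqrt_mean_sq"` / `"sum_sqrt"`). Quartiles are type-7 (linear
interpolation) and IQR = Q3 − Q1; these must be pinned for
reproducibility. Q3/IQR are computed genome-wide (not per chromosome),
and flagged windows are merged only when abutting — no gap tolerance.
The statistic is scale-free per technology: jointly rescaling one
technology's depths and its median leaves flagging unchanged.

**Dual-technology high coverage.** The printed expression
"coverage/2∗2.5" is read left-to-right as (mean/2)·2.5 = 1.25x mean; the
multiplier is a config knob because the expression is ambiguous.

**Assembly multi-contig regions.** Coverage is thresholded per
haplotype (≥2 contigs of one haplotype), union over haplotypes, then
intersected across assemblies and length-filtered (>10 kb). Summing
across haplotypes instead would be degenerate: a complete diploid
assembly covers every base once per haplotype, so the summed coverage
is ≥2 genome-wide and carries no signal.

**Segmental duplications.** Records longer than 10 kb with identity
>99% are stacked and bases with pile-up depth >5 are excluded. Identity
columns are auto-detected as fractions or percentages (any value >1.5
triggers rescaling, with a message).

**Fixed loci.** The KIR locus is emitted from built-in coordinates
(1-based inclusive source converted to 0-based half-open); the VDJ track
is restricted to chromosomes 2, 14 and 22; centromere/heterochromatin
applies to GRCh38 and the collapsed/expanded track to GRCh37.

**Progressive accounting.** `compose_exclusions` reports each class
after subtracting all classes above it, so the ledger rows sum exactly
to the union — the property the ledger tests assert for arbitrary
inputs. The final short window of each chromosome participates with its
true width.

# Integration

The per-technology repeat-class matrix (which repeat classes are
excluded from which technology's callable regions) is encoded cell by
cell and asserted cell by cell in a table-driven test. The inner
expert-heuristics of the historical integration (per-technology bias
annotations, rescue of filtered calls) are cited to prior work in the
source material and not recoverable from it; this package deliberately
implements the documented support/veto model instead: a site is accepted
when `min_support` (default 2) covering callsets agree exactly on
(chrom, pos, ref, alt, genotype) and no covering callset reports a
conflicting record. Genotypes must match exactly; phasing is ignored for
matching. Annotation-only callsets (Ion Torrent, SOLiD) contribute
annotations but never support, veto or exclusion. Conflict loci are
padded ±50 bp, mirroring the mask convention.

One composition rule follows from the benchmark semantics rather than
from any explicit statement: benchmark regions keep only bases where at
least `min_support` callsets are effectively callable. A base covered by
a single callable callset can never reach the support threshold, so
asserting hom-ref there would be unfalsifiable within the model; the
monotonicity property (shrinking any callable set never grows the
benchmark) holds under this rule and is tested.

Finally, any tandem repeat or homopolymer only partially covered by the
benchmark regions is removed wholesale (`remove_partial_repeats`,
idempotent), so the emitted BED never clips a repeat.

# Trio evaluation

`classify_trio_site` is validated against an exhaustive
parental-transmission oracle on all 27 biallelic genotype combinations.
Sites present in only one member inside the joint regions are imputed
0/0 for the others — required to detect genotype-absence violations, and
exactly what the benchmark regions assert. Multi-allelic sites are
classified on the joint allele set, not decomposed. Complex
representation differences across members are *not* reconciled by
haplotype resolution; such sites can surface as `violation_other`, which
is a documented limitation. Whether multi-allelic sites should count
once or per allele in violation totals is unspecified in the source
material; counting is per normalized site here.

# Comparison harness

Matching is normalized-exact: left-aligned, parsimony-trimmed,
multi-allelics decomposed with genotype bookkeeping (validated against
an independent haplotype-core oracle that computes the canonical form
from the full alternate haplotype by maximal common suffix, then
prefix). Full haplotype-aware matching engines are not reimplemented —
the comparator is harness, not contribution — so complex-representation
differences count as FP+FN pairs; normalization removes most
representational mismatch at fixture scale. Genotype mismatches at a
matching allele count strictly as FP+FN, with an optional separate
genotype-error class. Stratified sorting by precision − recall uses
unfiltered query counts.

# The synthetic world: what it does and does not emulate

The generator plants, at fixed coordinates on 2 chromosomes x 1 Mb
(large enough for 2,000 coverage windows and every repeat length class,
small enough for fast tests): tandem repeats of each matrix class,
perfect/imperfect homopolymers, LINE-like elements, a low-complexity
centromere, a dedicated low-mappability block, a 6-copy 12-kb
segmental-duplication family at 99.5% identity (which must trigger the
many-copy exclusion) and a 2-copy control (which must not), plus a 10-kb
2x duplication in the sample. Coverage is Poisson around per-technology
means (HiFi 35x, ONT 45x, short 50x, linked 40x — mid-range of what the
production datasets provide), doubled over the duplication, near zero
over the centromere, and collapsed for short reads over low-mappability
regions. Error structure mirrors the documented short-read failure
modes: agreeing paralog false positives inside the duplicated copies,
LINE heterozygous sites genotyped hom-alt by haplotype dropout, an
agreed homopolymer indel false positive. Each sub-generator draws from
its own RNG stream (`seed + 1 .. seed + 4`) so changing one profile does
not reshuffle the others; a fixed seed reproduces every output
byte-for-byte.

What the toy world does **not** emulate — and therefore what passing
tests do not show about real data: read-level errors and alignment
artifacts (tracks and VCFs are the interface), realistic repeat
polymorphism, population structure in variant sites, reference errors,
and the sheer scale at which quartile statistics and conflict resolution
meet long-tailed real coverage distributions. The planted guarantees
(duplication excluded, repeats fully in or out, errors absent, easy
recall ≈ 1) validate the machinery, not genome-scale performance.

# Numerical choices and degenerate inputs

* Weighted medians resolve exact 0.5 boundaries by averaging adjacent
  values; quartiles are type-7 throughout.
* A zero median depth in the elliptical statistic is an error
  (degenerate track); a zero-coverage haplotype track is simply
  not-callable.
* Empty region sets are legal everywhere; NG50 of an empty or
  insufficient set is NA.
* Slop in percent mode without a genome warns (no clipping guarantee).
* Chromosome names pass through verbatim; outputs are sorted in
  genome-file order when a genome is bound.

# Problem sizes

The test suite runs the full toy-world pipeline for all three trio
members (about 1,300 truth variants each, five callsets, 2,000 coverage
windows) plus ~300 randomized oracle instances for the interval algebra;
the acceptance script repeats the end-to-end construction from scratch
at the given seed. Both complete in well under a minute on one CPU,
which is the intended scale for a desk-checkable reference
implementation.
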