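# benchforge

Construction and evaluation of small-variant benchmark sets in R.

## The problem

A small-variant *benchmark set* is a pair of files — a VCF of trusted
variants and a BED of confident regions — with a strong semantic: inside
the BED, every true variant is asserted to be in the VCF, so a query
callset can be scored for false positives *and* false negatives there.
Building one for a real genome means integrating callsets from many
sequencing technologies (short reads, linked reads, accurate long reads),
trusting each only where its evidence supports confident calling, and
carefully excluding regions that no current technology can benchmark
reliably: many-copy segmental duplications, copy-number variants in the
sample relative to the reference, long tandem repeats, structural
variants, and fixed problematic loci such as centromeres and the VDJ.

`benchforge` implements that construction pipeline end to end, for users
who build or study reference benchmarks: exact genomic interval algebra,
callable-region computation from depth tracks (including haplotype-split
tracks), the difficult-region exclusion stack with progressive
accounting, cross-callset arbitration under a per-technology repeat-class
exclusion matrix, trio Mendelian evaluation with de novo classification,
and a stratified precision/recall comparison harness. A deterministic
synthetic-data generator produces a complete toy diploid-trio world so
every stage is testable without any downloads.

## The methods at the core

**Callable regions.** A dataset's callable regions are depth windows with
`minDepth <= depth <= maxDepth`, where `maxDepth` is a multiple of the
median coverage at the callset's variant positions (defaults: min 20 /
max 2x median for the unsplit track; min 5 / max 1x median per
haplotype-split track). HiFi callsets take the *union* of the unsplit and
two haplotype callable sets (a region callable on one haplotype alone is
callable), minus a mask of removed VCF entries (multi-allelic entries and
RefCall entries with QUAL < 40, each ±50 bp). Linked-read callsets
additionally subtract regions callable on one haplotype but not the other.

**Coverage-outlier CNV exclusion.** For 1,000-bp windows with mean HiFi
and ONT depths, each window's elliptical value is

    value_i = sqrt(((hifi_i / median_hifi)^2 + (ont_i / median_ont)^2) / 2)

so a window at median depth in both technologies scores exactly 1 and a
window duplicated in the sample (~2x in both) scores ~2. Windows with
`value > Q3 + 1.5*IQR` are excluded as candidate duplications, alongside
windows >1.25x mean in both technologies intersected with external CNV
calls, and regions covered by ≥2 assembly contigs of one haplotype in
every assembly.

**Integration.** A variant is accepted when at least `min_support`
(default 2) callsets — each effectively callable at the locus after its
technology-specific repeat-class exclusions — report an identical
(chrom, pos, ref, alt, genotype); loci where covering callsets disagree
are excluded ±50 bp. Benchmark regions keep only bases where the support
threshold is attainable, subtract the exclusion stack, and then remove
*all* of any tandem repeat or homopolymer that is only partially covered.

**Trio evaluation.** Within the intersection of the three members'
regions, a site is Mendelian-consistent iff the son's alleles can be
drawn one-from-each-parent; the one biologically plausible violation
(son 0/1, both parents 0/0) is classified as a potential de novo, and all
other violations are excluded ±50 bp from all three benchmarks.

## Worked example

Build the seeded synthetic trio world (2 chromosomes x 1 Mb, with planted
segmental-duplication families, tandem repeats, homopolymers, LINEs, a
centromere, a 2x duplication, and five per-technology callsets with
planted short-read error structure), then run the full pipeline:

```r
library(benchforge)

fx  <- make_fixtures(fixture_config(seed = 42))
res <- run_fixture_pipeline(fx, "son")

res$benchmark
#> benchmark_set: 1091 variant(s) in 40 region(s) (1,824,070 bp)

res$ledger
#> Exclusion ledger (progressive subtraction):
#>                        label bp_raw bp_progressive
#> 1 centromere_heterochromatin  40000          40000
#> 2                        vdj   1000           1000
#> 3            segdup_highcopy  72000          72000
#> 4               cnv_coverage  17000          17000
#> 5                sv_expanded   1500           1500
#> 6                   tr_gt10k  12000          12000
#> Total excluded bp: 143,500
```

The benchmark covers 91.2% of the toy genome; the ledger shows what the
remaining 7.2% of excluded sequence is (each row reports bases not
already excluded by the rows above it, so the rows sum to the union).
The six-copy 12-kb duplication family is fully excluded
(`segdup_highcopy`), and `cnv_coverage` is the planted 10-kb sample
duplication found by the elliptical coverage outlier plus the flagged
windows around it.

Mendelian evaluation of the three members' benchmarks recovers exactly
the planted de novo mutations and nothing else:

```r
runs <- lapply(c(son = "son", father = "father", mother = "mother"),
               function(m) run_fixture_pipeline(fx, m)$benchmark)
mendelian_report(runs$son, runs$father, runs$mother)$summary
#> $n_sites            1572
#> $n_consistent       1562
#> $n_de_novo_snv      7
#> $n_de_novo_indel    3
#> $n_violation_other  0
```

A command-line wrapper is installed at `exec/benchforge` with
`fixtures`, `run` (YAML config of file paths), `trio` and `compare`
subcommands.

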