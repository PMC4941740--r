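# multicom

Reproducibility-consensus SNP selection across variant callers, with the
downstream candidate-gene discovery chain used in targeted resequencing
studies of contrasted phenotype groups (e.g. high- vs low-milk-yield
livestock cohorts).

## The problem

Different variant callers disagree: on the same alignments, each tool emits
thousands of calls no other tool reproduces. In exome-target data these
non-reproducible ("tool-specific") calls behave like false positives — their
transition/transversion (ts/tv) ratio drifts from the ~2.6–3.5 expected for
true exonic SNPs toward the ~0.5 of random artifacts, and they fall in
intergenic sequence at roughly twice the rate of reproducible calls.

`multicom` implements the simple, effective remedy: call variants with
*n* independent tools and retain a SNP only when it is reported by at least
*k* of them (default *k* = 2 of 3). Because caller errors are largely
independent while true variants are seen by every tool, the consensus set has
higher precision than any single caller *and* a larger yield than the
strict intersection. Formally, for callsets `C_1..C_n` (each a set of variant
keys `(chrom, pos, ref, alt)` filtered at depth ≥ 5 and QUAL ≥ 30):

    shared(k) = { v : |{ i : v ∈ C_i }| ≥ k }

Downstream, the package derives group-specific SNP sets by set difference of
the two groups' consensus sets, maps SNPs to genes and region classes
(CDS > 5'UTR > 3'UTR > exon > intronic > intergenic) from BED/GFF3 intervals,
partitions candidate genes against reference QTL gene lists, tests gene-set
overlaps with the upper-tail hypergeometric test

    P(X ≥ k) = Σ_{i=k}^{min(K,n)} C(K,i) C(N−K,n−i) / C(N,n)

under Benjamini–Hochberg correction, overlaps candidates with differential
expression tables, and aggregates per-sample sequencing run metrics. A seeded
simulator generates multi-caller two-group callsets with the error structure
above (true ts/tv 2.6, false-positive ts/tv 1.8, 2× intergenic placement of
false positives, per-caller sensitivity 0.95, independent errors), so every
pipeline stage is testable end to end without external data.

## Worked example

```r
library(multicom)

cfg <- sim_config(seed = 42)            # ~10,000 true SNPs, 3 callers, 2 groups
sim <- simulate_dataset(cfg)

filtered <- lapply(sim$callsets$high, filter_callset, min_depth = 5, min_qual = 30)
res <- multicom(filtered, min_support = 2)
res
#> <consensus_result> group=high k=2 callers=samtools,freebayes,varscan
#>   per-tool totals: samtools=7229 freebayes=7268 varscan=7256
#>   shared (support >= 2): 7396
#>   tool-specific: samtools=443 freebayes=452 varscan=419

tstv_ratio(res$shared, label = "shared", group = "high")
#> <tstv_report> shared/high ts=5347 tv=2049 ratio=2.61
tstv_ratio(res$tool_specific$samtools, label = "samtools-specific", group = "high")
#> <tstv_report> samtools-specific/high ts=293 tv=150 ratio=1.95

low <- multicom(lapply(sim$callsets$low, filter_callset), 2)
partition_groups(res, low)
#> <group_partition> high-specific=1714 (23.2%) low-specific=2489 (30.5%) common=5682
```

Reading the output: the 2-of-3 consensus keeps 7,396 SNPs — more than any
single tool kept on its own — while the ~440 calls unique to each tool show
the depressed ts/tv (1.95 vs 2.61) expected of artifacts. The group partition
then isolates the SNPs found only in the high- or only in the low-phenotype
group's consensus set, with percentages relative to each group's total.

A full file-based run (filter → consensus → QC → group partition → genes →
QTL partition → DEG overlap → run summary) is driven by
`run_pipeline(pipeline_config(...))` or the CLI:

```sh
inst/scripts/multicom simulate -o simdir --seed 7
inst/scripts/multicom filter --vcf simdir/high_samtools.vcf --min-dp 5 --min-qual 30 -o filtered.vcf
inst/scripts/multicom run --config pipeline.cfg
```

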