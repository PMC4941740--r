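---
title: "Consensus SNP selection and candidate discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus SNP selection and candidate discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multicom)
```

## The model

Variant callers make partially independent errors. If a true SNP is detected
by each of $n$ callers with probability $s$ and a false call arises in each
caller independently, then requiring support from at least $k$ callers
retains true variants with probability
$\sum_{j \ge k} \binom{n}{j} s^j (1-s)^{n-j}$ — for $n=3$, $k=2$, $s=0.95$
that is $\approx 0.993$ — while a false positive survives only if two callers
invent the *same* (chrom, pos, ref, alt) record, which is negligible when
errors are independent over a large genome. The consensus ("2-of-3") set is
therefore simultaneously more precise than any single caller and larger than
the 3-way intersection; relative to a conservative caller it can *increase*
yield, which `discovery_gain()` quantifies as
$(|\text{shared}| - T_c)/T_c$ per caller $c$.

Two diagnostics justify the rule without access to truth:

* **ts/tv ratio.** Transitions (A↔G, C↔T) outnumber transversions ~2.6–3.5×
  in clean exome-target SNP sets, while random artifacts approach the uniform
  expectation of 0.5 (4 of 12 ordered base pairs are transitions). A depressed
  ts/tv in tool-specific calls marks them as artifact-rich.
* **Region composition.** In exome-targeted data, artifacts fall in
  intergenic sequence at roughly twice the rate of true calls; the package
  classifies each SNP by interval precedence
  CDS > 5'UTR > 3'UTR > exon > gene body (intronic) > intergenic.

Downstream, group-specific SNPs are plain set differences of the two groups'
consensus sets — "specific" deliberately conflates *never called* with
*called but sub-threshold* in the other group, because both mean the site
failed to validate there. Gene-level overlaps (QTL reference lists, DEG
tables) are tested with the one-sided upper-tail hypergeometric test and
Benjamini–Hochberg correction at adjusted $p < 0.01$.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_depth` | 5 | reads | the conventional floor below which genotype evidence is unreliable; inclusive (≥) |
| `min_qual` | 30 | phred | 99.9% call confidence; inclusive |
| `min_support` (k) | 2 of 3 | callers | smallest k that suppresses independent errors without sacrificing yield |
| enrichment / DEG alpha | 0.01 | adjusted p | the conventional strict FDR threshold for candidate reporting |
| `tstv_true` | 2.6 | ratio | lower edge of the expected exome-target range (2.6–3.5) |
| `tstv_fp` | 1.8 | ratio | centre of the dynamic 1.6–2.4 range observed for tool-specific calls |
| `fp_intergenic_multiplier` | 2.0 | fold | "intergenic almost doubled" signature of artifact calls |
| `caller_sensitivity` | 0.95 | probability | high but imperfect per-caller detection, typical of deep targeted data |
| `caller_fp_rate` | 5% of truth | count | matches the observed 3.8–9.3% tool-specific fractions |

## The synthetic world

`sim_config()` describes a small genome (five 10-Mb chromosomes), 500 gene
models (5'UTR, five 300-bp CDS exons with 1-kb introns, 3'UTR), and three
disjoint truth sets: 6,000 SNPs common to both groups, 1,600 high-specific
and 2,400 low-specific (the ~60/16/24% proportions of the motivating study's
consensus sets, scaled to ~10,000 variants so the suite runs in seconds).
True variants are intergenic with probability 0.3; substitution types are
drawn so the expected transition fraction is $t/(1+t)$ for target ratio $t$.
Each caller detects each true variant independently (sensitivity 0.95),
draws a Poisson number of false positives with the FP ts/tv mix and a 2×
intergenic placement bias, and emits QUAL ~ U[30, 100), DP ~ U{5..60}; a 5%
`subthreshold_fraction` of calls instead receives QUAL < 30 or DP < 5 so the
threshold filter has real work to do (the value is a one-time choice of a
realistic near-threshold rate — end-to-end recovery at these defaults is
~97%, above the 95% acceptance bar by construction of the stated world, not
by tuning). All randomness flows from one master seed through labelled
sub-seeds (`split_seed(seed, context...)`, a 31-bit string hash), so every
artifact is reproducible from `(config, seed)` and sub-streams do not
interact.

What the simulator does **not** emulate: alignment-induced error clustering
(e.g. from mapping reads to a cross-species reference), sequence-context
(CpG) substitution bias, capture-efficiency variation along targets, and
correlated caller errors — except through the explicit `fp_correlation`
knob, which exists precisely to demonstrate where k-of-n consensus fails
(shared false positives pass the 2-of-3 rule; the test suite asserts this
failure mode). A green simulation test therefore establishes internal
consistency of the method under independent errors, not performance on any
particular real dataset.

## Numerical and interface choices

* **Variant identity** is allele-aware `(chrom, pos, ref, alt)` after
  multi-allelic splitting; two callers reporting different alt alleles at a
  site disagree. A position-only mode (`allele_aware = FALSE`) is available
  because pairwise VCF comparisons in older toolchains often matched on
  position alone. Chromosome names are normalized by stripping a leading
  `chr` so mixed reference dialects intersect correctly.
* **SNP-only scope**: indels, MNPs and symbolic alleles are dropped and
  counted (`io_stats`), never silently.
* **Missing depth**: records lacking both INFO/DP and per-sample DP keep
  `depth = NA` and fail any depth filter, rather than being guessed at.
* **Rounding**: reported percentages and ratios round half *up*
  (`round_half_up()`), matching how such tables are conventionally printed;
  base R's round-half-even would flip boundary cases like 21.25 → 21.2.
* **Undefined ts/tv** (no transversions) propagates as `NA` with a warning,
  never as `Inf` or an error in reports.
* **The location test** behind the shared-vs-specific ts/tv comparison is
  Welch's t-test on the per-tool-per-group ratio values (6 vs 6 in the
  three-caller two-group design), with a Mann–Whitney option; the choice of
  test is this package's interpretation, since ratio comparisons of this
  kind are reported in the literature without naming one.
* **The enrichment universe is an explicit argument** everywhere a
  hypergeometric test is computed: p-values are sensitive to the background,
  and a hidden default (all annotation genes) is used only by the pipeline,
  which records it in `summary.json`.
* **Disjoint gene categories**: the pipeline assigns a gene hit by both
  groups' specific SNPs to the *common* category before DEG overlap, so the
  three categories partition the candidates and each DEG lands in exactly
  one.
* **BED dialect**: the annotation reader accepts the feature class (CDS,
  5UTR, 3UTR, exon, gene) in BED column 7; standard GFF3 is parsed with
  rtracklayer and converted to the same 1-based inclusive intervals.
  Intronic is inferred as gene-body-minus-exonic-features rather than read
  from the file, and strand is ignored (point containment is
  strand-symmetric).

## Degenerate inputs

Empty callsets filter and partition cleanly; an empty variant set has no
defined ts/tv (error, not 0/0); an empty universe is an error for every
enrichment entry point; `k = 0` overlaps return $p = 1$ exactly; duplicate
VCF records collapse to the highest-QUAL entry with a count; duplicate
reference-list genes deduplicate with a warning.

## Known limitations

* Cross-species gene matching (e.g. buffalo SNP genes vs cattle expression
  data) is plain case-folded symbol matching; no orthology mapping.
* Region classification is interval containment only — no codon-level
  effect prediction, transcript isoforms, or upstream/downstream classes, so
  absolute candidate-gene counts are annotation-dependent and not comparable
  across annotation sources.
* The run-metric summary averages percentages unweighted across samples.
  One published summary row this reproduces contains an on-target average
  (67.8) that matches neither the unweighted column mean (68.9) nor any
  obvious weighting; that column is documented but not asserted.
* Genotypes, phasing and multi-sample reconciliation are out of scope; the
  pooled-calling interpretation reduces each caller × group to one SNP set.
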