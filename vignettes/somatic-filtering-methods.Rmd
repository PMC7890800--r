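---
title: "Two-stage somatic variant filtering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage somatic variant filtering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Somatic variant callers compare a tumor sample against its matched normal
and report candidate mutations. They are tuned for recall: on well-studied
benchmark genomes, raw caller output typically recovers over 90% of true
somatic SNVs while as much as half of the reported calls are false
positives, driven by sample purity, subclonal heterogeneity, copy-number
aberrations, sequencing-chemistry artifacts, alignment errors and the
repetitive structure of reference genomes. Most groups therefore apply ad
hoc post-calling filters — scripts that differ between laboratories and are
rarely published in runnable form, which makes filtered call sets hard to
reproduce.

somafilt implements this post-calling step as a standalone, fully
configurable tool: a VCF from any somatic caller plus the two BAM files go
in, a standard VCF annotated in its FILTER column comes out, and the entire
filtering policy is expressed in a two-column text file that can be shipped
alongside a paper.

## The two-stage procedure

**Stage one (metrics).** For every candidate site the tool queries both BAM
files and reduces the overlapping reads to a per-sample panel of read-level
metrics that are not available in either the VCF or the BAM alone:

| metric | meaning |
|---|---|
| `depth`, `ref_count`, `alt_count`, `other_count` | included reads and their allele class at the site |
| `vaf` | `alt_count / depth` |
| `median_bq_alt`, `median_bq_ref` | median base quality of alt / ref reads |
| `median_mq_alt`, `median_mq_all` | median mapping quality of alt / all reads |
| `alt_fwd`, `alt_rev`, `ref_fwd`, `ref_rev` | per-strand allele counts |
| `median_dist_readend_alt` | median distance of the variant base from the nearer read end |
| `mad_pos_alt` | median absolute deviation of the variant's position within its reads |
| `softclip_frac_alt` | fraction of alt reads whose CIGAR contains a soft-clip |
| `mean_excess_nm_alt` | mean of `max(NM - 1, 0)` over alt reads |
| `mq0_frac` | fraction of included reads with mapping quality 0 |
| `near_indel_frac` | fraction of included reads with an insertion/deletion within 5 bp of the site |
| `improper_pair_frac_alt` | fraction of alt reads not flagged properly paired |

Read inclusion follows mainstream somatic-calling practice: unmapped,
secondary, supplementary, QC-fail and duplicate-flagged reads are excluded;
improper pairs and MAPQ-0 reads are *included* so that `mq0_frac` and
`improper_pair_frac_alt` measure something. Reads whose alignment deletes
or skips the site count toward depth as `other`. Overlapping mates are
counted independently (no fragment-level deduplication), which users should
keep in mind when interpreting depth near the fragment length.

Numerical conventions, chosen once and matched bit-for-bit by the
brute-force oracle in the test suite: medians use the midpoint of the two
central order statistics for even counts; the MAD carries no consistency
scaling; alt-conditioned statistics are `NA` exactly when a sample has no
alt reads; `vaf` is `NA` exactly at zero depth; reads without a base-quality
string are dropped from base-quality medians only. Allele classing is by
exact string match of the read's bases at the site, so third alleles,
deletions and reference skips all land in `other_count` and depth is always
conserved as `ref + alt + other`.

Only SNVs receive the full panel. Non-SNV candidates get depth, allele
counts and VAF (alt defined by exact allele match at POS) with all
read-geometry metrics `NA` — the method's validation heritage is SNV-only,
and pileup geometry statistics are not meaningful for indels without
realignment, which is out of scope.

The stage is chunked (default 1000 variants per chunk) and each completed
chunk is persisted as gzipped TSV before the next begins, so interrupted or
re-parameterised runs resume instead of recomputing; a fingerprint
(candidate count, VCF path, tool version) prevents silent reuse of a cache
built from different inputs. Chunks may be computed by parallel workers;
because the computation is free of randomness, output is identical for any
worker count.

**Stage two (filters).** Each configured filter reads one metric and one
threshold. A `min`-direction filter fails a variant when the metric is
strictly below the threshold, a `max` filter when strictly above; equality
always passes, in both directions — one global tie-break rule rather than
per-filter conventions. Missing metrics resolve through an explicit policy:
alt-conditioned filters fail on `NA`, because for a somatic call the total
absence of alt evidence is itself disqualifying. The strand filter is
`not_applicable` below 10 alt reads, where a minor-strand fraction is too
noisy to judge; `not_applicable` never fails a variant. The overall verdict
is a pure function of the per-filter outcomes (pass iff nothing failed), so
verdicts are idempotent and invariant to the order of the configuration
file.

## The filter catalogue and its thresholds

The catalogue (see `filter_catalogue()`) contains sixteen named filters.
The upstream tool this package re-implements defers its exact threshold
table to supplementary material whose cells are not available to us; both
preset tables here are therefore **reconstructions**, built from the
described feature set (depth-of-coverage and VAF heuristics plus the ICGC
benchmarking recommendations) and from what those recommendations emphasise.
They are honest defaults, not a copy of the original tool's numbers, and
every value can be overridden by a configuration file.

Default preset highlights (units in parentheses): tumor and normal depth at
least 10 (reads); at least 3 tumor alt reads; tumor VAF at least 0.05;
normal VAF at most 0.03 and at most 1 normal alt read; median alt base
quality at least 30 (phred) and median alt mapping quality at least 40;
minor-strand fraction of alt reads at least 0.05 (evaluated from 10 alt
reads); median distance from the nearer read end at least 10 (bp); MAD of
position-in-read at least 3 (bp, catching single-position PCR/alignment
stacks); soft-clipped alt fraction at most 0.30; mean excess NM at most
2.0; MAPQ-0 fraction at most 0.10; near-indel fraction at most 0.30;
improper-pair alt fraction at most 0.50.

The ICGC-style preset keeps the same catalogue and tightens what those
recommendations stress: minimum tumor VAF 0.10, maximum normal VAF 0.02,
maximum MAPQ-0 fraction 0.05. Where the recommendations state no number the
default value is kept, so the two presets differ only where there was a
stated reason.

`near_indel` uses a ±5 bp window; no window is canonical in the literature,
and 5 bp reflects the indel-adjacent miscall radius the ICGC
recommendations worry about. `mean_excess_nm_alt` subtracts exactly 1 from
NM (the candidate mismatch itself) and floors at zero; indel operations
inside NM are not otherwise corrected — it is a monotone noisiness proxy,
not an exact mismatch count.

## Multi-allelic records and emission

Candidates are split per ALT allele and filtered independently. The FILTER
column emitted for the original record carries the verdict of its first ALT
(per-allele verdicts live in the per-variant results TSV); this keeps the
output record count equal to the input record count, so the annotated VCF
is a drop-in superset for downstream tools. A pass-only output mode exists
for pipelines that want the reduced file. Records are re-emitted verbatim
except for the FILTER field; only CHROM/POS/REF/ALT are ever interpreted,
which is what makes the tool caller-agnostic.

## Evaluation

`evaluate_calls()` scores a passing set against a truth set by exact
(contig, pos, ref, alt) identity — no distance window, no normalization,
which SNV-only scope makes unnecessary. Recall is TP/(TP+FN), precision
TP/(TP+FP), and F1 their harmonic mean 2TP/(2TP+FP+FN); any 0/0 ratio is
reported `NA` rather than 0, since scoring an empty set is undefined. When
the truth set contains variants the upstream caller never emitted, the
resulting FNs belong to the combined caller-plus-filter pipeline, not to
the filtering step alone; the evaluator scores whatever sets it is given.

## What the synthetic fixtures emulate — and what they do not

`generate_pair()` builds a seeded, download-free tumor/normal pair: a
uniform-random reference (`synth1`), 100-bp ungapped single-segment reads
with hand-built CIGARs, a candidate VCF and a truth table. True somatic
sites draw alt reads binomially at the target VAF (default depth 80, VAF
0.4) with balanced strands, base quality ~ N(35, 3) clipped to [2, 41] and
mapping quality 60. Each artifact class violates exactly its targeted
metric by a designed margin: all alt reads on one strand; all at one query
position; within 5 bp of a read end; soft-clipped; NM-inflated; MAPQ-0
enriched; deletion-adjacent; improperly paired; base- or mapping-quality
degraded; VAF below threshold; alt evidence planted in the normal at VAF
0.5. Mate flags are synthesized without emitting real mates — a documented
simplification the flag-based read-inclusion logic never notices.

Randomness flows from one master seed through a deterministic per-locus
sub-seed, so any locus is reproducible independent of generation order, and
two runs at the same seed produce identical manifests and BAM record sets.

These fixtures are filter-targeted, not caller-targeted: there is no
sequencing-error model, no quality recalibration profile, no fragment-length
distribution, no copy-number structure and no subclonal architecture.
Passing the artifact suite demonstrates that each filter measures what it
claims and trips where it should — it does not demonstrate performance on
real tumors, where error modes overlap and thresholds interact with purity
and depth. The problem sizes used by the test suite (60-site artifact
suite, 60-site VAF sweep, 20-site clean pair, depth 80) were chosen as the
smallest sets that give every artifact class at least three loci and keep
binomial sampling noise well inside the asserted margins.

## Degenerate inputs and numerical corner cases

Zero-depth sites produce `NA` VAF and all-`NA` panels and then fail the
depth filters; sites with depth but no alt reads have VAF 0 and fail
alt-conditioned filters through the `NA` policy. Empty filter
configurations load with a prominent warning and pass everything —
explicitly vacuous, never an error. Contig-naming mismatches between VCF
and either BAM ("chr1" vs "1") abort before any metric is computed; a
truth/call contig disjointness in evaluation warns but still counts, since
partial overlap can be legitimate. Threshold equality passing means a
threshold equal to an attainable metric value (e.g. minimum depth 10 at
depth exactly 10) keeps the variant — configs should be read as "reject
strictly worse than".

## Known limitations

* SNV-focused: indels receive counts and VAF only, and no indel-aware
  truth matching is provided.
* No fragment-level treatment of overlapping mates, no BAQ, no
  realignment.
* No panel-of-normals, population-frequency or repeat-annotation filters,
  and no learned scoring — the tool is deliberately a transparent
  threshold engine.
* The preset thresholds are reconstructions (see above); users replicating
  a published analysis should obtain and supply that study's configuration
  file, which is exactly the sharing workflow the configuration format is
  designed for.
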