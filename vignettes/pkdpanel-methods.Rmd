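---
title: "Methods: variant prioritization and read-depth CNV detection for a pseudogene-contaminated two-gene panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant prioritization and read-depth CNV detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkdpanel)
```

## The diagnostic problem

Autosomal dominant polycystic kidney disease (ADPKD) is caused by mutations
in *PKD1* (~85% of families) and *PKD2* (~15%). Molecular diagnosis by
capture-based NGS is complicated by a specific artifact source: roughly 70%
of the 5' genomic region of *PKD1* (exons 1–33) is duplicated six times on
chromosome 16p in pseudogenes sharing ~97.7% sequence identity with the
genuine gene. Reads originating from the pseudogenes that misalign onto
*PKD1* accumulate as low-allele-fraction, often strand-skewed variant
calls. The analysis implemented here takes variant calls and per-target read
counts as given (read mapping is upstream, third-party work) and answers the
diagnostic question: which samples carry a reportable pathogenic mutation?

The pipeline has five stages, each its own module:

1. **Filter cascade** — both-strand support, ≥20% allele fraction, <5%
   population frequency with disease-database rescue.
2. **Consequence annotation** — a transcript model maps each variant to
   stop-gain, frameshift, splice, missense, inframe-indel, synonymous or
   intronic.
3. **Classification** — truncating consequences are *definitely pathogenic*;
   missense, noncanonical-splice and inframe changes are Unclassified
   Sequence Variants (UCV) scored by an integer Variant Score (VS).
4. **Read-depth CNV calling** — RPKM → per-target cohort z-score (ZRPKM) →
   SVD denoising → thresholded runs of consecutive targets.
5. **Coverage audit and reporting** — per-gene/per-exon depth statistics,
   automatic low-coverage region reporting with a Sanger-follow-up flag for
   undiagnosed samples, and cohort diagnostic rates.

## Filter cascade

A candidate call carries stranded read counts (`fwd_ref`, `rev_ref`,
`fwd_alt`, `rev_alt`), per-database population frequencies and a
disease-database membership flag. The rules are:

* **Strand**: at least one alt read on each strand.
* **Fraction**: alt reads ≥ 20% of the call's ref+alt depth. Depth is
  deliberately ref+alt of this call — third alleles at the site are out of
  scope, and a zero-depth call fails with an explicit `zero_depth` tag.
* **Frequency**: the *maximum* frequency over databases (dbSNP-style,
  1000G-style, exome-server-style and an in-house artifact database are all
  just frequency sources) must stay below 5%; a failing variant passes with
  `rescue_applied` when it is a known disease mutation, because population
  databases also contain disease alleles.

The retained set is the intersection of the three per-rule pass sets, so
rule order cannot matter; `run_cascade()` returns the per-rule audit trail.
The 20% cut-off is the discriminator against pseudogene leakage: the
tightest allele fraction among the packaged cohort records is 26/122 ≈ 21.3%,
just above it, while leakage fractions concentrate well below.

## Classification

Stop-gains, frameshifts, canonical ±1/±2 splice changes and exon-spanning
structural deletions can produce truncated protein and are reported
*definitely pathogenic* regardless of any score. UCVs receive an integer VS,
the sum of satisfied evidence points, and are classed as:

| class | VS |
|---|---|
| highly likely pathogenic | ≥ 11 |
| likely pathogenic | 5–10 |
| indeterminate | 0–4 |
| highly likely neutral | ≤ −1 |

The boundaries only partition the *integers* (the 4→5 and 10→11 gaps close
over no other set), so non-integer scores are rejected at configuration
time. The published component table behind the original two-gene scoring
system is not reproducible offline, so `default_scoring_config()` ships a
documented stand-in rule set (conservation, Grantham-distance bins, splice
predictor loss, control-population absence, cosegregation) and the whole
rule table is configuration, not code. Cohort fixture records carry their
printed classes, which `classify_variant()` uses whenever score features are
unavailable; synonymous and deep-intronic changes need no score and are a
priori neutral. Reportable classes — the ones that diagnose a sample — are
definitely / highly likely / likely pathogenic.

One parsing subtlety is load-bearing: two printed records
(`c.10170+25_+45del19` and `c.11017-10C>A`) are annotated with downstream
frameshift protein labels but were scored as UCVs, so intronic-offset
patterns in the cDNA label take precedence over the protein label when a
consequence is curated from printed notation. The noncanonical-splice window
is intronic offsets 3–10 (the deepest printed noncanonical case sits at
−10); it is configurable because the boundary between "noncanonical splice"
and "deep intronic" is a judgment call.

## Read-depth deletion calling

For a samples × targets count matrix:

* **RPKM**: `counts * 1e9 / (target_length * sample_total)` — removes
  library size and target length.
* **ZRPKM**: per target, center on the cohort median and scale by the
  cohort standard deviation; targets with sd below `1e-8` (e.g. dropout
  exons that are near-zero in everyone) are masked rather than divided by
  ~0.
* **SVD denoising**: zero the `k` largest singular values and reconstruct.
  The per-target sd is dominated by systematic capture covariance shared
  across samples (capture efficiency, GC sensitivity, batch); removing the
  leading components leaves residuals far smaller than one z-unit, which is
  what makes a fixed threshold usable.
* **Calling**: maximal runs of ≥ 2 consecutive unmasked targets at
  SVD-ZRPKM ≤ −1.5 are deletions (≥ +1.5 duplications).

`k = 3`, threshold 1.5 and minimum 2 targets are defaults, exposed as
arguments. The signal budget that justifies them on the synthetic panel
(99 targets, 41 samples, mean target depth 330, rank-3 capture bias with
log-sd 0.10): per-target relative sd ≈ √(3·0.10² + 1/330) ≈ 0.18, so a
heterozygous deletion (copy ratio 0.5) sits at ≈ −2.8 z per target while
post-SVD Poisson residuals have sd ≈ 0.3 z — batch singular values (~30+)
stand clearly above deletion components (~9–11), which stand above the noise
floor (~5). Removing three components therefore strips the batch structure
and keeps the deletions. Because single targets can still wobble above the
−1.5 line, an event occasionally surfaces as two adjacent run fragments;
detection is judged per sample, and calls report target spans, not
breakpoints.

## Coverage audit

Per-base depth (not per-target means) drives gap reporting, so a partially
covered exon reports only its weak sub-interval. `summarize_coverage()`
computes the panel-QC statistics (mean depth; % of bases at 0X and ≥
1X/20X/50X/100X, which are monotone by construction) per gene and per exon;
`low_coverage_regions()` emits the merged intervals of bases under 20X
(configurable — 20 reads is the depth treated as sufficient for reliable
detection). When a sample finishes the pipeline without a reportable
mutation, its low-coverage intervals are attached to the report with a
Sanger-recommended flag: those regions are where a missed mutation most
likely hides. This mirrors how the two undiagnosed discovery samples were
resolved in practice.

## The synthetic world

`sim_config()` defaults are the study conditions, chosen once:

* **Six pseudogene copies at per-base divergence 0.023**, giving ~97.7%
  identity (the published figure). The mini-genome is one contig: the gene
  (30 equal exons alternating with equal introns over ~12 kb, CDS a proper
  ORF so codon-level consequence calls are well defined), then each copy
  after an N-spacer.
* **41 samples** (36 patients + 5 controls) and **mean depth 330**, the
  printed validation-cohort coverage.
* **True heterozygous variants**: binomial alt counts at mean fraction 0.5,
  alt reads on both strands, absent from every frequency database, planted
  as missense or stop-gain (the panel's common kinds) with pathogenic score
  evidence attached.
* **Leakage calls**: Poisson-many per sample; the *observed* alt fraction is
  drawn inside (0.02, 0.18) — strictly below the 20% threshold, because the
  upper bound of the leakage-fraction interval must stay below the filter
  cut-off for the cascade to be the discriminator — and half of them carry
  single-strand support only. Benign variants get frequencies ≥ 0.05.
* **Coverage**: Poisson counts around
  `mean_depth × length_weight × library_scale × capture_bias × copy_ratio`,
  with lognormal per-sample library scale (sd 0.2; RPKM must remove it), the
  rank-3 capture-bias term above (the SVD stage must remove it), spiked
  heterozygous deletions (copy ratio 0.5) and dropout targets forced to 1%
  of expectation — the "not captured" GC-rich exon analogue. The default
  coverage panel has 99 targets of median length ~995 bp, the published
  panel geometry; a deletion spanning a minority of the panel is what keeps
  it separable from panel-wide batch structure.

Everything is deterministic under the config seed. What the generator does
**not** emulate, and what passing tests therefore cannot show: read-level
alignment (leakage is modeled by its observable signature, not by
misaligning reads), GC-content gradients beyond fixed dropout targets,
duplication CNVs, multi-allelic sites, and any base-quality structure.
Performance numbers on this synthetic world say the *rules* behave as
designed, not that the laboratory assay achieves them.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; 1-based numbers
  appear only in HGVS-like text and VCF output. HGVS output is a simplified
  dialect without 3'-rule indel shifting; fixture records carry curated
  labels.
* Strand-split counts for fixture records (totals are printed, strands are
  not) are divided as evenly as possible, forward taking the odd read —
  a documented convention, not data.
* The two printed large deletions enter as structural events with their
  printed genomic coordinates (the read-depth route demonstrates the same
  events on synthetic scale); they bypass the SNV cascade, whose evidence
  model (allele counts) does not apply.
* Diagnostic rates are rendered to one decimal with half-up rounding
  (35/36 → 97.2, 10/12 → 83.3); a sample with only indeterminate or neutral
  UCVs counts as undiagnosed; an empty cohort has no defined rate.
* The duplicated-region tally of the validation table is 24 as printed
  row-by-row (the running text says 25; the table is taken as authoritative,
  the same policy used for a sample-ID discrepancy between text and table).
* Problem sizes used in tests (41 × 99 coverage matrices, 20 replicates,
  10^4-variant filter cross-checks) were chosen so the full suite runs in
  about a minute while keeping every stochastic margin wide.

## Limitations

The scoring rule table is a configurable stand-in, so absolute VS values are
not comparable to the original system — only the threshold logic and the
fixture concordance are guaranteed. The CNV caller reports target spans and
is validated for heterozygous deletions only. Real-panel coverage tables
(QC-passed reads, per-exon capture profiles) and array-based
sensitivity/specificity comparisons require real sequencing data and are
represented here only by their property-level analogues.
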