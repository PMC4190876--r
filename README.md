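# pkdpanel

Diagnostic analysis for targeted next-generation sequencing of the autosomal
dominant polycystic kidney disease (ADPKD) genes *PKD1* and *PKD2*. The
catch with this panel: ~70% of the 5' region of *PKD1* is duplicated six
times in pseudogenes at ~97.7% sequence identity, so reads misaligned out of
the pseudogenes surface as spurious low-allele-fraction variant calls. The
package is for people building or validating clinical variant-prioritization
pipelines on pseudogene-contaminated gene panels, and for reproducing the
published two-cohort ADPKD analysis offline.

## What it implements

* **Variant filter cascade** — a call is retained iff it has alt reads on
  both strands, alt fraction ≥ 0.20 of its site depth, and max population
  frequency < 0.05 across databases (with a rescue for known disease
  mutations). The retained set is the intersection of the three rule sets;
  every decision is audited.
* **Consequence annotation** — transcript-model projection to HGVS-like c.
  coordinates and codon-level classification (stop-gain, frameshift,
  canonical/noncanonical splice, missense, inframe indel, synonymous,
  intronic, structural deletion).
* **Pathogenicity classification** — truncating consequences are definitely
  pathogenic; Unclassified Sequence Variants get an integer Variant Score
  VS = Σ evidence points, classed highly likely pathogenic (VS ≥ 11),
  likely pathogenic (5 ≤ VS ≤ 10), indeterminate (0 ≤ VS ≤ 4), highly
  likely neutral (VS ≤ −1).
* **Read-depth CNV calling** (CoNIFER-style) — RPKM_st = counts_st · 10⁹ /
  (length_t · total_s), per-target cohort z-score (ZRPKM, median/sd across
  samples), SVD denoising (top k = 3 singular values removed), then
  deletion calls as runs of ≥ 2 consecutive targets at SVD-ZRPKM ≤ −1.5.
* **Coverage audit** — per-gene/per-exon depth statistics, merged < 20X
  intervals, and a Sanger-follow-up flag for undiagnosed samples.
* **Cohort fixtures** — the published validation (36 samples) and discovery
  (12 samples) mutation tables ship as TSV under `inst/extdata/` and drive
  the cohort-level reproduction.
* **Synthetic data** — a seeded generator for the mini-genome (gene + six
  diverged pseudogene copies), true/benign/leakage variant calls, and
  Poisson coverage matrices with spiked heterozygous deletions, so every
  stage is testable without downloads.

## Worked example

```r
library(pkdpanel)

v    <- load_validation_cohort()          # packaged cohort table
conv <- records_to_variant_calls(v)       # calls + structural events
res  <- run_pipeline(conv$calls, sv_events = conv$sv_events,
                     samples = conv$samples)
res
#> diagnostic_result: 36 samples, 35 diagnosed (rate 97.2%), 35 reported mutations
head(res$mutations[, c("sample_id", "gene", "cdna_label", "consequence", "class")], 4)
#>   sample_id gene   cdna_label consequence                 class
#> 1 12-331-P1 PKD1     c.566C>G   stop_gain definitely_pathogenic
#> 2 12-382-P1 PKD1 c.736_737del  frameshift definitely_pathogenic
#> 3 04-016-P6 PKD1    c.1831C>T    missense     likely_pathogenic
#> 4 12-235-P1 PKD1    c.2329C>T   stop_gain definitely_pathogenic
```

35 of 36 samples carry a reportable mutation (30 in *PKD1*, 5 in *PKD2*,
including two large deletions entering as structural events), a 97.2%
diagnostic rate; the one all-dash sample stays undiagnosed and is flagged
for Sanger follow-up of low-coverage regions. The discovery cohort gives 11
mutations in 10 of 12 samples (83.3%), one sample carrying hits in both
genes.

The numbered scripts under `analysis/` run the whole study as a workflow —
`01_simulate.R` (synthetic world), `02_filter_classify.R` (cascade +
classification, leakage suppression), `03_cnv_detection.R` (SVD-ZRPKM
deletion recovery), `04_coverage_audit.R`, `05_cohort_reproduction.R` — each
printing what it found and writing tables under `results/`.

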