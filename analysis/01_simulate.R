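#!/usr/bin/env Rscript
# Build the synthetic study world: a mini-genome with the genuine gene and
# six pseudogene copies at 2.3% per-base divergence, per-sample variant calls
# (true heterozygous, common benign, pseudogene-leakage), a 41-sample
# coverage matrix over a 99-target panel, and one per-base depth track.
# Everything is written under results/sim/ for the downstream steps.

suppressPackageStartupMessages(library(pkdpanel))

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(dropout_exons = 1L, seed = 2014L)
reference <- generate_reference(cfg)
write_reference(reference, out)

ids <- pseudogene_identity(reference)
cat(sprintf("gene span %d bp; %d pseudogene copies; mean identity %.2f%% (range %.2f-%.2f)\n",
            reference$loci$end[1], length(ids), 100 * mean(ids),
            100 * min(ids), 100 * max(ids)))

sim <- simulate_variant_calls(cfg, reference)
write_variant_calls_tsv(sim$calls, file.path(out, "variant_calls.tsv"))
write_calls_vcf(sim$calls[nchar(sim$calls$ref) == 1, ], sim$samples,
                file.path(out, "variant_calls.vcf"),
                contig_length = length(reference$genome[["panel_sim"]]))
for (nm in names(sim$truth)) {
  write.table(sim$truth[[nm]], file.path(out, paste0("truth_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat(sprintf("%d calls across %d samples: %d true, %d benign, %d pseudogene-leakage\n",
            nrow(sim$calls), cfg$n_samples, nrow(sim$truth$true_variants),
            nrow(sim$truth$benign_variants), nrow(sim$truth$spurious_calls)))

# coverage matrix with the two Fig-2-style heterozygous deletions spiked in
deletions <- data.frame(sample = c(6L, 30L), first_target = c(5L, 70L),
                        last_target = c(20L, 80L), copy_ratio = 0.5)
cov <- simulate_coverage_matrix(cfg, deletions = deletions)
write.table(cov$matrix$counts, file.path(out, "coverage_counts.tsv"),
            sep = "\t", quote = FALSE)
write.table(cov$matrix$targets, file.path(out, "coverage_targets.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(deletions, file.path(out, "truth_deletions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("coverage matrix: %d samples x %d targets, spiked het deletions in S06 and S30\n",
            nrow(cov$matrix$counts), ncol(cov$matrix$counts)))

track <- simulate_depth_track(cfg, reference, sample_id = "S01")
write.table(track, file.path(out, "depth_track_S01.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote per-base depth track for S01 (target 1 is a forced dropout exon)\n")
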