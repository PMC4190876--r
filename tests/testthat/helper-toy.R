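# A hand-checkable two-exon transcript:
#   contig "toy" (60 bp), exons [10,22) and [34,46), CDS [20,44).
#   Spliced CDS = ATG GCT CAG TGA (Met Ala Gln Stop).
# The CAG codon sits at genomic 38-40, so 38 C>T gives TAG (stop-gain).
toy_genome_seq <- paste0(
  "ACGTACGTAC",  #  0-9   intergenic
  "TTTTTCCCCC",  # 10-19  exon 1, 5' UTR
  "AT",          # 20-21  CDS codon 1 start
  "GTAAGTTTTCAG",# 22-33  intron (GT...AG)
  "GGCTCAGTGA",  # 34-43  CDS remainder
  "AA",          # 44-45  3' UTR
  "ACGTACGTACGTAC" # 46-59 intergenic
)

make_toy_tx <- function() {
  genome <- Biostrings::DNAStringSet(toy_genome_seq)
  names(genome) <- "toy"
  transcript_model("TOY", "toy", "+",
                   data.frame(start = c(10L, 34L), end = c(22L, 46L)),
                   cds_start = 20L, cds_end = 44L, genome = genome)
}

# Mirror of a transcript on the reverse-complemented genome: position p maps
# to L-1-p, intervals [s,e) to [L-e, L-s), strand flips.
mirror_tx <- function(tx) {
  L <- length(tx$genome[[tx$contig]])
  genome <- Biostrings::DNAStringSet(Biostrings::reverseComplement(tx$genome[[tx$contig]]))
  names(genome) <- tx$contig
  transcript_model(tx$gene_id, tx$contig,
                   if (tx$strand == "+") "-" else "+",
                   data.frame(start = L - tx$exons$end, end = L - tx$exons$start),
                   cds_start = L - tx$cds_end, cds_end = L - tx$cds_start,
                   genome = genome)
}

# Independent consequence oracle for coding SNVs: rebuild the whole mutant
# CDS, translate both with Biostrings::translate, and compare the proteins.
oracle_snv_consequence <- function(pos, ref, alt, tx) {
  g <- as.character(tx$genome[[tx$contig]])
  stopifnot(substr(g, pos + 1, pos + 1) == ref)
  mut <- g
  substr(mut, pos + 1, pos + 1) <- alt
  mut_genome <- Biostrings::DNAStringSet(mut)
  names(mut_genome) <- tx$contig
  mut_tx <- transcript_model(tx$gene_id, tx$contig, tx$strand, tx$exons,
                             tx$cds_start, tx$cds_end, mut_genome)
  p0 <- as.character(Biostrings::translate(cds_seq(tx), no.init.codon = TRUE))
  p1 <- as.character(Biostrings::translate(cds_seq(mut_tx), no.init.codon = TRUE))
  stops0 <- regexpr("\\*", p0)
  stops1 <- regexpr("\\*", p1)
  if (stops1 > 0 && (stops0 < 0 || stops1 < stops0)) "stop_gain"
  else if (p0 == p1) "synonymous"
  else "missense"
}

# Random strand/fraction/frequency call table for filter-rule checks.
random_filter_calls <- function(n, seed) {
  set.seed(seed)
  depth <- sample(1:300, n, replace = TRUE)
  alt <- vapply(depth, function(d) sample(0:d, 1L), 1L)
  fwd_alt <- vapply(alt, function(a) if (a == 0) 0L else sample(0:a, 1L), 1L)
  ref <- depth - alt
  fwd_ref <- vapply(ref, function(r) if (r == 0) 0L else sample(0:r, 1L), 1L)
  freq <- ifelse(runif(n) < 0.4, runif(n, 0, 0.2), NA_real_)
  variant_calls(sample_id = sprintf("R%04d", seq_len(n)),
                fwd_ref = fwd_ref, rev_ref = ref - fwd_ref,
                fwd_alt = fwd_alt, rev_alt = alt - fwd_alt,
                freq_g1000 = freq,
                in_pathogenic_db = runif(n) < 0.2,
                consequence = "missense")
}
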