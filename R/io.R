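# File renderings of the synthetic world: FASTA mini-genome (Biostrings),
# BED target/locus annotation, TSV call tables and a minimal VCFv4.2 export
# of simulated calls with stranded allele depths in the sample columns.
# BED uses 0-based half-open coordinates, matching the internal convention;
# VCF positions are 1-based.

#' Write the synthetic reference to disk
#'
#' Emits `genome.fa`, `targets.bed`, `loci.bed` and `transcript.tsv`
#' (exon table with CDS span and strand) into `dir`.
#'
#' @param reference a [generate_reference()] result.
#' @param dir output directory (created if absent).
#' @return named vector of written paths, invisibly.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             targets = file.path(dir, "targets.bed"),
             loci = file.path(dir, "loci.bed"),
             transcript = file.path(dir, "transcript.tsv"))
  Biostrings::writeXStringSet(reference$genome, paths["genome"])
  tg <- reference$targets
  write.table(tg[, c("contig", "start", "end", "name")], paths["targets"],
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  loci <- reference$loci
  write.table(data.frame(contig = "panel_sim", loci[, c("start", "end", "name")]),
              paths["loci"], sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  tx <- reference$transcript
  write.table(data.frame(gene_id = tx$gene_id, contig = tx$contig,
                         strand = tx$strand, exon_start = tx$exons$start,
                         exon_end = tx$exons$end, cds_start = tx$cds_start,
                         cds_end = tx$cds_end),
              paths["transcript"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a transcript model written by [write_reference()]
#'
#' @param dir directory holding `genome.fa` and `transcript.tsv`.
#' @return a [transcript_model()].
#' @export
read_transcript <- function(dir) {
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*", "", names(genome))
  tt <- read.delim(file.path(dir, "transcript.tsv"))
  transcript_model(tt$gene_id[1], tt$contig[1], tt$strand[1],
                   data.frame(start = tt$exon_start, end = tt$exon_end),
                   cds_start = tt$cds_start[1], cds_end = tt$cds_end[1],
                   genome = genome)
}

#' Write variant calls as TSV
#'
#' Flat rendering of the call table (the `features` list-column is dropped).
#'
#' @param calls a `variant_calls` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_calls_tsv <- function(calls, path) {
  flat <- calls[, setdiff(names(calls), "features"), drop = FALSE]
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render simulated calls as VCF
#'
#' Minimal VCFv4.2 with one column per cohort sample; the carrying sample
#' holds `GT:AD:ADF:ADR` (total and per-strand ref,alt depths), others are
#' missing. Only positioned SNV-style calls are rendered.
#'
#' @param calls a `variant_calls` data frame with genomic positions.
#' @param samples cohort sample ids (VCF column order).
#' @param path output path.
#' @param contig_length declared contig length for the header.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, samples, path, contig_length = NA) {
  stopifnot(!any(is.na(calls$pos)))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s%s>", unique(calls$contig)[1],
            if (is.na(contig_length)) "" else sprintf(",length=%d", contig_length)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"Forward-strand allelic depths\">",
    "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"Reverse-strand allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  ord <- order(calls$pos)
  body <- vapply(ord, function(i) {
    v <- calls[i, ]
    gt <- sprintf("0/1:%d,%d:%d,%d:%d,%d",
                  v$fwd_ref + v$rev_ref, v$fwd_alt + v$rev_alt,
                  v$fwd_ref, v$fwd_alt, v$rev_ref, v$rev_alt)
    cells <- ifelse(samples == v$sample_id, gt, "./.:.:.:.")
    paste(c(v$contig, v$pos + 1L, ".", v$ref, v$alt, ".", "PASS", ".",
            "GT:AD:ADF:ADR", cells), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}
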