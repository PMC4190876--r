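# Molecular consequence prediction on a transcript model: the discriminator
# between truncating changes (reported definitely pathogenic) and UCVs
# (missense / noncanonical splice / inframe indels, routed to VS scoring).

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "*")

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[toupper(codon)]])
}

#' Predict the molecular consequence of a variant
#'
#' SNVs in the CDS are classified by mutating and translating their codon
#' (stop-gain / missense / synonymous); CDS indels by length modulo 3
#' (frameshift / inframe indel); intronic SNVs by their offset from the
#' nearest exon boundary (1-2 canonical splice, 3 to `splice_window`
#' noncanonical splice, deeper intronic); structural events spanning at least
#' one exon are structural deletions. Exonic positions outside the CDS are
#' lumped with `intronic` (noncoding), positions outside the transcript span
#' are `intergenic`.
#'
#' @param variant list or one-row data frame with `pos`, `ref`, `alt`
#'   (genomic plus-strand alleles, 0-based `pos`), or `sv_start`/`sv_end`
#'   for a structural event.
#' @param tx a [transcript_model()].
#' @param splice_window largest intronic offset still called noncanonical
#'   splice (the printed noncanonical case sits at offset 10).
#' @return list with `kind`, `cdna_label`, `protein_label` (`NA` for
#'   splice/intronic kinds).
#' @export
classify_consequence <- function(variant, tx, splice_window = 10L) {
  if (!is.null(variant$sv_start) && !is.na(variant$sv_start)) {
    spans_exon <- any(variant$sv_end > tx$exons$start &
                        variant$sv_start < tx$exons$end)
    abort_if(!spans_exon, "structural event %d-%d spans no exon of %s",
             variant$sv_start, variant$sv_end, tx$gene_id)
    return(list(kind = "structural_deletion",
                cdna_label = sprintf("g.%d-%ddel", variant$sv_start, variant$sv_end),
                protein_label = NA_character_))
  }
  pos <- variant$pos
  ref <- variant$ref
  alt <- variant$alt
  cdna <- project_to_cdna(pos, tx)
  if (identical(cdna, "intergenic")) {
    return(list(kind = "intergenic", cdna_label = NA_character_,
                protein_label = NA_character_))
  }

  ioff <- intronic_offset(tx, pos)
  if (!is.na(ioff)) {
    k <- abs(ioff)
    kind <- if (k <= 2L) "canonical_splice"
            else if (k <= splice_window) "noncanonical_splice"
            else "intronic"
    return(list(kind = kind,
                cdna_label = sprintf("%s%s>%s", cdna, ref, alt),
                protein_label = NA_character_))
  }

  # Exonic. Check the reference allele against the genome.
  genome_ref <- as.character(Biostrings::subseq(tx$genome[[tx$contig]],
                                                start = pos + 1L,
                                                end = pos + nchar(ref)))
  abort_if(!identical(genome_ref, ref),
           "reference mismatch at %s:%d: variant says '%s', reference has '%s'",
           tx$contig, pos, ref, genome_ref)

  cpos <- cds_position(tx, pos)
  in_cds <- cpos >= 1L && is.null(attr(cpos, "after_stop"))
  if (!in_cds) {  # exonic UTR: noncoding bucket
    return(list(kind = "intronic", cdna_label = cdna,
                protein_label = NA_character_))
  }

  indel_len <- abs(nchar(ref) - nchar(alt))
  if (indel_len > 0L) {
    kind <- if (indel_len %% 3L == 0L) "inframe_indel" else "frameshift"
    res <- (as.integer(cpos) - 1L) %/% 3L + 1L
    cds <- as.character(cds_seq(tx))
    codon <- substr(cds, (res - 1L) * 3L + 1L, res * 3L)
    aa <- AA3[translate_codon(codon)]
    lab <- if (kind == "frameshift") sprintf("p.(%s%dfs)", aa, res)
           else sprintf("p.(%s%ddel)", aa, res)
    return(list(kind = kind,
                cdna_label = sprintf("%sdel", cdna),
                protein_label = lab))
  }

  # Coding SNV: mutate the codon and translate.
  cds <- as.character(cds_seq(tx))
  res <- (as.integer(cpos) - 1L) %/% 3L + 1L
  within <- (as.integer(cpos) - 1L) %% 3L
  codon <- substr(cds, (res - 1L) * 3L + 1L, res * 3L)
  alt_t <- if (tx$strand == "+") alt
           else as.character(Biostrings::complement(Biostrings::DNAString(alt)))
  new_codon <- codon
  substr(new_codon, within + 1L, within + 1L) <- alt_t
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(new_codon)
  kind <- if (aa_alt == "*" && aa_ref != "*") "stop_gain"
          else if (aa_alt == aa_ref) "synonymous"
          else "missense"
  ref_t <- if (tx$strand == "+") ref
           else as.character(Biostrings::complement(Biostrings::DNAString(ref)))
  prot <- if (kind == "synonymous") sprintf("p.(%s%d=)", AA3[aa_ref], res)
          else sprintf("p.(%s%d%s)", AA3[aa_ref], res,
                       if (aa_alt == "*") "*" else AA3[aa_alt])
  list(kind = kind,
       cdna_label = sprintf("%s%s>%s", cdna, ref_t, alt_t),
       protein_label = prot)
}

#' Is a consequence truncating?
#'
#' Truncating kinds (stop-gain, frameshift, canonical splice, structural
#' deletion) are reported definitely pathogenic without scoring; everything
#' else is at most a UCV.
#'
#' @param consequence a consequence kind string or the list returned by
#'   [classify_consequence()].
#' @return logical.
#' @export
is_truncating <- function(consequence) {
  kind <- if (is.list(consequence)) consequence$kind else consequence
  kind %in% c("stop_gain", "frameshift", "canonical_splice",
              "structural_deletion")
}

#' UCV consequence kinds
#'
#' Kinds routed to Variant Score evaluation rather than reported outright.
#'
#' @param consequence kind string or [classify_consequence()] result.
#' @return logical.
#' @export
is_ucv <- function(consequence) {
  kind <- if (is.list(consequence)) consequence$kind else consequence
  kind %in% c("missense", "noncanonical_splice", "inframe_indel")
}
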