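# The variant-call table: one row per candidate variant per sample, carrying
# stranded read counts, population frequencies (columns prefixed "freq_",
# NA = not observed in that database), pathogenic-database membership and,
# once annotated, a consequence kind. Coordinates are 0-based internally.

FREQ_DATABASES <- c("freq_dbsnp", "freq_g1000", "freq_evs", "freq_inhouse")

CONSEQUENCE_KINDS <- c("stop_gain", "frameshift", "canonical_splice",
                       "noncanonical_splice", "missense", "inframe_indel",
                       "synonymous", "intronic", "intergenic",
                       "structural_deletion")

#' Construct a variant-call table
#'
#' Builds the standard candidate-variant data frame used throughout the
#' pipeline. All arguments are recycled to a common length; population
#' frequency columns default to `NA` (variant unobserved in that database).
#'
#' @param sample_id,contig,pos,ref,alt call identity (pos is 0-based).
#' @param fwd_ref,rev_ref,fwd_alt,rev_alt stranded read counts (nonnegative).
#' @param freq_dbsnp,freq_g1000,freq_evs,freq_inhouse population frequencies
#'   in \[0,1\], `NA` when unobserved.
#' @param in_pathogenic_db logical; membership in a curated disease-mutation
#'   database (used to rescue frequency-filter failures).
#' @param consequence consequence kind or `NA` when not yet annotated.
#' @param cdna_label,protein_label HGVS-like labels when known.
#' @param curated_class printed pathogenicity class for fixture records.
#' @param in_duplicated_region,gene cohort annotations.
#' @return a `variant_calls` data frame.
#' @export
variant_calls <- function(sample_id, contig = NA_character_, pos = NA_integer_,
                          ref = NA_character_, alt = NA_character_,
                          fwd_ref = 0L, rev_ref = 0L, fwd_alt = 0L, rev_alt = 0L,
                          freq_dbsnp = NA_real_, freq_g1000 = NA_real_,
                          freq_evs = NA_real_, freq_inhouse = NA_real_,
                          in_pathogenic_db = FALSE,
                          consequence = NA_character_,
                          cdna_label = NA_character_,
                          protein_label = NA_character_,
                          curated_class = NA_character_,
                          in_duplicated_region = NA,
                          gene = NA_character_) {
  n <- length(sample_id)
  args <- list(contig = contig, pos = pos, ref = ref, alt = alt,
               fwd_ref = fwd_ref, rev_ref = rev_ref, fwd_alt = fwd_alt,
               rev_alt = rev_alt, freq_dbsnp = freq_dbsnp,
               freq_g1000 = freq_g1000, freq_evs = freq_evs,
               freq_inhouse = freq_inhouse, in_pathogenic_db = in_pathogenic_db,
               consequence = consequence, cdna_label = cdna_label,
               protein_label = protein_label, curated_class = curated_class,
               in_duplicated_region = in_duplicated_region, gene = gene)
  for (nm in names(args)) assign(nm, rep_len(args[[nm]], n))
  df <- data.frame(
    sample_id = sample_id, contig = contig, pos = as.integer(pos),
    ref = ref, alt = alt,
    fwd_ref = as.integer(fwd_ref), rev_ref = as.integer(rev_ref),
    fwd_alt = as.integer(fwd_alt), rev_alt = as.integer(rev_alt),
    freq_dbsnp = freq_dbsnp, freq_g1000 = freq_g1000,
    freq_evs = freq_evs, freq_inhouse = freq_inhouse,
    in_pathogenic_db = in_pathogenic_db,
    consequence = consequence,
    cdna_label = cdna_label, protein_label = protein_label,
    curated_class = curated_class,
    in_duplicated_region = in_duplicated_region,
    gene = gene,
    stringsAsFactors = FALSE
  )
  validate_variant_calls(df)
}

#' @rdname variant_calls
#' @export
empty_variant_calls <- function() {
  variant_calls(sample_id = character())
}

validate_variant_calls <- function(df) {
  counts <- as.matrix(df[, c("fwd_ref", "rev_ref", "fwd_alt", "rev_alt")])
  abort_if(any(counts < 0, na.rm = TRUE), "negative read counts in variant calls")
  freqs <- as.matrix(df[, FREQ_DATABASES])
  abort_if(any(freqs < 0 | freqs > 1, na.rm = TRUE),
           "population frequencies must lie in [0, 1]")
  known <- is.na(df$consequence) | df$consequence %in% CONSEQUENCE_KINDS
  abort_if(!all(known), "unknown consequence kind(s): %s",
           paste(unique(df$consequence[!known]), collapse = ", "))
  class(df) <- unique(c("variant_calls", class(df)))
  df
}

#' Total depth and alt allele fraction of calls
#'
#' Depth is the sum of the four stranded ref/alt counts of the call itself
#' (other alleles at the site are out of scope); fraction is alt reads over
#' that depth (`NaN` at zero depth).
#'
#' @param calls a `variant_calls` data frame.
#' @return numeric vector.
#' @export
call_depth <- function(calls) {
  calls$fwd_ref + calls$rev_ref + calls$fwd_alt + calls$rev_alt
}

#' @rdname call_depth
#' @export
allele_fraction <- function(calls) {
  (calls$fwd_alt + calls$rev_alt) / call_depth(calls)
}
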