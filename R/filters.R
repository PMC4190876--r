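# The variant prioritization cascade: both-strand support, >=20% allele
# fraction, and <5% population frequency with pathogenic-database rescue.
# Spurious calls from reads misaligned out of the pseudogenes show up as
# low-fraction and/or strand-skewed candidates; these rules are the
# discriminator that removes them.

#' Both-strand support filter
#'
#' A candidate variant must be seen on both sequenced DNA strands.
#'
#' @param calls a `variant_calls` data frame.
#' @return logical vector, `TRUE` where `fwd_alt >= 1` and `rev_alt >= 1`.
#' @export
strand_filter <- function(calls) {
  calls$fwd_alt >= 1L & calls$rev_alt >= 1L
}

#' Allele-fraction filter
#'
#' Alt reads must account for at least `min_fraction` of the reads at the
#' site (ref + alt of this call); zero-depth calls fail.
#'
#' @param calls a `variant_calls` data frame.
#' @param min_fraction minimum alt fraction (default 0.20).
#' @return logical vector.
#' @export
allele_fraction_filter <- function(calls, min_fraction = 0.20) {
  depth <- call_depth(calls)
  ifelse(depth > 0, (calls$fwd_alt + calls$rev_alt) / depth >= min_fraction,
         FALSE)
}

#' Population-frequency filter with pathogenic-database rescue
#'
#' A call fails when its frequency in any population database reaches
#' `max_freq` (common polymorphism / recurrent artifact); a failing call is
#' rescued when it is a known disease mutation (`in_pathogenic_db`), since
#' population databases also contain disease-associated variants. Frequency
#' is the maximum over databases; absence everywhere passes.
#'
#' @param calls a `variant_calls` data frame.
#' @param max_freq frequency threshold (default 0.05).
#' @return data frame with logical columns `pass` and `rescue_applied`.
#' @export
frequency_filter <- function(calls, max_freq = 0.05) {
  freqs <- as.matrix(calls[, FREQ_DATABASES, drop = FALSE])
  abort_if(any(freqs < 0 | freqs > 1, na.rm = TRUE),
           "population frequencies must lie in [0, 1]")
  fmax <- apply(freqs, 1, max_or)
  common <- fmax >= max_freq
  rescue <- common & calls$in_pathogenic_db
  data.frame(pass = !common | rescue, rescue_applied = rescue)
}

#' Run the full filter cascade
#'
#' Applies the strand, allele-fraction and frequency rules to every call and
#' returns one decision per call with the list of failed rules (the audit
#' trail). A call is retained iff it fails no rule; the retained set is the
#' intersection of the three per-rule pass sets, so rule order is irrelevant.
#'
#' @param calls a `variant_calls` data frame.
#' @param min_fraction allele-fraction threshold (default 0.20).
#' @param max_freq population-frequency threshold (default 0.05).
#' @return a `filter_decisions` data frame: per-rule passes, `rescue_applied`,
#'   `failed_rules` (comma-joined, `"zero_depth"` tagged explicitly) and
#'   `passed`.
#' @export
run_cascade <- function(calls, min_fraction = 0.20, max_freq = 0.05) {
  calls <- validate_variant_calls(calls)
  strand_pass <- strand_filter(calls)
  fraction_pass <- allele_fraction_filter(calls, min_fraction)
  freq <- frequency_filter(calls, max_freq)
  depth <- call_depth(calls)

  failed <- mapply(function(s, f, q, d) {
    rules <- c(if (!s) "strand",
               if (!f) if (d == 0) "zero_depth" else "fraction",
               if (!q) "frequency")
    paste(rules, collapse = ",")
  }, strand_pass, fraction_pass, freq$pass, depth)
  if (nrow(calls) == 0) failed <- character(0)

  out <- data.frame(
    sample_id = calls$sample_id,
    strand_pass = strand_pass,
    fraction_pass = fraction_pass,
    frequency_pass = freq$pass,
    rescue_applied = freq$rescue_applied,
    failed_rules = failed,
    passed = strand_pass & fraction_pass & freq$pass,
    stringsAsFactors = FALSE
  )
  class(out) <- c("filter_decisions", "data.frame")
  out
}

#' Write the filter audit trail as TSV
#'
#' One row per call per rule, with the rule outcome; the long-format audit
#' companion to [run_cascade()].
#'
#' @param calls a `variant_calls` data frame.
#' @param decisions matching [run_cascade()] output.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_audit <- function(calls, decisions, path) {
  stopifnot(nrow(calls) == nrow(decisions))
  rule_cols <- c(strand = "strand_pass", fraction = "fraction_pass",
                 frequency = "frequency_pass")
  long <- do.call(rbind, lapply(names(rule_cols), function(rule) {
    data.frame(sample_id = calls$sample_id,
               cdna_label = calls$cdna_label,
               rule = rule,
               pass = decisions[[rule_cols[[rule]]]],
               rescue_applied = if (rule == "frequency")
                 decisions$rescue_applied else FALSE,
               stringsAsFactors = FALSE)
  }))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
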