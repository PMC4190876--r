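# Transcript model: exon structure + CDS on a mini-genome contig, with
# strand-aware projection of genomic positions to HGVS-like c. coordinates.
# All internal coordinates are 0-based half-open; 1-based numbers appear only
# inside HGVS-like text.

#' Construct a transcript model
#'
#' @param gene_id gene name.
#' @param contig contig name in `genome`.
#' @param strand `"+"` or `"-"`.
#' @param exons data frame with 0-based half-open `start`/`end` columns,
#'   sorted, non-overlapping.
#' @param cds_start,cds_end genomic CDS span (0-based half-open); boundaries
#'   must fall inside exons.
#' @param genome a [Biostrings::DNAStringSet] holding `contig`.
#' @return a `transcript_model` object.
#' @export
transcript_model <- function(gene_id, contig, strand, exons,
                             cds_start, cds_end, genome) {
  stopifnot(strand %in% c("+", "-"),
            all(c("start", "end") %in% names(exons)),
            contig %in% names(genome))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  abort_if(any(exons$end <= exons$start), "empty exon in transcript %s", gene_id)
  abort_if(any(utils::head(exons$end, -1) > utils::tail(exons$start, -1)),
           "overlapping exons in transcript %s", gene_id)
  in_exon <- function(g) any(g >= exons$start & g < exons$end)
  abort_if(!in_exon(cds_start) || !in_exon(cds_end - 1L),
           "CDS boundaries of %s fall outside exons", gene_id)
  tx <- list(gene_id = gene_id, contig = contig, strand = strand,
             exons = exons, cds_start = as.integer(cds_start),
             cds_end = as.integer(cds_end), genome = genome)
  class(tx) <- "transcript_model"
  tx
}

# 0-based offset of an exonic genomic position within the spliced transcript
# (strand-aware); NA for non-exonic positions.
spliced_offset <- function(tx, g) {
  ex <- tx$exons
  i <- which(g >= ex$start & g < ex$end)
  if (length(i) == 0) return(NA_integer_)
  plus <- sum(pmax(0L, pmin(ex$end, g) - ex$start)[seq_len(i - 1)]) + (g - ex$start[i])
  total <- sum(ex$end - ex$start)
  if (tx$strand == "+") as.integer(plus) else as.integer(total - 1L - plus)
}

# Offset of the first / last CDS base in transcript order.
cds_span_offsets <- function(tx) {
  if (tx$strand == "+") {
    c(first = spliced_offset(tx, tx$cds_start),
      last = spliced_offset(tx, tx$cds_end - 1L))
  } else {
    c(first = spliced_offset(tx, tx$cds_end - 1L),
      last = spliced_offset(tx, tx$cds_start))
  }
}

# 1-based CDS coordinate of an exonic genomic position; negative for 5' UTR
# (c.-n), NA for non-exonic, attribute "after_stop" when 3' of the CDS.
cds_position <- function(tx, g) {
  off <- spliced_offset(tx, g)
  if (is.na(off)) return(NA_integer_)
  span <- cds_span_offsets(tx)
  if (off < span["first"]) return(off - span["first"])  # <= -1
  cpos <- off - span["first"] + 1L
  if (off > span["last"]) attr(cpos, "after_stop") <- cpos - (span["last"] - span["first"] + 1L)
  cpos
}

format_cpos <- function(cpos) {
  after <- attr(cpos, "after_stop")
  if (!is.null(after)) sprintf("*%d", after)
  else if (cpos < 0) sprintf("-%d", -cpos)
  else sprintf("%d", cpos)
}

#' Project a genomic position to a cDNA coordinate label
#'
#' Exonic positions map to `"c.N"` (negative for 5' UTR, `*N` past the stop);
#' intronic positions to the nearest-exon offset forms `"c.N+k"` / `"c.N-k"`,
#' strand-aware; positions outside the transcript span to `"intergenic"`.
#'
#' @param pos genomic position (0-based).
#' @param tx a [transcript_model()].
#' @return character label.
#' @export
project_to_cdna <- function(pos, tx) {
  ex <- tx$exons
  if (pos < min(ex$start) || pos >= max(ex$end)) return("intergenic")
  off <- spliced_offset(tx, pos)
  if (!is.na(off)) return(sprintf("c.%s", format_cpos(cds_position(tx, pos))))
  i <- max(which(ex$end <= pos))            # intron between exon i and i+1
  d_left <- pos - ex$end[i] + 1L            # distance from exon i's last base
  d_right <- ex$start[i + 1] - pos          # distance to exon i+1's first base
  if (tx$strand == "+") {
    if (d_left <= d_right) {
      sprintf("c.%s+%d", format_cpos(cds_position(tx, ex$end[i] - 1L)), d_left)
    } else {
      sprintf("c.%s-%d", format_cpos(cds_position(tx, ex$start[i + 1])), d_right)
    }
  } else {
    if (d_right <= d_left) {
      sprintf("c.%s+%d", format_cpos(cds_position(tx, ex$start[i + 1])), d_right)
    } else {
      sprintf("c.%s-%d", format_cpos(cds_position(tx, ex$end[i] - 1L)), d_left)
    }
  }
}

# Signed intronic offset of a genomic position: +k downstream of a donor,
# -k upstream of an acceptor (transcript orientation); NA if exonic/outside.
intronic_offset <- function(tx, pos) {
  ex <- tx$exons
  if (pos < min(ex$start) || pos >= max(ex$end)) return(NA_integer_)
  if (!is.na(spliced_offset(tx, pos))) return(NA_integer_)
  i <- max(which(ex$end <= pos))
  d_left <- pos - ex$end[i] + 1L
  d_right <- ex$start[i + 1] - pos
  if (tx$strand == "+") {
    if (d_left <= d_right) d_left else -d_right
  } else {
    if (d_right <= d_left) d_right else -d_left
  }
}

# Spliced transcript sequence (strand-aware) and the CDS within it.
spliced_seq <- function(tx) {
  chunks <- Biostrings::DNAStringSet(tx$genome[[tx$contig]],
                                     start = tx$exons$start + 1L,
                                     end = tx$exons$end)
  s <- Biostrings::DNAString(paste(as.character(chunks), collapse = ""))
  if (tx$strand == "-") Biostrings::reverseComplement(s) else s
}

#' Coding sequence of a transcript
#'
#' @param tx a [transcript_model()].
#' @return a [Biostrings::DNAString] of the CDS (multiple of 3 long for
#'   synthetic transcripts).
#' @export
cds_seq <- function(tx) {
  span <- cds_span_offsets(tx)
  Biostrings::subseq(spliced_seq(tx), start = span["first"] + 1L,
                     end = span["last"] + 1L)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s strand) on %s: %d exons, CDS %d-%d\n",
              x$gene_id, x$strand, x$contig, nrow(x$exons),
              x$cds_start, x$cds_end))
  invisible(x)
}
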