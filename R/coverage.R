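# Coverage audit: per-gene/per-exon summary statistics of a per-base depth
# track, plus automatic reporting of low/zero-coverage target sub-intervals
# for orthogonal (Sanger) follow-up of undiagnosed samples. Per-base depth
# drives gap reporting, so a partially covered exon reports only its weak
# sub-interval.

#' Build a depth track
#'
#' @param contig,pos,depth per-base records (0-based positions, nonnegative
#'   depths); every targeted base must appear exactly once.
#' @param sample_id label.
#' @return a `depth_track` data frame.
#' @export
depth_track <- function(contig, pos, depth, sample_id = NA_character_) {
  abort_if(any(depth < 0), "depths must be nonnegative")
  abort_if(anyDuplicated(paste(contig, pos)) > 0,
           "a depth track must cover each base exactly once")
  track <- data.frame(contig = contig, pos = as.integer(pos),
                      depth = as.integer(depth), stringsAsFactors = FALSE)
  attr(track, "sample_id") <- sample_id
  class(track) <- c("depth_track", "data.frame")
  track
}

pct <- function(x) 100 * mean(x)

#' Summarize coverage per gene and per exon
#'
#' Mean depth and the fraction of bases at 0X and at >=1X/20X/50X/100X per
#' gene, plus per-exon mean depth. Every annotated base must be present in
#' the track.
#'
#' @param track a `depth_track`.
#' @param annotation data frame with `gene`, `exon`, `contig`, `start`, `end`
#'   (0-based half-open exon intervals).
#' @return list with `genes` and `exons` data frames.
#' @export
summarize_coverage <- function(track, annotation) {
  stopifnot(all(c("gene", "exon", "contig", "start", "end") %in% names(annotation)))
  key <- paste(track$contig, track$pos)
  depth_at <- setNames(track$depth, key)

  exon_rows <- lapply(seq_len(nrow(annotation)), function(i) {
    a <- annotation[i, ]
    k <- paste(a$contig, a$start:(a$end - 1L))
    miss <- !(k %in% key)
    abort_if(any(miss), "annotation interval %s:%d-%d has %d base(s) absent from the track",
             a$contig, a$start, a$end, sum(miss))
    d <- depth_at[k]
    data.frame(gene = a$gene, exon = a$exon, mean_depth = mean(d),
               stringsAsFactors = FALSE)
  })
  exons <- do.call(rbind, exon_rows)

  genes <- do.call(rbind, lapply(unique(annotation$gene), function(g) {
    ga <- annotation[annotation$gene == g, , drop = FALSE]
    k <- unlist(lapply(seq_len(nrow(ga)), function(i)
      paste(ga$contig[i], ga$start[i]:(ga$end[i] - 1L))))
    d <- depth_at[k]
    data.frame(gene = g, mean_depth = mean(d),
               pct_0x = pct(d == 0), pct_ge_1x = pct(d >= 1),
               pct_ge_20x = pct(d >= 20), pct_ge_50x = pct(d >= 50),
               pct_ge_100x = pct(d >= 100), stringsAsFactors = FALSE)
  }))
  list(genes = genes, exons = exons)
}

#' Report low-coverage regions
#'
#' Maximal runs of targeted bases with depth below `min_depth`, merged across
#' adjacent bases, as 0-based half-open intervals. The union of the reported
#' intervals is exactly the set of bases below threshold.
#'
#' @param track a `depth_track`.
#' @param min_depth depth below which a base is reported (default 20).
#' @return data frame `contig`, `start`, `end` (BED-compatible).
#' @export
low_coverage_regions <- function(track, min_depth = 20L) {
  low <- track[track$depth < min_depth, , drop = FALSE]
  out <- data.frame(contig = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  for (ctg in unique(low$contig)) {
    pos <- sort(low$pos[low$contig == ctg])
    ir <- IRanges::reduce(IRanges::IRanges(start = pos + 1L, width = 1L))
    out <- rbind(out, data.frame(contig = ctg,
                                 start = IRanges::start(ir) - 1L,
                                 end = IRanges::end(ir),
                                 stringsAsFactors = FALSE))
  }
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Write regions as BED
#'
#' @param regions `contig`/`start`/`end` data frame (0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  write.table(regions[, c("contig", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Flag a sample for Sanger follow-up of low-coverage regions
#'
#' When a sample's pipeline run reports no pathogenic mutation, its
#' low-coverage regions are attached with a Sanger-recommended flag (these
#' regions are where a missed mutation is most likely to hide); samples with
#' a reportable finding are not flagged.
#'
#' @param regions [low_coverage_regions()] output (possibly empty).
#' @param variants_found logical; did the sample yield a reportable mutation?
#' @return list with `flag`, `regions` and a human-readable `message`.
#' @export
flag_missed_mutation_risk <- function(regions, variants_found) {
  flag <- !isTRUE(variants_found)
  msg <- if (!flag) {
    "reportable mutation found; no follow-up needed"
  } else if (nrow(regions) == 0) {
    "no reportable mutation; no low-coverage regions to screen"
  } else {
    sprintf("no reportable mutation; recommend Sanger screening of %d low-coverage region(s)",
            nrow(regions))
  }
  list(flag = flag, regions = regions, message = msg)
}
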