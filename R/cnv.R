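# Read-depth CNV detection over capture targets, CoNIFER-style:
# RPKM -> per-target cohort z-score (ZRPKM, median/sd across samples) ->
# SVD denoising (zero the top k singular values, removing systematic capture
# covariance) -> thresholded runs of consecutive targets.

#' Construct a coverage matrix
#'
#' @param counts samples x targets nonnegative integer matrix (row names are
#'   sample ids, column names target names).
#' @param targets target table with at least `name` and `length` (bp) columns.
#' @param totals per-sample total mapped reads; defaults to row sums (totals
#'   may exceed row sums when reads map off-target).
#' @return a `coverage_matrix` object.
#' @export
coverage_matrix <- function(counts, targets, totals = rowSums(counts)) {
  stopifnot(is.matrix(counts), nrow(targets) == ncol(counts),
            all(c("name", "length") %in% names(targets)))
  abort_if(any(counts < 0), "negative counts in coverage matrix")
  abort_if(any(targets$length <= 0), "target lengths must be positive")
  abort_if(length(totals) != nrow(counts), "one total per sample required")
  abort_if(any(totals < rowSums(counts)),
           "per-sample totals cannot be below on-target row sums")
  structure(list(counts = counts, targets = targets, totals = totals,
                 samples = rownames(counts)),
            class = "coverage_matrix")
}

new_zrpkm <- function(values, targets, stage, mask = rep(FALSE, ncol(values)),
                      removed_components = NA_integer_) {
  structure(list(values = values, targets = targets, stage = stage,
                 mask = mask, removed_components = removed_components),
            class = "zrpkm_matrix")
}

#' Reads per kilobase of target per million mapped reads
#'
#' `rpkm[s, t] = counts[s, t] * 1e9 / (length[t] * totals[s])`; invariant to
#' per-sample library-size multipliers. Samples with zero total reads are
#' excluded with a warning.
#'
#' @param cm a [coverage_matrix()].
#' @return a `zrpkm_matrix` at stage `"rpkm"`.
#' @export
compute_rpkm <- function(cm) {
  stopifnot(inherits(cm, "coverage_matrix"))
  keep <- cm$totals > 0
  if (!all(keep)) {
    warning(sprintf("excluding %d sample(s) with zero total reads: %s",
                    sum(!keep), paste(cm$samples[!keep], collapse = ", ")))
  }
  counts <- cm$counts[keep, , drop = FALSE]
  values <- counts * 1e9 /
    outer(cm$totals[keep], cm$targets$length, function(tot, len) len * tot)
  new_zrpkm(values, cm$targets, "rpkm")
}

#' Per-target cohort z-score of RPKM (ZRPKM)
#'
#' For each target, centers on the cohort median and scales by the cohort
#' standard deviation across samples. Targets whose sd falls below `sd_floor`
#' (e.g. all-zero dropout targets) are masked (set to 0 and flagged) rather
#' than divided by ~0.
#'
#' @param r a stage-`"rpkm"` `zrpkm_matrix`.
#' @param sd_floor minimum sd for a target to stay unmasked.
#' @return a `zrpkm_matrix` at stage `"zrpkm"` with a `mask` vector.
#' @export
compute_zrpkm <- function(r, sd_floor = 1e-8) {
  stopifnot(inherits(r, "zrpkm_matrix"), r$stage == "rpkm")
  abort_if(nrow(r$values) < 8L,
           "need >= 8 samples for a stable cohort baseline, got %d",
           nrow(r$values))
  med <- apply(r$values, 2, median)
  sds <- apply(r$values, 2, sd)
  mask <- sds < sd_floor
  z <- sweep(r$values, 2, med)
  z[, !mask] <- sweep(z[, !mask, drop = FALSE], 2, sds[!mask], "/")
  z[, mask] <- 0
  new_zrpkm(z, r$targets, "zrpkm", mask = mask)
}

#' SVD denoising of the ZRPKM matrix
#'
#' Singular value decomposition of the samples x targets matrix with the `k`
#' largest singular values set to zero before reconstruction, removing the
#' strongest systematic (batch/capture) components. `k = 0` returns the input
#' unchanged.
#'
#' @param z a stage-`"zrpkm"` `zrpkm_matrix`.
#' @param k number of leading components to remove; must satisfy
#'   `0 <= k < min(dim)`.
#' @return a `zrpkm_matrix` at stage `"svd_zrpkm"`.
#' @export
svd_denoise <- function(z, k = 3L) {
  stopifnot(inherits(z, "zrpkm_matrix"), z$stage == "zrpkm")
  abort_if(k < 0, "k must be nonnegative")
  abort_if(k >= min(dim(z$values)), "k must be below min(n_samples, n_targets)")
  values <- z$values
  if (k > 0) {
    dec <- svd(values)
    d <- dec$d
    d[seq_len(k)] <- 0
    values <- dec$u %*% (d * t(dec$v))
    dimnames(values) <- dimnames(z$values)
  }
  new_zrpkm(values, z$targets, "svd_zrpkm", mask = z$mask,
            removed_components = as.integer(k))
}

#' Call CNVs from the denoised signal
#'
#' Per sample, maximal runs of at least `min_targets` consecutive unmasked
#' targets with signal `<= -threshold` become deletion calls (`>= +threshold`
#' duplications), reporting the target span and mean signal.
#'
#' @param z a stage-`"svd_zrpkm"` `zrpkm_matrix`.
#' @param threshold SVD-ZRPKM magnitude cut-off (default 1.5).
#' @param min_targets minimum run length in targets (default 2).
#' @return data frame of calls: `sample_id`, `first_target`, `last_target`
#'   (1-based target indices), `direction`, `n_targets`, `mean_signal`.
#' @export
call_cnvs <- function(z, threshold = 1.5, min_targets = 2L) {
  stopifnot(inherits(z, "zrpkm_matrix"), z$stage == "svd_zrpkm")
  abort_if(threshold <= 0, "threshold must be positive")
  runs_of <- function(flag) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_targets
    cbind(start = starts[keep], end = ends[keep])
  }
  calls <- list()
  for (s in seq_len(nrow(z$values))) {
    row <- z$values[s, ]
    for (dir in c("deletion", "duplication")) {
      flag <- if (dir == "deletion") row <= -threshold else row >= threshold
      flag[z$mask] <- FALSE
      spans <- runs_of(flag)
      for (i in seq_len(nrow(spans))) {
        idx <- spans[i, "start"]:spans[i, "end"]
        calls[[length(calls) + 1L]] <- data.frame(
          sample_id = rownames(z$values)[s],
          first_target = spans[i, "start"], last_target = spans[i, "end"],
          direction = dir, n_targets = length(idx),
          mean_signal = mean(row[idx]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(calls) == 0) {
    return(data.frame(sample_id = character(), first_target = integer(),
                      last_target = integer(), direction = character(),
                      n_targets = integer(), mean_signal = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Run the whole read-depth pipeline
#'
#' Convenience composition: RPKM, ZRPKM, SVD denoising and CNV calling.
#'
#' @param cm a [coverage_matrix()].
#' @param k removed SVD components (default 3).
#' @param threshold,min_targets see [call_cnvs()].
#' @return list with the three stage matrices and `calls`.
#' @export
detect_deletions <- function(cm, k = 3L, threshold = 1.5, min_targets = 2L) {
  r <- compute_rpkm(cm)
  z <- compute_zrpkm(r)
  s <- svd_denoise(z, k)
  list(rpkm = r, zrpkm = z, svd_zrpkm = s,
       calls = call_cnvs(s, threshold, min_targets))
}

#' Write CNV calls as a BED-like TSV
#'
#' @param calls [call_cnvs()] output.
#' @param targets target table with `contig`, `start`, `end` (0-based
#'   half-open) used to translate target spans into coordinates.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cnv_calls <- function(calls, targets, path) {
  out <- data.frame(
    contig = targets$contig[calls$first_target],
    start = targets$start[calls$first_target],
    end = targets$end[calls$last_target],
    sample_id = calls$sample_id,
    direction = calls$direction,
    mean_signal = calls$mean_signal,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
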