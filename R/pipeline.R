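# End-to-end orchestration: filter cascade -> classification -> structural /
# read-depth deletion events -> coverage audit -> per-sample diagnostic
# reports and cohort summary (diagnostic rate, per-gene and duplicated-region
# mutation counts).

#' Run the diagnostic pipeline over a cohort
#'
#' Applies the filter cascade to the candidate calls, classifies the retained
#' variants (truncating consequences outright; UCVs via their Variant Score
#' features, falling back to curated classes for fixture records), folds in
#' structural deletion events and, when a coverage matrix is supplied,
#' read-depth deletion calls, audits per-base depth tracks, and assembles one
#' report per sample plus a cohort summary. A sample is diagnosed iff it has
#' at least one reportable mutation or a deletion event; undiagnosed samples
#' get the Sanger low-coverage flag.
#'
#' @param calls a `variant_calls` data frame (may have a `features`
#'   list-column of VS evidence).
#' @param sv_events structural events (`sample_id`, `gene`, `coordinates`,
#'   optional `curated_class`, `in_duplicated_region`) or `NULL`.
#' @param coverage optional [coverage_matrix()] for read-depth calling.
#' @param depth_tracks optional named list of `depth_track`s keyed by sample.
#' @param samples cohort sample ids (defaults to those seen in the inputs;
#'   pass explicitly so mutation-free samples count in the denominator).
#' @param scoring a [scoring_config()].
#' @param min_fraction,max_freq cascade thresholds.
#' @param cnv_k,cnv_threshold,cnv_min_targets read-depth caller settings.
#' @param low_cov_min_depth coverage-audit threshold.
#' @return a `diagnostic_result` list: `reports` (per sample), `mutations`
#'   (cohort mutation table), `decisions` (filter audit), `cnv_calls`,
#'   and `summary`.
#' @export
run_pipeline <- function(calls, sv_events = NULL, coverage = NULL,
                         depth_tracks = NULL, samples = NULL,
                         scoring = default_scoring_config(),
                         min_fraction = 0.20, max_freq = 0.05,
                         cnv_k = 3L, cnv_threshold = 1.5, cnv_min_targets = 2L,
                         low_cov_min_depth = 20L) {
  calls <- validate_variant_calls(calls)
  abort_if(any(is.na(calls$consequence)),
           "all calls must be consequence-annotated before the pipeline runs")
  if (is.null(samples)) {
    samples <- unique(c(calls$sample_id,
                        if (!is.null(sv_events)) sv_events$sample_id))
  }

  decisions <- run_cascade(calls, min_fraction, max_freq)
  retained <- calls[decisions$passed, , drop = FALSE]

  classify_row <- function(row) {
    feats <- if (!is.null(row$features)) row$features[[1]] else NULL
    score <- if (!is.null(feats) && is_ucv(row$consequence))
      compute_variant_score(unlist(feats), scoring) else NULL
    curated <- if (!is.null(row$curated_class)) row$curated_class else NA_character_
    classify_variant(row$consequence, score = score,
                     curated_class = curated, cfg = scoring)
  }

  mutations <- data.frame(
    sample_id = character(), gene = character(), cdna_label = character(),
    protein_label = character(), consequence = character(),
    class = character(), reportable = logical(),
    in_duplicated_region = logical(), source = character(),
    stringsAsFactors = FALSE)
  if (nrow(retained) > 0) {
    cls <- vapply(seq_len(nrow(retained)), function(i)
      classify_row(retained[i, , drop = FALSE]), "")
    mutations <- data.frame(
      sample_id = retained$sample_id, gene = retained$gene,
      cdna_label = retained$cdna_label, protein_label = retained$protein_label,
      consequence = retained$consequence, class = cls,
      reportable = is_reportable(cls),
      in_duplicated_region = retained$in_duplicated_region,
      source = "snv_indel", stringsAsFactors = FALSE)
  }
  if (!is.null(sv_events) && nrow(sv_events) > 0) {
    sv_class <- if (!is.null(sv_events$curated_class))
      ifelse(is.na(sv_events$curated_class), "definitely_pathogenic",
             sv_events$curated_class)
    else rep("definitely_pathogenic", nrow(sv_events))
    mutations <- rbind(mutations, data.frame(
      sample_id = sv_events$sample_id, gene = sv_events$gene,
      cdna_label = sv_events$coordinates, protein_label = NA_character_,
      consequence = "structural_deletion", class = sv_class,
      reportable = is_reportable(sv_class),
      in_duplicated_region = if (!is.null(sv_events$in_duplicated_region))
        sv_events$in_duplicated_region else NA,
      source = "sv", stringsAsFactors = FALSE))
  }

  cnv_calls <- NULL
  if (!is.null(coverage)) {
    cnv_calls <- detect_deletions(coverage, k = cnv_k,
                                  threshold = cnv_threshold,
                                  min_targets = cnv_min_targets)$calls
  }

  reports <- lapply(samples, function(s) {
    mut <- mutations[mutations$sample_id == s & mutations$reportable, , drop = FALSE]
    cnv <- if (!is.null(cnv_calls))
      cnv_calls[cnv_calls$sample_id == s & cnv_calls$direction == "deletion", ,
                drop = FALSE]
    else NULL
    diagnosed <- nrow(mut) > 0 || (!is.null(cnv) && nrow(cnv) > 0)
    track <- if (!is.null(depth_tracks) && s %in% names(depth_tracks))
      depth_tracks[[s]] else NULL
    gaps <- if (!is.null(track)) low_coverage_regions(track, low_cov_min_depth)
            else data.frame(contig = character(), start = integer(),
                            end = integer(), stringsAsFactors = FALSE)
    list(sample_id = s, mutations = mut, cnv_events = cnv,
         diagnosed = diagnosed,
         sanger = flag_missed_mutation_risk(gaps, diagnosed))
  })
  names(reports) <- samples

  n <- length(samples)
  diagnosed <- vapply(reports, `[[`, TRUE, "diagnosed")
  reported_mut <- mutations[mutations$reportable, , drop = FALSE]
  summary <- list(
    n_samples = n,
    n_diagnosed = sum(diagnosed),
    diagnostic_rate = if (n == 0) NA_real_
                      else round_half_up(100 * sum(diagnosed) / n, 1),
    rate_defined = n > 0,
    n_reported_mutations = nrow(reported_mut),
    per_gene = if (nrow(reported_mut) > 0) table(reported_mut$gene) else table(character()),
    n_duplicated_region = sum(reported_mut$in_duplicated_region, na.rm = TRUE)
  )

  structure(list(reports = reports, mutations = mutations,
                 decisions = decisions, cnv_calls = cnv_calls,
                 summary = summary),
            class = "diagnostic_result")
}

#' Cohort diagnostic rate
#'
#' Percentage of samples with at least one reportable mutation, printed to
#' one decimal (half-up). An empty cohort has no defined rate (`NA` with an
#' `n = 0` marker in the summary).
#'
#' @param result a `diagnostic_result` from [run_pipeline()].
#' @return numeric percentage (`NA_real_` for an empty cohort).
#' @export
diagnostic_rate <- function(result) {
  stopifnot(inherits(result, "diagnostic_result"))
  result$summary$diagnostic_rate
}

#' Count reported mutations in the segmentally duplicated region
#'
#' @param result a `diagnostic_result`.
#' @return integer count (records without the annotation contribute 0).
#' @export
duplicated_region_count <- function(result) {
  stopifnot(inherits(result, "diagnostic_result"))
  result$summary$n_duplicated_region
}

#' @export
print.diagnostic_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("diagnostic_result: %d samples, %d diagnosed (rate %s%%), %d reported mutations\n",
              s$n_samples, s$n_diagnosed,
              if (s$rate_defined) format(s$diagnostic_rate) else "undefined (n=0)",
              s$n_reported_mutations))
  invisible(x)
}

#' Write per-sample diagnostic reports
#'
#' JSON report (per-sample mutations, deletion events, Sanger flags, cohort
#' summary) plus a TSV mutation table.
#'
#' @param result a `diagnostic_result`.
#' @param dir output directory (created if absent).
#' @return the JSON path, invisibly.
#' @export
write_diagnostic_reports <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    summary = result$summary[c("n_samples", "n_diagnosed", "diagnostic_rate",
                               "n_reported_mutations", "n_duplicated_region")],
    samples = lapply(result$reports, function(r) {
      list(sample_id = r$sample_id, diagnosed = r$diagnosed,
           mutations = r$mutations,
           cnv_events = r$cnv_events,
           sanger_flag = r$sanger$flag,
           sanger_message = r$sanger$message,
           low_coverage_regions = r$sanger$regions)
    })
  )
  path <- file.path(dir, "diagnostic_report.json")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  write.table(result$mutations, file.path(dir, "mutations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
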