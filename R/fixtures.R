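# Cohort fixtures: the published validation (36 samples) and discovery
# (12 samples) mutation tables, shipped verbatim as TSV under inst/extdata.
#
# Fixture conventions:
#   * "-" marks an absent field, mirroring the dashes of the printed tables.
#   * Strand-split read counts are not printed; when fixture records are
#     converted to variant calls, totals are split as evenly as possible
#     across strands (forward strand gets the extra read for odd counts).
#     This is a fixture convention, not data.
#   * The two large deletions carry their printed genomic coordinates in
#     `sv_coordinates` and enter the pipeline as structural events, not
#     through the SNV filter cascade.

VALID_CLASSES <- c("definitely_pathogenic", "highly_likely_pathogenic",
                   "likely_pathogenic", "indeterminate",
                   "highly_likely_neutral")

normalize_classification <- function(x) {
  key <- gsub("[ _]+", " ", trimws(tolower(x)))
  map <- c("definitely pathogenic"    = "definitely_pathogenic",
           "highly likely pathogenic" = "highly_likely_pathogenic",
           "likely pathogenic"        = "likely_pathogenic",
           "indeterminate"            = "indeterminate",
           "highly likely neutral"    = "highly_likely_neutral")
  out <- unname(map[key])
  out[is.na(x)] <- NA_character_
  bad <- !is.na(x) & is.na(out)
  abort_if(any(bad), "unrecognised classification label(s): %s",
           paste(unique(x[bad]), collapse = ", "))
  out
}

load_cohort_tsv <- function(path, expected_samples = NULL) {
  abort_if(!file.exists(path), "fixture not found: %s", path)
  raw <- read.delim(path, colClasses = "character", na.strings = "-",
                    check.names = FALSE)
  needed <- c("sample_id", "gene", "duplicated_region", "cdna_change",
              "protein_change", "pkdb", "prior_patients", "classification",
              "ref_count", "variant_count", "sv_coordinates")
  missing <- setdiff(needed, names(raw))
  abort_if(length(missing) > 0, "fixture %s lacks column(s): %s", path,
           paste(missing, collapse = ", "))

  parse_count <- function(x, col, line) {
    if (is.na(x)) return(NA_integer_)
    n <- suppressWarnings(as.integer(x))
    abort_if(is.na(n) || n < 0,
             "line %d of %s: column %s has malformed count '%s'",
             line, basename(path), col, x)
    n
  }

  rec <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    line <- i + 1L  # header is line 1
    r <- raw[i, ]
    abort_if(is.na(r$sample_id) || !nzchar(r$sample_id),
             "line %d of %s: missing sample id", line, basename(path))
    ref <- parse_count(r$ref_count, "ref_count", line)
    var <- parse_count(r$variant_count, "variant_count", line)
    abort_if(xor(is.na(ref), is.na(var)),
             "line %d of %s: ref_count/variant_count must be both present or both absent",
             line, basename(path))
    has_counts <- !is.na(ref)
    has_sv <- !is.na(r$sv_coordinates)
    has_mut <- !is.na(r$cdna_change)
    abort_if(has_counts && has_sv,
             "line %d of %s: record carries both read counts and SV coordinates",
             line, basename(path))
    abort_if(has_mut && !(has_counts || has_sv),
             "line %d of %s: mutation row lacks both counts and SV coordinates",
             line, basename(path))
    rec[[i]] <- data.frame(
      sample_id = r$sample_id,
      gene = if (is.na(r$gene)) NA_character_ else r$gene,
      in_duplicated_region = identical(r$duplicated_region, "Yes"),
      cdna_change = r$cdna_change,
      protein_change = r$protein_change,
      pkdb_present = identical(r$pkdb, "Present"),
      prior_patient_count = parse_count(r$prior_patients, "prior_patients", line),
      classification = r$classification,
      ref_count = ref,
      variant_count = var,
      sv_coordinates = r$sv_coordinates,
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, rec)
  records$class <- normalize_classification(records$classification)
  if (!is.null(expected_samples)) {
    n <- length(unique(records$sample_id))
    abort_if(n != expected_samples,
             "fixture %s: expected %d distinct samples, found %d",
             basename(path), expected_samples, n)
  }
  class(records) <- c("cohort_records", "data.frame")
  records
}

#' Load the validation cohort fixture
#'
#' The packaged table of mutations identified in the 36 previously
#' characterised validation samples: per-record gene, duplicated-region flag,
#' HGVS-like cDNA/protein labels, mutation-database membership, printed
#' pathogenicity classification and stranded-total read counts (or genomic
#' coordinates for the two large deletions; all dashes for the one sample in
#' which the known mutation was not re-detected).
#'
#' @param path fixture TSV; defaults to the copy shipped with the package.
#' @return a `cohort_records` data frame, one row per sample (36 rows).
#' @export
load_validation_cohort <- function(path = system.file("extdata", "validation_cohort.tsv",
                                                      package = "pkdpanel")) {
  load_cohort_tsv(path, expected_samples = 36L)
}

#' Load the discovery cohort fixture
#'
#' The packaged table of mutations identified in the 12 uncharacterised
#' discovery samples: 11 mutation rows (one sample carries a mutation in each
#' gene) plus two all-absent rows for the samples in which no pathogenic
#' variant was called.
#'
#' @inheritParams load_validation_cohort
#' @return a `cohort_records` data frame (13 rows, 12 distinct samples).
#' @export
load_discovery_cohort <- function(path = system.file("extdata", "discovery_cohort.tsv",
                                                     package = "pkdpanel")) {
  load_cohort_tsv(path, expected_samples = 12L)
}

#' Write cohort records back to fixture TSV
#'
#' Inverse of the loaders; writing and reloading round-trips exactly.
#'
#' @param records a `cohort_records` data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_fixture <- function(records, path) {
  out <- data.frame(
    sample_id = records$sample_id,
    gene = records$gene,
    duplicated_region = ifelse(records$in_duplicated_region, "Yes", NA),
    cdna_change = records$cdna_change,
    protein_change = records$protein_change,
    pkdb = ifelse(is.na(records$gene), NA,
                  ifelse(records$pkdb_present, "Present", "Absent")),
    prior_patients = records$prior_patient_count,
    classification = records$classification,
    ref_count = records$ref_count,
    variant_count = records$variant_count,
    sv_coordinates = records$sv_coordinates,
    stringsAsFactors = FALSE
  )
  out[] <- lapply(out, function(col) ifelse(is.na(col), "-", as.character(col)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Curate a molecular consequence from HGVS-like labels
#'
#' Parses the printed cDNA/protein notation of a fixture record into a
#' consequence kind. Intronic-offset patterns in the cDNA label take
#' precedence over the protein label (an intronic change annotated with a
#' downstream frameshift is a splice/intronic change, not a coding
#' frameshift): offsets 1-2 are canonical splice, 3-10 noncanonical splice,
#' deeper offsets intronic. Otherwise `*` is stop-gain, `fs` frameshift,
#' `del`/`dup` without `fs` an inframe indel, and a single residue
#' substitution missense.
#'
#' @param cdna,protein HGVS-like labels as printed (protein may be `NA` or "p.(?)").
#' @param splice_window largest intronic offset still called noncanonical splice.
#' @return one of `"stop_gain"`, `"frameshift"`, `"canonical_splice"`,
#'   `"noncanonical_splice"`, `"intronic"`, `"missense"`, `"inframe_indel"`.
#' @export
curate_consequence <- function(cdna, protein, splice_window = 10L) {
  stopifnot(length(cdna) == 1L)
  m <- regmatches(cdna, regexec("c\\.[0-9]+([+-])([0-9]+)", cdna))[[1]]
  if (length(m) == 3L) {
    k <- as.integer(m[3])
    if (k <= 2L) return("canonical_splice")
    if (k <= splice_window) return("noncanonical_splice")
    return("intronic")
  }
  p <- if (is.na(protein) || protein %in% c("p.(?)", "p.?")) "" else protein
  if (grepl("\\*", p)) return("stop_gain")
  if (grepl("fs", p)) return("frameshift")
  if (grepl("del|dup|ins", p)) return("inframe_indel")
  if (grepl("^p\\.\\(?[A-Z][a-z]{2}[0-9]+[A-Z][a-z]{2}\\)?$", p)) return("missense")
  stop(sprintf("cannot curate a consequence for cDNA '%s' / protein '%s'",
               cdna, protein), call. = FALSE)
}

# Even strand split of a read-count total; forward gets the odd read.
split_strand_counts <- function(n) {
  fwd <- ceiling(n / 2)
  cbind(fwd = fwd, rev = n - fwd)
}

#' Convert cohort records to pipeline inputs
#'
#' Count-bearing records become variant calls with evenly strand-split counts,
#' a curated consequence (see [curate_consequence()]) and the printed
#' classification attached as `curated_class`; SV records become structural
#' deletion events; all-absent rows contribute only to the sample list.
#'
#' @param records a `cohort_records` data frame.
#' @return list with `calls` (variant-call data frame), `sv_events`
#'   (structural events), and `samples` (all cohort sample ids).
#' @export
records_to_variant_calls <- function(records) {
  stopifnot(inherits(records, "cohort_records"))
  mut <- records[!is.na(records$cdna_change), , drop = FALSE]
  cnt <- mut[!is.na(mut$variant_count), , drop = FALSE]
  svs <- mut[!is.na(mut$sv_coordinates), , drop = FALSE]

  calls <- empty_variant_calls()
  if (nrow(cnt) > 0) {
    rs <- split_strand_counts(cnt$ref_count)
    as <- split_strand_counts(cnt$variant_count)
    snv <- regmatches(cnt$cdna_change,
                      regexec("^c\\.[0-9]+([ACGT])>([ACGT])$", cnt$cdna_change))
    ref_allele <- vapply(snv, function(m) if (length(m) == 3) m[2] else NA_character_, "")
    alt_allele <- vapply(snv, function(m) if (length(m) == 3) m[3] else NA_character_, "")
    calls <- variant_calls(
      sample_id = cnt$sample_id,
      contig = cnt$gene,
      pos = NA_integer_,
      ref = ref_allele,
      alt = alt_allele,
      fwd_ref = rs[, "fwd"], rev_ref = rs[, "rev"],
      fwd_alt = as[, "fwd"], rev_alt = as[, "rev"],
      in_pathogenic_db = cnt$pkdb_present,
      consequence = vapply(seq_len(nrow(cnt)), function(i)
        curate_consequence(cnt$cdna_change[i], cnt$protein_change[i]), ""),
      cdna_label = cnt$cdna_change,
      protein_label = cnt$protein_change,
      curated_class = cnt$class,
      in_duplicated_region = cnt$in_duplicated_region,
      gene = cnt$gene
    )
  }

  sv_events <- data.frame(
    sample_id = character(), gene = character(), coordinates = character(),
    cdna_label = character(), in_duplicated_region = logical(),
    curated_class = character(), stringsAsFactors = FALSE
  )
  if (nrow(svs) > 0) {
    sv_events <- data.frame(
      sample_id = svs$sample_id,
      gene = svs$gene,
      coordinates = svs$sv_coordinates,
      cdna_label = svs$cdna_change,
      in_duplicated_region = svs$in_duplicated_region,
      curated_class = svs$class,
      stringsAsFactors = FALSE
    )
  }

  list(calls = calls, sv_events = sv_events,
       samples = unique(records$sample_id))
}
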