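# Synthetic-data generator: the statistical world the analysis assumes.
# A genuine gene plus diverged pseudogene copies (the misalignment source),
# true heterozygous variants at ~50% allele fraction, pseudogene-leakage
# calls at low fraction and/or single-strand support, and Poisson coverage
# matrices with library-size variation, low-rank capture bias, spiked
# heterozygous deletions and forced dropout exons.

#' Simulation configuration
#'
#' Defaults model the study conditions: six pseudogene copies at per-base
#' divergence 0.023 (~97.7% identity), 41 samples (36 patients + 5 controls),
#' mean target depth 330 (the printed panel coverage), heterozygous variants
#' at mean alt fraction 0.5, leakage-call fractions strictly below the 0.20
#' filter threshold, lognormal library-size scatter (sd 0.2 on the log scale)
#' and a rank-3 multiplicative capture-bias component (sd 0.10 per log-unit)
#' that the SVD stage is designed to remove.
#'
#' @param gene_length_bp genomic span of the genuine gene.
#' @param n_exons exons laid out alternating with equal-length introns;
#'   the exons double as capture targets.
#' @param n_pseudogenes number of pseudogene copies.
#' @param divergence per-base substitution probability of each copy.
#' @param n_samples cohort size (>= 8 for the read-depth baseline).
#' @param mean_depth expected reads per call site / per target.
#' @param leakage_rate expected spurious leakage calls per sample.
#' @param leakage_fraction_range observed alt-fraction interval of leakage
#'   calls; upper bound must stay below 0.20 so the fraction filter is the
#'   discriminator.
#' @param het_fraction_mean expected alt fraction of true heterozygous calls.
#' @param n_true_per_sample,n_benign_per_sample planted true pathogenic and
#'   common benign variants per sample.
#' @param dropout_exons 1-based target indices forced to <5% of mean depth
#'   in every sample (the uncapturable GC-rich exon analogue).
#' @param n_targets,target_length_bp size of the default capture panel used
#'   by [simulate_coverage_matrix()] when no explicit targets are given:
#'   99 regions of median length ~995 bp, the printed panel geometry. A CNV
#'   spans a minority of the panel, which is what lets the SVD separate it
#'   from panel-wide batch structure.
#' @param library_scale_sd lognormal sd of per-sample library size.
#' @param batch_rank,batch_sd rank and per-component log-sd of the
#'   multiplicative capture-bias structure shared across samples.
#' @param seed integer; fully determines every output.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(gene_length_bp = 12000L, n_exons = 30L,
                       n_pseudogenes = 6L, divergence = 0.023,
                       n_samples = 41L, mean_depth = 330,
                       leakage_rate = 3, leakage_fraction_range = c(0.02, 0.18),
                       het_fraction_mean = 0.5,
                       n_true_per_sample = 1L, n_benign_per_sample = 2L,
                       dropout_exons = integer(0),
                       n_targets = 99L, target_length_bp = 995,
                       library_scale_sd = 0.2,
                       batch_rank = 3L, batch_sd = 0.10,
                       seed = 1L) {
  cfg <- list(gene_length_bp = as.integer(gene_length_bp),
              n_exons = as.integer(n_exons),
              n_pseudogenes = as.integer(n_pseudogenes),
              divergence = divergence, n_samples = as.integer(n_samples),
              mean_depth = mean_depth, leakage_rate = leakage_rate,
              leakage_fraction_range = leakage_fraction_range,
              het_fraction_mean = het_fraction_mean,
              n_true_per_sample = as.integer(n_true_per_sample),
              n_benign_per_sample = as.integer(n_benign_per_sample),
              dropout_exons = as.integer(dropout_exons),
              n_targets = as.integer(n_targets),
              target_length_bp = target_length_bp,
              library_scale_sd = library_scale_sd,
              batch_rank = as.integer(batch_rank), batch_sd = batch_sd,
              seed = as.integer(seed))
  abort_if(cfg$divergence <= 0 && cfg$n_pseudogenes > 0 && cfg$divergence < 0,
           "divergence must be nonnegative")
  abort_if(cfg$divergence < 0 || cfg$divergence >= 1,
           "divergence must lie in [0, 1)")
  abort_if(length(cfg$leakage_fraction_range) != 2 ||
             cfg$leakage_fraction_range[1] <= 0 ||
             cfg$leakage_fraction_range[2] >= 0.20 ||
             diff(cfg$leakage_fraction_range) < 0,
           "leakage_fraction_range must be an interval inside (0, 0.20)")
  abort_if(cfg$het_fraction_mean <= 0 || cfg$het_fraction_mean >= 1,
           "het_fraction_mean must lie in (0, 1)")
  abort_if(cfg$n_exons < 1 || cfg$gene_length_bp < 60L * (2L * cfg$n_exons - 1L),
           "gene_length_bp too small for %d exons of >= 60 bp", cfg$n_exons)
  abort_if(is.na(cfg$seed), "seed must be an integer")
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_sequence <- function(seq_chr, rate) {
  bases <- strsplit(seq_chr, "")[[1]]
  hit <- runif(length(bases)) < rate
  if (any(hit)) {
    bases[hit] <- vapply(bases[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  }
  paste(bases, collapse = "")
}

#' Generate the mini-genome reference
#'
#' One contig carrying the genuine gene (equal-length exons alternating with
#' equal-length introns, CDS trimmed to a multiple of 3) followed by
#' `n_pseudogenes` copies each substituted at the configured per-base
#' divergence. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `genome` ([Biostrings::DNAStringSet]), `transcript`
#'   (a [transcript_model()]), `targets` (exon capture targets, 0-based
#'   half-open), `loci` (gene/pseudogene spans) and `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  unit <- config$gene_length_bp %/% (2L * config$n_exons - 1L)
  exon_len <- unit
  starts <- (seq_len(config$n_exons) - 1L) * 2L * unit
  exons <- data.frame(start = starts, end = starts + exon_len)
  gene_span <- max(exons$end)

  # gene body is random except the CDS, which is a proper ORF (ATG, sense
  # codons only, terminal stop) so codon-level consequence calls are
  # well-defined against whole-CDS translation
  bases <- sample(c("A", "C", "G", "T"), gene_span, replace = TRUE)
  exonic <- config$n_exons * exon_len
  cds_len <- exonic - (exonic %% 3L)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"])
  codons <- c("ATG", sample(sense, cds_len %/% 3L - 2L, replace = TRUE), "TGA")
  exonic_pos <- unlist(lapply(seq_len(config$n_exons), function(i)
    exons$start[i]:(exons$end[i] - 1L)))
  bases[exonic_pos[seq_len(cds_len)] + 1L] <-
    strsplit(paste(codons, collapse = ""), "")[[1]]
  gene_seq <- paste(bases, collapse = "")
  spacer <- 500L
  pieces <- gene_seq
  loci <- data.frame(name = "GENE", start = 0L, end = gene_span,
                     stringsAsFactors = FALSE)
  offset <- gene_span + spacer
  for (p in seq_len(config$n_pseudogenes)) {
    pieces <- c(pieces, strrep("N", spacer),
                mutate_sequence(gene_seq, config$divergence))
    loci <- rbind(loci, data.frame(name = sprintf("PSEUDO%d", p),
                                   start = offset, end = offset + gene_span))
    offset <- offset + gene_span + spacer
  }
  genome <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
  names(genome) <- "panel_sim"

  # genomic end of the CDS: walk off the trailing UTR bases of the last exon
  utr <- exonic - cds_len
  cds_end <- exons$end[config$n_exons] - utr

  tx <- transcript_model("GENE", "panel_sim", "+", exons,
                         cds_start = 0L, cds_end = cds_end, genome = genome)
  targets <- data.frame(contig = "panel_sim", start = exons$start,
                        end = exons$end,
                        name = sprintf("GENE_ex%02d", seq_len(config$n_exons)),
                        length = exons$end - exons$start,
                        stringsAsFactors = FALSE)
  structure(list(genome = genome, transcript = tx, targets = targets,
                 loci = loci, config = config),
            class = "sim_reference")
}

#' Gene-to-pseudogene sequence identity
#'
#' Per-copy fraction of positions identical to the genuine gene; expectation
#' is `1 - divergence`.
#'
#' @param reference a [generate_reference()] result.
#' @return numeric vector, one identity per pseudogene copy.
#' @export
pseudogene_identity <- function(reference) {
  genome <- reference$genome[["panel_sim"]]
  loci <- reference$loci
  gene <- strsplit(as.character(Biostrings::subseq(
    genome, loci$start[1] + 1L, loci$end[1])), "")[[1]]
  ps <- loci[loci$name != "GENE", , drop = FALSE]
  vapply(seq_len(nrow(ps)), function(i) {
    copy <- strsplit(as.character(Biostrings::subseq(
      genome, ps$start[i] + 1L, ps$end[i])), "")[[1]]
    mean(copy == gene)
  }, numeric(1))
}

coding_positions <- function(reference) {
  tx <- reference$transcript
  ex <- tx$exons
  pos <- unlist(lapply(seq_len(nrow(ex)), function(i) ex$start[i]:(ex$end[i] - 1L)))
  pos[pos >= tx$cds_start & pos < tx$cds_end]
}

het_counts <- function(depth, p) {
  alt <- rbinom(1L, depth, p)
  alt <- min(max(alt, 2L), depth - 2L)
  ref <- depth - alt
  fwd_alt <- min(max(rbinom(1L, alt, 0.5), 1L), alt - 1L)
  fwd_ref <- rbinom(1L, ref, 0.5)
  c(fwd_ref = fwd_ref, rev_ref = ref - fwd_ref,
    fwd_alt = fwd_alt, rev_alt = alt - fwd_alt)
}

#' Simulate per-sample variant calls with known truth
#'
#' Plants, per sample: true heterozygous pathogenic variants (binomial alt
#' counts around the het fraction, alt reads forced onto both strands,
#' frequency absent from every database, score features set to pathogenic
#' evidence); common benign variants (population frequency >= 0.05, benign
#' score features); and Poisson-many pseudogene-leakage calls whose observed
#' alt fraction is drawn inside `leakage_fraction_range` (hence < 0.20) and
#' which carry single-strand alt support with probability 0.5.
#'
#' @param config a [sim_config()].
#' @param reference matching [generate_reference()] output.
#' @return list with `calls` (a `variant_calls` data frame with `call_id` and
#'   a `features` list-column) and `truth` (disjoint `true_variants`,
#'   `benign_variants`, `spurious_calls` data frames keyed by `call_id`).
#' @export
simulate_variant_calls <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"), inherits(reference, "sim_reference"))
  set.seed(config$seed + 1L)
  tx <- reference$transcript
  genome_seq <- reference$genome[["panel_sim"]]
  cds_pos <- coding_positions(reference)
  samples <- sprintf("S%02d", seq_len(config$n_samples))

  path_features <- list(conservation_strong = TRUE, conservation_moderate = FALSE,
                        grantham_radical = TRUE, grantham_moderate = FALSE,
                        splice_predictor_loss = FALSE, absent_in_controls = TRUE,
                        cosegregation = FALSE, benign_cosegregation = FALSE,
                        present_in_controls = FALSE)
  benign_features <- list(conservation_strong = FALSE, conservation_moderate = FALSE,
                          grantham_radical = FALSE, grantham_moderate = FALSE,
                          splice_predictor_loss = FALSE, absent_in_controls = FALSE,
                          cosegregation = FALSE, benign_cosegregation = TRUE,
                          present_in_controls = TRUE)

  rows <- list(); origin <- character(0); feats <- list()
  add_row <- function(row, kind, f) {
    rows[[length(rows) + 1L]] <<- row
    origin[length(origin) + 1L] <<- kind
    feats[length(feats) + 1L] <<- list(f)  # list() so NULL features append
  }

  snv_at <- function(pos) {
    ref <- as.character(Biostrings::subseq(genome_seq, pos + 1L, pos + 1L))
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    list(ref = ref, alt = alt)
  }

  for (s in samples) {
    for (i in seq_len(config$n_true_per_sample)) {
      # pathogenic plants are missense or stop-gain, the panel's common kinds
      repeat {
        pos <- sample(cds_pos, 1L)
        al <- snv_at(pos)
        cons <- classify_consequence(list(pos = pos, ref = al$ref, alt = al$alt), tx)
        if (cons$kind %in% c("missense", "stop_gain")) break
      }
      depth <- max(rpois(1L, config$mean_depth), 8L)
      cnt <- het_counts(depth, config$het_fraction_mean)
      add_row(data.frame(sample_id = s, pos = pos, ref = al$ref, alt = al$alt,
                         fwd_ref = cnt["fwd_ref"], rev_ref = cnt["rev_ref"],
                         fwd_alt = cnt["fwd_alt"], rev_alt = cnt["rev_alt"],
                         freq_g1000 = NA_real_, in_pathogenic_db = FALSE,
                         consequence = cons$kind, cdna_label = cons$cdna_label,
                         protein_label = cons$protein_label,
                         stringsAsFactors = FALSE),
              "true", path_features)
    }
    for (i in seq_len(config$n_benign_per_sample)) {
      pos <- sample(cds_pos, 1L)
      al <- snv_at(pos)
      depth <- max(rpois(1L, config$mean_depth), 8L)
      cnt <- het_counts(depth, 0.5)
      cons <- classify_consequence(list(pos = pos, ref = al$ref, alt = al$alt), tx)
      add_row(data.frame(sample_id = s, pos = pos, ref = al$ref, alt = al$alt,
                         fwd_ref = cnt["fwd_ref"], rev_ref = cnt["rev_ref"],
                         fwd_alt = cnt["fwd_alt"], rev_alt = cnt["rev_alt"],
                         freq_g1000 = runif(1L, 0.05, 0.5),
                         in_pathogenic_db = FALSE,
                         consequence = cons$kind, cdna_label = cons$cdna_label,
                         protein_label = cons$protein_label,
                         stringsAsFactors = FALSE),
              "benign", benign_features)
    }
    n_leak <- rpois(1L, config$leakage_rate)
    for (i in seq_len(n_leak)) {
      pos <- sample(cds_pos, 1L)
      al <- snv_at(pos)
      depth <- max(rpois(1L, config$mean_depth), 10L)
      f <- runif(1L, config$leakage_fraction_range[1],
                 config$leakage_fraction_range[2])
      alt <- max(1L, as.integer(floor(depth * f)))  # observed fraction <= f < 0.20
      single <- runif(1L) < 0.5
      if (single || alt == 1L) {
        fwd_alt <- if (runif(1L) < 0.5) alt else 0L
      } else {
        fwd_alt <- min(max(rbinom(1L, alt, 0.5), 1L), alt - 1L)
      }
      ref <- depth - alt
      fwd_ref <- rbinom(1L, ref, 0.5)
      cons <- classify_consequence(list(pos = pos, ref = al$ref, alt = al$alt), tx)
      add_row(data.frame(sample_id = s, pos = pos, ref = al$ref, alt = al$alt,
                         fwd_ref = fwd_ref, rev_ref = ref - fwd_ref,
                         fwd_alt = fwd_alt, rev_alt = alt - fwd_alt,
                         freq_g1000 = NA_real_, in_pathogenic_db = FALSE,
                         consequence = cons$kind, cdna_label = cons$cdna_label,
                         protein_label = cons$protein_label,
                         stringsAsFactors = FALSE),
              "spurious", NULL)
    }
  }

  df <- do.call(rbind, rows)
  calls <- variant_calls(
    sample_id = df$sample_id, contig = "panel_sim", pos = df$pos,
    ref = df$ref, alt = df$alt,
    fwd_ref = df$fwd_ref, rev_ref = df$rev_ref,
    fwd_alt = df$fwd_alt, rev_alt = df$rev_alt,
    freq_g1000 = df$freq_g1000, in_pathogenic_db = df$in_pathogenic_db,
    consequence = df$consequence, cdna_label = df$cdna_label,
    protein_label = df$protein_label, gene = "GENE"
  )
  calls$call_id <- seq_len(nrow(calls))
  calls$features <- feats
  frac <- allele_fraction(calls)

  truth <- list(
    true_variants = data.frame(call_id = calls$call_id[origin == "true"],
                               sample_id = calls$sample_id[origin == "true"],
                               pos = calls$pos[origin == "true"],
                               consequence = calls$consequence[origin == "true"],
                               alt_fraction = frac[origin == "true"],
                               stringsAsFactors = FALSE),
    benign_variants = data.frame(call_id = calls$call_id[origin == "benign"],
                                 sample_id = calls$sample_id[origin == "benign"],
                                 pos = calls$pos[origin == "benign"],
                                 alt_fraction = frac[origin == "benign"],
                                 stringsAsFactors = FALSE),
    spurious_calls = data.frame(call_id = calls$call_id[origin == "spurious"],
                                sample_id = calls$sample_id[origin == "spurious"],
                                pos = calls$pos[origin == "spurious"],
                                alt_fraction = frac[origin == "spurious"],
                                single_strand = calls$fwd_alt[origin == "spurious"] == 0L |
                                  calls$rev_alt[origin == "spurious"] == 0L,
                                stringsAsFactors = FALSE)
  )
  list(calls = calls, truth = truth, samples = samples)
}

#' Simulate a samples-by-targets coverage matrix
#'
#' Counts are Poisson with expectation
#' `mean_depth * length_weight * library_scale * capture_bias * copy_ratio`:
#' lognormal per-sample library scale (removed by RPKM), a rank-`batch_rank`
#' multiplicative capture-bias term shared across samples (removed by the SVD
#' stage), spiked deletions thinning their target span by the event copy
#' ratio, and dropout targets forced to 3% of expectation in every sample.
#'
#' @param config a [sim_config()] (needs `n_samples >= 8`).
#' @param targets target table (`name`, `length`, optional coordinates);
#'   defaults to the exon targets of `reference` when one is given, else to
#'   a synthetic `n_targets`-region panel with lognormal lengths around
#'   `target_length_bp`.
#' @param deletions data frame of spiked events with `sample` (index or id),
#'   `first_target`, `last_target` (1-based, inclusive) and `copy_ratio`
#'   (0.5 heterozygous, 0 homozygous).
#' @param reference optional [generate_reference()] result supplying targets.
#' @return list with `matrix` (a [coverage_matrix()]) and `truth`
#'   (deletion events and dropout targets).
#' @export
simulate_coverage_matrix <- function(config, targets = NULL, deletions = NULL,
                                     reference = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  if (is.null(targets)) {
    if (!is.null(reference)) {
      targets <- reference$targets
    } else {
      lens <- round(rlnorm(config$n_targets, log(config$target_length_bp), 0.5))
      starts <- cumsum(c(0L, utils::head(lens, -1) + 200L))
      targets <- data.frame(contig = "panel_sim",
                            start = as.integer(starts),
                            end = as.integer(starts + lens),
                            name = sprintf("T%03d", seq_len(config$n_targets)),
                            length = as.integer(lens),
                            stringsAsFactors = FALSE)
    }
  }
  n_s <- config$n_samples
  n_t <- nrow(targets)
  abort_if(n_s < 8L, "need >= 8 samples for the read-depth baseline, got %d", n_s)
  abort_if(n_t < 20L, "need >= 20 targets, got %d", n_t)
  abort_if(length(config$dropout_exons) > 0 &&
             any(config$dropout_exons < 1L | config$dropout_exons > n_t),
           "dropout_exons out of target range")

  samples <- sprintf("S%02d", seq_len(n_s))
  lenw <- targets$length / median(targets$length)
  scale_s <- rlnorm(n_s, 0, config$library_scale_sd)
  b <- matrix(sample(c(-1, 1), n_t * config$batch_rank, replace = TRUE),
              nrow = n_t)
  gamma <- matrix(rnorm(n_s * config$batch_rank), nrow = n_s)
  bias <- exp(config$batch_sd * gamma %*% t(b))

  cr <- matrix(1, n_s, n_t)
  if (!is.null(deletions) && nrow(deletions) > 0) {
    for (i in seq_len(nrow(deletions))) {
      d <- deletions[i, ]
      si <- if (is.character(d$sample)) match(d$sample, samples) else d$sample
      abort_if(is.na(si), "unknown deletion sample '%s'", d$sample)
      abort_if(!d$copy_ratio %in% c(0, 0.5),
               "deletion copy_ratio must be 0 (hom) or 0.5 (het)")
      cr[si, d$first_target:d$last_target] <- d$copy_ratio
    }
  }

  mu <- config$mean_depth * outer(scale_s, lenw) * bias * cr
  if (length(config$dropout_exons) > 0)
    mu[, config$dropout_exons] <- mu[, config$dropout_exons] * 0.01
  counts <- matrix(rpois(n_s * n_t, mu), n_s, n_t,
                   dimnames = list(samples, targets$name))

  truth <- list(deletion_events = deletions, dropout_targets = config$dropout_exons)
  list(matrix = coverage_matrix(counts, targets), truth = truth)
}

#' Simulate a per-base depth track for one sample
#'
#' Per-base depths over every targeted base, Poisson around the mean depth,
#' with dropout targets thinned to 3% of expectation.
#'
#' @param config a [sim_config()].
#' @param reference a [generate_reference()] result.
#' @param sample_id label attached to the track.
#' @return a `depth_track` data frame (`contig`, `pos` 0-based, `depth`) with
#'   a `sample_id` attribute.
#' @export
simulate_depth_track <- function(config, reference, sample_id = "S01") {
  stopifnot(inherits(reference, "sim_reference"))
  set.seed(config$seed + 3L)
  tg <- reference$targets
  rows <- lapply(seq_len(nrow(tg)), function(i) {
    pos <- tg$start[i]:(tg$end[i] - 1L)
    mu <- config$mean_depth *
      (if (i %in% config$dropout_exons) 0.01 else 1)
    data.frame(contig = tg$contig[i], pos = pos,
               depth = rpois(length(pos), mu), stringsAsFactors = FALSE)
  })
  track <- do.call(rbind, rows)
  attr(track, "sample_id") <- sample_id
  class(track) <- c("depth_track", "data.frame")
  track
}
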