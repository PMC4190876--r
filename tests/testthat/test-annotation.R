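test_that("genomic positions project to HGVS-like c. coordinates", {
  tx <- make_toy_tx()
  expect_equal(project_to_cdna(20L, tx), "c.1")     # first CDS base
  expect_equal(project_to_cdna(21L, tx), "c.2")
  expect_equal(project_to_cdna(34L, tx), "c.3")     # across the intron
  expect_equal(project_to_cdna(22L, tx), "c.2+1")   # first intron base
  expect_equal(project_to_cdna(23L, tx), "c.2+2")
  expect_equal(project_to_cdna(33L, tx), "c.3-1")   # last intron base
  expect_equal(project_to_cdna(31L, tx), "c.3-3")
  expect_equal(project_to_cdna(10L, tx), "c.-10")   # 10 bases 5' of CDS start
  expect_equal(project_to_cdna(44L, tx), "c.*1")    # 3' UTR
  expect_equal(project_to_cdna(5L, tx), "intergenic")
  expect_equal(project_to_cdna(59L, tx), "intergenic")
})

test_that("coding SNVs classify by codon translation", {
  tx <- make_toy_tx()
  cons <- function(pos, ref, alt)
    classify_consequence(list(pos = pos, ref = ref, alt = alt), tx)

  stop <- cons(38L, "C", "T")   # CAG -> TAG at the Gln codon
  expect_equal(stop$kind, "stop_gain")
  expect_equal(stop$protein_label, "p.(Gln3*)")
  expect_equal(stop$cdna_label, "c.7C>T")

  mis <- cons(35L, "G", "A")    # GCT -> ACT
  expect_equal(mis$kind, "missense")
  expect_equal(mis$protein_label, "p.(Ala2Thr)")

  syn <- cons(37L, "T", "C")    # GCT -> GCC
  expect_equal(syn$kind, "synonymous")

  expect_error(cons(35L, "T", "A"), "reference mismatch")
})

test_that("indels classify by frame, splice sites by intronic offset", {
  tx <- make_toy_tx()
  cons <- function(pos, ref, alt)
    classify_consequence(list(pos = pos, ref = ref, alt = alt), tx)

  expect_equal(cons(36L, "CT", "C")$kind, "frameshift")       # 1 bp deletion
  expect_equal(cons(36L, "CTCA", "C")$kind, "inframe_indel")  # 3 bp deletion
  expect_equal(cons(22L, "G", "C")$kind, "canonical_splice")  # donor +1
  expect_equal(cons(23L, "T", "C")$kind, "canonical_splice")  # donor +2
  expect_equal(cons(24L, "A", "C")$kind, "noncanonical_splice") # donor +3
  expect_equal(cons(31L, "T", "C")$kind, "noncanonical_splice") # acceptor -3
  expect_equal(cons(31L, "T", "C")$protein_label, NA_character_)
  # a long intron in the simulated gene exercises the deep-intronic bucket
  ref <- generate_reference(sim_config(seed = 3))
  stx <- ref$transcript
  deep <- stx$exons$end[1] + 50L
  g <- as.character(Biostrings::subseq(ref$genome[["panel_sim"]], deep + 1, deep + 1))
  expect_equal(classify_consequence(list(pos = deep, ref = g, alt = setdiff(c("A","C","G","T"), g)[1]),
                                    stx)$kind, "intronic")
})

test_that("structural events spanning exons are structural deletions", {
  tx <- make_toy_tx()
  sv <- classify_consequence(list(sv_start = 15L, sv_end = 40L), tx)
  expect_equal(sv$kind, "structural_deletion")
  expect_error(classify_consequence(list(sv_start = 25L, sv_end = 30L), tx),
               "spans no exon")
})

test_that("truncating and UCV predicates split the consequence kinds", {
  expect_true(all(is_truncating(c("stop_gain", "frameshift",
                                  "canonical_splice", "structural_deletion"))))
  expect_false(any(is_truncating(c("missense", "inframe_indel", "synonymous",
                                   "noncanonical_splice", "intronic"))))
  expect_true(all(is_ucv(c("missense", "noncanonical_splice", "inframe_indel"))))
  expect_false(any(is_ucv(c("stop_gain", "synonymous", "intronic"))))
})

test_that("SNV consequences agree with a whole-CDS translation oracle", {
  ref <- generate_reference(sim_config(seed = 11))
  tx <- ref$transcript
  cds_pos <- pkdpanel:::coding_positions(ref)
  set.seed(42)
  for (pos in sample(cds_pos, 60)) {
    b <- as.character(Biostrings::subseq(ref$genome[["panel_sim"]],
                                         pos + 1, pos + 1))
    alt <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    got <- classify_consequence(list(pos = pos, ref = b, alt = alt), tx)$kind
    expect_equal(got, oracle_snv_consequence(pos, b, alt, tx),
                 info = sprintf("pos %d %s>%s", pos, b, alt))
  }
})

test_that("consequence kinds are invariant under reverse-complementing the genome", {
  tx <- make_toy_tx()
  mtx <- mirror_tx(tx)
  L <- length(tx$genome[["toy"]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(9)
  positions <- c(20:21, 34:43, 22:33, 10:19)
  for (pos in positions) {
    b <- substr(toy_genome_seq, pos + 1, pos + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    k1 <- classify_consequence(list(pos = pos, ref = b, alt = alt), tx)$kind
    k2 <- classify_consequence(list(pos = L - 1L - pos,
                                    ref = unname(comp[b]),
                                    alt = unname(comp[alt])), mtx)$kind
    expect_equal(k2, k1, info = sprintf("pos %d", pos))
  }
})
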