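test_that("validation cohort fixture loads with the printed structure", {
  v <- load_validation_cohort()
  expect_equal(length(unique(v$sample_id)), 36L)
  expect_equal(nrow(v), 36L)

  # one sample with every field absent (mutation never re-detected)
  blank <- v[is.na(v$cdna_change), ]
  expect_equal(blank$sample_id, "09-393-P3")
  expect_true(is.na(blank$gene) && is.na(blank$ref_count) &&
                is.na(blank$sv_coordinates))

  # the two large deletions carry coordinates, not read counts
  svs <- v[!is.na(v$sv_coordinates), ]
  expect_setequal(svs$sample_id, c("03-106-P6", "11-571-P2"))
  expect_equal(svs$sv_coordinates[svs$sample_id == "03-106-P6"],
               "g.2154344-2186386del")
  expect_true(all(is.na(svs$ref_count)))

  # gene tallies: 30 + 5 mutation-bearing records; 24 rows flagged in the
  # duplicated region (the printed table's "Yes" tally)
  mut <- v[!is.na(v$gene), ]
  expect_equal(sum(mut$gene == "PKD1"), 30L)
  expect_equal(sum(mut$gene == "PKD2"), 5L)
  expect_equal(sum(v$in_duplicated_region), 24L)

  # a spot-checked record
  r <- v[v$sample_id == "12-331-P1", ]
  expect_equal(r$cdna_change, "c.566C>G")
  expect_equal(r$protein_change, "p.(Ser189*)")
  expect_equal(r$ref_count, 188L)
  expect_equal(r$variant_count, 62L)
  expect_true(r$pkdb_present)
})

test_that("discovery cohort fixture loads with the printed structure", {
  d <- load_discovery_cohort()
  expect_equal(length(unique(d$sample_id)), 12L)
  expect_equal(sum(!is.na(d$cdna_change)), 11L)  # 11 distinct mutation rows
  expect_setequal(d$sample_id[is.na(d$cdna_change)], c("13-102", "07-335"))

  two <- d[d$sample_id == "12-444", ]
  expect_equal(nrow(two), 2L)
  expect_setequal(two$gene, c("PKD1", "PKD2"))
  ins <- two[two$gene == "PKD2", ]
  expect_equal(ins$cdna_change, "c.1532_1533insAT")
  expect_equal(ins$ref_count, 156L)
  expect_equal(ins$variant_count, 70L)
})

test_that("fixtures round-trip through TSV unchanged", {
  for (load in list(load_validation_cohort, load_discovery_cohort)) {
    rec <- load()
    tmp <- withr::local_tempfile(fileext = ".tsv")
    write_cohort_fixture(rec, tmp)
    again <- load_cohort_tsv <- pkdpanel:::load_cohort_tsv(tmp)
    expect_equal(as.data.frame(again), as.data.frame(rec))
  }
})

test_that("malformed fixture rows fail naming the line number", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  v <- readLines(system.file("extdata", "validation_cohort.tsv",
                             package = "pkdpanel"))
  bad <- sub("188\t62", "-5\t62", v)  # corrupt line 3's ref count
  writeLines(bad, tmp)
  expect_error(pkdpanel:::load_cohort_tsv(tmp), "line 3")
})

test_that("records convert to calls with curated consequences and even strand splits", {
  v <- load_validation_cohort()
  conv <- records_to_variant_calls(v)
  expect_equal(nrow(conv$calls), 33L)  # 35 mutations - 2 SVs
  expect_equal(nrow(conv$sv_events), 2L)
  expect_equal(length(conv$samples), 36L)

  by_cdna <- function(label) conv$calls[conv$calls$cdna_label == label, ]
  expect_equal(by_cdna("c.2329C>T")$consequence, "stop_gain")       # p.(Gln777*)
  expect_equal(by_cdna("c.8161+1G>C")$consequence, "canonical_splice")
  expect_equal(by_cdna("c.12004-2A>G")$consequence, "canonical_splice")
  expect_equal(by_cdna("c.6778_6780delATT")$consequence, "inframe_indel")
  expect_equal(by_cdna("c.11017-10C>A")$consequence, "noncanonical_splice")
  # intronic deletion annotated with a downstream frameshift stays non-truncating
  expect_equal(by_cdna("c.10170+25_+45del19")$consequence, "intronic")
  expect_equal(by_cdna("c.1831C>T")$consequence, "missense")

  # even strand split, forward takes the odd read; SNV alleles parsed
  r <- by_cdna("c.566C>G")
  expect_equal(c(r$fwd_ref, r$rev_ref), c(94L, 94L))
  expect_equal(c(r$fwd_alt, r$rev_alt), c(31L, 31L))
  expect_equal(c(r$ref, r$alt), c("C", "G"))
  odd <- by_cdna("c.1831C>T")  # 25 ref reads
  expect_equal(c(odd$fwd_ref, odd$rev_ref), c(13L, 12L))

  expect_error(curate_consequence("c.notparseable", "p.(weird)"), "curate")
})

test_that("consequence curation covers the discovery table's typographic artifact", {
  d <- load_discovery_cohort()
  conv <- records_to_variant_calls(d)
  r <- conv$calls[conv$calls$cdna_label == "c.50174_5015delAG", ]
  expect_equal(r$consequence, "frameshift")  # from its protein column
})
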