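call1 <- function(...) variant_calls(sample_id = "S", consequence = "missense", ...)

test_that("strand rule requires alt support on both strands", {
  expect_false(strand_filter(call1(fwd_alt = 0L, rev_alt = 50L, fwd_ref = 10L)))
  expect_true(strand_filter(call1(fwd_alt = 31L, rev_alt = 31L)))  # 62 split
  expect_true(strand_filter(call1(fwd_alt = 1L, rev_alt = 1L)))
})

test_that("allele-fraction rule uses ref+alt depth with a 20% default", {
  # 26/122 (the lowest printed fixture fraction) just clears the bar
  expect_true(allele_fraction_filter(call1(fwd_ref = 48L, rev_ref = 48L,
                                           fwd_alt = 13L, rev_alt = 13L)))
  expect_false(allele_fraction_filter(call1(fwd_ref = 10L, rev_ref = 10L,
                                            fwd_alt = 2L, rev_alt = 2L)))  # 4/24
  expect_true(allele_fraction_filter(call1(fwd_alt = 25L, rev_alt = 25L)))  # 1.0
  expect_false(allele_fraction_filter(call1()))  # zero depth
})

test_that("frequency rule discards common variants unless rescued by a disease database", {
  common <- call1(freq_dbsnp = 0.06, fwd_alt = 1L, rev_alt = 1L)
  res <- frequency_filter(common)
  expect_false(res$pass)
  expect_false(res$rescue_applied)

  rescued <- call1(freq_dbsnp = 0.06, in_pathogenic_db = TRUE,
                   fwd_alt = 1L, rev_alt = 1L)
  res <- frequency_filter(rescued)
  expect_true(res$pass)
  expect_true(res$rescue_applied)

  unseen <- call1(fwd_alt = 1L, rev_alt = 1L)
  expect_true(frequency_filter(unseen)$pass)

  # the max over databases decides; rescue never fires below threshold
  multi <- call1(freq_dbsnp = 0.01, freq_evs = 0.07, fwd_alt = 1L, rev_alt = 1L)
  expect_false(frequency_filter(multi)$pass)
  expect_false(frequency_filter(call1(freq_dbsnp = 0.04, in_pathogenic_db = TRUE,
                                      fwd_alt = 1L, rev_alt = 1L))$rescue_applied)
  expect_error(frequency_filter(call1(freq_dbsnp = 1.2)), "\\[0, 1\\]")
})

test_that("the cascade audits every rule and tags zero depth explicitly", {
  calls <- rbind(call1(fwd_ref = 40L, rev_ref = 40L, fwd_alt = 15L, rev_alt = 15L),
                 call1(fwd_alt = 30L),                       # single strand
                 call1(fwd_ref = 90L, rev_ref = 90L, fwd_alt = 5L, rev_alt = 5L),
                 call1())                                    # zero depth
  dec <- run_cascade(calls)
  expect_equal(dec$passed, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(dec$failed_rules,
               c("", "strand", "fraction", "strand,zero_depth"))
  expect_equal(nrow(run_cascade(empty_variant_calls())), 0L)
})

test_that("retained set is the intersection of per-rule pass sets (order independence)", {
  calls <- random_filter_calls(500, seed = 21)
  dec <- run_cascade(calls)
  manual <- strand_filter(calls) & allele_fraction_filter(calls) &
    frequency_filter(calls)$pass
  expect_equal(dec$passed, manual)
})

test_that("raising the fraction threshold never grows the retained set", {
  calls <- random_filter_calls(400, seed = 33)
  thresholds <- c(0.05, 0.10, 0.20, 0.35, 0.50)
  kept <- lapply(thresholds, function(t) which(run_cascade(calls, min_fraction = t)$passed))
  for (i in seq_along(kept)[-1]) {
    expect_true(all(kept[[i]] %in% kept[[i - 1]]),
                info = sprintf("threshold %.2f", thresholds[i]))
  }
})

test_that("the filter audit trail writes one row per call per rule", {
  calls <- random_filter_calls(10, seed = 5)
  dec <- run_cascade(calls)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_filter_audit(calls, dec, tmp)
  audit <- read.delim(tmp)
  expect_equal(nrow(audit), 30L)
  expect_setequal(unique(audit$rule), c("strand", "fraction", "frequency"))
})
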