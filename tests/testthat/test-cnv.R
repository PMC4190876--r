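make_cm <- function(counts, lengths = rep(1000L, ncol(counts))) {
  rownames(counts) <- sprintf("S%02d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("T%03d", seq_len(ncol(counts)))
  coverage_matrix(counts, data.frame(name = colnames(counts), length = lengths))
}

test_that("RPKM is the depth normalized by target length and library size", {
  cm <- make_cm(matrix(c(100L, 0L), 2, 1), lengths = 1000L)
  cm$totals <- c(1e6, 1e6)
  r <- compute_rpkm(cm)
  expect_equal(r$values[1, 1], 100)
  expect_equal(r$values[2, 1], 0)

  # doubling a sample's counts and total leaves RPKM unchanged
  counts <- matrix(rpois(10 * 25, 200), 10, 25)
  cm1 <- make_cm(counts)
  cm2 <- make_cm(counts * 2L)
  expect_equal(compute_rpkm(cm1)$values, compute_rpkm(cm2)$values)

  # zero-total sample excluded with a warning
  counts0 <- counts; counts0[3, ] <- 0L
  expect_warning(r0 <- compute_rpkm(make_cm(counts0)), "S03")
  expect_equal(nrow(r0$values), 9L)
})

test_that("coverage matrix construction validates its invariants", {
  counts <- matrix(5L, 8, 20)
  expect_error(make_cm(counts, lengths = rep(0L, 20)), "positive")
  expect_error(make_cm(counts - 10L), "negative")
  cm <- make_cm(counts)
  expect_error(coverage_matrix(cm$counts, cm$targets, totals = rep(1, 8)),
               "totals")
})

test_that("ZRPKM centers each target on the cohort median and masks flat targets", {
  counts <- matrix(rpois(12 * 24, 300), 12, 24)
  z <- compute_zrpkm(compute_rpkm(make_cm(counts)))
  expect_equal(unname(apply(z$values[, !z$mask], 2, median)),
               rep(0, sum(!z$mask)))

  # identical rows: every target flat -> fully masked, all zeros
  flat <- matrix(100L, 10, 20, dimnames = NULL)
  zf <- compute_zrpkm(compute_rpkm(make_cm(flat)))
  expect_true(all(zf$mask))
  expect_true(all(zf$values == 0))

  # a sample at half depth on one target gets a negative z there
  counts2 <- matrix(1000L, 10, 20)
  counts2[4, 7] <- 500L
  z2 <- compute_zrpkm(compute_rpkm(make_cm(counts2)))
  expect_lt(z2$values[4, 7], 0)

  expect_error(compute_zrpkm(compute_rpkm(make_cm(matrix(5L, 4, 20)))), ">= 8")
})

test_that("SVD denoising: k=0 identity, exact rank removal, monotone Frobenius norm", {
  set.seed(17)
  m <- matrix(rnorm(15 * 30), 15, 30)
  z <- pkdpanel:::new_zrpkm(m, data.frame(name = sprintf("T%d", 1:30),
                                          length = 1000L), "zrpkm",
                            mask = rep(FALSE, 30))
  expect_equal(svd_denoise(z, 0L)$values, m)

  rank1 <- outer(rnorm(15), rnorm(30))
  z1 <- pkdpanel:::new_zrpkm(rank1, z$targets, "zrpkm", mask = rep(FALSE, 30))
  expect_lt(max(abs(svd_denoise(z1, 1L)$values)), 1e-10)

  norms <- vapply(0:10, function(k) sqrt(sum(svd_denoise(z, k)$values^2)), 1)
  expect_true(all(diff(norms) <= 1e-12))

  expect_error(svd_denoise(z, -1L), "nonnegative")
  expect_error(svd_denoise(z, 15L), "below min")
})

test_that("CNV calling finds thresholded runs of consecutive targets", {
  mk <- function(values) pkdpanel:::new_zrpkm(
    values, data.frame(name = sprintf("T%03d", seq_len(ncol(values))),
                       length = 1000L),
    "svd_zrpkm", mask = rep(FALSE, ncol(values)), removed_components = 0L)

  zero <- matrix(0, 8, 20, dimnames = list(sprintf("S%02d", 1:8), NULL))
  expect_equal(nrow(call_cnvs(mk(zero))), 0L)

  v <- zero
  v[2, 5:9] <- -2          # five-target deletion
  v[3, 12] <- -3           # single target: below min_targets
  v[4, 15:16] <- 2.1       # duplication
  calls <- call_cnvs(mk(v))
  expect_equal(nrow(calls), 2L)
  del <- calls[calls$direction == "deletion", ]
  expect_equal(del$sample_id, "S02")
  expect_equal(c(del$first_target, del$last_target), c(5L, 9L))
  expect_equal(del$mean_signal, -2)
  dup <- calls[calls$direction == "duplication", ]
  expect_equal(c(dup$sample_id, dup$first_target), c("S04", "15"))

  # masked targets never contribute to a run
  zmask <- mk(v)
  zmask$mask[5:9] <- TRUE
  expect_equal(sum(call_cnvs(zmask)$direction == "deletion"), 0L)
})

test_that("permuting sample order permutes every stage and the call list", {
  dels <- data.frame(sample = 5L, first_target = 10L, last_target = 20L,
                     copy_ratio = 0.5)
  sim <- simulate_coverage_matrix(sim_config(n_samples = 12L, seed = 8),
                                  deletions = dels)
  cm <- sim$matrix
  perm <- sample(seq_len(12))
  cm2 <- coverage_matrix(cm$counts[perm, ], cm$targets, cm$totals[perm])

  d1 <- detect_deletions(cm)
  d2 <- detect_deletions(cm2)
  expect_equal(d2$svd_zrpkm$values, d1$svd_zrpkm$values[perm, ])
  key <- function(calls) calls[order(calls$sample_id, calls$first_target), ]
  expect_equal(key(d2$calls), key(d1$calls), ignore_attr = TRUE)
})
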