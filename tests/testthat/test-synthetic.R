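test_that("the reference generator is deterministic and respects its knobs", {
  cfg <- sim_config(seed = 19)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_equal(as.character(r1$genome), as.character(r2$genome))
  expect_equal(r1$targets, r2$targets)

  # no divergence -> identical copies; no pseudogenes -> gene-only annotation
  same <- generate_reference(sim_config(divergence = 0, seed = 19))
  expect_true(all(pseudogene_identity(same) == 1))
  solo <- generate_reference(sim_config(n_pseudogenes = 0L, seed = 19))
  expect_equal(solo$loci$name, "GENE")

  # CDS length is a multiple of 3 and lies inside the exons
  tx <- r1$transcript
  expect_equal(length(cds_seq(tx)) %% 3L, 0L)

  expect_error(sim_config(gene_length_bp = 500L), "too small")
  expect_error(sim_config(divergence = 1.2), "divergence")
  expect_error(sim_config(leakage_fraction_range = c(0.05, 0.30)), "0.20")
})

test_that("pseudogene identity concentrates at 1 - divergence", {
  cfg <- sim_config(seed = 23)
  ids <- pseudogene_identity(generate_reference(cfg))
  expect_length(ids, 6L)
  L <- max(generate_reference(cfg)$loci$end[1])
  se <- sqrt(0.023 * 0.977 / (L * 6))
  expect_lt(abs(mean(ids) - 0.977), 3 * se)
})

test_that("variant-call simulation is seeded and labels a disjoint truth", {
  cfg <- sim_config(n_samples = 10L, seed = 31)
  ref <- generate_reference(cfg)
  s1 <- simulate_variant_calls(cfg, ref)
  s2 <- simulate_variant_calls(cfg, ref)
  expect_equal(s1$calls[, setdiff(names(s1$calls), "features")],
               s2$calls[, setdiff(names(s2$calls), "features")])

  ids <- list(s1$truth$true_variants$call_id, s1$truth$benign_variants$call_id,
              s1$truth$spurious_calls$call_id)
  expect_equal(length(unlist(ids)), length(unique(unlist(ids))))
  expect_setequal(unlist(ids), s1$calls$call_id)

  # no leakage configured -> no spurious calls
  quiet <- simulate_variant_calls(sim_config(n_samples = 10L, leakage_rate = 0,
                                             seed = 31), ref)
  expect_equal(nrow(quiet$truth$spurious_calls), 0L)
})

test_that("every spurious call is below the fraction threshold or single-stranded", {
  cfg <- sim_config(n_samples = 15L, seed = 37)
  sim <- simulate_variant_calls(cfg, generate_reference(cfg))
  sp <- sim$calls[sim$calls$call_id %in% sim$truth$spurious_calls$call_id, ]
  frac <- allele_fraction(sp)
  expect_true(all(frac < 0.20 | sp$fwd_alt == 0L | sp$rev_alt == 0L))
  expect_true(all(frac < 0.20))  # by construction the fraction alone suffices
})

test_that("true het variants have binomial allele fractions around one half", {
  cfg <- sim_config(n_samples = 41L, n_true_per_sample = 3L, seed = 41)
  sim <- simulate_variant_calls(cfg, generate_reference(cfg))
  tv <- sim$calls[sim$calls$call_id %in% sim$truth$true_variants$call_id, ]
  depth <- call_depth(tv)
  alt <- tv$fwd_alt + tv$rev_alt
  # binomial oracle: central 95% interval at each call's own depth
  lo <- qbinom(0.025, depth, 0.5)
  hi <- qbinom(0.975, depth, 0.5)
  inside <- mean(alt >= lo & alt <= hi)
  expect_gt(inside, 0.90)
  expect_lt(abs(mean(alt / depth) - 0.5), 0.01)
  # alt reads always on both strands
  expect_true(all(tv$fwd_alt >= 1L & tv$rev_alt >= 1L))
})

test_that("coverage matrices are seeded Poisson with working spikes and dropout", {
  cfg <- sim_config(n_samples = 20L, dropout_exons = c(1L, 7L), seed = 43)
  s1 <- simulate_coverage_matrix(cfg)
  s2 <- simulate_coverage_matrix(cfg)
  expect_equal(s1$matrix$counts, s2$matrix$counts)

  # dropout targets sit far below the cohort mean in every sample
  cm <- s1$matrix
  rpkm <- compute_rpkm(cm)$values
  for (t in c(1L, 7L)) {
    expect_true(all(rpkm[, t] < 0.05 * rowMeans(rpkm[, -c(1L, 7L)])))
  }

  # Poisson thinning oracle: a het deletion halves RPKM against the cohort
  dels <- data.frame(sample = 3L, first_target = 10L, last_target = 25L,
                     copy_ratio = 0.5)
  sd1 <- simulate_coverage_matrix(sim_config(n_samples = 20L, seed = 47),
                                  deletions = dels)
  r <- compute_rpkm(sd1$matrix)$values
  span <- 10:25
  ratio <- mean(r[3, span] / apply(r[-3, span], 2, median))
  expect_lt(abs(ratio - 0.5), 0.06)

  expect_error(simulate_coverage_matrix(sim_config(n_samples = 5L)), ">= 8")
  expect_error(simulate_coverage_matrix(sim_config(n_samples = 10L,
                                                   dropout_exons = 500L)),
               "range")
})

test_that("depth tracks cover every targeted base once and honor dropout", {
  cfg <- sim_config(dropout_exons = 2L, seed = 53)
  ref <- generate_reference(cfg)
  track <- simulate_depth_track(cfg, ref, sample_id = "S01")
  expect_equal(nrow(track), sum(ref$targets$length))
  expect_equal(anyDuplicated(track$pos), 0L)
  ex2 <- ref$targets[2, ]
  in_ex2 <- track$pos >= ex2$start & track$pos < ex2$end
  expect_lt(mean(track$depth[in_ex2]), 0.05 * mean(track$depth[!in_ex2]))
})
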