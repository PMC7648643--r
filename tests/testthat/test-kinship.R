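test_that("pairwise mismatch handles the trivial and enumerated cases", {
  # identical call vectors -> rate 0
  calls <- cbind(rep(c(0L, 2L), 10), rep(c(0L, 2L), 10))
  gm <- toy_matrix(calls, ploidy = "pseudohaploid")
  mm <- pairwise_mismatch(gm, "s1", "s2", blocks = rep(1:2, each = 10),
                          min_snps = 10)
  expect_identical(mm$rate, 0)
  expect_identical(mm$ci95, c(0, 0))

  # complementary calls -> rate 1
  calls <- cbind(rep(0L, 10), rep(2L, 10))
  gm <- toy_matrix(calls, ploidy = "pseudohaploid")
  mm <- pairwise_mismatch(gm, "s1", "s2", blocks = rep(1:2, each = 5),
                          min_snps = 5)
  expect_identical(mm$rate, 1)

  # 20-SNP toy: 16 overlapping, 4 mismatches -> rate 0.25 (enumerated)
  a <- c(rep(0L, 16), rep(9L, 4))
  b <- c(rep(0L, 12), rep(2L, 4), rep(0L, 4))
  gm <- toy_matrix(cbind(a, b), ploidy = "pseudohaploid")
  mm <- pairwise_mismatch(gm, "s1", "s2", blocks = rep(1:2, each = 10),
                          min_snps = 10)
  expect_identical(mm$n_overlap, 16L)
  expect_identical(mm$n_mismatch, 4L)
  expect_identical(mm$rate, 0.25)
  expect_true(mm$qc_pass)

  # symmetry in the pair arguments
  mm2 <- pairwise_mismatch(gm, "s2", "s1", blocks = rep(1:2, each = 10),
                           min_snps = 10)
  expect_identical(mm2$rate, mm$rate)
  expect_identical(mm2$std_error, mm$std_error)

  # no overlap -> error; low overlap -> flagged, not suppressed
  gm9 <- toy_matrix(cbind(c(0L, 9L), c(9L, 0L)), ploidy = "pseudohaploid")
  expect_error(pairwise_mismatch(gm9, "s1", "s2", blocks = c(1L, 1L)),
               "no overlapping SNPs")
  mm3 <- pairwise_mismatch(gm, "s1", "s2", blocks = rep(1:2, each = 10),
                           min_snps = 100)
  expect_false(mm3$qc_pass)
  expect_identical(mm3$rate, 0.25)
})

test_that("diploid samples are pseudo-haploidised deterministically", {
  set.seed(31)
  calls <- cbind(sample(c(0L, 1L, 2L), 50, replace = TRUE), rep(0L, 50))
  gm <- toy_matrix(calls)  # s1 inferred diploid
  expect_identical(unname(gm$ploidy), c("diploid", "pseudohaploid"))
  bl <- rep(1:2, each = 25)
  m1 <- pairwise_mismatch(gm, "s1", "s2", blocks = bl, min_snps = 10,
                          seed = 4)
  m2 <- pairwise_mismatch(gm, "s1", "s2", blocks = bl, min_snps = 10,
                          seed = 4)
  expect_identical(m1$rate, m2$rate)
})

test_that("baseline estimation defaults to the analytic halving", {
  # one unrelated pair with rate 0.24 -> m_unrelated 0.24, m_identical 0.12
  L <- 2500
  a <- rep(0L, L)
  b <- c(rep(2L, 600), rep(0L, L - 600))
  gm <- toy_matrix(cbind(a, b), ploidy = "pseudohaploid")
  bl <- rep(1:5, each = 500)
  base <- estimate_baselines(gm, rbind(c("s1", "s2")), blocks = bl,
                             min_snps = 100)
  expect_identical(base$m_unrelated, 0.24)
  expect_identical(base$m_identical, 0.12)

  # supplied observed identical rate overrides the default
  base2 <- estimate_baselines(gm, rbind(c("s1", "s2")),
                              observed_identical = 0.1, blocks = bl,
                              min_snps = 100)
  expect_identical(base2$m_identical, 0.1)

  expect_error(estimate_baselines(gm, rbind(c("s1", "s2")),
                                  observed_identical = 0.5, blocks = bl,
                                  min_snps = 100), "degenerate")
  expect_error(estimate_baselines(gm, matrix(character(0), 0, 2)),
               "at least one")
})

test_that("relatedness coefficient is exact linear interpolation", {
  expect_identical(relatedness_coefficient(0.24, 0.24, 0.12)$r, 0)
  expect_identical(relatedness_coefficient(0.12, 0.24, 0.12)$r, 1)
  expect_equal(relatedness_coefficient(0.225, 0.24, 0.12)$r, 0.125)
  # default identical endpoint is m_unrelated / 2
  expect_identical(relatedness_coefficient(0.18, 0.24)$r, 0.5)
  # unclipped outside [0,1]
  expect_lt(relatedness_coefficient(0.3, 0.24, 0.12)$r, 0)
  # CI: first-order propagation, baselines fixed
  rc <- relatedness_coefficient(0.225, 0.24, 0.12, se_pair = 0.012)
  expect_equal(rc$se, 0.1)
  expect_equal(rc$ci95, c(0.125 - 1.96 * 0.1, 0.125 + 1.96 * 0.1))
  expect_error(relatedness_coefficient(0.2, 0.1, 0.2), "degenerate")
})

test_that("degree classification uses midpoint bins with documented ties", {
  shares <- c(identical = 1, first = 0.5, second = 0.25, third = 0.125,
              fourth = 0.0625, unrelated = 0)
  for (nm in names(shares)) {
    expect_identical(classify_degree(shares[[nm]])$degree_label, nm)
  }
  expect_identical(classify_degree(0.1)$degree_label, "third")
  expect_identical(classify_degree(0.05)$degree_label, "fourth")
  # boundary ties go to the more-related class
  expect_identical(classify_degree(0.75)$degree_label, "identical")
  expect_identical(classify_degree(0.09375)$degree_label, "third")
  # QC failure dominates
  expect_identical(classify_degree(0.5, qc_pass = FALSE)$degree_label,
                   "indeterminate")
  # CI rule: a CI spanning a boundary is indeterminate under within_bin
  expect_identical(classify_degree(0.1, c(0.05, 0.15),
                                   ci_rule = "within_bin")$degree_label,
                   "indeterminate")
  expect_identical(classify_degree(0.1, c(0.095, 0.15),
                                   ci_rule = "within_bin")$degree_label,
                   "third")
  expect_identical(classify_degree(0.1, c(0.05, 0.15))$degree_label, "third")
})

test_that("sex determination from X/Y read counts", {
  s <- sex_from_counts(1000, 0)
  expect_identical(s$r_y, 0)
  expect_identical(s$call, "XX")

  s <- sex_from_counts(900, 100)
  expect_identical(s$r_y, 0.1)
  expect_identical(s$call, "XY")

  expect_warning(s <- sex_from_counts(0, 0), "indeterminate")
  expect_identical(s$call, "indeterminate")
  expect_true(is.na(s$r_y))

  expect_identical(sex_from_counts(960, 40)$call, "indeterminate")
  expect_error(sex_from_counts(-1, 5), "non-negative")
})

test_that("kinship_analysis recovers simulated degrees end to end", {
  L <- 30000
  panel <- simulate_founders(founder_model(L, seed = 17))
  smodel <- sampling_model(missing_rate = 0.1)
  parts <- list(
    simulate_pair_panel("twin", panel, 2, smodel, seed = 51),
    simulate_pair_panel("parent_offspring", panel, 2, smodel, seed = 52),
    simulate_pair_panel("unrelated", panel, 4, smodel, seed = 53)
  )
  calls <- do.call(cbind, lapply(parts, function(p) p$matrix$calls))
  ind <- do.call(rbind, lapply(parts, function(p) p$matrix$ind))
  gm <- genotype_matrix(calls, parts[[1]]$matrix$snp, ind,
                        ploidy = "pseudohaploid")
  pairs <- rbind(c("twin_1_a", "twin_1_b"),
                 c("parent_offspring_1_a", "parent_offspring_1_b"))
  upairs <- rbind(c("unrelated_1_a", "unrelated_1_b"),
                  c("unrelated_2_a", "unrelated_2_b"),
                  c("unrelated_3_a", "unrelated_3_b"),
                  c("unrelated_4_a", "unrelated_4_b"))
  res <- kinship_analysis(gm, pairs, upairs, min_snps = 10000)
  expect_identical(res$degree, c("identical", "first"))
  expect_true(all(res$qc_pass))
  expect_gt(attr(res, "m_unrelated"), attr(res, "m_identical"))
})
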