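mkResults <- function(variant_id, protein_id, aa_from, aa_to, delta_ds) {
  data.frame(variant_id = variant_id, protein_id = protein_id,
             aa_from = aa_from, aa_to = aa_to, delta_ds = delta_ds,
             stringsAsFactors = FALSE)
}

test_that("isoform pairwise shifts follow direct arithmetic", {
  tab <- mkResults(c("v1", "v1"), c("pA", "pA.iso1"), "I", "K",
                   c(0.05, -0.02))
  s <- isoformShiftDistribution(tab)
  expect_equal(s$n_pairs, 1L)
  expect_equal(s$mean_abs_shift, 0.07)
  expect_equal(s$sign_flip_fraction, 1.0)
  # groups of one are skipped and counted, not silently dropped
  tab2 <- rbind(tab, mkResults("v2", "pB", "A", "V", 0.01))
  s2 <- isoformShiftDistribution(tab2)
  expect_equal(s2$n_pairs, 1L)
  expect_equal(s2$n_groups_skipped, 1L)
  # empty input: counts zero, summary fields marked undefined
  s0 <- isoformShiftDistribution(tab[0, ])
  expect_equal(s0$n_pairs, 0L)
  expect_true(is.na(s0$mean_abs_shift))
})

test_that("pair counting and sign-flip accounting are exact", {
  # group of size m contributes m(m-1)/2 pairs
  for (m in 2:5) {
    tab <- mkResults(rep("v1", m), sprintf("p%d", 1:m), "I", "K",
                     seq(0.01, by = 0.01, length.out = m))
    s <- isoformShiftDistribution(tab)
    expect_equal(s$n_pairs, m * (m - 1L) / 2L)
    # single-sign cohort flips exactly never
    expect_equal(s$sign_flip_fraction, 0)
  }
  # pairs involving an exact zero are tallied separately from flips
  tab <- mkResults(rep("v1", 3), c("p1", "p2", "p3"), "I", "K",
                   c(0, 0.1, -0.1))
  s <- isoformShiftDistribution(tab)
  expect_equal(s$n_zero_involved_pairs, 2L)
  expect_equal(s$sign_flip_fraction, 1)  # the one nonzero pair flips
})

test_that("cross-protein shifts pair distinct proteins per substitution", {
  # one substitution in 3 proteins -> C(3,2) = 3 pairs
  tab <- mkResults(sprintf("v%d", 1:3), sprintf("p%d", 1:3), "W", "R",
                   c(0.10, 0.12, 0.05))
  s <- crossProteinShiftDistribution(tab)
  expect_equal(s$n_pairs, 3L)
  # same-protein rows never pair
  tab2 <- rbind(tab, mkResults("v4", "p1", "W", "R", 0.50))
  s2 <- crossProteinShiftDistribution(tab2)
  expect_equal(s2$n_pairs, 5L)  # C(4,2) minus the p1-with-p1 pair
  # identical contexts (duplicated protein content) give zero shift
  same <- mkResults(c("v1", "v2"), c("p1", "p2"), "A", "V",
                    c(0.03, 0.03))
  expect_equal(crossProteinShiftDistribution(same)$mean_abs_shift, 0)
})

test_that("substitution-class summaries match hand arithmetic and oracle", {
  tab <- mkResults(sprintf("v%d", 1:4), sprintf("p%d", 1:4),
                   c("I", "I", "I", "W"), c("K", "K", "K", "R"),
                   c(0.1, 0.2, 0.3, 0.05))
  sct <- substitutionClassTable(tab, topK = 1L)
  ik <- sct$table[sct$table$substitution == "I>K", ]
  expect_equal(ik$n, 3L)
  expect_equal(ik$mean_delta_ds, 0.2)
  expect_equal(ik$std_delta_ds, 0.1)  # sample STD of {0.1, 0.2, 0.3}
  # singleton: STD undefined
  wr <- sct$table[sct$table$substitution == "W>R", ]
  expect_true(is.na(wr$std_delta_ds))
  # top tables ordered by signed mean
  expect_equal(sct$top_positive$substitution[1], "I>K")
  neg <- mkResults(c("v5", "v6"), c("p5", "p6"), c("K", "S"),
                   c("I", "C"), c(-0.3, -0.1))
  sctn <- substitutionClassTable(rbind(tab, neg), topK = 2L)
  expect_equal(sctn$top_negative$substitution, c("K>I", "S>C"))
  expect_true(all(diff(sctn$top_positive$mean_delta_ds) <= 0))
  expect_true(all(diff(sctn$top_negative$mean_delta_ds) >= 0))
})

test_that("grouped means agree with a flat-scan oracle to 1e-12", {
  set.seed(21)
  sb <- enumerateSingleBaseChanges()$substitutions
  pick <- sb[sample.int(nrow(sb), 200, replace = TRUE), ]
  tab <- mkResults(sprintf("v%d", 1:200),
                   sprintf("p%d", sample.int(40, 200, replace = TRUE)),
                   pick$aa_from, pick$aa_to,
                   round(runif(200, -0.2, 0.2), 4))
  got <- substitutionClassTable(tab)$table
  oracle <- flatScanMeans(tab)
  expect_equal(stats::setNames(got$mean_delta_ds, got$substitution),
               oracle[got$substitution], tolerance = 1e-12)
  # codon-level grouping requires codon columns
  expect_error(substitutionClassTable(tab, by = "codon"), "codon_from")
})
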