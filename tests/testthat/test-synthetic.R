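test_that("cohort generation is deterministic and mix-exact", {
  cfg <- cohortConfig(n_genes = 15L, mean_cds_length = 100,
                      n_individuals = 40L, n_snvs = 300L,
                      consequence_mix = c(synonymous = 0.3,
                                          missense = 0.65,
                                          nonsense = 0.05),
                      n_causal_per_trait = c(3L, 3L, 3L), seed = 101L)
  co <- generateCohort(cfg)
  expect_s4_class(co, "SyntheticCohort")
  expect_equal(nrow(co$variants), 300L)
  mix <- table(co$groundTruth$consequence)
  # quotas are met exactly (largest-remainder rounding of 0.3/0.65/0.05)
  expect_equal(as.integer(mix[c("synonymous", "missense", "nonsense")]),
               c(90L, 195L, 15L))
  # same seed, same config: identical objects and byte-identical files
  co2 <- generateCohort(cfg)
  expect_identical(co$variants, co2$variants)
  expect_identical(co$genotypes, co2$genotypes)
  expect_identical(co$groundTruth, co2$groundTruth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeCohort(co, d1, force = TRUE); writeCohort(co2, d2, force = TRUE)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # a different seed changes the cohort
  co3 <- generateCohort(cohortConfig(n_genes = 15L,
                                     mean_cds_length = 100,
                                     n_individuals = 40L, n_snvs = 300L,
                                     consequence_mix = cfg$consequence_mix,
                                     n_causal_per_trait = c(3L, 3L, 3L),
                                     seed = 102L))
  expect_false(identical(co$variants, co3$variants))
})

test_that("generated cohorts satisfy their structural invariants", {
  co <- generateCohort(smallCohortConfig(seed = 23L))
  gt <- co$groundTruth
  # every variant maps cleanly on the canonical protein
  saps <- mapVariants(co$variants, co$cds, co$proteins,
                      proteinGenes = co$proteinMeta[!co$proteinMeta$isoform, ])
  expect_true(all(saps$mapped))
  expect_equal(saps$consequence, gt$consequence)
  # generating MAFs lie in [0, 0.5]; answer sheet is referentially intact
  expect_true(all(gt$true_maf >= 0 & gt$true_maf <= 0.5))
  expect_true(all(co$answerSheet$variant_id %in% co$variants$variant_id))
  expect_true(all(co$answerSheet$gene_id ==
                    co$variants$gene_id[match(co$answerSheet$variant_id,
                                              co$variants$variant_id)]))
  # synonymous ground truth is exactly zero; nonsense is NA
  expect_true(all(gt$true_delta_ds[gt$consequence == "synonymous"] == 0))
  expect_true(all(is.na(gt$true_delta_ds[gt$consequence == "nonsense"])))
})

test_that("genotype-derived MAFs converge to generating MAFs", {
  cfg <- cohortConfig(n_genes = 10L, mean_cds_length = 80,
                      n_individuals = 3000L, n_snvs = 60L,
                      n_causal_per_trait = c(2L, 2L, 2L), seed = 53L)
  co <- generateCohort(cfg)
  got <- computeMafMatrix(co$genotypes)
  p <- co$groundTruth$true_maf
  se <- sqrt(p * (1 - p) / (2 * cfg$n_individuals))
  # folded at 0.5: compare against min(p, 1-p); tolerance 3 SE
  expect_true(all(abs(got$maf - pmin(p, 1 - p)) <= pmax(3 * se, 1e-6)))
})

test_that("MAF coupling lowers the coupled group's frequencies", {
  cfg <- cohortConfig(n_genes = 30L, mean_cds_length = 150,
                      n_individuals = 10L, n_snvs = 2000L,
                      n_causal_per_trait = c(2L, 2L, 2L), seed = 61L)
  co <- generateCohort(cfg)
  gt <- co$groundTruth
  coupled <- gt$coupling_group == "coupled"
  expect_gt(sum(coupled), 20L)
  expect_lt(mean(gt$true_maf[coupled]), mean(gt$true_maf[!coupled]))
  # coupling disabled: the two groups share one Beta spectrum
  cfgOff <- cohortConfig(n_genes = 30L, mean_cds_length = 150,
                         n_individuals = 10L, n_snvs = 2000L,
                         coupling_effect = 1,
                         n_causal_per_trait = c(2L, 2L, 2L), seed = 61L)
  gtOff <- generateCohort(cfgOff)$groundTruth
  wouldCouple <- gtOff$consequence == "missense" &
    !is.na(gtOff$true_delta_ds) &
    gtOff$true_delta_ds <= -cfgOff$coupling_threshold
  ks <- suppressWarnings(stats::ks.test(gtOff$true_maf[wouldCouple],
                                        gtOff$true_maf[!wouldCouple]))
  expect_gt(ks$p.value, 0.01)
})

test_that("isoform edits are terminal deletions that preserve context", {
  set.seed(71)
  protein <- paste0("M", strrep("L", 30), strrep("P", 30),
                    strrep("E", 39))
  isos <- generateIsoforms(protein, list(type = "terminal",
                                         mean_len = 10), n = 6L)
  for (iso in isos) {
    expect_true(nchar(iso) >= 15)
    # terminal deletion: the isoform is a prefix or suffix of canonical
    expect_true(startsWith(protein, iso) || endsWith(protein, iso))
  }
  expect_error(generateIsoforms("MLLP", list(mean_len = 2)), "too short")
  # a deletion entirely beyond the predictor window leaves delta-DS
  # unchanged (locality of the builtin predictor)
  p <- builtinPredictor()
  iso <- substr(protein, 1, nchar(protein) - 30)  # C-terminal cut
  pos <- 31L  # > window half-width away from the cut
  maj <- substr(protein, pos, pos)
  full <- computeDeltaDS(protein, pos, maj, "K", p)
  cut <- computeDeltaDS(iso, pos, maj, "K", p)
  expect_identical(full$delta_ds, cut$delta_ds)
})
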