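test_that("codon translation follows the standard genetic code", {
  expect_equal(translateCodon("ATG"), "M")
  expect_equal(translateCodon("TAA"), "*")
  expect_equal(translateCodon("TGG"), "W")
  expect_equal(translateCodon(c("atg", "gaa")), c("M", "E"))
  # the whole table agrees with an independently hardcoded code
  oracle <- oracleGeneticCode()
  expect_equal(translateCodon(names(oracle)), unname(oracle))
  expect_error(translateCodon("AT"), "invalid codon")
  expect_error(translateCodon("ANG"), "ANG")
})

test_that("full nonsynonymous substitution space has 380 ordered pairs", {
  all380 <- enumerateAllNonsynChanges()
  expect_equal(nrow(all380), 380L)
  key <- paste(all380$aa_from, all380$aa_to, sep = ">")
  expect_false(anyDuplicated(key) > 0)
  expect_true("A>V" %in% key)
  expect_false("A>A" %in% key)
})

test_that("single-base-accessible space matches the brute-force oracle", {
  sb <- enumerateSingleBaseChanges()
  expect_equal(nrow(sb$substitutions), 150L)
  got <- paste(sb$substitutions$aa_from, sb$substitutions$aa_to,
               sep = ">")
  expect_setequal(got, oracleSingleBaseSubs())
  # subset of the full space
  all380 <- paste(enumerateAllNonsynChanges()$aa_from,
                  enumerateAllNonsynChanges()$aa_to, sep = ">")
  expect_true(all(got %in% all380))
  # every codon change differs at exactly one base, both codons sense
  cc <- sb$codonChanges
  diffs <- mapply(function(a, b) sum(strsplit(a, "")[[1]] !=
                                       strsplit(b, "")[[1]]),
                  cc$codon_from, cc$codon_to)
  expect_true(all(diffs == 1L))
  expect_true(all(translateCodon(cc$codon_from) != "*"))
  expect_true(all(translateCodon(cc$codon_to) != "*"))
  # mismatching base is the recorded position
  at <- mapply(function(a, b) which(strsplit(a, "")[[1]] !=
                                      strsplit(b, "")[[1]]),
               cc$codon_from, cc$codon_to)
  expect_equal(unname(at), cc$position_in_codon)
  # W>R is reachable via TGG>AGG and TGG>CGG; W>M is not reachable
  wr <- cc[cc$aa_from == "W" & cc$aa_to == "R", ]
  expect_setequal(wr$codon_to, c("AGG", "CGG"))
  expect_false(any(cc$aa_from == "W" & cc$aa_to == "M"))
  # multimap counts are consistent
  expect_equal(sum(sb$substitutions$n_codon_changes), nrow(cc))
})

test_that("variants map onto protein positions with consequence calls", {
  m <- mapVariantToProtein("ATGTGGGAA", "MWE", 4, "T", "A")
  expect_true(m$mapped)
  expect_equal(m$protein_position, 2L)
  expect_equal(m$major_aa, "W")
  expect_equal(m$minor_aa, "R")
  expect_equal(m$consequence, "missense")
  expect_equal(m$codon_from, "TGG")
  expect_equal(m$codon_to, "AGG")

  syn <- mapVariantToProtein("ATGTGGGAA", "MWE", 9, "A", "G")
  expect_equal(syn$consequence, "synonymous")
  expect_equal(syn$major_aa, syn$minor_aa)

  non <- mapVariantToProtein("ATGTGGGAA", "MWE", 5, "G", "A")  # TGG>TAG
  expect_equal(non$consequence, "nonsense")
  expect_equal(non$minor_aa, "*")
})

test_that("mapping failures are reported with reason codes", {
  # declared reference disagrees with the sequence
  mm <- mapVariantToProtein("ATGTGGGAA", "MWE", 4, "C", "A")
  expect_false(mm$mapped)
  expect_equal(mm$reason, "ref_mismatch")
  # no frame translates to the protein
  nm <- mapVariantToProtein("ATGTGGGAA", "MKY", 4, "T", "A")
  expect_equal(nm$reason, "no_match")
  # repeated protein inside the translation -> ambiguous, not guessed
  amb <- mapVariantToProtein("ATGATGATG", "MM", 4, "A", "C")
  expect_equal(amb$reason, "ambiguous")
  # frame shifted by one: still found (frame search)
  fr <- mapVariantToProtein("CATGTGGGAA", "MWE", 5, "T", "A")
  expect_true(fr$mapped)
  expect_equal(fr$protein_position, 2L)
  # reverse-complement strand only found when asked for
  rcSeq <- "TTCCCACAT"  # revcomp of ATGTGGGAA
  fwd <- mapVariantToProtein(rcSeq, "MWE", 6, "A", "T")
  expect_false(fwd$mapped)
  rev <- mapVariantToProtein(rcSeq, "MWE", 6, "A", "T",
                             searchReverse = TRUE)
  expect_true(rev$mapped)
  expect_equal(rev$protein_position, 2L)
  expect_equal(rev$minor_aa, "R")
})

test_that("translating the mutated CDS reproduces the mapped minor allele", {
  set.seed(11)
  cfg <- smallCohortConfig()
  co <- generateCohort(cfg)
  v <- co$variants[1:50, ]
  saps <- mapVariants(v, co$cds, co$proteins,
                      proteinGenes = co$proteinMeta[!co$proteinMeta$isoform, ])
  expect_true(all(saps$mapped))
  for (i in seq_len(nrow(saps))) {
    cdsSeq <- co$cds[[saps$gene_id[i]]]
    substr(cdsSeq, saps$cds_position[i], saps$cds_position[i]) <-
      saps$alt_base[i]
    ci <- (saps$cds_position[i] - 1L) %/% 3L + 1L
    altCodon <- substr(cdsSeq, (ci - 1L) * 3L + 1L, ci * 3L)
    expect_equal(translateCodon(altCodon), saps$minor_aa[i])
  }
})

test_that("missense filtering tallies every excluded class", {
  saps <- data.frame(
    variant_id = sprintf("v%d", 1:5),
    mapped = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    consequence = c("missense", "synonymous", "nonsense", NA,
                    "missense"),
    stringsAsFactors = FALSE)
  flt <- filterSaps(saps)
  expect_equal(nrow(flt$missense), 2L)
  expect_equal(flt$excluded[["synonymous"]], 1L)
  expect_equal(flt$excluded[["nonsense"]], 1L)
  expect_equal(flt$excluded[["unmapped"]], 1L)
})
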