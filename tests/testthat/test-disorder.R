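test_that("builtin scores are hand-computable window-sigmoid values", {
  p <- builtinPredictor()
  scale <- disorderPropensity()
  # homopolymers: window mean equals the residue propensity, so every
  # score is the sigmoid of that propensity
  best <- names(which.max(scale))   # most disorder-promoting residue
  worst <- names(which.min(scale))  # most order-promoting residue
  sBest <- predictDisorder(strrep(best, 50), p)
  sWorst <- predictDisorder(strrep(worst, 50), p)
  expect_equal(sBest, rep(plogis(p@k * (scale[[best]] - p@p0)), 50))
  expect_equal(sWorst, rep(plogis(p@k * (scale[[worst]] - p@p0)), 50))
  expect_true(all(sBest > 0.5))
  expect_true(all(sWorst < 0.5))
  # single residue: window truncates to size 1
  s1 <- predictDisorder("A", p)
  expect_length(s1, 1L)
  expect_equal(s1, plogis(p@k * (scale[["A"]] - p@p0)))
  # hand-computed truncated window at a sequence end
  seq <- "WPA"
  half <- (p@windowLength - 1L) / 2L
  expect_true(half >= 2)  # full truncation applies on this short seq
  pbar1 <- mean(scale[c("W", "P", "A")])
  expect_equal(predictDisorder(seq, p)[1], plogis(p@k * (pbar1 - p@p0)))
  expect_error(predictDisorder("AXZ", p), "position 2")
  expect_error(predictDisorder("", p), "length")
})

test_that("scores respond monotonically to raised propensity", {
  p <- builtinPredictor()
  scale <- disorderPropensity()
  set.seed(3)
  seq <- paste(sample(names(scale), 60, replace = TRUE), collapse = "")
  base <- predictDisorder(seq, p)
  # replace a middling residue by the most disorder-promoting one
  up <- seq
  substr(up, 30, 30) <- names(which.max(scale))
  raised <- predictDisorder(up, p)
  expect_true(all(raised >= base - 1e-15))
})

test_that("delta-DS obeys its defining algebra", {
  p <- builtinPredictor()
  set.seed(5)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seq <- paste(sample(aa20, 80, replace = TRUE), collapse = "")
  pos <- 40L
  maj <- substr(seq, pos, pos)
  min_ <- setdiff(aa20, maj)[1]
  dd <- computeDeltaDS(seq, pos, maj, min_, p)
  expect_equal(dd$delta_ds, dd$ds_min - dd$ds_maj, tolerance = 1e-9)
  expect_lte(abs(dd$delta_ds), 1)
  # degenerate substitution: identical alleles give exactly zero
  dd0 <- computeDeltaDS(seq, pos, maj, maj, p)
  expect_identical(dd0$delta_ds, 0)
  # antisymmetry under allele swap, exactly
  mutated <- seq
  substr(mutated, pos, pos) <- min_
  back <- computeDeltaDS(mutated, pos, min_, maj, p)
  expect_identical(back$delta_ds, -dd$delta_ds)
  # stale-mapping guard
  expect_error(computeDeltaDS(seq, pos, min_, maj, p), "major allele")
  # I>K in an order-promoting context raises the disorder score
  ctx <- paste0(strrep("L", 15), "I", strrep("L", 15))
  expect_gt(computeDeltaDS(ctx, 16, "I", "K", p)$delta_ds, 0)
})

test_that("a substitution only perturbs scores inside its window", {
  p <- builtinPredictor(windowLength = 21L)
  half <- 10L
  set.seed(9)
  seq <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      100, replace = TRUE), collapse = "")
  pos <- 50L
  alt <- seq
  substr(alt, pos, pos) <- if (substr(seq, pos, pos) == "P") "W" else "P"
  a <- predictDisorder(seq, p)
  b <- predictDisorder(alt, p)
  idx <- seq_along(a)
  outside <- abs(idx - pos) > half
  expect_identical(a[outside], b[outside])
  expect_false(identical(a[!outside], b[!outside]))
})

test_that("region classification applies the 0.5 rule with ties structured", {
  expect_equal(classifyRegion(0.81), "disordered")
  expect_equal(classifyRegion(0.11), "structured")
  expect_equal(classifyRegion(0.5), "structured")
  expect_equal(classifyRegion(c(0.51, 0.49)),
               c("disordered", "structured"))
  expect_error(classifyRegion(1.2), "0, 1")
})

test_that("external score files feed the same pipeline exactly", {
  set.seed(13)
  seqs <- c(pA = paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                              30, replace = TRUE), collapse = ""))
  profiles <- list(pA = round(runif(30), 6))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeScores(profiles, path, proteins = seqs)
  back <- readScores(path, proteins = seqs)
  expect_identical(back$pA, profiles$pA)  # exact round trip
  ext <- externalPredictor(back)
  expect_identical(predictDisorder(seqs[["pA"]], ext, "pA"), profiles$pA)
  expect_error(predictDisorder(seqs[["pA"]], ext, "pB"), "no external")
  expect_error(predictDisorder(substr(seqs[["pA"]], 1, 10), ext, "pA"),
               "length")
})

test_that("DeltaDSResults validity enforces the defining invariants", {
  tab <- data.frame(variant_id = "v1", protein_id = "p1",
                    protein_position = 1L, aa_from = "A", aa_to = "V",
                    ds_maj = 0.6, ds_min = 0.4, delta_ds = -0.2,
                    stringsAsFactors = FALSE)
  res <- DeltaDSResults(tab)
  expect_s4_class(res, "DeltaDSResults")
  expect_equal(resultsTable(res)$region_class, "disordered")
  bad <- tab
  bad$delta_ds <- 0.1
  expect_error(DeltaDSResults(bad), "delta_ds")
  bad2 <- tab
  bad2$ds_min <- 1.4
  bad2$delta_ds <- bad2$ds_min - bad2$ds_maj
  expect_error(DeltaDSResults(bad2), "\\[0, 1\\]")
})
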