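# Stable hash of a configuration list (order-independent within names).
.configHash <- function(x) {
  s <- paste(deparse(x[order(names(x))]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647)
}

#' Generate a synthetic cohort and optionally write it to disk
#'
#' Wraps \code{\link{generateCohort}} and \code{\link{writeCohort}},
#' attaching a manifest (config hash, seed, stage list) so identical
#' configurations are recognisably identical on disk.
#'
#' @param config A \code{\link{cohortConfig}}.
#' @param dir Optional output directory.
#' @param force Overwrite an existing directory.
#' @param predictor Predictor for the ground-truth scores.
#' @return list with \code{cohort} and \code{manifest}.
#' @export
simulateCohort <- function(config = cohortConfig(), dir = NULL,
                           force = FALSE,
                           predictor = builtinPredictor()) {
  cohort <- generateCohort(config, predictor)
  manifest <- list(
    stages = c("genes", "variants", "ground_truth", "maf", "genotypes",
               "isoforms", "traits"),
    config_hash = .configHash(unclass(config)),
    seed = config$seed,
    n_genes = length(cohort@cds),
    n_snvs = nrow(cohort@variants),
    n_individuals = ncol(cohort@genotypes))
  if (!is.null(dir)) {
    writeCohort(cohort, dir, force = force)
    mf <- file.path(dir, "manifest.tsv")
    writeTsv(data.frame(key = names(manifest),
                        value = vapply(manifest, function(v)
                          paste(v, collapse = ","), "")), mf)
  }
  list(cohort = cohort, manifest = manifest)
}

#' Run the full disorder-change pipeline
#'
#' Executes the stages in order: variant-to-protein mapping, MAF
#' computation from genotypes (with major/minor swap propagation),
#' missense filtering, \eqn{\Delta DS} scoring, partition counting, MAF
#' group comparison, and trait answer-sheet intersection. Input is either
#' a \code{\linkS4class{SyntheticCohort}}, a cohort directory path, or a
#' list with the same components as \code{\link{readCohortDir}}.
#'
#' @param input Cohort object, directory path, or component list.
#' @param predictor A \code{\linkS4class{DisorderPredictor}}.
#' @param threshold,comparison \eqn{|\Delta DS|} partition threshold
#'   (default 0.04, inclusive).
#' @param mode,test Passed to \code{\link{compareMafGroups}}.
#' @param mapIsoforms Also map variants into isoform sequences and report
#'   the isoform shift distribution.
#' @return list with components \code{saps} (all mapped records),
#'   \code{exclusions}, \code{results} (canonical-protein
#'   \code{\linkS4class{DeltaDSResults}}), \code{isoformResults} (when
#'   isoforms were mapped), \code{partition}, \code{mafComparison},
#'   \code{traits} (per-trait intersection report, when an answer sheet
#'   is present), \code{settings}.
#' @export
runPipeline <- function(input, predictor = builtinPredictor(),
                        threshold = 0.04,
                        comparison = c("inclusive", "strict"),
                        mode = c("beyond", "within"),
                        test = c("ranksum", "ttest"),
                        mapIsoforms = TRUE) {
  comparison <- match.arg(comparison)
  mode <- match.arg(mode)
  test <- match.arg(test)
  if (is.character(input) && length(input) == 1L) {
    input <- readCohortDir(input)
  } else if (is(input, "SyntheticCohort")) {
    input <- list(cds = input@cds, proteins = input@proteins,
                  proteinMeta = input@proteinMeta,
                  variants = input@variants, genotypes = input@genotypes,
                  answerSheet = input@answerSheet,
                  groundTruth = input@groundTruth)
  }
  stopifnot(is.list(input),
            all(c("cds", "proteins", "variants") %in% names(input)))
  meta <- input$proteinMeta
  if (is.null(meta))
    meta <- data.frame(protein_id = names(input$proteins),
                       gene_id = names(input$proteins),
                       isoform = FALSE, stringsAsFactors = FALSE)

  ## MAF: from genotypes when available, else from the maf column
  variants <- input$variants
  if (!is.null(input$genotypes)) {
    mafTab <- computeMafMatrix(input$genotypes)
    variants <- merge(variants, mafTab[, c("variant_id", "maf",
                                           "swapped")],
                      by = "variant_id", sort = FALSE)
  } else {
    if (!"maf" %in% names(variants))
      stop("variants carry neither genotypes nor a maf column")
    variants$swapped <- FALSE
  }

  ## mapping: canonical proteins (and isoforms for the context analysis)
  canonical <- meta[!meta$isoform, , drop = FALSE]
  saps <- mapVariants(variants, input$cds, input$proteins,
                      proteinGenes = canonical)
  # propagate major/minor swap: when the declared alternate allele is the
  # major one, the roles of the two residues (and codons) are exchanged
  sw <- which(saps$swapped & saps$mapped)
  if (length(sw)) {
    tmp <- saps$major_aa[sw]
    saps$major_aa[sw] <- saps$minor_aa[sw]
    saps$minor_aa[sw] <- tmp
    tmp <- saps$codon_from[sw]
    saps$codon_from[sw] <- saps$codon_to[sw]
    saps$codon_to[sw] <- tmp
  }
  names(saps)[names(saps) == "swapped"] <- "allele_swapped"
  flt <- filterSaps(saps)
  # a swapped "missense" record whose new major allele is absent from the
  # canonical protein cannot be scored; exclude stop-carrying majors
  mis <- flt$missense
  mis <- mis[mis$major_aa %in% .AA20 & mis$minor_aa %in% .AA20, ,
             drop = FALSE]
  results <- scoreVariants(mis, input$proteins, predictor)

  out <- list(saps = saps, exclusions = flt$excluded, results = results,
              settings = list(threshold = threshold,
                              comparison = comparison, mode = mode,
                              test = test,
                              predictor = predictor@kind))

  ## isoform-level scoring for the context analysis
  if (mapIsoforms && any(meta$isoform)) {
    isoMeta <- meta[meta$isoform, , drop = FALSE]
    isoGenes <- unique(isoMeta$gene_id)
    vSub <- variants[variants$gene_id %in% isoGenes, , drop = FALSE]
    if (nrow(vSub)) {
      isoSaps <- mapVariants(vSub, input$cds, input$proteins,
                             proteinGenes = meta[meta$gene_id %in%
                                                   isoGenes, ])
      swi <- which(isoSaps$swapped & isoSaps$mapped)
      if (length(swi)) {
        tmp <- isoSaps$major_aa[swi]
        isoSaps$major_aa[swi] <- isoSaps$minor_aa[swi]
        isoSaps$minor_aa[swi] <- tmp
      }
      names(isoSaps)[names(isoSaps) == "swapped"] <- "allele_swapped"
      isoFlt <- filterSaps(isoSaps)
      misIso <- isoFlt$missense
      misIso <- misIso[misIso$major_aa %in% .AA20 &
                         misIso$minor_aa %in% .AA20, , drop = FALSE]
      out$isoformResults <- scoreVariants(misIso, input$proteins,
                                          predictor)
      out$isoformShift <-
        isoformShiftDistribution(out$isoformResults)
    }
  }

  tab <- resultsTable(results)
  consequence <- saps$consequence[saps$mapped]
  deltaByVariant <- setNames(rep(NA_real_, sum(saps$mapped)),
                             saps$variant_id[saps$mapped])
  deltaByVariant[tab$variant_id] <- tab$delta_ds
  out$partition <- partitionCounts(consequence,
                                   unname(deltaByVariant),
                                   threshold, comparison)
  out$mafComparison <- tryCatch(
    compareMafGroups(tab$delta_ds, tab$maf, threshold, comparison,
                     mode, test),
    error = function(e) {
      warning("MAF comparison skipped: ", conditionMessage(e))
      NULL
    })
  if (!is.null(input$answerSheet) && nrow(input$answerSheet) > 0L) {
    out$traits <- intersectTrait(results, input$answerSheet,
                                 threshold, comparison)
    out$destabilization <-
      destabilizationProfile(out$traits$details)
  }
  out
}
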