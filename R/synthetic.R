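# Derived per-stage RNG seeds: one global seed feeds a fixed hierarchy so
# stages can be regenerated independently. Kept below 2^31 - 1.
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

#' Configuration of a synthetic GAW17-like cohort
#'
#' Defaults mirror the structure of the GAW17 exome cohort the pipeline is
#' designed for: 697 individuals, 24,487 exonic SNVs in 3,205 coding
#' genes, a synonymous/missense/nonsense mix of roughly 0.42/0.56/0.02,
#' a rare-variant-heavy neutral MAF spectrum (Beta(0.5, 8)), and trait
#' answer sheets of causal SNVs. Smaller runs simply override
#' \code{n_genes}/\code{n_snvs}/\code{n_individuals}.
#'
#' @param n_genes Number of coding genes.
#' @param mean_cds_length Mean gene length in codons (gamma-distributed
#'   across genes, minimum 30).
#' @param n_individuals Cohort size.
#' @param n_snvs Number of biallelic SNVs to place.
#' @param consequence_mix Named fractions for synonymous/missense/nonsense;
#'   must sum to 1.
#' @param isoform_rate Fraction of genes that receive isoform records.
#' @param isoform_edit list(type, mean_len): isoforms are derived from the
#'   canonical sequence by a terminal-segment deletion whose length is
#'   1 + Poisson(\code{mean_len} - 1).
#' @param maf_alpha,maf_beta Beta parameters of the neutral MAF spectrum.
#' @param coupling_effect Multiplier in (0, 1] applied to the drawn MAF of
#'   SNVs in the coupled group (see \code{coupling_threshold}); 1 disables
#'   the coupling. Stands in for purifying selection.
#' @param coupling_threshold \eqn{|\Delta DS|} threshold defining the
#'   coupled group: missense SNVs with \eqn{\Delta DS \le} -threshold
#'   (structure-gaining changes beyond the threshold).
#' @param composition_bias Mean per-gene weight of the disorder-promoting
#'   residue pool; per-gene weights are drawn from
#'   Beta(2 bias, 2 (1 - bias)) so genes span ordered, disordered and
#'   mixed composition.
#' @param traits Trait names for the answer sheets.
#' @param n_causal_per_trait Causal SNVs per trait (recycled over
#'   \code{traits}).
#' @param causal_weight Exponent biasing causal-SNV selection towards high
#'   \eqn{|\Delta DS|} (sampling weight \eqn{(|\Delta DS| + 0.01)^w}).
#' @param seed Global integer seed; every stage derives its own stream
#'   seed from it.
#' @return Validated list of class \code{"cohortConfig"}.
#' @export
cohortConfig <- function(n_genes = 3205L, mean_cds_length = 500,
                         n_individuals = 697L, n_snvs = 24487L,
                         consequence_mix = c(synonymous = 0.42,
                                             missense = 0.56,
                                             nonsense = 0.02),
                         isoform_rate = 0.4,
                         isoform_edit = list(type = "terminal",
                                             mean_len = 15),
                         maf_alpha = 0.5, maf_beta = 8,
                         coupling_effect = 0.5,
                         coupling_threshold = 0.04,
                         composition_bias = 0.5,
                         traits = c("Q1", "Q2", "liability"),
                         n_causal_per_trait = c(10L, 15L, 12L),
                         causal_weight = 2,
                         seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              mean_cds_length = mean_cds_length,
              n_individuals = as.integer(n_individuals),
              n_snvs = as.integer(n_snvs),
              consequence_mix = consequence_mix,
              isoform_rate = isoform_rate,
              isoform_edit = isoform_edit,
              maf_alpha = maf_alpha, maf_beta = maf_beta,
              coupling_effect = coupling_effect,
              coupling_threshold = coupling_threshold,
              composition_bias = composition_bias,
              traits = traits,
              n_causal_per_trait = rep_len(as.integer(n_causal_per_trait),
                                           length(traits)),
              causal_weight = causal_weight,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes > 0L, cfg$n_individuals > 0L, cfg$n_snvs > 0L,
            cfg$mean_cds_length >= 30,
            abs(sum(cfg$consequence_mix) - 1) < 1e-8,
            all(cfg$consequence_mix >= 0),
            cfg$coupling_effect > 0, cfg$coupling_effect <= 1,
            cfg$coupling_threshold >= 0,
            cfg$isoform_rate >= 0, cfg$isoform_rate <= 1,
            cfg$composition_bias > 0, cfg$composition_bias < 1,
            cfg$maf_alpha > 0, cfg$maf_beta > 0)
  if (!identical(sort(names(cfg$consequence_mix)),
                 c("missense", "nonsense", "synonymous")))
    stop("consequence_mix must be named synonymous/missense/nonsense")
  class(cfg) <- "cohortConfig"
  cfg
}

#' Draw minor allele frequencies from the cohort's spectrum
#'
#' Draws from Beta(alpha, beta), resampling the rare draws above 0.5 so
#' every value is a valid MAF, then scales by the coupling multiplier —
#' the generator's purifying-selection stand-in.
#'
#' @param n Number of draws.
#' @param alpha,beta Beta parameters of the neutral spectrum.
#' @param coupling Multiplier in (0, 1] applied to each draw.
#' @return Numeric vector in [0, 0.5].
#' @export
sampleMaf <- function(n, alpha = 0.5, beta = 8, coupling = 1) {
  x <- rbeta(n, alpha, beta)
  while (any(bad <- x > 0.5)) x[bad] <- rbeta(sum(bad), alpha, beta)
  x * coupling
}

#' Derive isoform sequences from a canonical protein
#'
#' Isoforms are modelled as terminal-segment deletions (N- or C-terminal),
#' leaving the shared sequence identical to the canonical — the mild
#' context perturbation needed to study isoform-level \eqn{\Delta DS}
#' shifts. SNV sites falling inside a deleted segment are simply absent
#' from that isoform and are reported as unmapped by the mapping stage.
#'
#' @param proteinSeq Canonical amino-acid sequence.
#' @param editModel list(type = "terminal", mean_len): deletion length is
#'   1 + Poisson(mean_len - 1), capped so at least 15 residues remain.
#' @param n Number of isoforms to derive.
#' @return Character vector of isoform sequences (uses the current RNG
#'   stream; seed externally for reproducibility).
#' @export
generateIsoforms <- function(proteinSeq,
                             editModel = list(type = "terminal",
                                              mean_len = 15),
                             n = 1L) {
  L <- nchar(proteinSeq)
  if (L <= 16L) stop("sequence too short to derive an isoform")
  vapply(seq_len(n), function(i) {
    len <- min(1L + rpois(1L, max(editModel$mean_len - 1, 0)), L - 15L)
    if (runif(1) < 0.5) substr(proteinSeq, len + 1L, L)  # N-terminal cut
    else substr(proteinSeq, 1L, L - len)                 # C-terminal cut
  }, "")
}

# Sample a protein sequence from the ordered/disordered residue-pool
# mixture. First residue fixed to M (initiator).
.sampleProtein <- function(lengthCodons, disWeight, scale) {
  props <- disorderPropensity(scale)
  disPool <- names(props)[props > median(props)]
  ordPool <- names(props)[props <= median(props)]
  fromDis <- runif(lengthCodons - 1L) < disWeight
  res <- character(lengthCodons - 1L)
  res[fromDis] <- sample(disPool, sum(fromDis), replace = TRUE)
  res[!fromDis] <- sample(ordPool, sum(!fromDis), replace = TRUE)
  paste0("M", paste(res, collapse = ""))
}

# Back-translate a protein to a CDS with uniformly random synonymous
# codons, plus a random stop codon.
.backTranslate <- function(proteinSeq) {
  byAA <- codonsByAA()
  res <- strsplit(proteinSeq, "")[[1]]
  codons <- vapply(res, function(a) {
    opts <- byAA[[a]]
    opts[sample.int(length(opts), 1L)]
  }, "")
  stops <- byAA[[STOP_CHAR]]
  paste0(paste(codons, collapse = ""),
         stops[sample.int(length(stops), 1L)])
}

#' Generate a synthetic exome-like cohort with known ground truth
#'
#' Produces everything the pipeline consumes, plus the generation-time
#' truth needed to verify every downstream stage. In order: (1) protein
#' sequences are sampled from a per-gene mixture of order- and
#' disorder-promoting residue pools; (2) each protein is back-translated
#' with uniformly random synonymous codons; (3) SNVs are placed at random
#' codon positions by rejection sampling until the configured
#' synonymous/missense/nonsense mix is met exactly; (4) the true
#' \eqn{\Delta DS} of every missense SNV is computed with the supplied
#' predictor on the canonical protein; (5) each SNV's MAF is drawn from
#' the neutral Beta spectrum, scaled by \code{coupling_effect} for
#' missense SNVs with \eqn{\Delta DS \le} -\code{coupling_threshold};
#' (6) genotype dosages are drawn Binomial(2, MAF) per individual
#' (Hardy-Weinberg); (7) isoforms are derived for a fraction of genes;
#' (8) causal SNVs are sampled per trait with weight
#' \eqn{(|\Delta DS| + 0.01)^{causal\_weight}} and written to the answer
#' sheet. Identical config and seed give identical cohorts.
#'
#' @param config A \code{\link{cohortConfig}}.
#' @param predictor Predictor used for the ground-truth \eqn{\Delta DS}
#'   (default \code{\link{builtinPredictor}()}).
#' @return A \code{\linkS4class{SyntheticCohort}}.
#' @export
generateCohort <- function(config = cohortConfig(),
                           predictor = builtinPredictor()) {
  stopifnot(inherits(config, "cohortConfig"))

  ## stage 1: genes ----------------------------------------------------
  set.seed(.stageSeed(config$seed, "genes"))
  geneIds <- sprintf("g%04d", seq_len(config$n_genes))
  lens <- pmax(30L, as.integer(round(
    rgamma(config$n_genes, shape = 4, rate = 4 / config$mean_cds_length))))
  b <- config$composition_bias
  disWeights <- rbeta(config$n_genes, 2 * b, 2 * (1 - b))
  scaleName <- if (predictor@kind == "builtin") predictor@scaleName
               else "topidp"
  proteins <- setNames(vapply(seq_len(config$n_genes), function(i)
    .sampleProtein(lens[i], disWeights[i], scaleName), ""), geneIds)
  cds <- setNames(vapply(proteins, .backTranslate, ""), geneIds)

  ## stage 2: variant placement ---------------------------------------
  set.seed(.stageSeed(config$seed, "variants"))
  quota <- round(config$consequence_mix * config$n_snvs)
  # largest-remainder touch-up so the counts sum exactly to n_snvs
  while (sum(quota) > config$n_snvs) {
    i <- which.max(quota); quota[i] <- quota[i] - 1L
  }
  while (sum(quota) < config$n_snvs) {
    i <- which.max(config$consequence_mix * config$n_snvs - quota)
    quota[i] <- quota[i] + 1L
  }
  need <- quota
  seen <- new.env(parent = emptyenv())
  recs <- vector("list", config$n_snvs)
  filled <- 0L
  maxIter <- 200L * config$n_snvs
  iter <- 0L
  gc <- geneticCode()
  geneProb <- lens / sum(lens)
  while (filled < config$n_snvs && iter < maxIter) {
    iter <- iter + 1L
    gi <- sample.int(config$n_genes, 1L, prob = geneProb)
    ci <- sample.int(lens[gi], 1L)
    pic <- sample.int(3L, 1L)
    cdsPos <- (ci - 1L) * 3L + pic
    codon <- substr(cds[[gi]], (ci - 1L) * 3L + 1L, ci * 3L)
    ref <- substr(codon, pic, pic)
    alt <- sample(.BASES[.BASES != ref], 1L)
    key <- paste(gi, cdsPos, alt)
    if (exists(key, envir = seen)) next
    altCodon <- codon
    substr(altCodon, pic, pic) <- alt
    aaTo <- gc[[altCodon]]
    cons <- if (aaTo == gc[[codon]]) "synonymous"
            else if (aaTo == STOP_CHAR) "nonsense" else "missense"
    if (need[[cons]] <= 0L) next
    need[[cons]] <- need[[cons]] - 1L
    assign(key, TRUE, envir = seen)
    filled <- filled + 1L
    recs[[filled]] <- list(gene = geneIds[gi], cds_position = cdsPos,
                           ref = ref, alt = alt, consequence = cons,
                           codon_index = ci)
  }
  if (filled < config$n_snvs)
    stop("could not realise the requested consequence mix ",
         "(genes too small or mix infeasible); still missing: ",
         paste(names(need)[need > 0], need[need > 0], collapse = ", "))
  ord <- order(vapply(recs, `[[`, "", "gene"),
               vapply(recs, `[[`, 0L, "cds_position"))
  recs <- recs[ord]
  variants <- data.frame(
    variant_id = sprintf("V%05d", seq_len(config$n_snvs)),
    gene_id = vapply(recs, `[[`, "", "gene"),
    cds_position = vapply(recs, `[[`, 0L, "cds_position"),
    ref_base = vapply(recs, `[[`, "", "ref"),
    alt_base = vapply(recs, `[[`, "", "alt"),
    stringsAsFactors = FALSE)
  consequence <- vapply(recs, `[[`, "", "consequence")

  ## stage 3: ground-truth delta-DS -----------------------------------
  trueDelta <- rep(NA_real_, config$n_snvs)
  trueDsMaj <- rep(NA_real_, config$n_snvs)
  trueDelta[consequence == "synonymous"] <- 0
  profCache <- new.env(parent = emptyenv())
  for (i in which(consequence == "missense")) {
    g <- variants$gene_id[i]
    pos <- (variants$cds_position[i] - 1L) %/% 3L + 1L
    pic <- (variants$cds_position[i] - 1L) %% 3L + 1L
    codon <- substr(cds[[g]], (pos - 1L) * 3L + 1L, pos * 3L)
    altCodon <- codon
    substr(altCodon, pic, pic) <- variants$alt_base[i]
    dd <- computeDeltaDS(proteins[[g]], pos, gc[[codon]], gc[[altCodon]],
                         predictor, proteinId = g)
    trueDelta[i] <- dd$delta_ds
    trueDsMaj[i] <- dd$ds_maj
  }

  ## stage 4: MAF spectrum with selection coupling --------------------
  set.seed(.stageSeed(config$seed, "maf"))
  coupled <- consequence == "missense" &
    !is.na(trueDelta) & trueDelta <= -config$coupling_threshold
  trueMaf <- sampleMaf(config$n_snvs, config$maf_alpha, config$maf_beta)
  trueMaf[coupled] <- trueMaf[coupled] * config$coupling_effect

  ## stage 5: genotypes under Hardy-Weinberg --------------------------
  set.seed(.stageSeed(config$seed, "genotypes"))
  genotypes <- matrix(rbinom(config$n_snvs * config$n_individuals, 2L,
                             rep(trueMaf, config$n_individuals)),
                      nrow = config$n_snvs,
                      dimnames = list(variants$variant_id,
                                      sprintf("ind%04d",
                                              seq_len(config$n_individuals))))

  ## stage 6: isoforms -------------------------------------------------
  set.seed(.stageSeed(config$seed, "isoforms"))
  nIso <- round(config$isoform_rate * config$n_genes)
  eligible <- geneIds[lens > 16L]
  isoGenes <- sample(eligible, min(nIso, length(eligible)))
  isoSeqs <- character(0)
  for (g in isoGenes) {
    iso <- generateIsoforms(proteins[[g]], config$isoform_edit, n = 1L)
    isoSeqs[paste0(g, ".iso1")] <- iso
  }
  allProteins <- c(proteins, isoSeqs)
  proteinMeta <- data.frame(
    protein_id = names(allProteins),
    gene_id = sub("\\.iso[0-9]+$", "", names(allProteins)),
    isoform = grepl("\\.iso", names(allProteins)),
    stringsAsFactors = FALSE)

  ## stage 7: trait answer sheets --------------------------------------
  set.seed(.stageSeed(config$seed, "traits"))
  mis <- which(consequence == "missense")
  w <- (abs(trueDelta[mis]) + 0.01)^config$causal_weight
  sheets <- list()
  causalFlags <- matrix(FALSE, config$n_snvs, length(config$traits),
                        dimnames = list(NULL, config$traits))
  for (ti in seq_along(config$traits)) {
    k <- min(config$n_causal_per_trait[ti], length(mis))
    pick <- mis[sample.int(length(mis), k, prob = w)]
    causalFlags[pick, ti] <- TRUE
    sheets[[ti]] <- data.frame(trait = config$traits[ti],
                               variant_id = variants$variant_id[pick],
                               gene_id = variants$gene_id[pick],
                               stringsAsFactors = FALSE)
  }
  answerSheet <- do.call(rbind, sheets)

  groundTruth <- data.frame(
    variant_id = variants$variant_id,
    gene_id = variants$gene_id,
    cds_position = variants$cds_position,
    consequence = consequence,
    true_delta_ds = trueDelta,
    true_ds_maj = trueDsMaj,
    true_maf = trueMaf,
    coupling_group = ifelse(coupled, "coupled", "neutral"),
    stringsAsFactors = FALSE)
  for (tr in config$traits)
    groundTruth[[paste0("causal_", tr)]] <- causalFlags[, tr]

  new("SyntheticCohort", cds = cds, proteins = allProteins,
      proteinMeta = proteinMeta, variants = variants,
      genotypes = genotypes, answerSheet = answerSheet,
      groundTruth = groundTruth, config = unclass(config))
}
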