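#' DisorderPredictor: a pluggable per-residue disorder predictor
#'
#' The downstream \eqn{\Delta DS} machinery is predictor-agnostic. Two
#' kinds are supported: \code{"builtin"}, a window-averaged residue
#' disorder-propensity model passed through a monotone sigmoid, and
#' \code{"external"}, which carries per-residue scores produced by any
#' external predictor (e.g. read from a score TSV with
#' \code{\link{readScores}}).
#'
#' @slot kind \code{"builtin"} or \code{"external"}.
#' @slot windowLength Odd positive integer; the centred averaging window of
#'   the builtin model (truncated at sequence ends).
#' @slot scaleName Identifier of the shipped propensity scale.
#' @slot p0 Sigmoid midpoint on the propensity scale.
#' @slot k Sigmoid steepness (> 0).
#' @slot scores Named list of per-residue numeric score vectors (external
#'   kind only).
#'
#' @seealso \code{\link{builtinPredictor}}, \code{\link{externalPredictor}},
#'   \code{\link{predictDisorder}}
#' @export
setClass("DisorderPredictor",
         representation(kind = "character",
                        windowLength = "integer",
                        scaleName = "character",
                        p0 = "numeric",
                        k = "numeric",
                        scores = "list"))

setValidity("DisorderPredictor", function(object) {
  msgs <- character(0)
  if (!object@kind %in% c("builtin", "external"))
    msgs <- c(msgs, "kind must be 'builtin' or 'external'")
  if (object@kind == "builtin") {
    if (length(object@windowLength) != 1L || object@windowLength < 1L ||
        object@windowLength %% 2L == 0L)
      msgs <- c(msgs, "windowLength must be an odd positive integer")
    if (length(object@k) != 1L || object@k <= 0)
      msgs <- c(msgs, "k must be > 0")
    if (!object@scaleName %in% names(.DISORDER_SCALES))
      msgs <- c(msgs, paste0("unknown propensity scale '",
                             object@scaleName, "'"))
  } else {
    if (length(object@scores) == 0L || is.null(names(object@scores)))
      msgs <- c(msgs, "external predictor needs a named list of scores")
    ok <- vapply(object@scores,
                 function(s) is.numeric(s) && all(s >= 0 & s <= 1), TRUE)
    if (!all(ok))
      msgs <- c(msgs, "external scores must be numeric in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "DisorderPredictor", function(object) {
  if (object@kind == "builtin") {
    cat(sprintf(
      "DisorderPredictor (builtin): scale '%s', window %d, p0 = %g, k = %g\n",
      object@scaleName, object@windowLength, object@p0, object@k))
  } else {
    cat(sprintf("DisorderPredictor (external): scores for %d protein(s)\n",
                length(object@scores)))
  }
})

#' DeltaDSResults: per-SNV disorder-change records
#'
#' A validated container for the per-variant results of the
#' \eqn{\Delta DS = DS_{min} - DS_{maj}} computation. The validity method
#' enforces the defining identity (to 1e-9), the score ranges, and the
#' consistency of the structured/disordered region class with the 0.5 rule
#' applied to the major-allele score.
#'
#' @slot table data.frame with (at least) columns \code{variant_id},
#'   \code{protein_id}, \code{protein_position}, \code{aa_from},
#'   \code{aa_to}, \code{ds_maj}, \code{ds_min}, \code{delta_ds},
#'   \code{region_class}, and optionally \code{gene_id}, \code{maf},
#'   \code{codon_from}, \code{codon_to}, \code{allele_swapped}.
#'
#' @seealso \code{\link{scoreVariants}}, \code{\link{resultsTable}}
#' @export
setClass("DeltaDSResults", representation(table = "data.frame"))

setValidity("DeltaDSResults", function(object) {
  tab <- object@table
  need <- c("variant_id", "protein_id", "protein_position", "aa_from",
            "aa_to", "ds_maj", "ds_min", "delta_ds", "region_class")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  if (nrow(tab) == 0L) return(TRUE)
  msgs <- character(0)
  if (any(tab$ds_maj < 0 | tab$ds_maj > 1) ||
      any(tab$ds_min < 0 | tab$ds_min > 1))
    msgs <- c(msgs, "disorder scores must lie in [0, 1]")
  if (any(abs(tab$delta_ds - (tab$ds_min - tab$ds_maj)) > 1e-9))
    msgs <- c(msgs, "delta_ds must equal ds_min - ds_maj (tol 1e-9)")
  expect <- ifelse(tab$ds_maj > 0.5, "disordered", "structured")
  if (any(tab$region_class != expect))
    msgs <- c(msgs, "region_class inconsistent with the 0.5 rule on ds_maj")
  if ("maf" %in% names(tab)) {
    maf <- tab$maf[!is.na(tab$maf)]
    if (any(maf < 0 | maf > 0.5))
      msgs <- c(msgs, "maf must lie in [0, 0.5]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DeltaDSResults object
#'
#' @param table data.frame of per-variant records; \code{region_class} is
#'   derived from \code{ds_maj} when absent.
#' @return A \code{\linkS4class{DeltaDSResults}} object.
#' @export
DeltaDSResults <- function(table) {
  if (!"region_class" %in% names(table) && nrow(table) > 0L)
    table$region_class <- classifyRegion(table$ds_maj)
  if (!"region_class" %in% names(table))
    table$region_class <- character(0)
  new("DeltaDSResults", table = table)
}

#' @describeIn DeltaDSResults-class Extract the underlying data.frame.
#' @param x A \code{DeltaDSResults} object.
#' @export
setGeneric("resultsTable", function(x) standardGeneric("resultsTable"))

#' @rdname DeltaDSResults-class
#' @export
setMethod("resultsTable", "DeltaDSResults", function(x) x@table)

setMethod("show", "DeltaDSResults", function(object) {
  tab <- object@table
  cat(sprintf("DeltaDSResults with %d variant record(s)\n", nrow(tab)))
  if (nrow(tab) > 0L) {
    cat(sprintf("  delta_ds range: [%.4f, %.4f]; %d disordered / %d structured site(s)\n",
                min(tab$delta_ds), max(tab$delta_ds),
                sum(tab$region_class == "disordered"),
                sum(tab$region_class == "structured")))
    print(head(tab, 5L))
    if (nrow(tab) > 5L) cat("  ...\n")
  }
})

#' SyntheticCohort: a generated exome-like cohort with ground truth
#'
#' Holds everything the pipeline consumes — coding sequences, canonical
#' and isoform protein sequences, a variant table, a genotype dosage
#' matrix, trait answer sheets — plus the generation-time ground truth
#' (true \eqn{\Delta DS}, MAF coupling group, causal flags) that makes
#' every downstream stage verifiable.
#'
#' @slot cds Named character vector of coding sequences (gene ids).
#' @slot proteins Named character vector of protein sequences (protein
#'   ids; canonical id equals the gene id, isoforms are suffixed).
#' @slot proteinMeta data.frame \code{protein_id}, \code{gene_id},
#'   \code{isoform} (logical).
#' @slot variants data.frame \code{variant_id}, \code{gene_id},
#'   \code{cds_position}, \code{ref_base}, \code{alt_base}.
#' @slot genotypes Integer matrix of minor-allele dosages (variants x
#'   individuals), rownames = variant ids.
#' @slot answerSheet data.frame \code{trait}, \code{variant_id},
#'   \code{gene_id}.
#' @slot groundTruth data.frame of per-variant generation-time truth.
#' @slot config The \code{\link{cohortConfig}} list used.
#' @export
setClass("SyntheticCohort",
         representation(cds = "character",
                        proteins = "character",
                        proteinMeta = "data.frame",
                        variants = "data.frame",
                        genotypes = "matrix",
                        answerSheet = "data.frame",
                        groundTruth = "data.frame",
                        config = "list"))

setValidity("SyntheticCohort", function(object) {
  msgs <- character(0)
  if (!all(object@variants$gene_id %in% names(object@cds)))
    msgs <- c(msgs, "every variant's gene must have a CDS")
  if (nrow(object@variants) != nrow(object@genotypes))
    msgs <- c(msgs, "genotype matrix must have one row per variant")
  if (!all(object@answerSheet$variant_id %in% object@variants$variant_id))
    msgs <- c(msgs, "answer-sheet SNVs must be generated variants")
  if (length(msgs)) msgs else TRUE
})

#' @param x,name Slot access helpers (\code{cohort$variants} etc.).
#' @rdname SyntheticCohort-class
#' @export
setMethod("$", "SyntheticCohort", function(x, name) slot(x, name))

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf(paste0(
    "SyntheticCohort: %d gene(s), %d protein sequence(s), %d SNV(s), ",
    "%d individual(s)\n"),
    length(object@cds), length(object@proteins), nrow(object@variants),
    ncol(object@genotypes)))
  mix <- table(object@groundTruth$consequence)
  cat("  consequence mix:",
      paste(names(mix), as.integer(mix), sep = "=", collapse = ", "), "\n")
  cat(sprintf("  answer sheet: %d causal SNV record(s) across %d trait(s)\n",
              nrow(object@answerSheet),
              length(unique(object@answerSheet$trait))))
})
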