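# Residue disorder-propensity scales shipped with the package.
# "topidp" is the TOP-IDP scale of Campen et al. (2008): positive values
# are disorder-promoting (P, E, K the strongest), negative values are
# order-promoting (W, F, Y, I the strongest).
.DISORDER_SCALES <- list(
  topidp = c(A =  0.060, C = -0.020, D =  0.192, E =  0.736, F = -0.697,
             G =  0.166, H =  0.303, I = -0.486, K =  0.586, L = -0.326,
             M = -0.397, N =  0.007, P =  0.987, Q =  0.318, R =  0.180,
             S =  0.341, T =  0.059, V = -0.121, W = -0.884, Y = -0.510)
)

#' Shipped disorder-propensity scale
#'
#' @param name Scale identifier; currently only \code{"topidp"}.
#' @return Named numeric vector of per-residue propensities (20 values;
#'   higher = more disorder-promoting).
#' @export
disorderPropensity <- function(name = "topidp") {
  if (!name %in% names(.DISORDER_SCALES))
    stop("unknown propensity scale '", name, "'")
  .DISORDER_SCALES[[name]]
}

#' Construct the builtin disorder predictor
#'
#' The builtin model averages the shipped residue disorder propensities
#' over a centred window (truncated at sequence ends) and maps the window
#' mean through a monotone sigmoid
#' \deqn{score = 1 / (1 + e^{-k(\bar p - p_0)})}
#' so that every residue receives a score in [0, 1], with 0.5 separating
#' predicted structure from predicted disorder. The default calibration
#' (\code{p0 = 0.05}, \code{k = 8}) places homopolymers of the extreme
#' residues of the scale clearly on either side of 0.5.
#'
#' This is a deterministic, documented stand-in with the same interface
#' and score semantics as trained per-residue predictors; it makes no
#' claim to their accuracy. Real predictor output can be supplied via
#' \code{\link{externalPredictor}}.
#'
#' @param windowLength Odd positive integer window (default 21).
#' @param scale Propensity scale name (see
#'   \code{\link{disorderPropensity}}).
#' @param p0,k Sigmoid midpoint and steepness.
#' @return A \code{\linkS4class{DisorderPredictor}} of kind
#'   \code{"builtin"}.
#' @export
builtinPredictor <- function(windowLength = 21L, scale = "topidp",
                             p0 = 0.05, k = 8) {
  new("DisorderPredictor", kind = "builtin",
      windowLength = as.integer(windowLength), scaleName = scale,
      p0 = p0, k = k, scores = list())
}

#' Construct an external-score disorder predictor
#'
#' Wraps per-residue scores produced by any external predictor so that the
#' downstream pipeline is predictor-agnostic.
#'
#' @param scores Named list (protein id -> numeric vector of per-residue
#'   scores in [0, 1]), e.g. from \code{\link{readScores}}.
#' @return A \code{\linkS4class{DisorderPredictor}} of kind
#'   \code{"external"}.
#' @export
externalPredictor <- function(scores) {
  new("DisorderPredictor", kind = "external",
      windowLength = 1L, scaleName = "external", p0 = 0, k = 1,
      scores = scores)
}

#' Predict per-residue disorder scores
#'
#' @param sequence Amino-acid string over the 20 standard residues.
#' @param predictor A \code{\linkS4class{DisorderPredictor}}; default the
#'   builtin model.
#' @param proteinId Protein identifier; required for external predictors
#'   to look up the right score vector.
#' @return Numeric vector of length \code{nchar(sequence)}, each value in
#'   [0, 1].
#' @examples
#' predictDisorder(strrep("P", 10))   # disorder-promoting homopolymer
#' @export
predictDisorder <- function(sequence, predictor = builtinPredictor(),
                            proteinId = NULL) {
  stopifnot(is(predictor, "DisorderPredictor"))
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  if (L < 1L) stop("sequence must have length >= 1")
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% .AA20)
  if (length(bad))
    stop("non-standard residue '", res[bad[1]], "' at position ", bad[1])
  if (predictor@kind == "external") {
    if (is.null(proteinId))
      stop("external predictor requires a proteinId")
    if (!proteinId %in% names(predictor@scores))
      stop("no external scores for protein '", proteinId, "'")
    sc <- predictor@scores[[proteinId]]
    if (length(sc) != L)
      stop("external scores for '", proteinId, "' have length ",
           length(sc), " but sequence has ", L, " residues")
    return(unname(sc))
  }
  props <- unname(disorderPropensity(predictor@scaleName)[res])
  half <- (predictor@windowLength - 1L) %/% 2L
  # each window sum is computed independently (not via running sums) so
  # that a substitution perturbs scores only inside its own window,
  # bit-for-bit
  pbar <- vapply(seq_len(L), function(i) {
    w <- props[max(1L, i - half):min(L, i + half)]
    sum(w) / length(w)
  }, 0)
  plogis(predictor@k * (pbar - predictor@p0))
}

#' Classify residues as structured or disordered
#'
#' Scores above 0.5 indicate predicted disorder, at or below 0.5 predicted
#' structure. The tie at exactly 0.5 is classed structured, so
#' "disordered" strictly requires a score > 0.5.
#'
#' @param score Numeric vector of disorder scores in [0, 1].
#' @return Character vector, \code{"disordered"} or \code{"structured"}.
#' @export
classifyRegion <- function(score) {
  score <- as.numeric(score)
  if (any(is.na(score) | score < 0 | score > 1))
    stop("disorder scores must lie in [0, 1]")
  ifelse(score > 0.5, "disordered", "structured")
}

#' Compute the disorder-score change of one substitution
#'
#' Builds the minor-allele sequence by substituting \code{minorAA} at
#' \code{position}, re-predicts the disorder profile of both full
#' sequences, and takes the score difference at the substituted residue:
#' \deqn{\Delta DS = DS_{min} - DS_{maj}.}
#' Both alleles are re-predicted in full because per-residue predictors
#' are context-sensitive: the same substitution can score differently in
#' different sequence contexts.
#'
#' @param proteinSeq Major-allele protein sequence.
#' @param position 1-based residue position of the substitution.
#' @param majorAA,minorAA One-letter residues; \code{proteinSeq} must carry
#'   \code{majorAA} at \code{position} (guards against stale mappings).
#' @param predictor A \code{\linkS4class{DisorderPredictor}}.
#' @param proteinId Identifier passed to \code{\link{predictDisorder}}.
#' @param minorScores Per-residue score vector for the minor-allele
#'   sequence; required for external predictors, whose score files are
#'   keyed by sequence identifier rather than by sequence content.
#' @return list with \code{ds_maj}, \code{ds_min}, \code{delta_ds},
#'   \code{region_class}.
#' @export
computeDeltaDS <- function(proteinSeq, position, majorAA, minorAA,
                           predictor = builtinPredictor(),
                           proteinId = NULL, minorScores = NULL) {
  proteinSeq <- toupper(as.character(proteinSeq))
  position <- as.integer(position)
  stopifnot(position >= 1L, position <= nchar(proteinSeq))
  if (substr(proteinSeq, position, position) != majorAA)
    stop("sequence carries '", substr(proteinSeq, position, position),
         "' at position ", position, ", not the declared major allele '",
         majorAA, "'")
  if (!minorAA %in% .AA20)
    stop("minor allele '", minorAA, "' is not a standard residue; ",
         "nonsense changes are excluded from delta-DS analysis")
  majProfile <- predictDisorder(proteinSeq, predictor, proteinId)
  minorSeq <- proteinSeq
  substr(minorSeq, position, position) <- minorAA
  minProfile <- if (!is.null(minorScores)) {
    if (length(minorScores) != nchar(proteinSeq))
      stop("minorScores length mismatch")
    minorScores
  } else if (predictor@kind == "external") {
    stop("external predictors need explicit minorScores per substitution")
  } else {
    predictDisorder(minorSeq, predictor, proteinId)
  }
  dsMaj <- majProfile[position]
  dsMin <- minProfile[position]
  list(ds_maj = dsMaj, ds_min = dsMin, delta_ds = dsMin - dsMaj,
       region_class = classifyRegion(dsMaj))
}

#' Score a table of missense SAPs
#'
#' Runs \code{\link{computeDeltaDS}} over every mapped missense SAP and
#' assembles a \code{\linkS4class{DeltaDSResults}} object. Columns present
#' in \code{saps} (e.g. \code{maf}, \code{gene_id}, codon changes) are
#' carried through.
#'
#' @param saps Missense SAP data.frame (see \code{\link{filterSaps}}),
#'   with columns \code{variant_id}, \code{protein_id},
#'   \code{protein_position}, \code{major_aa}, \code{minor_aa}.
#' @param proteins Named character vector of protein sequences.
#' @param predictor A \code{\linkS4class{DisorderPredictor}}. For external
#'   predictors the score file must additionally hold, for each variant,
#'   the profile of the alternate (non-reference) sequence under the id
#'   \code{<protein_id>|<variant_id>}.
#' @return A \code{\linkS4class{DeltaDSResults}} object.
#' @export
scoreVariants <- function(saps, proteins, predictor = builtinPredictor()) {
  stopifnot(is.data.frame(saps))
  isTRUE_v <- function(x) !is.na(x) & x
  n <- nrow(saps)
  dsMaj <- dsMin <- numeric(n)
  # cache major-allele profiles per protein: they are shared by all SNVs
  # mapped to that protein
  cache <- new.env(parent = emptyenv())
  swapped <- if ("allele_swapped" %in% names(saps))
    isTRUE_v(saps$allele_swapped) else rep(FALSE, n)
  for (i in seq_len(n)) {
    pid <- saps$protein_id[i]
    seq <- proteins[[pid]]
    if (is.null(seq)) stop("no sequence for protein '", pid, "'")
    if (!exists(pid, envir = cache))
      assign(pid, predictDisorder(seq, predictor, pid), envir = cache)
    refProfile <- get(pid, envir = cache)
    pos <- saps$protein_position[i]
    # the supplied sequence carries the reference residue: the major
    # allele normally, the minor one when the alleles were swapped
    carried <- if (swapped[i]) saps$minor_aa[i] else saps$major_aa[i]
    other <- if (swapped[i]) saps$major_aa[i] else saps$minor_aa[i]
    if (substr(seq, pos, pos) != carried)
      stop("stale mapping for variant ", saps$variant_id[i])
    altSeq <- seq
    substr(altSeq, pos, pos) <- other
    altId <- if (predictor@kind == "external")
      paste(pid, saps$variant_id[i], sep = "|") else pid
    dsAlt <- predictDisorder(altSeq, predictor, altId)[pos]
    dsMaj[i] <- if (swapped[i]) dsAlt else refProfile[pos]
    dsMin[i] <- if (swapped[i]) refProfile[pos] else dsAlt
  }
  tab <- data.frame(variant_id = saps$variant_id,
                    protein_id = saps$protein_id,
                    protein_position = saps$protein_position,
                    aa_from = saps$major_aa, aa_to = saps$minor_aa,
                    ds_maj = dsMaj, ds_min = dsMin,
                    delta_ds = dsMin - dsMaj,
                    stringsAsFactors = FALSE)
  for (col in intersect(c("gene_id", "codon_from", "codon_to", "maf",
                          "allele_swapped"), names(saps)))
    tab[[col]] <- saps[[col]]
  if (n == 0L) {
    tab <- data.frame(variant_id = character(0), protein_id = character(0),
                      protein_position = integer(0),
                      aa_from = character(0), aa_to = character(0),
                      ds_maj = numeric(0), ds_min = numeric(0),
                      delta_ds = numeric(0), stringsAsFactors = FALSE)
  }
  DeltaDSResults(tab)
}
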