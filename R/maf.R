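#' Minor allele frequency from genotype dosages
#'
#' The MAF is the frequency of the less frequent allele. Dosages count the
#' declared alternate allele (0/1/2 per individual); when the alternate
#' allele turns out to be the more frequent one, the major/minor roles are
#' swapped and the swap is reported so callers can propagate it to the SAP
#' (the minor allele defines \eqn{DS_{min}}). An exact 50/50 tie keeps the
#' declared reference as major, for determinism.
#'
#' @param dosages Integer vector of alternate-allele dosages in
#'   \{0, 1, 2\}; \code{NA} marks a missing genotype and is excluded from
#'   both numerator and denominator.
#' @return list with \code{maf} (in [0, 0.5]), \code{swapped} (TRUE when
#'   the declared alternate is the major allele), \code{n_missing}.
#' @examples
#' computeMaf(c(0, 0, 1))$maf  # 1/6
#' @export
computeMaf <- function(dosages) {
  dosages <- as.integer(dosages)
  miss <- is.na(dosages)
  d <- dosages[!miss]
  if (length(d) == 0L) stop("all genotypes missing")
  if (any(d < 0L | d > 2L)) stop("dosages must be 0, 1 or 2")
  pAlt <- sum(d) / (2 * length(d))
  swapped <- pAlt > 0.5
  list(maf = if (swapped) 1 - pAlt else pAlt,
       swapped = swapped, n_missing = sum(miss))
}

#' Per-variant MAFs from a dosage matrix
#'
#' @param genotypes Integer matrix, variants in rows (rownames = variant
#'   ids), individuals in columns.
#' @return data.frame \code{variant_id}, \code{maf}, \code{swapped},
#'   \code{n_missing}.
#' @export
computeMafMatrix <- function(genotypes) {
  stopifnot(is.matrix(genotypes), !is.null(rownames(genotypes)))
  rows <- lapply(seq_len(nrow(genotypes)), function(i)
    computeMaf(genotypes[i, ]))
  data.frame(variant_id = rownames(genotypes),
             maf = vapply(rows, `[[`, 0, "maf"),
             swapped = vapply(rows, `[[`, TRUE, "swapped"),
             n_missing = vapply(rows, `[[`, 0L, "n_missing"),
             stringsAsFactors = FALSE)
}

.beyondThreshold <- function(delta, threshold, comparison) {
  if (comparison == "inclusive") abs(delta) >= threshold
  else abs(delta) > threshold
}

#' Partition SNV counts by consequence, delta-DS sign and magnitude
#'
#' Tabulates the variant classes the disorder-change analysis partitions
#' the data into: synonymous and nonsense variants (excluded from delta-DS
#' analysis), and missense variants split by \eqn{\Delta DS} sign, with
#' counts of those beyond the magnitude threshold.
#'
#' @param consequence Character vector of consequence classes per SNV
#'   (\code{"synonymous"}, \code{"missense"}, \code{"nonsense"}).
#' @param deltaDs Numeric \eqn{\Delta DS} per SNV (ignored, may be
#'   \code{NA}, for non-missense records).
#' @param threshold Magnitude threshold (default 0.04).
#' @param comparison \code{"inclusive"} (\code{>=}, default) or
#'   \code{"strict"} (\code{>}).
#' @return list of counts: \code{synonymous}, \code{nonsense},
#'   \code{missense_total}, \code{missense_pos}, \code{missense_neg},
#'   \code{missense_zero}, \code{pos_beyond}, \code{neg_beyond},
#'   \code{fraction_beyond} (of missense), plus the threshold/comparison
#'   used.
#' @export
partitionCounts <- function(consequence, deltaDs, threshold = 0.04,
                            comparison = c("inclusive", "strict")) {
  comparison <- match.arg(comparison)
  stopifnot(length(consequence) == length(deltaDs), threshold >= 0)
  mis <- consequence == "missense"
  d <- deltaDs[mis]
  beyond <- .beyondThreshold(d, threshold, comparison)
  nMis <- sum(mis)
  list(synonymous = sum(consequence == "synonymous"),
       nonsense = sum(consequence == "nonsense"),
       missense_total = nMis,
       missense_pos = sum(d > 0),
       missense_neg = sum(d < 0),
       missense_zero = sum(d == 0),
       pos_beyond = sum(d > 0 & beyond),
       neg_beyond = sum(d < 0 & beyond),
       fraction_beyond = if (nMis > 0) sum(beyond) / nMis else NA_real_,
       threshold = threshold, comparison = comparison)
}

#' Compare MAFs between positive- and negative-delta-DS variants
#'
#' Under purifying selection, variants that strongly perturb the
#' structure/disorder balance should segregate at lower frequencies. This
#' compares the MAF distributions of the \eqn{+\Delta DS} and
#' \eqn{-\Delta DS} missense groups, restricted to variants beyond (or
#' within) the magnitude threshold. The default test is the two-sided
#' Wilcoxon rank-sum test, robust to the heavy right skew of rare-variant
#' MAF spectra; a Welch t-test is available for sensitivity analysis.
#'
#' @param deltaDs Numeric \eqn{\Delta DS} per missense SNV.
#' @param maf Numeric MAF per SNV, in [0, 0.5].
#' @param threshold,comparison As \code{\link{partitionCounts}}.
#' @param mode \code{"beyond"} (default) restricts both groups to
#'   \code{|delta| } beyond the threshold; \code{"within"} to below it.
#' @param test \code{"ranksum"} (default) or \code{"ttest"}.
#' @return list: \code{group_pos} and \code{group_neg} (each with \code{n}
#'   and \code{mean_maf}), \code{statistic}, \code{p_value},
#'   \code{test_name}, \code{stars} (significance marker, \code{"***"}
#'   for p < 0.001), and the threshold/comparison/mode used.
#' @export
compareMafGroups <- function(deltaDs, maf, threshold = 0.04,
                             comparison = c("inclusive", "strict"),
                             mode = c("beyond", "within"),
                             test = c("ranksum", "ttest")) {
  comparison <- match.arg(comparison)
  mode <- match.arg(mode)
  test <- match.arg(test)
  stopifnot(length(deltaDs) == length(maf))
  ok <- !is.na(deltaDs) & !is.na(maf)
  deltaDs <- deltaDs[ok]; maf <- maf[ok]
  if (any(maf < 0 | maf > 0.5)) stop("MAFs must lie in [0, 0.5]")
  beyond <- .beyondThreshold(deltaDs, threshold, comparison)
  sel <- if (mode == "beyond") beyond else !beyond
  pos <- maf[sel & deltaDs > 0]
  neg <- maf[sel & deltaDs < 0]
  if (length(pos) == 0L)
    stop("positive-delta-DS group is empty (mode '", mode, "')")
  if (length(neg) == 0L)
    stop("negative-delta-DS group is empty (mode '", mode, "')")
  ht <- if (test == "ranksum") {
    wilcox.test(pos, neg, exact = FALSE)
  } else {
    t.test(pos, neg)
  }
  p <- ht$p.value
  stars <- if (is.na(p)) "" else if (p < 0.001) "***"
           else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
  list(group_pos = list(n = length(pos), mean_maf = mean(pos)),
       group_neg = list(n = length(neg), mean_maf = mean(neg)),
       statistic = unname(ht$statistic), p_value = p,
       test_name = if (test == "ranksum") "wilcoxon_rank_sum"
                   else "welch_t",
       stars = stars, threshold = threshold, comparison = comparison,
       mode = mode)
}
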