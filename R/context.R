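# Pairwise |delta-DS| shifts within groups of results.
# `values` numeric, `group` factor-like, `unit` optional second key that
# must differ within a pair (e.g. protein id for cross-protein pairs).
.pairShifts <- function(values, group, unit = NULL) {
  groups <- split(seq_along(values), group)
  rows <- list()
  skipped <- 0L
  for (idx in groups) {
    if (length(idx) < 2L) { skipped <- skipped + 1L; next }
    cmb <- utils::combn(idx, 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      if (!is.null(unit) && unit[a] == unit[b]) next
      rows[[length(rows) + 1L]] <- c(values[a], values[b])
    }
  }
  list(pairs = if (length(rows)) do.call(rbind, rows)
               else matrix(numeric(0), ncol = 2L),
       n_groups_skipped = skipped)
}

.shiftSummary <- function(pairs, nSkipped, binWidth) {
  n <- nrow(pairs)
  if (n == 0L) {
    return(list(n_pairs = 0L, n_groups_skipped = nSkipped,
                mean_abs_shift = NA_real_, median_abs_shift = NA_real_,
                modal_bin = NULL, sign_flip_fraction = NA_real_,
                n_zero_involved_pairs = 0L))
  }
  shift <- abs(pairs[, 1] - pairs[, 2])
  zeroInvolved <- pairs[, 1] == 0 | pairs[, 2] == 0
  bothNonzero <- !zeroInvolved
  # sign flips are assessed only among pairs of two nonzero values;
  # pairs involving an exact zero are tallied separately so they cannot
  # inflate the flip rate
  flips <- sign(pairs[bothNonzero, 1]) != sign(pairs[bothNonzero, 2])
  bins <- floor(shift / binWidth)
  modal <- as.integer(names(which.max(table(bins))))
  list(n_pairs = n,
       n_groups_skipped = nSkipped,
       mean_abs_shift = mean(shift),
       median_abs_shift = median(shift),
       modal_bin = list(left = modal * binWidth,
                        right = (modal + 1L) * binWidth,
                        count = sum(bins == modal)),
       sign_flip_fraction = if (any(bothNonzero)) mean(flips) else NA_real_,
       n_zero_involved_pairs = sum(zeroInvolved))
}

#' Isoform-context shift distribution of delta-DS values
#'
#' For each SNV mapped into two or more isoforms of its gene, every
#' unordered pair of isoform-level \eqn{\Delta DS} values contributes one
#' absolute shift \eqn{|\Delta DS_a - \Delta DS_b|} and one sign-flip
#' indicator. Because isoforms of a gene share most of their sequence,
#' these shifts measure the mildest form of sequence-context dependence.
#'
#' @param results A \code{\linkS4class{DeltaDSResults}} object or its
#'   data.frame, with one row per (variant, isoform) pair.
#' @param binWidth Histogram bin width used to locate the modal
#'   \code{|shift|} bin (default 0.001). The mean and median are reported
#'   alongside so nothing rests on the binning.
#' @return list: \code{n_pairs}, \code{n_groups_skipped} (SNVs seen in a
#'   single isoform only), \code{mean_abs_shift}, \code{median_abs_shift},
#'   \code{modal_bin} (left/right/count), \code{sign_flip_fraction}
#'   (among pairs of two nonzero values), \code{n_zero_involved_pairs}.
#' @export
isoformShiftDistribution <- function(results, binWidth = 0.001) {
  tab <- if (is(results, "DeltaDSResults")) resultsTable(results) else results
  ps <- .pairShifts(tab$delta_ds, tab$variant_id)
  .shiftSummary(ps$pairs, ps$n_groups_skipped, binWidth)
}

#' Cross-protein shift distribution for the same substitution
#'
#' Pairs \eqn{\Delta DS} values of the same amino-acid substitution
#' observed in distinct proteins. Unrelated proteins provide unrelated
#' sequence contexts, so this distribution is expected to be much broader
#' than the isoform-based one.
#'
#' @inheritParams isoformShiftDistribution
#' @return As \code{\link{isoformShiftDistribution}}; pairs within the
#'   same protein are excluded.
#' @export
crossProteinShiftDistribution <- function(results, binWidth = 0.001) {
  tab <- if (is(results, "DeltaDSResults")) resultsTable(results) else results
  key <- paste(tab$aa_from, tab$aa_to, sep = ">")
  ps <- .pairShifts(tab$delta_ds, key, unit = tab$protein_id)
  .shiftSummary(ps$pairs, ps$n_groups_skipped, binWidth)
}

#' Per-substitution-class summary of delta-DS values
#'
#' Groups results by amino-acid substitution (or by realising codon
#' change) and reports n, mean and sample standard deviation of
#' \eqn{\Delta DS} — the machinery behind ranked top-positive /
#' top-negative substitution tables.
#'
#' @inheritParams isoformShiftDistribution
#' @param by \code{"aa"} (default) to group by amino-acid substitution, or
#'   \code{"codon"} to group by codon change (requires \code{codon_from} /
#'   \code{codon_to} columns).
#' @param topK When > 0, also return the top-\code{topK} classes by mean
#'   \eqn{\Delta DS}: positives sorted descending, negatives ascending.
#' @return list with \code{table} (substitution, n, mean_delta_ds,
#'   std_delta_ds; STD is \code{NA} for singletons) and, when requested,
#'   \code{top_positive} / \code{top_negative}.
#' @export
substitutionClassTable <- function(results, by = c("aa", "codon"),
                                   topK = 0L) {
  by <- match.arg(by)
  tab <- if (is(results, "DeltaDSResults")) resultsTable(results) else results
  key <- if (by == "aa") {
    paste(tab$aa_from, tab$aa_to, sep = ">")
  } else {
    if (!all(c("codon_from", "codon_to") %in% names(tab)))
      stop("codon-level grouping needs codon_from/codon_to columns")
    paste(tab$codon_from, tab$codon_to, sep = ">")
  }
  groups <- split(tab$delta_ds, key)
  out <- data.frame(substitution = names(groups),
                    n = vapply(groups, length, 0L),
                    mean_delta_ds = vapply(groups, mean, 0),
                    std_delta_ds = vapply(groups, function(v)
                      if (length(v) >= 2L) sd(v) else NA_real_, 0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  res <- list(table = out)
  if (topK > 0L) {
    pos <- out[out$mean_delta_ds > 0, ]
    neg <- out[out$mean_delta_ds < 0, ]
    res$top_positive <- head(pos[order(-pos$mean_delta_ds), ], topK)
    res$top_negative <- head(neg[order(neg$mean_delta_ds), ], topK)
    rownames(res$top_positive) <- rownames(res$top_negative) <- NULL
  }
  res
}
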