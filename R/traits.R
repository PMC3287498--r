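#' Intersect high-impact SNVs with a trait answer sheet
#'
#' Restricts scored variants to the genes simulated as causal for a trait,
#' keeps those whose \eqn{|\Delta DS|} lies beyond the magnitude
#' threshold, and flags which of them are themselves listed as causal
#' SNVs. This validates overlap against a known answer key; it performs no
#' association testing.
#'
#' @param results A \code{\linkS4class{DeltaDSResults}} object or its
#'   data.frame; rows must carry \code{gene_id}, \code{delta_ds},
#'   \code{ds_maj}.
#' @param sheet Answer-sheet data.frame with columns \code{trait},
#'   \code{variant_id}, \code{gene_id}; may hold several traits.
#' @param threshold,comparison Magnitude threshold on
#'   \eqn{|\Delta DS|} (default 0.04, inclusive).
#' @return list with
#'   \describe{
#'     \item{summary}{one row per trait: \code{trait}, \code{n_genes},
#'       \code{n_high_delta_in_genes}, \code{n_high_delta_in_sheet},
#'       \code{n_sheet_snvs}, \code{n_unknown_genes} (sheet genes absent
#'       from the results).}
#'     \item{details}{one row per high-\eqn{|\Delta DS|} SNV in a causal
#'       gene: \code{trait}, \code{variant_id}, \code{gene_id},
#'       \code{aa_change}, \code{delta_ds}, \code{ds_maj},
#'       \code{region_class}, \code{in_answer_sheet}; sorted by trait then
#'       \eqn{|\Delta DS|} descending.}
#'   }
#' @export
intersectTrait <- function(results, sheet, threshold = 0.04,
                           comparison = c("inclusive", "strict")) {
  comparison <- match.arg(comparison)
  tab <- if (is(results, "DeltaDSResults")) resultsTable(results) else results
  stopifnot(all(c("gene_id", "delta_ds", "ds_maj") %in% names(tab)),
            all(c("trait", "variant_id", "gene_id") %in% names(sheet)))
  # deduplicate: set semantics for both inputs
  tab <- tab[!duplicated(tab$variant_id), , drop = FALSE]
  sheet <- unique(sheet[, c("trait", "variant_id", "gene_id")])
  beyond <- .beyondThreshold(tab$delta_ds, threshold, comparison)
  summaries <- list(); details <- list()
  for (tr in unique(sheet$trait)) {
    sh <- sheet[sheet$trait == tr, ]
    genes <- unique(sh$gene_id)
    unknown <- setdiff(genes, unique(tab$gene_id))
    if (length(unknown))
      warning("trait ", tr, ": ", length(unknown),
              " answer-sheet gene(s) absent from results")
    hit <- tab$gene_id %in% genes & beyond
    rows <- tab[hit, , drop = FALSE]
    inSheet <- rows$variant_id %in% sh$variant_id
    det <- data.frame(trait = rep(tr, nrow(rows)),
                      variant_id = rows$variant_id,
                      gene_id = rows$gene_id,
                      aa_change = paste(rows$aa_from, rows$aa_to,
                                        sep = ">"),
                      delta_ds = rows$delta_ds, ds_maj = rows$ds_maj,
                      region_class = rows$region_class,
                      in_answer_sheet = inSheet,
                      stringsAsFactors = FALSE)
    det <- det[order(-abs(det$delta_ds)), , drop = FALSE]
    details[[tr]] <- det
    summaries[[tr]] <- data.frame(
      trait = tr, n_genes = length(genes),
      n_high_delta_in_genes = nrow(det),
      n_high_delta_in_sheet = sum(inSheet),
      n_sheet_snvs = nrow(sh),
      n_unknown_genes = length(unknown),
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summaries)
  details <- do.call(rbind, details)
  rownames(summary) <- rownames(details) <- NULL
  list(summary = summary, details = details)
}

#' Cross-tabulate delta-DS sign against the major-allele region class
#'
#' A positive \eqn{\Delta DS} in a region predicted to be structured
#' (major-allele score <= 0.5) marks potential destabilisation of a folded
#' region — the putative-destabilising class; a negative \eqn{\Delta DS}
#' in a predicted disordered region marks a disorder-to-structure shift.
#' Rows with \eqn{\Delta DS = 0} belong to no sign class and are counted
#' separately.
#'
#' @param rows data.frame with columns \code{delta_ds} and \code{ds_maj}
#'   (e.g. the \code{details} component of \code{\link{intersectTrait}}).
#' @return list of counts: \code{pos_structured} (flagged putative
#'   destabilising), \code{neg_structured}, \code{pos_disordered},
#'   \code{neg_disordered}, \code{zero_delta}.
#' @export
destabilizationProfile <- function(rows) {
  stopifnot(all(c("delta_ds", "ds_maj") %in% names(rows)))
  region <- classifyRegion(rows$ds_maj)
  pos <- rows$delta_ds > 0
  neg <- rows$delta_ds < 0
  list(pos_structured = sum(pos & region == "structured"),
       neg_structured = sum(neg & region == "structured"),
       pos_disordered = sum(pos & region == "disordered"),
       neg_disordered = sum(neg & region == "disordered"),
       zero_delta = sum(rows$delta_ds == 0))
}
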