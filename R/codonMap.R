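#' Translate a codon under the standard genetic code
#'
#' @param codon Character vector of codons, each exactly three bases over
#'   \code{A,C,G,T} (case-insensitive). Ambiguous IUPAC letters are
#'   rejected: the variant model is biallelic SNVs, so every codon must be
#'   fully resolved.
#'
#' @return Character vector of one-letter amino acids, with \code{"*"} for
#'   the three stop codons.
#'
#' @examples
#' translateCodon(c("ATG", "TGG", "TAA"))
#' @export
translateCodon <- function(codon) {
  codon <- toupper(as.character(codon))
  bad <- nchar(codon) != 3L | !grepl("^[ACGT]{3}$", codon)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "),
         " (need exactly 3 bases over A/C/G/T)")
  }
  unname(geneticCode()[codon])
}

# Standard genetic code as a named character vector (codon -> AA, "*" = stop).
geneticCode <- function() {
  Biostrings::GENETIC_CODE
}

# The 61 sense codons.
senseCodons <- function() {
  gc <- geneticCode()
  names(gc)[gc != STOP_CHAR]
}

# Codons encoding each amino acid, as a named list.
codonsByAA <- function() {
  gc <- geneticCode()
  split(names(gc), unname(gc))
}

#' Enumerate the full nonsynonymous substitution space
#'
#' All ordered pairs of distinct standard amino acids, irrespective of
#' whether a single nucleotide change can realise them. There are
#' \eqn{20 \times 19 = 380} such pairs.
#'
#' @return A data.frame with columns \code{aa_from}, \code{aa_to}
#'   (380 rows).
#' @seealso \code{\link{enumerateSingleBaseChanges}} for the subset
#'   reachable by one base change within a codon.
#' @export
enumerateAllNonsynChanges <- function() {
  grid <- expand.grid(aa_to = .AA20, aa_from = .AA20,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$aa_from != grid$aa_to, c("aa_from", "aa_to")]
  rownames(grid) <- NULL
  grid
}

#' Enumerate amino-acid substitutions reachable by one base change
#'
#' Scans the 9 single-base neighbours of each of the 61 sense codons and
#' keeps the pairs in which both codons are sense codons and their
#' translations differ. The genetic code restricts the 380-pair full
#' substitution space to 150 distinct substitution types; each type may be
#' realised by one or more codon changes.
#'
#' @return A list with components:
#'   \describe{
#'     \item{substitutions}{data.frame \code{aa_from}, \code{aa_to},
#'       \code{n_codon_changes} — the 150 distinct substitution types.}
#'     \item{codonChanges}{data.frame \code{codon_from}, \code{codon_to},
#'       \code{position_in_codon}, \code{aa_from}, \code{aa_to} — every
#'       realising single-base codon change (the multimap).}
#'   }
#' @examples
#' sb <- enumerateSingleBaseChanges()
#' nrow(sb$substitutions)  # 150
#' subset(sb$codonChanges, aa_from == "W" & aa_to == "R")
#' @export
enumerateSingleBaseChanges <- function() {
  gc <- geneticCode()
  sense <- senseCodons()
  rows <- vector("list", length(sense) * 9L)
  k <- 0L
  for (cd in sense) {
    aaFrom <- gc[[cd]]
    for (p in 1:3) {
      ref <- substr(cd, p, p)
      for (b in .BASES[.BASES != ref]) {
        alt <- cd
        substr(alt, p, p) <- b
        aaTo <- gc[[alt]]
        if (aaTo == STOP_CHAR || aaTo == aaFrom) next
        k <- k + 1L
        rows[[k]] <- data.frame(codon_from = cd, codon_to = alt,
                                position_in_codon = p,
                                aa_from = aaFrom, aa_to = aaTo,
                                stringsAsFactors = FALSE)
      }
    }
  }
  changes <- do.call(rbind, rows[seq_len(k)])
  key <- paste(changes$aa_from, changes$aa_to)
  tab <- table(key)
  subs <- unique(changes[, c("aa_from", "aa_to")])
  subs <- subs[order(subs$aa_from, subs$aa_to), ]
  rownames(subs) <- NULL
  subs$n_codon_changes <- as.integer(tab[paste(subs$aa_from, subs$aa_to)])
  list(substitutions = subs, codonChanges = changes)
}

#' Report on the substitution space accessible to single base changes
#'
#' Convenience wrapper around \code{\link{enumerateAllNonsynChanges}} and
#' \code{\link{enumerateSingleBaseChanges}} that returns both cardinalities
#' and optionally writes the substitution-to-codon-change multimap to a
#' tab-separated file.
#'
#' @param path Optional path of a TSV file to write the codon-change
#'   multimap to.
#' @return A list with \code{n_all_nonsynonymous},
#'   \code{n_single_base_accessible}, \code{n_codon_changes} and the
#'   \code{codonChanges} data.frame.
#' @export
substitutionSpaceReport <- function(path = NULL) {
  all380 <- enumerateAllNonsynChanges()
  sb <- enumerateSingleBaseChanges()
  if (!is.null(path)) {
    writeTsv(sb$codonChanges, path)
  }
  list(n_all_nonsynonymous = nrow(all380),
       n_single_base_accessible = nrow(sb$substitutions),
       n_codon_changes = nrow(sb$codonChanges),
       codonChanges = sb$codonChanges)
}

# Translate one reading frame of a nucleotide string into codons + AAs.
# offset is 0..2; returns list(codons, aa) or NULL when no complete codon.
.frameTranslation <- function(seq, offset) {
  L <- nchar(seq)
  ncod <- (L - offset) %/% 3L
  if (ncod < 1L) return(NULL)
  starts <- offset + 3L * (seq_len(ncod) - 1L) + 1L
  codons <- substring(seq, starts, starts + 2L)
  list(codons = codons, aa = unname(geneticCode()[codons]))
}

#' Map a nucleotide variant onto a protein sequence
#'
#' Finds the reading frame and offset under which the translated coding
#' sequence contains the supplied protein as an exact, contiguous match
#' (the contiguity of the match enforces that matched residues appear in
#' the same sequential order in both sequences), then converts the
#' CDS-relative variant position into a protein position and classifies
#' the consequence. Frames 1-3 of the forward strand are searched by
#' default; set \code{searchReverse = TRUE} to also search the
#' reverse-complement frames.
#'
#' The mapping is reported as unmapped (with a reason code) when the
#' declared reference base disagrees with the coding sequence
#' (\code{"ref_mismatch"}), when no frame/offset matches
#' (\code{"no_match"}), when more than one distinct mapping is consistent
#' (\code{"ambiguous"}), or when the variant codon lies outside the
#' matched protein, e.g. in the stop codon (\code{"outside_protein"}).
#'
#' @param codingSeq Nucleotide string (A/C/G/T) holding the CDS.
#' @param proteinSeq Amino-acid string (standard 20 letters).
#' @param cdsPosition 1-based position of the variant within
#'   \code{codingSeq}.
#' @param refBase,altBase Single reference/alternate bases; must differ.
#' @param searchReverse Also search reverse-complement frames.
#'
#' @return A one-row data.frame with columns \code{mapped}, \code{reason},
#'   \code{protein_position}, \code{position_in_codon}, \code{codon_from},
#'   \code{codon_to}, \code{major_aa}, \code{minor_aa}, \code{consequence}.
#'   For unmapped variants all mapping columns are \code{NA}.
#'
#' @examples
#' mapVariantToProtein("ATGTGGGAA", "MWE", 4, "T", "A")  # W -> R missense
#' @export
mapVariantToProtein <- function(codingSeq, proteinSeq, cdsPosition,
                                refBase, altBase, searchReverse = FALSE) {
  codingSeq <- toupper(as.character(codingSeq))
  proteinSeq <- toupper(as.character(proteinSeq))
  refBase <- toupper(refBase); altBase <- toupper(altBase)
  stopifnot(nchar(codingSeq) > 0L, nchar(proteinSeq) > 0L)
  if (!grepl("^[ACGT]+$", codingSeq))
    stop("coding sequence contains non-A/C/G/T characters")
  if (!grepl(sprintf("^[%s]+$", paste(.AA20, collapse = "")), proteinSeq))
    stop("protein sequence contains non-standard residues")
  if (refBase == altBase) stop("ref_base and alt_base must differ")
  if (!refBase %in% .BASES || !altBase %in% .BASES)
    stop("ref/alt bases must be one of A/C/G/T")
  L <- nchar(codingSeq)
  cdsPosition <- as.integer(cdsPosition)
  if (is.na(cdsPosition) || cdsPosition < 1L || cdsPosition > L)
    stop("cds_position ", cdsPosition, " outside sequence bounds [1, ", L, "]")

  unmapped <- function(reason) {
    data.frame(mapped = FALSE, reason = reason,
               protein_position = NA_integer_,
               position_in_codon = NA_integer_,
               codon_from = NA_character_, codon_to = NA_character_,
               major_aa = NA_character_, minor_aa = NA_character_,
               consequence = NA_character_, stringsAsFactors = FALSE)
  }

  if (substr(codingSeq, cdsPosition, cdsPosition) != refBase)
    return(unmapped("ref_mismatch"))

  strands <- list(list(seq = codingSeq, pos = cdsPosition,
                       ref = refBase, alt = altBase))
  if (isTRUE(searchReverse)) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", codingSeq), "")[[1]]),
                collapse = "")
    strands[[2]] <- list(seq = rc, pos = L - cdsPosition + 1L,
                         ref = comp[[refBase]], alt = comp[[altBase]])
  }

  candidates <- list()
  for (st in strands) {
    for (offset in 0:2) {
      tr <- .frameTranslation(st$seq, offset)
      if (is.null(tr)) next
      trans <- paste(tr$aa, collapse = "")
      # lookahead so repeated segments give every (overlapping) match
      hits <- gregexpr(paste0("(?=", proteinSeq, ")"), trans,
                       perl = TRUE)[[1]]
      if (hits[1] == -1L) next
      # codon index of the variant in this frame, if it falls on a
      # complete codon
      rel <- st$pos - offset
      if (rel < 1L) next
      ci <- (rel - 1L) %/% 3L + 1L
      if (ci > length(tr$codons)) next
      pic <- (rel - 1L) %% 3L + 1L
      for (h in as.integer(hits)) {
        pp <- ci - h + 1L
        cand <- if (pp >= 1L && pp <= nchar(proteinSeq)) {
          list(pp = pp, pic = pic, codon = tr$codons[ci], inside = TRUE)
        } else {
          list(pp = NA_integer_, pic = pic, codon = tr$codons[ci],
               inside = FALSE)
        }
        candidates[[length(candidates) + 1L]] <- c(cand, list(st = st))
      }
    }
  }

  if (length(candidates) == 0L) return(unmapped("no_match"))
  inside <- Filter(function(x) x$inside, candidates)
  if (length(inside) == 0L) return(unmapped("outside_protein"))
  keys <- vapply(inside, function(x) paste(x$pp, x$pic, x$codon), "")
  if (length(unique(keys)) > 1L) return(unmapped("ambiguous"))
  hit <- inside[[1]]

  codonFrom <- hit$codon
  codonTo <- codonFrom
  substr(codonTo, hit$pic, hit$pic) <- hit$st$alt
  majorAA <- translateCodon(codonFrom)
  minorAA <- unname(geneticCode()[codonTo])
  stopifnot(substr(proteinSeq, hit$pp, hit$pp) == majorAA)
  consequence <- if (minorAA == majorAA) "synonymous"
                 else if (minorAA == STOP_CHAR) "nonsense"
                 else "missense"
  data.frame(mapped = TRUE, reason = NA_character_,
             protein_position = hit$pp, position_in_codon = hit$pic,
             codon_from = codonFrom, codon_to = codonTo,
             major_aa = majorAA, minor_aa = minorAA,
             consequence = consequence, stringsAsFactors = FALSE)
}

#' Map a variant table onto proteins
#'
#' Applies \code{\link{mapVariantToProtein}} to every variant against every
#' protein recorded for the variant's gene, producing one row per
#' (variant, protein) pair — the per-isoform mapping used by the
#' context-dependence analysis. Unmapped pairs are retained with their
#' reason code so that nothing is silently dropped.
#'
#' @param variants data.frame with columns \code{variant_id},
#'   \code{gene_id}, \code{cds_position}, \code{ref_base}, \code{alt_base}
#'   (extra columns such as \code{maf} are carried through).
#' @param cds Named character vector of coding sequences (names =
#'   gene ids).
#' @param proteins Named character vector of protein sequences (names =
#'   protein ids).
#' @param proteinGenes data.frame \code{protein_id}, \code{gene_id} linking
#'   proteins to genes; by default protein ids are assumed to equal gene
#'   ids.
#' @param searchReverse Passed to \code{\link{mapVariantToProtein}}.
#'
#' @return data.frame of SAP (single amino-acid polymorphism) records:
#'   variant columns plus \code{protein_id}, \code{mapped}, \code{reason},
#'   \code{protein_position}, \code{position_in_codon}, \code{codon_from},
#'   \code{codon_to}, \code{major_aa}, \code{minor_aa}, \code{consequence}.
#' @export
mapVariants <- function(variants, cds, proteins, proteinGenes = NULL,
                        searchReverse = FALSE) {
  stopifnot(is.data.frame(variants),
            all(c("variant_id", "gene_id", "cds_position",
                  "ref_base", "alt_base") %in% names(variants)))
  if (is.null(proteinGenes)) {
    proteinGenes <- data.frame(protein_id = names(proteins),
                               gene_id = names(proteins),
                               stringsAsFactors = FALSE)
  }
  out <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (!v$gene_id %in% names(cds))
      stop("gene ", v$gene_id, " (variant ", v$variant_id,
           ") has no coding sequence")
    pids <- proteinGenes$protein_id[proteinGenes$gene_id == v$gene_id]
    if (length(pids) == 0L)
      stop("gene ", v$gene_id, " has no protein records")
    maps <- lapply(pids, function(pid) {
      m <- mapVariantToProtein(cds[[v$gene_id]], proteins[[pid]],
                               v$cds_position, v$ref_base, v$alt_base,
                               searchReverse = searchReverse)
      cbind(v, protein_id = pid, m, row.names = NULL)
    })
    out[[i]] <- do.call(rbind, maps)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter mapped SAPs to missense and tally exclusions
#'
#' Synonymous variants cannot change the disorder score of the encoded
#' residue and nonsense variants truncate the protein, so both classes are
#' excluded from the disorder-change analysis; the tally preserves how many
#' of each were dropped.
#'
#' @param saps SAP data.frame from \code{\link{mapVariants}}.
#' @return list with \code{missense} (the retained rows) and
#'   \code{excluded} (named integer counts for synonymous, nonsense and
#'   unmapped records).
#' @export
filterSaps <- function(saps) {
  stopifnot(is.data.frame(saps), "consequence" %in% names(saps))
  unmappedN <- sum(!saps$mapped)
  mapped <- saps[saps$mapped, , drop = FALSE]
  counts <- c(synonymous = sum(mapped$consequence == "synonymous"),
              nonsense = sum(mapped$consequence == "nonsense"),
              unmapped = unmappedN)
  list(missense = mapped[mapped$consequence == "missense", , drop = FALSE],
       excluded = counts)
}
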