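# All tabular outputs are TSV: UTF-8, Unix newlines, mandatory header.
writeTsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", eol = "\n")
  invisible(path)
}

readTsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

# Full-precision formatting for scores so that write -> read is exact.
.num17 <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)

#' Read a FASTA file
#'
#' Thin, validating wrapper over Biostrings' FASTA reader. Record ids are
#' the first whitespace-delimited token of the header; sequences are
#' uppercased on read.
#'
#' @param path FASTA file path.
#' @param type \code{"protein"} or \code{"dna"}; controls alphabet
#'   validation.
#' @return Named character vector of sequences.
#' @export
readFastaFile <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  alphabet <- if (type == "dna") "^[ACGT]+$"
              else sprintf("^[%s]+$", paste(.AA20, collapse = ""))
  for (i in seq_along(seqs)) {
    if (!grepl(alphabet, seqs[i])) {
      badPos <- regexpr(if (type == "dna") "[^ACGT]"
                        else sprintf("[^%s]", paste(.AA20, collapse = "")),
                        seqs[i])
      stop("invalid character in record '", ids[i], "' at position ",
           as.integer(badPos), " (", type, " mode)")
    }
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
writeFastaFile <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a variant table
#'
#' Canonical tab-separated variant format: header row with columns
#' \code{variant_id}, \code{gene_id}, \code{cds_position},
#' \code{ref_base}, \code{alt_base}, followed either by a \code{maf}
#' column or by per-individual genotype dosage columns (0/1/2, \code{NA}
#' for missing).
#'
#' @param path TSV path.
#' @param mode \code{"auto"} (default; inferred from the columns),
#'   \code{"maf"} or \code{"genotypes"}.
#' @return list with \code{variants} (data.frame) and \code{genotypes}
#'   (integer matrix or \code{NULL}).
#' @export
readVariants <- function(path, mode = c("auto", "maf", "genotypes")) {
  mode <- match.arg(mode)
  df <- readTsv(path)
  need <- c("variant_id", "gene_id", "cds_position", "ref_base",
            "alt_base")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("variant file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$variant_id)) {
    dup <- which(duplicated(df$variant_id))[1]
    stop("duplicated variant_id '", df$variant_id[dup], "' at row ", dup)
  }
  badBase <- which(!(df$ref_base %in% .BASES & df$alt_base %in% .BASES &
                       df$ref_base != df$alt_base))
  if (length(badBase))
    stop("invalid ref/alt bases at row ", badBase[1])
  hasMaf <- "maf" %in% names(df)
  genoCols <- setdiff(names(df), c(need, "maf"))
  if (mode == "auto") mode <- if (hasMaf) "maf" else "genotypes"
  genotypes <- NULL
  if (mode == "maf") {
    if (!hasMaf) stop("maf mode requested but no maf column present")
    bad <- which(is.na(df$maf) | df$maf < 0 | df$maf > 0.5)
    if (length(bad))
      stop("maf outside [0, 0.5] at row ", bad[1])
  } else {
    if (length(genoCols) == 0L)
      stop("genotype mode requested but no dosage columns present")
    genotypes <- as.matrix(df[, genoCols, drop = FALSE])
    storage.mode(genotypes) <- "integer"
    bad <- which(!(is.na(genotypes) | genotypes %in% 0:2), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop("invalid dosage value at row ", bad[1, 1],
           " (individual column '", genoCols[bad[1, 2]], "')")
    rownames(genotypes) <- df$variant_id
  }
  list(variants = df[, c(need, if (hasMaf) "maf")], genotypes = genotypes)
}

#' Write a variant table
#'
#' @param variants Variant data.frame (see \code{\link{readVariants}}).
#' @param path Output TSV path.
#' @param genotypes Optional dosage matrix (variants x individuals) to
#'   append as genotype columns.
#' @export
writeVariants <- function(variants, path, genotypes = NULL) {
  df <- variants
  if (!is.null(genotypes)) {
    stopifnot(nrow(genotypes) == nrow(variants))
    df <- cbind(df, as.data.frame(genotypes))
  }
  writeTsv(df, path)
}

#' Read per-residue disorder scores from an external predictor
#'
#' Adapter for score files produced by any per-residue predictor. One file
#' may hold many proteins; each protein's rows must cover positions
#' \code{1..L} contiguously with scores in [0, 1].
#'
#' @param path TSV with columns \code{protein_id}, \code{position},
#'   \code{residue}, \code{score}.
#' @param proteins Optional named character vector of sequences; when
#'   given, the residue column is cross-checked against them.
#' @return Named list of numeric score vectors (one per protein),
#'   suitable for \code{\link{externalPredictor}}.
#' @export
readScores <- function(path, proteins = NULL) {
  df <- readTsv(path)
  need <- c("protein_id", "position", "residue", "score")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("score file lacks column(s): ", paste(missing, collapse = ", "))
  bad <- which(is.na(df$score) | df$score < 0 | df$score > 1)
  if (length(bad))
    stop("score outside [0, 1] for protein '", df$protein_id[bad[1]],
         "' position ", df$position[bad[1]])
  out <- list()
  for (pid in unique(df$protein_id)) {
    sub <- df[df$protein_id == pid, ]
    sub <- sub[order(sub$position), ]
    expect <- seq_len(max(sub$position))
    if (!identical(as.integer(sub$position), expect)) {
      gap <- setdiff(expect, sub$position)
      stop("score file for protein '", pid, "' misses position ",
           if (length(gap)) gap[1] else "(duplicated positions)")
    }
    if (!is.null(proteins) && pid %in% names(proteins)) {
      res <- strsplit(proteins[[pid]], "")[[1]]
      mm <- which(sub$residue != res[sub$position])
      if (length(mm))
        stop("residue mismatch for protein '", pid, "' at position ",
             sub$position[mm[1]])
    }
    out[[pid]] <- sub$score
  }
  out
}

#' Write per-residue disorder profiles
#'
#' Counterpart of \code{\link{readScores}}; scores are written at full
#' precision so the round trip is exact.
#'
#' @param profiles Named list of numeric score vectors.
#' @param path Output TSV path.
#' @param proteins Optional named sequences used to fill the residue
#'   column (\code{"X"} written when unknown).
#' @export
writeScores <- function(profiles, path, proteins = NULL) {
  rows <- lapply(names(profiles), function(pid) {
    sc <- profiles[[pid]]
    res <- if (!is.null(proteins) && pid %in% names(proteins))
      strsplit(proteins[[pid]], "")[[1]] else rep("X", length(sc))
    data.frame(protein_id = pid, position = seq_along(sc),
               residue = res[seq_along(sc)], score = .num17(sc),
               stringsAsFactors = FALSE)
  })
  writeTsv(do.call(rbind, rows), path)
}

#' Read a trait answer sheet
#'
#' @param path TSV with columns \code{trait}, \code{variant_id},
#'   \code{gene_id} (one row per causal SNV).
#' @return data.frame.
#' @export
readAnswerSheet <- function(path) {
  df <- readTsv(path)
  need <- c("trait", "variant_id", "gene_id")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("answer sheet lacks column(s): ", paste(missing, collapse = ", "))
  df[, need]
}

#' Import variants from a plain-text VCF
#'
#' Convenience shim for biallelic SNV records in an (uncompressed) VCF
#' whose INFO field carries the gene id and CDS-relative position; the
#' CDS-relative TSV remains the canonical variant format. Records that are
#' not single-base biallelic substitutions, or that lack the INFO tags,
#' are skipped and counted.
#'
#' @param path VCF path.
#' @param geneTag,posTag INFO keys holding the gene id and the 1-based CDS
#'   position (defaults \code{GENE} and \code{CDSPOS}).
#' @return list with \code{variants} (canonical columns) and
#'   \code{n_skipped}.
#' @export
readVcfVariants <- function(path, geneTag = "GENE", posTag = "CDSPOS") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  skipped <- 0L
  rows <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) < 8L) { skipped <- skipped + 1L; next }
    ref <- toupper(f[4]); alt <- toupper(f[5])
    info <- strsplit(f[8], ";")[[1]]
    kv <- strsplit(info, "=")
    keys <- vapply(kv, `[[`, "", 1L)
    gene <- if (geneTag %in% keys) kv[[match(geneTag, keys)]][2] else NA
    pos <- if (posTag %in% keys) kv[[match(posTag, keys)]][2] else NA
    if (is.na(gene) || is.na(pos) || !ref %in% .BASES ||
        !alt %in% .BASES || ref == alt) {
      skipped <- skipped + 1L; next
    }
    id <- if (f[3] != ".") f[3] else paste0(f[1], ":", f[2])
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = id, gene_id = gene,
      cds_position = as.integer(pos), ref_base = ref, alt_base = alt,
      stringsAsFactors = FALSE)
  }
  if (skipped > 0L)
    message("readVcfVariants: skipped ", skipped, " record(s)")
  list(variants = if (length(rows)) do.call(rbind, rows) else
         data.frame(variant_id = character(0), gene_id = character(0),
                    cds_position = integer(0), ref_base = character(0),
                    alt_base = character(0)),
       n_skipped = skipped)
}

#' Read a YAML run configuration
#'
#' @param path YAML file with any of the keys \code{threshold},
#'   \code{comparison}, \code{window}, \code{predictor}, \code{test},
#'   \code{mode}, \code{seed}, \code{scores}, plus free-form paths.
#' @return Validated list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read run configurations")
  cfg <- yaml::read_yaml(path)
  defaults <- list(threshold = 0.04, comparison = "inclusive",
                   window = 21L, predictor = "builtin",
                   test = "ranksum", mode = "beyond", seed = 1L)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  stopifnot(cfg$threshold >= 0,
            cfg$comparison %in% c("inclusive", "strict"),
            cfg$window >= 1, cfg$window %% 2 == 1,
            cfg$predictor %in% c("builtin", "external"),
            cfg$test %in% c("ranksum", "ttest"),
            cfg$mode %in% c("beyond", "within"))
  if (cfg$predictor == "external" && is.null(cfg$scores))
    stop("external predictor requires a 'scores' path")
  cfg
}

#' Write a synthetic cohort to disk
#'
#' Emits exactly the formats the pipeline consumes: \code{cds.fasta},
#' \code{proteins.fasta}, \code{protein_meta.tsv}, \code{variants.tsv}
#' (with genotype columns), \code{answer_sheet.tsv} and
#' \code{ground_truth.tsv}.
#'
#' @param cohort A \code{\linkS4class{SyntheticCohort}}.
#' @param dir Output directory.
#' @param force Overwrite an existing directory.
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force)
    stop("output directory ", dir, " exists; use force = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFastaFile(cohort@cds, file.path(dir, "cds.fasta"))
  writeFastaFile(cohort@proteins, file.path(dir, "proteins.fasta"))
  writeTsv(cohort@proteinMeta, file.path(dir, "protein_meta.tsv"))
  writeVariants(cohort@variants, file.path(dir, "variants.tsv"),
                genotypes = cohort@genotypes)
  writeTsv(cohort@answerSheet, file.path(dir, "answer_sheet.tsv"))
  gt <- cohort@groundTruth
  for (col in c("true_delta_ds", "true_ds_maj", "true_maf"))
    gt[[col]] <- .num17(gt[[col]])
  writeTsv(gt, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}

#' Read a cohort directory written by \code{\link{writeCohort}}
#'
#' @param dir Cohort directory.
#' @return list with \code{cds}, \code{proteins}, \code{proteinMeta},
#'   \code{variants}, \code{genotypes}, \code{answerSheet},
#'   \code{groundTruth} (the latter two \code{NULL} when absent).
#' @export
readCohortDir <- function(dir) {
  v <- readVariants(file.path(dir, "variants.tsv"))
  list(cds = readFastaFile(file.path(dir, "cds.fasta"), "dna"),
       proteins = readFastaFile(file.path(dir, "proteins.fasta"),
                                "protein"),
       proteinMeta = readTsv(file.path(dir, "protein_meta.tsv")),
       variants = v$variants, genotypes = v$genotypes,
       answerSheet = if (file.exists(file.path(dir, "answer_sheet.tsv")))
         readAnswerSheet(file.path(dir, "answer_sheet.tsv")) else NULL,
       groundTruth = if (file.exists(file.path(dir, "ground_truth.tsv")))
         readTsv(file.path(dir, "ground_truth.tsv")) else NULL)
}
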