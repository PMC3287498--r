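# Shared fixtures: everything is generated in code at test time.

# Small cohort used by several tests; cheap to regenerate.
smallCohortConfig <- function(seed = 7L) {
  cohortConfig(n_genes = 20L, mean_cds_length = 120, n_individuals = 50L,
               n_snvs = 200L, n_causal_per_trait = c(3L, 4L, 3L),
               seed = seed)
}

# Flat one-pass oracle for per-substitution mean delta-DS: a literal
# scan with no grouping machinery.
flatScanMeans <- function(tab) {
  keys <- unique(paste(tab$aa_from, tab$aa_to, sep = ">"))
  means <- numeric(length(keys))
  for (i in seq_along(keys)) {
    s <- 0; n <- 0L
    for (j in seq_len(nrow(tab))) {
      if (paste(tab$aa_from[j], tab$aa_to[j], sep = ">") == keys[i]) {
        s <- s + tab$delta_ds[j]; n <- n + 1L
      }
    }
    means[i] <- s / n
  }
  stats::setNames(means, keys)
}

readTsvForTest <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

writeTsvForTest <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

# Independent genetic-code oracle: the 64 translations hardcoded in
# TCAG order (first base slowest), independent of the package's source
# of the code table.
oracleGeneticCode <- function() {
  aa <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    "")[[1]]
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  stats::setNames(aa, codons)
}

# Literal triple-loop oracle over all codon neighbours; returns the set
# of single-base-accessible nonsynonymous substitutions as "X>Y" strings.
oracleSingleBaseSubs <- function() {
  gc <- oracleGeneticCode()
  bases <- c("A", "C", "G", "T")
  subs <- character(0)
  for (cd in names(gc)) {
    if (gc[[cd]] == "*") next
    for (p in 1:3) {
      for (b in bases) {
        if (substr(cd, p, p) == b) next
        alt <- cd
        substr(alt, p, p) <- b
        if (gc[[alt]] == "*" || gc[[alt]] == gc[[cd]]) next
        subs <- c(subs, paste0(gc[[cd]], ">", gc[[alt]]))
      }
    }
  }
  unique(subs)
}
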