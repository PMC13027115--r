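# Hand-built toy germline segments with known anchors.
# TRBV: 48-nt body then TGT GCC AGC AGC (C A S S), anchor at offset 48.
TOY_TRBV_SEQ <- paste0(
  "ATGGCTACATTGCTTCAAGGAACGAAGCTCGAAACCATCTCGTTGACT",
  "TGTGCCAGCAGC")
# TRBJ: contains TTT-GGT-CAA-GGC (F G Q G); the F codon sits at offset 6.
TOY_TRBJ_SEQ <- "GAAACGTTTGGTCAAGGCACAGTGGTT"

writeToyRefFasta <- function(path, declare_j_anchor = FALSE) {
  lines <- c(
    ">TRBV99*01 type=V locus=TRB anchor=48", TOY_TRBV_SEQ,
    if (declare_j_anchor) ">TRBJ99*01 type=J locus=TRB anchor=6"
    else ">TRBJ99*01 type=J locus=TRB",
    TOY_TRBJ_SEQ)
  writeLines(lines, path)
  path
}

toyReference <- function(k = 15L) {
  f <- tempfile(fileext = ".fasta")
  writeToyRefFasta(f)
  loadReference(f, k = k)
}

# Small full reference + simulation shared across tests (built once).
sharedRef <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- syntheticGermlineReference()
    ref
  }
})

smallSimConfig <- function(seed = 42L, n_clonotypes_per_sample = 6L,
                           tissues = c("blood", "tumor"), ...) {
  simConfig(seed = seed,
            patients = c("P01", "P03"),
            groups = setNames(c("MSS", "MSI"), c("P01", "P03")),
            tissues = tissues, timepoints = "Pre",
            n_clonotypes_per_sample = n_clonotypes_per_sample,
            clone_size_param = 1,
            reads_per_cell_chain = 5L, error_rate = 0,
            shared_clone_fraction = 0, ...)
}

# Brute-force k-mer scan: does `read` (either strand) share an exact
# k-length word with `segment_seq`? Independent of the package index.
bruteForceSharesKmer <- function(read, segment_seq, k) {
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", read), "")[[1]]),
              collapse = "")
  for (s in c(read, rc)) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      if (grepl(substr(s, i, i + k - 1L), segment_seq, fixed = TRUE))
        return(TRUE)
    }
  }
  FALSE
}

# Exhaustive merge-order search over exact suffix-prefix overlaps
# (forward orientation); returns the longest contig reachable by any
# merge order.
exhaustiveAssembleMax <- function(seqs, min_overlap) {
  exactOverlap <- function(a, b) {
    na <- nchar(a); nb <- nchar(b)
    for (o in seq(min(na, nb), min_overlap)) {
      if (substr(a, na - o + 1L, na) == substr(b, 1L, o)) return(o)
    }
    0L
  }
  best <- max(nchar(seqs))
  recurse <- function(state) {
    n <- length(state)
    merged_any <- FALSE
    if (n >= 2L) {
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        o <- exactOverlap(state[i], state[j])
        if (o > 0L) {
          merged_any <- TRUE
          m <- paste0(state[i], substr(state[j], o + 1L, nchar(state[j])))
          recurse(c(state[-c(i, j)], m))
        }
      }
    }
    if (!merged_any) best <<- max(best, max(nchar(state)))
  }
  recurse(seqs)
  best
}

# Random repertoire generator for property tests.
randomCloneSizes <- function(n_max = 30L) {
  n <- sample(2:n_max, 1L)
  sample(1:20, n, replace = TRUE)
}
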