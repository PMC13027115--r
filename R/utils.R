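#' @importFrom Biostrings DNAString DNAStringSet translate
#'   reverseComplement pairwiseAlignment readDNAStringSet
#'   nucleotideSubstitutionMatrix score pid GENETIC_CODE
#' @importFrom IRanges start
#' @importFrom stats rpois rgeom setNames p.adjust t.test wilcox.test
#'   runif aggregate sd
#' @importFrom SummarizedExperiment rowData<- assayNames
#' @importFrom utils head read.delim write.table
NULL

# Translate an in-frame nucleotide string (length divisible by 3) to
# amino acids with the standard genetic code. Vectorised over x.
translateNt <- function(x) {
  stopifnot(all(nchar(x) %% 3 == 0))
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::translate(DNAStringSet(x), no.init.codon = TRUE))
}

# Amino acid encoded at a 0-based codon offset.
anchorResidue <- function(sequence, offset) {
  codon <- substr(sequence, offset + 1L, offset + 3L)
  unname(Biostrings::GENETIC_CODE[codon])
}

revComp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), "",
         USE.NAMES = FALSE)
}

# All k-mers of a sequence (character vector of length nchar - k + 1);
# k-mers containing non-ACGT letters are dropped.
seqKmers <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  km <- substring(sequence, starts, starts + k - 1L)
  km[grepl("^[ACGT]+$", km)]
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Strip the allele suffix from a segment call ("TRBV27*01" -> "TRBV27").
stripAllele <- function(call) {
  sub("\\*.*$", "", call)
}

# Round half up to `digits` decimals (reporting layer only).
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.cache <- new.env(parent = emptyenv())

# Local alignment score settings shared by the screen and the annotator:
# match +1, mismatch -1, gap -2 per gapped base.
localAlign <- function(patterns, subject) {
  if (is.null(.cache$submat))
    .cache$submat <- nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE)
  pairwiseAlignment(
    pattern = DNAStringSet(patterns), subject = DNAString(subject),
    type = "local", substitutionMatrix = .cache$submat,
    gapOpening = 0, gapExtension = 2
  )
}
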