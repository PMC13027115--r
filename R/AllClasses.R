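#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment rowData colData assay
NULL

TCR_LOCI <- c("TRA", "TRB", "TRG", "TRD")

#' ReferenceSet: an indexed germline V(D)J segment reference
#'
#' Holds validated germline V, D and J segments for one or more TCR loci
#' together with a k-mer index used for read screening and annotation.
#' Each segment carries its locus, segment type, allele-stripped gene name
#' and, for V and J segments, the 0-based offset of the conserved anchor
#' codon (the second cysteine codon of the V region; the J-region
#' phenylalanine/tryptophan codon). CDR3 junctions are defined between
#' these two anchors, both codons inclusive.
#'
#' @slot segments a \code{DataFrame} with columns \code{segment_id},
#'   \code{locus}, \code{segment_type}, \code{gene}, \code{allele},
#'   \code{sequence}, \code{anchor_offset} (NA for D segments).
#' @slot kmerIndex named list mapping each k-mer (forward strand of the
#'   segments) to the character vector of segment ids containing it.
#' @slot k integer word size of the index.
#'
#' @seealso [loadReference()], [kmerCandidates()]
#' @export
setClass("ReferenceSet",
  representation(
    segments = "DataFrame",
    kmerIndex = "list",
    k = "integer"
  )
)

setValidity("ReferenceSet", function(object) {
  seg <- object@segments
  need <- c("segment_id", "locus", "segment_type", "gene", "allele",
            "sequence", "anchor_offset")
  if (!all(need %in% colnames(seg)))
    return(paste("segments must have columns:", paste(need, collapse = ", ")))
  if (nrow(seg) == 0L) return("reference contains no segments")
  if (anyDuplicated(seg$segment_id))
    return("duplicate segment_id in reference")
  if (!all(seg$locus %in% TCR_LOCI))
    return("locus must be one of TRA/TRB/TRG/TRD")
  if (!all(seg$segment_type %in% c("V", "D", "J")))
    return("segment_type must be V, D or J")
  if (!all(grepl("^[ACGT]+$", seg$sequence)))
    return("segment sequences must be non-empty uppercase A/C/G/T")
  bad_id <- seg$segment_id != paste0(seg$gene, "*", seg$allele)
  if (any(bad_id))
    return(paste("segment_id must equal gene*allele for:",
                 paste(seg$segment_id[bad_id], collapse = ", ")))
  vj <- seg$segment_type %in% c("V", "J")
  if (any(is.na(seg$anchor_offset[vj])))
    return("V and J segments must carry an anchor_offset")
  off <- seg$anchor_offset[vj]
  len <- nchar(seg$sequence[vj])
  if (any(off < 0L | off + 3L > len))
    return("anchor_offset out of range for a V/J segment")
  aa <- anchorResidue(seg$sequence[vj], seg$anchor_offset[vj])
  isV <- seg$segment_type[vj] == "V"
  if (any(aa[isV] != "C"))
    return("V anchor codon must encode C")
  if (any(!aa[!isV] %in% c("F", "W")))
    return("J anchor codon must encode F or W")
  for (loc in unique(seg$locus)) {
    tt <- seg$segment_type[seg$locus == loc]
    if (!("V" %in% tt) || !("J" %in% tt))
      return(paste0("locus ", loc, " lacks a V or a J segment"))
  }
  if (length(object@k) != 1L || object@k < 8L)
    return("k must be a single integer >= 8")
  TRUE
})

#' RepertoireTable: clonotypes by samples with metadata
#'
#' A \code{SummarizedExperiment} whose single assay \code{"cells"} is the
#' clonotype-by-sample matrix of cell counts. \code{rowData} carries the
#' clonotype key (locus, allele-stripped V gene, CDR3 amino-acid sequence),
#' the modal J gene, and (after [classifySharing()]) the sharing class;
#' \code{colData} carries sample metadata (patient, group, tissue,
#' timepoint).
#'
#' @seealso [callClonotypes()], [classifySharing()]
#' @export
setClass("RepertoireTable", contains = "SummarizedExperiment")

setValidity("RepertoireTable", function(object) {
  rd <- rowData(object)
  cd <- colData(object)
  if (!all(c("locus", "v_gene", "cdr3_aa") %in% colnames(rd)))
    return("rowData needs columns locus, v_gene, cdr3_aa")
  if (!all(c("patient", "group", "tissue", "timepoint") %in% colnames(cd)))
    return("colData needs columns patient, group, tissue, timepoint")
  if (!("cells" %in% SummarizedExperiment::assayNames(object)))
    return("assay 'cells' missing")
  m <- assay(object, "cells")
  if (any(m < 0) || any(m != round(m)))
    return("cell counts must be non-negative integers")
  if (nrow(object) > 0 && any(rowSums(m) < 1))
    return("every clonotype must have at least one cell")
  TRUE
})

#' BenchmarkResult: reconstruction benchmark counts and rates
#'
#' Matched/unmatched chain counts from comparing a reconstructed chain set
#' against a reference (ground-truth) chain set under one match mode, plus
#' per-component true-positive counts for V/J/D gene and CDR3 precision.
#' Percentages are computed on demand and rounded only for display.
#'
#' @slot matchMode one of \code{"junction_nt"}, \code{"junction_aa"},
#'   \code{"gene_level"}.
#' @slot nReference,nQuery,nMatched chain counts.
#' @slot tp named integer vector of true-positive counts for components
#'   V, J, D, CDR3 among matched pairs.
#' @slot nEvaluable named integer vector: records evaluable per component
#'   (D is only evaluable where both records carry a D call).
#' @slot pairs a \code{DataFrame} of matched (query, reference) row indices.
#'
#' @seealso [matchContigs()], [overlapRates()], [precisionRate()]
#' @export
setClass("BenchmarkResult",
  representation(
    matchMode = "character",
    nReference = "integer",
    nQuery = "integer",
    nMatched = "integer",
    tp = "integer",
    nEvaluable = "integer",
    pairs = "DataFrame"
  )
)

setValidity("BenchmarkResult", function(object) {
  if (object@nMatched > min(object@nReference, object@nQuery))
    return("n_matched cannot exceed min(n_reference, n_query)")
  if (object@nMatched < 0L) return("negative match count")
  if (!object@matchMode %in% c("junction_nt", "junction_aa", "gene_level"))
    return("unknown match mode")
  TRUE
})

#' SimConfig: parameters of the synthetic V(D)J repertoire generator
#'
#' The generator emulates a multi-patient, multi-tissue (blood / normal /
#' tumor), pre/post-treatment single-cell study with MSI and MSS patient
#' groups, skewed clone sizes, biased segment usage, junctional diversity
#' and sequencing error. See the constructor [simConfig()] for defaults
#' and units.
#'
#' @export
setClass("SimConfig",
  representation(
    seed = "integer",
    patients = "character",
    groups = "character",          # named by patient, values MSI/MSS
    tissues = "character",
    timepoints = "character",
    nClonotypesPerSample = "integer",
    cloneSizeLaw = "character",    # "geometric" or "power_law"
    cloneSizeParam = "numeric",
    locusWeights = "numeric",      # named by locus
    usageBiasBase = "numeric",     # geometric decay of V/J gene usage
    insertionMean = "numeric",     # Poisson mean of N-insertions per side
    maxTrim = "integer",           # max 3'V / 5'J exonuclease trim
    sharedCloneFraction = "numeric",
    readsPerCellChain = "integer",
    readLength = "integer",
    errorRate = "numeric",
    barcodeLength = "integer",
    umiLength = "integer"
  )
)

setValidity("SimConfig", function(object) {
  probs <- c(object@errorRate, object@sharedCloneFraction)
  if (any(probs < 0 | probs > 1))
    return("error_rate and shared_clone_fraction must be in [0,1]")
  if (object@readsPerCellChain < 1L)
    return("reads_per_cell_chain must be >= 1")
  if (!all(object@groups %in% c("MSI", "MSS")))
    return("groups must be MSI or MSS")
  if (!all(names(object@groups) == object@patients))
    return("groups must be named by patient, in patient order")
  if (!all(object@tissues %in% c("blood", "normal", "tumor")))
    return("tissues must be a subset of blood/normal/tumor")
  if (!object@cloneSizeLaw %in% c("geometric", "power_law"))
    return("clone_size_law must be geometric or power_law")
  if (object@readLength < 2L * object@maxTrim + 20L)
    return("read_length too small for the configured trims")
  TRUE
})
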