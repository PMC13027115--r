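#' Load a germline V(D)J segment reference from FASTA
#'
#' Reads a segment FASTA, parses locus / segment type / anchor metadata from
#' the headers, validates every record, infers missing anchor offsets, and
#' builds a k-mer index over the segment sequences.
#'
#' Two header dialects are supported. The key-value dialect (written by
#' [writeReference()] and the simulator) looks like
#' \code{>TRBV27*01 type=V locus=TRB anchor=285} with \code{anchor} the
#' 0-based offset of the conserved anchor codon (optional). The pipe
#' dialect looks like \code{>TRBV27*01|TRB|V}.
#'
#' Records are excluded (with a warning and an entry in the exclusion
#' report) when the sequence contains non-ACGT letters, the id lacks an
#' allele suffix, a declared V anchor does not encode cysteine, a declared
#' J anchor does not encode phenylalanine/tryptophan, or no anchor can be
#' inferred. A J segment without a declared anchor gets one inferred at the
#' first F/W of the [FW]-G-x-G junction-closing motif, scanning all three
#' frames and preferring the frame with the longest stop-free translation;
#' a V segment without one gets the rightmost cysteine codon of that frame.
#'
#' @param fasta_path path to the reference FASTA.
#' @param header_dialect \code{"keyvalue"} (default) or \code{"pipe"}.
#' @param k word size of the k-mer index (>= 8).
#' @param report_path optional path; the plain-text exclusion report is
#'   written there.
#' @return a validated [ReferenceSet-class]; the exclusion report is
#'   attached as \code{metadata(x)$excluded}.
#' @export
loadReference <- function(fasta_path, header_dialect = c("keyvalue", "pipe"),
                          k = 15L, report_path = NULL) {
  header_dialect <- match.arg(header_dialect)
  if (!file.exists(fasta_path)) stop("reference FASTA not found: ", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty reference FASTA: ", fasta_path)
  headers <- names(seqs)
  sequences <- toupper(as.character(seqs))

  parsed <- lapply(headers, parseSegmentHeader, dialect = header_dialect)
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad))
    stop("unparseable header(s): ", paste(headers[bad], collapse = "; "))
  meta <- do.call(rbind, lapply(parsed, as.data.frame))
  meta$sequence <- unname(sequences)

  if (anyDuplicated(meta$segment_id))
    stop("duplicate segment ids: ",
         paste(unique(meta$segment_id[duplicated(meta$segment_id)]),
               collapse = ", "))

  checked <- validateSegments(meta)
  excluded <- checked$excluded
  seg <- checked$segments
  if (nrow(excluded) > 0L)
    warning(nrow(excluded), " segment(s) excluded: ",
            paste(excluded$segment_id, excluded$reason,
                  sep = " [", collapse = "], "), "]")
  if (!is.null(report_path))
    utils::write.table(excluded, report_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (nrow(seg) == 0L) stop("no valid segments after validation")
  for (loc in unique(meta$locus)) {
    tt <- seg$segment_type[seg$locus == loc]
    if (!("V" %in% tt))
      stop("locus ", loc, " present in file but has no valid V segment")
    if (!("J" %in% tt))
      stop("locus ", loc, " present in file but has no valid J segment")
  }
  rs <- newReferenceSet(seg, k = as.integer(k))
  metadata(rs@segments)$excluded <- excluded
  rs
}

parseSegmentHeader <- function(header, dialect) {
  header <- trimws(header)
  if (dialect == "pipe") {
    parts <- strsplit(header, "|", fixed = TRUE)[[1]]
    if (length(parts) < 3L) return(NULL)
    out <- list(segment_id = parts[1], locus = parts[2],
                segment_type = parts[3], anchor_offset = NA_integer_)
  } else {
    toks <- strsplit(header, "[ \t]+")[[1]]
    id <- toks[1]
    kv <- toks[-1][grepl("=", toks[-1])]
    vals <- setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
    if (!all(c("type", "locus") %in% names(vals))) return(NULL)
    out <- list(segment_id = id, locus = unname(vals[["locus"]]),
                segment_type = unname(vals[["type"]]),
                anchor_offset = if ("anchor" %in% names(vals))
                  as.integer(vals[["anchor"]]) else NA_integer_)
  }
  if (!out$segment_type %in% c("V", "D", "J")) return(NULL)
  if (!out$locus %in% TCR_LOCI) return(NULL)
  out
}

# Per-record validation and anchor inference; returns kept segments plus an
# exclusion report (segment_id, reason).
validateSegments <- function(meta) {
  reasons <- character(0); ids <- character(0)
  keep <- logical(nrow(meta))
  gene <- character(nrow(meta)); allele <- character(nrow(meta))
  anchor <- meta$anchor_offset
  for (i in seq_len(nrow(meta))) {
    id <- meta$segment_id[i]
    seqi <- meta$sequence[i]
    drop <- function(reason) {
      ids <<- c(ids, id); reasons <<- c(reasons, reason)
    }
    if (!grepl("^[ACGT]+$", seqi)) { drop("degenerate_or_empty_sequence"); next }
    if (!grepl("\\*", id)) { drop("no_allele_in_id"); next }
    gene[i] <- sub("\\*.*$", "", id)
    allele[i] <- sub("^[^*]*\\*", "", id)
    type <- meta$segment_type[i]
    if (type %in% c("V", "J")) {
      a <- anchor[i]
      if (is.na(a)) {
        a <- inferAnchor(seqi, type)
        if (is.na(a)) { drop("anchor_not_inferable"); next }
        anchor[i] <- a
      }
      if (a < 0L || a + 3L > nchar(seqi)) { drop("anchor_out_of_range"); next }
      aa <- anchorResidue(seqi, a)
      if (type == "V" && !identical(aa, "C")) { drop("v_anchor_not_cys"); next }
      if (type == "J" && !(aa %in% c("F", "W"))) { drop("j_anchor_not_fw"); next }
    } else {
      anchor[i] <- NA_integer_
    }
    keep[i] <- TRUE
  }
  seg <- DataFrame(
    segment_id = meta$segment_id[keep],
    locus = meta$locus[keep],
    segment_type = meta$segment_type[keep],
    gene = gene[keep],
    allele = allele[keep],
    sequence = meta$sequence[keep],
    anchor_offset = as.integer(anchor[keep])
  )
  list(segments = seg,
       excluded = data.frame(segment_id = ids, reason = reasons,
                             stringsAsFactors = FALSE))
}

# Anchor inference used when the header declares none. Frame choice: the
# frame whose translation runs longest before the first stop codon.
inferAnchor <- function(sequence, type) {
  best_frame <- NA_integer_; best_len <- -1L
  aas <- vector("list", 3L)
  for (f in 0:2) {
    n <- nchar(sequence) - f
    n <- n - n %% 3L
    if (n < 3L) next
    aa <- translateNt(substr(sequence, f + 1L, f + n))
    aas[[f + 1L]] <- aa
    stop_at <- regexpr("*", aa, fixed = TRUE)
    run <- if (stop_at < 0L) nchar(aa) else stop_at - 1L
    if (run > best_len) { best_len <- run; best_frame <- f }
  }
  if (is.na(best_frame)) return(NA_integer_)
  aa <- aas[[best_frame + 1L]]
  if (type == "J") {
    m <- regexpr("[FW]G.G", aa)
    if (m < 0L) return(NA_integer_)
    return(best_frame + 3L * (as.integer(m) - 1L))
  }
  hits <- gregexpr("C", aa, fixed = TRUE)[[1]]
  if (hits[1] < 0L) return(NA_integer_)
  best_frame + 3L * (max(hits) - 1L)
}

newReferenceSet <- function(segments, k = 15L) {
  idx <- buildKmerIndex(segments$sequence, segments$segment_id, k)
  new("ReferenceSet", segments = segments, kmerIndex = idx, k = as.integer(k))
}

buildKmerIndex <- function(sequences, ids, k) {
  kms <- lapply(sequences, seqKmers, k = k)
  all_k <- unlist(kms, use.names = FALSE)
  all_id <- rep(ids, lengths(kms))
  split(all_id, all_k)
}

#' Segment table of a reference
#' @param x a [ReferenceSet-class].
#' @return the segment \code{DataFrame}.
#' @export
refSegments <- function(x) {
  stopifnot(is(x, "ReferenceSet"))
  x@segments
}

#' K-mer size of a reference index
#' @param x a [ReferenceSet-class].
#' @export
kmerSize <- function(x) x@k

#' Candidate segments sharing a k-mer with a read
#'
#' Returns every segment id sharing at least one exact k-mer with the read
#' or its reverse complement (segments are indexed on their forward strand
#' only). This is a superset of the segments the read aligns to with >= k
#' consecutive matches, and is used to pre-filter alignment targets.
#' K-mers containing N are skipped.
#'
#' @param reference a [ReferenceSet-class].
#' @param read_sequence nucleotide string, length >= k.
#' @param k word size; must equal the index word size.
#' @return character vector of segment ids (possibly empty), sorted.
#' @export
kmerCandidates <- function(reference, read_sequence, k = kmerSize(reference)) {
  if (k != reference@k)
    stop("k = ", k, " does not match the index word size ", reference@k)
  read_sequence <- toupper(read_sequence)
  if (nchar(read_sequence) < k)
    stop("read shorter than k = ", k)
  kms <- unique(c(seqKmers(read_sequence, k),
                  seqKmers(revComp(read_sequence), k)))
  hit <- match(kms, names(reference@kmerIndex))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0L) return(character(0))
  sort(unique(unlist(reference@kmerIndex[hit], use.names = FALSE)))
}

#' Write a reference back to FASTA (key-value header dialect)
#'
#' The output round-trips through [loadReference()] to an identical
#' \code{ReferenceSet}.
#'
#' @param reference a [ReferenceSet-class].
#' @param fasta_path output path.
#' @return \code{fasta_path}, invisibly.
#' @export
writeReference <- function(reference, fasta_path) {
  seg <- refSegments(reference)
  hdr <- sprintf(">%s type=%s locus=%s%s", seg$segment_id, seg$segment_type,
                 seg$locus,
                 ifelse(is.na(seg$anchor_offset), "",
                        sprintf(" anchor=%d", seg$anchor_offset)))
  writeLines(as.vector(rbind(hdr, seg$sequence)), fasta_path)
  invisible(fasta_path)
}

setMethod("show", "ReferenceSet", function(object) {
  seg <- object@segments
  cat("ReferenceSet with", nrow(seg), "segments (k =", object@k, ")\n")
  tab <- table(seg$locus, seg$segment_type)
  print(tab)
})
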