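#' Chain-specific CDR3 validity filter
#'
#' Applies the conserved-motif filtering rules used to retain valid CDR3
#' amino-acid sequences. For TRA and TRG chains a CDR3 is valid when it
#' starts with cysteine (C) and ends with tryptophan (W) or phenylalanine
#' (F). For the more stringently conserved TRB and TRD chains it must
#' begin with the "CASS" motif and end with phenylalanine. Any stop
#' character (\code{*}) is always invalid. \code{relaxed = TRUE} applies
#' the C...F/W rule to all four loci (TRD junctions rarely begin with
#' CASS in practice; the strict rule is the default, the relaxation is
#' opt-in).
#'
#' @param cdr3_aa non-empty amino-acid string.
#' @param locus one of TRA/TRB/TRG/TRD.
#' @param relaxed apply the C...F/W rule to TRB/TRD as well.
#' @return list with \code{valid} (logical) and \code{reason} (NA when
#'   valid; otherwise \code{"stop_codon"}, \code{"motif"} or
#'   \code{"terminal"}).
#' @examples
#' filterCdr3Validity("CAVRDSNYQLIW", "TRA")$valid   # TRUE
#' filterCdr3Validity("CSARDPGLAGGF", "TRB")$reason  # "motif"
#' @export
filterCdr3Validity <- function(cdr3_aa, locus, relaxed = FALSE) {
  if (!is.character(cdr3_aa) || length(cdr3_aa) != 1L || nchar(cdr3_aa) == 0L)
    stop("cdr3_aa must be a single non-empty string")
  if (!locus %in% TCR_LOCI) stop("unknown locus: ", locus)
  fail <- function(reason) list(valid = FALSE, reason = reason)
  if (grepl("*", cdr3_aa, fixed = TRUE)) return(fail("stop_codon"))
  last <- substr(cdr3_aa, nchar(cdr3_aa), nchar(cdr3_aa))
  strict_bd <- locus %in% c("TRB", "TRD") && !relaxed
  if (strict_bd) {
    if (substr(cdr3_aa, 1L, 4L) != "CASS") return(fail("motif"))
    if (last != "F") return(fail("terminal"))
  } else {
    if (substr(cdr3_aa, 1L, 1L) != "C") return(fail("motif"))
    if (!last %in% c("F", "W")) return(fail("terminal"))
  }
  list(valid = TRUE, reason = NA_character_)
}

#' Embed cell barcodes and UMIs into read identifiers
#'
#' Rewrites read ids as \code{barcode:umi:original_id} so that per-cell
#' demultiplexing reduces to grouping by id prefix. In the
#' \code{paired_end} layout the barcode and UMI are read from the first
#' bases of mate 1 and the identical embedded prefix is written to both
#' mates of a pair. In the \code{single_end} layout the barcode and UMI
#' are the first bases of the read itself and are trimmed off the emitted
#' sequence. Reads whose barcode bases contain non-ACGT letters (or are
#' too short) are dropped and counted.
#'
#' @param fastq_r1 path to mate 1 (or the only read in single-end mode).
#' @param fastq_r2 path to mate 2 (paired-end mode).
#' @param out_r1,out_r2 output FASTQ paths; in paired-end mode
#'   \code{out_r2} receives the embedded cDNA mate.
#' @param barcode_length,umi_length barcode/UMI coordinates within the
#'   designated mate.
#' @param layout \code{"paired_end"} or \code{"single_end"}.
#' @return invisibly, a list with counts \code{n_in}, \code{n_out},
#'   \code{n_dropped} and the output paths.
#' @export
embedBarcodes <- function(fastq_r1, fastq_r2 = NULL, out_r1, out_r2 = NULL,
                          barcode_length = 16L, umi_length = 10L,
                          layout = c("paired_end", "single_end")) {
  layout <- match.arg(layout)
  r1 <- readFastq(fastq_r1)
  tag_len <- barcode_length + umi_length
  bc <- substr(r1$sequence, 1L, barcode_length)
  umi <- substr(r1$sequence, barcode_length + 1L, tag_len)
  ok <- nchar(r1$sequence) >= tag_len & grepl("^[ACGT]+$", bc)
  if (layout == "paired_end") {
    if (is.null(fastq_r2) || is.null(out_r2))
      stop("paired_end layout needs fastq_r2 and out_r2")
    r2 <- readFastq(fastq_r2)
    if (nrow(r2) != nrow(r1) || any(r1$id != r2$id))
      stop("desynchronized mates: ids of R1 and R2 differ")
    new_id <- paste(bc, umi, r1$id, sep = ":")
    writeFastq(new_id[ok], r1$sequence[ok], out_r1)
    writeFastq(new_id[ok], r2$sequence[ok], out_r2)
    paths <- list(r1 = out_r1, r2 = out_r2)
  } else {
    new_id <- paste(bc, umi, r1$id, sep = ":")
    writeFastq(new_id[ok], substr(r1$sequence, tag_len + 1L,
                                  nchar(r1$sequence))[ok], out_r1)
    paths <- list(r1 = out_r1)
  }
  invisible(list(n_in = nrow(r1), n_out = sum(ok),
                 n_dropped = sum(!ok), paths = paths))
}

#' Parse embedded read identifiers back to (barcode, umi, original id)
#'
#' Inverse of the embedding rule: splits only the first two
#' colon-delimited fields, so original ids containing \code{:} round-trip
#' losslessly.
#'
#' @param ids character vector of embedded ids.
#' @return data.frame with columns \code{barcode}, \code{umi},
#'   \code{original_id}; unparseable ids yield NA barcode.
#' @export
parseEmbeddedIds <- function(ids) {
  m <- regmatches(ids, regexec("^([^:]+):([^:]+):(.*)$", ids))
  bad <- lengths(m) != 4L
  data.frame(
    barcode = ifelse(bad, NA_character_, vapply(m, function(x)
      if (length(x) == 4L) x[2] else NA_character_, "")),
    umi = ifelse(bad, NA_character_, vapply(m, function(x)
      if (length(x) == 4L) x[3] else NA_character_, "")),
    original_id = ifelse(bad, NA_character_, vapply(m, function(x)
      if (length(x) == 4L) x[4] else NA_character_, "")),
    stringsAsFactors = FALSE)
}

#' Screen reads for TCR origin
#'
#' Keeps a read iff at least one reference segment shares an exact k-mer
#' with it (either strand) and a local alignment to such a segment
#' (match +1, mismatch -1, gap -2) reaches \code{min_score} on either
#' strand. With \code{min_score <= 0} the screen reduces to k-mer
#' candidacy. Retained reads carry the locus of the segment that admitted
#' them as \code{locus_hint}.
#'
#' @param reads data.frame with columns \code{id}, \code{sequence}.
#' @param reference a [ReferenceSet-class].
#' @param min_score minimum local alignment score.
#' @return the retained subset of \code{reads} with an added
#'   \code{locus_hint} column; counts in \code{attr(,"counts")}.
#' @export
screenTcrReads <- function(reads, reference, min_score = 25) {
  n <- nrow(reads)
  cand <- lapply(reads$sequence, function(s)
    tryCatch(kmerCandidates(reference, s), error = function(e) character(0)))
  keep <- lengths(cand) > 0L
  hint <- rep(NA_character_, n)
  seg <- refSegments(reference)
  if (min_score > 0) {
    decided <- !keep            # reads with no candidates are decided (drop)
    keep <- logical(n)
    all_cand <- unlist(cand, use.names = FALSE)
    for (sid in names(sort(table(all_cand), decreasing = TRUE))) {
      todo <- which(!decided & vapply(cand, function(x) sid %in% x, TRUE))
      if (length(todo) == 0L) next
      sseq <- seg$sequence[seg$segment_id == sid]
      sc <- pmax(
        score(localAlign(reads$sequence[todo], sseq)),
        score(localAlign(revComp(reads$sequence[todo]), sseq)))
      hit <- sc >= min_score
      keep[todo[hit]] <- TRUE
      hint[todo[hit]] <- seg$locus[seg$segment_id == sid]
      decided[todo[hit]] <- TRUE
      if (all(decided)) break
    }
  } else {
    hint[keep] <- vapply(cand[keep], function(x)
      seg$locus[match(x[1], seg$segment_id)], "")
  }
  out <- reads[keep, , drop = FALSE]
  out$locus_hint <- hint[keep]
  rownames(out) <- NULL
  attr(out, "counts") <- c(input = n, retained = nrow(out),
                           dropped = n - nrow(out))
  out
}

#' Group embedded reads by cell barcode
#'
#' Partitions reads on the barcode field of their embedded ids. The UMI
#' is retained per read. The union of the groups plus the dropped reads
#' equals the input.
#'
#' @param reads data.frame with columns \code{id}, \code{sequence}
#'   (embedded ids).
#' @param on_unparseable \code{"drop"} (count and skip) or \code{"abort"}.
#' @return list with \code{groups} (named list of data.frames with
#'   columns \code{barcode}, \code{umi}, \code{original_id},
#'   \code{sequence}) and \code{n_dropped}.
#' @export
groupByBarcode <- function(reads, on_unparseable = c("drop", "abort")) {
  on_unparseable <- match.arg(on_unparseable)
  if (nrow(reads) == 0L)
    return(list(groups = list(), n_dropped = 0L))
  parsed <- parseEmbeddedIds(reads$id)
  bad <- is.na(parsed$barcode)
  if (any(bad) && on_unparseable == "abort")
    stop(sum(bad), " read id(s) do not parse as barcode:umi:id")
  df <- cbind(parsed[!bad, , drop = FALSE],
              sequence = reads$sequence[!bad])
  groups <- split(df, df$barcode)
  groups <- lapply(groups, function(g) { rownames(g) <- NULL; g })
  list(groups = groups, n_dropped = sum(bad))
}

# Longest suffix(a)-prefix(b) overlap with at most max_mismatch
# mismatches; returns the overlap length (0 if none >= min_overlap).
# Operates on utf8ToInt-encoded sequences.
bestOverlapInt <- function(av, bv, min_overlap, max_mismatch) {
  na <- length(av); nb <- length(bv)
  top <- min(na, nb)
  if (top < min_overlap) return(0L)
  for (o in seq(top, min_overlap)) {
    mm <- sum(av[(na - o + 1L):na] != bv[1:o])
    if (mm <= max_mismatch) return(o)
  }
  0L
}

bestOverlap <- function(a, b, min_overlap, max_mismatch) {
  bestOverlapInt(utf8ToInt(a), utf8ToInt(b), min_overlap, max_mismatch)
}

# Merge b onto the 3' end of a with overlap o; mismatching overlap bases
# follow the higher-support sequence (ties to a).
mergeOverlap <- function(a, b, o, support_a, support_b) {
  ov <- if (support_b > support_a) substr(b, 1L, o)
        else substr(a, nchar(a) - o + 1L, nchar(a))
  paste0(substr(a, 1L, nchar(a) - o), ov,
         substr(b, o + 1L, nchar(b)))
}

#' Assemble one cell's reads into contigs by greedy overlap consensus
#'
#' Duplicate sequences are collapsed (summing support), sequences fully
#' contained in a longer one are absorbed, and then the pair of sequences
#' with the longest suffix-prefix overlap of at least \code{min_overlap}
#' bases and at most \code{max_mismatch} mismatches is merged repeatedly
#' until no merge is possible. Mismatching overlap positions take the
#' base of the higher-support sequence (ties to the sequence that sorts
#' first). Both strands are considered. Processing order is fixed by
#' sorting sequences lexicographically, so the result is deterministic.
#'
#' @param sequences character vector of read sequences from one barcode
#'   group.
#' @param min_overlap minimum suffix-prefix overlap (nt).
#' @param max_mismatch maximum mismatches tolerated inside an overlap.
#' @param min_contig_len contigs shorter than this are discarded.
#' @return data.frame with columns \code{sequence}, \code{support},
#'   ordered by support (desc) then sequence.
#' @export
assembleCell <- function(sequences, min_overlap = 20L, max_mismatch = 2L,
                         min_contig_len = 50L) {
  if (length(sequences) == 0L)
    return(data.frame(sequence = character(0), support = integer(0)))
  tab <- table(sequences)
  seqs <- names(tab)
  supp <- as.integer(tab)
  rcs <- revComp(seqs)
  ints <- lapply(seqs, utf8ToInt)
  rcints <- lapply(rcs, utf8ToInt)

  reorder <- function() {
    ord <- order(seqs)
    seqs <<- seqs[ord]; supp <<- supp[ord]; rcs <<- rcs[ord]
    ints <<- ints[ord]; rcints <<- rcints[ord]
  }
  dropIdx <- function(drop) {
    keep <- !drop
    seqs <<- seqs[keep]; supp <<- supp[keep]; rcs <<- rcs[keep]
    ints <<- ints[keep]; rcints <<- rcints[keep]
  }
  absorbContained <- function() {
    repeat {
      n <- length(seqs)
      if (n < 2L) return()
      drop <- rep(FALSE, n)
      for (i in seq_len(n)) {
        if (drop[i]) next
        for (j in seq_len(n)) {
          if (i == j || drop[j] || drop[i]) next
          if (nchar(seqs[i]) > nchar(seqs[j])) next
          if (nchar(seqs[i]) == nchar(seqs[j]) && i > j) next
          if (grepl(seqs[i], seqs[j], fixed = TRUE) ||
              grepl(rcs[i], seqs[j], fixed = TRUE)) {
            supp[j] <<- supp[j] + supp[i]
            drop[i] <- TRUE
            break
          }
        }
      }
      if (!any(drop)) return()
      dropIdx(drop)
    }
  }

  reorder()
  absorbContained()
  repeat {
    n <- length(seqs)
    if (n < 2L) break
    best <- NULL
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      o <- bestOverlapInt(ints[[i]], ints[[j]], min_overlap, max_mismatch)
      if (o > 0L && (is.null(best) || o > best$o))
        best <- list(i = i, j = j, o = o, rc = FALSE)
      orc <- bestOverlapInt(ints[[i]], rcints[[j]], min_overlap,
                            max_mismatch)
      if (orc > 0L && (is.null(best) || orc > best$o))
        best <- list(i = i, j = j, o = orc, rc = TRUE)
    }
    if (is.null(best)) break
    b <- if (best$rc) rcs[best$j] else seqs[best$j]
    merged <- mergeOverlap(seqs[best$i], b, best$o,
                           supp[best$i], supp[best$j])
    msupp <- supp[best$i] + supp[best$j]
    drop <- seq_along(seqs) %in% c(best$i, best$j)
    dropIdx(drop)
    seqs <- c(seqs, merged)
    supp <- c(supp, msupp)
    mrc <- revComp(merged)
    rcs <- c(rcs, mrc)
    ints <- c(ints, list(utf8ToInt(merged)))
    rcints <- c(rcints, list(utf8ToInt(mrc)))
    reorder()
    absorbContained()
  }
  keep <- nchar(seqs) >= min_contig_len
  out <- data.frame(sequence = seqs[keep], support = supp[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$support, out$sequence), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

# Project a 1-based pattern position through a local pairwiseAlignment
# onto subject coordinates; NA when the position is outside the aligned
# block or falls in a subject gap.
projectThroughAlignment <- function(al, pattern_pos) {
  pr <- as.integer(Biostrings::start(Biostrings::pattern(al)))
  sr <- as.integer(Biostrings::start(Biostrings::subject(al)))
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  p <- pr - 1L; s <- sr - 1L
  for (k in seq_along(pa)) {
    if (pa[k] != "-") p <- p + 1L
    if (sa[k] != "-") s <- s + 1L
    if (pa[k] != "-" && p == pattern_pos) {
      if (sa[k] == "-") return(NA_integer_)
      return(s)
    }
  }
  NA_integer_
}

# Best-scoring alignments of a set of segments to a contig; returns the
# index of the winner (ties: higher identity, then lexicographic id) and
# its alignment/score.
bestSegmentHit <- function(contig, seg_rows) {
  if (nrow(seg_rows) == 0L) return(NULL)
  als <- localAlign(seg_rows$sequence, contig)
  sc <- score(als)
  pid <- Biostrings::pid(als)
  ord <- order(-sc, -pid, seg_rows$segment_id)
  best <- ord[1]
  list(idx = best, score = sc[best], alignment = als[best],
       scores = sc, alignments = als)
}

#' Annotate a contig with V/J calls and extract the CDR3 junction
#'
#' Aligns every k-mer-candidate V and J segment to the contig on both
#' strands (match +1, mismatch -1, gap -2), fixes the contig orientation
#' to the V-forward strand, and projects the segment anchor codons
#' through the alignments to delimit the CDR3: contig bases from the
#' projected second-cysteine codon of V through the projected F/W codon
#' of J, both inclusive. If the best V hits from different loci score
#' within \code{locus_margin} of each other the locus is taken from the J
#' call and \code{ambiguous_locus} is set (guards against cross-locus
#' V mis-assignment, e.g. delta V segments resembling alpha ones). A
#' record is productive when V and J are called, the junction is in
#' frame and stop-free, and it passes [filterCdr3Validity()].
#'
#' @param contig_sequence nucleotide string.
#' @param reference a [ReferenceSet-class].
#' @param min_score minimum local alignment score for a V or J call.
#' @param locus_margin score margin under which the V locus is considered
#'   ambiguous and deferred to the J call.
#' @param relaxed_filter passed to [filterCdr3Validity()].
#' @return one-row data.frame: \code{sequence} (V-forward orientation),
#'   \code{locus}, \code{v_call}, \code{d_call}, \code{j_call},
#'   \code{v_score}, \code{j_score}, \code{cdr3_nt}, \code{cdr3_aa},
#'   \code{productive}, \code{ambiguous_locus}, \code{fail_reasons}
#'   (comma-joined codes).
#' @export
annotateContig <- function(contig_sequence, reference, min_score = 25,
                           locus_margin = 5, relaxed_filter = FALSE) {
  seg <- refSegments(reference)
  cand <- tryCatch(kmerCandidates(reference, contig_sequence),
                   error = function(e) character(0))
  segc <- seg[seg$segment_id %in% cand, , drop = FALSE]
  vs <- segc[segc$segment_type == "V", , drop = FALSE]
  js <- segc[segc$segment_type == "J", , drop = FALSE]
  blank <- data.frame(
    sequence = contig_sequence, locus = NA_character_,
    v_call = NA_character_, d_call = NA_character_, j_call = NA_character_,
    v_score = NA_real_, j_score = NA_real_,
    cdr3_nt = NA_character_, cdr3_aa = NA_character_,
    productive = FALSE, ambiguous_locus = FALSE,
    fail_reasons = "", stringsAsFactors = FALSE)
  failWith <- function(ann, ...) {
    ann$fail_reasons <- paste(c(...), collapse = ",")
    ann
  }

  # orientation: strand with the best V (fall back to best J) score
  strands <- c(contig_sequence, revComp(contig_sequence))
  vhits <- lapply(strands, function(s)
    if (nrow(vs)) bestSegmentHit(s, vs) else NULL)
  vsc <- vapply(vhits, function(h) if (is.null(h)) -Inf else h$score, 0)
  if (all(vsc < min_score)) {
    jh <- lapply(strands, function(s)
      if (nrow(js)) bestSegmentHit(s, js) else NULL)
    jsc <- vapply(jh, function(h) if (is.null(h)) -Inf else h$score, 0)
    if (all(jsc < min_score)) return(failWith(blank, "no_v", "no_j"))
    k <- which.max(jsc)
    ann <- blank
    ann$sequence <- strands[k]
    ann$j_call <- js$segment_id[jh[[k]]$idx]
    ann$j_score <- jh[[k]]$score
    ann$locus <- js$locus[jh[[k]]$idx]
    return(failWith(ann, "no_v"))
  }
  k <- which.max(vsc)
  oriented <- strands[k]
  vhit <- vhits[[k]]

  # cross-locus ambiguity of the V call
  v_loci <- vs$locus
  best_by_locus <- vapply(split(vhit$scores, v_loci), max, 0)
  v_locus <- vs$locus[vhit$idx]
  ambiguous <- FALSE
  if (length(best_by_locus) > 1L) {
    others <- best_by_locus[names(best_by_locus) != v_locus]
    if (max(others) > vhit$score - locus_margin) ambiguous <- TRUE
  }

  jhit <- if (nrow(js)) bestSegmentHit(oriented, js) else NULL
  if (is.null(jhit) || jhit$score < min_score) {
    ann <- blank
    ann$sequence <- oriented
    ann$locus <- v_locus
    ann$v_call <- vs$segment_id[vhit$idx]
    ann$v_score <- vhit$score
    ann$ambiguous_locus <- ambiguous
    return(failWith(ann, "no_j"))
  }
  locus <- if (ambiguous) js$locus[jhit$idx] else v_locus
  if (ambiguous && locus != v_locus) {
    # re-pick the best V within the J's locus if one scores
    in_locus <- which(vs$locus == locus)
    if (length(in_locus) > 0L) {
      sub <- vs[in_locus, , drop = FALSE]
      vhit_l <- bestSegmentHit(oriented, sub)
      if (vhit_l$score >= min_score) {
        vs <- sub
        vhit <- vhit_l
      }
    }
  }

  ann <- blank
  ann$sequence <- oriented
  ann$locus <- locus
  ann$v_call <- vs$segment_id[vhit$idx]
  ann$j_call <- js$segment_id[jhit$idx]
  ann$v_score <- vhit$score
  ann$j_score <- jhit$score
  ann$ambiguous_locus <- ambiguous

  v_anchor <- projectThroughAlignment(vhit$alignment,
                                      vs$anchor_offset[vhit$idx] + 1L)
  j_anchor <- projectThroughAlignment(jhit$alignment,
                                      js$anchor_offset[jhit$idx] + 1L)
  if (is.na(v_anchor) || is.na(j_anchor) || j_anchor + 2L < v_anchor)
    return(failWith(ann, "anchor_unaligned"))
  cdr3_nt <- substr(oriented, v_anchor, j_anchor + 2L)
  ann$cdr3_nt <- cdr3_nt
  if (nchar(cdr3_nt) %% 3L != 0L)
    return(failWith(ann, "out_of_frame"))
  cdr3_aa <- translateNt(cdr3_nt)
  ann$cdr3_aa <- cdr3_aa
  flt <- filterCdr3Validity(cdr3_aa, locus, relaxed = relaxed_filter)
  if (!flt$valid) return(failWith(ann, flt$reason))
  ann$d_call <- callDSegment(cdr3_nt, locus, seg)
  ann$productive <- TRUE
  ann
}

# Naive D-segment call: the D segment of the locus sharing the longest
# exact substring (>= min_len nt) with the junction interior.
callDSegment <- function(cdr3_nt, locus, seg, min_len = 8L) {
  if (!locus %in% c("TRB", "TRD")) return(NA_character_)
  ds <- seg[seg$locus == locus & seg$segment_type == "D", , drop = FALSE]
  if (nrow(ds) == 0L) return(NA_character_)
  interior <- substr(cdr3_nt, 4L, max(4L, nchar(cdr3_nt) - 3L))
  best_id <- NA_character_; best_len <- min_len - 1L
  for (i in seq_len(nrow(ds))) {
    dseq <- ds$sequence[i]
    for (len in seq(nchar(dseq), min_len)) {
      found <- FALSE
      for (st in seq_len(nchar(dseq) - len + 1L)) {
        if (grepl(substr(dseq, st, st + len - 1L), interior, fixed = TRUE)) {
          found <- TRUE; break
        }
      }
      if (found) {
        if (len > best_len) { best_len <- len; best_id <- ds$segment_id[i] }
        break
      }
    }
  }
  best_id
}
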