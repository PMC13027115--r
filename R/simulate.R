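#' Simulator configuration
#'
#' Builds a validated [SimConfig-class]. The defaults emulate the study
#' design the analytics layers target: six patients, two of them in the
#' microsatellite-stable (MSS) group and four microsatellite-instable
#' (MSI), each sampled in blood, adjacent normal and tumor tissue before
#' (Pre) and after (Post) treatment, with skewed clone sizes, biased V/J
#' gene usage, junctional N-insertions and exonuclease trimming, a public
#' clonotype pool shared across patients, and substitution sequencing
#' error. Scale parameters (clonotypes per sample, reads per chain) are
#' desk-scale so a full run stays in seconds to minutes.
#'
#' @param seed integer seed; all simulator randomness derives from it.
#' @param patients character vector of patient ids.
#' @param groups named character vector (MSI/MSS) over patients.
#' @param tissues subset of blood/normal/tumor.
#' @param timepoints ordered labels.
#' @param n_clonotypes_per_sample clonotypes drawn per sample.
#' @param clone_size_law \code{"geometric"} (cells per clonotype
#'   \code{1 + rgeom(prob = clone_size_param)}) or \code{"power_law"}
#'   (Pareto tail with exponent \code{clone_size_param}).
#' @param clone_size_param law parameter (see above).
#' @param locus_weights sampling weights of TRA/TRB/TRG/TRD per clonotype.
#' @param usage_bias_base geometric decay of V/J gene usage weights within
#'   a locus (gene ranked r gets weight \code{base^(r-1)}).
#' @param insertion_mean Poisson mean of junctional N-insertions per side.
#' @param max_trim maximum 3'V / 5'J exonuclease trim (nt).
#' @param shared_clone_fraction fraction of each sample's clonotypes drawn
#'   from the cross-patient public pool.
#' @param reads_per_cell_chain reads tiling each chain of each cell.
#' @param read_length cDNA read length (nt).
#' @param error_rate per-base substitution probability.
#' @param barcode_length,umi_length cell barcode / UMI lengths (nt).
#' @return a [SimConfig-class].
#' @export
simConfig <- function(seed = 1L,
                      patients = sprintf("P%02d", 1:6),
                      groups = setNames(c("MSS", "MSS", "MSI", "MSI",
                                          "MSI", "MSI"), patients),
                      tissues = c("blood", "normal", "tumor"),
                      timepoints = c("Pre", "Post"),
                      n_clonotypes_per_sample = 50L,
                      clone_size_law = "geometric",
                      clone_size_param = 0.6,
                      locus_weights = c(TRA = 0.35, TRB = 0.35,
                                        TRG = 0.15, TRD = 0.15),
                      usage_bias_base = 0.6,
                      insertion_mean = 4,
                      max_trim = 3L,
                      shared_clone_fraction = 0.05,
                      reads_per_cell_chain = 6L,
                      read_length = 90L,
                      error_rate = 0.001,
                      barcode_length = 16L,
                      umi_length = 10L) {
  new("SimConfig",
      seed = as.integer(seed), patients = patients,
      groups = groups[patients], tissues = tissues, timepoints = timepoints,
      nClonotypesPerSample = as.integer(n_clonotypes_per_sample),
      cloneSizeLaw = clone_size_law, cloneSizeParam = clone_size_param,
      locusWeights = locus_weights, usageBiasBase = usage_bias_base,
      insertionMean = insertion_mean, maxTrim = as.integer(max_trim),
      sharedCloneFraction = shared_clone_fraction,
      readsPerCellChain = as.integer(reads_per_cell_chain),
      readLength = as.integer(read_length), errorRate = error_rate,
      barcodeLength = as.integer(barcode_length),
      umiLength = as.integer(umi_length))
}

# Run code under a fixed RNG state, restoring the caller's state after.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Built-in synthetic germline segment reference
#'
#' A deterministic, fully synthetic V(D)J segment set covering all four TCR
#' loci (it is generated in code, not derived from any germline database).
#' Each locus carries several V genes ending in the conserved second
#' cysteine plus a short germline region after it (encoding C-A-S-S for
#' TRB/TRD so junctions can satisfy the stringent beta/delta CDR3 motif,
#' C-A-x-x otherwise), several J genes whose anchor F/W opens an
#' [FW]-G-x-G motif, and, for TRB/TRD, short D segments.
#'
#' @param n_v,n_j genes per locus.
#' @param v_length,j_length segment lengths (nt).
#' @param seed seed for the deterministic sequence draw.
#' @param k k-mer index word size.
#' @return a [ReferenceSet-class].
#' @export
syntheticGermlineReference <- function(n_v = 6L, n_j = 4L, v_length = 180L,
                                       j_length = 45L, seed = 20260101L,
                                       k = 15L) {
  withSeed(seed, {
    rows <- list()
    for (locus in TCR_LOCI) {
      post <- if (locus %in% c("TRB", "TRD"))
        "TGTGCCAGCAGCCAA" else "TGTGCTGTGAGAGGA"   # CASSQ / CAVRG
      for (i in seq_len(n_v)) {
        body <- randomCodingDna(v_length - nchar(post))
        rows[[length(rows) + 1L]] <- list(
          segment_id = sprintf("%sV%d*01", locus, i), locus = locus,
          segment_type = "V", sequence = paste0(body, post),
          anchor_offset = v_length - nchar(post))
      }
      for (i in seq_len(n_j)) {
        pre <- randomCodingDna(9L)
        anchor <- if (locus %in% c("TRB", "TRD")) "TTT" else
          sample(c("TTT", "TTC", "TGG"), 1L)
        tail_len <- j_length - 9L - 3L - 9L
        jseq <- paste0(pre, anchor, "GGCCAAGGC", randomCodingDna(tail_len))
        rows[[length(rows) + 1L]] <- list(
          segment_id = sprintf("%sJ%d*01", locus, i), locus = locus,
          segment_type = "J", sequence = jseq, anchor_offset = 9L)
      }
      if (locus %in% c("TRB", "TRD")) {
        for (i in 1:2) {
          rows[[length(rows) + 1L]] <- list(
            segment_id = sprintf("%sD%d*01", locus, i), locus = locus,
            segment_type = "D", sequence = randomCodingDna(15L),
            anchor_offset = NA_integer_)
        }
      }
    }
    seg <- DataFrame(
      segment_id = vapply(rows, `[[`, "", "segment_id"),
      locus = vapply(rows, `[[`, "", "locus"),
      segment_type = vapply(rows, `[[`, "", "segment_type"),
      gene = stripAllele(vapply(rows, `[[`, "", "segment_id")),
      allele = "01",
      sequence = vapply(rows, `[[`, "", "sequence"),
      anchor_offset = vapply(rows, `[[`, NA_integer_, "anchor_offset"))
    newReferenceSet(seg, k = as.integer(k))
  })
}

# Random DNA with no in-frame stop codon (frame 0).
randomCodingDna <- function(n) {
  repeat {
    x <- randomDna(n)
    m <- n - n %% 3L
    if (m < 3L || !grepl("*", translateNt(substr(x, 1, m)), fixed = TRUE))
      return(x)
  }
}

# Usage weights over the segments of one locus/type: geometric decay over
# segment_id order.
usageWeights <- function(seg, locus, type, base) {
  idx <- which(seg$locus == locus & seg$segment_type == type)
  idx <- idx[order(seg$segment_id[idx])]
  w <- base^(seq_along(idx) - 1L)
  setNames(w / sum(w), seg$segment_id[idx])
}

#' Simulate one V(D)J recombination event
#'
#' Draws a V (and, for TRB/TRD, D) and J segment under the configured
#' usage bias, applies exonuclease trimming at the 3' end of V and 5' end
#' of J, inserts non-templated N nucleotides, and retries until the
#' resulting junction — V anchor codon through J anchor codon inclusive —
#' is in frame, stop-free and passes the chain-specific CDR3 validity
#' filter (productive by construction). The full transcript (whole V
#' through whole J) is recorded for read sampling.
#'
#' Uses the current RNG state; seed via [withSeed()] or \code{set.seed}.
#'
#' @param reference a [ReferenceSet-class] with V and J for \code{locus}.
#' @param locus one of TRA/TRB/TRG/TRD.
#' @param config a [SimConfig-class] (bias, trims, insertions).
#' @param max_retries bound on rejection sampling.
#' @return list with \code{v_id}, \code{d_id} (NA for TRA/TRG),
#'   \code{j_id}, \code{junction_nt}, \code{junction_aa},
#'   \code{transcript}.
#' @export
recombineVDJ <- function(reference, locus, config = simConfig(),
                         max_retries = 500L) {
  seg <- refSegments(reference)
  wv <- usageWeights(seg, locus, "V", config@usageBiasBase)
  wj <- usageWeights(seg, locus, "J", config@usageBiasBase)
  if (length(wv) == 0L || length(wj) == 0L)
    stop("reference lacks V or J segments for locus ", locus)
  has_d <- locus %in% c("TRB", "TRD")
  d_ids <- seg$segment_id[seg$locus == locus & seg$segment_type == "D"]
  for (try in seq_len(max_retries)) {
    v_id <- sample(names(wv), 1L, prob = wv)
    j_id <- sample(names(wj), 1L, prob = wj)
    v <- seg[seg$segment_id == v_id, ]
    j <- seg[seg$segment_id == j_id, ]
    v_post <- nchar(v$sequence) - v$anchor_offset    # bases from anchor to V end
    trim_v <- sample(0:min(config@maxTrim, v_post - 3L), 1L)
    trim_j <- sample(0:min(config@maxTrim, j$anchor_offset), 1L)
    ins1 <- randomDna(rpois(1L, config@insertionMean))
    d_id <- NA_character_
    d_frag <- ""
    if (has_d && length(d_ids) > 0L) {
      d_id <- sample(d_ids, 1L)
      d_seq <- seg$sequence[seg$segment_id == d_id]
      a <- sample.int(nchar(d_seq), 1L)
      b <- sample(a:nchar(d_seq), 1L)
      d_frag <- substr(d_seq, a, b)
      ins2 <- randomDna(rpois(1L, config@insertionMean))
    } else ins2 <- ""
    v_part <- substr(v$sequence, v$anchor_offset + 1L,
                     nchar(v$sequence) - trim_v)
    j_part <- substr(j$sequence, trim_j + 1L, j$anchor_offset + 3L)
    junction <- paste0(v_part, ins1, d_frag, ins2, j_part)
    if (nchar(junction) %% 3L != 0L) next
    aa <- translateNt(junction)
    if (grepl("*", aa, fixed = TRUE)) next
    if (!filterCdr3Validity(aa, locus)$valid) next
    transcript <- paste0(substr(v$sequence, 1L, nchar(v$sequence) - trim_v),
                         ins1, d_frag, ins2,
                         substr(j$sequence, trim_j + 1L, nchar(j$sequence)))
    return(list(locus = locus, v_id = v_id, d_id = d_id, j_id = j_id,
                junction_nt = junction, junction_aa = aa,
                transcript = transcript))
  }
  stop("no productive junction for locus ", locus, " after ",
       max_retries, " retries")
}

drawCloneSizes <- function(n, law, param) {
  if (law == "geometric") 1L + rgeom(n, prob = param)
  else pmax(1L, floor(runif(n)^(-1 / (param - 1))))
}

randomBarcodes <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    cand <- vapply(seq_len(n - length(out) + 4L), function(i) randomDna(len), "")
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

addSubstitutionErrors <- function(sequence, rate) {
  if (rate <= 0) return(sequence)
  chars <- strsplit(sequence, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) > 0L) {
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
  }
  paste(chars, collapse = "")
}

#' Simulate a multi-sample single-cell V(D)J read set with ground truth
#'
#' For every (patient, tissue, timepoint) sample the generator draws
#' clonotypes — a configurable fraction from a cross-patient public pool
#' (identical V/J and junction, creating private / intra-group /
#' inter-group sharing structure), the rest private — assigns each a clone
#' size under the clone-size law, gives every cell a unique barcode, and
#' emits reads tiling each cell's chain transcript with substitution
#' errors. Mate 1 carries barcode + UMI bases; mate 2 the cDNA fragment.
#' With \code{embedded_ids = TRUE} a single FASTQ per sample is written
#' with \code{barcode:umi:original_id} read ids instead.
#'
#' @param config a [SimConfig-class].
#' @param reference a [ReferenceSet-class].
#' @param out_dir output directory (created if needed).
#' @param embedded_ids also exercise the pre-embedded id path.
#' @return list with \code{truth} (AIRR-dialect data.frame, one row per
#'   cell chain), \code{samples} (sample sheet data.frame with file
#'   paths), and \code{paths} of the written truth/sheet TSVs.
#' @export
simulateRepertoire <- function(config, reference, out_dir,
                               embedded_ids = FALSE) {
  validObject(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withSeed(config@seed, {
    n_pool <- max(2L, ceiling(config@sharedCloneFraction *
                              config@nClonotypesPerSample *
                              length(config@patients) / 2))
    pool <- lapply(seq_len(n_pool), function(i) {
      locus <- sample(names(config@locusWeights), 1L,
                      prob = config@locusWeights)
      recombineVDJ(reference, locus, config)
    })
    truth <- list()
    sheet <- list()
    clono_counter <- 0L
    for (pat in config@patients) for (tis in config@tissues)
      for (tp in config@timepoints) {
        sample_id <- paste(pat, tis, tp, sep = "_")
        n <- config@nClonotypesPerSample
        n_shared <- round(config@sharedCloneFraction * n)
        picks <- if (n_shared > 0L)
          sample.int(n_pool, n_shared, replace = n_shared > n_pool)
        else integer(0)
        clones <- lapply(picks, function(i) c(pool[[i]],
                                              list(public = TRUE, pool_id = i)))
        for (i in seq_len(n - n_shared)) {
          locus <- sample(names(config@locusWeights), 1L,
                          prob = config@locusWeights)
          clones[[length(clones) + 1L]] <-
            c(recombineVDJ(reference, locus, config),
              list(public = FALSE, pool_id = NA_integer_))
        }
        for (i in seq_along(clones)) {
          if (clones[[i]]$public) {
            clones[[i]]$clonotype_id <- sprintf("public_%03d",
                                                clones[[i]]$pool_id)
          } else {
            clono_counter <- clono_counter + 1L
            clones[[i]]$clonotype_id <- sprintf("clone_%06d", clono_counter)
          }
        }
        sizes <- drawCloneSizes(length(clones), config@cloneSizeLaw,
                                config@cloneSizeParam)
        n_cells <- sum(sizes)
        barcodes <- randomBarcodes(n_cells, config@barcodeLength)
        cell_clone <- rep(seq_along(clones), sizes)
        r1 <- character(0); r2 <- character(0); ids <- character(0)
        umis <- character(0)
        rows <- vector("list", n_cells)
        for (ci in seq_len(n_cells)) {
          cl <- clones[[cell_clone[ci]]]
          bc <- barcodes[ci]
          tx <- cl$transcript
          L <- nchar(tx)
          rl <- min(config@readLength, L)
          starts <- unique(round(seq(1L, L - rl + 1L,
                                     length.out = config@readsPerCellChain)))
          starts <- rep(starts,
                        length.out = config@readsPerCellChain)
          for (ri in seq_along(starts)) {
            frag <- substr(tx, starts[ri], starts[ri] + rl - 1L)
            frag <- addSubstitutionErrors(frag, config@errorRate)
            umi <- randomDna(config@umiLength)
            ids <- c(ids, sprintf("%s_c%d_r%d", sample_id, ci, ri))
            umis <- c(umis, umi)
            r1 <- c(r1, paste0(bc, umi))
            r2 <- c(r2, frag)
          }
          rows[[ci]] <- data.frame(
            sample_id = sample_id, patient = pat,
            group = unname(config@groups[pat]), tissue = tis,
            timepoint = tp, cell_id = bc, locus = cl$locus,
            v_call = cl$v_id, d_call = cl$d_id, j_call = cl$j_id,
            junction = cl$junction_nt, junction_aa = cl$junction_aa,
            sequence = cl$transcript,
            productive = TRUE,
            duplicate_count = config@readsPerCellChain,
            clonotype_id = cl$clonotype_id,
            public_pool = cl$public, stringsAsFactors = FALSE)
        }
        if (embedded_ids) {
          fq <- file.path(out_dir, paste0(sample_id, ".fastq"))
          emb_ids <- paste(substr(r1, 1L, config@barcodeLength),
                           substr(r1, config@barcodeLength + 1L,
                                  config@barcodeLength + config@umiLength),
                           ids, sep = ":")
          writeFastq(emb_ids, r2, fq)
          sheet[[sample_id]] <- data.frame(
            sample_id = sample_id, patient = pat,
            group = unname(config@groups[pat]), tissue = tis, timepoint = tp,
            fastq_r1 = fq, fastq_r2 = NA_character_,
            stringsAsFactors = FALSE)
        } else {
          f1 <- file.path(out_dir, paste0(sample_id, "_R1.fastq"))
          f2 <- file.path(out_dir, paste0(sample_id, "_R2.fastq"))
          writeFastq(ids, r1, f1)
          writeFastq(ids, r2, f2)
          sheet[[sample_id]] <- data.frame(
            sample_id = sample_id, patient = pat,
            group = unname(config@groups[pat]), tissue = tis, timepoint = tp,
            fastq_r1 = f1, fastq_r2 = f2, stringsAsFactors = FALSE)
        }
        truth[[sample_id]] <- do.call(rbind, rows)
      }
    truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
    sheet <- do.call(rbind, c(sheet, list(make.row.names = FALSE)))
    truth_path <- file.path(out_dir, "truth.tsv")
    sheet_path <- file.path(out_dir, "samples.tsv")
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(truth = truth, samples = sheet,
         paths = list(truth = truth_path, samples = sheet_path,
                      out_dir = out_dir))
  })
}

# Minimal plain-text FASTQ writer (constant quality).
writeFastq <- function(ids, seqs, path) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  invisible(path)
}

# Minimal FASTQ reader: returns data.frame(id, sequence).
readFastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  ids <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  ids <- sub("[ \t].*$", "", ids)
  data.frame(id = ids, sequence = lines[seq(2L, length(lines), by = 4L)],
             stringsAsFactors = FALSE)
}
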