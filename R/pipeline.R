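AIRR_COLUMNS <- c("cell_id", "locus", "v_call", "d_call", "j_call",
                  "junction", "junction_aa", "productive",
                  "duplicate_count")

#' Read an AIRR-dialect rearrangement TSV
#'
#' @param path TSV with at least the columns \code{cell_id},
#'   \code{locus}, \code{v_call}, \code{j_call}, \code{junction},
#'   \code{junction_aa}, \code{productive}.
#' @return data.frame.
#' @export
readAirr <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- setdiff(AIRR_COLUMNS, c("d_call", "duplicate_count"))
  missing <- setdiff(need, colnames(df))
  if (length(missing) > 0L)
    stop("AIRR table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  df$productive <- as.logical(df$productive)
  df
}

#' Write a chain table as an AIRR-dialect rearrangement TSV
#'
#' @param df data.frame of chain records.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAirr <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reconstruct per-cell TCR chains from one sample's reads
#'
#' Runs the per-sample pipeline: barcode embedding (paired-end layout;
#' skipped when the reads already carry embedded \code{barcode:umi:id}
#' identifiers), TCR read screening against the reference, optional
#' deduplication by (barcode, UMI, sequence), per-barcode grouping,
#' greedy overlap-consensus assembly, and V/J/CDR3 annotation with the
#' chain validity filter.
#'
#' @param fastq_r1 mate-1 FASTQ (barcode+UMI bases), or the embedded
#'   FASTQ when \code{fastq_r2} is NULL.
#' @param fastq_r2 mate-2 (cDNA) FASTQ, or NULL for pre-embedded input.
#' @param reference a [ReferenceSet-class].
#' @param barcode_length,umi_length barcode geometry of mate 1.
#' @param min_score alignment score threshold for the screen and the
#'   annotator.
#' @param min_overlap,max_mismatch,min_contig_len assembler parameters.
#' @param locus_margin cross-locus ambiguity margin for the annotator.
#' @param dedup collapse duplicate (barcode, UMI, sequence) reads before
#'   assembly.
#' @param relaxed_filter passed to [filterCdr3Validity()].
#' @param work_dir directory for the intermediate embedded FASTQ.
#' @return list with \code{annotations} (data.frame, one row per contig:
#'   AIRR columns plus scores and fail reasons) and \code{counts}
#'   (named integer stage log).
#' @export
reconstructSample <- function(fastq_r1, fastq_r2 = NULL, reference,
                              barcode_length = 16L, umi_length = 10L,
                              min_score = 25, min_overlap = 20L,
                              max_mismatch = 2L, min_contig_len = 50L,
                              locus_margin = 5, dedup = TRUE,
                              relaxed_filter = FALSE,
                              work_dir = tempdir()) {
  if (!is.null(fastq_r2)) {
    emb1 <- file.path(work_dir, paste0(basename(fastq_r1), ".emb"))
    emb2 <- file.path(work_dir, paste0(basename(fastq_r2), ".emb"))
    embedBarcodes(fastq_r1, fastq_r2, emb1, emb2,
                  barcode_length = barcode_length, umi_length = umi_length,
                  layout = "paired_end")
    reads <- readFastq(emb2)
  } else {
    reads <- readFastq(fastq_r1)
  }
  n_input <- nrow(reads)
  screened <- screenTcrReads(reads, reference, min_score = min_score)
  grouped <- groupByBarcode(screened[, c("id", "sequence")])
  n_cells <- length(grouped$groups)
  rows <- list()
  n_contigs <- 0L
  for (bc in names(grouped$groups)) {
    g <- grouped$groups[[bc]]
    if (dedup)
      g <- g[!duplicated(g[, c("barcode", "umi", "sequence")]), ,
             drop = FALSE]
    contigs <- assembleCell(g$sequence, min_overlap = min_overlap,
                            max_mismatch = max_mismatch,
                            min_contig_len = min_contig_len)
    if (nrow(contigs) == 0L) next
    for (i in seq_len(nrow(contigs))) {
      n_contigs <- n_contigs + 1L
      ann <- annotateContig(contigs$sequence[i], reference,
                            min_score = min_score,
                            locus_margin = locus_margin,
                            relaxed_filter = relaxed_filter)
      ann$cell_id <- bc
      ann$contig_id <- sprintf("%s_%d", bc, i)
      ann$duplicate_count <- contigs$support[i]
      rows[[length(rows) + 1L]] <- ann
    }
  }
  annotations <- if (length(rows) > 0L) {
    out <- do.call(rbind, rows)
    out$junction <- out$cdr3_nt
    out$junction_aa <- out$cdr3_aa
    out[, c("cell_id", "contig_id", "locus", "v_call", "d_call", "j_call",
            "junction", "junction_aa", "productive", "duplicate_count",
            "v_score", "j_score", "ambiguous_locus", "fail_reasons",
            "sequence")]
  } else {
    data.frame()
  }
  counts <- c(input = n_input, screened = nrow(screened),
              grouped_cells = n_cells, dropped_unparseable = grouped$n_dropped,
              contigs = n_contigs,
              productive = if (nrow(annotations)) sum(annotations$productive)
                           else 0L)
  list(annotations = annotations, counts = counts)
}

#' Run the full pipeline end to end
#'
#' Simulates a multi-sample read set (or uses a provided sample sheet),
#' reconstructs chains for every sample, calls and classifies clonotypes,
#' computes per-sample repertoire metrics, benchmarks the reconstruction
#' against the ground truth under all three match modes, and writes every
#' artifact plus a JSON manifest with md5 checksums. Identical
#' configuration and seed yield identical manifest checksums.
#'
#' @param reference a [ReferenceSet-class]; defaults to the built-in
#'   synthetic germline reference.
#' @param config a [SimConfig-class] driving the simulation.
#' @param out_dir output directory.
#' @param truth optional AIRR-dialect ground-truth data.frame; defaults
#'   to the simulated truth.
#' @param ... passed to [reconstructSample()].
#' @return list with \code{annotations}, \code{repertoire} (a
#'   [RepertoireTable-class]), \code{metrics}, \code{benchmark},
#'   \code{stage_counts}, \code{manifest_path}.
#' @export
runEndToEnd <- function(reference = syntheticGermlineReference(),
                        config = simConfig(), out_dir, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateRepertoire(config, reference, file.path(out_dir, "reads"))
  sheet <- sim$samples
  all_ann <- list()
  logs <- list()
  for (i in seq_len(nrow(sheet))) {
    res <- reconstructSample(sheet$fastq_r1[i], sheet$fastq_r2[i],
                             reference,
                             barcode_length = config@barcodeLength,
                             umi_length = config@umiLength,
                             work_dir = file.path(out_dir, "reads"), ...)
    if (nrow(res$annotations) > 0L)
      res$annotations$sample_id <- sheet$sample_id[i]
    all_ann[[sheet$sample_id[i]]] <- res$annotations
    logs[[sheet$sample_id[i]]] <-
      c(list(stage = "reconstruct", sample_id = sheet$sample_id[i]),
        as.list(res$counts))
  }
  annotations <- do.call(rbind, c(all_ann, list(make.row.names = FALSE)))
  ann_path <- file.path(out_dir, "annotations.tsv")
  writeAirr(annotations, ann_path)
  log_path <- file.path(out_dir, "stages.jsonl")
  writeLines(vapply(logs, function(x)
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE)), ""), log_path)

  rep_table <- callClonotypes(annotations, sheet)
  rep_table <- classifySharing(rep_table)
  clono_path <- file.path(out_dir, "clonotypes.tsv")
  utils::write.table(clonotypeTable(rep_table), clono_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  metrics <- sampleMetrics(rep_table)
  metrics_path <- file.path(out_dir, "metrics.tsv")
  utils::write.table(metrics, metrics_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  prod <- annotations[annotations$productive, , drop = FALSE]
  bench <- benchmarkAllModes(prod, sim$truth,
                             path = file.path(out_dir, "benchmark.tsv"))
  files <- c(sim$paths$truth, sim$paths$samples,
             sheet$fastq_r1, sheet$fastq_r2[!is.na(sheet$fastq_r2)],
             ann_path, log_path,
             clono_path, metrics_path, file.path(out_dir, "benchmark.tsv"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  list(annotations = annotations, repertoire = rep_table,
       metrics = metrics, benchmark = bench,
       truth = sim$truth, samples = sheet,
       stage_counts = logs, manifest_path = manifest_path)
}
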