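AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Call clonotypes from chain annotations
#'
#' A clonotype is defined per chain as the combination of locus,
#' allele-stripped V gene and CDR3 amino-acid sequence. Only productive
#' annotations contribute. A cell contributes one count to a clonotype
#' per (sample, key) regardless of read support; a cell with two
#' productive chains of the same locus contributes to both keys. The
#' modal allele-stripped J gene among member cells is recorded per
#' clonotype (ties to the lexicographically smaller gene).
#'
#' @param annotations data.frame with columns \code{sample_id},
#'   \code{cell_id}, \code{locus}, \code{v_call}, \code{j_call},
#'   \code{cdr3_aa} (AIRR columns \code{junction_aa} accepted) and
#'   \code{productive}.
#' @param samples data.frame with columns \code{sample_id},
#'   \code{patient}, \code{group}, \code{tissue}, \code{timepoint}.
#' @return a [RepertoireTable-class] (clonotypes x samples, assay
#'   \code{"cells"}).
#' @export
callClonotypes <- function(annotations, samples) {
  ann <- as.data.frame(annotations)
  if (!"cdr3_aa" %in% colnames(ann) && "junction_aa" %in% colnames(ann))
    ann$cdr3_aa <- ann$junction_aa
  need <- c("sample_id", "cell_id", "locus", "v_call", "j_call",
            "cdr3_aa", "productive")
  if (!all(need %in% colnames(ann)))
    stop("annotations must have columns: ", paste(need, collapse = ", "))
  missing_s <- setdiff(unique(ann$sample_id), samples$sample_id)
  if (length(missing_s) > 0L)
    stop("sample_id absent from metadata: ",
         paste(missing_s, collapse = ", "))
  ann <- ann[as.logical(ann$productive) & !is.na(ann$cdr3_aa) &
             !is.na(ann$v_call), , drop = FALSE]
  ann$v_gene <- stripAllele(ann$v_call)
  ann$j_gene <- stripAllele(ann$j_call)
  ann$key <- paste(ann$locus, ann$v_gene, ann$cdr3_aa, sep = "|")
  # one contribution per (sample, cell, key)
  ann <- ann[!duplicated(ann[, c("sample_id", "cell_id", "key")]), ,
             drop = FALSE]
  keys <- sort(unique(ann$key))
  sids <- samples$sample_id
  m <- matrix(0L, nrow = length(keys), ncol = length(sids),
              dimnames = list(keys, sids))
  tab <- table(ann$key, ann$sample_id)
  m[rownames(tab), colnames(tab)] <- as.integer(tab)
  modal_j <- vapply(split(ann$j_gene, ann$key), function(j) {
    t <- table(j)
    names(t)[order(-t, names(t))][1]
  }, "")[keys]
  parts <- strsplit(keys, "|", fixed = TRUE)
  rd <- DataFrame(
    clonotype_id = sprintf("ct%05d", seq_along(keys)),
    locus = vapply(parts, `[`, "", 1L),
    v_gene = vapply(parts, `[`, "", 2L),
    j_gene = unname(modal_j),
    cdr3_aa = vapply(parts, `[`, "", 3L),
    sharing_class = NA_character_,
    row.names = keys)
  cd <- DataFrame(samples[match(sids, samples$sample_id), , drop = FALSE],
                  row.names = sids)
  new("RepertoireTable",
      SummarizedExperiment(assays = list(cells = m), rowData = rd,
                           colData = cd))
}

#' Clonotype table as a data.frame
#'
#' Flattens a [RepertoireTable-class] to one row per clonotype with its
#' key columns, per-sample counts, total cells and patient set.
#'
#' @param table a [RepertoireTable-class].
#' @return data.frame.
#' @export
clonotypeTable <- function(table) {
  rd <- as.data.frame(rowData(table))
  m <- assay(table, "cells")
  rd$total_cells <- as.integer(rowSums(m))
  rd$n_patients <- vapply(seq_len(nrow(m)), function(i)
    length(unique(colData(table)$patient[m[i, ] > 0])), 0L)
  rd
}

clonotypePatients <- function(table) {
  m <- assay(table, "cells")
  pats <- colData(table)$patient
  lapply(seq_len(nrow(m)), function(i) sort(unique(pats[m[i, ] > 0])))
}

#' Classify clonotype sharing across patients
#'
#' A clonotype present in a single patient is private; one present in
#' multiple patients of the same group (MSI or MSS) is intra-group
#' shared; one present in patients of both groups is inter-group shared.
#' The three classes partition the table.
#'
#' @param table a [RepertoireTable-class].
#' @param group_map named character vector patient -> group; defaults to
#'   the mapping in \code{colData(table)}.
#' @return the table with \code{rowData()$sharing_class} and
#'   \code{rowData()$n_patients} filled in.
#' @export
classifySharing <- function(table, group_map = NULL) {
  cd <- colData(table)
  if (is.null(group_map)) {
    group_map <- setNames(as.character(cd$group), cd$patient)
    group_map <- group_map[!duplicated(names(group_map))]
  }
  pat_sets <- clonotypePatients(table)
  unmapped <- setdiff(unique(unlist(pat_sets)), names(group_map))
  if (length(unmapped) > 0L)
    stop("patient(s) missing from group map: ",
         paste(unmapped, collapse = ", "))
  cls <- vapply(pat_sets, function(p) {
    if (length(p) <= 1L) return("private")
    g <- unique(group_map[p])
    if (length(g) == 1L) "intra_group" else "inter_group"
  }, "")
  rowData(table)$sharing_class <- cls
  rowData(table)$n_patients <- lengths(pat_sets)
  validObject(table)
  table
}

#' CDR3 amino-acid length distribution
#'
#' Histogram of CDR3 lengths with the modal length (ties broken to the
#' smaller length).
#'
#' @param cdr3 character vector of CDR3 amino-acid sequences, or a
#'   [RepertoireTable-class] (all clonotypes used).
#' @return list with \code{histogram} (named integer vector, names are
#'   lengths) and \code{modal_length}.
#' @export
cdr3LengthDistribution <- function(cdr3) {
  if (is(cdr3, "RepertoireTable")) cdr3 <- rowData(cdr3)$cdr3_aa
  if (length(cdr3) == 0L) stop("empty selection")
  len <- nchar(cdr3)
  h <- table(len)
  counts <- as.integer(h)
  lens <- as.integer(names(h))
  modal <- lens[order(-counts, lens)][1]
  list(histogram = setNames(counts, lens), modal_length = modal)
}

#' Positional residue frequencies and information content of a CDR3 set
#'
#' For CDR3 sequences of one fixed length L, computes the L x 20
#' per-position residue frequency matrix (columns of the logo) and the
#' per-position information content \eqn{IC_j = \log_2 20 - H_j} in
#' bits, where \eqn{H_j} is the Shannon entropy of position j. No
#' pseudocounts or small-sample correction are applied.
#'
#' @param cdr3_set character vector of equal-length amino-acid sequences.
#' @return list with \code{freq} (L x 20 matrix, rows sum to 1) and
#'   \code{ic} (length-L numeric, in [0, log2 20]).
#' @export
positionalFrequencyMatrix <- function(cdr3_set) {
  if (length(cdr3_set) == 0L) stop("empty selection")
  L <- unique(nchar(cdr3_set))
  if (length(L) != 1L) stop("sequences must all have the same length")
  chars <- do.call(rbind, strsplit(cdr3_set, ""))
  freq <- t(apply(chars, 2, function(col) {
    t <- table(factor(col, levels = AA_ALPHABET20))
    as.numeric(t) / length(col)
  }))
  colnames(freq) <- AA_ALPHABET20
  rownames(freq) <- seq_len(L)
  ent <- apply(freq, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  list(freq = freq, ic = log2(20) - ent)
}

#' V-J gene pairing counts
#'
#' Cell-weighted counts over (V gene, J gene) pairs, restricted to the
#' \code{top_n} most frequent V genes; rows ordered by count descending,
#' then lexicographically.
#'
#' @param table a [RepertoireTable-class], or a data.frame with columns
#'   \code{v_gene}, \code{j_gene} and optionally \code{weight}.
#' @param top_n number of V genes retained.
#' @return data.frame with columns \code{v_gene}, \code{j_gene},
#'   \code{count}.
#' @export
vjPairingMatrix <- function(table, top_n = 30L) {
  if (is(table, "RepertoireTable")) {
    df <- data.frame(v_gene = rowData(table)$v_gene,
                     j_gene = rowData(table)$j_gene,
                     weight = as.numeric(rowSums(assay(table, "cells"))),
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(table)
    if (!"weight" %in% colnames(df)) df$weight <- rep(1, nrow(df))
  }
  if (nrow(df) == 0L)
    return(data.frame(v_gene = character(0), j_gene = character(0),
                      count = numeric(0)))
  v_tot <- sort(tapply(df$weight, df$v_gene, sum), decreasing = TRUE)
  keep_v <- names(v_tot)[seq_len(min(top_n, length(v_tot)))]
  df <- df[df$v_gene %in% keep_v, , drop = FALSE]
  agg <- stats::aggregate(weight ~ v_gene + j_gene, data = df, FUN = sum)
  names(agg)[names(agg) == "weight"] <- "count"
  agg <- agg[order(-agg$count, agg$v_gene, agg$j_gene), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Select the most widely shared clonotypes
#'
#' Optionally restricts to clonotypes present in both normal and tumor
#' tissue, then ranks by number of carrying patients (descending), total
#' cells (descending) and CDR3 sequence, returning the first \code{n}.
#' Per-group patient counts (how many MSI and MSS patients carry each
#' clonotype) are included for downstream tissue-flow (Sankey) exports.
#'
#' @param table a classified [RepertoireTable-class].
#' @param n number of clonotypes to return.
#' @param scope \code{"all"} or \code{"normal_tumor_shared"}.
#' @return data.frame of the selected clonotypes with columns
#'   \code{clonotype_id}, key fields, \code{n_patients},
#'   \code{n_patients_MSI}, \code{n_patients_MSS}, \code{total_cells},
#'   \code{sharing_class}.
#' @export
selectTopShared <- function(table, n = 50L,
                            scope = c("all", "normal_tumor_shared")) {
  scope <- match.arg(scope)
  if (n < 1L) stop("n must be >= 1")
  m <- assay(table, "cells")
  cd <- colData(table)
  if (scope == "normal_tumor_shared") {
    in_normal <- rowSums(m[, cd$tissue == "normal", drop = FALSE]) > 0
    in_tumor <- rowSums(m[, cd$tissue == "tumor", drop = FALSE]) > 0
    table <- table[in_normal & in_tumor, ]
    m <- assay(table, "cells")
  }
  if (nrow(table) == 0L)
    return(data.frame())
  rd <- as.data.frame(rowData(table))
  pat_sets <- clonotypePatients(table)
  group_map <- setNames(as.character(cd$group), cd$patient)
  group_map <- group_map[!duplicated(names(group_map))]
  rd$n_patients <- lengths(pat_sets)
  rd$n_patients_MSI <- vapply(pat_sets, function(p)
    sum(group_map[p] == "MSI"), 0L)
  rd$n_patients_MSS <- vapply(pat_sets, function(p)
    sum(group_map[p] == "MSS"), 0L)
  rd$total_cells <- as.integer(rowSums(m))
  ord <- order(-rd$n_patients, -rd$total_cells, rd$cdr3_aa)
  rd <- rd[ord, , drop = FALSE]
  rownames(rd) <- NULL
  utils::head(rd, n)
}

#' Export tissue-flow (Sankey) edges for shared clonotypes
#'
#' One edge per (clonotype, group:tissue) combination with the cell count
#' as weight, plus the patient-count node of the clonotype.
#'
#' @param table a classified [RepertoireTable-class].
#' @param top data.frame from [selectTopShared()].
#' @param path optional output TSV path.
#' @return the edge-list data.frame (invisibly when written to file).
#' @export
sankeyEdges <- function(table, top, path = NULL) {
  m <- assay(table, "cells")
  cd <- colData(table)
  rd <- rowData(table)
  edges <- list()
  for (i in seq_len(nrow(top))) {
    ri <- match(top$clonotype_id[i], rd$clonotype_id)
    w <- tapply(m[ri, ], paste(cd$group, cd$tissue, sep = ":"), sum)
    w <- w[w > 0]
    edges[[i]] <- data.frame(
      clonotype_id = top$clonotype_id[i],
      patient_count_node = paste0("patients_", top$n_patients[i]),
      group_tissue_node = names(w),
      weight = as.integer(w), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}

setMethod("show", "RepertoireTable", function(object) {
  cat("RepertoireTable:", nrow(object), "clonotypes x", ncol(object),
      "samples\n")
  cls <- rowData(object)$sharing_class
  if (!all(is.na(cls))) {
    cat("sharing:", paste(names(table(cls)), table(cls), sep = "=",
                          collapse = ", "), "\n")
  }
  callNextMethod()
})
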