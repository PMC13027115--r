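normalizeChainColumns <- function(df) {
  df <- as.data.frame(df)
  if (!"cdr3_nt" %in% colnames(df) && "junction" %in% colnames(df))
    df$cdr3_nt <- df$junction
  if (!"cdr3_aa" %in% colnames(df) && "junction_aa" %in% colnames(df))
    df$cdr3_aa <- df$junction_aa
  if (!"cell_id" %in% colnames(df) && "cell_barcode" %in% colnames(df))
    df$cell_id <- df$cell_barcode
  need <- c("cell_id", "locus")
  if (!all(need %in% colnames(df)))
    stop("chain set must carry cell_id (or cell_barcode) and locus")
  if (!"d_call" %in% colnames(df)) df$d_call <- NA_character_
  df
}

matchKey <- function(df, mode) {
  switch(mode,
    junction_nt = paste(df$cell_id, df$locus, df$cdr3_nt, sep = "\r"),
    junction_aa = paste(df$cell_id, df$locus, df$cdr3_aa, sep = "\r"),
    gene_level = paste(df$cell_id, df$locus, df$cdr3_aa,
                       stripAllele(df$v_call), stripAllele(df$j_call),
                       sep = "\r"))
}

#' Match reconstructed chains against a reference chain set
#'
#' A query chain matches when the same cell barcode holds a reference
#' chain of the same locus that agrees under the chosen mode:
#' \code{junction_nt} (identical CDR3 nucleotide junction),
#' \code{junction_aa} (identical CDR3 amino-acid sequence), or
#' \code{gene_level} (junction_aa plus identical allele-stripped V and J
#' genes). Each reference chain is consumed at most once. Per-component
#' true positives (allele-stripped V and J calls, D where both records
#' carry one, CDR3 under the active mode) are tallied over the matched
#' pairs.
#'
#' @param query,reference data.frames of chain annotations with columns
#'   \code{cell_id} (or \code{cell_barcode}), \code{locus},
#'   \code{v_call}, \code{j_call}, \code{d_call} (optional),
#'   \code{cdr3_nt}/\code{junction}, \code{cdr3_aa}/\code{junction_aa}.
#' @param mode match mode (see above).
#' @return a [BenchmarkResult-class].
#' @export
matchContigs <- function(query, reference,
                         mode = c("junction_nt", "junction_aa",
                                  "gene_level")) {
  mode <- match.arg(mode)
  q <- normalizeChainColumns(query)
  r <- normalizeChainColumns(reference)
  if (any(is.na(q$cell_id)) || any(is.na(r$cell_id)))
    stop("missing cell barcodes")
  qk <- matchKey(q, mode)
  rk <- matchKey(r, mode)
  # greedy within equality classes = maximum matching here
  q_idx <- integer(0); r_idx <- integer(0)
  r_used <- rep(FALSE, nrow(r))
  r_by_key <- split(seq_len(nrow(r)), rk)
  for (i in seq_len(nrow(q))) {
    avail <- r_by_key[[qk[i]]]
    avail <- avail[!r_used[avail]]
    if (length(avail) > 0L) {
      q_idx <- c(q_idx, i)
      r_idx <- c(r_idx, avail[1])
      r_used[avail[1]] <- TRUE
    }
  }
  nm <- length(q_idx)
  tp_v <- sum(stripAllele(q$v_call[q_idx]) == stripAllele(r$v_call[r_idx]),
              na.rm = TRUE)
  tp_j <- sum(stripAllele(q$j_call[q_idx]) == stripAllele(r$j_call[r_idx]),
              na.rm = TRUE)
  d_eval <- !is.na(q$d_call[q_idx]) & !is.na(r$d_call[r_idx])
  tp_d <- sum(stripAllele(q$d_call[q_idx[d_eval]]) ==
              stripAllele(r$d_call[r_idx[d_eval]]))
  new("BenchmarkResult",
      matchMode = mode,
      nReference = nrow(r), nQuery = nrow(q), nMatched = nm,
      tp = c(V = as.integer(tp_v), J = as.integer(tp_j),
             D = as.integer(tp_d), CDR3 = as.integer(nm)),
      nEvaluable = c(V = as.integer(nm), J = as.integer(nm),
                     D = as.integer(sum(d_eval)), CDR3 = as.integer(nm)),
      pairs = DataFrame(query_row = q_idx, reference_row = r_idx))
}

#' Overlap rates between a reconstructed and a reference chain set
#'
#' Given the reference count, query count and matched count, returns the
#' overlap percentage relative to each set, reported to two decimals
#' (half-up; underlying values are exact ratios).
#'
#' @param n_reference,n_query,n_matched counts, or a
#'   [BenchmarkResult-class] as the single first argument.
#' @return named numeric \code{c(vs_reference_pct, vs_query_pct)}.
#' @export
overlapRates <- function(n_reference, n_query = NULL, n_matched = NULL) {
  if (is(n_reference, "BenchmarkResult")) {
    b <- n_reference
    n_query <- b@nQuery; n_matched <- b@nMatched
    n_reference <- b@nReference
  }
  if (n_reference <= 0L || n_query <= 0L) stop("zero denominator")
  if (n_matched < 0L || n_matched > min(n_reference, n_query))
    stop("inconsistent counts")
  c(vs_reference_pct = roundHalfUp(100 * n_matched / n_reference, 2),
    vs_query_pct = roundHalfUp(100 * n_matched / n_query, 2))
}

#' Read-level recall rate
#'
#' Percentage of the original reads identified (retained by the TCR
#' screen), to two decimals.
#'
#' @param n_identified,n_total_reads counts.
#' @return percentage.
#' @export
recallRate <- function(n_identified, n_total_reads) {
  if (n_total_reads <= 0L) stop("zero total reads")
  if (n_identified < 0L || n_identified > n_total_reads)
    stop("inconsistent counts")
  roundHalfUp(100 * n_identified / n_total_reads, 2)
}

#' Per-component precision rate
#'
#' Percentage of identified records that are true positives for one TCR
#' component (V, D, J gene — allele-stripped — or CDR3 region), to two
#' decimals.
#'
#' @param n_true_positive,n_identified counts.
#' @param component one of V, D, J, CDR3 (annotation only).
#' @return percentage.
#' @export
precisionRate <- function(n_true_positive, n_identified,
                          component = c("V", "D", "J", "CDR3")) {
  component <- match.arg(component)
  if (n_identified <= 0L) stop("zero identified records")
  if (n_true_positive < 0L || n_true_positive > n_identified)
    stop("inconsistent counts")
  roundHalfUp(100 * n_true_positive / n_identified, 2)
}

#' Summarise a benchmark result as one row
#'
#' @param result a [BenchmarkResult-class].
#' @return one-row data.frame with counts, overlap percentages and
#'   per-component precision percentages (NA for D when no pair was
#'   evaluable).
#' @export
benchmarkSummary <- function(result) {
  ov <- if (result@nReference > 0L && result@nQuery > 0L)
    overlapRates(result) else c(vs_reference_pct = NA_real_,
                                vs_query_pct = NA_real_)
  prec <- function(comp) {
    ne <- result@nEvaluable[[comp]]
    if (ne == 0L) return(NA_real_)
    precisionRate(result@tp[[comp]], ne, comp)
  }
  data.frame(
    match_mode = result@matchMode,
    n_reference = result@nReference, n_query = result@nQuery,
    n_matched = result@nMatched,
    overlap_vs_reference_pct = unname(ov[1]),
    overlap_vs_query_pct = unname(ov[2]),
    precision_v_pct = prec("V"), precision_j_pct = prec("J"),
    precision_d_pct = prec("D"), precision_cdr3_pct = prec("CDR3"),
    stringsAsFactors = FALSE)
}

#' Benchmark a chain set against a reference under all three match modes
#'
#' @param query,reference chain annotation data.frames (see
#'   [matchContigs()]).
#' @param path optional TSV output path for the one-row-per-mode table.
#' @return data.frame with one row per match mode.
#' @export
benchmarkAllModes <- function(query, reference, path = NULL) {
  out <- do.call(rbind, lapply(
    c("junction_nt", "junction_aa", "gene_level"),
    function(mode) benchmarkSummary(matchContigs(query, reference, mode))))
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

setMethod("show", "BenchmarkResult", function(object) {
  s <- benchmarkSummary(object)
  cat("BenchmarkResult (mode:", object@matchMode, ")\n")
  cat(sprintf("  reference: %d  query: %d  matched: %d\n",
              s$n_reference, s$n_query, s$n_matched))
  cat(sprintf("  overlap: %.2f%% vs reference, %.2f%% vs query\n",
              s$overlap_vs_reference_pct, s$overlap_vs_query_pct))
  cat(sprintf("  precision: V %.2f%%  J %.2f%%  CDR3 %.2f%%  D %s\n",
              s$precision_v_pct, s$precision_j_pct, s$precision_cdr3_pct,
              ifelse(is.na(s$precision_d_pct), "NA",
                     sprintf("%.2f%%", s$precision_d_pct))))
})
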