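#' Repertoire clonality score
#'
#' Cumulative frequency of the top 10 percent highest-frequency clones:
#' with n unique clonotypes, \eqn{k = \max(1, \lfloor 0.1 n \rfloor)}
#' (configurably rounded instead of floored), clonality is the summed
#' size of the k largest clones divided by the total number of cells.
#' A monoclonal repertoire scores 1; an even repertoire of n clones
#' scores about k/n.
#'
#' @param clone_sizes positive integer cell counts, one per clonotype.
#' @param bracket \code{"floor"} (default) or \code{"round"} for k.
#' @return list with \code{clonality} and \code{k_used}.
#' @export
clonalityScore <- function(clone_sizes, bracket = c("floor", "round")) {
  bracket <- match.arg(bracket)
  if (length(clone_sizes) == 0L) stop("empty clone size list")
  if (any(clone_sizes <= 0)) stop("clone sizes must be positive")
  n <- length(clone_sizes)
  k <- max(1L, if (bracket == "floor") floor(0.1 * n) else round(0.1 * n))
  sizes <- sort(clone_sizes, decreasing = TRUE)
  list(clonality = sum(sizes[seq_len(k)]) / sum(sizes), k_used = as.integer(k))
}

#' Repertoire diversity score
#'
#' Ratio of clonotype richness (unique clonotypes) to the total number of
#' cells; 1 iff every clonotype is a singleton.
#'
#' @param n_unique number of unique clonotypes (>= 1).
#' @param total_clones total cell count (>= n_unique).
#' @return the ratio in (0, 1].
#' @export
diversityScore <- function(n_unique, total_clones) {
  if (total_clones <= 0L || n_unique <= 0L)
    stop("counts must be positive")
  if (n_unique > total_clones)
    stop("n_unique cannot exceed total_clones")
  n_unique / total_clones
}

#' Clonal expansion index
#'
#' Arithmetic mean of the per-clonotype frequencies \eqn{R_i}:
#' \eqn{CEI = \frac{1}{N}\sum_i R_i}. In \code{proportion} mode the
#' \eqn{R_i} are relative frequencies summing to 1, so the index
#' algebraically collapses to 1/N regardless of skew — this consequence
#' of the definition is kept as-is and asserted, not corrected. In
#' \code{count} mode the \eqn{R_i} are clone sizes and the index is the
#' mean clone size.
#'
#' @param frequencies per-clonotype frequencies (proportions or counts).
#' @param mode \code{"proportion"} or \code{"count"}.
#' @return the mean.
#' @export
clonalExpansionIndex <- function(frequencies, mode = c("proportion", "count")) {
  mode <- match.arg(mode)
  if (length(frequencies) == 0L) stop("empty frequency list")
  if (mode == "proportion" && abs(sum(frequencies) - 1) > 1e-6)
    stop("proportions must sum to 1")
  mean(frequencies)
}

#' Expansion proportion across two time points
#'
#' The pooled clonotype count across both time points is taken as 100
#' percent and each time point's share is reported.
#'
#' @param pre_count,post_count non-negative counts; not both zero.
#' @return named numeric c(pre_pct, post_pct), summing to 100.
#' @export
expansionProportion <- function(pre_count, post_count) {
  if (pre_count < 0 || post_count < 0) stop("counts must be non-negative")
  tot <- pre_count + post_count
  if (tot == 0) stop("both counts are zero")
  c(pre_pct = 100 * pre_count / tot, post_pct = 100 * post_count / tot)
}

logRatioScore <- function(num, den, pseudocount, what) {
  if (num < 0 || den < 0) stop("abundances must be non-negative")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (pseudocount == 0 && (num == 0 || den == 0))
    stop(what, ": zero abundance with zero pseudocount; supply pseudocount > 0")
  log2((num + pseudocount) / (den + pseudocount))
}

#' Tissue enrichment score
#'
#' \eqn{E = \log_2(T_{pre} / N_{pre})}: the pre-treatment log2 ratio of a
#' T-cell subset's abundance in tumor versus adjacent normal tissue.
#' E > 0 indicates tumor enrichment, E < 0 normal-tissue enrichment.
#' Zero abundances require a positive pseudocount (none is applied
#' silently).
#'
#' @param t_pre,n_pre abundances (cells or proportions) in tumor / normal
#'   tissue before treatment.
#' @param pseudocount added to both terms; default 0.
#' @return E.
#' @export
tissueEnrichmentScore <- function(t_pre, n_pre, pseudocount = 0) {
  logRatioScore(t_pre, n_pre, pseudocount, "tissue enrichment")
}

#' Tumor response score
#'
#' \eqn{\Delta = \log_2(T_{post} / T_{pre})}: the log2 change of a
#' subset's abundance in tumor tissue after treatment relative to
#' baseline. Positive values indicate relative expansion.
#'
#' @param t_pre,t_post tumor abundances before / after treatment.
#' @param pseudocount added to both terms; default 0.
#' @return Delta.
#' @export
tumorResponseScore <- function(t_pre, t_post, pseudocount = 0) {
  logRatioScore(t_post, t_pre, pseudocount, "tumor response")
}

#' Net tumor-versus-normal response table
#'
#' For each subset, the post-minus-pre change in tumor tissue minus the
#' corresponding change in normal tissue; antisymmetric under swapping
#' the tumor and normal columns.
#'
#' @param tumor_pre,tumor_post,normal_pre,normal_post equal-length
#'   numeric abundance vectors (named by subset).
#' @return data.frame with \code{delta_tumor}, \code{delta_normal},
#'   \code{net} (= delta_tumor - delta_normal).
#' @export
netResponseTable <- function(tumor_pre, tumor_post, normal_pre,
                             normal_post) {
  stopifnot(length(tumor_pre) == length(tumor_post),
            length(normal_pre) == length(normal_post),
            length(tumor_pre) == length(normal_pre))
  dt <- tumor_post - tumor_pre
  dn <- normal_post - normal_pre
  data.frame(subset = if (is.null(names(tumor_pre)))
               seq_along(tumor_pre) else names(tumor_pre),
             delta_tumor = dt, delta_normal = dn, net = dt - dn,
             row.names = NULL)
}

#' Per-sample repertoire metrics
#'
#' Computes unique clonotypes, total cells, clonality, diversity and the
#' clonal expansion index for every sample of a repertoire table.
#'
#' @param table a [RepertoireTable-class].
#' @return data.frame, one row per sample with columns \code{sample_id},
#'   \code{patient}, \code{group}, \code{tissue}, \code{timepoint},
#'   \code{n_unique}, \code{total_clones}, \code{clonality},
#'   \code{diversity}, \code{cei}, \code{k_used}.
#' @export
sampleMetrics <- function(table) {
  m <- assay(table, "cells")
  cd <- as.data.frame(colData(table))
  rows <- lapply(seq_len(ncol(m)), function(j) {
    sizes <- m[, j]
    sizes <- sizes[sizes > 0]
    if (length(sizes) == 0L)
      return(cbind(cd[j, , drop = FALSE],
                   n_unique = 0L, total_clones = 0L, clonality = NA_real_,
                   diversity = NA_real_, cei = NA_real_, k_used = NA_integer_))
    cl <- clonalityScore(sizes)
    cbind(cd[j, , drop = FALSE],
          n_unique = length(sizes), total_clones = sum(sizes),
          clonality = cl$clonality,
          diversity = diversityScore(length(sizes), sum(sizes)),
          cei = clonalExpansionIndex(sizes / sum(sizes)),
          k_used = cl$k_used)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-group comparison of repertoire statistics
#'
#' Thin wrapper over the independent two-sample t-test and the
#' Mann-Whitney U (Wilcoxon rank-sum) test; two-sided.
#'
#' @param values_a,values_b numeric vectors.
#' @param test \code{"t_test"} or \code{"wilcoxon"}.
#' @return list with \code{statistic} and \code{p_value}.
#' @export
compareGroups <- function(values_a, values_b,
                          test = c("t_test", "wilcoxon")) {
  test <- match.arg(test)
  if (test == "t_test") {
    if (length(values_a) < 2L || length(values_b) < 2L)
      stop("t-test needs >= 2 values per group")
    if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0)
      stop("zero variance in both groups")
    ht <- t.test(values_a, values_b)
  } else {
    if (length(values_a) < 1L || length(values_b) < 1L)
      stop("each group needs >= 1 value")
    na <- length(values_a); nb <- length(values_b)
    if (na + nb <= 12L)
      return(exactRankSum(values_a, values_b))
    ht <- suppressWarnings(wilcox.test(values_a, values_b, exact = TRUE))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

# Exact two-sided Mann-Whitney by full enumeration of group assignments
# (average ranks, so ties are handled exactly); used for small samples
# where the large-sample approximation is poor.
exactRankSum <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(length(r), na)
  w_all <- colSums(matrix(r[combos], nrow = na))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  list(statistic = unname(w_obs - na * (na + 1) / 2),  # Mann-Whitney U
       p_value = min(1, 2 * min(p_le, p_ge)))
}

#' Compare a metric between patient groups with FDR correction
#'
#' Runs [compareGroups()] for each requested metric column of a
#' [sampleMetrics()] table between the MSI and MSS samples and applies
#' Benjamini-Hochberg correction across metrics.
#'
#' @param metrics data.frame from [sampleMetrics()].
#' @param columns metric columns to test.
#' @param test passed to [compareGroups()].
#' @return data.frame with \code{metric}, \code{statistic},
#'   \code{p_value}, \code{fdr}.
#' @export
compareGroupMetrics <- function(metrics, columns = c("clonality",
                                                     "diversity"),
                                test = "wilcoxon") {
  rows <- lapply(columns, function(colname) {
    a <- metrics[[colname]][metrics$group == "MSI"]
    b <- metrics[[colname]][metrics$group == "MSS"]
    r <- compareGroups(a[!is.na(a)], b[!is.na(b)], test = test)
    data.frame(metric = colname, statistic = r$statistic,
               p_value = r$p_value)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out
}
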