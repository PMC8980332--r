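#' Quality-filter cells of a clustered count matrix
#'
#' Keeps cells with a mitochondrial read fraction strictly below
#' `max_mito_frac` and strictly more than `min_genes` detected genes
#' (count > 0). Both bounds are strict: a cell at exactly 20% mitochondrial
#' reads or exactly 900 genes is removed.
#'
#' @param counts Genes x cells matrix of non-negative integer counts, with
#'   row (gene) and column (cell) names.
#' @param clusters Named vector mapping every cell to a cluster label.
#' @param mito_genes Character vector of mitochondrial gene ids, or a regex
#'   prefix applied to rownames when `mito_prefix` is used instead.
#' @param mito_prefix Prefix identifying mitochondrial genes (default
#'   `"mt-"`); ignored when `mito_genes` is given.
#' @param max_mito_frac Strict upper bound on mitochondrial fraction
#'   (default 0.20).
#' @param min_genes Strict lower bound on detected genes (default 900).
#' @return List with the filtered `counts`, matching `clusters`, and
#'   `n_removed`.
#' @export
qc_filter_cells <- function(counts, clusters, mito_genes = NULL,
                            mito_prefix = "mt-", max_mito_frac = 0.20,
                            min_genes = 900L) {
  counts <- as.matrix(counts)
  if (is.null(mito_genes)) {
    mito_genes <- grep(paste0("^", mito_prefix), rownames(counts),
                       value = TRUE)
  }
  totals <- colSums(counts)
  mito <- if (length(mito_genes)) {
    colSums(counts[rownames(counts) %in% mito_genes, , drop = FALSE])
  } else {
    rep(0, ncol(counts))
  }
  mito_frac <- ifelse(totals > 0, mito / totals, 0)
  n_detected <- colSums(counts > 0)
  keep <- mito_frac < max_mito_frac & n_detected > min_genes
  if (!any(keep)) {
    stop("all ", ncol(counts), " cells removed by QC (",
         sum(mito_frac >= max_mito_frac), " failed the mitochondrial cut, ",
         sum(n_detected <= min_genes), " the detected-gene cut)")
  }
  list(counts = counts[, keep, drop = FALSE],
       clusters = clusters[colnames(counts)[keep]],
       n_removed = sum(!keep))
}

#' Library-size normalise a count matrix
#'
#' Per cell: `ln(1 + count / cell_total * scale_factor)` — the standard
#' log-normalisation of single-cell pipelines. Cells with zero total counts
#' are removed with a warning.
#'
#' @param counts Genes x cells count matrix.
#' @param scale_factor Target library size (default 10,000).
#' @return Normalised matrix of the same shape (minus zero-total cells).
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " zero-total cell(s) removed")
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  log1p(sweep(counts, 2L, totals / scale_factor, "/"))
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact when the pooled sample is tie-free and no larger than
#' `exact_max_n` (via the exact Wilcoxon distribution); small tied samples
#' are enumerated exhaustively while `choose(n, n_a)` stays at or below
#' `enum_limit`; otherwise the normal approximation with tie correction and
#' continuity correction is used. Identical pooled values give p = 1.
#'
#' @param a,b Numeric samples, each non-empty.
#' @param exact_max_n Largest combined sample size treated exactly
#'   (default 50).
#' @param enum_limit Cap on the number of group assignments enumerated for
#'   tied exact p-values (default 2e5).
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(a, b, exact_max_n = 50L, enum_limit = 2e5) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) return(1)
  n <- length(pooled)
  ties <- anyDuplicated(pooled) > 0L
  if (n <= exact_max_n && !ties) {
    return(stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
  if (n <= exact_max_n && choose(n, length(a)) <= enum_limit) {
    return(exact_ranksum_enum(a, b))
  }
  stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
}

## Exhaustive two-sided rank-sum p by enumerating every assignment of n_a
## pooled values to group a; handles ties through average ranks.
exact_ranksum_enum <- function(a, b) {
  pooled <- c(a, b)
  rk <- rank(pooled)
  na <- length(a)
  obs <- sum(rk[seq_len(na)])
  combos <- utils::combn(length(pooled), na)
  ws <- colSums(matrix(rk[combos], nrow = na))
  eps <- 1e-9
  p_lo <- mean(ws <= obs + eps)
  p_hi <- mean(ws >= obs - eps)
  min(1, 2 * min(p_lo, p_hi))
}

#' Cell-type marker genes by rank-sum test and fold-change filters
#'
#' For one target cluster against all other cells: genes expressed
#' (count > 0) in at least `min_pct` of either group are tested with a
#' two-sided Wilcoxon rank-sum on log-normalised expression; log2 fold
#' change is the log-ratio of mean normalised expression on the linear
#' scale (`expm1` of the log-normalised values, i.e. depth-normalised
#' counts per `scale_factor`), target vs rest, with a small guard `eps` —
#' the convention of the standard single-cell pipelines, under which a
#' 16-fold planted marker shows log2FC near 4. A gene passes when
#' `log2fc > log2fc_min`,
#' `p < p_max` and `max(pct_in, pct_out) >= min_pct`.
#'
#' @param counts Genes x cells count matrix (post-QC).
#' @param clusters Named cluster labels for the columns of `counts`.
#' @param target_cluster Cluster whose markers are sought.
#' @param log2fc_min Strict lower bound on log2 fold change (default 2).
#' @param p_max Strict upper bound on the p-value (default 0.05).
#' @param min_pct Expression-fraction prefilter (default 0.25).
#' @param tf_list Optional character vector of TF gene ids; fills `is_tf`.
#' @param use_raw_means Compute log2FC on raw rather than normalised means
#'   (default FALSE).
#' @param eps Guard added to both means before the ratio (default 1e-9).
#' @return Data.frame sorted by p then decreasing log2fc: `gene_id`,
#'   `target_cluster`, `log2fc`, `p_value`, `p_adj` (BH; informational,
#'   not used by `passes`), `pct_in`, `pct_out`, `is_tf`, `passes`.
#' @export
find_markers <- function(counts, clusters, target_cluster, log2fc_min = 2,
                         p_max = 0.05, min_pct = 0.25, tf_list = NULL,
                         use_raw_means = FALSE, eps = 1e-9) {
  counts <- as.matrix(counts)
  clusters <- clusters[colnames(counts)]
  in_grp <- clusters == target_cluster
  if (!any(in_grp) || all(in_grp)) {
    stop("target cluster '", target_cluster,
         "' must be non-empty and a proper subset of the cells")
  }
  norm <- normalize_counts(counts)
  pct_in <- rowMeans(counts[, in_grp, drop = FALSE] > 0)
  pct_out <- rowMeans(counts[, !in_grp, drop = FALSE] > 0)
  tested <- which(pmax(pct_in, pct_out) >= min_pct)
  if (!length(tested)) {
    return(empty_markers())
  }
  base <- if (use_raw_means) counts else expm1(norm)
  mean_in <- rowMeans(base[tested, in_grp, drop = FALSE])
  mean_out <- rowMeans(base[tested, !in_grp, drop = FALSE])
  log2fc <- log2((mean_in + eps) / (mean_out + eps))
  pv <- vapply(tested, function(i) {
    rank_sum_test(norm[i, in_grp], norm[i, !in_grp])
  }, numeric(1))
  res <- data.frame(
    gene_id = rownames(counts)[tested], target_cluster = target_cluster,
    log2fc = log2fc, p_value = pv, p_adj = stats::p.adjust(pv, "BH"),
    pct_in = pct_in[tested], pct_out = pct_out[tested],
    stringsAsFactors = FALSE)
  res$is_tf <- if (is.null(tf_list)) NA else res$gene_id %in% tf_list
  res$passes <- res$log2fc > log2fc_min & res$p_value < p_max &
    pmax(res$pct_in, res$pct_out) >= min_pct
  res <- res[order(res$p_value, -res$log2fc), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_markers <- function() {
  data.frame(gene_id = character(0), target_cluster = character(0),
             log2fc = numeric(0), p_value = numeric(0), p_adj = numeric(0),
             pct_in = numeric(0), pct_out = numeric(0), is_tf = logical(0),
             passes = logical(0), stringsAsFactors = FALSE)
}

#' Restrict passing markers to transcription factors
#'
#' Intersects the passing markers with a TF gene list, preserving the
#' marker ordering; the result is the cell-type-enriched TF panel whose
#' binding profiles drive the density prescreen.
#'
#' @param markers Output of [find_markers()].
#' @param tf_list Character vector of TF gene ids (duplicates ignored).
#' @return The passing, TF subset of `markers`.
#' @export
select_tfs <- function(markers, tf_list) {
  tf_list <- unique(tf_list)
  panel <- markers[markers$passes & markers$gene_id %in% tf_list, ,
                   drop = FALSE]
  if (!nrow(panel)) {
    warning("no passing marker is in the TF list; empty TF panel")
  }
  rownames(panel) <- NULL
  panel
}
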