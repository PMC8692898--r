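#' Quality-control filter for a cell-by-gene matrix
#'
#' One pass, cells then genes: cells expressing fewer than
#' `min_genes_per_cell` genes (value > 0) are removed, then genes expressed in
#' fewer than `min_cells_per_gene` of the remaining cells are removed. The
#' defaults reproduce the standard droplet-data rule of dropping cells with
#' fewer than 400 expressed genes and genes expressed in fewer than four
#' cells.
#'
#' @param matrix an [expression_matrix()].
#' @param min_genes_per_cell keep cells with at least this many expressed genes.
#' @param min_cells_per_gene keep genes expressed in at least this many cells.
#' @return The filtered [expression_matrix()]; attribute `qc_order` records
#'   the filter order applied.
#' @export
qc_filter <- function(matrix, min_genes_per_cell = 400, min_cells_per_gene = 4) {
  stopifnot(inherits(matrix, "expression_matrix"))
  v <- matrix$values
  keep_cells <- rowSums(v > 0) >= min_genes_per_cell
  if (!any(keep_cells)) stop("all cells removed by the QC filter", call. = FALSE)
  v <- v[keep_cells, , drop = FALSE]
  keep_genes <- colSums(v > 0) >= min_cells_per_gene
  v <- v[, keep_genes, drop = FALSE]
  out <- expression_matrix(v, matrix$cell_data[keep_cells, , drop = FALSE])
  attr(out, "qc_order") <- "cells_then_genes"
  out
}

#' Rank-based p-EMT signature score per cell
#'
#' For each cell, all genes are ranked by expression within that cell
#' (ascending, ties get average ranks) and the score is the mean rank of the
#' signature genes present in the matrix, divided by the number of ranked
#' genes, giving a score in \[0, 1\] comparable across cells. Signature genes
#' absent from the matrix are excluded and reported via `n_signature_used`.
#' Being rank-based, the score is invariant under any strictly increasing
#' per-cell transformation of the expression values.
#'
#' `method = "cell_rank"` implements the alternative reading of a mean
#' expression rank: each signature gene's cells are ranked across cells and
#' the per-cell score is the mean of the cell's ranks over signature genes,
#' normalized by the number of cells.
#'
#' @param matrix an [expression_matrix()].
#' @param signature character vector of signature gene names.
#' @param method `"gene_rank"` (default, within-cell gene ranks) or
#'   `"cell_rank"` (within-gene cell ranks).
#' @return A `signature_score`: `score` (named per-cell numeric in \[0, 1\]),
#'   `signature`, `n_signature_used`, `method`.
#' @export
pemt_score <- function(matrix, signature, method = c("gene_rank", "cell_rank")) {
  stopifnot(inherits(matrix, "expression_matrix"), length(signature) >= 1)
  method <- match.arg(method)
  v <- matrix$values
  present <- intersect(signature, colnames(v))
  if (!length(present)) stop("no signature gene present in the matrix", call. = FALSE)
  if (method == "gene_rank") {
    g <- ncol(v)
    sig_idx <- match(present, colnames(v))
    score <- apply(v, 1, function(x) mean(rank(x, ties.method = "average")[sig_idx]) / g)
  } else {
    n <- nrow(v)
    ranks <- apply(v[, present, drop = FALSE], 2, rank, ties.method = "average")
    ranks <- base::matrix(ranks, nrow = n)
    score <- rowMeans(ranks) / n
  }
  names(score) <- rownames(v)
  structure(list(score = score, signature = signature,
                 n_signature_used = length(present), method = method),
            class = "signature_score")
}

#' @export
print.signature_score <- function(x, ...) {
  cat(sprintf("<signature_score> %d cells, %d/%d signature genes used (%s); mean %.3f\n",
              length(x$score), x$n_signature_used, length(x$signature),
              x$method, mean(x$score)))
  invisible(x)
}

#' Compare signature scores between two groups (Wilcoxon rank-sum)
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of per-cell scores between
#' two groups; exact for small untied samples, normal approximation with tie
#' correction otherwise.
#'
#' @param scores a `signature_score` or a numeric vector of per-cell scores.
#' @param groups per-cell two-level label, same length/order as the scores.
#' @return A `test_result` (method `wilcoxon_rank_sum`; `statistic` is the
#'   Mann-Whitney U of the first group).
#' @export
compare_scores <- function(scores, groups) {
  x <- if (inherits(scores, "signature_score")) scores$score else scores
  stopifnot(is.numeric(x), length(groups) == length(x))
  lev <- unique(as.character(groups))
  if (length(lev) != 2) stop("groups must have exactly two levels", call. = FALSE)
  a <- x[groups == lev[1]]; b <- x[groups == lev[2]]
  if (!length(a) || !length(b)) stop("a group is empty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && max(length(a), length(b)) <= 50
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  test_result("wilcoxon_rank_sum", statistic = wt$statistic,
              p = max(wt$p.value, .Machine$double.xmin),
              n = c(length(a), length(b)))
}

#' Cluster marker genes by the Wilcoxon / Bonferroni / fold-change rule
#'
#' Each gene is compared between the target cluster and all other cells with
#' a two-sided Wilcoxon rank-sum test; p-values are Bonferroni-corrected over
#' the genes actually tested (those not constant across cells). Markers are
#' genes with corrected p below `alpha` and mean expression in the target
#' cluster more than `min_fold`-fold its mean in the other cells (a pseudo
#' count of 1e-9 guards the zero-mean denominator), sorted by fold change.
#'
#' @param matrix an [expression_matrix()].
#' @param clusters per-cell cluster label.
#' @param target label of the cluster whose markers are sought (>= 3 cells).
#' @param alpha corrected-p cutoff.
#' @param min_fold fold-change cutoff (strict).
#' @return Data frame `gene`, `p`, `p_adj`, `fold_change`, `mean_target`,
#'   `mean_rest`, sorted by decreasing fold change; attribute `n_tested` is
#'   the Bonferroni denominator.
#' @export
find_markers <- function(matrix, clusters, target, alpha = 0.05, min_fold = 2) {
  stopifnot(inherits(matrix, "expression_matrix"))
  clusters <- as.character(clusters)
  stopifnot(length(clusters) == nrow(matrix$values))
  if (length(unique(clusters)) < 2) stop("need at least two clusters", call. = FALSE)
  in_t <- clusters == target
  if (sum(in_t) < 3) stop("target cluster has fewer than 3 cells", call. = FALSE)
  v <- matrix$values
  testable <- apply(v, 2, function(x) length(unique(x)) > 1)
  n_tested <- sum(testable)
  res <- lapply(which(testable), function(j) {
    x <- v[in_t, j]; y <- v[!in_t, j]
    p <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    c(p = p, mt = mean(x), mr = mean(y))
  })
  res <- do.call(rbind, res)
  p_adj <- pmin(1, res[, "p"] * n_tested)
  fc <- res[, "mt"] / (res[, "mr"] + 1e-9)
  keep <- which(p_adj < alpha & fc > min_fold)
  out <- data.frame(gene = colnames(v)[testable][keep],
                    p = res[keep, "p"], p_adj = p_adj[keep],
                    fold_change = fc[keep],
                    mean_target = res[keep, "mt"], mean_rest = res[keep, "mr"])
  out <- out[order(-out$fold_change), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  out
}

#' Compare per-sample fractions between groups with a normality gate
#'
#' Reproduces the common Prism-style workflow for comparing per-sample cell
#' fractions: Shapiro-Wilk normality (alpha 0.05) and, for unpaired data, an
#' F-test of equal variances gate the choice of test. If the gate passes, a
#' two-sided t test is used (paired or unpaired with pooled variance);
#' otherwise the Mann-Whitney test (unpaired) or Wilcoxon signed-rank test
#' (paired). Degenerate cases (constant values, zero-variance differences)
#' fail the gate and fall back to the rank test.
#'
#' @param x,y numeric vectors of per-sample fractions (same length if paired).
#' @param paired are the samples paired (e.g. compartments within patients)?
#' @param alpha gate significance level.
#' @return A `test_result`; `gate` records the Shapiro/F-test outcomes and
#'   which branch was taken.
#' @export
compare_fractions <- function(x, y, paired = FALSE, alpha = 0.05) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (paired) {
    if (length(x) != length(y)) stop("paired groups must have equal length", call. = FALSE)
    if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
    d <- x - y
    degenerate <- sd(d) == 0
    sh_p <- if (degenerate) NA_real_ else shapiro.test(d)$p.value
    normal <- !degenerate && sh_p >= alpha
    gate <- list(outcome = if (normal) "normal" else "non-normal",
                 shapiro_p = sh_p, degenerate = degenerate)
    if (normal) {
      tt <- t.test(x, y, paired = TRUE)
      return(test_result("t_paired", tt$statistic, tt$p.value, length(x), gate))
    }
    wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                       correct = TRUE))
    p <- if (is.finite(wt$p.value)) wt$p.value else 1
    return(test_result("wilcoxon_signed_rank", wt$statistic, max(p, .Machine$double.xmin),
                       length(x), gate))
  }
  if (length(x) < 3 || length(y) < 3) stop("need at least 3 samples per group", call. = FALSE)
  const_x <- sd(x) == 0; const_y <- sd(y) == 0
  sh_x <- if (const_x) NA_real_ else shapiro.test(x)$p.value
  sh_y <- if (const_y) NA_real_ else shapiro.test(y)$p.value
  f_p <- if (const_x || const_y) NA_real_ else var.test(x, y)$p.value
  normal <- !const_x && !const_y && sh_x >= alpha && sh_y >= alpha && f_p >= alpha
  gate <- list(outcome = if (normal) "normal" else "non-normal",
               shapiro_p = c(sh_x, sh_y), var_ratio_p = f_p)
  if (normal) {
    tt <- t.test(x, y, var.equal = TRUE)
    return(test_result("t_unpaired", tt$statistic, tt$p.value,
                       c(length(x), length(y)), gate))
  }
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  p <- if (is.finite(wt$p.value)) wt$p.value else 1
  test_result("mann_whitney", wt$statistic, max(p, .Machine$double.xmin),
              c(length(x), length(y)), gate)
}
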