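#' Simulate an expression matrix with a planted signature effect
#'
#' Draws an RPKM-like nonnegative cells x genes matrix: per-gene baseline
#' means are log-normal, per-cell values are log-normal around the gene mean
#' with Bernoulli dropout. In the elevated group every signature gene is
#' multiplied by `1 + effect`, so the expected rank-based signature-score
#' difference between groups is zero at `effect = 0` and monotone increasing
#' in `effect` (an `effect` of 9 is a x10 boost).
#'
#' @param n_cells,n_genes matrix size (cells may be 0 for an empty matrix).
#' @param signature character vector of signature genes; must be a subset of
#'   the gene names (`gene1 ... geneG` unless `gene_names` is supplied).
#' @param group_labels length-`n_cells` vector with at least two levels.
#' @param effect nonnegative multiplicative boost minus one.
#' @param seed integer seed.
#' @param elevated_group label of the boosted group; defaults to the last
#'   level of `group_labels`.
#' @param gene_names optional gene names (length `n_genes`).
#' @param detect_prob probability a gene is detected (nonzero) in a cell.
#' @param sdlog within-gene log-normal spread.
#' @return An [expression_matrix()] whose `cell_data` has a `group` column.
#' @export
simulate_expression <- function(n_cells, n_genes, signature = character(0),
                                group_labels = NULL, effect = 0, seed = 1,
                                elevated_group = NULL, gene_names = NULL,
                                detect_prob = 0.35, sdlog = 0.6) {
  stopifnot(n_cells >= 0, n_genes >= 1, effect >= 0)
  if (is.null(gene_names)) gene_names <- sprintf("gene%d", seq_len(n_genes))
  stopifnot(length(gene_names) == n_genes)
  if (length(signature) && !all(signature %in% gene_names)) {
    stop(sprintf("signature gene(s) absent from gene names: %s",
                 paste(setdiff(signature, gene_names), collapse = ", ")),
         call. = FALSE)
  }
  if (n_cells == 0) {
    m <- matrix(numeric(0), 0, n_genes, dimnames = list(NULL, gene_names))
    return(expression_matrix(m, data.frame(group = character(0))))
  }
  if (is.null(group_labels)) {
    group_labels <- rep(c("A", "B"), length.out = n_cells)
  }
  stopifnot(length(group_labels) == n_cells)
  lev <- unique(as.character(group_labels))
  if (length(lev) < 2) stop("need at least two groups", call. = FALSE)
  if (is.null(elevated_group)) elevated_group <- lev[length(lev)]
  stopifnot(elevated_group %in% lev)

  with_seed(seed, {
    mu <- exp(rnorm(n_genes, 0, 1))                      # gene baselines
    vals <- matrix(rlnorm(n_cells * n_genes,
                          meanlog = rep(log(mu), each = n_cells),
                          sdlog = sdlog),
                   n_cells, n_genes)
    det <- matrix(rbinom(n_cells * n_genes, 1, detect_prob), n_cells, n_genes)
    vals <- vals * det
    if (effect > 0 && length(signature)) {
      boost_cells <- as.character(group_labels) == elevated_group
      sig_idx <- match(signature, gene_names)
      vals[boost_cells, sig_idx] <- vals[boost_cells, sig_idx] * (1 + effect)
    }
    colnames(vals) <- gene_names
    rownames(vals) <- sprintf("cell%d", seq_len(n_cells))
    expression_matrix(vals, data.frame(group = as.character(group_labels),
                                       row.names = rownames(vals)))
  })
}
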