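test_that("QC filter applies the exact cell and gene thresholds", {
  # cells: expressed-gene counts 399 / 400 / 450 against the default 400 cutoff
  set.seed(1)
  v <- matrix(0, 4, 500)
  v[1, sample(500, 399)] <- 1
  v[2, sample(500, 400)] <- 1
  v[3, sample(500, 450)] <- 1
  v[4, ] <- 1
  m <- expression_matrix(v)
  out <- qc_filter(m, min_genes_per_cell = 400, min_cells_per_gene = 0)
  expect_identical(rownames(out$values), c("cell2", "cell3", "cell4"))
  # genes: expressed in 3 vs exactly 4 cells against the default 4 cutoff
  v2 <- matrix(1, 5, 3)
  v2[1:2, 1] <- 0   # gene1 in 3 cells -> removed
  v2[1, 2] <- 0     # gene2 in 4 cells -> kept
  m2 <- expression_matrix(v2)
  out2 <- qc_filter(m2, min_genes_per_cell = 0, min_cells_per_gene = 4)
  expect_identical(colnames(out2$values), c("gene2", "gene3"))
  # re-running the filter is a no-op
  again <- qc_filter(out2, min_genes_per_cell = 0, min_cells_per_gene = 4)
  expect_identical(again$values, out2$values)
  expect_error(qc_filter(m2, min_genes_per_cell = 10), "all cells removed")
})

test_that("QC filter on a hand-enumerated toy matrix drops one cell and two genes", {
  # 6 cells x 6 genes; thresholds 3 genes/cell then 2 cells/gene
  v <- rbind(c(1, 1, 1, 0, 0, 0),   # 3 genes -> kept
             c(1, 1, 1, 1, 0, 0),
             c(1, 0, 1, 1, 0, 0),
             c(0, 1, 1, 1, 0, 1),
             c(1, 1, 0, 1, 0, 0),
             c(0, 0, 1, 0, 1, 0))   # 2 genes -> removed
  m <- expression_matrix(v)
  out <- qc_filter(m, min_genes_per_cell = 3, min_cells_per_gene = 2)
  # survivors by hand: cells 1-5; gene5 seen only in cell6 (0 left), gene6 once
  expect_identical(dim(out$values), c(5L, 4L))
  expect_identical(colnames(out$values), c("gene1", "gene2", "gene3", "gene4"))
})

test_that("p-EMT score matches the brute-force rank oracle exactly", {
  set.seed(42)
  v <- matrix(round(rlnorm(50 * 200), 1), 50, 200)   # rounding forces ties
  m <- expression_matrix(v)
  sig <- colnames(m$values)[seq(5, 100, by = 5)]     # 20 genes
  sc <- pemt_score(m, sig)
  expect_equal(unname(sc$score), unname(oracle_score(m$values, sig)))
  expect_identical(sc$n_signature_used, 20L)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
})

test_that("score limits: complete ties and a top-expressed singleton signature", {
  g <- 30
  flat <- expression_matrix(matrix(5, 2, g))
  s <- pemt_score(flat, c("gene3", "gene17"))
  expect_equal(unname(s$score), rep(0.5 + 1 / (2 * g), 2))
  v <- matrix(seq_len(g), 1, g)   # gene30 is the top-expressed gene
  m <- expression_matrix(v)
  expect_equal(unname(pemt_score(m, "gene30")$score), 1)
  expect_error(pemt_score(m, "nope"), "no signature gene")
})

test_that("score is invariant under strictly increasing per-cell transforms", {
  set.seed(7)
  v <- matrix(rlnorm(30 * 80), 30, 80)
  m <- expression_matrix(v)
  sig <- sprintf("gene%d", 1:10)
  base <- pemt_score(m, sig)$score
  tr <- expression_matrix(exp(v) * rep(runif(30, 1, 5), 80))
  expect_equal(pemt_score(tr, sig)$score, base)
  # missing signature genes are excluded but counted
  s2 <- pemt_score(m, c(sig, "absent1", "absent2"))
  expect_identical(s2$n_signature_used, 10L)
  expect_equal(unname(s2$score), unname(base))
})

test_that("Wilcoxon comparison matches exhaustive enumeration on a tiny example", {
  res <- compare_scores(c(1, 2, 3, 4, 5, 6), c("a", "a", "a", "b", "b", "b"))
  expect_equal(res$statistic, 0)           # U of group a: all b exceed all a
  # exhaustive oracle: all C(6,3)=20 label assignments of the pooled values
  pool <- 1:6
  us <- apply(combn(6, 3), 2, function(ix) {
    sum(outer(pool[ix], pool[-ix], ">")) })
  p_exact <- mean(us <= 0) * 2
  expect_equal(res$p, p_exact)             # = 0.1
  # identical multisets -> p = 1
  same <- compare_scores(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$p, 1)
  expect_error(compare_scores(1:3, rep("a", 3)), "two levels")
})

test_that("planted signature shifts are detected and the null is calibrated", {
  # power: x10 boost, 200 cells/group, 97-of-2000 signature
  sig <- sprintf("gene%d", 1:97)
  rej <- vapply(1:50, function(s) {
    m <- simulate_expression(400, 2000, signature = sig,
                             group_labels = rep(c("normal", "tumor"), each = 200),
                             effect = 9, seed = 1000 + s)
    sc <- pemt_score(m, sig)
    compare_scores(sc, m$cell_data$group)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)
  # null calibration at alpha 0.05 over 500 seeds (small matrices; the score
  # comparison only sees exchangeable scores under the null)
  sig2 <- sprintf("gene%d", 1:20)
  p0 <- vapply(1:500, function(s) {
    m <- simulate_expression(40, 150, signature = sig2,
                             group_labels = rep(c("A", "B"), each = 20),
                             effect = 0, seed = 2000 + s)
    compare_scores(pemt_score(m, sig2), m$cell_data$group)$p
  }, numeric(1))
  expect_lt(abs(mean(p0 < 0.05) - 0.05), 0.02)
})

test_that("marker-gene rule keeps only Bonferroni-significant >2-fold genes", {
  set.seed(11)
  n_t <- 50; n_r <- 150; g <- 300
  v <- matrix(rlnorm(200 * g, sdlog = 0.5), 200, g,
              dimnames = list(NULL, sprintf("gene%d", 1:g)))
  cl <- rep(c("eCAF", "other"), c(n_t, n_r))
  v[cl == "eCAF", 1] <- v[cl == "eCAF", 1] * 10    # planted marker
  v[cl == "eCAF", 2] <- v[cl == "eCAF", 2] * 1.5   # fails the fold rule
  m <- expression_matrix(v)
  res <- find_markers(m, cl, "eCAF")
  expect_true("gene1" %in% res$gene)
  expect_false("gene2" %in% res$gene)
  expect_true(all(res$p_adj < 0.05 & res$fold_change > 2))
  expect_identical(res$gene[1], "gene1")   # sorted by fold change
  # constant gene is excluded (fold = 1, untestable)
  v2 <- cbind(v, const = 3)
  res2 <- find_markers(expression_matrix(v2), cl, "eCAF")
  expect_false("const" %in% res2$gene)
  expect_identical(attr(res2, "n_tested"), as.integer(g))
  # invariance to gene and cell order
  perm_g <- sample(g); perm_c <- sample(200)
  res3 <- find_markers(expression_matrix(v[perm_c, perm_g]), cl[perm_c], "eCAF")
  expect_identical(res3$gene, res$gene)
  expect_equal(res3$fold_change, res$fold_change)
  expect_error(find_markers(m, rep("x", 200), "x"), "two clusters")
})

test_that("a hand-checked 3-gene toy yields exactly the constructed marker", {
  # gene1: strong difference, fold 10; gene2: strong difference, fold 1.6;
  # gene3: fold > 2 but no separation (p high)
  x_t <- c(10, 11, 12, 13, 14, 15, 14, 13, 12, 11)
  x_r <- x_t / 10
  y_t <- c(8, 9, 10, 11, 12, 10, 9, 11, 10, 12); y_r <- y_t / 1.6
  z <- c(5, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  v <- cbind(gene1 = c(x_t, x_r), gene2 = c(y_t, y_r), gene3 = c(z, z / 10))
  m <- expression_matrix(v)
  res <- find_markers(m, rep(c("t", "r"), each = 10), "t")
  expect_identical(res$gene, "gene1")
})

test_that("fraction comparisons route through the normality gate", {
  # identical (skewed, so the gate fails) groups -> Mann-Whitney, p = 1
  x <- c(0.1, 0.1, 0.2, 0.9, 5, 9)
  res <- compare_fractions(x, x)
  expect_identical(res$method, "mann_whitney")
  expect_equal(res$p, 1)
  # paired constant difference: degenerate paired t flagged, signed-rank used
  res2 <- compare_fractions(c(1, 2, 3), c(2, 3, 4), paired = TRUE)
  expect_identical(res2$method, "wilcoxon_signed_rank")
  expect_true(res2$gate$degenerate)
  # clean normal data with equal variance -> unpaired t
  set.seed(3)
  a <- rnorm(30); b <- rnorm(30) + 0.5
  res3 <- compare_fractions(a, b)
  expect_identical(res3$method, "t_unpaired")
  expect_identical(res3$gate$outcome, "normal")
  expect_error(compare_fractions(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("empirical power of the gated test tracks the analytic t-test power", {
  set.seed(21)
  delta <- 0.6; n <- 30; sims <- 400
  rej <- vapply(seq_len(sims), function(i) {
    compare_fractions(rnorm(n), rnorm(n) + delta)$p < 0.05
  }, logical(1))
  analytic <- power.t.test(n = n, delta = delta, sd = 1,
                           sig.level = 0.05)$power
  expect_lt(abs(mean(rej) - analytic), 0.05)
})

test_that("expression simulation honours its edge cases", {
  empty <- simulate_expression(0, 10)
  expect_identical(dim(empty$values), c(0L, 10L))
  expect_error(simulate_expression(10, 5, signature = "geneX"),
               "absent from gene names")
  m1 <- simulate_expression(20, 50, seed = 4)
  m2 <- simulate_expression(20, 50, seed = 4)
  expect_identical(m1$values, m2$values)
  expect_true(all(m1$values >= 0))
})
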